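# Distribution-rate matrix and the damped iterative propagation that turns
# initial scores into final essentiality scores (a modified PageRank with
# restart to the initial-score distribution).

#' Build the distribution-rate matrix
#'
#' Entry (k, r) is `WP(k, r) * proscore(r) / sum_{i in NG(k)} proscore(i)`
#' when (k, r) is a weighted PPI edge and 0 otherwise, so mass leaving a
#' protein is directed toward neighbors with high edge weight and high
#' initial score. Rows whose neighbors all score 0, and isolated proteins,
#' are all-zero. With `normalize_rows` (default) each nonzero row is divided
#' by its sum, making the matrix row-substochastic and the iteration a
#' contraction.
#'
#' @param wp weighted PPI matrix (masked to the edge set)
#' @param proscore nonnegative initial score vector
#' @param normalize_rows divide nonzero rows by their sums (default TRUE)
#' @return N x N nonnegative matrix
#' @export
build_drpm <- function(wp, proscore, normalize_rows = TRUE) {
  if (any(proscore < 0)) stop("proscore must be nonnegative")
  stopifnot(nrow(wp) == length(proscore))
  edge <- wp != 0
  denom <- drop(edge %*% proscore)  # sum of neighbor scores per row
  drpm <- t(t(wp) * proscore)                  # column-wise proscore(r)
  drpm <- drpm * ifelse(denom > 0, 1 / denom, 0)  # row-wise denominator
  if (normalize_rows) {
    rs <- rowSums(drpm)
    nz <- rs > 0
    drpm[nz, ] <- drpm[nz, , drop = FALSE] / rs[nz]
  }
  dimnames(drpm) <- dimnames(wp)
  drpm
}

#' Damped iterative score propagation
#'
#' Iterates `s <- alpha * s %*% DRPM + (1 - alpha) * s0` from `s = s0` until
#' the L2 step norm drops below `eps` or `max_iter` is reached. With a
#' row-substochastic matrix the map is a contraction with factor <= alpha,
#' so convergence is geometric.
#'
#' @param drpm matrix from [build_drpm()]
#' @param proscore0 restart vector (normalized to sum 1 if it is not)
#' @param alpha damping in (0, 1); default 0.9
#' @param eps L2 stopping tolerance; default 1e-6
#' @param max_iter iteration cap; default 100
#' @return list with `scores`, `iterations`, `converged`, `residual`
#'   (fixed-point residual at exit) and `history` of step norms
#' @export
iterate_scores <- function(drpm, proscore0, alpha = 0.9, eps = 1e-6,
                           max_iter = 100L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(eps > 0, max_iter >= 1L)
  s0 <- proscore0 / sum(proscore0)
  s <- s0
  history <- numeric(0)
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    s_next <- alpha * drop(s %*% drpm) + (1 - alpha) * s0
    if (any(!is.finite(s_next)))
      stop("non-finite score at iteration ", t)
    step <- sqrt(sum((s_next - s)^2))
    history <- c(history, step)
    s <- s_next
    if (step < eps) { converged <- TRUE; break }
  }
  residual <- sqrt(sum((s - (alpha * drop(s %*% drpm) + (1 - alpha) * s0))^2))
  names(s) <- names(proscore0)
  list(scores = s, iterations = length(history), converged = converged,
       residual = residual, history = history)
}
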