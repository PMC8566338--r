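# Gaussian interaction-profile (GIP) kernel over the densified domain
# profiles, plus the rescaled, edge-masked weight matrix WP consumed by the
# propagation stage.

#' Domain-interaction profile of a protein
#'
#' @param mrm binary protein x domain matrix (mutual recommendation matrix)
#' @param i protein index or ID
#' @return binary vector of length M (number of domains)
#' @export
profile_of <- function(mrm, i) {
  if (is.character(i)) i <- match(i, rownames(mrm))
  if (is.na(i) || i < 1L || i > nrow(mrm)) stop("protein index out of range")
  mrm[i, ]
}

#' GIP kernel bandwidth
#'
#' The raw bandwidth parameter is normalized by the mean squared profile
#' norm, making the kernel scale-free in the number of domain annotations:
#' `delta_p = delta_prime / mean_i(||profile(i)||^2)`.
#'
#' @param mrm binary protein x domain matrix
#' @param delta_prime raw bandwidth parameter (> 0; default 1)
#' @return normalized bandwidth
#' @export
gip_bandwidth <- function(mrm, delta_prime = 1) {
  stopifnot(delta_prime > 0)
  msq <- mean(rowSums(mrm^2))
  if (msq == 0) stop("all interaction profiles are zero: bandwidth undefined")
  delta_prime / msq
}

#' Gaussian interaction-profile kernel between proteins
#'
#' `WBP(i, j) = exp(-delta_p * ||profile(i) - profile(j)||^2)`. Values lie
#' in (0, 1], the diagonal is 1, and WBP(i, j) = 1 iff the profiles are
#' identical.
#'
#' @param mrm binary protein x domain matrix
#' @param delta_p bandwidth from [gip_bandwidth()]
#' @return symmetric N x N kernel matrix
#' @export
gip_kernel <- function(mrm, delta_p) {
  stopifnot(delta_p > 0)
  sq <- rowSums(mrm^2)
  # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y ; clamp tiny negatives
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(mrm)
  d2[d2 < 0] <- 0
  wbp <- exp(-delta_p * d2)
  dimnames(wbp) <- list(rownames(mrm), rownames(mrm))
  wbp
}

#' Rescale the kernel and mask it to the PPI edge set
#'
#' Every kernel value is scaled by `(1 + max_offdiag(WBP)) / 2` (a single
#' global factor), and entries for protein pairs without a PPI edge are set
#' to 0, so the support of the weighted network equals the PPI edge set.
#'
#' @param wbp kernel matrix from [gip_kernel()]
#' @param ppi a `ppi_network` over the same proteins
#' @param mask mask to PPI edges (default TRUE)
#' @return symmetric weighted adjacency WP
#' @export
wp_transform <- function(wbp, ppi, mask = TRUE) {
  stopifnot(inherits(ppi, "ppi_network"), nrow(wbp) == length(ppi$proteins))
  off <- wbp
  diag(off) <- -Inf
  mx <- max(off)
  wp <- wbp * (1 + mx) / 2
  if (mask) wp <- wp * ppi$adj else diag(wp) <- 0
  wp
}

#' Weighted PPI network from a densified protein-domain matrix
#'
#' Convenience wrapper: bandwidth, kernel, rescale-and-mask.
#'
#' @param mrm binary protein x domain matrix (rows must match `ppi$proteins`)
#' @param ppi a `ppi_network`
#' @param delta_prime raw bandwidth parameter
#' @param mask mask WP to PPI edges
#' @return list with `wbp`, `wp`, `delta_p`
#' @export
weight_ppi <- function(mrm, ppi, delta_prime = 1, mask = TRUE) {
  if (!identical(rownames(mrm), ppi$proteins))
    stop("mrm rows and PPI registry differ")
  delta_p <- gip_bandwidth(mrm, delta_prime)
  wbp <- gip_kernel(mrm, delta_p)
  list(wbp = wbp, wp = wp_transform(wbp, ppi, mask), delta_p = delta_p)
}
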