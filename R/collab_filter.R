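# Two-sided collaborative filtering on the protein-domain bipartite network.
#
# The protein-based pass treats domains as "items" shared between protein
# "users"; the domain-based pass swaps the roles. Each pass runs once from
# the ORIGINAL adjacency; the two densified matrices are then merged into a
# mutual recommendation matrix (logical OR). The step only ever adds edges.

#' Co-occurrence matrix of one side of a bipartite graph
#'
#' Entry (i, j) is 1 iff rows i and j of the adjacency share at least one
#' neighbor on the other side; the diagonal is 0.
#'
#' @param adjacency binary matrix (rows are the side being compared)
#' @return symmetric 0/1 matrix with zero diagonal
#' @export
cooccurrence <- function(adjacency) {
  shared <- tcrossprod(adjacency)
  cm <- (shared > 0) * 1
  diag(cm) <- 0
  cm
}

#' Cosine-style similarity between rows of a binary adjacency
#'
#' For distinct rows i and j with neighbor sets N(i), N(j):
#' `|N(i) n N(j)| / sqrt(|N(i)| * |N(j)|)`. The diagonal is 0, and rows with
#' empty neighbor sets get similarity 0 to everything (the 0/0 limit).
#'
#' @param adjacency binary matrix
#' @return symmetric similarity matrix with values in \[0, 1\]
#' @export
cf_similarity <- function(adjacency) {
  shared <- tcrossprod(adjacency)
  deg <- rowSums(adjacency)
  denom <- sqrt(outer(deg, deg))
  sm <- ifelse(denom > 0, shared / denom, 0)
  diag(sm) <- 0
  dimnames(sm) <- list(rownames(adjacency), rownames(adjacency))
  sm
}

#' Recommendation matrix: similarity times adjacency
#'
#' @param sim square similarity matrix over one side
#' @param adjacency binary adjacency with that side as rows
#' @return real matrix of the same shape as `adjacency`
#' @export
recommend_matrix <- function(sim, adjacency) {
  if (ncol(sim) != nrow(adjacency))
    stop("similarity and adjacency are not conformable")
  sim %*% adjacency
}

#' Per-column recommendation standard
#'
#' The threshold for adding an edge into a column: the column mean of the
#' recommendation matrix over all rows (zeros included).
#'
#' @param rm recommendation matrix
#' @return numeric vector, one standard per column
#' @export
recommendation_standard <- function(rm) {
  colMeans(rm)
}

#' Add recommended edges above the per-column standard
#'
#' A cell (k, j) is set to 1 where the recommendation strictly exceeds the
#' column standard and the original adjacency has no edge there. Existing
#' edges are never removed.
#'
#' @param rm recommendation matrix
#' @param std per-column standards from [recommendation_standard()]
#' @param adjacency original binary adjacency
#' @return updated binary adjacency (>= input element-wise)
#' @export
apply_recommendations <- function(rm, std, adjacency) {
  if (!all(dim(rm) == dim(adjacency)))
    stop("recommendation matrix and adjacency shapes differ")
  add <- sweep(rm, 2L, std, ">") & adjacency == 0
  out <- adjacency
  out[add] <- 1
  out
}

#' Merge the two densified adjacencies into the mutual recommendation matrix
#'
#' An entry is 1 when either pass (or the original network) supports the
#' edge; the both-sides case caps at 1.
#'
#' @param uam_pd updated protein x domain adjacency (protein-based pass)
#' @param uam_dp updated domain x protein adjacency (domain-based pass)
#' @return binary protein x domain matrix
#' @export
mutual_recommend <- function(uam_pd, uam_dp) {
  if (!all(dim(uam_pd) == rev(dim(uam_dp))))
    stop("protein-side and domain-side shapes are not transposes")
  (uam_pd + t(uam_dp) > 0) * 1
}

#' Densify a protein-domain network by mutual collaborative filtering
#'
#' Runs the protein-based and the domain-based recommendation pass, each
#' once and each from the original adjacency, then merges them. The result
#' carries per-edge provenance: "original", "protein", "domain" or "both"
#' for edges added by one or both passes.
#'
#' @param pdi a `bipartite_net`
#' @param iterations number of densification rounds (default 1; each further
#'   round restarts both passes from the previous round's merged matrix)
#' @return list with elements `mrm` (binary N x M matrix), `provenance`
#'   (character matrix), `added` (count of new edges), plus the intermediate
#'   `sim_pp`, `sim_dd`, `rm_pd`, `rm_dp`, `std_pd`, `std_dp` of the last round
#' @export
run_cf <- function(pdi, iterations = 1L) {
  stopifnot(inherits(pdi, "bipartite_net"), iterations >= 1L)
  am <- pdi$adjacency
  orig <- am
  for (it in seq_len(iterations)) {
    am_pd <- am
    am_dp <- t(am)

    sim_pp <- cf_similarity(am_pd)
    rm_pd <- recommend_matrix(sim_pp, am_pd)
    std_pd <- recommendation_standard(rm_pd)
    uam_pd <- apply_recommendations(rm_pd, std_pd, am_pd)

    sim_dd <- cf_similarity(am_dp)
    rm_dp <- recommend_matrix(sim_dd, am_dp)
    std_dp <- recommendation_standard(rm_dp)
    uam_dp <- apply_recommendations(rm_dp, std_dp, am_dp)

    am <- mutual_recommend(uam_pd, uam_dp)
    prot_side <- uam_pd == 1 & orig == 0
    dom_side <- t(uam_dp) == 1 & orig == 0
  }
  provenance <- matrix("none", nrow(am), ncol(am), dimnames = dimnames(am))
  provenance[orig == 1] <- "original"
  provenance[prot_side & !dom_side] <- "protein"
  provenance[!prot_side & dom_side] <- "domain"
  provenance[prot_side & dom_side] <- "both"
  list(mrm = am, provenance = provenance, added = sum(am) - sum(orig),
       sim_pp = sim_pp, sim_dd = sim_dd,
       rm_pd = rm_pd, rm_dp = rm_dp, std_pd = std_pd, std_dp = std_dp)
}
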