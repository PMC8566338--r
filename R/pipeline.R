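# End-to-end orchestration: densify the protein-domain network, weight the
# PPI edges, compute and fuse features, propagate, rank, and (optionally)
# evaluate against a gold standard.

#' Run the full essential-protein ranking pipeline
#'
#' Accepts either in-memory objects (a `ppi_network`, a `bipartite_net` and
#' an annotation list) or file paths to the standard TSV inputs. Stages:
#' collaborative-filtering densification of the protein-domain network, GIP
#' kernel weighting of the PPI edges, entropy-weighted feature fusion into
#' the initial score, damped propagation, and ranking.
#'
#' @param ppi a `ppi_network` or path to a PPI edge list
#' @param pdi a `bipartite_net` or path to a protein-domain table
#' @param annotations annotation list or NULL; alternatively give
#'   `subcell_path`, `ortho_path`, `expr_path`
#' @param subcell_path,ortho_path,expr_path file-based annotation inputs
#' @param essential optional gold-standard ID vector or file path; when
#'   given, an evaluation report is attached
#' @param alpha damping factor in (0, 1), default 0.9
#' @param lambda biology/topology blend in \[0, 1\], default 0.65
#'   (0.8 suits smaller, denser complex-derived networks)
#' @param delta_prime raw GIP bandwidth, default 1
#' @param eps propagation stopping tolerance, default 1e-6
#' @param max_iter propagation iteration cap, default 100
#' @param cf_iterations collaborative-filtering rounds, default 1
#' @param normalize_rows row-normalize the distribution-rate matrix
#' @param mask_wp mask kernel weights to PPI edges
#' @param verbose log stage summaries to stderr
#' @return list with `ranking` (data.frame), `scores`, `features`,
#'   `weights`, `cf` (densification result), `iterations`, `residual`,
#'   `evaluation` (NULL without a gold standard)
#' @export
run_cfmm <- function(ppi, pdi, annotations = NULL,
                     subcell_path = NULL, ortho_path = NULL,
                     expr_path = NULL, essential = NULL,
                     alpha = 0.9, lambda = 0.65, delta_prime = 1,
                     eps = 1e-6, max_iter = 100L, cf_iterations = 1L,
                     normalize_rows = TRUE, mask_wp = TRUE,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.character(ppi)) ppi <- read_ppi(ppi)
  if (is.character(pdi)) pdi <- read_pdi(pdi, proteins = ppi$proteins)
  if (is.null(annotations))
    annotations <- read_annotations(subcell_path, ortho_path, expr_path)
  if (is.character(essential) && length(essential) == 1L &&
      file.exists(essential))
    essential <- read_essential(essential)

  if (!identical(pdi$proteins, ppi$proteins)) {
    # align the bipartite rows to the PPI registry (the protein universe)
    adjacency <- matrix(0, length(ppi$proteins), length(pdi$domains),
                        dimnames = list(ppi$proteins, pdi$domains))
    keep <- intersect(pdi$proteins, ppi$proteins)
    adjacency[keep, ] <- pdi$adjacency[keep, ]
    pdi <- new_bipartite_net(ppi$proteins, pdi$domains, adjacency)
  }

  cf <- run_cf(pdi, iterations = cf_iterations)
  say("collaborative filtering: %d edges added (%d -> %d)",
      cf$added, sum(pdi$adjacency), sum(cf$mrm))

  w <- weight_ppi(cf$mrm, ppi, delta_prime = delta_prime, mask = mask_wp)
  feats <- feature_table(ppi, annotations, lambda = lambda)
  say("entropy weights: %s",
      paste(sprintf("%s=%.3f", names(feats$weights), feats$weights),
            collapse = ", "))

  drpm <- build_drpm(w$wp, feats$proscore, normalize_rows = normalize_rows)
  it <- iterate_scores(drpm, feats$proscore, alpha = alpha, eps = eps,
                       max_iter = max_iter)
  say("propagation: %d iterations, residual %.3g, converged: %s",
      it$iterations, it$residual, it$converged)

  ranking <- rank_proteins(it$scores, initial = feats$proscore)
  evaluation <- if (!is.null(essential))
    evaluate_ranking(ranking, essential, scores = it$scores) else NULL

  list(ranking = ranking, scores = it$scores, features = feats$features,
       weights = feats$weights, cf = cf, wp = w$wp,
       iterations = it$iterations, residual = it$residual,
       converged = it$converged, evaluation = evaluation)
}

#' Grid sweep over the damping and blend parameters
#'
#' Re-runs the pipeline for every (alpha, lambda) pair and tabulates the
#' count of true essentials within each top-k% cutoff.
#'
#' @param ppi,pdi,annotations,essential as in [run_cfmm()]
#' @param alphas damping grid (default 0.1 to 0.9)
#' @param lambdas blend grid (default 0.65)
#' @param percents top-k percentages
#' @param ... further arguments passed to [run_cfmm()]
#' @return data.frame with alpha, lambda, percent, cutoff, hits, precision
#' @export
parameter_sweep <- function(ppi, pdi, annotations, essential,
                            alphas = seq(0.1, 0.9, by = 0.1),
                            lambdas = 0.65,
                            percents = c(1, 5, 10, 15, 20, 25), ...) {
  grid <- expand.grid(alpha = alphas, lambda = lambdas)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    res <- run_cfmm(ppi, pdi, annotations, essential = essential,
                    alpha = grid$alpha[g], lambda = grid$lambda[g], ...)
    cbind(alpha = grid$alpha[g], lambda = grid$lambda[g],
          topk_precision(res$ranking$protein, essential, percents))
  })
  do.call(rbind, out)
}
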