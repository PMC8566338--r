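# Seeded generators: the 5-protein/4-domain desk example used throughout
# the documentation and tests, and a full synthetic dataset (PPI + PDI +
# annotations + planted essential labels) so the whole pipeline can run
# without any database downloads.

#' The 5-protein / 4-domain desk example
#'
#' A small protein-domain network (p1 = \{d1, d2\}, p2 = \{d1, d3\},
#' p3 = \{d2\}, p4 = \{d3, d4\}, p5 = \{d4\}) whose collaborative-filtering
#' quantities can be traced by hand, together with the expected values:
#' RMPD(p3, d1) = 1/sqrt(2) (0.71 to two decimals), the d1 recommendation
#' standard 0.4414 (0.44), RMPD(p2, d2) = 0.5 exactly, and the protein-side
#' additions (p3, d1) and (p4, d1).
#'
#' @return list with `pdi` (a `bipartite_net`) and `expected` (named list of
#'   reference values)
#' @export
toy_pdi <- function() {
  proteins <- paste0("p", 1:5)
  domains <- paste0("d", 1:4)
  adjacency <- matrix(0, 5, 4, dimnames = list(proteins, domains))
  adjacency[cbind(c(1, 1, 2, 2, 3, 4, 4, 5),
                  c(1, 2, 1, 3, 2, 3, 4, 4))] <- 1
  list(
    pdi = new_bipartite_net(proteins, domains, adjacency),
    expected = list(
      rmpd_p3_d1 = 1 / sqrt(2),
      std_d1 = (0.5 + 0.5 + 1 / sqrt(2) + 0.5 + 0) / 5,
      rmpd_p2_d2 = 0.5,
      smpp_p1_p2 = 0.5,
      smpp_p1_p3 = 1 / sqrt(2),
      protein_side_added = list(c("p3", "d1"), c("p4", "d1"))
    )
  )
}

#' Default effect sizes for the synthetic generator
#'
#' `degree_boost`: multiplier on an essential node's attachment propensity
#' in the preferential-attachment PPI model; `domain_enrich`: probability an
#' essential draws its domains from a small shared pool; `loc_enrich`:
#' probability an essential's compartments are drawn from the
#' nucleus/mitochondrion pair; `ortho_p` / `ortho_p_null`: per-genome
#' ortholog probabilities for essentials vs. the rest; `expr_signal`:
#' loading of essentials' expression profiles on a shared periodic latent
#' factor.
#'
#' @return named list of effect sizes
#' @export
default_effects <- function() {
  list(degree_boost = 3, domain_enrich = 0.7, loc_enrich = 0.7,
       ortho_p = 0.6, ortho_p_null = 0.25, expr_signal = 1.5)
}

#' Zero effect sizes (labels independent of all features)
#' @return named list of effect sizes
#' @export
null_effects <- function() {
  list(degree_boost = 1, domain_enrich = 0, loc_enrich = 0,
       ortho_p = 0.25, ortho_p_null = 0.25, expr_signal = 0)
}

#' Simulate a full dataset with planted essential proteins
#'
#' Generates a preferential-attachment PPI network in which planted
#' essentials attract extra edges (heavy-tailed degrees with an essentiality
#' signal in degree and triangle participation), a protein-domain bipartite
#' network in which essentials share a small domain pool, subcellular
#' annotations over the 11-compartment yeast vocabulary with essentials
#' enriched in nucleus/mitochondrion, per-genome ortholog counts, and an
#' expression matrix in which essentials load on a shared periodic latent
#' factor so neighbor co-expression is elevated.
#'
#' @param n number of proteins (default 300)
#' @param m_domains number of domains (default 150)
#' @param essential_frac fraction of planted essentials (default 0.2)
#' @param pa_edges edges added per arriving node (default 3)
#' @param effects effect-size list, see [default_effects()]
#' @param expr_len expression time points (default 36)
#' @param n_genomes reference genomes for ortholog counts (default 100)
#' @param seed RNG seed (required: the contract is bit-reproducibility)
#' @param out_dir if non-NULL, also write the five standard input files
#'   (ppi.tsv, pdi.tsv, subcell.tsv, ortho.tsv, expr.tsv, essential.txt)
#' @return list with `ppi`, `pdi`, `annotations`, `essential`, `proteins`
#' @export
simulate_data <- function(n = 300L, m_domains = 150L, essential_frac = 0.2,
                          pa_edges = 3L, effects = default_effects(),
                          expr_len = 36L, n_genomes = 100L, seed,
                          out_dir = NULL) {
  stopifnot(n >= 10L, m_domains >= 4L, expr_len >= 2L,
            essential_frac > 0, essential_frac < 1)
  if (essential_frac * n < 1) stop("infeasible: essential_frac * n < 1")
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)

  proteins <- sprintf("P%04d", seq_len(n))
  ess_idx <- sort(sample.int(n, round(essential_frac * n)))
  essential <- proteins[ess_idx]
  is_ess <- seq_len(n) %in% ess_idx

  # PPI: preferential attachment; essential nodes attract more edges
  deg <- numeric(n)
  boost <- ifelse(is_ess, effects$degree_boost, 1)
  edges <- matrix(integer(0), ncol = 2)
  init <- min(pa_edges + 1L, n)
  for (i in 2:init) for (j in 1:(i - 1L)) {
    edges <- rbind(edges, c(i, j)); deg[c(i, j)] <- deg[c(i, j)] + 1
  }
  for (v in (init + 1L):n) {
    w <- (deg[1:(v - 1L)] + 1) * boost[1:(v - 1L)]
    k <- min(pa_edges, v - 1L)
    targets <- sample.int(v - 1L, k, prob = w)
    edges <- rbind(edges, cbind(v, targets))
    deg[targets] <- deg[targets] + 1
    deg[v] <- deg[v] + k
  }
  ppi <- ppi_from_edges(cbind(proteins[edges[, 1]], proteins[edges[, 2]]),
                        proteins = proteins)

  # PDI: essentials draw from a shared pool of the first few domains
  domains <- sprintf("PF%05d", seq_len(m_domains))
  pool <- seq_len(max(4L, round(m_domains / 10)))
  pdi_rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    from_pool <- is_ess[i] & stats::runif(1) < effects$domain_enrich
    ds <- if (from_pool) sample(pool, min(k, length(pool)))
          else sample.int(m_domains, k)
    cbind(proteins[i], domains[ds])
  })
  pdi_m <- do.call(rbind, pdi_rows)
  pdi <- new_bipartite_net(proteins, domains, {
    a <- matrix(0, n, m_domains, dimnames = list(proteins, domains))
    a[cbind(match(pdi_m[, 1], proteins), match(pdi_m[, 2], domains))] <- 1
    a
  })

  # subcellular: 11 compartments; essentials lean nucleus/mitochondrion
  vocab <- yeast_compartments()
  enriched <- c("nucleus", "mitochondrion")
  base_w <- stats::setNames(rep(1, length(vocab)), vocab)
  base_w[c("nucleus", "cytosol")] <- 3  # common compartments are common
  subcell <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    if (is_ess[i] && stats::runif(1) < effects$loc_enrich)
      unique(c(sample(enriched, 1), sample(vocab, k, prob = base_w)))
    else sample(vocab, k, prob = base_w)
  })
  names(subcell) <- proteins

  # orthology: per-genome presence probability differs by class
  p_orth <- ifelse(is_ess, effects$ortho_p, effects$ortho_p_null)
  ortho <- stats::setNames(stats::rbinom(n, n_genomes, p_orth), proteins)

  # expression: essentials share a periodic latent factor
  tt <- seq_len(expr_len)
  latent <- sin(2 * pi * tt / expr_len)
  expr <- t(vapply(seq_len(n), function(i) {
    load <- if (is_ess[i]) effects$expr_signal else 0
    load * latent + stats::rnorm(expr_len)
  }, numeric(expr_len)))
  rownames(expr) <- proteins
  colnames(expr) <- sprintf("T%02d", tt)

  annotations <- list(subcell = subcell, ortho = as.numeric(ortho),
                      expr = expr)
  names(annotations$ortho) <- proteins

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    eidx <- which(ppi$adj == 1, arr.ind = TRUE)
    eidx <- eidx[eidx[, 1] < eidx[, 2], , drop = FALSE]
    utils::write.table(cbind(proteins[eidx[, 1]], proteins[eidx[, 2]]),
                       file.path(out_dir, "ppi.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_pdi(pdi, file.path(out_dir, "pdi.tsv"))
    sc <- do.call(rbind, lapply(proteins, function(p)
      if (length(subcell[[p]])) cbind(p, sort(subcell[[p]]))))
    utils::write.table(sc, file.path(out_dir, "subcell.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(cbind(proteins, annotations$ortho[proteins]),
                       file.path(out_dir, "ortho.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(protein = proteins, expr,
                                  check.names = FALSE),
                       file.path(out_dir, "expr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    writeLines(essential, file.path(out_dir, "essential.txt"))
  }

  list(ppi = ppi, pdi = pdi, annotations = annotations,
       essential = essential, proteins = proteins)
}
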