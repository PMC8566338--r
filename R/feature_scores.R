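# Per-protein feature scores: subcellular localization, orthology,
# co-expression with PPI neighbors, and a triangle topology score; the three
# biological features are fused with entropy weights and blended with the
# topology score into the initial score used as the restart distribution.

#' Per-compartment localization scores
#'
#' Each compartment's score is its protein count divided by the average
#' count over all compartments, so compartments that host many proteins
#' (nucleus, mitochondrion in yeast) score above 1.
#'
#' @param subcell named list: protein ID -> character vector of compartments
#' @param vocabulary compartment vocabulary (defaults to the 11 yeast
#'   compartments: cytoskeleton, mitochondrion, nucleus, peroxisome, plasma,
#'   extracellular, endosome, vacuole, endoplasmic, cytosol, Golgi)
#' @return list with `counts`, `average`, `score` (one per compartment)
#' @export
location_scores <- function(subcell, vocabulary = yeast_compartments()) {
  stopifnot(length(vocabulary) > 0L)
  counts <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  for (comps in subcell) {
    comps <- intersect(comps, vocabulary)
    counts[comps] <- counts[comps] + 1
  }
  avg <- sum(counts) / length(vocabulary)
  score <- if (avg > 0) counts / avg else counts * 0
  list(counts = counts, average = avg, score = score)
}

#' The 11-compartment yeast subcellular vocabulary
#' @export
yeast_compartments <- function() {
  c("cytoskeleton", "mitochondrion", "nucleus", "peroxisome", "plasma",
    "extracellular", "endosome", "vacuole", "endoplasmic", "cytosol", "golgi")
}

#' Subcellular localization score per protein
#'
#' Sum of the compartment scores over the compartments a protein occupies;
#' 0 for unannotated proteins.
#'
#' @param proteins protein IDs (defines output order)
#' @param subcell named list: protein ID -> compartments
#' @param loc result of [location_scores()]
#' @return numeric vector named by protein
#' @export
prosub <- function(proteins, subcell, loc) {
  vapply(proteins, function(p) {
    comps <- intersect(subcell[[p]], names(loc$score))
    if (length(comps) == 0L) 0 else sum(loc$score[comps])
  }, numeric(1))
}

#' Orthology score: ortholog-genome count, max-normalized
#'
#' @param proteins protein IDs
#' @param ortho named numeric vector of counts (missing proteins get 0)
#' @return numeric vector in \[0, 1\]
#' @export
proort <- function(proteins, ortho) {
  cnt <- ortho[proteins]
  cnt[is.na(cnt)] <- 0
  names(cnt) <- proteins
  mx <- max(cnt)
  if (mx > 0) cnt / mx else cnt
}

#' Pearson correlation of two expression vectors
#'
#' Sample correlation (n - 1 denominator); returns 0 when either vector is
#' constant, treating an undefined correlation as no co-expression evidence.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return correlation in \[-1, 1\]
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("expression vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Co-expression score: summed neighbor correlation, floored and normalized
#'
#' For each protein the raw score is the sum of Pearson correlations with
#' its PPI neighbors' expression profiles. Negative raw sums are floored at
#' 0 before max-normalization, so anti-correlated neighborhoods do not
#' corrupt the nonnegative entropy-weighting step.
#'
#' @param ppi a `ppi_network`
#' @param expr numeric matrix, rownames protein IDs (proteins absent from
#'   the matrix contribute and receive 0)
#' @return numeric vector in \[0, 1\] named by protein
#' @export
proexp <- function(ppi, expr) {
  proteins <- ppi$proteins
  raw <- stats::setNames(numeric(length(proteins)), proteins)
  if (!is.null(expr) && nrow(expr) > 0L) {
    have <- intersect(proteins, rownames(expr))
    sub <- expr[have, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    ok <- have[sds > 0]
    if (length(ok) >= 2L) {
      cm <- stats::cor(t(expr[ok, , drop = FALSE]))
      aok <- ppi$adj[ok, ok, drop = FALSE]
      raw[ok] <- rowSums(cm * aok)
    }
  }
  raw[raw < 0] <- 0
  mx <- max(raw)
  if (mx > 0) raw / mx else raw
}

#' Triangle topology score
#'
#' For protein k with neighbors NG(k), the raw score is
#' `sum_{r in NG(k)} |NG(k) n NG(r)| / |NG(k)|` — twice the number of
#' triangles through k divided by its degree. Degree-0 proteins score 0.
#'
#' @param ppi a `ppi_network`
#' @param normalize max-normalize to \[0, 1\] (default TRUE, the scale used
#'   when blending with the fused biological score)
#' @return numeric vector named by protein
#' @export
protri <- function(ppi, normalize = TRUE) {
  a <- ppi$adj
  deg <- rowSums(a)
  common <- a %*% a           # (k, r): shared neighbors of k and r
  raw <- rowSums(common * a)  # sum over actual neighbors r
  raw <- ifelse(deg > 0, raw / deg, 0)
  names(raw) <- ppi$proteins
  if (normalize && max(raw) > 0) raw <- raw / max(raw)
  raw
}

#' Entropy weights for a nonnegative feature matrix
#'
#' Each column is turned into proportions over proteins; its Shannon entropy
#' (normalized by ln N) measures how undiscriminating the feature is, and
#' weights are proportional to 1 - entropy. A constant feature carries no
#' information and gets weight 0; if every feature is constant the weights
#' fall back to uniform.
#'
#' @param bf N x F nonnegative matrix (proteins x features)
#' @return list with `entropy` and `weights` (weights sum to 1)
#' @export
entropy_weights <- function(bf) {
  if (any(bf < 0)) stop("entropy weighting requires nonnegative features")
  n <- nrow(bf)
  stopifnot(n >= 2L)
  e <- apply(bf, 2L, function(col) {
    s <- sum(col)
    if (s == 0) return(1)  # empty feature: maximally uninformative
    q <- col / s
    q <- q[q > 0]
    -sum(q * log(q)) / log(n)
  })
  d <- 1 - e
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / length(e), length(e))
  names(w) <- colnames(bf)
  list(entropy = e, weights = w)
}

#' Fuse features with given weights
#'
#' @param bf N x F feature matrix
#' @param w weight vector of length F
#' @return weighted row sums, named by protein
#' @export
fuse_features <- function(bf, w) {
  if (ncol(bf) != length(w)) stop("feature matrix and weights differ in size")
  drop(bf %*% w)
}

#' Initial protein score: blend of biology and topology
#'
#' `proscore = lambda * proBio + (1 - lambda) * ProTri`, then rescaled to
#' sum 1 for use as the restart distribution of the propagation.
#'
#' @param pro_bio fused biological score vector
#' @param pro_tri normalized triangle score vector
#' @param lambda blend proportion in \[0, 1\] (default 0.65)
#' @param normalize rescale to a probability vector (default TRUE)
#' @return numeric vector named by protein
#' @export
initial_score <- function(pro_bio, pro_tri, lambda = 0.65, normalize = TRUE) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  s <- lambda * pro_bio + (1 - lambda) * pro_tri
  if (normalize) {
    tot <- sum(s)
    s <- if (tot > 0) s / tot else rep(1 / length(s), length(s))
    names(s) <- names(pro_bio)
  }
  s
}

#' Full per-protein feature table
#'
#' Computes ProSub, ProOrt, ProExp and ProTri, min-max scales each
#' biological feature to \[0, 1\], derives entropy weights, and blends the
#' fused biological score with the triangle score.
#'
#' @param ppi a `ppi_network`
#' @param annotations list from [read_annotations()]
#' @param lambda blend proportion (default 0.65)
#' @param vocabulary compartment vocabulary
#' @return list with `features` (data.frame), `weights`, `entropy`,
#'   `proscore` (sum-1 restart vector)
#' @export
feature_table <- function(ppi, annotations, lambda = 0.65,
                          vocabulary = yeast_compartments()) {
  proteins <- ppi$proteins
  loc <- location_scores(annotations$subcell, vocabulary)
  f_sub <- prosub(proteins, annotations$subcell, loc)
  f_ort <- proort(proteins, annotations$ortho)
  f_exp <- proexp(ppi, annotations$expr)
  f_tri <- protri(ppi, normalize = TRUE)

  minmax <- function(x) {
    rng <- range(x)
    if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  }
  bf <- cbind(ProSub = minmax(f_sub), ProOrt = minmax(f_ort),
              ProExp = minmax(f_exp))
  rownames(bf) <- proteins
  ew <- entropy_weights(bf)
  pro_bio <- fuse_features(bf, ew$weights)
  proscore <- initial_score(pro_bio, f_tri, lambda)

  features <- data.frame(protein = proteins, ProSub = f_sub, ProOrt = f_ort,
                         ProExp = f_exp, ProTri = f_tri, proBio = pro_bio,
                         proscore = proscore, row.names = NULL,
                         stringsAsFactors = FALSE)
  list(features = features, weights = ew$weights, entropy = ew$entropy,
       proscore = proscore)
}
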