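# Evaluation machinery: top-k% precision, jackknife cumulative curves,
# ROC/PR with AUC, and pairwise ranking-overlap difference statistics.

#' Top-k% precision of a ranking
#'
#' For each percentage p the cutoff is `ceiling(p/100 * N)` over the ranked
#' universe of N proteins (the convention matching cutoffs 51 and 1274 for
#' 1% and 25% of 5093), and precision is 100 times the fraction of true
#' essentials within the cutoff. Gold-standard proteins absent from the
#' ranking are dropped with a warning.
#'
#' @param ranking character vector of protein IDs, best first
#' @param essential character vector of true essential IDs
#' @param percents percentages to evaluate (default 1, 5, 10, 15, 20, 25)
#' @return data.frame with percent, cutoff, hits, precision
#' @export
topk_precision <- function(ranking, essential,
                           percents = c(1, 5, 10, 15, 20, 25)) {
  if (length(ranking) == 0L) stop("empty ranking")
  out <- setdiff(essential, ranking)
  if (length(out) > 0L)
    warning(length(out), " essential proteins absent from the ranking; dropped")
  ess <- intersect(essential, ranking)
  n <- length(ranking)
  cutoff <- ceiling(percents / 100 * n)
  hits <- vapply(cutoff, function(k) sum(ranking[seq_len(k)] %in% ess),
                 numeric(1))
  data.frame(percent = percents, cutoff = cutoff, hits = hits,
             precision = 100 * hits / cutoff)
}

#' Jackknife cumulative curve
#'
#' Entry r is the number of true essentials among the top r ranked proteins.
#'
#' @param ranking character vector of IDs, best first
#' @param essential true essential IDs
#' @param depth curve depth (default min(1000, length(ranking)))
#' @return integer vector of cumulative counts
#' @export
jackknife_curve <- function(ranking, essential,
                            depth = min(1000L, length(ranking))) {
  stopifnot(depth <= length(ranking))
  cumsum(ranking[seq_len(depth)] %in% essential)
}

#' ROC and precision-recall curves with AUC
#'
#' Sweeps thresholds over the unique scores; the ROC AUC is computed by the
#' Mann-Whitney pair-counting statistic with rank-averaged ties (equivalent
#' to the trapezoid rule on the tie-grouped ROC curve).
#'
#' @param scores numeric score vector (higher = more likely positive)
#' @param labels 0/1 (or logical) vector, same length
#' @return list with `roc` (fpr, tpr), `pr` (recall, precision), `auc`
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute ROC/PR")
  # Mann-Whitney AUC with ties handled by midranks
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  # tie-grouped threshold sweep, descending score
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  roc <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  pr <- data.frame(recall = tp / npos, precision = tp / (tp + fp))
  list(roc = roc, pr = pr, auc = auc)
}

#' Overlap and difference statistics between two top-k sets
#'
#' Reports the intersection size, the two set differences, and the
#' percentage of true essentials within each difference set (NA when a
#' difference set is empty).
#'
#' @param top_a,top_b character vectors (top-k IDs of two methods)
#' @param essential true essential IDs
#' @return list of statistics
#' @export
overlap_diff <- function(top_a, top_b, essential) {
  a_only <- setdiff(top_a, top_b)
  b_only <- setdiff(top_b, top_a)
  pct <- function(s) if (length(s) == 0L) NA_real_ else
    100 * sum(s %in% essential) / length(s)
  list(intersection = length(intersect(top_a, top_b)),
       a_minus_b = length(a_only), b_minus_a = length(b_only),
       pct_essential_a_minus_b = pct(a_only),
       pct_essential_b_minus_a = pct(b_only))
}

#' Bundle the evaluation blocks into one report
#'
#' @param ranking data.frame from [rank_proteins()] or a character ID vector
#' @param essential true essential IDs
#' @param scores optional named score vector for ROC/PR (defaults to the
#'   ranking scores when a ranking data.frame is given)
#' @param percents top-k percentages
#' @param jackknife_depth depth of the jackknife curve
#' @return list with `topk`, `jackknife`, `roc_pr` (NULL if labels are
#'   one-class), `n`, `n_essential`
#' @export
evaluate_ranking <- function(ranking, essential,
                             scores = NULL,
                             percents = c(1, 5, 10, 15, 20, 25),
                             jackknife_depth = 1000L) {
  if (is.data.frame(ranking)) {
    if (is.null(scores))
      scores <- stats::setNames(ranking$score, ranking$protein)
    ranking <- ranking$protein
  }
  topk <- topk_precision(ranking, essential, percents)
  jk <- jackknife_curve(ranking, essential,
                        depth = min(jackknife_depth, length(ranking)))
  rp <- NULL
  if (!is.null(scores)) {
    labels <- as.integer(names(scores) %in% essential)
    if (length(unique(labels)) == 2L) rp <- roc_pr(scores, labels)
  }
  list(topk = topk, jackknife = jk, roc_pr = rp,
       n = length(ranking), n_essential = sum(ranking %in% essential))
}

#' Write an evaluation report as JSON
#'
#' @param report list from [evaluate_ranking()]
#' @param path output path
#' @export
write_report <- function(report, path) {
  out <- list(n = report$n, n_essential = report$n_essential,
              topk = report$topk, jackknife = report$jackknife)
  if (!is.null(report$roc_pr)) out$auc <- report$roc_pr$auc
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
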