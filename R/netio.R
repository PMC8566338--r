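# -- in-memory data model ----------------------------------------------------
#
# ppi_network:    list(proteins, adj) where adj is a symmetric 0/1 matrix with
#                 zero diagonal and dimnames = protein IDs.
# bipartite_net:  list(proteins, domains, adjacency) with adjacency an N x M
#                 0/1 matrix (proteins x domains).
# annotations:    list(subcell, ortho, expr): subcell is a named list of
#                 compartment-name character vectors, ortho a named numeric
#                 vector of ortholog-genome counts, expr a numeric matrix with
#                 protein IDs as rownames (one column per time point).

new_ppi_network <- function(proteins, adj) {
  stopifnot(is.character(proteins), nrow(adj) == length(proteins))
  dimnames(adj) <- list(proteins, proteins)
  structure(list(proteins = proteins, adj = adj), class = "ppi_network")
}

new_bipartite_net <- function(proteins, domains, adjacency) {
  stopifnot(nrow(adjacency) == length(proteins),
            ncol(adjacency) == length(domains))
  dimnames(adjacency) <- list(proteins, domains)
  structure(list(proteins = proteins, domains = domains,
                 adjacency = adjacency),
            class = "bipartite_net")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d edges\n",
              length(x$proteins), sum(x$adj) / 2))
  invisible(x)
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("bipartite_net: %d proteins x %d domains, %d edges\n",
              length(x$proteins), length(x$domains), sum(x$adjacency)))
  invisible(x)
}

#' Neighbor set of a protein in the PPI network
#'
#' @param ppi a `ppi_network`
#' @param id protein ID (character) or index
#' @return character vector of neighbor IDs
#' @export
neighbors_of <- function(ppi, id) {
  stopifnot(inherits(ppi, "ppi_network"))
  i <- if (is.character(id)) match(id, ppi$proteins) else as.integer(id)
  if (is.na(i) || i < 1L || i > length(ppi$proteins))
    stop("unknown protein: ", id)
  ppi$proteins[ppi$adj[i, ] != 0]
}

read_two_col <- function(path, sep = "\t", what = "edge list") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", what, " file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed line %d in %s (expected 2 columns): %s",
                 bad[1L], path, lines[bad[1L]]))
  do.call(rbind, parts)
}

#' Read an undirected PPI edge list
#'
#' Reads a two-column delimited file of protein-ID pairs, drops self-loops,
#' and collapses duplicate pairs (in either order) into a single undirected
#' edge. Proteins that appear only in dropped self-loops are retained as
#' isolated nodes so that the registry covers every ID seen.
#'
#' @param path path to a two-column edge list (tab-separated by default;
#'   lines starting with `#` are skipped)
#' @param sep field delimiter
#' @return a `ppi_network`
#' @export
read_ppi <- function(path, sep = "\t") {
  m <- read_two_col(path, sep, "PPI")
  proteins <- unique(as.vector(t(m)))
  n <- length(proteins)
  adj <- matrix(0, n, n, dimnames = list(proteins, proteins))
  i <- match(m[, 1L], proteins)
  j <- match(m[, 2L], proteins)
  keep <- i != j
  adj[cbind(i[keep], j[keep])] <- 1
  adj[cbind(j[keep], i[keep])] <- 1
  new_ppi_network(proteins, adj)
}

#' Construct a PPI network from an edge data frame
#'
#' @param edges two-column character matrix or data.frame of protein pairs
#' @param proteins optional full protein universe (keeps isolated nodes)
#' @return a `ppi_network`
#' @export
ppi_from_edges <- function(edges, proteins = NULL) {
  edges <- as.matrix(edges)
  if (is.null(proteins)) proteins <- unique(as.vector(t(edges)))
  n <- length(proteins)
  adj <- matrix(0, n, n, dimnames = list(proteins, proteins))
  if (nrow(edges) > 0L) {
    i <- match(edges[, 1L], proteins)
    j <- match(edges[, 2L], proteins)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint outside protein universe")
    keep <- i != j
    adj[cbind(i[keep], j[keep])] <- 1
    adj[cbind(j[keep], i[keep])] <- 1
  }
  new_ppi_network(proteins, adj)
}

#' Read a protein-domain annotation table into a bipartite network
#'
#' Each line pairs a protein ID with a domain accession; duplicates collapse
#' to a single 0/1 entry. When a protein registry is supplied, annotation
#' rows for proteins outside it are either dropped with a warning (default)
#' or rejected (`strict = TRUE`); registry proteins with no domain rows keep
#' an all-zero profile row.
#'
#' @param path two-column file (protein, domain)
#' @param proteins optional protein universe defining row order
#' @param strict error (rather than warn) on proteins outside the registry
#' @param sep field delimiter
#' @return a `bipartite_net`
#' @export
read_pdi <- function(path, proteins = NULL, strict = FALSE, sep = "\t") {
  m <- read_two_col(path, sep, "PDI")
  if (is.null(proteins)) {
    proteins <- unique(m[, 1L])
  } else {
    unknown <- setdiff(unique(m[, 1L]), proteins)
    if (length(unknown) > 0L) {
      if (strict)
        stop("proteins not in registry: ", paste(unknown, collapse = ", "))
      warning(sprintf("dropping %d PDI rows for %d proteins outside the registry",
                      sum(m[, 1L] %in% unknown), length(unknown)))
      m <- m[!(m[, 1L] %in% unknown), , drop = FALSE]
    }
  }
  domains <- unique(m[, 2L])
  adjacency <- matrix(0, length(proteins), length(domains),
                      dimnames = list(proteins, domains))
  if (nrow(m) > 0L)
    adjacency[cbind(match(m[, 1L], proteins), match(m[, 2L], domains))] <- 1
  new_bipartite_net(proteins, domains, adjacency)
}

#' Read subcellular, orthology and expression annotation files
#'
#' Proteins absent from a source are imputed neutrally downstream: empty
#' compartment set, ortholog count 0, no expression vector (which yields
#' feature score 0 in [feature_table()]).
#'
#' @param subcell_path TSV of (protein, compartment) pairs, or NULL
#' @param ortho_path TSV of (protein, ortholog-genome count), or NULL
#' @param expr_path TSV expression matrix: header of sample names, then one
#'   row per protein (ID in column 1), or NULL
#' @param sep field delimiter
#' @return a list with elements `subcell`, `ortho`, `expr`
#' @export
read_annotations <- function(subcell_path = NULL, ortho_path = NULL,
                             expr_path = NULL, sep = "\t") {
  subcell <- list()
  if (!is.null(subcell_path)) {
    m <- read_two_col(subcell_path, sep, "subcellular")
    subcell <- lapply(split(m[, 2L], m[, 1L]), unique)
  }
  ortho <- numeric(0)
  if (!is.null(ortho_path)) {
    m <- read_two_col(ortho_path, sep, "orthology")
    cnt <- as.numeric(m[, 2L])
    if (anyNA(cnt)) stop("non-numeric ortholog count in ", ortho_path)
    if (any(cnt < 0)) stop("negative ortholog count in ", ortho_path)
    ortho <- tapply(cnt, m[, 1L], max)
    ortho <- stats::setNames(as.numeric(ortho), names(ortho))
  }
  expr <- NULL
  if (!is.null(expr_path)) {
    tab <- utils::read.delim(expr_path, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE,
                             comment.char = "#")
    expr <- as.matrix(tab)
    if (!is.numeric(expr)) stop("non-numeric expression values in ", expr_path)
    if (ncol(expr) < 2L) stop("expression matrix needs >= 2 time points")
  }
  list(subcell = subcell, ortho = ortho, expr = expr)
}

#' Read a gold-standard essential-protein list
#'
#' @param path plain text, one protein ID per line
#' @return character vector of IDs
#' @export
read_essential <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids[!grepl("^\\s*#", ids)])
  unique(ids[nzchar(ids)])
}

#' Rank proteins by score with deterministic tie-breaking
#'
#' Descending score, ties broken by descending initial score (when given),
#' then ascending protein ID.
#'
#' @param scores named numeric vector over proteins
#' @param initial optional named numeric vector used as secondary key
#' @return data.frame with columns rank, protein, score
#' @export
rank_proteins <- function(scores, initial = NULL) {
  if (any(!is.finite(scores))) stop("non-finite score encountered")
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by protein ID")
  init <- if (is.null(initial)) rep(0, length(scores)) else initial[ids]
  ord <- order(-scores, -init, ids)
  data.frame(rank = seq_along(scores), protein = ids[ord],
             score = unname(scores[ord]), stringsAsFactors = FALSE)
}

#' Write a ranking table to TSV
#'
#' @param ranking data.frame from [rank_proteins()]
#' @param path output path
#' @param header write a header row
#' @export
write_ranking <- function(ranking, path, header = TRUE) {
  if (any(!is.finite(ranking$score))) stop("non-finite score in ranking")
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Write a bipartite network as a two-column edge list
#'
#' @param net a `bipartite_net`
#' @param path output path
#' @export
write_pdi <- function(net, path) {
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  m <- cbind(net$proteins[idx[, 1L]], net$domains[idx[, 2L]])
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
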