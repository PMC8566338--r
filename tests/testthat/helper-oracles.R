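# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders.

# similarity by explicit set intersection over neighbor sets
bf_similarity <- function(adjacency) {
  n <- nrow(adjacency)
  sm <- matrix(0, n, n)
  sets <- lapply(seq_len(n), function(i) which(adjacency[i, ] == 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- sets[[i]]; b <- sets[[j]]
    if (length(a) == 0 || length(b) == 0) next
    sm[i, j] <- length(intersect(a, b)) / sqrt(length(a) * length(b))
  }
  dimnames(sm) <- list(rownames(adjacency), rownames(adjacency))
  sm
}

# triple-loop matrix product
bf_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(b)))
    for (k in seq_len(ncol(a))) out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# co-occurrence by pairwise set intersection
bf_cooccurrence <- function(adjacency) {
  n <- nrow(adjacency)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && any(adjacency[i, ] == 1 & adjacency[j, ] == 1))
      cm[i, j] <- 1
  }
  cm
}

# AUC by counting concordant positive-negative pairs (ties count 1/2)
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# triangles through each node by explicit triple enumeration
bf_triangles <- function(adj) {
  n <- nrow(adj)
  tri <- numeric(n)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n)
      if (adj[i, j] == 1 && adj[j, k] == 1 && adj[i, k] == 1)
        tri[c(i, j, k)] <- tri[c(i, j, k)] + 1
  tri
}

# random binary bipartite adjacency with row/col names
random_bipartite <- function(n, m, p = 0.35) {
  a <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(paste0("p", seq_len(n)),
                              paste0("d", seq_len(m))))
  a
}

# small undirected random graph as a ppi_network
random_ppi <- function(n, p = 0.3) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- cbind(paste0("p", idx[, 1]), paste0("p", idx[, 2]))
  ppi_from_edges(edges, proteins = paste0("p", seq_len(n)))
}

tmp_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
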