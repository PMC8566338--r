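test_that("compartment scores are counts over the average count", {
  subcell <- list(a = c("nucleus"), b = c("nucleus", "cytosol"),
                  c = c("vacuole"))
  loc <- location_scores(subcell, vocabulary = c("nucleus", "cytosol",
                                                 "vacuole"))
  expect_equal(unname(loc$counts), c(2, 1, 1))
  expect_equal(loc$average, 4 / 3)
  expect_equal(unname(loc$score), c(2, 1, 1) / (4 / 3))
  expect_equal(sum(loc$score), 3)  # Evesub sums to the compartment count

  # hand case from counts (30, 10, 20): average 20, scores (1.5, 0.5, 1.0)
  sc <- rep(list("x"), 30)
  sc <- c(sc, rep(list("y"), 10), rep(list("z"), 20))
  loc2 <- location_scores(sc, vocabulary = c("x", "y", "z"))
  expect_equal(unname(loc2$score), c(1.5, 0.5, 1.0))

  expect_equal(length(location_scores(list())$score), 11L)
})

test_that("prosub sums compartment scores; unannotated proteins get 0", {
  subcell <- list(a = c("x", "z"), b = character(0))
  loc <- list(score = c(x = 1.5, y = 0.5, z = 1.0))
  expect_equal(unname(prosub(c("a", "b", "missing"), subcell, loc)),
               c(2.5, 0, 0))
  # a protein in all compartments scores the compartment total
  all_in <- list(a = c("x", "y", "z"))
  expect_equal(unname(prosub("a", all_in, loc)), sum(loc$score))
})

test_that("proort max-normalizes ortholog counts with a zero guard", {
  expect_equal(unname(proort(c("a", "b", "c"),
                             c(a = 0, b = 5, c = 10))), c(0, 0.5, 1))
  expect_equal(unname(proort(c("a", "b"), c(a = 0, b = 0))), c(0, 0))
  expect_equal(unname(proort("a", c(a = 7))), 1)
})

test_that("pcc matches hand values and guards constant vectors", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 0, 1, 0), c(1, 0, 0, 1)), 0)
  expect_equal(pcc(c(2, 2, 2), c(1, 5, 3)), 0)
  expect_error(pcc(1:3, 1:4), "length")
})

test_that("proexp sums neighbor correlations, floors negatives, normalizes", {
  # triangle-free path a-b-c; construct expression so that raw sums are known
  ppi <- ppi_from_edges(rbind(c("a", "b"), c("b", "c")))
  expr <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5), c = c(4, 3, 2, 1))
  out <- proexp(ppi, expr)
  raw_a <- pcc(expr["a", ], expr["b", ])
  raw_b <- pcc(expr["b", ], expr["a", ]) + pcc(expr["b", ], expr["c", ])
  raw_c <- pcc(expr["c", ], expr["b", ])
  raw <- c(raw_a, raw_b, raw_c)
  raw[raw < 0] <- 0
  expect_equal(unname(out), raw / max(raw), tolerance = 1e-12)

  # isolated protein and protein without expression both get 0
  ppi2 <- ppi_from_edges(rbind(c("a", "b")), proteins = c("a", "b", "iso"))
  expect_equal(unname(proexp(ppi2, expr)["iso"]), 0)
  expect_equal(unname(proexp(ppi2, NULL)), c(0, 0, 0))
})

test_that("protri matches brute-force triangle enumeration", {
  # K3: each node has 2 neighbors, each sharing 1 common neighbor -> raw 1
  k3 <- ppi_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(unname(protri(k3, normalize = FALSE)), c(1, 1, 1))
  # star: no triangles -> all zero
  star <- ppi_from_edges(rbind(c("h", "l1"), c("h", "l2"), c("h", "l3")))
  expect_equal(unname(protri(star)), c(0, 0, 0, 0))
  # path: middle node has no triangles either
  path <- ppi_from_edges(rbind(c("a", "b"), c("b", "c")))
  expect_equal(unname(protri(path)), c(0, 0, 0))

  set.seed(31)
  for (rep in 1:10) {
    ppi <- random_ppi(sample(5:15, 1), runif(1, 0.2, 0.6))
    deg <- rowSums(ppi$adj)
    tri <- bf_triangles(ppi$adj)
    raw_expected <- unname(ifelse(deg > 0, 2 * tri / deg, 0))
    expect_equal(unname(protri(ppi, normalize = FALSE)), raw_expected,
                 tolerance = 1e-12)
  }
})

test_that("entropy weights: constant features lose all weight, weights sum to 1", {
  # one constant feature, one concentrated on a single protein -> (0, 1)
  bf <- cbind(flat = rep(0.5, 4), sharp = c(1, 0, 0, 0))
  ew <- entropy_weights(bf)
  expect_equal(unname(ew$entropy), c(1, 0))
  expect_equal(unname(ew$weights), c(0, 1))

  set.seed(32)
  for (rep in 1:10) {
    bf <- matrix(runif(15), 5, 3)
    ew <- entropy_weights(bf)
    expect_equal(sum(ew$weights), 1)
    expect_true(all(ew$weights >= 0))
    # permutation of proteins leaves weights unchanged
    expect_equal(entropy_weights(bf[sample(5), ])$weights, ew$weights)
  }

  # all features constant -> uniform fallback
  expect_equal(unname(entropy_weights(matrix(1, 3, 2))$weights), c(0.5, 0.5))
  expect_error(entropy_weights(matrix(c(-1, 1, 1, 1), 2, 2)), "nonnegative")
})

test_that("fusion and the initial-score blend behave at the limits", {
  bf <- rbind(c(0.2, 0.4, 0.6), c(1, 0, 0))
  expect_equal(unname(fuse_features(bf, c(0.5, 0.3, 0.2))[1]), 0.34)
  expect_equal(unname(fuse_features(bf, c(1, 0, 0))), bf[, 1])

  bio <- c(a = 0.2, b = 0.8); tri <- c(a = 0.6, b = 0.4)
  expect_equal(initial_score(bio, tri, 1, normalize = FALSE), bio)
  expect_equal(initial_score(bio, tri, 0, normalize = FALSE),
               c(a = 0.6, b = 0.4))
  expect_equal(sum(initial_score(bio, tri, 0.65)), 1)
  expect_error(initial_score(bio, tri, 1.2), "lambda")
})

test_that("feature_table produces [0,1] features and a sum-1 restart vector", {
  set.seed(33)
  sim <- simulate_data(n = 60, m_domains = 30, seed = 5)
  ft <- feature_table(sim$ppi, sim$annotations)
  for (col in c("ProOrt", "ProExp", "ProTri"))
    expect_true(all(ft$features[[col]] >= 0 & ft$features[[col]] <= 1))
  expect_true(all(ft$features$ProSub >= 0))
  expect_equal(sum(ft$proscore), 1)
  expect_equal(sum(ft$weights), 1)
})
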