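toy <- toy_pdi()

test_that("toy network reproduces the hand-traced recommendation values", {
  am <- toy$pdi$adjacency
  sm <- cf_similarity(am)
  expect_equal(sm["p1", "p2"], 0.5)
  expect_equal(sm["p1", "p3"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(sm["p1", "p4"], 0)

  rm_pd <- recommend_matrix(sm, am)
  expect_equal(rm_pd["p3", "d1"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(rm_pd["p3", "d1"], 2), 0.71)
  expect_equal(rm_pd["p2", "d2"], 0.5)

  std <- recommendation_standard(rm_pd)
  expect_equal(unname(std["d1"]), (1.5 + 1 / sqrt(2)) / 5, tolerance = 1e-12)
  expect_equal(round(unname(std["d1"]), 2), 0.44)

  uam <- apply_recommendations(rm_pd, std, am)
  added <- which(uam == 1 & am == 0, arr.ind = TRUE)
  added_pairs <- paste(rownames(am)[added[, 1]], colnames(am)[added[, 2]])
  expect_true(all(c("p3 d1", "p4 d1") %in% added_pairs))
  # p2 and p5 are not recommended to d2 (0.5 below that column's standard)
  expect_equal(uam["p5", "d2"], 0)
})

test_that("the merged toy matrix includes the domain-side addition (p1, d3)", {
  cf <- run_cf(toy$pdi)
  expect_equal(cf$mrm["p3", "d1"], 1)
  expect_equal(cf$mrm["p4", "d1"], 1)
  expect_equal(cf$mrm["p1", "d3"], 1)
  expect_true(all(cf$mrm >= toy$pdi$adjacency))
  expect_true(all(cf$provenance[toy$pdi$adjacency == 1] == "original"))
  expect_true(cf$provenance["p1", "d3"] %in% c("domain", "both"))
})

test_that("cooccurrence and similarity match set-based oracles on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    a <- random_bipartite(sample(2:8, 1), sample(2:8, 1), runif(1, 0.2, 0.7))
    expect_equal(unname(cooccurrence(a)), bf_cooccurrence(a))
    sm <- cf_similarity(a)
    expect_equal(sm, bf_similarity(a), tolerance = 1e-12)
    # structural invariants
    expect_equal(sm, t(sm))
    expect_true(all(diag(sm) == 0))
    expect_true(all(sm >= 0 & sm <= 1 + 1e-12))
    expect_equal(unname((sm > 0) * 1), bf_cooccurrence(a))
  }
})

test_that("recommend_matrix and standards match triple-loop oracles", {
  set.seed(43)
  for (rep in 1:20) {
    a <- random_bipartite(sample(2:8, 1), sample(2:8, 1))
    sm <- cf_similarity(a)
    rm <- recommend_matrix(sm, a)
    expect_equal(unname(rm), bf_matmul(sm, a), tolerance = 1e-12)
    expect_equal(unname(recommendation_standard(rm)),
                 unname(apply(rm, 2, function(col) sum(col) / length(col))),
                 tolerance = 1e-12)
  }
})

test_that("recommendation threshold is strict and never removes edges", {
  # entry exactly equal to the standard must NOT be added
  rm <- matrix(c(0.5, 0.5), 2, 1)
  adj <- matrix(0, 2, 1)
  expect_equal(apply_recommendations(rm, 0.5, adj), adj)
  # zero recommendations leave the adjacency untouched
  expect_equal(apply_recommendations(adj * 0, 0, adj), adj)
})

test_that("mutual recommendation is the logical OR of the two passes", {
  pd <- matrix(c(1, 0, 0, 1), 2, 2)
  dp <- matrix(c(1, 1, 0, 0), 2, 2)  # transpose = (1,0 / 1,0)
  mrm <- mutual_recommend(pd, dp)
  expect_equal(mrm, (pd + t(dp) > 0) * 1)
  expect_equal(mrm[1, 1], 1)  # both sides agree -> capped at 1
  expect_equal(mrm[1, 2], 1)  # domain side only
  expect_equal(mrm[2, 2], 1)  # protein side only
  expect_equal(mrm[2, 1], 0)  # neither side
  expect_error(mutual_recommend(matrix(0, 2, 3), matrix(0, 2, 3)), "transpose")
})

test_that("degenerate networks yield no recommendations", {
  # single edge: no pair shares a neighbor, all similarities 0
  single <- cfmm:::new_bipartite_net(c("a", "b"), c("x", "y"),
                                     matrix(c(1, 0, 0, 0), 2, 2))
  cf1 <- run_cf(single)
  expect_equal(cf1$mrm, single$adjacency)
  expect_equal(cf1$added, 0)

  # complete bipartite: nothing left to add
  full <- cfmm:::new_bipartite_net(c("a", "b"), c("x", "y"),
                                   matrix(1, 2, 2))
  expect_equal(run_cf(full)$mrm, full$adjacency)
})

test_that("CF is monotone and equivariant under relabeling", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    a <- random_bipartite(n, m)
    net <- cfmm:::new_bipartite_net(rownames(a), colnames(a), a)
    cf <- run_cf(net)
    expect_true(all(cf$mrm >= a))

    pp <- sample(n); pd <- sample(m)
    perm <- cfmm:::new_bipartite_net(rownames(a)[pp], colnames(a)[pd],
                                     a[pp, pd, drop = FALSE])
    cf_perm <- run_cf(perm)
    expect_equal(unname(cf_perm$mrm), unname(cf$mrm[pp, pd, drop = FALSE]))
  }
})
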