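ring_graph <- function(P, w = 1) {
  A <- matrix(0, P, P)
  for (i in seq_len(P)) {
    j <- i %% P + 1
    A[i, j] <- w; A[j, i] <- w
  }
  A
}

random_graph <- function(P, density = 0.5, seed = 1, signed = FALSE) {
  set.seed(seed)
  A <- matrix(0, P, P)
  up <- which(upper.tri(A))
  on <- sample(up, round(density * length(up)))
  A[on] <- runif(length(on), 0.1, 1) * if (signed)
    sample(c(-1, 1), length(on), replace = TRUE) else 1
  A + t(A)
}

test_that("onnela clustering matches brute-force triangle enumeration", {
  for (seed in 1:5) {
    A <- random_graph(12, 0.5, seed, signed = TRUE)
    W <- abs(A)
    Wn <- W / max(W)
    expect_lt(max(abs(weighted_clustering(A) - brute_onnela(Wn))), 1e-12)
  }
})

test_that("complete equal-weight graphs have clustering one, stars zero", {
  A <- matrix(0.7, 5, 5); diag(A) <- 0
  expect_equal(unname(weighted_clustering(A)), rep(1, 5))
  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  cc <- weighted_clustering(star)
  expect_equal(unname(cc), rep(0, 6))  # no triangles anywhere in a star
  # ring: neighbours of any node are never adjacent
  expect_equal(unname(weighted_clustering(ring_graph(8))), rep(0, 8))
})

test_that("equal-weight graphs reduce to the binary clustering coefficient", {
  for (seed in 6:8) {
    A <- random_graph(10, 0.4, seed) > 0
    A <- A * 0.37                          # all nonzero weights equal
    binA <- (A > 0) * 1
    tri <- diag(binA %*% binA %*% binA)
    k <- rowSums(binA)
    expected <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(unname(weighted_clustering(A)), expected)
  }
})

test_that("clustering is permutation-equivariant and bounded in [0,1]", {
  A <- random_graph(11, 0.5, seed = 9, signed = TRUE)
  cc <- weighted_clustering(A)
  expect_true(all(cc >= 0 & cc <= 1))
  set.seed(10)
  p <- sample(11)
  expect_equal(unname(weighted_clustering(A[p, p])), unname(cc)[p])
})

test_that("literal clustering variant follows its printed formula", {
  A <- random_graph(7, 0.6, seed = 11)
  Wn <- A / max(A)
  k <- rowSums(Wn > 0)
  expected <- ifelse(k >= 2, 2 * rowSums(Wn^(1 / 3)) / (k * (k - 1)), 0)
  expect_equal(unname(weighted_clustering(A, formula = "literal")), expected)
})

test_that("weight transforms and validity checks behave", {
  A <- random_graph(6, 0.8, seed = 12, signed = TRUE)
  expect_false(identical(weighted_clustering(A, weight_transform = "abs"),
                         weighted_clustering(A,
                                             weight_transform = "positive_only")))
  bad <- A; bad[1, 2] <- bad[1, 2] + 1  # asymmetric
  expect_error(weighted_clustering(bad), "symmetric")
})

test_that("node degree counts edges or sums weights", {
  empty <- matrix(0, 4, 4)
  expect_equal(unname(node_degree(empty)), rep(0, 4))
  comp <- matrix(1, 5, 5); diag(comp) <- 0
  expect_equal(unname(node_degree(comp, "binary")), rep(4, 5))
  expect_equal(unname(node_degree(comp, "strength")), rep(4, 5))
  A <- random_graph(9, 0.5, seed = 13, signed = TRUE)
  expect_equal(unname(node_degree(A, "strength")), rowSums(abs(A)))
})

test_that("hub score concentrates degree mass as designed", {
  # ten nodes: every node is in the top ten
  A <- random_graph(10, 0.6, seed = 14)
  expect_equal(hub_score(A)$hub_score, 100)
  # regular 20-node graph: top ten hold exactly half the mass
  expect_equal(suppressMessages(hub_score(ring_graph(20)))$hub_score, 50)
  # hand-built hub structure: node 1 connected to all, rest a chain
  P <- 20
  H <- matrix(0, P, P); H[1, 2:P] <- 1; H <- H + t(H)
  deg <- rowSums(H > 0)                # 19, then 1s
  ord <- order(-deg, seq_len(P))
  expected <- 100 * sum(deg[ord[1:10]]) / sum(deg)
  expect_equal(hub_score(H)$hub_score, expected)
  expect_identical(hub_score(H)$top_ids[1], 1L)
  # ties at the boundary resolve to lowest index
  expect_identical(hub_score(H)$top_ids[-1], 2:10)
  expect_error(hub_score(matrix(0, 12, 12)), "zero")
})

test_that("feature tables index samples by subject and window", {
  cs <- local({
    set.seed(15)
    mats <- lapply(1:3, function(m) lapply(1:4, function(k) {
      A <- symmetrize(matrix(rnorm(36), 6, 6)); diag(A) <- 0; A
    }))
    connectivity_set(mats, c("a", "b", "c"), c(0, 1, 0), stage = "wrt")
  })
  ft <- feature_table(cs)
  expect_identical(nrow(ft), 12L)
  expect_identical(ft$subject_id, rep(c("a", "b", "c"), each = 4))
  expect_identical(ft$window_id, rep(1:4, 3))
  expect_identical(ft$label, rep(c(0L, 1L, 0L), each = 4))
  expect_identical(colnames(ft)[-(1:3)], cs$region_ids)
  # subject_mean equals the explicit per-subject average
  fm <- feature_table(cs, aggregation = "subject_mean")
  expect_identical(nrow(fm), 3L)
  for (s in c("a", "b", "c")) {
    expect_equal(
      as.numeric(fm[fm$subject_id == s, -(1:3)]),
      unname(colMeans(ft[ft$subject_id == s, -(1:3)])))
  }
  # rebuilding gives the same table (stable ordering)
  expect_identical(ft, feature_table(cs))
})
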