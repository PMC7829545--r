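test_that("cohort simulation is bitwise deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_spec(n_per_group = 2, P = 8, V = 30,
                                   n_blocks = 2, seed = 5))
  b <- simulate_cohort(cohort_spec(n_per_group = 2, P = 8, V = 30,
                                   n_blocks = 2, seed = 5))
  expect_identical(a$subjects[[1]]$X, b$subjects[[1]]$X)
  expect_identical(a$subjects[[4]]$X, b$subjects[[4]]$X)
  d <- simulate_cohort(cohort_spec(n_per_group = 2, P = 8, V = 30,
                                   n_blocks = 2, seed = 6))
  expect_false(identical(a$subjects[[1]]$X, d$subjects[[1]]$X))
})

test_that("group difference in population correlation is the planted delta", {
  edges <- pick_effect_edges(12, 3, 4, seed = 1)
  spec <- cohort_spec(n_per_group = 2, P = 12, V = 30, n_blocks = 3,
                      effect_edges = edges, effect_delta = 0.3, seed = 1)
  co <- cohort_correlations(spec)
  D <- co$R1 - co$R0
  planted <- matrix(0, 12, 12)
  for (r in seq_len(nrow(edges))) {
    planted[edges[r, 1], edges[r, 2]] <- 0.3
    planted[edges[r, 2], edges[r, 1]] <- 0.3
  }
  expect_lt(max(abs(D - planted)), 1e-6)
})

test_that("within-block sample correlation converges to the target", {
  spec <- cohort_spec(n_per_group = 1, P = 10, V = 5000, n_blocks = 2,
                      within_r = 0.6, between_r = 0.1, noise_sd = 0,
                      seed = 8)
  co <- simulate_cohort(spec)
  R <- cor(t(co$subjects[[1]]$X))
  blocks <- sort(rep_len(1:2, 10))
  within <- R[outer(blocks, blocks, "==") & row(R) != col(R)]
  between <- R[outer(blocks, blocks, "!=")]
  expect_lt(abs(mean(within) - 0.6), 0.02)
  expect_lt(abs(mean(between) - 0.1), 0.02)
})

test_that("no-effect cohorts show no group difference on effect edges", {
  edges <- pick_effect_edges(12, 3, 4, seed = 2)
  spec <- cohort_spec(n_per_group = 10, P = 12, V = 120, n_blocks = 3,
                      effect_edges = edges, effect_delta = 0, seed = 2)
  co <- simulate_cohort(spec)
  z <- sapply(co$subjects, function(s) {
    R <- cor(t(s$X))
    atanh(mean(R[edges]))
  })
  lab <- sapply(co$subjects, function(s) s$label)
  p <- t.test(z[lab == 0], z[lab == 1], var.equal = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("non-PSD targets are rejected with a diagnostic", {
  # three effect edges on one region at delta close to 1 break PSD
  edges <- rbind(c(1, 4), c(1, 5), c(1, 6))
  spec <- cohort_spec(n_per_group = 2, P = 9, V = 30, n_blocks = 3,
                      effect_edges = edges, effect_delta = 0.85, seed = 1)
  expect_error(simulate_cohort(spec), "not positive semidefinite")
})

test_that("degree-capped effect edges stay between blocks and disjoint", {
  edges <- pick_effect_edges(20, 4, 8, seed = 3)
  blocks <- sort(rep_len(1:4, 20))
  expect_identical(nrow(edges), 8L)
  expect_true(all(blocks[edges[, 1]] != blocks[edges[, 2]]))
  expect_identical(anyDuplicated(as.vector(edges)), 0L)
  expect_error(pick_effect_edges(10, 2, 8, seed = 1), "degree cap")
})

test_that("AR(1) signals carry the requested autocorrelation", {
  spec <- cohort_spec(n_per_group = 1, P = 4, V = 4000, n_blocks = 1,
                      within_r = 0.5, noise_sd = 0, ar = 0.6, seed = 9)
  co <- simulate_cohort(spec)
  x <- co$subjects[[1]]$X[1, ]
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.6), 0.05)
})

test_that("low-rank sparse tensors have the advertised structure", {
  spec <- lowrank_sparse_spec(dims = c(20, 20, 10), tubal_rank = 3,
                              sparsity = 0.05, seed = 4)
  sim <- simulate_lowrank_sparse_tensor(spec)
  # planted sparse support size is exact
  expect_identical(sum(sim$E_true != 0), 200L)
  expect_equal(sim$W, sim$Omega_true + sim$E_true)
  # every mode-3 Fourier frontal slice of the low-rank part has rank <= 3,
  # checked through an independent per-tube FFT
  Af <- array(0 + 0i, dim(sim$Omega_true))
  for (i in 1:20) for (j in 1:20) {
    Af[i, j, ] <- fft(sim$Omega_true[i, j, ])
  }
  for (k in 1:10) {
    expect_lte(sum(svd(Af[, , k])$d > 1e-8), 3)
  }
})

test_that("zero sparsity gives an uncorrupted tensor, deterministically", {
  spec <- lowrank_sparse_spec(dims = c(10, 10, 4), tubal_rank = 2,
                              sparsity = 0, seed = 5)
  sim <- simulate_lowrank_sparse_tensor(spec)
  expect_identical(sim$W, sim$Omega_true)
  expect_true(all(sim$E_true == 0))
  sim2 <- simulate_lowrank_sparse_tensor(spec)
  expect_identical(sim$W, sim2$W)
})
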