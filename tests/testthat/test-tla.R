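test_that("nuclear prox with one slice is plain matrix SVT", {
  set.seed(1)
  A <- matrix(rnorm(15 * 15), 15, 15)
  got <- tensor_nuclear_prox(array(A, c(15, 15, 1)), 0.7)[, , 1]
  s <- svd(A)
  svt <- s$u %*% (pmax(s$d - 0.7, 0) * t(s$v))
  expect_lt(max(abs(got - svt)), 1e-12)
})

test_that("nuclear prox limits: huge tau annihilates, tiny tau is identity", {
  set.seed(2)
  A <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  big <- max(abs(fft(A))) * 10    # above any Fourier singular value
  expect_true(all(tensor_nuclear_prox(A, big) == 0))
  expect_lt(max(abs(tensor_nuclear_prox(A, 1e-14) - A)), 1e-12)
})

test_that("L1 shrinkage matches the scalar rule on flattened input", {
  set.seed(3)
  A <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_identical(shrink_l1(A, 0), A)
  expect_true(all(shrink_l1(A, max(abs(A)) + 1) == 0))
  expect_equal(as.vector(shrink_l1(A, 0.3)),
               soft_threshold(as.vector(A), 0.3))
})

test_that("default gamma follows the configured rule", {
  expect_equal(default_gamma(90, 90, 60, "inv_sqrt_nk"), 1 / sqrt(5400))
  expect_equal(default_gamma(90, 90, 60, "literal_inv_nk"), 1 / 5400)
  expect_equal(default_gamma(90, 90, 60, "literal_inv_nk", value = 0.3), 0.3)
})

make_tiny_set <- function(P = 4, K = 3, M = 2, seed = 11) {
  set.seed(seed)
  mats <- lapply(seq_len(M), function(m) {
    lapply(seq_len(K), function(k) {
      A <- symmetrize(matrix(rnorm(P * P), P, P))
      diag(A) <- 0
      A
    })
  })
  connectivity_set(mats, sprintf("s%d", seq_len(M)),
                   labels = rep_len(0:1, M), stage = "wr")
}

test_that("stacking bookkeeping and round-trip are lossless", {
  cs <- make_tiny_set()
  per <- stack_tensor(cs, "per_window")
  expect_length(per, 3)
  expect_identical(dim(per[[1]]$W), c(4L, 4L, 2L))
  expect_identical(per[[2]]$W[, , 2], cs$arr[, , 2, 2])
  all_st <- stack_tensor(cs, "all_slabs")
  expect_identical(dim(all_st$W), c(4L, 4L, 6L))
  # subject-major slab order: slabs 1..3 are subject 1, windows 1..3
  expect_identical(all_st$slab_index$subject_id, rep(c("s1", "s2"), each = 3))
  expect_identical(all_st$slab_index$window_id, rep(1:3, 2))
  expect_identical(all_st$W[, , 5], cs$arr[, , 2, 2])
  # round-trips
  back1 <- unstack_tensor(per, cs, stage = "wr")
  back2 <- unstack_tensor(all_st, cs, stage = "wr")
  expect_equal(back1$arr, cs$arr)
  expect_equal(back2$arr, cs$arr)
})

test_that("clean low-rank input is returned as Omega with E ~ 0", {
  sim <- simulate_lowrank_sparse_tensor(
    lowrank_sparse_spec(dims = c(12, 12, 4), tubal_rank = 2, sparsity = 0,
                        seed = 6))
  fit <- trpca_admm(sim$W, admm_config(gamma = 5))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$Omega - sim$W)), 1e-6)
  expect_lt(max(abs(fit$E)), 1e-6)
})

test_that("planted low-rank + sparse structure is recovered", {
  sim <- simulate_lowrank_sparse_tensor(
    lowrank_sparse_spec(dims = c(12, 12, 4), tubal_rank = 2,
                        sparsity = 0.05, seed = 7))
  fit <- trpca_admm(sim$W)
  expect_true(fit$converged)
  rel <- sqrt(sum((fit$Omega - sim$Omega_true)^2) / sum(sim$Omega_true^2))
  expect_lt(rel, 1e-3)
  # recovered sparse support covers the planted support
  expect_true(all(fit$E[sim$E_true != 0] != 0))
  # feasibility at convergence
  expect_lte(max(abs(fit$Omega + fit$E - sim$W)), 1e-8)
  # constraint residual ends no larger than it started
  res <- fit$residuals[, "constraint"]
  expect_lte(res[length(res)], res[1])
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  sim <- simulate_lowrank_sparse_tensor(
    lowrank_sparse_spec(dims = c(8, 8, 3), tubal_rank = 2, sparsity = 0.1,
                        seed = 8))
  expect_warning(fit <- trpca_admm(sim$W, admm_config(max_iter = 3)),
                 "did not converge")
  expect_false(fit$converged)
  expect_identical(fit$iterations, 3L)
})

test_that("symmetric zero-diagonal slices stay symmetric through the ADMM", {
  cs <- make_tiny_set(P = 6, K = 1, M = 5, seed = 12)
  st <- stack_tensor(cs, "per_window")[[1]]
  fit <- trpca_admm(st)
  for (k in 1:5) {
    expect_lt(max(abs(fit$Omega[, , k] - t(fit$Omega[, , k]))), 1e-8)
    expect_lt(max(abs(fit$E[, , k] - t(fit$E[, , k]))), 1e-8)
  }
  expect_identical(fit$slab_index$subject_id, cs$subject_ids)
})

test_that("tla_denoise rebuilds a wrt-stage set aligned with its input", {
  cs <- make_tiny_set(P = 5, K = 2, M = 4, seed = 13)
  den <- tla_denoise(cs, admm_config(), "per_window")
  expect_identical(den$networks$stage, "wrt")
  expect_identical(dim(den$networks$arr), dim(cs$arr))
  expect_length(den$fits, 2)
  # low-rank part plus sparse part reproduces the input per window
  rebuilt <- den$fits[[1]]$Omega + den$fits[[1]]$E
  expect_lt(max(abs(rebuilt - stack_tensor(cs, "per_window")[[1]]$W)), 1e-7)
})
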