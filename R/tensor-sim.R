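#' Specification of a low-rank-plus-sparse test tensor
#'
#' @param dims Integer vector `(n1, n2, n3)`.
#' @param tubal_rank Target tubal rank, `<= min(n1, n2)`.
#' @param sparsity Fraction of corrupted entries in `[0, 1)`.
#' @param magnitude Corruption amplitude (entries are `+-magnitude`).
#' @param seed RNG seed.
#' @return An object of class `"lowrank_sparse_spec"`.
#' @export
lowrank_sparse_spec <- function(dims = c(20L, 20L, 10L), tubal_rank = 3L,
                                sparsity = 0.05, magnitude = 1, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  tubal_rank <- as.integer(tubal_rank)
  if (tubal_rank < 1L || tubal_rank > min(dims[1], dims[2])) {
    stop("tubal_rank must lie in 1..min(n1, n2) = ", min(dims[1], dims[2]))
  }
  if (!(sparsity >= 0 && sparsity < 1)) stop("sparsity must lie in [0, 1)")
  stopifnot(magnitude > 0)
  structure(
    list(dims = dims, tubal_rank = tubal_rank, sparsity = sparsity,
         magnitude = magnitude, seed = as.integer(seed)),
    class = "lowrank_sparse_spec"
  )
}

#' Simulate a low-rank tensor with sparse corruption
#'
#' The low-rank component is the t-product of two Gaussian factor tensors
#' (`n1 x r x n3` and `r x n2 x n3`, scaled by `1/sqrt(r * n3)` so entries
#' are O(1)), which has tubal rank at most `r`: every mode-3 Fourier
#' frontal slice has matrix rank `<= r`. The sparse component places
#' exactly `round(sparsity * n1 * n2 * n3)` entries of value
#' `+-magnitude` at uniformly random positions. Deterministic for a fixed
#' spec.
#'
#' @param spec A [lowrank_sparse_spec()].
#' @return List with `W` (observed tensor), `Omega_true` (low-rank),
#'   `E_true` (sparse), and the `spec`.
#' @export
simulate_lowrank_sparse_tensor <- function(spec) {
  stopifnot(inherits(spec, "lowrank_sparse_spec"))
  d <- spec$dims
  r <- spec$tubal_rank
  set.seed(spec$seed)
  A <- array(stats::rnorm(d[1] * r * d[3]), c(d[1], r, d[3]))
  B <- array(stats::rnorm(r * d[2] * d[3]), c(r, d[2], d[3]))
  Omega <- tprod(A, B) / sqrt(r * d[3])
  n <- prod(d)
  m <- round(spec$sparsity * n)
  E <- array(0, d)
  if (m < 1) {
    if (spec$sparsity > 0) {
      message("requested sparsity yields < 1 corrupted entry; E_true is zero")
    }
  } else {
    pos <- sample.int(n, m)
    E[pos] <- spec$magnitude * sample(c(-1, 1), m, replace = TRUE)
  }
  list(W = Omega + E, Omega_true = Omega, E_true = E, spec = spec)
}
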