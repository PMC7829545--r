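#' Weighted-regularization configuration
#'
#' Controls the weighted-L1 shrinkage applied to each window's Pearson
#' matrix. The penalty on edge (i, j) is `lam * c_ij` with
#' `c_ij = exp(-w_ij^2 / sigma)`, so strong correlations are shrunk less.
#'
#' @param lam Regularization parameter, `lam > 0`. The reference operating
#'   point in this framework is `lam = 0.2`.
#' @param sigma_rule How sigma is estimated from the Pearson matrix:
#'   `"std_abs_all"` (population SD of |entries| over the full matrix,
#'   diagonal included — the literal rule) or `"std_abs_offdiag"`
#'   (off-diagonal entries only, both triangles).
#' @param sample_sd Use the sample (n-1) rather than population SD.
#' @param prox_half_factor If `TRUE`, threshold at `lam * c_ij / 2`
#'   (the convention arising from a 1/2 factor on the fitting term) instead
#'   of the plain `lam * c_ij`.
#' @param zero_diagonal Zero the diagonal of the solved network
#'   (self-connections are not edges).
#' @return An object of class `"wr_config"`.
#' @export
wr_config <- function(lam = 0.2,
                      sigma_rule = c("std_abs_all", "std_abs_offdiag"),
                      sample_sd = FALSE,
                      prox_half_factor = FALSE,
                      zero_diagonal = TRUE) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("lam must be a single finite number > 0, got ", lam)
  }
  structure(
    list(lam = lam,
         sigma_rule = match.arg(sigma_rule),
         sample_sd = isTRUE(sample_sd),
         prox_half_factor = isTRUE(prox_half_factor),
         zero_diagonal = isTRUE(zero_diagonal)),
    class = "wr_config"
  )
}

#' Decay-scale sigma from a correlation matrix
#'
#' `sigma` is the standard deviation of the absolute values of the matrix
#' entries; it sets how fast the penalty weight `c_ij = exp(-w_ij^2/sigma)`
#' decays with connection strength. The default scans every entry of the
#' matrix (diagonal included); `std_abs_offdiag` scans the off-diagonal
#' entries of both triangles.
#'
#' @param W Finite numeric matrix (typically a Pearson matrix).
#' @param rule `"std_abs_all"` or `"std_abs_offdiag"`.
#' @param sample_sd Use the sample (n-1) SD instead of the population SD.
#' @return Scalar `sigma > 0`.
#' @export
estimate_sigma <- function(W, rule = c("std_abs_all", "std_abs_offdiag"),
                           sample_sd = FALSE) {
  rule <- match.arg(rule)
  W <- as.matrix(W)
  if (anyNA(W) || any(!is.finite(W))) stop("W must be finite")
  vals <- abs(if (rule == "std_abs_all") as.vector(W) else W[row(W) != col(W)])
  n <- length(vals)
  if (n < 2L) stop("need at least two entries to estimate sigma")
  v <- sum((vals - mean(vals))^2) / (if (isTRUE(sample_sd)) n - 1L else n)
  sigma <- sqrt(v)
  if (sigma == 0) {
    stop("sigma is zero: |entries| of the correlation matrix are constant, ",
         "weighted penalties are undefined")
  }
  sigma
}

#' Connection-strength penalty weights
#'
#' `c_ij = exp(-w_ij^2 / sigma)`: entries in `(0, 1]`, decreasing in
#' `|w_ij|`, so strong connections receive small penalties.
#'
#' @param W Correlation matrix.
#' @param sigma Positive decay scale, typically from [estimate_sigma()].
#' @return List with the `P x P` weight matrix `C` and the `sigma` used.
#' @export
connection_weights <- function(W, sigma) {
  W <- as.matrix(W)
  if (anyNA(W) || any(!is.finite(W))) stop("W must be finite")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single finite number > 0, got ", sigma)
  }
  list(C = exp(-W^2 / sigma), sigma = sigma)
}

#' Elementwise soft-thresholding
#'
#' `sgn(x) * max(|x| - tau, 0)`, the proximal operator of the (weighted)
#' L1 norm. `tau` may be a scalar or an array conformable with `x`.
#'
#' @param x Numeric vector, matrix or array.
#' @param tau Non-negative threshold(s).
#' @return Object shaped like `x`.
#' @export
soft_threshold <- function(x, tau) {
  if (any(tau < 0)) stop("threshold tau must be >= 0")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Weighted-regularization shrinkage of a Pearson matrix
#'
#' Solves `min_A ||A - W||_F^2 + lam * sum_ij c_ij |a_ij|` for one window's
#' Pearson matrix `W`, with `c_ij = exp(-w_ij^2 / sigma)` computed once from
#' `W` itself. The objective is elementwise separable, so the solution is
#' the closed-form weighted soft-threshold
#' `a_ij = sgn(w_ij) * max(|w_ij| - lam * c_ij, 0)` — the exact fixed point
#' of proximal-gradient iteration on the same objective.
#'
#' @param W `P x P` Pearson matrix.
#' @param cfg A [wr_config()].
#' @return `P x P` shrunk network matrix (diagonal zeroed when configured).
#' @examples
#' W <- pearson_matrix(matrix(rnorm(80), 4, 20))
#' A <- solve_wr(W, wr_config(lam = 0.2))
#' all(abs(A) <= abs(W) + 1e-15)
#' @export
solve_wr <- function(W, cfg = wr_config()) {
  stopifnot(inherits(cfg, "wr_config"))
  W <- as.matrix(W)
  sigma <- estimate_sigma(W, cfg$sigma_rule, cfg$sample_sd)
  C <- connection_weights(W, sigma)$C
  thr <- cfg$lam * C
  if (cfg$prox_half_factor) thr <- thr / 2
  A <- soft_threshold(W, thr)
  if (cfg$zero_diagonal) diag(A) <- 0
  dimnames(A) <- dimnames(W)
  A
}

#' Symmetrize a matrix
#'
#' `(W + t(W)) / 2`; idempotent on symmetric input. Regularized network
#' estimates are symmetrized unconditionally before stacking.
#'
#' @param W Square numeric matrix.
#' @return Symmetric matrix of the same dimension.
#' @export
symmetrize <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  (W + t(W)) / 2
}
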