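# Order-3 tensor primitives in the t-SVD convention: the tensor is
# transformed by a DFT along mode 3, operated on slice-by-slice in the
# Fourier domain, and transformed back.

#' @noRd
tensor_fft <- function(A, inverse = FALSE) {
  d <- dim(A)
  M <- matrix(A, d[1] * d[2], d[3])
  Ft <- t(stats::mvfft(t(M), inverse = inverse))
  if (inverse) Ft <- Ft / d[3]
  array(Ft, d)
}

#' @noRd
as_real_tensor <- function(A, tol = 1e-8) {
  im <- max(abs(Im(A)))
  if (im > tol) {
    warning("discarding imaginary residue of magnitude ", format(im))
  }
  array(Re(A), dim(A))
}

#' Tensor t-product
#'
#' Multiplies two order-3 tensors slice-by-slice in the mode-3 Fourier
#' domain (circular convolution along mode 3 in the original domain).
#' Dimensions must satisfy `n2(A) == n1(B)` and equal mode-3 length.
#'
#' @param A `n1 x r x n3` tensor (numeric array).
#' @param B `r x n2 x n3` tensor.
#' @return `n1 x n2 x n3` tensor.
#' @export
tprod <- function(A, B) {
  da <- dim(A); db <- dim(B)
  stopifnot(length(da) == 3, length(db) == 3, da[2] == db[1], da[3] == db[3])
  Af <- tensor_fft(A)
  Bf <- tensor_fft(B)
  Cf <- array(0 + 0i, c(da[1], db[2], da[3]))
  for (k in seq_len(da[3])) {
    Cf[, , k] <- Af[, , k] %*% Bf[, , k]
  }
  as_real_tensor(tensor_fft(Cf, inverse = TRUE), tol = 1e-6)
}

#' Proximal map of the tensor nuclear norm
#'
#' Computes the unique minimizer of `tau * ||X||_* + 0.5 * ||X - A||_F^2`
#' under the t-SVD tensor nuclear norm: DFT along mode 3, singular-value
#' soft-thresholding of every Fourier-domain frontal slice at `tau`,
#' inverse DFT. Conjugate-symmetric slices are mirrored so the output is
#' exactly real up to round-off (imaginary residue below `1e-10` is
#' discarded). With `n3 = 1` this is plain matrix singular-value
#' thresholding.
#'
#' @param A Numeric `n1 x n2 x n3` array.
#' @param tau Positive threshold.
#' @return Array of the same dimensions.
#' @export
tensor_nuclear_prox <- function(A, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a single finite number > 0")
  }
  if (anyNA(A) || any(!is.finite(A))) stop("A must be finite")
  d <- dim(A)
  stopifnot(length(d) == 3)
  Af <- tensor_fft(A)
  half <- d[3] %/% 2L + 1L
  for (k in seq_len(half)) {
    s <- svd(Af[, , k])
    dshr <- pmax(s$d - tau, 0)
    keep <- dshr > 0
    slice <- if (!any(keep)) {
      matrix(0 + 0i, d[1], d[2])
    } else {
      s$u[, keep, drop = FALSE] %*%
        (dshr[keep] * Conj(t(s$v[, keep, drop = FALSE])))
    }
    Af[, , k] <- slice
    j <- d[3] - k + 2L
    if (j >= 1L && j <= d[3] && j != k) Af[, , j] <- Conj(slice)
  }
  as_real_tensor(tensor_fft(Af, inverse = TRUE), tol = 1e-10)
}

#' Elementwise L1 shrinkage of a tensor
#'
#' Soft-thresholds every entry at `tau` — the proximal map of
#' `tau * ||.||_1`. Shares its scalar rule with [soft_threshold()].
#'
#' @param A Numeric array.
#' @param tau Threshold, `tau >= 0`.
#' @return Array like `A`.
#' @export
shrink_l1 <- function(A, tau) {
  soft_threshold(A, tau)
}

#' Default sparsity weight for tensor robust PCA
#'
#' The weight `gamma` balancing the L1 term against the tensor nuclear
#' norm. `"inv_sqrt_nk"` is `1 / sqrt(max(n1, n2) * n3)`, the standard
#' robust-PCA rate; `"literal_inv_nk"` is `1 / (n1 * n3)`, the literal
#' reading of the printed 1/(N x K) rule. An explicit `value` overrides
#' both.
#'
#' @param n1,n2,n3 Tensor dimensions.
#' @param rule `"inv_sqrt_nk"` or `"literal_inv_nk"`.
#' @param value Optional explicit gamma.
#' @return Scalar gamma.
#' @export
default_gamma <- function(n1, n2, n3,
                          rule = c("inv_sqrt_nk", "literal_inv_nk"),
                          value = NULL) {
  if (!is.null(value)) {
    stopifnot(is.numeric(value), value > 0)
    return(value)
  }
  stopifnot(n1 >= 1, n2 >= 1, n3 >= 1)
  switch(match.arg(rule),
         inv_sqrt_nk = 1 / sqrt(max(n1, n2) * n3),
         literal_inv_nk = 1 / (n1 * n3))
}

#' ADMM configuration for tensor robust PCA
#'
#' @param gamma Explicit sparsity weight; overrides `gamma_rule`.
#' @param gamma_rule Rule for [default_gamma()] when `gamma` is `NULL`.
#' @param mu0 Initial augmented-Lagrangian penalty.
#' @param rho Penalty growth factor per iteration, `rho >= 1`.
#' @param mu_max Penalty cap.
#' @param tol Convergence tolerance on the three max-norm residuals.
#' @param max_iter Iteration cap.
#' @return An object of class `"admm_config"`.
#' @export
admm_config <- function(gamma = NULL,
                        gamma_rule = c("inv_sqrt_nk", "literal_inv_nk"),
                        mu0 = 1e-3, rho = 1.1, mu_max = 1e10,
                        tol = 1e-8, max_iter = 500L) {
  stopifnot(mu0 > 0, rho >= 1, mu_max >= mu0, tol > 0, max_iter >= 1)
  if (!is.null(gamma)) stopifnot(is.numeric(gamma), gamma > 0)
  structure(
    list(gamma = gamma, gamma_rule = match.arg(gamma_rule),
         mu0 = mu0, rho = rho, mu_max = mu_max, tol = tol,
         max_iter = as.integer(max_iter)),
    class = "admm_config"
  )
}

#' Tensor robust principal component analysis by ADMM
#'
#' Splits an order-3 tensor `W` into a low-rank component `Omega` (t-SVD
#' tensor nuclear norm) and a sparse component `E` (weighted L1) by solving
#' `min ||Omega||_* + gamma ||E||_1  s.t.  W = Omega + E` with the
#' alternating direction method of multipliers:
#' `Omega <- prox_*(W - E - Y/mu, 1/mu)`,
#' `E <- shrink_l1(W - Omega - Y/mu, gamma/mu)`,
#' `Y <- Y + mu (Omega + E - W)`, `mu <- min(rho mu, mu_max)`,
#' starting from `Omega = E = Y = 0` and stopping when the max-norms of
#' the Omega step, the E step and the constraint violation all fall below
#' `tol` (or at `max_iter`, returned with `converged = FALSE` and a
#' warning — never silently).
#'
#' @param W Numeric `n1 x n2 x n3` array, or a `stacked_tensor` from
#'   [stack_tensor()].
#' @param cfg An [admm_config()].
#' @return An object of class `"trpca"`: `Omega`, `E`, `gamma`,
#'   `iterations`, `residuals` (iterations x 3 matrix: Omega step, E step,
#'   constraint), `converged`, and `slab_index` when input was stacked.
#' @examples
#' sim <- simulate_lowrank_sparse_tensor(
#'   lowrank_sparse_spec(dims = c(12, 12, 4), tubal_rank = 2,
#'                       sparsity = 0.05, seed = 3))
#' fit <- trpca_admm(sim$W, admm_config())
#' fit$converged
#' @export
trpca_admm <- function(W, cfg = admm_config()) {
  stopifnot(inherits(cfg, "admm_config"))
  slab_index <- NULL
  if (inherits(W, "stacked_tensor")) {
    slab_index <- W$slab_index
    W <- W$W
  }
  d <- dim(W)
  stopifnot(length(d) == 3)
  if (anyNA(W) || any(!is.finite(W))) stop("W must be finite")
  gamma <- default_gamma(d[1], d[2], d[3], cfg$gamma_rule, cfg$gamma)
  Omega <- array(0, d)
  E <- array(0, d)
  Y <- array(0, d)
  mu <- cfg$mu0
  res <- matrix(NA_real_, cfg$max_iter, 3,
                dimnames = list(NULL, c("omega_step", "e_step", "constraint")))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    Omega_new <- tensor_nuclear_prox(W - E - Y / mu, 1 / mu)
    E_new <- shrink_l1(W - Omega_new - Y / mu, gamma / mu)
    viol <- Omega_new + E_new - W
    Y <- Y + mu * viol
    res[it, ] <- c(max(abs(Omega_new - Omega)), max(abs(E_new - E)),
                   max(abs(viol)))
    Omega <- Omega_new
    E <- E_new
    mu <- min(cfg$rho * mu, cfg$mu_max)
    if (all(res[it, ] <= cfg$tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("trpca_admm did not converge in ", cfg$max_iter,
            " iterations (final residuals: ",
            paste(format(res[it, ], digits = 3), collapse = ", "), ")")
  }
  structure(
    list(Omega = Omega, E = E, gamma = gamma, iterations = it,
         residuals = res[seq_len(it), , drop = FALSE],
         converged = converged, slab_index = slab_index),
    class = "trpca"
  )
}

#' @export
print.trpca <- function(x, ...) {
  d <- dim(x$Omega)
  cat(sprintf(
    "tensor RPCA decomposition: %d x %d x %d, gamma = %.4g\n",
    d[1], d[2], d[3], x$gamma))
  cat(sprintf("  %d iterations, converged: %s, sparse support: %d entries\n",
              x$iterations, x$converged, sum(x$E != 0)))
  invisible(x)
}

#' Collection of per-(subject, window) connectivity matrices
#'
#' @param mats List over subjects of lists over windows of `P x P`
#'   matrices (equal window count per subject).
#' @param subject_ids,labels Per-subject metadata (parallel to `mats`).
#' @param stage Provenance tag: `"pc"` (Pearson), `"wr"` (weighted
#'   regularization), or `"wrt"` (after tensor low-rank approximation).
#' @param region_ids Optional region names.
#' @return An object of class `"connectivity_set"` holding a
#'   `P x P x K x M` array.
#' @export
connectivity_set <- function(mats, subject_ids, labels,
                             stage = c("pc", "wr", "wrt"),
                             region_ids = NULL) {
  stage <- match.arg(stage)
  M <- length(mats)
  stopifnot(M >= 1, length(subject_ids) == M, length(labels) == M)
  K <- length(mats[[1]])
  Ps <- unique(unlist(lapply(mats, function(m) lapply(m, nrow))))
  if (length(Ps) != 1L) {
    stop("inconsistent region count across connectivity matrices: ",
         paste(Ps, collapse = ", "))
  }
  P <- Ps[[1]]
  if (any(vapply(mats, length, 1L) != K)) {
    stop("all subjects must have the same number of windows")
  }
  if (is.null(region_ids)) {
    region_ids <- rownames(mats[[1]][[1]])
    if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(P))
  }
  arr <- array(NA_real_, c(P, P, K, M))
  for (m in seq_len(M)) for (k in seq_len(K)) arr[, , k, m] <- mats[[m]][[k]]
  structure(
    list(arr = arr, subject_ids = as.character(subject_ids),
         labels = as.integer(labels), region_ids = region_ids,
         stage = stage, P = P, K = K, M = M),
    class = "connectivity_set"
  )
}

#' @export
print.connectivity_set <- function(x, ...) {
  cat(sprintf(
    "connectivity set [%s]: %d subjects x %d windows of %d x %d matrices\n",
    x$stage, x$M, x$K, x$P, x$P))
  invisible(x)
}

#' Stack connectivity matrices into order-3 tensors
#'
#' `per_window` yields one `P x P x M` tensor per window (subjects along
#' mode 3): the grouping that shares topology across subjects within a
#' time window. `all_slabs` yields a single `P x P x (M*K)` tensor with
#' slabs ordered subject-major (all windows of subject 1, then subject 2,
#' ...). `slab_index` records the (subject, window) of every slab so the
#' stack is losslessly invertible by [unstack_tensor()].
#'
#' @param networks A [connectivity_set()].
#' @param grouping `"per_window"` or `"all_slabs"`.
#' @return For `per_window`, a list of `K` objects of class
#'   `"stacked_tensor"`; for `all_slabs`, a single such object.
#' @export
stack_tensor <- function(networks, grouping = c("per_window", "all_slabs")) {
  stopifnot(inherits(networks, "connectivity_set"))
  grouping <- match.arg(grouping)
  if (grouping == "per_window") {
    lapply(seq_len(networks$K), function(k) {
      structure(
        list(W = array(networks$arr[, , k, ],
                       c(networks$P, networks$P, networks$M)),
             slab_index = data.frame(slab = seq_len(networks$M),
                                     subject_id = networks$subject_ids,
                                     window_id = k,
                                     stringsAsFactors = FALSE),
             grouping = grouping),
        class = "stacked_tensor")
    })
  } else {
    n3 <- networks$M * networks$K
    W <- array(NA_real_, c(networks$P, networks$P, n3))
    subj <- character(n3)
    win <- integer(n3)
    slab <- 0L
    for (m in seq_len(networks$M)) {
      for (k in seq_len(networks$K)) {
        slab <- slab + 1L
        W[, , slab] <- networks$arr[, , k, m]
        subj[slab] <- networks$subject_ids[m]
        win[slab] <- k
      }
    }
    structure(
      list(W = W,
           slab_index = data.frame(slab = seq_len(n3), subject_id = subj,
                                   window_id = win, stringsAsFactors = FALSE),
           grouping = grouping),
      class = "stacked_tensor")
  }
}

#' Rebuild a connectivity set from stacked tensors
#'
#' Inverse of [stack_tensor()]: routes each slab of the given tensor(s)
#' back to its (subject, window) cell using `slab_index`.
#'
#' @param tensors A `stacked_tensor` (or list of them, one per window),
#'   or arrays paired with `slab_index` data frames of the same shape.
#' @param template The original [connectivity_set()] (for subject order,
#'   labels and region ids).
#' @param stage Provenance tag for the rebuilt set.
#' @return A [connectivity_set()].
#' @export
unstack_tensor <- function(tensors, template, stage = "wrt") {
  stopifnot(inherits(template, "connectivity_set"))
  if (inherits(tensors, "stacked_tensor")) tensors <- list(tensors)
  arr <- array(NA_real_, c(template$P, template$P, template$K, template$M))
  for (tns in tensors) {
    for (r in seq_len(nrow(tns$slab_index))) {
      m <- match(tns$slab_index$subject_id[r], template$subject_ids)
      k <- tns$slab_index$window_id[r]
      arr[, , k, m] <- tns$W[, , tns$slab_index$slab[r]]
    }
  }
  if (anyNA(arr)) stop("unstack_tensor: slab index does not cover all cells")
  out <- template
  out$arr <- arr
  out$stage <- stage
  out
}

#' Apply tensor low-rank approximation to a connectivity set
#'
#' Stacks the networks per `grouping`, runs [trpca_admm()] on each stacked
#' tensor, and rebuilds a connectivity set from the low-rank components —
#' each subject's denoised network sequence.
#'
#' @param networks A [connectivity_set()] (typically stage `"wr"`).
#' @param cfg An [admm_config()].
#' @param grouping Passed to [stack_tensor()].
#' @return List with `networks` (stage `"wrt"` [connectivity_set()]) and
#'   `fits` (list of [trpca_admm()] results).
#' @export
tla_denoise <- function(networks, cfg = admm_config(),
                        grouping = c("per_window", "all_slabs")) {
  grouping <- match.arg(grouping)
  stacks <- stack_tensor(networks, grouping)
  if (inherits(stacks, "stacked_tensor")) stacks <- list(stacks)
  fits <- lapply(stacks, trpca_admm, cfg = cfg)
  lows <- Map(function(st, ft) {
    st$W <- ft$Omega
    st
  }, stacks, fits)
  list(networks = unstack_tensor(lows, networks, stage = "wrt"),
       fits = fits)
}
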