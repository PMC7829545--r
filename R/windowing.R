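#' Sliding-window configuration
#'
#' Bundles the window width `N` and step size `S` (both in time points) used
#' to slice a full-length regional time series into overlapping segments.
#' With `V` time points the number of windows is
#' `K = floor((V - N) / S) + 1`; trailing time points that do not fill a
#' whole window are dropped.
#'
#' @param N Window width in time points (`N >= 2`).
#' @param S Step size in time points (`S >= 1`).
#' @return An object of class `"window_config"`.
#' @examples
#' cfg <- window_config(N = 70, S = 1)
#' count_windows(137, cfg)
#' @export
window_config <- function(N, S = 1L) {
  N <- as.integer(N)
  S <- as.integer(S)
  if (is.na(N) || N < 2L) {
    stop("window width N must be an integer >= 2, got ", N)
  }
  if (is.na(S) || S < 1L) {
    stop("step size S must be an integer >= 1, got ", S)
  }
  structure(list(N = N, S = S), class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("sliding-window config: width N = %d, step S = %d\n", x$N, x$S))
  invisible(x)
}

#' Number of sliding windows
#'
#' For a series of `V` time points, width `N` and step `S`, the number of
#' windows is `floor((V - N) / S) + 1`.
#'
#' @param V Number of time points in the full series.
#' @param cfg A [window_config()].
#' @return Integer window count `K >= 1`.
#' @export
count_windows <- function(V, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  V <- as.integer(V)
  if (cfg$N > V) {
    stop(sprintf("window width N = %d exceeds series length V = %d", cfg$N, V))
  }
  as.integer((V - cfg$N) %/% cfg$S + 1L)
}

#' A single subject's regional time series
#'
#' @param subject_id Subject identifier (scalar character).
#' @param label Group label, 0 (control / negative) or 1 (case / positive),
#'   or `NA` when unknown.
#' @param X Numeric `P x V` matrix, regions in rows and time points in
#'   columns. Row names, when present, are taken as region ids.
#' @return An object of class `"subject_series"`.
#' @export
subject_series <- function(subject_id, label, X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    stop("time series for subject '", subject_id,
         "' must be finite numeric with no missing values")
  }
  if (is.null(rownames(X))) {
    rownames(X) <- sprintf("R%03d", seq_len(nrow(X)))
  }
  if (!is.na(label) && !label %in% c(0, 1)) {
    stop("label must be 0, 1 or NA, got ", label)
  }
  structure(
    list(subject_id = as.character(subject_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         X = X),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("subject '%s' (label %s): %d regions x %d time points\n",
              x$subject_id, ifelse(is.na(x$label), "?", x$label),
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Slice a series into overlapping windows
#'
#' Window `k` (1-based in the returned list) covers the half-open time-index
#' range `[(k-1) * S, (k-1) * S + N)` in 0-based coordinates, i.e. columns
#' `((k-1) * S + 1):((k-1) * S + N)` of `X`.
#'
#' @param series A [subject_series()] or a plain `P x V` matrix.
#' @param cfg A [window_config()].
#' @return List of `K` matrices, each `P x N`.
#' @export
slice_windows <- function(series, cfg) {
  X <- if (inherits(series, "subject_series")) series$X else as.matrix(series)
  K <- count_windows(ncol(X), cfg)
  lapply(seq_len(K), function(k) {
    start <- (k - 1L) * cfg$S + 1L
    X[, start:(start + cfg$N - 1L), drop = FALSE]
  })
}

#' Pearson correlation matrix of one window
#'
#' Each region row is mean-centred and scaled to unit Euclidean norm; the
#' cross-product of the normalized rows is then exactly the sample Pearson
#' correlation matrix: symmetric, unit diagonal, entries in `[-1, 1]`.
#'
#' @param window `P x N` matrix (regions x time points within the window).
#' @param window_id Optional window identifier used in error messages.
#' @return `P x P` correlation matrix.
#' @export
pearson_matrix <- function(window, window_id = NA) {
  X <- as.matrix(window)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop(sprintf(
      "zero-variance region(s) %s in window %s: Pearson correlation undefined",
      paste(rownames(X)[bad], collapse = ", "),
      ifelse(is.na(window_id), "?", window_id)))
  }
  Xn <- Xc / nrm
  W <- tcrossprod(Xn)
  # clamp round-off excursions beyond [-1, 1]
  W[W > 1] <- 1
  W[W < -1] <- -1
  diag(W) <- 1
  dimnames(W) <- list(rownames(X), rownames(X))
  W
}
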