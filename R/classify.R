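# Feature screening, confusion/ROC metrics, and the repeated stratified
# cross-validation harness around a linear SVM.

#' Two-sample t-test feature screening
#'
#' Tests every feature for a mean difference between class 0 and class 1
#' training samples (pooled-variance t by default — Welch optional) and
#' keeps those with `p < alpha`. No multiple-testing correction is
#' applied: the screen is a filter, not an inference. An empty selection
#' falls back to the single smallest-p feature (with a message), so the
#' classifier always has input. Constant features get `p = 1`.
#'
#' @param x Samples-by-features numeric matrix, or a
#'   [feature_table()] data frame.
#' @param y Optional 0/1 labels (taken from the `label` column when `x`
#'   is a feature table).
#' @param alpha Significance level.
#' @param var_equal Pooled-variance t (`TRUE`, default) or Welch.
#' @return List of class `"selection_result"`: `selected` (feature
#'   indices), `pvalues`, `tstat`, `alpha`, `fallback` (flag).
#' @export
ttest_select <- function(x, y = NULL, alpha = 0.05, var_equal = TRUE) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; t-test screening undefined")
  }
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  i0 <- y == 0L
  n0 <- sum(i0); n1 <- sum(!i0)
  m0 <- colMeans(x[i0, , drop = FALSE])
  m1 <- colMeans(x[!i0, , drop = FALSE])
  v0 <- apply(x[i0, , drop = FALSE], 2, stats::var)
  v1 <- apply(x[!i0, , drop = FALSE], 2, stats::var)
  if (var_equal) {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2, length(se))
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  tstat[!is.finite(tstat)] <- 0
  selected <- which(p < alpha)
  fallback <- FALSE
  if (!length(selected)) {
    selected <- which.min(p)
    fallback <- TRUE
    message("no feature passed the ", alpha,
            " screen; falling back to the smallest-p feature")
  }
  structure(
    list(selected = unname(selected), pvalues = unname(p),
         tstat = unname(tstat), alpha = alpha, fallback = fallback),
    class = "selection_result"
  )
}

#' Confusion-matrix classification metrics
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. Class 1 (the cases) is positive.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Named numeric vector `(ACC, SEN, SPE)`, each in `[0, 1]`.
#'   A metric whose denominator is empty (no positives for SEN, no
#'   negatives for SPE) is `NA` with a warning; an entirely empty table
#'   is an error.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("empty confusion table")
  sen <- if (tp + fn == 0) {
    warning("no positive samples: sensitivity undefined")
    NA_real_
  } else tp / (tp + fn)
  spe <- if (tn + fp == 0) {
    warning("no negative samples: specificity undefined")
    NA_real_
  } else tn / (tn + fp)
  c(ACC = (tp + tn) / total, SEN = sen, SPE = spe)
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a uniformly random positive sample
#' outscores a uniformly random negative one, ties counted one half —
#' identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric decision values (larger = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
stratified_folds <- function(strata, folds) {
  # strata: per-unit label vector; returns per-unit fold ids 1..folds
  fold <- integer(length(strata))
  for (g in unique(strata)) {
    idx <- which(strata == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' @noRd
svm_positive_scores <- function(model, newdata) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cn <- colnames(dv)[1]
  first <- strsplit(cn, "/", fixed = TRUE)[[1]][1]
  score <- if (identical(first, "1")) dv[, 1] else -dv[, 1]
  list(pred = as.integer(as.character(pr)), score = as.numeric(score))
}

#' Repeated stratified cross-validation of the SVM classifier
#'
#' For each of `reps` repetitions: draw a stratified `folds`-fold split
#' (by sample, or by subject when `group_by_subject` so all windows of a
#' subject share a fold); in each fold, screen features by [ttest_select()]
#' on the training rows only, fit a linear SVM (cost `cost`) on the
#' selected features, and score the held-out rows. Fold
#' predictions are pooled into one confusion table and one AUC per
#' repetition; the report gives each metric's mean and SD over
#' repetitions. A training fold missing a class triggers a fold re-draw
#' (up to 20 attempts, with a message). Fully deterministic for a fixed
#' seed.
#'
#' Note: with per-window samples and `group_by_subject = FALSE`, windows
#' of one subject land in both training and test folds, so the estimate
#' includes subject-identity leakage; subject-grouped folds give the
#' honest generalization estimate.
#'
#' @param features A [feature_table()] (or data frame with `subject_id`,
#'   `label` and feature columns).
#' @param folds,reps Fold count and repetition count.
#' @param alpha Screening level for [ttest_select()].
#' @param cost Linear-SVM cost parameter C.
#' @param scale_features Standardize features inside the SVM (the usual
#'   LIBSVM practice; disable for raw-feature fidelity).
#' @param seed RNG seed for fold assignment.
#' @param group_by_subject Keep all windows of a subject in one fold.
#' @param var_equal Passed to [ttest_select()].
#' @return An object of class `"cv_report"`: `per_rep` data frame of
#'   (ACC, SEN, SPE, AUC), `folds` (per-repetition fold assignments),
#'   `mean`, `sd`, `selection_counts` (how often each feature was
#'   selected across all folds), and the settings.
#' @export
cross_validate <- function(features, folds = 10L, reps = 10L, alpha = 0.05,
                           cost = 1, seed = 1L, group_by_subject = FALSE,
                           var_equal = TRUE, scale_features = TRUE) {
  y <- as.integer(features$label)
  X <- feature_matrix(features)
  subj <- as.character(features$subject_id)
  folds <- as.integer(folds); reps <- as.integer(reps)
  if (min(table(y)) < folds && !group_by_subject) {
    stop("need at least `folds` samples per class")
  }
  if (group_by_subject) {
    usub <- unique(subj)
    ulab <- y[match(usub, subj)]
    if (min(table(ulab)) < folds) {
      stop("need at least `folds` subjects per class for grouped folds")
    }
  }
  set.seed(seed)
  per_rep <- matrix(NA_real_, reps, 4,
                    dimnames = list(NULL, c("ACC", "SEN", "SPE", "AUC")))
  sel_counts <- integer(ncol(X))
  names(sel_counts) <- colnames(X)
  fold_log <- vector("list", reps)
  for (r in seq_len(reps)) {
    for (attempt in seq_len(20L)) {
      if (group_by_subject) {
        usub <- unique(subj)
        ulab <- y[match(usub, subj)]
        sfold <- stratified_folds(ulab, folds)
        fold <- sfold[match(subj, usub)]
      } else {
        fold <- stratified_folds(y, folds)
      }
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(y[fold != f])) == 2L && sum(fold == f) > 0L
      }, logical(1)))
      if (ok) break
      message("fold draw left a training fold single-class; re-drawing")
    }
    if (!ok) stop("could not draw valid folds after 20 attempts")
    fold_log[[r]] <- fold
    pred <- integer(length(y))
    score <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      te <- !tr
      sel <- ttest_select(X[tr, , drop = FALSE], y[tr], alpha, var_equal)
      sel_counts[sel$selected] <- sel_counts[sel$selected] + 1L
      dtr <- as.data.frame(X[tr, sel$selected, drop = FALSE])
      dte <- as.data.frame(X[te, sel$selected, drop = FALSE])
      model <- e1071::svm(x = dtr, y = factor(y[tr], levels = c(0, 1)),
                          kernel = "linear", cost = cost,
                          scale = scale_features)
      out <- svm_positive_scores(model, dte)
      pred[te] <- out$pred
      score[te] <- out$score
    }
    tp <- sum(pred == 1L & y == 1L)
    tn <- sum(pred == 0L & y == 0L)
    fp <- sum(pred == 1L & y == 0L)
    fn <- sum(pred == 0L & y == 1L)
    per_rep[r, 1:3] <- confusion_metrics(tp, tn, fp, fn)
    per_rep[r, 4] <- auc_score(score, y)
  }
  per_rep <- as.data.frame(per_rep)
  structure(
    list(per_rep = per_rep,
         folds = fold_log,
         mean = colMeans(per_rep),
         sd = apply(per_rep, 2, stats::sd),
         selection_counts = sel_counts,
         settings = list(folds = folds, reps = reps, alpha = alpha,
                         cost = cost, seed = seed,
                         group_by_subject = group_by_subject,
                         var_equal = var_equal,
                         scale_features = scale_features,
                         n_samples = length(y),
                         n_features = ncol(X))),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  s <- x$settings
  cat(sprintf(
    "%d-fold cross-validation, %d repetitions (%d samples, %d features%s)\n",
    s$folds, s$reps, s$n_samples, s$n_features,
    if (s$group_by_subject) ", subject-grouped folds" else ""))
  fmt <- function(m, sdv, pct) {
    if (pct) sprintf("%.*f%% ± %.*f%%", digits, 100 * m, digits, 100 * sdv)
    else sprintf("%.4f ± %.4f", m, sdv)
  }
  cat("  ACC ", fmt(x$mean["ACC"], x$sd["ACC"], TRUE), "\n", sep = "")
  cat("  SEN ", fmt(x$mean["SEN"], x$sd["SEN"], TRUE), "\n", sep = "")
  cat("  SPE ", fmt(x$mean["SPE"], x$sd["SPE"], TRUE), "\n", sep = "")
  cat("  AUC ", fmt(x$mean["AUC"], x$sd["AUC"], FALSE), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cv_report <- function(x, ...) {
  data.frame(metric = colnames(x$per_rep),
             mean = unname(x$mean), sd = unname(x$sd))
}
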