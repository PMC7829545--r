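#' Fit the full WRTLA dynamic-network classification pipeline
#'
#' Runs, for a whole cohort of labelled subjects: sliding-window Pearson
#' correlation ([pearson_matrix()]), weighted-regularization shrinkage of
#' every window network ([solve_wr()] followed by [symmetrize()]),
#' cross-subject tensor robust PCA ([trpca_admm()]) to share low-rank
#' topology across subjects, weighted clustering-coefficient features
#' ([feature_table()]), and repeated cross-validated linear-SVM
#' classification with t-test screening ([cross_validate()]).
#'
#' @param cohort A `wrtla_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]) or a list of [subject_series()].
#' @param window A [window_config()].
#' @param wr A [wr_config()].
#' @param admm An [admm_config()]; ignored when `use_tla = FALSE`.
#' @param grouping Tensor grouping, see [stack_tensor()].
#' @param use_tla Run the tensor low-rank stage (`FALSE` gives the
#'   WR-only ablation).
#' @param formula,weight_transform,aggregation Feature settings, see
#'   [feature_table()].
#' @param folds,reps,alpha,cost,group_by_subject,var_equal CV settings,
#'   see [cross_validate()].
#' @param seed RNG seed for the cross-validation fold draws.
#' @param keep_networks Keep the stage-wise connectivity sets on the
#'   returned object (memory-hungry for large cohorts).
#' @return An object of class `"wrtla"` with components `cv`
#'   (a `cv_report`), `features`, `selection_freq` (per-region selection
#'   frequency across CV folds), `admm` (per-tensor iteration/convergence
#'   diagnostics), `networks` (when kept), `mean_network` (grand mean of
#'   the final-stage networks), and `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(
#'   n_per_group = 6, P = 12, V = 40, n_blocks = 3,
#'   effect_edges = pick_effect_edges(12, 3, 5, seed = 2),
#'   effect_delta = 0.4, seed = 2))
#' fit <- wrtla(cohort, window = window_config(25, 5),
#'              folds = 3, reps = 2, seed = 2)
#' print(fit)
#' }
#' @export
wrtla <- function(cohort,
                  window = window_config(60, 10),
                  wr = wr_config(lam = 0.2),
                  admm = admm_config(),
                  grouping = c("per_window", "all_slabs"),
                  use_tla = TRUE,
                  formula = c("onnela", "literal"),
                  weight_transform = c("abs", "positive_only"),
                  aggregation = c("per_window", "subject_mean"),
                  folds = 10L, reps = 10L, alpha = 0.05, cost = 1,
                  group_by_subject = FALSE, var_equal = TRUE,
                  seed = 1L, keep_networks = FALSE) {
  grouping <- match.arg(grouping)
  formula <- match.arg(formula)
  weight_transform <- match.arg(weight_transform)
  aggregation <- match.arg(aggregation)
  subjects <- if (inherits(cohort, "wrtla_cohort")) cohort$subjects else cohort
  stopifnot(length(subjects) >= 2L)
  networks <- build_wr_networks(subjects, window, wr)
  fits <- NULL
  if (use_tla) {
    den <- tla_denoise(networks, admm, grouping)
    final <- den$networks
    fits <- den$fits
  } else {
    final <- networks
  }
  features <- feature_table(final, formula, weight_transform, aggregation)
  cv <- cross_validate(features, folds = folds, reps = reps, alpha = alpha,
                       cost = cost, seed = seed,
                       group_by_subject = group_by_subject,
                       var_equal = var_equal)
  nfolds_total <- folds * reps
  admm_diag <- if (is.null(fits)) NULL else data.frame(
    tensor = seq_along(fits),
    iterations = vapply(fits, function(f) f$iterations, 1L),
    converged = vapply(fits, function(f) f$converged, TRUE),
    final_constraint = vapply(
      fits, function(f) f$residuals[nrow(f$residuals), "constraint"], 1))
  structure(
    list(cv = cv,
         features = features,
         selection_freq = cv$selection_counts / nfolds_total,
         admm = admm_diag,
         networks = if (keep_networks) final else NULL,
         mean_network = apply(final$arr, c(1, 2), mean),
         region_ids = final$region_ids,
         config = list(window = window, wr = wr, admm = admm,
                       grouping = grouping, use_tla = use_tla,
                       formula = formula,
                       weight_transform = weight_transform,
                       aggregation = aggregation, folds = folds,
                       reps = reps, alpha = alpha, cost = cost,
                       group_by_subject = group_by_subject,
                       var_equal = var_equal, seed = seed)),
    class = "wrtla"
  )
}

#' @noRd
build_wr_networks <- function(subjects, window, wr) {
  mats <- lapply(subjects, function(s) {
    wins <- slice_windows(s, window)
    lapply(seq_along(wins), function(k) {
      symmetrize(solve_wr(pearson_matrix(wins[[k]], window_id = k), wr))
    })
  })
  connectivity_set(
    mats,
    subject_ids = vapply(subjects, function(s) s$subject_id, ""),
    labels = vapply(subjects, function(s) s$label, 0L),
    stage = "wr",
    region_ids = rownames(subjects[[1]]$X))
}

#' @export
print.wrtla <- function(x, ...) {
  cfg <- x$config
  cat("WRTLA dynamic functional network fit\n")
  cat(sprintf("  window width %d, step %d; lambda = %g; TLA: %s (%s)\n",
              cfg$window$N, cfg$window$S, cfg$wr$lam,
              ifelse(cfg$use_tla, "yes", "no"), cfg$grouping))
  print(x$cv)
  invisible(x)
}

#' @export
summary.wrtla <- function(object, n_regions = 10L, ...) {
  freq <- sort(object$selection_freq, decreasing = TRUE)
  top <- utils::head(freq[freq > 0], n_regions)
  out <- list(cv = object$cv, top_regions = top, admm = object$admm,
              config = object$config)
  class(out) <- "summary.wrtla"
  out
}

#' @export
print.summary.wrtla <- function(x, ...) {
  print(x$cv)
  cat("\nmost frequently selected regions (fraction of CV folds):\n")
  for (nm in names(x$top_regions)) {
    cat(sprintf("  %-8s %.2f\n", nm, x$top_regions[[nm]]))
  }
  if (!is.null(x$admm)) {
    cat(sprintf("\nADMM: %d tensor(s), %d/%d converged, median %d iterations\n",
                nrow(x$admm), sum(x$admm$converged), nrow(x$admm),
                as.integer(stats::median(x$admm$iterations))))
  }
  invisible(x)
}

#' Per-region discriminability coefficients
#'
#' Returns, for each region feature, the pooled t statistic computed on
#' the full feature table together with its CV selection frequency.
#'
#' @param object A fitted [wrtla()] object.
#' @param ... Unused.
#' @return Data frame with columns `region`, `tstat`, `pvalue`,
#'   `selection_freq`, ordered by |t|.
#' @export
coef.wrtla <- function(object, ...) {
  sel <- ttest_select(object$features, alpha = 1,
                      var_equal = object$config$var_equal)
  out <- data.frame(region = feature_columns(object$features),
                    tstat = sel$tstat, pvalue = sel$pvalues,
                    selection_freq = unname(object$selection_freq))
  out[order(-abs(out$tstat)), ]
}

#' Plot method for WRTLA fits
#'
#' `which = "metrics"` draws per-repetition boxplots of ACC/SEN/SPE/AUC;
#' `which = "network"` draws the grand-mean final-stage network as an
#' image with regions in index order.
#'
#' @param x A fitted [wrtla()] object.
#' @param which `"metrics"` or `"network"`.
#' @param ... Passed to the underlying graphics call.
#' @export
plot.wrtla <- function(x, which = c("metrics", "network"), ...) {
  which <- match.arg(which)
  if (which == "metrics") {
    graphics::boxplot(x$cv$per_rep, ylim = c(0, 1),
                      ylab = "value per repetition",
                      main = "cross-validated classification metrics", ...)
  } else {
    A <- x$mean_network
    graphics::image(seq_len(nrow(A)), seq_len(ncol(A)), A,
                    xlab = "region", ylab = "region",
                    main = "grand-mean network", useRaster = TRUE, ...)
  }
  invisible(x)
}

#' Predict group labels for new samples
#'
#' Refits the screening and the linear SVM on the full training feature
#' table of the fit, then scores new samples. `newdata` must be a feature
#' table with the same region columns (labels, if present, are ignored).
#'
#' @param object A fitted [wrtla()] object.
#' @param newdata A [feature_table()] or data frame of features.
#' @param ... Unused.
#' @return Data frame with `subject_id`, `window_id`, predicted `label`
#'   and decision `score` (positive favours class 1).
#' @export
predict.wrtla <- function(object, newdata, ...) {
  cfg <- object$config
  X <- feature_matrix(object$features)
  y <- as.integer(object$features$label)
  sel <- ttest_select(X, y, cfg$alpha, cfg$var_equal)
  model <- e1071::svm(x = as.data.frame(X[, sel$selected, drop = FALSE]),
                      y = factor(y, levels = c(0, 1)),
                      kernel = "linear", cost = cfg$cost, scale = FALSE)
  cols <- feature_columns(object$features)
  missing <- setdiff(cols, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks feature columns: ", paste(missing, collapse = ", "))
  }
  Xn <- as.matrix(newdata[, cols, drop = FALSE])
  out <- svm_positive_scores(
    model, as.data.frame(Xn[, sel$selected, drop = FALSE]))
  data.frame(
    subject_id = if ("subject_id" %in% colnames(newdata))
      newdata$subject_id else NA_character_,
    window_id = if ("window_id" %in% colnames(newdata))
      newdata$window_id else NA_integer_,
    label = out$pred, score = out$score)
}
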