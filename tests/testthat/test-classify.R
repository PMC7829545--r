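make_features <- function(n_per_class = 20, P = 6, shift = 0, seed = 1,
                          windows = 2) {
  set.seed(seed)
  n <- 2 * n_per_class * windows
  lab <- rep(rep(0:1, each = n_per_class), times = windows)
  subj <- rep(sprintf("s%02d", seq_len(2 * n_per_class)), times = windows)
  X <- matrix(rnorm(n * P), n, P)
  X[lab == 1, 1] <- X[lab == 1, 1] + shift
  colnames(X) <- sprintf("R%03d", seq_len(P))
  out <- data.frame(subject_id = subj,
                    window_id = rep(seq_len(windows), each = 2 * n_per_class),
                    label = lab, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  class(out) <- c("wrtla_features", "data.frame")
  out
}

test_that("t screening keeps shifted features and drops identical ones", {
  ft <- make_features(n_per_class = 50, P = 5, shift = 5, seed = 2,
                      windows = 1)
  sel <- ttest_select(ft)
  expect_true(1 %in% sel$selected)
  # a feature constant across all samples is never selected
  X <- feature_matrix(ft)
  X[, 4] <- 1
  sel2 <- ttest_select(X, ft$label)
  expect_false(4 %in% sel2$selected)
  expect_equal(sel2$pvalues[4], 1)
})

test_that("pooled-variance t matches a hand-worked 4 + 4 example", {
  x0 <- c(1.1, 0.9, 1.3, 0.7)   # class 0
  x1 <- c(2.0, 1.6, 2.4, 1.8)   # class 1
  m0 <- mean(x0); m1 <- mean(x1)
  sp2 <- (3 * var(x0) + 3 * var(x1)) / 6
  t_hand <- (m1 - m0) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  sel <- ttest_select(matrix(c(x0, x1), ncol = 1), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(sel$tstat[1], t_hand, tolerance = 1e-12)
  expect_equal(sel$pvalues[1], p_hand, tolerance = 1e-12)
  # agrees with stats::t.test as an independent implementation
  expect_equal(sel$pvalues[1],
               t.test(x1, x0, var.equal = TRUE)$p.value, tolerance = 1e-12)
})

test_that("screening rejects single-class input and falls back when empty", {
  ft <- make_features(windows = 1)
  expect_error(ttest_select(feature_matrix(ft), rep(1, nrow(ft))),
               "single class")
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, 10)
  sel <- suppressMessages(ttest_select(X, y, alpha = 1e-12))
  expect_true(sel$fallback)
  expect_length(sel$selected, 1)
  expect_identical(sel$selected, which.min(sel$pvalues))
})

test_that("confusion metrics reproduce their defining ratios", {
  m <- confusion_metrics(9, 8, 2, 1)
  expect_equal(unname(m), c(0.85, 0.90, 0.80))
  m2 <- suppressWarnings(confusion_metrics(7, 0, 0, 0))
  expect_equal(m2[["ACC"]], 1)
  expect_equal(m2[["SEN"]], 1)
  expect_true(is.na(m2[["SPE"]]))
  expect_warning(confusion_metrics(0, 5, 2, 0), "sensitivity")
  expect_warning(confusion_metrics(5, 0, 0, 2), "specificity")
  expect_error(confusion_metrics(-1, 1, 1, 1), ">= 0")
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("accuracy decomposes over sensitivity and specificity", {
  set.seed(4)
  for (i in 1:20) {
    cnt <- rpois(4, 5) + 1
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    lhs <- m[["ACC"]] * sum(cnt)
    rhs <- m[["SEN"]] * (cnt[1] + cnt[4]) + m[["SPE"]] * (cnt[2] + cnt[3])
    expect_equal(lhs, rhs)
  }
})

test_that("AUC equals exhaustive pair counting, with ties at half", {
  expect_equal(auc_score(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc_score(c(11, 12, 13, 1, 2, 3), c(0, 0, 0, 1, 1, 1)), 0)
  set.seed(5)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    scores <- sample(1:4, n, replace = TRUE)   # plenty of ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc_score(scores, labels), allpairs_auc(scores, labels))
  }
  expect_error(auc_score(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("random scores give near-chance AUC", {
  set.seed(6)
  auc <- auc_score(rnorm(4000), rep(0:1, 2000))
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("cross-validation is deterministic and bounded", {
  ft <- make_features(n_per_class = 15, shift = 1.5, seed = 7)
  a <- cross_validate(ft, folds = 5, reps = 3, seed = 9)
  b <- cross_validate(ft, folds = 5, reps = 3, seed = 9)
  expect_identical(a$per_rep, b$per_rep)
  expect_identical(a$folds, b$folds)
  expect_true(all(as.matrix(a$per_rep) >= 0 & as.matrix(a$per_rep) <= 1))
  d <- cross_validate(ft, folds = 5, reps = 3, seed = 10)
  expect_false(identical(a$per_rep, d$per_rep))
})

test_that("a separable feature yields near-perfect CV metrics", {
  ft <- make_features(n_per_class = 20, shift = 8, seed = 8)
  cv <- cross_validate(ft, folds = 5, reps = 2, seed = 1)
  expect_gt(cv$mean[["ACC"]], 0.95)
  expect_gt(cv$mean[["AUC"]], 0.99)
  # the informative feature dominates the selections
  expect_identical(unname(which.max(cv$selection_counts)), 1L)
})

test_that("feature selection uses training rows only (no leakage)", {
  ft <- make_features(n_per_class = 15, shift = 1.2, seed = 11)
  cv <- cross_validate(ft, folds = 5, reps = 1, seed = 3)
  fold <- cv$folds[[1]]
  X <- feature_matrix(ft)
  y <- ft$label
  for (f in 1:5) {
    tr <- fold != f
    base <- ttest_select(X[tr, ], y[tr])$selected
    # removing any held-out row leaves the fold's selection unchanged
    drop <- which(!tr)[1]
    keep <- setdiff(seq_along(y), drop)
    again <- ttest_select(X[keep, ][fold[keep] != f, ],
                          y[keep][fold[keep] != f])$selected
    expect_identical(base, again)
  }
})

test_that("subject-grouped folds never split a subject", {
  ft <- make_features(n_per_class = 12, shift = 1, seed = 12, windows = 3)
  cv <- cross_validate(ft, folds = 4, reps = 2, seed = 5,
                       group_by_subject = TRUE)
  for (fold in cv$folds) {
    expect_true(all(tapply(fold, ft$subject_id,
                           function(z) length(unique(z))) == 1))
  }
  expect_error(cross_validate(make_features(n_per_class = 3, windows = 2),
                              folds = 4, group_by_subject = TRUE),
               "subjects per class")
})

test_that("stratified folds balance classes within each fold", {
  ft <- make_features(n_per_class = 20, shift = 0, seed = 13)
  cv <- cross_validate(ft, folds = 4, reps = 1, seed = 6)
  fold <- cv$folds[[1]]
  tab <- table(fold, ft$label)
  expect_true(all(tab == 10))   # 40 per class over 4 folds
})
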