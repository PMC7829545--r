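# Staged, resumable on-disk pipeline: simulate -> construct (window + WR)
# -> tla -> features -> classify. Every stage writes its output (plus a
# ".done" marker) before the next begins, so a rerun resumes from the
# last completed stage and, given the same seed, reproduces the same
# results bit for bit.

#' Pipeline configuration
#'
#' Gathers every stage's settings plus the output directory and seed.
#' The resolved configuration round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]) and is logged
#' into the run summary.
#'
#' @param cohort A [cohort_spec()] (to simulate) or a directory of series
#'   files written by [write_cohort()].
#' @param out_dir Run directory for all stage outputs.
#' @param window,wr,admm Stage configs.
#' @param grouping,use_tla Tensor stage settings, see [wrtla()].
#' @param formula,weight_transform,aggregation Feature settings.
#' @param folds,reps,alpha,cost,group_by_subject,var_equal CV settings.
#' @param seed Seed for the CV fold draws.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort, out_dir,
                            window = window_config(60, 10),
                            wr = wr_config(lam = 0.2),
                            admm = admm_config(),
                            grouping = "per_window", use_tla = TRUE,
                            formula = "onnela", weight_transform = "abs",
                            aggregation = "per_window",
                            folds = 10L, reps = 10L, alpha = 0.05,
                            cost = 1, group_by_subject = FALSE,
                            var_equal = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec") || is.character(cohort))
  structure(
    list(cohort = cohort, out_dir = out_dir, window = window, wr = wr,
         admm = admm, grouping = grouping, use_tla = isTRUE(use_tla),
         formula = formula, weight_transform = weight_transform,
         aggregation = aggregation, folds = as.integer(folds),
         reps = as.integer(reps), alpha = alpha, cost = cost,
         group_by_subject = isTRUE(group_by_subject),
         var_equal = isTRUE(var_equal), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write a pipeline configuration as JSON
#' @param cfg A [pipeline_config()].
#' @param path Output file.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  plain$cohort_kind <- if (inherits(cfg$cohort, "cohort_spec"))
    "spec" else "dir"
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pipeline configuration written by [write_pipeline_config()]
#' @param path JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- if (identical(raw$cohort_kind, "spec")) {
    sp <- raw$cohort
    cohort_spec(n_per_group = sp$n_per_group, P = sp$P, V = sp$V,
                n_blocks = sp$n_blocks, within_r = sp$within_r,
                between_r = sp$between_r,
                effect_edges = if (is.null(sp$effect_edges)) NULL
                  else matrix(as.integer(unlist(sp$effect_edges)),
                              ncol = 2),
                effect_delta = sp$effect_delta, noise_sd = sp$noise_sd,
                ar = sp$ar, seed = sp$seed)
  } else {
    raw$cohort
  }
  pipeline_config(
    cohort = cohort, out_dir = raw$out_dir,
    window = window_config(raw$window$N, raw$window$S),
    wr = wr_config(raw$wr$lam, raw$wr$sigma_rule, raw$wr$sample_sd,
                   raw$wr$prox_half_factor, raw$wr$zero_diagonal),
    admm = admm_config(gamma = raw$admm$gamma,
                       gamma_rule = raw$admm$gamma_rule,
                       mu0 = raw$admm$mu0, rho = raw$admm$rho,
                       mu_max = raw$admm$mu_max, tol = raw$admm$tol,
                       max_iter = raw$admm$max_iter),
    grouping = raw$grouping, use_tla = raw$use_tla,
    formula = raw$formula, weight_transform = raw$weight_transform,
    aggregation = raw$aggregation, folds = raw$folds, reps = raw$reps,
    alpha = raw$alpha, cost = raw$cost,
    group_by_subject = raw$group_by_subject, var_equal = raw$var_equal,
    seed = raw$seed)
}

#' @noRd
stage_done <- function(dir) file.exists(file.path(dir, ".done"))

#' @noRd
mark_done <- function(dir) {
  writeLines(format(Sys.time()), file.path(dir, ".done"))
}

#' @noRd
stage_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the staged pipeline on disk
#'
#' Executes simulate -> construct -> tla -> features -> classify,
#' writing each stage under `cfg$out_dir` (`cohort/`, `wr/`, `wrt/`,
#' `features.csv`, `cv_report.json`, `summary.json`). Completed stages
#' (marker file present) are reloaded rather than recomputed, so a run
#' is resumable from any stage; given the same config and seed, a
#' resumed run equals a full rerun.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The [cross_validate()] report, invisibly; all artifacts on
#'   disk.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(cfg, file.path(out, "config.json"))

  # stage: cohort
  cohort_dir <- if (is.character(cfg$cohort)) {
    cfg$cohort
  } else {
    cd <- file.path(out, "cohort")
    if (!stage_done(cd)) {
      t0 <- Sys.time()
      write_cohort(simulate_cohort(cfg$cohort), cd)
      mark_done(cd)
      stage_log(quiet, "[cohort] simulated and wrote %d subjects (%.1fs)",
                2 * cfg$cohort$n_per_group,
                as.numeric(Sys.time() - t0, units = "secs"))
    } else stage_log(quiet, "[cohort] reusing completed stage")
    cd
  }
  cohort <- read_cohort(cohort_dir)

  # stage: construct (windowing + WR)
  wr_dir <- file.path(out, "wr")
  if (!stage_done(wr_dir)) {
    t0 <- Sys.time()
    networks <- build_wr_networks(cohort$subjects, cfg$window, cfg$wr)
    write_connectivity_set(networks, wr_dir)
    mark_done(wr_dir)
    stage_log(quiet, "[construct] %d x %d WR networks (%.1fs)",
              networks$M, networks$K,
              as.numeric(Sys.time() - t0, units = "secs"))
  } else {
    stage_log(quiet, "[construct] reusing completed stage")
    networks <- read_connectivity_set(wr_dir)
  }

  # stage: tla
  if (cfg$use_tla) {
    wrt_dir <- file.path(out, "wrt")
    if (!stage_done(wrt_dir)) {
      t0 <- Sys.time()
      den <- tla_denoise(networks, cfg$admm, cfg$grouping)
      final <- den$networks
      write_connectivity_set(final, wrt_dir)
      conv <- vapply(den$fits, function(f) f$converged, TRUE)
      jsonlite::write_json(
        list(iterations = vapply(den$fits, function(f) f$iterations, 1L),
             converged = conv),
        file.path(wrt_dir, "admm.json"), auto_unbox = FALSE, digits = NA)
      mark_done(wrt_dir)
      stage_log(quiet, "[tla] %d tensor(s), %d converged (%.1fs)",
                length(conv), sum(conv),
                as.numeric(Sys.time() - t0, units = "secs"))
    } else {
      stage_log(quiet, "[tla] reusing completed stage")
      final <- read_connectivity_set(wrt_dir)
    }
  } else {
    final <- networks
  }

  # stage: features
  feat_path <- file.path(out, "features.csv")
  if (!file.exists(feat_path)) {
    features <- feature_table(final, cfg$formula, cfg$weight_transform,
                              cfg$aggregation)
    # doubles at 17 significant digits so cached reruns are bit-identical
    printable <- features
    for (j in seq_along(printable)) {
      if (is.double(printable[[j]])) {
        printable[[j]] <- sprintf("%.17g", printable[[j]])
      }
    }
    utils::write.csv(printable, feat_path, row.names = FALSE, quote = FALSE)
    stage_log(quiet, "[features] %d samples x %d regions",
              nrow(features), length(feature_columns(features)))
  } else {
    stage_log(quiet, "[features] reusing completed stage")
    features <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
    class(features) <- c("wrtla_features", "data.frame")
  }

  # stage: classify
  cv <- cross_validate(features, folds = cfg$folds, reps = cfg$reps,
                       alpha = cfg$alpha, cost = cfg$cost, seed = cfg$seed,
                       group_by_subject = cfg$group_by_subject,
                       var_equal = cfg$var_equal)
  jsonlite::write_json(
    list(per_rep = cv$per_rep, mean = as.list(cv$mean),
         sd = as.list(cv$sd), settings = cv$settings),
    file.path(out, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  summary <- list(
    package_version = as.character(utils::packageVersion("wrtla")),
    seed = cfg$seed,
    metrics = list(mean = as.list(cv$mean), sd = as.list(cv$sd)),
    config = jsonlite::read_json(file.path(out, "config.json")))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log(quiet, "[classify] ACC %.3f, SEN %.3f, SPE %.3f, AUC %.3f",
            cv$mean[["ACC"]], cv$mean[["SEN"]], cv$mean[["SPE"]],
            cv$mean[["AUC"]])
  invisible(cv)
}
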