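# Plain-text file contracts: time series as TSV with V rows x P columns
# (header = region ids), square matrices as TSV, labels as a two-column
# table. Numbers are written with 12 significant digits so write/read
# round-trips are reproducible across platforms.

#' @noRd
format_num <- function(x) sprintf("%.12g", x)

#' Write a square matrix as TSV
#' @param W Numeric matrix.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(W, path) {
  W <- as.matrix(W)
  out <- apply(W, 1, function(r) paste(format_num(r), collapse = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#' @param path Input file.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a cohort of subject time series to a directory
#'
#' One `<subject_id>.tsv` per subject with V rows and P columns (header
#' row of region ids), plus `labels.tsv` with columns `subject_id` and
#' `label`.
#'
#' @param cohort A `wrtla_cohort` (from [simulate_cohort()]) or plain
#'   list of [subject_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  subjects <- if (inherits(cohort, "wrtla_cohort")) cohort$subjects else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- data.frame(
    subject_id = vapply(subjects, function(s) s$subject_id, ""),
    label = vapply(subjects, function(s) s$label, 0L))
  for (s in subjects) {
    tab <- t(s$X)                               # V rows x P columns on disk
    lines <- c(paste(rownames(s$X), collapse = "\t"),
               apply(tab, 1, function(r) paste(format_num(r),
                                               collapse = "\t")))
    writeLines(lines, file.path(dir, paste0(s$subject_id, ".tsv")))
  }
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read one subject's time-series file
#'
#' Expects the layout written by [write_cohort()]: a header row of region
#' ids followed by V rows of P numeric columns (time runs down the rows).
#' Ragged or non-numeric rows are reported by row number.
#'
#' @param path TSV file.
#' @param labels Optional labels data frame (`subject_id`, `label`) or
#'   path to one; the label is joined by subject id (the file stem).
#' @return A [subject_series()] (label `NA` if no labels given).
#' @export
read_timeseries <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such time-series file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("time-series file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  P <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != P)) {
    bad <- which(widths != P)[1]
    stop("ragged time-series file ", path, ": data row ", bad, " has ",
         widths[bad], " fields, expected ", P)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / P)
    stop("non-numeric cell in ", path, " at data row ", bad)
  }
  X <- matrix(vals, nrow = P)     # column j = data row j, so X is P x V
  rownames(X) <- header
  id <- sub("\\.tsv$", "", basename(path))
  lab <- NA_integer_
  if (!is.null(labels)) {
    if (is.character(labels)) {
      labels <- utils::read.table(labels, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    }
    hit <- match(id, labels$subject_id)
    if (is.na(hit)) stop("subject id '", id, "' not present in labels table")
    lab <- as.integer(labels$label[hit])
  }
  subject_series(id, lab, X)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `*.tsv` series files and `labels.tsv`.
#' @return A `wrtla_cohort` (without population correlation matrices).
#' @export
read_cohort <- function(dir) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) stop("no labels.tsv in ", dir)
  labels <- utils::read.table(lab_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  files <- file.path(dir, paste0(labels$subject_id, ".tsv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing series files for subjects: ",
         paste(labels$subject_id[missing], collapse = ", "))
  }
  subjects <- lapply(files, read_timeseries, labels = labels)
  structure(list(subjects = subjects, spec = NULL, R0 = NULL, R1 = NULL),
            class = "wrtla_cohort")
}

#' Write the networks of a connectivity set to a directory
#'
#' One `<subject>_w<k>.tsv` per (subject, window) plus an `index.json`
#' manifest (subjects, labels, stage, region ids, window count).
#'
#' @param networks A [connectivity_set()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_connectivity_set <- function(networks, dir) {
  stopifnot(inherits(networks, "connectivity_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_len(networks$M)) {
    for (k in seq_len(networks$K)) {
      write_matrix_tsv(networks$arr[, , k, m],
                       file.path(dir, sprintf("%s_w%d.tsv",
                                              networks$subject_ids[m], k)))
    }
  }
  manifest <- list(subject_ids = networks$subject_ids,
                   labels = networks$labels,
                   region_ids = networks$region_ids,
                   stage = networks$stage, K = networks$K)
  jsonlite::write_json(manifest, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a connectivity-set directory written by [write_connectivity_set()]
#' @param dir Directory with per-window matrices and `index.json`.
#' @return A [connectivity_set()].
#' @export
read_connectivity_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "index.json"),
                                  simplifyVector = TRUE)
  mats <- lapply(manifest$subject_ids, function(sid) {
    lapply(seq_len(manifest$K), function(k) {
      read_matrix_tsv(file.path(dir, sprintf("%s_w%d.tsv", sid, k)))
    })
  })
  connectivity_set(mats, manifest$subject_ids, manifest$labels,
                   stage = manifest$stage, region_ids = manifest$region_ids)
}
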