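# Node-level graph metrics on weighted connectivity matrices. Networks may
# carry negative (shrunk-correlation) weights; a weight transform makes
# them non-negative before any fractional power is taken.

#' @noRd
transform_weights <- function(A, weight_transform = c("abs", "positive_only")) {
  weight_transform <- match.arg(weight_transform)
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (anyNA(A) || any(!is.finite(A))) stop("adjacency matrix must be finite")
  if (max(abs(A - t(A))) > 1e-10) {
    stop("adjacency matrix must be symmetric (max asymmetry ",
         format(max(abs(A - t(A))), digits = 3), ")")
  }
  A <- (A + t(A)) / 2
  diag(A) <- 0
  W <- if (weight_transform == "abs") abs(A) else pmax(A, 0)
  if (any(W < 0)) stop("transformed weights must be non-negative")
  W
}

#' Weighted local clustering coefficient
#'
#' Weights are first made non-negative (`weight_transform`) and normalized
#' by the maximum weight of the graph. The default `"onnela"` formulation
#' scores node i by the mean cube-rooted geometric intensity of the
#' triangles through it:
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_ij w_ih w_jh)^{1/3}`
#' with `k_i` the binary degree; nodes with `k_i < 2` get 0, and all
#' values lie in `[0, 1]`. The `"literal"` variant scores node i by
#' `C_i = 2 * sum_{j in v_i} (w_ij)^{1/3} / (|v_i| (|v_i| - 1))` — a
#' degree-weighted sum of single edge weights that ignores triadic
#' closure; it is retained for comparability but `"onnela"` is the
#' measure of local structural density used downstream.
#'
#' @param A Symmetric `P x P` weight matrix with zero diagonal.
#' @param formula `"onnela"` or `"literal"`.
#' @param weight_transform `"abs"` (default) or `"positive_only"`.
#' @return Numeric length-P vector of clustering coefficients.
#' @examples
#' A <- matrix(1, 4, 4); diag(A) <- 0
#' weighted_clustering(A)   # complete graph: all 1
#' @export
weighted_clustering <- function(A, formula = c("onnela", "literal"),
                                weight_transform = c("abs", "positive_only")) {
  formula <- match.arg(formula)
  W <- transform_weights(A, weight_transform)
  P <- nrow(W)
  mx <- max(W)
  Wn <- if (mx > 0) W / mx else W
  k <- rowSums(Wn > 0)
  denom <- k * (k - 1)
  B <- Wn^(1 / 3)
  ci <- if (formula == "onnela") {
    diag(B %*% B %*% B)
  } else {
    2 * rowSums(B)
  }
  out <- ifelse(k >= 2, ci / denom, 0)
  names(out) <- rownames(A)
  out
}

#' Node degree of a weighted graph
#'
#' @param A Symmetric weight matrix, zero diagonal.
#' @param mode `"binary"` (count of nonzero incident edges) or
#'   `"strength"` (sum of transformed weights).
#' @param weight_transform `"abs"` or `"positive_only"`.
#' @return Numeric length-P vector.
#' @export
node_degree <- function(A, mode = c("binary", "strength"),
                        weight_transform = c("abs", "positive_only")) {
  mode <- match.arg(mode)
  W <- transform_weights(A, weight_transform)
  out <- if (mode == "binary") rowSums(W > 0) else rowSums(W)
  names(out) <- rownames(A)
  out
}

#' Hub score of a network
#'
#' The percentage of total node degree concentrated in the ten
#' highest-degree nodes (fewer when `P < 10`, noted via a message): a
#' proxy for hub / scale-free structure. Ties at the rank-10 boundary are
#' broken by lowest node index, so the score is deterministic.
#'
#' @param A Symmetric weight matrix, zero diagonal.
#' @param mode Degree mode, see [node_degree()].
#' @param weight_transform `"abs"` or `"positive_only"`.
#' @param n_top Number of top nodes (10 by the standard recipe).
#' @return List of class `"hub_report"`: `top_ids` (indices of the top
#'   nodes, highest degree first) and `hub_score` (percentage).
#' @export
hub_score <- function(A, mode = c("binary", "strength"),
                      weight_transform = c("abs", "positive_only"),
                      n_top = 10L) {
  deg <- node_degree(A, mode, weight_transform)
  P <- length(deg)
  total <- sum(deg)
  if (total == 0) stop("all node degrees are zero; hub score undefined")
  n_use <- min(n_top, P)
  if (n_use < n_top) {
    message("graph has only ", P, " nodes; hub score uses top ", n_use)
  }
  ord <- order(-deg, seq_along(deg))
  top <- ord[seq_len(n_use)]
  structure(
    list(top_ids = top, hub_score = 100 * sum(deg[top]) / total,
         mode = match.arg(mode), n_top = n_use),
    class = "hub_report"
  )
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub score (%s degree, top %d nodes): %.2f%%\n",
              x$mode, x$n_top, x$hub_score))
  cat("top nodes:", paste(x$top_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Clustering-coefficient feature table
#'
#' Computes the weighted local clustering coefficient of every region in
#' every network of a [connectivity_set()] and assembles the
#' samples-by-features table used for classification. `per_window` yields
#' one sample per (subject, window) — the many-samples design that
#' sliding windows afford; `subject_mean` averages windows within subject.
#'
#' @param networks A [connectivity_set()].
#' @param formula,weight_transform Passed to [weighted_clustering()].
#' @param aggregation `"per_window"` or `"subject_mean"`.
#' @return A `data.frame` of class `"wrtla_features"` with metadata
#'   columns `subject_id`, `window_id` (`NA` under `subject_mean`),
#'   `label`, then one column per region in region-index order.
#' @export
feature_table <- function(networks, formula = c("onnela", "literal"),
                          weight_transform = c("abs", "positive_only"),
                          aggregation = c("per_window", "subject_mean")) {
  stopifnot(inherits(networks, "connectivity_set"))
  formula <- match.arg(formula)
  weight_transform <- match.arg(weight_transform)
  aggregation <- match.arg(aggregation)
  if (anyNA(networks$arr)) stop("connectivity set has missing windows")
  M <- networks$M; K <- networks$K; P <- networks$P
  feats <- matrix(NA_real_, M * K, P)
  meta_subj <- character(M * K)
  meta_win <- integer(M * K)
  meta_lab <- integer(M * K)
  row <- 0L
  for (m in seq_len(M)) {
    for (k in seq_len(K)) {
      row <- row + 1L
      feats[row, ] <- weighted_clustering(networks$arr[, , k, m],
                                          formula, weight_transform)
      meta_subj[row] <- networks$subject_ids[m]
      meta_win[row] <- k
      meta_lab[row] <- networks$labels[m]
    }
  }
  colnames(feats) <- networks$region_ids
  if (aggregation == "subject_mean") {
    agg <- rowsum(feats, group = meta_subj, reorder = FALSE) / K
    subj <- unique(meta_subj)
    lab <- networks$labels[match(subj, networks$subject_ids)]
    out <- data.frame(subject_id = subj, window_id = NA_integer_,
                      label = lab, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(agg))
  } else {
    out <- data.frame(subject_id = meta_subj, window_id = meta_win,
                      label = meta_lab, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(feats))
  }
  rownames(out) <- NULL
  class(out) <- c("wrtla_features", "data.frame")
  out
}

#' Feature column names of a feature table
#' @param features A [feature_table()] data frame.
#' @return Character vector of region feature columns.
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features), c("subject_id", "window_id", "label"))
}

#' Numeric feature matrix of a feature table
#' @param features A [feature_table()] data frame.
#' @return Samples-by-features numeric matrix.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, feature_columns(features), drop = FALSE])
}
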