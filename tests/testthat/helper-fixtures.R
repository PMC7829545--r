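# Shared fixture builders and independent oracles used across test files.

# Pearson matrix of a random P x N window
random_pearson <- function(P, N, seed) {
  set.seed(seed)
  pearson_matrix(matrix(rnorm(P * N), P, N))
}

# small cohort for pipeline-level tests: 3+3 subjects, 12 regions
tiny_cohort <- function(seed = 42, effect_delta = 0, n_per_group = 3) {
  edges <- pick_effect_edges(12, 3, 4, seed = seed)
  simulate_cohort(cohort_spec(
    n_per_group = n_per_group, P = 12, V = 40, n_blocks = 3,
    effect_edges = if (effect_delta != 0) edges else NULL,
    effect_delta = effect_delta, noise_sd = 0.1, seed = seed))
}

# run-to-convergence proximal-gradient solver for the weighted-L1
# shrinkage objective ||A - W||_F^2 + lam * sum c_ij |a_ij|: gradient
# step of 1/2 on 2(A - W), then elementwise prox at lam * c_ij / 2 * 2
# (threshold lam * c_ij). Kept deliberately independent of solve_wr.
prox_gradient_oracle <- function(W, lam, sigma, max_iter = 1000,
                                 tol = 1e-14) {
  C <- exp(-W^2 / sigma)
  A <- W
  for (i in seq_len(max_iter)) {
    G <- A - 0.5 * (2 * (A - W))
    Anew <- sign(G) * pmax(abs(G) - lam * C, 0)
    if (max(abs(Anew - A)) < tol) return(Anew)
    A <- Anew
  }
  A
}

# independently coded matrix robust PCA via ADMM (inexact ALM form with
# plain matrix SVT), used as the n3 = 1 cross-check
matrix_rpca_oracle <- function(W, gamma, mu0 = 1e-3, rho = 1.1,
                               mu_max = 1e10, tol = 1e-8,
                               max_iter = 500) {
  L <- matrix(0, nrow(W), ncol(W))
  S <- L
  Y <- L
  mu <- mu0
  for (i in seq_len(max_iter)) {
    sv <- svd(W - S - Y / mu)
    dshr <- pmax(sv$d - 1 / mu, 0)
    Lnew <- sv$u %*% (dshr * t(sv$v))
    arg <- W - Lnew - Y / mu
    Snew <- sign(arg) * pmax(abs(arg) - gamma / mu, 0)
    viol <- Lnew + Snew - W
    Y <- Y + mu * viol
    done <- max(abs(Lnew - L)) <= tol && max(abs(Snew - S)) <= tol &&
      max(abs(viol)) <= tol
    L <- Lnew
    S <- Snew
    mu <- min(rho * mu, mu_max)
    if (done) break
  }
  list(L = L, S = S)
}

# brute-force triple-loop Onnela clustering on a non-negative
# max-normalized weight matrix
brute_onnela <- function(Wn) {
  P <- nrow(Wn)
  k <- rowSums(Wn > 0)
  out <- numeric(P)
  for (i in seq_len(P)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(P)) {
      for (h in seq_len(P)) {
        if (j == i || h == i || j == h) next
        acc <- acc + (Wn[i, j] * Wn[j, h] * Wn[h, i])^(1 / 3)
      }
    }
    out[i] <- acc / (k[i] * (k[i] - 1))
  }
  out
}

# exhaustive pair-counting AUC with half-credit ties
allpairs_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# collapse a per-window feature table to one row per subject
subject_mean_features <- function(features) {
  cols <- setdiff(colnames(features), c("subject_id", "window_id", "label"))
  X <- as.matrix(features[, cols, drop = FALSE])
  agg <- rowsum(X, group = features$subject_id, reorder = FALSE)
  counts <- as.vector(table(factor(features$subject_id,
                                   levels = rownames(agg))))
  agg <- agg / counts
  subj <- rownames(agg)
  lab <- features$label[match(subj, features$subject_id)]
  out <- data.frame(subject_id = subj, window_id = NA_integer_,
                    label = lab, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(agg))
  rownames(out) <- NULL
  class(out) <- c("wrtla_features", "data.frame")
  out
}
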