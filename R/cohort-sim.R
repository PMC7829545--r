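#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of `2 * n_per_group` subjects whose regional time
#' series are drawn from a zero-mean multivariate normal with block-modular
#' correlation: `within_r` inside each of `n_blocks` contiguous region
#' blocks, `between_r` across blocks. Group 1 differs from group 0 only on
#' `effect_edges`, whose population correlations are shifted by
#' `effect_delta` (disjoint between-block pairs, as produced by
#' [pick_effect_edges()], keep the perturbed matrix positive
#' semidefinite). Independent Gaussian observation noise of scale
#' `noise_sd` is added on top of the correlated signal, and an optional
#' AR(1) coefficient induces temporal autocorrelation in the signal
#' (off by default: sliding-window estimates are sensitive to it, and the
#' null should stay simple).
#'
#' @param n_per_group Subjects per group.
#' @param P Number of regions.
#' @param V Number of time points.
#' @param n_blocks Number of contiguous region blocks (modules).
#' @param within_r Within-block correlation, in (0, 1).
#' @param between_r Between-block correlation, `|between_r| < within_r`.
#' @param effect_edges Two-column integer matrix (or list of length-2
#'   vectors) of region pairs perturbed in group 1.
#' @param effect_delta Correlation shift added to `effect_edges` in group 1.
#' @param noise_sd Additive observation-noise SD (signal has unit variance).
#' @param ar AR(1) coefficient of the signal innovations, in [0, 1).
#' @param seed RNG seed; identical spec => bitwise-identical cohort.
#' @return An object of class `"cohort_spec"`.
#' @examples
#' spec <- cohort_spec(n_per_group = 3, P = 12, V = 40, seed = 7)
#' cohort <- simulate_cohort(spec)
#' length(cohort$subjects)
#' @export
cohort_spec <- function(n_per_group = 30L, P = 90L, V = 137L, n_blocks = 6L,
                        within_r = 0.6, between_r = 0.1,
                        effect_edges = NULL, effect_delta = 0,
                        noise_sd = 0.1, ar = 0, seed = 1L) {
  stopifnot(n_per_group >= 1, P >= 2, V >= 4, n_blocks >= 1, n_blocks <= P)
  if (!(within_r > 0 && within_r < 1)) {
    stop("within_r must lie in (0, 1), got ", within_r)
  }
  if (!(abs(between_r) < within_r)) {
    stop("|between_r| must be smaller than within_r (",
         between_r, " vs ", within_r, ")")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(ar >= 0 && ar < 1)) stop("ar must lie in [0, 1)")
  if (!is.null(effect_edges)) {
    if (is.list(effect_edges)) effect_edges <- do.call(rbind, effect_edges)
    effect_edges <- matrix(as.integer(effect_edges), ncol = 2)
    if (any(effect_edges < 1 | effect_edges > P)) {
      stop("effect_edges indices must lie in 1..P")
    }
    if (any(effect_edges[, 1] == effect_edges[, 2])) {
      stop("effect_edges must connect distinct regions")
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), P = as.integer(P),
         V = as.integer(V), n_blocks = as.integer(n_blocks),
         within_r = within_r, between_r = between_r,
         effect_edges = effect_edges, effect_delta = effect_delta,
         noise_sd = noise_sd, ar = ar, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Block membership of regions for a cohort spec
#' @noRd
block_assignment <- function(P, n_blocks) {
  sort(rep_len(seq_len(n_blocks), P))
}

#' All within-block edges of selected blocks
#'
#' Returns every region pair inside each of the given blocks — the edge
#' set of those blocks' cliques. Weakening whole modules this way (a
#' negative `effect_delta`) models module disintegration: the perturbed
#' matrix is again a valid block-correlation matrix (hence positive
#' semidefinite), and the group-difference matrix is low-rank, so the
#' effect survives cross-subject low-rank sharing.
#'
#' @param P Number of regions.
#' @param n_blocks Number of blocks.
#' @param blocks Block indices whose within pairs are returned.
#' @return Integer matrix with two columns.
#' @export
block_clique_edges <- function(P, n_blocks, blocks) {
  assign <- block_assignment(P, n_blocks)
  out <- matrix(0L, 0, 2)
  for (b in blocks) {
    idx <- which(assign == b)
    if (length(idx) < 2) next
    pairs <- t(utils::combn(idx, 2))
    out <- rbind(out, pairs)
  }
  out
}

#' Population correlation matrices of the two groups
#'
#' Builds the compound-symmetry block target correlation matrix for group 0
#' and the perturbed matrix for group 1, and verifies positive
#' semidefiniteness. Matrices failing PSD are repaired by clipping negative
#' eigenvalues at zero and re-normalizing to unit diagonal; if the repair
#' moves any entry by more than `1e-6` the spec is rejected, so the
#' advertised group difference (`effect_delta` exactly on `effect_edges`,
#' zero elsewhere) holds to that tolerance.
#'
#' @param spec A [cohort_spec()].
#' @return List with matrices `R0` and `R1` and the block assignment.
#' @export
cohort_correlations <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  blocks <- block_assignment(spec$P, spec$n_blocks)
  R0 <- matrix(spec$between_r, spec$P, spec$P)
  same <- outer(blocks, blocks, "==")
  R0[same] <- spec$within_r
  diag(R0) <- 1
  R1 <- R0
  if (!is.null(spec$effect_edges) && spec$effect_delta != 0) {
    for (e in seq_len(nrow(spec$effect_edges))) {
      i <- spec$effect_edges[e, 1]
      j <- spec$effect_edges[e, 2]
      R1[i, j] <- R1[i, j] + spec$effect_delta
      R1[j, i] <- R1[i, j]
    }
    if (any(abs(R1) > 1)) {
      stop("effect_delta pushes correlations outside [-1, 1]; ",
           "reduce effect_delta or between_r")
    }
  }
  list(R0 = ensure_psd(R0, "group 0"), R1 = ensure_psd(R1, "group 1"),
       blocks = blocks)
}

#' @noRd
ensure_psd <- function(R, what) {
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) >= -1e-12) return(R)
  vals <- pmax(eg$values, 0)
  Rc <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(Rc))
  Rc <- Rc / tcrossprod(d)
  if (max(abs(Rc - R)) > 1e-6) {
    stop("target correlation matrix for ", what,
         " is not positive semidefinite (min eigenvalue ",
         format(min(eg$values), digits = 3),
         ") and PSD repair would change entries by up to ",
         format(max(abs(Rc - R)), digits = 3),
         "; adjust within_r/between_r/effect_delta/effect_edges")
  }
  Rc
}

#' Simulate a two-group cohort of regional time series
#'
#' Draws each subject's `P x V` series from the group's block correlation
#' structure (optionally with AR(1) temporal dependence in the signal),
#' adds independent observation noise, and labels groups 0/1. Deterministic
#' for a fixed spec.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `"wrtla_cohort"`: list with `subjects`
#'   (list of [subject_series()]), the `spec`, and the population
#'   correlation matrices `R0`, `R1`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  corrs <- cohort_correlations(spec)
  L0 <- chol_psd(corrs$R0)
  L1 <- chol_psd(corrs$R1)
  region_ids <- sprintf("R%03d", seq_len(spec$P))
  set.seed(spec$seed)
  subjects <- vector("list", 2L * spec$n_per_group)
  idx <- 0L
  for (g in 0:1) {
    Lg <- if (g == 0) L0 else L1
    for (s in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      Z <- matrix(stats::rnorm(spec$V * spec$P), spec$V, spec$P)
      if (spec$ar > 0) {
        # AR(1) with unit marginal variance, stationary start
        Z <- apply(Z, 2, function(z) {
          out <- stats::filter(z * sqrt(1 - spec$ar^2), spec$ar,
                               method = "recursive",
                               init = z[1])
          as.numeric(out)
        })
        Z <- matrix(Z, spec$V, spec$P)
      }
      X <- t(Z %*% Lg)                      # P x V correlated signal
      if (spec$noise_sd > 0) {
        X <- X + spec$noise_sd * matrix(stats::rnorm(spec$P * spec$V),
                                        spec$P, spec$V)
      }
      rownames(X) <- region_ids
      subjects[[idx]] <- subject_series(sprintf("sub%02d", idx), g, X)
    }
  }
  structure(list(subjects = subjects, spec = spec,
                 R0 = corrs$R0, R1 = corrs$R1),
            class = "wrtla_cohort")
}

# Upper-triangular factor L with t(L) %*% L = R, tolerant of PSD rank
# deficiency (pivots below tolerance get zero rows).
#' @noRd
chol_psd <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(out)) return(out)
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  t(eg$vectors %*% diag(sqrt(vals), nrow = length(vals)))
}

#' @export
print.wrtla_cohort <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "synthetic cohort: %d + %d subjects, P = %d regions, V = %d time points\n",
    sp$n_per_group, sp$n_per_group, sp$P, sp$V))
  cat(sprintf("  %d blocks, within r = %.2f, between r = %.2f, noise sd = %.2f\n",
              sp$n_blocks, sp$within_r, sp$between_r, sp$noise_sd))
  ne <- if (is.null(sp$effect_edges)) 0L else nrow(sp$effect_edges)
  cat(sprintf("  group effect: delta = %.2f on %d edges\n",
              sp$effect_delta, ne))
  invisible(x)
}

#' Default group-1 effect edges for a cohort spec
#'
#' Picks `n_edges` region pairs, deterministically from `seed`, suitable
#' as `effect_edges`. Each region appears in at most `max_degree` effect
#' edges, which keeps the perturbation's spectral norm small so the
#' group-1 correlation matrix remains positive semidefinite: for
#' disjoint pairs the perturbation's harmful eigen-directions align with
#' pair contrasts (between-block placement, use with a positive shift)
#' or pair sums (within-block placement, use with a negative shift —
#' the weakened-connectivity phenotype), where the block model has a
#' comfortable PSD margin. Within-block weakening is the placement that
#' clustering-coefficient features are most sensitive to, because
#' within-block edges participate in many strong triangles.
#'
#' @param P Number of regions.
#' @param n_blocks Number of blocks.
#' @param n_edges Number of edges.
#' @param seed RNG seed.
#' @param regions Optional subset of region indices to draw endpoints
#'   from (defaults to all).
#' @param max_degree Cap on effect edges per region.
#' @param where Draw pairs between blocks (default) or within blocks.
#' @return `n_edges x 2` integer matrix.
#' @export
pick_effect_edges <- function(P, n_blocks, n_edges = 20L, seed = 1L,
                              regions = NULL, max_degree = 1L,
                              where = c("between", "within")) {
  where <- match.arg(where)
  blocks <- block_assignment(P, n_blocks)
  if (is.null(regions)) regions <- seq_len(P)
  keep <- matrix(FALSE, P, P)
  keep[regions, regions] <- TRUE
  rel <- if (where == "between") outer(blocks, blocks, "!=")
         else outer(blocks, blocks, "==")
  pairs <- which(upper.tri(matrix(0, P, P)) & rel & keep, arr.ind = TRUE)
  set.seed(seed)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  deg <- integer(P)
  sel <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (deg[i] < max_degree && deg[j] < max_degree) {
      sel <- rbind(sel, c(i, j))
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
      if (nrow(sel) == n_edges) break
    }
  }
  if (nrow(sel) < n_edges) {
    stop("could not place ", n_edges, " ", where, "-block edges with degree cap ",
         max_degree, " among ", length(regions), " regions")
  }
  unname(sel)
}
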