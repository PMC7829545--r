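---
title: "Dynamic functional networks by weighted regularization and tensor low-rank approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional networks by weighted regularization and tensor low-rank approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI yields, per subject, a matrix of `P` regional time
series over `V` time points. Functional connectivity between regions is
not static; the standard way to expose its dynamics is to slide a window
of width `N` at step `S` along the series and compute a Pearson
correlation matrix per window, giving `K = floor((V - N)/S) + 1`
networks per subject. Raw sliding-window Pearson networks are dense and
noisy; the pipeline implemented here addresses that in two stages before
any group comparison:

1. **Weighted regularization (WR).** Each window's Pearson matrix `W` is
   replaced by the minimizer of
   `||A - W||_F^2 + lambda * sum_ij c_ij |a_ij|` with
   `c_ij = exp(-w_ij^2 / sigma)`. Because the penalty weight decays with
   connection strength, weak (likely spurious) correlations are pruned
   aggressively while strong connections are barely shrunk. The
   objective is elementwise separable, so the solution is the exact
   closed form `a_ij = sgn(w_ij) max(|w_ij| - lambda c_ij, 0)`.
2. **Tensor low-rank approximation (TLA).** The shrunk networks of all
   subjects in a window are stacked into a `P x P x M` tensor and split
   as `W = Omega + E` by tensor robust PCA:
   `min ||Omega||_* + gamma ||E||_1 s.t. W = Omega + E`, where
   `||.||_*` is the t-SVD tensor nuclear norm (sum over mode-3 Fourier
   frontal slices of matrix nuclear norms). The low-rank `Omega` carries
   topology shared across subjects — similar but not identical between
   individuals — while idiosyncratic noise lands in the sparse `E`.

Each subject's slice of `Omega` is their denoised dynamic network. Node
features are weighted local clustering coefficients; features are
screened per training fold by a two-sample t-test (`alpha = 0.05`,
no multiplicity correction — it is a filter, not an inference), and a
linear SVM (`C = 1`) is evaluated by stratified 10-fold
cross-validation repeated 10 times, reporting ACC/SEN/SPE/AUC with the
SD over repetitions. Group 1 (the cases) is the positive class.

```{r}
library(wrtla)
cohort <- simulate_cohort(cohort_spec(
  n_per_group = 20, P = 60, V = 137, n_blocks = 12,
  within_r = 0.5, between_r = 0.1, noise_sd = 0.1,
  effect_edges = block_clique_edges(60, 12, 1:2),
  effect_delta = -0.4, seed = 1))
fit <- wrtla(cohort, window = window_config(70, 3),
             admm = admm_config(gamma = 0.05), seed = 1)
summary(fit)
```

## Parameters that matter

* `lambda` (WR penalty, dimensionless; default 0.2): the operating
  point of the method. The dyadic grid `2^-4 .. 2^-1` is the
  conventional sweep range (`run_lambda_sweep()`); density of the
  resulting networks is non-increasing in `lambda`.
* `sigma` (penalty decay scale): estimated per window as the
  population SD of the absolute entries of that window's Pearson
  matrix. The literal "all elements" rule includes the unit diagonal,
  which inflates `sigma`; `sigma_rule = "std_abs_offdiag"` is provided
  for the off-diagonal variant. Population vs sample SD is not
  critical (`P^2` entries); a `sample_sd` flag exposes the
  alternative.
* Window geometry `N`, `S` (time points): defaults 70 and 3 here.
  Width trades temporal specificity against correlation estimation
  noise (`SE ~ (1 - r^2)/sqrt(N)`); the step controls how many (and
  how overlapping) samples the classifier sees.
* `gamma` (TRPCA sparsity weight): the default rule
  `1/sqrt(max(n1, n2) * n3)` is the scaling under which robust PCA
  provably separates incoherent low-rank structure from *random
  sparse* corruption, and it is exactly right for that task (the
  planted-tensor recovery tests use it). Connectivity stacks are a
  different regime: their "corruption" is dense sampling noise plus
  genuine per-subject deviation, and on the reference cohort the rule
  value (0.0204) makes the sparse term so cheap that *all*
  across-subject variability is absorbed into `E` — every subject
  receives the identical low-rank network and classification becomes
  impossible — while `gamma >= 0.1` leaves `E` empty. The reference
  pipeline therefore fixes `gamma = 0.05` explicitly, the middle
  regime in which `E` removes a few percent of weak idiosyncratic
  connections, which is what the sparsity term is for in this
  application; the calibration scan behind that number is a
  three-line loop over `trpca_admm(st, admm_config(gamma = g))`
  watching the across-subject variance of `Omega`. The dimensionally
  anomalous alternative `1/(n1 * n3)` is retained as
  `gamma_rule = "literal_inv_nk"` for comparability (it sits even
  deeper in the collapse regime), and an explicit value overrides
  both.
* ADMM: `mu0 = 1e-3`, `rho = 1.1`, `mu_max = 1e10`, tolerance `1e-8`
  on all three max-norm residuals (the step sizes of `Omega` and `E`
  and the constraint violation), cap 500 iterations. These are the
  conventions of the tensor RPCA literature; convergence is typically
  reached in 80–200 iterations on the problems in this package, and a
  non-converged result is returned flagged, never silently.
* Tensor grouping: `per_window` (default) stacks the `M` subjects of
  one window, which matches the goal of sharing topology across
  subjects; `all_slabs` stacks all `M * K` subject-windows into one
  tensor. Both are exposed because the construction is ambiguous in
  general; `slab_index` makes any grouping losslessly invertible.

## Feature definition

The clustering coefficient printed as
`C_i = 2 sum_{j in v_i} (w_ij)^{1/3} / (|v_i|(|v_i| - 1))` sums single
edge weights and therefore cannot measure triadic closure — it is
internally inconsistent with its own description as a density of local
structure. The package's default is the standard Onnela formulation

`C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_ij w_jh w_hi)^{1/3}`

on weights normalized by the graph maximum, which is what "density of
the local structure" actually quantifies; the printed variant is kept
behind `formula = "literal"`. Networks can carry negative (shrunk
correlation) weights, for which fractional powers are undefined; the
default transform is `abs`, with `positive_only` as the alternative.
Node degree for hub scoring is binary by default (count of surviving
edges), with `strength` available.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` draws each subject's series from a zero-mean
multivariate normal whose correlation matrix is block-modular:
`n_blocks` contiguous modules with compound-symmetry correlation
`within_r` inside and `between_r` across modules, plus independent
observation noise (`noise_sd`) and optional AR(1) temporal dependence
(off by default, keeping the null simple — sliding-window statistics
are sensitive to autocorrelation, and the option exists precisely to
probe that). Group 1 differs from group 0 only on `effect_edges`,
shifted by exactly `effect_delta`; positive semidefiniteness of both
group matrices is verified (eigenvalue clipping is allowed only below
a 1e-6 entrywise repair, otherwise the spec is rejected).

The reference study conditions used by the tests and the acceptance
script are: 20 + 20 subjects, `P = 60` regions in 12 modules of 5,
`V = 137` time points, `within_r = 0.5`, `between_r = 0.1`,
`noise_sd = 0.1`, windows of width 70 at step 3 (`K = 23`), and
`lambda = 0.2`. The planted group effect weakens all within-module
connections of two modules by 0.4 (`block_clique_edges()`), i.e. two
modules disintegrate in the case group. This choice is deliberate on
two grounds: weakened within-module connectivity is the canonical
disconnection phenotype of early cognitive impairment, and a
module-structured difference is low-rank, so it is the kind of group
structure that survives the tensor stage. Its converse is a real
limitation worth knowing: a group difference scattered over many
mutually disjoint edges is nearly full-rank, is treated by the tensor
nuclear norm as if it were noise, and is largely moved into the sparse
residual — the WR-only ablation (`use_tla = FALSE`) then outperforms
the full pipeline. The problem sizes were chosen so the whole
validation cycle runs comfortably on one CPU; they are stated here as
the package's reference conditions, and every one of them is a plain
argument.

What the generator does *not* emulate: hemodynamics, scanner drift and
physiological artifacts, spatial autocorrelation of parcellations,
inter-subject variability in the *base* connectome (all subjects share
one population matrix per group), and non-stationarity within a
subject (the population correlation is constant over the series, so
all window-to-window variation is sampling noise). Passing tests on
these cohorts therefore validate the estimator chain — shrinkage
arithmetic, tensor decomposition, feature extraction, leakage-free
selection, metric bookkeeping — not the claim that real resting-state
data are this well-behaved.

## Cross-validation conventions

Per repetition, fold predictions are pooled into a single confusion
table and a single AUC (per-fold metrics on ~2-subject test sets are
too unstable to average); the reported SD is across the 10
repetitions, i.e. it measures fold-assignment variability, not
subject-sampling variability. With per-window samples the default fold
unit is the sample, mirroring the many-samples protocol this method
family uses; windows of one subject then appear on both sides of a
split, so the estimate contains subject-identity leakage and
overlapping-window near-duplication. That inflation is inherent to the
protocol, not a bug: `group_by_subject = TRUE` keeps all windows of a
subject in one fold and is the honest generalization estimate — it is
what the null-calibration check uses, and what we recommend for any
substantive claim. Features are standardized inside the SVM
(`scale_features = TRUE`), the usual practice with LIBSVM-family
classifiers; the raw-feature variant is one flag away.

The same pseudo-replication point governs *which regions* one may call
affected: window rows are not independent observations, and a t-test
across ~900 of them declares arbitrarily small systematic shifts
significant, burying the truly affected regions in a long significance
list. Region-level inference should therefore be run on subject-mean
features (one independent unit per subject), which is how the
validation suite and the acceptance script evaluate whether selection
concentrates on the planted regions; the per-window screen inside the
classifier is a prediction filter, not an inferential claim.

## Numerical choices

* Pearson rows are centred and normalized once; products are clamped
  to `[-1, 1]` against round-off.
* The t-SVD prox computes only the first `floor(n3/2) + 1` Fourier
  slices and mirrors their conjugates, so the inverse transform is
  real by construction; imaginary residue beyond 1e-10 would raise a
  warning rather than be silently discarded.
* The ADMM starts from `Omega = E = Y = 0`; `mu` grows geometrically
  and is capped.
* Hub-score ties at the rank-10 boundary break toward the lowest
  region index, making reports deterministic.
* Sweep cells derive their seeds from the base seed by a stable string
  hash of the cell key, so cells are mutually independent yet the
  whole table is reproducible, and any cell can be reproduced in
  isolation.
* Matrices are written to disk with 12 significant digits; read/write
  round-trips are reproducible across platforms at 1e-11.

## Known limitations

* With `per_window` grouping the tensor sees `M` subjects per window;
  group labels are not used anywhere before the classifier, so the
  tensor stage can only preserve, never create, group structure — and
  it actively suppresses high-rank group structure (see above).
* The t-test screen is marginal: correlated features are selected or
  dropped together, and no multiplicity control is attempted.
* `sigma` and the penalty weights are computed once per window from
  the same matrix being shrunk; no reweighting iterations are
  performed.
* The AR(1) option models temporal dependence of the signal only; the
  additive observation noise is always white.
* No nested cross-validation: `lambda`, window geometry and `C` are
  protocol constants (swept transparently by `run_lambda_sweep()` /
  `run_window_sweep()`, not optimized per fold).
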