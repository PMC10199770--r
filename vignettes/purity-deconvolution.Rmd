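---
title: "Methods: tumour purity deconvolution from serum exosome miRNA-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour purity deconvolution from serum exosome miRNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopurity)
```

## The problem and the model

Serum exosomes of a cancer patient mix vesicles from two sources: cancer
cells and healthy cells. Writing `T` for the patient's miRNA expression
profile (CPM) restricted to a set of signature miRNAs, and `E` for the m × 2
profile of mean signature expression in cancer cell-derived and healthy
cell-derived exosomes, the package assumes the linear two-source mixture

```
T = E %*% alpha + eps,    alpha >= 0,    sum(alpha) = 1
```

and estimates `alpha` by constrained least squares on the simplex,
`min || E %*% alpha - T ||^2`, solved as a quadratic program. The first
component `alpha[1]` is the tumour purity. The model is deliberately
two-source: exosome subpopulations, batch effects and more granular cell
types are out of scope.

Because the mixture is linear in expression, everything on the deconvolution
path stays on the **linear CPM scale**: the signature profile `E` is a mean
of CPM values, and `T` enters untransformed. `T` is *not* re-normalized to
the signature subset before solving; the sum-to-one constraint absorbs the
overall scale difference, and the estimator is exactly equivariant to a
common positive rescaling of `T` and `E` (a tested invariant).

## Signature selection

`build_signature()` implements a two-filter chain on a reference cohort of
cancer cell-derived and healthy cell-derived exosome samples:

* **Between-group signal** — a negative-binomial Wald test per miRNA (run
  through DESeq2: median-of-ratios size factors, NB GLM with a group
  indicator). A miRNA passes with `|log2FC| > 1` and BH `FDR < 0.01`, both
  strict. FDR is recomputed over the full p-value vector with independent
  filtering and outlier handling disabled, so the BH adjustment is exactly
  the textbook step-up procedure (tested against a brute-force oracle). The
  DE backend is pluggable: `de_table=` accepts any externally computed table
  with `mirna_id`, `log2fc`, `fdr`.
* **Within-group stability** — the variance of `log2(CPM + 1)` must be
  strictly below 2 within the cancer group *and* within the healthy group.
  The threshold of 2 is only meaningful on the log scale: raw-CPM variances
  of expressed miRNAs are orders of magnitude larger, so the package fixes
  log2(CPM+1) as the stability scale and exposes `var_threshold` for tuning.

miRNAs exactly on a threshold are excluded (strict inequalities throughout).
The retained miRNAs' mean CPM per group forms `E`; rows with identical means
in both columns carry no signal and are dropped, and fewer than two
surviving miRNAs is an error rather than a degenerate model.

`pan_cancer_signature()` assembles a cross-cancer signature from per-cancer
signatures: a miRNA is kept when it appears in strictly more than
`min_cancer_count` (default 5) of them, and its `E` row is the unweighted
mean over the cancers carrying it. Unweighted averaging is a design choice —
per-cancer cohort sizes are not comparable evidence weights for a shared
reference profile.

Counts are rounded to integers before the NB test (the model is defined on
integers); the I/O layer itself never modifies values and accepts declared
CPM matrices directly.

## Solving the quadratic program

`estimate_purity()` builds the Hessian `crossprod(E)` and linear term
`crossprod(E, T)` and calls `quadprog::solve.QP` with one equality
(sum-to-one) and two bound constraints. Numerical choices:

* The objective is divided by `max(crossprod(E))` before solving — the
  argmin is unchanged, but the solver operates on O(1) numbers instead of
  squared-CPM magnitudes (~1e9), where its feasibility checks break down.
* If the 2 × 2 Hessian has condition number above 1e12, a ridge of 1e-10 is
  added; with two well-separated signature columns this never triggers in
  practice.
* Solver round-off can leave a component marginally negative; components are
  clamped to 0 and the pair renormalized to sum exactly to 1.

For the two-component case the problem has a closed form,
`alpha1 = clip((E1-E2)'(T-E2) / ||E1-E2||^2, 0, 1)`; the test suite checks
the QP against this closed form (1e-6) and against a 1e-4-step grid search
(1e-3) on random noisy instances, keeping implementation and oracle on
separate routes.

## Classification against an empirical null

Purities predicted for healthy-derived samples form the null `H0`
(`build_null()`; at least 10 values required, fewer than 20 warns). The
p-value of an observed purity uses the add-one permutation-style estimator
`p = (1 + sum(H0 >= obs)) / (1 + n)`, which can never return 0 — with n null
values the smallest attainable p is `1/(n+1)`, so a usable null at the 0.05
level needs at least 20 healthy-derived samples. The tumour call is
`p < 0.05` (configurable, strict).

## Simulated mixtures and the synthetic cohort

`simulate_cohort()` builds mixtures of known purity from source CPM
profiles: `x * cancer + (1 - x) * healthy`, optionally plus i.i.d. Gaussian
noise on the CPM scale, truncated at 0 (the deconvolution requires
non-negative input; truncation is the package's choice for an otherwise
unspecified boundary). Noise SDs of 1–9 are small relative to typical
signature CPMs (tens to thousands), which is why recovery degrades only
gently with noise.

By default the mixture sources are the **group-mean profiles** of the
supplied samples (`mixture_design(source = "mean")`). With per-sample draws
(`source = "sample"`) the drawn source column deviates from the signature's
group mean by the full within-group sampling variance, which caps noiseless
recovery around r ≈ 0.96–0.97 at NB dispersion 0.05 — incompatible with the
near-exact noiseless recovery the linear model admits, and with the
interpretation of "x% of the cancer expression profile" as mixing a profile,
not a random sample. Both modes are kept; the benchmark default is `mean`.

`synthetic_cohort()` generates the reference cohorts all tests run on:
baseline mean CPM drawn log-uniformly from 5–5000 (about the dynamic range
of a typical small-RNA library), negative-binomial counts with dispersion
0.05 (tight, cell-line-like replicates) at an expected library size of 2e6
reads, and planted differential expression with |log2FC| = 3 by default and
random sign. The defaults mirror the benchmark conditions used throughout:
500 miRNAs, 30 planted DE, 20 + 20 samples. `synthetic_pan_cancer()` builds
six such cohorts sharing one baseline and 40 shared planted miRNAs with a
common signed effect, plus 15 private DE miRNAs per type.

What the generator does **not** emulate: compositional coupling beyond the
CPM constraint, correlated miRNAs, outlier samples, batch effects, library
preparation biases, or heavy-tailed dispersion across miRNAs. Passing the
recovery benchmarks therefore demonstrates correctness of the pipeline
under its own model assumptions, not performance on real serum data.

## Purity-corrected differential expression

For each miRNA, expression in sample j is modelled as
`Z_j = m + lambda_j * mu + eps_j`, where `lambda_j` is the sample's tumour
purity (0 for healthy controls) and `mu` the tumour-associated shift
extrapolated to purity 1. In matrix form `Z = W beta + eps` with healthy
rows `[1, 0]` and tumour rows `[1, lambda_j]`.

Design choices where the procedure was genuinely open:

* **Expression scale**: `log2(CPM + 1)`. The mixture argument is additive in
  expression on any scale; the log scale makes `mu` directly interpretable
  as a log2 fold-change and stabilizes the variance, and `mu` is reported
  as the corrected log2FC.
* **The GLS covariance**: a diagonal with two variance groups (healthy vs
  tumour), estimated from the residuals of an initial OLS pass, followed by
  one re-weighting pass (feasible GLS). This matches the model's framing of
  separate healthy and tumour noise without inventing per-sample structure.
  `ols = TRUE` disables the re-weighting; when the two estimated variances
  coincide the GLS fit reduces to OLS exactly (tested).
* **Reference distribution**: the Wald statistic `mu_hat / se(mu_hat)` is
  compared to the standard normal, appropriate for the target regime of
  tens of samples per group; the type-I error at nominal 0.05 calibrates to
  0.03–0.07 in the null simulations.
* `lambda_j` may come from `estimate_purity_matrix()` or from any external
  purity table — the design matrix does not care who estimated the purity.

Significance combines `FDR < 0.05` with `|log2FC| > 1`, both strict, after
joint BH adjustment. Per-miRNA fit failures become NA rows and are counted
in a message, never fatal. With tumour samples at low purity (e.g. 0.3), a
true `mu` of 3 appears as a raw group shift of only 0.9 — below the
fold-change cut — while the corrected model recovers it; this dilution
reversal is the point of the correction and is exercised directly in the
tests.

## Evaluation protocol and problem sizes

`run_recovery_benchmark()` chains cohort simulation, deconvolution and
scoring (Pearson correlation and MAE against the planted purities) per
noise level. The packaged benchmarks use a synthetic cohort of 500 miRNAs
(30 planted DE, 20 + 20 samples), 100 mixtures on an even 0–1 purity grid
for the per-cancer pipeline, and 25 mixtures per type across six types for
the pan-cancer pipeline; null-calibration simulations use 2000 features.
These sizes make every statistic stable to well under the tolerances tested
while keeping a full run in tens of seconds.

`split_cohort()` provides the stratified five-part split (one part held
out) with three-fold cross-validation folds over the remainder; splits are
stratified by group, and additionally by cancer type when present, since an
unstratified split can starve a fold of one source entirely. In
cross-validated use the intended reading is: build the signature on the
training folds, validate predicted purity on the held-out fold.

## Known limitations

* Strictly two mixture components; no subpopulation or batch structure.
* The NB test inherits DESeq2's behaviour on pathological inputs (e.g. a
  fully constant count matrix is rejected outright).
* The empirical null needs enough healthy-derived samples to resolve the
  0.05 level (>= 20).
* Purity estimates near the simplex vertices are clamped, so calibration of
  downstream models using many exact-0/1 purities should be checked.
* The synthetic generator's independence assumptions make its benchmarks a
  necessary, not sufficient, indicator of performance on real cohorts.
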