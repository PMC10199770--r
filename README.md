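# exopurity

Tumour purity deconvolution for serum exosome miRNA-Seq.

Serum exosomes of cancer patients are a mixture of vesicles shed by cancer
cells and by healthy cells. The fraction contributed by cancer cells — the
*tumour purity* of the sample — matters twice over: it is itself a
non-invasive disease readout (including for early, low-purity disease), and
ignoring it biases differential-expression analysis, because an miRNA change
in tumour-derived exosomes is diluted by the healthy-derived background.
`exopurity` is for bioinformaticians working with liquid-biopsy small-RNA-Seq
count matrices who want to estimate that fraction per sample, call
tumour-vs-normal against an empirical null, and run purity-corrected
differential expression.

## The model

**Signature.** From a reference cohort of cancer cell-derived and healthy
cell-derived exosome samples, select miRNAs that are differentially expressed
between the two sources (negative-binomial Wald test via DESeq2,
|log2FC| > 1, BH FDR < 0.01) and stably expressed within each source
(variance of log2(CPM+1) < 2 in both groups). Their mean CPM per source forms
the signature profile *E* (m × 2). A pan-cancer signature keeps miRNAs
appearing in more than five per-cancer signatures.

**Deconvolution.** A patient profile *T* (CPM over the signature miRNAs) is
modelled as a two-source mixture

    T = E α + ε,   α = (α₁, α₂),   α ≥ 0,   α₁ + α₂ = 1

and α is the solution of the constrained least-squares problem
min ‖Eα − T‖² on the simplex, solved by quadratic programming
(`quadprog::solve.QP`). α₁ is the tumour purity.

**Classification.** Purities predicted for healthy-derived samples form an
empirical null H₀; a sample with add-one empirical p-value
p = (1 + #{H₀ ≥ α₁}) / (1 + n) below 0.05 is called tumour-derived.

**Purity-corrected differential expression.** Per miRNA, expression
Z (log2(CPM+1)) follows Z = m + λμ + ε, where λ is the sample's tumour purity
(0 for healthy controls) and μ the tumour-associated shift at purity 1. The
model is fitted by feasible generalized least squares with separate healthy
and tumour variance groups; μ is Wald-tested and p-values are BH-adjusted.

## Worked example

Everything below runs offline on a synthetic cohort (negative-binomial
counts, 30 planted differentially expressed miRNAs at |log2FC| = 3, 20 cancer
and 20 healthy samples):

```r
library(exopurity)

coh <- synthetic_cohort(synthetic_cohort_spec(seed = 1))
sig <- build_signature(coh$counts, coh$meta)
sig
#> signature_profile: 30 miRNAs
#>   provenance: lfc_threshold=1 fdr_threshold=0.01 var_threshold=2 n_cancer=20 n_healthy=20

cpm <- cpm_normalize(coh$counts)
can <- count_matrix(cpm$values[, coh$meta$group == "cancer"], "cpm")
hea <- count_matrix(cpm$values[, coh$meta$group == "healthy"], "cpm")
run_recovery_benchmark(sig, can, hea, sigmas = c(0, 1, 3, 5, 7, 9), seed = 2)
#> benchmark_report: 100 mixtures per noise level, seed 2
#>  sigma pearson_r          mae
#>      0 1.0000000 3.744351e-16
#>      1 1.0000000 7.424862e-06
#>      3 1.0000000 2.316991e-05
#>      5 1.0000000 3.526877e-05
#>      7 1.0000000 6.234369e-05
#>      9 0.9999999 7.403522e-05
```

The signature recovers exactly the 30 planted miRNAs, and purities planted on
a 0–1 grid are recovered with Pearson r ≥ 0.9999999 and mean absolute error
below 1e-4 even at noise SD 9 (CPM scale). Deconvolving the cohort itself and
classifying against the healthy-derived null:

```r
purity <- estimate_purity_matrix(cpm, sig)
head(purity, 3)
#>   sample_id alpha_tumour alpha_healthy residual_norm
#> 1 cancer_01    0.9160121    0.08398786      20916.03
#> 2 cancer_02    1.0000000    0.00000000      21318.45
#> 3 cancer_03    0.9733921    0.02660785      32969.24

h0 <- build_null(purity$alpha_tumour[coh$meta$group == "healthy"])
head(classify(purity[coh$meta$group == "cancer", ], h0), 3)
#>   sample_id tumour_purity    p_value  label
#> 1 cancer_01     0.9160121 0.04761905 tumour
#> 2 cancer_02     1.0000000 0.04761905 tumour
#> 3 cancer_03     0.9733921 0.04761905 tumour

de <- corrected_de_table(coh$counts, coh$meta, purity)
sum(de$significant)
#> [1] 30
```

`alpha_tumour` is the estimated cancer-derived fraction of each sample
(cancer cell-line samples sit near 1, healthy controls near 0);
`residual_norm` is the fit residual ‖Eα − T‖ on the CPM scale. The purity-
corrected test flags exactly the 30 planted miRNAs at FDR < 0.05 and
|log2FC| > 1.

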