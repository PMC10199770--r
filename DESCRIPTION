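Package: exopurity
Title: Tumour Purity Deconvolution for Serum Exosome miRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of cancer cell-derived exosomes (tumour
    purity) in serum exosome miRNA-Seq samples. Builds miRNA signature
    profiles from cancer cell line-derived and healthy cell-derived exosome
    cohorts (negative-binomial differential expression plus a within-group
    stability filter), deconvolves mixed serum profiles by constrained
    quadratic programming on the two-component simplex, classifies samples
    against an empirical null distribution of healthy-derived purities,
    simulates mixtures of known purity with Gaussian noise for benchmarking,
    and performs purity-corrected differential expression via a generalized
    least squares model with a Wald test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    DESeq2,
    quadprog,
    jsonlite,
    optparse,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
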