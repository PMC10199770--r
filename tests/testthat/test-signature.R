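# The NB test runs through DESeq2; these tests exercise the filter chain and
# the contract of the module, with small cohorts to keep runs quick.

test_that("identical counts in both groups give log2fc 0 for every miRNA", {
  # the cancer columns replicate the healthy columns exactly, so the fitted
  # group ratio must vanish for every miRNA
  set.seed(21)
  half <- matrix(rnbinom(100 * 4, mu = 80, size = 10), 100, 4)
  x <- make_counts(cbind(half, half))
  meta <- data.frame(sample_id = sample_ids(x),
                     group = rep(c("cancer", "healthy"), each = 4))
  de <- nb_de_test(x, meta)
  expect_true(all(abs(de$log2fc) < 1e-5))
  expect_true(all(de$fdr >= de$pvalue - 1e-12, na.rm = TRUE))
})

test_that("nb_de_test enforces group sizes and drops all-zero rows", {
  set.seed(3)
  vals <- matrix(rpois(30 * 6, 40), 30, 6)
  vals[5, ] <- 0
  x <- make_counts(vals)
  meta <- data.frame(sample_id = sample_ids(x),
                     group = c("cancer", rep("healthy", 5)))
  expect_error(nb_de_test(x, meta), "at least 2 samples")

  meta$group <- rep(c("cancer", "healthy"), 3)
  expect_message(de <- nb_de_test(x, meta), "1 all-zero")
  expect_false(mirna_ids(x)[5] %in% de$mirna_id)
  expect_equal(nrow(de), 29)
})

test_that("nb_de_test recovers a planted 4-fold change", {
  spec <- synthetic_cohort_spec(n_mirna = 400, n_de = 30,
                                log2fc_range = c(2, 2), nb_dispersion = 0.05,
                                mean_cpm_range = c(20, 2000), seed = 77)
  coh <- synthetic_cohort(spec)
  de <- nb_de_test(coh$counts, coh$meta)
  planted <- merge(de, coh$truth[coh$truth$is_de, ], by = "mirna_id")
  expect_equal(nrow(planted), 30)
  hit <- abs(planted$log2fc - planted$true_log2fc) <= 0.3
  expect_gte(mean(hit), 0.9)
})

test_that("variance_filter keeps stable and drops noisy miRNAs", {
  # log2(CPM+1) values: row 1 constant per group (var 0), row 2 alternates
  # 0 <-> 4 within each group (var 16/3 > 2), row 3 mildly variable
  to_cpm <- function(l2) 2^l2 - 1
  vals <- rbind(to_cpm(c(5, 5, 5, 2, 2, 2)),
                to_cpm(c(0, 4, 0, 4, 0, 4)),
                to_cpm(c(3, 3.5, 3.1, 1, 1.2, 0.9)))
  x <- make_counts(vals, scale = "cpm")
  meta <- data.frame(sample_id = sample_ids(x),
                     group = rep(c("cancer", "healthy"), each = 3))
  kept <- variance_filter(x, meta)
  expect_true(mirna_ids(x)[1] %in% kept)
  expect_false(mirna_ids(x)[2] %in% kept)
  expect_true(mirna_ids(x)[3] %in% kept)
  expect_identical(variance_filter(x, meta, var_threshold = Inf),
                   mirna_ids(x))
})

test_that("build_signature applies strict thresholds via an external DE table", {
  set.seed(5)
  vals <- matrix(rpois(6 * 8, 200) + 50, 6, 8)
  x <- make_counts(vals)
  meta <- data.frame(sample_id = sample_ids(x),
                     group = rep(c("cancer", "healthy"), each = 4))
  de <- data.frame(
    mirna_id = mirna_ids(x),
    log2fc = c(2.5, 1.0, -1.5, 3.0, 0.2, -2.0),   # row 2 sits on the boundary
    fdr =    c(1e-4, 1e-4, 0.01, 1e-3, 1e-4, 5e-3) # row 3 sits on the boundary
  )
  sig <- build_signature(x, meta, de_table = de)
  expect_setequal(sig$mirna_ids, mirna_ids(x)[c(1, 4, 6)])
  expect_equal(sig$provenance$n_cancer, 4)

  # all rows fail -> empty-signature error advising relaxation
  de_null <- transform(de, fdr = 0.5)
  expect_error(build_signature(x, meta, de_table = de_null), "relaxing")
})

test_that("signature E holds the per-group mean CPM", {
  vals <- rbind(c(100, 300, 10, 30), c(8, 12, 400, 600), c(50, 50, 50, 50))
  x <- make_counts(vals)
  meta <- data.frame(sample_id = sample_ids(x),
                     group = rep(c("cancer", "healthy"), each = 2))
  de <- data.frame(mirna_id = mirna_ids(x), log2fc = c(3, -3, 0),
                   fdr = c(1e-5, 1e-5, 1))
  sig <- build_signature(x, meta, de_table = de)
  cpm <- cpm_normalize(x)$values
  expect_equal(sig$E[, "cancer"],
               rowMeans(cpm[sig$mirna_ids, 1:2, drop = FALSE]))
  expect_equal(sig$E[, "healthy"],
               rowMeans(cpm[sig$mirna_ids, 3:4, drop = FALSE]))
})

test_that("the signature set is invariant to sample and miRNA order", {
  coh <- synthetic_cohort(synthetic_cohort_spec(n_mirna = 120, n_de = 8,
                                                n_cancer = 6, n_healthy = 6,
                                                seed = 13))
  sig1 <- build_signature(coh$counts, coh$meta)
  set.seed(99)
  perm_r <- sample(nrow(coh$counts$values))
  perm_c <- sample(ncol(coh$counts$values))
  shuffled <- count_matrix(coh$counts$values[perm_r, perm_c], "raw_counts")
  sig2 <- build_signature(shuffled, coh$meta[perm_c, ])
  expect_setequal(sig1$mirna_ids, sig2$mirna_ids)
  expect_equal(sig1$E[sort(sig1$mirna_ids), ], sig2$E[sort(sig1$mirna_ids), ],
               tolerance = 1e-10)
})

test_that("signature_profile rejects degenerate inputs", {
  expect_error(signature_profile("a", matrix(1:2, 1, 2)), "at least 2")
  E_flat <- cbind(c(10, 20), c(10, 5))
  expect_error(signature_profile(c("a", "b"), E_flat), "a")
  expect_error(signature_profile(c("a", "b"), cbind(c(-1, 2), c(3, 4))),
               "non-negative")
})

test_that("pan-cancer signature applies the strict 'more than k cancers' rule", {
  base_E <- cbind(c(100, 200, 300, 400), c(10, 20, 30, 40))
  mk <- function(ids, rows) signature_profile(ids, base_E[rows, , drop = FALSE])
  # mir-a appears in 6 of 11 signatures, mir-b in 5 of 11, mir-c/d in all
  sigs <- lapply(1:11, function(k) {
    ids <- c("mir-c", "mir-d", if (k <= 6) "mir-a", if (k <= 5) "mir-b")
    rows <- c(3, 4, if (k <= 6) 1, if (k <= 5) 2)
    mk(ids, rows)
  })
  pan <- pan_cancer_signature(sigs, min_cancer_count = 5)
  expect_setequal(pan$mirna_ids, c("mir-c", "mir-d", "mir-a"))

  # three identical signatures -> output equals each input
  trio <- lapply(1:3, function(k) mk(c("m1", "m2", "m3"), 1:3))
  out <- pan_cancer_signature(trio, min_cancer_count = 2)
  expect_identical(out$mirna_ids, c("m1", "m2", "m3"))
  expect_equal(unname(out$E), unname(base_E[1:3, ]))

  expect_error(pan_cancer_signature(trio, min_cancer_count = 5), "at least 6")
})

test_that("pan-cancer E is the unweighted mean over the cancers carrying it", {
  s1 <- signature_profile(c("x", "y"), cbind(c(10, 100), c(1, 2)))
  s2 <- signature_profile(c("x", "y"), cbind(c(30, 200), c(3, 4)))
  s3 <- signature_profile(c("x", "z"), cbind(c(50, 7), c(5, 1)))
  pan <- pan_cancer_signature(list(s1, s2, s3), min_cancer_count = 1)
  expect_setequal(pan$mirna_ids, c("x", "y"))
  expect_equal(unname(pan$E["x", ]), c(mean(c(10, 30, 50)), mean(c(1, 3, 5))))
  expect_equal(unname(pan$E["y", ]), c(150, 3))
})

test_that("signature TSV round-trips through write/read", {
  sig <- toy_signature()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$mirna_ids, sig$mirna_ids)
  expect_equal(back$E, sig$E, tolerance = 1e-12)
})
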