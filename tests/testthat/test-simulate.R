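test_that("mix_profiles matches its defining arithmetic", {
  can <- c(a = 100, b = 0)
  hea <- c(a = 0, b = 40)
  expect_identical(mix_profiles(can, hea, 1), can)
  expect_identical(mix_profiles(can, hea, 0), hea)
  expect_equal(unname(mix_profiles(100, 0, 0.3)), 30)
  expect_error(mix_profiles(can, hea, 1.2), "\\[0, 1\\]")
  expect_error(mix_profiles(can, hea[1], 0.5), "equal length")
  expect_error(mix_profiles(can, rev(hea), 0.5), "aligned")
})

test_that("mixing is affine: a mixture of mixtures is a single mixture", {
  set.seed(31)
  can <- runif(20, 0, 1000)
  hea <- runif(20, 0, 1000)
  for (rep in 1:20) {
    a <- runif(1); b <- runif(1); p <- runif(1)
    two_step <- mix_profiles(mix_profiles(can, hea, a),
                             mix_profiles(can, hea, b), p)
    one_step <- mix_profiles(can, hea, p * a + (1 - p) * b)
    expect_equal(two_step, one_step, tolerance = 1e-12)
  }
})

test_that("purity_grid spans the requested interval", {
  expect_equal(purity_grid(0, 1, 3), c(0, 0.5, 1))
  expect_equal(purity_grid(0, 0.1, 11), seq(0, 0.1, by = 0.01))
  g <- purity_grid(0.2, 0.8, 13)
  expect_true(all(g >= 0.2 & g <= 0.8))
  expect_identical(g, sort(g))
  expect_error(purity_grid(0.5, 0.5, 5), "lo < hi")
  expect_error(purity_grid(0, 1, 1), "at least 2")
})

test_that("noiseless single-source mixtures are exact endpoint blends", {
  src <- toy_sources()
  design <- mixture_design(c(0, 0.5, 1), noise_sd = 0, seed = 4)
  sim <- simulate_cohort(src$cancer, src$healthy, design)
  expect_equal(unname(sim$mixtures$values[, 1]),
               unname(src$healthy$values[, 1]))
  expect_equal(unname(sim$mixtures$values[, 3]),
               unname(src$cancer$values[, 1]))
  expect_equal(unname(sim$mixtures$values[, 2]),
               unname(0.5 * src$cancer$values[, 1] +
                        0.5 * src$healthy$values[, 1]))
})

test_that("the same design reproduces the same cohort bit for bit", {
  src <- toy_sources()
  design <- mixture_design(purity_grid(0, 1, 15), noise_sd = 3, seed = 12,
                           source = "sample")
  s1 <- simulate_cohort(src$cancer, src$healthy, design)
  s2 <- simulate_cohort(src$cancer, src$healthy, design)
  expect_identical(s1$mixtures$values, s2$mixtures$values)
  d2 <- mixture_design(purity_grid(0, 1, 15), noise_sd = 3, seed = 13,
                       source = "sample")
  s3 <- simulate_cohort(src$cancer, src$healthy, d2)
  expect_false(identical(s1$mixtures$values, s3$mixtures$values))
})

test_that("added noise has the designed standard deviation", {
  # constant clean profiles far above 5*sigma, so truncation is negligible
  n <- 2000
  flat <- make_counts(matrix(1000, n, 1), scale = "cpm")
  design <- mixture_design(rep(0.5, 10), noise_sd = 5, seed = 8)
  sim <- simulate_cohort(flat, flat, design)
  noise <- sim$mixtures$values - 1000
  expect_equal(sd(noise), 5, tolerance = 0.05 * 5)
  expect_equal(mean(noise), 0, tolerance = 0.2)
})

test_that("negative noisy expression is truncated at zero", {
  tiny <- make_counts(matrix(0.5, 200, 1), scale = "cpm")
  design <- mixture_design(rep(0.5, 5), noise_sd = 5, seed = 2)
  sim <- simulate_cohort(tiny, tiny, design)
  expect_true(all(sim$mixtures$values >= 0))
  expect_true(any(sim$mixtures$values == 0))
})

test_that("synthetic cohorts are reproducible and carry a faithful truth table", {
  spec <- synthetic_cohort_spec(n_mirna = 100, n_de = 10, n_cancer = 5,
                                n_healthy = 7, seed = 42)
  c1 <- synthetic_cohort(spec)
  c2 <- synthetic_cohort(spec)
  expect_identical(c1$counts$values, c2$counts$values)
  expect_equal(sum(c1$truth$is_de), 10)
  expect_true(all(abs(c1$truth$true_log2fc[c1$truth$is_de]) == 3))
  expect_true(all(c1$truth$true_log2fc[!c1$truth$is_de] == 0))
  expect_equal(table(c1$meta$group)[["cancer"]], 5)
  expect_equal(dim(c1$counts$values), c(100, 12))
})

test_that("synthetic counts follow the negative-binomial moments", {
  mu_cpm <- 200
  spec <- synthetic_cohort_spec(n_mirna = 2000, n_de = 0, n_cancer = 2,
                                n_healthy = 2, nb_dispersion = 0.1,
                                baseline_cpm = rep(mu_cpm, 2000),
                                library_size = 1e6, seed = 6)
  coh <- synthetic_cohort(spec)
  x <- as.vector(coh$counts$values)   # 8000 draws from NB(mu=200, disp=0.1)
  expect_equal(mean(x), 200, tolerance = 0.03 * 200)
  expect_equal(var(x), 200 + 0.1 * 200^2, tolerance = 0.15 * (200 + 4000))
})

test_that("pan-cancer cohorts share planted miRNAs with consistent effects", {
  pm <- synthetic_pan_cancer(n_types = 3, n_shared = 10, n_private = 5,
                             n_mirna = 120, n_cancer = 4, n_healthy = 4,
                             seed = 19)
  expect_length(pm$cohorts, 3)
  expect_length(pm$shared_mirnas, 10)
  shared_fc <- sapply(pm$cohorts, function(co) {
    tr <- co$truth
    tr$true_log2fc[match(pm$shared_mirnas, tr$mirna_id)]
  })
  expect_true(all(shared_fc != 0))
  expect_equal(shared_fc[, 1], shared_fc[, 2])
  expect_equal(shared_fc[, 1], shared_fc[, 3])
  # private DE miRNAs differ between types
  de_sets <- lapply(pm$cohorts, function(co) co$truth$mirna_id[co$truth$is_de])
  expect_equal(length(Reduce(intersect, de_sets)), 10)
})
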