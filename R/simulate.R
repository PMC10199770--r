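#' Mixture design for simulated cohorts
#'
#' Records the planted purities, the Gaussian noise level, how source
#' profiles are chosen and the RNG seed, so a simulated cohort is fully
#' reproducible from its design.
#'
#' @param purities Numeric vector of planted tumour purities in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   CPM scale (0 disables noise).
#' @param seed Integer seed; all randomness of [simulate_cohort()] flows
#'   through it.
#' @param source `"mean"` (default) mixes the group-mean expression profiles
#'   of the supplied source samples; `"sample"` draws one random cancer and
#'   one random healthy source column per mixture.
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(purities, noise_sd = 0, seed = 1L,
                           source = c("mean", "sample")) {
  source <- match.arg(source)
  if (anyNA(purities) || any(purities < 0 | purities > 1)) {
    stop("purities must lie in [0, 1]", call. = FALSE)
  }
  if (length(noise_sd) != 1 || is.na(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  structure(list(purities = as.numeric(purities), noise_sd = noise_sd,
                 seed = as.integer(seed), source = source),
            class = "mixture_design")
}

#' Mix two expression profiles at a known purity
#'
#' `out = purity * cancer + (1 - purity) * healthy`, elementwise.
#'
#' @param cancer_profile,healthy_profile Non-negative numeric vectors of equal
#'   length (and identical names, when named).
#' @param purity Mixing proportion of the cancer profile, in `[0, 1]`.
#' @return The mixed expression vector.
#' @export
mix_profiles <- function(cancer_profile, healthy_profile, purity) {
  if (length(cancer_profile) != length(healthy_profile)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  if (!is.null(names(cancer_profile)) && !is.null(names(healthy_profile)) &&
      !identical(names(cancer_profile), names(healthy_profile))) {
    stop("profiles must be aligned to the same miRNA ids", call. = FALSE)
  }
  if (any(cancer_profile < 0) || any(healthy_profile < 0)) {
    stop("profiles must be non-negative", call. = FALSE)
  }
  if (length(purity) != 1 || is.na(purity) || purity < 0 || purity > 1) {
    stop("purity must be a single value in [0, 1]", call. = FALSE)
  }
  purity * cancer_profile + (1 - purity) * healthy_profile
}

#' Evenly spaced purity grid
#'
#' @param lo,hi Grid limits with `0 <= lo < hi <= 1`.
#' @param n Number of grid points (>= 2), including both endpoints.
#' @return Sorted numeric vector of length `n`.
#' @export
purity_grid <- function(lo = 0, hi = 1, n = 100) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  }
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  seq(lo, hi, length.out = n)
}

#' Simulate serum-exosome mixtures of known tumour purity
#'
#' For each planted purity `x`, builds `x * cancer + (1 - x) * healthy` from
#' the source CPM profiles (group means by default, or randomly drawn source
#' columns; see [mixture_design()]), then adds i.i.d. Gaussian noise with the
#' design's SD on the CPM scale, truncating negative values at 0.
#'
#' @param cancer_samples,healthy_samples [count_matrix()] objects on the
#'   `cpm` scale with at least one sample each, sharing the same miRNA rows.
#' @param design A [mixture_design()].
#' @return A list with `mixtures` (a `cpm`-scale [count_matrix()], one column
#'   per planted purity, named `mix_001`, ...), `purities` (the planted
#'   vector) and the `design`.
#' @export
simulate_cohort <- function(cancer_samples, healthy_samples, design) {
  stopifnot(inherits(cancer_samples, "count_matrix"),
            inherits(healthy_samples, "count_matrix"),
            inherits(design, "mixture_design"))
  if (cancer_samples$scale != "cpm" || healthy_samples$scale != "cpm") {
    stop("source matrices must be on the CPM scale", call. = FALSE)
  }
  if (!identical(mirna_ids(cancer_samples), mirna_ids(healthy_samples))) {
    stop("source matrices must share identical miRNA rows", call. = FALSE)
  }
  n_mix <- length(design$purities)
  C <- cancer_samples$values
  H <- healthy_samples$values
  mix <- withr::with_seed(design$seed, {
    out <- matrix(0, nrow(C), n_mix)
    mean_c <- rowMeans(C)
    mean_h <- rowMeans(H)
    for (k in seq_len(n_mix)) {
      if (design$source == "mean") {
        src_c <- mean_c
        src_h <- mean_h
      } else {
        src_c <- C[, sample.int(ncol(C), 1)]
        src_h <- H[, sample.int(ncol(H), 1)]
      }
      v <- mix_profiles(src_c, src_h, design$purities[k])
      if (design$noise_sd > 0) {
        v <- pmax(v + stats::rnorm(length(v), 0, design$noise_sd), 0)
      }
      out[, k] <- v
    }
    out
  })
  dimnames(mix) <- list(mirna_ids(cancer_samples),
                        sprintf("mix_%03d", seq_len(n_mix)))
  list(mixtures = count_matrix(mix, scale = "cpm"),
       purities = design$purities,
       design = design)
}

#' Specification of a fully synthetic two-group cohort
#'
#' Describes a negative-binomial miRNA-Seq cohort with planted differential
#' expression: a shared baseline mean-CPM profile (log-uniform across
#' `mean_cpm_range`), a subset of `n_de` miRNAs whose cancer-group mean is
#' shifted by a signed log2 fold-change drawn from `log2fc_range`, and counts
#' drawn as `NB(mean = cpm / 1e6 * library_size, dispersion)`.
#'
#' @param n_mirna Number of miRNAs (default 500).
#' @param n_de Number of differentially expressed miRNAs (default 30).
#' @param n_cancer,n_healthy Samples per group (default 20 each).
#' @param log2fc_range Interval from which `|log2FC|` of planted miRNAs is
#'   drawn (default `c(3, 3)`, i.e. exactly 3); the sign is random.
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param mean_cpm_range Baseline mean-CPM interval, sampled log-uniformly
#'   (default `c(5, 5000)`).
#' @param library_size Expected sequencing depth per sample (default 2e6).
#' @param seed Integer seed.
#' @param mirna_ids,baseline_cpm,de_ids,de_log2fc Optional overrides fixing
#'   the miRNA labels, the baseline profile, which miRNAs are differentially
#'   expressed (indices or ids) and their signed log2 fold-changes; used to
#'   build related cohorts (e.g. several cancer types sharing miRNAs).
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_mirna = 500, n_de = 30, n_cancer = 20,
                                  n_healthy = 20, log2fc_range = c(3, 3),
                                  nb_dispersion = 0.05,
                                  mean_cpm_range = c(5, 5000),
                                  library_size = 2e6, seed = 1L,
                                  mirna_ids = NULL, baseline_cpm = NULL,
                                  de_ids = NULL, de_log2fc = NULL) {
  stopifnot(n_mirna >= 1, n_de >= 0, n_de <= n_mirna,
            n_cancer >= 1, n_healthy >= 1,
            length(log2fc_range) == 2, log2fc_range[1] <= log2fc_range[2],
            nb_dispersion > 0, length(mean_cpm_range) == 2,
            all(mean_cpm_range > 0),
            mean_cpm_range[1] <= mean_cpm_range[2], library_size > 0)
  if (!is.null(baseline_cpm)) stopifnot(length(baseline_cpm) == n_mirna,
                                        all(baseline_cpm > 0))
  if (!is.null(de_ids)) stopifnot(length(de_ids) == n_de)
  if (!is.null(de_log2fc)) stopifnot(length(de_log2fc) == n_de)
  structure(list(n_mirna = n_mirna, n_de = n_de, n_cancer = n_cancer,
                 n_healthy = n_healthy, log2fc_range = log2fc_range,
                 nb_dispersion = nb_dispersion,
                 mean_cpm_range = mean_cpm_range,
                 library_size = library_size, seed = as.integer(seed),
                 mirna_ids = mirna_ids, baseline_cpm = baseline_cpm,
                 de_ids = de_ids, de_log2fc = de_log2fc),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic two-group exosome cohort
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A list with `counts` (a `raw_counts` [count_matrix()]), `meta`
#'   (sample metadata data.frame) and `truth` (data.frame with `mirna_id`,
#'   `is_de`, `true_log2fc`).
#' @export
synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  withr::with_seed(spec$seed, {
    ids <- spec$mirna_ids %||% sprintf("syn-miR-%04d", seq_len(spec$n_mirna))
    base <- spec$baseline_cpm %||%
      exp(stats::runif(spec$n_mirna, log(spec$mean_cpm_range[1]),
                       log(spec$mean_cpm_range[2])))
    de_idx <- if (is.null(spec$de_ids)) {
      sample.int(spec$n_mirna, spec$n_de)
    } else if (is.character(spec$de_ids)) {
      match(spec$de_ids, ids)
    } else {
      as.integer(spec$de_ids)
    }
    if (anyNA(de_idx)) stop("de_ids not found among miRNA ids", call. = FALSE)
    lfc <- spec$de_log2fc %||%
      (sample(c(-1, 1), spec$n_de, replace = TRUE) *
         stats::runif(spec$n_de, spec$log2fc_range[1], spec$log2fc_range[2]))
    mu_healthy <- base
    mu_cancer <- base
    if (spec$n_de > 0) mu_cancer[de_idx] <- base[de_idx] * 2^lfc
    draw <- function(mu, n) {
      vapply(seq_len(n), function(j) {
        stats::rnbinom(length(mu), mu = mu / 1e6 * spec$library_size,
                       size = 1 / spec$nb_dispersion)
      }, numeric(length(mu)))
    }
    vals <- cbind(draw(mu_cancer, spec$n_cancer),
                  draw(mu_healthy, spec$n_healthy))
    dimnames(vals) <- list(ids, c(sprintf("cancer_%02d", seq_len(spec$n_cancer)),
                                  sprintf("healthy_%02d", seq_len(spec$n_healthy))))
    truth <- data.frame(mirna_id = ids, is_de = FALSE, true_log2fc = 0,
                        stringsAsFactors = FALSE)
    if (spec$n_de > 0) {
      truth$is_de[de_idx] <- TRUE
      truth$true_log2fc[de_idx] <- lfc
    }
    list(counts = count_matrix(vals, scale = "raw_counts"),
         meta = data.frame(
           sample_id = colnames(vals),
           group = rep(c("cancer", "healthy"),
                       c(spec$n_cancer, spec$n_healthy)),
           stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate related synthetic cohorts for several cancer types
#'
#' All types share one baseline expression profile and `n_shared` planted
#' differentially expressed miRNAs with a common signed log2 fold-change
#' (emulating miRNAs recurrently deregulated across cancers); each type adds
#' `n_private` private DE miRNAs. This is the fixture for the pan-cancer
#' signature ("present in more than five cancer types") workflow.
#'
#' @param n_types Number of cancer types (default 6).
#' @param n_shared Planted DE miRNAs shared by all types (default 40).
#' @param n_private Additional type-private DE miRNAs (default 15).
#' @param seed Integer seed; per-type cohort seeds are derived from it.
#' @inheritParams synthetic_cohort_spec
#' @return A list with `cohorts` (named list of [synthetic_cohort()] outputs),
#'   `shared_mirnas` (ids of the shared DE miRNAs) and `specs`.
#' @export
synthetic_pan_cancer <- function(n_types = 6, n_shared = 40, n_private = 15,
                                 n_mirna = 500, n_cancer = 20, n_healthy = 20,
                                 log2fc_range = c(3, 3), nb_dispersion = 0.05,
                                 mean_cpm_range = c(5, 5000),
                                 library_size = 2e6, seed = 1L) {
  stopifnot(n_types >= 2, n_shared >= 2,
            n_shared + n_types * n_private <= n_mirna)
  withr::with_seed(seed, {
    ids <- sprintf("syn-miR-%04d", seq_len(n_mirna))
    base <- exp(stats::runif(n_mirna, log(mean_cpm_range[1]),
                             log(mean_cpm_range[2])))
    shared_idx <- sample.int(n_mirna, n_shared)
    shared_lfc <- sample(c(-1, 1), n_shared, replace = TRUE) *
      stats::runif(n_shared, log2fc_range[1], log2fc_range[2])
    pool <- setdiff(seq_len(n_mirna), shared_idx)
    type_seeds <- sample.int(2^31 - 2, n_types)
    specs <- lapply(seq_len(n_types), function(k) {
      priv_idx <- if (n_private > 0) sample(pool, n_private) else integer(0)
      priv_lfc <- if (n_private > 0) {
        sample(c(-1, 1), n_private, replace = TRUE) *
          stats::runif(n_private, log2fc_range[1], log2fc_range[2])
      } else numeric(0)
      synthetic_cohort_spec(
        n_mirna = n_mirna, n_de = n_shared + n_private,
        n_cancer = n_cancer, n_healthy = n_healthy,
        log2fc_range = log2fc_range, nb_dispersion = nb_dispersion,
        mean_cpm_range = mean_cpm_range, library_size = library_size,
        seed = type_seeds[k], mirna_ids = ids, baseline_cpm = base,
        de_ids = c(shared_idx, priv_idx),
        de_log2fc = c(shared_lfc, priv_lfc))
    })
    names(specs) <- sprintf("type_%02d", seq_len(n_types))
    cohorts <- lapply(specs, synthetic_cohort)
    list(cohorts = cohorts, shared_mirnas = ids[shared_idx], specs = specs)
  })
}
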