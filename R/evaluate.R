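#' Pearson correlation between predicted and true values
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Pearson correlation is undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Mean absolute error
#'
#' @param x,y Numeric vectors of equal length.
#' @return `mean(|x - y|)`.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must have equal, positive length", call. = FALSE)
  }
  mean(abs(x - y))
}

#' Confusion-matrix metrics for tumour/normal classification
#'
#' Counts true/false positives and negatives (positive class: `tumour`) and
#' derives Precision, Recall, Specificity and F1. A ratio whose denominator
#' is zero is reported as `NA`, never as 0.
#'
#' @param truth,predicted Character (or factor) vectors of equal length with
#'   values `tumour` or `normal`.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  ok <- c("tumour", "normal")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'tumour' or 'normal'", call. = FALSE)
  }
  tp <- sum(truth == "tumour" & predicted == "tumour")
  fp <- sum(truth == "normal" & predicted == "tumour")
  tn <- sum(truth == "normal" & predicted == "normal")
  fn <- sum(truth == "tumour" & predicted == "normal")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = precision, recall = recall,
       specificity = ratio(tn, tn + fp), f1 = f1)
}

#' Purity-recovery benchmark across noise levels
#'
#' For each noise SD (0 = noiseless): simulate mixtures of known purity from
#' the source samples ([simulate_cohort()]), deconvolve them with the given
#' signature ([estimate_purity_matrix()]), and score predicted against
#' planted purity by Pearson correlation and MAE.
#'
#' @param sig A [signature_profile()].
#' @param cancer_sources,healthy_sources `cpm`-scale [count_matrix()] source
#'   samples.
#' @param grid Planted purity grid (default [purity_grid()] with 100 points
#'   on `[0, 1]`).
#' @param sigmas Gaussian noise SDs on the CPM scale
#'   (default `c(0, 1, 3, 5, 7, 9)`).
#' @param seed Integer seed; one sub-seed per noise level is derived from it.
#' @param source Mixture source mode, see [mixture_design()].
#' @return An object of class `benchmark_report`: list with `results` (one
#'   data.frame row per noise SD: `sigma`, `pearson_r`, `mae`), `n_samples`,
#'   `seed` and `config`.
#' @export
run_recovery_benchmark <- function(sig, cancer_sources, healthy_sources,
                                   grid = purity_grid(0, 1, 100),
                                   sigmas = c(0, 1, 3, 5, 7, 9),
                                   seed = 1L, source = c("mean", "sample")) {
  source <- match.arg(source)
  sub_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, length(sigmas)))
  rows <- lapply(seq_along(sigmas), function(k) {
    design <- mixture_design(grid, noise_sd = sigmas[k], seed = sub_seeds[k],
                             source = source)
    sim <- simulate_cohort(cancer_sources, healthy_sources, design)
    est <- estimate_purity_matrix(sim$mixtures, sig)
    data.frame(sigma = sigmas[k],
               pearson_r = pearson(sim$purities, est$alpha_tumour),
               mae = mae(sim$purities, est$alpha_tumour))
  })
  structure(list(results = do.call(rbind, rows),
                 n_samples = length(grid),
                 seed = seed,
                 config = list(grid_lo = min(grid), grid_hi = max(grid),
                               n_grid = length(grid), source = source,
                               n_signature = length(sig$mirna_ids))),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d mixtures per noise level, seed %d\n",
              x$n_samples, x$seed))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Serialize a benchmark report as JSON
#'
#' @param report A [run_recovery_benchmark()] result.
#' @param path Output path.
#' @export
write_benchmark_json <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Stratified evaluation split: held-out part plus cross-validation folds
#'
#' Partitions the cohort into `n_parts` parts, stratified by group (and by
#' `cancer_type` when present); the first part is held out as an independent
#' cohort and the remaining samples are folded `n_folds` ways, again
#' stratified. Deterministic given the seed.
#'
#' @param meta Sample metadata with `sample_id`, `group` and optionally
#'   `cancer_type`.
#' @param n_parts Number of parts (default 5).
#' @param n_folds Number of cross-validation folds over the non-held-out
#'   samples (default 3).
#' @param seed Integer seed.
#' @return A list with `holdout` (sample ids), `folds` (list of `n_folds`
#'   disjoint sample-id vectors covering the remainder) and `assignments`
#'   (data.frame with `sample_id`, `part`, `fold`).
#' @export
split_cohort <- function(meta, n_parts = 5, n_folds = 3, seed = 1L) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "group") %in% names(meta)),
            n_parts >= 2, n_folds >= 2)
  small <- table(meta$group) < n_parts
  if (any(small)) {
    stop("group(s) smaller than n_parts: ",
         paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  strata <- if ("cancer_type" %in% names(meta)) {
    paste(meta$group, ifelse(is.na(meta$cancer_type), "", meta$cancer_type))
  } else {
    meta$group
  }
  withr::with_seed(seed, {
    part <- integer(nrow(meta))
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      part[idx] <- rep_len(seq_len(n_parts), length(idx))
    }
    fold <- rep(NA_integer_, nrow(meta))
    rest <- part != 1
    for (s in unique(strata)) {
      idx <- sample(which(strata == s & rest))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    list(holdout = meta$sample_id[part == 1],
         folds = lapply(seq_len(n_folds),
                        function(f) meta$sample_id[!is.na(fold) & fold == f]),
         assignments = data.frame(sample_id = meta$sample_id,
                                  part = part, fold = fold,
                                  stringsAsFactors = FALSE))
  })
}
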