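#' Build the purity design matrix
#'
#' Assembles the two-column design `W` of the purity-corrected expression
#' model `Z = W beta + eps` with `beta = (m, mu)`: healthy samples contribute
#' rows `[1, 0]`, tumour samples rows `[1, lambda_j]` where `lambda_j` is the
#' sample's estimated tumour purity. The sample order of `meta` is recorded
#' and fixed.
#'
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param purities Purity table: a data.frame with `sample_id` and
#'   `alpha_tumour` (or `tumour_purity`), e.g. from
#'   [estimate_purity_matrix()]. Every tumour (cancer) sample needs an
#'   estimate; healthy samples need none.
#' @return An object of class `purity_design`: list with the design matrix
#'   `W` (rownames = sample ids), `sample_ids` and `group`.
#' @export
build_design <- function(meta, purities) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "group") %in% names(meta)))
  if (is.data.frame(purities)) {
    lam <- purities$alpha_tumour %||% purities$tumour_purity
    if (is.null(lam) || is.null(purities$sample_id)) {
      stop("purities needs columns sample_id and alpha_tumour", call. = FALSE)
    }
    lam <- stats::setNames(lam, purities$sample_id)
  } else {
    lam <- purities
    if (is.null(names(lam))) {
      stop("a purity vector must be named by sample_id", call. = FALSE)
    }
  }
  is_tum <- meta$group == "cancer"
  if (!any(is_tum)) {
    stop("no tumour samples: the design is rank deficient", call. = FALSE)
  }
  missing <- setdiff(meta$sample_id[is_tum], names(lam))
  if (length(missing)) {
    stop("tumour sample(s) without a purity estimate: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lambda <- ifelse(is_tum, lam[meta$sample_id], 0)
  if (anyNA(lambda) || any(lambda < 0 | lambda > 1)) {
    stop("purities must lie in [0, 1]", call. = FALSE)
  }
  if (all(lambda == 0)) {
    stop("all purities are 0: the design is rank deficient", call. = FALSE)
  }
  W <- cbind(intercept = 1, purity = as.numeric(lambda))
  rownames(W) <- meta$sample_id
  structure(list(W = W, sample_ids = meta$sample_id,
                 group = ifelse(is_tum, "cancer", "healthy")),
            class = "purity_design")
}

#' Fit the purity-corrected model for one miRNA
#'
#' Fits `Z = W beta + eps` by feasible generalized least squares with a
#' diagonal covariance holding two variance groups (healthy vs tumour): an
#' ordinary least squares pass estimates the residual variance within each
#' group, then one re-weighting pass gives
#' `beta = (W' S^-1 W)^-1 W' S^-1 Z`. The tumour effect `mu` (the expression
#' shift extrapolated to purity 1, on the `Z` scale) is Wald-tested against
#' the standard normal: `wald = mu / se(mu)`, `p = 2 (1 - Phi(|wald|))`.
#'
#' @param z Numeric expression vector over samples, in the design's sample
#'   order; `log2(CPM + 1)` is the intended scale, so that `mu` reads as a
#'   log2 fold-change.
#' @param design A [build_design()] object.
#' @param ols If `TRUE`, skip the re-weighting and report the ordinary least
#'   squares fit (single pooled residual variance). Default `FALSE`.
#' @return A list with `m_hat`, `mu_hat`, `se_mu`, `wald_stat`, `pvalue` and
#'   `log2fc` (equal to `mu_hat`).
#' @export
fit_corrected <- function(z, design, ols = FALSE) {
  stopifnot(inherits(design, "purity_design"))
  W <- design$W
  n <- nrow(W)
  if (length(z) != n || anyNA(z) || any(!is.finite(z))) {
    stop("z must hold one finite value per design row", call. = FALSE)
  }
  fit0 <- stats::lm.fit(W, z)
  res <- fit0$residuals
  if (ols) {
    s2 <- sum(res^2) / max(n - 2, 1)
    XtX <- crossprod(W)
    if (rcond(XtX) < 1e-14) stop("singular design", call. = FALSE)
    cov_beta <- s2 * solve(XtX)
    beta <- fit0$coefficients
  } else {
    tum <- design$group == "cancer"
    v <- numeric(n)
    v[tum] <- sum(res[tum]^2) / max(sum(tum) - 1, 1)
    v[!tum] <- sum(res[!tum]^2) / max(sum(!tum) - 1, 1)
    v <- pmax(v, 1e-8)
    w <- 1 / v
    WtSW <- crossprod(W * w, W)
    if (rcond(WtSW) < 1e-14) stop("singular design", call. = FALSE)
    cov_beta <- solve(WtSW)
    beta <- drop(cov_beta %*% crossprod(W * w, z))
  }
  mu <- beta[[2]]
  se <- sqrt(cov_beta[2, 2])
  wald <- mu / se
  list(m_hat = beta[[1]], mu_hat = mu, se_mu = se, wald_stat = wald,
       pvalue = 2 * stats::pnorm(-abs(wald)), log2fc = mu)
}

#' Purity-corrected differential expression table
#'
#' Fits [fit_corrected()] to every miRNA on the `log2(CPM + 1)` scale,
#' adjusts the p-values jointly by Benjamini-Hochberg, and flags significance
#' by `fdr < fdr_threshold` and `|log2fc| > lfc_threshold` (both strict).
#' Per-miRNA fit failures are recorded as NA rows and reported as a message,
#' never fatal.
#'
#' @param counts A [count_matrix()] (raw counts are CPM-normalized first; a
#'   `cpm`-scale matrix is used as is).
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param purities Purity table passed to [build_design()].
#' @param fdr_threshold Strict FDR cut-off (default 0.05).
#' @param lfc_threshold Strict `|log2FC|` cut-off (default 1).
#' @param ols Passed to [fit_corrected()].
#' @return A data.frame with one row per miRNA: `mirna_id`, `m_hat`,
#'   `mu_hat`, `se_mu`, `wald_stat`, `pvalue`, `fdr`, `log2fc`,
#'   `significant`.
#' @export
corrected_de_table <- function(counts, meta, purities, fdr_threshold = 0.05,
                               lfc_threshold = 1, ols = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  cpm <- if (counts$scale == "raw_counts") cpm_normalize(counts) else counts
  m <- match_meta(cpm, meta)
  design <- build_design(m, purities)
  lv <- log2(cpm$values[, design$sample_ids, drop = FALSE] + 1)
  fits <- vector("list", nrow(lv))
  failed <- 0L
  for (i in seq_len(nrow(lv))) {
    fits[[i]] <- tryCatch(fit_corrected(lv[i, ], design, ols = ols),
                          error = function(e) {
                            failed <<- failed + 1L
                            list(m_hat = NA_real_, mu_hat = NA_real_,
                                 se_mu = NA_real_, wald_stat = NA_real_,
                                 pvalue = NA_real_, log2fc = NA_real_)
                          })
  }
  if (failed > 0) {
    message("corrected_de_table: ", failed, " miRNA fit(s) failed (NA rows)")
  }
  grab <- function(f) vapply(fits, `[[`, numeric(1), f)
  out <- data.frame(
    mirna_id = rownames(lv),
    m_hat = grab("m_hat"), mu_hat = grab("mu_hat"), se_mu = grab("se_mu"),
    wald_stat = grab("wald_stat"), pvalue = grab("pvalue"),
    fdr = stats::p.adjust(grab("pvalue"), method = "BH"),
    log2fc = grab("log2fc"),
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold &
    abs(out$log2fc) > lfc_threshold
  attr(out, "thresholds") <- list(fdr = fdr_threshold, lfc = lfc_threshold,
                                  ols = ols)
  out
}

#' Write a (corrected) differential expression table as TSV
#'
#' @param de A data.frame from [corrected_de_table()] or [nb_de_test()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  params <- attr(de, "thresholds") %||% list()
  write_tsv_commented(de, path, params)
}
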