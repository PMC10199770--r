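#' Negative-binomial differential expression test (cancer vs healthy)
#'
#' Per-miRNA Wald test of cancer against healthy exosome samples, run through
#' DESeq2 (median-of-ratios size factors, negative-binomial GLM with a group
#' indicator, Wald p-value on the group coefficient). The log2 fold-change is
#' the unshrunken fitted group ratio. FDR is recomputed here by
#' Benjamini-Hochberg over the full p-value vector, with DESeq2's independent
#' filtering and outlier handling disabled so every tested miRNA keeps a row.
#'
#' All-zero miRNA rows are dropped before testing (the number dropped is
#' reported as a message). Non-integer raw counts are rounded, as the
#' negative-binomial model is defined on integers.
#'
#' @param counts A [count_matrix()] on the `raw_counts` scale.
#' @param meta Sample metadata with columns `sample_id` and `group`; every
#'   group needs at least 2 samples.
#' @param quiet Suppress DESeq2 progress messages (default `TRUE`).
#' @return A data.frame with columns `mirna_id`, `base_mean`, `log2fc`
#'   (cancer vs healthy), `pvalue`, `fdr`, in input row order.
#' @export
nb_de_test <- function(counts, meta, quiet = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (counts$scale != "raw_counts") {
    stop("nb_de_test() needs raw counts, not '", counts$scale, "'",
         call. = FALSE)
  }
  m <- match_meta(counts, meta)
  n_per <- table(m$group)
  if (any(n_per < 2)) {
    stop("each group needs at least 2 samples (healthy: ", n_per[["healthy"]],
         ", cancer: ", n_per[["cancer"]], ")", call. = FALSE)
  }
  vals <- round(counts$values)
  keep <- rowSums(vals) > 0
  if (any(!keep)) {
    message("nb_de_test: dropped ", sum(!keep), " all-zero miRNA row(s)")
    vals <- vals[keep, , drop = FALSE]
  }
  storage.mode(vals) <- "integer"
  run <- function() {
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = vals,
      colData = data.frame(group = m$group, row.names = colnames(vals)),
      design = ~group)
    dds <- DESeq2::DESeq(dds, quiet = quiet)
    DESeq2::results(dds, contrast = c("group", "cancer", "healthy"),
                    independentFiltering = FALSE, cooksCutoff = FALSE)
  }
  res <- if (quiet) suppressWarnings(suppressMessages(run())) else run()
  data.frame(
    mirna_id = rownames(vals),
    base_mean = res$baseMean,
    log2fc = res$log2FoldChange,
    pvalue = res$pvalue,
    fdr = stats::p.adjust(res$pvalue, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' Within-group expression stability filter
#'
#' Keeps the miRNAs whose `log2(CPM + 1)` variance is strictly below
#' `var_threshold` within the cancer group AND within the healthy group.
#' Raw-CPM variance is never below 2 for expressed miRNAs, so the filter is
#' defined on the log scale.
#'
#' @param cpm A [count_matrix()] on the `cpm` scale.
#' @param meta Sample metadata (both groups must be present).
#' @param var_threshold Strict upper bound on the within-group variance
#'   (default 2).
#' @return Character vector of retained miRNA ids, in input row order.
#' @export
variance_filter <- function(cpm, meta, var_threshold = 2) {
  stopifnot(inherits(cpm, "count_matrix"))
  if (cpm$scale != "cpm") {
    stop("variance_filter() expects CPM values", call. = FALSE)
  }
  m <- match_meta(cpm, meta)
  if (!all(c("cancer", "healthy") %in% as.character(m$group))) {
    stop("both a cancer and a healthy group are required", call. = FALSE)
  }
  lv <- log2(cpm$values + 1)
  v_can <- apply(lv[, m$group == "cancer", drop = FALSE], 1, stats::var)
  v_hea <- apply(lv[, m$group == "healthy", drop = FALSE], 1, stats::var)
  mirna_ids(cpm)[v_can < var_threshold & v_hea < var_threshold]
}

#' Construct a signature profile
#'
#' The signature expression profile E: for each signature miRNA, the mean CPM
#' in cancer cell-derived exosomes (column `cancer`) and in healthy
#' cell-derived exosomes (column `healthy`). E is kept on the linear CPM scale
#' because the mixture model is linear in expression.
#'
#' @param mirna_ids Character vector of at least 2 unique miRNA ids.
#' @param E Numeric m x 2 matrix of non-negative mean expression values,
#'   cancer then healthy. A row with identical values in both columns carries
#'   no deconvolution signal and is rejected.
#' @param provenance Optional list recording thresholds and sample counts.
#' @return An object of class `signature_profile`.
#' @export
signature_profile <- function(mirna_ids, E, provenance = list()) {
  E <- as.matrix(E)
  if (!is.character(mirna_ids) || length(mirna_ids) != nrow(E) || ncol(E) != 2) {
    stop("E must be an m x 2 matrix matching `mirna_ids`", call. = FALSE)
  }
  if (anyDuplicated(mirna_ids)) {
    stop("duplicated miRNA id in signature", call. = FALSE)
  }
  if (length(mirna_ids) < 2) {
    stop("a signature needs at least 2 miRNAs", call. = FALSE)
  }
  if (anyNA(E) || any(E < 0)) {
    stop("signature expression values must be non-negative and complete",
         call. = FALSE)
  }
  flat <- E[, 1] == E[, 2]
  if (any(flat)) {
    stop("no deconvolution signal (identical cancer/healthy expression) for: ",
         paste(mirna_ids[flat], collapse = ", "), call. = FALSE)
  }
  dimnames(E) <- list(mirna_ids, c("cancer", "healthy"))
  structure(list(mirna_ids = mirna_ids, E = E, provenance = provenance),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("signature_profile: %d miRNAs\n", length(x$mirna_ids)))
  pv <- x$provenance
  if (length(pv)) {
    cat("  provenance:",
        paste(names(pv), vapply(pv, function(p) paste(format(p), collapse = ","),
                                character(1)),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Build an miRNA signature from a cohort
#'
#' Selects miRNAs that are differentially expressed between cancer- and
#' healthy-derived exosomes (`|log2FC| > lfc_threshold` and
#' `FDR < fdr_threshold`, strict) and stably expressed within each group
#' (log2-CPM variance strictly below `var_threshold` in both groups), then
#' averages their CPM per group into the signature profile E.
#'
#' @inheritParams nb_de_test
#' @param lfc_threshold Strict lower bound on `|log2FC|` (default 1).
#' @param fdr_threshold Strict upper bound on the BH FDR (default 0.01).
#' @param var_threshold Passed to [variance_filter()] (default 2).
#' @param de_table Optional precomputed DE table (data.frame with columns
#'   `mirna_id`, `log2fc`, `fdr`), e.g. an external DESeq2 result; bypasses
#'   the internal test.
#' @return A [signature_profile()].
#' @export
build_signature <- function(counts, meta, lfc_threshold = 1,
                            fdr_threshold = 0.01, var_threshold = 2,
                            de_table = NULL, quiet = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(de_table)) {
    de_table <- nb_de_test(counts, meta, quiet = quiet)
  } else if (!all(c("mirna_id", "log2fc", "fdr") %in% names(de_table))) {
    stop("de_table needs columns mirna_id, log2fc, fdr", call. = FALSE)
  }
  de_ok <- !is.na(de_table$log2fc) & !is.na(de_table$fdr) &
    abs(de_table$log2fc) > lfc_threshold & de_table$fdr < fdr_threshold
  de_set <- de_table$mirna_id[de_ok]
  cpm <- cpm_normalize(counts)
  stable <- variance_filter(cpm, meta, var_threshold = var_threshold)
  sig <- intersect(mirna_ids(counts), intersect(de_set, stable))
  if (length(sig) == 0) {
    stop("empty signature: no miRNA passed |log2FC| > ", lfc_threshold,
         ", FDR < ", fdr_threshold, " and variance < ", var_threshold,
         "; consider relaxing the thresholds", call. = FALSE)
  }
  m <- match_meta(cpm, meta)
  sub <- cpm$values[sig, , drop = FALSE]
  E <- cbind(rowMeans(sub[, m$group == "cancer", drop = FALSE]),
             rowMeans(sub[, m$group == "healthy", drop = FALSE]))
  flat <- E[, 1] == E[, 2]
  if (any(flat)) {
    warning("dropped ", sum(flat),
            " signature miRNA(s) with identical group means")
    sig <- sig[!flat]
    E <- E[!flat, , drop = FALSE]
  }
  if (length(sig) < 2) {
    stop("fewer than 2 signature miRNAs remain; consider relaxing thresholds",
         call. = FALSE)
  }
  signature_profile(
    sig, E,
    provenance = list(lfc_threshold = lfc_threshold,
                      fdr_threshold = fdr_threshold,
                      var_threshold = var_threshold,
                      n_cancer = sum(m$group == "cancer"),
                      n_healthy = sum(m$group == "healthy"))
  )
}

#' Assemble a pan-cancer signature
#'
#' Keeps the miRNAs that appear in strictly more than `min_cancer_count` of
#' the per-cancer signatures, averaging (unweighted) each miRNA's cancer and
#' healthy mean expression over the cancers in which it appears.
#'
#' @param signatures Named list of [signature_profile()] objects, one per
#'   cancer type; needs at least `min_cancer_count + 1` entries.
#' @param min_cancer_count A miRNA must appear in more than this many
#'   signatures to be retained (default 5, i.e. "more than five cancers").
#' @return A [signature_profile()].
#' @export
pan_cancer_signature <- function(signatures, min_cancer_count = 5) {
  if (!is.list(signatures) ||
      !all(vapply(signatures, inherits, logical(1), "signature_profile"))) {
    stop("`signatures` must be a list of signature_profile objects",
         call. = FALSE)
  }
  if (length(signatures) < min_cancer_count + 1) {
    stop("need at least ", min_cancer_count + 1, " per-cancer signatures",
         call. = FALSE)
  }
  all_ids <- unlist(lapply(signatures, `[[`, "mirna_ids"), use.names = FALSE)
  freq <- table(all_ids)
  uniq <- unique(all_ids)                      # first-appearance order
  keep <- uniq[freq[uniq] > min_cancer_count]
  if (length(keep) == 0) {
    stop("no miRNA is shared by more than ", min_cancer_count,
         " cancer types", call. = FALSE)
  }
  E <- t(vapply(keep, function(id) {
    rows <- lapply(signatures, function(s) {
      if (id %in% s$mirna_ids) s$E[id, ] else NULL
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    colMeans(rows)
  }, numeric(2)))
  signature_profile(keep, E,
                    provenance = list(min_cancer_count = min_cancer_count,
                                      n_cancers = length(signatures)))
}

#' Write / read a signature profile as TSV
#'
#' Columns `mirna_id`, `E_cancer`, `E_healthy`, preceded by a `#` header line
#' recording the tool version and selection thresholds.
#'
#' @param sig A [signature_profile()].
#' @param path Output (input) file path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_profile"))
  df <- data.frame(mirna_id = sig$mirna_ids,
                   E_cancer = sig$E[, "cancer"],
                   E_healthy = sig$E[, "healthy"],
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, sig$provenance)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("mirna_id", "E_cancer", "E_healthy") %in% names(df))) {
    stop("signature file needs columns mirna_id, E_cancer, E_healthy",
         call. = FALSE)
  }
  signature_profile(as.character(df$mirna_id),
                    cbind(df$E_cancer, df$E_healthy))
}
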