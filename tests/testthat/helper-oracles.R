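# Independent oracles and small fixture builders used across the suite.

# Closed-form solution of the two-component simplex least squares:
# alpha1 = clip((E1-E2)'(t - E2) / ||E1-E2||^2, 0, 1).
closed_form_alpha <- function(t_vec, E) {
  d <- E[, 1] - E[, 2]
  min(max(sum(d * (t_vec - E[, 2])) / sum(d^2), 0), 1)
}

# Brute-force grid search over alpha1 on a fixed step, evaluating the
# objective ||E alpha - t||^2 directly.
grid_search_alpha <- function(t_vec, E, step = 1e-4) {
  a <- seq(0, 1, by = step)
  sse <- vapply(a, function(ai) {
    sum((E[, 1] * ai + E[, 2] * (1 - ai) - t_vec)^2)
  }, numeric(1))
  a[which.min(sse)]
}

# Benjamini-Hochberg by its definition: sort, p * n / rank, cumulative
# minimum from the largest p down, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

make_counts <- function(vals, mirnas = NULL, samples = NULL,
                        scale = "raw_counts") {
  vals <- as.matrix(vals)
  rownames(vals) <- mirnas %||% rownames(vals) %||%
    sprintf("mir-%02d", seq_len(nrow(vals)))
  colnames(vals) <- samples %||% colnames(vals) %||%
    sprintf("s%02d", seq_len(ncol(vals)))
  count_matrix(vals, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small hand-made signature with well-separated cancer/healthy columns.
toy_signature <- function(m = 5) {
  E <- cbind(cancer = c(800, 40, 300, 1200, 90)[seq_len(m)],
             healthy = c(100, 400, 30, 200, 900)[seq_len(m)])
  signature_profile(sprintf("mir-%02d", seq_len(m)), E)
}

# CPM source matrices matching toy_signature(): single-sample sources equal
# to the signature columns, padded with shared background rows.
toy_sources <- function(m = 5, n_background = 15) {
  sig <- toy_signature(m)
  bg <- matrix(rep(50, n_background), ncol = 1)
  can <- rbind(matrix(sig$E[, "cancer"], ncol = 1), bg)
  hea <- rbind(matrix(sig$E[, "healthy"], ncol = 1), bg)
  ids <- c(sig$mirna_ids, sprintf("bg-%02d", seq_len(n_background)))
  list(cancer = make_counts(can, ids, "c1", scale = "cpm"),
       healthy = make_counts(hea, ids, "h1", scale = "cpm"),
       sig = sig)
}

# Read back the package's commented-TSV outputs.
read_tsv_commented_for_test <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
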