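#' Construct a count matrix
#'
#' The universal expression carrier: a non-negative miRNA x sample matrix with
#' an explicit scale. The scale is declared, never guessed, because raw counts
#' (used for the negative-binomial test) and counts-per-million (used for
#' signatures and deconvolution) flow through the same functions.
#'
#' @param values Numeric matrix, miRNAs in rows, samples in columns. Row names
#'   are miRNA ids, column names are sample ids; both must be present and
#'   unique. All entries must be finite and non-negative.
#' @param scale Either `"raw_counts"` or `"cpm"`.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (the matrix), `scale`, and accessors [mirna_ids()] / [sample_ids()].
#' @seealso [read_counts()], [cpm_normalize()]
#' @export
count_matrix <- function(values, scale = c("raw_counts", "cpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry miRNA row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicated miRNA id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicated sample id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing or negative value at miRNA '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d miRNAs x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
mirna_ids <- function(x) rownames(x$values)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a count matrix from a delimited file
#'
#' Expects the first column to hold miRNA ids and the header row to hold
#' sample ids. Lines starting with `#` are ignored.
#'
#' @param path Path to an existing TSV/CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param scale Declared scale of the stored values; CPM tables are accepted
#'   directly when declared as such.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, dialect = c("tsv", "csv"),
                        scale = c("raw_counts", "cpm")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("no sample columns found in ", path, call. = FALSE)
  ids <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated miRNA id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop("duplicated sample id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value at miRNA '%s', sample '%s'",
                   ids[bad[1]], samples[j]), call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop(sprintf("negative value at miRNA '%s', sample '%s'",
                   ids[neg[1]], samples[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  count_matrix(vals, scale = scale)
}

#' Write a count matrix to a delimited file
#'
#' Values are written with 15 significant digits so that
#' `read_counts(write_counts(x))` reproduces `x` beyond 12 significant digits.
#'
#' @inheritParams read_counts
#' @param x A [count_matrix()].
#' @export
write_counts <- function(x, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(x, "count_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  body <- apply(x$values, 2, function(col) {
    formatC(col, digits = 15, format = "g")
  })
  df <- data.frame(mirna_id = mirna_ids(x), body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("mirna_id", sample_ids(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' A TSV with columns `sample_id`, `group` (`cancer` or `healthy`) and an
#' optional `cancer_type`.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_tsv_commented(path)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must have columns 'sample_id' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicated sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- !meta$group %in% c("cancer", "healthy")
  if (any(bad)) {
    stop("invalid group value(s): ", paste(unique(meta$group[bad]), collapse = ", "),
         "; expected 'cancer' or 'healthy'", call. = FALSE)
  }
  meta
}

#' Counts-per-million normalization
#'
#' Rescales every column to sum to one million: `value / column_sum * 1e6`.
#' CPM is computed against the per-column total of the provided matrix.
#'
#' @param x A [count_matrix()] on the `raw_counts` scale with strictly
#'   positive column sums.
#' @return A `count_matrix` on the `cpm` scale.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (x$scale != "raw_counts") {
    stop("cpm_normalize() expects raw counts; this matrix is already on the '",
         x$scale, "' scale", call. = FALSE)
  }
  cs <- colSums(x$values)
  zero <- which(cs == 0)
  if (length(zero)) {
    stop("zero-total sample(s): ", paste(sample_ids(x)[zero], collapse = ", "),
         call. = FALSE)
  }
  count_matrix(sweep(x$values, 2, cs, "/") * 1e6, scale = "cpm")
}
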