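# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

tool_version <- function() {
  as.character(utils::packageVersion("exopurity"))
}

# One-line "# exopurity <version> | key=value ..." header followed by a TSV
# body. Readers skip '#' lines, so round-trips stay lossless.
write_tsv_commented <- function(df, path, params = list()) {
  kv <- if (length(params)) {
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                character(1)),
          sep = "=", collapse = " ")
  } else ""
  header <- sprintf("# exopurity %s | %s", tool_version(), kv)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# Align metadata rows to a count matrix's samples; every sample must have
# exactly one metadata row and a non-missing group.
match_meta <- function(x, meta) {
  stopifnot(is.data.frame(meta))
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must have columns 'sample_id' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicated sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ids <- sample_ids(x)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing)) {
    stop("samples without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$group) || !all(m$group %in% c("cancer", "healthy"))) {
    stop("group must be 'cancer' or 'healthy' for every sample", call. = FALSE)
  }
  m$group <- factor(m$group, levels = c("healthy", "cancer"))
  rownames(m) <- NULL
  m
}
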