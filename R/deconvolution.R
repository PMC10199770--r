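#' Estimate tumour purity for one expression profile
#'
#' Solves the two-component deconvolution `T = E alpha + eps` by constrained
#' least squares on the probability simplex:
#' `argmin ||E alpha - T||^2` subject to `alpha >= 0` and
#' `alpha_tumour + alpha_healthy = 1`. The quadratic program (Hessian `E'E`,
#' linear term `E'T`, one equality and two bound constraints) is solved with
#' [quadprog::solve.QP()]. `T` is used as supplied, on the CPM scale, with no
#' per-sample renormalization to the signature subset.
#'
#' If `E'E` is near-singular (condition number above 1e12) a ridge term
#' `1e-10 * I` is added before solving. Solver round-off can leave components
#' a hair below zero; these are clamped to 0 and the pair renormalized to
#' sum to 1.
#'
#' @param t_vec Non-negative expression vector (CPM) over the signature
#'   miRNAs. If named, names must cover the signature's miRNA ids (values are
#'   aligned by name); if unnamed, its order must match `sig$mirna_ids`.
#' @param sig A [signature_profile()].
#' @return A list with `alpha_tumour`, `alpha_healthy` and `residual_norm`
#'   (`||E alpha - T||`).
#' @export
estimate_purity <- function(t_vec, sig) {
  stopifnot(inherits(sig, "signature_profile"))
  E <- sig$E
  if (!is.null(names(t_vec))) {
    missing <- setdiff(sig$mirna_ids, names(t_vec))
    if (length(missing)) {
      stop("expression vector lacks signature miRNA(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    t_vec <- t_vec[sig$mirna_ids]
  } else if (length(t_vec) != nrow(E)) {
    stop("expression vector length (", length(t_vec),
         ") does not match signature size (", nrow(E), ")", call. = FALSE)
  }
  if (anyNA(t_vec) || any(t_vec < 0)) {
    stop("expression vector must be non-negative and complete", call. = FALSE)
  }
  if (all(E[, 1] == E[, 2])) {
    stop("cancer and healthy signature columns are identical: purity is not ",
         "identifiable", call. = FALSE)
  }
  D <- crossprod(E)
  if (kappa(D, exact = TRUE) > 1e12) {
    D <- D + 1e-10 * diag(2)
  }
  d <- drop(crossprod(E, t_vec))
  # rescale the objective (solution-invariant) so the solver sees O(1) numbers
  # instead of squared-CPM magnitudes
  s <- max(D)
  # first constraint column is the sum-to-one equality, then alpha >= 0
  Amat <- cbind(c(1, 1), diag(2))
  sol <- quadprog::solve.QP(D / s, d / s, Amat, bvec = c(1, 0, 0),
                            meq = 1)$solution
  sol[sol < 0] <- 0
  sol <- sol / sum(sol)
  list(alpha_tumour = sol[1],
       alpha_healthy = sol[2],
       residual_norm = sqrt(sum((E %*% sol - t_vec)^2)))
}

#' Estimate tumour purity for every sample of a CPM matrix
#'
#' @param cpm A [count_matrix()] on the `cpm` scale whose rows cover the
#'   signature miRNAs.
#' @param sig A [signature_profile()].
#' @param allow_partial If some signature miRNAs are absent from `cpm`,
#'   restrict both the signature and the data to the shared set instead of
#'   failing (the restriction is reported as a message). Default `FALSE`.
#' @return A data.frame with columns `sample_id`, `alpha_tumour`,
#'   `alpha_healthy`, `residual_norm`, one row per sample in input order.
#' @export
estimate_purity_matrix <- function(cpm, sig, allow_partial = FALSE) {
  stopifnot(inherits(cpm, "count_matrix"), inherits(sig, "signature_profile"))
  if (cpm$scale != "cpm") {
    stop("estimate_purity_matrix() expects CPM values; run cpm_normalize() ",
         "first", call. = FALSE)
  }
  missing <- setdiff(sig$mirna_ids, mirna_ids(cpm))
  if (length(missing)) {
    if (!allow_partial) {
      stop("count matrix lacks signature miRNA(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    shared <- intersect(sig$mirna_ids, mirna_ids(cpm))
    if (length(shared) < 2) {
      stop("fewer than 2 signature miRNAs are present in the count matrix",
           call. = FALSE)
    }
    message("estimate_purity_matrix: restricting signature to ",
            length(shared), " of ", length(sig$mirna_ids), " miRNAs")
    sig <- signature_profile(shared, sig$E[shared, , drop = FALSE],
                             sig$provenance)
  }
  sub <- cpm$values[sig$mirna_ids, , drop = FALSE]
  res <- lapply(seq_len(ncol(sub)), function(j) {
    estimate_purity(sub[, j], sig)
  })
  data.frame(
    sample_id = sample_ids(cpm),
    alpha_tumour = vapply(res, `[[`, numeric(1), "alpha_tumour"),
    alpha_healthy = vapply(res, `[[`, numeric(1), "alpha_healthy"),
    residual_norm = vapply(res, `[[`, numeric(1), "residual_norm"),
    stringsAsFactors = FALSE
  )
}

#' Build the empirical null distribution of tumour purity
#'
#' Predicted tumour purities of healthy cell-derived exosome samples form the
#' null distribution H0 against which observed purities are tested.
#'
#' @param healthy_purities Numeric vector of purities in `[0, 1]`; at least
#'   10 values are required, and fewer than 20 triggers a warning.
#' @return An object of class `purity_null` with sorted `values` and `n`.
#' @export
build_null <- function(healthy_purities) {
  if (length(healthy_purities) == 0) {
    stop("no healthy-derived purities supplied", call. = FALSE)
  }
  if (anyNA(healthy_purities) || any(healthy_purities < 0 | healthy_purities > 1)) {
    stop("purities must lie in [0, 1]", call. = FALSE)
  }
  if (length(healthy_purities) < 10) {
    stop("at least 10 healthy-derived purities are needed for a usable null",
         call. = FALSE)
  }
  if (length(healthy_purities) < 20) {
    warning("fewer than 20 healthy-derived purities; the empirical null ",
            "will be coarse")
  }
  structure(list(values = sort(healthy_purities), n = length(healthy_purities)),
            class = "purity_null")
}

#' @export
print.purity_null <- function(x, ...) {
  cat(sprintf("purity_null: n=%d, median=%.4g, max=%.4g\n",
              x$n, stats::median(x$values), max(x$values)))
  invisible(x)
}

#' Classify samples against the healthy-derived null
#'
#' The empirical p-value uses the add-one (permutation-style) estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n)`, so p is never 0. A sample is
#' labelled `tumour` when `p < alpha_level`, otherwise `normal`.
#'
#' @param purity Either a numeric vector of tumour purities or the data.frame
#'   returned by [estimate_purity_matrix()] (column `alpha_tumour` is used and
#'   `sample_id` carried through).
#' @param null A [build_null()] object.
#' @param alpha_level Rejection threshold on the empirical p-value
#'   (default 0.05).
#' @return A data.frame with columns `sample_id`, `tumour_purity`, `p_value`,
#'   `label`.
#' @export
classify <- function(purity, null, alpha_level = 0.05) {
  stopifnot(inherits(null, "purity_null"))
  if (is.data.frame(purity)) {
    ids <- purity$sample_id %||% as.character(seq_len(nrow(purity)))
    vals <- purity$alpha_tumour %||% purity$tumour_purity
    if (is.null(vals)) {
      stop("purity data.frame needs an 'alpha_tumour' column", call. = FALSE)
    }
  } else {
    vals <- as.numeric(purity)
    ids <- names(purity) %||% as.character(seq_along(vals))
  }
  p <- vapply(vals, function(x) (1 + sum(null$values >= x)) / (1 + null$n),
              numeric(1))
  data.frame(sample_id = ids,
             tumour_purity = vals,
             p_value = p,
             label = ifelse(p < alpha_level, "tumour", "normal"),
             stringsAsFactors = FALSE)
}

#' Write a purity table as TSV
#'
#' @param purity Data.frame from [estimate_purity_matrix()] or [classify()].
#' @param path Output path.
#' @param params Optional named list recorded in the `#` header line.
#' @export
write_purity <- function(purity, path, params = list()) {
  write_tsv_commented(purity, path, params)
}
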