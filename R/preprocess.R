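#' Quantile normalization
#'
#' Forces every sample column to share one empirical distribution: the
#' reference distribution is the vector of per-rank means of the sorted
#' columns, and each column's values are replaced by the reference value at
#' their rank. Ties within a column receive the mean of the reference values
#' at their tied ranks, so the map is well defined and idempotent.
#'
#' @param matrix Numeric genes x samples matrix (log-scale intensities).
#' @return Matrix of the same shape and dimnames, quantile normalized.
#' @export
quantile_normalize <- function(matrix) {
  validate_expression(matrix)
  if (ncol(matrix) < 2L) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(matrix, 2L, sort, method = "radix"))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    col <- matrix[, j]
    tmp <- numeric(length(col))
    tmp[order(col, method = "radix")] <- ref
    # tied input values share the mean of their assigned reference values
    out[, j] <- stats::ave(tmp, col, FUN = mean)
  }
  out
}

#' Filter low-signal and low-variance genes
#'
#' Removes genes whose mean absolute expression falls strictly below the
#' `abs_percentile` quantile of per-gene means, and genes whose across-sample
#' variance falls strictly below the `var_percentile` quantile of per-gene
#' variances. Removal is the union of the two criteria by default (the
#' `combine` switch selects intersection instead). Quantiles use the
#' inclusive linear-interpolation convention (R type 7); a gene exactly at
#' the cut is kept.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param abs_percentile Fraction in `[0, 1)`; default 0.10.
#' @param var_percentile Fraction in `[0, 1)`; default 0.10.
#' @param combine `"union"` (default) or `"intersection"` of the two criteria.
#' @return List with `matrix` (filtered, row order preserved) and `report`,
#'   a list with `removed_low_abs`, `removed_low_var` and `kept` gene id sets.
#' @export
filter_low_signal <- function(matrix, abs_percentile = 0.10,
                              var_percentile = 0.10,
                              combine = c("union", "intersection")) {
  validate_expression(matrix)
  combine <- match.arg(combine)
  if (abs_percentile < 0 || abs_percentile >= 1 ||
      var_percentile < 0 || var_percentile >= 1)
    stop("filter percentiles must lie in [0, 1)")
  means <- rowMeans(matrix)
  vars <- apply(matrix, 1L, stats::var)
  low_abs <- means < stats::quantile(means, abs_percentile, type = 7L)
  low_var <- vars < stats::quantile(vars, var_percentile, type = 7L)
  drop <- if (combine == "union") low_abs | low_var else low_abs & low_var
  if (all(drop)) stop("filtering removed every gene")
  report <- list(removed_low_abs = rownames(matrix)[low_abs & drop],
                 removed_low_var = rownames(matrix)[low_var & drop],
                 kept = rownames(matrix)[!drop])
  list(matrix = matrix[!drop, , drop = FALSE], report = report)
}

#' Write a filter report as two-column TSV (gene_id, reason)
#' @param report Report list from [filter_low_signal()].
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  df <- rbind(
    data.frame(gene_id = report$removed_low_abs,
               reason = rep("low_abs", length(report$removed_low_abs))),
    data.frame(gene_id = report$removed_low_var,
               reason = rep("low_var", length(report$removed_low_var))),
    data.frame(gene_id = report$kept, reason = rep("kept", length(report$kept))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict an expression matrix to a gene signature
#'
#' Keeps the rows whose gene ids appear in the signature, preserving matrix
#' order. Signature genes absent from the matrix are reported with a warning,
#' not an error; an empty intersection is an error.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param signature Non-empty character vector of gene ids.
#' @return The row-subset matrix.
#' @export
subset_to_signature <- function(matrix, signature) {
  validate_expression(matrix)
  if (!length(signature)) stop("signature must be non-empty")
  missing <- setdiff(signature, rownames(matrix))
  keep <- rownames(matrix) %in% signature
  if (!any(keep)) stop("no signature gene present in the matrix")
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from the matrix: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  matrix[keep, , drop = FALSE]
}
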