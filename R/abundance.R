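#' Construct an abundance matrix
#'
#' Bundles a nonnegative feature-by-sample matrix (integer counts for
#' RNA-seq/Ribo-seq, reporter intensities for TMT proteomics) with the
#' condition label of each sample. This is the common currency of the
#' normalization, differential-abundance and translation-efficiency
#' functions.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature identifiers, column names sample identifiers.
#' @param conditions character or factor of length `ncol(values)` giving
#'   the condition of each sample. The first factor level is treated as
#'   the reference (control) condition throughout the package.
#' @return An object of class `abundance_matrix`: the values matrix with
#'   a `conditions` attribute (a factor).
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' am <- abundance_matrix(m, c("ctrl", "ctrl", "trt", "trt"))
#' conditions(am)
#' @export
abundance_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (anyNA(values)) {
    # NA is allowed (missing proteomics values); negatives are not
    if (any(values < 0, na.rm = TRUE)) stopf("negative values are not allowed")
  } else if (any(values < 0)) {
    stopf("negative values are not allowed")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate feature identifiers")
  if (length(conditions) != ncol(values)) {
    stopf("`conditions` length (%d) != number of samples (%d)",
          length(conditions), ncol(values))
  }
  cond <- if (is.factor(conditions)) droplevels(conditions) else
    factor(conditions, levels = unique(conditions))
  structure(values, conditions = cond, class = c("abundance_matrix", "matrix", "array"))
}

#' @rdname abundance_matrix
#' @param x an `abundance_matrix` (or normalized matrix carrying conditions).
#' @export
conditions <- function(x) attr(x, "conditions")

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  cat("conditions:", paste(sprintf("%s=%d", levels(conditions(x)),
                                   tabulate(conditions(x))), collapse = ", "), "\n")
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

# Rebuild the class/condition attributes after a plain-matrix operation.
restore_abundance <- function(values, template) {
  structure(values, conditions = conditions(template),
            class = c("abundance_matrix", "matrix", "array"))
}

#' Filter features before normalization and testing
#'
#' Always removes rows that are zero (or missing) in every sample. With
#' `require_complete = TRUE` it additionally applies the proteomics
#' completeness rule: a feature must be detected (finite, nonzero) in
#' every sample to be retained.
#'
#' @param matrix an [abundance_matrix()].
#' @param require_complete logical; drop rows with any missing/zero entry.
#' @return The filtered `abundance_matrix`, same row order as the input.
#' @export
filter_features <- function(matrix, require_complete = FALSE) {
  vals <- unclass(matrix)
  detected <- is.finite(vals) & vals > 0
  keep <- rowSums(detected) > 0L
  if (require_complete) keep <- rowSums(detected) == ncol(vals)
  if (!any(keep)) stopf("no feature survives filtering (all rows empty%s)",
                        if (require_complete) " or incomplete" else "")
  restore_abundance(vals[keep, , drop = FALSE], matrix)
}
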