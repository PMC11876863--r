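# Median-of-ratios normalization and Welch/BH differential abundance.
#
# The same engine serves counts (RNA-seq, Ribo-seq) and strictly positive
# intensities (TMT proteomics): a pseudo-reference per feature (geometric
# mean across samples), a per-sample size factor (median ratio to the
# pseudo-reference), division by the size factor, then a two-sided Welch
# t-test on log2 values with Benjamini-Hochberg correction.

#' Compute median-of-ratios size factors
#'
#' For each feature \eqn{i} the pseudo-reference is the geometric mean of
#' its values across samples, \eqn{R_i = \exp(\frac{1}{n}\sum_j \log I_{ij})};
#' the size factor of sample \eqn{j} is the median over features of
#' \eqn{I_{ij}/R_i}. Features with any zero or missing value are excluded
#' from the pseudo-reference and the median (the geometric mean is
#' undefined at zero) but are still normalized downstream.
#'
#' @param matrix an [abundance_matrix()] of nonnegative values.
#' @return A list of class `size_factors` with components
#'   `pseudo_reference` (named vector `R_i` over eligible features) and
#'   `size_factors` (named positive vector `S_j`, one per sample).
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' sf <- compute_size_factors(abundance_matrix(m, c("c", "t")))
#' sf$size_factors  # 1/sqrt(2), sqrt(2)
#' @export
compute_size_factors <- function(matrix) {
  vals <- unclass(matrix)
  eligible <- rowSums(!is.finite(vals) | vals <= 0) == 0L
  if (!any(eligible)) {
    stopf("no feature is strictly positive in all samples; size factors undefined")
  }
  v <- vals[eligible, , drop = FALSE]
  r <- exp(rowMeans(log(v)))
  s <- apply(v / r, 2L, stats::median)
  structure(list(pseudo_reference = r, size_factors = s),
            class = "size_factors")
}

#' Normalize by size factors
#'
#' Divides each sample column by its size factor: \eqn{N_{ij} = I_{ij}/S_j}.
#'
#' @param matrix an [abundance_matrix()].
#' @param sf a `size_factors` object from [compute_size_factors()], or a
#'   named numeric vector covering every sample.
#' @return A normalized `abundance_matrix` (conditions preserved).
#' @export
normalize_matrix <- function(matrix, sf = compute_size_factors(matrix)) {
  s <- if (inherits(sf, "size_factors")) sf$size_factors else sf
  missing <- setdiff(colnames(matrix), names(s))
  if (length(missing)) {
    stopf("no size factor for sample(s): %s", paste(missing, collapse = ", "))
  }
  s <- s[colnames(matrix)]
  if (any(!is.finite(s) | s <= 0)) stopf("size factors must be finite and > 0")
  restore_abundance(sweep(unclass(matrix), 2L, s, `/`), matrix)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement. Differs
#' from [stats::p.adjust()] only in its missing-value contract: `NA`
#' entries propagate as `NA` and are excluded from the ranking (they do
#' not inflate `n`).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0L) return(q)
  o <- order(p[ok], decreasing = TRUE)
  ro <- ok[o]
  q[ro] <- pmin(1, cummin(p[ro] * n / (n:1)))
  q
}

#' Welch differential abundance on log2 normalized values
#'
#' Per feature, a two-sided Welch t-test of `log2(N + pseudocount)`
#' between the two conditions, with Welch-Satterthwaite degrees of
#' freedom and BH correction across features. The log2 fold change is
#' the treated mean minus the control mean (control = first condition
#' level). If both group variances are exactly zero the test is
#' degenerate: p = 1 when the means agree, p = 0 (flagged) otherwise.
#'
#' @param norm a normalized [abundance_matrix()] with exactly two
#'   condition levels and >= 2 samples per condition.
#' @param threshold significance threshold on the BH q-value (default 0.05).
#' @param pseudocount added before the log2 transform; use 0.5 for counts,
#'   0 for strictly positive intensities.
#' @return A `data.frame` with columns `feature_id`, `log2fc`, `t`, `df`,
#'   `p`, `q`, `significant`, `direction` (`up`/`down`/`flat`) and
#'   `degenerate`.
#' @export
welch_differential <- function(norm, threshold = 0.05, pseudocount = 0.5) {
  cond <- conditions(norm)
  if (is.null(cond) || nlevels(cond) != 2L) {
    stopf("exactly two condition levels are required")
  }
  if (any(tabulate(cond) < 2L)) stopf("each condition needs >= 2 samples")
  lv <- levels(cond)
  x <- log2(unclass(norm) + pseudocount)
  g1 <- x[, cond == lv[1L], drop = FALSE]  # control
  g2 <- x[, cond == lv[2L], drop = FALSE]  # treated
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- row_vars(g1); v2 <- row_vars(g2)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m2 - m1
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & lfc == 0
    p[eq] <- 1; tt[eq] <- 0; df[eq] <- NA_real_
    ne <- degen & lfc != 0
    p[ne] <- 0; tt[ne] <- sign(lfc[ne]) * Inf; df[ne] <- NA_real_
  }
  q <- bh_adjust(p)
  data.frame(
    feature_id = rownames(norm),
    log2fc = lfc, t = tt, df = df, p = p, q = q,
    significant = !is.na(q) & q < threshold,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
    degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fraction of significantly deregulated features, in percent
#'
#' Bookkeeping helper used in summaries: the percentage of tested
#' features called significant at the given q threshold.
#'
#' @param result a differential result `data.frame` with a `q` column.
#' @param threshold q-value cut-off (default 0.05).
#' @param digits rounding applied to the percentage (default 1, i.e. the
#'   precision used in prose summaries).
#' @return A single number, e.g. `13.1` for 113 of 865.
#' @export
percent_deregulated <- function(result, threshold = 0.05, digits = 1) {
  q <- result$q
  round(100 * sum(!is.na(q) & q < threshold) / sum(!is.na(q)), digits)
}
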