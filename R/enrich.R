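# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov-like running
# sum with a gene-sampling permutation null) and hypergeometric
# overrepresentation with a detected-gene background.

#' Build a ranked gene list
#'
#' Orders genes by a ranking statistic, descending, with a deterministic
#' tie-break (statistic descending, then gene id ascending).
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @param stat numeric ranking statistic (e.g. log2 fold change).
#' @return A `data.frame` of class `ranked_list` with columns `gene_id`
#'   and `stat`, ordered for enrichment.
#' @export
ranked_list <- function(gene_ids, stat) {
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids in ranking")
  if (length(gene_ids) != length(stat)) stopf("ids and stats differ in length")
  o <- order(-stat, gene_ids)
  structure(data.frame(gene_id = gene_ids[o], stat = stat[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Enrichment score from sorted hit positions (1-based) and their weights.
# Increments are |stat|^weight normalized over the set's hits; each miss
# decrements 1/(n - K). Extremes of the running sum occur at hit
# positions (just after a hit) and just before each hit, so an O(K) scan
# suffices. Returns the deviation of maximal magnitude (positive wins a
# tie).
running_sum_es <- function(hit_idx, hit_w, n) {
  K <- length(hit_idx)
  nr <- sum(hit_w)
  if (nr == 0) {   # all-zero stats at weight > 0: fall back to equal hits
    hit_w <- rep(1, K); nr <- K
  }
  miss_pen <- 1 / (n - K)
  cum <- cumsum(hit_w) / nr
  miss_before <- (hit_idx - seq_len(K)) * miss_pen
  top <- max(cum - miss_before)
  # deviation just before hit j uses the cumulative hits through j-1
  bottom <- min(c(0, cum[-K]) - miss_before)
  if (top >= -bottom) top else bottom
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted running-sum enrichment on a ranked list: at each gene in the
#' set the running sum rises by \eqn{|s|^{weight}} (normalized over the
#' set), at each other gene it falls by \eqn{1/(n-K)}; ES is the
#' deviation of maximal magnitude. The null is generated by drawing
#' random gene subsets of size K from the ranked universe; NES divides
#' ES by the mean magnitude of same-sign permutation scores, and the
#' permutation p-value is lower-bounded by \eqn{1/(n_{perm}+1)}.
#'
#' @param ranked a [ranked_list()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param weight exponent on |stat| for hit increments (1 = classic
#'   weighted statistic; 0 = unweighted Kolmogorov-Smirnov).
#' @return A `data.frame` with one row per scored set: `set`, `size`,
#'   `ES`, `NES`, `p`, `padj`, `leading_edge` (comma-separated gene ids)
#'   and `nes_undefined`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n_perm < 100L) stopf("`n_perm` must be >= 100")
  n <- nrow(ranked)
  w_all <- abs(ranked$stat)^weight
  idx_of <- stats::setNames(seq_len(n), ranked$gene_id)

  sets <- lapply(sets, function(s) unique(s[s %in% ranked$gene_id]))
  sizes <- lengths(sets)
  drop <- sizes == 0L | sizes >= n
  if (any(drop)) {
    warning(sprintf("excluding %d set(s) with zero or full overlap: %s",
                    sum(drop), paste(names(sets)[drop], collapse = ", ")),
            call. = FALSE)
    sets <- sets[!drop]
  }
  if (!length(sets)) stopf("no scorable gene set remains")

  res <- with_seed(seed, {
    lapply(names(sets), function(nm) {
      hit_idx <- sort(idx_of[sets[[nm]]])
      K <- length(hit_idx)
      es <- running_sum_es(hit_idx, w_all[hit_idx], n)
      perm <- vapply(seq_len(n_perm), function(b) {
        ri <- sort(sample.int(n, K))
        running_sum_es(ri, w_all[ri], n)
      }, numeric(1L))
      same <- perm[sign(perm) == sign(es)]
      p <- max(sum(abs(same) >= abs(es)) / max(1L, length(same)),
               1 / (n_perm + 1))
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      # leading edge: genes at or before the extreme of the running sum
      cum <- cumsum(w_all[hit_idx]) / max(sum(w_all[hit_idx]), .Machine$double.eps)
      dev_at_hit <- cum - (hit_idx - seq_len(K)) / (n - K)
      le <- if (es >= 0) {
        sets[[nm]][order(idx_of[sets[[nm]]])][seq_len(which.max(dev_at_hit))]
      } else {
        prev <- c(0, cum[-K])
        dev_before <- prev - (hit_idx - seq_len(K)) / (n - K)
        j <- which.min(dev_before)
        sets[[nm]][order(idx_of[sets[[nm]]])][seq(j, K)]
      }
      data.frame(set = nm, size = K, ES = es, NES = nes, p = p,
                 leading_edge = paste(le, collapse = ","),
                 nes_undefined = is.na(nes),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out[, c("set", "size", "ES", "NES", "p", "padj", "leading_edge",
          "nes_undefined")]
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test \eqn{P(X \ge k)} of the overlap between
#' a hit list and each gene set, against a detected-gene background. Sets
#' are intersected with the background first and only those with between
#' `min_size` and `max_size` members are tested; BH correction is applied
#' across tested sets and a term is reported as enriched when both p and
#' q fall below the threshold.
#'
#' @param hits character vector of significant gene ids (subset of
#'   `background`).
#' @param background character vector of detected gene ids.
#' @param sets named list of gene-id vectors.
#' @param min_size,max_size set-size bounds applied after background
#'   intersection (defaults 10 and 500).
#' @param threshold cut-off applied to both p and q (default 0.05).
#' @return A `data.frame` with columns `set`, `k` (overlap), `K` (set
#'   size in background), `n` (hit-list size), `N` (background size),
#'   `p`, `q` and `enriched`.
#' @export
hypergeometric_ora <- function(hits, background, sets,
                               min_size = 10L, max_size = 500L,
                               threshold = 0.05) {
  bad <- setdiff(hits, background)
  if (length(bad)) {
    stopf("hits not in background: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  hits <- unique(hits); background <- unique(background)
  N <- length(background); n_hit <- length(hits)
  sets <- lapply(sets, function(s) unique(s[s %in% background]))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (!length(sets)) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  }
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, hits)), integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, n_hit, lower.tail = FALSE)
  q <- bh_adjust(p)
  data.frame(set = names(sets), k = k, K = K, n = n_hit, N = N,
             p = p, q = q, enriched = p < threshold & q < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
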