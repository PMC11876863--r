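# Ribo-seq analytics: P-site assignment, QC, translation efficiency,
# differential-TE testing and regulatory classification, codon occupancy
# at the ribosomal A/P sites, and per-codon pause scores.
#
# All coordinates are 0-based, half-open, in transcript space. The codon
# index of a nucleotide site is floor((site - utr5_len) / 3).

#' Default P-site offset table
#'
#' 12 nt for footprints of 28-31 nt and 13 nt for 32-34 nt, the standard
#' mammalian convention for the distance from the read 5' end to the
#' P-site.
#'
#' @return Named integer vector, length -> offset.
#' @export
default_psite_offsets <- function() {
  stats::setNames(c(rep(12L, 4L), rep(13L, 3L)), 28:34)
}

lookup_offset <- function(lengths, offsets, default = NA_integer_) {
  off <- offsets[as.character(lengths)]
  if (anyNA(off)) {
    if (is.na(default)) {
      stopf("no P-site offset for read length(s): %s",
            paste(sort(unique(lengths[is.na(off)])), collapse = ", "))
    }
    off[is.na(off)] <- default
  }
  as.integer(off)
}

#' Assign P- and A-sites to footprints
#'
#' P-site = 5' end + length-dependent offset; A-site = P-site + 3 nt.
#' Footprints whose P-site falls outside the transcript are dropped and
#' counted.
#'
#' @param footprints `data.frame` with `transcript_id`, `pos5`, `length`.
#' @param models transcript model table (`transcript_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`, ...).
#' @param offsets named offset table (length -> offset).
#' @param default_offset offset applied to lengths missing from the
#'   table; `NA` (the default) makes a missing length an error.
#' @return The footprint table with added `psite` and `asite` columns and
#'   an attribute `n_dropped` (out-of-bounds P-sites).
#' @export
assign_psites <- function(footprints, models,
                          offsets = default_psite_offsets(),
                          default_offset = NA_integer_) {
  off <- lookup_offset(footprints$length, offsets, default_offset)
  psite <- footprints$pos5 + off
  tx_len <- stats::setNames(models$utr5_len + models$cds_len + models$utr3_len,
                            models$transcript_id)
  lim <- tx_len[footprints$transcript_id]
  ok <- psite >= 0L & psite < lim
  out <- footprints[ok, , drop = FALSE]
  out$psite <- psite[ok]
  out$asite <- psite[ok] + 3L
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Ribo-seq quality control
#'
#' Read-length histogram and the fraction of footprints whose P-site lies
#' in the 5'UTR, the ORF or the 3'UTR of coding transcripts; footprints
#' on non-coding transcripts count as `other`.
#'
#' @param footprints P-site-annotated footprints ([assign_psites()]).
#' @param models transcript model table with a logical `coding` column.
#' @return A list with `length_histogram` (named counts) and
#'   `region_fractions` (`utr5`, `orf`, `utr3`, `other`; sums to 1).
#' @export
riboseq_qc <- function(footprints, models) {
  if (!nrow(footprints)) stopf("empty footprint table")
  if (is.null(footprints$psite)) stopf("P-sites not assigned; run assign_psites()")
  hist <- table(footprints$length)
  m <- models[match(footprints$transcript_id, models$transcript_id), ]
  region <- rep("other", nrow(footprints))
  cod <- m$coding
  region[cod & footprints$psite < m$utr5_len] <- "utr5"
  region[cod & footprints$psite >= m$utr5_len &
           footprints$psite < m$utr5_len + m$cds_len] <- "orf"
  region[cod & footprints$psite >= m$utr5_len + m$cds_len] <- "utr3"
  frac <- vapply(c("utr5", "orf", "utr3", "other"),
                 function(r) mean(region == r), numeric(1L))
  list(length_histogram = stats::setNames(as.integer(hist), names(hist)),
       region_fractions = frac)
}

#' Per-sample log2 translation efficiency
#'
#' TE is the ratio of ribosome-protected-fragment abundance to mRNA
#' abundance. Both matrices must already be size-factor normalized
#' (independently); the function computes
#' `log2(rpf + pc) - log2(rna + pc)` per gene and sample for genes whose
#' mean normalized abundance reaches `min_mean` in both assays.
#'
#' @param rna,rpf normalized [abundance_matrix()]s sharing gene ids and
#'   condition labels.
#' @param min_mean expression filter on the mean normalized abundance
#'   (default 10).
#' @param pseudocount added inside the logs (default 0.5).
#' @return A list of class `te_result`: `log2_te` (gene x sample matrix),
#'   `conditions`, and `excluded` (a data.frame of gene id + reason).
#' @export
compute_te <- function(rna, rpf, min_mean = 10, pseudocount = 0.5) {
  shared <- intersect(rownames(rna), rownames(rpf))
  if (!length(shared)) stopf("no overlapping genes between RNA and RPF matrices")
  if (!identical(colnames(rna), colnames(rpf)) ||
      !identical(as.character(conditions(rna)), as.character(conditions(rpf)))) {
    stopf("RNA and RPF matrices must share samples and condition labels")
  }
  a <- unclass(rna)[shared, , drop = FALSE]
  b <- unclass(rpf)[shared, , drop = FALSE]
  low_rna <- rowMeans(a) < min_mean
  low_rpf <- rowMeans(b) < min_mean
  keep <- !(low_rna | low_rpf)
  excluded <- data.frame(
    gene_id = shared[!keep],
    reason = ifelse(low_rna[!keep] & low_rpf[!keep], "low_rna_and_rpf",
                    ifelse(low_rna[!keep], "low_rna", "low_rpf")),
    stringsAsFactors = FALSE)
  if (!any(keep)) stopf("no gene passes the expression filter")
  lt <- log2(b[keep, , drop = FALSE] + pseudocount) -
        log2(a[keep, , drop = FALSE] + pseudocount)
  structure(list(log2_te = lt, conditions = conditions(rna),
                 excluded = excluded),
            class = "te_result")
}

#' Differential translation efficiency
#'
#' Welch t-test on replicate log2 TE between the two conditions, BH
#' correction across tested genes. `delta_log2_te` is the treated minus
#' control mean.
#'
#' @param te a `te_result` from [compute_te()].
#' @param threshold q-value significance threshold (default 0.05).
#' @return A `data.frame` with `gene_id`, `delta_log2_te`, `t`, `df`,
#'   `p`, `q`, `te_significant`, `direction`.
#' @export
differential_te <- function(te, threshold = 0.05) {
  stopifnot(inherits(te, "te_result"))
  res <- welch_on_log2(te$log2_te, te$conditions, threshold)
  data.frame(gene_id = rownames(te$log2_te),
             delta_log2_te = res$log2fc, t = res$t, df = res$df,
             p = res$p, q = res$q, te_significant = res$significant,
             direction = res$direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Welch test on an already-log2 matrix (shared by welch_differential,
# which logs first, and differential_te, which works in log space).
welch_on_log2 <- function(x, cond, threshold) {
  fake <- structure(2^x, conditions = cond,
                    class = c("abundance_matrix", "matrix", "array"))
  welch_differential(fake, threshold = threshold, pseudocount = 0)
}

#' Classify differential-TE genes into regulatory classes
#'
#' Combines mRNA-level and TE-level calls per gene:
#' \itemize{
#'   \item \strong{exclusive}: TE significant, mRNA not — ribosome
#'     occupancy changes with no change in mRNA level;
#'   \item \strong{intensified}: both significant, same direction;
#'   \item \strong{buffered}: both significant, opposite directions — TE
#'     offsets the mRNA change;
#'   \item \strong{forwarded}: mRNA significant, TE not — the mRNA change
#'     passes through to ribosome occupancy unchanged;
#'   \item \strong{none}: neither significant.
#' }
#' A significant layer whose log2FC is exactly 0 cannot be given a
#' direction and is flagged `unclassifiable` rather than silently binned.
#'
#' @param rna_de differential result for mRNA ([welch_differential()]).
#' @param te_de differential TE result ([differential_te()]).
#' @return A `data.frame` over the shared gene universe with `gene_id`,
#'   `rna_sig`, `rna_dir`, `te_sig`, `te_dir`, `dteg_class`,
#'   `unclassifiable`.
#' @export
classify_dteg <- function(rna_de, te_de) {
  shared <- intersect(rna_de$feature_id, te_de$gene_id)
  if (!length(shared)) stopf("no shared genes between mRNA and TE results")
  r <- rna_de[match(shared, rna_de$feature_id), ]
  t_ <- te_de[match(shared, te_de$gene_id), ]
  rna_sig <- r$significant; te_sig <- t_$te_significant
  rna_dir <- r$direction;   te_dir <- t_$direction
  unclass_flag <- (rna_sig & rna_dir == "flat") | (te_sig & te_dir == "flat")
  cls <- ifelse(te_sig & !rna_sig, "exclusive",
         ifelse(te_sig & rna_sig & rna_dir == te_dir, "intensified",
         ifelse(te_sig & rna_sig, "buffered",
         ifelse(rna_sig, "forwarded", "none"))))
  cls[unclass_flag] <- NA_character_
  data.frame(gene_id = shared, rna_sig = rna_sig, rna_dir = rna_dir,
             te_sig = te_sig, te_dir = te_dir, dteg_class = cls,
             unclassifiable = unclass_flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Summarise a DTEG classification
#'
#' @param records output of [classify_dteg()], or any `data.frame` with a
#'   `dteg_class` column.
#' @return A list with `counts` (named, over the four regulated classes
#'   and `none`) and `n_dteg`, the number of differential-TE genes
#'   (exclusive + intensified + buffered).
#' @export
dteg_summary <- function(records) {
  lv <- c("exclusive", "intensified", "buffered", "forwarded", "none")
  counts <- table(factor(records$dteg_class, levels = lv))
  list(counts = stats::setNames(as.integer(counts), lv),
       n_dteg = sum(counts[c("exclusive", "intensified", "buffered")]))
}

#' Fraction of genes with increased signal, in percent
#'
#' Bookkeeping helper: the percentage of entries of `delta` (e.g. the
#' RPF or TE log2 fold change of a gene family of interest) that are
#' positive.
#'
#' @param delta numeric vector of per-gene changes.
#' @param digits rounding (default 1).
#' @return A percentage, e.g. `91.2` for 93 positive out of 102.
#' @export
percent_increased <- function(delta, digits = 1) {
  round(100 * sum(delta > 0) / length(delta), digits)
}

# Count per-codon site occurrences for one transcript. Returns NULL when
# the transcript is absent from the footprints.
codon_site_counts <- function(fp_tx, model_row, site_col) {
  ncod <- model_row$cds_len %/% 3L
  site <- fp_tx[[site_col]]
  k <- (site - model_row$utr5_len) %/% 3L
  k <- k[site >= model_row$utr5_len & k < ncod]
  tabulate(k + 1L, nbins = ncod)
}

#' Codon occupancy at the ribosomal A or P site
#'
#' For each transcript passing the coverage filter, the per-codon density
#' is the site count divided by the transcript's mean count over included
#' codons (edge-trimmed CDS). Occupancy per codon identity is then the
#' position-count-weighted mean density across transcripts, so the
#' weighted mean over identities is 1 by construction. Stop codons only
#' occupy the A site.
#'
#' @param footprints P-site-annotated footprints ([assign_psites()]).
#' @param models transcript models with sequences.
#' @param site `"A"` or `"P"`.
#' @param edge_trim codons excluded at each CDS end (default 5).
#' @param min_coverage minimum mean reads per included codon (default 0.5).
#' @return A `data.frame` with `codon`, `occupancy`, `n_positions`, plus
#'   attribute `n_transcripts_used`.
#' @export
codon_occupancy <- function(footprints, models, site = c("A", "P"),
                            edge_trim = 5L, min_coverage = 0.5) {
  site <- match.arg(site)
  if (!nrow(footprints)) stopf("empty footprint table")
  if (is.null(footprints$psite)) stopf("P-sites not assigned; run assign_psites()")
  site_col <- if (site == "A") "asite" else "psite"
  by_tx <- split(footprints, footprints$transcript_id)
  dens <- list(); cods <- list()
  used <- 0L
  for (tx in intersect(models$transcript_id, names(by_tx))) {
    mrow <- models[models$transcript_id == tx, ]
    if (!isTRUE(mrow$coding) || is.na(mrow$sequence) || mrow$sequence == "") next
    ncod <- mrow$cds_len %/% 3L
    keep <- seq_len(ncod) > edge_trim & seq_len(ncod) <= ncod - edge_trim
    if (!any(keep)) next
    counts <- codon_site_counts(by_tx[[tx]], mrow, site_col)[keep]
    if (mean(counts) < min_coverage || mean(counts) == 0) next
    used <- used + 1L
    dens[[tx]] <- counts / mean(counts)
    cods[[tx]] <- cds_codons(mrow)[keep]
  }
  if (!used) stopf("no transcript passes the coverage filter")
  d <- unlist(dens, use.names = FALSE)
  cc <- unlist(cods, use.names = FALSE)
  agg <- tapply(d, cc, mean)
  npos <- table(cc)[names(agg)]
  out <- data.frame(codon = names(agg),
                    occupancy = as.numeric(agg),
                    n_positions = as.integer(npos),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_transcripts_used") <- used
  out
}

#' Per-codon pause scores
#'
#' For each transcript, the pause score at codon k is the P-site count at
#' k divided by the mean count over included (edge-trimmed) codons, so
#' the mean score per transcript is 1 by construction. Transcripts below
#' `min_coverage` still get scores but are marked `coverage_ok = FALSE`.
#'
#' @inheritParams codon_occupancy
#' @return A `data.frame` with `transcript_id`, `codon_index` (0-based),
#'   `pause_score`, `coverage_ok`.
#' @export
pause_scores <- function(footprints, models, edge_trim = 5L,
                         min_coverage = 0.5) {
  if (!nrow(footprints)) stopf("empty footprint table")
  if (is.null(footprints$psite)) stopf("P-sites not assigned; run assign_psites()")
  by_tx <- split(footprints, footprints$transcript_id)
  out <- lapply(intersect(models$transcript_id, names(by_tx)), function(tx) {
    mrow <- models[models$transcript_id == tx, ]
    if (!isTRUE(mrow$coding)) return(NULL)
    ncod <- mrow$cds_len %/% 3L
    keep <- seq_len(ncod) > edge_trim & seq_len(ncod) <= ncod - edge_trim
    if (!any(keep)) return(NULL)
    counts <- codon_site_counts(by_tx[[tx]], mrow, "psite")[keep]
    if (mean(counts) == 0) return(NULL)
    data.frame(transcript_id = tx,
               codon_index = which(keep) - 1L,
               pause_score = counts / mean(counts),
               coverage_ok = mean(counts) >= min_coverage,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) stopf("no coding transcript with P-site coverage")
  rownames(res) <- NULL
  res
}
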