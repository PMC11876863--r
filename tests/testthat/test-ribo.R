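# Ribo-seq analytics.

test_that("assign_psites applies offsets and drops out-of-bounds sites", {
  model <- tiny_model(c("ATG", "GCT", "AAA", "TAA"), utr5 = 20, utr3 = 20)
  fp <- data.frame(transcript_id = "tx_1",
                   pos5 = c(0L, 30L), length = c(28L, 28L))
  got <- assign_psites(fp, model)
  expect_equal(got$psite, c(12L, 42L))
  expect_equal(got$asite, got$psite + 3L)
  expect_equal(attr(got, "n_dropped"), 0L)

  # psite beyond the transcript end is dropped and counted
  long <- data.frame(transcript_id = "tx_1", pos5 = 45L, length = 28L)
  got2 <- assign_psites(long, model)   # total length 52; psite 57 -> dropped
  expect_equal(nrow(got2), 0L)
  expect_equal(attr(got2, "n_dropped"), 1L)

  odd <- data.frame(transcript_id = "tx_1", pos5 = 0L, length = 35L)
  expect_error(assign_psites(odd, model), "length")
  expect_equal(assign_psites(odd, model, default_offset = 12L)$psite, 12L)
})

test_that("riboseq_qc counts regions by P-site and sums to one", {
  model <- rbind(tiny_model(c("ATG", "GCT", "AAA", "TAA"), utr5 = 30, utr3 = 30),
                 within(tiny_model(c("ATG", "TAA", "AAA"), utr5 = 30, utr3 = 30,
                                   id = "tx_nc"), coding <- FALSE))
  # psites at: 5'UTR (2), ORF (6), 3'UTR (2) on tx_1
  psites <- c(5, 10, 31, 33, 35, 37, 39, 41, 45, 50)
  fp <- data.frame(transcript_id = "tx_1", pos5 = psites - 12L, length = 28L)
  got <- riboseq_qc(assign_psites(fp, model), model)
  expect_equal(unname(got$region_fractions),
               c(0.2, 0.6, 0.2, 0))
  expect_equal(sum(got$region_fractions), 1)
  expect_equal(got$length_histogram, c(`28` = 10L))

  # non-coding transcripts count as "other"
  fp_nc <- data.frame(transcript_id = "tx_nc", pos5 = 20L, length = 28L)
  got2 <- riboseq_qc(assign_psites(fp_nc, model), model)
  expect_equal(unname(got2$region_fractions["other"]), 1)
  expect_error(riboseq_qc(fp[0, ], model), "empty")
})

test_that("compute_te obeys its identities and exclusion contract", {
  set.seed(1)
  vals <- matrix(rpois(40, 100), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  cond <- rep(c("control", "treated"), each = 2)
  rna <- abundance_matrix(vals, cond)
  te <- compute_te(rna, rna, min_mean = 1, pseudocount = 0.5)
  expect_true(all(te$log2_te == 0))

  rpf4 <- abundance_matrix(4 * vals, cond)
  te4 <- compute_te(rna, rpf4, min_mean = 1, pseudocount = 0)
  expect_equal(unname(te4$log2_te), matrix(2, 10, 4), ignore_attr = TRUE)

  low <- vals; low[3, ] <- 0.5
  te_f <- compute_te(abundance_matrix(low, cond), rpf4, min_mean = 10,
                     pseudocount = 0)
  expect_equal(te_f$excluded$gene_id, "g3")
  expect_equal(te_f$excluded$reason, "low_rna")
  expect_false("g3" %in% rownames(te_f$log2_te))

  other <- abundance_matrix(matrix(1, 2, 4,
                                   dimnames = list(c("x1", "x2"), colnames(vals))),
                            cond)
  expect_error(compute_te(rna, other), "no overlapping genes")
})

test_that("differential_te is calibrated on permuted nulls and flat inputs", {
  set.seed(6)
  cond <- rep(c("control", "treated"), each = 4)
  flat <- abundance_matrix(matrix(64, 5, 8,
                                  dimnames = list(paste0("g", 1:5), paste0("s", 1:8))),
                           cond)
  te <- compute_te(flat, flat, min_mean = 1)
  res <- differential_te(te)
  expect_equal(res$p, rep(1, 5))
  expect_false(any(res$te_significant))

  # balanced null: p-values approximately uniform (KS)
  sim <- simulate_multiomics(sim_config(
    n_genes = 800, seed = 10,
    class_proportions = c(forwarded = 0, exclusive = 0, intensified = 0,
                          buffered = 0, concordant_protein = 0,
                          discordant_protein = 0, null = 1)))
  norm <- lapply(sim[c("rna", "rpf")],
                 function(m) normalize_matrix(filter_features(m)))
  ted <- differential_te(compute_te(norm$rna, norm$rpf))
  ks <- suppressWarnings(ks.test(ted$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("classify_dteg matches the rule table over every combination", {
  sigs <- c(TRUE, FALSE)
  dirs <- c("up", "down", "flat")
  grid <- expand.grid(rs = sigs, rd = dirs, ts = sigs, td = dirs,
                      stringsAsFactors = FALSE)
  ids <- sprintf("g%02d", seq_len(nrow(grid)))
  rna <- fake_de(ids, ifelse(grid$rd == "up", 1, ifelse(grid$rd == "down", -1, 0)),
                 ifelse(grid$rs, 0.01, 0.5))
  te <- data.frame(gene_id = ids,
                   delta_log2_te = ifelse(grid$td == "up", 1,
                                          ifelse(grid$td == "down", -1, 0)),
                   p = NA, q = NA,
                   te_significant = grid$ts,
                   direction = grid$td, stringsAsFactors = FALSE)
  got <- classify_dteg(rna, te)
  # independent rule-table oracle
  want <- mapply(function(rs, rd, ts, td) {
    if ((rs && rd == "flat") || (ts && td == "flat")) return(NA_character_)
    if (ts && !rs) return("exclusive")
    if (ts && rs && rd == td) return("intensified")
    if (ts && rs) return("buffered")
    if (rs) return("forwarded")
    "none"
  }, grid$rs, grid$rd, grid$ts, grid$td)
  expect_identical(got$dteg_class, unname(want))
  # partition: every gene classified or flagged, never both
  expect_true(all(xor(is.na(got$dteg_class), !got$unclassifiable)))
  ok <- !got$unclassifiable
  expect_equal(sum(got$dteg_class[ok] %in% c("exclusive", "intensified", "buffered")),
               sum(got$te_sig[ok]))
  # boundary examples
  expect_equal(got$dteg_class[got$te_sig & got$te_dir == "up" &
                                !got$rna_sig & got$rna_dir == "down"], "exclusive")
  expect_equal(got$dteg_class[got$rna_sig & got$rna_dir == "up" &
                                got$te_sig & got$te_dir == "down"], "buffered")
})

test_that("dteg_summary and percent helpers do the bookkeeping", {
  rec <- data.frame(dteg_class = rep(c("exclusive", "intensified", "buffered",
                                       "forwarded", "none"), c(2, 1, 3, 4, 5)))
  s <- dteg_summary(rec)
  expect_equal(s$n_dteg, 6L)
  expect_equal(s$counts[["forwarded"]], 4L)
  expect_equal(percent_increased(c(rep(1, 3), -1)), 75)
  expect_equal(percent_deregulated(data.frame(q = c(0.01, 0.2, 0.6))), 33.3)
})

test_that("codon occupancy self-normalizes and recovers structure", {
  model <- tiny_model(rep("GCT", 40), utr5 = 18, utr3 = 18)
  fp <- fp_at_codons(model, rep(5:34, each = 3))  # uniform over inner codons
  fp <- assign_psites(fp, model)
  occ <- codon_occupancy(fp, model, site = "P", edge_trim = 5, min_coverage = 0.5)
  expect_equal(occ$occupancy, 1)
  expect_equal(occ$codon, "GCT")

  # weighted-mean invariant on arbitrary random input
  models <- simulate_transcript_models(4, cds_codons_range = c(60, 90), seed = 3)
  fpr <- assign_psites(
    simulate_footprints(models, footprint_sim_config(5000, seed = 4)), models)
  occ2 <- codon_occupancy(fpr, models, site = "A")
  expect_equal(sum(occ2$occupancy * occ2$n_positions) / sum(occ2$n_positions),
               1, tolerance = 1e-6)
  expect_error(codon_occupancy(fpr[0, ], models), "empty")
})

test_that("pause scores normalize per transcript and flag low coverage", {
  model <- tiny_model(rep("AAA", 10), utr5 = 18, utr3 = 18)
  counts <- c(10, rep(1, 9))
  fp <- assign_psites(fp_at_codons(model, rep(0:9, counts)), model)
  ps <- pause_scores(fp, model, edge_trim = 0, min_coverage = 0.5)
  expect_equal(ps$pause_score[1], 10 / 1.9, tolerance = 1e-9)
  expect_equal(mean(ps$pause_score), 1, tolerance = 1e-9)
  expect_true(all(ps$coverage_ok))

  sparse <- assign_psites(fp_at_codons(model, c(2L, 5L)), model)
  ps2 <- pause_scores(sparse, model, edge_trim = 0, min_coverage = 0.5)
  expect_false(any(ps2$coverage_ok))
  expect_equal(mean(ps2$pause_score), 1, tolerance = 1e-9)
})
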