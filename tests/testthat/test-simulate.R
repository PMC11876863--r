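# Synthetic multi-omics generator.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_reps_per_condition = 1), ">= 2")
  bad <- c(forwarded = 0.2, exclusive = 0.2, intensified = 0.2,
           buffered = 0.2, concordant_protein = 0.1,
           discordant_protein = 0.1, null = 0.1)
  expect_error(sim_config(class_proportions = bad), "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "strictly positive")
})

test_that("simulation is deterministic and respects planted structure", {
  cfg <- sim_config(n_genes = 300, seed = 7)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a, b)

  # truth consistency: class re-derivable from planted effects
  tr <- a$truth
  rederived <- ifelse(tr$true_log2fc_te == 0 & tr$true_log2fc_rna == 0, "none",
               ifelse(tr$true_log2fc_te == 0, "forwarded",
               ifelse(tr$true_log2fc_rna == 0, "exclusive",
               ifelse(sign(tr$true_log2fc_rna) == sign(tr$true_log2fc_te),
                      "intensified", "buffered"))))
  expect_identical(tr$true_dteg_class, rederived)
  expect_true(all(tr$true_log2fc_rna[tr$true_dteg_class == "exclusive"] == 0))
  expect_true(all(tr$true_log2fc_te[tr$true_dteg_class == "exclusive"] != 0))
  # buffered genes have exactly offsetting effects (RPF fold ~ 1)
  buf <- tr$true_dteg_class == "buffered"
  expect_true(all(tr$true_log2fc_rna[buf] + tr$true_log2fc_te[buf] == 0))
  # druggable hierarchy holds in the truth table
  expect_true(all(!tr$has_approved_drug | tr$has_ligand))
  expect_true(all(!tr$has_ligand | tr$druggable))
})

test_that("null simulation is symmetric around zero log2FC", {
  props <- c(forwarded = 0, exclusive = 0, intensified = 0, buffered = 0,
             concordant_protein = 0, discordant_protein = 0, null = 1)
  sim <- simulate_multiomics(sim_config(n_genes = 2000, class_proportions = props,
                                        seed = 21))
  norm <- normalize_matrix(filter_features(sim$rna))
  cond <- conditions(norm)
  lfc <- rowMeans(log2(unclass(norm)[, cond == "treated"] + 0.5)) -
         rowMeans(log2(unclass(norm)[, cond == "control"] + 0.5))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("NB counts match their configured means (moment check)", {
  cfg <- sim_config(n_genes = 300, n_reps_per_condition = 200, seed = 5)
  sim <- simulate_multiomics(cfg)
  tr <- sim$truth
  # Null genes have configured mean s_j * q_i in every sample; after
  # dividing by the true size factors the sample mean must fall within 3
  # standard errors of q_i for >= 99% of genes at n = 200 per condition.
  counts <- unclass(sim$rna)
  cond <- conditions(sim$rna)
  s <- sim$size_factors$rna
  nulls <- tr$sim_class == "null"
  q <- tr$true_baseline[nulls]
  normed <- sweep(counts[nulls, , drop = FALSE], 2, s, `/`)
  se <- sqrt(rowSums(outer(q, 1 / s) + cfg$nb_dispersion * q^2)) / length(s)
  frac_ok <- mean(abs(rowMeans(normed) - q) <= 3 * se)
  expect_gte(frac_ok, 0.99)
  # and exclusive genes show the planted 2x RPF fold with 1x RNA fold
  rpf <- unclass(sim$rpf)
  excl <- tr$true_dteg_class == "exclusive" & tr$true_log2fc_te > 0
  sf_ratio <- mean(sim$size_factors$rpf[cond == "treated"]) /
              mean(sim$size_factors$rpf[cond == "control"])
  fold_rpf <- rowMeans(rpf[excl, cond == "treated"]) /
              rowMeans(rpf[excl, cond == "control"]) / sf_ratio
  expect_equal(median(fold_rpf), 2, tolerance = 0.1)
  sf_ratio_rna <- mean(sim$size_factors$rna[cond == "treated"]) /
                  mean(sim$size_factors$rna[cond == "control"])
  fold_rna <- rowMeans(counts[excl, cond == "treated"]) /
              rowMeans(counts[excl, cond == "control"]) / sf_ratio_rna
  expect_equal(median(fold_rna), 1, tolerance = 0.1)
})

test_that("footprint simulation honours geometry, determinism and edge cases", {
  models <- simulate_transcript_models(5, seed = 2)
  cfg <- footprint_sim_config(n_reads = 5000, seed = 9)
  fp1 <- simulate_footprints(models, cfg)
  fp2 <- simulate_footprints(models, cfg)
  expect_identical(fp1, fp2)
  expect_equal(nrow(simulate_footprints(models,
                                        footprint_sim_config(n_reads = 0))), 0)
  tot <- setNames(models$utr5_len + models$cds_len + models$utr3_len,
                  models$transcript_id)
  expect_true(all(fp1$pos5 >= 0))
  expect_true(all(fp1$pos5 + fp1$length <= tot[fp1$transcript_id]))
  expect_true(all(fp1$length %in% 28:32))

  short <- tiny_model(c("ATG", "TAA"))
  expect_error(simulate_footprints(short, cfg), "3 codons")
})

test_that("uniform pause multipliers give flat per-codon A-site density", {
  model <- simulate_transcript_models(1, cds_codons_range = c(80, 80), seed = 4)
  fp <- simulate_footprints(model, footprint_sim_config(n_reads = 100000, seed = 1))
  fp <- assign_psites(fp, model)
  k <- (fp$asite - model$utr5_len) %/% 3
  counts <- tabulate(k + 1, nbins = 80)
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("a 2x pause multiplier doubles density relative to background", {
  set.seed(31)
  codons <- sample(c("GCT", "AAA", "GGG", "CCC"), 200, replace = TRUE)
  model <- tiny_model(c(codons, "TAA"))
  cfg <- footprint_sim_config(n_reads = 100000,
                              pause_multipliers = c(GCT = 2), seed = 13)
  fp <- assign_psites(simulate_footprints(model, cfg), model)
  k <- (fp$asite - model$utr5_len) %/% 3
  counts <- tabulate(k + 1, nbins = 201)
  is_gct <- c(codons, "TAA") == "GCT"
  ratio <- mean(counts[is_gct]) / mean(counts[!is_gct])
  # independent oracle: direct multinomial sampling from the same weights
  w <- ifelse(is_gct, 2, 1)
  oracle <- tabulate(sample(201, 100000, TRUE, prob = w), nbins = 201)
  oracle_ratio <- mean(oracle[is_gct]) / mean(oracle[!is_gct])
  expect_equal(ratio, oracle_ratio, tolerance = 0.07)
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("generate_annotation partitions genes and is reproducible", {
  sim <- simulate_multiomics(sim_config(n_genes = 200, seed = 3))
  ann1 <- generate_annotation(sim$truth, seed = 8)
  ann2 <- generate_annotation(sim$truth, seed = 8)
  expect_identical(ann1, ann2)
  expect_setequal(ann1$localisation$gene_id, sim$truth$gene_id)
  expect_true(all(ann1$localisation$class %in% c("SP", "TM", "IC", "SPTM")))
  ctrl <- ann1$gene_sets[[ann1$control_set]]
  up <- sim$truth$gene_id[sim$truth$true_log2fc_rna > 0]
  expect_true(all(ctrl %in% up))
  expect_error(generate_annotation(sim$truth, set_size_range = c(1, 50)),
               "set_size_range")
  # GMT round-trip byte identity for the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(ann1$gene_sets, f1); write_gmt(ann2$gene_sets, f2)
  expect_identical(readLines(f1), readLines(f2))
})
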