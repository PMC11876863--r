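# End-to-end orchestration of the synthetic-to-report pipeline, plus the
# run manifest that makes a run reproducible and auditable.

#' Pipeline configuration
#'
#' Collects every knob of the full pipeline run. All randomness derives
#' from `seed`, so two runs with identical configs produce identical
#' outputs (and identical manifest checksums for deterministic stages).
#'
#' @param outdir output directory (created if absent).
#' @param seed master integer seed.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param n_transcripts,n_footprints size of the footprint simulation.
#' @param threshold q-value significance cut-off used by every test.
#' @param min_mean TE expression filter.
#' @param n_perm GSEA permutations.
#' @param min_size,max_size ORA set-size bounds.
#' @param offsets P-site offset table.
#' @param edge_trim,min_coverage codon-level analysis settings.
#' @param gmt optional path to an external GMT file; by default gene sets
#'   are generated alongside the simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            sim = sim_config(n_genes = 500L,
                                             n_reps_per_condition = 3L),
                            n_transcripts = 20L,
                            n_footprints = 50000L,
                            threshold = 0.05,
                            min_mean = 10,
                            n_perm = 1000L,
                            min_size = 10L,
                            max_size = 500L,
                            offsets = default_psite_offsets(),
                            edge_trim = 5L,
                            min_coverage = 0.5,
                            gmt = NULL) {
  if (!is.null(gmt) && !file.exists(gmt)) {
    stopf("validation: GMT file does not exist: %s", gmt)
  }
  if (threshold <= 0 || threshold >= 1) stopf("validation: threshold must be in (0,1)")
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 n_transcripts = as.integer(n_transcripts),
                 n_footprints = as.integer(n_footprints),
                 threshold = threshold, min_mean = min_mean,
                 n_perm = as.integer(n_perm),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 offsets = offsets, edge_trim = as.integer(edge_trim),
                 min_coverage = min_coverage, gmt = gmt),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
  message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full synthetic-to-report pipeline
#'
#' simulate -> filter/normalize -> differential abundance (RNA, protein)
#' -> TE/DTEG -> footprint QC, codon occupancy, pause scores -> GSEA and
#' ORA -> five-group integration, then writes every table and a JSON run
#' manifest with per-file checksums.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (invisibly), also written to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  t_start <- proc.time()[["elapsed"]]

  config$sim$seed <- derive_seed(config$seed, 1L)
  sim <- run_stage("simulate", simulate_multiomics(config$sim))
  ann <- run_stage("annotation",
                   generate_annotation(sim$truth, seed = derive_seed(config$seed, 2L)))
  write_matrix_tsv(sim$rna, out("rna_counts.tsv"), "gene_id")
  write_matrix_tsv(sim$rpf, out("rpf_counts.tsv"), "gene_id")
  write_matrix_tsv(sim$protein, out("protein_intensities.tsv"), "gene_id")
  write_result_tsv(sim$truth, out("truth.tsv"))
  write_gmt(ann$gene_sets, out("gene_sets.gmt"))
  sets <- if (is.null(config$gmt)) ann$gene_sets else read_gmt(config$gmt)

  norm <- run_stage("normalize", {
    lapply(list(rna = sim$rna, rpf = sim$rpf, protein = sim$protein),
           function(m) normalize_matrix(filter_features(m)))
  })
  de <- run_stage("differential", {
    list(rna = welch_differential(norm$rna, config$threshold, pseudocount = 0.5),
         protein = welch_differential(
           filter_features(norm$protein, require_complete = TRUE),
           config$threshold, pseudocount = 0))
  })
  write_result_tsv(de$rna, out("de_rna.tsv"))
  write_result_tsv(de$protein, out("de_protein.tsv"))

  dteg <- run_stage("te_dteg", {
    te <- compute_te(norm$rna, norm$rpf, min_mean = config$min_mean)
    te_de <- differential_te(te, config$threshold)
    write_result_tsv(te_de, out("te_differential.tsv"))
    cls <- classify_dteg(de$rna, te_de)
    write_result_tsv(cls, out("dteg_classes.tsv"))
    cls
  })

  ribo <- run_stage("footprints", {
    models <- simulate_transcript_models(config$n_transcripts,
                                         seed = derive_seed(config$seed, 3L))
    fp <- simulate_footprints(models,
            footprint_sim_config(n_reads = config$n_footprints,
                                 seed = derive_seed(config$seed, 4L)),
            offsets = config$offsets)
    write_models_tsv(models, out("transcript_models.tsv"))
    write_fasta(stats::setNames(models$sequence, models$transcript_id),
                out("transcripts.fasta"))
    write_footprints_tsv(fp, out("footprints.tsv"))
    fp <- assign_psites(fp, models, config$offsets)
    qc <- riboseq_qc(fp, models)
    writeLines(jsonlite::toJSON(lapply(qc, as.list), auto_unbox = TRUE, digits = NA),
               out("ribo_qc.json"))
    occ <- codon_occupancy(fp, models, site = "A",
                           edge_trim = config$edge_trim,
                           min_coverage = config$min_coverage)
    write_result_tsv(occ, out("codon_occupancy_A.tsv"))
    ps <- pause_scores(fp, models, config$edge_trim, config$min_coverage)
    write_result_tsv(ps, out("pause_scores.tsv"))
    TRUE
  })

  enr <- run_stage("enrichment", {
    ranked <- ranked_list(de$rna$feature_id, de$rna$log2fc)
    gsea <- preranked_gsea(ranked, sets, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 5L))
    write_result_tsv(gsea, out("gsea.tsv"))
    hits <- de$rna$feature_id[de$rna$significant]
    ora <- hypergeometric_ora(hits, de$rna$feature_id, sets,
                              config$min_size, config$max_size,
                              config$threshold)
    write_result_tsv(ora, out("ora.tsv"))
    TRUE
  })

  integ <- run_stage("integrate", {
    strat <- stratify_five_groups(de$rna, de$protein)
    strat <- assign_localisation(strat, ann$localisation, default = "IC")
    write_result_tsv(strat, out("concordance.tsv"))
    write_result_tsv(group_subcategory_proportions(strat),
                     out("concordance_subcategories.tsv"))
    dg <- druggable_overlap(de$protein, ann$druggable, config$threshold)
    writeLines(jsonlite::toJSON(dg, auto_unbox = TRUE), out("druggable.json"))
    cs <- concordance_summary(strat)
    writeLines(jsonlite::toJSON(cs, auto_unbox = TRUE, digits = NA),
               out("concordance_summary.json"))
    TRUE
  })

  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    tool = "translatomics",
    version = as.character(utils::packageVersion("translatomics")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    checksums = as.list(tools::md5sum(file.path(config$outdir, files))),
    wall_time_s = round(proc.time()[["elapsed"]] - t_start, 3)
  )
  names(manifest$checksums) <- files
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             out("manifest.json"))
  invisible(manifest)
}

# Serialise the config deterministically for hashing.
write_config_tmp <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  tmp
}
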