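# Synthetic multi-omics generator with planted ground truth.
#
# Emits matched RNA-seq counts, Ribo-seq RPF counts and TMT-like protein
# intensities for a two-condition design, together with a truth table of
# the planted per-gene effects, so that normalization, differential
# testing, TE classification and enrichment can all be validated against
# a known answer.

SIM_CLASSES <- c("forwarded", "exclusive", "intensified", "buffered",
                 "concordant_protein", "discordant_protein", "null")

#' Simulation configuration
#'
#' Defaults describe the stated world of the package's validation suite:
#' negative-binomial counts (variance \eqn{\mu + \alpha\mu^2}) with a
#' shared dispersion of 0.05, four replicates per condition, log-uniform
#' per-sample size factors in \[0.7, 1.4\], planted |log2FC| of 1, and
#' log2-normal protein noise with sd 0.3.
#'
#' @param n_genes number of genes.
#' @param n_reps_per_condition replicates per condition (>= 2).
#' @param baseline_mean expected count scale of a typical gene.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha*mu^2).
#' @param size_factor_range range for log-uniform per-sample size factors.
#' @param class_proportions named fractions over the regulatory classes
#'   `forwarded`, `exclusive`, `intensified`, `buffered`,
#'   `concordant_protein`, `discordant_protein`, `null`; must sum to 1.
#' @param effect_log2fc magnitude of planted log2 fold changes.
#' @param protein_sd_log2 sd of log2-normal protein intensity noise.
#' @param seed integer seed; identical configs reproduce bit-identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_reps_per_condition = 4L,
                       baseline_mean = 100,
                       nb_dispersion = 0.05,
                       size_factor_range = c(0.7, 1.4),
                       class_proportions = c(forwarded = 0.05, exclusive = 0.05,
                                             intensified = 0.05, buffered = 0.05,
                                             concordant_protein = 0.05,
                                             discordant_protein = 0.05,
                                             null = 0.70),
                       effect_log2fc = 1,
                       protein_sd_log2 = 0.3,
                       seed = 1L) {
  if (n_genes < 1) stopf("`n_genes` must be positive")
  if (n_reps_per_condition < 2) stopf("`n_reps_per_condition` must be >= 2")
  scales <- c(baseline_mean, nb_dispersion, effect_log2fc, protein_sd_log2,
              size_factor_range)
  if (any(scales <= 0)) stopf("all scale parameters must be strictly positive")
  if (!setequal(names(class_proportions), SIM_CLASSES)) {
    stopf("`class_proportions` must name exactly: %s",
          paste(SIM_CLASSES, collapse = ", "))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stopf("class proportions must sum to 1 (got %.12f)", sum(class_proportions))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_condition = as.integer(n_reps_per_condition),
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion,
                 size_factor_range = size_factor_range,
                 class_proportions = class_proportions[SIM_CLASSES],
                 effect_log2fc = effect_log2fc,
                 protein_sd_log2 = protein_sd_log2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder allocation of n items to the configured proportions.
allocate_classes <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(props), counts)
}

# Planted per-channel log2 effects for one gene of a given class.
# Protein follows translational output (rna + te) for the TE classes;
# the two protein classes decouple it to exercise concordance analysis.
plant_effects <- function(class, s, e) {
  switch(class,
    forwarded          = c(rna = s * e, te = 0,       prot = s * e),
    exclusive          = c(rna = 0,     te = s * e,   prot = s * e),
    intensified        = c(rna = s * e, te = s * e,   prot = 2 * s * e),
    buffered           = c(rna = s * e, te = -s * e,  prot = 0),
    concordant_protein = c(rna = s * e, te = 0,       prot = s * e),
    discordant_protein = c(rna = s * e, te = 0,       prot = -s * e),
    null               = c(rna = 0,     te = 0,       prot = 0)
  )
}

# Re-derive the TE regulatory class from planted effects (truth contract).
dteg_class_from_effects <- function(b_rna, b_te) {
  ifelse(b_te == 0 & b_rna == 0, "none",
  ifelse(b_te == 0,              "forwarded",
  ifelse(b_rna == 0,             "exclusive",
  ifelse(sign(b_rna) == sign(b_te), "intensified", "buffered"))))
}

# Truth-level five-group label from rna/protein effects; a zero effect is
# folded onto its partner's direction (the observed direction of a null
# layer is noise, so the canonical group is the one named by the
# significant layer).
group_from_effects <- function(b_rna, b_prot) {
  ifelse(b_rna == 0 & b_prot == 0, 1L,
  ifelse(b_prot > 0 & b_rna >= 0 | b_rna > 0 & b_prot >= 0, 2L,
  ifelse(b_rna > 0 & b_prot < 0, 3L,
  ifelse(b_prot < 0 & b_rna <= 0 | b_rna < 0 & b_prot <= 0, 4L, 5L))))
}

#' Generate matched RNA-seq, Ribo-seq and proteomics data with known truth
#'
#' RNA counts are NB with mean \eqn{s_j q_i 2^{x_j \beta_{rna,i}}}; RPF
#' counts use \eqn{\beta_{rna,i} + \beta_{te,i}} in the exponent (TE acts
#' on ribosome occupancy on top of mRNA abundance); protein intensities
#' are log2-normal around a baseline shifted by \eqn{x_j \beta_{prot,i}}
#' and scaled by their own sample loading factors. \eqn{x_j} is the
#' condition indicator (0 = control, 1 = treated).
#'
#' @param config a [sim_config()].
#' @return A list with `rna`, `rpf`, `protein` ([abundance_matrix()]s,
#'   conditions `control`/`treated`), `truth` (per-gene planted effects,
#'   classes and annotations) and `size_factors` (the true per-sample
#'   scalings used).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    n <- config$n_reps_per_condition
    genes <- sprintf("gene_%04d", seq_len(G))
    cond <- factor(rep(c("control", "treated"), each = n),
                   levels = c("control", "treated"))
    x <- as.numeric(cond == "treated")
    samples <- paste0(rep(c("ctrl_", "trt_"), each = n), rep(seq_len(n), 2L))

    cls <- sample(allocate_classes(config$class_proportions, G))
    sgn <- sample(c(-1, 1), G, replace = TRUE)
    eff <- t(vapply(seq_len(G),
                    function(i) plant_effects(cls[i], sgn[i], config$effect_log2fc),
                    numeric(3L)))

    q <- stats::rlnorm(G, meanlog = log(config$baseline_mean), sdlog = 1)
    sf_rng <- function() exp(stats::runif(2L * n, log(config$size_factor_range[1L]),
                                          log(config$size_factor_range[2L])))
    sf_rna <- sf_rng(); sf_rpf <- sf_rng(); sf_prot <- sf_rng()

    nb_matrix <- function(beta, sf) {
      mu <- outer(q, sf) * 2^(eff[, beta, drop = TRUE] %o% x)
      m <- matrix(stats::rnbinom(G * 2L * n, mu = mu, size = 1 / config$nb_dispersion),
                  G, 2L * n, dimnames = list(genes, samples))
      abundance_matrix(m, cond)
    }
    rna <- nb_matrix("rna", sf_rna)
    eff_rpf <- eff; eff_rpf[, "rna"] <- eff[, "rna"] + eff[, "te"]
    mu_rpf <- outer(q, sf_rpf) * 2^(eff_rpf[, "rna"] %o% x)
    rpf <- abundance_matrix(
      matrix(stats::rnbinom(G * 2L * n, mu = mu_rpf, size = 1 / config$nb_dispersion),
             G, 2L * n, dimnames = list(genes, samples)), cond)

    base_prot <- q * 1e4  # reporter-intensity scale
    lp <- log2(outer(base_prot, sf_prot)) + eff[, "prot"] %o% x +
      matrix(stats::rnorm(G * 2L * n, 0, config$protein_sd_log2), G, 2L * n)
    protein <- abundance_matrix(
      matrix(2^lp, G, 2L * n, dimnames = list(genes, samples)), cond)

    loc <- sample(c("IC", "TM", "SP", "SPTM"), G, replace = TRUE,
                  prob = c(0.60, 0.20, 0.12, 0.08))
    druggable <- stats::runif(G) < 0.12
    has_ligand <- druggable & stats::runif(G) < 0.40
    has_drug <- has_ligand & stats::runif(G) < 0.25

    truth <- data.frame(
      gene_id = genes,
      sim_class = cls,
      true_baseline = q,
      true_log2fc_rna = eff[, "rna"],
      true_log2fc_te = eff[, "te"],
      true_log2fc_protein = eff[, "prot"],
      true_dteg_class = dteg_class_from_effects(eff[, "rna"], eff[, "te"]),
      true_group = group_from_effects(eff[, "rna"], eff[, "prot"]),
      localisation = loc,
      druggable = druggable,
      has_ligand = has_ligand,
      has_approved_drug = has_drug,
      stringsAsFactors = FALSE
    )
    list(rna = rna, rpf = rpf, protein = protein, truth = truth,
         size_factors = list(rna = sf_rna, rpf = sf_rpf, protein = sf_prot))
  })
}

#' Footprint simulation configuration
#'
#' @param n_reads total number of footprints to draw (>= 0).
#' @param length_distribution named probabilities over read lengths in nt;
#'   the default puts its mass on 28-32 nt, the footprint size protected
#'   by an elongating mammalian ribosome.
#' @param pause_multipliers named positive multipliers per codon (e.g.
#'   `c(GCT = 2)`); unlisted codons get 1.
#' @param seed integer seed.
#' @return A list of class `footprint_sim_config`.
#' @export
footprint_sim_config <- function(n_reads = 100000L,
                                 length_distribution = c(`28` = 0.10, `29` = 0.25,
                                                         `30` = 0.30, `31` = 0.25,
                                                         `32` = 0.10),
                                 pause_multipliers = numeric(0),
                                 seed = 1L) {
  if (n_reads < 0) stopf("`n_reads` must be >= 0")
  if (abs(sum(length_distribution) - 1) > 1e-9) {
    stopf("length distribution must sum to 1")
  }
  if (length(pause_multipliers) && any(pause_multipliers <= 0)) {
    stopf("pause multipliers must be strictly positive")
  }
  structure(list(n_reads = as.integer(n_reads),
                 length_distribution = length_distribution,
                 pause_multipliers = pause_multipliers,
                 seed = as.integer(seed)),
            class = "footprint_sim_config")
}

ALL_CODONS <- {
  b <- c("T", "C", "A", "G")
  apply(expand.grid(b, b, b)[, 3:1], 1L, paste0, collapse = "")
}
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Simulate transcript models with random coding sequences
#'
#' Builds coding transcripts with fixed UTR lengths and random CDS
#' sequences (uniform sense codons, one terminal stop codon). UTR
#' defaults leave room for the 5' P-site offset so every CDS codon is
#' reachable by a full-length footprint.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_codons_range inclusive range of CDS length in codons
#'   (including the stop codon).
#' @param utr5_len,utr3_len UTR lengths in nt.
#' @param seed integer seed.
#' @return A `data.frame` with columns `transcript_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`, `coding` and `sequence`.
#' @export
simulate_transcript_models <- function(n_transcripts = 20L,
                                       cds_codons_range = c(100L, 300L),
                                       utr5_len = 48L, utr3_len = 60L,
                                       seed = 1L) {
  with_seed(seed, {
    ncod <- sample_vec(cds_codons_range[1L]:cds_codons_range[2L],
                       n_transcripts, replace = TRUE)
    seqs <- vapply(ncod, function(k) {
      paste0(paste0(c(sample(SENSE_CODONS, k - 1L, replace = TRUE),
                      sample(STOP_CODONS, 1L)), collapse = ""))
    }, character(1L))
    utr5 <- vapply(seq_len(n_transcripts), function(i)
      paste0(sample(c("T", "C", "A", "G"), utr5_len, replace = TRUE),
             collapse = ""), character(1L))
    utr3 <- vapply(seq_len(n_transcripts), function(i)
      paste0(sample(c("T", "C", "A", "G"), utr3_len, replace = TRUE),
             collapse = ""), character(1L))
    data.frame(
      transcript_id = sprintf("tx_%03d", seq_len(n_transcripts)),
      utr5_len = as.integer(utr5_len),
      cds_len = 3L * ncod,
      utr3_len = as.integer(utr3_len),
      coding = TRUE,
      sequence = paste0(utr5, seqs, utr3),
      stringsAsFactors = FALSE
    )
  })
}

# Codon identity of each CDS codon of one transcript model row.
cds_codons <- function(model_row) {
  cds <- substr(model_row$sequence, model_row$utr5_len + 1L,
                model_row$utr5_len + model_row$cds_len)
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Simulate ribosome footprints with per-codon pause multipliers
#'
#' Reads are allocated across transcripts proportionally to CDS length;
#' within a transcript the A-site codon is drawn with probability
#' proportional to the pause multiplier of its codon identity. The read
#' 5' end is then placed so that the standard length-dependent P-site
#' offset recovers the intended A-site.
#'
#' @param models transcript models as from [simulate_transcript_models()];
#'   sequences are required and every CDS must be >= 3 codons.
#' @param config a [footprint_sim_config()].
#' @param offsets P-site offset table, see [default_psite_offsets()].
#' @return A footprint `data.frame` with columns `transcript_id`,
#'   `pos5` (0-based 5'-end coordinate) and `length`.
#' @export
simulate_footprints <- function(models, config,
                                offsets = default_psite_offsets()) {
  stopifnot(inherits(config, "footprint_sim_config"))
  if (any(models$cds_len < 9L)) stopf("every CDS must be at least 3 codons")
  if (any(models$cds_len %% 3L != 0L)) stopf("CDS length must be divisible by 3")
  empty <- data.frame(transcript_id = character(0), pos5 = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (config$n_reads == 0L) return(empty)
  lens <- as.integer(names(config$length_distribution))
  with_seed(config$seed, {
    ncod <- models$cds_len %/% 3L
    per_tx <- as.vector(stats::rmultinom(1L, config$n_reads, ncod))
    out <- vector("list", nrow(models))
    for (i in seq_len(nrow(models))) {
      if (per_tx[i] == 0L) next
      cods <- cds_codons(models[i, ])
      w <- rep(1, length(cods))
      hit <- cods %in% names(config$pause_multipliers)
      w[hit] <- config$pause_multipliers[cods[hit]]
      k <- sample.int(length(cods), per_tx[i], replace = TRUE, prob = w) - 1L
      L <- sample_vec(lens, per_tx[i], replace = TRUE,
                      prob = config$length_distribution)
      pos5 <- models$utr5_len[i] + 3L * k - 3L - lookup_offset(L, offsets)
      tot <- models$utr5_len[i] + models$cds_len[i] + models$utr3_len[i]
      ok <- pos5 >= 0L & pos5 + L <= tot
      out[[i]] <- data.frame(transcript_id = models$transcript_id[i],
                             pos5 = pos5[ok], length = L[ok],
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(out, list(empty)))
    rownames(res) <- NULL
    res
  })
}

#' Generate annotation tables and gene sets for a simulated cohort
#'
#' Emits a localisation table (one class per gene), a druggable-proteome
#' table obeying the drug => ligand => druggable hierarchy, and a gene-set
#' collection of random sets plus one positive-control set drawn from
#' genes with a planted positive mRNA effect (for GSEA validation).
#'
#' @param truth truth table from [simulate_multiomics()].
#' @param n_gene_sets number of random sets.
#' @param set_size_range inclusive size range for random sets; must lie
#'   within \[2, n_genes\].
#' @param control_size size of the positive-control set (default 50).
#' @param seed integer seed.
#' @return A list with `localisation`, `druggable` (data.frames),
#'   `gene_sets` (named list, GMT-ready) and `control_set` (its name).
#' @export
generate_annotation <- function(truth, n_gene_sets = 20L,
                                set_size_range = c(15L, 80L),
                                control_size = 50L, seed = 1L) {
  G <- nrow(truth)
  if (set_size_range[1L] < 2L || set_size_range[2L] > G) {
    stopf("`set_size_range` must lie within [2, %d]", G)
  }
  with_seed(seed, {
    up <- truth$gene_id[truth$true_log2fc_rna > 0]
    control <- sample_vec(up, min(control_size, length(up)))
    sets <- lapply(seq_len(n_gene_sets), function(i) {
      sample(truth$gene_id,
             sample_vec(set_size_range[1L]:set_size_range[2L], 1L))
    })
    names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_gene_sets))
    sets <- c(list(POSITIVE_CONTROL_UP = control), sets)
    list(
      localisation = data.frame(gene_id = truth$gene_id,
                                class = truth$localisation,
                                stringsAsFactors = FALSE),
      druggable = data.frame(gene_id = truth$gene_id,
                             druggable = truth$druggable,
                             has_ligand = truth$has_ligand,
                             has_approved_drug = truth$has_approved_drug,
                             stringsAsFactors = FALSE),
      gene_sets = sets,
      control_set = "POSITIVE_CONTROL_UP"
    )
  })
}
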