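# Cross-omics integration: five-group mRNA-protein concordance
# stratification, localisation subcategories, GO-term cross-checks,
# druggable-proteome overlap, and hierarchical clustering.

#' Stratify genes into five mRNA-protein concordance groups
#'
#' Each gene in the intersection of the two result tables is placed in
#' exactly one group from its per-layer significance (SS: q < threshold)
#' and direction (sign of log2FC):
#' \itemize{
#'   \item Group 1 — mRNA NS and protein NS;
#'   \item Group 2 — up/up with at least one layer SS (concordant induced);
#'   \item Group 3 — mRNA up, protein down, at least one SS (discordant);
#'   \item Group 4 — down/down with at least one layer SS (concordant
#'     repressed);
#'   \item Group 5 — mRNA down, protein up, at least one SS (discordant).
#' }
#' Combinations outside this rule table (an SS layer with log2FC exactly
#' 0, or a lone NS-flat layer paired with an SS layer) are flagged
#' `unclassified` with `group = NA` rather than silently binned.
#'
#' @param rna,protein differential result `data.frame`s from
#'   [welch_differential()] (columns `feature_id`, `log2fc`,
#'   `significant`, `direction`).
#' @return A `data.frame` with `gene_id`, `mrna_sig`, `mrna_dir`,
#'   `prot_sig`, `prot_dir`, `group` (integer 1-5 or NA) and
#'   `unclassified`.
#' @export
stratify_five_groups <- function(rna, protein) {
  shared <- intersect(rna$feature_id, protein$feature_id)
  if (!length(shared)) stopf("no shared genes between mRNA and protein results")
  r <- rna[match(shared, rna$feature_id), ]
  p <- protein[match(shared, protein$feature_id), ]
  grp <- mapply(five_group_rule, r$significant, r$direction,
                p$significant, p$direction)
  data.frame(gene_id = shared,
             mrna_sig = r$significant, mrna_dir = r$direction,
             prot_sig = p$significant, prot_dir = p$direction,
             group = grp, unclassified = is.na(grp),
             row.names = NULL, stringsAsFactors = FALSE)
}

# The rule table, one gene at a time. `sig` is logical, `dir` is one of
# "up"/"down"/"flat". Returns 1..5 or NA (unclassified).
five_group_rule <- function(m_sig, m_dir, p_sig, p_dir) {
  if (!m_sig && !p_sig) return(1L)                     # Group 1, direction-free
  if ((m_sig && m_dir == "flat") || (p_sig && p_dir == "flat")) return(NA_integer_)
  # at least one SS layer below; both directions must be defined
  if (m_dir == "flat" || p_dir == "flat") return(NA_integer_)
  if (m_dir == "up"   && p_dir == "up")   return(2L)
  if (m_dir == "up"   && p_dir == "down") return(3L)
  if (m_dir == "down" && p_dir == "down") return(4L)
  return(5L)                                           # down / up
}

#' Attach localisation subcategories to concordance records
#'
#' @param records output of [stratify_five_groups()].
#' @param annotation `data.frame` with `gene_id` and `class` (one of
#'   `SP`, `TM`, `IC`, `SPTM`).
#' @param default class assigned to unannotated genes; `NA` (the
#'   default) makes an unannotated gene an error.
#' @return `records` with a `subcategory` column; the number of genes
#'   that fell back to the default is stored in attribute `n_defaulted`.
#' @export
assign_localisation <- function(records, annotation, default = NA_character_) {
  sub <- annotation$class[match(records$gene_id, annotation$gene_id)]
  n_def <- sum(is.na(sub))
  if (n_def > 0L) {
    if (is.na(default)) {
      stopf("%d gene(s) lack a localisation annotation and no default is set",
            n_def)
    }
    sub[is.na(sub)] <- default
  }
  bad <- setdiff(unique(sub), c("SP", "TM", "IC", "SPTM"))
  if (length(bad)) stopf("unknown localisation class(es): %s",
                         paste(bad, collapse = ", "))
  records$subcategory <- sub
  attr(records, "n_defaulted") <- n_def
  records
}

#' Per-group subcategory proportions
#'
#' @param records localisation-annotated concordance records.
#' @return A `data.frame` with `group`, `subcategory`, `n`, `proportion`
#'   (proportions sum to 1 within each group).
#' @export
group_subcategory_proportions <- function(records) {
  rec <- records[!is.na(records$group), ]
  tab <- table(group = rec$group, subcategory = rec$subcategory)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("group", "subcategory", "n")
  tot <- stats::ave(df$n, df$group, FUN = sum)
  df$proportion <- ifelse(tot > 0, df$n / tot, 0)
  df$group <- as.integer(df$group)
  df[order(df$group, df$subcategory), ]
}

#' Cross-check concordance groups against term membership
#'
#' Pure counting (no statistics): for every group x subcategory x term
#' cell, the number of member genes.
#'
#' @param records localisation-annotated concordance records.
#' @param term_membership named list, term -> gene-id vector.
#' @return A `data.frame` with `group`, `subcategory`, `term`, `n_genes`.
#' @export
go_crosscheck <- function(records, term_membership) {
  rec <- records[!is.na(records$group), ]
  combos <- unique(rec[, c("group", "subcategory")])
  out <- lapply(names(term_membership), function(tm) {
    members <- term_membership[[tm]]
    n <- vapply(seq_len(nrow(combos)), function(i) {
      sum(rec$group == combos$group[i] &
            rec$subcategory == combos$subcategory[i] &
            rec$gene_id %in% members)
    }, integer(1L))
    data.frame(group = combos$group, subcategory = combos$subcategory,
               term = tm, n_genes = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$term, res$group, res$subcategory), ]
}

#' Load and validate a druggable-proteome annotation
#'
#' Enforces the hierarchy approved drug => known ligand => druggable.
#'
#' @param annotation `data.frame` with `gene_id`, `druggable`,
#'   `has_ligand`, `has_approved_drug` (logicals).
#' @return The validated annotation.
#' @export
validate_druggable <- function(annotation) {
  need <- c("gene_id", "druggable", "has_ligand", "has_approved_drug")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stopf("druggable annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(annotation$has_approved_drug & !annotation$has_ligand) ||
      any(annotation$has_ligand & !annotation$druggable)) {
    stopf("druggable hierarchy violated: approved drug => ligand => druggable")
  }
  annotation
}

#' Overlap of deregulated proteins with the druggable proteome
#'
#' Counts significantly deregulated druggable proteins, their up/down
#' split, and — on the up-regulated subset — those with a known active
#' ligand or an approved drug.
#'
#' @param protein_de protein differential result ([welch_differential()]).
#' @param annotation druggable annotation (see [validate_druggable()]).
#' @param threshold q-value cut-off (default 0.05).
#' @return A named list of counts: `deregulated`, `down`, `up`,
#'   `up_with_ligand`, `up_with_drug`.
#' @export
druggable_overlap <- function(protein_de, annotation, threshold = 0.05) {
  ann <- validate_druggable(annotation)
  d <- protein_de[match(ann$gene_id, protein_de$feature_id), ]
  sig <- !is.na(d$q) & d$q < threshold & ann$druggable
  up <- sig & d$direction == "up"
  down <- sig & d$direction == "down"
  list(deregulated = sum(sig),
       down = sum(down),
       up = sum(up),
       up_with_ligand = sum(up & ann$has_ligand),
       up_with_drug = sum(up & ann$has_approved_drug))
}

#' Hierarchical clustering with Euclidean or correlation distance
#'
#' Agglomerative clustering of matrix rows with Ward linkage (Ward.D2,
#' i.e. Ward on squared dissimilarities) over either Euclidean distance
#' or one minus the Pearson correlation.
#'
#' @param matrix numeric matrix (rows are clustered).
#' @param metric `"euclidean"` or `"one_minus_pearson"`.
#' @return An object of class `hclust` (merge order, heights, labels).
#' @export
hierarchical_cluster <- function(matrix,
                                 metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  if (nrow(matrix) < 2L) stopf("need at least 2 rows to cluster")
  d <- if (metric == "euclidean") {
    stats::dist(matrix)
  } else {
    v <- row_vars(matrix)
    if (any(v == 0)) stopf("constant row(s) have undefined Pearson correlation")
    stats::as.dist(1 - stats::cor(t(matrix)))
  }
  stats::hclust(d, method = "ward.D2")
}

#' Concordance summary over the five groups
#'
#' Counts per group, plus the concordant (groups 2 and 4) versus
#' discordant (groups 3 and 5) fractions of genes with at least one
#' significant layer.
#'
#' @param records output of [stratify_five_groups()].
#' @return A list with `group_counts` (named, groups 1-5),
#'   `concordant_fraction` and `discordant_fraction` (sum to 1 over
#'   non-Group-1 classified genes), and `n_unclassified`.
#' @export
concordance_summary <- function(records) {
  g <- records$group
  counts <- vapply(1:5, function(k) sum(!is.na(g) & g == k), integer(1L))
  names(counts) <- paste0("group", 1:5)
  changed <- sum(counts[2:5])
  conc <- if (changed > 0) (counts[2] + counts[4]) / changed else NA_real_
  list(group_counts = counts,
       concordant_fraction = unname(conc),
       discordant_fraction = unname(if (is.na(conc)) NA_real_ else 1 - conc),
       n_unclassified = sum(is.na(g)))
}
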