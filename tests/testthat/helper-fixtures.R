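# Shared fixtures and independent oracles, built in code at test time.

toy_matrix <- function(values, n_per_cond = NULL, conditions = NULL) {
  m <- as.matrix(values)
  if (is.null(conditions)) {
    conditions <- rep(c("control", "treated"), each = ncol(m) / 2)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  abundance_matrix(m, conditions)
}

random_positive_matrix <- function(nr, nc) {
  matrix(exp(rnorm(nr * nc, 3, 1)), nr, nc,
         dimnames = list(paste0("g", seq_len(nr)), paste0("s", seq_len(nc))))
}

# Literal transcription of the three printed normalization equations,
# evaluated term by term (the brute-force oracle; independent of the
# vectorized implementation).
oracle_normalization <- function(vals) {
  n <- ncol(vals)
  r <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) r[i] <- exp(mean(log(vals[i, ])))
  s <- numeric(n)
  for (j in seq_len(n)) {
    ratios <- numeric(nrow(vals))
    for (i in seq_len(nrow(vals))) ratios[i] <- vals[i, j] / r[i]
    s[j] <- median(ratios)
  }
  nij <- vals
  for (j in seq_len(n)) nij[, j] <- vals[, j] / s[j]
  list(r = r, s = s, n = nij)
}

# Full O(n) walk of the weighted GSEA running sum (oracle for the O(K)
# implementation).
oracle_running_sum <- function(stats_sorted, in_set, weight = 1) {
  n <- length(stats_sorted)
  K <- sum(in_set)
  w <- abs(stats_sorted)^weight
  nr <- sum(w[in_set])
  dev <- 0; best <- 0
  for (i in seq_len(n)) {
    dev <- if (in_set[i]) dev + w[i] / nr else dev - 1 / (n - K)
    if (abs(dev) > abs(best)) best <- dev
  }
  best
}

# Exact upper hypergeometric tail by term-wise enumeration.
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Independent transcription of the five-group rule table, enumerating the
# listed combinations verbatim (first element mRNA, second protein).
oracle_five_groups <- function(m_sig, m_dir, p_sig, p_dir) {
  ss <- function(sig, dir, want) sig && dir == want
  ns <- function(sig, dir, want) !sig && dir == want
  if (!m_sig && !p_sig) return(1L)
  if (ss(m_sig, m_dir, "up") && ss(p_sig, p_dir, "up")) return(2L)
  if (ss(m_sig, m_dir, "up") && ns(p_sig, p_dir, "up")) return(2L)
  if (ns(m_sig, m_dir, "up") && ss(p_sig, p_dir, "up")) return(2L)
  if (ss(m_sig, m_dir, "up") && ss(p_sig, p_dir, "down")) return(3L)
  if (ss(m_sig, m_dir, "up") && ns(p_sig, p_dir, "down")) return(3L)
  if (ns(m_sig, m_dir, "up") && ss(p_sig, p_dir, "down")) return(3L)
  if (ss(m_sig, m_dir, "down") && ss(p_sig, p_dir, "down")) return(4L)
  if (ss(m_sig, m_dir, "down") && ns(p_sig, p_dir, "down")) return(4L)
  if (ns(m_sig, m_dir, "down") && ss(p_sig, p_dir, "down")) return(4L)
  if (ss(m_sig, m_dir, "down") && ss(p_sig, p_dir, "up")) return(5L)
  if (ns(m_sig, m_dir, "down") && ss(p_sig, p_dir, "up")) return(5L)
  if (ss(m_sig, m_dir, "down") && ns(p_sig, p_dir, "up")) return(5L)
  NA_integer_
}

# A differential-result row in the shape welch_differential() emits.
fake_de <- function(ids, lfc, q, threshold = 0.05) {
  data.frame(feature_id = ids, log2fc = lfc, t = NA_real_, df = NA_real_,
             p = q, q = q, significant = q < threshold,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

# A tiny transcript model with a prescribed codon sequence.
tiny_model <- function(codons, utr5 = 18L, utr3 = 18L, id = "tx_1") {
  data.frame(transcript_id = id, utr5_len = utr5,
             cds_len = 3L * length(codons), utr3_len = utr3, coding = TRUE,
             sequence = paste0(strrep("A", utr5), paste(codons, collapse = ""),
                               strrep("A", utr3)),
             stringsAsFactors = FALSE)
}

# Footprints that put one P-site on codon k (0-based) of a model, using
# length-28 reads and the default 12 nt offset.
fp_at_codons <- function(model, codon_idx) {
  data.frame(transcript_id = model$transcript_id,
             pos5 = model$utr5_len + 3L * codon_idx - 12L,
             length = 28L, stringsAsFactors = FALSE)
}

# Naive O(n^3) agglomerative Ward.D2 oracle via Lance-Williams updates.
oracle_ward_d2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  labels <- -seq_len(n)          # hclust convention: negative = singleton
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && d[active[a], active[b]] < bestd) {
        bestd <- d[active[a], active[b]]; best <- c(a, b)
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    merges[step, ] <- sort(c(labels[i], labels[j]))
    heights[step] <- bestd
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2 <- ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
               nk * d[i, j]^2) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(d2)
    }
    sizes[i] <- ni + nj
    labels[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}
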