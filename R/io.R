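# Readers and writers for the package's on-disk formats.
#
# TSV dialect: tab-separated, UTF-8, '#' comment lines permitted only
# before the header, '.' denotes a missing value. Matrices carry the
# feature id in the first column and sample ids in the header.

read_tsv_raw <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body_start <- 1L
  while (body_start <= length(lines) && startsWith(lines[body_start], "#")) {
    body_start <- body_start + 1L
  }
  if (body_start > length(lines)) stopf("%s: no header line found", path)
  list(lines = lines[body_start:length(lines)], offset = body_start - 1L)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV file: header of sample ids, first column of feature
#'   ids, '.' for missing values, optional leading '#' comments.
#' @param conditions condition label per sample, either a vector in
#'   column order or a named vector keyed by sample id.
#' @return An [abundance_matrix()].
#' @export
read_matrix_tsv <- function(path, conditions) {
  raw <- read_tsv_raw(path)
  header <- strsplit(raw$lines[1L], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  rows <- strsplit(raw$lines[-1L], "\t", fixed = TRUE)
  n_fields <- lengths(rows)
  bad <- which(n_fields != length(header))
  if (length(bad)) {
    stopf("%s line %d: expected %d fields, found %d",
          path, raw$offset + 1L + bad[1L], length(header), n_fields[bad[1L]])
  }
  ids <- vapply(rows, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, length(rows), length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(rows)) {
    v <- rows[[i]][-1L]
    v[v == "."] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & v != "." & !is.na(v))) {
      stopf("%s line %d: non-numeric value", path, raw$offset + 1L + i)
    }
    if (any(num < 0, na.rm = TRUE)) {
      stopf("%s line %d: negative value not allowed", path, raw$offset + 1L + i)
    }
    vals[i, ] <- num
  }
  if (!is.null(names(conditions))) conditions <- conditions[samples]
  abundance_matrix(vals, conditions)
}

#' Write an abundance (or plain) matrix as TSV
#'
#' @param matrix numeric matrix with dimnames.
#' @param path output path.
#' @param id_column name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(matrix, path, id_column = "feature_id") {
  vals <- unclass(matrix)
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  df[is.na(df)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes. Duplicate
#' genes within a set are dropped; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors, with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) stopf("%s line %d: GMT lines need name, description and >= 1 gene",
                           path, short[1L])
  nms <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) stopf("%s: duplicate set name '%s'",
                                path, nms[duplicated(nms)][1L])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), nms)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (default the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write transcript sequences as FASTA
#'
#' Thin wrappers around plain-text FASTA with one record per transcript.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path,
                              width = width)
  invisible(path)
}

#' Read/write transcript model tables
#'
#' Model TSV columns: `transcript_id`, `utr5_len`, `cds_len`, `utr3_len`,
#' `coding`; sequences travel separately as FASTA and are joined by id.
#'
#' @param path model TSV path.
#' @param fasta optional FASTA path supplying sequences.
#' @return A transcript model `data.frame`.
#' @export
read_models_tsv <- function(path, fasta = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (is.null(df$coding)) df$coding <- TRUE
  if (any(df$coding & df$cds_len %% 3L != 0L)) {
    stopf("%s: coding transcript with CDS not divisible by 3", path)
  }
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    df$sequence <- unname(seqs[df$transcript_id])
    tot <- df$utr5_len + df$cds_len + df$utr3_len
    n <- nchar(df$sequence)
    if (any(!is.na(n) & n != tot)) {
      stopf("%s: sequence length disagrees with model geometry", fasta)
    }
  }
  df
}

#' @rdname read_models_tsv
#' @param models transcript model `data.frame`.
#' @export
write_models_tsv <- function(models, path) {
  cols <- intersect(c("transcript_id", "utr5_len", "cds_len", "utr3_len",
                      "coding"), names(models))
  utils::write.table(models[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write footprint tables
#'
#' Columns: `transcript_id`, `pos5` (0-based 5'-end position), `length`.
#'
#' @param path footprint TSV path.
#' @return A footprint `data.frame`.
#' @export
read_footprints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("transcript_id", "pos5", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (any(df$pos5 < 0)) stopf("%s: negative pos5", path)
  df
}

#' @rdname read_footprints_tsv
#' @param footprints footprint `data.frame`.
#' @export
write_footprints_tsv <- function(footprints, path) {
  utils::write.table(footprints[, c("transcript_id", "pos5", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential result table as TSV
#'
#' @param result differential result `data.frame`.
#' @param path output path.
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
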