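# Format readers and writers shared by all stages. Readers validate at
# load and report offending data lines (1-based, counting the header as
# line 1). All tabular output is TSV/CSV with headers; FASTA is wrapped at
# 80 columns; motif hits are written as BED6.

read_table_checked <- function(path, reader, required, what) {
  if (!file.exists(path)) abort_input(sprintf("%s not found: %s", what, path))
  df <- reader(path)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(
      sprintf("%s %s: missing column(s) %s.", what, path,
              paste(missing, collapse = ", ")),
      class = "riplab_format_error"
    )
  }
  df
}

fail_rows <- function(bad, path, what, msg) {
  if (any(bad)) {
    rlang::abort(
      sprintf("%s %s: %s at line(s) %s.", what, path, msg,
              paste(head(which(bad) + 1L, 5L), collapse = ", ")),
      class = "riplab_format_error"
    )
  }
}

#' Read a RIP-seq count table
#'
#' Tab-separated with header `gene_id`, `biotype`, `input`, `ip`,
#' `mock_ip` (biotype optional if supplied separately to downstream calls).
#' Counts must be non-negative integers; gene ids unique.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_counts <- function(path) {
  df <- read_table_checked(
    path,
    function(p) readr::read_tsv(p, show_col_types = FALSE),
    c("gene_id", "input", "ip", "mock_ip"), "count table"
  )
  for (col in c("input", "ip", "mock_ip")) {
    fail_rows(!is.finite(df[[col]]) | df[[col]] < 0 |
                df[[col]] != floor(df[[col]]),
              path, "count table",
              sprintf("negative or non-integer `%s`", col))
  }
  fail_rows(duplicated(df$gene_id), path, "count table", "duplicated gene_id")
  df
}

#' Write a RIP-seq count table
#' @param counts Count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a courtship bout log
#'
#' Comma-separated with header `male_id`, `group`, `bout_start_s`,
#' `bout_end_s`, `observation_s`. Bouts must satisfy
#' `0 <= start < end <= observation_s`; `NA` bouts mark males without
#' courtship.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_bouts <- function(path) {
  df <- read_table_checked(
    path,
    function(p) readr::read_csv(p, show_col_types = FALSE),
    c("male_id", "group", "bout_start_s", "bout_end_s", "observation_s"),
    "bout log"
  )
  real <- !is.na(df$bout_start_s) & !is.na(df$bout_end_s)
  fail_rows(real & (df$bout_end_s <= df$bout_start_s),
            path, "bout log", "bout end not after start")
  fail_rows(real & (df$bout_start_s < 0 | df$bout_end_s > df$observation_s),
            path, "bout log", "bout outside the observation window")
  df
}

#' Read a densitometry table
#'
#' Comma-separated with header `genotype`, `replicate`, `fraction`, `lane`,
#' `relative_load`, `chemi_signal`, `total_protein_signal`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_densitometry <- function(path) {
  df <- read_table_checked(
    path,
    function(p) readr::read_csv(p, show_col_types = FALSE),
    c("genotype", "replicate", "relative_load", "chemi_signal",
      "total_protein_signal"), "densitometry table"
  )
  fail_rows(!is.finite(df$relative_load) | df$relative_load <= 0,
            path, "densitometry table", "non-positive relative load")
  fail_rows(!is.finite(df$chemi_signal) | df$chemi_signal < 0,
            path, "densitometry table", "negative chemiluminescent signal")
  fail_rows(!is.finite(df$total_protein_signal) |
              df$total_protein_signal <= 0,
            path, "densitometry table", "non-positive total-protein signal")
  df
}

#' Read a qPCR Ct table
#'
#' Comma-separated with header `sample_id`, `ct_target`, `ct_reference`
#' (optional `target`, `reference`, `input_fraction` columns carried
#' through).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_ct <- function(path) {
  df <- read_table_checked(
    path,
    function(p) readr::read_csv(p, show_col_types = FALSE),
    c("sample_id", "ct_target", "ct_reference"), "Ct table"
  )
  for (col in c("ct_target", "ct_reference")) {
    fail_rows(!is.finite(df[[col]]) | df[[col]] <= 0,
              path, "Ct table", sprintf("non-positive `%s`", col))
  }
  df
}

#' Read / write FASTA
#'
#' Multi-record FASTA via Biostrings; sequences returned as a named
#' character vector. Writing wraps at 80 columns.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("FASTA not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- as_sequence_vector(sequences)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 80L
  )
  invisible(path)
}

#' Write motif hits as BED6
#'
#' `chrom = seq_id`, 0-based half-open `start`/`end`, `name = pattern`,
#' `score = 0`, `strand = +` (only the sense strand is ever scanned).
#'
#' @param hits A hit tibble from [scan_motifs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  check_columns(hits, c("seq_id", "start", "end", "pattern"), "hit table")
  bed <- tibble(
    chrom = hits$seq_id, start = hits$start, end = hits$end,
    name = hits$pattern, score = 0L, strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene set (one id per line) or GMT file
#'
#' Files ending in `.gmt` are parsed as GMT (set name, description, then
#' members, tab-separated; returns a named list); anything else as one gene
#' id per line (returns a character vector).
#'
#' @param path Path to the gene-set file.
#' @return Character vector, or named list of character vectors for GMT.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("gene set not found: %s", path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad)) {
      rlang::abort(
        sprintf("GMT file %s: fewer than 3 tab-separated fields at line(s) %s.",
                path, paste(head(which(bad), 5L), collapse = ", ")),
        class = "riplab_format_error"
      )
    }
    setNames(
      lapply(parts, function(p) unique(trimws(p[-(1:2)]))),
      vapply(parts, `[[`, character(1), 1L)
    )
  } else {
    ids <- trimws(readLines(path))
    unique(ids[nzchar(ids)])
  }
}
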