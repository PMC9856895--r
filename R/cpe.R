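#' Scan sequences for CPE motifs
#'
#' Reports every occurrence of every pattern in a [cpe_motifs()] set on the
#' sense strand of the given sequence(s). Overlapping occurrences are
#' counted at distinct start positions, and a pattern is matched literally
#' (IUPAC degeneracy allowed inside the pattern; `N` in the sequence never
#' matches). The reverse complement is never scanned: inputs are mRNA 3'UTRs
#' written as DNA, so only the sense strand is meaningful.
#'
#' @param sequences A character vector of DNA sequences (alphabet
#'   `A,C,G,T,N`, case-insensitive), optionally named, or a
#'   [Biostrings::DNAStringSet].
#' @param motifs A [cpe_motifs()] object. Default: [cpe_motifs()].
#' @return A tibble with one row per hit: `seq_id`, `start` (0-based),
#'   `end` (exclusive), `pattern`, `cpe_class` (`"canonical"` or
#'   `"noncanonical"`). Coordinates are 0-based half-open (BED convention).
#' @examples
#' scan_motifs("AAATTTTATAAA", cpe_motifs(canonical = "TTTTAT",
#'                                        noncanonical = "TTTTGT"))
#' @export
scan_motifs <- function(sequences, motifs = cpe_motifs()) {
  motifs <- as_cpe_motifs(motifs)
  sequences <- as_sequence_vector(sequences)
  pat_tbl <- tibble(
    pattern = c(motifs$canonical, motifs$noncanonical),
    cpe_class = rep(
      c("canonical", "noncanonical"),
      c(length(motifs$canonical), length(motifs$noncanonical))
    )
  )
  hits <- purrr::map2_dfr(sequences, names(sequences), function(seq, id) {
    purrr::pmap_dfr(pat_tbl, function(pattern, cpe_class) {
      starts <- match_starts(seq, pattern)
      tibble(
        seq_id = id,
        start = starts,
        end = starts + nchar(pattern),
        pattern = pattern,
        cpe_class = cpe_class
      )
    })
  })
  if (nrow(hits) == 0L) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      pattern = character(), cpe_class = character()
    ))
  }
  dplyr::arrange(hits, .data$seq_id, .data$start, .data$pattern)
}

# 0-based start positions of `pattern` in `seq` (both already validated).
match_starts <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer())
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern),
    Biostrings::DNAString(seq),
    fixed = c(pattern = FALSE, subject = TRUE)
  )
  as.integer(Biostrings::start(m)) - 1L
}

as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet") || inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences)) {
    abort_input("`sequences` must be a character vector or DNAStringSet.")
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- if (length(sequences) == 1L) "seq1" else {
      paste0("seq", seq_along(sequences))
    }
  }
  sequences <- toupper(sequences)
  bad <- !grepl("^[ACGTN]*$", sequences)
  if (any(bad)) {
    abort_input(sprintf(
      "sequence(s) %s contain letters outside the A,C,G,T,N alphabet.",
      paste(names(sequences)[bad], collapse = ", ")
    ))
  }
  sequences
}

#' CPE census of one or more sequences
#'
#' Counts canonical and noncanonical CPE motif occurrences per sequence.
#'
#' @inheritParams scan_motifs
#' @return A tibble of class `cpe_census` with one row per sequence:
#'   `seq_id`, `n_canonical`, `n_noncanonical`, `n_total`. The full hit
#'   table (as from [scan_motifs()]) is attached as attribute `"hits"`.
#' @examples
#' utr <- simulate_utr(length = 500, planted = c(TTTTAT = 3), seed = 1)
#' cpe_census(utr$sequence)
#' @export
cpe_census <- function(sequences, motifs = cpe_motifs()) {
  sequences <- as_sequence_vector(sequences)
  hits <- scan_motifs(sequences, motifs)
  counts <- hits |>
    dplyr::count(.data$seq_id, .data$cpe_class) |>
    tidyr::pivot_wider(
      names_from = "cpe_class", values_from = "n", values_fill = 0L
    )
  out <- tibble(seq_id = names(sequences)) |>
    dplyr::left_join(counts, by = "seq_id")
  for (cls in c("canonical", "noncanonical")) {
    if (!cls %in% names(out)) out[[cls]] <- 0L
    out[[cls]][is.na(out[[cls]])] <- 0L
  }
  out <- out |>
    dplyr::transmute(
      seq_id = .data$seq_id,
      n_canonical = as.integer(.data$canonical),
      n_noncanonical = as.integer(.data$noncanonical),
      n_total = .data$n_canonical + .data$n_noncanonical
    )
  structure(out, hits = hits, class = c("cpe_census", class(out)))
}

#' Delete an interval from a sequence
#'
#' Removes the 0-based half-open interval `[start, end)` and joins the
#' flanks, mimicking a genomic deletion such as a 3'UTR truncation allele.
#' Motifs spanning a breakpoint are destroyed unless the junction happens to
#' recreate a match; a census of the returned sequence is computed on the
#' joined sequence, so junction-created sites are counted.
#'
#' @param sequence A single DNA sequence string.
#' @param start,end 0-based half-open interval to remove;
#'   `0 <= start <= end <= nchar(sequence)`.
#' @return The shortened sequence (length `nchar(sequence) - (end - start)`).
#' @examples
#' apply_deletion("ACGTACG", 2, 5)  # keeps positions 0,1,5,6
#' @export
apply_deletion <- function(sequence, start, end) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort_input("`sequence` must be a single string.")
  }
  n <- nchar(sequence)
  check_scalar_num(start, "start", min = 0, integerish = TRUE)
  check_scalar_num(end, "end", min = 0, integerish = TRUE)
  if (start > end || end > n) {
    abort_input(sprintf(
      "deletion interval [%d, %d) out of bounds for a %d nt sequence.",
      start, end, n
    ))
  }
  paste0(substr(sequence, 1L, start), substr(sequence, end + 1L, n))
}

#' @export
print.cpe_census <- function(x, ...) {
  cat("CPE census (", nrow(x), " sequence",
      if (nrow(x) != 1L) "s", ")\n", sep = "")
  NextMethod()
}

#' @rdname cpe_census
#' @param x A `cpe_census` object.
#' @param ... Unused.
#' @export
tidy.cpe_census <- function(x, ...) {
  as_tibble(attr(x, "hits"))
}
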