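#' Define a CPE motif set
#'
#' A cytoplasmic polyadenylation element (CPE) motif set splits patterns into
#' the two classes used when describing CPEB-binding sites in 3'UTRs:
#' canonical (A-containing, e.g. `TTTTAT`) and noncanonical (G-containing,
#' e.g. `TTTTGT`) variants of the U-rich element, written as DNA.
#'
#' The default set is a minimal, commonly used collection of hexa/heptamer
#' variants. It is deliberately user-configurable and *not authoritative*:
#' published per-isoform CPE counts depend on the exact motif list used by
#' each study, so reproducing a printed census requires supplying that
#' study's list (e.g. via [read_motifs()]).
#'
#' Patterns may use fixed-length IUPAC degeneracy codes (e.g. `TTTTRT`);
#' they are matched literally against the sequence, in which `N` never
#' matches anything.
#'
#' @param canonical Character vector of canonical (A-containing) patterns.
#' @param noncanonical Character vector of noncanonical (G-containing)
#'   patterns.
#' @return An object of class `cpe_motifs`: a list with elements
#'   `canonical` and `noncanonical`.
#' @examples
#' cpe_motifs()
#' cpe_motifs(canonical = "TTTTAT", noncanonical = "TTTTGT")
#' @export
cpe_motifs <- function(canonical = c("TTTTAT", "TTTTAAT", "TTTTTAT"),
                       noncanonical = c("TTTTGT", "TTTTGAT", "TTTTTGT")) {
  canonical <- toupper(as.character(canonical))
  noncanonical <- toupper(as.character(noncanonical))
  if (length(canonical) == 0L || length(noncanonical) == 0L) {
    abort_config("both motif classes must contain at least one pattern.")
  }
  pats <- c(canonical, noncanonical)
  bad <- pats[nchar(pats) < 4L | !grepl("^[ACGTRYSWKMBDHVN]+$", pats)]
  if (length(bad)) {
    abort_config(sprintf(
      "invalid motif pattern(s): %s (must be >= 4 nt over the DNA/IUPAC alphabet).",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(pats)) {
    abort_config("motif patterns must be unique across classes.")
  }
  structure(
    list(canonical = canonical, noncanonical = noncanonical),
    class = "cpe_motifs"
  )
}

#' @export
print.cpe_motifs <- function(x, ...) {
  cat("<cpe_motifs>\n")
  cat("  canonical:    ", paste(x$canonical, collapse = ", "), "\n")
  cat("  noncanonical: ", paste(x$noncanonical, collapse = ", "), "\n")
  invisible(x)
}

#' Read a CPE motif set from a YAML file
#'
#' The file must define `canonical:` and `noncanonical:` pattern lists.
#'
#' @param path Path to a YAML file.
#' @return A [cpe_motifs()] object.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("motif file not found: %s", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$canonical) || is.null(spec$noncanonical)) {
    abort_input("motif file must define `canonical` and `noncanonical` lists.")
  }
  cpe_motifs(unlist(spec$canonical), unlist(spec$noncanonical))
}

as_cpe_motifs <- function(x) {
  if (inherits(x, "cpe_motifs")) return(x)
  if (is.list(x) && all(c("canonical", "noncanonical") %in% names(x))) {
    return(cpe_motifs(x$canonical, x$noncanonical))
  }
  abort_config("`motifs` must be a cpe_motifs object (see cpe_motifs()).")
}
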