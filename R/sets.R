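# Overlap and over-representation statistics for called target lists
# against published gene sets and annotation terms.

as_id_set <- function(x, name) {
  if (is.list(x) && !is.null(x$members)) x <- x$members
  if (!is.character(x)) {
    abort_input(sprintf("`%s` must be a character vector of gene ids.", name))
  }
  unique(trimws(x))
}

#' Overlap between two gene sets
#'
#' Counts the intersection of two gene sets, reports the overlap as a
#' percentage of the second set, and computes an upper-tail hypergeometric
#' p-value for an overlap at least this large under random draws from the
#' universe. The percentage does not depend on the universe; the p-value
#' does.
#'
#' @param a,b Character vectors of gene ids (ids are assumed
#'   case-consistent across inputs; only surrounding whitespace is
#'   trimmed). `b` is the reference set the percentage refers to.
#' @param universe Character vector of gene ids forming the sampling frame
#'   (e.g. all detected protein-coding genes). `a` and `b` are intersected
#'   with it before testing.
#' @return A one-row tibble: `n_a`, `n_b`, `n_overlap`, `pct_of_b`,
#'   `p_value`.
#' @examples
#' overlap_sets(letters[1:10], letters[7:10], universe = letters[1:20])
#' @export
overlap_sets <- function(a, b, universe) {
  a <- as_id_set(a, "a")
  b <- as_id_set(b, "b")
  if (length(b) == 0L) {
    abort_input("reference set `b` is empty; overlap percentage undefined.")
  }
  universe <- as_id_set(universe, "universe")
  if (length(universe) == 0L) abort_input("`universe` is empty.")
  n_overlap_raw <- length(intersect(a, b))
  a_u <- intersect(a, universe)
  b_u <- intersect(b, universe)
  k <- length(intersect(a_u, b_u))
  p <- phyper(k - 1, length(a_u), length(universe) - length(a_u),
              length(b_u), lower.tail = FALSE)
  tibble(
    n_a = length(a),
    n_b = length(b),
    n_overlap = n_overlap_raw,
    pct_of_b = 100 * n_overlap_raw / length(b),
    p_value = p
  )
}

#' Over-representation analysis with fold enrichment
#'
#' For each annotation term, compares the term's frequency among target
#' genes with its frequency in the universe:
#' `fold = (k / n_targets) / (K / n_universe)` where `k` targets and `K`
#' universe genes carry the term. Significance is the upper-tail
#' hypergeometric p-value, adjusted across tested terms by
#' Benjamini-Hochberg. Only terms with at least one target member are
#' tested. Annotation genes are intersected with the universe first.
#'
#' @param targets Character vector of target gene ids; must be a subset of
#'   `universe`.
#' @param annotation A two-column tibble (or data frame) `term`, `gene`
#'   mapping annotation terms to genes, or a named list of gene-id vectors.
#' @param universe Character vector of gene ids (the sampling frame).
#' @return A tibble with one row per tested term: `term`,
#'   `n_term_in_targets`, `n_term_in_universe`, `fold_enrichment`,
#'   `p_value`, `q_value`, sorted by increasing p-value.
#' @examples
#' ann <- tibble::tibble(term = rep("axon", 20), gene = letters[1:20])
#' ora_fold_enrichment(letters[1:5], ann, universe = letters)
#' @export
ora_fold_enrichment <- function(targets, annotation, universe) {
  universe <- as_id_set(universe, "universe")
  if (length(universe) == 0L) abort_input("`universe` is empty.")
  targets <- as_id_set(targets, "targets")
  stray <- setdiff(targets, universe)
  if (length(stray)) {
    abort_input(sprintf("%d target id(s) are not in the universe.",
                        length(stray)))
  }
  if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation <- tibble(
      term = rep(names(annotation), lengths(annotation)),
      gene = unlist(annotation, use.names = FALSE)
    )
  }
  check_columns(annotation, c("term", "gene"), "annotation table")
  ann <- annotation |>
    dplyr::distinct(.data$term, .data$gene) |>
    dplyr::filter(.data$gene %in% universe)

  n_t <- length(targets)
  n_u <- length(universe)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_term_in_targets = sum(.data$gene %in% targets),
      n_term_in_universe = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_term_in_targets >= 1L) |>
    dplyr::mutate(
      fold_enrichment = (.data$n_term_in_targets / n_t) /
        (.data$n_term_in_universe / n_u),
      p_value = phyper(.data$n_term_in_targets - 1,
                       .data$n_term_in_universe,
                       n_u - .data$n_term_in_universe,
                       n_t, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_value, .data$term)
  res
}
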