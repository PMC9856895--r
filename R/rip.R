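# Control-calibrated RIP-seq target calling.
#
# The rule chain mirrors a gene-level RIP-seq analysis with one experimental
# IP, one mock IP (pre-immune IgG) and the Input lysate: CPM-normalize,
# require detection in Input and IP, form the two enrichment ratios
# (IP/Input and IP/mock), calibrate per-ratio thresholds on three positive
# control transcripts, and keep protein-coding genes whose ratios are at or
# above both thresholds.

validate_counts <- function(counts) {
  check_columns(counts, c("gene_id", "input", "ip", "mock_ip"),
                "count table")
  if (nrow(counts) == 0L) abort_input("count table is empty.")
  if (anyDuplicated(counts$gene_id)) {
    abort_input("count table has duplicated gene ids.")
  }
  for (col in c("input", "ip", "mock_ip")) {
    x <- counts[[col]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      abort_input(sprintf("column `%s` must hold non-negative counts.", col))
    }
  }
  invisible(counts)
}

#' Counts-per-million normalization
#'
#' `cpm(g, s) = 1e6 * (count(g, s) + pseudocount) /
#'   sum_g'(count(g', s) + pseudocount)`, so each sample column sums to
#' exactly one million. The default pseudocount of 0.5 keeps all downstream
#' enrichment ratios finite for genes absent from one sample;
#' `pseudocount = 0` gives exact proportions.
#'
#' @param counts A count table: tibble with columns `gene_id`, `input`,
#'   `ip`, `mock_ip` (a `biotype` column, if present, is carried through).
#' @param pseudocount Non-negative value added to every count (default 0.5).
#' @return A tibble with `gene_id` (and `biotype` if supplied) and CPM
#'   columns `input`, `ip`, `mock_ip`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), input = c(100, 900),
#'                          ip = c(500, 500), mock_ip = c(250, 750))
#' compute_cpm(counts, pseudocount = 0)
#' @export
compute_cpm <- function(counts, pseudocount = 0.5) {
  validate_counts(counts)
  check_scalar_num(pseudocount, "pseudocount", min = 0)
  out <- dplyr::select(counts, dplyr::any_of(c("gene_id", "biotype")))
  for (col in c("input", "ip", "mock_ip")) {
    shifted <- counts[[col]] + pseudocount
    total <- sum(shifted)
    if (total == 0) {
      abort_input(sprintf(
        "sample `%s` has zero total count and pseudocount 0; CPM undefined.",
        col
      ))
    }
    out[[col]] <- 1e6 * shifted / total
  }
  as_tibble(out)
}

#' Detection filter
#'
#' A gene is *detected* when its raw count is at least `min_count` in both
#' the Input and the experimental IP sample. The mock IP is not consulted:
#' absence from the mock is informative for enrichment, not detection.
#'
#' @inheritParams compute_cpm
#' @param min_count Positive integer detection floor (default 1: raw-count
#'   presence).
#' @return Character vector of detected gene ids.
#' @export
detect_genes <- function(counts, min_count = 1) {
  validate_counts(counts)
  check_scalar_num(min_count, "min_count", min = 1, integerish = TRUE)
  counts$gene_id[counts$input >= min_count & counts$ip >= min_count]
}

#' Per-gene enrichment ratios
#'
#' Builds the per-gene table of the two enrichment parameters: the ratio of
#' CPM in the experimental IP to CPM in Input, and the ratio of CPM in the
#' experimental IP to CPM in the mock IP.
#'
#' @param cpm A CPM table from [compute_cpm()]; must have been computed with
#'   a positive pseudocount so ratios are finite (an all-finite check is
#'   enforced).
#' @param detected Character vector of detected gene ids (from
#'   [detect_genes()]).
#' @param biotypes Optional tibble `gene_id`, `biotype` when the CPM table
#'   lacks a biotype column.
#' @return A tibble: `gene_id`, `biotype`, `detected`, `ratio_ip_input`,
#'   `ratio_ip_mock`. The pass/fail call is left to [call_targets()].
#' @export
enrichment_table <- function(cpm, detected, biotypes = NULL) {
  check_columns(cpm, c("gene_id", "input", "ip", "mock_ip"), "CPM table")
  if (!"biotype" %in% names(cpm)) {
    if (is.null(biotypes)) {
      abort_input("supply `biotypes` when the CPM table has no biotype column.")
    }
    check_columns(biotypes, c("gene_id", "biotype"), "biotype table")
    cpm <- dplyr::left_join(cpm, dplyr::distinct(biotypes), by = "gene_id")
    if (anyNA(cpm$biotype)) {
      abort_input("some genes have no biotype annotation.")
    }
  }
  if (any(cpm$input == 0) || any(cpm$mock_ip == 0)) {
    abort_input(paste(
      "zero CPM in a denominator sample; recompute CPM with a positive",
      "pseudocount so enrichment ratios are finite."
    ))
  }
  cpm |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      biotype = .data$biotype,
      detected = .data$gene_id %in% detected,
      ratio_ip_input = .data$ip / .data$input,
      ratio_ip_mock = .data$ip / .data$mock_ip
    )
}

#' Calibrate enrichment thresholds on positive-control transcripts
#'
#' The discard rule keeps genes whose enrichment is not lower than that
#' observed for the positive-control mRNAs. Per ratio, the threshold is the
#' *minimum* of that ratio over the three controls — the most permissive
#' reading of "not lower than the controls" that still guarantees every
#' control passes its own calibration.
#'
#' @param table An enrichment table from [enrichment_table()].
#' @param control_ids Character vector of exactly three positive-control
#'   gene ids (classically `orb2`, `act5C`, `tub56D`).
#' @return An object of class `filter_thresholds`: list with
#'   `min_ratio_ip_input`, `min_ratio_ip_mock`, `control_ids`.
#' @export
calibrate_thresholds <- function(table, control_ids) {
  check_columns(table, c("gene_id", "detected", "ratio_ip_input",
                         "ratio_ip_mock"), "enrichment table")
  control_ids <- as.character(control_ids)
  if (length(control_ids) != 3L) {
    abort_config("exactly three positive-control gene ids are required.",
                 "control_ids")
  }
  rows <- table[match(control_ids, table$gene_id), ]
  missing <- control_ids[is.na(rows$gene_id)]
  if (length(missing)) {
    rlang::abort(
      sprintf("control gene(s) absent from the table: %s.",
              paste(missing, collapse = ", ")),
      class = "riplab_calibration_error"
    )
  }
  undetected <- control_ids[!rows$detected]
  if (length(undetected)) {
    rlang::abort(
      sprintf("control gene(s) not detected in Input and IP: %s.",
              paste(undetected, collapse = ", ")),
      class = "riplab_calibration_error"
    )
  }
  structure(
    list(
      min_ratio_ip_input = min(rows$ratio_ip_input),
      min_ratio_ip_mock = min(rows$ratio_ip_mock),
      control_ids = control_ids
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("<filter_thresholds>\n")
  cat(sprintf("  IP/Input >= %.4g, IP/mock >= %.4g (controls: %s)\n",
              x$min_ratio_ip_input, x$min_ratio_ip_mock,
              paste(x$control_ids, collapse = ", ")))
  invisible(x)
}

#' Call target genes from an enrichment table
#'
#' A gene passes when it is detected, protein-coding, and both of its
#' enrichment ratios are at or above the calibrated thresholds (ties pass:
#' the controls themselves must pass their own calibration).
#'
#' @param table An enrichment table from [enrichment_table()].
#' @param thresholds A [calibrate_thresholds()] object.
#' @return A list: `targets` (gene ids sorted by descending IP/mock ratio,
#'   gene id as tie-break) and `table` (the enrichment table with a logical
#'   `passes` column added).
#' @export
call_targets <- function(table, thresholds) {
  if (!inherits(thresholds, "filter_thresholds")) {
    abort_input("`thresholds` must come from calibrate_thresholds().")
  }
  check_columns(table, c("gene_id", "biotype", "detected", "ratio_ip_input",
                         "ratio_ip_mock"), "enrichment table")
  annotated <- table |>
    dplyr::mutate(
      passes = .data$detected &
        .data$biotype == "protein_coding" &
        .data$ratio_ip_input >= thresholds$min_ratio_ip_input &
        .data$ratio_ip_mock >= thresholds$min_ratio_ip_mock
    )
  targets <- annotated |>
    dplyr::filter(.data$passes) |>
    dplyr::arrange(dplyr::desc(.data$ratio_ip_mock), .data$gene_id) |>
    dplyr::pull("gene_id")
  list(targets = targets, table = annotated)
}

#' One-call RIP-seq target calling
#'
#' Runs the full chain — CPM normalization, detection, enrichment ratios,
#' control calibration, target calling — and returns a fitted result object
#' with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams compute_cpm
#' @inheritParams detect_genes
#' @param controls Three positive-control gene ids used for calibration.
#' @param biotypes Optional `gene_id`/`biotype` tibble when `counts` lacks
#'   a biotype column.
#' @return An object of class `rip_targets`: list with `targets`, `table`
#'   (per-gene enrichment table with `passes`), `thresholds`, `params`.
#' @examples
#' sim <- simulate_ripseq(n_genes = 300, n_targets = 30, seed = 1)
#' fit <- call_rip_targets(sim$counts)
#' glance(fit)
#' @export
call_rip_targets <- function(counts,
                             controls = c("orb2", "act5C", "tub56D"),
                             pseudocount = 0.5,
                             min_count = 1,
                             biotypes = NULL) {
  validate_counts(counts)
  if (!"biotype" %in% names(counts) && !is.null(biotypes)) {
    check_columns(biotypes, c("gene_id", "biotype"), "biotype table")
    counts <- dplyr::left_join(counts, dplyr::distinct(biotypes),
                               by = "gene_id")
    if (anyNA(counts$biotype)) abort_input("some genes lack a biotype.")
  }
  if (!"biotype" %in% names(counts)) {
    abort_input("counts need a `biotype` column or a `biotypes` table.")
  }
  cpm <- compute_cpm(counts, pseudocount)
  detected <- detect_genes(counts, min_count)
  tab <- enrichment_table(cpm, detected)
  thr <- calibrate_thresholds(tab, controls)
  called <- call_targets(tab, thr)
  structure(
    list(
      targets = called$targets,
      table = called$table,
      thresholds = thr,
      params = list(controls = controls, pseudocount = pseudocount,
                    min_count = min_count)
    ),
    class = "rip_targets"
  )
}

#' @export
print.rip_targets <- function(x, ...) {
  cat("RIP-seq target call\n")
  cat(sprintf("  genes: %d, detected: %d, called targets: %d\n",
              nrow(x$table), sum(x$table$detected), length(x$targets)))
  print(x$thresholds)
  invisible(x)
}
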