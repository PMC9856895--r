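# broom-style tidiers for the fitted result objects.

#' Tidy a RIP-seq target call
#'
#' @param x A `rip_targets` object from [call_rip_targets()].
#' @param ... Unused.
#' @return `tidy()`: the per-gene enrichment table (one row per gene, with
#'   `passes`). `glance()`: a one-row summary with gene/detection/call
#'   counts and the calibrated thresholds.
#' @export
tidy.rip_targets <- function(x, ...) {
  as_tibble(x$table)
}

#' @rdname tidy.rip_targets
#' @export
glance.rip_targets <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_detected = sum(x$table$detected),
    n_called = length(x$targets),
    min_ratio_ip_input = x$thresholds$min_ratio_ip_input,
    min_ratio_ip_mock = x$thresholds$min_ratio_ip_mock,
    pseudocount = x$params$pseudocount,
    min_count = x$params$min_count
  )
}

#' Tidy a randomization test
#'
#' @param x A `randomization_test` object.
#' @param ... Unused.
#' @return `tidy()`: one row with the observed statistic and `alpha_R`.
#'   `glance()`: one row with the full test configuration and outcome.
#' @export
tidy.randomization_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    estimate = x$statistic_observed,
    alpha_R = x$alpha_R
  )
}

#' @rdname tidy.randomization_test
#' @export
glance.randomization_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    sides = x$sides,
    statistic_observed = x$statistic_observed,
    alpha_R = x$alpha_R,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    alpha = x$alpha,
    reject = x$reject
  )
}

#' Tidy a learning-index result
#'
#' @param x A `learning_index` object.
#' @param ... Unused.
#' @return A one-row tibble: `li`, `ci_naive`, `ci_trained` (percentages).
#' @export
tidy.learning_index <- function(x, ...) {
  tibble(li = x$li, ci_naive = x$ci_naive, ci_trained = x$ci_trained)
}

#' Tidy a relative-level result
#'
#' @param x A `relative_level` object from [relative_level()].
#' @param ... Unused.
#' @return `tidy()`: per-replicate normalized levels. `glance()`: one row
#'   with the mutant/WT ratio, t-statistic and p-value.
#' @export
tidy.relative_level <- function(x, ...) {
  as_tibble(x$levels)
}

#' @rdname tidy.relative_level
#' @export
glance.relative_level <- function(x, ...) {
  tibble(
    ratio_mut_over_wt = x$ratio_mut_over_wt,
    t_statistic = x$t_statistic,
    p_value = x$p_value,
    n_mut = x$n_mut,
    n_wt = x$n_wt,
    test = x$test
  )
}

#' @rdname cpe_census
#' @export
glance.cpe_census <- function(x, ...) {
  tibble(
    n_sequences = nrow(x),
    n_canonical = sum(x$n_canonical),
    n_noncanonical = sum(x$n_noncanonical),
    n_total = sum(x$n_total)
  )
}
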