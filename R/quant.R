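# Semiquantitative immunoblot quantification from serial-dilution series,
# relative qPCR expression (delta-delta-Ct) and IP yield (% of input).

#' Normalized protein level from one dilution series
#'
#' Stain-free quantification: both the chemiluminescent band signal and the
#' total-protein signal are proportional to the loaded amount, so each
#' channel is fit by least squares *through the origin* against the relative
#' load, and the level is the ratio of the two slopes:
#' `level = slope(chemi ~ load) / slope(total_protein ~ load)`.
#' The level is invariant under joint rescaling of both channels.
#'
#' @param series A tibble for one replicate series with columns
#'   `relative_load` (in `(0, 1]`), `chemi_signal` (>= 0),
#'   `total_protein_signal` (> 0); at least two lanes with distinct loads.
#' @return A single normalized level (arbitrary units).
#' @examples
#' s <- tibble::tibble(relative_load = c(1/2, 1/4, 1/6),
#'                     chemi_signal = 10 * c(1/2, 1/4, 1/6),
#'                     total_protein_signal = 2 * c(1/2, 1/4, 1/6))
#' normalized_level(s)  # exactly 5
#' @export
normalized_level <- function(series) {
  check_columns(series, c("relative_load", "chemi_signal",
                          "total_protein_signal"), "dilution series")
  load <- series$relative_load
  if (any(!is.finite(load)) || any(load <= 0)) {
    abort_input("relative loads must be positive.")
  }
  if (length(unique(load)) < 2L) {
    abort_input("a dilution series needs at least two distinct loads.")
  }
  slope_origin <- function(y) sum(load * y) / sum(load^2)
  denom <- slope_origin(series$total_protein_signal)
  if (denom == 0) {
    rlang::abort("total-protein slope is zero; series is degenerate.",
                 class = "riplab_degenerate_input_error")
  }
  slope_origin(series$chemi_signal) / denom
}

#' Relative protein level between two genotypes
#'
#' Computes one normalized level per replicate series (per genotype) via
#' [normalized_level()], then the ratio of genotype means and a two-sample
#' t-test on the per-replicate levels (Welch by default; the pooled-variance
#' Student test is available via `test = "pooled"`).
#'
#' @param data A densitometry tibble (as from [simulate_western()] or
#'   [read_densitometry()]) with columns `genotype`, `replicate`,
#'   `fraction`, `relative_load`, `chemi_signal`, `total_protein_signal`.
#' @param mut,wt Genotype labels of the numerator and denominator arms.
#' @param test `"welch"` (default) or `"pooled"`.
#' @return An object of class `relative_level`: list with
#'   `ratio_mut_over_wt`, `levels` (tibble of per-replicate normalized
#'   levels), `p_value`, `t_statistic`, `n_mut`, `n_wt`, `test`.
#' @examples
#' d <- simulate_western(cv = 0, n_replicates = 3, seed = 1)
#' relative_level(d)$ratio_mut_over_wt  # exactly 1/3 at cv = 0
#' @export
relative_level <- function(data, mut = "mut", wt = "wt",
                           test = c("welch", "pooled")) {
  test <- rlang::arg_match(test)
  check_columns(data, c("genotype", "replicate", "relative_load",
                        "chemi_signal", "total_protein_signal"),
                "densitometry table")
  data <- dplyr::filter(data, .data$genotype %in% c(mut, wt))
  if ("fraction" %in% names(data)) {
    fr <- split(data$fraction, data$genotype)
    if (!setequal(unique(fr[[mut]]), unique(fr[[wt]]))) {
      abort_input("fraction labels differ between the two genotype arms.")
    }
  }
  keys <- c("genotype", "replicate", intersect("fraction", names(data)))
  levels <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ tibble(level = normalized_level(.x))) |>
    dplyr::ungroup()
  lv_mut <- levels$level[levels$genotype == mut]
  lv_wt <- levels$level[levels$genotype == wt]
  if (length(lv_mut) < 2L || length(lv_wt) < 2L) {
    abort_input("at least two replicate series per genotype are required.")
  }
  ratio <- mean(lv_mut) / mean(lv_wt)
  tt <- tryCatch(
    t.test(lv_mut, lv_wt, var.equal = (test == "pooled")),
    error = function(e) NULL  # zero-variance fixtures
  )
  structure(
    list(
      ratio_mut_over_wt = ratio,
      levels = levels,
      t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) {
        if (isTRUE(all.equal(mean(lv_mut), mean(lv_wt)))) 1 else NA_real_
      } else tt$p.value,
      n_mut = length(lv_mut),
      n_wt = length(lv_wt),
      test = test,
      mut = mut,
      wt = wt
    ),
    class = "relative_level"
  )
}

#' @export
print.relative_level <- function(x, ...) {
  cat(sprintf(
    "Relative level %s/%s = %.4g (n = %d/%d, %s t-test p = %.4g)\n",
    x$mut, x$wt, x$ratio_mut_over_wt, x$n_mut, x$n_wt, x$test, x$p_value
  ))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ratio = 2^-ddCt` with `dCt = Ct_target - Ct_reference` per sample and
#' `ddCt = dCt(sample) - dCt(calibrator)`. Amplification efficiency is fixed
#' at 2.0 per cycle (no standard-curve efficiency estimation). The
#' calibrator's relative expression is exactly 1.
#'
#' @param table A Ct tibble with columns `sample_id`, `ct_target`,
#'   `ct_reference` (one row per sample; optional `target` / `reference`
#'   gene-name columns are carried through).
#' @param calibrator `sample_id` of the calibrator sample.
#' @return The input tibble with `delta_ct`, `delta_delta_ct` and
#'   `rel_expression` columns added.
#' @examples
#' ct <- tibble::tibble(sample_id = c("wt", "mut"),
#'                      ct_target = c(20, 21), ct_reference = c(16, 18))
#' relative_expression_ddct(ct, calibrator = "wt")
#' @export
relative_expression_ddct <- function(table, calibrator) {
  check_columns(table, c("sample_id", "ct_target", "ct_reference"),
                "Ct table")
  for (col in c("ct_target", "ct_reference")) {
    x <- table[[col]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      abort_input(sprintf("column `%s` must hold finite positive Ct values.",
                          col))
    }
  }
  i_cal <- match(calibrator, table$sample_id)
  if (is.na(i_cal)) {
    abort_input(sprintf("calibrator sample `%s` not found.", calibrator))
  }
  dct <- table$ct_target - table$ct_reference
  table |>
    dplyr::mutate(
      delta_ct = dct,
      delta_delta_ct = dct - dct[i_cal],
      rel_expression = 2^(-.data$delta_delta_ct)
    )
}

#' Immunoprecipitation yield as percent of input
#'
#' Yield of an mRNA recovered in an IP reaction relative to the starting
#' lysate, from qPCR Ct values of the IP and Input samples. The Input Ct is
#' measured on an aliquot comprising `input_fraction` of the lysate, so it
#' is first adjusted by `-log2(input_fraction)` cycles; the yield is then
#' `100 * input_fraction * 2^(Ct_input_adj - Ct_ip)`. (The fraction and its
#' Ct adjustment cancel algebraically, leaving
#' `100 * 2^(Ct_input - Ct_ip)`.)
#'
#' @param ct_ip,ct_input Finite Ct values (vectorized).
#' @param input_fraction Fraction of the lysate used as the Input aliquot,
#'   in `(0, 1]`; default 0.05 (100 uL of a 2 mL lysate).
#' @return Yield percentage(s), > 0, monotone decreasing in `ct_ip`.
#' @examples
#' percent_of_input(ct_ip = 22, ct_input = 22, input_fraction = 1)  # 100
#' percent_of_input(ct_ip = 23, ct_input = 22, input_fraction = 1)  # 50
#' @export
percent_of_input <- function(ct_ip, ct_input, input_fraction = 0.05) {
  if (!is.numeric(ct_ip) || !is.numeric(ct_input) ||
      any(!is.finite(ct_ip)) || any(!is.finite(ct_input))) {
    abort_input("Ct values must be finite numbers.")
  }
  check_scalar_num(input_fraction, "input_fraction", min = 0, max = 1,
                   strict_min = TRUE)
  ct_input_adj <- ct_input - log2(input_fraction)
  100 * input_fraction * 2^(ct_input_adj - ct_ip)
}
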