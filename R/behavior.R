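# Conditioned-courtship memory statistics: courtship index (CI), learning
# index (LI), and sampled randomization tests with direct estimation of the
# rejection probability alpha_R.

#' Courtship index from bout records
#'
#' The courtship index is the percentage of a fixed observation window
#' (default 300 s) that a male spends courting. Overlapping bouts are merged
#' before summation so time is never double-counted.
#'
#' @param bouts A tibble of bout records with columns `male_id`,
#'   `bout_start_s`, `bout_end_s`, `observation_s` and optionally `group`
#'   (as produced by [simulate_courtship()] or [read_bouts()]). Rows with
#'   `NA` bouts mark males observed without courtship. Each male must have a
#'   single `observation_s`.
#' @return A tibble with one row per male: `male_id`, `group` (if present),
#'   `observation_s`, `ci` (percentage in `[0, 100]`).
#' @examples
#' bouts <- tibble::tibble(male_id = "m1", bout_start_s = c(0, 100),
#'                         bout_end_s = c(50, 200), observation_s = 300)
#' courtship_index(bouts)  # 150 s of 300 -> CI 50
#' @export
courtship_index <- function(bouts) {
  check_columns(bouts, c("male_id", "bout_start_s", "bout_end_s",
                         "observation_s"), "bout table")
  real <- !is.na(bouts$bout_start_s) & !is.na(bouts$bout_end_s)
  bad <- real & (bouts$bout_start_s < 0 |
                   bouts$bout_end_s <= bouts$bout_start_s |
                   bouts$bout_end_s > bouts$observation_s)
  if (any(bad)) {
    abort_input(sprintf(
      "bout(s) outside the observation window for male(s): %s.",
      paste(unique(bouts$male_id[bad]), collapse = ", ")
    ))
  }
  keys <- c("male_id", intersect("group", names(bouts)), "observation_s")
  bouts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      ci = 100 * merged_bout_total(.data$bout_start_s, .data$bout_end_s) /
        .data$observation_s[1],
      .groups = "drop"
    )
}

# Total covered time of a set of intervals after merging overlaps.
merged_bout_total <- function(starts, ends) {
  keep <- !is.na(starts) & !is.na(ends)
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(0)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  total <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Learning index from naive and trained courtship indices
#'
#' `LI = (CIn - CIexp) / CIn * 100`, where `CIn` is the average CI of two
#' independent samples of naive males and `CIexp` the average CI of two
#' independent samples of trained males (each average is the mean of the two
#' sample means).
#'
#' @param naive,trained Each a list of one or more numeric vectors of CIs
#'   (percentages); the classical design uses two independent samples per
#'   arm. A bare numeric vector is treated as a single sample.
#' @return An object of class `learning_index`: list with `li`, `ci_naive`,
#'   `ci_trained` (all percentages).
#' @examples
#' learning_index(naive = list(c(55, 65), c(60)), trained = list(30, 30))
#' @export
learning_index <- function(naive, trained) {
  as_samples <- function(x, name) {
    if (is.numeric(x)) x <- list(x)
    if (!is.list(x) || length(x) == 0L ||
        any(!vapply(x, is.numeric, logical(1))) ||
        any(vapply(x, length, integer(1)) == 0L)) {
      abort_input(sprintf("`%s` must be (a list of) non-empty CI vectors.",
                          name))
    }
    x
  }
  naive <- as_samples(naive, "naive")
  trained <- as_samples(trained, "trained")
  ci_naive <- mean(vapply(naive, mean, numeric(1)))
  ci_trained <- mean(vapply(trained, mean, numeric(1)))
  if (ci_naive <= 0) {
    rlang::abort("learning index undefined: naive mean CI is zero.",
                 class = "riplab_undefined_index_error")
  }
  structure(
    list(
      li = (ci_naive - ci_trained) / ci_naive * 100,
      ci_naive = ci_naive,
      ci_trained = ci_trained
    ),
    class = "learning_index"
  )
}

#' @export
print.learning_index <- function(x, ...) {
  cat(sprintf("LI = %.2f%% (naive CI %.2f%%, trained CI %.2f%%)\n",
              x$li, x$ci_naive, x$ci_trained))
  invisible(x)
}

#' Sampled randomization test for courtship statistics
#'
#' Permutes group labels over the pooled per-male values and estimates the
#' probability of rejecting the null hypothesis, `alpha_R`, directly from
#' the randomization distribution. With `m` sampled permutations of which
#' `b` are as or more extreme than the observed statistic,
#' `alpha_R = (b + 1) / (m + 1)` (never zero). Whenever the number of
#' distinct label assignments is at most `n_permutations`, the test
#' enumerates all assignments exhaustively and `alpha_R = b / m` over the
#' complete enumeration (which includes the observed split).
#'
#' Statistics: `"mean_difference"` is `mean(a) - mean(b)`;
#' `"learning_index"` is `(mean(a) - mean(b)) / mean(a) * 100` with `a` in
#' the naive role. Two-sided extremity uses the absolute statistic;
#' one-sided counts permutations with statistic at or above the observed
#' value (upper tail in the statistic as computed). The study convention is
#' a two-sided test for courtship indices and a one-sided test for learning
#' indices, rejecting at `alpha_R < 0.05`.
#'
#' @param group_a,group_b Numeric vectors of per-male values (CIs). For the
#'   learning-index statistic, `group_a` is the naive arm (the two
#'   independent samples of a classical design are pooled before
#'   permutation; the statistic is recomputed per permutation from the
#'   permuted arms).
#' @param statistic `"mean_difference"` or `"learning_index"`.
#' @param sides `"two_sided"` or `"one_sided"`.
#' @param n_permutations Number of sampled permutations (default 10,000).
#' @param seed Integer seed for the sampled permutations.
#' @param alpha Rejection level for the `reject` flag (default 0.05).
#' @param exhaustive `NULL` (default): enumerate exhaustively whenever the
#'   number of distinct label assignments is at most `n_permutations`,
#'   otherwise sample. `FALSE` forces sampling (useful to study Monte-Carlo
#'   convergence against the exact value).
#' @return An object of class `randomization_test`: list with
#'   `statistic_observed`, `alpha_R`, `n_permutations` (permutations
#'   actually used), `exhaustive`, `sides`, `statistic`, `reject`, `seed`,
#'   and `perm_stats` (the randomization distribution, for plotting).
#' @examples
#' rt <- randomization_test(c(1, 2, 3), c(4, 5, 6))
#' rt$alpha_R  # exhaustive over the 20 assignments: 2/20
#' @export
randomization_test <- function(group_a, group_b,
                               statistic = c("mean_difference",
                                             "learning_index"),
                               sides = c("two_sided", "one_sided"),
                               n_permutations = 10000,
                               seed = NULL,
                               alpha = 0.05,
                               exhaustive = NULL) {
  statistic <- rlang::arg_match(statistic)
  sides <- rlang::arg_match(sides)
  if (!is.numeric(group_a) || !is.numeric(group_b) ||
      length(group_a) == 0L || length(group_b) == 0L) {
    abort_input("both groups must be non-empty numeric vectors.")
  }
  check_scalar_num(n_permutations, "n_permutations", min = 1,
                   integerish = TRUE)
  check_scalar_num(alpha, "alpha", min = 0, max = 1)

  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  total <- sum(pooled)
  stat_from_sum <- function(sum_a) {
    ma <- sum_a / na
    mb <- (total - sum_a) / nb
    if (statistic == "mean_difference") ma - mb
    else (ma - mb) / ma * 100
  }
  observed <- stat_from_sum(sum(group_a))

  n_assignments <- choose(n, na)
  feasible <- is.finite(n_assignments) && n_assignments <= n_permutations
  exhaustive <- if (is.null(exhaustive)) feasible else {
    isTRUE(exhaustive) && feasible
  }
  perm_sums <- if (exhaustive) {
    utils::combn(n, na, FUN = function(idx) sum(pooled[idx]))
  } else {
    with_seed(seed, vapply(
      seq_len(n_permutations),
      function(i) sum(pooled[sample.int(n, na)]),
      numeric(1)
    ))
  }
  perm_stats <- vapply(perm_sums, stat_from_sum, numeric(1))
  # an undefined LI (permuted naive mean 0) is treated as maximally extreme
  extreme <- if (sides == "two_sided") {
    !is.finite(perm_stats) | abs(perm_stats) >= abs(observed)
  } else {
    !is.finite(perm_stats) | perm_stats >= observed
  }
  b <- sum(extreme)
  m <- length(perm_stats)
  alpha_R <- if (exhaustive) b / m else (b + 1) / (m + 1)

  structure(
    list(
      statistic = statistic,
      sides = sides,
      statistic_observed = observed,
      n_permutations = m,
      exhaustive = exhaustive,
      alpha_R = alpha_R,
      alpha = alpha,
      reject = alpha_R < alpha,
      seed = seed,
      perm_stats = perm_stats
    ),
    class = "randomization_test"
  )
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf(
    "Sampled randomization test (%s, %s)\n", x$statistic, x$sides
  ))
  cat(sprintf(
    "  observed = %.4g, alpha_R = %.4g (%s %d permutations)%s\n",
    x$statistic_observed, x$alpha_R,
    if (x$exhaustive) "exhaustive," else "sampled,", x$n_permutations,
    if (x$reject) sprintf(" — reject at alpha_R < %.3g", x$alpha) else ""
  ))
  invisible(x)
}
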