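series <- function(loads, chemi, total) {
  tibble::tibble(relative_load = loads, chemi_signal = chemi,
                 total_protein_signal = total)
}

test_that("normalized level is the ratio of through-origin slopes", {
  ld <- c(1 / 2, 1 / 4, 1 / 6)
  expect_equal(normalized_level(series(ld, 10 * ld, 2 * ld)), 5)
  # chemi channel scaling scales the level; joint scaling cancels
  expect_equal(normalized_level(series(ld, 30 * ld, 2 * ld)), 15)
  expect_equal(normalized_level(series(ld, 7 * 10 * ld, 7 * 2 * ld)), 5)
  expect_error(normalized_level(series(0.5, 1, 1)),
               class = "riplab_input_error")
  expect_error(normalized_level(series(c(0.5, 0.5), c(1, 1), c(1, 1))),
               class = "riplab_input_error")
  expect_error(normalized_level(series(ld, 10 * ld, c(1, -1, -1.5))),
               class = "riplab_degenerate_input_error")
})

test_that("normalized level survives noise within tolerance", {
  # parameter recovery at the bench scenario: true ratio 2/3, cv 0.1, n = 5
  d <- simulate_western(true_level_wt = 3, true_level_mut = 2, cv = 0.1,
                        n_replicates = 5, seed = 123)
  rl <- relative_level(d)
  expect_gt(rl$ratio_mut_over_wt, 0.53)
  expect_lt(rl$ratio_mut_over_wt, 0.80)
})

test_that("relative level compares genotype means with a t-test", {
  d <- simulate_western(cv = 0.1, n_replicates = 4, seed = 8)
  ident <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(d, genotype == "wt")),
    dplyr::mutate(dplyr::filter(d, genotype == "wt"), genotype = "mut")
  )
  rl <- relative_level(ident)
  expect_equal(rl$ratio_mut_over_wt, 1)
  expect_equal(rl$p_value, 1)

  # exact 2/3 ratio with zero variance
  d0 <- simulate_western(true_level_wt = 3, true_level_mut = 2, cv = 0,
                         n_replicates = 3, seed = 9)
  expect_equal(relative_level(d0)$ratio_mut_over_wt, 2 / 3)

  # mismatched fraction labels between arms
  bad <- dplyr::mutate(d, fraction = ifelse(genotype == "wt", "LP", "P2"))
  expect_error(relative_level(bad), class = "riplab_input_error")
})

test_that("the pooled t-test arm matches the closed form on a 2+2 fixture", {
  lvls <- c(4, 6, 9, 11)  # wt: 4,6; mut: 9,11
  d <- tibble::tibble(
    genotype = rep(c("wt", "wt", "mut", "mut"), each = 2),
    replicate = rep(1:4, each = 2),
    fraction = "total",
    relative_load = rep(c(1, 0.5), 4),
    chemi_signal = rep(lvls, each = 2) * rep(c(1, 0.5), 4),
    total_protein_signal = rep(c(1, 0.5), 4)
  )
  rl <- relative_level(d, test = "pooled")
  # textbook pooled two-sample t: means 10 vs 5, s_p^2 = 2, n = 2 each
  sp2 <- (1 + 1) / 2 * 2
  t_manual <- (10 - 5) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(rl$t_statistic, t_manual)
  expect_equal(rl$p_value, 2 * stats::pt(-abs(t_manual), df = 2))
  expect_equal(rl$ratio_mut_over_wt, 2)
  expect_s3_class(autoplot(rl), "ggplot")
})

test_that("delta-delta-Ct follows the efficiency-2 model", {
  ct <- tibble::tibble(sample_id = c("cal", "s1", "s2"),
                       ct_target = c(20, 19, 21),
                       ct_reference = c(16, 16, 18))
  dd <- relative_expression_ddct(ct, calibrator = "cal")
  expect_equal(dd$rel_expression[dd$sample_id == "cal"], 1)
  # one cycle lower target, equal reference -> 2-fold
  expect_equal(dd$rel_expression[dd$sample_id == "s1"], 2)
  # ddCt = (21 - 18) - (20 - 16) = -1 -> 2-fold
  expect_equal(dd$rel_expression[dd$sample_id == "s2"], 2)

  # the reference gene itself is 1 in every sample
  ref <- tibble::tibble(sample_id = c("cal", "s1"),
                        ct_target = c(16, 18), ct_reference = c(16, 18))
  expect_equal(relative_expression_ddct(ref, "cal")$rel_expression, c(1, 1))

  expect_error(relative_expression_ddct(ct, "nope"),
               class = "riplab_input_error")
  expect_error(
    relative_expression_ddct(
      tibble::tibble(sample_id = "a", ct_target = 20, ct_reference = NA), "a"
    ),
    class = "riplab_input_error"
  )
})

test_that("percent of input follows the Ct arithmetic", {
  expect_equal(percent_of_input(20, 20, 1), 100)
  expect_equal(percent_of_input(21, 20, 1), 50)
  # input fraction 0.05: adjusted Ct 20 - log2(0.05) = 24.32..., yield
  # 5 * 2^(Ct_adj - 22.32) ~= 20%
  expect_equal(percent_of_input(22.32, 20, 0.05),
               100 * 0.05 * 2^((20 - log2(0.05)) - 22.32))
  expect_equal(percent_of_input(22.32, 20, 0.05), 20, tolerance = 0.01)
  # monotone decreasing in ct_ip, bounded below by 0
  y <- percent_of_input(seq(18, 30, by = 0.5), 20, 0.05)
  expect_true(all(diff(y) < 0))
  expect_true(all(y > 0))
  expect_error(percent_of_input(20, 20, 0), class = "riplab_config_error")
})
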