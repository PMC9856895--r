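toy_counts <- function(input, ip, mock_ip,
                       biotype = rep("protein_coding", length(input))) {
  tibble::tibble(
    gene_id = paste0("g", seq_along(input)),
    biotype = biotype, input = input, ip = ip, mock_ip = mock_ip
  )
}

test_that("CPM matches exact proportions and hand arithmetic", {
  cpm <- compute_cpm(toy_counts(c(100, 900), c(1, 1), c(1, 1)),
                     pseudocount = 0)
  expect_equal(cpm$input, c(100000, 900000))

  cpm1 <- compute_cpm(toy_counts(5, 3, 7), pseudocount = 0)
  expect_equal(cpm1$input, 1e6)
  expect_equal(cpm1$ip, 1e6)

  # pseudocount 0.5: totals (0.5 + 1.5 + 3.5) = 5.5
  cpm2 <- compute_cpm(toy_counts(c(0, 1, 3), c(1, 1, 1), c(1, 1, 1)),
                      pseudocount = 0.5)
  expect_equal(cpm2$input, c(90909.09, 272727.27, 636363.64),
               tolerance = 1e-6)
})

test_that("CPM columns always sum to one million", {
  for (seed in 1:5) {
    counts <- random_count_table(30, seed)
    for (pc in c(0, 0.5, 1)) {
      cpm <- compute_cpm(counts, pc)
      expect_equal(sum(cpm$input), 1e6)
      expect_equal(sum(cpm$ip), 1e6)
      expect_equal(sum(cpm$mock_ip), 1e6)
    }
  }
})

test_that("CPM rejects empty and all-zero inputs", {
  expect_error(compute_cpm(toy_counts(numeric(), numeric(), numeric())),
               class = "riplab_input_error")
  expect_error(compute_cpm(toy_counts(c(0, 0), c(1, 1), c(1, 1)),
                           pseudocount = 0),
               class = "riplab_input_error")
})

test_that("detection requires presence in Input and IP, mock not consulted", {
  counts <- toy_counts(input = c(5, 0, 1, 3), ip = c(0, 5, 1, 2),
                       mock_ip = c(9, 9, 0, 0))
  expect_setequal(detect_genes(counts), c("g3", "g4"))
  expect_setequal(detect_genes(counts, min_count = 2), "g4")
})

test_that("enrichment ratios follow the CPM arithmetic", {
  counts <- toy_counts(c(10, 10), c(10, 10), c(10, 10))
  tab <- enrichment_table(compute_cpm(counts, 0.5), detect_genes(counts))
  expect_equal(tab$ratio_ip_input, c(1, 1))
  expect_equal(tab$ratio_ip_mock, c(1, 1))

  cpm <- tibble::tibble(gene_id = "g1", biotype = "protein_coding",
                        input = 2, ip = 10, mock_ip = 5)
  tab2 <- enrichment_table(cpm, "g1")
  expect_equal(tab2$ratio_ip_input, 5)
  expect_equal(tab2$ratio_ip_mock, 2)

  # gene absent from mock: finite ratio under the pseudocount convention
  counts3 <- toy_counts(c(10, 5), c(20, 5), c(0, 5))
  cpm3 <- compute_cpm(counts3, 0.5)
  tab3 <- enrichment_table(cpm3, detect_genes(counts3))
  expect_equal(tab3$ratio_ip_mock[1], cpm3$ip[1] / cpm3$mock_ip[1])
  expect_true(all(is.finite(tab3$ratio_ip_mock)))

  # pseudocount-0 CPM with zero denominators is refused
  expect_error(enrichment_table(compute_cpm(counts3, 0),
                                detect_genes(counts3)),
               class = "riplab_input_error")
})

test_that("thresholds are the per-ratio minima over the three controls", {
  tab <- tibble::tibble(
    gene_id = c("c1", "c2", "c3", "x"),
    biotype = "protein_coding",
    detected = TRUE,
    ratio_ip_input = c(2, 4, 3, 10),
    ratio_ip_mock = c(3, 1, 2, 10)
  )
  thr <- calibrate_thresholds(tab, c("c1", "c2", "c3"))
  expect_equal(thr$min_ratio_ip_input, 2)
  expect_equal(thr$min_ratio_ip_mock, 1)

  same <- dplyr::mutate(tab, ratio_ip_input = 2.5, ratio_ip_mock = 1.5)
  thr2 <- calibrate_thresholds(same, c("c1", "c2", "c3"))
  expect_equal(thr2$min_ratio_ip_input, 2.5)
  expect_equal(thr2$min_ratio_ip_mock, 1.5)

  expect_error(calibrate_thresholds(tab, c("c1", "c2", "absent")),
               "absent", class = "riplab_calibration_error")
  undet <- dplyr::mutate(tab, detected = c(TRUE, FALSE, TRUE, TRUE))
  expect_error(calibrate_thresholds(undet, c("c1", "c2", "c3")),
               "c2", class = "riplab_calibration_error")
})

test_that("calls respect the >= convention and the biotype restriction", {
  tab <- tibble::tibble(
    gene_id = c("c1", "c2", "c3", "tie", "half", "rna"),
    biotype = c(rep("protein_coding", 5), "other"),
    detected = TRUE,
    ratio_ip_input = c(2, 4, 3, 2, 5, 9),
    ratio_ip_mock = c(3, 1, 2, 1, 0.5, 9)
  )
  thr <- calibrate_thresholds(tab, c("c1", "c2", "c3"))
  res <- call_targets(tab, thr)
  expect_true("tie" %in% res$targets)    # ties at both thresholds pass
  expect_false("half" %in% res$targets)  # one ratio below -> fail
  expect_false("rna" %in% res$targets)   # non-coding never passes
  expect_true(all(c("c1", "c2", "c3") %in% res$targets))
})

test_that("the positive controls always pass their own calibration", {
  for (seed in 1:10) {
    counts <- random_count_table(40, seed)
    fit <- call_rip_targets(counts)
    expect_true(all(c("orb2", "act5C", "tub56D") %in% fit$targets))
  }
})

test_that("raising either threshold never grows the called set", {
  counts <- random_count_table(60, 99)
  fit <- call_rip_targets(counts)
  base <- fit$targets
  for (bump in c(1.05, 1.5, 3)) {
    thr <- fit$thresholds
    thr$min_ratio_ip_input <- thr$min_ratio_ip_input * bump
    up1 <- call_targets(fit$table, thr)$targets
    expect_true(all(up1 %in% base))
    thr2 <- fit$thresholds
    thr2$min_ratio_ip_mock <- thr2$min_ratio_ip_mock * bump
    up2 <- call_targets(fit$table, thr2)$targets
    expect_true(all(up2 %in% base))
  }
})

test_that("calls are invariant to per-sample scaling at pseudocount zero", {
  counts <- random_count_table(30, 5)
  counts$mock_ip <- counts$mock_ip + 1L  # avoid zero denominators at pc 0
  run <- function(cts) {
    tab <- enrichment_table(compute_cpm(cts, 0), detect_genes(cts))
    call_targets(tab, calibrate_thresholds(tab, c("orb2", "act5C",
                                                  "tub56D")))$targets
  }
  scaled <- dplyr::mutate(counts, ip = ip * 7L)
  expect_identical(run(counts), run(scaled))
})

test_that("calls match a brute-force oracle on small tables", {
  controls <- c("orb2", "act5C", "tub56D")
  for (seed in 1:10) {
    counts <- random_count_table(10, seed)
    fit <- call_rip_targets(counts, controls = controls,
                            pseudocount = 0.5, min_count = 1)
    oracle <- brute_force_calls(counts, controls, pseudocount = 0.5,
                                min_count = 1)
    expect_identical(fit$targets, oracle)
  }
})

test_that("tidy and glance summarize a target call", {
  fit <- call_rip_targets(random_count_table(25, 2))
  td <- tidy(fit)
  expect_true(all(c("gene_id", "passes") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 25L)
  expect_equal(gl$n_called, length(fit$targets))
  expect_s3_class(autoplot(fit), "ggplot")
})
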