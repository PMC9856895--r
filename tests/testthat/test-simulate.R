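test_that("all generators are deterministic under a fixed seed", {
  expect_identical(simulate_ripseq(n_genes = 100, n_targets = 10, seed = 7),
                   simulate_ripseq(n_genes = 100, n_targets = 10, seed = 7))
  expect_identical(simulate_courtship(n_per_group = 8, seed = 7),
                   simulate_courtship(n_per_group = 8, seed = 7))
  expect_identical(simulate_western(n_replicates = 3, seed = 7),
                   simulate_western(n_replicates = 3, seed = 7))
  expect_identical(
    simulate_utr(length = 400, planted = c(TTTTAT = 2), seed = 7),
    simulate_utr(length = 400, planted = c(TTTTAT = 2), seed = 7)
  )
})

test_that("ripseq simulation with no planted signal carries no enrichment", {
  sim <- simulate_ripseq(n_genes = 2000, n_targets = 0,
                         control_enrichment = 1, dispersion = 0,
                         seed = 11)
  expect_length(sim$truth$target_ids, 0)
  cpm <- compute_cpm(sim$counts, pseudocount = 0.5)
  ratio <- cpm$ip / cpm$input
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("planted IP enrichment is recovered in the Poisson limit", {
  # law-of-large-numbers: mean target IP/Input CPM ratio over 100 replicates.
  # The planted fraction is kept tiny (20 of 5000 genes) so composition
  # compression of CPM by the enriched genes is negligible (< 2%).
  ratios <- vapply(seq_len(100), function(i) {
    sim <- simulate_ripseq(
      n_genes = 5000, n_targets = 20, target_enrichment_ip = 4,
      control_enrichment = 1, dispersion = 0,
      library_sizes = rep(1e6, 3), baseline_log_sd = 0.5, seed = 1000 + i
    )
    cpm <- compute_cpm(sim$counts, pseudocount = 0)
    idx <- cpm$gene_id %in% sim$truth$target_ids
    mean(cpm$ip[idx] / cpm$input[idx])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.1)
})

test_that("ripseq counts follow the declared negative-binomial model", {
  # iid batch: flat baselines make every Input count NB(mu, dispersion)
  mu <- 100; phi <- 0.2; n <- 1000
  sim <- simulate_ripseq(
    n_genes = n, n_targets = 0, control_enrichment = 1,
    library_sizes = rep(mu * n, 3), dispersion = phi,
    baseline_log_sd = 0, seed = 42
  )
  x <- sim$counts$input
  qs <- unique(qnbinom(seq(0, 1, length.out = 16), mu = mu, size = 1 / phi))
  breaks <- c(-1, qs[-length(qs)], Inf)
  obs <- table(cut(x, breaks))
  probs <- diff(pnbinom(breaks, mu = mu, size = 1 / phi))
  fit <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs,
                                            rescale.p = TRUE))
  expect_gt(fit$p.value, 0.01)
})

test_that("invalid ripseq configurations name the offending field", {
  expect_error(simulate_ripseq(n_genes = 100, n_targets = 99),
               class = "riplab_config_error")
  expect_error(simulate_ripseq(target_enrichment_ip = 0.5),
               "target_enrichment_ip")
  expect_error(simulate_ripseq(library_sizes = c(-1, 1, 1)),
               "library_sizes")
})

test_that("courtship simulation respects the observation window", {
  bouts <- simulate_courtship(n_per_group = 20, observation_s = 300,
                              seed = 3)
  expect_equal(nrow(bouts), 40)
  real <- !is.na(bouts$bout_start_s)
  expect_true(all(bouts$bout_start_s[real] >= 0))
  expect_true(all(bouts$bout_end_s[real] <= 300))
  expect_error(simulate_courtship(ci_mean_naive = 1.2),
               class = "riplab_config_error")
})

test_that("equal group means give a learning index centred on zero", {
  lis <- vapply(seq_len(500), function(i) {
    bouts <- simulate_courtship(n_per_group = 20, ci_mean_naive = 0.5,
                                ci_mean_trained = 0.5, seed = 2000 + i)
    ci <- courtship_index(bouts)
    learning_index(list(ci$ci[ci$group == "naive"]),
                   list(ci$ci[ci$group == "trained"]))$li
  }, numeric(1))
  expect_lt(abs(mean(lis)), 3)  # within 3 percentage points of 0
})

test_that("noise-free courtship draws give the deterministic learning index", {
  bouts <- simulate_courtship(ci_mean_naive = 0.6, ci_mean_trained = 0.3,
                              ci_concentration = Inf, seed = 1)
  ci <- courtship_index(bouts)
  li <- learning_index(list(ci$ci[ci$group == "naive"]),
                       list(ci$ci[ci$group == "trained"]))
  expect_equal(li$li, 50)
})

test_that("noise-free densitometry is exactly proportional to load", {
  d <- simulate_western(true_level_wt = 3, true_level_mut = 1, cv = 0,
                        n_replicates = 2, seed = 5)
  expect_equal(d$chemi_signal,
               ifelse(d$genotype == "wt", 3, 1) * d$relative_load)
  expect_equal(d$total_protein_signal, d$relative_load)
  # dilution ladder: three lanes per replicate series
  expect_equal(unname(table(d$genotype, d$replicate)["wt", "1"]), 3L)
  expect_error(simulate_western(loads = c(0, 0.5)),
               class = "riplab_config_error")
})

test_that("utr generator plants exact counts and screens the background", {
  utr <- simulate_utr(length = 1000, planted = c(TTTTAT = 3), seed = 9)
  expect_equal(nchar(utr$sequence), 1000)
  expect_length(naive_scan(utr$sequence, "TTTTAT"), 3)
  # zero unplanted occurrences of any configured motif
  for (m in setdiff(unlist(cpe_motifs()[c("canonical", "noncanonical")]),
                    "TTTTAT")) {
    expect_length(naive_scan(utr$sequence, m), 0)
  }
  cen <- cpe_census(utr$sequence)
  expect_equal(cen$n_canonical, 3L)
  expect_equal(cen$n_total, 3L)
})

test_that("utr generator with nothing planted yields a motif-free sequence", {
  utr <- simulate_utr(length = 2000, planted = integer(), seed = 10)
  expect_equal(cpe_census(utr$sequence)$n_total, 0L)
})

test_that("utr generator errors when motifs cannot fit", {
  expect_error(simulate_utr(length = 10, planted = c(TTTTAT = 5), seed = 1),
               class = "riplab_generation_error")
})
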