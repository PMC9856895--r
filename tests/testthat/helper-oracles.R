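# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the implementation.

# Naive substring scan: exact ACGT patterns only, every start position.
naive_scan <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  k <- nchar(pattern)
  hits <- integer()
  if (nchar(seq) >= k) {
    for (i in seq_len(nchar(seq) - k + 1L)) {
      if (substr(seq, i, i + k - 1L) == pattern) hits <- c(hits, i - 1L)
    }
  }
  hits
}

# Brute-force re-implementation of the full target-calling rule chain.
brute_force_calls <- function(counts, controls, pseudocount, min_count) {
  n <- nrow(counts)
  cpm <- matrix(0, n, 3, dimnames = list(counts$gene_id,
                                         c("input", "ip", "mock_ip")))
  for (s in colnames(cpm)) {
    shifted <- counts[[s]] + pseudocount
    for (i in seq_len(n)) cpm[i, s] <- 1e6 * shifted[i] / sum(shifted)
  }
  detected <- logical(n)
  for (i in seq_len(n)) {
    detected[i] <- counts$input[i] >= min_count && counts$ip[i] >= min_count
  }
  r1 <- cpm[, "ip"] / cpm[, "input"]
  r2 <- cpm[, "ip"] / cpm[, "mock_ip"]
  ci <- match(controls, counts$gene_id)
  thr1 <- min(r1[ci]); thr2 <- min(r2[ci])
  passes <- logical(n)
  for (i in seq_len(n)) {
    passes[i] <- detected[i] && counts$biotype[i] == "protein_coding" &&
      r1[i] >= thr1 && r2[i] >= thr2
  }
  ids <- counts$gene_id[passes]
  ids[order(-r2[passes], ids)]
}

# Exhaustive hypergeometric upper tail: probability that a random size-k
# subset of the universe overlaps `a` in at least `x` elements.
enumerated_overlap_p <- function(n_universe, n_a, k, x) {
  universe <- seq_len(n_universe)
  subsets <- utils::combn(universe, k)
  hits <- 0L
  for (j in seq_len(ncol(subsets))) {
    if (sum(subsets[, j] <= n_a) >= x) hits <- hits + 1L
  }
  hits / ncol(subsets)
}

# Random small count table for property tests.
random_count_table <- function(n_genes, seed) {
  set.seed(seed)
  tibble::tibble(
    gene_id = c("orb2", "act5C", "tub56D",
                sprintf("g%02d", seq_len(n_genes - 3L))),
    biotype = sample(c("protein_coding", "other"), n_genes,
                     replace = TRUE, prob = c(0.8, 0.2)),
    input = rpois(n_genes, 50) + 1L,  # controls must be detected
    ip = rpois(n_genes, 50) + 1L,
    mock_ip = rpois(n_genes, 50)
  ) |>
    dplyr::mutate(biotype = replace(.data$biotype, 1:3, "protein_coding"))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
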