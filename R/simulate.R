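# Seeded generators for every pipeline input. Each generator records its
# seed and parameters as attributes so a run manifest can be reconstructed
# from the objects alone.

RIP_POSITIVE_CONTROLS <- c("orb2", "act5C", "tub56D")
RIP_NEGATIVE_CONTROLS <- c("28S", "RplP0")

#' Simulate a three-sample RIP-seq count table
#'
#' Generates gene-level read counts for an Input sample, an experimental IP
#' and a mock IP (pre-immune IgG), with a planted subset of enriched target
#' genes and the five control transcripts of an Orb2 RIP design: `orb2`,
#' `act5C`, `tub56D` (positive controls, planted at `control_enrichment`)
#' and `28S`, `RplP0` (negative controls, never enriched).
#'
#' Counts are negative-binomial around expected abundances: per-gene
#' baseline abundances are log-normal
#' (`exp(rnorm(baseline_log_mean, baseline_log_sd))`); in the IP sample the
#' abundance of true targets is multiplied by `target_enrichment_ip` and of
#' positive controls by `control_enrichment`; Input and mock IP see baseline
#' abundance for every gene. Abundances are converted to expected counts by
#' scaling to each sample's library size, then counts are drawn
#' NB(mean, dispersion) with variance `mean + dispersion * mean^2`
#' (`dispersion = 0` gives the Poisson limit).
#'
#' @param n_genes Total number of genes (including the 5 controls).
#' @param n_targets Number of planted enriched targets (excluding controls).
#' @param target_enrichment_ip IP fold-enrichment of true targets (>= 1).
#' @param control_enrichment IP fold-enrichment of the three positive
#'   controls (>= 1).
#' @param library_sizes Named or unnamed numeric vector of three library
#'   sizes for `input`, `ip`, `mock_ip` (a single value is recycled).
#' @param dispersion Negative-binomial dispersion (>= 0; 0 = Poisson).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   per-gene baseline abundance distribution.
#' @param biotype_fraction_coding Fraction of non-control genes that are
#'   protein-coding. `28S` is always annotated as `other` (rRNA); all other
#'   controls are protein-coding.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return A list with elements
#'   * `counts`: tibble `gene_id`, `biotype`, `input`, `ip`, `mock_ip`;
#'   * `truth`: list with `target_ids` (planted targets, including the
#'     positive controls, which are planted enriched whenever
#'     `control_enrichment > 1`) and `control_ids` (named character vector
#'     mapping the five control roles to gene ids).
#' @examples
#' sim <- simulate_ripseq(n_genes = 200, n_targets = 20, seed = 1)
#' head(sim$counts)
#' @export
simulate_ripseq <- function(n_genes = 5000,
                            n_targets = 500,
                            target_enrichment_ip = 4,
                            control_enrichment = 2,
                            library_sizes = c(input = 2e6, ip = 2e6, mock_ip = 2e6),
                            dispersion = 0.01,
                            baseline_log_mean = 4,
                            baseline_log_sd = 1.5,
                            biotype_fraction_coding = 0.85,
                            seed = NULL) {
  check_scalar_num(n_genes, "n_genes", min = 6, integerish = TRUE)
  check_scalar_num(n_targets, "n_targets", min = 0, integerish = TRUE)
  if (n_targets + 5L > n_genes) {
    abort_config("n_targets plus the 5 designated controls exceeds n_genes.",
                 "n_targets")
  }
  check_scalar_num(target_enrichment_ip, "target_enrichment_ip", min = 1)
  check_scalar_num(control_enrichment, "control_enrichment", min = 1)
  if (length(library_sizes) == 1L) library_sizes <- rep(library_sizes, 3L)
  if (length(library_sizes) != 3L || any(!is.finite(library_sizes)) ||
      any(library_sizes <= 0)) {
    abort_config("`library_sizes` must be three positive numbers.",
                 "library_sizes")
  }
  library_sizes <- setNames(as.numeric(library_sizes),
                            c("input", "ip", "mock_ip"))
  check_scalar_num(dispersion, "dispersion", min = 0)
  check_scalar_num(baseline_log_sd, "baseline_log_sd", min = 0)
  check_scalar_num(biotype_fraction_coding, "biotype_fraction_coding",
                   min = 0, max = 1)

  with_seed(seed, {
    n_other <- n_genes - 5L
    gene_id <- c(RIP_POSITIVE_CONTROLS, RIP_NEGATIVE_CONTROLS,
                 sprintf("g%05d", seq_len(n_other)))
    biotype <- c(
      "protein_coding", "protein_coding", "protein_coding",  # orb2/act5C/tub56D
      "other", "protein_coding",                             # 28S rRNA, RplP0
      ifelse(runif(n_other) < biotype_fraction_coding,
             "protein_coding", "other")
    )
    # plant targets among protein-coding, non-control genes
    candidates <- setdiff(which(biotype == "protein_coding"), 1:5)
    if (n_targets > length(candidates)) {
      abort_config("not enough protein-coding non-control genes to plant targets.",
                   "n_targets")
    }
    target_idx <- sort(sample(candidates, n_targets))

    baseline <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    enrich_ip <- rep(1, n_genes)
    enrich_ip[target_idx] <- target_enrichment_ip
    enrich_ip[1:3] <- control_enrichment

    draw <- function(abund, lib) {
      mu <- lib * abund / sum(abund)
      if (dispersion == 0) rpois(n_genes, mu)
      else rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    counts <- tibble(
      gene_id = gene_id,
      biotype = biotype,
      input = draw(baseline, library_sizes[["input"]]),
      ip = draw(baseline * enrich_ip, library_sizes[["ip"]]),
      mock_ip = draw(baseline, library_sizes[["mock_ip"]])
    )
    planted <- gene_id[target_idx]
    if (control_enrichment > 1) planted <- c(RIP_POSITIVE_CONTROLS, planted)
    truth <- list(
      target_ids = planted,
      control_ids = setNames(
        c(RIP_POSITIVE_CONTROLS, RIP_NEGATIVE_CONTROLS),
        c("positive_1", "positive_2", "positive_3",
          "negative_1", "negative_2")
      )
    )
    structure(list(counts = counts, truth = truth),
              seed = seed, class = "ripseq_sim")
  })
}

#' Simulate conditioned-courtship observations
#'
#' Emulates the courtship-suppression memory paradigm: per male, the
#' courtship index (fraction of the observation window spent courting) is a
#' Beta draw around the group mean, emitted as a single courtship bout of
#' that total duration at a uniform offset within the window. Bout
#' microstructure is not modeled because the courtship index depends only on
#' total courtship time.
#'
#' @param n_per_group Males per group (default 20, the study design).
#' @param observation_s Observation window in seconds (default 300).
#' @param ci_mean_naive,ci_mean_trained Mean courtship fraction in `[0, 1]`
#'   for naive and trained males.
#' @param ci_concentration Beta concentration (> 0); `Inf` gives noise-free
#'   draws at the group mean.
#' @param seed Integer seed.
#' @return A tibble of bout records: `male_id`, `group` (`"naive"` /
#'   `"trained"`), `bout_start_s`, `bout_end_s`, `observation_s`. Males
#'   whose drawn courtship time is zero contribute no bout rows but are
#'   retained with an `NA` bout (so every male appears and
#'   [courtship_index()] scores them 0).
#' @examples
#' bouts <- simulate_courtship(n_per_group = 5, seed = 1)
#' courtship_index(bouts)
#' @export
simulate_courtship <- function(n_per_group = 20,
                               observation_s = 300,
                               ci_mean_naive = 0.6,
                               ci_mean_trained = 0.3,
                               ci_concentration = 10,
                               seed = NULL) {
  check_scalar_num(n_per_group, "n_per_group", min = 1, integerish = TRUE)
  check_scalar_num(observation_s, "observation_s", min = 0, strict_min = TRUE)
  check_scalar_num(ci_mean_naive, "ci_mean_naive", min = 0, max = 1)
  check_scalar_num(ci_mean_trained, "ci_mean_trained", min = 0, max = 1)
  if (!(is.numeric(ci_concentration) && length(ci_concentration) == 1L &&
        (is.infinite(ci_concentration) || ci_concentration > 0))) {
    abort_config("`ci_concentration` must be > 0 (Inf allowed).",
                 "ci_concentration")
  }

  with_seed(seed, {
    draw_ci <- function(mean) {
      if (is.infinite(ci_concentration)) return(rep(mean, n_per_group))
      if (mean == 0 || mean == 1) return(rep(mean, n_per_group))
      rbeta(n_per_group, mean * ci_concentration,
            (1 - mean) * ci_concentration)
    }
    groups <- tibble(
      group = rep(c("naive", "trained"), each = n_per_group),
      male_id = c(sprintf("naive_%02d", seq_len(n_per_group)),
                  sprintf("trained_%02d", seq_len(n_per_group))),
      ci = c(draw_ci(ci_mean_naive), draw_ci(ci_mean_trained))
    )
    groups |>
      dplyr::mutate(
        duration = .data$ci * observation_s,
        bout_start_s = ifelse(
          .data$duration > 0,
          runif(dplyr::n(), 0, observation_s - .data$duration),
          NA_real_
        ),
        bout_end_s = .data$bout_start_s + .data$duration,
        observation_s = observation_s
      ) |>
      dplyr::select("male_id", "group", "bout_start_s", "bout_end_s",
                    "observation_s")
  })
}

#' Simulate serial-dilution densitometry
#'
#' Emulates semiquantitative Western blotting on stain-free gels: each
#' replicate lysate is loaded in a dilution ladder, the chemiluminescent
#' band signal is proportional to `true_level * load` and the total-protein
#' (stain-free) signal to `load`, both corrupted by multiplicative
#' lognormal noise with coefficient of variation `cv` (noise mean exactly 1).
#'
#' @param true_level_wt,true_level_mut True protein abundance per genotype
#'   (arbitrary units, > 0). The default mutant/WT ratio of 1/3 mirrors a
#'   synaptic-fraction depletion scenario.
#' @param loads Relative loads of the dilution ladder, each in `(0, 1]`
#'   (default `c(1/2, 1/4, 1/6)`: dilution by factors of 2, 4 and 6).
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_replicates Biological replicates per genotype (>= 2 for any
#'   downstream test).
#' @param fraction Label of the analyzed fraction (e.g. `"total"`,
#'   `"LP_soma"`, `"P2_synaptic"`).
#' @param seed Integer seed.
#' @return A tibble: `genotype` (`"wt"` / `"mut"`), `replicate`, `fraction`,
#'   `lane`, `relative_load`, `chemi_signal`, `total_protein_signal`.
#' @examples
#' simulate_western(cv = 0, n_replicates = 2, seed = 1)
#' @export
simulate_western <- function(true_level_wt = 3,
                             true_level_mut = 1,
                             loads = c(1 / 2, 1 / 4, 1 / 6),
                             cv = 0.1,
                             n_replicates = 5,
                             fraction = "P2_synaptic",
                             seed = NULL) {
  check_scalar_num(true_level_wt, "true_level_wt", min = 0, strict_min = TRUE)
  check_scalar_num(true_level_mut, "true_level_mut", min = 0, strict_min = TRUE)
  if (!is.numeric(loads) || length(loads) < 1L || any(!is.finite(loads)) ||
      any(loads <= 0) || any(loads > 1)) {
    abort_config("`loads` must be relative loads in (0, 1].", "loads")
  }
  check_scalar_num(cv, "cv", min = 0)
  check_scalar_num(n_replicates, "n_replicates", min = 1, integerish = TRUE)

  sdlog <- sqrt(log1p(cv^2))
  noise <- function(n) {
    if (cv == 0) rep(1, n) else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      genotype = c("wt", "mut"),
      replicate = seq_len(n_replicates),
      lane = seq_along(loads)
    ) |>
      dplyr::mutate(
        fraction = fraction,
        relative_load = loads[.data$lane],
        true_level = ifelse(.data$genotype == "wt",
                            true_level_wt, true_level_mut)
      )
    grid |>
      dplyr::mutate(
        chemi_signal = .data$true_level * .data$relative_load *
          noise(dplyr::n()),
        total_protein_signal = .data$relative_load * noise(dplyr::n())
      ) |>
      dplyr::select("genotype", "replicate", "fraction", "lane",
                    "relative_load", "chemi_signal", "total_protein_signal")
  })
}

#' Simulate a 3'UTR sequence with planted CPE motifs
#'
#' Generates a random background sequence at a given GC content, screens it
#' so that it contains *zero* occurrences of any configured motif, then
#' plants each requested motif at uniformly drawn non-overlapping positions.
#' The returned sequence contains each planted motif exactly its requested
#' number of times and no other configured-motif occurrences, verified by a
#' final scan.
#'
#' Screening redraws only offending background bases (bounded by
#' `max_attempts` repair rounds) rather than rejecting whole sequences,
#' which would almost never terminate for kilobase-scale sequences.
#'
#' @param length Sequence length in nucleotides.
#' @param planted Named integer vector: `c(TTTTAT = 3)` plants 3 copies of
#'   `TTTTAT`. May be empty. Motif alphabet must be `A,C,G,T` (exact
#'   sequences, no degeneracy — they are written into the sequence).
#' @param motifs A [cpe_motifs()] set used for background screening (planted
#'   motifs are screened too, whether or not they belong to the set).
#' @param gc_background Background GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param max_attempts Bound on screening/placement repair rounds.
#' @return A list: `sequence` (character scalar), `hits` (tibble of planted
#'   positions: `motif`, `start` 0-based, `end` exclusive).
#' @examples
#' utr <- simulate_utr(length = 300, planted = c(TTTTAT = 2), seed = 7)
#' cpe_census(utr$sequence)
#' @export
simulate_utr <- function(length = 1000,
                         planted = integer(),
                         motifs = cpe_motifs(),
                         gc_background = 0.4,
                         seed = NULL,
                         max_attempts = 10000) {
  check_scalar_num(length, "length", min = 1, integerish = TRUE)
  check_scalar_num(gc_background, "gc_background", min = 0, max = 1)
  motifs <- as_cpe_motifs(motifs)
  planted <- unlist(planted)
  if (length(planted) && (is.null(names(planted)) ||
                          any(!nzchar(names(planted))))) {
    abort_config("`planted` must be a named vector: c(TTTTAT = 3).", "planted")
  }
  planted_motifs <- toupper(names(planted))
  if (any(!grepl("^[ACGT]+$", planted_motifs)) && length(planted)) {
    abort_config("planted motifs must be exact sequences over A,C,G,T.",
                 "planted")
  }
  planted_counts <- as.integer(planted)
  if (length(planted) && any(planted_counts < 0)) {
    abort_config("planted counts must be non-negative.", "planted")
  }
  total_planted_nt <- sum(nchar(planted_motifs) * planted_counts) +
    max(0L, sum(planted_counts) - 1L)  # >= 1 nt spacer between spans
  if (total_planted_nt > length) {
    rlang::abort(
      "planted motifs cannot fit in the requested length without overlap.",
      class = "riplab_generation_error"
    )
  }
  screened <- unique(c(motifs$canonical, motifs$noncanonical, planted_motifs))

  with_seed(seed, {
    base_probs <- c(
      A = (1 - gc_background) / 2, C = gc_background / 2,
      G = gc_background / 2, T = (1 - gc_background) / 2
    )
    draw_bases <- function(n) {
      sample(names(base_probs), n, replace = TRUE, prob = base_probs)
    }
    bases <- draw_bases(length)

    # expand planted motif list to individual copies, place without overlap
    copies <- rep(planted_motifs, planted_counts)
    placement <- place_motifs(copies, length, max_attempts)
    planted_mask <- rep(FALSE, length)
    for (i in seq_along(copies)) {
      idx <- (placement$start[i] + 1L):(placement$start[i] + nchar(copies[i]))
      bases[idx] <- strsplit(copies[i], "")[[1]]
      planted_mask[idx] <- TRUE
    }

    # repair background until the only configured-motif occurrences are the
    # planted copies themselves
    planted_tbl <- tibble(
      motif = copies,
      start = placement$start,
      end = placement$start + nchar(copies)
    )
    for (attempt in seq_len(max_attempts)) {
      seq_str <- paste(bases, collapse = "")
      all_hits <- purrr::map_dfr(screened, function(p) {
        s <- match_starts(seq_str, p)
        tibble(motif = p, start = s, end = s + nchar(p))
      })
      unwanted <- dplyr::anti_join(
        all_hits, planted_tbl, by = c("motif", "start")
      )
      if (nrow(unwanted) == 0L) {
        ok <- nrow(all_hits) == nrow(planted_tbl)
        if (!ok) {
          rlang::abort("planted motifs overlap each other's occurrences.",
                       class = "riplab_generation_error")
        }
        return(list(
          sequence = seq_str,
          hits = dplyr::arrange(planted_tbl, .data$start)
        ))
      }
      redraw <- unique(unlist(purrr::map2(
        unwanted$start, unwanted$end, function(s, e) (s + 1L):e
      )))
      redraw <- redraw[!planted_mask[redraw]]
      if (length(redraw) == 0L) {
        rlang::abort(
          "a screened motif occurs entirely within planted spans; cannot repair.",
          class = "riplab_generation_error"
        )
      }
      bases[redraw] <- draw_bases(length(redraw))
    }
    rlang::abort(
      sprintf("background screening did not converge in %d attempts.",
              max_attempts),
      class = "riplab_generation_error"
    )
  })
}

# Uniform non-overlapping placement of motif copies (with >= 1 nt gaps),
# by rejection over uniform starts, bounded by max_attempts.
place_motifs <- function(copies, length, max_attempts) {
  if (length(copies) == 0L) return(list(start = integer()))
  widths <- nchar(copies)
  for (attempt in seq_len(max_attempts)) {
    starts <- vapply(widths, function(w) {
      as.integer(floor(runif(1, 0, length - w + 1)))
    }, integer(1))
    ends <- starts + widths
    ord <- order(starts)
    if (all(diff(starts[ord]) > (widths[ord] + 0L)[-length(copies)])) {
      # strictly separated (>= 1 nt gap between consecutive spans)
      return(list(start = starts))
    }
  }
  rlang::abort(
    sprintf("could not place motifs without overlap in %d attempts.",
            max_attempts),
    class = "riplab_generation_error"
  )
}
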