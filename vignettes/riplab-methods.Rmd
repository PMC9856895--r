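---
title: "Methods and models behind riplab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind riplab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riplab)
```

riplab implements the computational side of a classic experimental design
in *Drosophila* memory research: a CPEB-family RNA-binding protein (Orb2)
is pulled down from fly-head lysate, its bound mRNAs are identified by
sequencing against Input and mock-IP controls, memory is assayed with the
conditioned courtship-suppression paradigm, and protein redistribution
between soma and synapse is quantified by serial-dilution immunoblots. This
vignette explains each model, the tunable parameters, and the design
decisions taken where the methods literature leaves choices open.

## RIP-seq target calling

The caller starts from a gene-level count table with three samples: Input
(the lysate), IP (pull-down with the specific antibody), and mock IP
(pre-immune IgG, capturing nonspecific background). The chain is:

1. **CPM normalization.** `cpm(g,s) = 1e6 (c(g,s)+p) / sum_g'(c(g',s)+p)`
   with pseudocount `p = 0.5` by default. The pseudocount keeps both
   enrichment ratios finite for genes with zero counts in a denominator
   sample; `p = 0` is supported for exact-proportion checks. Each CPM
   column sums to exactly one million by construction.
2. **Detection.** A gene is detected if its raw count is at least
   `min_count` (default 1) in *both* Input and IP. The mock IP is
   deliberately not consulted: absence there is evidence of specificity,
   not of non-expression. Raw-count presence is the weakest defensible
   reading of "detected"; a CPM floor would add a second tunable with no
   obvious calibration.
3. **Dual enrichment ratios.** `IP/Input` (enrichment over expression) and
   `IP/mock` (enrichment over nonspecific capture), both in CPM units.
4. **Control calibration.** Thresholds are set from three positive-control
   transcripts known to be bound (`orb2`, `act5C`, `tub56D`): per ratio,
   the threshold is the *minimum* over the three controls. "Not worse than
   the controls" admits several readings (minimum vs maximum over controls;
   per-ratio vs combined score); the per-ratio minimum is the most
   permissive one under which every control still passes its own
   calibration, and ties at the threshold pass (`>=`, not `>`) for the
   same reason.
5. **Call.** A gene passes if it is detected, protein-coding (from a
   user-supplied biotype annotation — no annotation service is consulted),
   and at or above both thresholds. The output list is sorted by
   descending IP/mock ratio with the gene id as tie-break, so output order
   is deterministic.

## The count simulator

`simulate_ripseq()` plants known targets so the caller can be scored
against truth. Per-gene baseline abundances are log-normal
(`baseline_log_mean = 4`, `baseline_log_sd = 1.5` on the natural-log
scale, giving a realistic four-orders-of-magnitude expression range);
IP abundance is multiplied by `target_enrichment_ip` (default 4) for
targets and `control_enrichment` (default 2) for the three positive
controls; the two negative controls (`28S`, `RplP0`) are never enriched
and `28S` is annotated non-coding. Abundances are scaled to each sample's
library size and counts drawn negative-binomially with variance
`mu + dispersion * mu^2` (`dispersion = 0` is the Poisson limit).

The dispersion default is 0.01 (a biological coefficient of variation of
0.1). The three samples of this design are aliquots of a *single* pooled
head lysate, not biological replicates, so gene-level variation between
them is technical and protocol-driven; a BCV of 0.1 is the canonical value
quoted for genetically identical material. Users simulating comparisons
across independent biological samples should raise the dispersion to
0.05–0.2 (bulk biological scale) — at those values the 2x-calibrated dual
ratio filter admits many false positives, which is itself informative
about the design's limits: with a single replicate per condition, the rule
chain has no way to absorb biological variance.

What the simulator does *not* emulate: positional read structure,
GC/length bias, isoform mixtures, and correlated capture efficiencies
between IP and mock. A passing recovery test therefore shows the rule
chain is implemented correctly and is well-behaved under count noise — not
that real libraries are free of those artifacts.

## Courtship statistics

The courtship index (CI) is the percentage of a 300-s observation window
spent courting; overlapping bouts are merged before summation so time is
never double-counted. The generator emits a single bout of the drawn total
duration at a uniform offset — CI depends only on total time, so bout
microstructure is deliberately unmodeled. Per-male CIs are Beta-distributed
around the group mean with concentration 10 (SD about 0.15 at a mean of
0.5, matching the wide spread typical of courtship data). The trained vs
naive means default to 0.3 vs 0.6; these are plausible placeholders for a
robust memory effect, not measured values, and every test that depends on
an effect size sets it explicitly.

The learning index is `LI = (CIn - CIexp)/CIn * 100` with `CIn` and
`CIexp` the averages of two independent naive and trained samples.

Group differences use a sampled randomization test: labels are permuted
over the pooled per-male values (the individual male is the permutation
unit; permuting at the replicate-sample level is possible by passing the
two sample means, but male-level is the default because the indices are
built from per-male CIs) and the rejection probability is estimated
directly as `alpha_R = (b+1)/(m+1)` over `m` sampled permutations — the
add-one correction keeps `alpha_R` positive. Whenever the number of
distinct label assignments is at most `m`, complete enumeration replaces
sampling and `alpha_R = b/m` over all assignments is exact. Two-sided
extremity is judged on the absolute statistic (not by doubling a tail);
the convention is two-sided for CIs, one-sided for LIs, rejection at
`alpha_R < 0.05`.

## CPE censuses

Cytoplasmic polyadenylation elements are U-rich 3'UTR motifs in two
classes: canonical A-containing (e.g. `TTTTAT`) and noncanonical
G-containing (e.g. `TTTTGT`) variants. The default `cpe_motifs()` set —
three hexa/heptamers per class — is a commonly used minimal collection and
is explicitly *not authoritative*: published per-isoform counts depend on
each study's exact motif list, so `cpe_census()` takes any user-supplied
set (YAML via `read_motifs()`). Matching is single-stranded (sense of the
mRNA written as DNA), case-insensitive, with every distinct start position
counted (overlaps allowed) and `N` never matching. Coordinates are 0-based
half-open throughout, so hits export directly as BED6.

`apply_deletion()` removes a half-open interval and joins the flanks,
mimicking 3'UTR deletion alleles; motifs spanning a breakpoint are
destroyed unless the junction recreates a match, which is counted because
the census is always computed on the joined sequence.

The UTR generator plants motifs at uniform non-overlapping positions (with
at least one spacer base) in a GC-controlled background that is screened to
contain zero occurrences of any configured motif. Screening repairs only
the offending background bases rather than rejecting whole sequences —
whole-sequence rejection would essentially never terminate at kilobase
scale, where chance motif hits are expected — and is bounded at 10,000
repair rounds before erroring. A final full rescan guarantees exactness:
each planted motif occurs exactly its requested number of times and
nothing else from the screened set occurs at all.

## Immunoblot and qPCR quantification

Serial-dilution Westerns on stain-free gels give two signals per lane,
both proportional to the loaded amount. Each channel is fit by least
squares *through the origin* against the relative load, and the normalized
level is the ratio of slopes. The origin constraint is a modeling choice:
the assay is proportional by construction and stain-free total-protein
normalization already removes background, so a free intercept would only
absorb noise. The level is invariant under joint rescaling of both
channels (exposure time, detector gain). Replicate levels feed a
two-sample t-test — Welch by default, since equal variances between
genotypes is an extra assumption; the pooled-variance Student test is one
flag away. The dilution ladder is always taken from the data file, never
assumed: default simulated loads are 1/2, 1/4, 1/6.

The simulator corrupts both channels with multiplicative lognormal noise
parameterized by a coefficient of variation; `meanlog` is set to
`-sdlog^2/2` so the noise has mean exactly 1 and recovered ratios are not
biased by the noise model itself.

qPCR relative expression uses delta-delta-Ct with amplification efficiency
fixed at 2.0 (no standard-curve estimation — none is typically reported
for this design); the calibrator sample is exactly 1 by construction. IP
yield is computed from IP and Input Ct values with the Input Ct adjusted
for the aliquot fraction (default 0.05, i.e. 100 uL of a 2 mL lysate);
note that the fraction and its Ct adjustment cancel algebraically, so the
yield reduces to `100 * 2^(Ct_input - Ct_ip)`.

## Gene-set statistics

Overlap of a called target list with a published set reports the raw
intersection percentage (universe-independent) and an upper-tail
hypergeometric p-value (universe-dependent — the choice of universe is the
single biggest lever on these p-values and is therefore an explicit
argument, defaulting in the pipeline to all detected protein-coding genes,
the sampling frame of the called list). Over-representation analysis
reports `fold = (k/n_targets)/(K/n_universe)` per annotation term with a
hypergeometric p and Benjamini–Hochberg q across tested terms; terms
without any target member are not tested. Annotation arrives as a plain
two-column table — reproducibility over the convenience of live
annotation services.

## Numerical and degenerate-input policy

* CPM with pseudocount 0 on an all-zero column is an input error, as are
  zero denominators in enrichment ratios.
* An undefined LI (naive mean CI of zero) is an error for the point
  estimate; inside a permutation it is counted as maximally extreme, a
  conservative choice that cannot inflate significance.
* `alpha_R` is never 0 (add-one correction) and never below `1/(m+1)`.
* Tie-breaks are deterministic everywhere (gene id in target lists, start
  position then pattern in motif tables), so equal inputs give
  byte-identical outputs.
* All generators restore the caller's RNG state, so seeding one stage
  never perturbs another.

## Problem sizes used in the test suite

The shipped tests run the randomization-null calibration at 1000
repetitions of n = 20 per group with 10,000 permutations; target-caller
recovery on 5000 genes with 500 planted targets; quantification power on
200 simulated dilution-series experiments; and the census replica on a
5794-nt synthetic UTR with 22 + 15 planted motifs. These sizes keep the
whole suite within a few minutes while leaving Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* The caller is gene-level only: no positional (CLIP-style) signal, no
  isoform resolution, no differential expression.
* With one library per condition, the control-calibrated filter has no
  variance model; its false-discovery behaviour degrades quickly as
  between-sample dispersion grows (see the count-simulator section).
* Published per-isoform CPE counts are reproducible only with the exact
  motif list used by the original census; the default set is a
  reasonable, clearly labelled stand-in.
* The hypergeometric overlap p-value assumes exchangeable genes within the
  universe; expression-matched null sets are out of scope.
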