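---
title: "Phasing three homologs by chromosome elimination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing three homologs by chromosome elimination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triphase)
```

## The phasing model

A trisomy 21 line carries three homologous copies of chromosome 21 — the
paternal homolog P and the two maternal homologs M1 and M2. At a biallelic
SNP the three copies realise one of four genotype classes (AAA, AAB, ABB,
BBB), and the two heterozygous classes cannot be told apart from bulk
sequencing of the trisomic line alone. With both alleles required to
appear, a single heterozygous site admits

$$S(a, h) = \sum_{i=0}^{a} (-1)^i \binom{a}{i} (a-i)^h$$

allele-to-homolog assignments (the surjection count by
inclusion–exclusion): $S(2,3) = 6$ per site, hence $6^3 = 216$ joint
assignments over three sites and $6^7 = 279{,}936$ over seven.
`theoretical_combinations()` computes exactly this.

The ambiguity collapses when three *corrected disomy* lines are available,
each produced from the trisomy by eliminating one homolog (ΔP retains
M1+M2, ΔM1 retains P+M2, ΔM2 retains P+M1). A base present in the trisomy
but absent from exactly one deletion line must reside on the homolog that
line lacks; once one homolog is pinned, the remaining two follow from the
bases shared by the lines that retain them. `phase_site()` implements this
subtraction, but never trusts it alone: every site is checked against
`enumerate_assignments()`, which scores all $|C|^3$ assignments of the
candidate bases $C$ against the observed presence pattern of all four
samples and keeps the consistent ones. The status taxonomy is total:

* `PHASED` — exactly one consistent assignment (≥ 2 candidates);
* `UNINFORMATIVE_HOMOZYGOUS` — one candidate base, all homologs identical;
* `CONFLICT` — no assignment reproduces the pattern (the signature of
  residual sequencing error);
* `AMBIGUOUS` — several consistent assignments;
* `FILTERED` — a sample contributed no usable base.

A structural fact worth stating: for the standard four-sample design the
three deletion lines expose all three homolog *pairs*, which
over-determines the assignment — an exhaustive sweep over every possible
presence pattern (run in the test suite) shows the consistent-assignment
count is always 0 or 1, never more. `AMBIGUOUS` is therefore unreachable
for complete data under this design; it is retained for degenerate designs
and defensive completeness. A corollary is that every `PHASED` site is
globally phased by construction: no linkage step is needed.

## Filters

Two filters precede phasing, both with inclusive comparisons:

* **Depth:** a site is kept only if *every* sample covers it with at least
  `min_depth = 10` reads; indel records are excluded regardless of depth
  (`filter_sites()`).
* **Base allele frequency (BAF):** per sample, a base is *present* when its
  count/depth ratio reaches `tau_present = 0.06`. The candidate set of a
  site is the bases present in the trisomy sample; bases below threshold
  there are treated as base-call error and ignored everywhere. The
  published analysis states the 0.06 rule for the trisomy sample and
  defers per-sample presence conditions to a supplementary table that is
  not available in the text; applying the same inclusive threshold
  symmetrically to every sample is this package's reconstruction of that
  step. It reproduces both published worked examples (rs74753297 and
  rs78248586) and is configurable via `tau_present`.

With ~30–45× depth the 0.06 threshold sits comfortably below the smallest
genuine heterozygous fraction (1/3 in the trisomy, 1/2 in a disomy) and
well above the per-base substitution error expected at any one site, but
it is a *stochastic* boundary: a 1/3-fraction allele drawn at, say, 2 reads
of 40 falls below it even without sequencing error (probability ≈ 2×10⁻⁵
per site, so expect zero-to-a-few occurrences per 50,000 sites). Such a
site reads as homozygous for the surviving base — this is the BAF filter
doing its job, and it is why recovery guarantees are stated for sites that
*pass* the filters with two or more candidate alleles.

## The simulator

`simulate_dataset()` emulates the four-cell-line experiment so that every
downstream stage is testable without the original sequencing data. What it
models, and what it deliberately does not:

* **Sites.** `n_sites` positions drawn uniformly without replacement along
  the chromosome. Each site takes one of seven configuration classes:
  monomorphic; P-, M1- or M2-private (the named homolog alone carries an
  alternate base); P+M1- or P+M2-shared alternates; tri-allelic (reference
  plus two distinct alternates permuted over the homologs). Phasing sees
  only the unordered allele pattern, so which side of a class carries the
  reference base is immaterial. The default weights (0.30 monomorphic,
  0.40 P-private, 0.07 each for the four other biallelic heterozygous
  classes, 0.02 tri-allelic) make P-private sites dominate the
  heterozygous fraction, emulating two maternal homologs that are
  genetically far closer to each other than to the paternal one — the
  structure expected when M1 and M2 segregate from one meiosis. The exact
  proportions are illustrative: the published site count (51,596 phased
  SNPs) comes without a class breakdown, so no calibration to it is
  attempted.
* **Depth.** Per-site, per-sample depth is Poisson with mean
  `depth_mean × k/2`, where `k` is the sample's homolog count:
  `depth_mean` is genome-wide (diploid) coverage, so a disomy site
  averages `depth_mean` (default 30) and a trisomy site 1.5× that. This
  makes each disomy's total chromosome-21 depth ≈ 2/3 of the trisomy's —
  the same copy-number signal the mapped-read-fraction statistic measures
  on real data. Reads are tallied as counts only; read length, mapping and
  quality scores are upstream of the method and are not modelled.
* **Allele sampling.** Each read draws its homolog uniformly, so
  heterozygous fractions are 1/3 or 2/3 in the trisomy and 1/2 in a
  disomy. Substitution error replaces a read's base with one of the other
  three uniformly at rate `error_rate`; no indel errors are simulated
  (indels are only recognised and excluded downstream).
* **Recombination.** `apply_recombination()` models an M1/M2 meiotic
  crossover: breakpoints split the chromosome into alternating segments
  and M2 is overwritten by M1 in every odd segment, creating the M1 = M2
  identity that a ΔP line displays as a homozygous run. P is never
  touched. The real experiment concluded *no* crossover occurred; the
  simulator exists to generate the counterfactual that conclusion was
  tested against.
* **Reproducibility.** `simulate_dataset()` seeds once from
  `SimParams$seed` and runs haplotypes → recombination → counts on a
  single RNG stream; the standalone operations accept an optional `seed`
  for isolated use.

What passing tests on this simulator do *not* show about real data:
mapping artefacts, strand bias, indel-adjacent miscalls, CNVs inside the
chromosome, and contamination are all absent, and real error is neither
uniform across substitutions nor independent across reads. The simulator
validates the *logic* of subtraction phasing and its filters, not the
upstream alignment pipeline.

## Recombination scan

`bin_het_density()` counts heterozygous sites (present-set size ≥ 2) per
sample in fixed 1-based closed bins of 10,000 bp, reporting empty bins
explicitly. `detect_homozygous_runs()` flags maximal stretches of at least
`min_run_bins = 5` consecutive zero-heterozygosity bins whose flanking
`min_run_bins` bins (on each side where the chromosome continues) average
at least `min_flank_density = 1` heterozygous site per bin. The published
inference was made by visual inspection of the binned histogram; the run
length and flank-density guard are this package's operationalisation of
"a homozygous region stands out against dense heterozygosity", chosen so
that a 50 kb signal is required (5 bins) and sparse-coverage gaps cannot
masquerade as homozygosity. Both knobs are exposed. An empty result for
the ΔP line is the "no recombination during the first meiosis" call.

## Supporting statistics

`chr21_read_fraction()` (100·mapped/total) and `elimination_efficiency()`
(100·disomic/picked) return unrounded percentages; `format_percent()`
renders them at two decimals with half-up rounding, the precision the
published figures use (1.81%; 3.48%, 3.57%, 3.13%). `mlpa_call()` encodes
the aneuploidy kit's decision rule — trisomy iff at least 4 of the 8
relative probe ratios are ≥ 1.30, both comparisons inclusive.

## Numerical and design choices

* Threshold comparisons are inclusive (`≥`) throughout, following the
  "at least 10", "0.06 or more" and "≥ 1.30" wordings.
* Coordinates are 1-based VCF positions; bases are reported on the
  positive strand.
* Multi-allelic VCF records are kept as single sites; every single-base
  allele contributes counts. Depth is the caller's `DP`, falling back to
  the sum of `AD` when `DP` is absent.
* The surjection count is computed in double precision; $6^7$ is far
  inside exact-integer range.
* Haplotype strings are assembled from `PHASED` heterozygous sites only;
  homozygous sites stay in the per-site table with their own status, so a
  consumer can include them if desired.
* VCF output is written through `vcfR`, which gzip-compresses; emitted
  files carry a `.vcf.gz` suffix. The phased VCF encodes the trisomy
  genotype as a triploid phased `GT` in homolog order `P|M1|M2`.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to exercise the statistics
without the original ~50 Mb chromosome: oracle-equivalence sweeps use
10,000 random presence profiles; recovery and error-robustness runs use
50,000 sites over a 46.7 Mb coordinate space at 30× depth (error 0 and
0.01); the crossover scan uses 100 seeds of 5,000 sites over 1 Mb with a
single breakpoint, detection required within one 10 kb bin. The headline
published count (51,596 phased SNPs) depends on the study's cell lines
and sequencing run and is not reproducible from simulation; the recovery
properties above are the package's substitute.

## Known limitations

* The per-sample presence rule reconstructs an unavailable supplementary
  specification; real thresholds may have been asymmetric between the
  trisomy and disomy samples.
* Sites with any sample missing data are dropped rather than rescued; no
  genotype-likelihood model is used.
* The scan detects homozygous runs; it does not locate breakpoints more
  finely than one bin, and it cannot distinguish identity-by-descent from
  a deletion in the retained homolog (copy-number input would be needed).
* No statistical/population phasing is attempted beyond the deterministic
  per-site subtraction, which is the method's point.
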