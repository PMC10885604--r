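---
title: "Scoring 3' UTR structure from DMS probing and relating it to mRNA fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 3' UTR structure from DMS probing and relating it to mRNA fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrstruct)
library(dplyr)
```

## The measurement model

DMS methylates N1 of adenosine and N3 of cytosine when those positions are
not engaged in a base pair. A processive reverse transcriptase transcribes
through the adduct and installs a random nucleotide, so a methylated
position appears as a mismatch in aligned reads. The analysis therefore
starts from per-base *pileups* — coverage `c_i` and mismatch count `m_i`
per position — for a DMS-treated sample and an untreated control.

The reactivity chain is:

* raw reactivity `r_i = m_i / c_i`, masked where `c_i` is below a coverage
  floor (default 100 for deep amplicon data, 20 for genome-wide
  poly(A)-anchored libraries, where coverage decays away from the 3' end);
* background correction `r'_i = max(0, r_treated,i − r_untreated,i)`,
  removing sequencing/RT error;
* normalization `ρ_i = min(1, r'_i / s)`, with `s` the median of the top
  5 % of unmasked values of that transcript, so profiles are comparable
  across transcripts with different overall modification efficiency.

Two choices here were genuinely open. First, "normalizing by the
untreated sample" can mean subtraction or division; we subtract with a
floor at zero, the dominant convention in probing analysis, and expose
division behind `background_method = "divide"`. Second, the order of
correction and top-5 % scaling matters; we fix one order — correct, then
normalize — and apply it in both modes, computing the top-5 % set on
background-corrected values. Normalization refuses transcripts with fewer
than 20 unmasked positions (the scale would be dominated by noise); the
pipeline drops and counts such transcripts instead of aborting. A
degenerate all-zero profile normalizes to all zeros with a warning rather
than NaN. An optional `trim_outliers` switch excludes values above
Q3 + 1.5·IQR from the scale estimation, mirroring the outlier flagging
used when reactivities feed a folding engine; it is off by default.

## The structure score

A structured region shows reactivity concentrated on a few loop bases; an
open region reacts broadly and evenly. The Gini index of the normalized
reactivities in a window captures exactly this inequality:

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x}$$

computed via the sorted-value identity in O(n log n) and verified in the
tests against the O(n²) double loop to 1e-12. `G` is scale-invariant, 0
for a constant vector, `(n-1)/n` for a one-hot vector, and undefined (NA)
for fewer than two values or a zero mean — such windows are skipped, never
errors.

Each 3' UTR is tiled into 50-nt windows every 25 nt; trailing partial
windows are not emitted, giving `⌊(L−50)/25⌋ + 1` windows for a length-L
region. A window is retained only when its mean raw mismatch count over
*all* window positions exceeds 20 — a signal-depth filter, deliberately
based on counts rather than reactivities, so low-coverage windows drop out
before they can contribute noisy scores. The per-transcript score is the
unweighted mean of retained windows (weighting by included-position count
was the alternative; unweighted keeps a long UTR's sparse 5' windows from
being silently down-weighted and is the simpler contract).

Two further decisions: the Gini is computed over A/C positions only, since
G and U carry no DMS signal and their structural zeros would deflate the
score (an `bases = "all"` switch exists for sensitivity analysis); and the
stop codon's three bases form their own stratum in the meta-gene profile,
belonging to neither the CDS nor the UTR flank mean.

## The synthetic experiment

The generator makes the whole pipeline testable without sequencing data.
It emulates, per transcript:

* a 3' UTR dot-bracket structure constructed by placing hairpin stem-loops
  (stems of ≥ 4 bp, loops ≥ 3 nt) in an unpaired scaffold until a target
  pairing fraction is hit within ±0.05. Structures are *constructed, not
  folded*: the analysis consumes reactivities, never energies, and
  thermodynamic folding is external to this package. Unreachable targets
  (above the single-hairpin ceiling `2⌊(L−loop)/2⌋/L`) raise an error
  naming the achievable maximum.
* sequence consistent with the structure (Watson–Crick complementary bases
  across each helix), a random CDS ending in UAA, and a CDS structure of
  its own (default target pairing 0.6 > the typical UTR level, so
  meta-gene contrasts across the stop codon have a ground truth).
* pileups with mismatch counts `Binomial(c_i, p)` where `p` is the
  background error (0.002) everywhere, plus a paired-A/C leak (0.005) or
  the unpaired-A/C rate (0.05) in treated samples. The background rate is
  a free parameter — untreated mismatch rates are rarely reported — and is
  exposed in the configuration. Coverage follows
  `c(i) = mean_coverage · ((i+1)/L)^b`, one parameter (`b`, default 1)
  capturing the 3'-end read enrichment of poly(A)-anchored libraries;
  `b = 0` recovers uniform coverage. Only substitutions are simulated — the
  mismatch caller ignores indels, so simulating them would test nothing.
* covariates: `log RPKM` and `log t½` linear in pairing fraction with
  negative slopes and Gaussian noise (defaults: baseline 4 log-RPKM and
  4 h, slopes −2 and −1.5, sd 0.5 and 0.4) — the structure-mediated decay
  scenario in which paired 3' UTRs mark transcripts for exonucleolytic
  turnover; poly(A) tail length lognormal around a median of 80 nt,
  independent of structure unless a coupling slope is set; miRNA-target
  flags independent Bernoulli draws.

Default coverage is 5000 at the 3'-most base (≈ 2500 averaged over the
transcript under `b = 1`): with the 0.002–0.05 rate span this places
typical windows at mean mismatch counts of 20–40, i.e. around the
count filter the way a real deep library sits, so the filter is exercised
rather than trivially satisfied.

What the generator does *not* emulate: pseudoknots and long-range pairs,
RT drop-off (stop-based) signal, indels, sequence-dependent modification
biases, protein footprints, and alternative polyadenylation. Passing tests
demonstrate that the pipeline recovers what the generative model encodes —
they do not certify performance on real libraries, where those effects
exist.

## Association analyses

Gene classes are the top and bottom `⌊0.10·n⌋` records by average Gini
(and analogously by half-life or a log2 half-life ratio), with boundary
ties broken by transcript id — an explicit, deterministic rule; with
heavily tied scores (e.g. many transcripts at Gini 1) any decile
assignment is a convention, and ours is a choice, not a reconstruction of
anyone else's. Quantiles elsewhere are R's type-7; median splits for
confounder stratification use ≥ median vs < median, so the two strata
differ in size by at most one.

The statistical layer deliberately delegates to `stats`: Wilcoxon
rank-sum, Kolmogorov–Smirnov, Pearson (on `log10(RPKM + 1e-6)`; whether
expression should be logged before correlating is a judgement call — we
log and say so), two-proportion tests for miRNA-target overlap. No
multiple-testing correction is applied: each comparison is a single
primary test, and all p-values are reported so a user can correct across
whatever family they assemble.

G-quadruplex sites are greedy left-to-right non-overlapping matches of
four G-tracts (≥ `min_g`, default 3, configurable down to 2 since
predictor conventions differ) separated by 1–7-nt loops, equal by test to
an exhaustive enumeration oracle. Decay curves are fit by least squares on
`log(abundance)`; `t½ = ln 2 / k`, with non-positive `k` reported as a
missing half-life rather than a negative one.

For the end-to-end recovery checks we summarize class separation as the
ratio of structured-gene shares in the high- vs low-Gini class with a 0.5
pseudo-count per cell (Haldane), which stays finite under the perfect
separation the generator can produce.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → reactivity → window Gini → covariate
join → classification → statistics, drops and counts genes without a
usable average Gini before classification, writes stage tables plus a JSON
manifest of parameters and per-filter counts, and is byte-deterministic
given its configuration (all randomness flows through one seed, from which
per-gene streams are derived).

The shipped tests and the acceptance script run the recovery analyses at
300 genes with pairing levels {0.1, 0.7}, monotonicity at 4 × 40 genes,
and the null control (coupling slopes set to zero) over 50 seeded runs —
sizes at which the coupled effects are comfortably detectable and a
laptop-scale run finishes in minutes, while the null control has room to
show its false-positive rate.

## Known limitations

* The half-life contrast after the average-Gini > 0.4 threshold filter is
  only informative when structure varies *within* the retained set; on
  strongly bimodal synthetic cohorts the filter removes one mode, so the
  pipeline also reports the unfiltered decile contrast.
* Normalization is per transcript; cross-transcript comparability
  therefore assumes the top-5 % scale is an equally good ceiling estimate
  everywhere, which degrades for transcripts with very few reactive bases.
* The BAM path is intentionally thin: the package starts at pileups (or
  gap-free aligned read tables); producing alignments is out of scope.
* Thermodynamic folding is exported to, not performed by, this package —
  `export_constraints()` writes SHAPE-style files (1-based positions,
  −999 for masked and G/U) for an external engine.
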