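# utrstruct

Quantify the secondary structure of mRNA 3′ untranslated regions from DMS
mutational-profiling data and test how that structure relates to transcript
expression and stability.

## The problem

Dimethyl sulfate (DMS) methylates unpaired adenosines and cytosines in RNA
in living cells. A processive reverse transcriptase reads each methylation
as a mismatch in cDNA, so after sequencing, the per-base mismatch rate
(mismatch count / coverage) reports how accessible — i.e. how *unpaired* —
each A and C is. Applied transcriptome-wide with a poly(A)-anchored
library, this probes the structure of 3′ UTRs, the region between the stop
codon and the poly(A) site that is a major determinant of mRNA fate:
transcripts with highly base-paired 3′ UTRs are preferentially degraded by
cytoplasmic exoribonucleases and accumulate to lower levels, while
transcripts with open 3′ UTRs are more stable and more highly expressed.

`utrstruct` implements the complete desk side of this analysis:

1. **Reactivity calling** — per-base raw reactivity `r_i = m_i / c_i`,
   background correction against an untreated control
   (`r′_i = max(0, r_treated − r_untreated)`), and normalization by the
   median of the top 5 % of values with capping at 1.0.
2. **Structure scoring** — each 3′ UTR is tiled into 50-nt windows every
   25 nt and each window is scored with the Gini index of its normalized
   A/C reactivities,

   `G = Σᵢ Σⱼ |x_i − x_j| / (2 n² x̄)`,

   high when reactivity is concentrated on few bases (structured RNA), low
   when it is spread evenly (open RNA). Windows with a mean mismatch count
   ≤ 20 are discarded; the per-transcript score is the mean Gini of the
   remaining windows.
3. **Association** — genes are split into the top/bottom 10 % of average
   Gini (high-/low-Gini classes); expression (RPKM) is compared between
   classes by Wilcoxon rank-sum, correlated with structure by Pearson, and
   half-life deciles are contrasted in Gini by Kolmogorov–Smirnov,
   with median-split stratification for GC content and poly(A)-tail
   length, G-quadruplex motif prediction, miRNA-target overlap, and
   exponential decay-curve fitting (`t½ = ln 2 / k`).
4. **Synthetic data** — a seeded generator builds transcripts with
   dot-bracket 3′ UTR structures across chosen pairing fractions,
   simulates treated/untreated pileups under the DMS error model with
   3′-biased coverage, and draws expression and half-life inversely coupled
   to structure, so the whole pipeline is testable with no sequencing data.

Meta-gene stop-codon profiles, codon-position reactivity, and SHAPE-style
constraint-file export for external folding engines are included. All
user-facing functions take and return tibbles, and results have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(utrstruct)

cfg <- run_config(
  sim = sim_config(n_genes = 100, pairing_fraction_levels = c(0.1, 0.7),
                   seed = 42),
  seed = 42)
res <- run_pipeline(cfg)

res$stats$expression_ranksum
#> <utr_group_compare> Wilcoxon rank-sum of rpkm by avg_gini_class (high vs low)
#>   statistic = 4, p = 0.00013
#> # A tibble: 2 × 5
#>   group     n median   q25   q75
#>   <chr> <int>  <dbl> <dbl> <dbl>
#> 1 high     10   16.1  11.5  22.3
#> 2 low      10   59.4  38.2  66.7

res$stats$gini_expression_correlation
#> <utr_correlation> avg_gini vs log10(rpkm): R = -0.7992, p = 2.14e-23 (n = 100)
```

The ten highest-Gini (most structured) 3′ UTRs have a median expression of
16 RPKM against 59 RPKM for the ten lowest-Gini ones, and average Gini is
strongly negatively correlated with log expression — the generator's
inverse structure–expression coupling, recovered end-to-end from simulated
mismatch counts.

Individual stages are ordinary functions on tibbles:

```r
ex <- simulate_probing_experiment(sim_config(n_genes = 20, seed = 1))
reactivity <- dms_reactivity(ex$treated, ex$untreated, min_coverage = 20,
                             on_few = "drop")
windows <- window_gini(utr_region(reactivity, ex$transcripts))
average_gini(windows)
```

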