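---
title: "Estimating recombination and mutation rates from drone colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recombination and mutation rates from drone colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dronemap)
```

## The measurement

Hymenopteran males develop from unfertilized eggs: a drone is a single
haploid recombinant product of his mother queen's meiosis. Sequencing a
cohort of brother drones therefore resolves, without ever sequencing the
queen,

* the queen's two chromosome-scale haplotypes (every drone is a mosaic of
  the two, and adjacent heterozygous sites are co-inherited far more often
  than not),
* every crossover (CO) and gene-conversion tract (NCO) in each gamete, as
  the switch points of that mosaic, and
* every de novo mutation, as an allele carried by exactly one drone and by
  neither reconstructed queen haplotype.

`fit_colony()` runs this analysis on a haploid genotype matrix and returns
a classed fit with `summary()`, `coef()`, `plot()` and `simulate()`
methods. The stages are exported individually (`screen_markers()`,
`phase_queen()`, `assign_blocks()`, `classify_events()`,
`group_shared_cos()`, `crossover_rate()`, `call_denovo()`,
`estimate_rate()`), and a colony simulator with ground truth
(`simulate_colony()`) makes every stage testable by parameter recovery.

## Marker screening

Drone SNPs are screened into colony markers by three rules, applied in a
fixed order with per-rule drop accounting:

1. no drone may be called heterozygous at the site (haploid genomes; such
   calls indicate mapping error or copy-number variation);
2. exactly two alleles must segregate among the called drones, each
   observed in at least `min_minor_count = 2` drones;
3. the site must be called at quality >= 30 in >= 90% of drones.

The minor-count requirement in rule 2 deserves a note, because it is what
makes the rest of the pipeline coherent. A site where one drone carries
one allele and all brothers the other is, at the genotype level,
indistinguishable from a de novo mutation (and, in a 10-drone colony,
whole sole-haplotype segments of such sites arise by segregation chance at
an appreciable rate: a given drone is alone on its haplotype over roughly
`2 * n / 2^n` of the genome). Requiring both alleles twice keeps such
sites out of the marker set - and out of the phasing votes, where a
singleton site would otherwise insert a spurious one-marker block into
half the drones - and routes them to the mutation caller, which owns the
job of deciding what they are.

## Phasing by adjacent-marker majority linkage

For each adjacent marker pair, every drone called at both sites votes for
one of the two possible queen linkage configurations; the majority wins
(crossover probability per inter-marker interval, at ~400 bp spacing and
~9 cM/Mb, is of order 1e-5, so even one vote is informative and a
near-split vote essentially never occurs in clean data). Phase is chained
left to right along the chromosome.

When a pair is uninformative - equal votes, or no drone called at both
sites - the marker is bridged against the nearest preceding marker (up to
`bridge = 10` back) with an informative vote. Bridging through a later
pair would carry exactly the same information; a single scan direction is
simpler. If no bridge is informative the chain is broken and a new phase
set starts: linkage is never fabricated, and all downstream quantities
treat haplotype labels as meaningful only within a phase set. Within each
set, haplotype 0 at the first marker carries the reference allele (else
the alphabetically smaller one).

## Event classification

Each drone's called markers map to haplotype 0 or 1, giving maximal
same-haplotype runs (`assign_blocks()`). Blocks spanning more than 10 kb
(marker-to-marker; spans are not interpolated beyond the outermost
markers, matching the marker-resolution limit of the data) form the
crossover backbone. A haplotype change between backbone blocks is one CO,
located to the inter-marker interval between them. Short blocks are
conversion tracts: flanked by the same haplotype they are NCOs; sitting
inside a backbone haplotype change they are CO-associated conversions.
Chromosome-terminal short blocks count as COs (only one flank exists);
this is configurable (`terminal_as_co`).

Crossovers from different drones with the exact same flanking-marker pair
form a shared group; requiring exact identity is deliberately
conservative, since near-identical intervals (off by one marker) are more
plausibly independent events. A shared CO adjacent to another shared CO in
the same drone and chromosome within 700 kb - the window covering the
observed ~100-700 kb separations of such pairs - is the signature of a
translocation or local mis-assembly, and both members are excluded
(category 2). Rates are reported with and without the exclusions:
`cM/Mb = 100 * (COs per drone) / genome Mb`.

## Mutation calling

A candidate is a site where exactly one drone carries an allele found in
no brother. The carrier must have depth >= 5, quality >= 30 and support
on both strands; marker sites are skipped (queen-heterozygous by
screening). Two deterministic rules replace the study-style manual review
of survivors:

* **phase concordance** - if every other called drone sits on the
  opposite haplotype to the carrier at the site, the split is exactly what
  queen heterozygosity would produce and the candidate is rejected. A true
  de novo allele instead rides a haplotype that other, reference-carrying
  drones also inherit. The false-negative cost is `2^-(n-1)` per true
  mutation. Haplotype context at non-marker sites comes from the drone's
  flanking blocks when they agree.
* **cluster rejection** - same-drone candidates within 10 kb of one
  another are rejected. Sole-haplotype segments (which are marker-free by
  construction, so phase concordance cannot anchor there) betray
  themselves by yielding runs of tens to thousands of same-drone
  candidates, while true de novo mutations arrive at ~1 per drone per
  genome, making a same-drone pair within 10 kb vanishingly unlikely.

Candidates near assembly gaps are flagged (`near_gap`), not dropped.

The rate is `count / (drone-summed callable sites)` - callable meaning
depth >= 5, mapping quality >= 20, unambiguous reference - with the exact
(Garwood) Poisson interval from chi-square quantiles scaled by the same
denominator, and a per-genome rate scaled to the full 274 Mb genome to
allow for unassembled sequence. The spectrum is tallied by transition
direction and corrected for base content (GC->AT per GC fraction vs
AT->GC per AT fraction).

## Randomization statistics

All Monte-Carlo tests use the unbiased estimator `p = (n+1)/(m+1)` with
"as extreme or more extreme" meaning `>=` the observed statistic, consume
an explicit seed, and return the full null sample.

* `dispersion_test()`: the (n-1) sample variance of per-drone counts
  against equal-probability multinomial re-allocation. Note that the
  analytic null mean is exactly `total/n` (the multinomial total is
  fixed, so `E[s^2] = n Var(c_i)/(n-1) = m/n`), which is why the expected
  null variance for 23 mutations over 32 drones is 0.719 - no
  callable-site weighting is needed to reproduce it, though a `weights`
  argument is available.
* `proximity_test()`: mutations within 1 kb of a breakpoint of *the same
  drone's* crossovers (mutation and recombination happened in the same
  meiosis, so coupling is only expected within a drone); the pooled
  variant is behind `pooled = TRUE`. The null redraws pseudo-mutation
  sites uniformly with drone labels preserved.
* `conversion_bias_test()`: conversions toward G/C among A/T-G/C
  polymorphic converted sites against a fair per-site coin, one-sided
  toward G/C; the matching one-sided exact binomial p is reported
  alongside (for a 23:13 split it is 0.066). A null under which the
  published randomization would give p < 0.001 is not reconstructible
  from the published description, so no stronger claim is made.
* `rate_difference_permutation()`: |difference of group mean rates| under
  re-partition of the pooled individuals.
* `merge_rank_correlate()`: windows ranked by the predictor are merged
  into 21-25 rank-neighbour bins (sizes differing by at most one) and the
  bin means correlated; the raw per-window Spearman correlation is
  reported alongside because a p-value on bin means is not comparable to
  one on raw windows. `partial_spearman()` is the textbook recursion on
  the rank-correlation matrix.

## The simulator

`simulate_colony()` generates a queen (heterozygous sites as a Bernoulli
process per non-gap bp, default 0.26%; reference bases at the genome's
37.5% GC), meiosis per drone, mutations, and a noisy observation channel,
with every event recorded in a ground-truth ledger. Defaults are the
study conditions; where the study gives no value the choice is stated
here and not revisited.

| parameter | default | basis |
|---|---|---|
| genome | 18 chromosomes, 216.85 Mb assembled, GC 37.5% | assembly scale |
| heterozygosity | 0.26% per bp | colony diversity |
| CO rate | 8.73 cM/Mb, Poisson per chromosome, uniform positions | measured rate; no interference claim, simplest null |
| NCO rate | 0.69 tracts/gamete, apportioned by chromosome length | measured rate |
| NCO tract length | geometric, mean 300 bp | standard conversion-tract model; tract lengths unmeasured in bees, kept well under the 10 kb calling rule |
| CO-associated conversion | 3/606 of COs, tract offset by a geometric spacer | observed frequency; the spacer makes the tract a distinct block, which is what detection requires |
| GC bias | 23/36 toward G/C at A/T-G/C sites | observed direction split |
| mutation rate | 3.58e-9/bp; all transitions, 20/23 GC->AT; 2/25 indels | observed spectrum |
| depth | Poisson, mean 26 | coverage regime |
| missing / error / het-artifact rates | 0.02 / 1e-6 / 1e-4 | plausible values for stringent haploid calling at 26x; not measured |
| call quality | N(38, 4) clipped to [0, 60]; erroneous calls N(18, 4) | miscalls at high depth are low-confidence, so quality filtering removes most of them, as in real pipelines |

An optional piecewise-constant hotspot map modulates CO placement; by
default positions are uniform (the study reports hotspots but no
generative model). Markers and mutations are never placed inside assembly
gaps; crossover breakpoints may fall in them, which is precisely what
makes distinct events in different drones appear "shared" on a gapped
assembly. Per-drone genome-wide callable-site counts are drawn
binomially at the channel's callable probability.

What the simulator does not emulate: read-level noise (alignment,
PCR/sequencing error profiles), diploid workers, copy-number variation,
selection or demography, and real marker clustering along chromosomes.
Passing recovery tests therefore demonstrate the correctness of the
genotype-level logic under the stated statistical structure, not
robustness to raw-read artifacts.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally, 1-based in TSV/VCF output,
0-based in BED. Ties in the phasing vote bridge backwards, then break the
phase set. A chromosome whose blocks are all short is classified like
terminal switches (each transition a CO). `exact_poisson_ci(0)` returns
`(0, -log(alpha/2))`. `marker_density()` refuses fewer than two markers;
`colony_heterogeneity()` refuses a zero total; `conversion_bias_test()`
declines (returns `NULL` with a message) when no converted site is
A/T-G/C polymorphic. Monte-Carlo p-values can never be zero by
construction.

## Problem sizes used by the test-suite

The packaged tests verify recovery on two simulated colonies of 22 and 10
drones on an 18-chromosome, 50 Mb genome at the study's heterozygosity
and crossover rate, with the mutation rate scaled so that ~20 mutations
are expected; confidence-interval coverage is measured over 200 replicate
32-drone colonies on 5 Mb genomes with ~25 expected mutations each
(coverage of an exact Poisson interval depends on the expected count, not
the genome size, so the count is held at study scale). These sizes are
the package's choice of a thorough-but-routine check; all thresholds are
the analysis defaults.

## Known limitations

* NCO detection is bounded by marker spacing: a tract containing no
  marker is invisible, so detected NCO counts per drone underestimate the
  generative rate by roughly the probability a geometric tract catches a
  marker (~0.4-0.6 at the simulated densities). Converted-marker counts
  of detected tracts are exact on a noiseless channel.
* A sole-haplotype segment containing exactly one heterozygous site
  yields a single isolated candidate that neither deterministic filter
  can reject; at 22 drones the expected number of such sites is well
  below one per colony, but it is the honest residual false-positive
  mode.
* Phase-set labels are arbitrary across sets; any analysis consuming
  `QueenPhase` must respect the `phase_set` column.
* The genotype-level spike-in (`spike_in_recovery()`) measures the
  pipeline's detection behaviour, not read-level callability; its
  fractions are not comparable to read-level spike-in figures.
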