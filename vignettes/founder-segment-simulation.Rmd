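---
title: "Founder-segment Wright-Fisher simulation for evolve-and-resequence experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-segment Wright-Fisher simulation for evolve-and-resequence experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package models

Long-term laboratory evolution experiments with outbreeding species such as
*Drosophila melanogaster* typically maintain several replicate populations of
moderate size (a few thousand breeding individuals) for hundreds of
generations, then sequence pooled DNA from each replicate ("evolve and
resequence" with pool-seq).  Interpreting the resulting genome-wide patterns
of heterozygosity and between-replicate differentiation (F~ST~) requires a
null and a family of alternatives: how much variation *should* be left after
`G` generations of drift alone?  How do directional selection, balancing
selection, polygenic optimizing selection, or low-level accidental migration
between replicates move those quantities?

`ersim` answers these questions by forward simulation on a single chromosome
arm.  No external data are needed: a synthetic founder-panel module emulates
the kind of inbred-line haplotype panel (a DGRP-like set of ~100 chromosomes)
that such experiments use as a simulation base population.

## The founder-segment representation

Since no *de novo* mutation is modeled, every allele in every generation is a
copy of a founder allele.  A gamete is therefore fully described by a founder
state vector `S` and a breakpoint vector `B` in map units (Morgans): for
example `S = {3, 17, 31, 3}`, `B = {0.20, 0.25, 0.60}` means founder 3's
sequence on [0, 0.20), founder 17's on [0.20, 0.25), founder 31's on
[0.25, 0.60) and founder 3's again above 0.60 M.  Segments are half-open, so
a site lying exactly on a breakpoint takes the right-hand founder.  Adjacent
equal states are never merged; the representation records the recombination
history as it happened.

Tracking segments instead of full sequences makes the generation loop
independent of the number of sites: a 2000-gamete deme over 800 generations
accumulates on the order of 250 breakpoints per surviving gamete
(0.63/2 expected new breakpoints per transmitted gamete per generation), and
alleles are materialized only once, at the final projection onto panel sites.

## The generation step and its RNG contract

Each deme holds exactly `N` gametes every generation.  In *gamete mode*
(used for drift and optimizing-selection scenarios) the loop to create
offspring slot `n = 1..N` is:

1. draw two parental gametes with replacement (uniformly, or with
   probability proportional to fitness weights);
2. if `n` is even, draw `r ~ U(0, 1)`; if `r < L` (the map length in
   Morgans, 0.63 for a 63 cM arm) the offspring joins parent 1 left of `r`
   to parent 2 right of `r` with a new breakpoint at `r`; otherwise, and on
   odd slots, the offspring is a copy of parent 1.

The even-slot rule halves the effective recombination rate, reflecting
female-limited recombination in *Drosophila*.  The engine deliberately
implements this literal single-potential-crossover rule — the classic
segment-tracking shortcut — rather than a biologically richer crossover
process; a Poisson multi-crossover variant (`crossover_model = "poisson"`,
rate `L` Morgans) is available but off by default.  The uniform crossover
deviate is consumed *only* on even slots; this convention is frozen as
part of the RNG contract.

Migration follows reproduction: `M` times per generation, two indices are
drawn uniformly on the pooled `D * N` gametes and the first gamete is
overwritten by a copy of the second.  This is a one-way island scheme —
nothing is exchanged back, and any ordered pair (including two members of
the same deme) is equally likely.  A `distinct_demes` option restricts pairs
to different demes for sensitivity analysis; the default matches the
uniform-pool description.

The compiled engine consumes R's own RNG (`unif_rand` / `norm_rand`) in
exactly the order above.  This is a deliberate design decision: the test
suite contains a pure-R oracle that materializes every gamete as an explicit
allele vector and consumes the same stream, and the two implementations are
required to agree *bit for bit* on the final allele-frequency matrices.  The
same contract lets users replay any trajectory step by step with the
exported R-level operations (`next_generation()`, `migrate()`).

## Selection models

**Per-locus fitness (diploid mode).**  Genotype fitnesses are `w11 = 1`,
`w12 = 1 + h s`, `w22 = 1 + s` in copies of the favored allele,
multiplicative across loci, with selection acting on fecundity: diploid
parents (adjacent gamete pairs) are drawn proportional to fitness, selfing
excluded by redrawing, and each parent transmits one gamete through a
Poisson multi-crossover meiosis on the sex-averaged (halved) map.
Overdominance is the `h > 1` corner of the same parameterization; the
interior equilibrium of the favored allele is `h / (2h - 1)`, which the
package records in the configuration so property tests can check that
simulated selected sites hold near it.  The overdominance default `h = 2`
is the package's own choice (no single value is canonical for such
scenarios); with `s = 0.1` it gives fitnesses (1, 1.2, 1.1) and equilibrium
2/3.

The choice of `h` is not cosmetic: it decides which side of neutrality the
scenario's genome-wide heterozygosity lands on.  Symmetric balancing
(equilibria near 1/2, e.g. `h = 2`) actively maintains polymorphism at and
around the selected sites, and in these simulations mean heterozygosity
over polymorphic sites then *exceeds* the neutral baseline, while mean
F~ST~ drops slightly.  Asymmetric overdominance with an equilibrium near
fixation (e.g. `h = 1.1`, equilibrium ~ 0.92) behaves like a partial
sweep — selected sites stay polymorphic, surrounding variation is
purged — and genome-wide heterozygosity falls below neutral, the ordering
usually reported for balancing-selection scenario families in E&R
comparisons.  Since no particular `h` is canonical for such scenarios,
the property tests assert the below-neutral ordering under near-fixation
equilibria and equilibrium maintenance under the symmetric default.

**Optimizing selection on a quantitative trait (gamete mode).**  `Q` QTL
are spaced evenly across the arm; founder states at the QTL are Bernoulli
draws at the configured starting frequency (0.05 or 0.5 in the shipped
scenario grids).  A gamete's phenotype is

```
pheno = sum(allele_q * effect_q) + N(0, Va_poly) + N(0, Ve) + polygenic_mean
```

and its selection weight is `exp(-(pheno - optimum)^2 / (2 * Vf))`,
normalized within the deme.  A common shorthand writes such a fitness
function as the quadratic deviation alone; the raw quadratic *increases*
away from the optimum, so the standard exponential Gaussian form is what
is implemented, and this interpretation is flagged here deliberately.  The
optimum sits `15` phenotypic standard deviations above the expected
starting mean, with `Vf = 12`; both are tunable — the 15-SD shift is of
the size used in long-term Drosophila selection experiments.

The polygenic background (the rest of the genome) responds through the
Breeder's equation: each generation, per deme,
`polygenic_mean += h2_poly * S` with `h2_poly = Va_poly / (Va_poly + Ve)`
and `S` the observed selective differential.  `S` is computed as the mean
phenotype of all `2N` realized parental draws minus the deme mean — both
parents are drawn proportional to fitness in gamete mode, so both count as
"chosen to reproduce".  The polygenic and environmental deviates are
drawn once per gamete per generation; letting them persist across repeated
fitness evaluations within a generation would be an equally defensible
convention, but no step in the model re-evaluates fitness, so the choice
has no observable consequence here.

**Variance bookkeeping.**  The default partition at generation zero is 12%
QTL, 38% polygenic, 50% environmental with total phenotypic variance 1.
Because phenotypes are per *gamete*, per-QTL variance is `p q a^2` (the
per-diploid equivalent of the usual `2 p q a^2`).  The preset effect
vectors — (1, 2, 2), (1×8, 0.71×2), (0.71×16, 0.5×4), with the sum of
squared effects held near 9 so heritability does not change with QTL
number — do not by themselves give `sum(p q a^2) = 0.12` at either preset
starting frequency, so by default effects are rescaled by the constant
`c` solving `sum(p_i q_i (c a_i)^2) = 0.12` at the nominal start
frequencies (`rescale_to_h2 = FALSE` restores the raw vectors).
Rescaling makes the heritability partition, not the raw effect sizes, the
binding quantity.

## Synthetic founder panels

`generate_founder_panel()` produces `F` binary haplotypes over `L`
polymorphic sites.  Site frequencies are drawn from a spectrum and alleles
sampled per haplotype; monomorphic outcomes are redrawn.  The binding
calibration is the panel mean heterozygosity (mean `2pq`), targeted at 0.32
by default — the one quantity the emulated base population pins down.  The
default spectrum is neutral-SFS-shaped (density proportional to `1/x`),
truncated to `[a, 1-a]` with `a` solved analytically from
`E[2x(1-x)] = (1-2a)/log((1-a)/a)`; a finite-panel correction `1 - 1/F` is
applied to the continuous target before solving.  A uniform spectrum is
available but its range-rescaled mean heterozygosity cannot go below 1/3
(it errors for lower targets); a Beta spectrum with user shapes is rescaled
around 0.5 to meet the target.  Which spectrum the real panel follows is
not determined by the calibration target, and no claim is made that the
default is "the" right one.

Alleles are abstract 0/1; nucleotide identity (random ref/alt base pairs)
is attached only when exporting pool-seq files, since no statistic in scope
depends on base identity.  Coordinates are 0-based half-open internally;
sync/mpileup exports are 1-based per those formats' conventions.  The
default genetic map is uniform, 63 cM over a 28 Mb arm in 100 kb windows
(a chromosome-3R-like arm); empirical per-window rates can be supplied, and
a `sex_averaged` flag halves female rates for diploid-mode maps.

## Pool-seq emulation and filters

`sample_pool_reads()` converts exact deme frequencies into read counts:
depth per site per pool is negative-binomial (default mean 60, dispersion
21.8, i.e. SD ~ 15, mimicking typical per-population coverages of 60-70X);
each read carries the alternate allele with probability equal to the true
frequency and is miscalled to each other base with probability
`error_rate/3`.  The depth model is a declared stand-in — the empirical
depth distribution of any particular experiment can be substituted by
resampling, but is not shipped.

`filter_snp_table()` applies the SNP-table rules: discard a site if
coverage in any population is below 20X or above 150X (bounds inclusive on
the retained side, since the stated discards are strictly "less than" /
"greater than"), and require a minimum minor-allele frequency of 2%.  The
2% rule is read as a single pooled criterion across populations — it is
stated as one threshold "across all five populations" — with a
per-population mode available.  Watterson's theta uses the truncated
denominator `a(b, d) = sum_{i=b}^{d-b} 1/i` at uniform depth `d` (after
hypergeometric subsampling to 30X) with minimum minor count `b = 2`, and a
window is reported missing when fewer than 60% of its sites have sufficient
coverage.  Depth, not pool size, is used as the sample size in the
denominator — valid because pooled chromosomes greatly outnumber reads —
and theta is normalized per tracked site, not per base pair, so absolute
theta values are not comparable to genome-scan values from full
pileups.

## Summary statistics

Per-site F~ST~ is `(H_T - H_S)/H_T` with `H_T = 2 pbar qbar` from the
unweighted mean frequency across demes and `H_S` the mean within-deme
`2pq`; sites with `H_T = 0` are skipped, not scored zero.  Scenario means
("average heterozygosity / F~ST~ across all polymorphic sites") are taken
over sites polymorphic in the pooled metapopulation at the measured
generation; "polymorphic" genuinely underdetermines the site set, and the
alternatives (polymorphic at generation 0, or in any single deme) are
selectable — they shift means by roughly 0.01-0.02.  Spatial variance uses
50 kb windows for scenario grids and 100 kb for genome scans, both
exposed.  Replicate aggregation reports 95% intervals as the 2.5/97.5
percentiles of the replicate distribution.

The closed-form theory module implements `F_ST = 1 - (1 - 1/(2N))^t` for
pure drift (with `N` the diploid effective size, so `2N` gametes) and the
island-model equilibrium `F_ST = 1/(4Nm + 1)`, plus exact inversions for
`N` and `Nm`.  These are the classical Wright/Nei forms; as reference
points, they give `F_ST ~ 0.33` at `N = 1000, t = 800`, `N ~ 4,700` for
an observed `F_ST = 0.08` at `t = 785`, and `Nm = 2.875` for an
equilibrium `F_ST = 0.08`.  Note that the one-way replacement
migration implemented in the engine is not the classical two-way island
model, so simulated migration equilibria are compared to `1/(4Nm+1)` only
qualitatively.

## Problem sizes, determinism, and numerical choices

- Scenario grids default to 10^4 panel sites and ~20 replicates, versus
  the hundreds of thousands of SNPs and hundreds of runs of a full-scale
  study.  Summary means are site- and replicate-averages and converge
  quickly; these sizes are the package's desk-scale defaults and are
  freely configurable upward.
- Replicate seeds are `base_seed + replicate index`; the founder panel is
  generated once per scenario from the base seed, so the same founders
  underlie every replicate, as when a fixed line panel founds each run.
- Breakpoint draws exactly equal to an existing breakpoint, or duplicate
  crossover positions within a meiosis, occur with probability zero and
  are not specially handled beyond strict-inequality splits.
- Fixation is not a stopping condition; runs always complete `G`
  generations.  A deme whose fitness weights are all zero (possible only
  under selection) halts with a diagnostic rather than silently recycling.
- A gamete may be drawn as both parents of one offspring ("selfing" in
  gamete mode); disallowing it would change nothing detectable at
  realistic `N`, and the permissive convention keeps the draw order
  simple.  Diploid mode excludes selfing by redrawing.

## What passing tests do and do not show

The synthetic pipeline emulates drift, recombination, linked selection and
migration on one arm with exact final allele frequencies.  It does not
emulate: *de novo* mutation, background selection, two sexes with distinct
demography, overlapping generations, real inbred-panel haplotype
structure (LD, inversions, empirical frequency spectra), repeat masking,
or mapping artefacts.  Passing tests therefore validate the engine and
the statistics, not any claim about real evolved populations; analyses of
actual pool-seq data enter only through the sync/mpileup readers and the
SNP-table filters.  Reported theta from this package additionally differs
from PoPoolation-style estimates by the per-site normalization noted
above.
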