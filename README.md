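# ersim

Forward-time Wright–Fisher simulation and pool-seq summary statistics for
evolve-and-resequence (E&R) experiments on a single chromosome arm.

## Who this is for

Experimental evolution studies with outbreeding species (classically
*Drosophila melanogaster*) maintain replicate populations of moderate size
for hundreds of generations and then sequence pooled DNA from each
replicate.  Making sense of the observed genome-wide heterozygosity and
between-replicate differentiation requires simulated baselines: how much
variation drift alone leaves after `G` generations, and how directional
selection, overdominance, polygenic optimizing selection, or accidental
migration between replicates shift those quantities.  `ersim` provides
those baselines from synthetic inputs — no sequence data required.

## The core machinery

**Founder-segment engine.**  With no new mutation, every chromosome in
every generation is a mosaic of founder haplotypes.  A gamete is stored as
a founder-state vector `S` and a breakpoint vector `B` in Morgans — e.g.
`S = {3, 17, 31, 3}`, `B = {0.20, 0.25, 0.60}` — so the generation loop
never touches individual sites.  Each generation, per offspring slot `n`,
two parents are drawn with replacement (optionally fitness-weighted); even
slots draw `r ~ U(0,1)` and cross over at `r` iff `r < L` (map length in
Morgans; 0.63 for a 63 cM arm), halving the effective rate as in
female-only recombination.  Migration is one-way island replacement: `M`
times per generation a random gamete in the pooled `D × N` set is
overwritten by a copy of another.  Exact allele frequencies are projected
onto panel sites only at the end.

**Selection.**  Two frameworks: multiplicative per-locus fitness
(`w11 = 1`, `w12 = 1 + hs`, `w22 = 1 + s`; `h > 1` gives overdominance
with interior equilibrium `h/(2h−1)`) acting on diploids with fecundity
selection, and gamete-level Gaussian optimizing selection on a
quantitative trait: phenotype = QTL effects + polygenic deviate +
environmental deviate + polygenic mean, weight
`∝ exp(−(pheno − opt)²/(2·Vf))`, with the polygenic background tracking
the Breeder's equation `Δmean = h²_poly · S` each generation.

**Statistics and theory.**  Windowed heterozygosity, pooled Watterson θ
with the truncated denominator `a(b,d) = Σ_{i=b}^{d−b} 1/i`, per-site
`F_ST = (H_T − H_S)/H_T`, spatial (between-window) variances with
percentile confidence intervals over replicate runs, drift theory
`F_ST = 1 − (1 − 1/(2N))^t` and island-model equilibrium
`F_ST = 1/(4Nm + 1)` with exact inversions for `N` and `Nm`.

**Pool-seq I/O.**  Conversion of exact frequencies to read counts
(negative-binomial depth, sequencing error), SNP-table filters (20–150X
coverage, 2% pooled minor-allele frequency), hypergeometric subsampling to
uniform depth, and sync / mpileup readers and writers.

## Worked example

```r
library(ersim)

# a DGRP-like synthetic base population: 100 haplotypes, mean 2pq -> 0.32
panel <- generate_founder_panel(n_haplotypes = 100, n_sites = 5000,
                                target_het = 0.32, seed = 1)
panel
#> founder_panel: 100 haplotypes x 5000 sites; mean 2pq = 0.3155

# five replicate demes of 2000 gametes, 800 neutral generations
run <- run_simulation(panel, n_demes = 5, n_gametes = 2000,
                      generations = 800, seed = 2)
run
#> wf_run: 5 demes x 2000 gametes, 800 generations, M = 0 ;
#>   mean breakpoints/gamete = 254.1

summarize_freqs(run$freqs, panel$positions_bp)
#>    mean_het  mean_fst     var_het    var_fst n_polymorphic
#> 1 0.2193606 0.2636811 0.006264557 0.00471768          4770
```

After 800 generations of drift, mean heterozygosity at sites still
polymorphic in the metapopulation has fallen from 0.32 to ~0.22, and the
five initially identical demes have differentiated to a mean per-site
F_ST around 0.25 — one replicate of the neutral no-migration scenario row.
The closed-form calculators give the matching analytic reference points:

```r
predict_fst_drift(N = 1000, t = 800)   # 0.329747  (~0.33 expected under drift)
solve_N(fst = 0.08, t = 785)           # 4707.523  (size needed for F_ST 0.08)
solve_Nm(fst = 0.08)                   # 2.875     (migrants/generation for 0.08)
```

An observed F_ST far below the drift prediction is thus compatible either
with an effective size near 4,700 or with roughly three successful
migrants per generation at equilibrium.

Replicated scenario grids with selection and migration go through
`scenario_config()` / `run_scenario()`, which aggregate per-replicate
summaries into scenario rows with percentile confidence intervals, and
`export_sweepscan_inputs()` writes per-deme mpileup files for external
sweep-scan tools.

## Package layout

- `R/`, `src/` — founder panels and genetic maps, the compiled
  founder-segment engine (R-RNG-compatible, replayable in pure R),
  selection models, pool-seq I/O, summary statistics and theory, scenario
  drivers.
- `tests/testthat/` — unit, property and acceptance tests, including an
  explicit-haplotype oracle that must match the segment engine bit for
  bit on a shared RNG stream.
- `vignettes/founder-segment-simulation.Rmd` — the model, its
  assumptions, parameter meanings, and design decisions.
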