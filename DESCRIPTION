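Package: ersim
Title: Founder-Segment Wright-Fisher Simulation and Pool-Seq Summary
    Statistics for Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of laboratory evolution
    experiments on a single chromosome arm, tracking gametes as founder
    haplotype segments with recombination breakpoints rather than explicit
    sequences.  Supports neutral drift, per-locus directional and
    overdominant selection, quantitative-trait optimizing (Gaussian)
    selection with a Breeder's-equation polygenic background, and one-way
    island migration among replicate demes.  Includes a synthetic founder
    panel generator calibrated to a target mean heterozygosity, pool-seq
    read sampling with coverage and error models, sync/mpileup input and
    output, windowed heterozygosity and pooled Watterson theta estimators,
    per-site F_ST, and closed-form drift and island-model F_ST theory with
    inversions for effective size and migrant number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
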