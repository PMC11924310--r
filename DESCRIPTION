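Package: polartrait
Title: Thermal, Photoperiod and Nitrate-Uptake Reaction Norms and
    Convergent Amino Acid Substitutions in Arctic and Temperate Diatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative trait analysis of
    Arctic- and temperate-adapted diatoms. Extracts maximum specific
    growth rates from abundance time series with smoothing splines,
    fits four-parameter exponential-times-quadratic thermal performance
    curves with bootstrapped derived traits (optimum temperature,
    maximum growth rate, thermal breadth, activation energy), compares
    photoperiod reaction-norm shapes between origins with
    difference-smooth additive models, converts 15N tracer enrichment
    of particulate nitrogen into absolute and cell-normalized nitrate
    uptake rates and fits Michaelis-Menten kinetics, and screens
    habitat-labeled protein homolog clusters for convergent amino acid
    substitutions with candidate filters (additional-species support,
    metatranscriptome expression, conserved gapless context, and
    phylogenetically independent origins by gains-only parsimony).
    Includes deterministic synthetic-data generators with ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mgcv,
    ape,
    phangorn,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
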