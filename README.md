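# polartrait

Comparative trait analysis of Arctic- and temperate-adapted diatoms
(*Thalassiosira gravida* vs *T. rotula* and relatives): what functional
and genetic traits distinguish a polar from a temperate phytoplankton
population? The package implements the four quantitative stages of that
comparison as a tested, reusable pipeline, together with
synthetic-data generators with known ground truth so every stage can be
validated without access to the original culture experiments.

## What it computes

**Growth kinetics.** The maximum specific growth rate of each
experimental unit is extracted from its abundance time series (cell
counts or blank-corrected chlorophyll-a fluorescence) as the maximum
first derivative of a smoothing spline fitted to ln N(t) — the
log-linear part of the growth curve.

**Thermal performance curves.** Per-temperature growth rates are fitted
with the four-parameter exponential-times-quadratic curve

    mu(T) = a e^(bT) [1 − ((T − z) / (w/2))²]

which allows negative rates (mortality) beyond the thermal limits. From
the fit, restricted to the tested temperature range: the optimum
temperature T_opt, maximum rate mu_max, thermal breadth Tb80 (width of
the interval where mu ≥ 0.8 mu_max), and activation energy E_A (eV,
Arrhenius slope over the rising limb). Uncertainty by nonparametric
case-resampling bootstrap; origin contrasts by Welch *t* tests on
strain means.

**Photoperiod reaction norms.** Growth rates across photoperiods
(1–24 h light) are normalized within origin and compared with a
penalized-spline additive model in the reference-plus-deviation form:
a common smooth plus a difference smooth for the second origin, whose
approximate Wald p-value tests for a shape difference. Reaction-norm
curves and their optima are estimated per origin.

**Nitrate uptake kinetics.** ¹⁵N tracer enrichment of particulate
nitrogen is converted to absolute uptake via the mass-balance mixing
model V_abs = [(A_PN − A₀)/(A_src − A₀)] · PN/Δt, normalized by cell
density, and fitted with Michaelis–Menten kinetics
V = V_max S / (K_s + S).

**Convergent amino-acid substitutions (CAAS).** Habitat-labeled protein
homolog clusters (75% identity, single linkage) are trimmed
(gappyout-style), scanned for alignment columns where the Arctic and
temperate residue sets are disjoint and at least one side has converged
on a single residue, and filtered: support from species beyond the
focal pair, expression in both habitats' metatranscriptomes, an
otherwise gapless conserved context, and phylogenetically independent
origins counted by gains-only parsimony on the species tree.

## Worked example

```r
library(polartrait)

# thermal stage on a simulated gradient experiment
rates <- simulate_tpc_experiment(list(a = 0.5, b = 0.05, z = 10, w = 20),
                                 temperatures = seq(-2, 20, length.out = 8),
                                 replicates = 4, noise_sd = 0.03, seed = 7)
bootstrap_tpc(rates, n_boot = 300, seed = 1)
#> <tpc_fit>
#>   params: a=0.5246, b=0.04799, z=9.965, w=20.03
#>   t_opt=12.25 C  mu_max=0.895 /d  tb80=8.40 C  e_a=1.350 eV
#>   bootstrap: 300 resamples (0 failed)
#>     t_opt  95% CI [12.069, 12.415]
#>     ...
```

`t_opt` is where the fitted curve peaks inside the tested range (the
true curve here peaks at 12.36 °C — the exponential term shifts the
peak right of z), `tb80` the width of the ≥80%-of-maximum interval, and
the CIs come from refitting 300 row resamples.

```r
# substitution screen on a planted synthetic dataset
sim  <- simulate_caas_dataset(seed = 11)       # 10 clusters, 5 planted sites each
recs <- caas_screen(sim$clusters)
nrow(recs)                                     # 50 candidates...
#> [1] 50
all(paste(recs$cluster_id, recs$column_orig) %in%
    paste(sim$truth$cluster_id, sim$truth$column))  # ...all planted
#> [1] TRUE

# the packaged worked example: candidate table of the focal species pair
fx <- read_caas_candidates(example_candidate_table())
summarize_candidates(fx$records, fx$annotations)
#> <candidate_summary> 26 candidate IDs (12 annotated)
#>   specificity: arctic 22, temperate 3, both 1
#>   functional letters: G=1 I=3 J=1 K=3 L=2 Q=3 R=1 S=14
```

Of 26 candidate gene alignments, 22 carry an Arctic-specific
substitution, 3 a temperate-specific one and 1 both; 12 are
functionally annotated, of which the central-dogma categories (J, K, L)
cover 6 IDs and the metabolic categories (G, I, Q) cover 5.

A full simulated pipeline run: `run_pipeline(list(seed = 1, out_dir = "out"))`.

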