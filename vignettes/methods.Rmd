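---
title: "Models and methods behind the polar-trait pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the polar-trait pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical and
algorithmic choices: the models each stage fits, the assumptions they
make, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Growth-rate extraction

Each experimental unit (strain x condition x replicate) contributes one
abundance time series with daily sampling. `fit_growth_rate()` fits a
smoothing spline to ln N(t) and reports the maximum of its first
derivative over the observed interval as mu_max (per day) — the
steepest log-linear stretch of the growth curve, robust to lag and
stationary phases at either end. Choices that matter:

* **Smoothing penalty.** Generalized cross-validation by default
  (`spar = NULL` in `stats::smooth.spline`), overridable. Different
  penalties shift mu_max slightly on curved (logistic) series; on a
  noiseless exponential the estimate is exact.
* **Derivative grid.** The derivative is maximized on a 200-point grid
  over the observed time range — resolution far beyond daily sampling.
* **Short series.** A spline needs four points; three-point series
  (the minimum the container accepts) fall back to the ordinary
  least-squares log-linear slope.
* **Truncation.** None: experiments are assumed to end at the onset of
  stationary phase, so the full recorded series is used.
* **Blank correction** subtracts the mean medium blank from
  fluorescence readings; nonpositive corrected values carry no signal
  and are dropped, and a series with fewer than three usable points is
  an error rather than a fit.

## Thermal performance curves

`fit_tpc()` fits mu(T) = a e^(bT) [1 − ((T − z)/(w/2))²] by
Levenberg–Marquardt least squares. The form deliberately permits
negative rates, so mortality beyond the thermal limits informs the fit;
derived traits, however, are never extrapolated beyond the tested
temperature range.

* **Multi-start initialization.** z starts at the empirically best
  temperature; w at 1, 1.5 and 2.5 times the tested span; b over
  {0, 0.05, 0.1} per degree; a back-transformed from the maximum
  observed rate. The best converged start by residual sum of squares
  wins. A fitted w exceeding 20x the tested span is reported as
  unidentifiable, as is an all-constant rate table.
* **Derived traits.** T_opt by grid search (512 points) plus local
  refinement; Tb80 bounds by root bisection on mu(T) = 0.8 mu_max,
  clipped to the range edge (and flagged) when the curve does not fall
  below 80% inside the tested range — clipping understates the true
  breadth but honors the no-extrapolation rule. E_A is the Arrhenius
  slope of ln mu against −1/(k_B T_K) over tested temperatures below
  T_opt with positive fitted rate (k_B = 8.617e-5 eV/K). The literature
  derives activation energies from thermal curves in several
  non-equivalent ways; this rising-limb regression is the package's
  definition, exact on log-linear (pure Arrhenius) input, and E_A
  values from other definitions need not match it.
* **Bootstrap.** Nonparametric case resampling of (temperature, rate)
  rows, refit from the full-data estimate, percentile 2.5/97.5
  intervals; failed refits are dropped and counted, and more than 50%
  failures aborts. Resampling is *unstratified* by default: with only a
  few replicates per temperature, resampling within levels shrinks the
  resampling variance (each stratum of size n understates variance by
  (n−1)/n) and the intervals undercover; in our recovery experiments
  plain resampling restored nominal-level coverage of T_opt.
  `stratify = TRUE` remains available for designs with many replicates
  per level. The package's simulation experiments use n_boot = 300,
  above the enforced minimum of 200 and ample for 95% percentile
  endpoints at the precision the recovery checks need.
* **Origin contrasts.** Welch t tests (`stats::t.test`,
  unequal variances) on strain-level trait means, the unit of
  biological replication.

## Photoperiod reaction norms

Rates are first normalized within origin by the origin's maximum
(`normalize_rates()`), so the comparison concerns shape, not absolute
growth. `fit_difference_gam()` then fits the reference-plus-deviation
additive model

mu* ~ origin + s(photoperiod) + s_diff(photoperiod) * [origin = temperate]

with cubic regression splines, smoothness by REML, and the approximate
Wald p-value of the deviation smooth as the shape-difference test.

* **Family.** Growth rates are positive with multiplicative
  (proportional) error, so the default family is Gamma with log link.
  A Gaussian fit on such data is heteroscedastic and makes the
  difference-smooth test anti-conservative; with the Gamma family the
  test's null rejection rate sits at its nominal level in the
  acceptance suite's 200-replicate calibration. `family` is a
  parameter for users with homoscedastic data.
* **Basis dimension.** k = 5 per smooth by default and never more than
  the number of distinct photoperiods — with the canonical 5-level
  design (1, 4, 8, 16, 24 h light), 5 is also the maximum the data can
  support.
* **Curves and optima.** Fitted reaction norms and their optimum
  photoperiods are estimated from per-origin smooths on the response
  scale — the scale on which a reaction norm and its peak are defined.
  The log-link model is kept for the test only: near-peak curvature is
  distorted more on the log scale, which biases the argmax (on this
  design, even exact interpolation of noiseless level means locates a
  17 h peak at about 16.7 h on the response scale; the log scale is
  worse). With 5 support levels the optimum is resolvable only to a few
  tenths of an hour; `bootstrap_optimum_h()` propagates replicate and
  normalization uncertainty by case resampling and re-normalizing
  within each resample.

## Nitrate uptake kinetics

The mixing model converts tracer enrichment to absolute uptake:
A_PN from delta-15N via R = R_ref (delta/1000 + 1),
atom% = 100 R/(1+R) with R_ref = 0.0036764 (0.3663 atom% at delta 0);
then V_abs = [(A_PN − A0)/(A_src − A0)] PN/Delta-t. Defaults:
A0 = 0.3663 atom% (natural abundance) unless a measured t0 sample is
supplied; A_src from the two label-mixing regimes (1:1 labeled:
unlabeled nitrate up to 2 umol/L, 9:1 unlabeled:labeled above), a 98
atom% labeled stock, and 0.1 umol/L residual unlabeled nitrate
(`source_atom_percent()`). PN is the measured end-of-incubation pool;
the 40-minute incubation is treated as short enough for A_src to stay
constant (no isotope-dilution correction). Cell-normalized rates are
fitted with V = V_max S/(K_s + S) by Levenberg–Marquardt with V_max
initialized at the maximum observed rate and K_s at the interpolated
half-maximum substrate level; weights are uniform (no error model is
asserted for the analyzer), and CIs come from case bootstrap. A fitted
K_s outside the tested substrate range triggers a warning rather than
an error: the estimate is then an extrapolation of the saturating form.

## The convergent-substitution screen

Homolog clusters arrive aligned and habitat-labeled
(`taxon|source|habitat[|focal]` FASTA headers). The screen proceeds:

1. **Trimming** (`trim_alignment()`): a simplified gappyout — columns
   above the steepest-jump breakpoint of the sorted distinct column gap
   fractions are removed (fallback: a fixed cutoff, default 0.2, when
   all fractions are equal). A column map is kept so every reported
   position is also given in original alignment coordinates. All
   positions in this package are 1-based.
2. **Scanning** (`scan_caas()`): a column is a candidate when the
   arctic and temperate residue sets are disjoint and at least one is a
   singleton; specificity is arctic / temperate / both according to
   which side converged. Columns containing any gap are skipped by
   default (conservative); `allow_gaps = TRUE` treats gapped members as
   missing instead. Taxa absent from a column contribute no residues
   and never veto a record. Two discrimination patterns are recognized
   (singleton vs multiple, singleton vs singleton); rarer patterns are
   out of scope.
3. **Filters**: (i) *additional species* — each habitat must be
   represented beyond the focal pair at the site; (ii) *expression* —
   the cluster must contain metatranscriptome members from both
   habitats, evidence the variant is expressed in its native habitat;
   (iii) *conserved context* — every column within +/-5 of the site
   gap-free and mean flank diversity (distinct residues / members) at
   most 0.3; the window half-width and diversity ceiling are
   configurable since the original criterion ("an otherwise gapless
   conserved region") is qualitative, and these defaults automate it;
   a window running off the alignment edge fails with an edge flag;
   (iv) *independence* — the convergent residue must have at least 2
   independent origins on the species tree. Filters i–iii gate the
   candidate list; independence is reported as a flag (and enforced
   only on request), since a screen may legitimately keep singletons
   of uncertain phylogenetic depth for inspection.
4. **Origin counting** (`count_origins_fitch()`): gains-only (Dollo-
   style irreversible) parsimony on the binary target-vs-other
   recoding — losses forbidden, each 0-to-1 edge one origin, a root in
   the target state one origin. Reversible Fitch parsimony would let a
   root-state-1 reconstruction with losses masquerade as a single
   origin for clearly interleaved presence patterns; counting
   convergent *gains* is the question being asked. The count is exact
   (dynamic programming, polytomies allowed) and is checked in the
   test suite against exhaustive enumeration on small trees.
5. **Summary** (`summarize_candidates()`): positions collapse to
   alignment IDs; an ID with several positions counts once, with
   specificity "both" if its positions disagree or any is "both";
   functional-category letters tally per ID (an ID with several letters
   counts under each). IDs without an annotation are "function
   unknown".

Clustering itself (`cluster_homologs()`) is single-linkage at 75%
pairwise identity (identities / pairwise alignment length), with exact
global alignments under a simple +1/−1 scoring — at the scale of a few
hundred homologs exact pairwise alignment is affordable and avoids a
heuristic search graph.

## Synthetic data and what passing means

Every stage has a generator whose defaults are the study conditions the
analyses assume, with ground truth returned alongside:

* `simulate_growth_series()`: logistic trajectories, multiplicative
  lognormal noise (abundances are positive); daily sampling.
* `simulate_tpc_experiment()`: curve values plus additive Gaussian
  noise (rates may be negative), default design 8 temperatures x 4
  replicates, noise sd 0.03/day — a realistic replicate scatter for
  microscopy-derived rates.
* `simulate_uptake_assay()`: true Michaelis–Menten uptake pushed
  backwards through the mixing model to the delta-15N the analyzer
  would report; multiplicative noise on delta-15N (cv 0.02); the seven
  canonical substrate levels 0.1–100 umol/L.
* `simulate_photoperiod_table()`: a saturating arctic truth curve and a
  temperate truth curve peaking at 17 h with decline under continuous
  light; lognormal noise, cv 0.05.
* `simulate_caas_dataset()`: neutral evolution on a 10-taxon species
  tree whose habitats interleave across clades (so planted residues
  have multiple independent origins), uniform 20-residue substitution
  kernel at 0.02 per branch per column; planted columns fixed for one
  arctic residue with a disjoint temperate set; planted flanks kept
  substitution- and gap-free so the conserved-context filter is tested
  against unambiguous truth; ~3% of remaining columns heavily gapped to
  exercise trimming. A realistic exchangeability matrix is deliberately
  not used: the scan is a presence/absence discrimination rule, and a
  uniform kernel tests it no less sharply.

All generators are deterministic in their seed, to the byte on
serialized output. The replicate-level noise magnitudes are calibration
choices of this package — the original experiments report none — so
recovery rates on synthetic data validate the machinery, not the
instruments. Passing these tests shows the estimators recover known
truth under the stated noise; it does not show the noise model matches
any particular lab's data, and real fluorescence drift, alignment
error, or assembly chimerism are outside what the generators emulate.

Problem sizes used by the simulation experiments (the package's chosen
trade-off between resolution and runtime): 20 datasets of 10 clusters x
300 columns for screen recovery; 50 experiments x 300 bootstrap
resamples for T_opt coverage; 200 null and 40 alternative replicates
for the shape test's calibration and power; 50 assays for
Michaelis–Menten recovery.

## Known limitations

* E_A depends on the chosen limb definition (above); comparisons with
  values derived differently are qualitative.
* Tb80 clipping at the tested range biases breadth downward for curves
  whose 80% interval extends beyond the gradient.
* The difference-smooth p-value is an approximate Wald test; its
  calibration is verified by simulation at the package's default noise
  model, not proven analytically.
* The screen's discrimination rule ignores within-habitat frequency:
  one aberrant sequence in the variable habitat cannot block a record,
  but one in the converged habitat can. That asymmetry is inherent to
  the fixed-residue definition of a convergent substitution.
* With single-linkage clustering, one promiscuous sequence can chain
  otherwise distinct families; the 75% threshold makes this rare but
  not impossible.
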