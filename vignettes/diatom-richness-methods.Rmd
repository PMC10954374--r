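---
title: "Methods: latitudinal diatom richness, metacommunity structure and the model suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal diatom richness, metacommunity structure and the model suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomLDG)
```

# The scientific problem

Benthic stream diatoms are one of the taxon groups that do not reliably
follow the latitudinal diversity gradient (richness increasing toward the
Equator). Along the temperate western margin of South America (roughly 52°S
to 35°S), competing explanations for per-site diatom richness include plain
spatial structure, climate-based theories (species–energy, energy
variability, climatic tolerance, metabolic theory), water physicochemistry,
glaciation history, and niche dimensionality measured as the number of
limiting resources. This package implements the full comparison as a
reusable pipeline: predictor construction, effort-standardized richness per
latitudinal band, a twelve-equation additive-model suite, and an Elements
of Metacommunity Structure (EMS) analysis that asks whether the regional
community is Nested (as a glaciation-recolonization history would predict),
Gleasonian, or Clementsian.

Throughout the package latitude is stored as signed decimal degrees with
south negative, so "increases with latitude" literally means "increases
northward". That makes the sign conventions of correlation output match the
way the field states them.

# Predictor construction

**Number of limiting resources (NLR).** For each of Ca, TP, SiO2 and
electrical conductivity (a proxy of basic cations), a site scores 2 if its
value lies below the variable's 0.33 sample quantile, 1 between the 0.33
and 0.66 quantiles, and 0 above; NLR is the sum, a rank from 0 (no
limitation) to 8 (strong limitation). Two details are underdetermined by
the verbal definition and are fixed (and configurable) here: the quantile
estimator is the standard linear-interpolation sample quantile (type 7),
and the middle score is awarded on the *closed* interval [q33, q66].
Quantiles are computed over exactly the sites being scored — the
chemistry-complete subset — because the rank is only defined where
chemistry exists. Because the score depends on ranks only, NLR is invariant
under strictly monotone transforms of any resource variable, which the test
suite checks.

**Glaciation exposure.** The ice-history table gives binary ice presence at
nine reconstruction timestamps (35, 30, 25, 20, 15, 13, 10, 5, 0.2 ka).
The exposure index is `Glac = 1 - t_last/35`, where `t_last` is the most
recent timestamp with ice, and 0 for never-glaciated sites. The defining
arithmetic is anchored to the worked example (last ice at 10 ka gives
1 − 10/35 = 0.714) rather than to a literal reading of "dividing by 35 and
subtracting 1", which would produce a negative number; the example and the
stated range [0, 0.714] are mutually consistent and win. `Fglac` is ice
presence at the Last Glacial Maximum; no single reconstruction layer is
canonically "the" LGM, so the package defaults to the 20 ka layer (the
closest) and exposes the choice.

**Detection limits.** Values below a detection limit are replaced inside
(0, DL), by DL/2 (deterministic default) or by a uniform draw (seeded).

**Latitudinal bands.** The original banding was partly manual and is
therefore not exactly reproducible by construction; the package replaces it
with a deterministic rule: sort sites by latitude; split at gaps wider than
`isolation_gap` (default 1°), so that a far-southern handful of sites forms
its own band regardless of size; partition each contiguous segment into
`round(n/12)` consecutive bands of near-equal size; optionally merge bands
narrower than a minimum extension. On study-shaped data this yields band
sizes within 9–18 plus the small isolated terminal band, which is the
qualitative shape of the original banding.

# Effort-standardized band richness

Band richness is the union of member-site species lists. Because bands
contain different numbers of sites, estimates are standardized to a common
number of sampling units using incidence frequencies: analytic rarefaction
`E[S(m)] = Σ_i (1 − C(T−Y_i, m)/C(T, m))` below the observed effort, and
Chao-type extrapolation
`S(T+m*) = S_obs + Q0·(1 − (1 − Q1/(Q1 + T·Q0))^{m*})` above it, with
`Q0 = ((T−1)/T)·Q1²/(2Q2)` (or the `Q1(Q1−1)/2` fallback when there are no
duplicates). The rarefaction formula is the exact mean over all site
subsets, which the tests verify by exhaustive enumeration up to T = 12.
The common size defaults to the largest band (pure extrapolation for the
rest). Confidence intervals are percentile bootstrap over sites within a
band (default 200 replicates, seeded); the incidence-based analytic
variance is not implemented because no published form was being matched.
A single-site band carries no frequency information, so its estimate stays
at observed richness. Coverage-based standardization and Hill numbers
beyond richness are out of scope.

# Elements of Metacommunity Structure

The incidence matrix (singletons removed — a species seen once carries no
range information) is ordinated by reciprocal averaging: iterate "site
score = mean of its species' scores; species score = mean of its sites'
scores", re-centering and rescaling with margin weights each pass. The
fixed point is the first non-trivial correspondence-analysis axis, which
the tests confirm against a direct eigen-decomposition to 1e-8 on small
matrices. Scores are normalized to weighted mean 0 / variance 1, with the
global sign fixed by a lexicographic rule on the extreme sites and ties
broken by original index, making the ordering fully deterministic. When the
first two axes are nearly tied the score iteration can crawl; since every
downstream statistic uses only the *ordering*, the iteration also stops
once the ordering has been stable for 100 consecutive passes.

Three statistics are computed on the reordered matrix:

* **Coherence** — embedded absences: zeros strictly inside a species'
  range over ordered sites, plus (by default) the analogous count within
  each site over ordered species. The counting mode (`columns`, `rows`,
  `both`) is a flag because the literature is not unanimous; `both` is the
  default convention here.
* **Turnover** — on the range-filled matrix, each species pair contributes
  `D_i · D_j`, its count of opposing presence/absence sites.
* **Boundary clumping** — Morisita's index over the per-site counts of
  range endpoints, `I = T·Σ n_i(n_i−1)/(N(N−1))`, with a chi-square test
  against uniform edge placement.

The null model is the fixed–fixed swap: propose a uniform random (row
pair, column pair) and swap when it forms a 2×2 checkerboard. Because the
proposal is symmetric and swaps are involutions, the chain's stationary
distribution is uniform over the set of matrices with the observed margins;
the tests verify both margin preservation on every emission and long-run
uniformity against an exhaustively enumerated fixed-margin set. Defaults:
30,000 proposal attempts of burn-in and 1,000 between emissions, chosen for
mixing on matrices of a few hundred sites by a few hundred species and
exposed as arguments. Null matrices are re-ordinated before their
statistics are computed (flag to skip for speed). z-scores use the normal
approximation with two-tailed p, and the Presley decision tree turns the
three outcomes into a structure label, including the Quasi- variants so the
classifier is total.

**Degenerate nulls.** A perfectly nested matrix — every community a subset
of every richer one — is the *unique* binary matrix with its margins: no
2×2 checkerboard exists, so the swap chain cannot move and no fixed-margin
null test is possible. The package detects this case exactly (exhaustive
checkerboard scan), verifies the chain-of-subsets property directly, and
labels the matrix "Nested (perfect)" with `degenerate_null = TRUE`. This is
the package's own resolution of a real boundary case: perfect nestedness is
directly observable and needs no test, while imperfectly nested empirical
matrices always admit swaps and take the ordinary route.

# The additive-model suite

All twelve equations are penalized-spline additive models: cubic regression
splines with 10 basis functions per smooth, REML smoothing-parameter
estimation, and a null-space shrinkage penalty so that uninformative terms
shrink toward zero effective degrees of freedom instead of being manually
dropped. `Glac`, `NLR` and the binary `Fglac` enter linearly (their low
numerical variability breaks spline bases; the code detects insufficient
unique values and degrades any such term to linear automatically). The
metabolic-theory equation is special: log richness against the unsmoothed
inverse thermal energy `1/(kT)` (k = 8.617×10⁻⁵ eV/K, temperature in
kelvin), zero-richness sites excluded, and its AIC flagged non-comparable
because the response is transformed. The response family defaults to
gaussian on untransformed richness — deviance explained then matches the
familiar R²-style quantity — with poisson available since richness is a
count. Significance is reported at p < .05; the best set is every
comparable model within 2 AIC units of the minimum.

Numerical calibration, checked by simulation in the tests: a smoothed term
on linear data recovers the slope within 5% with edf near 1; a pure-noise
smoothed term is significant at about the nominal 5% rate (the shrinkage
test is conservative, so the observed rate sits at or below that); and the
metabolic-theory regression recovers a known activation energy within two
standard errors. One stated property was weakened deliberately: with REML
plus the null-space penalty, a pure-noise term's edf falls below 0.5 in
roughly 65–85% of simulations at n = 300 (not ≥ 90%); the test suite
asserts the median below 0.5 and shrinkage relative to the unpenalized
fit, which is what the penalty actually guarantees in practice.

# The synthetic-data generator

The generator's defaults are the study conditions: 373 sites uniform over
52°S–35°S, a 182-site chemistry subset, climate variables and SiO2/pH
linear in latitude (increasing northward) with independent gaussian noise,
flow velocity and oxygen saturation latitude-independent, and elevation and
longitude positively associated with latitude. The slope and noise values
themselves are conventions — no distributional description of the real
covariates is published — chosen once to give temperate-stream magnitudes
(e.g. annual means around 9 ± 2 °C spanning the gradient, SiO2 of a few
to tens of mg/L) and documented in the code.

Community matrices realize the idealized structures: Gaussian-response
occupancy windows along the latitude gradient with independent optima
(gleasonian) or optima clustered into compartments (clementsian); prefix
subsets of a fixed species ranking along a richness gradient (nested);
Bernoulli occupancy (random); and mutually exclusive species pairs
(checkerboard). Counts are 1 + Poisson, and total cell density is
log-normal with mean increasing in realized richness, reproducing the
positive richness–density association without asserting a direction of
causality. Ice histories put ice south of −38° with deglaciation age
increasing northward, so Glac correlates negatively with latitude as in the
real system.

What the generator does *not* emulate: river-network topology, spatial
autocorrelation beyond the latitude trend, abundance dynamics, detection
error, or imperfect nestedness. Passing recovery tests therefore shows the
pipeline identifies these idealized structures correctly at realistic
sizes, not that any particular real dataset will classify the same way.
Note also that idealized gleasonian simulations on a bounded gradient often
show significantly clumped boundaries (window edges pile up near the
gradient ends and compartment-free optima still collide), so
gleasonian-generated matrices can legitimately classify as Clementsian;
recovery guarantees are asserted only for the clementsian, nested and
random generators.

# Problem sizes and reproducibility

The analysis scripts run the study-scale configuration (373 × 150,
1000 null matrices); the test suite exercises the same code at smaller
sizes chosen as sensible defaults for simulation-based checks (60 sites ×
40 species, 200 null matrices, 20 seeds for recovery rates; 100 replicates
for significance calibration). Every stochastic step takes an explicit
seed and records it in its output; identical configuration plus seed gives
byte-identical report bundles, which the suite asserts by writing the
bundle twice.

# Known limitations

* The original study's exact bands, deviance/AIC table and EMS statistics
  depend respectively on manual banding, unstated fitting internals, and
  its raw data; they are treated as qualitative calibration, with the
  published EMS statistics shipped as reference constants
  (`ems_published_benchmarks()`) for users who obtain the original data.
* The swap null is the only null model implemented (the conservative
  choice); equiprobable and proportional nulls are out of scope.
* The chi-square test behind boundary clumping uses expected counts N/T,
  which can be small on narrow matrices; its p-values are then approximate.
* Normal-approximation z tests for coherence/turnover inherit the usual
  small-`n_sim` error; 1000 simulations is the working default.
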