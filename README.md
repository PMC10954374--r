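# diatomLDG

Biogeographical analysis of stream-diatom species richness along the
temperate latitudinal gradient of southwestern South America (52°S–35°S),
packaged as a tested, reusable pipeline. Benthic diatoms are a group for
which the classical latitudinal diversity gradient keeps failing, and the
competing explanations span spatial phenomenology, climate-based theory,
water chemistry, glaciation history, and niche dimensionality. The package
is written for community ecologists who want to run — or stress-test — that
whole comparison on their own site/community tables, or on synthetic data
with known structure.

## What it computes

**Predictors.** The number of limiting resources
`NLR = Σ_v score_v`, where each of Ca, TP, SiO₂ and conductivity scores
2/1/0 by position below/between/above its 0.33 and 0.66 sample quantiles
(a 0–8 rank; 8 = strongly limited). The glaciation-exposure index
`Glac = 1 − t_last/35` from nine-timestamp ice-history tables (35–0.2 ka),
the Last-Glacial-Maximum indicator `Fglac`, detection-limit substitution,
and deterministic latitudinal bands of ~12 sites with isolation-gap
handling.

**Effort-standardized richness.** Incidence-based rarefaction
`E[S(m)] = Σ_i (1 − C(T−Y_i, m)/C(T, m))` and Chao-type extrapolation
`S(T+m*) = S_obs + Q̂₀ (1 − (1 − Q1/(Q1 + T·Q̂₀))^{m*})`,
`Q̂₀ = ((T−1)/T)·Q1²/(2Q2)`, with percentile-bootstrap intervals per band.

**Metacommunity structure.** A from-scratch Elements of Metacommunity
Structure analysis: reciprocal-averaging ordination, embedded-absence
coherence, pairwise turnover on range-filled matrices, Morisita boundary
clumping, a fixed–fixed swap null model (uniform over the fixed-margin set;
implemented in C++), and the Presley decision tree
(Checkerboard / Random / Nested / Clementsian / Gleasonian / Evenly spaced,
plus Quasi- variants).

**Model suite.** Twelve competing richness equations fitted as penalized
additive models (cubic regression splines, REML, null-space shrinkage so
uninformative terms drop toward 0 edf), including the metabolic-theory
regression `ln S ~ 1/(kT)` with Boltzmann's constant in eV/K; deviance
explained, AIC, and the ΔAIC < 2 best-set rule; pairwise Pearson
correlation matrix with significance stars.

**Synthetic data.** A generator that emulates the study design (373 sites,
182-site chemistry subset, northward climate/SiO₂/pH trends, spatially
unstructured flow velocity and oxygen saturation) and produces community
matrices with controllable clementsian / gleasonian / nested / random /
checkerboard structure, so every stage is testable end to end.

## Worked example

```r
library(diatomLDG)

d <- simulate_dataset(sim_config(n_sites = 120, n_species = 60,
                                 structure = "clementsian", seed = 42))
d
#> Synthetic diatom dataset: 120 sites, 60 species
#>   structure: clementsian | latitude: -52.0 to -35.2 | chemical subset: 59 sites

fit <- latitude_richness_gam(d$sites, "site")
sprintf("latitude GAM: edf = %.2f, F = %.2f, p = %.3g", fit$edf, fit$F, fit$p)
#> "latitude GAM: edf = 7.99, F = 30.02, p = 0"

ems_analysis(d$community, n_sim = 200, seed = 42)
#> Elements of Metacommunity Structure
#>   matrix: 120 sites x 60 species (after singleton removal)
#>   coherence: embAbs = 49, z = -105.61, p = 0
#>   turnover:  1,575,390, z = 193.64, p = 0
#>   clumping:  Morisita = 5.48, p = 1.875e-74
#>   structure: Clementsian
```

Reading the output: richness responds strongly (and non-linearly) to
latitude; the community matrix has far fewer embedded absences than its
fixed-margin nulls (coherent), species replace each other along the
gradient more than expected (positive turnover), and range boundaries
co-occur (Morisita > 1) — jointly a Clementsian, compartmented
metacommunity, which is exactly the structure this simulation was
configured to produce.

The full study-scale workflow lives in `analysis/01_simulate.R` through
`analysis/05_metacommunity.R`; each stage is a thin driver over the
package functions and writes its tables under `results/`.
`run_pipeline()` executes the same sequence programmatically on simulated
or CSV inputs.

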