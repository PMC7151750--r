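# reefdiv

Trait-based functional-diversity monitoring of reef fish communities.

Long-term underwater visual-census programs in multi-use marine
protected areas need more than species counts to tell whether
protection is working: two assemblages with the same richness can
support very different ecological processes. `reefdiv` implements a
complete, tested pipeline from raw census records to mixed-model
inference on both traditional metrics (species richness, density,
biomass) and trait-based functional metrics, together with a synthetic
survey generator with known ground truth so every stage can be
verified end to end.

## What it computes

**Survey processing.** Censuses done at the same site, day, and depth
stratum are merged into transects when separated by less than 200 m
(single-linkage closure over the proximity graph), with counts summed
and densities re-expressed per 100 m². Biomass comes from the
allometric length-weight relationship *W = a·L^b* applied at the 5-cm
size-class midpoint. Sampling adequacy is checked with randomized
species-accumulation curves and a one-way ANOVA of richness across
transect-area groups (Tukey HSD post hoc).

**Functional space.** Each species carries six categorical traits
(maximum body size, mobility, period of activity, gregariousness,
position in the water column, diet); species identical in all six form
one functional entity. Pairwise Gower dissimilarity (equal trait
weights, ordinal traits scored by equally spaced ranks) feeds a
principal coordinates analysis; negative eigenvalues are handled by a
square-root transform by default (Cailliez and Lingoes corrections are
available), and the number of retained axes *m* is chosen from a mean
squared-deviation quality profile, with an explicit override
(`axes = 4`) for monitoring configurations that fix it.

**Per-transect indices** (the eight monitored responses):

- species richness, total density, total biomass;
- **FRic** — functional richness: the convex-hull volume of the
  species present in the *m*-dimensional trait space, as a proportion
  of the full species pool's hull volume;
- **FDis** — functional dispersion: weighted mean distance to the
  weighted community centroid, normalized by half the pool's maximum
  pairwise distance, `FDis = (Σ wᵢ‖xᵢ − c‖ / Σ wᵢ) / (D_max/2)`;
- **FOri** — functional originality (inverse redundancy): weighted
  mean nearest-neighbor distance among the species present, normalized
  by the pool's maximum nearest-neighbor distance.

FDis and FOri are computed twice, weighted by density and by biomass.
The hull volume is computed by an exact incremental (beneath-beyond)
convex-hull construction in arbitrary dimension, verified in the test
suite against brute-force enumeration oracles.

**Inference.** Linear mixed models (Satterthwaite df via `lmerTest`)
compare each index across the three management-zone types (no-take,
traditional, sustainable; year, season, site as random intercepts) and
estimate 13-year temporal trends (site and season random; density and
biomass log2-transformed), converted to percent change over the span:
`%Δ = (2^(b·span) − 1)·100` for log2 responses. Common species
(present in ≥50% of transects) are classified as winners or losers per
metric with GLMMs — binomial for occurrence, negative binomial
(`glmmTMB`) for integer-rounded density and biomass — with automated
binned-residual validation and overdispersion reporting. A dedicated
model tracks the summed biomass of commercially targeted species.

## Worked example

Simulate a reduced monitoring design (6 sites, 7 years, 30 species,
6 of them declining 6 %/year) and run the full analysis:

```r
library(reefdiv)
cfg <- sim_config(seed = 42, n_species = 30, years = 2010:2016,
                  sites = default_sites()[c(1, 2, 5, 6, 8, 9), ],
                  censuses_per_visit = 3, baseline_mean = log(2),
                  baseline_sd = 1, year_slope = c(rep(log(0.94), 6), rep(0, 24)))
report <- run_pipeline(config = cfg, seed = 1, axes = 3)
print(report)
```

```
Monitoring analysis report
  transects: 84  species pool: 30  axes: 3 
  temporal percent changes over 6 years:
    species_richness   -1.8%  (p = 0.538)
    density_total      +5.0%  (p = 0.535)
    biomass_total     -14.6%  (p = 0.214)
    FRic               -4.6%  (p = 0.294)
    FDis_density       -7.3%  (p = 0.104)
    FDis_biomass       -8.0%  (p = 0.317)
    FOri_density       -3.1%  (p = 0.463)
    FOri_biomass       -9.9%  (p = 0.26)
  common species: 25 
    biomass    winners 0, losers 0, stable 21, excluded 4
    density    winners 0, losers 1, stable 23, excluded 1
    occurrence winners 0, losers 1, stable 20, excluded 4
```

Each line is a fitted mixed-model trend: the percent change of that
index over the simulated span with its Satterthwaite p-value; the
winner/loser block counts common species with significantly
increasing/decreasing occurrence, density, or biomass ("excluded" are
species whose model did not converge or failed validation). At this
small problem size and noise level the injected decline is visible but
not significant — the full 11-site, 13-year design has the power to
resolve such effects (see the vignette). Individual stages are
available as `report$survey`, `report$space`, `report$indices`,
`report$temporal_trends`, `report$winners_losers`, and
`write_report(report, dir)` persists everything as tidy CSV plus a
JSON manifest.

```r
print(report$temporal_trends$species_richness)
#> Trend for species_richness (none): b = -0.06845 per year [-0.2856, 0.1487], p = 0.538
#>   change over 6 years: -1.8% (CI -7.4% to +3.8%)
```

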