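---
title: "Methods: trait-based functional diversity monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based functional diversity monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiv)
```

This vignette documents the models behind `reefdiv`, the choices made
where several defensible conventions exist, and what the synthetic
surveys do and do not establish about real monitoring data.

## The monitoring problem

The package targets long-term visual-census monitoring of reef fish in
a zoned marine protected area: fixed sites surveyed repeatedly across
years and seasons, divers recording every fish by species, count, and
5-cm size class over a known transect area. Two questions drive the
analysis: whether community metrics differ between management-zone
types (no-take versus zones with regulated fishing), and how they
change through time — both for classical metrics and for trait-based
functional metrics that track the diversity of ecological roles rather
than of names.

## From censuses to transects

Replicate censuses are often laid close together on the same reef on
the same day. To consolidate replicates, censuses sharing site, date,
and depth stratum are merged when separated by less than a threshold
distance (default 200 m, the scale below which adjacent reef census
strips sample the same assemblage patch). Proximity is chained by
single linkage: if A–B and B–C are below the threshold, all three
merge even when A–C is not. Single linkage is the minimal closure
consistent with a pairwise rule — any finer grouping would depend on
presentation order — and each merge is recorded in a grouping log for
audit. Location input is, in order of precedence: a pre-assigned group
column, an explicit pairwise distance table, or planar x/y coordinates
(planar distances suffice at sub-kilometre scales).

Merged counts are summed and standardized to individuals per 100 m² of
combined area, so transects of different sizes are comparable. Weight
is obtained from the species' length-weight relationship $W = aL^b$
($L$ in cm, $W$ in g) evaluated at the size-class midpoint; for
schooling fish recorded at a modal size this treats every individual
in a school row as having that modal length, and no within-school size
spread is modeled. Records dated July or December are rejected: the
monitoring calendar defines a cold season (January–June) and a warm
season (August–November), and a record between seasons has no valid
seasonal stratum.

Two sampling-adequacy checks mirror standard practice: randomized
species-accumulation curves (`vegan::specaccum`, permutation method,
seeded for reproducibility) and a one-way ANOVA of species richness
across transect-area groups with Tukey HSD contrasts, which flags
whether the spread of aggregated areas biases richness comparisons.

## The functional space

Six categorical traits describe each species: maximum body size (six
ordered bins from 0–7 cm to >80 cm), mobility (low/medium/high),
period of activity (diurnal/nocturnal), gregariousness (solitary to
large groups), position in the water column (benthic to pelagic), and
diet (six classes). Species identical in all six form one *functional
entity* and are interchangeable under this trait scheme — they receive
identical coordinates, and their hull contribution deduplicates.

**Gower dissimilarity.** Traits get equal weight: $d_{ij} =
\frac{1}{6}\sum_k \delta_k(i,j)$, with $\delta = \mathbb{1}[x_i \neq
x_j]$ for nominal traits and $\delta = |r_i - r_j|$ for ordinal traits
scored by equally spaced ranks $0, 1/(L-1), \dots, 1$ over the *full
level vocabulary*. Scoring over the vocabulary rather than the
observed range keeps dissimilarities stable when a rare level is
absent from a particular species pool; the alternative of scoring the
body-size trait by bin midpoints (which stretches the upper bins) is
available via `size_scores = "midpoint"`. $d_{ij} = 0$ exactly for
species sharing an entity and $d_{ij} = 1$ for species differing
maximally in every trait.

**Ordination.** Principal coordinates analysis embeds the species in
Euclidean axes. A Gower matrix on categorical data is generally
non-Euclidean, so negative eigenvalues appear; the default handling
embeds the square root of the dissimilarities, which is
Euclidean-embeddable for Gower, keeps the rank order of distances, and
needs no data-dependent additive constant. Cailliez and Lingoes
corrections and a plain drop-negative-axes mode are available, and the
correction actually applied is recorded on the object (a correction is
only applied when negative eigenvalues exceed a $10^{-8}$ relative
tolerance).

**How many axes.** Quality profiles are computed for $m = 1, 2,
\dots$: the mean squared deviation (mSD) between the species-pair
distances in the first $m$ axes and a reference. Two conventions are
reported because they answer different questions:

- `msd` rescales the $m$-dimensional distances so their maximum
  matches the maximum input dissimilarity and compares against the
  raw Gower input. This profile usually has an interior minimum —
  adding near-noise axes inflates the rescaled large distances — and
  that minimum (capped at `max_m`, default 6) is the automatic choice
  of `chosen_m`.
- `msd_corrected` compares, without rescaling, against the distances
  over *all* positive axes, i.e. the dissimilarities the ordination
  actually embeds. Distances in nested subspaces grow monotonically
  toward the full embedding, so this profile is non-increasing by
  construction and reaches zero at full rank; it is the profile for
  which "more axes never fit worse" is a theorem rather than a hope,
  and the one asserted in the test suite.

The choice was genuinely open: the max-rescaled profile is the common
convention but is *not* monotone (small increases of order $10^{-3}$
appear on most random trait tables), so treating monotonicity as a
property of that convention would be wrong. Monitoring configurations
that fix the dimensionality for comparability across years should pass
`axes = 4` (or whatever their protocol states) — the profile is still
computed and stored, so the override remains auditable.

## The three functional indices

All indices use Euclidean distances in the chosen $m$ axes, with no
eigenvalue re-weighting, and are normalized by pool-level constants
computed once per space (`pool_constants()`): the pool hull volume,
the maximum pairwise distance $D_{max}$, and the maximum
nearest-neighbor distance $O_{max}$.

**FRic** is the convex-hull volume of the species present divided by
the pool hull volume — the fraction of the pool's trait-space range
realized in a transect. The hull volume is computed exactly by an
incremental beneath-beyond construction (initial full-dimensional
simplex; each added point replaces its visible facets with the cone
over the horizon ridges), with a visibility tolerance of $10^{-9}$
relative to the configuration diameter. The test suite checks it to
$10^{-10}$ against independent brute-force oracles (shoelace in 2-D,
recursive facet enumeration in 3-D/4-D).

**FDis** is the weighted mean distance to the weighted centroid,
divided by $D_{max}/2$; **FOri** the weighted mean nearest-neighbor
distance among the species present, divided by $O_{max}$. Weights are
the species' density or biomass; both indices are invariant to weight
rescaling, and both are 0 (flagged) for single-species transects.
Nearest-neighbor ties need no tie-break: only the minimum distance
value enters. One caveat discovered in testing: FDis is bounded by ~1,
but FOri is *not* — in a species-poor transect whose members' trait
neighbors are all absent, within-transect nearest-neighbor distances
can exceed every pool-wide nearest-neighbor distance, so FOri slightly
above 1 is legitimate and is left uncapped.

**Degenerate transects.** A transect with fewer than $m+1$ distinct
coordinate points (or an affinely degenerate configuration) encloses
no $m$-volume. Its FRic is reported as 0 with flag
`insufficient-dimensionality` rather than silently recomputed in a
lower dimension: a ratio of volumes taken in different dimensions is
not comparable across transects, and the flag lets the analyst decide
whether to drop or re-run the whole table at smaller `axes` (the
comparable alternative to per-transect dimension switching).

## Mixed models

Year enters temporal models as a numeric covariate centered on the
midpoint of the span (numerical stability; slopes are per calendar
year). The eight monitored indices are species richness, total
density, total biomass, FRic, and FDis/FOri under both weightings;
density and biomass are log2-transformed before Gaussian fits.

- **Zone comparison:** `index ~ zone + (1|year) + (1|season) +
  (1|site)`, F test of the zone factor with Satterthwaite degrees of
  freedom, per-zone adjusted means via `emmeans`. Year is a *random*
  intercept here because the comparison should hold regardless of the
  temporal trajectory.
- **Temporal trend:** `index ~ year + (1|site) + (1|season)`, with
  the site intercept absorbing the repeated-measures structure of
  fixed sites. The percent change over a span of $s$ years is
  $(2^{bs}-1) \times 100$ for log2 responses (confidence limits
  transformed the same way — Wald on the model scale, the simplest
  defensible choice; profile or bootstrap intervals could replace it
  but change nothing structurally), and $100\,b\,s/\hat y_{t_0}$
  relative to the fitted first-year value for untransformed responses.
- **Commercial biomass:** the summed biomass of the commercially
  targeted subset, log2, same temporal model. Transects with zero
  commercial biomass carry no log-scale information and are dropped
  with their count reported.
- **Winners and losers:** species present in at least half the
  transects (boundary inclusive) are tested per metric: binomial GLMM
  for occurrence; negative-binomial GLMM for density and biomass on
  integer-rounded per-100 m² values (base R's round-half-to-even).
  A species is a winner/loser on a metric when its year effect is
  significant at $\alpha = 0.05$ with the corresponding sign. No
  multiple-testing correction is applied across species × metrics by
  default (each species' trend is reported as its own hypothesis);
  `p.adjust` can be applied downstream by the analyst.

Model hygiene: a response with zero variance is returned as a flagged
degenerate result (slope 0) instead of a crash; random-effect terms
whose grouping factor has a single level in the data are dropped and
recorded; non-convergent or separation-affected species models are
marked *not classifiable* and excluded from winner/loser counts;
binomial fits are additionally screened by an automated binned-residual
check (10 quantile bins of fitted probability; at least 80% of bins
must have mean residual within ±2 SE). That check is a deliberately
crude stand-in for visual binned-plot inspection and is documented as
such. For the negative-binomial fits the overdispersion ratio is
reported as Pearson $\chi^2$ over residual degrees of freedom.

Gaussian LMMs are fit with `lmerTest` (Satterthwaite df); the
binomial/negative-binomial GLMMs use `glmmTMB`, whose ML fits are fast
and robust for the hundreds of per-species models a full winner/loser
table requires.

## The synthetic survey generator

`sim_config()` / `generate_surveys()` emulate the monitoring design
the pipeline expects, with every parameter explicit and a mandatory
seed:

- 11 fixed sites (4 no-take, 3 traditional, 4 sustainable), years
  2005–2017, one cold-season and one warm-season visit per year;
- 4–8 censuses per visit, 100 m² before the 2009 methodology change
  and 60 m² after, positioned so that within-visit clusters merge
  under the 200-m rule (a visit splits into two clusters with
  probability 0.15), yielding ≈320 transects from ≈1700 censuses;
- counts per (census, species) drawn negative-binomially with log
  mean `baseline + slope·(year − 2005) + site + season + zone`
  (Gaussian site/season effects, SD 0.4 and 0.3; dispersion size 0.7;
  `nb_size = Inf` switches to Poisson for closed-form oracle checks);
- species baselines lognormal (median 0.1 ind/100 m², log-SD 1.8), so
  a few dominant species carry most individuals and roughly a quarter
  of a 100-species pool passes the 50% occurrence filter — the shape
  of abundance distribution such monitoring actually sees;
- individual lengths lognormal around 60% of the species' size-class
  midpoint (CV 0.25), binned to 5-cm classes; length-weight
  coefficients $a \sim$ lognormal(log 0.015, 0.3), $b \sim$ U(2.7,
  3.2); each species commercial with probability 0.28.

Occurrence is derived from counts (> 0), not simulated separately, so
occurrence, density, and biomass stay internally consistent. The
generator returns the ground truth (slopes, random effects, expected
census-to-transect grouping, expected per-species directions), which
the tests use for end-to-end recovery.

**What the generator does not emulate** — and hence what green tests
do *not* establish about real data: no spatial structure beyond site
identity (no gradients, no autocorrelation between nearby sites), no
observer or detectability effects, no size-structured population
dynamics (lengths are independent draws each census), no environmental
covariates, no species interactions, and trait assignments independent
of abundance. One emulated artifact deserves emphasis: because census
area changes in 2009, *occurrence* (and raw richness) per transect is
confounded with sampled area — density and biomass are per-100 m²
standardized and immune, but occurrence-based trends in both synthetic
and real data inherit this design confound, which is why the
transect-area ANOVA is part of the standard checks.

## Verification strategy and problem sizes

Three layers, all in `tests/testthat/`:

1. *Exact oracles* — Gower against a naive loop implementation and
   `cluster::daisy`; PCoA distance reconstruction to $10^{-8}$; hull
   volumes, FDis, FOri against brute-force implementations to
   $10^{-10}$ on random communities of up to 12 species in 2–4 axes.
2. *Statistical calibration* — type-I error of the temporal LMM under
   a zero slope (500 replicates of a reduced 4-site, 8-year design;
   rejection rate must fall in [0.03, 0.08]); 95% CI coverage under an
   injected slope (200 replicates, must fall in [0.90, 0.985]);
   winner/loser direction recovery at ±5%/year on the full ≈320
   transect design (power > 0.8 among classifiable trending species);
   and the two canonical dispersion scenarios — adding weight to a
   species far from the centroid raises FDis, removing weight from a
   species at the centroid also raises FDis — asserted exactly on
   hand-built fixtures. The replicate counts are chosen to keep the
   suite under a few minutes on one core while leaving the acceptance
   bands well above Monte-Carlo noise.
3. *Reference reproduction* — when the original monitoring workbook
   (not redistributable with the package) is exported as CSV into
   `inst/extdata/monitoring/`, a dedicated test reruns the full
   analysis and compares percent changes and winner/loser counts
   against the published values. Without that file the test fails
   with an explanatory message rather than silently skipping.

## Known limitations

- FRic in 5+ dimensions is exact but the facet count of the
  incremental hull grows quickly; the default axis cap of 6 keeps this
  practical, and monitoring configurations typically fix 4.
- Percent-change CIs are Wald intervals transformed to the percent
  scale; they inherit the usual small-sample optimism of Wald
  intervals near variance boundaries.
- The binned-residual pass/fail rule and the single-linkage
  aggregation closure are documented conventions, not unique answers;
  both are switch-or-audit-able (validation flags and grouping logs
  are returned, never discarded).
- Season enters as a 2-level random intercept to mirror the
  monitoring model structure; with two levels its variance is weakly
  identified and frequently estimated at the boundary (the fit is
  then flagged singular but remains valid for the fixed effects).
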