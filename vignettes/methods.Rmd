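---
title: "Modelling nutrient release by cetacean communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutrient release by cetacean communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetapump)
```

## The bioenergetic consumption–egestion model

`cetapump` estimates the annual flux of eight nutrients — the major
nutrients N and P and the trace nutrients Fe, Cu, Mn, Se, Zn, Co — from
cetacean populations into surface waters. The chain is deliberately
simple and fully unit-tracked:

1. **Metabolism.** Basal metabolic rate follows Kleiber's three-quarter
   allometry, `BMR = β × 293.1 × BM^(3/4)` in kJ/day for body mass in kg.
   The multiplier `β` scales basal to field metabolism ("cost of
   living"): base values 2 (low, e.g. sperm whales), 3, or 4 (high, e.g.
   harbour porpoise), raised by 0.5 for lunge-feeding baleen whales whose
   feeding mode is energetically expensive.
2. **Ration.** Daily food intake is `BMR / (AE × E)` in kg fresh weight
   per day, with assimilation efficiency `AE` and mean diet energy
   density `E` (kJ/kg).
3. **Release.** Each kg of food carries `x_n` mg of nutrient `n`, of
   which a fraction `r_n` is egested or excreted rather than retained.
   Scaling by days of presence `t` and abundance `A` and converting
   mg → tonnes gives `Q_n = ration × x_n × r_n × t × A / 1e9` tonnes/yr.

A note on units: with `x_n` in mg/kg, the mg → tonne conversion is a
division by 1e9; the package carries this explicitly and the test suite
checks the whole chain against an independent step-by-step unit-tracking
oracle, so the output really is tonnes per year.

### Parameter distributions

Uncertainty and natural variability are propagated by Monte-Carlo
simulation with aligned draws (default `n_sim = 1e4`):

| Parameter | Distribution | Notes |
|---|---|---|
| `BM` | N(mean, 0.2·mean), truncated just above 0 | intra-species variability |
| `β` | truncN(base, 0.2·base, 1, 5) | physiologically plausible range |
| `AE` | truncN(0.85, 0.05, 0.80, 0.95) | conservative digestive efficiency |
| `r_n` | U(0.7, 0.9) | all nutrients, general case |
| `r_n`, fasting migrants | U(0.2, 0.4) for N, P; exactly 0 for trace | breeding-ground baleen whales urinate but do not defecate; trace excretion in urine is negligible |
| `t` | U(120, 240) days for migratory species in feeding **and** breeding grounds; 365 otherwise | four to eight months of seasonal presence |
| `A` | lognormal, moment-matched to the survey mean and CV | `mu = log(mean/√(1+cv²))`, `sigma = √log(1+cv²)` |
| `E`, `x_n` | smoothed bootstrap over prey-composition samples | see below |

Survey designs with several spatial blocks are combined with
`aggregate_abundance_blocks()`: means add, and CVs combine as
`√Σ(cv_i·mean_i)² / Σmean_i` under an independence assumption — the
block-error correlation structure is rarely published, and independence
is the weakest assumption that still propagates all block variances.

### Diet and the smoothed bootstrap

Each species has one diet, expressed as weights over nine functional prey
groups; `E` and `x_n` are the diet-weighted sums of group-level energy
and nutrient densities. Group-level variation is simulated by a smoothed
(kernel) bootstrap of the analytical composition samples: whole sample
records are resampled with replacement — preserving the between-nutrient
correlation within a sample — and per-variable Gaussian noise with
Silverman's rule-of-thumb bandwidth is added. Draws are reflected at zero
rather than clipped, which preserves the mean better for variables near
zero. Our Silverman implementation returns a zero bandwidth for samples
with no spread, so constant fixtures stay exactly constant.

A group represented by a single sample (zooplankton, in practice) cannot
be bootstrapped; variation is instead simulated as normal around the
sample value with a standard deviation of 20% of the value for energy and
major nutrients and 40% for trace nutrients.

One pool of draws per group is generated per run and shared by every
species, mirroring the idea of a single artificially extended composition
data set; per-species resampling would understate the between-species
correlation that a shared prey pool induces.

## Reproducible randomness

All randomness flows from one root seed through named sub-streams
(`substream_seed()`), keyed by (species, area, habitat, parameter).
Truncated normals are sampled by inverse-CDF on the truncated quantile
range, with no rejection loop. Two consequences the tests rely on: the
same configuration always reproduces bitwise-identical results, and the
draws for one species/cell are invariant to which other species are in
the run or the order in which cells are processed.

## Community aggregation

Species draws are summed per draw index into per-taxon accumulators, and
the community total is defined as the sum of the taxon totals, so the
conservation law (taxon shares sum to 100% per draw) holds exactly rather
than to rounding. Totals are converted to densities (kg km⁻² yr⁻¹) by
the habitat surface; whole-area values sum the habitats. Fold-changes
divide an area's mean density by the baseline (poorest) area's, per
nutrient.

Where a figure-style normalization is needed ("normalized per nutrient"),
the package divides by the per-nutrient maximum across entities: this
preserves zeros, ratios and ranking, and puts every nutrient on (0, 1].
For neritic-vs-oceanic habitat contrasts the two habitat means are
normalized by their maximum within each (area, nutrient) before
differencing, so the signed difference lives on [−1, 1]; the underlying
significance call is made on the full density draw distributions. Both
choices are package decisions — a maximum-based normalization is the
simplest order-preserving map — and are isolated behind
`normalize_per_nutrient()` and `habitat_difference()`.

## The draw-based significance test

Monte-Carlo output distributions are not samples of independent
observations, so classical tests do not apply. `binary_relation_test()`
computes the fraction of index-paired draws in which group 1 exceeds
group 2, calls the difference significant when that fraction is ≥ 0.95 or
≤ 0.05, and reports `p = min(fraction, 1 − fraction)`. Ties count 0.5,
which preserves antisymmetry exactly; `p` is floored at `1/n` because a
Monte-Carlo p of exactly zero is not defensible; an all-pairs
(Mann-Whitney-style) variant is exposed for sensitivity checking. No
multiple-testing correction is applied anywhere.

Two properties worth understanding before using it:

* the statistic is invariant under any strictly monotone transform of
  both groups;
* under an *exact* null (both groups iid from the same distribution,
  independent draws) the fraction concentrates at 0.5 with standard
  deviation `0.5/√n`, so at `n = 1e4` the 0.95/0.05 rule essentially
  never fires — Monte-Carlo noise alone cannot produce "significance".
  The test is therefore conservative against pure simulation noise; what
  it measures is the overlap of the two propagated uncertainty
  distributions, and it flags a difference only when those distributions
  are nearly disjoint. The test suite verifies this behaviour
  empirically.

## Waste stoichiometry and PCA

`x_n × r_n` is the nutrient released per kg of food ingested (mg/kg),
independent of ration, residence or abundance — a species-level
stoichiometric fingerprint. Species are summarized by the 2.5% quantile,
mean and 97.5% quantile per nutrient (24 variables), normalized per
nutrient by the maximum across species, and ordinated by PCA on
standardized columns. Variable cos2 on the first two components is
reported with the conventional 0.5 display cutoff; all loadings are
retained regardless. Constant columns are dropped with a warning before
standardization.

## Productivity regressions

Normalized mean release per area is regressed on mean surface
chlorophyll and on SST by ordinary least squares, one fit per nutrient.
Areas whose chlorophyll estimate is flagged as turbidity-driven (river
plumes inflate satellite chlorophyll without reflecting productivity)
are excluded from chlorophyll fits only. Fits are refused below three
areas.

## Sobol sensitivity analysis

`sobol_indices()` uses a Saltelli-type paired-matrix design: the Jansen
estimator for first-order indices (lower variance than the classic
estimator) and the Saltelli-2002 cross-matrix products for closed
second-order variances, at a cost of `n_base × (2k + 2)` model
evaluations. The release model's eight factors (BM, β, E, x, AE, r, A, t)
are treated as one scalar each: E and x are resampled from the species'
diet-draw pools, the rest from their parametric forms; factors that are
constant in a context (e.g. `t = 365` for residents, `r = 0` for trace
nutrients of fasting migrants) contribute zero variance by construction.
The default `n_base = 2^12` per cell balances estimator noise (±0.02 on
S1 at `2^14` against analytic oracles in the tests) against the cost of
sweeping every species × habitat × area cell. Pseudo-random sampling
under the hierarchical stream is the default so the whole pipeline keeps
one RNG contract.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the analysis
assumes, with known ground truth: 38 species in three taxa (masses drawn
log-uniformly within 30–300 kg for small cetaceans, 300–40,000 kg for
deep divers, 5,000–120,000 kg for baleen whales — documentation values,
not claims about real species), Dirichlet diets focused per taxon
(baleen whales on zooplankton, deep divers on cephalopods, small
cetaceans on pelagic/demersal fish), nine prey groups with ~17 composition
samples each (zooplankton forced to a single sample to exercise the
parametric branch), 14 areas (a 70% share surveyed in both habitats) and
survey CVs uniform on 0.1–0.8.

A latent productivity scale `g`, log-spaced over a 10× gradient, drives
*both* the covariates (chlorophyll ∝ `g` with lognormal noise and one
flagged turbidity outlier; SST decreasing in `log g`) *and* the
abundances (taxon-specific density × `g` × surface × lognormal noise,
sd 0.3 on the log scale). The productivity–release correlation is thus a
real signal the pipeline must recover, not one baked into outputs. β is
assigned by taxon (small cetaceans 4, deep divers 2, baleen whales 3,
+0.5 for lunge feeders), the study's high/low cost-of-living logic. The
poorest area is the fold-change baseline; the productivity terciles make
rich areas feeding grounds and poor areas breeding grounds for migratory
baleen whales.

What passing synthetic tests does **not** show: the generator draws
compositions as independent lognormals around group means, abundances
without spatial autocorrelation or inter-species covariance, and diets
stable in time — real data violate all three, so recovery here validates
the inference machinery, not the ecological realism of any particular
input set.

`generate_worked_example()` is the opposite extreme: two species, one
area, constant compositions and zero-variance distributions, so every
output is a closed-form number shipped alongside the fixture and checked
to 1e-12 relative tolerance against an independently ordered
hand-arithmetic chain.

## Problem sizes used by the test suite

Property tests run the full default study once at `n_sim = 1e4` (a few
seconds), the parameter-recovery study over 20 replicates at
`n_sim = 500` — Monte-Carlo error on mean fold-changes at that size is
far below the 10× between-area signal — and Sobol oracles at
`n_base = 2^14` (analytic checks) and `2^10`–`2^12` (study sweeps on a
cell subset). These are the package's own choices of demonstration
scale; all entry points accept larger sizes unchanged.

## Numerical choices and degenerate inputs

* Truncated normals with `sd = 0` return the clamped mean; abundances
  with `mean = 0` or `cv = 0` return constant draws.
* Zero community totals in a draw make taxa shares undefined; such draws
  are excluded from summaries and counted.
* Shares are computed as `100 × (taxon/total)` — dividing first — so a
  taxon that *is* the community gets exactly 100.
* All-zero nutrient columns refuse normalization (error), and constant
  columns are dropped from PCA with a warning.
* Diet weights off 1 by less than 1e-6 are renormalized on load; larger
  discrepancies are rejected with the species named.

## Known limitations

* One diet per species, no seasonal or spatial diet variation; the
  functional-prey-group abstraction is what makes this defensible.
* The model tracks basal-metabolism-driven consumption scaled by β; it
  does not model growth, reproduction or body-condition dynamics, and
  `t` is the only seasonal structure.
* Release rates for cetaceans are essentially unmeasured; the U(0.7,
  0.9) band encodes expert judgement, and the sensitivity analysis
  (which shows abundance dominating output variance) is the honest
  answer to how much this matters.
* The binary-relation test has no false-positive calibration in the
  classical sense (see above); treat its `p` as a descriptive overlap
  measure.
* Index-paired and all-pairs comparison conventions are both
  implemented (`all_pairs = TRUE`); they agree closely at these sample
  sizes, but the choice is exposed because it is a genuine degree of
  freedom in draw-based testing.
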