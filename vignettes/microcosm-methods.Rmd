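---
title: "Methods: eco-evolutionary analysis of bacterial microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary analysis of bacterial microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcosm)
```

## The experimental system

`microcosm` analyses serial-transfer evolution experiments with
decomposer bacteria growing on a single complex medium (leaf-extract
"tea"). Species are propagated either alone (monoculture) or together
(polyculture) through repeated dilution into fresh medium; ancestral and
evolved isolates are then compared through four assay families:

* **Growth assays** — optical density (OD600) time series on unused
  medium and on "used" (spent, filter-sterilised) medium previously
  conditioned by another species. Growth on a competitor's spent medium
  reveals niche overlap (slower growth), independence (equal growth), or
  facilitation/cross-feeding (faster growth).
* **NMR metabolic footprints** — vectors of peak integrals (dimensionless,
  relative to an internal standard) of media before and after growth.
  Their differences quantify net consumption (negative) and production
  (positive) of each compound.
* **Serial-transfer logs** — pre-transfer densities and dilution factors,
  from which generations and effective population sizes follow.
* **Colorimetric respiration** — cresol-red indicator absorbance changes
  converted to community CO2 production rates.

Every stage can be driven either by real CSV tables or by the package's
synthetic-community generator, which exists so that each estimator has a
known ground truth to recover.

## Growth-rate estimation

Raw plate readings are blank-corrected against the sterile-control well
of the same plate, column, and time, and floored at `epsilon = 0.001` OD
(the log-scale calibration is undefined at or below zero; the floor is
configurable). Calibration uses one linear model for all species,
`log10(colonies/ml) ~ species + OD600`: per-species intercepts, one
shared slope. Densities are reported as log2 cells/ml so that slopes are
doublings per day.

The maximum growth rate `V_MAX` is the ordinary least-squares slope of
log2 density against time over all readings in the first 48 h. OLS over
the window is a deliberate, reproducible choice: the raw "rate of change
from low densities" does not name an estimator, and OLS uses every
reading in the window rather than a two-point difference. With only two
points the standard error is reported as 0. Carrying capacity is the
calibrated density at the reading nearest 96 h (default tolerance
±4 h).

Treatment contrasts (evolved vs ancestral `V_MAX`, respiration of
reassembled communities) use a two-sided permutation test on the
difference of group means with the add-one correction
`p = (k + 1)/(B + 1)`; mixed-effects repeated-measures modelling is
intentionally out of scope — the permutation contrast is the package's
documented, assumption-light replacement.

## Interaction networks

The effect of donor species *j* on recipient *i* is the recipient's mean
`V_MAX` on *j*-conditioned medium minus its mean `V_MAX` on unused
medium; the ratio of the two means is reported alongside, with a
percentile-bootstrap interval (the assays provide replicates but no
analytic SE for a ratio). Edges are classed negative/positive when the
permutation p-value falls below `alpha = 0.05` (two-sided, configurable)
with the matching sign, neutral otherwise; neutral edges carry a dashed
flag in the exported networks (CSV, DOT, GraphML). Donor and recipient
assays must come from the same treatment — cross-treatment effects are
not defined in this design.

## NMR footprints and the Monte Carlo tests

Peak tables are validated on load (one row per sample × peak; missing
combinations are an error unless zero-filling is requested). Contaminant
peaks (e.g. solvent resonances) are dropped by name. Peaks whose
pairwise Pearson correlation across samples exceeds 0.95 are merged by
single linkage and summed, since tightly correlated resonances likely
derive from one compound; by default all distance statistics are
computed on this collapsed, filtered axis (the raw axis remains
available by skipping the collapse step).

Footprint deltas are filtrate minus the mean base-medium profile.
Principal components use centered, **unscaled** (covariance) PCA so that
compounds with larger absolute concentration changes dominate; each
component's largest-magnitude loading is made positive, a deterministic
sign convention with no scientific content.

Two distance statistics summarise evolution in footprint space:

* **evolution distance** — mean over species of the Euclidean distance
  between that species' ancestral and evolved delta profiles (mean over
  replicate cross-pairs when replicates exist);
* **divergence distance** — mean over unordered species pairs of the
  between-species distance within one treatment.

Significance comes from Monte Carlo permutation: profiles are shuffled
uniformly among all (species, treatment) labels, group sizes fixed, and
the statistic recomputed `B = 10000` times (default). The two-tailed
p-value doubles the smaller tail and counts the observed arrangement
among the permutations. Because both statistics depend on the profiles
only through pairwise Euclidean distances, the distance matrix is
computed once and permutations merely re-index it, which is what makes
calibration experiments with hundreds of datasets cheap. With eight or
fewer profiles an exact mode enumerates all `n!` assignments; a small
tie tolerance (`1e-9` relative) keeps permutations that reproduce the
observed pairing counted as ties regardless of floating-point summation
order.

**Exchangeability.** The full-label shuffle treats every profile as
exchangeable with every other. On real data species differ
systematically, so the "evolution" test partly reflects between-species
structure — a property inherited from the assay design itself. The
package's null generator therefore makes exchangeability true by
construction: `simulate_null_dataset()` sets the evolutionary effect to
zero *and* replaces every species' consumption/production parameters by
the community means, so all profiles are independent draws around one
mean. Under that null both tests hold their nominal type-I error (the
calibration experiment in the test suite uses 500 null datasets at
`B = 999`); on species-structured data the tests answer the question
"is this arrangement of profiles unusual among relabellings", exactly as
in the original analysis, and should be read with that caveat.

## Cross-feeding statistics

For a pair (first species, second species) assayed in the same
treatment, `delta_01` is filtrate-of-first minus base medium and
`delta_12` is filtrate-of-second minus filtrate-of-first; they telescope
to filtrate-of-second minus base exactly. Records compare evolved with
ancestral assays per compound: `x` is the production shift of the first
species, `y` the consumption shift of the second. Only compounds with
`delta_01(evolved) > 0` (actually produced by the evolved first isolate)
enter, focusing the analysis on waste products; the ancestral delta is
unconstrained. Each (pair, compound) is one unweighted observation —
replicate filtrate samples are averaged per cell first — and the
treatment comparison is the least-squares interaction term of
`y ~ x * treatment` with monoculture as the reference level, so the
interaction coefficient is slope(polyculture) − slope(monoculture).

## Demography

Generations per transfer are
`g_t = log2(N_pre(t) / (N_pre(t-1) / dilution))`; for the first recorded
transfer the pre-experiment density is taken equal to the first
pre-transfer density (the steady-state convention), so a culture at
constant density accumulates `n * log2(dilution)` generations —
15 transfers at 20-fold dilution give 64.8 generations. Apparent
declines below dilution replacement are clipped to zero and flagged
rather than propagated as negative generations. The default dilution is
20; 21 (0.1 ml into 2 ml) is an equally defensible reading of the
transfer protocol and is a plain argument, not a constant.

Effective size uses the classic serial-transfer approximation
`Ne = N0 * g` with `N0` the mean post-dilution census (cells, not
cells/ml) and `g` the mean generations per transfer; a harmonic-mean
alternative is provided and the convention used is recorded in the
output. `Ne` always lies between the bottleneck and the pre-transfer
census.

## Respiration

Indicator plates are normalised so that blank wells define the
zero-respiration baseline: each well's end/start OD570 ratio is divided
by the mean blank ratio, giving `Ai = 1` for a well that behaves exactly
like a blank. The indicator curve `%CO2 = A + B/(1 + D*Ai)` converts
absorbance to percent CO2; the shipped constants
(A = −0.2265, B = −1.606, D = −6.771) are the colorimetric assay's
published parameterisation and are configuration — real plates should
use their own calibration. Percent CO2 is converted to µg via the ideal
gas law (44 g/mol at 22.4 l/mol, corrected by 273/(273+T), default
25 °C) and divided by medium volume and incubation time (default 6 h).
Baseline-corrected values below zero — plate noise — are clipped to zero
and flagged.

## The synthetic-community generator

A `community_config` holds, per species: intrinsic rate `r`
(doublings/day), carrying capacity `K` (cells/ml), a consumption-fraction
row `U` over compounds (entries in [0, 1]), a production row `P`
(amounts per growth cycle), plus the base-medium composition, the OD
calibration, and noise levels. Spent medium after growth of species *i*
is `medium * (1 - U[i, ]) + P[i, ]`, which is non-negative by
construction.

Growth is logistic with rate `rho = r * ln(2) * phi(medium)`, where
`phi` is the species' consumable resource in the assay medium relative
to the unused base medium, clamped to `[0, phi_max]` with
`phi_max = 2`. The cap above 1 matters: `phi(base) = 1` by definition,
so facilitation — faster growth on spent medium enriched in a species'
preferred substrates — is only representable if `phi` may exceed 1. The
cap at 2 bounds the benefit at a doubling of the baseline rate.

`evolve_isolates()` emulates the direction, not the mechanism, of the
observed evolution. Monoculture isolates increase `r` by 40% per unit
effect size and pull their consumption rows halfway toward the community
mean (convergent adaptation to the medium). Polyculture isolates push
their rows away from the mean with weight `1.0 * effect_size` — about
twice the monoculture magnitude, mirroring the roughly two-fold larger
footprint changes seen in polyculture — add consumption of compounds
other species produce with weight `0.5 * coupling * effect_size`
(cross-feeding), and increase production of waste compounds by 30%. An
effect size of zero returns the input unchanged for every treatment.

Default study conditions follow the experiment's design where stated: 9
growth replicates per species × treatment × substrate, daily OD readings
over 4 days, 15 serial transfers at 20-fold dilution in 2 ml, a 6-h
respiration incubation with 10 replicate wells per group. Where no value
is stated the defaults are chosen once for realism, not fitted: OD noise
0.01 (SD, Gaussian), peak-integral noise 0.05 (Gaussian truncated at
zero — integrals are non-negative), lognormal regrowth noise 0.1,
carrying capacities `10^6.8`–`10^7.3` cells/ml as appropriate for a
dilute leaf extract (which also places bottleneck-times-generations
effective sizes in the few-millions range), inoculum at `K/1000`, and a
calibration whose OD span keeps the whole assay on-scale (inoculum near
OD 0.13, saturation near OD 1.1). Growth rates of 2–3.5 doublings/day
keep the first 48 h near-exponential relative to `K`, which is what
makes the 48-h OLS slope an unbiased estimate of `r`.

Community respiration in the generator is driven by *coverage*: the
fraction of the base medium consumable by the union of the community's
species. Monoculture-evolved communities converge and cover less;
polyculture-evolved communities diverge and cover more, hence respire
more — the generator's expression of complementarity raising ecosystem
function.

A single master seed drives everything; each sub-simulation derives a
deterministic child seed from the seed and a string key, so any table
can be regenerated in isolation and the full dataset is bitwise
reproducible.

**What the generator does not emulate:** mechanistic uptake kinetics
(Monod, flux balance), compound stoichiometry, mutation and drift,
spatial structure, toxins or signalling, and plate-reader artefacts
other than additive blanks and Gaussian noise. Passing
parameter-recovery tests on this generator therefore shows the
estimators are correct and calibrated under the stated statistical
structure — not that real assays satisfy that structure.

## Numerical choices and degenerate inputs

* Permutation p-values are never 0: Monte Carlo mode uses the add-one
  correction; exact mode counts the observed arrangement.
* `estimate_vmax` errors with fewer than two readings in the window;
  the ratio `relative` is reported as missing when the unused-medium
  mean is non-positive (the effect itself is still returned).
* `phi` with a zero consumable denominator is defined as 1 (no resource
  limitation modelled for a species that consumes nothing).
* The peak-collapse step requires at least 3 samples (correlations need
  degrees of freedom); constant peaks never merge (their correlation is
  undefined and treated as no edge).
* Exhaustive enumeration is limited to 8 profiles (8! = 40320
  assignments); beyond that only Monte Carlo mode is available.

## Problem sizes used by the shipped simulations

The test suite and the acceptance script run: type-I calibration on 500
null datasets (`B = 999`); power checks on 200 datasets for the
divergence test and 100 for the cross-feeding correlation; `V_MAX`
recovery on 200 noisy curves; calibration-slope CI coverage on 500
replicates; edge-sign recovery on 100 datasets of 6 edges with 9
replicates each; and the full demo at `B = 10000`. These sizes are the
package's chosen compromise between the precision of a Monte Carlo check
and a test suite that runs in minutes on one core.

## A worked demo

```{r demo, eval = FALSE}
res <- run_demo(tempdir(), seed = 1)
res$distances       # evolution/divergence distances per treatment
res$nmr_tests       # Monte Carlo permutation tests
res$crossfeed$correlations
res$demography
```

The demo writes the five synthetic input tables plus the complete
result bundle (V_MAX tables, networks per treatment in CSV/DOT/GraphML,
PCA scores and loadings, permutation tests, cross-feeding records and
model, demography, respiration contrasts, and a machine-readable run
log), and is byte-identical when re-run with the same seed.

## Known limitations

* The permutation tests assume full exchangeability; see above for what
  that means on species-structured data.
* The SE of the reported distance statistics across species is not
  modelled; the package reports the statistics and their permutation
  p-values only.
* The generator's evolutionary shifts are phenomenological. Effect-size
  units are "fractions of the configured shift", not measurable trait
  changes.
* Interaction inference is pairwise; higher-order effects and dynamic
  (Lotka–Volterra) coefficients are out of scope.
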