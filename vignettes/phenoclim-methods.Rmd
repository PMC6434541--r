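---
title: "Methods: phenology under manipulated temperature and moisture"
author: "phenoclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology under manipulated temperature and moisture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclim)
```

`phenoclim` analyses plot-level phenology in a factorial climate
manipulation: three prairie sites on a latitudinal Mediterranean-climate
gradient, four treatments (control; drought = −40 % precipitation;
warming = +2.5 °C canopy offset; warming + ppt = warming with feedback
irrigation), five replicate plots each. This vignette explains the
models and procedures, the tunable constants and why they hold their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Soil water: from probe readings to matric potential

Volumetric water content (VWC, a fraction) is not comparable across
sites with different soils; soil-water *tension* is. The pedotransfer
module fits, per site, the moisture-retention subset of the
Saxton–Rawls regressions from sand, clay and organic-matter fractions:
the water contents at −1500 kPa (wilting point, θ₁₅₀₀), −33 kPa (field
capacity, θ₃₃) and saturation (θs), and the air-entry tension. Between
θ₁₅₀₀ and θ₃₃ tension follows ψ = −A·θ^−B with
B = ln(1500/33)/ln(θ₃₃/θ₁₅₀₀) and A = 33·θ₃₃^B; between θ₃₃ and θs it is
linear from −33 kPa to the air-entry tension; at or above θs it is 0.
Two deliberate choices:

* **Extrapolation below θ₁₅₀₀** uses the same power law rather than
  erroring. Tensions drier than wilting must stay representable because
  the *date of first wilting point* and *days below wilting point* need
  ψ < −1500 to exist; the clamp at −1500 kPa is applied only to the mean
  annual matric potential, making the extrapolation's exact shape
  inconsequential for that summary.
* Gravel, salinity and bulk-density adjustments of the full pedotransfer
  system are omitted: only the VWC → ψ direction is used. Organic matter
  enters the regressions in percent by weight; the user supplies a mass
  fraction. There is a small (a few kPa) step at saturation where the
  linear segment ends at the air-entry tension and ψ is set to 0 — the
  conventional shape of this retention form.

Annual climate summaries use half-open windows: the hydrological year
15 July → 15 July, winter 1 Dec → 1 Mar, spring 1 Mar → 1 Jun (the
half-open convention prevents double counting; in leap years "winter"
therefore includes 29 February). Sub-daily datalogger records are
averaged to daily means *before* any thresholding, so "days below
wilting point" counts days whose daily-mean tension is strictly below
−1500 kPa; a day at exactly −1500 does not count, matching the strict
inequality of the clamp. Where wilting is never reached the date of
first wilting point is flagged missing and such plots drop from any
model that uses it.

## NDVI phenometrics

All detectors operate on the sampled survey dates, with no interpolation
or smoothing: a "first date at which" definition returns a date that was
actually sampled, so date resolution equals the sampling interval
(weekly at two sites, biweekly at the southern site by default). The
definitions:

* **Peak biomass**: maximum NDVI in the season window; ties break to the
  earliest date (stable and consistently biased, rather than arbitrary).
* **Senescence**: first date strictly after the peak with
  NDVI ≤ 0.80 × peak. Never crossed → censored flag, not a fabricated
  date.
* **Senescence rate**: among all runs of 3 consecutive samples (2 where
  senescence is too fast for three points to be linear), the run with
  the greatest endpoint decline (first − last), summarised by the
  least-squares slope of NDVI on days. Endpoint decline is used because
  "greatest decline" plainly reads as total decline, and the two
  criteria coincide on monotone windows; least squares because a slope
  over three unevenly spaced points is otherwise ill-defined. The search
  is restricted to post-peak samples in the pipeline (a switch exposes
  the whole-season variant). A non-declining best run returns its
  (positive) slope flagged `nonsenescent`.
* **Green-up**: minimum NDVI in a configured summer window (ties
  earliest), then the first later date with NDVI ≥ 1.25 × minimum. A
  multiplicative threshold degenerates when the minimum is near zero, so
  below a floor (0.05) the rule becomes minimum + 0.05 and is flagged.
* **Growing-season length**: days from fall green-up to the next
  season's senescence; censored inputs make it missing, excluded
  pairwise downstream.

Season windows (1 Oct → 1 Aug growth cycles; 15 Jun → 15 Oct summer
minimum window) are configuration, not algorithm: the underlying field
protocol implies but does not fix them.

## Flowering phenometrics

First flowering date (FFD) is the earliest survey with an open flower;
peak flowering date (PFD) the survey with the maximum count (ties
earliest). Temperature sensitivity for a warmed plot *i* is
(date*ᵢ* − mean ambient date)/ΔT with ΔT = 2.5 °C, negative meaning
advancement; site summaries are means ± s.e. across warmed plots. When
neither group varies, the contrast is flagged untestable instead of
emitting a p-value. Plot-season reproductive abundance is the maximum
flowering-individual count across the season's surveys — weekly tallies
do not define a unique seasonal abundance, and the season-max counts
every individual detected while never double counting across weeks; this
is an interpretive choice, stated as such. Species–site combinations
whose peaks are uncountable in the field can be excluded from PFD via a
configuration list, and species surviving at a single site are excluded
from cross-site environmental models.

## Inference

**Treatment collapsing.** The moisture manipulations are only retained
as separate factor levels if they matter: the pipeline runs two-tailed
Welch tests within the two pairs (control vs drought; warming vs
warming + ppt) and collapses to the two-level ambient/warming factor only
when both p-values are at or above `collapse_alpha`. The default 0.10
treats even marginal evidence of a moisture effect as a reason not to
collapse; under a true null the rule therefore collapses with
probability ≈ (1 − α)² = 0.81, which the test suite verifies by
simulation. Welch (unequal-variance) is the default two-sample test
throughout, the safer choice at n = 5 per cell; the classical test is a
switch.

**Group comparisons.** Warming effects are warming − ambient mean
differences (negative = advancement for dates). ANOVA with Tukey HSD
handles site and site × treatment structure; repeated-measures ANOVA
treats year (or survey date) as the within-subject effect, subjects
listwise deleted if any occasion is missing. Sphericity is tested with
Mauchly's criterion on the pooled within-cell covariance (checked in the
tests against the base-R implementation), and when rejected at 0.05 the
within-subject F degrees of freedom are multiplied by the
Greenhouse–Geisser epsilon, ε = (tr Σ*)²/((k−1)·tr Σ*²) on the
orthonormal-contrast covariance. NDVI-type responses bounded in [−1, 1]
are logit-transformed via (x + 1)/2 with a 10⁻⁶ clip.

**Abundance models.** Counts are fit to Poisson, negative-binomial,
zero-inflated Poisson and zero-inflated negative-binomial families
(constant zero-inflation; `glmmTMB` for the zero-inflated pair), the
winner chosen by AIC, its fit checked by a Pearson chi-square against
residual degrees of freedom, and factor effects tested by
likelihood-ratio chi-square on nested refits of the winning family. A
significant site × treatment interaction triggers within-site refits.
All-zero counts are reported as an absent population, not modelled.

**Multimodel attribution.** Because the three temperature summaries are
strongly mutually correlated (as are the three moisture summaries), one
multiple regression over all six is inappropriate. Instead each response
gets exactly 15 linear models: the nine one-temperature + one-moisture
pairs and the six singletons. AICc = −2logL + 2k + 2k(k+1)/(n−k−1), with
k counting intercept, slopes *and* the residual variance (the
information-theoretic counting convention, stated explicitly because it
is easy to get silently wrong). Akaike weights are computed over the
full 15-model set. The report filters to δAICc < 2 and drops any
two-predictor model beaten by one of its own singletons (parsimony), but
*weights are never renormalised for reporting and importances always sum
over all 15 models*, because relative variable importance is defined
over the whole set. One deliberate deviation from a pairwise-deletion
reading of missing data: all 15 models are fit on the rows complete for
the response and all six predictors, since AICc and ω are only
comparable between models of identical data (the standard multimodel
tooling enforces the same). Date responses enter the models as days
since the start of their own hydrological year, putting the two seasons
on a common scale for pooled fits.

## The synthetic experiment

The generator produces the complete bundle the pipeline consumes, with
stored ground truth, so every stage is testable without a field dataset.
What it emulates, and the defaults chosen once on realism grounds:

* **Temperature**: a site sinusoid (late-July maximum) plus per-plot
  AR(1) weather noise (stationary SD 1.6 °C, ρ = 0.7 — synoptic-scale
  persistence). South → north the means fall 12.5/11.5/10.5 °C and
  amplitudes 8.5/7.5/6.5 °C. Warming adds +2.5 °C to canopy temperature
  and 0.8 × that to soil temperature (soil damping; the magnitude is a
  configurable constant asserted only qualitatively).
* **Soil water**: one shared daily rain series per site
  (Bernoulli–gamma, wet-season probabilities 0.55–0.65, mean event
  8 mm), a 300-mm single-layer bucket bounded between a residual
  (0.6 × θ₁₅₀₀) and saturation, evapotranspiration =
  max(0, 0.28·T − 0.5) mm/day scaled by relative water availability
  (summer PET ≈ 5–7 mm/day in the south). Drought plots receive exactly
  0.60 × infiltration — an accounting identity the tests assert.
  Warming + ppt plots get a 6-mm nightly pulse whenever their
  previous-day VWC is below 95 % of the same-site control mean,
  emulating the feedback irrigation rule. Wet seasons end 5 Apr / 10 May
  / 20 May south → north, with dry-season rain probabilities 0.02–0.03,
  so winter soils sit near saturation and summer soils fall well below
  wilting point at every site, the southern site first — the regime the
  real gradient shows. Runs start mid-drought, so the bucket initialises
  near-dry. Site soil textures are plausible placeholders (no measured
  values exist): the three retention curves genuinely differ.
* **Greenness**: a latent curve per growth cycle — a fast logistic rise
  anchored 20 days after the first post-summer day the plot's matric
  potential climbs back above −1500 kPa (green-up follows the rains), a
  slower spring growth logistic, and a logistic senescence decline
  (ambient inflections DOY 125/145/156 south → north). Warming-category
  plots have the spring and senescence phases advanced by
  `warming_advance_days` (default 20, the scale of the community-level
  advance such manipulations produce); the rain-anchored fall rise is
  not shifted. Observed NDVI = latent + Gaussian noise (SD 0.02),
  clipped to [−1, 1]; plot-level phase jitter (SD 3 days) supplies
  biological replicate variation. Ground truth is computed by applying
  the detectors' own threshold definitions to the latent curve on the
  daily grid, so with zero noise, zero jitter and daily sampling every
  detected phenometric equals its truth exactly — the suite asserts
  this, and asserts that the stored truth peak differs by exactly the
  injected advance.
* **Flowering**: per species × plot, flowering-individual counts are
  zero-inflated negative binomial with mean rising (×0.3/×1/×2.5) and
  zero-inflation falling (0.6/0.35/0.15) south → north — the
  establishment gradient; two species establish only at the northern
  site and the grass fails in the south. Open-flower counts follow a
  discretised Gaussian pulse (SD 8 days) centred on a species date
  (site-shifted, warmed plots advanced by
  `warming_advance_days`/2.5 × ΔT), scaled by individuals, observed with
  Poisson noise (or exactly, for recovery tests, where counts use the
  floor so the pulse keeps a unique daily maximum). Onset truth is the
  first day the expected count reaches 1 — the detectability threshold
  of an integer survey — which makes "FFD recovered within one sampling
  interval" an exact bound in noise-free runs. Surveys run 15 Mar –
  20 Jun so the earliest warmed pulses stay inside the window, weekly
  (biweekly in the south).

What the generator does **not** emulate: mechanistic plant physiology,
spatially explicit rainfall, multi-layer soil hydrology, midwinter
greenness dynamics beyond the two logistic components, pollinator or
demographic feedbacks, and observation artefacts other than Gaussian
NDVI noise and Poisson count noise. Passing recovery tests therefore
shows the *pipeline* is faithful to its definitions under the assumed
data-generating shapes, not that those shapes exhaust real prairie data.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence property on 1000 randomised
series, parameter recovery on 100 seeded single-site experiments
(weekly sampling, 5 replicates per treatment), attribution recovery on
200 redraws of a response generated from spring soil temperature at
signal-to-noise 3 over one simulated experiment's 60-plot climate
summaries, collapse calibration on 1000 replicates, and count-family
selection on 200 replicates per regime — sizes chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo error far from the
asserted margins. Ties in peaks and minima always break to the earliest
date. The AICc correction returns ∞ when n ≤ k + 1 (undefined
otherwise). Degenerate inputs are flagged rather than silently handled:
zero residual variance in ANOVA, zero-variance warming contrasts,
all-zero counts, censored thresholds, non-converged model families.

## Known limitations

* Attribution among strongly collinear predictors is only as good as the
  plot-level variation separating them; with site effects dominating,
  importance values for predictors correlated at r > 0.97 should be read
  as pool-level, not variable-level, evidence.
* The heater-malfunction style exclusion is a generic masking facility
  (`exclude_plot_interval`); the analyst supplies the interval.
* DFWP is undefined in years a plot never wilts; such plots leave the
  candidate sets entirely (complete-case fitting), shrinking n rather
  than biasing weights.
* The senescence-rate window search defaults to post-peak observations;
  the whole-season variant is available but can select pre-peak dips.
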