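# phenoclim

Phenology analysis for warming × moisture manipulation experiments along
environmental gradients.

## The problem

In Mediterranean-climate grasslands the warmest temperatures and the
greatest moisture availability are seasonally out of phase: winters are
cool and wet (soils near saturation, ~0 kPa), summers hot and dry (soils
far below the permanent wilting point, −1500 kPa). Climate-manipulation
experiments in such systems cross infrared warming (+2.5 °C canopy
offset) with moisture treatments (rain-out drought shelters excluding
~40 % of precipitation; feedback irrigation that offsets warming-induced
drying) across replicated plots at several sites along a latitudinal
gradient, and ask: is the timing of plant phenology — flowering,
peak canopy biomass, senescence, growing-season length — controlled more
by temperature or by soil moisture?

`phenoclim` implements the full analysis chain for that question, for
ecologists running or simulating such experiments:

1. **Soil-climate summarisation** (`fit_retention_curve`,
   `vwc_to_matric_potential`, `summarize_climate`). Datalogger volumetric
   water content is converted to soil matric potential ψ via
   texture-based pedotransfer regressions (the Saxton–Rawls
   moisture-retention subset): ψ = −A·θ^−B between the −1500 kPa and
   −33 kPa anchors, linear up to air entry, 0 at saturation. Per plot and
   hydrological year (15 July → 15 July) it derives the six predictors
   MAT, MWT, MST (mean annual / winter / spring soil temperature) and
   MAMP, DFWP, DBWP (mean annual matric potential clamped at −1500 kPa,
   date of first wilting point, days below wilting point).
2. **NDVI phenometrics** (`peak_biomass`, `senescence_date`,
   `senescence_rate`, `greenup_date`, `growing_season_length`). From
   plot-level NDVI survey series: date of peak biomass (maximum NDVI,
   ties earliest), date of senescence (first post-peak date with
   NDVI ≤ 80 % of peak), rate of senescence (least-squares slope,
   ΔNDVI day⁻¹, over the 3 — or 2 — consecutive samples with the greatest
   decline), fall green-up (first date after the summer minimum with
   NDVI ≥ 125 % of the minimum) and growing-season length (green-up to
   the next senescence). No interpolation: every returned date is a
   sampled date.
3. **Flowering phenometrics** (`first_flowering_date`,
   `peak_flowering_date`, `temperature_sensitivity`, `abundance_table`).
   First and peak flowering dates per species × plot, temperature
   sensitivities (date_warm − mean ambient date)/ΔT in days °C⁻¹, and
   median reproductive abundances.
4. **Inference** (`collapse_treatments`, `compare_two_groups`,
   `anova_with_posthoc`, `repeated_measures`, `select_count_model`,
   `build_candidate_set`, `rank_and_filter`, `relative_importance`).
   Treatment collapsing to ambient/warming categories when the moisture
   manipulations show no within-pair effect; t tests, ANOVA with Tukey
   post-hoc, repeated-measures ANOVA with Greenhouse–Geisser correction;
   abundance GLM family selection among Poisson / negative-binomial /
   zero-inflated families by AIC; and the 15-model AICc candidate set per
   response (each of 3 temperature × 3 moisture predictor pairs, plus the
   6 singletons), with relative variable importance — the sum of Akaike
   weights ω = exp(−δAICc/2)/Σexp(−δAICc/2) over all models containing a
   predictor.
5. **Synthetic experiment** (`simulate_experiment`). A generator for the
   whole 3-site × 4-treatment × 5-replicate design — site temperature
   sinusoids with AR(1) weather, shared-rain bucket-model soil water with
   temperature-driven evapotranspiration, drought infiltration at 0.60×,
   nightly feedback irrigation, rain-anchored double-logistic greenness
   with an injected warming advance, and zero-inflated negative-binomial
   flowering counts — with stored ground truth, so the entire pipeline is
   testable without field data.

`run_pipeline()` chains everything and returns the climate summaries,
phenometric tables, collapse decisions, warming-effect tests,
sensitivities, count-model selections, candidate model tables and the
importance table. A thin command-line front end lives at
`inst/cli/phenoclim` (`simulate`, `climate-summary`, `phenometrics`,
`flowering`, `run-all`).

## Worked example

```r
library(phenoclim)

# a loam: 40% sand, 20% clay, 2.5% organic matter
rc <- fit_retention_curve(soil_texture(sand = 0.40, clay = 0.20, om = 0.025))
rc
#> <retention_curve>
#>   theta_1500 = 0.1370  theta_33 = 0.2796  theta_s = 0.4595
#>   tension segment: psi = -0.03605 * theta^-5.351 kPa;  air entry -4.15 kPa
round(vwc_to_matric_potential(c(0.12, 0.20, 0.30), rc), 1)
#> [1] -3050.7  -198.3   -29.7     # kPa: below wilting / mid-range / near field capacity

# phenometrics on a five-survey series (dates are day-of-year 100..140)
d  <- as.Date("2016-12-31") + c(100, 110, 120, 130, 140)
nd <- c(0.50, 0.60, 0.55, 0.47, 0.40)
pk <- peak_biomass(d, nd)                     # 2017-04-20 (DOY 110), NDVI 0.60
senescence_date(d, nd, pk)$senescence_date    # 2017-05-10: first NDVI <= 0.48
senescence_rate(d, nd)$slope                  # -0.0075 NDVI/day (steepest triple)
akaike_weights(c(0, 2, 4))                    # 0.665 0.245 0.090

# the full synthetic experiment and pipeline
ex  <- simulate_experiment(pheno_config(rng_seed = 1))
res <- run_pipeline(ex)
res
#> <pheno_results>
#>   climate summaries: 120 plot-years
#>   phenometrics: 120 plot-seasons
#>   candidate sets: 16 responses
#>   top predictors: peak_date=MAT, senescence_date=MAT, senescence_rate=MAT,
#>     gsl=DFWP_days, FFD_ACHMOL=MAT, FFD_COLGRA=MWT, ...
```

The last lines read: across the 16 phenology responses (four
community-level NDVI metrics pooled over two seasons, plus first- and
peak-flowering dates for six multi-site species), the predictor with the
highest relative variable importance is a temperature variable for 14 of
16 — the temperature-dominated attribution the manipulation is designed
to expose — with a moisture variable (date of first wilting point,
mean annual matric potential) taking two responses.

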