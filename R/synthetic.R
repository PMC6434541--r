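# Synthetic warming x moisture experiment with stored ground truth.
#
# The generator emulates the field design the analysis assumes: 3 sites on
# a latitudinal Mediterranean gradient x 4 climate treatments x 5
# replicate plots, +2.5 C canopy warming, 40% precipitation exclusion in
# the drought plots, and feedback irrigation in the warming + ppt plots
# (a nightly pulse whenever a plot's water content falls below 95% of the
# same-site control-plot mean). Every stochastic choice flows from one
# integer seed.

#' Site climate specification
#'
#' Parameters of one site's climate and soil for the synthetic generator.
#' The temperature course is a seasonal sinusoid (peak in late July) plus
#' AR(1) day-to-day weather noise; rain is a wet-season Bernoulli-gamma
#' process shared by all plots of the site; soil water follows a
#' single-layer bucket (infiltration minus temperature-driven
#' evapotranspiration) bounded between a residual water content and the
#' texture's saturation.
#'
#' @param name Site label.
#' @param mean_annual_temp_C,seasonal_temp_amplitude_C Sinusoid mean and
#'   half-amplitude (deg C).
#' @param wet_season_start_md,wet_season_end_md Month-day strings bounding
#'   the rainy season (wraps over the new year).
#' @param rain_prob_wet,rain_prob_dry Daily rain probability inside and
#'   outside the wet season.
#' @param rain_shape,rain_scale Gamma parameters of daily rain amount (mm).
#' @param texture A [soil_texture()].
#' @param latitude_order 1 = southernmost.
#' @return List with class `site_climate_spec`.
#' @export
site_climate_spec <- function(name, mean_annual_temp_C,
                              seasonal_temp_amplitude_C,
                              wet_season_start_md, wet_season_end_md,
                              rain_prob_wet, rain_prob_dry,
                              rain_shape = 0.8, rain_scale = 10,
                              texture, latitude_order) {
  structure(list(name = name, mean_annual_temp_C = mean_annual_temp_C,
                 seasonal_temp_amplitude_C = seasonal_temp_amplitude_C,
                 wet_season_start_md = wet_season_start_md,
                 wet_season_end_md = wet_season_end_md,
                 rain_prob_wet = rain_prob_wet, rain_prob_dry = rain_prob_dry,
                 rain_shape = rain_shape, rain_scale = rain_scale,
                 texture = texture, latitude_order = latitude_order),
            class = "site_climate_spec")
}

#' Default site specifications for the three-prairie gradient
#'
#' South-to-north defaults: the southern site is warmest with the earliest
#' dry-season onset and driest summers; the northern site is coolest with
#' the longest wet season and the most mesic summers; the central site is
#' intermediate. Soil textures are plausible placeholders for the three
#' regions (no measured values exist for the sites), chosen so the three
#' retention curves genuinely differ.
#'
#' @return Named list of [site_climate_spec()] objects.
#' @export
default_site_specs <- function() {
  list(
    southern = site_climate_spec(
      "southern", mean_annual_temp_C = 12.5, seasonal_temp_amplitude_C = 8.5,
      wet_season_start_md = "10-20", wet_season_end_md = "04-05",
      rain_prob_wet = 0.55, rain_prob_dry = 0.02,
      texture = soil_texture(sand = 0.45, clay = 0.18, om = 0.02),
      latitude_order = 1),
    central = site_climate_spec(
      "central", mean_annual_temp_C = 11.5, seasonal_temp_amplitude_C = 7.5,
      wet_season_start_md = "10-10", wet_season_end_md = "05-10",
      rain_prob_wet = 0.60, rain_prob_dry = 0.03,
      texture = soil_texture(sand = 0.35, clay = 0.25, om = 0.03),
      latitude_order = 2),
    northern = site_climate_spec(
      "northern", mean_annual_temp_C = 10.5, seasonal_temp_amplitude_C = 6.5,
      wet_season_start_md = "10-01", wet_season_end_md = "05-20",
      rain_prob_wet = 0.65, rain_prob_dry = 0.02,
      texture = soil_texture(sand = 0.40, clay = 0.20, om = 0.05),
      latitude_order = 3))
}

ar1_noise <- function(n, sd_stationary, rho = 0.7) {
  if (sd_stationary == 0) return(numeric(n))
  innov <- rnorm(n, 0, sd_stationary * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Generate plot-level environmental series
#'
#' Daily canopy temperature, soil temperature, volumetric water content
#' and water-budget terms for every plot in the design. Within a site all
#' plots share one daily rain series; treatments modify the budget:
#' drought plots receive `drought_infiltration_mult` (0.60 = a 40%
#' exclusion) times the rain as infiltration; warming and warming + ppt
#' plots receive `+warming_delta_C` on canopy temperature and
#' `soil_warming_frac` of it on soil temperature (soil damping), which
#' raises their evapotranspiration; warming + ppt plots additionally get a
#' nightly irrigation pulse on any day their previous-day water content
#' was below `irrigation_trigger` times the same-site control-plot mean —
#' the feedback rule of the field system.
#'
#' @param design Design tibble from [plot_design()].
#' @param specs Named list of [site_climate_spec()], one per site.
#' @param start,end Date range (inclusive); at least one full year.
#' @param seed Integer seed.
#' @param temp_noise_sd Stationary SD of the per-plot AR(1) canopy
#'   temperature noise (deg C); 0 gives a deterministic run in which all
#'   same-site, same-treatment plots are identical.
#' @param warming_delta_C Canopy warming offset (deg C).
#' @param soil_warming_frac Fraction of the canopy offset reaching the
#'   soil (default 0.8).
#' @param drought_infiltration_mult Infiltration multiplier for drought
#'   plots (default 0.60).
#' @param irrigation_trigger Fraction of the control-plot mean VWC below
#'   which a warming + ppt plot is irrigated that night (default 0.95).
#' @param irrigation_pulse_mm Water added per irrigation night (mm).
#' @param bucket_depth_mm Soil layer depth represented by the VWC probe.
#' @return Tibble `plot_id`, `date`, `canopy_temp_C`, `soil_temp_C`,
#'   `vwc`, `rain_mm`, `infiltration_mm`, `irrigation_mm`.
#' @export
generate_environment <- function(design, specs = default_site_specs(),
                                 start = as.Date("2016-07-01"),
                                 end = as.Date("2018-08-31"),
                                 seed = 1L,
                                 temp_noise_sd = 1.6,
                                 warming_delta_C = 2.5,
                                 soil_warming_frac = 0.8,
                                 drought_infiltration_mult = 0.60,
                                 irrigation_trigger = 0.95,
                                 irrigation_pulse_mm = 6,
                                 bucket_depth_mm = 300) {
  validate_design(design)
  miss <- setdiff(levels(design$site), names(specs))
  if (length(miss) > 0)
    stop("no site spec for: ", paste(miss, collapse = ", "), call. = FALSE)
  dates <- seq(start, end, by = "day")
  nd <- length(dates)
  if (nd < 365) stop("need at least one full year of daily steps", call. = FALSE)
  doy <- as.integer(format(dates, "%j"))
  set.seed(seed)

  out <- list()
  for (s in levels(design$site)) {
    spec <- specs[[s]]
    plots <- design[design$site == s, ]
    np <- nrow(plots)
    rc <- fit_retention_curve(spec$texture)
    theta_r <- 0.6 * rc$theta_1500
    w_cap <- rc$theta_s * bucket_depth_mm
    w_res <- theta_r * bucket_depth_mm

    wet <- in_md_window(dates, spec$wet_season_start_md, spec$wet_season_end_md)
    p_rain <- ifelse(wet, spec$rain_prob_wet, spec$rain_prob_dry)
    rain <- rbinom(nd, 1, p_rain) *
      rgamma(nd, shape = spec$rain_shape, scale = spec$rain_scale)

    base_T <- spec$mean_annual_temp_C + spec$seasonal_temp_amplitude_C *
      cos(2 * pi * (doy - 208) / 365.25)
    warm <- plots$temp_category == "warming"
    canopy <- matrix(base_T, nd, np)
    for (j in seq_len(np)) canopy[, j] <- canopy[, j] + ar1_noise(nd, temp_noise_sd)
    canopy[, warm] <- canopy[, warm] + warming_delta_C
    soil_T <- spec$mean_annual_temp_C + 0.75 * spec$seasonal_temp_amplitude_C *
      cos(2 * pi * (doy - 222) / 365.25)
    soil <- matrix(soil_T, nd, np) +
      0.6 * sweep(canopy, 1, base_T)[, , drop = FALSE] -
      0.6 * matrix(ifelse(warm, warming_delta_C, 0), nd, np, byrow = TRUE)
    soil[, warm] <- soil[, warm] + soil_warming_frac * warming_delta_C

    infil_mult <- ifelse(plots$treatment == "drought",
                         drought_infiltration_mult, 1)
    is_ctrl <- plots$treatment == "control"
    is_wppt <- plots$treatment == "warming_ppt"

    W <- matrix(NA_real_, nd, np)
    irrig <- matrix(0, nd, np)
    infil <- matrix(0, nd, np)
    # runs start in the Mediterranean summer drought: near-dry bucket
    w_now <- rep(w_res + 0.25 * (w_cap - w_res), np)
    for (t in seq_len(nd)) {
      if (any(is_wppt)) {
        ctrl_mean <- mean(w_now[is_ctrl]) / bucket_depth_mm
        dry <- is_wppt & (w_now / bucket_depth_mm < irrigation_trigger * ctrl_mean)
        irrig[t, dry] <- irrigation_pulse_mm
      }
      infil[t, ] <- rain[t] * infil_mult + irrig[t, ]
      pet <- pmax(0, 0.28 * canopy[t, ] - 0.5)
      avail <- pmin(pmax((w_now - w_res) / (w_cap - w_res), 0), 1)
      w_now <- pmin(pmax(w_now + infil[t, ] - pet * avail, w_res), w_cap)
      W[t, ] <- w_now
    }
    for (j in seq_len(np)) {
      out[[length(out) + 1]] <- tibble::tibble(
        plot_id = plots$plot_id[j], date = dates,
        canopy_temp_C = canopy[, j], soil_temp_C = soil[, j],
        vwc = W[, j] / bucket_depth_mm,
        rain_mm = rain, infiltration_mm = infil[, j],
        irrigation_mm = irrig[, j])
    }
  }
  dplyr::bind_rows(out)
}

# Latent seasonal greenness: two logistic growth components — a fast fall
# rise anchored at the return of plant-available water and a slower spring
# growth phase — both closed by a logistic senescence decline. The spring
# and senescence phases carry the warming shift; the fall rise stays tied
# to the rains. The curve rises appreciably into its spring peak, so the
# seasonal maximum is a genuine hump rather than a winter plateau.
latent_ndvi <- function(t, greenup, senesc_infl, amp_fall = 0.25,
                        amp_spring = 0.30, fall_rise_rate = 8,
                        spring_rise_rate = 20, fall_rate = 7,
                        rise_lag = 20, spring_lead = 55) {
  rise1 <- 1 / (1 + exp(-(t - (greenup + rise_lag)) / fall_rise_rate))
  rise2 <- 1 / (1 + exp(-(t - (senesc_infl - spring_lead)) / spring_rise_rate))
  fall <- 1 / (1 + exp((t - senesc_infl) / fall_rate))
  (amp_fall * rise1 + amp_spring * rise2) * fall
}

# Truth phenometrics from a latent daily curve over one season window,
# applying the same threshold definitions the detectors use.
truth_from_latent <- function(dates, latent, senescence_fraction = 0.80) {
  i <- which.max(latent)
  peak_date <- dates[i]
  after <- seq_along(dates) > i
  hit <- after & latent <= senescence_fraction * latent[i]
  sen_date <- if (any(hit)) dates[which(hit)[1]] else as.Date(NA)
  list(peak_date = peak_date, peak_value = latent[i], senescence_date = sen_date)
}

#' Generate plot-level NDVI series with ground truth
#'
#' For every plot, a latent seasonal greenness curve is built per growth
#' cycle: a double-logistic whose fall rise is anchored at the first
#' post-summer date the plot's matric potential climbs back above the
#' wilting point (the return of the rains) and whose spring decline
#' inflection is a site date advanced by `warming_advance_days` in
#' warming-category plots. Observed NDVI is the latent curve at the
#' sampling dates plus Gaussian noise, clipped to `[-1, 1]`. Ground truth
#' (peak, senescence and green-up dates) is computed from the latent curve
#' on the daily grid using the same threshold definitions as the
#' detectors, so noise-free daily sampling recovers it exactly.
#'
#' @param env Environmental series from [generate_environment()].
#' @param design Design tibble.
#' @param specs Site specs (for retention curves).
#' @param config A [pheno_config()] (season windows, thresholds).
#' @param sampling_interval_days Named vector of days between NDVI surveys
#'   per site (default biweekly southern, weekly elsewhere).
#' @param seed Integer seed.
#' @param noise_sd SD of observation noise (NDVI units, default 0.02).
#' @param pheno_jitter_sd Plot-level SD (days) of the spring/senescence
#'   phase timing, the plot-to-plot biological variation in phenology;
#'   0 makes same-site same-treatment plots identical.
#' @param warming_advance_days Advance of the spring growth and
#'   senescence phases in warming-category plots (days, default 20; the
#'   rain-anchored fall rise is not shifted).
#' @param senesc_doy Named vector: site-level day-of-year of the ambient
#'   senescence inflection (southern earliest).
#' @param base Summer baseline NDVI.
#' @param latent_args Named list of overrides for the latent-curve shape
#'   constants (see `latent_ndvi` internals: `amp_fall`, `amp_spring`,
#'   `fall_rise_rate`, `spring_rise_rate`, `fall_rate`, `rise_lag`,
#'   `spring_lead`).
#' @return List `ndvi` (tibble `plot_id`, `date`, `ndvi`) and `truth`
#'   (tibble `plot_id`, `season`, `true_peak_date`, `true_senescence_date`,
#'   `true_greenup_date`, `warming_advance_days`).
#' @export
generate_ndvi <- function(env, design, specs = default_site_specs(),
                          config = pheno_config(),
                          sampling_interval_days = c(southern = 14, central = 7,
                                                     northern = 7),
                          seed = 1L, noise_sd = 0.02,
                          pheno_jitter_sd = 3,
                          warming_advance_days = 20,
                          senesc_doy = c(southern = 125, central = 145,
                                         northern = 156),
                          base = 0.15, latent_args = list()) {
  validate_design(design)
  set.seed(seed + 1L)
  curves <- lapply(specs, function(sp) fit_retention_curve(sp$texture))
  psi <- matric_potential_series(env, design, curves,
                                 wilting_point_kPa = config$wilting_point_kPa)
  all_dates <- sort(unique(env$date))
  span <- range(all_dates)
  if (diff(span) < 300)
    stop("sampling window shorter than one season", call. = FALSE)

  ndvi_rows <- list(); truth_rows <- list()
  tnum <- as.numeric(all_dates)
  for (i in seq_len(nrow(design))) {
    pid <- design$plot_id[i]
    s <- as.character(design$site[i])
    warm <- design$temp_category[i] == "warming"
    p_psi <- psi[psi$plot_id == pid, ]
    latent_total <- rep(base, length(all_dates))
    jitter <- if (pheno_jitter_sd > 0) rnorm(1, 0, pheno_jitter_sd) else 0
    for (season in names(config$season_windows)) {
      yr <- as.integer(season)
      search_from <- as.Date(sprintf("%d-08-15", yr - 1))
      above <- p_psi$date >= search_from &
        p_psi$psi_kPa > config$wilting_point_kPa
      g_date <- if (any(above)) p_psi$date[which(above)[1]]
        else as.Date(sprintf("%d-10-15", yr - 1))
      s_infl <- as.numeric(as.Date(sprintf("%d-01-01", yr)) - 1) +
        senesc_doy[[s]] + jitter -
        (if (warm) warming_advance_days else 0)
      latent_total <- latent_total +
        do.call(latent_ndvi, c(list(t = tnum, greenup = as.numeric(g_date),
                                    senesc_infl = s_infl), latent_args))
    }
    # truth = the detectors' own threshold definitions applied to the
    # latent curve on the daily grid
    gu_truth <- greenup_date(all_dates, pmin(latent_total, 1),
                             config$summer_min_window,
                             fraction = config$greenup_fraction,
                             floor = config$greenup_floor,
                             offset = config$greenup_offset)
    for (season in names(config$season_windows)) {
      w <- config$season_windows[[season]]
      inw <- in_window(all_dates, w)
      tr <- truth_from_latent(all_dates[inw], latent_total[inw],
                              config$senescence_fraction)
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        plot_id = pid, season = season,
        true_peak_date = tr$peak_date,
        true_senescence_date = tr$senescence_date,
        true_greenup_date = if (season == as.character(config$years[2]))
          gu_truth$greenup_date else as.Date(NA),
        warming_advance_days = if (warm) warming_advance_days else 0)
    }
    interval <- sampling_interval_days[[s]]
    samp <- seq(span[1] + 3, span[2], by = interval)
    li <- match(samp, all_dates)
    obs <- latent_total[li] + rnorm(length(samp), 0, noise_sd)
    ndvi_rows[[length(ndvi_rows) + 1]] <- tibble::tibble(
      plot_id = pid, date = samp, ndvi = pmin(pmax(obs, -1), 1))
  }
  list(ndvi = dplyr::bind_rows(ndvi_rows), truth = dplyr::bind_rows(truth_rows))
}

#' Default focal-species parameters for the flowering generator
#'
#' Eight range-restricted focal species: per species, the ambient peak
#' flowering day-of-year (2017), a base mean reproductive abundance, and
#' the sites where the species established (two perennials establish only
#' in the north; the grass fails in the south), mirroring the strong
#' south-to-north increase in establishment the design emulates.
#'
#' @return Tibble `species`, `peak_doy`, `base_mu`, `sites` (list-column).
#' @export
default_species_params <- function() {
  tibble::tibble(
    species = c("ACHMOL", "COLGRA", "FESROE", "MICLAC",
                "PLANOT", "PLECON", "RANAUS", "SIDMAL"),
    peak_doy = c(125, 115, 150, 140, 110, 120, 135, 145),
    base_mu = c(6, 20, 10, 4, 8, 25, 3, 12),
    sites = list(c("southern", "central", "northern"),
                 c("southern", "central", "northern"),
                 c("central", "northern"),
                 "northern",
                 c("southern", "central", "northern"),
                 c("southern", "central", "northern"),
                 "northern",
                 c("southern", "central", "northern")))
}

#' Generate flowering surveys with ground truth
#'
#' Per species x plot, the number of flowering individuals is drawn from a
#' zero-inflated negative binomial whose mean rises and whose
#' zero-inflation falls from south to north (the establishment gradient).
#' Open-flower counts follow a discretised Gaussian pulse in time centred
#' on the plot's true peak flowering date — a site-shifted species date,
#' advanced by `warming_advance_days / 2.5 * warming_delta_C` in
#' warming-category plots — scaled by the number of individuals, observed
#' with Poisson noise (or exactly, when `count_noise = "none"`). Surveys
#' are weekly (biweekly at the southern site) within the spring season.
#'
#' @param design Design tibble.
#' @param species_params Tibble from [default_species_params()].
#' @param seed Integer seed.
#' @param survey_start,survey_end Survey season bounds (Dates).
#' @param sampling_interval_days Per-site days between surveys.
#' @param warming_advance_days,warming_delta_C Treatment shift controls.
#' @param site_mu_mult Named abundance multipliers (south < north).
#' @param site_zi Named zero-inflation probabilities (south > north).
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param flowers_per_plant Pulse height scale.
#' @param pulse_sd_days Gaussian pulse SD (days).
#' @param peak_jitter_sd Plot-level SD of the true peak date (days).
#' @param count_noise `"poisson"` or `"none"`.
#' @return List `surveys` (tibble `plot_id`, `species`, `date`,
#'   `open_flowers`, `flowering_individuals`) and `truth` (tibble
#'   `plot_id`, `species`, `n_individuals`, `true_onset_date`,
#'   `true_peak_flower_date`).
#' @export
generate_flowering <- function(design,
                               species_params = default_species_params(),
                               seed = 1L,
                               survey_start = as.Date("2017-03-15"),
                               survey_end = as.Date("2017-06-20"),
                               sampling_interval_days = c(southern = 14,
                                                          central = 7,
                                                          northern = 7),
                               warming_advance_days = 20,
                               warming_delta_C = 2.5,
                               site_mu_mult = c(southern = 0.3, central = 1,
                                                northern = 2.5),
                               site_zi = c(southern = 0.6, central = 0.35,
                                           northern = 0.15),
                               nb_size = 1.5, flowers_per_plant = 3,
                               pulse_sd_days = 8, peak_jitter_sd = 2,
                               count_noise = "poisson") {
  validate_design(design)
  stopifnot(nrow(species_params) >= 2, count_noise %in% c("poisson", "none"))
  set.seed(seed + 2L)
  advance <- warming_advance_days / 2.5 * warming_delta_C
  year0 <- as.Date(sprintf("%d-01-01", as.integer(format(survey_start, "%Y")))) - 1

  survey_rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(design))) {
    pid <- design$plot_id[i]
    s <- as.character(design$site[i])
    warm <- design$temp_category[i] == "warming"
    samp <- seq(survey_start, survey_end, by = sampling_interval_days[[s]])
    for (j in seq_len(nrow(species_params))) {
      sp <- species_params[j, ]
      present <- s %in% sp$sites[[1]]
      zi <- if (present) site_zi[[s]] else 1
      mu <- sp$base_mu * site_mu_mult[[s]]
      n_ind <- if (runif(1) < zi) 0L
        else rnbinom(1, size = nb_size, mu = mu)
      peak <- round(sp$peak_doy +
                      c(southern = -10, central = 0, northern = 8)[[s]] -
                      (if (warm) advance else 0) +
                      (if (peak_jitter_sd > 0) rnorm(1, 0, peak_jitter_sd) else 0))
      pulse_mean <- function(d) {
        n_ind * flowers_per_plant *
          exp(-(as.numeric(d - year0) - peak)^2 / (2 * pulse_sd_days^2))
      }
      mu_t <- pulse_mean(samp)
      # noise-free counts use floor so the pulse keeps a unique daily
      # maximum at its centre (rounding can tie adjacent days)
      flowers <- if (count_noise == "poisson") rpois(length(samp), mu_t)
        else as.integer(floor(mu_t + 1e-9))
      # onset truth: first day the expected count reaches 1, the
      # detectability threshold of an integer survey (daily grid)
      daily <- seq(survey_start - 30, survey_end, by = "day")
      mu_d <- pulse_mean(daily)
      onset <- if (n_ind > 0 && any(mu_d >= 1)) daily[which(mu_d >= 1)[1]]
        else as.Date(NA)
      survey_rows[[length(survey_rows) + 1]] <- tibble::tibble(
        plot_id = pid, species = sp$species, date = samp,
        open_flowers = as.integer(flowers),
        flowering_individuals = n_ind)
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        plot_id = pid, species = sp$species, n_individuals = n_ind,
        true_onset_date = onset,
        true_peak_flower_date = if (n_ind > 0) year0 + peak else as.Date(NA))
    }
  }
  list(surveys = dplyr::bind_rows(survey_rows),
       truth = dplyr::bind_rows(truth_rows))
}

#' Simulate a complete synthetic experiment
#'
#' Chains [generate_environment()], [generate_ndvi()] and
#' [generate_flowering()] under one seed into the bundle the pipeline
#' consumes, with all ground truth attached.
#'
#' @param config A [pheno_config()].
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @param specs Site specs.
#' @param env_args,ndvi_args,flowering_args Named lists of overrides
#'   passed to the three generators.
#' @return List with class `pheno_experiment`: `design`, `specs`, `env`,
#'   `ndvi`, `flowering`, `truth` (list with `ndvi` and `flowering`),
#'   `textures` (per-site tibble), `config`, `seed`.
#' @export
simulate_experiment <- function(config = pheno_config(),
                                seed = config$rng_seed,
                                specs = default_site_specs(),
                                env_args = list(), ndvi_args = list(),
                                flowering_args = list()) {
  design <- plot_design(sites = names(specs))
  env <- do.call(generate_environment,
                 c(list(design = design, specs = specs, seed = seed,
                        warming_delta_C = config$warming_delta_C), env_args))
  nd <- do.call(generate_ndvi,
                c(list(env = env, design = design, specs = specs,
                       config = config, seed = seed), ndvi_args))
  fl <- do.call(generate_flowering,
                c(list(design = design, seed = seed,
                       warming_delta_C = config$warming_delta_C),
                  flowering_args))
  textures <- dplyr::bind_rows(lapply(specs, function(sp)
    tibble::tibble(site = sp$name, sand = sp$texture$sand,
                   clay = sp$texture$clay, om = sp$texture$om)))
  structure(list(design = design, specs = specs, env = env,
                 ndvi = nd$ndvi, flowering = fl$surveys,
                 truth = list(ndvi = nd$truth, flowering = fl$truth),
                 textures = textures, config = config, seed = seed),
            class = "pheno_experiment")
}

#' @export
print.pheno_experiment <- function(x, ...) {
  cat("<pheno_experiment> seed", x$seed, "\n")
  cat(" ", nrow(x$design), "plots;", nrow(x$env), "env days x plots;",
      nrow(x$ndvi), "NDVI surveys;", nrow(x$flowering), "flowering rows\n")
  invisible(x)
}
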