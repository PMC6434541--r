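# Community phenometrics from plot-level NDVI survey series.
#
# All detectors operate on the sampled dates only: no interpolation or
# smoothing, so every returned date is a survey date and the date
# resolution equals the sampling interval.

check_ndvi_series <- function(dates, ndvi) {
  stopifnot(length(dates) == length(ndvi))
  if (is.unsorted(as.numeric(dates), strictly = TRUE))
    stop("NDVI series dates must be strictly increasing", call. = FALSE)
  if (any(ndvi < -1 | ndvi > 1, na.rm = TRUE))
    stop("NDVI out of [-1, 1]", call. = FALSE)
}

#' Date and value of peak biomass
#'
#' Peak biomass is the maximum NDVI observed within the season window;
#' ties break to the earliest date.
#'
#' @param dates Survey dates (Date), strictly increasing.
#' @param ndvi NDVI values in `[-1, 1]`, same length.
#' @param window Optional half-open `c(start, end)` Date window; default
#'   uses the whole series.
#' @return List `peak_date`, `peak_ndvi`.
#' @examples
#' d <- as.Date("2017-01-01") + c(100, 110, 120)
#' peak_biomass(d, c(0.5, 0.6, 0.55))
#' @export
peak_biomass <- function(dates, ndvi, window = NULL) {
  check_ndvi_series(dates, ndvi)
  if (!is.null(window)) {
    keep <- in_window(dates, window)
    dates <- dates[keep]; ndvi <- ndvi[keep]
  }
  if (length(dates) == 0) stop("no NDVI observations in window", call. = FALSE)
  i <- which.max(ndvi)  # earliest index attaining the max
  list(peak_date = dates[i], peak_ndvi = ndvi[i])
}

#' Date of senescence
#'
#' The first sampled date strictly after peak biomass at which NDVI has
#' fallen to at or below `fraction` of the peak value. If the threshold is
#' never crossed before the series (or window) ends the result is censored
#' rather than extrapolated.
#'
#' @inheritParams peak_biomass
#' @param peak Result of [peak_biomass()] on the same series/window.
#' @param fraction Threshold as a fraction of peak NDVI (default 0.80).
#' @return List `senescence_date` (Date or NA), `censored` (logical).
#' @export
senescence_date <- function(dates, ndvi, peak, fraction = 0.80,
                            window = NULL) {
  check_ndvi_series(dates, ndvi)
  if (!is.null(window)) {
    keep <- in_window(dates, window)
    dates <- dates[keep]; ndvi <- ndvi[keep]
  }
  after <- dates > peak$peak_date
  hit <- after & ndvi <= fraction * peak$peak_ndvi
  if (!any(hit)) return(list(senescence_date = as.Date(NA), censored = TRUE))
  list(senescence_date = dates[which(hit)[1]], censored = FALSE)
}

#' Rate of senescence
#'
#' Finds, among all runs of `window_points` consecutive sampled
#' observations in the season, the run with the greatest total decline
#' (first NDVI minus last NDVI) and returns the least-squares slope of
#' NDVI against time in days over that run. With `window_points = 2` this
#' is the steepest difference quotient. A two-point window is the fallback
#' where senescence is so rapid that three points would not be linear.
#'
#' @inheritParams peak_biomass
#' @param window_points Run length: 3 (default) or 2.
#' @param after Optional Date: restrict the search to observations at or
#'   after this date (e.g. the peak date).
#' @return List `slope` (delta-NDVI per day), `run_dates` (the run used),
#'   `nonsenescent` (TRUE when the best run does not decline, i.e. the
#'   slope is not negative).
#' @examples
#' d <- as.Date("2017-01-01") + c(110, 120, 130, 140)
#' senescence_rate(d, c(0.60, 0.55, 0.47, 0.40))$slope   # -0.0075
#' @export
senescence_rate <- function(dates, ndvi, window_points = 3, window = NULL,
                            after = NULL) {
  check_ndvi_series(dates, ndvi)
  stopifnot(window_points >= 2)
  if (!is.null(window)) {
    keep <- in_window(dates, window)
    dates <- dates[keep]; ndvi <- ndvi[keep]
  }
  if (!is.null(after)) {
    keep <- dates >= after
    dates <- dates[keep]; ndvi <- ndvi[keep]
  }
  n <- length(dates)
  if (n < window_points)
    stop("need at least ", window_points, " observations for the senescence slope",
         call. = FALSE)
  starts <- seq_len(n - window_points + 1)
  decline <- ndvi[starts] - ndvi[starts + window_points - 1]
  b <- starts[which.max(decline)]
  idx <- b:(b + window_points - 1)
  slope <- ls_slope(dates[idx], ndvi[idx])
  list(slope = slope, run_dates = dates[idx], nonsenescent = slope >= 0)
}

#' Fall green-up date
#'
#' Locates the summer minimum NDVI within a configured summer window
#' (ties to the earliest date), then returns the first sampled date after
#' the minimum at which NDVI is at or above `fraction` times the minimum.
#' When the minimum is at or below `floor` the multiplicative threshold is
#' degenerate, so `minimum + offset` is used instead and the substitution
#' is flagged.
#'
#' @inheritParams peak_biomass
#' @param summer_window Half-open Date window in which to locate the
#'   summer minimum.
#' @param fraction Threshold multiple of the minimum (default 1.25).
#' @param floor,offset Guard for near-zero minima (defaults 0.05, 0.05).
#' @return List `min_date`, `min_ndvi`, `greenup_date` (Date or NA),
#'   `censored`, `threshold_substituted`.
#' @export
greenup_date <- function(dates, ndvi, summer_window, fraction = 1.25,
                         floor = 0.05, offset = 0.05) {
  check_ndvi_series(dates, ndvi)
  inw <- in_window(dates, summer_window)
  if (!any(inw)) stop("no observations in the summer-minimum window", call. = FALSE)
  i <- which(inw)[which.min(ndvi[inw])]
  min_date <- dates[i]; min_ndvi <- ndvi[i]
  substituted <- min_ndvi <= floor
  threshold <- if (substituted) min_ndvi + offset else fraction * min_ndvi
  after <- dates > min_date
  hit <- after & ndvi >= threshold
  if (!any(hit))
    return(list(min_date = min_date, min_ndvi = min_ndvi,
                greenup_date = as.Date(NA), censored = TRUE,
                threshold_substituted = substituted))
  list(min_date = min_date, min_ndvi = min_ndvi,
       greenup_date = dates[which(hit)[1]], censored = FALSE,
       threshold_substituted = substituted)
}

#' Growing-season length
#'
#' Days from fall green-up to the following season's date of senescence.
#'
#' @param greenup Green-up date (Date).
#' @param senescence Senescence date (Date).
#' @return Integer day count, or NA if either date is NA (censored plots
#'   are excluded pairwise downstream).
#' @export
growing_season_length <- function(greenup, senescence) {
  if (is.na(greenup) || is.na(senescence)) return(NA_integer_)
  if (senescence < greenup)
    stop("senescence date precedes green-up date", call. = FALSE)
  as.integer(senescence - greenup)
}

#' All NDVI phenometrics for a set of plots
#'
#' Applies the four detectors per plot and season: peak biomass, date of
#' senescence, rate of senescence (searched after the peak), and — for the
#' first focal year — the fall green-up and the growing-season length
#' ending at the second year's senescence.
#'
#' @param ndvi Long tibble `plot_id`, `date`, `ndvi`.
#' @param config A [pheno_config()]; supplies season windows and thresholds.
#' @return Tibble: `plot_id`, `season`, `peak_date`, `peak_ndvi`,
#'   `senescence_date`, `senescence_rate`, `senescence_censored`,
#'   `nonsenescent`, `greenup_date`, `gsl_days`, `greenup_censored`,
#'   `threshold_substituted`.
#' @export
ndvi_phenometrics <- function(ndvi, config = pheno_config()) {
  stopifnot(all(c("plot_id", "date", "ndvi") %in% names(ndvi)))
  res <- list()
  for (pid in unique(ndvi$plot_id)) {
    p <- ndvi[ndvi$plot_id == pid, ]
    p <- p[order(p$date), ]
    gu <- tryCatch(
      greenup_date(p$date, p$ndvi, config$summer_min_window,
                   fraction = config$greenup_fraction,
                   floor = config$greenup_floor,
                   offset = config$greenup_offset),
      error = function(e) NULL)
    for (season in names(config$season_windows)) {
      w <- config$season_windows[[season]]
      keep <- in_window(p$date, w)
      if (sum(keep) < config$senescence_window_points) next
      pk <- peak_biomass(p$date[keep], p$ndvi[keep])
      sn <- senescence_date(p$date[keep], p$ndvi[keep], pk,
                            fraction = config$senescence_fraction)
      sr <- senescence_rate(p$date[keep], p$ndvi[keep],
                            window_points = config$senescence_window_points,
                            after = pk$peak_date)
      is_second <- season == as.character(config$years[2])
      gsl <- if (is_second && !is.null(gu) && !gu$censored && !sn$censored &&
                 sn$senescence_date >= gu$greenup_date)
        growing_season_length(gu$greenup_date, sn$senescence_date)
      else NA_integer_
      res[[length(res) + 1]] <- tibble::tibble(
        plot_id = pid, season = season,
        peak_date = pk$peak_date, peak_ndvi = pk$peak_ndvi,
        senescence_date = sn$senescence_date,
        senescence_rate = sr$slope,
        senescence_censored = sn$censored,
        nonsenescent = sr$nonsenescent,
        greenup_date = if (is_second && !is.null(gu)) gu$greenup_date else as.Date(NA),
        gsl_days = gsl,
        greenup_censored = if (is_second && !is.null(gu)) gu$censored else NA,
        threshold_substituted = if (!is.null(gu)) gu$threshold_substituted else NA)
    }
  }
  dplyr::bind_rows(res)
}
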