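#' Analysis configuration
#'
#' Bundle of the tunable constants the pipeline uses: calendar windows for
#' the annual/winter/spring climate summaries and for the NDVI seasons,
#' phenometric detection thresholds, the wilting-point tension, the warming
#' offset, the treatment-collapsing significance level, and the AICc
#' equivalence band. All windows are half-open `[start, end)` so adjacent
#' windows never double count a day.
#'
#' @param years Two consecutive focal phenology years (e.g. 2017, 2018).
#'   The annual climate window for year `y` runs 15 July `y-1` to
#'   15 July `y`, matching a Mediterranean hydrological year.
#' @param wilting_point_kPa Permanent wilting point tension (kPa, negative).
#'   Matric potentials below this are clamped for the mean-annual summary
#'   and counted as days below wilting point.
#' @param senescence_fraction Senescence is the first sampled date after
#'   peak biomass with NDVI at or below this fraction of the peak.
#' @param greenup_fraction Green-up is the first sampled date after the
#'   summer minimum with NDVI at or above this multiple of the minimum.
#' @param greenup_floor,greenup_offset If the summer minimum NDVI is at or
#'   below `greenup_floor`, the multiplicative green-up rule degenerates
#'   (125% of ~0 is ~0), so the threshold becomes `minimum + greenup_offset`
#'   and the substitution is flagged.
#' @param senescence_window_points Number of consecutive sampling points
#'   over which the senescence slope is computed (3, or 2 where senescence
#'   is too rapid for three points to be linear).
#' @param collapse_alpha Significance level for the within-pair treatment
#'   comparisons (control vs drought; warming vs warming + ppt); both must
#'   be non-significant at this level before collapsing to the two-level
#'   temperature factor. Default 0.10 treats marginal evidence as a
#'   difference.
#' @param delta_aicc_equiv Models within this many AICc units of the best
#'   model are reported as equivalent.
#' @param warming_delta_C Canopy-temperature offset imposed by the heaters
#'   (deg C); the denominator of the temperature-sensitivity formula.
#' @param rng_seed Integer seed used by any stochastic step.
#'
#' @return A list with class `pheno_config`.
#' @examples
#' cfg <- pheno_config()
#' cfg$annual_windows[["2017"]]
#' @export
pheno_config <- function(years = c(2017, 2018),
                         wilting_point_kPa = -1500,
                         senescence_fraction = 0.80,
                         greenup_fraction = 1.25,
                         greenup_floor = 0.05,
                         greenup_offset = 0.05,
                         senescence_window_points = 3,
                         collapse_alpha = 0.10,
                         delta_aicc_equiv = 2.0,
                         warming_delta_C = 2.5,
                         rng_seed = 1L) {
  stopifnot(length(years) == 2, diff(years) == 1,
            wilting_point_kPa < 0,
            senescence_fraction > 0, senescence_fraction <= 2,
            greenup_fraction > 0, greenup_fraction <= 2,
            senescence_window_points %in% c(2, 3),
            collapse_alpha > 0, collapse_alpha < 1,
            delta_aicc_equiv > 0, warming_delta_C > 0)
  annual <- lapply(years, function(y) {
    c(start = as.Date(sprintf("%d-07-15", y - 1)),
      end   = as.Date(sprintf("%d-07-15", y)))
  })
  names(annual) <- as.character(years)
  # NDVI season windows: growth cycle of year y runs from the preceding
  # fall through the following mid-summer; the summer-minimum window for
  # green-up detection sits between the two growth cycles.
  seasons <- lapply(years, function(y) {
    c(start = as.Date(sprintf("%d-10-01", y - 1)),
      end   = as.Date(sprintf("%d-08-01", y)))
  })
  names(seasons) <- as.character(years)
  structure(list(
    years = as.integer(years),
    annual_windows = annual,
    season_windows = seasons,
    summer_min_window = c(start = as.Date(sprintf("%d-06-15", years[1])),
                          end   = as.Date(sprintf("%d-10-15", years[1]))),
    winter_window = c(start_md = "12-01", end_md = "03-01"),
    spring_window = c(start_md = "03-01", end_md = "06-01"),
    wilting_point_kPa = wilting_point_kPa,
    senescence_fraction = senescence_fraction,
    greenup_fraction = greenup_fraction,
    greenup_floor = greenup_floor,
    greenup_offset = greenup_offset,
    senescence_window_points = as.integer(senescence_window_points),
    collapse_alpha = collapse_alpha,
    delta_aicc_equiv = delta_aicc_equiv,
    warming_delta_C = warming_delta_C,
    rng_seed = as.integer(rng_seed)
  ), class = "pheno_config")
}

#' @export
print.pheno_config <- function(x, ...) {
  cat("<pheno_config>\n")
  cat("  phenology years:", paste(x$years, collapse = ", "), "\n")
  cat("  wilting point:", x$wilting_point_kPa, "kPa\n")
  cat("  senescence threshold:", x$senescence_fraction, "x peak NDVI\n")
  cat("  green-up threshold:", x$greenup_fraction, "x summer minimum\n")
  cat("  warming offset:", x$warming_delta_C, "deg C\n")
  cat("  collapse alpha:", x$collapse_alpha,
      " | AICc equivalence band:", x$delta_aicc_equiv, "\n")
  invisible(x)
}

#' Read an analysis configuration from YAML
#'
#' Reads a YAML file whose keys are arguments of [pheno_config()] and
#' builds the configuration; absent keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pheno_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pheno_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pheno_config, raw)
}
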