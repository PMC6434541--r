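# Population flowering phenometrics from repeated count surveys.

#' First flowering date
#'
#' Earliest survey date with at least one open flower; `NA` if the species
#' never flowered in the plot (absence is a value, not an error).
#'
#' @param dates Survey dates (Date), sorted increasing.
#' @param open_flowers Nonnegative integer counts, same length.
#' @return Date or NA.
#' @examples
#' d <- as.Date("2017-01-01") + c(100, 107, 114)
#' first_flowering_date(d, c(0, 2, 5))
#' @export
first_flowering_date <- function(dates, open_flowers) {
  stopifnot(length(dates) == length(open_flowers), all(open_flowers >= 0))
  hit <- which(open_flowers > 0)
  if (length(hit) == 0) return(as.Date(NA))
  dates[hit[1]]
}

#' Peak flowering date
#'
#' Survey date with the maximum open-flower count; ties break to the
#' earliest date; `NA` if all counts are zero.
#'
#' @inheritParams first_flowering_date
#' @return Date or NA.
#' @export
peak_flowering_date <- function(dates, open_flowers) {
  stopifnot(length(dates) == length(open_flowers), all(open_flowers >= 0))
  if (all(open_flowers == 0)) return(as.Date(NA))
  dates[which.max(open_flowers)]
}

#' Flowering metrics per species and plot
#'
#' Derives, for every species x plot, the first flowering date (FFD), peak
#' flowering date (PFD), maximum open-flower count, and the plot-season
#' reproductive abundance, taken as the maximum `flowering_individuals`
#' across the season's surveys (the season-max captures every individual
#' that flowered at detection while never double counting across weeks —
#' an interpretive choice, since weekly tallies do not define a unique
#' seasonal abundance).
#'
#' @param surveys Long tibble `plot_id`, `species`, `date`, `open_flowers`,
#'   `flowering_individuals`.
#' @param pfd_exclusions Optional tibble `species`, `site` (or `plot_id`)
#'   combinations whose PFD is uncountable in the field and must be
#'   dropped; requires `design` when site-level.
#' @param design Optional design tibble (needed for site-level exclusions).
#' @return Tibble `species`, `plot_id`, `ffd`, `pfd`, `max_open_flowers`,
#'   `abundance`.
#' @export
flowering_metrics <- function(surveys, pfd_exclusions = NULL, design = NULL) {
  need <- c("plot_id", "species", "date", "open_flowers", "flowering_individuals")
  stopifnot(all(need %in% names(surveys)))
  if (nrow(surveys) == 0)
    return(tibble::tibble(species = character(), plot_id = character(),
                          ffd = as.Date(character()), pfd = as.Date(character()),
                          max_open_flowers = integer(), abundance = integer()))
  out <- dplyr::summarise(
    dplyr::group_by(surveys, .data$species, .data$plot_id),
    ffd = first_flowering_date(.data$date[order(.data$date)],
                               .data$open_flowers[order(.data$date)]),
    pfd = peak_flowering_date(.data$date[order(.data$date)],
                              .data$open_flowers[order(.data$date)]),
    max_open_flowers = as.integer(max(.data$open_flowers)),
    abundance = as.integer(max(.data$flowering_individuals)),
    .groups = "drop")
  if (!is.null(pfd_exclusions) && nrow(pfd_exclusions) > 0) {
    if ("site" %in% names(pfd_exclusions)) {
      stopifnot(!is.null(design))
      site_of <- setNames(as.character(design$site), design$plot_id)
      key <- paste(out$species, site_of[out$plot_id])
      drop <- key %in% paste(pfd_exclusions$species, pfd_exclusions$site)
    } else {
      drop <- paste(out$species, out$plot_id) %in%
        paste(pfd_exclusions$species, pfd_exclusions$plot_id)
    }
    out$pfd[drop] <- as.Date(NA)
  }
  out
}

#' Temperature sensitivity of a phenological event
#'
#' For each warmed plot i with an event date, the sensitivity is
#' `(date_i - mean(ambient dates)) / delta_T` in days per degree C
#' (negative = advancement with warming), with the site summary the mean
#' and standard error across warmed plots. When neither the warmed nor the
#' ambient dates vary, the warming contrast carries no within-group
#' variance and is flagged untestable (no p-value can be attached), though
#' the sensitivities themselves are still reported.
#'
#' @param warm_dates Event dates (Date or numeric day-of-year) in warmed
#'   plots.
#' @param ambient_dates Event dates in ambient plots.
#' @param delta_T Imposed warming offset in degrees C (default 2.5).
#' @return List `sensitivity` (per warmed plot, days/C), `mean`, `se`,
#'   `n_warm`, `n_ambient`, `untestable`.
#' @examples
#' temperature_sensitivity(100, 110)          # -4 days/C
#' temperature_sensitivity(c(98, 102), c(108, 112))
#' @export
temperature_sensitivity <- function(warm_dates, ambient_dates, delta_T = 2.5) {
  warm <- as.numeric(warm_dates[!is.na(warm_dates)])
  amb <- as.numeric(ambient_dates[!is.na(ambient_dates)])
  if (length(warm) == 0 || length(amb) == 0)
    stop("temperature sensitivity needs at least one warmed and one ambient date",
         call. = FALSE)
  sens <- (warm - mean(amb)) / delta_T
  untestable <- (length(warm) < 2 || var(warm) == 0) &&
    (length(amb) < 2 || var(amb) == 0)
  list(sensitivity = sens,
       mean = mean(sens),
       se = if (length(sens) > 1) sd(sens) / sqrt(length(sens)) else NA_real_,
       n_warm = length(warm), n_ambient = length(amb),
       untestable = untestable)
}

#' Sensitivity table across species, sites and events
#'
#' Computes per-warmed-plot temperature sensitivities of FFD and PFD for
#' every species x site with at least one warmed and one ambient event
#' date, using the collapsed temperature categories from the design.
#'
#' @param metrics Output of [flowering_metrics()].
#' @param design Design tibble with `plot_id`, `site`, `temp_category`.
#' @param delta_T Warming offset in degrees C.
#' @return Tibble `species`, `site`, `event`, `plot_id`, `sensitivity`,
#'   plus per-combination `site_mean`, `site_se`, `untestable`.
#' @export
sensitivity_table <- function(metrics, design, delta_T = 2.5) {
  d <- dplyr::left_join(metrics, design[, c("plot_id", "site", "temp_category")],
                        by = "plot_id")
  rows <- list()
  for (ev in c("ffd", "pfd")) {
    for (sp in unique(d$species)) {
      for (s in levels(factor(d$site))) {
        g <- d[d$species == sp & d$site == s & !is.na(d[[ev]]), ]
        warm <- g[g$temp_category == "warming", ]
        amb <- g[g$temp_category == "ambient", ]
        if (nrow(warm) == 0 || nrow(amb) == 0) next
        ts <- temperature_sensitivity(warm[[ev]], amb[[ev]], delta_T)
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = sp, site = s, event = toupper(ev),
          plot_id = warm$plot_id,
          sensitivity = ts$sensitivity,
          site_mean = ts$mean, site_se = ts$se,
          untestable = ts$untestable)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Median reproductive abundance by species, site and treatment
#'
#' Plot abundance is the season-max flowering-individual count; the table
#' reports the median across replicate plots (zeros included).
#'
#' @param metrics Output of [flowering_metrics()].
#' @param design Design tibble.
#' @return Tibble `species`, `site`, `treatment`, `median_abundance`, `n_plots`.
#' @export
abundance_table <- function(metrics, design) {
  d <- dplyr::left_join(metrics, design[, c("plot_id", "site", "treatment")],
                        by = "plot_id")
  dplyr::summarise(
    dplyr::group_by(d, .data$species, .data$site, .data$treatment),
    median_abundance = median(.data$abundance),
    n_plots = dplyr::n(), .groups = "drop")
}
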