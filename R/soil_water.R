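#' Soil texture description
#'
#' @param sand,clay,om Mass fractions (0-1) of sand, clay and organic
#'   matter. Sand and clay must not sum above 1.
#' @return A list with class `soil_texture`.
#' @examples
#' soil_texture(sand = 0.40, clay = 0.20, om = 0.025)
#' @export
soil_texture <- function(sand, clay, om = 0.025) {
  stopifnot(is.numeric(sand), is.numeric(clay), is.numeric(om),
            sand >= 0, sand <= 1, clay >= 0, clay <= 1, om >= 0, om <= 1,
            sand + clay <= 1)
  structure(list(sand = sand, clay = clay, om = om), class = "soil_texture")
}

#' Fit a soil-water retention curve from texture
#'
#' Computes the moisture-retention anchor points of the Saxton-Rawls
#' pedotransfer regressions from sand, clay and organic-matter fractions:
#' the volumetric water contents at -1500 kPa (permanent wilting point,
#' `theta_1500`), at -33 kPa (field capacity, `theta_33`) and at saturation
#' (`theta_s`), the air-entry tension `psi_air_entry_kPa`, and the
#' power-law coefficients `A`, `B` of the -1500..-33 kPa tension segment
#' (tension = A * theta^-B). Organic matter enters the regressions in
#' percent by weight; the input is a mass fraction and is converted
#' internally. Gravel, salinity and density adjustments of the full
#' pedotransfer system are not implemented: only matric potential from
#' volumetric water content is needed downstream.
#'
#' @param texture A [soil_texture()].
#' @return A list with class `retention_curve`: `theta_1500`, `theta_33`,
#'   `theta_s`, `psi_air_entry_kPa` (<= 0), `A`, `B`, plus the input texture.
#' @examples
#' rc <- fit_retention_curve(soil_texture(0.40, 0.20, 0.025))
#' rc$theta_33    # ~0.28 for a loam
#' @export
fit_retention_curve <- function(texture) {
  stopifnot(inherits(texture, "soil_texture"))
  S <- texture$sand; C <- texture$clay; OM <- texture$om * 100

  t1500t <- -0.024 * S + 0.487 * C + 0.006 * OM + 0.005 * S * OM -
    0.013 * C * OM + 0.068 * S * C + 0.031
  theta_1500 <- t1500t + (0.14 * t1500t - 0.02)

  t33t <- -0.251 * S + 0.195 * C + 0.011 * OM + 0.006 * S * OM -
    0.027 * C * OM + 0.452 * S * C + 0.299
  theta_33 <- t33t + (1.283 * t33t^2 - 0.374 * t33t - 0.015)

  ts33t <- 0.278 * S + 0.034 * C + 0.022 * OM - 0.018 * S * OM -
    0.027 * C * OM - 0.584 * S * C + 0.078
  theta_s33 <- ts33t + (0.636 * ts33t - 0.107)

  psiet <- -21.67 * S - 27.93 * C - 81.97 * theta_s33 +
    71.12 * S * theta_s33 + 8.29 * C * theta_s33 + 14.05 * S * C + 27.16
  psi_e <- psiet + (0.02 * psiet^2 - 0.113 * psiet - 0.70)

  theta_s <- theta_33 + theta_s33 - 0.097 * S + 0.043

  if (!(theta_1500 > 0 && theta_1500 < theta_33 && theta_33 < theta_s &&
        theta_s <= 1))
    stop("degenerate texture: retention anchors not ordered ",
         sprintf("(theta_1500=%.3f, theta_33=%.3f, theta_s=%.3f)",
                 theta_1500, theta_33, theta_s), call. = FALSE)

  B <- log(1500 / 33) / (log(theta_33) - log(theta_1500))
  A <- exp(log(33) + B * log(theta_33))

  structure(list(theta_1500 = theta_1500, theta_33 = theta_33,
                 theta_s = theta_s,
                 psi_air_entry_kPa = -max(psi_e, 0),
                 A = A, B = B, texture = texture),
            class = "retention_curve")
}

#' @export
print.retention_curve <- function(x, ...) {
  cat("<retention_curve>\n")
  cat(sprintf("  theta_1500 = %.4f  theta_33 = %.4f  theta_s = %.4f\n",
              x$theta_1500, x$theta_33, x$theta_s))
  cat(sprintf("  tension segment: psi = -%.4g * theta^-%.3f kPa;  air entry %.2f kPa\n",
              x$A, x$B, x$psi_air_entry_kPa))
  invisible(x)
}

#' Convert volumetric water content to soil matric potential
#'
#' Piecewise retention relation: below field capacity (`theta <= theta_33`)
#' the power law `psi = -A * theta^-B` (extrapolated below `theta_1500` so
#' tensions drier than wilting point remain representable); between field
#' capacity and saturation, linear in theta from -33 kPa down in magnitude
#' to the air-entry tension; at or above saturation, 0 kPa.
#'
#' @param theta Numeric vector of volumetric water contents, each in (0, 1].
#' @param curve A [fit_retention_curve()] result.
#' @return Matric potential in kPa (<= 0), same length as `theta`;
#'   non-decreasing in `theta`.
#' @examples
#' rc <- fit_retention_curve(soil_texture(0.40, 0.20, 0.025))
#' vwc_to_matric_potential(c(0.10, rc$theta_33, rc$theta_s), rc)
#' @export
vwc_to_matric_potential <- function(theta, curve) {
  stopifnot(inherits(curve, "retention_curve"))
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be finite and > 0", call. = FALSE)
  psi <- numeric(length(theta))
  lo <- theta <= curve$theta_33
  psi[lo] <- -curve$A * theta[lo]^(-curve$B)
  mid <- theta > curve$theta_33 & theta < curve$theta_s
  frac <- (theta[mid] - curve$theta_33) / (curve$theta_s - curve$theta_33)
  psi[mid] <- -33 + frac * (33 + curve$psi_air_entry_kPa)
  psi[theta >= curve$theta_s] <- 0
  pmin(psi, 0)
}

#' Matric-potential series for a set of plots
#'
#' Applies the site-appropriate retention curve to a daily environmental
#' series and returns the tension series with its wilting-point-clamped
#' companion.
#'
#' @param env Daily environmental tibble with columns `plot_id`, `date`,
#'   `vwc` (and typically temperatures), as from [read_env_series()] or the
#'   synthetic generator.
#' @param design Design tibble mapping `plot_id` to `site`.
#' @param curves Named list of `retention_curve` objects, one per site.
#' @param wilting_point_kPa Clamp tension (negative), default -1500.
#' @return Tibble `plot_id`, `date`, `psi_kPa`, `psi_clamped_kPa`.
#' @export
matric_potential_series <- function(env, design, curves,
                                    wilting_point_kPa = -1500) {
  stopifnot(all(c("plot_id", "date", "vwc") %in% names(env)))
  site_of <- setNames(as.character(design$site), design$plot_id)
  miss <- setdiff(unique(env$plot_id), names(site_of))
  if (length(miss) > 0)
    stop("plot(s) not in design: ", paste(miss, collapse = ", "), call. = FALSE)
  miss_curve <- setdiff(unique(site_of[unique(env$plot_id)]), names(curves))
  if (length(miss_curve) > 0)
    stop("no retention curve for site(s): ",
         paste(miss_curve, collapse = ", "), call. = FALSE)
  psi <- numeric(nrow(env))
  for (s in unique(site_of[unique(env$plot_id)])) {
    idx <- site_of[env$plot_id] == s
    psi[idx] <- vwc_to_matric_potential(pmax(env$vwc[idx], 1e-4), curves[[s]])
  }
  tibble::tibble(plot_id = env$plot_id, date = env$date, psi_kPa = psi,
                 psi_clamped_kPa = pmax(psi, wilting_point_kPa))
}

#' Annual soil-climate summary per plot
#'
#' Computes, over a half-open annual window (default 15 July to 15 July),
#' the six plot-level climate variables used as phenology predictors:
#' mean annual soil temperature (MAT), mean winter soil temperature (MWT,
#' 1 Dec-28 Feb), mean spring soil temperature (MST, 1 Mar-31 May), mean
#' annual matric potential on the wilting-point-clamped series (MAMP), the
#' date of first wilting point (DFWP, first day with tension strictly below
#' the wilting point; `NA` and flagged if never reached), and the number of
#' days below wilting point (DBWP). A day is below wilting point if its
#' daily-mean tension is; daily aggregation precedes thresholding.
#'
#' @param env Daily environmental tibble (`plot_id`, `date`, `soil_temp_C`).
#' @param psi Matric-potential tibble from [matric_potential_series()].
#' @param window Length-2 Date vector `c(start, end)`, half-open.
#' @param config A [pheno_config()]; supplies sub-window month-days and the
#'   wilting point.
#' @param min_coverage Minimum fraction of window days that must carry
#'   observations (after any exclusions), else an error names the window.
#' @return Tibble with one row per plot: `plot_id`, `window`, `MAT`, `MWT`,
#'   `MST`, `MAMP`, `DFWP` (Date or NA), `DFWP_days` (days from window
#'   start, NA if never), `DBWP`, `wilting_reached`.
#' @examples
#' # see the package tests for worked numerical examples
#' @export
summarize_climate <- function(env, psi, window, config = pheno_config(),
                              min_coverage = 0.9) {
  stopifnot(all(c("plot_id", "date", "soil_temp_C") %in% names(env)),
            all(c("plot_id", "date", "psi_kPa") %in% names(psi)))
  window_days <- as.integer(window[["end"]] - window[["start"]])
  wp <- config$wilting_point_kPa
  label <- sprintf("%s..%s", window[["start"]], window[["end"]])

  env <- env[in_window(env$date, window), c("plot_id", "date", "soil_temp_C")]
  psi <- psi[in_window(psi$date, window), ]
  x <- dplyr::inner_join(env, psi, by = c("plot_id", "date"))

  out <- lapply(split(x, x$plot_id), function(p) {
    p <- p[order(p$date), ]
    if (nrow(p) < min_coverage * window_days)
      stop(sprintf("coverage below %.0f%% for plot %s in window %s (%d/%d days)",
                   100 * min_coverage, p$plot_id[1], label, nrow(p),
                   window_days), call. = FALSE)
    wtr <- in_md_window(p$date, config$winter_window[["start_md"]],
                        config$winter_window[["end_md"]])
    spr <- in_md_window(p$date, config$spring_window[["start_md"]],
                        config$spring_window[["end_md"]])
    below <- p$psi_kPa < wp
    dfwp <- if (any(below)) p$date[which(below)[1]] else as.Date(NA)
    dfwp_days <- as.numeric(dfwp - window[["start"]])
    tibble::tibble(
      plot_id = p$plot_id[1], window = label,
      MAT = mean(p$soil_temp_C),
      MWT = mean(p$soil_temp_C[wtr]),
      MST = mean(p$soil_temp_C[spr]),
      MAMP = mean(pmax(p$psi_kPa, wp)),
      DFWP = dfwp,
      DFWP_days = dfwp_days,
      DBWP = sum(below),
      wilting_reached = any(below))
  })
  dplyr::bind_rows(out)
}
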