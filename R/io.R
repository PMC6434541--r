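# Reading and writing the long-format CSV tables, plus interval masking.

read_table_checked <- function(path, required, name) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stop(sprintf("%s file %s is missing column(s): %s", name, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x
}

resolve_plots <- function(x, design, name) {
  known <- x$plot_id %in% design$plot_id
  n_bad <- sum(!known)
  if (n_bad > 0)
    warning(sprintf("%s: rejected %d row(s) with unresolvable plot_id", name,
                    n_bad), call. = FALSE)
  x[known, ]
}

#' Read a plot-level environmental series
#'
#' Reads the long-format datalogger export (`plot_id`, `timestamp`
#' ISO 8601, `canopy_temp_C`, `soil_temp_C`, `vwc`), resolves plots
#' against the design (unresolvable rows are rejected with a count),
#' checks bounds and per-plot timestamp monotonicity, and aggregates
#' sub-daily records to daily means.
#'
#' @param path CSV path.
#' @param design Design tibble.
#' @param daily Aggregate to daily means (default TRUE).
#' @return Tibble `plot_id`, `date` (or `timestamp` if `daily = FALSE`),
#'   `canopy_temp_C`, `soil_temp_C`, `vwc`.
#' @export
read_env_series <- function(path, design, daily = TRUE) {
  need <- c("plot_id", "timestamp", "canopy_temp_C", "soil_temp_C", "vwc")
  x <- read_table_checked(path, need, "environmental series")
  x <- resolve_plots(x, design, "read_env_series")
  bad <- which(x$vwc < 0 | x$vwc > 1)
  if (length(bad) > 0)
    stop("vwc out of [0, 1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  for (pid in unique(x$plot_id)) {
    tt <- x$timestamp[x$plot_id == pid]
    if (is.unsorted(as.numeric(tt), strictly = TRUE))
      stop("non-monotone timestamps in plot ", pid, call. = FALSE)
  }
  if (!daily) return(x)
  daily_means(x, c("canopy_temp_C", "soil_temp_C", "vwc"))
}

#' Read a plot-level NDVI survey series
#'
#' @param path CSV with columns `plot_id`, `date`, `ndvi`.
#' @param design Design tibble.
#' @return Tibble sorted by plot and date; NDVI bounds and per-plot date
#'   uniqueness enforced.
#' @export
read_ndvi_series <- function(path, design) {
  x <- read_table_checked(path, c("plot_id", "date", "ndvi"), "NDVI series")
  x <- resolve_plots(x, design, "read_ndvi_series")
  x$date <- as.Date(x$date)
  if (any(x$ndvi < -1 | x$ndvi > 1))
    stop("NDVI out of [-1, 1]", call. = FALSE)
  dup <- duplicated(x[, c("plot_id", "date")])
  if (any(dup)) stop("duplicate NDVI survey dates within a plot", call. = FALSE)
  dplyr::arrange(x, .data$plot_id, .data$date)
}

#' Read flowering surveys
#'
#' @param path CSV with columns `plot_id`, `species`, `date`,
#'   `open_flowers`, `flowering_individuals`.
#' @param design Design tibble.
#' @return Tibble with integer nonnegative counts.
#' @export
read_flowering_surveys <- function(path, design) {
  need <- c("plot_id", "species", "date", "open_flowers",
            "flowering_individuals")
  x <- read_table_checked(path, need, "flowering surveys")
  x <- resolve_plots(x, design, "read_flowering_surveys")
  x$date <- as.Date(x$date)
  if (any(x$open_flowers < 0 | x$flowering_individuals < 0))
    stop("negative counts in flowering surveys", call. = FALSE)
  x
}

#' Read per-site soil textures
#'
#' @param path CSV with columns `site`, `sand`, `clay`, `om` (fractions).
#' @return Named list of [soil_texture()] objects.
#' @export
read_soil_textures <- function(path) {
  x <- read_table_checked(path, c("site", "sand", "clay", "om"),
                          "soil texture")
  out <- lapply(seq_len(nrow(x)), function(i)
    soil_texture(x$sand[i], x$clay[i], x$om[i]))
  names(out) <- x$site
  out
}

#' Write an experiment bundle to CSV files
#'
#' Emits the same schemas the readers consume, plus `truth_ndvi.csv`,
#' `truth_flowering.csv` and `textures.csv` sidecars.
#'
#' @param experiment A `pheno_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "pheno_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env <- experiment$env
  env_out <- tibble::tibble(plot_id = env$plot_id,
                            timestamp = format(env$date, "%Y-%m-%d"),
                            canopy_temp_C = env$canopy_temp_C,
                            soil_temp_C = env$soil_temp_C, vwc = env$vwc)
  paths <- c(env = file.path(dir, "env_series.csv"),
             ndvi = file.path(dir, "ndvi_series.csv"),
             flowering = file.path(dir, "flowering_surveys.csv"),
             design = file.path(dir, "design.csv"),
             textures = file.path(dir, "textures.csv"),
             truth_ndvi = file.path(dir, "truth_ndvi.csv"),
             truth_flowering = file.path(dir, "truth_flowering.csv"))
  readr::write_csv(env_out, paths["env"])
  readr::write_csv(experiment$ndvi, paths["ndvi"])
  readr::write_csv(experiment$flowering, paths["flowering"])
  readr::write_csv(experiment$design, paths["design"])
  readr::write_csv(experiment$textures, paths["textures"])
  readr::write_csv(experiment$truth$ndvi, paths["truth_ndvi"])
  readr::write_csv(experiment$truth$flowering, paths["truth_flowering"])
  invisible(paths)
}

#' Mask an interval of a plot's series
#'
#' Removes all observations for one plot inside a half-open date interval
#' (e.g. a heater-malfunction period, whose dates are supplied by the
#' analyst); all other observations are untouched and the exclusion is
#' recorded in the `exclusions` attribute.
#'
#' @param series Tibble with `plot_id` and a `date` (or `timestamp`)
#'   column — environmental, NDVI or flowering.
#' @param plot_id Plot to mask.
#' @param interval Length-2 Dates `c(start, end)`, half-open.
#' @return The series without the masked rows.
#' @export
exclude_plot_interval <- function(series, plot_id, interval) {
  datecol <- if ("date" %in% names(series)) "date" else "timestamp"
  stopifnot(datecol %in% names(series), length(interval) == 2)
  interval <- as.Date(interval)
  if (is.na(interval[1]) || is.na(interval[2]) || interval[1] > interval[2])
    stop("malformed interval", call. = FALSE)
  if (!plot_id %in% series$plot_id)
    stop("unknown plot_id: ", plot_id, call. = FALSE)
  d <- as.Date(series[[datecol]])
  drop <- series$plot_id == plot_id & d >= interval[1] & d < interval[2]
  out <- series[!drop, ]
  attr(out, "exclusions") <- c(attr(series, "exclusions"),
                               sprintf("%s: [%s, %s) (%d rows)", plot_id,
                                       interval[1], interval[2], sum(drop)))
  out
}
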