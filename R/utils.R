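# Internal date and aggregation helpers.

# Half-open window membership [start, end).
in_window <- function(dates, window) {
  dates >= window[["start"]] & dates < window[["end"]]
}

# Month-day window within a hydrological-year span, e.g. winter "12-01".."03-01"
# inside [2016-07-15, 2017-07-15). Returns logical over `dates`.
in_md_window <- function(dates, start_md, end_md) {
  md <- format(dates, "%m-%d")
  if (start_md <= end_md) md >= start_md & md < end_md
  else md >= start_md | md < end_md    # wraps over new year
}

# Aggregate a sub-daily (or daily) long series to daily means per plot.
# x: tibble with plot_id, timestamp (POSIXct or Date), value columns in `cols`.
daily_means <- function(x, cols) {
  x$date <- as.Date(x$timestamp)
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$plot_id, .data$date),
    dplyr::across(dplyr::all_of(cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  dplyr::arrange(out, .data$plot_id, .data$date)
}

# Least-squares slope of y on x (x in days); with 2 points this is the
# difference quotient.
ls_slope <- function(x, y) {
  x <- as.numeric(x)
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

# logit transform for NDVI-like responses bounded in [-1, 1]:
# map to (0, 1), clip away from the boundary, then logit.
logit_ndvi <- function(x, eps = 1e-6) {
  p <- pmin(pmax((x + 1) / 2, eps), 1 - eps)
  qlogis(p)
}
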