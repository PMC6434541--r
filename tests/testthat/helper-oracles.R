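# Independent reference implementations (plain linear scans) used as
# oracles for the phenometric detectors, plus small fixture builders.

ref_peak <- function(dates, ndvi) {
  best <- -Inf; bd <- NA
  for (i in seq_along(dates)) {
    if (ndvi[i] > best) { best <- ndvi[i]; bd <- dates[i] }
  }
  list(peak_date = bd, peak_ndvi = best)
}

ref_senescence <- function(dates, ndvi, peak_date, peak_ndvi, fraction) {
  for (i in seq_along(dates)) {
    if (dates[i] > peak_date && ndvi[i] <= fraction * peak_ndvi)
      return(dates[i])
  }
  NA
}

ref_greenup <- function(dates, ndvi, min_date, min_ndvi, threshold) {
  for (i in seq_along(dates)) {
    if (dates[i] > min_date && ndvi[i] >= threshold) return(dates[i])
  }
  NA
}

ref_steepest_run <- function(dates, ndvi, wp) {
  n <- length(dates)
  best <- -Inf; bi <- NA
  for (b in 1:(n - wp + 1)) {
    dec <- ndvi[b] - ndvi[b + wp - 1]
    if (dec > best) { best <- dec; bi <- b }
  }
  idx <- bi:(bi + wp - 1)
  x <- as.numeric(dates[idx]); y <- ndvi[idx]
  unname(coef(lm(y ~ x))[2])
}

random_ndvi_series <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:25, 1)
  dates <- as.Date("2017-01-01") + sort(sample(1:250, n))
  ndvi <- round(runif(n, -0.1, 0.9), 3)
  list(dates = dates, ndvi = ndvi)
}

# small complete design for cheap tests
tiny_design <- function() plot_design(sites = "central", n_replicates = 3)

# one cached default experiment, shared across test files
shared_experiment <- local({
  ex <- NULL
  function() {
    if (is.null(ex)) ex <<- simulate_experiment(pheno_config(rng_seed = 101))
    ex
  }
})
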