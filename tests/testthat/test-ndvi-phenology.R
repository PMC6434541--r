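d0 <- as.Date("2017-01-01") - 1  # DOY helper: d0 + doy

test_that("peak biomass takes the maximum, ties to the earliest date", {
  expect_equal(peak_biomass(d0 + c(100, 110, 120), c(0.5, 0.6, 0.55)),
               list(peak_date = d0 + 110, peak_ndvi = 0.6))
  tie <- peak_biomass(d0 + c(100, 110, 120, 125), c(0.5, 0.6, 0.55, 0.6))
  expect_equal(tie$peak_date, d0 + 110)
  expect_error(peak_biomass(d0 + c(100, 110), c(0.5, 0.6),
                            window = c(start = d0 + 300, end = d0 + 320)),
               "no NDVI")
  expect_error(peak_biomass(d0 + c(110, 100), c(0.5, 0.6)), "increasing")
  expect_error(peak_biomass(d0 + c(100, 110), c(0.5, 1.4)), "-1, 1")
})

test_that("senescence is the first post-peak date at or below the peak fraction", {
  dates <- d0 + c(100, 110, 120, 130, 140)
  ndvi <- c(0.50, 0.60, 0.55, 0.47, 0.40)
  pk <- peak_biomass(dates, ndvi)
  sn <- senescence_date(dates, ndvi, pk, fraction = 0.80)
  expect_equal(sn$senescence_date, d0 + 130)  # 0.47 <= 0.48
  expect_false(sn$censored)
  # constant after the peak: censored, no fabricated date
  flat <- senescence_date(d0 + c(100, 110, 120), c(0.5, 0.6, 0.6),
                          peak_biomass(d0 + c(100, 110, 120), c(0.5, 0.6, 0.6)))
  expect_true(flat$censored)
  expect_true(is.na(flat$senescence_date))
  # fraction 1: the next observation not exceeding the peak
  nx <- senescence_date(dates, ndvi, pk, fraction = 1.0)
  expect_equal(nx$senescence_date, d0 + 120)
})

test_that("senescence rate picks the steepest run and fits its slope", {
  dates <- d0 + c(110, 120, 130, 140)
  ndvi <- c(0.60, 0.55, 0.47, 0.40)
  sr <- senescence_rate(dates, ndvi, window_points = 3)
  expect_equal(sr$slope, -0.0075)  # run 120..140; hand least squares
  expect_equal(sr$run_dates, d0 + c(120, 130, 140))
  sr2 <- senescence_rate(dates, ndvi, window_points = 2)
  expect_equal(sr2$slope, -0.008)  # steepest pair 120..130
  expect_equal(senescence_rate(d0 + c(130, 140), c(0.47, 0.40),
                               window_points = 2)$slope, -0.007)
  up <- senescence_rate(d0 + c(100, 110, 120), c(0.1, 0.2, 0.3))
  expect_true(up$nonsenescent)
  expect_gt(up$slope, 0)
  expect_error(senescence_rate(d0 + c(100, 110), c(0.5, 0.4),
                               window_points = 3), "at least 3")
})

test_that("green-up crosses the 125% threshold inclusively, with a floor guard", {
  dates <- d0 + c(230, 280, 290)
  ndvi <- c(0.20, 0.22, 0.26)
  sw <- c(start = d0 + 200, end = d0 + 260)
  gu <- greenup_date(dates, ndvi, sw)
  expect_equal(gu$min_date, d0 + 230)
  expect_equal(gu$greenup_date, d0 + 290)  # threshold 0.25; 0.22 < .25 <= 0.26
  expect_false(gu$threshold_substituted)
  # inclusive boundary: exactly 125% of the minimum counts
  gu2 <- greenup_date(d0 + c(230, 280), c(0.20, 0.25), sw)
  expect_equal(gu2$greenup_date, d0 + 280)
  # near-zero minimum switches to the additive offset rule
  gu3 <- greenup_date(d0 + c(230, 280, 290), c(0.02, 0.04, 0.08), sw)
  expect_true(gu3$threshold_substituted)
  expect_equal(gu3$greenup_date, d0 + 290)  # threshold 0.02 + 0.05
  # never crossed: censored
  gu4 <- greenup_date(d0 + c(230, 280), c(0.20, 0.21), sw)
  expect_true(gu4$censored)
})

test_that("growing season length is plain day arithmetic with ordering checks", {
  expect_equal(growing_season_length(as.Date("2017-10-15"),
                                     as.Date("2018-05-01")), 198)
  expect_equal(growing_season_length(as.Date("2018-05-01"),
                                     as.Date("2018-05-01")), 0)
  expect_error(growing_season_length(as.Date("2018-05-01"),
                                     as.Date("2018-04-01")), "precedes")
  expect_true(is.na(growing_season_length(as.Date(NA), as.Date("2018-05-01"))))
})

test_that("detectors agree with the exhaustive linear-scan reference on random series", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_ndvi_series()
    pk <- peak_biomass(s$dates, s$ndvi)
    rp <- ref_peak(s$dates, s$ndvi)
    expect_identical(pk$peak_date, rp$peak_date)
    expect_identical(pk$peak_ndvi, rp$peak_ndvi)
    sn <- senescence_date(s$dates, s$ndvi, pk, fraction = 0.8)
    rs <- ref_senescence(s$dates, s$ndvi, pk$peak_date, pk$peak_ndvi, 0.8)
    expect_equal(is.na(rs[1]), sn$censored)
    if (!sn$censored) expect_identical(sn$senescence_date, rs)
    wp <- sample(2:3, 1)
    if (length(s$dates) >= wp) {
      sr <- senescence_rate(s$dates, s$ndvi, window_points = wp)
      expect_equal(sr$slope, ref_steepest_run(s$dates, s$ndvi, wp),
                   tolerance = 1e-10)
    }
  }
})

test_that("moving the thresholds never moves the dates the wrong way", {
  set.seed(32)
  for (i in 1:50) {
    s <- random_ndvi_series(15)
    # positive greenness: the fraction thresholds are multiplicative
    s$ndvi <- round(pmin(s$ndvi - min(s$ndvi) + 0.1, 1), 3)
    pk <- peak_biomass(s$dates, s$ndvi)
    prev <- NULL
    for (f in c(0.9, 0.8, 0.7)) {   # lower fraction => never earlier
      sn <- senescence_date(s$dates, s$ndvi, pk, fraction = f)
      if (!is.null(prev) && !sn$censored && !prev$censored)
        expect_gte(as.numeric(sn$senescence_date - prev$senescence_date), 0)
      prev <- sn
    }
    sw <- c(start = s$dates[1], end = s$dates[length(s$dates)])
    prev <- NULL
    for (f in c(1.05, 1.25, 1.5)) {  # higher fraction => never earlier
      gu <- greenup_date(s$dates, s$ndvi, sw, fraction = f, floor = -1)
      if (!is.null(prev) && !gu$censored && !prev$censored)
        expect_gte(as.numeric(gu$greenup_date - prev$greenup_date), 0)
      prev <- gu
    }
  }
})
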