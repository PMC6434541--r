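# Pedotransfer retention curves and climate summaries.
#
# The frozen anchor values below were computed with an independent
# transcription of the published moisture-retention regressions
# (theta1500/theta33/thetaS as polynomials in sand, clay, organic matter).

test_that("retention anchors match the independent transcription to 3 decimals", {
  cases <- list(
    list(tx = soil_texture(0.40, 0.20, 0.025),
         t1500 = 0.137024, t33 = 0.279610, ts = 0.459478),
    list(tx = soil_texture(0.65, 0.10, 0.015),
         t1500 = 0.071707, t33 = 0.164984, ts = 0.423277),
    list(tx = soil_texture(0.25, 0.40, 0.030),
         t1500 = 0.245335, t33 = 0.383715, ts = 0.496366),
    list(tx = soil_texture(0.20, 0.15, 0.040),
         t1500 = 0.118499, t33 = 0.322814, ts = 0.531571))
  for (cs in cases) {
    rc <- fit_retention_curve(cs$tx)
    expect_equal(rc$theta_1500, cs$t1500, tolerance = 5e-4)
    expect_equal(rc$theta_33, cs$t33, tolerance = 5e-4)
    expect_equal(rc$theta_s, cs$ts, tolerance = 5e-4)
    expect_true(rc$theta_1500 < rc$theta_33 && rc$theta_33 < rc$theta_s)
    expect_gt(rc$B, 0)
    expect_equal(rc$B, log(1500 / 33) / log(rc$theta_33 / rc$theta_1500))
  }
  # determinism
  expect_identical(fit_retention_curve(soil_texture(0.4, 0.2, 0.025)),
                   fit_retention_curve(soil_texture(0.4, 0.2, 0.025)))
})

test_that("wilting-point water content is non-decreasing in clay", {
  prev <- -Inf
  for (clay in seq(0.05, 0.5, by = 0.05)) {
    rc <- fit_retention_curve(soil_texture(0.35, clay, 0.025))
    expect_gte(rc$theta_1500, prev)
    prev <- rc$theta_1500
  }
})

test_that("matric potential hits the anchor tensions and the worked value", {
  rc <- fit_retention_curve(soil_texture(0.40, 0.20, 0.025))
  expect_equal(vwc_to_matric_potential(rc$theta_33, rc), -33, tolerance = 1e-8)
  expect_equal(vwc_to_matric_potential(rc$theta_s, rc), 0)
  expect_equal(vwc_to_matric_potential(1, rc), 0)
  # hand-built curve: theta_33 = .30, theta_1500 = .15 => B ~ 5.506,
  # psi(0.20) = -33 * 1.5^B ~ -307.7 kPa
  B <- log(1500 / 33) / log(0.30 / 0.15)
  hand <- structure(list(theta_1500 = 0.15, theta_33 = 0.30, theta_s = 0.45,
                         psi_air_entry_kPa = -3, A = 33 * 0.30^B, B = B),
                    class = "retention_curve")
  expect_equal(vwc_to_matric_potential(0.20, hand), -307.7, tolerance = 5e-3)
  expect_error(vwc_to_matric_potential(0, rc), "theta")
})

test_that("matric potential is monotone in theta and continuous at field capacity", {
  rc <- fit_retention_curve(soil_texture(0.45, 0.18, 0.02))
  th <- seq(0.02, 1, by = 0.002)
  psi <- vwc_to_matric_potential(th, rc)
  expect_true(all(psi <= 0))
  expect_true(all(diff(psi) >= -1e-9))
  eps <- 1e-7
  expect_equal(vwc_to_matric_potential(rc$theta_33 - eps, rc),
               vwc_to_matric_potential(rc$theta_33 + eps, rc),
               tolerance = 1e-3)
  # drier (more negative) with more clay at fixed mid-range theta
  psis <- vapply(seq(0.1, 0.4, by = 0.05), function(cl)
    vwc_to_matric_potential(0.2, fit_retention_curve(soil_texture(0.3, cl, 0.025))),
    numeric(1))
  expect_true(all(diff(psis) < 0))
})

make_daily_env <- function(window, soil_temp, psi_kPa, plot = "p1") {
  dates <- seq(window[["start"]], window[["end"]] - 1, by = "day")
  n <- length(dates)
  list(env = tibble::tibble(plot_id = plot, date = dates,
                            soil_temp_C = rep_len(soil_temp, n),
                            canopy_temp_C = rep_len(soil_temp, n),
                            vwc = 0.2),
       psi = tibble::tibble(plot_id = plot, date = dates,
                            psi_kPa = rep_len(psi_kPa, n),
                            psi_clamped_kPa = pmax(rep_len(psi_kPa, n), -1500)))
}

test_that("climate summary reduces constant series to their constants", {
  cfg <- pheno_config()
  w <- cfg$annual_windows[["2017"]]
  fx <- make_daily_env(w, 10, -100)
  cs <- summarize_climate(fx$env, fx$psi, w, cfg)
  expect_equal(cs$MAT, 10)
  expect_equal(cs$MWT, 10)
  expect_equal(cs$MST, 10)
  expect_equal(cs$MAMP, -100)
  expect_true(is.na(cs$DFWP))
  expect_equal(cs$DBWP, 0)
  expect_false(cs$wilting_reached)
})

test_that("permanently dry series clamps to wilting point across the window", {
  cfg <- pheno_config()
  w <- cfg$annual_windows[["2017"]]
  fx <- make_daily_env(w, 12, -2000)
  cs <- summarize_climate(fx$env, fx$psi, w, cfg)
  expect_equal(cs$MAMP, -1500)
  expect_equal(cs$DBWP, as.integer(w[["end"]] - w[["start"]]))
  expect_equal(cs$DFWP, unname(w[["start"]]))
  expect_equal(cs$DFWP_days, 0)
})

test_that("a three-day dry spell gives DBWP 3 and DFWP at its first day", {
  cfg <- pheno_config()
  w <- cfg$annual_windows[["2017"]]
  dates <- seq(w[["start"]], w[["end"]] - 1, by = "day")
  psi <- rep(-100, length(dates))
  dry <- dates >= as.Date("2016-07-20") & dates <= as.Date("2016-07-22")
  psi[dry] <- -1600
  fx <- make_daily_env(w, 10, -100)
  fx$psi$psi_kPa <- psi
  fx$psi$psi_clamped_kPa <- pmax(psi, -1500)
  cs <- summarize_climate(fx$env, fx$psi, w, cfg)
  expect_equal(cs$DBWP, 3)
  expect_equal(cs$DFWP, as.Date("2016-07-20"))
  expect_equal(cs$MAMP, mean(pmax(psi, -1500)))
  # clamp conservation + day-count partition
  expect_equal(cs$MAMP, mean(fx$psi$psi_clamped_kPa))
  expect_equal(cs$DBWP + sum(psi >= -1500), length(dates))
  # boundary day exactly at -1500 does not count as below
  psi2 <- rep(-1500, length(dates))
  fx$psi$psi_kPa <- psi2
  cs2 <- summarize_climate(fx$env, fx$psi, w, cfg)
  expect_equal(cs2$DBWP, 0)
  expect_true(is.na(cs2$DFWP))
})

test_that("insufficient coverage raises a window-naming error", {
  cfg <- pheno_config()
  w <- cfg$annual_windows[["2017"]]
  fx <- make_daily_env(w, 10, -100)
  short_env <- fx$env[1:100, ]
  short_psi <- fx$psi[1:100, ]
  expect_error(summarize_climate(short_env, short_psi, w, cfg), "coverage")
})
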