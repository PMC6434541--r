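test_that("AICc formula and its large-n limit", {
  expect_equal(aicc(-10, k = 3, n = 20), 27.5)  # 26 + 24/16
  # correction vanishes as n grows: AICc -> AIC
  expect_equal(aicc(-10, k = 3, n = 1e6), 26, tolerance = 1e-4)
  expect_equal(aicc(-10, k = 3, n = 4), Inf)
})

test_that("Akaike weights normalise exp(-delta/2)", {
  w <- akaike_weights(c(0, 2, 4))
  expect_equal(w, c(0.665, 0.245, 0.090), tolerance = 1e-3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
})

# hand-built candidate set for closed-form checks
fake_set <- function(models) {
  structure(list(response = "y", models = models, fits = list(),
                 temp_vars = c("MAT", "MWT", "MST"),
                 moist_vars = c("MAMP", "DFWP_days", "DBWP"),
                 dropped = character(), n_models = nrow(models)),
            class = "candidate_set")
}

test_that("equal-likelihood set gives closed-form importances", {
  # all 15 models with the same logL: 6 singles (k = 3) and 9 pairs (k = 4)
  tv <- c("MAT", "MWT", "MST"); mv <- c("MAMP", "DFWP_days", "DBWP")
  terms <- c(as.list(c(tv, mv)),
             unlist(lapply(tv, function(a) lapply(mv, function(b) c(a, b))),
                    recursive = FALSE))
  k <- vapply(terms, function(t) length(t) + 2, numeric(1))
  n <- 30; logL <- -20
  aiccs <- vapply(seq_along(terms), function(i) aicc(logL, k[i], n),
                  numeric(1))
  m <- tibble::tibble(model = vapply(terms, paste, "", collapse = "+"),
                      terms = terms, k = k, n = n, logL = logL,
                      AICc = aiccs)
  m$delta <- m$AICc - min(m$AICc)
  m$weight <- akaike_weights(m$AICc)
  ri <- relative_importance(fake_set(m))
  # closed form: w_single, w_pair from the two distinct AICc values
  a_s <- aicc(logL, 3, n); a_p <- aicc(logL, 4, n)
  es <- exp(-(a_s - min(a_s, a_p)) / 2); ep <- exp(-(a_p - min(a_s, a_p)) / 2)
  Z <- 6 * es + 9 * ep
  expect_equal(unname(ri$importance), rep((es + 3 * ep) / Z, 6),
               tolerance = 1e-12)
  expect_true(all(ri$importance >= 0 & ri$importance <= 1))
})

test_that("candidate set fits 15 models on common rows with unit weight sum", {
  set.seed(21)
  n <- 40
  d <- tibble::tibble(MAT = rnorm(n, 11, 1), MWT = rnorm(n, 5, 1),
                      MST = rnorm(n, 9, 1), MAMP = rnorm(n, -700, 100),
                      DFWP_days = rnorm(n, 300, 20), DBWP = rnorm(n, 90, 10))
  d$y <- 100 - 4 * d$MST + rnorm(n, 0, 1)
  d$DFWP_days[1:5] <- NA          # incomplete plots drop for every model
  cs <- build_candidate_set(d, "y")
  expect_equal(cs$n_models, 15)
  expect_equal(sum(cs$models$weight), 1, tolerance = 1e-12)
  expect_true(all(cs$models$n == n - 5))
  expect_true(all(cs$models$delta >= 0))
  expect_equal(sum(cs$models$delta == 0), 1)
  expect_equal(sort(unique(cs$models$k)), c(3, 4))
  # AICc recomputes from logLik, k, n
  expect_equal(cs$models$AICc,
               mapply(aicc, cs$models$logLik, cs$models$k, cs$models$n))
  ri <- relative_importance(cs)
  expect_equal(ri$predictor[ri$is_max], "MST")
})

test_that("dropping one moisture variable leaves 5 singles and 6 pairs", {
  set.seed(22)
  n <- 30
  d <- tibble::tibble(MAT = rnorm(n), MWT = rnorm(n), MST = rnorm(n),
                      MAMP = rnorm(n), DFWP_days = rnorm(n), DBWP = 1)
  d$y <- rnorm(n)
  cs <- build_candidate_set(d, "y")
  expect_equal(cs$n_models, 11)
  expect_equal(cs$dropped, "DBWP")
})

test_that("the parsimony filter matches a brute-force reimplementation", {
  # hand case: pair within the band but beaten by its own submodel
  tv <- "MAT"; mv <- "MAMP"
  m <- tibble::tibble(
    model = c("MAT", "MAMP", "MAT+MAMP"),
    terms = list("MAT", "MAMP", c("MAT", "MAMP")),
    k = c(3, 3, 4), n = 20, logL = NA,
    AICc = c(10.0, 9.5, 10.5))
  m$delta <- m$AICc - min(m$AICc)
  m$weight <- akaike_weights(m$AICc)
  rep1 <- rank_and_filter(fake_set(m), delta_equiv = 2)
  expect_false("MAT+MAMP" %in% rep1$model)   # delta 1.0 but loses to MAT alone
  expect_setequal(rep1$model, c("MAT", "MAMP"))
  # lone clear winner: report of exactly one model
  m2 <- m; m2$AICc <- c(3, 6.5, 7.2)
  m2$delta <- m2$AICc - min(m2$AICc); m2$weight <- akaike_weights(m2$AICc)
  expect_equal(rank_and_filter(fake_set(m2))$model, "MAT")

  brute <- function(m, band) {
    keep <- character()
    for (i in seq_len(nrow(m))) {
      if (m$AICc[i] - min(m$AICc) >= band) next
      tt <- m$terms[[i]]
      if (length(tt) == 2) {
        bad <- FALSE
        for (v in tt) {
          j <- which(m$model == v)
          if (length(j) == 1 && m$AICc[i] > m$AICc[j]) bad <- TRUE
        }
        if (bad) next
      }
      keep <- c(keep, m$model[i])
    }
    keep
  }
  set.seed(23)
  tv <- c("MAT", "MWT", "MST"); mv <- c("MAMP", "DFWP_days", "DBWP")
  terms <- c(as.list(c(tv, mv)),
             unlist(lapply(tv, function(a) lapply(mv, function(b) c(a, b))),
                    recursive = FALSE))
  for (r in 1:50) {
    m3 <- tibble::tibble(model = vapply(terms, paste, "", collapse = "+"),
                         terms = terms,
                         k = vapply(terms, function(t) length(t) + 2, 0),
                         n = 30, logL = NA,
                         AICc = round(runif(15, 0, 6), 2))
    m3$delta <- m3$AICc - min(m3$AICc)
    m3$weight <- akaike_weights(m3$AICc)
    got <- rank_and_filter(fake_set(m3), delta_equiv = 2)$model
    expect_setequal(got, brute(m3, 2))
  }
})

test_that("a single dominant predictor takes importance toward one", {
  tv <- c("MAT", "MWT", "MST"); mv <- c("MAMP", "DFWP_days", "DBWP")
  terms <- c(as.list(c(tv, mv)),
             unlist(lapply(tv, function(a) lapply(mv, function(b) c(a, b))),
                    recursive = FALSE))
  has_mst <- vapply(terms, function(t) "MST" %in% t, logical(1))
  m <- tibble::tibble(model = vapply(terms, paste, "", collapse = "+"),
                      terms = terms,
                      k = vapply(terms, function(t) length(t) + 2, 0),
                      n = 30, logL = NA,
                      AICc = ifelse(has_mst, 0, 500))
  m$delta <- m$AICc - min(m$AICc)
  m$weight <- akaike_weights(m$AICc)
  ri <- relative_importance(fake_set(m))
  expect_equal(ri$importance[ri$predictor == "MST"], 1, tolerance = 1e-12)
  expect_lt(max(ri$importance[ri$predictor %in% c("MAT", "MWT")]), 1e-10)
})
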