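test_that("treatment collapsing requires both within-pair tests non-significant", {
  design <- plot_design(sites = "central")
  tr <- as.character(design$treatment)
  # identical values everywhere: p = 1, collapse
  dec <- collapse_treatments(rep(5, nrow(design)), design)
  expect_true(dec$collapsed)
  expect_equal(dec$p_control_vs_drought, 1)
  expect_equal(nlevels(dec$factor), 2)
  # control == drought but warming >> warming_ppt: no collapse
  v <- rnorm(nrow(design), 0, 0.1)
  v[tr == "warming"] <- v[tr == "warming"] + 50
  dec2 <- collapse_treatments(v, design)
  expect_false(dec2$collapsed)
  expect_lt(dec2$p_warming_vs_warmingppt, 0.1)
  expect_equal(nlevels(dec2$factor), 4)
  # a treatment with < 2 plots defers the decision
  v3 <- rnorm(nrow(design)); v3[tr == "drought"][-1] <- NA
  dec3 <- collapse_treatments(v3, design)
  expect_true(dec3$deferred)
  expect_false(dec3$collapsed)
})

test_that("two-group comparison reports warming minus ambient with a textbook p", {
  g <- rep(c("warming", "ambient"), each = 3)
  r <- compare_two_groups(c(100, 102, 104, 110, 112, 114), g,
                          var_equal = TRUE)
  expect_equal(r$difference, -10)
  # classical two-sample t by hand: sp2 = 4, t = -10/sqrt(4 * 2/3), df = 4
  t_hand <- -10 / sqrt(4 * 2 / 3)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_value, 2 * pt(t_hand, 4))
  same <- compare_two_groups(c(10, 12, 10, 12), rep(c("warming", "ambient"),
                                                    each = 2))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  zv <- compare_two_groups(c(7, 7, 9, 9), rep(c("warming", "ambient"),
                                              each = 2))
  expect_true(zv$untestable)
  expect_true(is.na(zv$p_value))
})

test_that("t-test p-values rank like a permutation test on small samples", {
  set.seed(41)
  perm_p <- function(a, b, nperm = 2000) {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b); na <- length(a)
    hits <- 0
    for (i in seq_len(nperm)) {
      idx <- sample(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
        hits <- hits + 1
    }
    hits / nperm
  }
  ps_t <- c(); ps_perm <- c()
  shifts <- c(0.3, 1.5, 4)
  for (s in shifts) {
    a <- rnorm(6); b <- rnorm(6) + s
    r <- compare_two_groups(c(b, a), rep(c("warming", "ambient"), each = 6))
    ps_t <- c(ps_t, r$p_value)
    ps_perm <- c(ps_perm, perm_p(a, b))
  }
  expect_equal(order(ps_t), order(ps_perm))
})

test_that("one-factor two-level ANOVA F equals the squared t statistic", {
  set.seed(42)
  d <- tibble::tibble(y = rnorm(12), g = rep(c("a", "b"), each = 6))
  an <- anova_with_posthoc(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(an$anova_table$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_true(!is.null(an$tukey$g))
})

test_that("zero residual variance is flagged instead of fabricating F", {
  d <- tibble::tibble(y = rep(c(1, 2, 3), each = 4),
                      g = rep(c("a", "b", "c"), each = 4))
  an <- anova_with_posthoc(d, "y", "g")
  expect_true(an$zero_residual)
  expect_null(an$tukey)
})

test_that("Tukey separates a well-spaced site mean in nearly every simulation", {
  set.seed(43)
  hits <- 0; nsim <- 200
  for (i in seq_len(nsim)) {
    d <- tibble::tibble(y = c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 10)),
                        site = rep(c("s1", "s2", "s3"), each = 5))
    an <- anova_with_posthoc(d, "y", "site")
    tk <- an$tukey$site
    sep <- all(tk$p_adj[tk$contrast %in% c("s3-s1", "s3-s2")] < 0.05)
    if (sep) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.95)
})

sim_rm_data <- function(n_subj, k, Sigma, between = NULL) {
  L <- chol(Sigma)
  y <- matrix(rnorm(n_subj * k), n_subj) %*% L
  d <- tibble::tibble(subj = rep(sprintf("s%02d", 1:n_subj), each = k),
                      occ = rep(sprintf("t%d", 1:k), n_subj),
                      y = as.vector(t(y)))
  d
}

test_that("two occasions need no sphericity correction", {
  set.seed(44)
  d <- sim_rm_data(12, 2, diag(2))
  rm <- repeated_measures(d, "y", "subj", "occ")
  expect_true(is.na(rm$mauchly_p))
  expect_false(any(rm$effects$corrected))
  expect_equal(rm$epsilon, 1, tolerance = 1e-9)
})

test_that("compound symmetry gives epsilon near one; AR(1) shrinks it and inflates p", {
  set.seed(45)
  k <- 5
  cs_eps <- replicate(20, {
    Sigma <- matrix(0.5, k, k); diag(Sigma) <- 1
    rm <- repeated_measures(sim_rm_data(40, k, Sigma), "y", "subj", "occ")
    rm$epsilon
  })
  expect_gt(mean(cs_eps), 0.85)
  ar <- 0.9^abs(outer(1:k, 1:k, "-"))
  rms <- replicate(20, {
    rm <- repeated_measures(sim_rm_data(20, k, ar), "y", "subj", "occ")
    occ <- rm$effects[rm$effects$effect == "occasion", ]
    c(eps = rm$epsilon, pu = occ$p_uncorrected, pg = occ$p_gg, F = occ$F)
  })
  expect_lt(mean(rms["eps", ]), 0.8)
  # deflating both dfs is conservative whenever F >= 1
  conserv <- rms["F", ] >= 1
  expect_true(all(rms["pg", conserv] >= rms["pu", conserv] - 1e-12))
  # epsilon bounds: 1/(k-1) <= eps <= 1
  expect_true(all(rms["eps", ] >= 1 / (k - 1) - 1e-9))
  expect_true(all(rms["eps", ] <= 1 + 1e-9))
})

test_that("the sphericity test agrees with the base mauchly.test oracle", {
  set.seed(46)
  for (i in 1:5) {
    k <- 4; n <- 25
    Sigma <- 0.7^abs(outer(1:k, 1:k, "-"))
    Y <- matrix(rnorm(n * k), n) %*% chol(Sigma)
    fit <- lm(Y ~ 1)
    idata <- data.frame(occ = factor(1:k))
    ref <- mauchly.test(fit, X = ~1, idata = idata)
    S <- crossprod(sweep(Y, 2, colMeans(Y))) / (n - 1)
    got <- phenoclim:::mauchly_p(S, n - 1)
    expect_equal(got, ref$p.value, tolerance = 1e-6)
  }
})

test_that("logit transform maps NDVI bounds into finite working values", {
  set.seed(47)
  d <- sim_rm_data(10, 3, diag(3))
  d$y <- pmax(pmin(d$y / 5, 0.99), -0.99)
  rm <- repeated_measures(d, "y", "subj", "occ", transform = "logit")
  expect_true(all(is.finite(rm$effects$F[!is.na(rm$effects$F)])))
  expect_equal(rm$transform, "logit")
})
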