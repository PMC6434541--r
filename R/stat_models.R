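# Treatment collapsing, group comparisons, ANOVA with Tukey post hoc, and
# repeated-measures ANOVA with Greenhouse-Geisser correction.

#' Decide whether to collapse climate treatments to temperature categories
#'
#' Runs the two within-pair two-tailed mean-difference tests (control vs
#' drought; warming vs warming + ppt). The four treatments collapse to the
#' two-level ambient/warming factor only when both tests are
#' non-significant at `collapse_alpha`, i.e. the moisture manipulations
#' show no evidence of an effect within either temperature level.
#'
#' @param values Numeric response, one per plot.
#' @param design Design tibble aligned with `values` (column `treatment`).
#' @param collapse_alpha Significance threshold (default 0.10).
#' @param var_equal Passed to [stats::t.test()]; default FALSE (Welch).
#' @return List with class `collapse_decision`: `p_control_vs_drought`,
#'   `p_warming_vs_warmingppt`, `collapsed`, `factor` (the 2- or 4-level
#'   factor to use downstream), `deferred` (TRUE when a treatment has < 2
#'   usable plots so no decision is possible).
#' @examples
#' d <- plot_design()
#' collapse_treatments(rnorm(60), d)
#' @export
collapse_treatments <- function(values, design, collapse_alpha = 0.10,
                                var_equal = FALSE) {
  stopifnot(length(values) == nrow(design))
  tr <- as.character(design$treatment)
  ok <- !is.na(values)
  counts <- table(tr[ok])
  pairs <- list(c("control", "drought"), c("warming", "warming_ppt"))
  if (any(!c("control", "drought", "warming", "warming_ppt") %in% names(counts)) ||
      any(counts[c("control", "drought", "warming", "warming_ppt")] < 2)) {
    return(structure(list(p_control_vs_drought = NA_real_,
                          p_warming_vs_warmingppt = NA_real_,
                          collapsed = FALSE, deferred = TRUE,
                          factor = factor(tr)), class = "collapse_decision"))
  }
  pvals <- vapply(pairs, function(pr) {
    a <- values[ok & tr == pr[1]]; b <- values[ok & tr == pr[2]]
    if (var(a) == 0 && var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1))
  collapsed <- all(pvals >= collapse_alpha)
  fct <- if (collapsed) temperature_category(tr) else factor(tr)
  structure(list(p_control_vs_drought = pvals[1],
                 p_warming_vs_warmingppt = pvals[2],
                 collapsed = collapsed, deferred = FALSE, factor = fct),
            class = "collapse_decision")
}

#' @export
print.collapse_decision <- function(x, ...) {
  cat("<collapse_decision>",
      if (x$deferred) "deferred (insufficient plots)"
      else sprintf("collapsed = %s (p C-vs-D = %.3f, p W-vs-WP = %.3f)",
                   x$collapsed, x$p_control_vs_drought,
                   x$p_warming_vs_warmingppt), "\n")
  invisible(x)
}

#' Two-group comparison (warming effect)
#'
#' Two-tailed two-sample t test of a response between the warming and
#' ambient categories, reported as warming minus ambient so that a
#' negative difference on a date response is an advancement.
#'
#' @param values Numeric response per plot.
#' @param grouping Factor/character with levels `ambient` and `warming`.
#' @param var_equal Equal-variance (classical) vs Welch (default) test.
#' @return List: `difference` (warming - ambient), `se`, `p_value`,
#'   `statistic`, `df`, `n` (per group), `untestable` (TRUE when both
#'   groups have zero variance, where no test statistic exists).
#' @examples
#' compare_two_groups(c(100, 102, 104, 110, 112, 114),
#'                    rep(c("warming", "ambient"), each = 3))
#' @export
compare_two_groups <- function(values, grouping, var_equal = FALSE) {
  grouping <- as.character(grouping)
  ok <- !is.na(values) & grouping %in% c("ambient", "warming")
  a <- values[ok & grouping == "ambient"]
  w <- values[ok & grouping == "warming"]
  if (length(a) < 2 || length(w) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  diff <- mean(w) - mean(a)
  if (var(a) == 0 && var(w) == 0) {
    return(list(difference = diff, se = 0, p_value = NA_real_,
                statistic = NA_real_, df = NA_real_,
                n = c(ambient = length(a), warming = length(w)),
                untestable = TRUE))
  }
  tt <- t.test(w, a, var.equal = var_equal)
  list(difference = diff, se = unname(tt$stderr), p_value = tt$p.value,
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       n = c(ambient = length(a), warming = length(w)), untestable = FALSE)
}

#' ANOVA with Tukey post hoc comparisons
#'
#' Fixed-effects ANOVA of a plot-level response on site and/or treatment
#' (with their interaction when both are supplied), followed by Tukey
#' honest-significant-difference all-pairs comparisons for each factor.
#'
#' @param data Tibble with the response and factor columns.
#' @param response Response column name.
#' @param factors Character vector of one or two factor column names.
#' @return List: `anova_table` (effect, df, F, p), `tukey` (named list of
#'   tibbles of pairwise comparisons), `fit` (the `aov` object),
#'   `zero_residual` (TRUE when residual variance is 0, making F
#'   undefined and flagged).
#' @export
anova_with_posthoc <- function(data, response, factors) {
  stopifnot(response %in% names(data), all(factors %in% names(data)),
            length(factors) %in% c(1, 2))
  df <- data[!is.na(data[[response]]), c(response, factors)]
  for (f in factors) df[[f]] <- droplevels(factor(df[[f]]))
  cells <- table(df[, factors])
  if (any(cells == 0))
    warning("empty design cell(s); affected levels excluded from the fit")
  rhs <- paste(factors, collapse = " * ")
  fit <- aov(as.formula(paste(response, "~", rhs)), data = df)
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  anova_table <- tibble::tibble(
    effect = eff, df = tab$Df, sum_sq = tab$`Sum Sq`,
    F = tab$`F value`, p = tab$`Pr(>F)`)
  zero_resid <- tab[eff == "Residuals", "Sum Sq"] < .Machine$double.eps * 100
  tukey <- NULL
  if (!zero_resid) {
    tk <- TukeyHSD(fit)
    tukey <- lapply(tk, function(m)
      tibble::tibble(contrast = rownames(m), diff = m[, "diff"],
                     lwr = m[, "lwr"], upr = m[, "upr"],
                     p_adj = m[, "p adj"]))
  }
  list(anova_table = anova_table, tukey = tukey, fit = fit,
       zero_residual = zero_resid)
}

# Greenhouse-Geisser epsilon from a pooled within-cell covariance matrix
# of the occasions, via normalized orthogonal contrasts.
gg_epsilon <- function(S) {
  k <- nrow(S)
  M <- stats::contr.helmert(k)
  M <- apply(M, 2, function(v) v / sqrt(sum(v^2)))
  Sc <- t(M) %*% S %*% M
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

# Mauchly's sphericity test on the same contrast-transformed covariance.
# n_resid = residual df of the between-subject model (n subjects - cells).
mauchly_p <- function(S, n_resid) {
  k <- nrow(S)
  d <- k - 1
  if (d < 2) return(NA_real_)  # 2 occasions: sphericity trivially holds
  M <- stats::contr.helmert(k)
  M <- apply(M, 2, function(v) v / sqrt(sum(v^2)))
  Sc <- t(M) %*% S %*% M
  W <- det(Sc) / (sum(diag(Sc)) / d)^d
  if (!is.finite(W) || W <= 0) return(0)
  # chi-square approximation with the standard second-order refinement
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * n_resid)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * k + 2) /
    (288 * (n_resid * d * rho)^2)
  z <- -n_resid * rho * log(W)
  f <- d * (d + 1) / 2 - 1
  p1 <- pchisq(z, f, lower.tail = FALSE)
  p2 <- pchisq(z, f + 4, lower.tail = FALSE)
  p1 + w2 * (p2 - p1)
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' Univariate repeated-measures ANOVA of a response observed on every
#' subject (plot) at every occasion, with between-subject factors and the
#' occasion as the within-subject effect. Subjects with any missing
#' occasion are listwise deleted (and counted). An optional logit
#' transform (for NDVI-type responses bounded in `[-1, 1]`, mapped through
#' `(x + 1)/2` with a 1e-6 clip) is applied before modelling. Sphericity
#' of the occasion covariance is tested with Mauchly's criterion on the
#' pooled within-cell covariance; when it is rejected at `alpha`, the
#' within-subject F-test degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon.
#'
#' @param data Long tibble with subject, occasion, response and
#'   between-factor columns.
#' @param response,subject,occasion Column names.
#' @param between Character vector of between-subject factor columns
#'   (may be empty).
#' @param transform `"none"` or `"logit"`.
#' @param alpha Sphericity-test level governing whether the correction is
#'   applied (default 0.05).
#' @return List: `effects` (tibble: effect, df1, df2, F, p_uncorrected,
#'   p_gg, p (the one to read), corrected), `epsilon`, `mauchly_p`,
#'   `n_subjects`, `n_dropped`, `transform`.
#' @export
repeated_measures <- function(data, response, subject, occasion,
                              between = character(), transform = "none",
                              alpha = 0.05) {
  stopifnot(all(c(response, subject, occasion, between) %in% names(data)),
            transform %in% c("none", "logit"))
  df <- data[, c(subject, occasion, response, between)]
  names(df)[1:3] <- c(".subj", ".occ", ".y")
  df$.occ <- factor(df$.occ)
  k <- nlevels(df$.occ)
  if (k < 2) stop("need at least 2 occasions", call. = FALSE)
  if (transform == "logit") df$.y <- logit_ndvi(df$.y)

  wide <- tidyr::pivot_wider(df, names_from = ".occ", values_from = ".y")
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, ]
  n <- nrow(wide)
  if (n < 3) stop("fewer than 3 complete subjects", call. = FALSE)

  # pooled within-cell covariance of the occasion columns
  occ_cols <- as.matrix(wide[, levels(df$.occ), drop = FALSE])
  cell <- if (length(between) > 0)
    interaction(wide[, between], drop = TRUE) else factor(rep(1, n))
  g <- nlevels(cell)
  centered <- occ_cols
  for (lv in levels(cell)) {
    idx <- cell == lv
    centered[idx, ] <- sweep(occ_cols[idx, , drop = FALSE], 2,
                             colMeans(occ_cols[idx, , drop = FALSE]))
  }
  S <- crossprod(centered) / (n - g)
  eps <- gg_epsilon(S)
  mau_p <- mauchly_p(S, n - g)
  correct <- !is.na(mau_p) && mau_p < alpha

  long <- df[df$.subj %in% wide$.subj, ]
  rhs <- if (length(between) > 0)
    paste0("(", paste(between, collapse = " * "), ") * .occ") else ".occ"
  form <- as.formula(paste(".y ~", rhs, "+ Error(.subj/.occ)"))
  fit <- aov(form, data = long)
  sm <- summary(fit)

  rows <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    eff <- trimws(rownames(tab))
    resid_row <- eff == "Residuals"
    df2 <- tab$Df[resid_row]
    within <- grepl("\\.occ", stratum) || any(grepl("\\.occ", eff))
    for (i in which(!resid_row)) {
      F <- tab$`F value`[i]; p <- tab$`Pr(>F)`[i]
      is_within <- grepl("\\.occ", eff[i])
      p_gg <- if (is_within && is.finite(F))
        pf(F, eps * tab$Df[i], eps * df2, lower.tail = FALSE) else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = gsub("\\.occ", "occasion", eff[i]),
        df1 = tab$Df[i], df2 = df2, F = F,
        p_uncorrected = p, p_gg = p_gg,
        p = if (is_within && correct) p_gg else p,
        corrected = is_within && correct)
    }
  }
  list(effects = dplyr::bind_rows(rows), epsilon = eps, mauchly_p = mau_p,
       n_subjects = n, n_dropped = n_dropped, transform = transform)
}
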