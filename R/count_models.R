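# Count-model family selection for reproductive abundances.

fit_count_family <- function(family, formula_full, zi, data) {
  switch(family,
    poisson = stats::glm(formula_full, family = stats::poisson(), data = data),
    nbinom = MASS::glm.nb(formula_full, data = data),
    zi_poisson = glmmTMB::glmmTMB(formula_full, ziformula = zi,
                                  family = stats::poisson(), data = data),
    zi_nbinom = glmmTMB::glmmTMB(formula_full, ziformula = zi,
                                 family = glmmTMB::nbinom2(), data = data))
}

lr_test <- function(fit_full, fit_reduced) {
  ll1 <- as.numeric(logLik(fit_full)); ll0 <- as.numeric(logLik(fit_reduced))
  df <- attr(logLik(fit_full), "df") - attr(logLik(fit_reduced), "df")
  stat <- max(2 * (ll1 - ll0), 0)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Select a count-model family and test design effects
#'
#' Fits a reproductive-abundance count to four candidate families —
#' Poisson, negative binomial, zero-inflated Poisson and zero-inflated
#' negative binomial (constant zero-inflation) — selects the family with
#' the lowest AIC, reports a chi-square goodness-of-fit check on the
#' winner (Pearson statistic against its residual degrees of freedom), and
#' tests the design factors with likelihood-ratio chi-square tests on
#' nested refits of the winning family. When two factors are supplied and
#' their interaction is significant at `alpha`, the model is refit within
#' each level of the first factor to test the second factor there (the
#' within-site treatment tests of a site x treatment design).
#'
#' @param data Tibble with the count column and factor columns.
#' @param response Count column name (nonnegative integers).
#' @param factors Character vector of 0-2 factor column names (e.g.
#'   `c("site", "treatment")`); `NULL` fits intercept-only (family
#'   selection alone).
#' @param alpha Significance level for the interaction gate.
#' @return List with class `count_model_selection`: `family` (winner),
#'   `aic` (named vector, non-converged families NA), `fit`, `gof`
#'   (statistic, df, p), `effects` (tibble of LR tests, or NULL),
#'   `within_level` (per-level refits, or NULL), `failed_families`,
#'   `all_zero` (TRUE when every count is 0: no population, nothing fit).
#' @examples
#' d <- data.frame(n = rpois(40, 4), g = gl(2, 20))
#' select_count_model(d, "n", "g")$family
#' @export
select_count_model <- function(data, response, factors = NULL, alpha = 0.05) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  y <- data[[response]]
  if (any(is.na(y) | y < 0 | y != floor(y)))
    stop("counts must be nonnegative integers without NAs", call. = FALSE)
  if (all(y == 0))
    return(structure(list(family = NA_character_, aic = NULL, fit = NULL,
                          gof = NULL, effects = NULL, within_level = NULL,
                          failed_families = character(), all_zero = TRUE),
                     class = "count_model_selection"))
  for (f in factors) data[[f]] <- droplevels(factor(data[[f]]))
  rhs <- if (length(factors) == 0) "1" else paste(factors, collapse = " * ")
  form <- as.formula(paste(response, "~", rhs))

  families <- c("poisson", "nbinom", "zi_poisson", "zi_nbinom")
  fits <- setNames(vector("list", length(families)), families)
  aic <- setNames(rep(NA_real_, length(families)), families)
  for (fam in families) {
    fit <- tryCatch(suppressWarnings(fit_count_family(fam, form, ~1, data)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      a <- tryCatch(AIC(fit), error = function(e) NA_real_)
      if (is.finite(a)) { fits[[fam]] <- fit; aic[fam] <- a }
    }
  }
  if (all(is.na(aic))) stop("no count-model family converged", call. = FALSE)
  winner <- names(which.min(aic))
  fit <- fits[[winner]]

  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df_resid <- stats::df.residual(fit)
  gof <- list(statistic = pearson, df = df_resid,
              p = pchisq(pearson, df_resid, lower.tail = FALSE))

  effects <- NULL; within_level <- NULL
  if (length(factors) >= 1) {
    refit <- function(rhs2) suppressWarnings(
      fit_count_family(winner, as.formula(paste(response, "~", rhs2)), ~1, data))
    rows <- list()
    if (length(factors) == 2) {
      additive <- refit(paste(factors, collapse = " + "))
      lt <- lr_test(fit, additive)
      rows$interaction <- tibble::tibble(
        effect = paste(factors, collapse = ":"),
        statistic = lt$statistic, df = lt$df, p = lt$p_value)
      for (i in 1:2) {
        solo <- refit(factors[-i])
        lt <- lr_test(additive, solo)
        rows[[factors[i]]] <- tibble::tibble(
          effect = factors[i], statistic = lt$statistic, df = lt$df,
          p = lt$p_value)
      }
      if (rows$interaction$p < alpha) {
        within_level <- lapply(levels(data[[factors[1]]]), function(lv) {
          sub <- data[data[[factors[1]]] == lv, , drop = FALSE]
          tryCatch(select_count_model(sub, response, factors[2], alpha),
                   error = function(e) NULL)
        })
        names(within_level) <- levels(data[[factors[1]]])
      }
    } else {
      null_fit <- refit("1")
      lt <- lr_test(fit, null_fit)
      rows[[factors]] <- tibble::tibble(
        effect = factors, statistic = lt$statistic, df = lt$df, p = lt$p_value)
    }
    effects <- dplyr::bind_rows(rows)
  }
  structure(list(family = winner, aic = aic, fit = fit, gof = gof,
                 effects = effects, within_level = within_level,
                 failed_families = families[is.na(aic)], all_zero = FALSE),
            class = "count_model_selection")
}

#' @export
print.count_model_selection <- function(x, ...) {
  cat("<count_model_selection>")
  if (x$all_zero) { cat(" all counts zero: no population\n"); return(invisible(x)) }
  cat(" family =", x$family, "\n  AIC:",
      paste(sprintf("%s %.1f", names(x$aic), x$aic), collapse = ", "), "\n")
  if (!is.null(x$effects))
    for (i in seq_len(nrow(x$effects)))
      cat(sprintf("  LR %s: chi2 = %.2f (df %d), p = %.4g\n",
                  x$effects$effect[i], x$effects$statistic[i],
                  x$effects$df[i], x$effects$p[i]))
  invisible(x)
}
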