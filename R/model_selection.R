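# Information-theoretic attribution of phenology to temperature vs
# moisture predictors: a fixed 15-model candidate set per response
# (3 temperature x 3 moisture pairs + 6 singletons), ranked by AICc, with
# Akaike-weight relative variable importance.

TEMP_VARS <- c("MAT", "MWT", "MST")
MOIST_VARS <- c("MAMP", "DFWP_days", "DBWP")

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, where `k` counts every
#' estimated parameter including the intercept and the residual variance.
#'
#' @param logLik Model log-likelihood.
#' @param k Parameter count (intercept + slopes + residual variance).
#' @param n Number of observations.
#' @return AICc value. Infinite when `n <= k + 1` (correction undefined).
#' @examples
#' aicc(-10, k = 3, n = 20)  # 27.5
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2, 4))  # ~0.665, 0.245, 0.090
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Build the 15-model candidate set for one response
#'
#' Fits ordinary linear models of a plot-level phenometric on every
#' combination of one temperature variable (MAT, MWT, MST) with one
#' moisture variable (MAMP, DFWP_days, DBWP) — nine models — plus each of
#' the six variables alone. The six predictors are strongly correlated
#' within their pools, which is why single-pool-member models replace one
#' multiple regression. All 15 models are fit on the same rows — those
#' complete for the response and every non-constant predictor — because
#' AICc values (and hence Akaike weights) are only comparable between
#' models of identical data. `k` counts intercept, slopes and the
#' residual variance.
#'
#' @param data Tibble holding the response column and the six predictor
#'   columns (plot-level climate summaries joined to phenometrics).
#' @param response Name of the response column.
#' @param temp_vars,moist_vars Predictor pools (defaults MAT/MWT/MST and
#'   MAMP/DFWP_days/DBWP).
#' @return List with class `candidate_set`: `response`, `models` (tibble:
#'   `model`, `terms`, `k`, `n`, `logLik`, `AICc`, `delta`, `weight`),
#'   `fits` (named list of `lm` objects), `dropped` (constant predictors
#'   excluded, with the resulting set size).
#' @examples
#' # see tests for closed-form weight examples
#' @export
build_candidate_set <- function(data, response,
                                temp_vars = TEMP_VARS,
                                moist_vars = MOIST_VARS) {
  stopifnot(response %in% names(data), all(c(temp_vars, moist_vars) %in% names(data)))
  all_vars <- c(temp_vars, moist_vars)
  usable <- !is.na(data[[response]])
  const <- vapply(all_vars, function(v) {
    x <- data[[v]][usable & !is.na(data[[v]])]
    length(unique(x)) < 2
  }, logical(1))
  dropped <- all_vars[const]
  temp_vars <- setdiff(temp_vars, dropped)
  moist_vars <- setdiff(moist_vars, dropped)

  specs <- c(
    lapply(c(temp_vars, moist_vars), function(v) v),
    unlist(lapply(temp_vars, function(tv)
      lapply(moist_vars, function(mv) c(tv, mv))), recursive = FALSE))
  keep <- usable & stats::complete.cases(
    data[, c(temp_vars, moist_vars), drop = FALSE])
  df <- data[keep, , drop = FALSE]
  fits <- list()
  rows <- lapply(specs, function(terms) {
    f <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    fit <- lm(f, data = df)
    nm <- paste(terms, collapse = "+")
    fits[[nm]] <<- fit
    ll <- as.numeric(logLik(fit))
    k <- length(coef(fit)) + 1  # + residual variance
    n <- nrow(df)
    tibble::tibble(model = nm, terms = list(terms), k = k, n = n,
                   logLik = ll, AICc = aicc(ll, k, n))
  })
  models <- dplyr::bind_rows(rows)
  models$delta <- models$AICc - min(models$AICc)
  models$weight <- akaike_weights(models$AICc)
  models <- models[order(models$AICc), ]
  structure(list(response = response, models = models, fits = fits,
                 temp_vars = temp_vars, moist_vars = moist_vars,
                 dropped = dropped, n_models = nrow(models)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set>", x$response, "-", x$n_models, "models\n")
  m <- x$models
  top <- utils::head(m, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-14s k=%d n=%d AICc=%8.2f delta=%6.2f w=%.3f\n",
                top$model[i], top$k[i], top$n[i], top$AICc[i],
                top$delta[i], top$weight[i]))
  if (nrow(m) > 5) cat("  ...", nrow(m) - 5, "more\n")
  invisible(x)
}

#' Equivalent-model report with the parsimony rule
#'
#' Reports the models within `delta_equiv` AICc units of the best model,
#' but removes any two-predictor model whose AICc exceeds that of either
#' of its own single-predictor submodels (a pair that cannot beat its own
#' parts adds nothing but parameters). Weights are not renormalised: they
#' remain the full-set weights.
#'
#' @param set A `candidate_set`.
#' @param delta_equiv Equivalence band in AICc units (default 2).
#' @return The `models` tibble restricted to the reported models, with a
#'   `reported` column also added to `set$models` for reference.
#' @export
rank_and_filter <- function(set, delta_equiv = 2.0) {
  stopifnot(inherits(set, "candidate_set"))
  m <- set$models
  aicc_of <- setNames(m$AICc, m$model)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$delta[i] >= delta_equiv) next
    terms <- m$terms[[i]]
    if (length(terms) == 2) {
      subs <- aicc_of[terms]
      subs <- subs[!is.na(subs)]
      if (length(subs) > 0 && any(m$AICc[i] > subs)) next
    }
    keep[i] <- TRUE
  }
  m$reported <- keep
  m[keep, ]
}

#' Relative variable importance
#'
#' For each predictor, the sum of the Akaike weights of every model in the
#' full candidate set that contains it. Computed over all models, never
#' over the filtered report, because the importance definition sums over
#' the whole set.
#'
#' @param set A `candidate_set`.
#' @return Tibble `predictor`, `importance`, `is_max` (one flagged
#'   maximum; ties flag the first in pool order), `pool`
#'   (temperature/moisture).
#' @export
relative_importance <- function(set) {
  stopifnot(inherits(set, "candidate_set"))
  preds <- c(set$temp_vars, set$moist_vars)
  imp <- vapply(preds, function(v) {
    has <- vapply(set$models$terms, function(tt) v %in% tt, logical(1))
    sum(set$models$weight[has])
  }, numeric(1))
  tibble::tibble(
    predictor = preds,
    importance = unname(imp),
    is_max = seq_along(imp) == which.max(imp),
    pool = ifelse(preds %in% set$temp_vars, "temperature", "moisture"))
}

#' Importance table across responses
#'
#' Convenience wrapper: builds a candidate set and importance row for each
#' named response column, shaped one row per response with one column per
#' predictor plus the flagged maximum.
#'
#' @param data Tibble with response and predictor columns.
#' @param responses Character vector of response column names.
#' @inheritParams build_candidate_set
#' @return Tibble `response`, one column per predictor, `top_predictor`.
#' @export
importance_table <- function(data, responses,
                             temp_vars = TEMP_VARS, moist_vars = MOIST_VARS) {
  rows <- lapply(responses, function(r) {
    cs <- build_candidate_set(data, r, temp_vars, moist_vars)
    ri <- relative_importance(cs)
    wide <- as.list(setNames(ri$importance, ri$predictor))
    tibble::as_tibble(c(list(response = r), wide,
                        list(top_predictor = ri$predictor[ri$is_max])))
  })
  dplyr::bind_rows(rows)
}
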