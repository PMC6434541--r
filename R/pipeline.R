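# End-to-end pipeline: climate summaries -> phenometrics -> inference.

annual_start <- function(config, season) config$annual_windows[[season]][["start"]]

#' Run the full phenology pipeline
#'
#' Chains every stage on an input bundle: soil matric potential from
#' texture-based retention curves, annual plot-level climate summaries
#' (MAT/MWT/MST/MAMP/DFWP/DBWP per hydrological year), NDVI phenometrics
#' per plot and season, flowering metrics and temperature sensitivities,
#' the treatment-collapse decision, warming-effect tests, count-model
#' family selection for abundances, and the 15-model AICc candidate sets
#' with relative variable importance for every phenology response. Date
#' responses enter the models as days since the start of the matching
#' annual window, so 2017 and 2018 phenometrics pool on a common scale.
#'
#' @param inputs A `pheno_experiment` from [simulate_experiment()], or a
#'   list with elements `design`, `env` (daily), `ndvi`, `flowering`,
#'   `textures` (named list of [soil_texture()]).
#' @param config A [pheno_config()].
#' @param exclusions Optional list of `list(plot_id =, interval = c(start,
#'   end))` masks applied to the environmental and NDVI series (e.g. a
#'   heater-malfunction period).
#' @return List with class `pheno_results`: `climate`, `phenometrics`,
#'   `responses`, `collapse`, `warming_effects`, `flowering_metrics`,
#'   `sensitivity`, `abundance`, `count_models`, `candidate_sets`,
#'   `importance`, `provenance`.
#' @export
run_pipeline <- function(inputs, config = pheno_config(), exclusions = list()) {
  design <- inputs$design
  validate_design(design)
  env <- inputs$env
  ndvi <- inputs$ndvi
  flowering <- inputs$flowering
  textures <- if (inherits(inputs, "pheno_experiment"))
    lapply(inputs$specs, function(sp) sp$texture) else inputs$textures
  set.seed(config$rng_seed)
  provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    input_hash = rlang::hash(list(design, env, ndvi, flowering)),
    n_plots = nrow(design), exclusions = character())

  for (ex in exclusions) {
    env <- exclude_plot_interval(env, ex$plot_id, ex$interval)
    ndvi <- exclude_plot_interval(ndvi, ex$plot_id, ex$interval)
    provenance$exclusions <- c(provenance$exclusions,
                               sprintf("%s [%s..%s]", ex$plot_id,
                                       ex$interval[1], ex$interval[2]))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  curves <- stage("retention_curves",
                  lapply(textures, fit_retention_curve))
  psi <- stage("matric_potential",
               matric_potential_series(env, design, curves,
                                       config$wilting_point_kPa))
  climate <- stage("climate_summary", {
    rows <- lapply(names(config$annual_windows), function(season) {
      cs <- summarize_climate(env, psi, config$annual_windows[[season]],
                              config)
      cs$season <- season
      cs
    })
    dplyr::bind_rows(rows)
  })

  phen <- stage("ndvi_phenometrics", ndvi_phenometrics(ndvi, config))

  # long response table: one row per plot x season x response, in days
  # since the matching annual-window start (dates) or raw units (rates)
  responses <- stage("responses", {
    ph <- dplyr::left_join(phen, design, by = "plot_id")
    rows <- list()
    for (i in seq_len(nrow(ph))) {
      a0 <- annual_start(config, ph$season[i])
      add <- function(resp, val) tibble::tibble(
        plot_id = ph$plot_id[i], season = ph$season[i], response = resp,
        value = val)
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        add("peak_date", as.numeric(ph$peak_date[i] - a0)),
        add("senescence_date",
            if (ph$senescence_censored[i]) NA_real_
            else as.numeric(ph$senescence_date[i] - a0)),
        add("senescence_rate",
            if (ph$nonsenescent[i]) NA_real_ else ph$senescence_rate[i]),
        if (ph$season[i] == as.character(config$years[2]))
          add("gsl", as.numeric(ph$gsl_days[i])))
    }
    dplyr::bind_rows(rows)
  })

  ndvi_resp <- c("peak_date", "senescence_date", "senescence_rate", "gsl")
  collapse <- stage("collapse", {
    rows <- lapply(ndvi_resp, function(r) {
      x <- merge_response(responses, r, design)
      dec <- collapse_treatments(x$value[match(design$plot_id, x$plot_id)],
                                 design, config$collapse_alpha)
      tibble::tibble(response = r,
                     p_control_vs_drought = dec$p_control_vs_drought,
                     p_warming_vs_warmingppt = dec$p_warming_vs_warmingppt,
                     collapsed = dec$collapsed, deferred = dec$deferred)
    })
    dplyr::bind_rows(rows)
  })

  warming_effects <- stage("warming_effects", {
    rows <- list()
    for (r in ndvi_resp) {
      for (season in unique(responses$season[responses$response == r])) {
        x <- responses[responses$response == r & responses$season == season, ]
        x <- dplyr::left_join(x, design, by = "plot_id")
        x <- x[!is.na(x$value), ]
        pooled <- tryCatch(
          compare_two_groups(x$value, x$temp_category), error = function(e) NULL)
        if (!is.null(pooled))
          rows[[length(rows) + 1]] <- tibble::tibble(
            response = r, season = season, site = "all",
            difference = pooled$difference, se = pooled$se,
            p_value = pooled$p_value, untestable = pooled$untestable)
        for (s in levels(design$site)) {
          xs <- x[x$site == s, ]
          g <- tryCatch(compare_two_groups(xs$value, xs$temp_category),
                        error = function(e) NULL)
          if (!is.null(g))
            rows[[length(rows) + 1]] <- tibble::tibble(
              response = r, season = season, site = s,
              difference = g$difference, se = g$se, p_value = g$p_value,
              untestable = g$untestable)
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  # flowering stages are independent of the NDVI stages: an empty survey
  # table yields empty flowering outputs, not a failure
  has_flowering <- !is.null(flowering) && nrow(flowering) > 0
  fmetrics <- stage("flowering_metrics",
                    if (has_flowering) flowering_metrics(flowering)
                    else flowering_metrics(empty_surveys()))
  sens <- stage("sensitivity",
                if (has_flowering)
                  sensitivity_table(fmetrics, design, config$warming_delta_C)
                else tibble::tibble())
  abund <- stage("abundance",
                 if (has_flowering) abundance_table(fmetrics, design)
                 else tibble::tibble())
  count_models <- stage("count_models", {
    if (!has_flowering) list()
    else {
      out <- list()
      for (sp in unique(fmetrics$species)) {
        d <- complete_abundance(fmetrics[fmetrics$species == sp, ], design)
        out[[sp]] <- tryCatch(
          select_count_model(d, "abundance", c("site", "treatment")),
          error = function(e) structure(
            list(family = NA_character_, error = conditionMessage(e)),
            class = "count_model_selection"))
      }
      out
    }
  })

  model_data <- stage("model_data", {
    cl <- climate[, c("plot_id", "season", "MAT", "MWT", "MST", "MAMP",
                      "DFWP_days", "DBWP")]
    dplyr::left_join(responses, cl, by = c("plot_id", "season"))
  })

  candidate_sets <- list(); importance_rows <- list()
  stage("model_selection", {
    for (r in ndvi_resp) {
      d <- model_data[model_data$response == r, ]
      if (sum(!is.na(d$value)) < 10) next
      names(d)[names(d) == "value"] <- r
      cs <- build_candidate_set(d, r)
      candidate_sets[[r]] <- cs
      ri <- relative_importance(cs)
      importance_rows[[r]] <- tibble::tibble(
        response = r, predictor = ri$predictor, importance = ri$importance,
        is_max = ri$is_max, pool = ri$pool)
    }
    if (has_flowering) {
      y1 <- as.character(config$years[1])
      cl1 <- climate[climate$season == y1,
                     c("plot_id", "MAT", "MWT", "MST", "MAMP", "DFWP_days",
                       "DBWP")]
      a0 <- annual_start(config, y1)
      site_of <- setNames(as.character(design$site), design$plot_id)
      for (ev in c("ffd", "pfd")) {
        for (sp in unique(fmetrics$species)) {
          fm <- fmetrics[fmetrics$species == sp & !is.na(fmetrics[[ev]]), ]
          if (length(unique(site_of[fm$plot_id])) < 2) next  # single-site species
          d <- dplyr::left_join(
            tibble::tibble(plot_id = fm$plot_id,
                           value = as.numeric(fm[[ev]] - a0)),
            cl1, by = "plot_id")
          if (sum(!is.na(d$value)) < 10) next
          rname <- paste0(toupper(ev), "_", sp)
          names(d)[names(d) == "value"] <- rname
          cs <- build_candidate_set(d, rname)
          candidate_sets[[rname]] <- cs
          ri <- relative_importance(cs)
          importance_rows[[rname]] <- tibble::tibble(
            response = rname, predictor = ri$predictor,
            importance = ri$importance, is_max = ri$is_max, pool = ri$pool)
        }
      }
    }
    invisible(NULL)
  })
  importance <- dplyr::bind_rows(importance_rows)

  structure(list(climate = climate, phenometrics = phen,
                 responses = responses, collapse = collapse,
                 warming_effects = warming_effects,
                 flowering_metrics = fmetrics, sensitivity = sens,
                 abundance = abund, count_models = count_models,
                 candidate_sets = candidate_sets, importance = importance,
                 provenance = provenance, config = config),
            class = "pheno_results")
}

merge_response <- function(responses, r, design) {
  x <- responses[responses$response == r, ]
  # one value per plot: mean over seasons (dates are on a common
  # days-since-window-start scale)
  dplyr::summarise(dplyr::group_by(x, .data$plot_id),
                   value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

empty_surveys <- function() {
  tibble::tibble(plot_id = character(), species = character(),
                 date = as.Date(character()), open_flowers = integer(),
                 flowering_individuals = integer())
}

complete_abundance <- function(fm, design) {
  d <- dplyr::left_join(design, fm[, c("plot_id", "abundance")],
                        by = "plot_id")
  d$abundance[is.na(d$abundance)] <- 0L
  d
}

#' @export
print.pheno_results <- function(x, ...) {
  cat("<pheno_results>\n")
  cat("  climate summaries:", nrow(x$climate), "plot-years\n")
  cat("  phenometrics:", nrow(x$phenometrics), "plot-seasons\n")
  cat("  candidate sets:", length(x$candidate_sets), "responses\n")
  if (nrow(x$importance) > 0) {
    tops <- x$importance[x$importance$is_max, ]
    cat("  top predictors:",
        paste(sprintf("%s=%s", tops$response, tops$predictor),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write pipeline result tables to CSV
#'
#' @param results A `pheno_results`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "pheno_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(climate = results$climate, phenometrics = results$phenometrics,
               responses = results$responses, collapse = results$collapse,
               warming_effects = results$warming_effects,
               flowering_metrics = results$flowering_metrics,
               sensitivity = results$sensitivity,
               abundance = results$abundance,
               importance = results$importance)
  model_rows <- lapply(names(results$candidate_sets), function(r) {
    m <- results$candidate_sets[[r]]$models
    tibble::tibble(response = r, model = m$model, k = m$k, n = m$n,
                   logLik = m$logLik, AICc = m$AICc, delta = m$delta,
                   weight = m$weight)
  })
  tabs$model_table <- dplyr::bind_rows(model_rows)
  paths <- character()
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]]) || nrow(tabs[[nm]]) == 0) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], p)
    paths[nm] <- p
  }
  writeLines(c(paste0("config_hash: ", results$provenance$config_hash),
               paste0("input_hash: ", results$provenance$input_hash),
               paste0("exclusions: ",
                      paste(results$provenance$exclusions, collapse = "; "))),
             file.path(dir, "provenance.txt"))
  invisible(paths)
}
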