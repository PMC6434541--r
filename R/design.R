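#' Experimental plot design
#'
#' Construct the plot-level design table for a warming x moisture
#' manipulation experiment: every combination of site, climate treatment and
#' replicate, with a stable plot identifier and the derived two-level
#' temperature category (heated plots vs unheated plots).
#'
#' The default design is 3 sites x 4 treatments x 5 replicates = 60 plots.
#' Treatments are `control` (ambient temperature and precipitation),
#' `drought` (rain-out shelters excluding a fixed fraction of precipitation),
#' `warming` (infrared heaters raising canopy temperature by a fixed offset)
#' and `warming_ppt` (warming plus feedback irrigation that offsets the
#' warming-induced drying). Control and drought are `ambient` temperature
#' category; warming and warming_ppt are `warming`.
#'
#' @param sites Character vector of site labels, ordered south to north.
#' @param treatments Character vector of treatment labels.
#' @param n_replicates Number of replicate plots per site x treatment.
#'
#' @return A tibble with columns `plot_id`, `site`, `treatment`, `replicate`
#'   and `temp_category`, one row per plot. `site`, `treatment` and
#'   `temp_category` are factors with levels in design order.
#' @examples
#' d <- plot_design()
#' nrow(d)           # 60
#' table(d$temp_category)
#' @export
plot_design <- function(sites = c("southern", "central", "northern"),
                        treatments = c("control", "drought", "warming", "warming_ppt"),
                        n_replicates = 5) {
  stopifnot(length(sites) >= 1, length(treatments) >= 1, n_replicates >= 1)
  d <- expand.grid(replicate = seq_len(n_replicates),
                   treatment = treatments, site = sites,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- tibble::tibble(
    plot_id = sprintf("%s_%s_%02d", substr(d$site, 1, 1), d$treatment, d$replicate),
    site = factor(d$site, levels = sites),
    treatment = factor(d$treatment, levels = treatments),
    replicate = as.integer(d$replicate),
    temp_category = temperature_category(d$treatment)
  )
  validate_design(d)
  d
}

#' Map climate treatments to temperature categories
#'
#' Collapses the four climate treatments into the two-level temperature
#' factor used when the moisture manipulations show no effect: `ambient`
#' (control, drought) vs `warming` (warming, warming_ppt).
#'
#' @param treatment Character or factor vector of treatment labels.
#' @return Factor with levels `ambient`, `warming`.
#' @examples
#' temperature_category(c("control", "drought", "warming", "warming_ppt"))
#' @export
temperature_category <- function(treatment) {
  treatment <- as.character(treatment)
  bad <- setdiff(unique(treatment),
                 c("control", "drought", "warming", "warming_ppt"))
  if (length(bad) > 0)
    stop("unknown treatment(s): ", paste(bad, collapse = ", "), call. = FALSE)
  factor(ifelse(treatment %in% c("warming", "warming_ppt"), "warming", "ambient"),
         levels = c("ambient", "warming"))
}

#' Validate a plot design table
#'
#' Checks structural invariants: required columns, unique plot ids, a
#' complete crossed design (every site x treatment x replicate cell present
#' exactly once), and consistency of the derived temperature category.
#'
#' @param design A design tibble as produced by [plot_design()].
#' @return The design, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(design) {
  need <- c("plot_id", "site", "treatment", "replicate", "temp_category")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$plot_id))
    stop("duplicate plot_id in design", call. = FALSE)
  cells <- table(design$site, design$treatment)
  if (length(unique(as.vector(cells))) != 1)
    stop("design is not a complete crossed site x treatment layout", call. = FALSE)
  ok <- as.character(design$temp_category) ==
    as.character(temperature_category(design$treatment))
  if (!all(ok))
    stop("temp_category inconsistent with treatment", call. = FALSE)
  invisible(design)
}
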