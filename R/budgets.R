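# Activity budgets: convert classified behavior time series plus diel
# annotations into proportion-of-time tables at configurable groupings,
# and join nightly covariates for modeling.

#' Compute activity budgets
#'
#' Each classified window is assigned to the light phase (and night,
#' moon state) containing its midpoint; counts and proportions of the
#' four behaviors are then computed within every grouping cell.
#' Proportions within one cell sum to 1 and `n_windows` conserves the
#' total classified time.
#'
#' @param predictions data.frame from [annotate_deployment()] (columns
#'   `deployment_id`, `start`, `end`, `behavior`), possibly from several
#'   deployments; a column `individual` is honored, otherwise
#'   `deployment_id` is used as the individual.
#' @param site A [site_context()] used to annotate window midpoints; or
#'   pass a precomputed `diel` table.
#' @param grouping Character subset of
#'   `c("individual", "night", "phase", "moon_intensity", "moon_up")`.
#' @param diel Optional precomputed [diel_annotation()] at the window
#'   midpoints (must align row-for-row with `predictions`).
#' @return data.frame of class cells: grouping columns, `behavior`,
#'   `n_windows`, `total_windows`, `proportion`.
#' @export
compute_budgets <- function(predictions, site = NULL,
                            grouping = c("individual", "night", "phase"),
                            diel = NULL) {
  stopifnot(nrow(predictions) > 0)
  grouping <- match.arg(grouping,
    c("individual", "night", "phase", "moon_intensity", "moon_up"),
    several.ok = TRUE
  )
  mid <- .as_utc(predictions$start) +
    (as.numeric(predictions$end) - as.numeric(predictions$start)) / 2
  if (is.null(diel)) {
    if (is.null(site)) stop("supply either a site_context or a diel table")
    diel <- diel_annotation(site, mid)
  } else if (nrow(diel) != nrow(predictions)) {
    stop(
      "diel annotation does not cover the prediction span: ",
      nrow(diel), " rows vs ", nrow(predictions), " windows"
    )
  }
  individual <- if ("individual" %in% names(predictions)) {
    predictions$individual
  } else {
    predictions$deployment_id
  }
  keys <- list()
  if ("individual" %in% grouping) keys$individual <- individual
  if ("night" %in% grouping) {
    if (is.null(site)) stop("night grouping requires a site_context")
    keys$night <- night_id(site, mid)
  }
  if ("phase" %in% grouping) keys$phase <- as.character(diel$light_phase)
  if ("moon_intensity" %in% grouping) {
    keys$moon_intensity <- as.character(diel$moon_intensity)
  }
  if ("moon_up" %in% grouping) keys$moon_up <- diel$moon_up
  if (length(keys) == 0L) keys$all <- rep("all", nrow(predictions))

  cell <- interaction(as.data.frame(keys), drop = TRUE, sep = "\r")
  beh <- factor(predictions$behavior, levels = behavior_classes())
  counts <- table(cell = cell, behavior = beh)
  totals <- rowSums(counts)
  keydf <- unique(data.frame(as.data.frame(keys), cell = as.character(cell),
    stringsAsFactors = FALSE
  ))
  out <- merge(
    keydf,
    data.frame(
      cell = rep(rownames(counts), 4),
      behavior = rep(colnames(counts), each = nrow(counts)),
      n_windows = as.vector(counts),
      total_windows = rep(totals, 4)
    ),
    by = "cell"
  )
  out$cell <- NULL
  out$proportion <- out$n_windows / out$total_windows
  o <- do.call(order, out[c(names(keys), "behavior")])
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.MOON_PHASES <- c("dusk", "evening_twilight", "night", "morning_twilight", "dawn")

#' Attach nightly covariates to a budget table
#'
#' Joins moon illumination/intensity, weather and sex onto the budget
#' cells by night. With `moon_analysis = TRUE`, rows are restricted to
#' the light phases where the sun is below the horizon (dusk, evening
#' twilight, night, morning twilight, dawn), matching the moonlight
#' analysis design. Nights flagged `excluded` (precipitation) are dropped
#' and counted.
#'
#' @param budgets Budget table from [compute_budgets()]; must carry a
#'   `night` column (and `phase` if `moon_analysis`).
#' @param covariates Nightly covariate table (`night`, `moon_illumination`,
#'   `temperature`, `wind`, `humidity`, optional `excluded`).
#' @param individuals Optional data.frame `individual`, `sex`.
#' @param moon_analysis Restrict to below-horizon phases.
#' @param drop_excluded Drop precipitation-excluded nights (default TRUE
#'   when an `excluded` column is present).
#' @return Model-ready data.frame; attribute `"n_dropped_excluded"`
#'   counts rows removed by the precipitation exclusion.
#' @export
attach_covariates <- function(budgets, covariates, individuals = NULL,
                              moon_analysis = FALSE, drop_excluded = TRUE) {
  stopifnot("night" %in% names(budgets))
  missing <- setdiff(unique(budgets$night), covariates$night)
  if (length(missing) > 0L) {
    stop(
      "no covariates for night(s): ",
      paste(as.Date(missing, origin = "1970-01-01"), collapse = ", ")
    )
  }
  covs <- covariates
  if (!"moon_intensity" %in% names(covs) && "moon_illumination" %in% names(covs)) {
    covs$moon_intensity_nightly <- as.character(moon_intensity(covs$moon_illumination))
  }
  out <- merge(budgets, covs, by = "night", all.x = TRUE, sort = FALSE)
  n_dropped <- 0L
  if (drop_excluded && "excluded" %in% names(out)) {
    n_dropped <- sum(out$excluded)
    out <- out[!out$excluded, , drop = FALSE]
  }
  if (moon_analysis) {
    if (!"phase" %in% names(out)) {
      stop("moon_analysis requires a phase column in the budget table")
    }
    out <- out[out$phase %in% .MOON_PHASES, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    out <- merge(out, individuals, by = "individual", all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_excluded") <- n_dropped
  out
}
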