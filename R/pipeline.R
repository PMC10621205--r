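# End-to-end pipeline: simulate (or read) deployments, build labeled
# feature tables, select the best classifier, annotate every deployment,
# annotate light phases and moon state, compute activity budgets, attach
# covariates and fit the covariate GLMMs. One call, one seed, one output
# directory of tidy CSVs plus a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every knob of a full run. Defaults mirror the study design:
#' a West Texas site, 25 Hz sampling, window sizes 1/2/3/6/9 s, all three
#' algorithms and both feature sets.
#'
#' @param site A [site_context()].
#' @param fs Sampling frequency, Hz.
#' @param window_sizes Candidate window sizes in seconds.
#' @param algorithms Candidate algorithms (see [model_spec()]).
#' @param feature_sets Candidate feature sets.
#' @param n_individuals,nights Synthetic study size.
#' @param start_date First night of the synthetic study.
#' @param humidity_effect Injected ground-truth humidity-to-foraging
#'   effect (0 = none).
#' @param train_cap_per_class Maximum labeled windows per class offered to
#'   the model grid (seeded subsample). Mirrors the field protocol, where
#'   only a modest video-validated subset of each deployment is labeled
#'   (about two hours of footage in total), and bounds training cost.
#' @param moon_analysis Also produce the moon-restricted model table.
#' @param exclude_precipitation Drop precipitation nights from modeling.
#' @param output_dir Directory for result CSVs and the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(site = site_context(30.2, -103.5, "America/Chicago"),
                            fs = 25,
                            window_sizes = c(1, 2, 3, 6, 9),
                            algorithms = c("linear_svm", "decision_tree", "random_forest"),
                            feature_sets = c("all", "reduced"),
                            n_individuals = 4, nights = 2,
                            start_date = "2021-06-01",
                            humidity_effect = 0,
                            train_cap_per_class = 400,
                            moon_analysis = TRUE,
                            exclude_precipitation = FALSE,
                            output_dir = tempfile("accelbudget_run_")) {
  stopifnot(inherits(site, "site_context"), fs > 0, all(window_sizes > 0))
  structure(
    list(
      site = site, fs = fs, window_sizes = window_sizes,
      algorithms = algorithms, feature_sets = feature_sets,
      n_individuals = n_individuals, nights = nights,
      start_date = start_date, humidity_effect = humidity_effect,
      train_cap_per_class = train_cap_per_class,
      moon_analysis = moon_analysis,
      exclude_precipitation = exclude_precipitation,
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

.write_result_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- .format_ts(out[[nm]])
    } else if (inherits(out[[nm]], "Date")) {
      out[[nm]] <- as.character(out[[nm]])
    } else if (is.numeric(out[[nm]])) {
      out[[nm]] <- sprintf("%.10g", out[[nm]])
    } else if (is.factor(out[[nm]])) {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Chains every stage on synthetic deployments: simulate traces with
#' ground truth, build labeled feature tables per candidate window size,
#' balance/split/evaluate the model grid, annotate all deployments with
#' the best model, compute diel-annotated activity budgets, attach the
#' nightly covariates, and fit the light-phase GLMM per behavior (plus
#' the moon-restricted model when configured). All randomness derives
#' from `seed`; two runs with the same config and seed write bit-identical
#' result tables.
#'
#' @param config A [pipeline_config()].
#' @param seed Master integer seed.
#' @return Invisibly, a list: `study`, `selection`, `annotations`
#'   (predictions), `budgets`, `model_ready`, `fits`, `results`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  study <- simulate_study(
    n_individuals = config$n_individuals, nights = config$nights,
    start_date = config$start_date, site = config$site,
    fs = config$fs, seed = seed,
    humidity_effect = config$humidity_effect
  )

  # labeled feature tables pooled over deployments, one per window size;
  # capped per class to emulate the video-validated labeled subset
  labeled <- lapply(config$window_sizes, function(w) {
    tabs <- Map(function(tr, ann) {
      wins <- label_windows(segment(tr, w), ann)
      feature_table(wins)
    }, study$traces, study$annotations)
    tab <- do.call(rbind, tabs)
    cap <- config$train_cap_per_class
    if (is.finite(cap)) {
      .run_seeded(seed + round(w * 100), {
        keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$label), function(rows) {
          if (length(rows) > cap) sort(sample(rows, cap)) else rows
        }))
        tab <- tab[sort(keep), , drop = FALSE]
      })
    }
    tab
  })
  names(labeled) <- as.character(config$window_sizes)

  selection <- model_selection(
    labeled,
    algorithms = config$algorithms,
    feature_sets = config$feature_sets,
    seed = seed
  )

  predictions <- do.call(rbind, lapply(study$traces, function(tr) {
    annotate_deployment(tr, selection$best$model)
  }))
  rownames(predictions) <- NULL
  predictions$individual <- predictions$deployment_id

  budgets <- compute_budgets(
    predictions,
    site = config$site,
    grouping = c("individual", "night", "phase", "moon_up")
  )
  covs <- study$covariates
  covs$excluded <- config$exclude_precipitation & covs$precipitation > 0
  model_ready <- attach_covariates(
    budgets, covs,
    individuals = study$individuals,
    moon_analysis = FALSE
  )
  model_ready$moon_intensity <- as.character(
    moon_intensity(model_ready$moon_illumination)
  )

  fits <- list()
  results <- list()
  for (beh in behavior_classes()) {
    d <- model_ready[model_ready$behavior == beh, , drop = FALSE]
    d$n_behavior <- d$n_windows
    d$n_total <- d$total_windows
    d$proportion <- d$n_behavior / d$n_total
    sel <- tryCatch(
      select_family(d, fixed = c("phase", "sex"), candidates = c("gaussian", "binomial")),
      error = function(e) NULL
    )
    if (is.null(sel)) next
    fits[[beh]] <- sel$fit
    results[[beh]] <- model_results_table(sel$fit, behavior = beh)
  }
  results_tab <- do.call(rbind, results)
  rownames(results_tab) <- NULL

  moon_results <- NULL
  if (config$moon_analysis) {
    moon_ready <- attach_covariates(
      budgets, covs,
      individuals = study$individuals, moon_analysis = TRUE
    )
    moon_ready$moon_intensity <- as.character(
      moon_intensity(moon_ready$moon_illumination)
    )
    mr <- list()
    for (beh in behavior_classes()) {
      d <- moon_ready[moon_ready$behavior == beh, , drop = FALSE]
      d$n_behavior <- d$n_windows
      d$n_total <- d$total_windows
      d$proportion <- d$n_behavior / d$n_total
      if (length(unique(d$moon_up)) < 2L || length(unique(d$moon_intensity)) < 2L) next
      fit <- tryCatch(
        fit_mixed(d, fixed = c("moon_intensity * moon_up", "sex"), family = "binomial"),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      mr[[beh]] <- model_results_table(fit, behavior = beh)
    }
    if (length(mr) > 0L) {
      moon_results <- do.call(rbind, mr)
      rownames(moon_results) <- NULL
    }
  }

  od <- config$output_dir
  .write_result_csv(selection$leaderboard, file.path(od, "leaderboard.csv"))
  .write_result_csv(predictions, file.path(od, "annotations.csv"))
  .write_result_csv(budgets, file.path(od, "budgets.csv"))
  .write_result_csv(model_ready, file.path(od, "model_ready.csv"))
  if (!is.null(results_tab)) {
    .write_result_csv(results_tab, file.path(od, "model_results.csv"))
  }
  if (!is.null(moon_results)) {
    .write_result_csv(moon_results, file.path(od, "moon_model_results.csv"))
  }
  write_covariates(covs, file.path(od, "covariates.csv"))
  cfg <- config
  cfg$site <- unclass(config$site)
  cfg$output_dir <- NULL # path varies between runs; not part of the science
  write_manifest(unclass(cfg), seed, path = file.path(od, "manifest.json"))

  invisible(list(
    study = study, selection = selection, annotations = predictions,
    budgets = budgets, model_ready = model_ready, fits = fits,
    results = results_tab, moon_results = moon_results,
    output_dir = od
  ))
}
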