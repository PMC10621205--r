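# Synthetic deployment generator: diel-structured behavior bout sequences
# (continuous-time Markov chain with phase-switched generators), per-behavior
# tri-axial acceleration signals, and nightly covariates -- all with known
# ground truth so every downstream stage can be validated.

#' The four-behavior vocabulary
#'
#' Behavior classes used throughout the pipeline: `motionless`, `travel`,
#' `foraging`, `grooming`. Serialized as lowercase strings everywhere.
#'
#' @return Character vector of the four class names.
#' @export
behavior_classes <- function() {
  c("motionless", "travel", "foraging", "grooming")
}

.run_seeded <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Build a CTMC generator (rates per minute) from a named list of
# off-diagonal rates, e.g. list(motionless = c(travel = 0.5, ...)).
.make_generator <- function(rates) {
  cls <- behavior_classes()
  Q <- matrix(0, 4, 4, dimnames = list(cls, cls))
  for (from in names(rates)) {
    r <- rates[[from]]
    Q[from, names(r)] <- r
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

.validate_generator <- function(Q) {
  cls <- behavior_classes()
  if (!is.matrix(Q) || !identical(dim(Q), c(4L, 4L)) ||
    !identical(rownames(Q), cls) || !identical(colnames(Q), cls)) {
    stop("generator must be a 4x4 matrix with the four behavior classes as dimnames")
  }
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal transition rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-9)) {
    stop("generator rows must sum to zero (conservative rate matrix)")
  }
  invisible(Q)
}

#' Default phase-dependent activity profile
#'
#' A continuous-time Markov chain generator (transition rates per minute)
#' over the four behaviors for each of the eight light phases. The
#' defaults encode a strictly nocturnal animal: during the sun-up phases
#' (morning, day, evening) the animal is almost always motionless; dusk
#' and evening twilight carry moderate activity; night, morning twilight
#' and dawn carry peak travel and foraging -- matching the published
#' pattern of kangaroo rats being most active late in the night.
#'
#' @return Named list of eight 4x4 generator matrices, one per light phase.
#' @examples
#' prof <- default_diel_profile()
#' ctmc_stationary(prof$day)
#' @export
default_diel_profile <- function() {
  quiet <- .make_generator(list(
    motionless = c(travel = 0.005, foraging = 0.002, grooming = 0.008),
    travel = c(motionless = 3.0),
    foraging = c(motionless = 2.0),
    grooming = c(motionless = 1.5)
  ))
  early <- .make_generator(list(
    motionless = c(travel = 0.20, foraging = 0.15, grooming = 0.10),
    travel = c(motionless = 1.2, foraging = 0.3),
    foraging = c(motionless = 0.8, travel = 0.1, grooming = 0.15),
    grooming = c(motionless = 0.9, foraging = 0.15)
  ))
  peak <- .make_generator(list(
    motionless = c(travel = 0.8, foraging = 0.6, grooming = 0.35),
    travel = c(motionless = 0.9, foraging = 0.35),
    foraging = c(motionless = 0.7, travel = 0.15, grooming = 0.2),
    grooming = c(motionless = 0.8, foraging = 0.2)
  ))
  list(
    evening = quiet,
    dusk = early,
    evening_twilight = early,
    night = peak,
    morning_twilight = peak,
    dawn = peak,
    morning = quiet,
    day = quiet
  )
}

#' Stationary distribution of a CTMC generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for a conservative rate matrix.
#'
#' @param Q 4x4 generator matrix (rates per minute), rows summing to 0.
#' @return Named numeric vector of stationary occupancy fractions.
#' @export
ctmc_stationary <- function(Q) {
  .validate_generator(Q)
  A <- rbind(t(Q), rep(1, 4))
  b <- c(rep(0, 4), 1)
  pi <- qr.solve(A, b)
  names(pi) <- behavior_classes()
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Simulate a behavior bout schedule
#'
#' Samples a piecewise-homogeneous continuous-time Markov chain over the
#' four behaviors: within each light phase the chain evolves under that
#' phase's generator; at phase boundaries the generator switches while
#' the current behavior continues. Consecutive identical behaviors are
#' merged and bouts shorter than `min_bout_s` are absorbed into the
#' preceding bout so the schedule respects the 2 s minimum bout length.
#'
#' @param profile Named list of per-phase generators, as from
#'   [default_diel_profile()].
#' @param start POSIXct start time (UTC).
#' @param duration_h Duration in hours.
#' @param phase_fn Function mapping a POSIXct vector to light-phase names;
#'   typically built from [classify_light_phase()] with a fixed site.
#' @param seed Integer seed; schedules are exactly reproducible.
#' @param entry_scale Optional named numeric vector of multipliers applied
#'   to all transition rates *into* the named behaviors (the hook used to
#'   inject nightly covariate effects, e.g. a humidity to foraging slope).
#' @param initial Starting behavior (default `"motionless"`).
#' @param min_bout_s Minimum bout duration in seconds (default 2).
#' @return data.frame of class `bout_schedule`: columns `behavior`,
#'   `start`, `end` (POSIXct UTC); bouts contiguous and non-overlapping.
#' @export
simulate_bouts <- function(profile, start, duration_h, phase_fn, seed,
                           entry_scale = NULL, initial = "motionless",
                           min_bout_s = 2) {
  stopifnot(duration_h > 0)
  start <- .as_utc(start)
  for (Q in profile) .validate_generator(Q)
  if (!is.null(entry_scale)) {
    stopifnot(all(names(entry_scale) %in% behavior_classes()),
              all(entry_scale >= 0))
    profile <- lapply(profile, function(Q) {
      for (b in names(entry_scale)) Q[, b] <- Q[, b] * entry_scale[[b]]
      diag(Q) <- 0
      diag(Q) <- -rowSums(Q)
      Q
    })
  }
  end <- start + duration_h * 3600
  # phase boundaries on a 60 s grid (phases change over minutes, not seconds)
  grid <- seq(start, end, by = 60)
  if (grid[length(grid)] < end) grid <- c(grid, end)
  ph <- as.character(phase_fn(grid))
  if (any(is.na(ph)) || !all(ph %in% names(profile))) {
    stop("phase_fn must return phases named in the profile for every time")
  }
  chg <- c(TRUE, ph[-1] != ph[-length(ph)])
  seg_start <- as.numeric(grid[chg])
  seg_phase <- ph[chg]
  seg_end <- c(seg_start[-1], as.numeric(end))

  cls <- behavior_classes()
  .run_seeded(seed, {
    state <- match.arg(initial, cls)
    t_cur <- as.numeric(start)
    ev_time <- t_cur
    ev_state <- state
    for (s in seq_along(seg_start)) {
      Q <- profile[[seg_phase[s]]]
      t_cur <- max(t_cur, seg_start[s])
      repeat {
        rate <- -Q[state, state] / 60 # per minute -> per second
        if (rate <= 0) {
          t_cur <- seg_end[s]
          break
        }
        dt <- stats::rexp(1, rate)
        if (t_cur + dt >= seg_end[s]) {
          t_cur <- seg_end[s]
          break
        }
        t_cur <- t_cur + dt
        others <- setdiff(cls, state)
        state <- sample(others, 1, prob = Q[state, others])
        ev_time <- c(ev_time, t_cur)
        ev_state <- c(ev_state, state)
      }
    }
    sched <- data.frame(
      behavior = ev_state,
      start = as.POSIXct(ev_time, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(c(ev_time[-1], as.numeric(end)),
        origin = "1970-01-01", tz = "UTC"
      )
    )
    sched <- .merge_bouts(sched, min_bout_s)
    class(sched) <- c("bout_schedule", class(sched))
    sched
  })
}

# Merge consecutive identical bouts; absorb bouts shorter than min_s into
# the preceding (or, for a leading short bout, the following) bout.
.merge_bouts <- function(sched, min_s) {
  repeat {
    dur <- as.numeric(sched$end) - as.numeric(sched$start)
    short <- which(dur < min_s)
    if (nrow(sched) > 1L && length(short) > 0L) {
      i <- short[1]
      j <- if (i == 1L) 2L else i - 1L
      # absorb bout i into neighbour j
      keep_behavior <- sched$behavior[j]
      sched$behavior[i] <- keep_behavior
    } else {
      break
    }
    sched <- .collapse_runs(sched)
  }
  .collapse_runs(sched)
}

.collapse_runs <- function(sched) {
  if (nrow(sched) <= 1L) {
    rownames(sched) <- NULL
    return(sched)
  }
  run <- cumsum(c(TRUE, sched$behavior[-1] != sched$behavior[-nrow(sched)]))
  out <- data.frame(
    behavior = tapply(sched$behavior, run, `[`, 1),
    start = as.POSIXct(tapply(as.numeric(sched$start), run, min),
      origin = "1970-01-01", tz = "UTC"
    ),
    end = as.POSIXct(tapply(as.numeric(sched$end), run, max),
      origin = "1970-01-01", tz = "UTC"
    )
  )
  rownames(out) <- NULL
  out
}

#' Default per-behavior acceleration signal parameters
#'
#' Signal models standing in for real kangaroo-rat signatures: a fixed
#' gravity orientation per behavior (packages were mounted in the same
#' orientation on all animals) plus behavior-specific sinusoidal bursts
#' and Gaussian noise. Travel carries strong hop-like 4-8 Hz vertical
#' oscillation; foraging (2-4 Hz) and grooming (2.5-4.5 Hz) share a
#' head-down posture and deliberately overlapping amplitude/frequency
#' ranges so that those two classes are partially confusable, as in the
#' field data. Motionless has no oscillation.
#'
#' @return Named list (one element per behavior) of parameter lists with
#'   entries `orientation` (unit gravity vector, g), `noise_sd` (g),
#'   `freq_range` (Hz), `amp_range` (g), `duty` (burst duty cycle in
#'   `[0,1]`) and `axis_weights`.
#' @export
default_signal_params <- function() {
  norm <- function(v) v / sqrt(sum(v^2))
  list(
    motionless = list(
      orientation = c(0, 0, 1), noise_sd = 0.02,
      freq_range = c(0, 0), amp_range = c(0, 0), duty = 0,
      axis_weights = c(0, 0, 0)
    ),
    travel = list(
      orientation = norm(c(0.25, 0, 0.97)), noise_sd = 0.10,
      freq_range = c(4, 8), amp_range = c(0.8, 1.5), duty = 0.9,
      axis_weights = c(0.4, 0.15, 1)
    ),
    foraging = list(
      orientation = norm(c(0.45, 0.10, 0.89)), noise_sd = 0.08,
      freq_range = c(2, 4), amp_range = c(0.25, 0.55), duty = 0.70,
      axis_weights = c(0.8, 0.3, 0.6)
    ),
    grooming = list(
      orientation = norm(c(0.45, 0.10, 0.89)), noise_sd = 0.08,
      freq_range = c(2.2, 4.2), amp_range = c(0.2, 0.5), duty = 0.62,
      axis_weights = c(0.8, 0.3, 0.6)
    )
  )
}

.validate_signal_params <- function(params, fs) {
  for (b in names(params)) {
    p <- params[[b]]
    if (p$noise_sd < 0) stop("noise_sd must be >= 0 for ", b)
    if (any(p$amp_range < 0)) stop("amplitudes must be >= 0 for ", b)
    if (p$duty < 0 || p$duty > 1) stop("duty cycle must lie in [0,1] for ", b)
    if (max(p$freq_range) > fs / 2) {
      stop("oscillation frequency exceeds Nyquist (fs/2) for ", b)
    }
  }
  invisible(params)
}

#' Synthesize a tri-axial acceleration trace from a bout schedule
#'
#' Each sample is the behavior's gravity orientation plus a behavior-
#' specific sinusoidal burst (frequency, amplitude and phase drawn once
#' per bout from the configured ranges; bursts gated by the duty cycle)
#' plus Gaussian noise. Samples are clipped to the +/-10 g sensor range
#' and the number of clipped samples is recorded.
#'
#' @param schedule A `bout_schedule` from [simulate_bouts()] (or any
#'   data.frame with `behavior`, `start`, `end`).
#' @param params Signal parameters per behavior, see
#'   [default_signal_params()].
#' @param fs Sampling frequency in Hz (default 25).
#' @param seed Integer seed.
#' @param deployment_id Identifier stored on the trace.
#' @return An [accel_trace()] with per-sample ground-truth labels in
#'   `trace$labels` and the clipped-sample count in
#'   `attr(trace, "n_clipped")`.
#' @export
synthesize_accel <- function(schedule, params = default_signal_params(),
                             fs = 25, seed = 1, deployment_id = "synthetic") {
  stopifnot(fs > 0, nrow(schedule) > 0)
  missing <- setdiff(unique(schedule$behavior), names(params))
  if (length(missing) > 0L) {
    stop(
      "no signal parameters for behavior class(es): ",
      paste(missing, collapse = ", ")
    )
  }
  .validate_signal_params(params, fs)
  t0 <- .as_utc(schedule$start[1])
  total <- as.numeric(schedule$end[nrow(schedule)]) - as.numeric(t0)
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs # seconds since t0
  # per-sample bout index (samples at bout end belong to the next bout)
  bout_start <- as.numeric(schedule$start) - as.numeric(t0)
  idx <- findInterval(tt, bout_start)
  labels <- schedule$behavior[idx]

  .run_seeded(seed, {
    xyz <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    phase_off <- c(0, pi / 3, pi / 2) # fixed per-axis phase offsets
    for (b in seq_len(nrow(schedule))) {
      p <- params[[schedule$behavior[b]]]
      rows <- which(idx == b)
      if (length(rows) == 0L) next
      f <- stats::runif(1, p$freq_range[1], p$freq_range[2])
      a <- stats::runif(1, p$amp_range[1], p$amp_range[2])
      ph <- stats::runif(1, 0, 2 * pi)
      gate_off <- stats::runif(1, 0, 1.5)
      tau <- tt[rows] - bout_start[b]
      gate <- if (p$duty >= 1) {
        1
      } else if (p$duty <= 0) {
        0
      } else {
        as.numeric(((tau + gate_off) %% 1.5) < 1.5 * p$duty)
      }
      for (ax in 1:3) {
        xyz[rows, ax] <- p$orientation[ax] +
          a * p$axis_weights[ax] * gate *
            sin(2 * pi * f * tau + ph + phase_off[ax])
      }
      if (p$noise_sd > 0) {
        xyz[rows, ] <- xyz[rows, ] +
          matrix(stats::rnorm(length(rows) * 3, 0, p$noise_sd), ncol = 3)
      }
    }
    n_clipped <- sum(xyz > 10 | xyz < -10)
    xyz[xyz > 10] <- 10
    xyz[xyz < -10] <- -10
    tr <- accel_trace(deployment_id, fs, t0, xyz, labels = labels)
    attr(tr, "n_clipped") <- n_clipped
    tr
  })
}

#' Simulate nightly covariates
#'
#' One row per night: moon illumination from the ephemeris (evaluated at
#' local solar midnight), plus temperature, wind speed and relative
#' humidity drawn from configured seasonal means with Gaussian noise.
#' Optional injected effects (e.g. a humidity-to-foraging slope) are
#' recorded as ground-truth metadata on the returned table.
#'
#' @param nights Number of consecutive nights (>= 1).
#' @param start_date First night identifier (`Date` or string).
#' @param site A [site_context()].
#' @param weather_params List with elements `temp_mean`, `temp_sd` (deg C),
#'   `wind_mean`, `wind_sd` (m/s), `rh_mean`, `rh_sd` (%RH).
#' @param seed Integer seed.
#' @param effects Optional named list of injected ground-truth effects,
#'   e.g. `list(foraging = c(humidity = 0.8))`; stored as metadata only.
#' @return data.frame: `night` (Date), `moon_illumination`, `temperature`,
#'   `wind`, `humidity`, `precipitation` (0); attribute `"effects"` holds
#'   the injected-effect metadata.
#' @export
simulate_covariates <- function(nights, start_date, site,
                                weather_params = list(
                                  temp_mean = 28, temp_sd = 2,
                                  wind_mean = 3, wind_sd = 1,
                                  rh_mean = 40, rh_sd = 8
                                ),
                                seed = 1, effects = NULL) {
  stopifnot(nights >= 1)
  dates <- as.Date(start_date) + seq_len(nights) - 1
  moon <- nightly_moon_value(site, dates)
  .run_seeded(seed, {
    wp <- weather_params
    out <- data.frame(
      night = dates,
      moon_illumination = moon,
      temperature = stats::rnorm(nights, wp$temp_mean, wp$temp_sd),
      wind = pmax(0, stats::rnorm(nights, wp$wind_mean, wp$wind_sd)),
      humidity = pmin(100, pmax(0, stats::rnorm(nights, wp$rh_mean, wp$rh_sd))),
      precipitation = 0
    )
    attr(out, "effects") <- effects
    out
  })
}

#' Write / read the ground-truth sidecar
#'
#' Serializes generator settings (seeds, parameters, injected effects) to
#' JSON next to the synthetic data so recovery tests can read back the
#' truth.
#'
#' @param truth Named list of ground-truth metadata.
#' @param path File path (JSON).
#' @return `read_ground_truth()` returns the list; `write_ground_truth()`
#'   returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  # named atomic vectors become JSON objects so names survive the round trip
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  jsonlite::write_json(namify(truth), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate binomial activity-budget counts with known effects
#'
#' The generator's budget-level ground-truth channel: for each
#' (individual, night) it draws the number of windows assigned to a focal
#' behavior from a binomial whose logit combines a baseline, covariate
#' slopes (on standardized covariates) and individual/night random
#' intercepts. Used to calibrate and power-test the mixed-model stage
#' against a known generative family.
#'
#' @param covariates Nightly covariate table (from
#'   [simulate_covariates()] or equivalent; needs `night` and any columns
#'   named in `slopes`).
#' @param n_individuals Number of animals (study default 14).
#' @param windows_per_group Binomial trials per (individual, night) cell.
#' @param base_p Baseline behavior proportion at covariate means.
#' @param slopes Named numeric vector of logit slopes per standardized
#'   covariate column, e.g. `c(humidity = 0.8)`; may be empty.
#' @param re_sd_id,re_sd_night Random-intercept standard deviations.
#' @param seed Integer seed.
#' @return Model-ready data.frame: `individual`, `night`, `sex`,
#'   `n_total`, `n_behavior`, `proportion` plus the covariate columns
#'   (standardized copies suffixed `_std`).
#' @export
simulate_budget_counts <- function(covariates, n_individuals = 14,
                                   windows_per_group = 40, base_p = 0.25,
                                   slopes = c(humidity = 0.8),
                                   re_sd_id = 0.5, re_sd_night = 0.5,
                                   seed = 1) {
  stopifnot(n_individuals >= 2, windows_per_group >= 1)
  .run_seeded(seed, {
    ids <- sprintf("id%02d", seq_len(n_individuals))
    sex <- rep(c("F", "M"), length.out = n_individuals)
    b_id <- stats::rnorm(n_individuals, 0, re_sd_id)
    b_night <- stats::rnorm(nrow(covariates), 0, re_sd_night)
    grid <- expand.grid(
      i = seq_len(n_individuals), n = seq_len(nrow(covariates)),
      KEEP.OUT.ATTRS = FALSE
    )
    eta <- stats::qlogis(base_p) + b_id[grid$i] + b_night[grid$n]
    out <- data.frame(
      individual = ids[grid$i],
      night = covariates$night[grid$n],
      sex = sex[grid$i],
      n_total = windows_per_group
    )
    for (v in names(slopes)) {
      x <- covariates[[v]][grid$n]
      xs <- as.numeric(scale(covariates[[v]]))[grid$n]
      out[[v]] <- x
      out[[paste0(v, "_std")]] <- xs
      eta <- eta + slopes[[v]] * xs
    }
    out$n_behavior <- stats::rbinom(nrow(out), windows_per_group, stats::plogis(eta))
    out$proportion <- out$n_behavior / out$n_total
    attr(out, "truth") <- list(
      base_p = base_p, slopes = as.list(slopes),
      re_sd_id = re_sd_id, re_sd_night = re_sd_night
    )
    out
  })
}

#' Simulate a complete multi-animal study
#'
#' Generates one deployment per individual: a diel-structured bout
#' schedule (optionally with a per-night humidity effect on the foraging
#' entry rate), the corresponding 25 Hz acceleration trace, a full
#' ground-truth annotation set, and the shared nightly covariate table.
#'
#' @param n_individuals Number of animals.
#' @param nights Deployment length in nights per animal.
#' @param start Deployment start (POSIXct UTC); defaults to local noon of
#'   `start_date` at the site.
#' @param start_date First night (Date or string).
#' @param site A [site_context()].
#' @param profile Diel activity profile (per-phase CTMC generators).
#' @param params Signal parameters.
#' @param fs Sampling frequency, Hz.
#' @param seed Integer master seed; per-animal seeds are derived from it.
#' @param humidity_effect Optional logit-scale-ish multiplier slope: the
#'   foraging entry rates on night j are scaled by
#'   `exp(humidity_effect * humidity_std[j])`. Recorded in the covariate
#'   metadata.
#' @return List with `traces` (list of [accel_trace()]), `annotations`
#'   (list of [annotation_set()]), `covariates` (nightly table) and
#'   `individuals` (data.frame with `individual`, `sex`).
#' @export
simulate_study <- function(n_individuals = 4, nights = 2,
                           start_date = "2021-06-01",
                           site = site_context(30.2, -103.5, "America/Chicago"),
                           profile = default_diel_profile(),
                           params = default_signal_params(),
                           fs = 25, seed = 1, humidity_effect = 0) {
  covs <- simulate_covariates(
    nights, start_date, site,
    seed = seed + 7919,
    effects = if (humidity_effect != 0) {
      list(foraging = c(humidity = humidity_effect))
    } else {
      NULL
    }
  )
  hum_std <- as.numeric(scale(covs$humidity))
  if (length(hum_std) == 1L || all(!is.finite(hum_std))) hum_std <- rep(0, nights)
  phase_fn <- function(t) classify_light_phase(site, t)
  noon0 <- as.POSIXct(paste(as.Date(start_date), "12:00:00"), tz = site$timezone)
  ids <- sprintf("id%02d", seq_len(n_individuals))
  traces <- vector("list", n_individuals)
  anns <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    segs <- vector("list", nights)
    for (j in seq_len(nights)) {
      scale_j <- if (humidity_effect != 0) {
        c(foraging = exp(humidity_effect * hum_std[j]))
      } else {
        NULL
      }
      segs[[j]] <- simulate_bouts(
        profile,
        start = noon0 + (j - 1) * 86400, duration_h = 24,
        phase_fn = phase_fn, seed = seed * 1000L + i * 100L + j,
        entry_scale = scale_j
      )
    }
    sched <- .collapse_runs(do.call(rbind, segs))
    class(sched) <- c("bout_schedule", class(sched))
    traces[[i]] <- synthesize_accel(
      sched, params,
      fs = fs,
      seed = seed * 1000L + i, deployment_id = ids[i]
    )
    anns[[i]] <- annotation_set(ids[i], sched)
  }
  names(traces) <- ids
  names(anns) <- ids
  list(
    traces = traces, annotations = anns, covariates = covs,
    individuals = data.frame(
      individual = ids,
      sex = rep(c("F", "M"), length.out = n_individuals)
    ),
    site = site
  )
}

#' Generate a balanced labeled training set
#'
#' Convenience generator for classifier validation: fixed-length bouts of
#' each behavior in rotation (no diel structure), synthesized to
#' acceleration and returned as a bout schedule plus trace, giving a
#' known, roughly balanced window count per class.
#'
#' @param windows_per_class Target complete windows per class at
#'   `window_s`.
#' @param window_s Window size in seconds the count is calibrated for.
#' @param bout_s Bout duration in seconds (multiple of `window_s` keeps
#'   the count exact).
#' @param params,fs,seed See [synthesize_accel()].
#' @return List with `trace` and `annotations`.
#' @export
simulate_training_data <- function(windows_per_class = 300, window_s = 6,
                                   bout_s = 30, params = default_signal_params(),
                                   fs = 25, seed = 1) {
  cls <- behavior_classes()
  wins_per_bout <- floor(bout_s / window_s)
  n_bouts <- ceiling(windows_per_class / wins_per_bout)
  t0 <- as.POSIXct("2021-06-01 03:00:00", tz = "UTC")
  beh <- rep(cls, times = n_bouts)
  starts <- t0 + (seq_along(beh) - 1) * bout_s
  sched <- data.frame(behavior = beh, start = starts, end = starts + bout_s)
  trace <- synthesize_accel(sched, params,
    fs = fs, seed = seed,
    deployment_id = "training"
  )
  list(trace = trace, annotations = annotation_set("training", sched))
}
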