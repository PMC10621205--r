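site <- site_context(30.2, -103.5, "America/Chicago")
phase_fn <- function(t) classify_light_phase(site, t)
t0 <- utc("2021-06-01 17:00:00")

test_that("an all-zero generator yields a single absorbing bout", {
  prof <- default_diel_profile()
  zero <- prof$day * 0
  prof <- lapply(prof, function(...) zero)
  b <- simulate_bouts(prof, t0, 5, phase_fn, seed = 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$behavior, "motionless")
  expect_equal(as.numeric(b$end) - as.numeric(b$start), 5 * 3600)
})

test_that("a non-conservative generator is rejected", {
  prof <- default_diel_profile()
  prof$day[1, 1] <- 0 # row no longer sums to zero
  expect_error(
    simulate_bouts(prof, t0, 1, phase_fn, seed = 1),
    "sum to zero"
  )
})

test_that("two-state equal-rate chain approaches 50/50 occupancy", {
  Q <- matrix(0, 4, 4, dimnames = list(behavior_classes(), behavior_classes()))
  r <- 2 # per minute
  Q["motionless", "travel"] <- r
  Q["travel", "motionless"] <- r
  diag(Q) <- -rowSums(Q)
  prof <- lapply(default_diel_profile(), function(...) Q)
  b <- simulate_bouts(prof, t0, 48, phase_fn, seed = 7)
  dur <- as.numeric(b$end) - as.numeric(b$start)
  occ_travel <- sum(dur[b$behavior == "travel"]) / sum(dur)
  # SE of occupancy from n independent-ish cycles
  n_bouts <- nrow(b)
  se <- 0.5 / sqrt(n_bouts)
  expect_lt(abs(occ_travel - 0.5), 3 * se)
})

test_that("the default profile keeps daytime travel occupancy below 5%", {
  pi_day <- ctmc_stationary(default_diel_profile()$day)
  expect_lt(pi_day["travel"], 0.05)
  expect_gte(pi_day["motionless"], 0.90)
  # and the simulated chain matches its stationary distribution in day phase
  prof <- lapply(default_diel_profile(), function(...) default_diel_profile()$day)
  b <- simulate_bouts(prof, t0, 200, phase_fn, seed = 11)
  dur <- as.numeric(b$end) - as.numeric(b$start)
  occ <- vapply(behavior_classes(), function(cl) {
    sum(dur[b$behavior == cl]) / sum(dur)
  }, numeric(1))
  expect_lt(abs(occ["travel"] - pi_day["travel"]), 0.05)
})

test_that("bout schedules are reproducible, contiguous and respect the 2 s minimum", {
  b1 <- simulate_bouts(default_diel_profile(), t0, 24, phase_fn, seed = 42)
  b2 <- simulate_bouts(default_diel_profile(), t0, 24, phase_fn, seed = 42)
  expect_identical(b1, b2)
  b3 <- simulate_bouts(default_diel_profile(), t0, 24, phase_fn, seed = 43)
  expect_false(identical(b1, b3))
  expect_true(all(as.numeric(b1$end) - as.numeric(b1$start) >= 2))
  expect_equal(as.numeric(b1$start[-1]), as.numeric(b1$end[-nrow(b1)]))
  expect_true(all(b1$behavior[-1] != b1$behavior[-nrow(b1)]))
})

test_that("entry-rate scaling shifts foraging occupancy in the expected direction", {
  prof <- default_diel_profile()
  b_hi <- simulate_bouts(prof, t0, 48, phase_fn,
    seed = 5,
    entry_scale = c(foraging = 3)
  )
  b_lo <- simulate_bouts(prof, t0, 48, phase_fn,
    seed = 5,
    entry_scale = c(foraging = 1 / 3)
  )
  occ <- function(b, cl) {
    dur <- as.numeric(b$end) - as.numeric(b$start)
    sum(dur[b$behavior == cl]) / sum(dur)
  }
  expect_gt(occ(b_hi, "foraging"), occ(b_lo, "foraging"))
})

test_that("zero-noise motionless trace equals the gravity vector with zero ODBA", {
  sched <- data.frame(
    behavior = "motionless",
    start = t0, end = t0 + 60
  )
  params <- default_signal_params()
  params$motionless$noise_sd <- 0
  tr <- synthesize_accel(sched, params, fs = 25, seed = 1)
  expect_equal(nrow(tr$xyz), 1500L)
  expect_true(all(abs(sweep(tr$xyz, 2, c(0, 0, 1))) < 1e-12))
  f <- compute_features(segment(tr, 6))
  expect_true(all(f[, "odba"] == 0))
})

test_that("a travel bout oscillates with near-full peak-to-peak range", {
  sched <- data.frame(behavior = "travel", start = t0, end = t0 + 6)
  params <- default_signal_params()
  params$travel$amp_range <- c(1, 1)
  # keep the tone incommensurate with fs so samples sweep the sine phase
  params$travel$freq_range <- c(4.8, 5.2)
  params$travel$duty <- 1
  params$travel$noise_sd <- 0
  tr <- synthesize_accel(sched, params, fs = 25, seed = 2)
  ptp <- apply(tr$xyz, 2, function(v) max(v) - min(v))
  expect_gte(ptp["z"], 1.9) # z weight is 1
})

test_that("synthesized samples always stay inside the sensor range", {
  sched <- data.frame(behavior = "travel", start = t0, end = t0 + 30)
  params <- default_signal_params()
  params$travel$amp_range <- c(15, 15) # deliberately beyond the range
  tr <- synthesize_accel(sched, params, fs = 25, seed = 3)
  expect_true(all(tr$xyz >= -10 & tr$xyz <= 10))
  expect_gt(attr(tr, "n_clipped"), 0)
})

test_that("a schedule with an unparameterized behavior names the missing class", {
  sched <- data.frame(behavior = "travel", start = t0, end = t0 + 10)
  params <- default_signal_params()
  params$travel <- NULL
  expect_error(synthesize_accel(sched, params, seed = 1), "travel")
})

test_that("traces carry per-sample labels aligned with the schedule", {
  b <- simulate_bouts(default_diel_profile(), t0, 6, phase_fn, seed = 9)
  tr <- synthesize_accel(b, seed = 9)
  expect_equal(length(tr$labels), nrow(tr$xyz))
  # label at each bout start sample matches the bout
  tt <- as.numeric(trace_times(tr))
  for (i in seq_len(min(nrow(b), 10))) {
    j <- which(tt >= as.numeric(b$start[i]))[1]
    expect_equal(tr$labels[j], b$behavior[i])
  }
})

test_that("class-conditional ODBA means are ordered motionless < grooming/foraging < travel", {
  td <- simulate_training_data(windows_per_class = 60, seed = 14)
  w <- label_windows(segment(td$trace, 6), td$annotations)
  ft <- feature_table(w)
  m <- tapply(ft$odba, ft$label, mean)
  expect_lt(m["motionless"], m["grooming"])
  expect_lt(m["motionless"], m["foraging"])
  expect_lt(m["grooming"], m["travel"])
  expect_lt(m["foraging"], m["travel"])
  # foraging and grooming overlap: their gap is small relative to the
  # motionless-to-travel spread
  expect_lt(
    abs(m["foraging"] - m["grooming"]),
    0.25 * (m["travel"] - m["motionless"])
  )
})

test_that("covariates honor configured means, spans and the effect sidecar", {
  wp0 <- list(temp_mean = 28, temp_sd = 0, wind_mean = 3, wind_sd = 0,
              rh_mean = 40, rh_sd = 0)
  cv0 <- simulate_covariates(5, "2021-06-01", site, weather_params = wp0, seed = 1)
  expect_true(all(cv0$temperature == 28))
  expect_true(all(cv0$wind == 3))
  expect_true(all(cv0$humidity == 40))
  cv <- simulate_covariates(30, "2021-06-01", site,
    seed = 2,
    effects = list(foraging = c(humidity = 0.8))
  )
  expect_gte(max(cv$moon_illumination) - min(cv$moon_illumination), 0.8)
  # ground-truth sidecar round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(list(seed = 2, effects = attr(cv, "effects")), path)
  back <- read_ground_truth(path)
  expect_equal(back$effects$foraging[["humidity"]], 0.8)
  expect_equal(back$seed, 2)
})

test_that("budget-count simulation embeds the configured slope as ground truth", {
  cv <- simulate_covariates(20, "2021-06-01", site, seed = 3)
  d <- simulate_budget_counts(cv, n_individuals = 14, slopes = c(humidity = 1.5), seed = 4)
  expect_equal(nrow(d), 14 * 20)
  expect_true(all(d$n_behavior <= d$n_total))
  expect_equal(attr(d, "truth")$slopes$humidity, 1.5)
  # higher humidity nights show higher mean proportions under a strong slope
  hi <- d$proportion[d$humidity_std > 0.5]
  lo <- d$proportion[d$humidity_std < -0.5]
  expect_gt(mean(hi), mean(lo))
})
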