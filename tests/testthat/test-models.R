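site <- site_context(30.2, -103.5, "America/Chicago")

test_that("VIF is 1 for orthogonal predictors and follows the closed form", {
  # two exactly orthogonal centered predictors
  a <- c(1, -1, 1, -1, 1, -1)
  b <- c(1, 1, -1, -1, 1, -1) * c(1, -1, 1, -1, 1, -1) # orthogonalize below
  b <- b - a * sum(a * b) / sum(a * a)
  v <- compute_vif(cbind(a = a, b = b))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)

  # a pair with sample correlation exactly 0.8: VIF = 1/(1-0.64) = 2.778
  withr::with_seed(11, {
    x <- scale(rnorm(200))[, 1]
    e <- scale(stats::resid(lm(rnorm(200) ~ x)))[, 1]
  })
  y <- 0.8 * x + sqrt(1 - 0.64) * e
  expect_equal(cor(x, y), 0.8, tolerance = 1e-12)
  v2 <- compute_vif(cbind(x = x, y = y))
  expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-3)

  # duplicated column is flagged as infinite
  expect_warning(v3 <- compute_vif(cbind(x = x, x2 = x, y = y)), "collinearity")
  expect_true(any(!is.finite(v3$vif)))
})

test_that("VIF agrees with the standard regression-package implementation", {
  withr::with_seed(12, {
    d <- data.frame(
      a = rnorm(150), b = rnorm(150), z = rnorm(150)
    )
    d$c <- 0.6 * d$a + 0.4 * d$b + rnorm(150)
    d$resp <- rnorm(150)
  })
  ours <- compute_vif(~ a + b + c + z, data = d)
  theirs <- car::vif(lm(resp ~ a + b + c + z, data = d))
  expect_equal(ours$vif, unname(theirs[ours$predictor]), tolerance = 1e-10)
})

test_that("mixed fits are deterministic and recover known slopes", {
  covs <- simulate_covariates(20, "2021-06-01", site, seed = 21)
  d <- simulate_budget_counts(covs,
    n_individuals = 14,
    slopes = c(humidity = 0.8), seed = 22
  )
  f1 <- fit_mixed(d, c("humidity_std", "sex"), "binomial")
  f2 <- fit_mixed(d, c("humidity_std", "sex"), "binomial")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-8)
  expect_false(f1$downgraded)
  # slope recovery across seeded replicates
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cv <- simulate_covariates(20, "2021-06-01", site, seed = 300 + r)
    dd <- simulate_budget_counts(cv,
      n_individuals = 14,
      slopes = c(humidity = 0.8), seed = 400 + r
    )
    fit <- fit_mixed(dd, c("humidity_std", "sex"), "binomial")
    est <- fit$coefficients$estimate[fit$coefficients$term == "humidity_std"]
    hits <- hits + (abs(est - 0.8) <= 0.25)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("a zero-variance random effect is estimated near the boundary", {
  covs <- simulate_covariates(20, "2021-06-01", site, seed = 31)
  d <- simulate_budget_counts(covs,
    n_individuals = 14, windows_per_group = 60,
    slopes = c(humidity = 0), re_sd_id = 0, re_sd_night = 0.4, seed = 32
  )
  fit <- fit_mixed(d, c("humidity_std"), "binomial")
  vc <- lme4::VarCorr(fit$model)
  expect_lte(sqrt(vc$individual[1, 1]), 0.1)
})

test_that("gaussian slope recovery mirrors the study-sized design", {
  # gaussian response with known beta and random-intercept structure
  n_ind <- 14
  n_night <- 20
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    d <- withr::with_seed(500 + r, {
      hum <- rnorm(n_night)
      b_id <- rnorm(n_ind, 0, 0.5)
      b_ni <- rnorm(n_night, 0, 0.5)
      g <- expand.grid(i = seq_len(n_ind), n = seq_len(n_night))
      data.frame(
        individual = sprintf("id%02d", g$i),
        night = as.Date("2021-06-01") + g$n,
        humidity_std = hum[g$n],
        n_total = 40,
        proportion = 0.5 + 0.8 * hum[g$n] + b_id[g$i] + b_ni[g$n] + rnorm(nrow(g), 0, 0.5)
      )
    })
    d$n_behavior <- d$proportion # placeholder; gaussian path ignores counts
    fit <- fit_mixed(d, "humidity_std", "gaussian")
    est <- fit$coefficients$estimate[fit$coefficients$term == "humidity_std"]
    hits <- hits + (abs(est - 0.8) <= 0.25)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("family selection recovers a binomial generative family", {
  wins <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cv <- simulate_covariates(20, "2021-06-01", site, seed = 600 + r)
    dd <- simulate_budget_counts(cv,
      n_individuals = 10,
      slopes = c(humidity = 0.5), seed = 700 + r
    )
    sel <- select_family(dd, fixed = c("humidity_std", "sex"))
    wins <- wins + (sel$family == "binomial")
    # bookkeeping: table sorted ascending by AIC among feasible rows, and
    # the returned fit is the head row
    feas <- sel$aic_table[sel$aic_table$feasible, ]
    expect_true(all(diff(feas$AIC) >= 0))
    expect_equal(sel$family, feas$family[1])
    expect_equal(sel$fit$AIC, feas$AIC[1])
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("one feasible candidate is returned as-is and zeros exclude gamma", {
  covs <- simulate_covariates(10, "2021-06-01", site, seed = 41)
  d <- simulate_budget_counts(covs, n_individuals = 6, seed = 42)
  d$n_behavior[1] <- 0
  d$proportion <- d$n_behavior / d$n_total
  sel <- select_family(d, fixed = "humidity_std", candidates = c("binomial", "gamma"))
  expect_equal(sel$family, "binomial")
  gam <- sel$aic_table[sel$aic_table$family == "gamma", ]
  expect_false(gam$feasible)
  expect_match(gam$reason, "zeros")
})

test_that("Wald tests follow the chi-square block formula", {
  covs <- simulate_covariates(20, "2021-06-01", site, seed = 51)
  d <- simulate_budget_counts(covs,
    n_individuals = 14,
    slopes = c(humidity = 0.6), seed = 52
  )
  fit <- fit_mixed(d, c("humidity_std", "sex"), "binomial")
  w <- wald_tests(fit)
  # single-df terms: chi-square equals (estimate / SE)^2
  for (tm in c("humidity_std", "sexM")) {
    co <- fit$coefficients[fit$coefficients$term == tm, ]
    if (nrow(co) == 0) next
    term_name <- if (tm == "sexM") "sex" else tm
    expect_equal(
      w$chisq[w$term == term_name],
      (co$estimate / co$se)^2,
      tolerance = 1e-8
    )
  }
  expect_equal(w$p, pchisq(w$chisq, w$df, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against the standard Wald chi-square implementation
  ca <- car::Anova(fit$model, type = "II")
  expect_equal(
    w$chisq[w$term == "humidity_std"],
    ca["humidity_std", "Chisq"],
    tolerance = 1e-6
  )
  # multi-contrast terms are tested jointly with df = block size
  d$phase3 <- sample(c("night", "dawn", "dusk"), nrow(d), replace = TRUE)
  fit2 <- fit_mixed(d, c("phase3", "humidity_std"), "binomial")
  w2 <- wald_tests(fit2)
  expect_equal(w2$df[w2$term == "phase3"], 2)
})

test_that("null Wald p-values are approximately uniform", {
  n_rep <- 120
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cv <- simulate_covariates(20, "2021-06-01", site, seed = 800 + r)
    dd <- simulate_budget_counts(cv,
      n_individuals = 14,
      slopes = c(humidity = 0), seed = 900 + r
    )
    fit <- fit_mixed(dd, "humidity_std", "binomial")
    w <- wald_tests(fit, "humidity_std")
    pvals[r] <- w$p
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lte(mean(pvals < 0.05), 0.08 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("conditional R2 matches known variance components", {
  # gaussian with var_fixed = 1, var_random = 1, var_resid = 2 -> R2c = 0.5
  n_grp <- 1000
  d <- withr::with_seed(61, {
    x <- rnorm(n_grp)
    id <- rep(sprintf("id%02d", 1:20), length.out = n_grp)
    night <- rep(as.Date("2021-06-01") + 1:50, length.out = n_grp)
    b_id <- rnorm(20, 0, sqrt(0.5))
    b_ni <- rnorm(50, 0, sqrt(0.5))
    data.frame(
      individual = id, night = night, x = x,
      n_total = 1, n_behavior = 0,
      proportion = 1 * x + b_id[match(id, sprintf("id%02d", 1:20))] +
        b_ni[match(night, as.Date("2021-06-01") + 1:50)] +
        rnorm(n_grp, 0, sqrt(2))
    )
  })
  fit <- fit_mixed(d, "x", "gaussian")
  expect_equal(conditional_r2(fit), 0.5, tolerance = 0.05)

  # no fixed or random structure: R2c near 0
  d0 <- d
  d0$proportion <- withr::with_seed(62, rnorm(n_grp))
  fit0 <- fit_mixed(d0, "x", "gaussian")
  expect_lt(conditional_r2(fit0), 0.05)

  # always within [0, 1] on assorted binomial fits
  for (r in 1:5) {
    cv <- simulate_covariates(15, "2021-06-01", site, seed = 70 + r)
    dd <- simulate_budget_counts(cv,
      n_individuals = 8,
      slopes = c(humidity = runif(1, 0, 1.5)), seed = 80 + r
    )
    fr <- fit_mixed(dd, "humidity_std", "binomial")
    r2 <- conditional_r2(fr)
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
})

test_that("model results table carries the printed-statistics layout", {
  covs <- simulate_covariates(15, "2021-06-01", site, seed = 91)
  d <- simulate_budget_counts(covs,
    n_individuals = 10,
    slopes = c(humidity = 0.8), seed = 92
  )
  fit <- fit_mixed(d, c("humidity_std", "sex"), "binomial")
  tab <- model_results_table(fit, behavior = "foraging")
  expect_setequal(
    names(tab),
    c(
      "behavior", "term", "chisq", "df", "p", "family",
      "r2_conditional", "converged", "downgraded"
    )
  )
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$behavior == "foraging"))
})
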