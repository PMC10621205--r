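# Mixed-model stage: VIF screening, AIC family selection over Gaussian /
# Poisson / Binomial / Gamma, GLMMs with individual and night random
# intercepts, Wald chi-square tests and Nakagawa-style conditional R2.

.FAMILIES <- c("gaussian", "poisson", "binomial", "gamma")

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on all the others (with intercept). Categorical predictors are
#' expanded to contrasts and reported per contrast column. Exactly
#' collinear columns are reported as `Inf`.
#'
#' @param x Either a numeric design matrix (columns = predictors, no
#'   intercept column) or a formula; with a formula, supply `data`.
#' @param data data.frame for the formula interface.
#' @return data.frame `predictor`, `vif`.
#' @examples
#' compute_vif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
compute_vif <- function(x, data = NULL) {
  if (inherits(x, "formula")) {
    mm <- stats::model.matrix(x, data = data)
    keep <- colnames(mm) != "(Intercept)"
    X <- mm[, keep, drop = FALSE]
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (ncol(X) < 2L) stop("need at least 2 predictors for VIF")
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "))
  }
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(r^2) / tot
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(predictor = colnames(X), vif = vif)
  if (any(!is.finite(out$vif))) {
    warning(
      "exact collinearity: infinite VIF for ",
      paste(out$predictor[!is.finite(out$vif)], collapse = ", ")
    )
  }
  out
}

# Build the model formula for one family. Response encoding:
#   gaussian / gamma : proportion (weights = n_total)
#   binomial         : cbind(successes, failures)
#   poisson          : counts with log(n_total) offset
.family_formula <- function(fixed, family) {
  rhs <- paste(c(fixed, "(1 | individual)", "(1 | night)"), collapse = " + ")
  switch(family,
    gaussian = stats::as.formula(paste("proportion ~", rhs)),
    gamma = stats::as.formula(paste("proportion ~", rhs)),
    binomial = stats::as.formula(
      paste("cbind(n_behavior, n_total - n_behavior) ~", rhs)
    ),
    poisson = stats::as.formula(
      paste("n_behavior ~", rhs, "+ offset(log(n_total))")
    )
  )
}

.family_feasible <- function(data, family) {
  if (family == "gamma" && any(data$proportion <= 0)) {
    return("gamma infeasible: response contains zeros")
  }
  if (family %in% c("binomial", "poisson") &&
    any(data$n_behavior != round(data$n_behavior))) {
    return(paste(family, "infeasible: non-integer counts"))
  }
  NULL
}

#' Fit a GLMM of a behavior proportion
#'
#' Maximum-likelihood fit (Laplace approximation for non-gaussian
#' families) with random intercepts for `individual` and `night`. The
#' data must carry `proportion`, `n_behavior`, `n_total`, `individual`,
#' `night` and the fixed-effect columns. On non-convergence the fit is
#' refit as a fixed-effects GLM with cluster-robust (by individual)
#' standard errors and flagged `downgraded` -- never silently.
#'
#' @param data Model-ready budget table.
#' @param fixed Character vector of fixed-effect terms (may include
#'   interactions, e.g. `"moon_intensity * moon_up"`).
#' @param family One of `"gaussian"`, `"poisson"`, `"binomial"`,
#'   `"gamma"`.
#' Response encoding per family: `proportion` with group-size weights for
#' gaussian, `proportion` for gamma, `cbind(successes, failures)` for
#' binomial and counts with a `log(n_total)` offset for poisson. The
#' reported `AIC` is always on the count scale (proportion-scale
#' likelihoods are shifted by the change-of-variables Jacobian) so the
#' four families can be ranked against each other; `AIC_raw` keeps the
#' unshifted value.
#'
#' @return List of class `budget_fit`: `model`, `family`, `fixed`,
#'   `coefficients` (estimate, SE), `vcov`, `AIC` (count-scale,
#'   cross-family comparable), `AIC_raw`, `converged`, `downgraded`.
#' @export
fit_mixed <- function(data, fixed, family = "binomial") {
  family <- match.arg(family, .FAMILIES)
  reason <- .family_feasible(data, family)
  if (!is.null(reason)) stop(reason)
  stopifnot(all(c("individual", "night") %in% names(data)))
  if (length(unique(data$individual)) < 2L || length(unique(data$night)) < 2L) {
    stop("need at least 2 levels of each random factor")
  }
  data$night <- as.factor(data$night)
  data$individual <- as.factor(data$individual)
  fml <- .family_formula(fixed, family)
  environment(fml) <- environment()
  fam_obj <- switch(family,
    gaussian = NULL,
    poisson = stats::poisson(),
    binomial = stats::binomial(),
    gamma = stats::Gamma(link = "log")
  )
  fit <- NULL
  converged <- FALSE
  warn <- character()
  res <- withCallingHandlers(
    tryCatch(
      {
        if (family == "gaussian") {
          lme4::lmer(fml, data = data, weights = data$n_total, REML = FALSE)
        } else {
          lme4::glmer(fml, data = data, family = fam_obj)
        }
      },
      error = function(e) e
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!inherits(res, "error")) {
    fit <- res
    conv_issue <- any(grepl("converge", warn, ignore.case = TRUE))
    converged <- !conv_issue
  }
  if (is.null(fit)) {
    # downgrade: fixed-effects GLM with cluster-robust errors, flagged
    rhs <- paste(fixed, collapse = " + ")
    gfml <- switch(family,
      gaussian = stats::as.formula(paste("proportion ~", rhs)),
      gamma = stats::as.formula(paste("proportion ~", rhs)),
      binomial = stats::as.formula(
        paste("cbind(n_behavior, n_total - n_behavior) ~", rhs)
      ),
      poisson = stats::as.formula(
        paste("n_behavior ~", rhs, "+ offset(log(n_total))")
      )
    )
    gfit <- stats::glm(gfml,
      data = data,
      family = if (family == "gaussian") stats::gaussian() else fam_obj
    )
    V <- sandwich::vcovCL(gfit, cluster = data$individual)
    beta <- stats::coef(gfit)
    out <- structure(
      list(
        model = gfit, family = family, fixed = fixed,
        coefficients = data.frame(
          term = names(beta), estimate = unname(beta),
          se = sqrt(diag(V))
        ),
        vcov = V,
        AIC = stats::AIC(gfit) + if (family %in% c("gaussian", "gamma")) {
          2 * sum(log(data$n_total))
        } else {
          0
        },
        AIC_raw = stats::AIC(gfit), converged = TRUE,
        downgraded = TRUE, warnings = warn, data = data
      ),
      class = "budget_fit"
    )
    warning("mixed fit failed; downgraded to cluster-robust GLM")
    return(out)
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  # families fit on the proportion scale (gaussian, gamma) have their AIC
  # mapped to the count scale via the change-of-variables Jacobian
  # (f_count(y) = f_prop(y / n) / n), so AICs are comparable across all
  # four candidate families
  aic <- stats::AIC(fit)
  if (family %in% c("gaussian", "gamma")) {
    aic <- aic + 2 * sum(log(data$n_total))
  }
  structure(
    list(
      model = fit, family = family, fixed = fixed,
      coefficients = data.frame(
        term = names(beta), estimate = unname(beta),
        se = sqrt(diag(V))
      ),
      vcov = V, AIC = aic, AIC_raw = stats::AIC(fit),
      converged = converged,
      downgraded = FALSE, warnings = warn, data = data
    ),
    class = "budget_fit"
  )
}

#' @export
print.budget_fit <- function(x, ...) {
  cat(sprintf(
    "<budget_fit> family %s, AIC %.1f, converged %s%s\n",
    x$family, x$AIC, x$converged,
    if (x$downgraded) " (downgraded to cluster-robust GLM)" else ""
  ))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' AIC-based family selection
#'
#' Fits each feasible candidate family with identical fixed and random
#' structure and returns the minimum-AIC fit plus the full AIC table.
#' Infeasible candidates (zeros under gamma, non-integer counts under
#' poisson/binomial) are skipped with the reason recorded.
#'
#' @inheritParams fit_mixed
#' @param candidates Families to consider.
#' @return List: `fit` (the selected `budget_fit`), `family`, `aic_table`
#'   (family, AIC, feasible, reason; sorted by AIC).
#' @export
select_family <- function(data, fixed, candidates = .FAMILIES) {
  candidates <- match.arg(candidates, .FAMILIES, several.ok = TRUE)
  rows <- list()
  fits <- list()
  for (fam in candidates) {
    reason <- .family_feasible(data, fam)
    if (!is.null(reason)) {
      rows[[fam]] <- data.frame(
        family = fam, AIC = NA_real_,
        feasible = FALSE, reason = reason
      )
      next
    }
    f <- tryCatch(fit_mixed(data, fixed, fam), error = function(e) e)
    if (inherits(f, "error")) {
      rows[[fam]] <- data.frame(
        family = fam, AIC = NA_real_,
        feasible = FALSE, reason = conditionMessage(f)
      )
    } else {
      fits[[fam]] <- f
      rows[[fam]] <- data.frame(
        family = fam, AIC = f$AIC, feasible = TRUE, reason = ""
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(!tab$feasible, tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  if (length(fits) == 0L) {
    stop(
      "no candidate family could be fit:\n",
      paste(sprintf("  %s: %s", tab$family, tab$reason), collapse = "\n")
    )
  }
  best <- tab$family[tab$feasible][1]
  list(fit = fits[[best]], family = best, aic_table = tab)
}

#' Wald chi-square tests per fixed-effect term
#'
#' For each term, all its contrast coefficients are tested jointly:
#' `chi2 = b' V^-1 b` on the term's coefficient block, `df` = block size,
#' `p` from the upper chi-square tail.
#'
#' @param fit A `budget_fit`.
#' @param terms Terms to test (default: all fixed-effect terms,
#'   including interactions).
#' @return data.frame: `term`, `chisq`, `df`, `p`.
#' @export
wald_tests <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "budget_fit"))
  if (!fit$converged) stop("Wald tests require a converged fit")
  rhs <- paste(fit$fixed, collapse = " + ")
  tt <- stats::terms(stats::as.formula(paste("~", rhs)))
  mm <- stats::model.matrix(tt, data = fit$data)
  asgn <- attr(mm, "assign")
  labels <- attr(tt, "term.labels")
  if (is.null(terms)) terms <- labels
  beta <- fit$coefficients$estimate
  names(beta) <- fit$coefficients$term
  V <- fit$vcov
  out <- lapply(terms, function(tm) {
    k <- match(tm, labels)
    if (is.na(k)) stop("term not in the model: ", tm)
    cols <- colnames(mm)[asgn == k]
    cols <- intersect(cols, names(beta))
    if (length(cols) == 0L) stop("no coefficients found for term: ", tm)
    b <- beta[cols]
    Vb <- V[cols, cols, drop = FALSE]
    chi <- tryCatch(
      as.numeric(t(b) %*% solve(Vb, b)),
      error = function(e) stop("singular covariance block for term: ", tm)
    )
    data.frame(
      term = tm, chisq = chi, df = length(cols),
      p = stats::pchisq(chi, df = length(cols), lower.tail = FALSE)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Conditional R-squared of a mixed fit
#'
#' Nakagawa-style variance partition:
#' `R2_c = (var_fixed + var_random) / (var_fixed + var_random + var_resid)`
#' where `var_fixed` is the variance of the fixed-effect linear predictor,
#' `var_random` the summed random-intercept variances, and `var_resid`
#' the family-appropriate residual term on the link scale: the residual
#' variance for gaussian, `pi^2 / 3` for binomial (logit link),
#' `log(1 + 1/lambda)` (lognormal approximation at the mean fitted count)
#' for poisson, and `trigamma(shape)` for gamma (log link).
#'
#' @param fit A converged `budget_fit` (not downgraded).
#' @return Conditional R2 in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "budget_fit"))
  if (!fit$converged) stop("conditional R2 is undefined for non-converged fits")
  if (fit$downgraded) stop("conditional R2 is undefined for downgraded GLM fits")
  m <- fit$model
  X <- lme4::getME(m, "X")
  beta <- lme4::fixef(m)
  eta_fixed <- as.numeric(X %*% beta)
  var_f <- stats::var(eta_fixed)
  vc <- lme4::VarCorr(m)
  var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_e <- switch(fit$family,
    gaussian = {
      # with group-size weights, Var(y_i) = sigma^2 / w_i; use the average
      # per-observation residual variance so R2 is on the response scale
      w <- stats::model.frame(m)[["(weights)"]]
      if (is.null(w)) w <- 1
      stats::sigma(m)^2 * mean(1 / w)
    },
    binomial = pi^2 / 3,
    poisson = {
      lambda <- mean(stats::fitted(m))
      log(1 + 1 / lambda)
    },
    gamma = {
      shape <- 1 / stats::sigma(m)^2
      trigamma(shape)
    }
  )
  r2 <- (var_f + var_r) / (var_f + var_r + var_e)
  min(max(r2, 0), 1)
}

#' Tidy model results table
#'
#' Combines per-term Wald tests with the family, conditional R2 and
#' convergence flag into one tidy row set for persisting.
#'
#' @param fit A `budget_fit`.
#' @param behavior Label for the response behavior.
#' @return data.frame: `behavior`, `term`, `chisq`, `df`, `p`, `family`,
#'   `r2_conditional`, `converged`, `downgraded`.
#' @export
model_results_table <- function(fit, behavior = "behavior") {
  w <- wald_tests(fit)
  r2 <- if (fit$downgraded) NA_real_ else conditional_r2(fit)
  data.frame(
    behavior = behavior, w,
    family = fit$family, r2_conditional = r2,
    converged = fit$converged, downgraded = fit$downgraded
  )
}
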