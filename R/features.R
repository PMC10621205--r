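# Window segmentation and the 44 summary statistics used for behavior
# classification. Definitions (fixed project conventions, since the
# upstream web tool does not publish formulas):
#   * moments use denominator n (population form), configurable nowhere --
#     documented so results are reproducible;
#   * DBA (dynamic body acceleration) per axis = sample minus the window's
#     own per-axis mean; "mean DBA" is the mean absolute DBA;
#   * ODBA = mean over samples of |DBAx| + |DBAy| + |DBAz| (mean, not sum,
#     so values are comparable across window sizes);
#   * mean-diff / std-diff = mean absolute / SD of first differences;
#   * wave amplitude = max - min per axis;
#   * line crossings = sign changes of the DBA sequence (zeros inherit the
#     previous sign);
#   * percentiles use linear interpolation (R quantile type 7);
#   * Pearson correlations on a zero-variance axis are set to 0 and
#     flagged rather than propagating NaN.

.AXES <- c("x", "y", "z")
.PAIRS <- c("xy", "xz", "yz")

#' Names of the 44 window features
#'
#' @param feature_set `"all"` (44 features) or `"reduced"` (per-axis mean
#'   and SD plus ODBA; 7 features).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(feature_set = c("all", "reduced")) {
  feature_set <- match.arg(feature_set)
  per_axis <- function(stem) paste0(stem, "_", .AXES)
  all_names <- c(
    per_axis("mean"), per_axis("sd"), per_axis("max"), per_axis("min"),
    "mean_vecnorm",
    paste0("cov_", .PAIRS), paste0("cor_", .PAIRS),
    per_axis("dba"), "odba",
    per_axis("meandiff"), per_axis("stddiff"),
    per_axis("waveamp"), per_axis("crossings"),
    per_axis("p25"), per_axis("p50"), per_axis("p75")
  )
  if (feature_set == "reduced") {
    c(per_axis("mean"), per_axis("sd"), "odba")
  } else {
    all_names
  }
}

#' Segment a trace into fixed-duration, non-overlapping windows
#'
#' Windows tile the trace from sample 1; a trailing partial window is
#' discarded. Non-overlapping tiling (no sliding stride) avoids sample
#' reuse between training and test windows.
#'
#' @param trace An [accel_trace()].
#' @param window_s Window duration in seconds; `window_s * fs` must be at
#'   least 2 samples.
#' @return Object of class `accel_windows`: window count `n`, per-window
#'   start times, and the per-axis sample matrices (length x n).
#' @examples
#' tr <- simulate_training_data(windows_per_class = 5)$trace
#' w <- segment(tr, 6)
#' @export
segment <- function(trace, window_s) {
  stopifnot(inherits(trace, "accel_trace"), window_s > 0)
  len <- round(window_s * trace$fs)
  if (len < 2) stop("window must span at least 2 samples (window_s * fs >= 2)")
  n <- floor(nrow(trace$xyz) / len)
  idx <- seq_len(n * len)
  shape <- function(col) matrix(trace$xyz[idx, col], nrow = len, ncol = n)
  starts <- trace$t0 + (seq_len(n) - 1) * len / trace$fs
  structure(
    list(
      deployment_id = trace$deployment_id, fs = trace$fs,
      window_s = window_s, length = len, n = n, starts = starts,
      x = shape(1), y = shape(2), z = shape(3),
      label = rep(NA_character_, n)
    ),
    class = "accel_windows"
  )
}

#' @export
print.accel_windows <- function(x, ...) {
  cat(sprintf(
    "<accel_windows> %s: %d windows of %g s (%d samples), %d labeled\n",
    x$deployment_id, x$n, x$window_s, x$length, sum(!is.na(x$label))
  ))
  invisible(x)
}

.col_sd_n <- function(M, mu) {
  # population SD (denominator n) per column
  sqrt(colMeans(M^2) - mu^2)
}

#' Compute the window feature matrix
#'
#' Vectorized computation of the 44 summary statistics for every window.
#'
#' @param windows An `accel_windows` object from [segment()].
#' @param feature_set `"all"` or `"reduced"`.
#' @return Numeric matrix, `n` windows x features, with an attribute
#'   `"zero_variance"` counting windows where a zero-variance axis forced
#'   a Pearson correlation to 0.
#' @export
compute_features <- function(windows, feature_set = c("all", "reduced")) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(windows, "accel_windows"))
  X <- windows$x
  Y <- windows$y
  Z <- windows$z
  L <- windows$length
  axes <- list(x = X, y = Y, z = Z)

  mu <- lapply(axes, colMeans)
  sd_n <- Map(.col_sd_n, axes, mu)
  mx <- lapply(axes, function(M) apply(M, 2, max))
  mn <- lapply(axes, function(M) apply(M, 2, min))
  vecnorm <- colMeans(sqrt(X^2 + Y^2 + Z^2))

  cov_n <- function(A, B, ma, mb) colMeans(A * B) - ma * mb
  covs <- list(
    xy = cov_n(X, Y, mu$x, mu$y),
    xz = cov_n(X, Z, mu$x, mu$z),
    yz = cov_n(Y, Z, mu$y, mu$z)
  )
  safe_cor <- function(cv, sa, sb) {
    den <- sa * sb
    out <- ifelse(den > 0, cv / den, 0)
    pmin(pmax(out, -1), 1)
  }
  cors <- list(
    xy = safe_cor(covs$xy, sd_n$x, sd_n$y),
    xz = safe_cor(covs$xz, sd_n$x, sd_n$z),
    yz = safe_cor(covs$yz, sd_n$y, sd_n$z)
  )
  n_zero_var <- sum((sd_n$x == 0) | (sd_n$y == 0) | (sd_n$z == 0))

  dba_mat <- Map(function(M, m) sweep(M, 2, m), axes, mu)
  mean_abs_dba <- lapply(dba_mat, function(D) colMeans(abs(D)))
  odba <- colMeans(abs(dba_mat$x) + abs(dba_mat$y) + abs(dba_mat$z))

  first_diff <- lapply(axes, function(M) {
    M[-1, , drop = FALSE] - M[-L, , drop = FALSE]
  })
  meandiff <- lapply(first_diff, function(D) colMeans(abs(D)))
  stddiff <- lapply(first_diff, function(D) .col_sd_n(D, colMeans(D)))

  waveamp <- Map(function(a, b) a - b, mx, mn)

  crossings <- lapply(dba_mat, function(D) {
    S <- sign(D)
    # zeros inherit the previous sign; any leading zeros take the first
    # nonzero sign (backward pass); an all-zero column stays zero
    for (i in seq_len(nrow(S))[-1]) {
      zero <- S[i, ] == 0
      if (any(zero)) S[i, zero] <- S[i - 1, zero]
    }
    for (i in rev(seq_len(nrow(S))[-nrow(S)])) {
      zero <- S[i, ] == 0
      if (any(zero)) S[i, zero] <- S[i + 1, zero]
    }
    colSums(S[-1, , drop = FALSE] != S[-nrow(S), , drop = FALSE])
  })

  qs <- lapply(axes, function(M) {
    apply(M, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  })

  out <- cbind(
    mu$x, mu$y, mu$z, sd_n$x, sd_n$y, sd_n$z,
    mx$x, mx$y, mx$z, mn$x, mn$y, mn$z,
    vecnorm,
    covs$xy, covs$xz, covs$yz, cors$xy, cors$xz, cors$yz,
    mean_abs_dba$x, mean_abs_dba$y, mean_abs_dba$z, odba,
    meandiff$x, meandiff$y, meandiff$z, stddiff$x, stddiff$y, stddiff$z,
    waveamp$x, waveamp$y, waveamp$z,
    crossings$x, crossings$y, crossings$z,
    qs$x[1, ], qs$y[1, ], qs$z[1, ],
    qs$x[2, ], qs$y[2, ], qs$z[2, ],
    qs$x[3, ], qs$y[3, ], qs$z[3, ]
  )
  colnames(out) <- feature_names("all")
  if (feature_set == "reduced") {
    out <- out[, feature_names("reduced"), drop = FALSE]
  }
  attr(out, "zero_variance") <- n_zero_var
  out
}

#' Label windows from a bout annotation set
#'
#' A window receives a behavior label only if its full span lies within a
#' single bout after allowing `slack_s` of alignment slack at the bout
#' edges (scores were time-matched to within 1 s in the field protocol);
#' windows straddling a transition by more than the slack stay unlabeled.
#' If the slack makes a window compatible with two adjacent bouts, the
#' bout containing the window midpoint wins.
#'
#' @param windows An `accel_windows` object.
#' @param annotations An [annotation_set()].
#' @param slack_s Edge alignment slack in seconds (default 1).
#' @return The `accel_windows` object with its `label` field filled;
#'   attribute `"n_boundary_dropped"` counts windows left unlabeled
#'   because they straddle a bout boundary.
#' @export
label_windows <- function(windows, annotations, slack_s = 1) {
  stopifnot(inherits(windows, "accel_windows"), inherits(annotations, "annotation_set"))
  b <- annotations$bouts
  if (nrow(b) == 0L) {
    return(windows)
  }
  ws <- as.numeric(windows$starts)
  we <- ws + windows$window_s
  mid <- (ws + we) / 2
  bs <- as.numeric(b$start)
  be <- as.numeric(b$end)
  lab <- rep(NA_character_, windows$n)
  dropped <- 0L
  for (i in seq_len(windows$n)) {
    ok <- which(ws[i] >= bs - slack_s & we[i] <= be + slack_s)
    if (length(ok) == 1L) {
      lab[i] <- b$behavior[ok]
    } else if (length(ok) > 1L) {
      holds <- ok[mid[i] >= bs[ok] & mid[i] < be[ok]]
      lab[i] <- if (length(holds) >= 1L) b$behavior[holds[1]] else b$behavior[ok[1]]
    } else {
      inside <- any(mid[i] >= bs & mid[i] < be)
      if (inside) dropped <- dropped + 1L
    }
  }
  windows$label <- lab
  attr(windows, "n_boundary_dropped") <- dropped
  windows
}

#' Tidy feature table for one deployment
#'
#' One row per window: deployment id, window start, window size, the
#' feature columns and the (possibly missing) label.
#'
#' @param windows An `accel_windows` (labeled or not).
#' @param feature_set `"all"` or `"reduced"`.
#' @return data.frame.
#' @export
feature_table <- function(windows, feature_set = c("all", "reduced")) {
  feats <- compute_features(windows, feature_set)
  out <- data.frame(
    deployment_id = windows$deployment_id,
    window_start = windows$starts,
    window_s = windows$window_s
  )
  out <- cbind(out, as.data.frame(feats))
  out$label <- windows$label
  out
}
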