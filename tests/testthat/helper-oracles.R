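# Independent reference implementations used as oracles. These stay
# deliberately naive / of different algorithmic lineage than the package
# code paths they check.

# ---- naive per-sample feature reference -------------------------------

# Compute all 44 features of one window (x, y, z numeric vectors) one
# sample at a time, straight from the definitions.
naive_window_features <- function(x, y, z) {
  n <- length(x)
  axes <- list(x = x, y = y, z = z)
  res <- c()
  mns <- sapply(axes, function(v) sum(v) / n)
  res[paste0("mean_", names(axes))] <- mns
  sds <- sapply(seq_along(axes), function(i) {
    v <- axes[[i]]
    sqrt(sum((v - mns[i])^2) / n)
  })
  res[paste0("sd_", names(axes))] <- sds
  res[paste0("max_", names(axes))] <- sapply(axes, max)
  res[paste0("min_", names(axes))] <- sapply(axes, min)
  res["mean_vecnorm"] <- sum(sqrt(x^2 + y^2 + z^2)) / n
  pair <- list(xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  for (p in names(pair)) {
    a <- axes[[pair[[p]][1]]]
    b <- axes[[pair[[p]][2]]]
    cv <- sum((a - mean(a)) * (b - mean(b))) / n
    res[paste0("cov_", p)] <- cv
    sa <- sqrt(sum((a - mean(a))^2) / n)
    sb <- sqrt(sum((b - mean(b))^2) / n)
    res[paste0("cor_", p)] <- if (sa > 0 && sb > 0) cv / (sa * sb) else 0
  }
  dba <- lapply(seq_along(axes), function(i) axes[[i]] - mns[i])
  names(dba) <- names(axes)
  res[paste0("dba_", names(axes))] <- sapply(dba, function(d) sum(abs(d)) / n)
  res["odba"] <- sum(abs(dba$x) + abs(dba$y) + abs(dba$z)) / n
  for (ax in names(axes)) {
    d <- diff(axes[[ax]])
    res[paste0("meandiff_", ax)] <- sum(abs(d)) / length(d)
    res[paste0("stddiff_", ax)] <- sqrt(sum((d - mean(d))^2) / length(d))
    res[paste0("waveamp_", ax)] <- max(axes[[ax]]) - min(axes[[ax]])
    s <- sign(dba[[ax]])
    # zeros inherit previous sign; leading zeros the first nonzero sign
    for (i in seq_len(n)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
    for (i in rev(seq_len(n)[-n])) if (s[i] == 0) s[i] <- s[i + 1]
    res[paste0("crossings_", ax)] <- sum(s[-1] != s[-n])
  }
  for (ax in names(axes)) {
    q <- stats::quantile(axes[[ax]], c(0.25, 0.5, 0.75), names = FALSE)
    res[paste0(c("p25_", "p50_", "p75_"), ax)] <- q
  }
  res[feature_names("all")]
}

# Wrap n random windows (matrix interface used by segment()) for the
# oracle-equivalence checks.
random_window_trace <- function(n_windows, len, seed, fs = 25) {
  withr::with_seed(seed, {
    n <- n_windows * len
    # mixture of smooth sinusoids, steps, constants and noise to hit edge
    # cases (ties, zero variance, clipping at the range limits)
    make_axis <- function() {
      kind <- sample(4, n_windows, replace = TRUE)
      unlist(lapply(seq_len(n_windows), function(i) {
        tt <- seq_len(len)
        switch(kind[i],
          sin(2 * pi * runif(1, 0.5, 8) * tt / fs) * runif(1, 0, 3),
          rep(round(runif(1, -9, 9)), len),
          cumsum(rnorm(len, 0, 0.2)),
          rnorm(len, runif(1, -2, 2), runif(1, 0, 1))
        )
      }))
    }
    xyz <- cbind(make_axis(), make_axis(), make_axis())
    xyz[xyz > 10] <- 10
    xyz[xyz < -10] <- -10
    accel_trace("oracle", fs, as.POSIXct("2021-06-01", tz = "UTC"), xyz)
  })
}

# ---- independent solar position (day-number almanac formulas) ---------

# Low-precision almanac sun: day-number linear elements, two-term
# equation of center -- a different lineage than the package's
# century-polynomial route.
oracle_sun_altitude <- function(lat, lon, t) {
  d2r <- pi / 180
  n <- as.numeric(t) / 86400 + 2440587.5 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r
  lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r
  eps <- (23.439 - 0.0000004 * n) * d2r
  ra <- atan2(cos(eps) * sin(lam), cos(lam)) / d2r
  dec <- asin(sin(eps) * sin(lam))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  H <- ((gmst_h * 15 + lon - ra) %% 360) * d2r
  phi <- lat * d2r
  asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)) / pi * 180
}

# ---- independent lunar position / illumination ------------------------

# Truncated lunar series with a longer term list than the package uses,
# plus illumination from the full elongation geometry (selenocentric
# phase angle from lunar and solar ecliptic positions) -- the package's
# illumination never touches this route (it uses the phase-angle
# polynomial in D, M, M' only).
oracle_moon_ecliptic <- function(t) {
  d2r <- pi / 180
  T <- (as.numeric(t) / 86400 + 2440587.5 - 2451545) / 36525
  Lp <- (218.3164477 + 481267.88123421 * T) %% 360
  D <- ((297.8501921 + 445267.1114034 * T) %% 360) * d2r
  M <- ((357.5291092 + 35999.0502909 * T) %% 360) * d2r
  Mp <- ((134.9633964 + 477198.8675055 * T) %% 360) * d2r
  F <- ((93.2720950 + 483202.0175233 * T) %% 360) * d2r
  lon <- Lp +
    6.288774 * sin(Mp) + 1.274027 * sin(2 * D - Mp) + 0.658314 * sin(2 * D) +
    0.213618 * sin(2 * Mp) - 0.185116 * sin(M) - 0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) + 0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) + 0.045758 * sin(2 * D - M) -
    0.040923 * sin(M - Mp) - 0.034720 * sin(D) - 0.030383 * sin(M + Mp) +
    0.015327 * sin(2 * D - 2 * F) - 0.012528 * sin(Mp + 2 * F) +
    0.010980 * sin(Mp - 2 * F) + 0.010675 * sin(4 * D - Mp) +
    0.010034 * sin(3 * Mp) + 0.008548 * sin(4 * D - 2 * Mp) -
    0.007888 * sin(2 * D + M - Mp) - 0.006766 * sin(2 * D + M) -
    0.005163 * sin(D - Mp)
  lat <- 5.128122 * sin(F) + 0.280602 * sin(Mp + F) + 0.277693 * sin(Mp - F) +
    0.173237 * sin(2 * D - F) + 0.055413 * sin(2 * D - Mp + F) +
    0.046271 * sin(2 * D - Mp - F) + 0.032573 * sin(2 * D + F) +
    0.017198 * sin(2 * Mp + F)
  dist <- 385000.56 - 20905.355 * cos(Mp) - 3699.111 * cos(2 * D - Mp) -
    2955.968 * cos(2 * D) - 569.925 * cos(2 * Mp) - 48.888 * cos(M) +
    246.158 * cos(2 * D - 2 * Mp) - 152.138 * cos(2 * D - M - Mp) -
    170.733 * cos(2 * D + Mp) - 204.586 * cos(2 * D - M)
  list(lon = lon %% 360, lat = lat, dist = dist)
}

oracle_sun_ecliptic_lon <- function(t) {
  n <- as.numeric(t) / 86400 + 2440587.5 - 2451545
  d2r <- pi / 180
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r
  (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360
}

oracle_moon_illumination <- function(t) {
  d2r <- pi / 180
  m <- oracle_moon_ecliptic(t)
  ls <- oracle_sun_ecliptic_lon(t)
  # geocentric elongation, then phase angle including the sun-earth /
  # earth-moon distance ratio term
  cpsi <- cos(m$lat * d2r) * cos((m$lon - ls) * d2r)
  psi <- acos(pmin(pmax(cpsi, -1), 1))
  R <- 149597870.7 # mean sun distance, km
  i <- atan2(R * sin(psi), m$dist - R * cpsi)
  (1 + cos(i)) / 2
}

oracle_moon_altitude <- function(lat, lon, t) {
  d2r <- pi / 180
  m <- oracle_moon_ecliptic(t)
  n <- as.numeric(t) / 86400 + 2440587.5 - 2451545
  eps <- (23.439 - 0.0000004 * n) * d2r
  laml <- m$lon * d2r
  beta <- m$lat * d2r
  dec <- asin(sin(beta) * cos(eps) + cos(beta) * sin(eps) * sin(laml))
  ra <- atan2(sin(laml) * cos(eps) - tan(beta) * sin(eps), cos(laml)) / d2r
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  H <- ((gmst_h * 15 + lon - ra) %% 360) * d2r
  phi <- lat * d2r
  alt <- asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)) / d2r
  alt - asin(6378.14 / m$dist) / d2r * cos(alt * d2r)
}

# Published almanac instants (UTC) used as absolute anchors. Eclipse-tied
# syzygies are known to the minute.
almanac <- list(
  new_moons = as.POSIXct(
    c("2021-06-10 10:53", "2021-12-04 07:43"),
    tz = "UTC"
  ), # both solar-eclipse new moons
  full_moons = as.POSIXct(
    c("2021-05-26 11:14", "2021-11-19 08:58"),
    tz = "UTC"
  ), # both lunar-eclipse full moons
  june_solstice_2021 = as.POSIXct("2021-06-21 03:32", tz = "UTC"),
  march_equinox_2021 = as.POSIXct("2021-03-20 09:37", tz = "UTC")
)

utc <- function(s) as.POSIXct(s, tz = "UTC")
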