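# Solar and lunar ephemeris: geometric altitudes, eight-phase diel
# classification, lunar illuminated fraction and moon up/down state.
#
# Solar position follows the NOAA/low-precision planetary theory
# (Julian-century polynomials for mean longitude, anomaly, equation of
# center, apparent longitude and obliquity); accuracy of the geometric
# altitude is a few hundredths of a degree over 1900-2100. Lunar position
# uses a truncated periodic-term expansion of the lunar longitude,
# latitude and distance (the dominant evection/variation/annual terms),
# good to roughly 0.1 degree, plus a parallax-in-altitude correction to
# make the altitude topocentric. All altitudes are airless (geometric);
# atmospheric refraction is applied only, optionally, when solving for
# sunrise/sunset instants.

DEG <- pi / 180

#' Site context for ephemeris computations
#'
#' Bundles the study-site coordinates and timezone used for solar/lunar
#' geometry and for the noon-to-noon definition of a "night".
#'
#' @param latitude Latitude in decimal degrees, north positive.
#' @param longitude Longitude in decimal degrees, east positive
#'   (a West Texas site is around -103.5).
#' @param timezone Olson timezone identifier used only to group
#'   observations into local nights; all internal times are UTC.
#' @return An object of class `site_context`.
#' @examples
#' site <- site_context(30.2, -103.5, "America/Chicago")
#' @export
site_context <- function(latitude, longitude, timezone = "UTC") {
  stopifnot(is.numeric(latitude), length(latitude) == 1L, abs(latitude) <= 90)
  stopifnot(is.numeric(longitude), length(longitude) == 1L, abs(longitude) <= 180)
  if (!timezone %in% OlsonNames()) {
    stop("unknown timezone identifier: ", timezone)
  }
  structure(
    list(latitude = latitude, longitude = longitude, timezone = timezone),
    class = "site_context"
  )
}

#' @export
print.site_context <- function(x, ...) {
  cat(sprintf(
    "<site_context> lat %.4f deg, lon %.4f deg, tz %s\n",
    x$latitude, x$longitude, x$timezone
  ))
  invisible(x)
}

# Julian day from POSIXct (UTC).
.julian_day <- function(t) {
  as.numeric(t) / 86400 + 2440587.5
}

.as_utc <- function(t) {
  if (inherits(t, "POSIXct")) {
    return(t)
  }
  as.POSIXct(t, tz = "UTC")
}

# Solar ecliptic/equatorial coordinates. Returns list of vectors (degrees):
# apparent longitude, declination, right ascension, and the true obliquity.
.sun_coords <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) * DEG
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) +
    0.000289 * sin(3 * M)
  true_lon <- L0 + C
  omega <- (125.04 - 1934.136 * T) * DEG
  app_lon <- true_lon - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.8150 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- eps0 + 0.00256 * cos(omega)
  lam <- app_lon * DEG
  epsr <- eps * DEG
  dec <- asin(sin(epsr) * sin(lam)) / DEG
  ra <- (atan2(cos(epsr) * sin(lam), cos(lam)) / DEG) %% 360
  list(lon = app_lon %% 360, dec = dec, ra = ra, eps = eps)
}

# Greenwich mean sidereal time, degrees.
.gmst <- function(jd) {
  T <- (jd - 2451545) / 36525
  (280.46061837 + 360.98564736629 * (jd - 2451545) +
    0.000387933 * T^2 - T^3 / 38710000) %% 360
}

.altitude_from_equatorial <- function(lat, lon, jd, ra, dec) {
  H <- (.gmst(jd) + lon - ra) * DEG
  phi <- lat * DEG
  d <- dec * DEG
  asin(sin(phi) * sin(d) + cos(phi) * cos(d) * cos(H)) / DEG
}

#' Geometric solar altitude
#'
#' @param site A [site_context()].
#' @param t POSIXct time(s), UTC.
#' @return Altitude of the sun above the horizon in degrees (airless,
#'   geometric: no refraction). Vectorized over `t`.
#' @examples
#' site <- site_context(30.2, -103.5)
#' sun_altitude(site, as.POSIXct("2021-06-21 19:00:00", tz = "UTC"))
#' @export
sun_altitude <- function(site, t) {
  stopifnot(inherits(site, "site_context"))
  jd <- .julian_day(.as_utc(t))
  s <- .sun_coords(jd)
  .altitude_from_equatorial(site$latitude, site$longitude, jd, s$ra, s$dec)
}

# Truncated lunar position. Returns geocentric ecliptic longitude and
# latitude (degrees) and distance (km). Dominant periodic terms only;
# adequate for phase-banding and rise/set to within a few minutes.
.moon_coords <- function(jd) {
  T <- (jd - 2451545) / 36525
  Lp <- (218.3164477 + 481267.88123421 * T - 0.0015786 * T^2 + T^3 / 538841) %% 360
  D <- ((297.8501921 + 445267.1114034 * T - 0.0018819 * T^2 + T^3 / 545868) %% 360) * DEG
  M <- ((357.5291092 + 35999.0502909 * T - 0.0001536 * T^2) %% 360) * DEG
  Mp <- ((134.9633964 + 477198.8675055 * T + 0.0087414 * T^2 + T^3 / 69699) %% 360) * DEG
  F <- ((93.2720950 + 483202.0175233 * T - 0.0036539 * T^2) %% 360) * DEG

  lon <- Lp +
    6.288774 * sin(Mp) +
    1.274027 * sin(2 * D - Mp) +
    0.658314 * sin(2 * D) +
    0.213618 * sin(2 * Mp) -
    0.185116 * sin(M) -
    0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) +
    0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) +
    0.045758 * sin(2 * D - M) -
    0.040923 * sin(M - Mp) -
    0.034720 * sin(D) -
    0.030383 * sin(M + Mp) +
    0.015327 * sin(2 * D - 2 * F) -
    0.012528 * sin(Mp + 2 * F) +
    0.010980 * sin(Mp - 2 * F)
  lat <- 5.128122 * sin(F) +
    0.280602 * sin(Mp + F) +
    0.277693 * sin(Mp - F) +
    0.173237 * sin(2 * D - F) +
    0.055413 * sin(2 * D - Mp + F) +
    0.046271 * sin(2 * D - Mp - F) +
    0.032573 * sin(2 * D + F) +
    0.017198 * sin(2 * Mp + F)
  dist <- 385000.56 -
    20905.355 * cos(Mp) -
    3699.111 * cos(2 * D - Mp) -
    2955.968 * cos(2 * D) -
    569.925 * cos(2 * Mp)
  list(lon = lon %% 360, lat = lat, dist = dist)
}

#' Topocentric lunar altitude
#'
#' Geometric (airless) altitude of the moon's center, corrected for
#' horizontal parallax so that `altitude > 0` means the moon is above
#' the local horizon.
#'
#' @inheritParams sun_altitude
#' @return Altitude in degrees, vectorized over `t`.
#' @export
moon_altitude <- function(site, t) {
  stopifnot(inherits(site, "site_context"))
  jd <- .julian_day(.as_utc(t))
  m <- .moon_coords(jd)
  eps <- .sun_coords(jd)$eps * DEG
  lam <- m$lon * DEG
  beta <- m$lat * DEG
  dec <- asin(sin(beta) * cos(eps) + cos(beta) * sin(eps) * sin(lam)) / DEG
  ra <- (atan2(
    sin(lam) * cos(eps) - tan(beta) * sin(eps),
    cos(lam)
  ) / DEG) %% 360
  alt <- .altitude_from_equatorial(site$latitude, site$longitude, jd, ra, dec)
  # parallax in altitude: geocentric -> topocentric
  hpar <- asin(6378.14 / m$dist) / DEG
  alt - hpar * cos(alt * DEG)
}

#' Lunar illuminated fraction
#'
#' Fraction of the lunar disk illuminated, from the phase angle of the
#' moon: `(1 + cos(i)) / 2`, ranging 0.00 at new moon to 1.00 at full
#' moon. The phase angle is computed from the mean elongation and the
#' solar and lunar anomalies (the standard low-precision expansion,
#' accurate to well under 0.02 in the fraction).
#'
#' @param t POSIXct time(s), UTC.
#' @return Illuminated fraction in `[0, 1]`, vectorized.
#' @examples
#' moon_illuminated_fraction(as.POSIXct("2021-06-10 10:53:00", tz = "UTC"))
#' @export
moon_illuminated_fraction <- function(t) {
  jd <- .julian_day(.as_utc(t))
  T <- (jd - 2451545) / 36525
  D <- ((297.8501921 + 445267.1114034 * T - 0.0018819 * T^2 + T^3 / 545868) %% 360)
  M <- ((357.5291092 + 35999.0502909 * T - 0.0001536 * T^2) %% 360) * DEG
  Mp <- ((134.9633964 + 477198.8675055 * T + 0.0087414 * T^2 + T^3 / 69699) %% 360) * DEG
  Dr <- D * DEG
  i <- 180 - D - 6.289 * sin(Mp) +
    2.100 * sin(M) -
    1.274 * sin(2 * Dr - Mp) -
    0.658 * sin(2 * Dr) -
    0.214 * sin(2 * Mp) -
    0.110 * sin(Dr)
  k <- (1 + cos(i * DEG)) / 2
  pmin(pmax(k, 0), 1)
}

#' Categorize moon illumination into intensity levels
#'
#' Thresholds: fraction below 0.33 is `low`, 0.33-0.66 inclusive is
#' `medium`, above 0.66 is `high`.
#'
#' @param fraction Illuminated fraction(s) in `[0, 1]`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' moon_intensity(c(0.2, 0.33, 0.66, 0.9))
#' @export
moon_intensity <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("moon illumination fraction must lie in [0, 1]")
  }
  out <- ifelse(fraction < 0.33, "low", ifelse(fraction <= 0.66, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Moon state at a time and site
#'
#' @inheritParams sun_altitude
#' @return A data.frame with one row per time: `time`, `altitude`
#'   (topocentric, degrees), `is_up` (geometric altitude above 0),
#'   `illumination` and `intensity`.
#' @export
moon_state <- function(site, t) {
  t <- .as_utc(t)
  alt <- moon_altitude(site, t)
  illum <- moon_illuminated_fraction(t)
  data.frame(
    time = t,
    altitude = alt,
    is_up = alt > 0,
    illumination = illum,
    intensity = moon_intensity(illum)
  )
}

# Find all crossings of `fun(t) - threshold` in [from, to], scanning at
# `step` seconds and bisecting each bracket to 1 s. Returns data.frame
# (time, rising).
.find_crossings <- function(fun, from, to, threshold = 0, step = 600) {
  grid <- seq(from, to, by = step)
  v <- fun(grid) - threshold
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0L) {
    return(data.frame(
      time = as.POSIXct(character(), tz = "UTC"),
      rising = logical()
    ))
  }
  times <- vapply(idx, function(i) {
    lo <- as.numeric(grid[i])
    hi <- as.numeric(grid[i + 1])
    flo <- v[i]
    while (hi - lo > 1) {
      mid <- (lo + hi) / 2
      fm <- fun(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC")) - threshold
      if (sign(fm) == sign(flo)) {
        lo <- mid
        flo <- fm
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(
    time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    rising = v[idx] < 0
  )
}

#' Sunrise/sunset and moonrise/moonset instants
#'
#' Horizon-crossing instants of the geometric altitude over a time span,
#' solved by bisection to 1 s. For the sun a refraction-style altitude
#' offset can be applied (the conventional -0.833 degrees accounts for
#' refraction plus the solar semidiameter); phase classification in
#' [classify_light_phase()] always uses the geometric 0-degree horizon.
#'
#' @inheritParams sun_altitude
#' @param from,to POSIXct span to search, UTC.
#' @param body `"sun"` or `"moon"`.
#' @param horizon Altitude of the event horizon in degrees (default 0,
#'   geometric).
#' @return data.frame with columns `time` (POSIXct, UTC) and `rising`.
#' @export
rise_set_times <- function(site, from, to, body = c("sun", "moon"), horizon = 0) {
  body <- match.arg(body)
  from <- .as_utc(from)
  to <- .as_utc(to)
  stopifnot(from < to)
  fun <- if (body == "sun") {
    function(t) sun_altitude(site, t)
  } else {
    function(t) moon_altitude(site, t)
  }
  .find_crossings(fun, from, to, threshold = horizon,
                  step = if (body == "sun") 600 else 300)
}

.PHASES <- c(
  "evening", "dusk", "evening_twilight", "night",
  "morning_twilight", "dawn", "morning", "day"
)

#' Eight-phase diel classification
#'
#' Assigns every timestamp to exactly one of eight light phases defined
#' by the geometric solar altitude and its direction of change:
#' `day` (sun above the horizon, outside the first/last hour),
#' `morning` (first hour after sunrise), `evening` (last hour before
#' sunset), `dusk` (0-6 degrees below the horizon, sun setting),
#' `evening_twilight` (6-18 degrees below, setting), `night` (more than
#' 18 degrees below), `morning_twilight` (18-6 degrees below, rising)
#' and `dawn` (6-0 degrees below, rising). Altitude bands are half-open
#' with the lower altitude bound included (an altitude of exactly -18
#' is twilight, exactly -6 is dawn/dusk, exactly 0 is above horizon).
#'
#' @inheritParams sun_altitude
#' @return Factor of length `length(t)` with the eight phase levels.
#' @seealso [diel_annotation()] for the full per-timestamp annotation.
#' @export
classify_light_phase <- function(site, t) {
  diel_annotation(site, t, moon = FALSE)$light_phase
}

#' Per-timestamp diel and lunar annotation
#'
#' @inheritParams sun_altitude
#' @param moon If `TRUE` (default) also compute the lunar columns.
#' @return data.frame with columns `time`, `sun_altitude`, `light_phase`
#'   and (if `moon`) `moon_altitude`, `moon_up`, `moon_illumination`,
#'   `moon_intensity`.
#' @export
diel_annotation <- function(site, t, moon = TRUE) {
  stopifnot(inherits(site, "site_context"))
  t <- .as_utc(t)
  if (length(t) == 0L) stop("no timestamps supplied")
  if (any(is.na(t))) stop("missing timestamps")
  if (abs(site$latitude) > 60) {
    stop("latitudes beyond 60 degrees (polar day/night possible) are unsupported")
  }
  alt <- sun_altitude(site, t)
  rising <- sun_altitude(site, t + 30) > sun_altitude(site, t - 30)

  span_from <- min(t) - 2 * 86400
  span_to <- max(t) + 2 * 86400
  cross <- rise_set_times(site, span_from, span_to, "sun", horizon = 0)
  rises <- cross$time[cross$rising]
  sets <- cross$time[!cross$rising]
  if (length(rises) == 0L || length(sets) == 0L) {
    stop("no sunrise/sunset found near the requested dates; unsupported site")
  }

  phase <- character(length(t))
  below <- alt < 0
  phase[below & alt >= -6 & rising] <- "dawn"
  phase[below & alt >= -6 & !rising] <- "dusk"
  phase[below & alt < -6 & alt >= -18 & rising] <- "morning_twilight"
  phase[below & alt < -6 & alt >= -18 & !rising] <- "evening_twilight"
  phase[alt < -18] <- "night"

  up <- which(!below)
  if (length(up) > 0L) {
    tn <- as.numeric(t[up])
    # most recent sunrise at or before t; next sunset strictly after t.
    # crossings are bisected to 1 s, so allow 2 s of slack: a sample can
    # sit above the horizon an instant before its recorded crossing time
    ri <- findInterval(tn + 2, as.numeric(rises))
    si <- findInterval(tn - 2, as.numeric(sets)) + 1L
    if (any(ri == 0L) || any(si > length(sets))) {
      stop("time span extends beyond the computed sunrise/sunset table")
    }
    last_rise <- as.numeric(rises)[ri]
    next_set <- as.numeric(sets)[si]
    ph <- rep("day", length(up))
    ph[tn >= next_set - 3600] <- "evening"
    ph[tn < last_rise + 3600] <- "morning"
    phase[up] <- ph
  }
  out <- data.frame(
    time = t,
    sun_altitude = alt,
    light_phase = factor(phase, levels = .PHASES)
  )
  if (moon) {
    ms <- moon_state(site, t)
    out$moon_altitude <- ms$altitude
    out$moon_up <- ms$is_up
    out$moon_illumination <- ms$illumination
    out$moon_intensity <- ms$intensity
  }
  out
}

#' Identify the local night a timestamp belongs to
#'
#' A night is labelled by the local calendar date of its preceding noon
#' (noon-to-noon grouping), so a continuous dark period is never split
#' across two night identifiers.
#'
#' @inheritParams sun_altitude
#' @return `Date` vector: the night identifier for each time.
#' @export
night_id <- function(site, t) {
  t <- .as_utc(t)
  lt <- as.POSIXlt(t, tz = site$timezone)
  d <- as.Date(format(lt, "%Y-%m-%d"))
  d[lt$hour < 12] <- d[lt$hour < 12] - 1
  d
}

#' Nightly moon illumination value
#'
#' The nightly continuous moonlight covariate: the lunar
#' illuminated fraction evaluated at local solar midnight of the night
#' (the altitude minimum of the sun between the two noons bounding the
#' night).
#'
#' @inheritParams sun_altitude
#' @param night `Date` vector of night identifiers (local date of the
#'   preceding noon, as returned by [night_id()]).
#' @return Numeric vector of illuminated fractions in `[0, 1]`.
#' @export
nightly_moon_value <- function(site, night) {
  stopifnot(inherits(site, "site_context"), inherits(night, "Date"))
  vapply(as.character(night), function(d) {
    noon <- as.POSIXct(paste(d, "12:00:00"), tz = site$timezone)
    noon2 <- noon + 86400
    opt <- stats::optimize(
      function(x) sun_altitude(site, as.POSIXct(x, origin = "1970-01-01", tz = "UTC")),
      interval = c(as.numeric(noon), as.numeric(noon2))
    )
    moon_illuminated_fraction(
      as.POSIXct(opt$minimum, origin = "1970-01-01", tz = "UTC")
    )
  }, numeric(1), USE.NAMES = FALSE)
}
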