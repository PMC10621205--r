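# Containers and readers/writers for accelerometry, annotations, weather
# and result tables. All timestamps are stored UTC internally; conversion
# to site-local time happens only when grouping into nights or assigning
# light phases.

.TS_FMT <- "%Y-%m-%dT%H:%M:%OS3Z"

.format_ts <- function(t) {
  # round to whole milliseconds first: format()'s %OS3 truncates, which
  # would corrupt the constant sampling interval on write
  ms <- round(as.numeric(.as_utc(t)) * 1000)
  whole <- floor(ms / 1000)
  frac <- ms - whole * 1000
  paste0(
    format(as.POSIXct(whole, origin = "1970-01-01", tz = "UTC"),
      "%Y-%m-%dT%H:%M:%S",
      tz = "UTC"
    ),
    sprintf(".%03dZ", frac)
  )
}

.parse_ts <- function(s) {
  t <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  bad <- which(is.na(t))
  if (length(bad) > 0L) {
    # fall back for timestamps without fractional seconds / trailing Z
    t[bad] <- as.POSIXct(sub("Z$", "", s[bad]),
      tz = "UTC",
      format = "%Y-%m-%dT%H:%M:%S"
    )
  }
  if (any(is.na(t))) {
    stop(
      "unparseable timestamp(s), first at row ",
      which(is.na(t))[1], ": ", s[which(is.na(t))[1]]
    )
  }
  t
}

#' Tri-axial acceleration trace
#'
#' A uniformly sampled tri-axial acceleration series for one deployment.
#' Timestamps are implicit: sample `i` is at `t0 + (i - 1) / fs`.
#'
#' @param deployment_id Deployment identifier string.
#' @param fs Sampling frequency, Hz (> 0).
#' @param t0 POSIXct UTC time of the first sample.
#' @param xyz Numeric matrix, n x 3, acceleration in g; values must be
#'   finite and within the +/-10 g sensor range.
#' @param labels Optional per-sample ground-truth behavior labels
#'   (length n), as produced by the synthetic generator.
#' @return Object of class `accel_trace`.
#' @export
accel_trace <- function(deployment_id, fs, t0, xyz, labels = NULL) {
  stopifnot(is.character(deployment_id), length(deployment_id) == 1L, fs > 0)
  t0 <- .as_utc(t0)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  colnames(xyz) <- c("x", "y", "z")
  if (any(!is.finite(xyz))) stop("acceleration values must be finite")
  if (any(abs(xyz) > 10 + 1e-9)) {
    stop("acceleration values outside the +/-10 g sensor range")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(xyz))
    labels <- as.character(labels)
  }
  structure(
    list(
      deployment_id = deployment_id, fs = fs, t0 = t0,
      xyz = xyz, labels = labels
    ),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "<accel_trace> %s: %d samples at %g Hz from %s (%.1f min)%s\n",
    x$deployment_id, nrow(x$xyz), x$fs, .format_ts(x$t0),
    nrow(x$xyz) / x$fs / 60,
    if (!is.null(x$labels)) ", labeled" else ""
  ))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace An [accel_trace()].
#' @return POSIXct vector of per-sample timestamps (UTC).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_len(nrow(trace$xyz)) - 1) / trace$fs
}

#' Behavioral annotation set
#'
#' Scored behavior bouts for one deployment. Bouts must not overlap and
#' behaviors must come from the four-class vocabulary.
#'
#' @param deployment_id Deployment identifier.
#' @param bouts data.frame with columns `behavior`, `start`, `end`
#'   (POSIXct UTC; `start < end`).
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(deployment_id, bouts) {
  stopifnot(is.character(deployment_id), length(deployment_id) == 1L)
  bouts <- as.data.frame(bouts)[, c("behavior", "start", "end")]
  bouts$behavior <- tolower(as.character(bouts$behavior))
  bad <- setdiff(unique(bouts$behavior), behavior_classes())
  if (length(bad) > 0L) {
    stop(
      "unknown behavior label(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(behavior_classes(), collapse = ", ")
    )
  }
  bouts$start <- .as_utc(bouts$start)
  bouts$end <- .as_utc(bouts$end)
  if (nrow(bouts) > 0L) {
    if (any(bouts$start >= bouts$end)) stop("every bout must have start < end")
    o <- order(bouts$start)
    bouts <- bouts[o, , drop = FALSE]
    if (nrow(bouts) > 1L &&
      any(as.numeric(bouts$start[-1]) < as.numeric(bouts$end[-nrow(bouts)]) - 1e-9)) {
      stop("bouts overlap within the deployment")
    }
  }
  rownames(bouts) <- NULL
  structure(list(deployment_id = deployment_id, bouts = bouts),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %s: %d bouts (%s)\n",
    x$deployment_id, nrow(x$bouts),
    paste(names(table(x$bouts$behavior)), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read an accelerometry CSV
#'
#' CSV dialect: header `timestamp,x,y,z`; ISO-8601 UTC timestamps with
#' milliseconds; acceleration in g. `read_accel_csv()` validates monotone
#' timestamps, a constant sampling interval (within 1% of `1/fs_expected`)
#' and the +/-10 g range. Gaps longer than 2 sample intervals split the
#' file into segments: with gaps present a list of traces is returned
#' (ids suffixed `_seg1`, `_seg2`, ...) with a warning; otherwise a single
#' trace. Never interpolates across gaps.
#'
#' @param trace An [accel_trace()].
#' @param path CSV file path.
#' @param fs_expected Expected sampling frequency, Hz.
#' @param deployment_id Id for the trace read back (default: file name).
#' @return `write_accel_csv()` returns `path` invisibly;
#'   `read_accel_csv()` an [accel_trace()] or list thereof.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(
    timestamp = .format_ts(trace_times(trace)),
    x = sprintf("%.9f", trace$xyz[, 1]),
    y = sprintf("%.9f", trace$xyz[, 2]),
    z = sprintf("%.9f", trace$xyz[, 3])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path, fs_expected, deployment_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("accelerometry CSV must have header columns: ", paste(need, collapse = ","))
  }
  if (is.null(deployment_id)) {
    deployment_id <- sub("\\.csv$", "", basename(path))
  }
  t <- .parse_ts(df$timestamp)
  n <- length(t)
  if (n < 2L) stop("need at least two samples")
  dt <- diff(as.numeric(t))
  dup <- which(dt <= 0)
  if (length(dup) > 0L) {
    stop(
      "non-monotone or duplicated timestamps at row(s): ",
      paste(utils::head(dup + 1L, 5), collapse = ", ")
    )
  }
  nominal <- 1 / fs_expected
  gap <- which(dt > 2.5 * nominal) # > 2 missing sample intervals
  regular <- dt[dt <= 2.5 * nominal]
  off <- which(abs(regular - nominal) > 0.01 * nominal)
  if (length(off) > 0L) {
    stop(
      "sampling interval deviates by more than 1% from 1/", fs_expected,
      " s at row(s): ", paste(utils::head(off + 1L, 5), collapse = ", ")
    )
  }
  xyz <- cbind(x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z))
  if (any(!is.finite(xyz))) stop("non-finite acceleration values")
  if (any(abs(xyz) > 10 + 1e-9)) {
    bad <- which(rowSums(abs(xyz) > 10 + 1e-9) > 0)[1]
    stop(
      "acceleration outside the +/-10 g sensor range at row ", bad + 1L,
      " (AXY-type loggers record -10..10 g)"
    )
  }
  seg_start <- c(1L, gap + 1L)
  seg_end <- c(gap, n)
  if (length(seg_start) == 1L) {
    return(accel_trace(deployment_id, fs_expected, t[1], xyz))
  }
  warning(
    length(gap), " gap(s) > 2 samples found; splitting into ",
    length(seg_start), " segments"
  )
  lapply(seq_along(seg_start), function(i) {
    rows <- seg_start[i]:seg_end[i]
    accel_trace(
      paste0(deployment_id, "_seg", i), fs_expected,
      t[rows[1]], xyz[rows, , drop = FALSE]
    )
  })
}

#' Write / read a behavioral annotation CSV
#'
#' Dialect: header `behavior,start,end`; ISO-8601 UTC timestamps. Labels
#' are normalized to lowercase; unknown labels and overlapping bouts are
#' rejected. An empty file (header only) yields an empty set with a
#' warning.
#'
#' @param ann An [annotation_set()].
#' @param path CSV file path.
#' @param deployment_id Id for the set read back (default: file name).
#' @return The annotation set (read) or `path` invisibly (write).
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  df <- data.frame(
    behavior = ann$bouts$behavior,
    start = .format_ts(ann$bouts$start),
    end = .format_ts(ann$bouts$end)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, deployment_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("behavior", "start", "end") %in% names(df))) {
    stop("annotation CSV must have header columns: behavior,start,end")
  }
  if (is.null(deployment_id)) {
    deployment_id <- sub("\\.csv$", "", basename(path))
  }
  if (nrow(df) == 0L) {
    warning("annotation file has no bouts: ", path)
    return(annotation_set(deployment_id, data.frame(
      behavior = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC")
    )))
  }
  annotation_set(deployment_id, data.frame(
    behavior = df$behavior,
    start = .parse_ts(df$start),
    end = .parse_ts(df$end)
  ))
}

#' Read nightly weather tables
#'
#' Reads one or more station CSVs (columns `night`, `temperature` in deg C,
#' `wind` in m/s, `humidity` in %RH, optional `precipitation`) and returns
#' one row per night. With multiple stations, values are averaged per
#' night across stations. A duplicated night within one station is an
#' error; nights missing from the requested range are flagged via the
#' `"missing_nights"` attribute.
#'
#' @param paths Character vector of CSV paths (one per station).
#' @param exclude_precipitation If `TRUE`, nights with `precipitation > 0`
#'   get `excluded = TRUE` (rows are kept; downstream stages drop them).
#' @param expected_nights Optional `Date` vector to check coverage against.
#' @return data.frame: `night` (Date), `temperature`, `wind`, `humidity`,
#'   `precipitation`, `excluded`.
#' @export
read_weather <- function(paths, exclude_precipitation = FALSE,
                         expected_nights = NULL) {
  stopifnot(length(paths) >= 1L)
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("night", "temperature", "wind", "humidity")
    if (!all(need %in% names(df))) {
      stop("weather CSV must have columns: ", paste(need, collapse = ","))
    }
    df$night <- as.Date(df$night)
    if (anyDuplicated(df$night)) {
      stop(
        "duplicated night-date in ", p, ": ",
        df$night[duplicated(df$night)][1]
      )
    }
    if (!"precipitation" %in% names(df)) df$precipitation <- 0
    df
  })
  all <- do.call(rbind, lapply(tabs, function(d) {
    d[, c("night", "temperature", "wind", "humidity", "precipitation")]
  }))
  agg <- stats::aggregate(
    all[, c("temperature", "wind", "humidity", "precipitation")],
    by = list(night = all$night), FUN = mean
  )
  agg <- agg[order(agg$night), ]
  rownames(agg) <- NULL
  agg$excluded <- exclude_precipitation & agg$precipitation > 0
  if (!is.null(expected_nights)) {
    missing <- as.Date(setdiff(expected_nights, agg$night), origin = "1970-01-01")
    if (length(missing) > 0L) {
      warning("weather missing for ", length(missing), " night(s)")
    }
    attr(agg, "missing_nights") <- missing
  }
  agg
}

#' Write a nightly covariate table
#'
#' @param covariates data.frame with a `night` column.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  df <- covariates
  df$night <- as.character(df$night)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.9f", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, master seed, package version and SHA-like
#' content hashes of the input files of a pipeline run.
#'
#' @param config Pipeline configuration list.
#' @param seed Master seed.
#' @param inputs Named character vector of input file paths (hashed).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, inputs = character(), path) {
  hash_file <- function(p) {
    con <- file(p, "rb")
    on.exit(close(con))
    raw <- readBin(con, "raw", n = file.info(p)$size)
    # cheap stable content hash (sum of bytes + length); enough to detect
    # input drift between runs without a digest dependency
    sprintf("%d-%.0f", length(raw), sum(as.integer(raw)))
  }
  manifest <- list(
    package = "accelbudget",
    version = as.character(utils::packageVersion("accelbudget")),
    seed = seed,
    config = config,
    input_hashes = if (length(inputs) > 0L) {
      stats::setNames(lapply(inputs, hash_file), names(inputs))
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
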