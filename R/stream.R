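# Sliding-window stream engine.
#
# Raw per-minute (heart rate, steps) records enter a time-sensitive queue
# that accumulates one window (w) of data, emits latent features (RHR, AHR,
# OHR, step total), then shrinks by the slide (s) to make room for new data.
# s = w gives non-overlapping windows; s < w overlapping ones.

#' Construct a vitals series
#'
#' @param user_id opaque user identifier (string).
#' @param timestamps `POSIXct` vector (UTC), strictly increasing.
#' @param heart_rate numeric, beats per minute, each in (20, 250).
#' @param steps nonnegative integer step counts per sampling interval.
#' @param cadence sampling interval in seconds (default 60).
#' @return Object of class `cw_vitals`: list with `user_id`, `records`
#'   (data frame `timestamp`, `heart_rate`, `steps`), `cadence`.
#' @export
vitals_series <- function(user_id, timestamps, heart_rate, steps, cadence = 60) {
  if (!inherits(timestamps, "POSIXct"))
    stop("vitals_series: timestamps must be POSIXct")
  n <- length(timestamps)
  if (n == 0L) stop("vitals_series: empty series")
  if (length(heart_rate) != n || length(steps) != n)
    stop("vitals_series: field lengths differ")
  dt <- diff(as.numeric(timestamps))
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("vitals_series: timestamps not strictly increasing at ",
         format(timestamps[bad], tz = "UTC"))
  }
  if (any(heart_rate <= 20 | heart_rate >= 250))
    stop("vitals_series: heart_rate outside physiological range (20, 250)")
  if (any(steps < 0)) stop("vitals_series: negative step counts")
  structure(list(
    user_id = as.character(user_id),
    records = data.frame(timestamp = timestamps,
                         heart_rate = as.numeric(heart_rate),
                         steps = as.numeric(steps)),
    cadence = as.numeric(cadence)
  ), class = "cw_vitals")
}

#' @export
print.cw_vitals <- function(x, ...) {
  r <- x$records
  cat("<vitals series> user", x$user_id, "-", nrow(r), "records,",
      format(r$timestamp[1L], tz = "UTC"), "to",
      format(r$timestamp[nrow(r)], tz = "UTC"), "\n")
  invisible(x)
}

#' Window/slide specification
#'
#' @param window window length `w` in seconds (e.g. 3600 for 1 h).
#' @param slide slide length `s` in seconds; must satisfy `0 < s <= w`.
#' @return Object of class `cw_windowspec`.
#' @export
window_spec <- function(window = 3600, slide = 1800) {
  window <- as.numeric(window); slide <- as.numeric(slide)
  if (!is.finite(window) || window <= 0) stop("window_spec: window must be > 0")
  if (!is.finite(slide) || slide <= 0 || slide > window)
    stop("window_spec: slide must satisfy 0 < s <= w (got s = ", slide,
         ", w = ", window, ")")
  structure(list(window = window, slide = slide), class = "cw_windowspec")
}

#' Enumerate window boundaries over a series
#'
#' Windows are half-open `[t0 + k*s, t0 + k*s + w)` anchored at the first
#' record's timestamp; the series span is `last timestamp + cadence - t0`
#' (each record covers one sampling interval). The window count is
#' `floor((T - w)/s) + 1` when the span `T >= w`.
#'
#' @param series a `cw_vitals` object.
#' @param spec a `cw_windowspec`.
#' @return Data frame with `start`, `end` (`POSIXct`); zero rows (with a
#'   warning) when the span is shorter than the window.
#' @export
window_slices <- function(series, spec) {
  stopifnot(inherits(series, "cw_vitals"), inherits(spec, "cw_windowspec"))
  ts <- series$records$timestamp
  t0 <- ts[1L]
  span <- as.numeric(ts[length(ts)]) + series$cadence - as.numeric(t0)
  if (span < spec$window) {
    warning("window_slices: series span (", span,
            " s) shorter than window; no windows")
    return(data.frame(start = ts[0L], end = ts[0L]))
  }
  k <- 0:floor((span - spec$window) / spec$slide)
  start <- t0 + k * spec$slide
  data.frame(start = start, end = start + spec$window)
}

#' Latent features of one window
#'
#' Aggregates the records in `[start, end)` into the detector's
#' window-level features: resting heart rate (RHR, mean heart rate over
#' zero-step minutes), active heart rate (AHR, mean over nonzero-step
#' minutes), overall heart rate (OHR), and the step total. When a window
#' has no zero-step minute, RHR falls back to the mean of the lowest decile
#' of heart-rate samples and is flagged `rhr_imputed`.
#'
#' @param series a `cw_vitals` object.
#' @param start,end window bounds (`POSIXct`), half-open `[start, end)`.
#' @return One-row data frame (`window_start`, `window_end`, `rhr`, `ahr`,
#'   `ohr`, `step_total`, `n_minutes`, `n_rest`, `degenerate`,
#'   `rhr_imputed`), or `NULL` when the window holds no records (a gap).
#' @export
window_latent_features <- function(series, start, end) {
  stopifnot(inherits(series, "cw_vitals"))
  r <- series$records
  i <- which(r$timestamp >= start & r$timestamp < end)
  if (!length(i)) return(NULL)
  features_from_rows(r$heart_rate[i], r$steps[i], start, end)
}

window_stats <- function(hr, st) {
  rest <- st == 0
  n_rest <- sum(rest)
  imputed <- FALSE
  if (n_rest > 0L) {
    rhr <- mean(hr[rest])
  } else {
    k <- max(1L, ceiling(length(hr) / 10))
    rhr <- mean(sort(hr)[seq_len(k)])
    imputed <- TRUE
  }
  list(rhr = rhr,
       ahr = if (n_rest < length(hr)) mean(hr[!rest]) else NA_real_,
       ohr = mean(hr), step_total = sum(st), n_minutes = length(hr),
       n_rest = n_rest,
       degenerate = (max(hr) == min(hr)) && (max(st) == min(st)),
       rhr_imputed = imputed)
}

features_from_rows <- function(hr, st, start, end) {
  w <- window_stats(hr, st)
  data.frame(window_start = start, window_end = end,
             rhr = w$rhr, ahr = w$ahr, ohr = w$ohr,
             step_total = w$step_total, n_minutes = w$n_minutes,
             n_rest = w$n_rest, degenerate = w$degenerate,
             rhr_imputed = w$rhr_imputed)
}

#' Process a stream window-by-window
#'
#' Replays the series through the bounded time-sensitive queue: records
#' accumulate until a full window is held, features are emitted, and the
#' queue drops the oldest slide's worth of data. Emission order is time
#' order and the queue never retains more than one window of records.
#'
#' @param series a `cw_vitals` object.
#' @param spec a `cw_windowspec`.
#' @param consumer optional callback invoked with each one-row feature frame
#'   as it is emitted.
#' @param min_coverage minimum fraction of expected samples for a window to
#'   be usable downstream; windows below it are flagged `low_coverage`.
#' @param trace_queue when `TRUE`, attach attribute `queue_trace`: a data
#'   frame with per-emission queue length at emission (`held`) and after the
#'   slide (`retained`), plus attribute `queue_peak`.
#' @return Data frame of window features (one row per non-empty window) with
#'   added `coverage` and `low_coverage` columns; empty windows are skipped
#'   and counted in attribute `n_gaps`.
#' @export
stream_process <- function(series, spec, consumer = NULL,
                           min_coverage = 0.5, trace_queue = FALSE) {
  stopifnot(inherits(series, "cw_vitals"), inherits(spec, "cw_windowspec"))
  ts_num <- as.numeric(series$records$timestamp)
  if (is.unsorted(ts_num, strictly = TRUE)) {
    bad <- which(diff(ts_num) <= 0)[1L] + 1L
    stop("stream_process: out-of-order record at ",
         format(series$records$timestamp[bad], tz = "UTC"))
  }
  slices <- suppressWarnings(window_slices(series, spec))
  expected <- spec$window / series$cadence
  nw <- nrow(slices)
  held <- retained <- integer(nw)
  keep <- logical(nw)
  rhr <- ahr <- ohr <- step_total <- numeric(nw)
  n_minutes <- n_rest <- integer(nw)
  degenerate <- imputed <- logical(nw)
  n_gaps <- 0L
  starts <- as.numeric(slices$start)
  hr_all <- series$records$heart_rate
  st_all <- series$records$steps
  for (k in seq_len(nw)) {
    s0 <- starts[k]; e0 <- s0 + spec$window
    # queue contents at emission = records in [start, end)
    i1 <- findInterval(s0 - 1e-9, ts_num) + 1L
    i2 <- findInterval(e0 - 1e-9, ts_num)
    held[k] <- max(0L, i2 - i1 + 1L)
    retained[k] <- {
      j1 <- findInterval(s0 + spec$slide - 1e-9, ts_num) + 1L
      max(0L, i2 - j1 + 1L)
    }
    if (i2 < i1) { n_gaps <- n_gaps + 1L; next }
    w <- window_stats(hr_all[i1:i2], st_all[i1:i2])
    keep[k] <- TRUE
    rhr[k] <- w$rhr; ahr[k] <- w$ahr; ohr[k] <- w$ohr
    step_total[k] <- w$step_total
    n_minutes[k] <- w$n_minutes; n_rest[k] <- w$n_rest
    degenerate[k] <- w$degenerate; imputed[k] <- w$rhr_imputed
    if (!is.null(consumer))
      consumer(features_from_rows(hr_all[i1:i2], st_all[i1:i2],
                                  slices$start[k], slices$end[k]))
  }
  out <- data.frame(
    window_start = slices$start[keep], window_end = slices$end[keep],
    rhr = rhr[keep], ahr = ahr[keep], ohr = ohr[keep],
    step_total = step_total[keep], n_minutes = n_minutes[keep],
    n_rest = n_rest[keep], degenerate = degenerate[keep],
    rhr_imputed = imputed[keep])
  out$coverage <- out$n_minutes / expected
  out$low_coverage <- out$coverage < min_coverage
  rownames(out) <- NULL
  attr(out, "n_gaps") <- n_gaps
  if (trace_queue) {
    attr(out, "queue_trace") <- data.frame(held = held, retained = retained)
    attr(out, "queue_peak") <- if (length(held)) max(held) else 0L
  }
  out
}
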