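# Healthy reference grid and Hellinger-distance anomaly scoring.
#
# The healthy state is represented not by stored raw history but by a
# lattice H of (heart rate, step-total) pairs spanning the ranges observed
# during a healthy calibration period. Each incoming window observation
# D = (rhr, step_total) is appended to the lattice (H' = H u {D}, multiset
# union) and the Hellinger distance between the feature-moment metrics of H
# and H' is the window's anomaly score; a threshold Delta turns scores into
# alerts.

#' Healthy vital ranges
#'
#' @param alpha_low,alpha_high heart-rate bounds in bpm (`alpha_low <
#'   alpha_high`).
#' @param beta_low,beta_high per-window step-total bounds (`beta_low <=
#'   beta_high`).
#' @return Object of class `cw_ranges`.
#' @export
healthy_ranges <- function(alpha_low, alpha_high, beta_low, beta_high) {
  if (!(alpha_low < alpha_high))
    stop("healthy_ranges: degenerate heart-rate range (alpha_low >= alpha_high)")
  if (!(beta_low <= beta_high))
    stop("healthy_ranges: beta_low > beta_high")
  structure(list(alpha_low = floor(alpha_low), alpha_high = ceiling(alpha_high),
                 beta_low = floor(beta_low), beta_high = ceiling(beta_high)),
            class = "cw_ranges")
}

#' Estimate healthy ranges from a calibration period
#'
#' Takes the min/max of window RHR and step totals over the first
#' `calibration_days` of a user's window features, excluding degenerate,
#' low-coverage, and (optionally) labeled-sick windows.
#'
#' A window RHR built from only a handful of zero-step minutes is a noisy
#' order statistic, and one freak value would inflate the heart-rate range
#' (and hence the grid) enough to swallow genuine elevations, so only
#' windows with at least `min_rest` resting minutes contribute to the
#' heart-rate range; all usable windows contribute to the step range.
#'
#' @param features window-feature data frame from [stream_process()].
#' @param calibration_days length of the designated healthy period (days).
#' @param sick_intervals optional data frame with `onset`, `end` (`POSIXct`)
#'   marking known sick intervals to exclude.
#' @param min_rest minimum resting minutes for a window's RHR to be
#'   considered reliable (default 10).
#' @return A `cw_ranges` object.
#' @export
estimate_healthy_ranges <- function(features, calibration_days = 7,
                                    sick_intervals = NULL, min_rest = 10L) {
  f <- features[!features$degenerate & !features$low_coverage & !is.na(features$rhr), ]
  if (!nrow(f)) stop("estimate_healthy_ranges: no usable windows")
  lim <- min(f$window_start) + calibration_days * 86400
  f <- f[f$window_start < lim, ]
  if (!is.null(sick_intervals) && nrow(sick_intervals)) {
    keep <- rep(TRUE, nrow(f))
    for (i in seq_len(nrow(sick_intervals)))
      keep <- keep & !(f$window_end > sick_intervals$onset[i] &
                       f$window_start < sick_intervals$end[i])
    f <- f[keep, ]
  }
  if (nrow(f) < 10L)
    stop("estimate_healthy_ranges: only ", nrow(f), " calibration windows")
  fr <- f[f$n_rest >= min_rest & !f$rhr_imputed, ]
  if (nrow(fr) < 10L) fr <- f # degraded stream: fall back to all windows
  healthy_ranges(min(fr$rhr), max(fr$rhr), min(f$step_total), max(f$step_total))
}

#' Build the healthy reference grid H
#'
#' Constructs the integer lattice over `[alpha_low, alpha_high] x
#' [beta_low, beta_high]`, subsampled until at most `cap` points remain,
#' and precomputes the grid's feature-moment metric `d2` together with the
#' raw power sums used by the fast scoring path.
#'
#' Each axis gets its own stride, chosen so the two axes keep a balanced
#' number of lattice levels (about `sqrt(cap)` each): the two vitals'
#' ranges differ by orders of magnitude (tens of bpm vs thousands of
#' steps), and a shared stride would collapse the heart-rate axis to a
#' handful of levels, distorting its marginal variance and kurtosis and
#' hence the scores. Ranges narrow enough to need no subsampling keep
#' stride 1 (a full lattice stays a full lattice).
#'
#' @param ranges a `cw_ranges` object.
#' @param cap maximum number of lattice points (default 2500, >= 100).
#' @return Object of class `cw_refgrid`: list with `points` (matrix, columns
#'   `alpha`, `beta`), `stride` (named length-2: per-axis), `ranges`, `d2`
#'   (FMM of the grid), and internal scoring state.
#' @export
build_reference_grid <- function(ranges, cap = 2500L) {
  stopifnot(inherits(ranges, "cw_ranges"))
  cap <- as.integer(cap)
  if (cap < 100L) stop("build_reference_grid: cap must be >= 100")
  na <- ranges$alpha_high - ranges$alpha_low + 1L
  nb <- ranges$beta_high - ranges$beta_low + 1L
  side <- floor(sqrt(cap))
  sa <- max(1L, as.integer(ceiling(na / side)))
  alphas <- seq(ranges$alpha_low, ranges$alpha_high, by = sa)
  max_beta_levels <- max(2L, cap %/% length(alphas))
  sb <- max(1L, as.integer(ceiling(nb / max_beta_levels)))
  betas <- seq(ranges$beta_low, ranges$beta_high, by = sb)
  stride <- c(alpha = sa, beta = sb)
  pts <- as.matrix(expand.grid(alpha = alphas, beta = betas,
                               KEEP.OUT.ATTRS = FALSE))
  if (length(unique(pts[, "alpha"])) < 2L || length(unique(pts[, "beta"])) < 2L)
    stop("build_reference_grid: grid degenerate along one axis; widen ranges")
  res <- fmm_of_matrix(pts)
  if (res$degenerate) stop("build_reference_grid: degenerate grid spectrum")
  center <- colMeans(pts)
  structure(list(points = pts, stride = stride, ranges = ranges,
                 d2 = as.numeric(res$fmm),
                 center = center,
                 sums = power_sums_2d(pts[, 1L] - center[1L],
                                      pts[, 2L] - center[2L]),
                 n = nrow(pts)),
            class = "cw_refgrid")
}

#' @export
print.cw_refgrid <- function(x, ...) {
  cat("<reference grid>", x$n, "points, stride (",
      paste(x$stride, collapse = ", "), ") -",
      "alpha [", x$ranges$alpha_low, ",", x$ranges$alpha_high,
      "], beta [", x$ranges$beta_low, ",", x$ranges$beta_high, "]\n",
      "  d2 =", paste(format(x$d2, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Raw power sums S[a,b] = sum(x^a * y^b) for a + b <= 4, as a 5 x 5 matrix
# indexed [a + 1, b + 1]. Coordinates are expected pre-centered for
# numerical stability.
power_sums_2d <- function(x, y) {
  S <- matrix(0, 5L, 5L)
  xp <- list(rep(1, length(x)), x, x^2, x^3, x^4)
  yp <- list(rep(1, length(y)), y, y^2, y^3, y^4)
  for (a in 0:4) for (b in 0:(4 - a)) S[a + 1L, b + 1L] <- sum(xp[[a + 1L]] * yp[[b + 1L]])
  S
}

# FMM of (grid + one appended observation) for a whole vector of candidate
# observations at once. Closed-form m = 2 pipeline, fully vectorized over
# observations: raw power sums -> central -> standardized moments ->
# cokurtosis entries -> eigen of the 2 x 2 unfolding Gram matrix -> FMM.
# `Sg` holds the grid's power sums on centered coordinates; `x`, `y` are
# the observations in the same centered coordinates. Returns list(f1, f2,
# degenerate), each a vector over observations.
fmm2_append_vec <- function(Sg, x, y) {
  N <- Sg[1L, 1L] + 1
  xp <- list(rep(1, length(x)), x, x^2, x^3, x^4)
  yp <- list(rep(1, length(y)), y, y^2, y^3, y^4)
  M <- vector("list", 25L) # M[[a*5 + b + 1]] = E[x^a y^b], vectorized
  for (a in 0:4) for (b in 0:(4 - a))
    M[[a * 5L + b + 1L]] <- (Sg[a + 1L, b + 1L] + xp[[a + 1L]] * yp[[b + 1L]]) / N
  mux <- M[[6L]]; muy <- M[[2L]]
  cmom <- function(a, b) {
    acc <- 0
    for (i in 0:a) for (j in 0:b)
      acc <- acc + choose(a, i) * choose(b, j) * M[[i * 5L + j + 1L]] *
        (-mux)^(a - i) * (-muy)^(b - j)
    acc
  }
  c20 <- cmom(2L, 0L); c02 <- cmom(0L, 2L)
  bad <- c20 <= 0 | c02 <= 0
  c20 <- pmax(c20, 1e-300); c02 <- pmax(c02, 1e-300)
  sx <- sqrt(c20); sy <- sqrt(c02)
  r <- cmom(1L, 1L) / (sx * sy)
  T1111 <- cmom(4L, 0L) / c20^2 - 3
  T1112 <- cmom(3L, 1L) / (c20 * sx * sy) - 3 * r
  T1122 <- cmom(2L, 2L) / (c20 * c02) - 1 - 2 * r^2
  T1222 <- cmom(1L, 3L) / (sx * c02 * sy) - 3 * r
  T2222 <- cmom(0L, 4L) / c02^2 - 3
  b11 <- T1111^2 + 3 * T1112^2 + 3 * T1122^2 + T1222^2
  b22 <- T2222^2 + 3 * T1222^2 + 3 * T1122^2 + T1112^2
  b12 <- T1111 * T1112 + 3 * T1112 * T1122 + 3 * T1122 * T1222 + T1222 * T2222
  tr <- b11 + b22
  disc <- sqrt(pmax((b11 - b22)^2 + 4 * b12^2, 0))
  e1 <- (tr + disc) / 2; e2 <- pmax((tr - disc) / 2, 0)
  l1 <- sqrt(pmax(e1, 0)); l2 <- sqrt(e2)
  tot <- l1 + l2
  bad <- bad | tot <= 1e-300
  tot <- pmax(tot, 1e-300)
  # eigenvector of the larger eigenvalue: pick the numerically larger of
  # the two algebraic forms, componentwise per observation
  v1a_1 <- b12; v1a_2 <- e1 - b11
  v1b_1 <- e1 - b22; v1b_2 <- b12
  use_b <- (v1b_1^2 + v1b_2^2) > (v1a_1^2 + v1a_2^2)
  w1 <- ifelse(use_b, v1b_1, v1a_1)
  w2 <- ifelse(use_b, v1b_2, v1a_2)
  nv <- sqrt(w1^2 + w2^2)
  degen_vec <- nv <= 1e-300
  w1 <- ifelse(degen_vec, 1, w1 / pmax(nv, 1e-300))
  w2 <- ifelse(degen_vec, 0, w2 / pmax(nv, 1e-300))
  f1 <- (l1 * w1^2 + l2 * w2^2) / tot
  list(f1 = f1, f2 = 1 - f1, degenerate = bad)
}

#' Anomaly score of one observation against the reference grid
#'
#' Appends the observation `d = (alpha, beta)` to the grid (multiset union
#' H' = H u {d}), computes the feature-moment metrics of H and H', and
#' returns their Hellinger distance. Interior observations barely change the
#' grid's moments and score near zero; observations far outside score
#' higher, monotonically along rays leaving the grid.
#'
#' @param grid a `cw_refgrid` from [build_reference_grid()].
#' @param d numeric length-2 observation `(heart rate, step total)`.
#' @param method `"fast"` (closed-form moment update, default) or
#'   `"direct"` (rebuilds the full matrix and reruns the tensor pipeline);
#'   the two agree to ~1e-10 and the direct path exists as an internal
#'   cross-check.
#' @return Nonnegative Hellinger score (0 when the augmented spectrum is
#'   degenerate, with attribute `degenerate = TRUE`).
#' @export
anomaly_score <- function(grid, d, method = c("fast", "direct")) {
  stopifnot(inherits(grid, "cw_refgrid"))
  method <- match.arg(method)
  d <- as.numeric(d)
  if (length(d) != 2L || !all(is.finite(d)))
    stop("anomaly_score: observation must be 2 finite numbers")
  if (method == "fast") {
    v <- fmm2_append_vec(grid$sums, d[1L] - grid$center[1L],
                         d[2L] - grid$center[2L])
    if (v$degenerate[1L]) return(structure(0, degenerate = TRUE))
    return(hellinger_distance(c(v$f1[1L], v$f2[1L]), grid$d2))
  }
  res <- fmm_of_matrix(rbind(grid$points, d))
  if (res$degenerate) return(structure(0, degenerate = TRUE))
  hellinger_distance(res$fmm, grid$d2)
}

#' Detect anomalies over a window-feature stream
#'
#' Scores every usable window's `(rhr, step_total)` observation against the
#' reference grid and flags windows whose score exceeds `delta`. Degenerate,
#' low-coverage, and RHR-less windows are skipped (recorded in attribute
#' `skipped`), not errors: flat or gappy stream segments must not halt
#' detection.
#'
#' @param features window-feature data frame from [stream_process()].
#' @param grid a `cw_refgrid`.
#' @param delta Hellinger-distance alert threshold (default 0.008, the
#'   selected operating point); must be > 0.
#' @param user_id optional user id carried into the output.
#' @param min_rest windows whose RHR rests on fewer than this many
#'   zero-step minutes (or was imputed) are skipped as `unreliable_rhr`.
#' @return Data frame of class `cw_alerts`: `user`, `window_start`,
#'   `window_end`, `rhr`, `steps`, `score`, `threshold`, `is_anomaly`
#'   (`score > delta` exactly). Attribute `skipped` lists skipped windows
#'   with reasons.
#' @export
detect_anomalies <- function(features, grid, delta = 0.008,
                             user_id = NA_character_, min_rest = 10L) {
  stopifnot(inherits(grid, "cw_refgrid"))
  if (!is.numeric(delta) || delta <= 0)
    stop("detect_anomalies: delta must be > 0")
  n <- nrow(features)
  reason <- rep(NA_character_, n)
  reason[features$degenerate] <- "degenerate"
  reason[is.na(reason) & features$low_coverage] <- "low_coverage"
  reason[is.na(reason) & is.na(features$rhr)] <- "no_rhr"
  reason[is.na(reason) & (features$rhr_imputed | features$n_rest < min_rest)] <-
    "unreliable_rhr"
  use <- which(is.na(reason))
  v <- fmm2_append_vec(grid$sums,
                       features$rhr[use] - grid$center[1L],
                       features$step_total[use] - grid$center[2L])
  score <- sqrt(0.5 * ((sqrt(v$f1) - sqrt(grid$d2[1L]))^2 +
                       (sqrt(v$f2) - sqrt(grid$d2[2L]))^2))
  score[v$degenerate] <- 0
  out <- data.frame(
    user = user_id,
    window_start = features$window_start[use],
    window_end = features$window_end[use],
    rhr = features$rhr[use],
    steps = features$step_total[use],
    score = score,
    threshold = delta,
    is_anomaly = score > delta
  )
  attr(out, "skipped") <- data.frame(
    window_start = features$window_start[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  class(out) <- c("cw_alerts", "data.frame")
  out
}

#' Adaptive personalized resting-heart-rate bound
#'
#' Observes the first `lookback_hours` (24-48 h) of a user's window RHR
#' values and returns the 90th percentile, clipped into the 90-110 bpm
#' band. The percentile (rather than the max) damps false positives from
#' transient spikes.
#'
#' @param features window-feature data frame from [stream_process()].
#' @param lookback_hours lookback duration in hours, within `[24, 48]`.
#' @param percentile percentile of the RHR sample (default 90).
#' @return Object of class `cw_adaptive`: list with `nabla` (bpm, in
#'   `[90, 110]`), `lookback_hours`, `n` (RHR values used), `raw_percentile`.
#' @export
adaptive_rhr_bound <- function(features, lookback_hours = 24, percentile = 90) {
  if (lookback_hours < 24 || lookback_hours > 48)
    stop("adaptive_rhr_bound: lookback must be within [24, 48] hours")
  lim <- min(features$window_start) + lookback_hours * 3600
  rhr <- features$rhr[features$window_start < lim & !is.na(features$rhr) &
                      !features$degenerate]
  if (length(rhr) < 10L)
    stop("adaptive_rhr_bound: insufficient history (", length(rhr),
         " RHR values, need >= 10)")
  p <- as.numeric(quantile(rhr, percentile / 100, names = FALSE))
  structure(list(nabla = min(max(p, 90), 110), lookback_hours = lookback_hours,
                 n = length(rhr), raw_percentile = p),
            class = "cw_adaptive")
}
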