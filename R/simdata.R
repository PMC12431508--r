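# Synthetic wearable-cohort simulator (the package's test fixture).
#
# Emulates the statistical structure the detector assumes: a diurnal
# resting heart-rate rhythm, activity bouts driving steps and an
# activity-linked heart-rate rise, minute-level Gaussian noise, and
# infection episodes that elevate resting heart rate with a linear
# pre-symptomatic on-ramp. It is not a physiological simulator (no HRV,
# sleep staging, or temperature) and does not match any real dataset's
# marginals.

#' A simulated user's physiological profile
#'
#' @param baseline_rhr resting heart rate baseline in bpm, within
#'   `[50, 90]`.
#' @param diurnal_amplitude half-range of the sinusoidal diurnal heart-rate
#'   rhythm in bpm (trough ~4 am).
#' @param activity_rate expected activity bouts per day.
#' @param hr_per_step heart-rate rise in bpm per (step/min) of activity.
#' @param noise_sd minute-level Gaussian heart-rate noise sd in bpm (> 0).
#' @param seed per-user RNG seed.
#' @export
user_profile <- function(baseline_rhr = 65, diurnal_amplitude = 6,
                         activity_rate = 8, hr_per_step = 0.25,
                         noise_sd = 3, seed = 1L) {
  if (baseline_rhr < 50 || baseline_rhr > 90)
    stop("user_profile: baseline_rhr must be within [50, 90]")
  if (noise_sd <= 0) stop("user_profile: noise_sd must be > 0")
  structure(list(baseline_rhr = baseline_rhr,
                 diurnal_amplitude = diurnal_amplitude,
                 activity_rate = activity_rate, hr_per_step = hr_per_step,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cw_profile")
}

#' An infection episode
#'
#' Elevates resting heart rate by `rhr_elevation` bpm. `onset` and `end`
#' are the *reported* (labeled) sickness bounds; the physiological
#' elevation precedes them: it ramps up linearly over `ramp` seconds and
#' is fully established `lead` seconds before `onset` (resting heart rate
#' rises one to several days before symptoms are reported — the
#' pre-symptomatic drift the detector is meant to catch), then ramps down
#' after `end`.
#'
#' @param onset,end `POSIXct` labeled episode bounds (`onset < end`).
#' @param rhr_elevation peak elevation in bpm (> 0).
#' @param ramp ramp duration in seconds (default 12 h).
#' @param lead pre-symptomatic lead in seconds: how long before `onset`
#'   the elevation is already at full strength (default 24 h).
#' @export
infection_episode <- function(onset, end, rhr_elevation = 15,
                              ramp = 12 * 3600, lead = 24 * 3600) {
  if (!(onset < end)) stop("infection_episode: onset must precede end")
  if (rhr_elevation <= 0) stop("infection_episode: rhr_elevation must be > 0")
  structure(list(onset = onset, end = end, rhr_elevation = rhr_elevation,
                 ramp = ramp, lead = lead), class = "cw_episode")
}

#' Simulate one user's minute-cadence vitals stream
#'
#' heart rate = baseline + diurnal sinusoid + `hr_per_step` * steps +
#' episode elevation (ramped) + N(0, noise_sd), clamped to the
#' physiological range; steps come from a Poisson bout process (lognormal
#' durations, 60-140 steps/min inside bouts, zero outside).
#'
#' @param profile a [user_profile()].
#' @param days number of days (>= 1).
#' @param episodes list of [infection_episode()]s (must not overlap,
#'   including ramps).
#' @param start series start (`POSIXct`, default 2026-01-01 UTC).
#' @param user_id identifier for the resulting series.
#' @return List with `series` (a `cw_vitals`) and `labels` (data frame
#'   `onset`, `end`, one row per episode).
#' @export
simulate_user <- function(profile, days, episodes = list(),
                          start = as.POSIXct("2026-01-01", tz = "UTC"),
                          user_id = "u1") {
  stopifnot(inherits(profile, "cw_profile"), days >= 1)
  if (length(episodes) > 1L) {
    b <- t(vapply(episodes, function(e)
      as.numeric(c(e$onset - e$lead - e$ramp, e$end + e$ramp)), numeric(2)))
    b <- b[order(b[, 1L]), , drop = FALSE]
    if (any(b[-1L, 1L] < b[-nrow(b), 2L]))
      stop("simulate_user: overlapping episodes")
  }
  set.seed(profile$seed)
  n <- as.integer(days * 1440)
  tmin <- seq(0, length.out = n, by = 60) # seconds since start
  ts <- start + tmin
  tod <- (tmin / 3600) %% 24
  diurnal <- -profile$diurnal_amplitude * cos(2 * pi * (tod - 4) / 24)
  # activity bouts: Poisson count, uniform daytime starts, lognormal length
  steps <- numeric(n)
  n_bouts <- rpois(1L, profile$activity_rate * days)
  if (n_bouts > 0) {
    day_idx <- which(tod >= 8 & tod < 22)
    starts <- sort(sample(day_idx, n_bouts, replace = TRUE))
    durs <- pmax(2L, round(rlnorm(n_bouts, log(20), 0.5)))
    for (b in seq_len(n_bouts)) {
      i <- starts[b]:min(n, starts[b] + durs[b] - 1L)
      steps[i] <- sample(60:140, length(i), replace = TRUE)
    }
  }
  elev <- numeric(n)
  tabs <- as.numeric(ts)
  for (e in episodes) {
    full_at <- as.numeric(e$onset) - e$lead
    off <- as.numeric(e$end); rp <- e$ramp
    frac <- pmin(1, pmax(0, (tabs - (full_at - rp)) / rp)) *
      pmin(1, pmax(0, ((off + rp) - tabs) / rp))
    elev <- elev + e$rhr_elevation * frac
  }
  hr <- profile$baseline_rhr + diurnal + profile$hr_per_step * steps + elev +
    rnorm(n, 0, profile$noise_sd)
  hr <- pmin(pmax(hr, 20.5), 249.5)
  labels <- if (length(episodes)) {
    data.frame(onset = do.call(c, lapply(episodes, `[[`, "onset")),
               end = do.call(c, lapply(episodes, `[[`, "end")))
  } else data.frame(onset = start[0L], end = start[0L])
  list(series = vitals_series(user_id, ts, hr, as.integer(steps)),
       labels = labels)
}

#' Simulate a cohort of users
#'
#' Profiles are drawn from realistic ranges (baselines spanning well over
#' 20 bpm, as the adaptive RHR bound requires); `ceiling(sick_fraction *
#' n_users)` randomly chosen users receive one infection episode. Episode
#' onsets fall at midnight of a uniformly chosen day after the first 10
#' (leaving the default 7-day calibration period clean): illness in the
#' emulated wearables datasets is reported at day granularity. The
#' physiological elevation is fully established 24 h before the reported
#' onset (see [infection_episode()]).
#'
#' @param n_users cohort size.
#' @param sick_fraction fraction of users given an episode, in `[0, 1]`.
#' @param days days per user (default 28).
#' @param seed cohort RNG seed; per-user seeds are derived from it.
#' @param rhr_elevation episode elevation in bpm (default 15).
#' @param episode_days episode duration in days (default 5).
#' @return List of per-user lists: `series`, `labels`, `sick` (flag),
#'   `profile`.
#' @export
simulate_cohort <- function(n_users, sick_fraction = 1 / 3, days = 28,
                            seed = 1L, rhr_elevation = 15, episode_days = 5) {
  stopifnot(sick_fraction >= 0, sick_fraction <= 1, n_users >= 1)
  set.seed(seed)
  n_sick <- ceiling(sick_fraction * n_users)
  sick_ids <- sample(n_users, n_sick)
  baselines <- runif(n_users, 55, 85)
  amps <- runif(n_users, 4, 8)
  rates <- runif(n_users, 5, 12)
  noise <- runif(n_users, 2.5, 4)
  onset_days <- sample(10:max(10, floor(days - episode_days - 2)), n_users,
                       replace = TRUE)
  user_seeds <- sample.int(.Machine$integer.max - 1L, n_users)
  start <- as.POSIXct("2026-01-01", tz = "UTC")
  lapply(seq_len(n_users), function(i) {
    prof <- user_profile(baseline_rhr = baselines[i], diurnal_amplitude = amps[i],
                         activity_rate = rates[i], noise_sd = noise[i],
                         seed = user_seeds[i])
    eps <- list()
    if (i %in% sick_ids) {
      onset <- start + onset_days[i] * 86400
      eps <- list(infection_episode(onset, onset + episode_days * 86400,
                                    rhr_elevation = rhr_elevation))
    }
    sim <- simulate_user(prof, days, eps, start = start,
                         user_id = sprintf("u%03d", i))
    c(sim, list(sick = i %in% sick_ids, profile = prof))
  })
}

#' Toy bivariate-Gaussian outlier dataset
#'
#' An uncorrelated bivariate Gaussian cloud with zero mean and the given
#' variances, mixed by rotation, plus a few planted outliers along a known
#' direction: the demonstration that the leading cokurtosis singular
#' vector aligns with the outlier direction.
#'
#' @param n points in the Gaussian cloud (>= 100).
#' @param variances length-2 positive variances before rotation (default
#'   `c(1.0, 0.2)`).
#' @param rotation mixing rotation angle in radians.
#' @param n_outliers number of planted outliers.
#' @param outlier_distance distance of the outliers from the origin, in
#'   units of the largest marginal sd.
#' @param outlier_angle direction of the outliers in radians (`NULL`:
#'   random).
#' @param seed optional RNG seed.
#' @return List with `X` (`(n + n_outliers) x 2` matrix), `u` (unit outlier
#'   direction in data units), `outlier_idx` (row indices of the planted
#'   points).
#' @export
toy_outlier_dataset <- function(n = 500L, variances = c(1.0, 0.2),
                                rotation = pi / 6, n_outliers = 5L,
                                outlier_distance = 8, outlier_angle = NULL,
                                seed = NULL) {
  stopifnot(n >= 100, all(variances > 0))
  if (!is.null(seed)) set.seed(seed)
  X0 <- cbind(rnorm(n, 0, sqrt(variances[1L])),
              rnorm(n, 0, sqrt(variances[2L])))
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2L, 2L)
  X <- X0 %*% t(R)
  if (is.null(outlier_angle)) outlier_angle <- runif(1L, 0, 2 * pi)
  u <- c(cos(outlier_angle), sin(outlier_angle))
  idx <- integer(0)
  if (n_outliers > 0) {
    d <- outlier_distance * sqrt(max(variances))
    O <- matrix(rep(d * u, each = n_outliers), n_outliers, 2L) +
      matrix(rnorm(2L * n_outliers, 0, 0.05), n_outliers, 2L)
    idx <- n + seq_len(n_outliers)
    X <- rbind(X, O)
  }
  list(X = X, u = u, outlier_idx = idx)
}
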