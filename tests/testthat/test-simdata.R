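test_that("simulate_user is a pure function of its seed and stays in range", {
  prof <- user_profile(seed = 41)
  a <- simulate_user(prof, 3)
  b <- simulate_user(prof, 3)
  expect_identical(a$series$records, b$series$records)
  r <- a$series$records
  expect_true(all(r$heart_rate > 20 & r$heart_rate < 250))
  expect_true(all(r$steps >= 0 & r$steps == round(r$steps)))
  expect_equal(nrow(r), 3 * 1440)
})

test_that("flat profile recovers the baseline through hourly windows", {
  prof <- user_profile(baseline_rhr = 68, diurnal_amplitude = 1e-9,
                       hr_per_step = 0, noise_sd = 2, activity_rate = 2,
                       seed = 43)
  sim <- simulate_user(prof, 3)
  f <- stream_process(sim$series, window_spec(3600, 3600))
  rhr <- f$rhr[f$n_rest >= 30]
  expect_true(all(abs(rhr - 68) < 3 * 2 / sqrt(30)))
})

test_that("episodes elevate in-episode window RHR by about the configured bump", {
  devs <- sapply(1:20, function(s) {
    prof <- user_profile(seed = 100 + s)
    onset <- as.POSIXct("2026-01-05", tz = "UTC")
    ep <- infection_episode(onset, onset + 3 * 86400, rhr_elevation = 15)
    sim <- simulate_user(prof, 10, list(ep))
    f <- stream_process(sim$series, window_spec(3600, 3600))
    ok <- f$n_rest >= 10
    inside <- ok & f$window_start >= onset & f$window_end <= ep$end
    outside <- ok & (f$window_end <= onset - 2 * 86400 |
                       f$window_start >= ep$end + 86400)
    mean(f$rhr[inside]) - mean(f$rhr[outside])
  })
  expect_true(all(devs > 12 & devs < 18))
})

test_that("episode windows exceed the healthy 90th-percentile RHR", {
  hits <- sapply(1:5, function(s) {
    prof <- user_profile(seed = 200 + s)
    onset <- as.POSIXct("2026-01-12", tz = "UTC")
    ep <- infection_episode(onset, onset + 4 * 86400)
    sim <- simulate_user(prof, 20, list(ep))
    f <- stream_process(sim$series, window_spec(3600, 3600))
    ok <- f$n_rest >= 10
    healthy <- ok & f$window_end <= onset - 2 * 86400
    q90 <- quantile(f$rhr[healthy], 0.9)
    inside <- ok & f$window_start >= onset & f$window_end <= ep$end
    mean(f$rhr[inside] > q90)
  })
  expect_true(all(hits >= 0.9))
})

test_that("overlapping episodes are rejected", {
  t0 <- as.POSIXct("2026-01-05", tz = "UTC")
  e1 <- infection_episode(t0, t0 + 2 * 86400)
  e2 <- infection_episode(t0 + 86400, t0 + 3 * 86400)
  expect_error(simulate_user(user_profile(seed = 1), 10, list(e1, e2)),
               "overlapping")
})

test_that("cohorts have the requested sick count and heterogeneous baselines", {
  coh <- simulate_cohort(60, 1 / 3, days = 1, seed = 55)
  expect_length(coh, 60)
  expect_equal(sum(sapply(coh, `[[`, "sick")), 20)
  bases <- sapply(coh, function(u) u$profile$baseline_rhr)
  expect_gte(diff(range(bases)), 20)
  ids <- sapply(coh, function(u) u$series$user_id)
  expect_equal(anyDuplicated(ids), 0)
  # sick users carry labels; healthy ones don't
  for (u in coh)
    expect_equal(nrow(u$labels), as.integer(u$sick))
})

test_that("toy generator reproduces its stated variances and plants outliers", {
  toy0 <- toy_outlier_dataset(n = 4000, rotation = 0, n_outliers = 0, seed = 61)
  v <- apply(toy0$X, 2, var)
  expect_equal(v[1], 1.0, tolerance = 0.1)
  expect_equal(v[2], 0.2, tolerance = 0.1 * 0.2 / 0.2) # within 10%

  toy <- toy_outlier_dataset(n = 500, rotation = pi / 6, n_outliers = 5,
                             outlier_distance = 8, seed = 62)
  expect_equal(nrow(toy$X), 505)
  expect_length(toy$outlier_idx, 5)
  Z <- standardize(toy$X)
  S <- hosvd_factors(cokurtosis_tensor(Z))
  u_std <- std_direction(toy$u, Z$sds)
  expect_gt(abs(sum(S$singular_vectors[, 1] * u_std)), 0.9)

  # planted outliers dominate the leading singular value
  ratios <- sapply(1:5, function(s) {
    t1 <- toy_outlier_dataset(n = 500, n_outliers = 5, outlier_distance = 8,
                              seed = s)
    t0 <- toy_outlier_dataset(n = 500, n_outliers = 0, seed = s)
    l1 <- hosvd_factors(cokurtosis_tensor(standardize(t1$X)))$singular_values[1]
    l0 <- hosvd_factors(cokurtosis_tensor(standardize(t0$X)))$singular_values[1]
    l1 / l0
  })
  expect_gt(min(ratios), 5)
})
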