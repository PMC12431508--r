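test_that("reference grid covers the ranges and honors the cap", {
  rg <- build_reference_grid(healthy_ranges(60, 100, 0, 40), cap = 2500)
  expect_equal(rg$n, 41 * 41) # full lattice, strides (1, 1)
  expect_equal(unname(rg$stride), c(1, 1))
  expect_equal(sum(rg$d2), 1, tolerance = 1e-10)

  rg2 <- build_reference_grid(healthy_ranges(60, 90, 0, 5000), cap = 2500)
  expect_lte(rg2$n, 2500)
  # retained points are lattice members within the ranges
  expect_true(all(rg2$points[, "alpha"] %in%
                    seq(60, 90, by = rg2$stride["alpha"])))
  expect_true(all(rg2$points[, "beta"] %in%
                    seq(0, 5000, by = rg2$stride["beta"])))
  # each axis keeps a healthy number of levels
  expect_gte(length(unique(rg2$points[, "alpha"])), 20)
  expect_gte(length(unique(rg2$points[, "beta"])), 20)

  expect_error(healthy_ranges(80, 80, 0, 10), "degenerate")
  expect_error(build_reference_grid(healthy_ranges(60, 100, 0, 40), cap = 10),
               "cap")
})

test_that("fast scoring path equals the direct tensor pipeline", {
  rg <- build_reference_grid(healthy_ranges(60, 100, 0, 1200), cap = 2500)
  set.seed(4)
  for (trial in 1:20) {
    d <- c(runif(1, 40, 160), runif(1, -100, 3000))
    expect_equal(as.numeric(anomaly_score(rg, d)),
                 as.numeric(anomaly_score(rg, d, method = "direct")),
                 tolerance = 1e-9)
  }
})

test_that("interior observations score near zero; scores are deterministic", {
  rg <- build_reference_grid(healthy_ranges(60, 100, 0, 1200), cap = 2500)
  center <- colMeans(rg$points)
  expect_lt(anomaly_score(rg, center), 1e-3)
  # duplicate of an existing grid point under multiset union
  expect_lt(anomaly_score(rg, rg$points[17, ]), 1e-3)
  d <- c(91.3, 400)
  expect_identical(anomaly_score(rg, d), anomaly_score(rg, d))
  expect_error(anomaly_score(rg, c(NA, 1)), "finite")
})

test_that("scores increase monotonically along rays leaving the grid", {
  rg <- build_reference_grid(healthy_ranges(60, 100, 0, 1200), cap = 2500)
  center <- colMeans(rg$points)
  half <- c(20, 600) # half-widths of the box
  set.seed(12)
  for (ray in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    u <- c(cos(ang), sin(ang))
    # from the box edge outwards
    scores <- sapply(seq(1, 4, length.out = 10), function(t)
      anomaly_score(rg, center + t * u * half))
    expect_true(all(diff(scores) > -1e-9))
  }
})

test_that("detect_anomalies applies the threshold and skip rules exactly", {
  set.seed(31)
  sim <- simulate_user(user_profile(seed = 31), days = 10)
  feats <- stream_process(sim$series, window_spec(3600, 1800))
  grid <- build_reference_grid(estimate_healthy_ranges(feats, 7))
  al <- detect_anomalies(feats, grid, delta = 0.008, user_id = "u")
  expect_s3_class(al, "cw_alerts")
  expect_identical(al$is_anomaly, al$score > 0.008)
  skipped <- attr(al, "skipped")
  expect_equal(nrow(al) + nrow(skipped), nrow(feats))

  # near-zero threshold: every scored window flagged (scores > 0 a.s.)
  al0 <- detect_anomalies(feats, grid, delta = 1e-12)
  expect_true(all(al0$is_anomaly))

  # anti-monotone in delta: flags shrink as the threshold grows
  d1 <- detect_anomalies(feats, grid, delta = 0.004)
  d2 <- detect_anomalies(feats, grid, delta = 0.012)
  expect_true(all(d2$window_start[d2$is_anomaly] %in%
                    d1$window_start[d1$is_anomaly]))
  expect_error(detect_anomalies(feats, grid, delta = 0), "delta")
})

test_that("healthy windows of a healthy user stay under the threshold", {
  set.seed(77)
  sim <- simulate_user(user_profile(baseline_rhr = 70, seed = 77), days = 14)
  feats <- stream_process(sim$series, window_spec(3600, 1800))
  grid <- build_reference_grid(estimate_healthy_ranges(feats, 7))
  al <- detect_anomalies(feats, grid, delta = 0.008)
  expect_equal(sum(al$is_anomaly), 0)
})

test_that("adaptive RHR bound is the clipped 90th percentile", {
  mk <- function(rhr) {
    data.frame(window_start = as.POSIXct("2026-01-01", tz = "UTC") +
                 1800 * (seq_along(rhr) - 1),
               rhr = rhr, degenerate = FALSE)
  }
  expect_equal(adaptive_rhr_bound(mk(rep(70, 48)))$nabla, 90) # clipped up
  expect_equal(adaptive_rhr_bound(mk(rep(130, 48)))$nabla, 110) # clipped down

  # constructed sample whose empirical 90th percentile is 104
  b <- adaptive_rhr_bound(mk(c(rep(95, 40), rep(104, 8))))
  expect_equal(b$nabla, 104)
  expect_true(b$nabla >= 90 && b$nabla <= 110)

  expect_error(adaptive_rhr_bound(mk(rep(70, 5))), "insufficient")
  expect_error(adaptive_rhr_bound(mk(rep(70, 48)), lookback_hours = 72),
               "lookback")
})
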