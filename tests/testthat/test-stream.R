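test_that("window count follows floor((T - w)/s) + 1", {
  s180 <- make_series(rep(65, 180), rep(0, 180))
  sl <- window_slices(s180, window_spec(3600, 1800))
  expect_equal(nrow(sl), 5)
  expect_equal(as.numeric(sl$start - sl$start[1], units = "mins"),
               c(0, 30, 60, 90, 120))

  # property sweep, including the four production configurations
  set.seed(2)
  cases <- rbind(expand.grid(Tm = c(60, 90, 180, 240, 1440),
                             w = c(60, 120), s = c(30, 60, 120)),
                 data.frame(Tm = 300, w = c(60, 120, 60, 120),
                            s = c(30, 60, 60, 120)))
  for (i in seq_len(nrow(cases))) {
    Tm <- cases$Tm[i]; w <- cases$w[i]; s <- cases$s[i]
    if (s > w || Tm < w) next
    ser <- make_series(rep(65, Tm), rep(0, Tm))
    sl <- window_slices(ser, window_spec(w * 60, s * 60))
    expect_equal(nrow(sl), floor((Tm - w) / s) + 1)
  }
})

test_that("non-overlapping windows partition the span", {
  ser <- make_series(rep(65, 240), rep(0, 240))
  sl <- window_slices(ser, window_spec(3600, 3600))
  expect_equal(nrow(sl), 4)
  expect_equal(sl$start[-1], sl$end[-nrow(sl)])
})

test_that("too-short series yields empty slices with a warning", {
  ser <- make_series(rep(65, 10), rep(0, 10))
  expect_warning(sl <- window_slices(ser, window_spec(3600, 3600)),
                 "shorter than window")
  expect_equal(nrow(sl), 0)
})

test_that("window latent features follow the RHR/AHR/OHR definitions", {
  ser <- make_series(rep(65, 60), rep(0, 60))
  f <- window_latent_features(ser, ser$records$timestamp[1],
                              ser$records$timestamp[1] + 3600)
  expect_equal(f$rhr, 65)
  expect_equal(f$ohr, 65)
  expect_true(is.na(f$ahr))
  expect_equal(f$step_total, 0)
  expect_true(f$degenerate)

  ser2 <- make_series(c(60, 120), c(0, 100))
  f2 <- window_latent_features(ser2, ser2$records$timestamp[1],
                               ser2$records$timestamp[1] + 120)
  expect_equal(f2$rhr, 60)
  expect_equal(f2$ahr, 120)
  expect_equal(f2$ohr, 90)
  expect_equal(f2$step_total, 100)

  # empty window is a gap marker
  expect_null(window_latent_features(ser2, ser2$records$timestamp[1] + 7200,
                                     ser2$records$timestamp[1] + 10800))
})

test_that("RHR falls back to the lowest decile when no minute is at rest", {
  hr <- seq(80, 139, length.out = 60)
  ser <- make_series(hr, rep(50, 60))
  f <- window_latent_features(ser, ser$records$timestamp[1],
                              ser$records$timestamp[1] + 3600)
  expect_true(f$rhr_imputed)
  expect_equal(f$rhr, mean(sort(hr)[1:6]))
})

test_that("stream_process is deterministic, bounded, and flags coverage", {
  set.seed(21)
  n <- 24 * 60
  hr <- 65 + 5 * sin(2 * pi * seq_len(n) / 1440) + rnorm(n)
  st <- ifelse(runif(n) < 0.1, 80, 0)
  ser <- make_series(hr, st)
  spec <- window_spec(3600, 1800)
  f1 <- stream_process(ser, spec, trace_queue = TRUE)
  f2 <- stream_process(ser, spec, trace_queue = TRUE)
  expect_identical(f1, f2)
  expect_lte(attr(f1, "queue_peak"), ceiling(spec$window / ser$cadence))
  tr <- attr(f1, "queue_trace")
  expect_true(all(tr$retained <= spec$window / ser$cadence -
                    spec$slide / ser$cadence + 1))

  # series of length exactly w: one emission
  serw <- make_series(rep(65, 60), rep(0, 60))
  expect_equal(nrow(stream_process(serw, window_spec(3600, 3600))), 1)

  # low-coverage flagging: thin the middle out
  keep <- c(1:45, 400:n)
  ser3 <- vitals_series("g", ser$records$timestamp[keep], hr[keep], st[keep])
  f3 <- stream_process(ser3, spec)
  expect_true(any(f3$low_coverage))
})

test_that("out-of-order records are rejected with the offending timestamp", {
  ser <- make_series(rep(65, 120), rep(0, 120))
  ser$records <- ser$records[c(2, 1, 3:120), ]
  expect_error(stream_process(ser, window_spec(3600, 3600)), "out-of-order")
  expect_error(make_series(rep(65, 2), rep(0, 2))$records |>
                 (\(r) vitals_series("x", r$timestamp[c(1, 1)],
                                     r$heart_rate, r$steps))(),
               "strictly increasing")
})

test_that("overlapping emissions interleave two non-overlapping passes", {
  set.seed(5)
  n <- 6 * 60
  ser <- make_series(65 + rnorm(n), rep(0, n))
  ov <- stream_process(ser, window_spec(3600, 1800))
  a <- stream_process(ser, window_spec(3600, 3600))
  # pass offset by w/2
  serb <- vitals_series("t1", ser$records$timestamp[-(1:30)],
                        ser$records$heart_rate[-(1:30)],
                        ser$records$steps[-(1:30)])
  b <- stream_process(serb, window_spec(3600, 3600))
  merged <- rbind(a, b)
  merged <- merged[order(merged$window_start), ]
  expect_equal(nrow(ov), nrow(merged))
  expect_equal(ov$rhr, merged$rhr)
  expect_equal(ov$step_total, merged$step_total)
})
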