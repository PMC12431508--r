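test_that("LHS places exactly one draw per stratum in every column", {
  for (n in c(4L, 100L)) {
    L <- lhs_normal_samples(n, 3, seed = 10 + n)
    U <- pnorm(L)
    for (j in 1:3) {
      bins <- findInterval(U[, j], seq(0, 1, length.out = n + 1),
                           rightmost.closed = TRUE)
      expect_equal(sort(bins), 1:n)
    }
  }
  expect_identical(lhs_normal_samples(50, 2, seed = 3),
                   lhs_normal_samples(50, 2, seed = 3))
})

test_that("LHS column means converge faster than 3/sqrt(n)", {
  set.seed(14)
  n <- 1e4
  means <- replicate(5, mean(lhs_normal_samples(n, 1)))
  expect_true(all(abs(means) < 3 / sqrt(n)))
})

test_that("perturbation follows the seven steps", {
  set.seed(15)
  R <- cbind(hr = runif(300, 55, 110), steps = rpois(300, 3))
  R[sample(300, 150), "steps"] <- 0

  p0 <- perturb_dataset(R, 0, seed = 1)
  expect_lt(max(abs(p0$values - R)), 1e-10) # identity round trip
  expect_equal(p0$real_range["min", ], apply(R, 2, min))

  p3 <- perturb_dataset(R, 0.03, seed = 1)
  # normalized rms deviation ~ rms(0.03 * L), in (0, 0.05]
  Rn <- sweep(sweep(R, 2, apply(R, 2, min), "-"), 2,
              apply(R, 2, max) - apply(R, 2, min), "/")
  Pn <- sweep(sweep(p3$values, 2, p3$real_range["min", ], "-"), 2,
              p3$real_range["max", ] - p3$real_range["min", ], "/")
  rms <- sqrt(colMeans((Pn - Rn)^2))
  expect_true(all(rms > 0 & rms <= 0.05))

  for (eps in c(0.01, 0.05, 0.2))
    expect_gte(min(perturb_dataset(R, eps, seed = 2)$values[, "steps"]), 0)
  ps <- perturb_dataset(R, 0.05, seed = 2, strict_steps = TRUE)
  expect_gte(min(ps$values[, "steps"]), 1)

  expect_true(all(p3$normalized >= 0 & p3$normalized <= 1))
  expect_error(perturb_dataset(R, -0.01), "epsilon")
})

test_that("rms deviation grows with epsilon", {
  set.seed(16)
  R <- cbind(runif(400, 55, 110), pmax(0, rpois(400, 2) - 1))
  rms_at <- sapply(c(0, 0.01, 0.02, 0.03, 0.05), function(e) {
    p <- perturb_dataset(R, e, seed = 7)
    sqrt(mean((p$values[, 1] - R[, 1])^2))
  })
  expect_true(all(diff(rms_at) > 0))
})

test_that("population loop harvests on the separation schedule and counts
           failures without aborting", {
  set.seed(17)
  sim <- simulate_user(user_profile(seed = 17), days = 1)
  user <- as.matrix(sim$series$records[seq(1, 1440, by = 6), c("heart_rate", "steps")])

  # vacuous tolerances, 300-epoch cap, 100-epoch separation, checks every
  # 50 epochs: harvests at exactly 100, 200, 300
  coh <- generate_population(
    list(a = user), epsilon_grid = 0.02,
    config = perturbation_config(realizations = 2, epoch_separation = 100,
                                 max_epochs = 300, seed = 18),
    train = train_config(rhr_tol = Inf, ahr_tol = Inf, ohr_tol = Inf,
                         check_every = 50L, gate_sample = 200L))
  expect_equal(coh$counts$n_harvests, c(3L, 3L))
  expect_equal(coh$failed, 0L)
  eps <- sapply(coh$members, `[[`, "epoch")
  expect_equal(sort(unique(eps)), c(100, 200, 300))
  for (rz in 1:2) {
    he <- sort(sapply(Filter(function(m) m$realization == rz, coh$members),
                      `[[`, "epoch"))
    expect_true(all(diff(he) >= 100))
  }
  # provenance bookkeeping
  m1 <- coh$members[[1]]
  expect_named(m1, c("synthetic", "user", "epsilon", "realization", "epoch",
                     "pdf_deltas"), ignore.order = TRUE)
  expect_equal(nrow(m1$synthetic), nrow(user))

  # unreachable tolerances: zero harvests, counted as failed, no abort
  coh2 <- generate_population(
    list(a = user), epsilon_grid = 0.02,
    config = perturbation_config(realizations = 1, epoch_separation = 100,
                                 max_epochs = 100, seed = 19),
    train = train_config(rhr_tol = 1e-12, ahr_tol = 1e-12, ohr_tol = 1e-12,
                         check_every = 50L, gate_sample = 200L))
  expect_equal(coh2$failed, 1L)
  expect_length(coh2$members, 0)
})
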