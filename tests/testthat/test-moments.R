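test_that("standardize produces exact z-scores with population sd", {
  Z <- standardize(matrix(c(1, 3), 2, 1))
  expect_equal(as.vector(Z$values), c(-1, 1)) # population sd = 1
  expect_equal(Z$means, 2, ignore_attr = TRUE)
  expect_equal(Z$sds, 1, ignore_attr = TRUE)

  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  Xz <- scale(X, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  Z2 <- standardize(Xz)
  expect_lt(max(abs(Z2$values - Xz)), 1e-10) # already standardized: identity

  # stored means/sds invert exactly
  Z3 <- standardize(X)
  back <- sweep(sweep(Z3$values, 2, Z3$sds, "*"), 2, Z3$means, "+")
  expect_lt(max(abs(back - X)), 1e-10)
})

test_that("zero-variance columns raise a degenerate-feature error naming them", {
  X <- cbind(hr = rnorm(20), flat = rep(5, 20))
  expect_error(standardize(X), "degenerate.*flat")
})

test_that("cokurtosis matches closed forms and the brute-force oracle", {
  # Rademacher two-point sample: E[x^4] - 3 E[x^2]^2 = 1 - 3 = -2
  T4 <- cokurtosis_tensor(matrix(c(-1, 1), 2, 1))
  expect_equal(T4$entries[1, 1, 1, 1], -2)

  set.seed(42)
  for (trial in 1:25) {
    n <- sample(8:50, 1)
    m <- sample(2:4, 1)
    Z <- standardize(matrix(rnorm(n * m), n, m))
    T4 <- cokurtosis_tensor(Z)$entries
    expect_lt(max(abs(T4 - brute_cokurtosis(Z))), 1e-10)
  }
})

test_that("cokurtosis tensor is invariant under all index permutations", {
  set.seed(7)
  Z <- standardize(matrix(rexp(120), 40, 3))
  T4 <- cokurtosis_tensor(Z)$entries
  for (p in perms4)
    expect_lt(max(abs(T4 - aperm(T4, p))), 1e-10)
  # the printed-definition instance: T1212 = T2211 = T1122
  expect_equal(T4[1, 2, 1, 2], T4[2, 2, 1, 1])
  expect_equal(T4[1, 2, 1, 2], T4[1, 1, 2, 2])
})

test_that("Gaussian data has vanishing cokurtosis at rate ~ n^(-1/2)", {
  set.seed(11)
  err <- sapply(c(1e3, 1e4, 1e5), function(n) {
    mean(replicate(3, max(abs(
      cokurtosis_tensor(standardize(matrix(rnorm(2 * n), n, 2)))$entries))))
  })
  expect_true(all(diff(err) < 0))
  # factor-10 n should shrink error ~ sqrt(10); allow generous slack
  expect_lt(err[3], err[1] / 3)
})

test_that("hosvd_factors recovers rank-one structure and handles zero", {
  v <- c(1, 0)
  T4 <- 2 * outer(outer(v, v), outer(v, v))
  S <- hosvd_factors(T4)
  expect_equal(S$singular_values, c(2, 0))
  expect_equal(abs(S$singular_vectors[, 1]), c(1, 0))

  S0 <- hosvd_factors(array(0, rep(2, 4)))
  expect_equal(S0$singular_values, c(0, 0))

  set.seed(3)
  Z <- standardize(matrix(rt(90, df = 5), 30, 3))
  S1 <- hosvd_factors(cokurtosis_tensor(Z))
  V <- S1$singular_vectors
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-8)
  expect_true(all(diff(S1$singular_values) <= 1e-12)) # descending
  # sign fix: largest-magnitude entry of each column positive
  for (k in 1:3) expect_gt(V[which.max(abs(V[, k])), k], 0)
})

test_that("feature moment metric matches closed forms and normalizes", {
  S <- structure(list(singular_values = c(3, 0),
                      singular_vectors = cbind(c(0, 1), c(1, 0))),
                 class = "cw_spectral")
  expect_equal(as.numeric(feature_moment_metric(S)), c(0, 1))

  S2 <- structure(list(singular_values = c(1, 1), singular_vectors = diag(2)),
                  class = "cw_spectral")
  expect_equal(as.numeric(feature_moment_metric(S2)), c(0.5, 0.5))

  set.seed(5)
  for (trial in 1:50) {
    m <- sample(2:6, 1)
    V <- qr.Q(qr(matrix(rnorm(m * m), m)))
    S3 <- structure(list(singular_values = sort(rexp(m), decreasing = TRUE),
                         singular_vectors = V), class = "cw_spectral")
    F <- feature_moment_metric(S3)
    expect_true(all(F >= 0 & F <= 1))
    expect_lt(abs(sum(F) - 1), 1e-10)
  }

  S4 <- structure(list(singular_values = c(0, 0), singular_vectors = diag(2)),
                  class = "cw_spectral")
  expect_error(feature_moment_metric(S4), "degenerate-spectrum|degenerate")
})

test_that("hellinger distance satisfies the metric axioms and closed forms", {
  expect_equal(hellinger_distance(c(.3, .7), c(.3, .7)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), 1)
  # 1/sqrt(2) * ||sqrt(p) - sqrt(q)|| with BC = sqrt(.125) + sqrt(.375)
  expect_equal(hellinger_distance(c(.5, .5), c(.25, .75)), 0.184591907,
               tolerance = 1e-7)
  set.seed(8)
  for (trial in 1:30) {
    p <- rand_dist(5); q <- rand_dist(5)
    h <- hellinger_distance(p, q)
    expect_equal(h, hellinger_distance(q, p))
    expect_true(h >= 0 && h <= 1)
  }
  # printed l2 variant
  expect_equal(hellinger_distance(c(.5, .5), c(.25, .75), form = "l2"),
               sqrt(0.5 * 2 * 0.25^2))
  expect_error(hellinger_distance(c(1, 0), c(1, 0, 0)), "length mismatch")
  expect_error(hellinger_distance(c(1.2, -0.2), c(.5, .5)), "negative")
})

test_that("derive_features expands a univariate window", {
  f <- derive_features(c(60, 62, 100, 61), block_length = 4)
  expect_equal(as.vector(f), c(70.75, 61.5, 60, 100))
  expect_equal(colnames(f), c("mean", "median", "min", "max"))

  # two blocks of a linear ramp: means differ by slope * block length
  ramp <- 2 * (1:20)
  f2 <- derive_features(ramp, block_length = 10)
  expect_equal(unname(f2[2, "mean"] - f2[1, "mean"]), 2 * 10)

  f3 <- derive_features(rep(70, 8), block_length = 4)
  expect_true(all(f3 == 70)) # constant input -> constant columns
  expect_error(derive_features(c(70, 70, 70, 70), block_length = 10),
               "too short")
  expect_error(derive_features(c(1, 2)), "length")
})
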