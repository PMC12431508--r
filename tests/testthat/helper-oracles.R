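# Independent oracles and small fixture builders shared by the suite.

# Brute-force fourth-order joint cumulant: quadruple loop over the printed
# definition, independent of the package's vectorized path.
brute_cokurtosis <- function(Z) {
  if (inherits(Z, "cw_standardized")) Z <- Z$values
  m <- ncol(Z)
  E <- function(...) mean(Reduce(`*`, list(...)))
  T4 <- array(0, rep(m, 4))
  for (i in 1:m) for (j in 1:m) for (k in 1:m) for (l in 1:m)
    T4[i, j, k, l] <-
      E(Z[, i], Z[, j], Z[, k], Z[, l]) -
      E(Z[, i], Z[, j]) * E(Z[, k], Z[, l]) -
      E(Z[, i], Z[, k]) * E(Z[, j], Z[, l]) -
      E(Z[, i], Z[, l]) * E(Z[, j], Z[, k])
  T4
}

# random discrete distribution of length m
rand_dist <- function(m) {
  p <- runif(m)
  p / sum(p)
}

# minute-cadence series from explicit vectors
make_series <- function(hr, steps, user = "t1",
                        start = as.POSIXct("2026-01-01", tz = "UTC")) {
  vitals_series(user, start + 60 * (seq_along(hr) - 1), hr, steps)
}

# standardized-coordinates outlier direction for alignment checks
std_direction <- function(u, sds) {
  v <- u / sds
  v / sqrt(sum(v^2))
}

# all 24 permutations of 4 indices
perms4 <- local({
  p <- list()
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4)
    if (length(unique(c(a, b, c, d))) == 4L)
      p[[length(p) + 1L]] <- c(a, b, c, d)
  p
})
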