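# Cokurtosis / HOSVD / feature-moment-metric core.
#
# The detector's statistic is built from the fourth-order joint cumulant
# (cokurtosis) tensor of a standardized data matrix:
#
#   T[i,j,k,l] = E[z_i z_j z_k z_l] - E[z_i z_j]E[z_k z_l]
#                                   - E[z_i z_k]E[z_j z_l]
#                                   - E[z_i z_l]E[z_j z_k]
#
# with E the sample expectation over rows. For Gaussian data every entry is
# zero, so nonzero structure signals outliers/heavy tails. The tensor is
# factorized by HOSVD (SVD of the mode-1 unfolding; all unfoldings coincide
# for a fully symmetric tensor), and the singular pairs are condensed into a
# per-feature "kurtosis share" vector that behaves as a discrete
# distribution, compared across datasets with the Hellinger distance.

#' Column-wise standardization (population-variance convention)
#'
#' Centers and scales each column of `X` to mean 0 and variance 1, using the
#' population standard deviation (denominator `n`, not `n - 1`). This
#' convention matches the moment estimator used by [cokurtosis_tensor()], so
#' that the tensor diagonal `T[i,i,i,i]` is exactly the sample excess
#' kurtosis of feature `i` and i.i.d. Rademacher data gives the closed form
#' `-2`.
#'
#' @param X numeric matrix (n observations x m features) or data frame of
#'   numeric columns. `n >= 2` required.
#' @return An object of class `cw_standardized`: a list with `values`
#'   (the z-scored matrix), `means` and `sds` (original units, population
#'   sd), allowing exact inverse transform.
#' @examples
#' Z <- standardize(cbind(hr = rnorm(50, 65, 5), steps = rpois(50, 20)))
#' colMeans(Z$values) # ~ 0
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("standardize: need at least 2 observations")
  if (anyNA(X) || !all(is.finite(X))) stop("standardize: non-finite values in input")
  mu <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(colMeans(X^2) - mu^2) # population sd
  bad <- which(sds <= .Machine$double.eps^0.5 * pmax(abs(mu), 1))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("standardize: degenerate (zero-variance) feature(s): ",
         paste(nm, collapse = ", "))
  }
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")
  structure(list(values = Z, means = mu, sds = sds),
            class = "cw_standardized")
}

as_standardized_matrix <- function(Z, caller = "cokurtosis_tensor") {
  if (inherits(Z, "cw_standardized")) return(Z$values)
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (!all(is.finite(Z))) stop(caller, ": non-finite values in input")
  mu <- colMeans(Z)
  v <- colMeans(Z^2) - mu^2
  if (any(abs(mu) > 1e-6) || any(abs(v - 1) > 1e-4))
    stop(caller, ": input is not standardized; call standardize() first")
  Z
}

#' Cokurtosis joint cumulant tensor
#'
#' Computes the fourth-order joint cumulant tensor of a standardized matrix:
#' the fourth raw moment tensor minus the three Gaussian pair-product terms.
#' All expectations are sample means over rows. The result is fully
#' symmetric under any permutation of its four indices, and every entry of
#' the tensor of an i.i.d. Gaussian sample converges to zero.
#'
#' @param Z a `cw_standardized` object from [standardize()], or a numeric
#'   matrix that is already column-standardized (checked).
#' @return An object of class `cw_cokurtosis`: list with `entries`
#'   (an `m x m x m x m` array) and `m`.
#' @export
cokurtosis_tensor <- function(Z) {
  Z <- as_standardized_matrix(Z)
  n <- nrow(Z)
  m <- ncol(Z)
  if (m < 1L) stop("cokurtosis_tensor: need at least one feature")
  M2 <- crossprod(Z) / n
  # fourth raw moments via the (i,j) x (k,l) pair unfolding
  W <- matrix(0, n, m * m)
  idx <- 1L
  for (j in seq_len(m)) for (i in seq_len(m)) {
    W[, idx] <- Z[, i] * Z[, j]
    idx <- idx + 1L
  }
  M4 <- array(crossprod(W) / n, dim = c(m, m, m, m))
  A <- outer(M2, M2) # A[i,j,k,l] = M2[i,j] * M2[k,l]
  T4 <- M4 - A - aperm(A, c(1L, 3L, 2L, 4L)) - aperm(A, c(1L, 3L, 4L, 2L))
  structure(list(entries = T4, m = m), class = "cw_cokurtosis")
}

as_cokurtosis_array <- function(T4) {
  if (inherits(T4, "cw_cokurtosis")) T4$entries else {
    T4 <- as.array(T4)
    if (length(dim(T4)) != 4L || length(unique(dim(T4))) != 1L)
      stop("expected an m x m x m x m cokurtosis tensor")
    T4
  }
}

#' HOSVD factors of a symmetric fourth-order tensor
#'
#' For a fully symmetric tensor all four mode unfoldings coincide, so the
#' higher-order SVD reduces to one ordinary SVD of the `m x m^3` mode-1
#' unfolding. Returns all `m` singular pairs. Singular-vector signs are
#' fixed so each column's largest-magnitude entry is positive (the
#' downstream metric is sign-invariant; the fix makes results
#' deterministic).
#'
#' @param T4 a `cw_cokurtosis` object or an `m x m x m x m` array.
#' @return An object of class `cw_spectral`: list with `singular_values`
#'   (length m, nonnegative, descending) and `singular_vectors`
#'   (`m x m`, orthonormal columns).
#' @export
hosvd_factors <- function(T4) {
  A <- as_cokurtosis_array(T4)
  m <- dim(A)[1L]
  U <- matrix(A, nrow = m) # mode-1 unfolding (column-major: first index rows)
  s <- tryCatch(svd(U, nu = m, nv = 0L), error = function(e) {
    stop("hosvd_factors: SVD failed (tensor Frobenius norm ",
         format(sqrt(sum(A^2))), "): ", conditionMessage(e))
  })
  V <- fix_vector_signs(s$u)
  structure(list(singular_values = s$d, singular_vectors = V),
            class = "cw_spectral")
}

fix_vector_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Feature moment metric (per-feature kurtosis shares)
#'
#' Condenses HOSVD singular pairs \eqn{(\lambda_k, \hat v_k)} into
#' \deqn{F_i = \sum_k \lambda_k (e_i \cdot \hat v_k)^2 / \sum_k \lambda_k,}
#' the fraction of total kurtosis attributable to feature `i`. Because the
#' singular vectors are orthonormal the entries are nonnegative and sum to
#' one, so `F` behaves as a discrete distribution over features.
#'
#' @param S a `cw_spectral` object from [hosvd_factors()].
#' @return Numeric vector of length `m` summing to 1 (class `cw_fmm`).
#' @export
feature_moment_metric <- function(S) {
  stopifnot(inherits(S, "cw_spectral"))
  lam <- S$singular_values
  if (any(lam < -1e-12)) stop("feature_moment_metric: negative singular values")
  tot <- sum(lam)
  if (tot <= 0)
    stop("feature_moment_metric: degenerate spectrum (all singular values zero); no kurtosis signal")
  F <- as.vector((S$singular_vectors^2) %*% lam) / tot
  structure(F, class = "cw_fmm")
}

#' Hellinger distance between discrete distributions
#'
#' Default is the square-root form
#' \eqn{H(p,q) = \frac{1}{\sqrt 2}\lVert\sqrt p - \sqrt q\rVert_2},
#' which is symmetric, zero iff `p == q`, and bounded by 1. `form = "l2"`
#' selects the plain \eqn{\frac{1}{\sqrt 2}\lVert p - q\rVert_2} variant
#' (not bounded-normalized in the same way; kept as a config-selectable
#' alternative).
#'
#' @param p,q nonnegative numeric vectors of equal length, each summing to 1
#'   (tolerance 1e-6).
#' @param form `"sqrt"` (default) or `"l2"`.
#' @return A number in `[0, 1]` for the `"sqrt"` form.
#' @examples
#' hellinger_distance(c(.5, .5), c(.25, .75)) # 0.18459...
#' @export
hellinger_distance <- function(p, q, form = c("sqrt", "l2")) {
  form <- match.arg(form)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    stop("hellinger_distance: length mismatch (", length(p), " vs ", length(q), ")")
  if (any(p < -1e-12) || any(q < -1e-12))
    stop("hellinger_distance: negative entries; inputs must be distributions")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("hellinger_distance: inputs must each sum to 1")
  p <- pmax(p, 0); q <- pmax(q, 0)
  if (form == "sqrt") sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
  else sqrt(0.5 * sum((p - q)^2))
}

#' Derive a multivariate matrix from a univariate window sample
#'
#' The cokurtosis method needs at least two features. When only one vital is
#' available, the stream is expanded by computing descriptive statistics
#' (mean, median, min, max by default) over consecutive sub-blocks of the
#' window, one row per complete sub-block.
#'
#' @param x numeric vector (one window of a univariate stream), length >= 4.
#' @param block_length sub-block size in samples (default 60, one hour of
#'   minute-cadence data).
#' @param stats character vector of statistics to compute per block; any of
#'   `"mean"`, `"median"`, `"min"`, `"max"`, `"sd"`.
#' @return Numeric matrix with one row per complete block and one column per
#'   statistic (column names = `stats`).
#' @export
derive_features <- function(x, block_length = 60L,
                            stats = c("mean", "median", "min", "max")) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("derive_features: sample length must be >= 4")
  block_length <- as.integer(block_length)
  if (length(x) < block_length)
    stop("derive_features: window too short (", length(x),
         " samples) for block length ", block_length)
  funs <- list(mean = mean, median = stats::median, min = min, max = max,
               sd = stats::sd)
  stats <- match.arg(stats, names(funs), several.ok = TRUE)
  nb <- length(x) %/% block_length
  out <- matrix(NA_real_, nb, length(stats), dimnames = list(NULL, stats))
  for (b in seq_len(nb)) {
    blk <- x[((b - 1L) * block_length + 1L):(b * block_length)]
    for (s in seq_along(stats)) out[b, s] <- funs[[stats[s]]](blk)
  }
  out
}

# Full chain X -> FMM with degenerate-input signalling: returns list(fmm,
# degenerate). Degenerate inputs (constant column, zero spectrum) yield
# fmm = NULL and degenerate = TRUE instead of an error so that streaming
# callers can skip flat windows.
fmm_of_matrix <- function(X) {
  res <- tryCatch(
    list(fmm = feature_moment_metric(hosvd_factors(cokurtosis_tensor(standardize(X)))),
         degenerate = FALSE),
    error = function(e) {
      if (grepl("degenerate", conditionMessage(e)))
        list(fmm = NULL, degenerate = TRUE)
      else stop(e)
    })
  res
}

#' @export
print.cw_cokurtosis <- function(x, ...) {
  cat("<cokurtosis tensor> m =", x$m,
      " max |T| =", format(max(abs(x$entries))), "\n")
  invisible(x)
}

#' @export
print.cw_spectral <- function(x, ...) {
  cat("<HOSVD factors> singular values:",
      paste(format(x$singular_values, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
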