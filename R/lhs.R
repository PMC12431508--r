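# Latin-hypercube perturbation and the synthetic-population loop.
#
# A small number of real users is grown into a heterogeneous synthetic
# cohort: each realization perturbs the user's normalized data with
# stratified standard-normal noise (P = R + eps * L), feeds the perturbed
# set to the WGAN, and harvests a synthetic dataset at every epoch where
# all three per-channel Wasserstein tolerances hold, with at least
# `epoch_separation` epochs between harvests.

#' Latin hypercube sample from the standard normal
#'
#' For each column, `[0, 1]` is split into `n` equal-probability strata,
#' one uniform draw is taken per stratum, the draws are randomly permuted,
#' and mapped through the standard-normal quantile function — so each
#' column contains exactly one value per stratum.
#'
#' @param n number of samples (rows).
#' @param m number of columns (one per feature).
#' @param seed optional RNG seed (`NULL`: use the current RNG state).
#' @return `n x m` matrix of stratified N(0,1) draws.
#' @export
lhs_normal_samples <- function(n, m = 1L, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 1, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    u <- (sample.int(n) - 1L + runif(n)) / n
    out[, j] <- qnorm(u)
  }
  out
}

#' Perturb a real dataset with scaled LHS noise
#'
#' The seven-step procedure: (i) normalize each feature of the real data to
#' `[0, 1]`; (ii) draw one LHS standard-normal sample per feature, matching
#' the number of observations; (iii) form `P = R + eps * L` in normalized
#' units; (iv) scale back to each feature's original range; (v) clamp the
#' step count at >= 0 (exact zeros are physiological and preserved; the
#' strict-positivity reading is available via `strict_steps = TRUE`, which
#' floors steps at `min_positive`); (vi) re-normalize each feature of the
#' perturbed set to `[0, 1]`; (vii) the normalized matrix is what the WGAN
#' consumes.
#'
#' @param R matrix or data frame with columns (heart rate, steps) in
#'   original units.
#' @param epsilon perturbation factor (fraction, e.g. 0.03); must be >= 0.
#' @param seed optional RNG seed.
#' @param step_col index of the step-count column (default 2).
#' @param strict_steps floor steps at `min_positive` instead of 0.
#' @param min_positive strict-positivity floor (default 1).
#' @return List of class `cw_perturbed`: `values` (original units, after
#'   clamping), `normalized` (`[0, 1]` units for the WGAN), `real_range`
#'   (per-feature min/max of the real data, used for step iv),
#'   `perturbed_range` (per-feature min/max of the perturbed data, used for
#'   step vi and for inverse-scaling synthetic output), `epsilon`.
#' @export
perturb_dataset <- function(R, epsilon, seed = NULL, step_col = 2L,
                            strict_steps = FALSE, min_positive = 1) {
  if (epsilon < 0) stop("perturb_dataset: epsilon must be >= 0")
  R <- as.matrix(R)
  mins <- apply(R, 2L, min); maxs <- apply(R, 2L, max)
  if (any(maxs - mins <= 0))
    stop("perturb_dataset: degenerate (constant) feature")
  Rn <- sweep(sweep(R, 2L, mins, "-"), 2L, maxs - mins, "/")     # (i)
  L <- lhs_normal_samples(nrow(R), ncol(R), seed)                 # (ii)
  Pn <- Rn + epsilon * L                                          # (iii)
  P <- sweep(sweep(Pn, 2L, maxs - mins, "*"), 2L, mins, "+")      # (iv)
  floor_val <- if (strict_steps) min_positive else 0               # (v)
  P[, step_col] <- pmax(P[, step_col], floor_val)
  pmins <- apply(P, 2L, min); pmaxs <- apply(P, 2L, max)
  if (any(pmaxs - pmins <= 0))
    stop("perturb_dataset: perturbed feature collapsed to a constant")
  Pn2 <- sweep(sweep(P, 2L, pmins, "-"), 2L, pmaxs - pmins, "/")  # (vi)
  structure(list(values = P, normalized = Pn2,
                 real_range = rbind(min = mins, max = maxs),
                 perturbed_range = rbind(min = pmins, max = pmaxs),
                 epsilon = epsilon),
            class = "cw_perturbed")
}

#' Population-generation configuration
#'
#' @param realizations independent WGAN realizations per (user, epsilon).
#' @param epoch_separation minimum epochs between harvests (default 1000).
#' @param max_epochs epoch cap per realization (default 50000).
#' @param seed base seed; realization seeds are derived deterministically.
#' @export
perturbation_config <- function(realizations = 3L, epoch_separation = 1000L,
                                max_epochs = 50000L, seed = 1L) {
  stopifnot(realizations >= 1, epoch_separation >= 1, max_epochs >= 1)
  structure(list(realizations = as.integer(realizations),
                 epoch_separation = as.integer(epoch_separation),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "cw_perturbconfig")
}

#' Grow a synthetic population cohort
#'
#' For every (user, epsilon, realization) triple: draw a fresh LHS
#' perturbation of the user's data, train the WGAN on the perturbed set,
#' and at every `check_every`-epoch convergence check harvest the synthetic
#' dataset if all three channel tolerances (vs the perturbed data) hold and
#' at least `epoch_separation` epochs have passed since the previous
#' harvest (counting from epoch 0). Realizations that yield no harvest are
#' counted as failed but do not abort the run.
#'
#' @param users named list of user data matrices (columns heart rate,
#'   steps, original units).
#' @param epsilon_grid numeric vector of perturbation factors (<= 0.03
#'   recommended).
#' @param config a [perturbation_config()].
#' @param train a [train_config()] providing tolerances, cadence, optimizer
#'   settings; `channels` is forced to all three.
#' @return Object of class `cw_cohort`: list with `members` (each a list
#'   `synthetic`, `user`, `epsilon`, `realization`, `epoch`), `counts`
#'   (data frame of harvests per realization), `failed` (number of
#'   zero-harvest realizations).
#' @export
generate_population <- function(users, epsilon_grid, config = perturbation_config(),
                                train = train_config()) {
  stopifnot(inherits(config, "cw_perturbconfig"), length(users) >= 1)
  if (is.null(names(users))) names(users) <- paste0("user", seq_along(users))
  tol <- c(rhr = train$rhr_tol, ahr = train$ahr_tol, ohr = train$ohr_tol)
  members <- list()
  counts <- list()
  failed <- 0L
  run_id <- 0L
  for (uname in names(users)) {
    real <- as.matrix(users[[uname]])
    for (eps in epsilon_grid) {
      for (rz in seq_len(config$realizations)) {
        run_id <- run_id + 1L
        rseed <- (config$seed * 10007L + run_id * 7919L) %% .Machine$integer.max
        set.seed(rseed)
        pert <- perturb_dataset(real, eps)
        pv <- pert$values
        pv_has <- vapply(c("rhr", "ahr", "ohr"),
                         function(ch) length(channel_values(pv, ch)) > 0,
                         logical(1))
        sc <- pert$normalized * 2 - 1 # [0,1] -> (-1,1) for tanh output
        nets <- init_networks(generator_spec(output_dim = ncol(real)),
                              critic_spec(input_dim = ncol(real)),
                              seed = rseed)
        epochs <- 0L
        last_harvest <- 0L
        n_harvest <- 0L
        ok <- TRUE
        while (epochs < config$max_epochs && ok) {
          chunk <- min(train$check_every, config$max_epochs - epochs)
          res <- wgan_run_cpp(nets$params, nets$cache, sc, chunk,
                              train$batch_size, train$critic_steps,
                              train$learning_rate, 0.01, nets$gspec$noise_dim)
          if (!res$finite) {
            warning("generate_population: realization diverged (user ", uname,
                    ", eps ", eps, ", realization ", rz, ")")
            ok <- FALSE
            break
          }
          nets$params <- res$params
          nets$cache <- res$cache
          epochs <- epochs + chunk
          ng <- max(nrow(real), train$gate_sample)
          S <- wgan_generate_cpp(nets$params, ng, nets$gspec$noise_dim)
          Sn <- (S + 1) / 2
          gate_synth <- sweep(sweep(Sn, 2L, pert$perturbed_range["max", ] -
                                      pert$perturbed_range["min", ], "*"),
                              2L, pert$perturbed_range["min", ], "+")
          gate_synth[, 2L] <- pmax(gate_synth[, 2L], 0)
          synth <- gate_synth[seq_len(nrow(real)), , drop = FALSE]
          d <- vapply(c("rhr", "ahr", "ohr"), function(ch)
            suppressWarnings(pdf_delta(pv, gate_synth, ch)), numeric(1))
          met <- all(!pv_has | is.infinite(tol) | (!is.na(d) & d < tol))
          if (met && (epochs - last_harvest) >= config$epoch_separation) {
            n_harvest <- n_harvest + 1L
            last_harvest <- epochs
            members[[length(members) + 1L]] <- list(
              synthetic = data.frame(heart_rate = synth[, 1L],
                                     steps = synth[, 2L]),
              user = uname, epsilon = eps, realization = rz, epoch = epochs,
              pdf_deltas = d)
          }
        }
        if (n_harvest == 0L) failed <- failed + 1L
        counts[[length(counts) + 1L]] <-
          data.frame(user = uname, epsilon = eps, realization = rz,
                     n_harvests = n_harvest, epochs_run = epochs)
      }
    }
  }
  structure(list(members = members, counts = do.call(rbind, counts),
                 failed = failed),
            class = "cw_cohort")
}

#' @export
print.cw_cohort <- function(x, ...) {
  cat("<synthetic cohort>", length(x$members), "members from",
      nrow(x$counts), "realizations (", x$failed, "failed )\n")
  invisible(x)
}
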