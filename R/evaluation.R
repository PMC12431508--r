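# Patient-level evaluation: confusion matrix against the RHR proxy label
# (or known ground truth), F1 / false-negative-rate metrics, and the
# (Delta, nabla) threshold-uncertainty sweep with empirical confidence
# bands.

#' Patient-level labels from alert series
#'
#' Aggregates each user's scored windows to their maximum RHR and maximum
#' Hellinger score, then applies the strict-inequality rules: a patient is
#' observed sick when `max_rhr > nabla` and predicted sick when
#' `max_score > delta`.
#'
#' @param alerts a `cw_alerts` data frame or named list of them (one per
#'   user); each must carry `user`, `rhr`, `score` columns.
#' @param delta Hellinger threshold.
#' @param nabla RHR margin in bpm, or a named numeric vector of per-user
#'   adaptive bounds.
#' @return Data frame with `user`, `max_rhr`, `max_score`, `nabla`,
#'   `observed_sick`, `predicted_sick`. Users with zero scored windows are
#'   excluded (attribute `excluded`).
#' @export
label_patients <- function(alerts, delta = 0.008, nabla = 100) {
  if (is.data.frame(alerts)) alerts <- split(alerts, alerts$user)
  excluded <- character(0)
  rows <- list()
  for (u in names(alerts)) {
    a <- alerts[[u]]
    if (!nrow(a)) { excluded <- c(excluded, u); next }
    nb <- if (length(nabla) > 1L) {
      if (is.null(names(nabla)) || !u %in% names(nabla))
        stop("label_patients: no nabla for user ", u)
      nabla[[u]]
    } else nabla
    rows[[u]] <- data.frame(user = u, max_rhr = max(a$rhr),
                            max_score = max(a$score), nabla = nb)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("label_patients: no users with scored windows")
  out$observed_sick <- out$max_rhr > out$nabla
  out$predicted_sick <- out$max_score > delta
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Confusion matrix over patients
#'
#' @param labels data frame from [label_patients()]; the reference column
#'   defaults to the RHR proxy `observed_sick` but any logical column (e.g.
#'   simulator ground truth merged in) can be named via `truth`.
#' @param truth name of the reference logical column.
#' @return Object of class `cw_confusion`: list `tp`, `tn`, `fp`, `fn`
#'   (partitioning the patients).
#' @export
confusion_counts <- function(labels, truth = "observed_sick") {
  obs <- labels[[truth]]
  pred <- labels$predicted_sick
  structure(list(tp = sum(obs & pred), tn = sum(!obs & !pred),
                 fp = sum(!obs & pred), fn = sum(obs & !pred)),
            class = "cw_confusion")
}

#' F1 score and false negative rate
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; `FNR = FN / (TP + FN)`. An undefined
#' metric (empty denominator) is returned as `NA`, never coerced to 0.
#'
#' @param cm a `cw_confusion` object.
#' @return Named list `f1`, `fnr`.
#' @export
f1_fnr <- function(cm) {
  stopifnot(inherits(cm, "cw_confusion"))
  denom_f1 <- 2 * cm$tp + cm$fp + cm$fn
  denom_fnr <- cm$tp + cm$fn
  list(f1 = if (denom_f1 > 0) 2 * cm$tp / denom_f1 else NA_real_,
       fnr = if (denom_fnr > 0) cm$fn / denom_fnr else NA_real_)
}

#' Threshold-uncertainty sweep with confidence bands
#'
#' Relabels the cohort at every point of a `(Delta, nabla)` grid and
#' records F1 and FNR, then summarizes uncertainty as empirical confidence
#' bands: at each Delta, the (1-ci)/2 and (1+ci)/2 quantiles of the metric
#' across the nabla grid, and vice versa.
#'
#' @param labels data frame with `user`, `max_rhr`, `max_score` (e.g. from
#'   [label_patients()]); thresholds are re-applied internally.
#' @param delta_grid Hellinger thresholds (default `seq(0.005, 0.02,
#'   0.0005)`).
#' @param nabla_grid RHR margins in bpm (default `90:110`).
#' @param ci_level confidence level for the bands (default 0.90).
#' @param truth optional name of a logical ground-truth column in `labels`
#'   to score against instead of the RHR proxy (the proxy then still drives
#'   nothing; FNR/F1 use the fixed truth at every grid point).
#' @return Object of class `cw_sweep`: list with `grid` (data frame
#'   `delta`, `nabla`, `tp`, `fp`, `fn`, `tn`, `f1`, `fnr`), `ci_by_delta`,
#'   `ci_by_nabla` (band data frames), `ci_level`.
#' @export
uncertainty_sweep <- function(labels, delta_grid = seq(0.005, 0.02, by = 5e-4),
                              nabla_grid = 90:110, ci_level = 0.90,
                              truth = NULL) {
  stopifnot(all(c("max_rhr", "max_score") %in% names(labels)))
  rows <- vector("list", length(delta_grid) * length(nabla_grid))
  i <- 0L
  for (dl in delta_grid) for (nb in nabla_grid) {
    obs <- if (is.null(truth)) labels$max_rhr > nb else labels[[truth]]
    pred <- labels$max_score > dl
    cm <- structure(list(tp = sum(obs & pred), tn = sum(!obs & !pred),
                         fp = sum(!obs & pred), fn = sum(obs & !pred)),
                    class = "cw_confusion")
    met <- f1_fnr(cm)
    i <- i + 1L
    rows[[i]] <- data.frame(delta = dl, nabla = nb, tp = cm$tp, fp = cm$fp,
                            fn = cm$fn, tn = cm$tn, f1 = met$f1,
                            fnr = met$fnr)
  }
  grid <- do.call(rbind, rows)
  lo <- (1 - ci_level) / 2; hi <- 1 - lo
  band <- function(split_col, over_col) {
    sp <- split(grid, grid[[split_col]])
    do.call(rbind, lapply(sp, function(g) {
      qs <- function(v) if (all(is.na(v))) c(NA_real_, NA_real_)
        else quantile(v, c(lo, hi), na.rm = TRUE, names = FALSE)
      f <- qs(g$f1); r <- qs(g$fnr)
      data.frame(value = g[[split_col]][1L], f1_lo = f[1L], f1_hi = f[2L],
                 fnr_lo = r[1L], fnr_hi = r[2L])
    }))
  }
  structure(list(grid = grid,
                 ci_by_delta = band("delta", "nabla"),
                 ci_by_nabla = band("nabla", "delta"),
                 ci_level = ci_level),
            class = "cw_sweep")
}

#' @export
print.cw_sweep <- function(x, ...) {
  cat("<threshold sweep>", nrow(x$grid), "grid points; delta in [",
      min(x$grid$delta), ",", max(x$grid$delta), "], nabla in [",
      min(x$grid$nabla), ",", max(x$grid$nabla), "];",
      x$ci_level * 100, "% bands\n")
  invisible(x)
}
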