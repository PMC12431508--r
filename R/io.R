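# CSV readers/writers and the end-to-end pipeline driver.
#
# Wearables CSV: one row per record, header `user,datetime,heart_rate,steps`
# with ISO-8601 UTC datetimes. Labels CSV: `user,onset,end`. Alerts CSV:
# `user,window_start,window_end,rhr,steps,score,threshold,is_anomaly`.

TS_FMT <- "%Y-%m-%dT%H:%M:%SZ"

format_ts <- function(x) format(x, TS_FMT, tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = TS_FMT)
  retry <- is.na(out)
  if (any(retry)) # accept "YYYY-mm-dd HH:MM:SS" too
    out[retry] <- as.POSIXct(x[retry], tz = "UTC",
                             format = "%Y-%m-%d %H:%M:%S")
  out
}

#' Read a wearables CSV into per-user vitals series
#'
#' Malformed rows (unparseable datetime, non-numeric or out-of-range
#' vitals) are dropped, counted, and reported via attribute `rejects` and a
#' warning; records are time-sorted per user. gzip-compressed files are
#' accepted.
#'
#' @param path CSV path with header `user,datetime,heart_rate,steps`.
#' @return Named list of `cw_vitals`, one per user id (empty list, with a
#'   warning, for a header-only file). Attribute `rejects` gives the number
#'   of dropped rows.
#' @export
read_vitals_csv <- function(path) {
  if (!file.exists(path)) stop("read_vitals_csv: no such file: ", path)
  dt <- data.table::fread(path, showProgress = FALSE,
                          colClasses = list(character = c("user", "datetime")))
  missing <- setdiff(c("user", "datetime", "heart_rate", "steps"), names(dt))
  if (length(missing))
    stop("read_vitals_csv: missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(dt)) {
    warning("read_vitals_csv: empty file (header only)")
    return(structure(list(), rejects = 0L))
  }
  ts <- parse_ts(as.character(dt$datetime))
  hr <- suppressWarnings(as.numeric(dt$heart_rate))
  st <- suppressWarnings(as.numeric(dt$steps))
  bad <- is.na(ts) | is.na(hr) | is.na(st) | hr <= 20 | hr >= 250 | st < 0
  if (any(bad))
    warning("read_vitals_csv: dropped ", sum(bad), " malformed row(s)")
  keep <- which(!bad)
  users <- split(keep, dt$user[keep])
  out <- lapply(names(users), function(u) {
    i <- users[[u]][order(ts[users[[u]]])]
    vitals_series(u, ts[i], hr[i], st[i])
  })
  names(out) <- names(users)
  structure(out, rejects = sum(bad))
}

#' Write per-user vitals series to a wearables CSV
#' @param series_list named list of `cw_vitals` (or a single one).
#' @param path output path.
#' @export
write_vitals_csv <- function(series_list, path) {
  if (inherits(series_list, "cw_vitals")) series_list <- list(series_list)
  dt <- data.table::rbindlist(lapply(series_list, function(s)
    data.table::data.table(user = s$user_id,
                           datetime = format_ts(s$records$timestamp),
                           heart_rate = s$records$heart_rate,
                           steps = s$records$steps)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write/read episode labels (`user,onset,end`)
#' @param labels data frame with `user`, `onset`, `end`.
#' @param path CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  out <- data.frame(user = labels$user, onset = format_ts(labels$onset),
                    end = format_ts(labels$end))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE,
                          colClasses = list(character = c("user", "onset", "end")))
  data.frame(user = dt$user, onset = parse_ts(as.character(dt$onset)),
             end = parse_ts(as.character(dt$end)))
}

#' Write/read an alerts CSV
#' @param alerts a `cw_alerts` data frame (or plain data frame with the
#'   alert columns).
#' @param path CSV path.
#' @export
write_alerts_csv <- function(alerts, path) {
  out <- as.data.frame(alerts)
  out$window_start <- format_ts(out$window_start)
  out$window_end <- format_ts(out$window_end)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_alerts_csv
#' @export
read_alerts_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path, showProgress = FALSE,
    colClasses = list(character = c("user", "window_start", "window_end"))))
  dt$window_start <- parse_ts(as.character(dt$window_start))
  dt$window_end <- parse_ts(as.character(dt$window_end))
  dt
}

#' Pipeline run configuration
#'
#' Defaults are the selected operating points throughout: 1-h window with
#' 30-min slide, `delta = 0.008`, fixed `nabla = 100` (or the adaptive
#' 90th-percentile bound), grid cap 2500, 7 calibration days.
#'
#' @param window,slide window spec in seconds.
#' @param delta Hellinger alert threshold.
#' @param nabla fixed RHR margin in bpm.
#' @param adaptive_rhr use the per-user adaptive bound instead of `nabla`.
#' @param grid_cap reference-grid point cap.
#' @param calibration_days healthy calibration period in days.
#' @param min_coverage minimum window coverage fraction.
#' @param n_users,days,sick_fraction simulated-cohort shape.
#' @param seed run seed.
#' @param out output directory.
#' @export
run_config <- function(window = 3600, slide = 1800, delta = 0.008,
                       nabla = 100, adaptive_rhr = TRUE, grid_cap = 2500L,
                       calibration_days = 7, min_coverage = 0.5,
                       n_users = 60L, days = 28, sick_fraction = 1 / 3,
                       seed = 1L, out = tempfile("cowear_run_")) {
  spec <- window_spec(window, slide) # validates s <= w
  if (delta <= 0) stop("run_config: delta must be > 0")
  structure(list(spec = spec, delta = delta, nabla = nabla,
                 adaptive_rhr = adaptive_rhr, grid_cap = as.integer(grid_cap),
                 calibration_days = calibration_days,
                 min_coverage = min_coverage, n_users = as.integer(n_users),
                 days = days, sick_fraction = sick_fraction,
                 seed = as.integer(seed), out = out),
            class = "cw_runconfig")
}

#' Detect anomalies for one user end-to-end
#'
#' Convenience wrapper: windows the series, estimates healthy ranges from
#' the calibration period, builds the reference grid, picks the fixed or
#' adaptive RHR bound, and scores every usable window.
#'
#' @param series a `cw_vitals`.
#' @param config a [run_config()].
#' @param sick_intervals optional known sick intervals excluded from
#'   calibration.
#' @return List: `alerts` (`cw_alerts`), `features`, `grid`, `nabla`.
#' @export
detect_user <- function(series, config = run_config(), sick_intervals = NULL) {
  features <- stream_process(series, config$spec,
                             min_coverage = config$min_coverage)
  ranges <- estimate_healthy_ranges(features, config$calibration_days,
                                    sick_intervals)
  grid <- build_reference_grid(ranges, config$grid_cap)
  nabla <- if (config$adaptive_rhr)
    adaptive_rhr_bound(features)$nabla else config$nabla
  alerts <- detect_anomalies(features, grid, config$delta,
                             user_id = series$user_id)
  list(alerts = alerts, features = features, grid = grid, nabla = nabla)
}

#' Run the simulate -> detect -> evaluate pipeline
#'
#' Simulates a cohort, runs per-user detection, writes the cohort,
#' labels, alerts and sweep CSVs plus a manifest JSON under `config$out`,
#' and returns the in-memory artifacts.
#'
#' @param config a [run_config()].
#' @return List: `alerts` (combined data frame), `labels_df` (patient
#'   labels with ground truth), `sweep` (`cw_sweep`), `metrics` (F1/FNR at
#'   the operating point vs ground truth), `manifest`, `out`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config$n_users, config$sick_fraction,
                            config$days, seed = config$seed)
  write_vitals_csv(lapply(cohort, `[[`, "series"),
                   file.path(config$out, "cohort.csv"))
  lab_rows <- do.call(rbind, lapply(cohort, function(u)
    if (nrow(u$labels)) cbind(user = u$series$user_id, u$labels) else NULL))
  if (!is.null(lab_rows))
    write_labels_csv(lab_rows, file.path(config$out, "labels.csv"))
  alerts <- list()
  nablas <- c()
  truth <- c()
  for (u in cohort) {
    det <- detect_user(u$series, config, sick_intervals = u$labels)
    alerts[[u$series$user_id]] <- det$alerts
    nablas[u$series$user_id] <- det$nabla
    truth[u$series$user_id] <- u$sick
  }
  all_alerts <- do.call(rbind, lapply(alerts, as.data.frame))
  rownames(all_alerts) <- NULL
  write_alerts_csv(all_alerts, file.path(config$out, "alerts.csv"))
  labels_df <- label_patients(alerts, config$delta, nablas)
  labels_df$true_sick <- truth[labels_df$user]
  sweep <- uncertainty_sweep(labels_df)
  data.table::fwrite(sweep$grid, file.path(config$out, "sweep.csv"))
  metrics <- f1_fnr(confusion_counts(labels_df, truth = "true_sick"))
  manifest <- list(package = "cowear",
                   version = as.character(utils::packageVersion("cowear")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "spec")],
                   window = config$spec$window, slide = config$spec$slide,
                   n_users = length(cohort),
                   metrics = metrics)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  list(alerts = all_alerts, labels_df = labels_df, sweep = sweep,
       metrics = metrics, manifest = manifest, out = config$out)
}
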