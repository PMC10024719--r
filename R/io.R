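# Plain-text trial round-trip: delimited sensor/speed tables plus a
# JSON-dialect label file.

TRACE_COLS <- c("time_s", "acc_ap", "acc_ml", "acc_v",
                "gyr_x", "gyr_y", "gyr_z")
SPEED_COLS <- c("time_s", "speed_mps")

#' Write / read a trial directory
#'
#' A trial is stored as three plain-text files in `path`: `imu.csv`
#' (200 Hz, columns `time_s, acc_ap, acc_ml, acc_v, gyr_x, gyr_y,
#' gyr_z`), `gnss.csv` (10 Hz, `time_s, speed_mps`) and `labels.json`
#' (per-COD start/end, test start, photocell time). Unknown extra
#' columns are ignored with a warning; missing required columns or
#' non-numeric rows raise a parse error naming the file and line.
#'
#' @param trace an [inertial_trace()].
#' @param speed a [gnss_speed_trace()].
#' @param labels a `reference_labels` object.
#' @param path directory to create/fill.
#' @param truth optional `ground_truth`, stored as `truth.json`
#'   (synthetic ground truth, available for benchmarking only).
#' @return `write_trial` returns `path` invisibly; `read_trial` a list
#'   `trace`, `speed`, `labels` (+ `truth` when present).
#' @export
write_trial <- function(trace, speed, labels, path, truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gyr <- trace$gyr %||% matrix(0, length(trace$time_s), 3)
  df <- data.frame(time_s = trace$time_s, acc_ap = trace$acc_ap,
                   acc_ml = trace$acc_ml %||% 0,
                   acc_v = trace$acc_v %||% 0,
                   gyr_x = gyr[, 1], gyr_y = gyr[, 2], gyr_z = gyr[, 3])
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   file.path(path, "imu.csv"), row.names = FALSE,
                   quote = FALSE)
  sp <- data.frame(time_s = speed$time_s, speed_mps = speed$speed_mps)
  utils::write.csv(format(sp, digits = 12, trim = TRUE, scientific = FALSE),
                   file.path(path, "gnss.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(labels), file.path(path, "labels.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(truth)) {
    tt <- list(t_start_s = truth$timeline$t_start_s,
               cod = truth$timeline$cod,
               t_end_s = truth$timeline$t_end_s,
               photocell_time_s = truth$photocell_time_s,
               cone_touch_times_s = truth$cone_touch_times_s)
    jsonlite::write_json(tt, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

read_table_checked <- function(file, required) {
  if (!file.exists(file))
    codseg_stop("codseg_parse_error", "missing file: %s", file)
  df <- tryCatch(utils::read.csv(file, check.names = TRUE),
                 error = function(e)
                   codseg_stop("codseg_parse_error", "%s: %s", file,
                               conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    codseg_stop("codseg_parse_error", "%s: missing column(s) %s",
                file, paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s) %s", file,
                    paste(extra, collapse = ", ")), call. = FALSE)
    df <- df[required]
  }
  for (cn in required) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      codseg_stop("codseg_parse_error",
                  "%s: non-numeric value in column %s at line %d",
                  file, cn, which(is.na(v))[1] + 1L)
    df[[cn]] <- v
  }
  df
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  imu <- read_table_checked(file.path(path, "imu.csv"), TRACE_COLS)
  sp <- read_table_checked(file.path(path, "gnss.csv"), SPEED_COLS)
  fs_imu <- 1 / stats::median(diff(imu$time_s))
  fs_gnss <- 1 / stats::median(diff(sp$time_s))
  lf <- file.path(path, "labels.json")
  if (!file.exists(lf))
    codseg_stop("codseg_parse_error", "missing file: %s", lf)
  lr <- tryCatch(jsonlite::read_json(lf, simplifyVector = TRUE),
                 error = function(e)
                   codseg_stop("codseg_parse_error", "%s: %s", lf,
                               conditionMessage(e)))
  labels <- structure(list(cod_events = as.data.frame(lr$cod_events),
                           photocell_time_s = lr$photocell_time_s,
                           t_start_s = lr$t_start_s,
                           frame_rate_hz = lr$frame_rate_hz %||% 60),
                      class = "reference_labels")
  out <- list(
    trace = inertial_trace(imu$time_s, imu$acc_ap, imu$acc_ml, imu$acc_v,
                           gyr = as.matrix(imu[c("gyr_x", "gyr_y",
                                                 "gyr_z")]),
                           fs_hz = round(fs_imu)),
    speed = gnss_speed_trace(sp$time_s, sp$speed_mps,
                             fs_hz = round(fs_gnss)),
    labels = labels)
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    out$truth <- structure(
      list(timeline = event_timeline(tr$t_start_s,
                                     as.data.frame(tr$cod), tr$t_end_s),
           photocell_time_s = tr$photocell_time_s,
           cone_touch_times_s = tr$cone_touch_times_s),
      class = "ground_truth")
  }
  out
}
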