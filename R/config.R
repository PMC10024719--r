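# Pipeline configuration: every detection threshold and constant in one
# place, serializable to a JSON-dialect config file with --set
# overrides from the command line.

#' Pipeline configuration
#'
#' All thresholds and constants of the detection pipeline. Each default
#' is either a method constant (start-peak height 4 m/s^2, prominence
#' 15 m/s^2, 10 Hz order-2 low-pass, quarter-mean threshold factor,
#' 0.5-15 / 0.5-5 Hz bands, 9.14 m final phase, 1.42 m arm reach) or a
#' declared design choice (window lengths, stepping prominence floors;
#' see the methods vignette).
#'
#' @param ... named overrides of any default listed below.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    start_peak_height_mps2 = 4,     # start maxima must exceed this
    start_min_prominence_mps2 = 1,  # noise floor for start extrema
    prominence_mps2 = 15,           # ground-contact peak/trough prominence
    step_min_prominence_mps2 = 2,   # floor for minima used in stepping
    macro_band_hz = c(0.5, 15),
    micro_band_hz = c(0.5, 5),
    lowpass_fc_hz = 10,
    lowpass_order = 2L,
    t_ma_factor = 0.25,             # informational; threshold = mean/4
    L_dp5_m = 9.14,
    L_arm_m = 1.42,
    fs_imu_hz = 200,
    fs_gnss_hz = 10,
    analysis_window_s = 15,
    edge_exclude_s = 0.25,
    large_peak_window_s = 0.3,      # M2/M4 lookback/lookahead
    refine_window_s = 0.5,          # M1/M3 neighbourhood radius
    g_mps2 = 9.81,
    m2_end_rule = "positive",       # "positive" (push end fwd when value
                                    # > 0) or "negative" (legacy variant)
    method_map = list(cod1 = c(start = "M0", end = "M4"),
                      cod2 = c(start = "M2", end = "M2"),
                      cod3 = c(start = "M2", end = "M2"),
                      cod4 = c(start = "M0", end = "M0")),
    seeds = list(benchmark_base = 1L)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    codseg_stop("codseg_invalid_argument",
                "unknown config fields: %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file (JSON dialect)
#'
#' @param path file path.
#' @param cfg a [pipeline_config()].
#' @return `read_config` returns a [pipeline_config()];
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    codseg_stop("codseg_parse_error", "config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mm <- raw$method_map
  if (!is.null(mm))
    raw$method_map <- lapply(mm, function(v) {
      v <- unlist(v)
      if (is.null(names(v)) && length(v) == 2L)
        names(v) <- c("start", "end")
      v
    })
  do.call(pipeline_config, raw)
}

# Apply "--set key=value" overrides (scalars and comma-separated
# numeric vectors) onto a config.
apply_config_overrides <- function(cfg, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      codseg_stop("codseg_invalid_argument", "bad --set '%s'", s)
    val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    cfg[[kv[1]]] <- if (all(!is.na(num))) num else val
  }
  do.call(pipeline_config, unclass(cfg))
}

config_hash <- function(cfg) {
  # cheap stable digest for run logging (no digest dependency)
  s <- paste(utils::capture.output(utils::str(unclass(cfg))),
             collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 1e9
}
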