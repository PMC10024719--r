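# Validation against reference labels: signed event/duration errors,
# Bland-Altman agreement, per-participant shift detection, normality
# tests.

#' Per-COD event timing errors (reference minus estimate)
#'
#' @param est an [event_timeline()].
#' @param ref a `reference_labels` object (or an `event_timeline`).
#' @return data.frame `order`, `eps_start_ms`, `eps_end_ms`.
#' @export
event_errors <- function(est, ref) {
  ref_cod <- if (inherits(ref, "event_timeline")) ref$cod else ref$cod_events
  if (nrow(est$cod) != 4L || nrow(ref_cod) != 4L)
    codseg_stop("codseg_misaligned_detection",
                "both timelines must contain 4 CODs")
  data.frame(order = est$cod$order,
             eps_start_ms = (ref_cod$t_start_s - est$cod$t_start_s) * 1000,
             eps_end_ms = (ref_cod$t_end_s - est$cod$t_end_s) * 1000)
}

#' Per-segment duration errors
#'
#' Signed absolute error in ms and relative error in percent,
#' reference minus estimate, for the five displacement phases and four
#' CODs.
#'
#' @param est,ref [segment_durations()] objects (estimate, reference).
#' @return data.frame `segment` (DP1..DP5, COD1..COD4), `eps_abs_ms`,
#'   `eps_rel_pct`.
#' @export
duration_errors <- function(est, ref) {
  d_e <- c(est$dp_s, est$cod_s); d_r <- c(ref$dp_s, ref$cod_s)
  if (any(d_r <= 0))
    codseg_stop("codseg_degenerate_reference",
                "reference durations must be > 0")
  data.frame(segment = c(paste0("DP", 1:5), paste0("COD", 1:4)),
             eps_abs_ms = (d_r - d_e) * 1000,
             eps_rel_pct = (d_r - d_e) / d_r * 100)
}

#' Completion-time error (reference minus estimate)
#'
#' @param T_refc,T_estc completion durations (s).
#' @return signed error (s).
#' @export
completion_error <- function(T_refc, T_estc) T_refc - T_estc

#' Bland-Altman agreement statistics
#'
#' Bias is the mean difference; the 95% limits of agreement are
#' `bias +/- 1.96 * SD` (sample SD, n-1 denominator). When the paired
#' values are supplied, a least-squares slope of difference against
#' pair mean screens for a systematic trend.
#'
#' @param x differences, or (with `y`) the first measurement.
#' @param y optional second measurement; differences are `x - y`.
#' @return list `bias`, `loa_low`, `loa_high`, `trend_slope`, `n`.
#' @export
bland_altman <- function(x, y = NULL) {
  if (is.null(y)) {
    diffs <- x; means <- NULL
  } else {
    diffs <- x - y; means <- (x + y) / 2
  }
  n <- length(diffs)
  if (n < 3L)
    codseg_stop("codseg_insufficient_data",
                "Bland-Altman needs >= 3 differences")
  bias <- mean(diffs); s <- stats::sd(diffs)
  slope <- if (is.null(means)) NA_real_
           else if (stats::var(means) == 0) 0
           else unname(stats::coef(stats::lm(diffs ~ means))[2])
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       trend_slope = slope, n = n)
}

#' Per-participant systematic shift detection
#'
#' A shift is flagged when the mean error magnitude exceeds its SD:
#' positive when `mean > SD`, negative when `mean < -SD`, none
#' otherwise; participants with a single observation are undetermined.
#'
#' @param errors_by_participant named list of numeric error vectors.
#' @return named character vector of flags
#'   (`"positive"`, `"negative"`, `"none"`, `"undetermined"`).
#' @export
detect_shift <- function(errors_by_participant) {
  vapply(errors_by_participant, function(e) {
    if (length(e) < 2L) return("undetermined")
    m <- mean(e); s <- stats::sd(e)
    if (m > s) "positive" else if (m < -s) "negative" else "none"
  }, character(1))
}

#' Normality test for an error family
#'
#' Event-timing errors are tested with the Kolmogorov-Smirnov test
#' (against a normal with moments estimated from the sample; the
#' Lilliefors-corrected p-value is available via Monte Carlo), and
#' completion-time errors with the Shapiro-Wilk test.
#'
#' @param errors numeric vector.
#' @param family `"event"` (KS) or `"completion"` (Shapiro-Wilk).
#' @param lilliefors for the KS family, correct the p-value for the
#'   estimated parameters by Monte Carlo (default plain KS).
#' @param mc_reps Monte Carlo replicates for the Lilliefors correction.
#' @return list `statistic`, `p_value`, `method`.
#' @export
normality <- function(errors, family = c("event", "completion"),
                      lilliefors = FALSE, mc_reps = 2000L) {
  family <- match.arg(family)
  n <- length(errors)
  if (family == "event") {
    if (n < 5L)
      codseg_stop("codseg_insufficient_data",
                  "KS with estimated moments needs n >= 5")
    if (stats::sd(errors) == 0)
      codseg_stop("codseg_insufficient_data",
                  "constant sample has no normality test")
    ht <- suppressWarnings(
      stats::ks.test(errors, "pnorm", mean(errors), stats::sd(errors)))
    p <- ht$p.value
    if (lilliefors) {
      d0 <- unname(ht$statistic)
      sims <- vapply(seq_len(mc_reps), function(i) {
        z <- stats::rnorm(n)
        unname(suppressWarnings(
          stats::ks.test(z, "pnorm", mean(z), stats::sd(z)))$statistic)
      }, numeric(1))
      p <- mean(sims >= d0)
    }
    list(statistic = unname(ht$statistic), p_value = p,
         method = if (lilliefors) "ks-lilliefors" else "ks")
  } else {
    if (n < 3L)
      codseg_stop("codseg_insufficient_data", "Shapiro-Wilk needs n >= 3")
    if (stats::sd(errors) == 0)
      codseg_stop("codseg_insufficient_data",
                  "constant sample has no normality test")
    ht <- stats::shapiro.test(errors)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "shapiro-wilk")
  }
}

#' Assemble a validation report for a set of trials
#'
#' @param event_err data.frame rbind of [event_errors()] rows (pooled).
#' @param duration_err data.frame rbind of [duration_errors()] rows.
#' @param completion_err numeric vector of completion errors (s).
#' @param errors_by_participant optional named list for shift flags.
#' @return object of class `validation_report`.
#' @export
validation_report <- function(event_err, duration_err, completion_err,
                              errors_by_participant = NULL) {
  pooled <- c(event_err$eps_start_ms, event_err$eps_end_ms)
  ba <- bland_altman(pooled)
  structure(list(
    event_errors = event_err,
    duration_errors = duration_err,
    completion_errors_s = completion_err,
    bias_ms = ba$bias, loa_low_ms = ba$loa_low, loa_high_ms = ba$loa_high,
    shift_flags = if (!is.null(errors_by_participant))
      detect_shift(errors_by_participant) else NULL,
    normality_p = list(
      event = tryCatch(normality(pooled, "event")$p_value,
                       codseg_error = function(e) NA_real_),
      completion = tryCatch(
        normality(completion_err, "completion")$p_value,
        codseg_error = function(e) NA_real_))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d events, bias %.1f ms, LOA [%.1f, %.1f] ms\n",
              2L * nrow(x$event_errors), x$bias_ms, x$loa_low_ms,
              x$loa_high_ms))
  if (length(x$completion_errors_s))
    cat(sprintf("  completion error %.3f +/- %.3f s (n=%d)\n",
                mean(x$completion_errors_s), stats::sd(x$completion_errors_s),
                length(x$completion_errors_s)))
  invisible(x)
}
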