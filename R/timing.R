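# Completion time from GNSS ground speed, segment durations, and
# cohort performance metrics.

#' Event timeline of one T-test trial
#'
#' @param t_start_s test start, first-step convention (s).
#' @param cod data.frame with columns `order` (1..4), `angle_deg`
#'   (90/180), `t_start_s`, `t_end_s`.
#' @param t_end_s test end (s); may be `NA` until the GNSS-based
#'   estimate fills it in.
#' @return object of class `event_timeline`.
#' @export
event_timeline <- function(t_start_s, cod, t_end_s = NA_real_) {
  if (!is.data.frame(cod) || nrow(cod) != 4L ||
      !all(c("order", "angle_deg", "t_start_s", "t_end_s") %in% names(cod)))
    codseg_stop("codseg_invalid_timeline",
                "cod must be a 4-row data.frame of start/end events")
  cod <- cod[order(cod$order), , drop = FALSE]
  seqv <- c(t_start_s, rbind(cod$t_start_s, cod$t_end_s))
  if (!is.na(t_end_s)) seqv <- c(seqv, t_end_s)
  if (any(!is.finite(seqv)) || any(diff(seqv) <= 0))
    codseg_stop("codseg_invalid_timeline",
                "timeline events must be finite and strictly increasing")
  structure(list(t_start_s = t_start_s, cod = cod, t_end_s = t_end_s),
            class = "event_timeline")
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline> start %.3f s, end %s s\n", x$t_start_s,
              if (is.na(x$t_end_s)) "NA" else sprintf("%.3f", x$t_end_s)))
  for (k in 1:4)
    cat(sprintf("  COD%d (%3d deg): %.3f - %.3f s\n", x$cod$order[k],
                x$cod$angle_deg[k], x$cod$t_start_s[k], x$cod$t_end_s[k]))
  invisible(x)
}

#' Estimate the test-end instant by integrating GNSS ground speed
#'
#' Finds the smallest time `T` such that the trapezoidal integral of the
#' ground speed from the end of the last COD up to `T` equals the final
#' phase length minus the arm reach (the athlete touches the last cone
#' at arm's length, so the trunk covers `L_dp5 - L_arm` before crossing
#' the line). The crossing is located inside the final 10 Hz interval by
#' linear interpolation of cumulative distance.
#'
#' @param speed a [gnss_speed_trace()]; `NULL` signals the no-GNSS case.
#' @param t_cod4_end detected end of the last COD (s, absolute).
#' @param L_dp5 final phase length (m), default 9.14.
#' @param L_arm arm reach (m), default 1.42.
#' @return estimated test-end instant `T` (s, absolute, same clock as
#'   the speed trace).
#' @export
estimate_completion_time <- function(speed, t_cod4_end, L_dp5 = 9.14,
                                     L_arm = 1.42) {
  if (is.null(speed))
    codseg_stop("codseg_no_gnss", "no GNSS speed trace available")
  if (!(L_dp5 > L_arm && L_arm > 0))
    codseg_stop("codseg_invalid_argument", "need L_dp5 > L_arm > 0")
  tt <- speed$time_s; vv <- speed$speed_mps
  if (t_cod4_end < tt[1] || t_cod4_end >= tt[length(tt)])
    codseg_stop("codseg_insufficient_track",
                "speed trace does not cover the final phase")
  # speed at the (sub-sample) integration start
  i0 <- findInterval(t_cod4_end, tt)
  frac <- (t_cod4_end - tt[i0]) / (tt[i0 + 1L] - tt[i0])
  v0 <- vv[i0] + frac * (vv[i0 + 1L] - vv[i0])
  tt2 <- c(t_cod4_end, tt[tt > t_cod4_end])
  vv2 <- c(v0, vv[tt > t_cod4_end])
  dist <- cumtrapz(tt2, vv2)
  target <- L_dp5 - L_arm
  if (dist[length(dist)] < target)
    codseg_stop("codseg_insufficient_track",
                "cumulative GNSS distance never reaches %.2f m", target)
  j <- which(dist >= target)[1]
  if (j == 1L) return(tt2[1])
  tt2[j - 1L] + (target - dist[j - 1L]) / (dist[j] - dist[j - 1L]) *
    (tt2[j] - tt2[j - 1L])
}

#' Durations of the nine T-test segments
#'
#' Displacement phases are the gaps between consecutive COD events (and
#' between the test boundaries and the outer CODs), so the nine
#' durations partition the total time exactly.
#'
#' @param tl an [event_timeline()] with a non-`NA` end.
#' @return object of class `segment_durations`: `dp_s` (5 values),
#'   `cod_s` (4 values).
#' @export
segment_durations <- function(tl) {
  if (!inherits(tl, "event_timeline") || is.na(tl$t_end_s))
    codseg_stop("codseg_invalid_timeline",
                "need a complete event_timeline (with t_end_s)")
  cod <- tl$cod
  dp <- c(cod$t_start_s[1] - tl$t_start_s,
          cod$t_start_s[2:4] - cod$t_end_s[1:3],
          tl$t_end_s - cod$t_end_s[4])
  structure(list(dp_s = dp, cod_s = cod$t_end_s - cod$t_start_s),
            class = "segment_durations")
}

#' Total cutting time of each COD
#'
#' Sum of the approach phase, the COD itself, and the exit phase:
#' `tct[k] = dp[k] + cod[k] + dp[k+1]`.
#'
#' @param d a [segment_durations()].
#' @return numeric vector of four total cutting times (s).
#' @export
total_cutting_time <- function(d) {
  if (!inherits(d, "segment_durations"))
    codseg_stop("codseg_invalid_argument", "need segment_durations")
  d$dp_s[1:4] + d$cod_s + d$dp_s[2:5]
}

#' Cohort-level performance summary
#'
#' Computes per-COD Pearson correlation between total cutting time and
#' completion time, and contrasts the five fastest against the five
#' slowest athletes (by completion time) on all nine segment durations.
#'
#' @param trials list; each element a list with `durations`
#'   ([segment_durations()]), `completion_time_s`, and optional `id`.
#' @return object of class `performance_summary`: `total_cutting_time_s`
#'   (n x 4 matrix), `completion_time_s`, `pearson` (data.frame `cod`,
#'   `r`, `p`), `group_means` (2 x 9 matrix, best/worst rows),
#'   `best_ids`, `worst_ids`, `tie_flag`.
#' @export
cohort_performance <- function(trials) {
  n <- length(trials)
  if (n < 10L)
    codseg_stop("codseg_insufficient_data",
                "need >= 10 trials for a 5-best / 5-worst split")
  ids <- vapply(seq_len(n), function(i) {
    as.character(trials[[i]]$id %||% i)
  }, character(1))
  ct <- vapply(trials, function(x) x$completion_time_s, numeric(1))
  segs <- t(vapply(trials, function(x)
    c(x$durations$dp_s, x$durations$cod_s), numeric(9)))
  colnames(segs) <- c(paste0("DP", 1:5), paste0("COD", 1:4))
  tct <- t(vapply(trials, function(x)
    total_cutting_time(x$durations), numeric(4)))
  colnames(tct) <- paste0("COD", 1:4)
  pearson <- do.call(rbind, lapply(1:4, function(k) {
    ht <- stats::cor.test(tct[, k], ct)
    data.frame(cod = k, r = unname(ht$estimate), p = ht$p.value)
  }))
  ord <- order(ct, seq_len(n))    # stable: earliest trial wins ties
  tie_flag <- any(duplicated(ct)) &&
    (sum(ct == sort(ct)[5]) > 1L || sum(ct == sort(ct, TRUE)[5]) > 1L)
  best <- ord[1:5]; worst <- rev(ord)[1:5]
  gm <- rbind(best = colMeans(segs[best, , drop = FALSE]),
              worst = colMeans(segs[worst, , drop = FALSE]))
  structure(list(total_cutting_time_s = tct, completion_time_s = ct,
                 pearson = pearson, group_means = gm,
                 best_ids = ids[best], worst_ids = ids[worst],
                 tie_flag = tie_flag),
            class = "performance_summary")
}
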