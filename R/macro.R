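# Macro-analysis: test-start detection, adaptive threshold (quarter of
# the mean qualifying peak), and acceleration-impulse ranking of
# candidate COD segments on the band-reconstructed AP acceleration.

#' Detect the start of the test (first-step convention)
#'
#' Low-passes the AP acceleration (zero-phase Butterworth, 10 Hz, order
#' 2), finds the first two local maxima above the start threshold (push
#' off and first-step impact), and returns the time of the local minimum
#' immediately preceding the first of them.
#'
#' @param trace an [inertial_trace()].
#' @param cfg a [pipeline_config()].
#' @return start time (s).
#' @export
detect_start <- function(trace, cfg = pipeline_config()) {
  fs <- trace$fs_hz
  x <- clip_analysis_window(trace$acc_ap, fs, cfg$analysis_window_s)
  xl <- lowpass_zero_phase(x, fs, cfg$lowpass_fc_hz, cfg$lowpass_order)
  mx <- find_extrema(xl, "max", prominence = cfg$start_min_prominence_mps2,
                     height = cfg$start_peak_height_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)
  if (nrow(mx) < 2L)
    codseg_stop("codseg_no_start",
                "fewer than two local maxima above %g m/s^2",
                cfg$start_peak_height_mps2)
  mn <- find_extrema(xl, "min", prominence = cfg$start_min_prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)
  prev <- mn$index[mn$index < mx$index[1]]
  if (!length(prev))
    codseg_stop("codseg_no_start",
                "no local minimum precedes the first start peak")
  trace$time_s[max(prev)]
}

#' Adaptive macro-analysis threshold
#'
#' One quarter of the arithmetic mean of the qualifying local maximum
#' peak values (ground-contact peaks).
#'
#' @param max_peaks numeric vector of positive peak values (m/s^2).
#' @return threshold T_MA (m/s^2).
#' @export
compute_threshold <- function(max_peaks) {
  if (!length(max_peaks))
    codseg_stop("codseg_no_peaks", "no qualifying maxima for the threshold")
  mean(max_peaks) / 4
}

#' Acceleration impulse over a sample interval
#'
#' Trapezoidal time-integral of the AP acceleration between two sample
#' indices; approximates the change of velocity during a foot stance.
#'
#' @param acc_ap numeric AP acceleration (m/s^2).
#' @param fs sampling rate (Hz).
#' @param i0,i1 bounding sample indices, `i0 <= i1`.
#' @return impulse (m/s).
#' @export
acceleration_impulse <- function(acc_ap, fs, i0, i1) {
  if (i0 > i1 || i0 < 1L || i1 > length(acc_ap))
    codseg_stop("codseg_bad_interval",
                "indices [%d, %d] outside signal of length %d",
                i0, i1, length(acc_ap))
  if (i0 == i1) return(0)
  trapz(seq.int(i0, i1) / fs, acc_ap[seq.int(i0, i1)])
}

clip_analysis_window <- function(x, fs, window_s) {
  n_max <- floor(window_s * fs) + 1L
  if (length(x) > n_max) x[seq_len(n_max)] else x
}

# All candidate minima for macro pairing: primary rule (value below
# -T_MA, prominence above threshold) plus a fallback that admits the
# immediate flanking minima of every qualifying maximum (asymmetric
# impacts can leave a bounding minimum positive). `rule` records which
# fired.
macro_candidate_minima <- function(xr, fs, t_ma, cfg) {
  mn <- find_extrema(xr, "min", prominence = cfg$prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)
  primary <- mn[mn$value < -t_ma, , drop = FALSE]
  mx <- find_extrema(xr, "max", prominence = cfg$prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)
  all_min <- find_extrema(xr, "min",
                          prominence = cfg$step_min_prominence_mps2,
                          fs = fs, exclude_s = cfg$edge_exclude_s)
  flank <- unlist(lapply(mx$index, function(i) {
    c(max(all_min$index[all_min$index < i], -Inf),
      min(all_min$index[all_min$index > i], Inf))
  }))
  flank <- unique(flank[is.finite(flank)])
  fallback <- setdiff(flank, primary$index)
  idx <- sort(unique(c(primary$index, fallback)))
  data.frame(index = idx, value = xr[idx],
             rule = ifelse(idx %in% primary$index, "primary", "fallback"))
}

#' Macro-analysis COD segmentation
#'
#' Reconstructs the AP acceleration in the macro band (0.5-15 Hz by
#' default, mean re-added), detects qualifying local minima (below
#' `-T_MA` with prominence above threshold, plus flanking-minima
#' fallback), integrates the signal between each pair of consecutive
#' minima, and keeps the four non-overlapping pairs with the largest
#' acceleration impulse as the COD segments. Angle classes follow the
#' fixed T-test order 90-180-180-90.
#'
#' @param trace an [inertial_trace()].
#' @param cfg a [pipeline_config()].
#' @return object of class `macro_result`: `t_first_step_s`, `minima`
#'   (all candidate minima with the rule that admitted each),
#'   `threshold_mps2` (T_MA), `segments` (4-row data.frame `order`,
#'   `angle_deg`, `start_idx`, `end_idx`, `t_start_s`, `t_end_s`,
#'   `impulse_mps`), `band_signal` (the reconstructed AP signal used).
#' @export
detect_cod_segments <- function(trace, cfg = pipeline_config()) {
  fs <- trace$fs_hz
  t_first <- detect_start(trace, cfg)
  x <- clip_analysis_window(trace$acc_ap, fs, cfg$analysis_window_s)
  xr <- wavelet_band_reconstruct(x, fs,
                                 band_spec(cfg$macro_band_hz[1],
                                           cfg$macro_band_hz[2],
                                           keep_mean = TRUE))
  mx <- find_extrema(xr, "max", prominence = cfg$prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)
  t_ma <- compute_threshold(mx$value)
  cand <- macro_candidate_minima(xr, fs, t_ma, cfg)
  # only minima from the detected start onward belong to the test
  cand <- cand[trace$time_s[cand$index] >= t_first, , drop = FALSE]
  if (nrow(cand) < 5L)
    codseg_stop("codseg_too_few_minima",
                "%d candidate minima cannot form 4 COD pairs", nrow(cand))
  pairs <- data.frame(i0 = cand$index[-nrow(cand)], i1 = cand$index[-1])
  pairs$impulse <- vapply(seq_len(nrow(pairs)), function(r)
    acceleration_impulse(xr, fs, pairs$i0[r], pairs$i1[r]), numeric(1))
  # greedy selection: largest impulse first, pairs may not share minima;
  # ties broken in favour of the earlier pair
  ord <- order(-pairs$impulse, pairs$i0)
  used <- integer(0); sel <- integer(0)
  for (r in ord) {
    if (pairs$i0[r] %in% used || pairs$i1[r] %in% used) next
    sel <- c(sel, r); used <- c(used, pairs$i0[r], pairs$i1[r])
    if (length(sel) == 4L) break
  }
  if (length(sel) < 4L)
    codseg_stop("codseg_ambiguous_segmentation",
                "best impulse pairs overlap irreconcilably")
  sel <- sel[order(pairs$i0[sel])]
  seg <- data.frame(order = 1:4, angle_deg = c(90, 180, 180, 90),
                    start_idx = pairs$i0[sel], end_idx = pairs$i1[sel],
                    t_start_s = trace$time_s[pairs$i0[sel]],
                    t_end_s = trace$time_s[pairs$i1[sel]],
                    impulse_mps = pairs$impulse[sel])
  structure(list(t_first_step_s = t_first, minima = cand,
                 threshold_mps2 = t_ma, segments = seg,
                 band_signal = xr),
            class = "macro_result")
}

#' @export
print.macro_result <- function(x, ...) {
  cat(sprintf("<macro_result> start %.3f s, T_MA %.2f m/s^2, %d minima\n",
              x$t_first_step_s, x$threshold_mps2, nrow(x$minima)))
  print(x$segments[, c("order", "angle_deg", "t_start_s", "t_end_s",
                       "impulse_mps")])
  invisible(x)
}
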