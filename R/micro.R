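# Micro-analysis: refine macro COD boundaries with methods M0-M4 and
# assemble the best-method timeline.
#
# M0 keeps the macro boundaries. M1 re-detects minima in a narrower
# wavelet band (0.5-5 Hz). M2 (180 degree CODs only) captures the
# penultimate foot contact before the turn and the second toe-off after
# it. M3 snaps to the nearest sub-g sample of the acceleration norm
# (flight phase). M4 advances the end of COD 1 past a trailing push-off
# peak.

# Local minima of the macro-band signal used for "step one minimum"
# moves; a small prominence floor skips noise wiggles.
stepping_minima <- function(xr, fs, cfg) {
  find_extrema(xr, "min", prominence = cfg$step_min_prominence_mps2,
               fs = fs, exclude_s = cfg$edge_exclude_s)$index
}

#' Micro-method M1: narrow-band minima
#'
#' Reconstructs the AP acceleration in the micro band (0.5-5 Hz) and
#' moves each macro boundary to the nearest local minimum of that
#' narrower reconstruction within the refinement window.
#'
#' @param macro a `macro_result` from [detect_cod_segments()].
#' @param trace the [inertial_trace()] the macro result came from.
#' @param cfg a [pipeline_config()].
#' @return 4x2 matrix of refined boundary indices (columns `start`,
#'   `end`), with attribute `flags` marking boundaries left unrefined.
#' @export
refine_m1 <- function(macro, trace, cfg = pipeline_config()) {
  fs <- trace$fs_hz
  x <- clip_analysis_window(trace$acc_ap, fs, cfg$analysis_window_s)
  xn <- wavelet_band_reconstruct(x, fs,
                                 band_spec(cfg$micro_band_hz[1],
                                           cfg$micro_band_hz[2]))
  mins <- find_extrema(xn, "min",
                       prominence = cfg$step_min_prominence_mps2,
                       fs = fs, exclude_s = cfg$edge_exclude_s)$index
  w <- round(cfg$refine_window_s * fs)
  out <- as.matrix(macro$segments[, c("start_idx", "end_idx")])
  colnames(out) <- c("start", "end")
  flags <- matrix(FALSE, 4, 2, dimnames = list(NULL, c("start", "end")))
  for (k in 1:4) for (j in 1:2) {
    i <- out[k, j]
    near <- mins[abs(mins - i) <= w]
    if (length(near)) out[k, j] <- near[which.min(abs(near - i))]
    else flags[k, j] <- TRUE
  }
  attr(out, "flags") <- flags
  out
}

#' Micro-method M2: penultimate contact and second toe-off (180 deg)
#'
#' Start: if a large peak (prominence above the ground-contact
#' threshold) sits within the lookback window just before the macro
#' start, the start is advanced one local minimum earlier, capturing the
#' penultimate foot contact. End: if the reconstructed signal is still
#' positive at the macro end minimum, the end is pushed forward to the
#' next local minimum with a negative value, capturing the second
#' toe-off.
#'
#' @param segment one row of `macro$segments` (must be a 180 degree COD).
#' @param macro,trace,cfg as in [refine_m1()].
#' @return named vector `c(start, end)` of indices, with attribute
#'   `flags` for boundaries that could not be moved.
#' @export
refine_m2_180 <- function(segment, macro, trace, cfg = pipeline_config()) {
  if (segment$angle_deg != 180)
    codseg_stop("codseg_invalid_argument", "M2 applies to 180 degree CODs")
  fs <- trace$fs_hz
  xr <- macro$band_signal
  mins <- stepping_minima(xr, fs, cfg)
  mx <- find_extrema(xr, "max", prominence = cfg$prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)$index
  w <- round(cfg$large_peak_window_s * fs)
  out <- c(start = segment$start_idx, end = segment$end_idx)
  flags <- c(start = FALSE, end = FALSE)
  # start: large peak just before -> one minimum earlier (PFC)
  if (any(mx >= segment$start_idx - w & mx < segment$start_idx)) {
    prev <- mins[mins < segment$start_idx]
    if (length(prev)) out["start"] <- max(prev) else flags["start"] <- TRUE
  }
  # end: still positive -> next negative minimum (second toe-off)
  push <- if (cfg$m2_end_rule == "positive") xr[segment$end_idx] > 0
          else xr[segment$end_idx] < 0
  if (push) {
    nxt <- mins[mins > segment$end_idx & xr[mins] < 0]
    if (length(nxt)) out["end"] <- min(nxt) else flags["end"] <- TRUE
  }
  attr(out, "flags") <- flags
  out
}

#' Micro-method M3: flight-phase detection on the acceleration norm
#'
#' Moves each boundary to the nearest sample where the tri-axial
#' acceleration norm falls below g (free-fall indicates the flight
#' phase immediately before the first heel strike and after the second
#' toe-off), searching backward from the start and forward from the end
#' within the refinement window.
#'
#' @param segment one row of `macro$segments`.
#' @param trace [inertial_trace()] with all three acceleration axes.
#' @param cfg a [pipeline_config()].
#' @return named vector `c(start, end)` with attribute `flags`.
#' @export
refine_m3 <- function(segment, trace, cfg = pipeline_config()) {
  if (is.null(trace$acc_ml) || is.null(trace$acc_v))
    codseg_stop("codseg_invalid_argument",
                "M3 needs tri-axial acceleration")
  nrm <- sqrt(trace$acc_ap^2 + trace$acc_ml^2 + trace$acc_v^2)
  w <- round(cfg$refine_window_s * trace$fs_hz)
  out <- c(start = segment$start_idx, end = segment$end_idx)
  flags <- c(start = FALSE, end = FALSE)
  lo <- max(1L, segment$start_idx - w)
  sub <- which(nrm[lo:segment$start_idx] < cfg$g_mps2) + lo - 1L
  if (length(sub)) out["start"] <- max(sub) else flags["start"] <- TRUE
  hi <- min(length(nrm), segment$end_idx + w)
  sub <- which(nrm[segment$end_idx:hi] < cfg$g_mps2) + segment$end_idx - 1L
  if (length(sub)) out["end"] <- min(sub) else flags["end"] <- TRUE
  attr(out, "flags") <- flags
  out
}

#' Micro-method M4: advance the end of COD 1 past a trailing peak
#'
#' If the macro end of the first 90 degree COD is immediately followed
#' by a qualifying peak (the second toe-off push), the end moves
#' forward by one local minimum.
#'
#' @param segment one row of `macro$segments` (order 1).
#' @param macro,trace,cfg as in [refine_m2_180()].
#' @return named vector `c(start, end)` (start unchanged).
#' @export
refine_m4_cod1_end <- function(segment, macro, trace,
                               cfg = pipeline_config()) {
  fs <- trace$fs_hz
  xr <- macro$band_signal
  mx <- find_extrema(xr, "max", prominence = cfg$prominence_mps2,
                     fs = fs, exclude_s = cfg$edge_exclude_s)$index
  w <- round(cfg$large_peak_window_s * fs)
  out <- c(start = segment$start_idx, end = segment$end_idx)
  trailing <- mx[mx > segment$end_idx & mx <= segment$end_idx + w]
  if (length(trailing)) {
    mins <- stepping_minima(xr, fs, cfg)
    nxt <- mins[mins > trailing[1]]
    if (length(nxt)) out["end"] <- min(nxt)
  }
  out
}

# Dispatch one (segment, boundary, method) refinement; returns an index.
apply_micro_method <- function(method, boundary, segment, macro, trace,
                               cfg, m1_cache) {
  idx0 <- if (boundary == "start") segment$start_idx else segment$end_idx
  switch(method,
    M0 = idx0,
    M1 = m1_cache[segment$order, boundary],
    M2 = {
      if (segment$angle_deg != 180) idx0
      else refine_m2_180(segment, macro, trace, cfg)[[boundary]]
    },
    M3 = refine_m3(segment, trace, cfg)[[boundary]],
    M4 = {
      if (boundary == "end")
        refine_m4_cod1_end(segment, macro, trace, cfg)[["end"]]
      else idx0
    },
    codseg_stop("codseg_invalid_argument", "unknown method '%s'", method))
}

#' Refine the macro timeline with the best-method combination
#'
#' Applies the configured per-COD, per-boundary micro method (default:
#' COD1 start M0 / end M4, COD2 and COD3 M2 for both boundaries, COD4
#' M0) and assembles the event timeline. Any refinement that would move
#' a boundary further than the refinement window from its macro value,
#' or break the strict time ordering, is reverted to the macro boundary
#' and flagged.
#'
#' @param macro a `macro_result`.
#' @param trace the matching [inertial_trace()].
#' @param cfg a [pipeline_config()]; `cfg$method_map` selects methods.
#' @param diagnostics also compute all five methods for every boundary
#'   (for method-comparison output).
#' @return an [event_timeline()] with `t_end_s = NA` (filled in by the
#'   GNSS completion-time estimate); attributes `flags` (reverted
#'   boundaries) and, if requested, `diagnostics`.
#' @export
refine_timeline <- function(macro, trace, cfg = pipeline_config(),
                            diagnostics = FALSE) {
  if (nrow(macro$segments) != 4L)
    codseg_stop("codseg_invalid_argument", "macro must hold 4 segments")
  fs <- trace$fs_hz
  m1 <- refine_m1(macro, trace, cfg)
  w <- round(cfg$refine_window_s * fs)
  idx <- as.matrix(macro$segments[, c("start_idx", "end_idx")])
  colnames(idx) <- c("start", "end")
  out <- idx
  flags <- matrix(FALSE, 4, 2, dimnames = list(NULL, c("start", "end")))
  for (k in 1:4) {
    seg <- macro$segments[k, ]
    mm <- cfg$method_map[[paste0("cod", k)]]
    for (b in c("start", "end")) {
      cand <- apply_micro_method(mm[[b]], b, seg, macro, trace, cfg, m1)
      if (abs(cand - idx[k, b]) > w) flags[k, b] <- TRUE
      else out[k, b] <- cand
    }
  }
  # enforce strict ordering; revert offending boundaries to macro values
  repeat {
    seqv <- as.vector(t(out))
    ok <- all(diff(seqv) > 0)
    if (ok) break
    bad <- which(diff(seqv) <= 0)[1] + 1L
    k <- ceiling(bad / 2); b <- if (bad %% 2L) "end" else "start"
    if (out[k, b] == idx[k, b]) break   # macro itself degenerate
    out[k, b] <- idx[k, b]; flags[k, b] <- TRUE
  }
  tl <- event_timeline(
    t_start_s = macro$t_first_step_s,
    cod = data.frame(order = 1:4,
                     angle_deg = macro$segments$angle_deg,
                     t_start_s = trace$time_s[out[, "start"]],
                     t_end_s = trace$time_s[out[, "end"]]))
  attr(tl, "flags") <- flags
  if (diagnostics) {
    methods <- c("M0", "M1", "M2", "M3", "M4")
    diag <- array(NA_real_, c(4, 2, 5),
                  dimnames = list(paste0("cod", 1:4), c("start", "end"),
                                  methods))
    for (k in 1:4) for (b in c("start", "end")) for (m in methods) {
      ix <- tryCatch(
        apply_micro_method(m, b, macro$segments[k, ], macro, trace, cfg,
                           m1),
        codseg_error = function(e) NA_integer_)
      diag[k, b, m] <- if (is.na(ix)) NA_real_ else trace$time_s[ix]
    }
    attr(tl, "diagnostics") <- diag
  }
  tl
}
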