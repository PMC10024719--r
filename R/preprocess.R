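# Signal conditioning: zero-phase Butterworth low-pass filtering,
# stationary-wavelet band-limited reconstruction, and peak/trough
# detection with topographic prominence.

#' Inertial trace container
#'
#' A uniformly sampled tri-axial trunk acceleration record (optionally
#' with angular velocity), body-frame aligned: `acc_ap` antero-posterior,
#' `acc_ml` medio-lateral, `acc_v` vertical (includes gravity).
#'
#' @param time_s sample instants (s), uniform spacing `1/fs_hz`.
#' @param acc_ap,acc_ml,acc_v acceleration components (m/s^2).
#' @param gyr optional 3-column matrix of angular velocity (rad/s).
#' @param fs_hz sampling rate (Hz), 200 by default.
#' @return an object of class `inertial_trace`.
#' @export
inertial_trace <- function(time_s, acc_ap, acc_ml = NULL, acc_v = NULL,
                           gyr = NULL, fs_hz = 200) {
  n <- length(time_s)
  if (n < 2L)
    codseg_stop("codseg_insufficient_samples", "trace needs >= 2 samples")
  if (length(acc_ap) != n)
    codseg_stop("codseg_invalid_argument", "acc_ap length != time length")
  dt <- diff(time_s)
  if (any(!is.finite(c(time_s, acc_ap))) ||
      any(abs(dt - 1 / fs_hz) > 1e-6))
    codseg_stop("codseg_invalid_argument",
                "time grid must be uniform at 1/fs within 1e-6 s and finite")
  structure(list(time_s = time_s, acc_ap = acc_ap,
                 acc_ml = acc_ml, acc_v = acc_v, gyr = gyr,
                 fs_hz = fs_hz),
            class = "inertial_trace")
}

#' @export
print.inertial_trace <- function(x, ...) {
  cat(sprintf("<inertial_trace> %d samples @ %g Hz, %.2f-%.2f s\n",
              length(x$time_s), x$fs_hz, x$time_s[1],
              x$time_s[length(x$time_s)]))
  invisible(x)
}

#' Reconstruction band specification
#'
#' @param f_lo_hz,f_hi_hz band edges (Hz); must satisfy
#'   `0 < f_lo < f_hi < fs/2` for the sampling rate they are used with.
#' @param keep_mean re-add the signal mean (zero-frequency content) to the
#'   reconstruction, as the detection pipeline requires.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(f_lo_hz, f_hi_hz, keep_mean = TRUE) {
  stopifnot_scalar_num(f_lo_hz, "f_lo_hz")
  stopifnot_scalar_num(f_hi_hz, "f_hi_hz")
  if (f_lo_hz >= f_hi_hz)
    codseg_stop("codseg_invalid_band", "need f_lo < f_hi")
  structure(list(f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 keep_mean = isTRUE(keep_mean)),
            class = "band_spec")
}

## ---- Butterworth low-pass, zero phase ------------------------------------

# Digital Butterworth low-pass coefficients via bilinear transform.
# Returns list(b, a) with a[1] = 1.
butter_lowpass <- function(fc, fs, order = 2L) {
  stopifnot_scalar_num(fc, "fc"); stopifnot_scalar_num(fs, "fs")
  order <- as.integer(order)
  if (fc >= fs / 2)
    codseg_stop("codseg_invalid_argument", "fc must be below Nyquist")
  warped <- tan(pi * fc / fs)
  k <- seq_len(order)
  # analog prototype poles on the unit circle, scaled by the warped edge
  s <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- (1 + s) / (1 - s)                 # bilinear map
  a <- Re(poly_from_roots(z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)               # unit gain at DC
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Direct-form II transposed IIR filter with initial state zi * x[1]
# (steady-state initialization, as in standard filtfilt implementations).
iir_filter <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  nfilt <- max(nb, na)
  b <- c(b, rep(0, nfilt - nb)); a <- c(a, rep(0, nfilt - na))
  z <- if (is.null(zi)) rep(0, nfilt - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nfilt > 2L)
      for (j in seq_len(nfilt - 2L))
        z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-amplitude step input.
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b))); a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1L, n - 1L)            # companion(a) transposed
  A[, 1] <- -a[-1] / a[1]
  if (n > 2L) A[cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L)] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - A, B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a digital Butterworth low-pass forward and backward
#' (filtfilt), giving zero net phase shift and a squared magnitude
#' response. Signal edges are extended by odd reflection before
#' filtering, and filter state is initialised at steady state, so the
#' output has the same length as the input with suppressed end
#' transients.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param fc cut-off frequency (Hz), below Nyquist.
#' @param order filter order of each pass (default 2, the pipeline's
#'   convention).
#' @return filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, fs, fc, order = 2L) {
  ba <- butter_lowpass(fc, fs, order)
  padlen <- 3L * (max(length(ba$a), length(ba$b)) - 1L)
  if (length(x) <= 3L * padlen)
    codseg_stop("codseg_insufficient_samples",
                "signal too short for order-%d zero-phase filtering", order)
  n <- length(x)
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(ba$b, ba$a)
  y <- iir_filter(ba$b, ba$a, ext, zi * ext[1])
  y <- rev(iir_filter(ba$b, ba$a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

## ---- Stationary wavelet band reconstruction ------------------------------

# Orthonormal Daubechies-4 (8-tap) scaling filter; sum = sqrt(2).
DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
             0.030841381835986965, -0.187034811718881140,
            -0.027983769416983850, 0.630880767929590400,
             0.714846570552541500, 0.230377813308855230)

# Map requested band edges to dyadic detail levels. Each detail level j
# nominally covers [fs/2^(j+1), fs/2^j]; edges snap to the nearest dyadic
# edge fs/2^j. Returns integer vector of detail levels to keep.
swt_levels_for_band <- function(fs, f_lo, f_hi, max_level) {
  edges <- fs / 2^seq_len(max_level + 1L)
  j_hi <- which.min(abs(edges - f_hi))   # first kept level: band top = edge
  j_lo <- which.min(abs(edges - f_lo)) - 1L  # last kept level: band bottom
  if (j_lo < j_hi)
    codseg_stop("codseg_invalid_band",
                "band %g-%g Hz maps to no dyadic detail level at fs=%g",
                f_lo, f_hi, fs)
  seq.int(j_hi, j_lo)
}

#' Band-limited reconstruction with the stationary wavelet transform
#'
#' Decomposes the signal with an undecimated Daubechies-4 wavelet
#' filter bank and reconstructs only the detail levels whose dyadic
#' frequency bands lie inside the requested band (edges snapped to the
#' nearest dyadic edge `fs/2^j`; at fs = 200 Hz the 0.5-15 Hz band maps
#' to levels covering ~0.39-12.5 Hz and 0.5-5 Hz to ~0.39-6.25 Hz).
#' Analysis uses time-reversed synthesis filters, so each level's
#' combined response is the squared magnitude of the cascade --
#' zero-phase by construction -- and all levels plus the approximation
#' sum exactly to the input. The signal is symmetrically extended before
#' the circular transform to avoid wrap-around artifacts.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()]; `band$keep_mean` re-adds the signal mean
#'   so the reconstruction is aligned with the raw amplitude scale.
#' @return reconstructed signal, same length as `x`.
#' @export
wavelet_band_reconstruct <- function(x, fs, band) {
  if (!inherits(band, "band_spec"))
    band <- band_spec(band[[1]], band[[2]])
  if (band$f_hi_hz >= fs / 2 || band$f_lo_hz <= 0)
    codseg_stop("codseg_invalid_band",
                "band must lie strictly inside (0, fs/2)")
  n <- length(x)
  max_level <- min(14L, floor(log2(n)))
  levels <- swt_levels_for_band(fs, band$f_lo_hz, band$f_hi_hz, max_level)
  if (n < 2^max(levels))
    codseg_stop("codseg_insufficient_samples",
                "need >= 2^%d samples for level-%d reconstruction",
                max(levels), max(levels))
  xm <- mean(x)
  xe <- c(x, rev(x))                       # symmetric extension
  m <- length(xe)
  w <- fft(c(DB4_LO, rep(0, m - length(DB4_LO))))
  h2 <- Mod(w)^2 / 2                       # |H|^2/2; |G|^2/2 = 1 - this
  idx0 <- seq_len(m) - 1L
  transfer <- numeric(m)
  approx <- rep(1, m)                      # running product of h2 terms
  for (j in seq_len(max(levels))) {
    hj <- h2[(idx0 * 2^(j - 1L)) %% m + 1L]
    dj <- approx * (1 - hj)                # detail-level response
    if (j %in% levels) transfer <- transfer + dj
    approx <- approx * hj
  }
  ye <- Re(fft(fft(xe) * transfer, inverse = TRUE)) / m
  y <- ye[seq_len(n)]
  if (band$keep_mean) y <- y - mean(y) + xm
  y
}

## ---- Extrema with topographic prominence ---------------------------------

#' Local extrema with prominence and height thresholds
#'
#' Finds strict local maxima (or minima, by sign inversion of the same
#' detector) and their topographic prominence: the drop from the peak to
#' the higher of the two key saddles, where each side's base is the
#' minimum between the peak and the nearest higher sample (or the signal
#' edge). Plateaus count once, at their earliest index.
#'
#' @param x numeric signal (finite).
#' @param kind `"max"` or `"min"`.
#' @param prominence minimum prominence to keep (same units as `x`).
#' @param height optional height threshold: maxima with value > `height`
#'   (minima with value < `height`).
#' @param fs,exclude_s optionally exclude extrema within `exclude_s`
#'   seconds of either end (requires `fs`); guards against filter edge
#'   effects. Default excludes nothing.
#' @return data.frame with columns `index`, `value`, `prominence`,
#'   ordered by index. Empty data.frame when nothing qualifies.
#' @export
find_extrema <- function(x, kind = c("max", "min"), prominence = 0,
                         height = NULL, fs = NULL, exclude_s = 0) {
  kind <- match.arg(kind)
  if (any(!is.finite(x)))
    codseg_stop("codseg_invalid_argument", "signal must be finite")
  s <- if (kind == "min") -x else x
  idx <- plateau_maxima(s)
  if (length(idx)) {
    prom <- vapply(idx, peak_prominence, numeric(1), s = s)
    keep <- prom >= prominence
    if (!is.null(height))
      keep <- keep & (s[idx] > (if (kind == "min") -height else height))
    if (exclude_s > 0) {
      if (is.null(fs))
        codseg_stop("codseg_invalid_argument", "exclude_s needs fs")
      lo <- exclude_s * fs
      keep <- keep & idx > lo & idx <= length(x) - lo
    }
    idx <- idx[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  data.frame(index = idx, value = x[idx], prominence = prom)
}

# Indices of strict local maxima; plateaus yield their first index.
plateau_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  d <- diff(s)
  out <- integer(0)
  i <- 1L
  while (i < n) {
    if (d[i] > 0) {
      j <- i + 1L
      while (j < n && d[j] == 0) j <- j + 1L
      if (j <= n - 1L && d[j] < 0) out <- c(out, i + 1L)
      i <- j
    } else i <- i + 1L
  }
  out
}

# Topographic prominence of peak at index p in signal s.
peak_prominence <- function(s, p) {
  v <- s[p]
  left <- s[seq_len(p - 1L)]
  higher <- which(left > v)
  lbase <- min(left[seq.int(if (length(higher)) max(higher) + 1L else 1L,
                            p - 1L)])
  right <- s[seq.int(p + 1L, length(s))]
  higher <- which(right > v)
  rbase <- min(right[seq_len(if (length(higher)) min(higher) - 1L
                             else length(right))])
  v - max(lbase, rbase)
}
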