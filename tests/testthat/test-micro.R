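# Micro-analysis refinement methods M1-M4 and the best-method timeline.

fs <- 200

# Handcrafted 180-degree COD burst with known PFC/FFC/toe-off structure:
# PFC dip 1.0 s, PFC peak 1.15 s, FFC dip 1.3 s, FFC peak 1.45 s,
# positive inter-push minimum ~1.6 s, push peak 1.75 s, second toe-off
# dip 1.9 s.
m2_fixture <- function() {
  tt <- seq(0, 3.995, by = 1 / fs)
  x <- fixture_pulse(tt, 1.0, -20, 0.12) + fixture_pulse(tt, 1.15, 30, 0.12) +
    fixture_pulse(tt, 1.3, -18, 0.12) + fixture_pulse(tt, 1.45, 30, 0.12) +
    fixture_pulse(tt, 1.75, 25, 0.12) + fixture_pulse(tt, 1.9, -18, 0.12) +
    fixture_pulse(tt, 1.6, 2, 0.8)          # keeps the gap minimum positive
  trace <- inertial_trace(tt, x, fs_hz = fs)
  macro <- list(band_signal = x, t_first_step_s = 0.5)
  list(tt = tt, x = x, trace = trace, macro = macro,
       at = function(s) which.min(abs(tt - s)))
}

test_that("M2 captures the penultimate contact and the second toe-off", {
  f <- m2_fixture()
  # macro "mis-detected" the inner pair: FFC dip start, positive gap min end
  gap_min <- 300 + which.min(f$x[300:345])   # inside (1.50, 1.72) s
  seg <- data.frame(order = 2, angle_deg = 180,
                    start_idx = f$at(1.3), end_idx = gap_min)
  out <- refine_m2_180(seg, f$macro, f$trace)
  expect_equal(f$tt[out[["start"]]], 1.0, tolerance = 0.02)   # PFC dip
  expect_equal(f$tt[out[["end"]]], 1.9, tolerance = 0.02)     # second TO
  # end already negative: condition false, boundary kept
  seg2 <- data.frame(order = 3, angle_deg = 180,
                     start_idx = f$at(1.3), end_idx = f$at(1.9))
  out2 <- refine_m2_180(seg2, f$macro, f$trace)
  expect_equal(out2[["end"]], f$at(1.9))
  expect_error(refine_m2_180(data.frame(order = 1, angle_deg = 90,
                                        start_idx = 1, end_idx = 2),
                             f$macro, f$trace),
               class = "codseg_invalid_argument")
})

test_that("M2 beats M0 on 180-degree CODs in >= 80% of varied trials", {
  wins <- 0L; total <- 0L
  for (seed in 1:10) {
    trial <- simulate_trial(trial_spec(seed = seed, randomize = TRUE))
    macro <- detect_cod_segments(trial$trace)
    tl <- trial$truth$timeline
    for (k in 2:3) {
      seg <- macro$segments[k, ]
      m2 <- refine_m2_180(seg, macro, trial$trace)
      e0 <- abs(trial$trace$time_s[seg$start_idx] - tl$cod$t_start_s[k]) +
        abs(trial$trace$time_s[seg$end_idx] - tl$cod$t_end_s[k])
      e2 <- abs(trial$trace$time_s[m2[["start"]]] - tl$cod$t_start_s[k]) +
        abs(trial$trace$time_s[m2[["end"]]] - tl$cod$t_end_s[k])
      total <- total + 1L
      if (e2 <= e0) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.8)
})

test_that("M3 snaps boundaries to the flight-phase sub-g samples", {
  tt <- seq(0, 3.995, by = 1 / fs)
  n <- length(tt)
  av <- rep(10.5, n)
  # free-fall gaps: [1.30, 1.40] before the start, [2.10, 2.20] after end
  av[tt >= 1.30 & tt <= 1.40] <- 2
  av[tt >= 2.10 & tt <= 2.20] <- 2
  trace <- inertial_trace(tt, numeric(n), numeric(n), av, fs_hz = fs)
  # norm equals the per-sample brute-force oracle
  nrm <- sqrt(trace$acc_ap^2 + trace$acc_ml^2 + trace$acc_v^2)
  expect_equal(nrm, av, tolerance = 1e-12)
  seg <- data.frame(order = 2, angle_deg = 180,
                    start_idx = which.min(abs(tt - 1.5)),
                    end_idx = which.min(abs(tt - 2.0)))
  out <- refine_m3(seg, trace)
  expect_equal(tt[out[["start"]]], 1.40, tolerance = 1 / fs)
  expect_equal(tt[out[["end"]]], 2.10, tolerance = 1 / fs)
  # norm never below g: boundaries kept, flagged
  trace2 <- inertial_trace(tt, numeric(n), numeric(n), rep(10.81, n),
                           fs_hz = fs)
  out2 <- refine_m3(seg, trace2)
  expect_equal(unname(out2), c(seg$start_idx, seg$end_idx),
               ignore_attr = TRUE)
  expect_true(all(attr(out2, "flags")))
  expect_error(refine_m3(seg, inertial_trace(tt, numeric(n), fs_hz = fs)),
               class = "codseg_invalid_argument")
})

test_that("M4 advances the COD 1 end past a trailing push-off peak", {
  tt <- seq(0, 3.995, by = 1 / fs)
  x <- fixture_pulse(tt, 1.0, -18, 0.12) + fixture_pulse(tt, 1.2, 30, 0.14) +
    fixture_pulse(tt, 1.45, -6, 0.10) + fixture_pulse(tt, 1.6, 28, 0.12) +
    fixture_pulse(tt, 1.8, -16, 0.12)
  trace <- inertial_trace(tt, x, fs_hz = fs)
  macro <- list(band_signal = x)
  at <- function(s) which.min(abs(tt - s))
  seg <- data.frame(order = 1, angle_deg = 90,
                    start_idx = at(1.0), end_idx = at(1.45))
  out <- refine_m4_cod1_end(seg, macro, trace)
  expect_equal(tt[out[["end"]]], 1.8, tolerance = 0.02)
  # no trailing peak within the window: unchanged
  seg2 <- data.frame(order = 1, angle_deg = 90,
                     start_idx = at(1.0), end_idx = at(1.8))
  out2 <- refine_m4_cod1_end(seg2, macro, trace)
  expect_equal(out2[["end"]], at(1.8))
  # idempotent once the end sits past the last peak
  seg3 <- seg; seg3$end_idx <- out[["end"]]
  expect_equal(refine_m4_cod1_end(seg3, macro, trace)[["end"]],
               out[["end"]])
})

test_that("M1 lands on narrow-band minima and is idempotent", {
  trial <- default_trial(seed = 4L)
  macro <- detect_cod_segments(trial$trace)
  cfg <- pipeline_config()
  m1 <- refine_m1(macro, trial$trace, cfg)
  xn <- wavelet_band_reconstruct(
    trial$trace$acc_ap, fs,
    band_spec(cfg$micro_band_hz[1], cfg$micro_band_hz[2]))
  for (i in seq_along(m1)) {
    k <- m1[i]
    expect_true(xn[k] <= min(xn[max(1, k - 1)], xn[min(length(xn), k + 1)]))
  }
  macro2 <- macro
  macro2$segments$start_idx <- m1[, "start"]
  macro2$segments$end_idx <- m1[, "end"]
  expect_equal(refine_m1(macro2, trial$trace, cfg), m1,
               ignore_attr = TRUE)
})

test_that("refine_timeline applies the method map and stays monotone", {
  cfg_m0 <- pipeline_config(method_map = list(
    cod1 = c(start = "M0", end = "M0"), cod2 = c(start = "M0", end = "M0"),
    cod3 = c(start = "M0", end = "M0"), cod4 = c(start = "M0", end = "M0")))
  for (seed in c(1, 3, 7)) {
    trial <- default_trial(seed = seed)
    macro <- detect_cod_segments(trial$trace)
    # all-M0 map reproduces the macro boundaries exactly
    tl0 <- refine_timeline(macro, trial$trace, cfg_m0)
    expect_equal(tl0$cod$t_start_s, macro$segments$t_start_s)
    expect_equal(tl0$cod$t_end_s, macro$segments$t_end_s)
    # default map: strictly increasing, within the macro neighbourhood
    tl <- refine_timeline(macro, trial$trace)
    ev <- c(tl$t_start_s, rbind(tl$cod$t_start_s, tl$cod$t_end_s))
    expect_true(all(diff(ev) > 0))
    expect_true(all(abs(tl$cod$t_start_s - macro$segments$t_start_s) <= 0.5))
    expect_true(all(abs(tl$cod$t_end_s - macro$segments$t_end_s) <= 0.5))
  }
})

test_that("refine_timeline diagnostics cover all five methods", {
  trial <- default_trial(seed = 1L)
  macro <- detect_cod_segments(trial$trace)
  tl <- refine_timeline(macro, trial$trace, diagnostics = TRUE)
  d <- attr(tl, "diagnostics")
  expect_equal(dim(d), c(4L, 2L, 5L))
  expect_equal(d[, , "M0"],
               cbind(start = macro$segments$t_start_s,
                     end = macro$segments$t_end_s),
               ignore_attr = TRUE)
  expect_true(all(is.finite(d[, , "M1"])))
})
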