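# Synthetic Agility T-test trial generator.
#
# Emulates the signal structure the detection pipeline assumes: per-step
# impact transients on the antero-posterior (AP) trunk acceleration,
# large positive braking/push impulse bursts at the four CODs, a
# plausible along-path GNSS ground-speed profile over the ten-yard
# T-test geometry, and 60 Hz-quantized reference labels with bounded
# jitter. All amplitude choices that the stated measurement conditions
# do not pin down are generator parameters, not claims about real data.

#' Synthetic trial specification
#'
#' Defaults describe an elite-level trial: ten-yard T-test geometry
#' (9.14 / 4.57 m legs), completion time ~9.8 s, COD acceleration
#' impulses inside the 5-7 m/s range with 1-3 m/s per-step impulses in
#' the displacement phases, and 60 Hz labels jittered by up to 3 frames.
#'
#' @param seed integer RNG seed; the whole trial is deterministic given
#'   the spec (including this seed).
#' @param segment_lengths_m five cone-to-cone lengths, DP1..DP5 (m).
#' @param peak_speeds_mps per-phase peak speed (m/s).
#' @param cod_durations_s four COD ground-contact durations (s).
#' @param cod_impulses_mps target AP acceleration impulse of each COD,
#'   integrated between the flanking local minima (m/s).
#' @param dp_step_impulse_mps per-step AP impulse during displacement
#'   phases (m/s).
#' @param step_cadence_hz steps per second during displacement phases.
#' @param noise_sd_mps2 SD of additive white noise on all acceleration
#'   channels; GNSS speed noise is tied to it (0.06 x this value in m/s)
#'   so a noiseless spec silences both sensors.
#' @param hf_artifact_gain gain of the >15 Hz post-impact resonance
#'   content (1 = nominal); exercises the band-limited reconstruction.
#' @param label_jitter_frames default max jitter of simulated video
#'   labels, in 60 Hz frames.
#' @param gnss_phase_offset_s constant offset of the 10 Hz GNSS clock
#'   relative to the IMU clock (s); exercises resampling.
#' @param arm_reach_m arm reach subtracted from the final phase when the
#'   athlete touches the last cone (m).
#' @param fs_imu_hz,fs_gnss_hz sensor sampling rates (Hz).
#' @param randomize draw per-trial physiological variation (speeds,
#'   cadence, COD durations and impulses) around the defaults from
#'   `seed`; off by default so the default spec is a fixed stated world.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(seed = 1L,
                       segment_lengths_m = c(9.14, 4.57, 9.14, 4.57, 9.14),
                       peak_speeds_mps = c(6.5, 4.6, 5.6, 4.8, 5.0),
                       cod_durations_s = c(0.45, 0.50, 0.50, 0.45),
                       cod_impulses_mps = c(5.5, 6.0, 6.0, 5.5),
                       dp_step_impulse_mps = 2.0,
                       step_cadence_hz = 3.3,
                       noise_sd_mps2 = 0.8,
                       hf_artifact_gain = 1.0,
                       label_jitter_frames = 3L,
                       gnss_phase_offset_s = 0.02,
                       arm_reach_m = 1.42,
                       fs_imu_hz = 200, fs_gnss_hz = 10,
                       randomize = FALSE) {
  spec <- structure(list(
    seed = as.integer(seed),
    segment_lengths_m = segment_lengths_m,
    peak_speeds_mps = peak_speeds_mps,
    cod_durations_s = cod_durations_s,
    cod_impulses_mps = cod_impulses_mps,
    dp_step_impulse_mps = dp_step_impulse_mps,
    step_cadence_hz = step_cadence_hz,
    noise_sd_mps2 = noise_sd_mps2,
    hf_artifact_gain = hf_artifact_gain,
    label_jitter_frames = as.integer(label_jitter_frames),
    gnss_phase_offset_s = gnss_phase_offset_s,
    arm_reach_m = arm_reach_m,
    fs_imu_hz = fs_imu_hz, fs_gnss_hz = fs_gnss_hz),
    class = "trial_spec")
  if (isTRUE(randomize)) {
    spec <- with_seed(seed * 7L + 13L, {
      spec$peak_speeds_mps <- spec$peak_speeds_mps *
        runif(5, 0.96, 1.04)
      spec$cod_durations_s <- spec$cod_durations_s * runif(4, 0.92, 1.08)
      spec$cod_impulses_mps <- runif(4, 5.2, 6.8)
      spec$dp_step_impulse_mps <- runif(1, 1.5, 2.5)
      spec$step_cadence_hz <- spec$step_cadence_hz * runif(1, 0.95, 1.05)
      spec
    })
  }
  validate_trial_spec(spec)
}

validate_trial_spec <- function(spec) {
  pos <- c(spec$segment_lengths_m, spec$peak_speeds_mps,
           spec$cod_durations_s, spec$cod_impulses_mps,
           spec$dp_step_impulse_mps, spec$step_cadence_hz,
           spec$fs_imu_hz, spec$fs_gnss_hz, spec$arm_reach_m)
  if (any(!is.finite(pos)) || any(pos <= 0))
    codseg_stop("codseg_infeasible_spec",
                "lengths, speeds, durations, impulses and rates must be > 0")
  if (length(spec$segment_lengths_m) != 5L ||
      length(spec$peak_speeds_mps) != 5L ||
      length(spec$cod_durations_s) != 4L ||
      length(spec$cod_impulses_mps) != 4L)
    codseg_stop("codseg_infeasible_spec",
                "need 5 phase lengths/speeds and 4 COD durations/impulses")
  if (spec$noise_sd_mps2 < 0 || spec$hf_artifact_gain < 0 ||
      spec$label_jitter_frames < 0)
    codseg_stop("codseg_infeasible_spec",
                "noise, artifact gain and jitter must be >= 0")
  spec
}

# Internal speed-profile constants (stated world; see methods vignette).
# Entry/exit and minimum along-path speed at each COD, rise/fall
# fractions of each displacement phase.
.sim_profile <- list(
  v_edge = c(2.2, 1.8, 1.8, 1.9),    # speed entering/leaving each COD
  v_min  = c(1.3, 0.5, 0.5, 1.2),    # minimum speed at the cone
  rise   = c(0.45, 0.30, 0.30, 0.30, 0.35),
  fall   = c(0.25, 0.30, 0.30, 0.30, 0.00),
  t_stand = 1.25,                    # standing phase before the start
  t_tail  = 0.90,                    # recording continues after finish
  decay_s = 0.25                     # post-finish speed decay width
)

# Raised-cosine pulse, possibly asymmetric: peak `amp` at `center`,
# support [center - wl, center + wr].
rc_pulse <- function(t, center, amp, wl, wr = wl) {
  y <- numeric(length(t))
  i <- t >= center - wl & t < center
  y[i] <- amp * cos(pi * (t[i] - center) / (2 * wl))^2
  i <- t >= center & t <= center + wr
  y[i] <- amp * cos(pi * (t[i] - center) / (2 * wr))^2
  y
}

# Build the trial's phase timing and the along-path speed function.
sim_plan <- function(spec) {
  p <- .sim_profile
  L <- spec$segment_lengths_m
  vpk <- spec$peak_speeds_mps
  d <- spec$cod_durations_s
  ve <- p$v_edge; vm <- p$v_min
  # distance covered during each COD (entry/exit half-cosine dip)
  delta <- d * (2 * ve + 2 * vm) / 4
  dp_dist <- c(L[1] - delta[1] / 2,
               L[2] - delta[1] / 2 - delta[2] / 2,
               L[3] - delta[2] / 2 - delta[3] / 2,
               L[4] + spec$arm_reach_m - delta[3] / 2 - delta[4],
               L[5] - spec$arm_reach_m)
  v0 <- c(0, ve[1], ve[2], ve[3], ve[4])
  v1 <- c(ve[1], ve[2], ve[3], ve[4], vpk[5])
  if (any(dp_dist <= 0) || any(vpk < pmax(v0, v1)))
    codseg_stop("codseg_infeasible_spec",
                "speed profile cannot cover the segment lengths")
  vmean <- vpk - (vpk - v0) * p$rise / 2 - (vpk - v1) * p$fall / 2
  if (any(vmean <= 0.2))
    codseg_stop("codseg_infeasible_spec", "mean phase speed too low")
  T_dp <- dp_dist / vmean
  t_start <- p$t_stand
  cod_start <- cod_end <- numeric(4)
  t <- t_start
  for (k in 1:4) {
    t <- t + T_dp[k]; cod_start[k] <- t
    t <- t + d[k]; cod_end[k] <- t
  }
  t_end <- t + T_dp[5]
  list(t_start = t_start, cod_start = cod_start, cod_end = cod_end,
       t_end = t_end, T_dp = T_dp, dp_dist = dp_dist,
       v0 = v0, v1 = v1, vpk = vpk, ve = ve, vm = vm, d = d,
       duration = t_end + p$t_tail)
}

# Along-path speed at arbitrary times for a given plan (noise-free).
sim_speed_at <- function(tt, plan) {
  p <- .sim_profile
  v <- numeric(length(tt))
  dp_lo <- c(plan$t_start, plan$cod_end[1:4])
  dp_hi <- c(plan$cod_start[1:4], plan$t_end)
  for (k in 1:5) {
    i <- tt >= dp_lo[k] & tt < dp_hi[k]
    if (!any(i)) next
    u <- (tt[i] - dp_lo[k]) / plan$T_dp[k]
    a <- p$rise[k]; cc <- p$fall[k]
    vv <- rep(plan$vpk[k], sum(i))
    r <- u < a
    vv[r] <- plan$v0[k] +
      (plan$vpk[k] - plan$v0[k]) * sin(pi * u[r] / (2 * a))^2
    if (cc > 0) {
      f <- u > 1 - cc
      vv[f] <- plan$vpk[k] - (plan$vpk[k] - plan$v1[k]) *
        sin(pi * (u[f] - (1 - cc)) / (2 * cc))^2
    }
    v[i] <- vv
  }
  for (k in 1:4) {
    i <- tt >= plan$cod_start[k] & tt < plan$cod_end[k]
    if (!any(i)) next
    tau <- tt[i] - plan$cod_start[k]; d <- plan$d[k]
    vin <- plan$ve[k]; vmin <- plan$vm[k]
    first <- tau < d / 2
    vv <- numeric(sum(i))
    vv[first] <- vin + (vmin - vin) * sin(pi * tau[first] / d)^2
    vv[!first] <- vmin + (vin - vmin) * sin(pi * (tau[!first] - d / 2) / d)^2
    v[i] <- vv
  }
  i <- tt >= plan$t_end & tt < plan$t_end + p$decay_s
  if (any(i))
    v[i] <- plan$v1[5] * cos(pi * (tt[i] - plan$t_end) / (2 * p$decay_s))^2
  v
}

# Geometric layout (relative to COD duration d) of the AP-acceleration
# burst for each COD type. Positive components are later scaled so the
# integral between the flanking minima hits the target impulse.
cod_burst_components <- function(type, ts, d) {
  dip_w <- 0.16 * d / 2                   # half-width of boundary dips
  if (type == "cod90_first") {
    list(dips = list(c(ts, -14, dip_w, dip_w),
                     c(ts + d, -12, dip_w, dip_w)),
         peaks = list(c(ts + 0.30 * d, 24, 0.15 * d, 0.28 * d),   # braking
                      c(ts + 0.75 * d, 14.4, 0.17 * d, 0.11 * d), # push
                      c(ts + 0.58 * d, 5, 0.28 * d, 0.30 * d)),   # pedestal
         n_impact = 2L)
  } else if (type == "cod90_last") {
    # unimodal merged braking+push (pivot into the backward sprint)
    list(dips = list(c(ts, -14, dip_w, dip_w),
                     c(ts + d, -12, dip_w, dip_w)),
         peaks = list(c(ts + 0.45 * d, 24, 0.35 * d, 0.40 * d)),
         n_impact = 1L)
  } else {                                # 180 degree split-step
    list(dips = list(c(ts, -16, dip_w, dip_w),          # PFC heel strike
                     c(ts + 0.36 * d, -12, dip_w, dip_w), # FFC heel strike
                     c(ts + d, -12, dip_w, dip_w)),       # second toe-off
         peaks = list(c(ts + 0.20 * d, 22, 0.10 * d, 0.14 * d),   # PFC
                      c(ts + 0.53 * d, 26, 0.10 * d, 0.175 * d),  # FFC
                      c(ts + 0.82 * d, 20, 0.115 * d, 0.09 * d),  # push
                      c(ts + 0.66 * d, 5, 0.28 * d, 0.28 * d)),   # pedestal
         n_impact = 2L)
  }
}

eval_components <- function(t, comps, scale_pos = 1) {
  y <- numeric(length(t))
  for (cmp in comps$dips)
    y <- y + rc_pulse(t, cmp[1], cmp[2], cmp[3], cmp[4])
  for (cmp in comps$peaks)
    y <- y + scale_pos * rc_pulse(t, cmp[1], cmp[2], cmp[3], cmp[4])
  y
}

# Scale the positive components of one COD burst so that the integral of
# the noise-free AP signal between the flanking local minima equals the
# target impulse. Two fixed-point passes are ample (minima barely move).
calibrate_cod_scale <- function(t, fs, comps, target) {
  ts <- comps$dips[[1]][1]
  te <- comps$dips[[length(comps$dips)]][1]
  win <- t >= ts - 0.1 & t <= te + 0.1
  tw <- t[win]
  s <- 1
  for (pass in 1:2) {
    y <- eval_components(tw, comps, s)
    i0 <- which.min(abs(tw - ts)); i1 <- which.min(abs(tw - te))
    i0 <- local_min_near(y, i0); i1 <- local_min_near(y, i1)
    ipos <- trapz(tw[i0:i1], eval_components(tw[i0:i1], comps, 1) -
                    eval_components_neg(tw[i0:i1], comps))
    ineg <- trapz(tw[i0:i1], eval_components_neg(tw[i0:i1], comps))
    s <- (target - ineg) / ipos
  }
  s
}

eval_components_neg <- function(t, comps) {
  y <- numeric(length(t))
  for (cmp in comps$dips)
    y <- y + rc_pulse(t, cmp[1], cmp[2], cmp[3], cmp[4])
  y
}

local_min_near <- function(y, i) {
  n <- length(y)
  while (i > 1L && y[i - 1L] < y[i]) i <- i - 1L
  while (i < n && y[i + 1L] < y[i]) i <- i + 1L
  i
}

#' Simulate one T-test trial
#'
#' Generates the 200 Hz tri-axial trunk acceleration (plus angular
#' velocity), the 10 Hz GNSS ground-speed trace on its own phase-offset
#' clock, and the exact ground-truth timeline. Deterministic given the
#' spec, including its seed.
#'
#' @param spec a [trial_spec()].
#' @return list with elements `trace` ([inertial_trace()]),
#'   `speed` ([gnss_speed_trace()]) and `truth` (class `ground_truth`:
#'   `timeline`, `photocell_time_s`, `cone_touch_times_s`).
#' @export
simulate_trial <- function(spec) {
  validate_trial_spec(spec)
  plan <- sim_plan(spec)
  fs <- spec$fs_imu_hz
  t <- seq(0, plan$duration, by = 1 / fs)
  n <- length(t)

  ap <- numeric(n)
  step_times <- list()
  impact_times <- numeric(0)   # impact instants that get HF resonance

  # -- start sequence: counter-movement dip, push-off peak -----------------
  ap <- ap + rc_pulse(t, plan$t_start, -2.5, 0.06, 0.06)
  ap <- ap + rc_pulse(t, plan$t_start + 0.13, 6.5, 0.11, 0.11)

  # -- displacement-phase steps -------------------------------------------
  dip_amp <- -10; dip_w <- 0.035
  step_wl <- 0.05; step_wr <- 0.11
  # per-step impulse between flanking dips: amp*(wl+wr)/2 - dip area
  step_amp <- (spec$dp_step_impulse_mps - 2 * dip_amp * dip_w / 2) /
    ((step_wl + step_wr) / 2)
  dp_lo <- c(plan$t_start + 0.38, plan$cod_end + 0.22)
  dp_hi <- c(plan$cod_start - 0.20, plan$t_end - 0.10)
  for (k in 1:5) {
    st <- seq(dp_lo[k], dp_hi[k], by = 1 / spec$step_cadence_hz)
    if (!length(st)) st <- (dp_lo[k] + dp_hi[k]) / 2
    step_times[[k]] <- st
    sgn <- if (k == 5) -1 else 1         # backward sprint: mirrored pattern
    for (s0 in st) {
      ap <- ap + sgn * rc_pulse(t, s0 - 0.10, dip_amp, dip_w, dip_w)
      ap <- ap + sgn * rc_pulse(t, s0, step_amp, step_wl, step_wr)
      impact_times <- c(impact_times, s0)
    }
  }

  # -- COD bursts, impulse-calibrated -------------------------------------
  types <- c("cod90_first", "cod180", "cod180", "cod90_last")
  cod_scales <- numeric(4)
  for (k in 1:4) {
    comps <- cod_burst_components(types[k], plan$cod_start[k], plan$d[k])
    s <- calibrate_cod_scale(t, fs, comps, spec$cod_impulses_mps[k])
    cod_scales[k] <- s
    ap <- ap + eval_components(t, comps, s)
    impact_times <- c(impact_times,
                      vapply(comps$peaks, `[`,
                             numeric(1), 1)[seq_len(comps$n_impact)])
  }

  trial <- with_seed(spec$seed, {
    # -- high-frequency post-impact resonance (>15 Hz) --------------------
    if (spec$hf_artifact_gain > 0) {
      ring_f <- 45
      for (t0 in impact_times) {
        i <- t >= t0 & t <= t0 + 0.08
        ap[i] <- ap[i] + spec$hf_artifact_gain * 4 *
          exp(-(t[i] - t0) / 0.03) * sin(2 * pi * ring_f * (t[i] - t0))
      }
    }
    ap <- ap + rnorm(n, 0, spec$noise_sd_mps2)

    # -- vertical: gravity, impact bumps, flight-phase sub-g dips ---------
    av <- rep(9.81, n)
    moving <- t >= plan$t_start & t <= plan$t_end
    av[moving] <- av[moving] + 0.5
    for (k in 1:5) for (s0 in step_times[[k]])
      av <- av + rc_pulse(t, s0, 12, 0.05, 0.09)
    for (k in 1:4) {
      av <- av + rc_pulse(t, plan$cod_start[k] - 0.09, -8.5, 0.05, 0.05)
      av <- av + rc_pulse(t, plan$cod_end[k] + 0.09, -8.5, 0.05, 0.05)
      av <- av + rc_pulse(t, plan$cod_start[k] + plan$d[k] / 2, 14,
                          0.12, 0.12)
    }
    av <- av + rnorm(n, 0, spec$noise_sd_mps2)

    # -- medio-lateral: shuffle oscillation, COD bursts -------------------
    am <- numeric(n)
    for (k in c(2, 3, 4)) {
      i <- t >= plan$cod_end[k - 1] & t <= plan$cod_start[k]
      am[i] <- am[i] + 6 * sin(2 * pi * spec$step_cadence_hz *
                                 (t[i] - plan$cod_end[k - 1]))
    }
    for (k in 1:4) {
      sgn <- c(1, -1, 1, -1)[k]
      am <- am + sgn * rc_pulse(t, plan$cod_start[k] + plan$d[k] / 2, 10,
                                plan$d[k] / 3, plan$d[k] / 3)
    }
    am <- am + rnorm(n, 0, spec$noise_sd_mps2)

    # -- angular velocity (not used by detection; realism) ----------------
    gz <- numeric(n)
    for (k in 1:4) {
      ang <- c(pi / 2, pi, pi, pi / 2)[k] * c(1, -1, 1, -1)[k]
      gz <- gz + rc_pulse(t, plan$cod_start[k] + plan$d[k] / 2,
                          2 * ang / plan$d[k], plan$d[k] / 2, plan$d[k] / 2)
    }
    gyr <- cbind(gyr_x = rnorm(n, 0, 0.2), gyr_y = rnorm(n, 0, 0.2),
                 gyr_z = gz + rnorm(n, 0, 0.2))

    # -- GNSS ground speed on its own clock -------------------------------
    tg <- seq(spec$gnss_phase_offset_s, plan$duration,
              by = 1 / spec$fs_gnss_hz)
    vg <- sim_speed_at(tg, plan) +
      rnorm(length(tg), 0, 0.06 * spec$noise_sd_mps2)
    vg <- pmax(vg, 0)
    list(ap = ap, av = av, am = am, gyr = gyr, tg = tg, vg = vg)
  })

  timeline <- event_timeline(
    t_start_s = plan$t_start,
    cod = data.frame(order = 1:4, angle_deg = c(90, 180, 180, 90),
                     t_start_s = plan$cod_start, t_end_s = plan$cod_end),
    t_end_s = plan$t_end)
  truth <- structure(list(
    timeline = timeline,
    photocell_time_s = plan$t_end - plan$t_start,
    cone_touch_times_s = plan$cod_start + plan$d / 2,
    cod_scales = cod_scales),
    class = "ground_truth")

  list(trace = inertial_trace(t, trial$ap, trial$am, trial$av,
                              gyr = trial$gyr, fs_hz = fs),
       speed = gnss_speed_trace(trial$tg, trial$vg,
                                fs_hz = spec$fs_gnss_hz),
       truth = truth)
}

#' GNSS ground-speed trace container
#'
#' @param time_s sample instants (s), uniform at `1/fs_hz`.
#' @param speed_mps scalar over-ground speed (m/s), non-negative.
#' @param fs_hz sampling rate, 10 Hz by default.
#' @return object of class `gnss_speed_trace`.
#' @export
gnss_speed_trace <- function(time_s, speed_mps, fs_hz = 10) {
  if (length(time_s) != length(speed_mps) || length(time_s) < 2L)
    codseg_stop("codseg_invalid_argument",
                "speed trace needs matching time/speed vectors (>= 2)")
  if (any(!is.finite(speed_mps)) ||
      any(abs(diff(time_s) - 1 / fs_hz) > 1e-6))
    codseg_stop("codseg_invalid_argument",
                "speed trace must be finite and uniform at 1/fs")
  structure(list(time_s = time_s, speed_mps = speed_mps, fs_hz = fs_hz),
            class = "gnss_speed_trace")
}

#' Quantize ground-truth events into simulated video labels
#'
#' Each COD start/end instant is perturbed by a uniform integer number
#' of frames in `[-jitter, +jitter]` and snapped to the 1/60 s video
#' grid, emulating manual labelling accuracy of about 3 frames. The
#' photocell completion time is copied unperturbed.
#'
#' @param gt a `ground_truth` object from [simulate_trial()].
#' @param jitter_frames max jitter in 60 Hz frames (>= 0).
#' @param seed RNG seed for the jitter draw.
#' @param frame_rate_hz label grid rate (60 Hz video by default).
#' @return object of class `reference_labels`: `cod_events` (data.frame
#'   `order`, `angle_deg`, `t_start_s`, `t_end_s` on the 1/60 s grid),
#'   `photocell_time_s`, `t_start_s` (photocell-synchronised test start,
#'   unperturbed), `frame_rate_hz`.
#' @export
quantize_labels <- function(gt, jitter_frames = 3L, seed = 1L,
                            frame_rate_hz = 60) {
  if (jitter_frames < 0)
    codseg_stop("codseg_invalid_argument", "jitter_frames must be >= 0")
  cod <- gt$timeline$cod
  snap <- function(x, k) (round(x * frame_rate_hz) + k) / frame_rate_hz
  with_seed(seed, {
    js <- sample.int(2L * jitter_frames + 1L, 4L, replace = TRUE) -
      jitter_frames - 1L
    je <- sample.int(2L * jitter_frames + 1L, 4L, replace = TRUE) -
      jitter_frames - 1L
    structure(list(
      cod_events = data.frame(order = cod$order, angle_deg = cod$angle_deg,
                              t_start_s = snap(cod$t_start_s, js),
                              t_end_s = snap(cod$t_end_s, je)),
      photocell_time_s = gt$photocell_time_s,
      t_start_s = gt$timeline$t_start_s,
      frame_rate_hz = frame_rate_hz),
      class = "reference_labels")
  })
}
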