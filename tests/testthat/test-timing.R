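# Completion-time estimation, segment durations, performance metrics.

test_that("estimate_completion_time solves the distance equation", {
  tt <- seq(0, 12, by = 0.1)
  # constant 3.86 m/s from 8.0 s: (9.14 - 1.42)/3.86 = 2.0 s exactly
  sp <- gnss_speed_trace(tt, rep(3.86, length(tt)))
  expect_equal(estimate_completion_time(sp, 8.0), 10.0, tolerance = 1e-9)
  # linear ramp v = a t: T = sqrt(2 D / a + t0^2), trapezoid-exact
  a <- 0.55; t0 <- 3.0; D <- 9.14 - 1.42
  sp2 <- gnss_speed_trace(tt, a * tt)
  expect_equal(estimate_completion_time(sp2, t0),
               sqrt(2 * D / a + t0^2), tolerance = 1e-3)
  # zero speed never covers the distance
  sp0 <- gnss_speed_trace(tt, rep(0, length(tt)))
  expect_error(estimate_completion_time(sp0, 8.0),
               class = "codseg_insufficient_track")
  expect_error(estimate_completion_time(NULL, 8.0),
               class = "codseg_no_gnss")
  expect_error(estimate_completion_time(sp, 8.0, L_dp5 = 1, L_arm = 2),
               class = "codseg_invalid_argument")
})

test_that("completion estimate is strictly monotone in arm reach", {
  tt <- seq(0, 12, by = 0.1)
  set.seed(2)
  sp <- gnss_speed_trace(tt, 3 + 0.5 * sin(tt) + runif(length(tt), 0, 0.2))
  Ts <- vapply(c(0.5, 1.0, 1.42, 2.0), function(arm)
    estimate_completion_time(sp, 6.0, L_arm = arm), numeric(1))
  expect_true(all(diff(Ts) < 0))
})

test_that("segment durations partition the timeline", {
  cod <- data.frame(order = 1:4, angle_deg = c(90, 180, 180, 90),
                    t_start_s = c(2, 4, 6, 8), t_end_s = c(2.5, 4.5, 6.5, 8.5))
  tl <- event_timeline(0.5, cod, 10.25)
  d <- segment_durations(tl)
  expect_equal(d$cod_s, rep(0.5, 4))
  expect_equal(d$dp_s, c(1.5, 1.5, 1.5, 1.5, 1.75))
  expect_equal(sum(d$dp_s) + sum(d$cod_s), 10.25 - 0.5, tolerance = 1e-9)
  # generator truth reproduces the specified COD durations exactly
  spec <- trial_spec(seed = 5)
  trial <- simulate_trial(spec)
  dt <- segment_durations(trial$truth$timeline)
  expect_equal(dt$cod_s, spec$cod_durations_s, tolerance = 1e-9)
  # random valid timelines satisfy the sum property
  set.seed(77)
  for (i in 1:20) {
    ev <- sort(runif(10, 0, 20))
    tli <- event_timeline(ev[1],
                          data.frame(order = 1:4, angle_deg = c(90, 180, 180, 90),
                                     t_start_s = ev[c(2, 4, 6, 8)],
                                     t_end_s = ev[c(3, 5, 7, 9)]), ev[10])
    di <- segment_durations(tli)
    expect_equal(sum(di$dp_s) + sum(di$cod_s), ev[10] - ev[1],
                 tolerance = 1e-9)
  }
  # degenerate timelines are rejected by the constructor
  expect_error(event_timeline(0.5, within(cod, t_end_s[1] <- t_start_s[1]),
                              10), class = "codseg_invalid_timeline")
  expect_error(segment_durations(event_timeline(0.5, cod)),
               class = "codseg_invalid_timeline")
})

test_that("total cutting time sums approach, COD and exit phases", {
  d <- structure(list(dp_s = rep(1, 5), cod_s = rep(1, 4)),
                 class = "segment_durations")
  expect_equal(total_cutting_time(d), rep(3, 4))
  set.seed(99)
  for (i in 1:20) {
    d <- structure(list(dp_s = runif(5, 0.5, 3), cod_s = runif(4, 0.2, 1)),
                   class = "segment_durations")
    tct <- total_cutting_time(d)
    expect_equal(tct, d$dp_s[1:4] + d$cod_s + d$dp_s[2:5], tolerance = 1e-12)
    # algebraic identity on the sums
    expect_equal(sum(tct),
                 sum(d$dp_s) + sum(d$cod_s) + sum(d$dp_s[2:4]),
                 tolerance = 1e-12)
  }
})

random_cohort <- function(n, completion = NULL) {
  lapply(seq_len(n), function(i) {
    d <- structure(list(dp_s = runif(5, 0.8, 2.2), cod_s = runif(4, 0.3, 0.7)),
                   class = "segment_durations")
    list(durations = d,
         completion_time_s = completion[i] %||%
           (sum(d$dp_s) + sum(d$cod_s)),
         id = sprintf("athlete%02d", i))
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cohort_performance: correlations, groups, tie handling", {
  set.seed(11)
  # cohort where cutting time is proportional to completion time
  base <- runif(12, 0.4, 0.6)
  trials <- lapply(seq_len(12), function(i) {
    d <- structure(list(dp_s = rep(base[i], 5), cod_s = rep(base[i], 4)),
                   class = "segment_durations")
    list(durations = d, completion_time_s = 9 * base[i])
  })
  perf <- cohort_performance(trials)
  expect_equal(perf$pearson$r, rep(1, 4), tolerance = 1e-9)
  # r equals the covariance-formula oracle, and is permutation-invariant
  trials2 <- random_cohort(15)
  perf2 <- cohort_performance(trials2)
  ct <- vapply(trials2, `[[`, numeric(1), "completion_time_s")
  for (k in 1:4) {
    tct_k <- vapply(trials2, function(x)
      total_cutting_time(x$durations)[k], numeric(1))
    expect_equal(perf2$pearson$r[k], pearson_oracle(tct_k, ct),
                 tolerance = 1e-12)
  }
  perm <- sample(15)
  perf2p <- cohort_performance(trials2[perm])
  expect_equal(perf2p$pearson$r, perf2$pearson$r, tolerance = 1e-12)
  # groups: best = five smallest completion times
  expect_equal(sort(perf2$best_ids),
               sort(sprintf("athlete%02d", order(ct)[1:5])))
  expect_equal(dim(perf2$group_means), c(2L, 9L))
  # tie at the 5th rank: earliest trial wins and the tie is flagged
  trials3 <- random_cohort(10, completion = c(1, 2, 3, 4, 5, 5, 7, 8, 9, 10))
  perf3 <- cohort_performance(trials3)
  expect_true(perf3$tie_flag)
  expect_true("athlete05" %in% perf3$best_ids)
  expect_false("athlete06" %in% perf3$best_ids)
  expect_error(cohort_performance(trials3[1:8]),
               class = "codseg_insufficient_data")
})

test_that("benchmark completion-time error is tightly distributed", {
  bm <- benchmark_default()
  expect_lt(sd(bm$completion_errors_s), 0.22)
  # estimator on the true COD4 end recovers the true end closely
  trial <- default_trial(seed = 1L)
  tl <- trial$truth$timeline
  Tend <- estimate_completion_time(trial$speed, tl$cod$t_end_s[4])
  expect_equal(Tend, tl$t_end_s, tolerance = 0.05)
})
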