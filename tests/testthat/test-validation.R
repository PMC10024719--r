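# Error metrics, Bland-Altman, shift detection, normality tests.

mk_tl <- function(ev) {
  event_timeline(ev[1], data.frame(order = 1:4,
                                   angle_deg = c(90, 180, 180, 90),
                                   t_start_s = ev[c(2, 4, 6, 8)],
                                   t_end_s = ev[c(3, 5, 7, 9)]), ev[10])
}

test_that("event errors are signed reference-minus-estimate in ms", {
  ev <- c(1, 2, 2.5, 4, 4.5, 6, 6.5, 8, 8.5, 10)
  est <- mk_tl(ev)
  expect_equal(unlist(event_errors(est, est)[, 2:3]), rep(0, 8),
               ignore_attr = TRUE)
  # uniform +50 ms shift of the estimate: all errors -50 ms
  est2 <- mk_tl(ev + 0.05); est2$t_start_s <- est$t_start_s
  ee <- event_errors(est2, est)
  expect_equal(c(ee$eps_start_ms, ee$eps_end_ms), rep(-50, 8),
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    r <- sort(runif(10, 0, 20)); e <- sort(runif(10, 0, 20))
    ee <- event_errors(mk_tl(e), mk_tl(r))
    expect_equal(ee$eps_start_ms, (r[c(2, 4, 6, 8)] - e[c(2, 4, 6, 8)]) * 1000,
                 tolerance = 1e-9)
    expect_equal(ee$eps_end_ms, (r[c(3, 5, 7, 9)] - e[c(3, 5, 7, 9)]) * 1000,
                 tolerance = 1e-9)
  }
})

test_that("duration errors follow the signed ms / percent definitions", {
  mk_d <- function(dp, cod) structure(list(dp_s = dp, cod_s = cod),
                                      class = "segment_durations")
  ref <- mk_d(rep(0.5, 5), rep(0.5, 4))
  est <- mk_d(rep(0.45, 5), rep(0.45, 4))
  de <- duration_errors(est, ref)
  expect_equal(de$eps_abs_ms, rep(50, 9), tolerance = 1e-9)
  expect_equal(de$eps_rel_pct, rep(10, 9), tolerance = 1e-9)
  expect_equal(duration_errors(ref, ref)$eps_abs_ms, rep(0, 9))
  set.seed(21)
  for (i in 1:20) {
    r <- mk_d(runif(5, 0.5, 2), runif(4, 0.3, 0.8))
    e <- mk_d(runif(5, 0.5, 2), runif(4, 0.3, 0.8))
    de <- duration_errors(e, r)
    dr <- c(r$dp_s, r$cod_s); dd <- c(e$dp_s, e$cod_s)
    expect_equal(de$eps_abs_ms, (dr - dd) * 1000, tolerance = 1e-12)
    expect_equal(de$eps_rel_pct, (dr - dd) / dr * 100, tolerance = 1e-12)
    # ms vs % bookkeeping identity
    expect_equal(de$eps_rel_pct, de$eps_abs_ms / (dr * 10),
                 tolerance = 1e-12)
  }
  expect_error(duration_errors(est, mk_d(rep(0, 5), rep(0.5, 4))),
               class = "codseg_degenerate_reference")
})

test_that("completion error keeps the reference-minus-estimate sign", {
  expect_equal(completion_error(9.11, 9.27), -0.16, tolerance = 1e-12)
  expect_equal(completion_error(5, 5), 0)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 8, 11); b <- runif(1, 8, 11)
    expect_equal(completion_error(a, b), a - b, tolerance = 1e-12)
  }
})

test_that("Bland-Altman matches the direct formulas", {
  z <- bland_altman(rep(0, 10), rep(0, 10))
  expect_equal(unlist(z[c("bias", "loa_low", "loa_high", "trend_slope")]),
               c(bias = 0, loa_low = 0, loa_high = 0, trend_slope = 0))
  z2 <- bland_altman(c(-1, 0, 1))
  expect_equal(z2$bias, 0)
  expect_equal(z2$loa_high, 1.96, tolerance = 1e-12)
  expect_equal(z2$loa_low, -1.96, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:30) {
    x <- rnorm(25); y <- rnorm(25)
    z <- bland_altman(x, y)
    d <- x - y; m <- (x + y) / 2
    expect_equal(z$bias, sum(d) / 25, tolerance = 1e-12)
    expect_equal(z$loa_high - z$bias,
                 1.96 * sqrt(sum((d - mean(d))^2) / 24), tolerance = 1e-12)
    # LOA symmetric about the bias by construction
    expect_equal(z$loa_high - z$bias, z$bias - z$loa_low, tolerance = 1e-12)
    expect_equal(z$trend_slope,
                 sum((m - mean(m)) * (d - mean(d))) / sum((m - mean(m))^2),
                 tolerance = 1e-12)
  }
  expect_error(bland_altman(c(1, 2)), class = "codseg_insufficient_data")
})

test_that("shift detection compares mean magnitude against SD", {
  e <- list(a = c(40, 60, 80),            # mean 60, sd 20 -> positive
            b = c(-40, 10, 60),           # mean 10, sd 50 -> none
            c = c(-40, -30, -20),         # mean -30, sd 10 -> negative
            d = 15)                       # single value -> undetermined
  expect_equal(unname(detect_shift(e)),
               c("positive", "none", "negative", "undetermined"))
})

test_that("normality tests are calibrated", {
  # standard-normal samples: plain KS with estimated moments rarely
  # rejects at the 1% level
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality(rnorm(500), "event")$p_value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # uniform samples: Shapiro-Wilk rejects essentially always at n = 500
  bad <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    normality(runif(500), "completion")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(bad), 0.95)
  expect_error(normality(rep(1, 50), "event"),
               class = "codseg_insufficient_data")
  expect_error(normality(c(1, 2), "completion"),
               class = "codseg_insufficient_data")
  # Lilliefors-corrected p is smaller than plain KS on the same sample
  set.seed(123)
  x <- rnorm(60)
  expect_lt(normality(x, "event", lilliefors = TRUE, mc_reps = 500)$p_value,
            normality(x, "event")$p_value + 1e-9)
})

test_that("validation_report aggregates pooled statistics", {
  ev <- data.frame(order = rep(1:4, 3),
                   eps_start_ms = rnorm(12, 0, 30),
                   eps_end_ms = rnorm(12, 0, 30))
  du <- data.frame(segment = rep(c(paste0("DP", 1:5), paste0("COD", 1:4)), 2),
                   eps_abs_ms = rnorm(18, 0, 40),
                   eps_rel_pct = rnorm(18, 0, 4))
  rep_ <- validation_report(ev, du, rnorm(5, -0.1, 0.2),
                            list(p1 = rnorm(8, 50, 10),
                                 p2 = rnorm(8, 0, 60)))
  expect_true(rep_$loa_low_ms <= rep_$bias_ms &&
                rep_$bias_ms <= rep_$loa_high_ms)
  expect_equal(unname(rep_$shift_flags["p1"]), "positive")
  expect_true(is.numeric(rep_$normality_p$event))
})
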