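# Independent oracles and shared fixtures. Oracles are deliberately
# written as brute-force / closed-form re-derivations, not calls into
# the package code paths they check.

# O(n^2) topographic prominence of every strict local maximum.
prominence_oracle <- function(x) {
  n <- length(x)
  peaks <- which(diff(sign(diff(x))) == -2) + 1L
  prom <- vapply(peaks, function(i) {
    lhs <- which(x[seq_len(i - 1L)] > x[i])
    lo <- if (length(lhs)) max(lhs) + 1L else 1L
    lbase <- min(x[lo:(i - 1L)])
    rhs <- which(x[(i + 1L):n] > x[i]) + i
    hi <- if (length(rhs)) min(rhs) - 1L else n
    rbase <- min(x[(i + 1L):hi])
    x[i] - max(lbase, rbase)
  }, numeric(1))
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}

trapz_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1L))
    s <- s + (y[i] + y[i + 1L]) / 2 * (t[i + 1L] - t[i])
  s
}

pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Raised-cosine helper for handcrafted fixture signals.
fixture_pulse <- function(t, center, amp, w) {
  y <- numeric(length(t))
  i <- abs(t - center) <= w / 2
  y[i] <- amp * cos(pi * (t[i] - center) / w)^2
  y
}

# Shared 50-trial benchmarks, computed once per test run.
.bm_cache <- new.env(parent = emptyenv())

benchmark_default <- function() {
  if (is.null(.bm_cache$default))
    .bm_cache$default <- run_benchmark(50L, 1L)
  .bm_cache$default
}

benchmark_noiseless <- function() {
  if (is.null(.bm_cache$noiseless))
    .bm_cache$noiseless <- run_benchmark(
      50L, 1L, jitter_frames = 0L,
      spec_overrides = list(noise_sd_mps2 = 0, hf_artifact_gain = 0))
  .bm_cache$noiseless
}

default_trial <- function(seed = 1L, ...) {
  key <- paste0("trial_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.bm_cache[[key]]))
    .bm_cache[[key]] <- simulate_trial(trial_spec(seed = seed, ...))
  .bm_cache[[key]]
}
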