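# Independent brute-force oracles and small signal builders.
# These re-state the difference equations as plain sample-by-sample loops,
# deliberately not sharing any code with the package implementation.

oracle_baseline <- function(r, a = 127 / 128) {
  n <- length(r)
  y <- numeric(n)
  y1 <- r[1]; y2 <- r[1]  # history seeded at the first sample
  for (i in seq_len(n)) {
    y[i] <- 2 * a * y1 - a^2 * y2 + (1 - 2 * a + a^2) * r[i]
    y2 <- y1; y1 <- y[i]
  }
  y
}

oracle_lowpass12 <- function(r) {
  a1 <- 46 / 512; a2 <- 93 / 512; b1 <- 125 / 128; b2 <- 44 / 128
  n <- length(r)
  y <- numeric(n)
  xv <- function(i) if (i >= 1) r[i] else 0
  yv <- function(i) if (i >= 1) y[i] else 0
  for (i in seq_len(n))
    y[i] <- a1 * xv(i) + a2 * xv(i - 1) + a1 * xv(i - 2) +
      b1 * yv(i - 1) - b2 * yv(i - 2)
  y
}

oracle_bandpass13 <- function(v) {
  a1 <- 16139 / 2^22; a2 <- 32278 / 2^22
  b1 <- 15565 / 4096; b2 <- 22279 / 4096; b3 <- 14239 / 4096; b4 <- 3429 / 4096
  n <- length(v)
  y <- numeric(n)
  xv <- function(i) if (i >= 1) v[i] else 0
  yv <- function(i) if (i >= 1) y[i] else 0
  for (i in seq_len(n))
    y[i] <- a1 * xv(i) - a2 * xv(i - 2) + a1 * xv(i - 4) +
      b1 * yv(i - 1) - b2 * yv(i - 2) + b3 * yv(i - 3) - b4 * yv(i - 4)
  y
}

# Closed-form magnitude response of the baseline low-pass recursion.
baseline_gain <- function(freq_hz, sample_rate = 100, a = 127 / 128) {
  z <- exp(-1i * 2 * pi * freq_hz / sample_rate)
  Mod((1 - 2 * a + a^2) / (1 - 2 * a * z + a^2 * z^2))
}

naive_step_mad_mg <- function(r, r_lf, j, n) {
  acc <- 0
  for (i in j:(j + n - 1)) acc <- acc + abs(r[i] - r_lf[i])
  1000 * acc / n
}

# steady-state amplitude of a filtered sinusoid (last half of the trace)
steady_amplitude <- function(y) {
  tail_part <- y[(length(y) %/% 2):length(y)]
  (max(tail_part) - min(tail_part)) / 2
}

sinusoid <- function(freq_hz, amp, duration_s, sample_rate = 100, offset = 0) {
  t <- seq_len(duration_s * sample_rate) / sample_rate
  offset + amp * sin(2 * pi * freq_hz * t)
}

# quick steady-walk recording for feature tests
steady_recording <- function(duration_s = 60, speed = 1.4, seed = 42,
                             noise_sd = 0.02, amp = NULL) {
  amap <- if (is.null(amp)) {
    function(v) ifelse(v <= 0, 0, pmax(0.25 * v, 0.08))
  } else {
    function(v) rep(amp, length(v))
  }
  prof <- gait_profile(stages = data.frame(duration_s = duration_s,
                                           speed_ms = speed),
                       amp_map = amap, noise_sd = noise_sd, seed = seed)
  simulate_recording(prof)
}
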