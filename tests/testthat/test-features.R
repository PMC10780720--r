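make_steps <- function(j, n) {
  out <- data.frame(k = seq_along(j), j = j, n = n,
                    step_time_s = n / 100, bout = 1L)
  class(out) <- c("step_table", "data.frame")
  out
}

test_that("per-step MAD matches closed forms and the naive-loop oracle", {
  # constant deviation of 0.1 g -> exactly 100 mg
  r <- rep(1.1, 200); r_lf <- rep(1.0, 200)
  sf <- step_mad(r, r_lf, make_steps(j = 51, n = 100))
  expect_equal(sf$mad_mg, 100)

  # sinusoidal deviation over whole cycles: mean |A sin| = 2A/pi
  A <- 0.5
  r2 <- 1 + sinusoid(2, A, 10)  # 2 Hz at 100 Hz: 50-sample period
  sf2 <- step_mad(r2, rep(1, 1000), make_steps(j = 101, n = 200))
  expect_equal(sf2$mad_mg, 1000 * 2 * A / pi, tolerance = 0.01)

  # random steps agree with a brute-force loop to 1e-12
  set.seed(31)
  r3 <- 1 + rnorm(2000, 0, 0.2); lf3 <- 1 + rnorm(2000, 0, 0.01)
  j <- c(5, 300, 1500); n <- c(77, 120, 301)
  sf3 <- step_mad(r3, lf3, make_steps(j, n))
  for (i in 1:3)
    expect_equal(sf3$mad_mg[i], naive_step_mad_mg(r3, lf3, j[i], n[i]),
                 tolerance = 1e-12)

  # out-of-bounds step errors
  expect_error(step_mad(r3, lf3, make_steps(1990, 50)), "bounds")
})

test_that("floating MAD is the sample-weighted mean of adjacent steps", {
  base <- make_steps(j = c(1, 101), n = c(100, 100))
  base$mad_mg <- c(10, 20)
  ff <- floating_features(base, 100)
  expect_equal(nrow(ff), 1)            # first step of a bout has no epoch
  expect_equal(ff$mad_mg, 15)          # equal N -> unweighted mean
  expect_equal(ff$fs_hz, 1)            # 2*100/(100+100)
  expect_equal(ff$start_sample, 1)
  expect_equal(ff$end_sample, 200)

  # unequal N weighting: (10*100 + 4*50) / 150 = 8
  s2 <- make_steps(j = c(1, 101), n = c(100, 50))
  s2$mad_mg <- c(10, 4)
  expect_equal(floating_features(s2, 100)$mad_mg, 8)

  # identical steps: idempotence
  s3 <- make_steps(j = c(1, 81), n = c(80, 80))
  s3$mad_mg <- c(7, 7)
  expect_equal(floating_features(s3, 100)$mad_mg, 7)
})

test_that("floating epochs satisfy betweenness and one-step overlap", {
  set.seed(17)
  n_steps <- 30
  s <- make_steps(j = cumsum(c(1, sample(40:120, n_steps - 1, TRUE))),
                  n = sample(40:120, n_steps, TRUE))
  # rebuild contiguity: j[k+1] = j[k] + n[k]
  s$j <- cumsum(c(1, s$n[-n_steps]))
  s$mad_mg <- runif(n_steps, 50, 400)
  ff <- floating_features(s, 100)
  expect_equal(nrow(ff), n_steps - 1)
  lo <- pmin(s$mad_mg[-n_steps], s$mad_mg[-1])
  hi <- pmax(s$mad_mg[-n_steps], s$mad_mg[-1])
  expect_true(all(ff$mad_mg >= lo - 1e-12 & ff$mad_mg <= hi + 1e-12))

  # every interior step participates in exactly two epochs: epoch k spans
  # steps k-1 and k, so step counts across [start,end] pairs double up
  cover <- table(unlist(Map(seq, ff$k - 1, ff$k)))
  interior <- as.character(2:(n_steps - 1))
  expect_true(all(cover[interior] == 2))

  # dMAD telescopes over the bout
  expect_equal(sum(ff$dmad_mg_signed, na.rm = TRUE),
               ff$mad_mg[nrow(ff)] - ff$mad_mg[1])

  # step frequency is exactly 2*sr/(N_{k-1}+N_k)
  expect_equal(ff$fs_hz, 2 * 100 / (s$n[-n_steps] + s$n[-1]))
})

test_that("dMAD is signed per epoch and absolute in summaries", {
  s <- make_steps(j = c(1, 101, 201, 301), n = rep(100, 4))
  s$mad_mg <- c(100, 140, 60, 100)
  ff <- floating_features(s, 100)
  # epoch MADs: 120, 100, 80 -> signed dMADs NA, -20, -20
  expect_equal(ff$mad_mg, c(120, 100, 80))
  expect_equal(ff$dmad_mg_signed, c(NA, -20, -20))

  summ <- summarize_features(ff, "floating")
  expect_equal(summ$mean_abs_dmad_mg, 20)
  expect_equal(summ$mean_mad_mg, 100)
})

test_that("step frequency arithmetic follows the two-step definition", {
  s <- make_steps(j = c(1, 84), n = c(83, 84))
  s$mad_mg <- c(1, 1)
  expect_equal(floating_features(s, 100)$fs_hz, 200 / 167)

  s2 <- make_steps(j = c(1, 43), n = c(42, 42))
  s2$mad_mg <- c(1, 1)
  s3 <- make_steps(j = c(1, 85), n = c(84, 84))
  s3$mad_mg <- c(1, 1)
  expect_equal(floating_features(s2, 100)$fs_hz,
               2 * floating_features(s3, 100)$fs_hz)
})

test_that("fixed 6 s epochs tile the recording and match a loop oracle", {
  set.seed(23)
  r <- 1 + rnorm(6000, 0, 0.3)
  r_lf <- 1 + rnorm(6000, 0, 0.01)
  fe <- fixed_epoch_mad(r, r_lf, 100)
  expect_equal(nrow(fe), 10)           # 60 s -> 10 epochs
  expect_equal(fe$start_sample, seq(1, 5401, by = 600))
  for (e in c(1, 4, 10)) {
    idx <- ((e - 1) * 600 + 1):(e * 600)
    expect_equal(fe$mad_mg[e], 1000 * mean(abs(r[idx] - r_lf[idx])),
                 tolerance = 1e-12)
  }

  # constant resultant: exactly zero MAD with the epoch-mean reference
  fe0 <- fixed_epoch_mad(rep(1, 1200), sample_rate = 100,
                         reference = "epoch_mean")
  expect_equal(fe0$mad_mg, c(0, 0))

  # trailing partial epoch dropped; short recording warns and is empty
  expect_equal(nrow(fixed_epoch_mad(r[1:899], r_lf[1:899], 100)), 1)
  expect_warning(short <- fixed_epoch_mad(r[1:300], r_lf[1:300], 100),
                 "shorter")
  expect_equal(nrow(short), 0)
})

test_that("summaries average only epochs fully inside the window", {
  s <- make_steps(j = c(1, 101, 201), n = rep(100, 3))
  s$mad_mg <- c(100, 200, 300)
  ff <- floating_features(s, 100)   # epochs [0,2] s and [1,3] s
  expect_equal(summarize_features(ff, "floating")$mean_mad_mg, c(150 + 250) / 2)
  # a window covering only the first epoch
  one <- summarize_features(ff, "floating", window = c(0, 2))
  expect_equal(one$n_epochs, 1)
  expect_equal(one$mean_mad_mg, 150)
  expect_error(summarize_features(ff, "floating", window = c(10, 20)),
               "no floating epochs")
})

test_that("floating and fixed 6 s MAD nearly coincide on steady walking", {
  sim <- steady_recording(duration_s = 90, speed = 1.4, seed = 9)
  feats <- epoch_features(sim$recording)
  w <- c(2, 90)
  flo <- summarize_features(feats, "floating", window = w)$mean_mad_mg
  fix <- summarize_features(feats, "fixed6s", window = w)$mean_mad_mg
  expect_lt(abs(flo - fix) / fix, 0.02)
})
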