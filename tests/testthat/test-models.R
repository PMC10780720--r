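summary_of <- function(mad, dmad = NA_real_, fs = NA_real_,
                       kind = c("fixed6s", "floating")) {
  kind <- match.arg(kind)
  structure(list(epoch_kind = kind, n_epochs = 1L, window = c(0, 60),
                 mean_mad_mg = mad, mean_abs_dmad_mg = dmad,
                 mean_fs_hz = fs),
            class = "feature_summary")
}

test_that("bundled equations evaluate to their published worked examples", {
  cs6 <- bundled_model("cs_6s")
  expect_equal(predict(cs6, summary_of(0)), 7.929)
  expect_equal(predict(cs6, summary_of(300)), 7.929 + 0.033 * 300)

  expect_equal(predict(bundled_model("acdc_6s"), summary_of(0)), 10.379)

  csf <- bundled_model("cs_float")
  # all three predictor terms zero: exp(fs) term vanishes at fs = -Inf is
  # not meaningful, so evaluate the intercept-only limit algebraically
  expect_equal(csf$intercept, 7.186)
  expect_equal(csf$coef_mad, 0.033)
  expect_equal(csf$coef_dmad, 0.068)
  expect_equal(csf$coef_expfs, -0.004)

  acf <- bundled_model("acdc_float")
  expect_equal(predict(acf, summary_of(400, 40, 1.2, kind = "floating")),
               -3.160 + 0.005 * 400 + 0.218 * 40 + 2.004 * exp(1.2))
  expect_equal(predict(acf, summary_of(400, 40, 1.2, kind = "floating")),
               14.214, tolerance = 1e-4)
})

test_that("epoch-kind mismatches and missing terms are rejected", {
  expect_error(predict(bundled_model("cs_6s"),
                       summary_of(100, 5, 1, kind = "floating")),
               "mismatch")
  expect_error(predict(bundled_model("acdc_float"), summary_of(100)),
               "mismatch")
  expect_error(vo2_model(1, 1, epoch_kind = "floating"), "require")
})

test_that("per-epoch prediction traces preserve timing and linearity", {
  s <- data.frame(epoch_kind = "floating", k = 2:4, bout = 1,
                  start_sample = c(1, 101, 201),
                  end_sample = c(200, 300, 400),
                  start_s = c(0, 1, 2), end_s = c(2, 3, 4),
                  mad_mg = c(200, 200, 200),
                  dmad_mg_signed = c(5, -5, 5), fs_hz = c(2, 2, 2))
  m <- bundled_model("acdc_float")
  tr <- predict_series(m, s)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$start_s, s$start_s)
  # constant features -> constant trace
  expect_equal(diff(tr$vo2), c(0, 0))
  # singleton equals scalar predict
  expect_equal(predict_series(m, s[1, ])$vo2,
               predict(m, summary_of(200, 5, 2, kind = "floating")))
  # doubling coef_mad doubles the MAD term only
  m2 <- vo2_model(m$intercept, 2 * m$coef_mad, m$coef_dmad, m$coef_expfs,
                  epoch_kind = "floating")
  expect_equal(predict_series(m2, s)$vo2 - tr$vo2, rep(0.005 * 200, 3))
})

test_that("OLS fitting recovers generating coefficients", {
  set.seed(71)
  # noiseless fixed-epoch data from the cs_6s coefficients
  d6 <- data.frame(mean_mad_mg = runif(30, 50, 660))
  d6$vo2 <- 7.929 + 0.033 * d6$mean_mad_mg
  m6 <- fit_vo2_model(d6, "fixed6s")
  expect_equal(m6$intercept, 7.929, tolerance = 1e-8)
  expect_equal(m6$coef_mad, 0.033, tolerance = 1e-8)

  # noisy floating-epoch data from the acdc_float coefficients: each
  # estimate within 3 standard errors of truth
  truth <- bundled_model("acdc_float")
  n <- 200
  df <- data.frame(mean_mad_mg = runif(n, 50, 660),
                   mean_abs_dmad_mg = runif(n, 5, 63),
                   mean_fs_hz = runif(n, 0.5, 1.4))
  df$vo2 <- truth$intercept + truth$coef_mad * df$mean_mad_mg +
    truth$coef_dmad * df$mean_abs_dmad_mg +
    truth$coef_expfs * exp(df$mean_fs_hz) + rnorm(n, 0, 1)
  mf <- fit_vo2_model(df, "floating")
  se <- summary(attr(mf, "fit"))$coefficients[, 2]
  est <- c(mf$intercept, mf$coef_mad, mf$coef_dmad, mf$coef_expfs)
  tru <- c(truth$intercept, truth$coef_mad, truth$coef_dmad, truth$coef_expfs)
  expect_true(all(abs(est - tru) < 3 * se))
  expect_named(mf$p_values)

  # constant response: intercept c, slope 0
  dc <- data.frame(mean_mad_mg = runif(10, 50, 660), vo2 = 12)
  mc <- fit_vo2_model(dc, "fixed6s")
  expect_equal(mc$intercept, 12)
  expect_equal(mc$coef_mad, 0, tolerance = 1e-12)

  # defined failures: too few observations, rank deficiency
  expect_error(fit_vo2_model(d6[1:2, ], "fixed6s"), "observations")
  dr <- data.frame(mean_mad_mg = rep(100, 10), vo2 = rnorm(10, 15))
  expect_error(fit_vo2_model(dr, "fixed6s"), "rank")
})

test_that("fitting leaves orthogonal residuals and zero training bias", {
  set.seed(72)
  n <- 60
  df <- data.frame(mean_mad_mg = runif(n, 50, 660),
                   mean_abs_dmad_mg = runif(n, 5, 63),
                   mean_fs_hz = runif(n, 0.5, 1.4))
  df$vo2 <- 5 + 0.02 * df$mean_mad_mg + 0.1 * df$mean_abs_dmad_mg +
    exp(df$mean_fs_hz) + rnorm(n, 0, 2)
  m <- fit_vo2_model(df, "floating")
  fit <- attr(m, "fit")
  res <- resid(fit)
  X <- model.matrix(fit)
  # residuals orthogonal to every (unit-scaled) regressor column
  for (col in seq_len(ncol(X))) {
    u <- X[, col] / sqrt(sum(X[, col]^2))
    expect_lt(abs(sum(res * u)), 1e-8)
  }
  # refitting predictions reproduce the fitted values; training bias ~ 0
  st <- validate_model(m, df)
  expect_equal(attr(st, "predicted"), unname(fitted(fit)), tolerance = 1e-10)
  expect_lt(abs(st$bias), 1e-10)
  ts <- attr(m, "training_stats")
  expect_lt(abs(ts$bias), 1e-10)
  expect_equal(ts$r2, summary(fit)$r.squared)
  expect_equal(ts$see, summary(fit)$sigma)
})

test_that("agreement statistics match their closed forms", {
  # perfect prediction
  st <- agreement_stats(c(10, 20, 30), c(10, 20, 30))
  expect_equal(st$bias, 0)
  expect_equal(st$mape, 0)
  expect_equal(st$r2, 1)
  expect_equal(st$loa_high - st$loa_low, 0)

  # (20,10) vs (18,11): MAPE = (0.1 + 0.1)/2 = 10%
  expect_equal(agreement_stats(c(20, 10), c(18, 11))$mape, 10)

  # constant offset: bias -5, zero spread, perfect correlation
  meas <- c(12, 18, 25, 31)
  st2 <- agreement_stats(meas, meas + 5)
  expect_equal(st2$bias, -5)
  expect_equal(st2$sd_diff, 0)
  expect_equal(st2$r2, 1)
  expect_equal(st2$loa_low, -5)
  expect_equal(st2$loa_high, -5)
  expect_equal(st2$see, 0)

  # invariants and defined failures
  expect_true(st2$loa_low <= st2$bias && st2$bias <= st2$loa_high)
  expect_error(agreement_stats(c(10, -1), c(9, 0)), "positive")
  expect_error(agreement_stats(10, 9), "at least 2")
})

test_that("model JSON round-trips losslessly", {
  m <- vo2_model(-3.16, 0.005, 0.218, 2.004, name = "rt",
                 epoch_kind = "floating", training_label = "test",
                 p_values = c(intercept = 0.3, coef_mad = 0.6,
                              coef_dmad = 0.01, coef_expfs = 0.001))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coef_mad, m$coef_mad)
  expect_equal(back$coef_dmad, m$coef_dmad)
  expect_equal(back$coef_expfs, m$coef_expfs)
  expect_equal(back$epoch_kind, m$epoch_kind)
  expect_equal(back$name, m$name)
  expect_equal(back$p_values, m$p_values)
})
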