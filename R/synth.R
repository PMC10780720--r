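#' Describe a synthetic walking bout
#'
#' A gait profile is the recipe for one synthetic hip-worn recording: a
#' piecewise-constant speed profile plus the maps linking speed to the
#' dominant-harmonic frequency and amplitude of the acceleration signal.
#' The maps are simple monotone defaults — deliberate test scaffolding, not
#' physiological claims: frequency `1.4 + 0.4 * speed` Hz clipped to the
#' 1.2-3.0 Hz detection band, amplitude `0.25 * speed` g with a 0.08 g
#' floor (zero at zero speed).
#'
#' @param stages A data.frame (or list of 2-vectors) with columns
#'   `duration_s` and `speed_ms`: consecutive constant-speed stages.
#' @param freq_map Function speed (m/s) -> fundamental frequency (Hz).
#' @param amp_map Function speed (m/s) -> dominant-harmonic amplitude (g).
#' @param turns Optional data.frame `time_s`, `multiplier`, `width_s`:
#'   transient Gaussian amplitude modulations emulating turns.
#' @param noise_sd White-noise SD per axis in g (default 0.02, a realistic
#'   MEMS-plus-soft-tissue noise floor).
#' @param seed Integer seed; the same profile and seed always produce an
#'   identical recording.
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(stages,
                         freq_map = function(v) pmin(pmax(1.4 + 0.4 * v, 1.2), 3.0),
                         amp_map = function(v) ifelse(v <= 0, 0, pmax(0.25 * v, 0.08)),
                         turns = NULL, noise_sd = 0.02, seed = 1L) {
  if (!is.data.frame(stages))
    stages <- data.frame(duration_s = vapply(stages, `[[`, numeric(1), 1),
                         speed_ms = vapply(stages, `[[`, numeric(1), 2))
  stopifnot(all(stages$duration_s > 0), nrow(stages) > 0)
  structure(list(stages = stages, freq_map = freq_map, amp_map = amp_map,
                 turns = turns, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gait_profile")
}

# Per-sample speed, frequency, amplitude and turn modulation for a profile.
profile_tracks <- function(profile, sample_rate) {
  ns <- round(profile$stages$duration_s * sample_rate)
  v <- rep(profile$stages$speed_ms, times = ns)
  t <- (seq_along(v) - 0.5) / sample_rate
  amp <- profile$amp_map(v)
  if (!is.null(profile$turns) && nrow(profile$turns) > 0) {
    for (i in seq_len(nrow(profile$turns))) {
      tu <- profile$turns[i, ]
      s <- tu$width_s / 2.355  # FWHM -> sigma
      amp <- amp * (1 + (tu$multiplier - 1) * exp(-(t - tu$time_s)^2 / (2 * s^2)))
    }
  }
  list(t = t, v = v, f = profile$freq_map(v), amp = amp,
       stage_end_s = cumsum(profile$stages$duration_s))
}

# Noiseless axis signals for given instantaneous amplitude and phase.
clean_axes <- function(amp, phase) {
  list(x = 0.4 * amp * sin(phase + pi / 2),
       y = 0.3 * amp * sin(2 * phase + 1.1),
       z = 1 + amp * sin(phase) + 0.3 * amp * sin(2 * phase + 0.8))
}

#' Simulate a hip-worn accelerometer recording
#'
#' Generates a triaxial recording from a [gait_profile()]: the vertical
#' axis carries 1 g of gravity plus a fundamental sinusoid at the
#' instantaneous step frequency and one weaker second harmonic; the two
#' horizontal axes carry smaller phase-shifted components; independent
#' white noise is added per axis. Turns transiently scale the amplitude.
#'
#' Alongside the recording, a `synthetic_truth` list records what the
#' generator implied per stage, computed on the noiseless signal
#' independently of the filter pipeline: the true mean MAD (mean absolute
#' deviation of the clean resultant about its stage mean), the true mean
#' |dMAD| (from per-cycle MADs at the known phase boundaries), and the true
#' step frequency.
#'
#' @param profile A [gait_profile()].
#' @param sample_rate Sampling frequency in Hz (default 100).
#' @return A list with elements `recording` (a [triaxial_recording()]) and
#'   `truth` (stage-level truth data.frame plus generator settings).
#' @export
simulate_recording <- function(profile, sample_rate = 100) {
  stopifnot(inherits(profile, "gait_profile"))
  tr <- profile_tracks(profile, sample_rate)
  n <- length(tr$v)
  phase <- 2 * pi * cumsum(tr$f) / sample_rate
  cl <- clean_axes(tr$amp, phase)

  set.seed(profile$seed)
  noise <- profile$noise_sd
  rec <- triaxial_recording(
    x = cl$x + stats::rnorm(n, 0, noise),
    y = cl$y + stats::rnorm(n, 0, noise),
    z = cl$z + stats::rnorm(n, 0, noise),
    sample_rate = sample_rate,
    meta = list(generator = "fepoch::simulate_recording", seed = profile$seed))

  r_clean <- sqrt(cl$x^2 + cl$y^2 + cl$z^2)
  stage_start <- c(0, tr$stage_end_s[-length(tr$stage_end_s)])
  truth_rows <- lapply(seq_len(nrow(profile$stages)), function(si) {
    i1 <- floor(stage_start[si] * sample_rate) + 1L
    i2 <- floor(tr$stage_end_s[si] * sample_rate)
    idx <- i1:i2
    data.frame(stage = si,
               start_s = stage_start[si], end_s = tr$stage_end_s[si],
               speed_ms = profile$stages$speed_ms[si],
               true_mad_mg = 1000 * mean(abs(r_clean[idx] - mean(r_clean[idx]))),
               true_abs_dmad_mg = true_abs_dmad(r_clean, phase, idx),
               true_fs_hz = mean(tr$f[idx]))
  })
  list(recording = rec,
       truth = list(stages = do.call(rbind, truth_rows),
                    turns = profile$turns, noise_sd = profile$noise_sd,
                    seed = profile$seed))
}

# True mean |dMAD| over a window: per-cycle MADs of the clean resultant at
# the generator's known phase boundaries, combined into two-cycle floating
# windows exactly as the analysis defines them.
true_abs_dmad <- function(r_clean, phase, idx) {
  ph <- phase[idx]
  cyc <- floor(ph / (2 * pi))
  b <- idx[which(diff(cyc) >= 1) + 1L]  # first sample of each new cycle
  if (length(b) < 4L) return(NA_real_)
  j <- b[-length(b)]; nn <- diff(b)
  ref <- mean(r_clean[idx])
  madc <- vapply(seq_along(j), function(k)
    mean(abs(r_clean[j[k]:(j[k] + nn[k] - 1L)] - ref)), numeric(1))
  prev <- seq_len(length(madc) - 1L); cur <- prev + 1L
  mad_f <- (madc[prev] * nn[prev] + madc[cur] * nn[cur]) / (nn[prev] + nn[cur])
  1000 * mean(abs(diff(mad_f)))
}

# Deterministic per-subject sub-seed below 2^31.
sub_seed <- function(seed, i) (as.integer(seed) %% 1000003L) * 1000L + i

#' Simulate a constant-speed staged walking cohort
#'
#' Emulates a progressive pace-conducted walking test: every subject walks
#' consecutive constant-speed stages starting at 0.6 m/s and increasing by
#' 0.4 m/s per stage (2.5 min stages by default), with subject-level random
#' amplitude and frequency offsets. Stage-level features are extracted with
#' the full analysis pipeline over the final portion of each stage
#' (`analysis_window_s`, emulating steady state), and each stage's VO2 is
#' generated from `true_model` applied to the stage's floating-epoch
#' summary plus Gaussian noise.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param stages Number of speed stages per subject (default 5).
#' @param stage_duration_s Stage length in s (default 150).
#' @param seed Integer seed for all randomness.
#' @param true_model The generating [vo2_model()] (default the bundled
#'   `acdc_float` equation, the headline floating-epoch model).
#' @param vo2_noise_sd SD of the VO2 noise in mL/kg/min (default 1).
#' @param analysis_window_s Length of the per-stage analysis window at the
#'   end of each stage (default 120 s).
#' @param sample_rate Hz (default 100).
#' @param keep_recordings Keep the raw recordings in the result (default
#'   FALSE; they are large).
#' @return A list with data.frames `floating` and `fixed6s` (one row per
#'   subject-stage: features + `vo2`), `truths` (per-subject truth), and
#'   optionally `recordings`.
#' @export
simulate_cs_cohort <- function(n_subjects, stages = 5, stage_duration_s = 150,
                               seed = 1L,
                               true_model = bundled_model("acdc_float"),
                               vo2_noise_sd = 1, analysis_window_s = 120,
                               sample_rate = 100, keep_recordings = FALSE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  set.seed(seed)
  amp_scale <- exp(stats::rnorm(n_subjects, 0, 0.08))
  freq_shift <- stats::rnorm(n_subjects, 0, 0.05)
  vo2_noise <- matrix(stats::rnorm(n_subjects * stages, 0, vo2_noise_sd),
                      n_subjects, stages)
  speeds <- 0.6 + 0.4 * (seq_len(stages) - 1)

  flo <- fix <- list(); truths <- recs <- list()
  for (s in seq_len(n_subjects)) {
    a_s <- amp_scale[s]; f_s <- freq_shift[s]
    prof <- gait_profile(
      stages = data.frame(duration_s = rep(stage_duration_s, stages),
                          speed_ms = speeds),
      freq_map = function(v) pmin(pmax(1.4 + 0.4 * v + f_s, 1.2), 3.0),
      amp_map = function(v) ifelse(v <= 0, 0, pmax(0.25 * v * a_s, 0.08)),
      seed = sub_seed(seed, s))
    sim <- simulate_recording(prof, sample_rate)
    feats <- epoch_features(sim$recording)
    for (st in seq_len(stages)) {
      w_end <- st * stage_duration_s
      w <- c(w_end - min(analysis_window_s, stage_duration_s), w_end)
      sf <- summarize_features(feats, "floating", window = w)
      xf <- summarize_features(feats, "fixed6s", window = w)
      vo2 <- predict(true_model, sf) + vo2_noise[s, st]
      flo[[length(flo) + 1L]] <- data.frame(
        subject = s, stage = st, speed_ms = speeds[st],
        mean_mad_mg = sf$mean_mad_mg, mean_abs_dmad_mg = sf$mean_abs_dmad_mg,
        mean_fs_hz = sf$mean_fs_hz, n_epochs = sf$n_epochs, vo2 = vo2)
      fix[[length(fix) + 1L]] <- data.frame(
        subject = s, stage = st, speed_ms = speeds[st],
        mean_mad_mg = xf$mean_mad_mg, n_epochs = xf$n_epochs, vo2 = vo2)
    }
    truths[[s]] <- sim$truth
    if (keep_recordings) recs[[s]] <- sim$recording
  }
  out <- list(floating = do.call(rbind, flo), fixed6s = do.call(rbind, fix),
              truths = truths, true_model = true_model,
              vo2_noise_sd = vo2_noise_sd, seed = seed)
  if (keep_recordings) out$recordings <- recs
  out
}

#' Simulate a fast back-and-forth (shuttle) walking cohort
#'
#' Emulates a 6 min maximal-effort walk on a short track: each lap is a
#' trapezoidal speed profile (accelerate, cruise, brake) ending in a slow
#' turn with a transient amplitude burst, repeated for the test duration.
#' Subjects differ in cruise speed. One VO2 value per subject is generated
#' from `true_model` applied to the whole-test floating-epoch summary plus
#' Gaussian noise.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param lap_length_m Track length in m (default 15).
#' @param duration_s Test duration in s (default 360).
#' @param seed Integer seed.
#' @param true_model,vo2_noise_sd As in [simulate_cs_cohort()].
#' @param cruise_speed_ms Mean cruise speed in m/s (default 2.0; subjects
#'   vary around it with SD 0.15, truncated to [1.5, 2.6]).
#' @param sample_rate Hz (default 100).
#' @param keep_recordings Keep raw recordings (default FALSE).
#' @return A list with data.frame `floating` and `fixed6s` (one row per
#'   subject), `truths`, and optionally `recordings`.
#' @export
simulate_acdc_cohort <- function(n_subjects, lap_length_m = 15,
                                 duration_s = 360, seed = 1L,
                                 true_model = bundled_model("acdc_float"),
                                 vo2_noise_sd = 1, cruise_speed_ms = 2.0,
                                 sample_rate = 100, keep_recordings = FALSE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  set.seed(seed)
  v_cruise <- pmin(pmax(stats::rnorm(n_subjects, cruise_speed_ms, 0.15),
                        1.5), 2.6)
  vo2_noise <- stats::rnorm(n_subjects, 0, vo2_noise_sd)

  flo <- fix <- list(); truths <- recs <- list()
  for (s in seq_len(n_subjects)) {
    lap <- shuttle_lap(v_cruise[s], lap_length_m)
    n_laps <- ceiling(duration_s / sum(lap$stages$duration_s))
    st <- do.call(rbind, replicate(n_laps, lap$stages, simplify = FALSE))
    lap_t <- sum(lap$stages$duration_s)
    turn_times <- lap$turn_time_s + lap_t * (seq_len(n_laps) - 1)
    # trim to the requested duration
    cum <- cumsum(st$duration_s)
    keep <- which(cum < duration_s)
    st <- st[seq_len(min(length(keep) + 1L, nrow(st))), ]
    st$duration_s[nrow(st)] <- st$duration_s[nrow(st)] -
      (sum(st$duration_s) - duration_s)
    turns <- data.frame(time_s = turn_times[turn_times < duration_s],
                        multiplier = 1.6, width_s = 0.8)
    prof <- gait_profile(stages = st, turns = turns, seed = sub_seed(seed, s))
    sim <- simulate_recording(prof, sample_rate)
    feats <- epoch_features(sim$recording)
    w <- c(2, duration_s)
    sf <- summarize_features(feats, "floating", window = w)
    xf <- summarize_features(feats, "fixed6s", window = w)
    vo2 <- predict(true_model, sf) + vo2_noise[s]
    flo[[s]] <- data.frame(
      subject = s, cruise_ms = v_cruise[s],
      mean_mad_mg = sf$mean_mad_mg, mean_abs_dmad_mg = sf$mean_abs_dmad_mg,
      mean_fs_hz = sf$mean_fs_hz, n_epochs = sf$n_epochs, vo2 = vo2)
    fix[[s]] <- data.frame(
      subject = s, cruise_ms = v_cruise[s],
      mean_mad_mg = xf$mean_mad_mg, n_epochs = xf$n_epochs, vo2 = vo2)
    truths[[s]] <- sim$truth
    if (keep_recordings) recs[[s]] <- sim$recording
  }
  out <- list(floating = do.call(rbind, flo), fixed6s = do.call(rbind, fix),
              truths = truths, true_model = true_model,
              vo2_noise_sd = vo2_noise_sd, seed = seed)
  if (keep_recordings) out$recordings <- recs
  out
}

# One shuttle lap: accelerate (4 ramp sub-stages), cruise, brake, slow turn.
shuttle_lap <- function(v_cruise, lap_length_m, accel = 0.7, turn_s = 1.0,
                        turn_speed = 0.5) {
  t_ramp <- v_cruise / accel
  d_ramp <- v_cruise^2 / (2 * accel)
  d_cruise <- max(lap_length_m - 2 * d_ramp, 1)
  t_cruise <- d_cruise / v_cruise
  ramp_v <- v_cruise * (seq_len(4) - 0.5) / 4
  stages <- data.frame(
    duration_s = c(rep(t_ramp / 4, 4), t_cruise, rep(t_ramp / 4, 4), turn_s),
    speed_ms = c(ramp_v, v_cruise, rev(ramp_v), turn_speed))
  list(stages = stages,
       turn_time_s = sum(stages$duration_s) - turn_s / 2)
}

#' Simulate a steady-walking cohort spanning a target MAD range
#'
#' Generates one steady 100 Hz walking recording per subject with
#' subject-specific constant signal amplitudes chosen so that the
#' per-subject mean MAD spans (approximately) the requested range — the
#' spread observed across walking speeds in field data. Used to compare the
#' fixed 6 s and floating epoch MAD summaries across a wide intensity
#' range.
#'
#' Amplitudes are inverted from the target MAD via `A = MAD * pi/2` (the
#' mean |sin| identity), with a 0.10 g floor: below that the band-passed
#' sinusoidal signal cannot exceed the +/-0.05 g hysteresis on both sides
#' (the band-pass chain's peak gain is about 0.8), so no steps would be
#' segmentable; the lowest-intensity subjects therefore sit at ~65 mg
#' rather than exactly the lower target. All subjects walk at ordinary
#' cadence (the low-amplitude end emulating a shuffling gait).
#'
#' @param n_subjects Number of subjects (default 29).
#' @param duration_s Recording length per subject in s (default 120).
#' @param mad_range_mg Target span of per-subject mean MAD (default
#'   c(50, 660) mg).
#' @param seed Integer seed.
#' @param sample_rate Hz (default 100).
#' @return A data.frame with one row per subject: `subject`, `amp_g`,
#'   `mean_mad_fixed_mg`, `mean_mad_floating_mg`, `mean_fs_hz`.
#' @export
simulate_steady_cohort <- function(n_subjects = 29, duration_s = 120,
                                   mad_range_mg = c(50, 660), seed = 1L,
                                   sample_rate = 100) {
  stopifnot(n_subjects >= 2)
  # mean |sin| = 2/pi: invert MAD ~ (2/pi) * A, with a detectability floor
  target <- seq(mad_range_mg[1], mad_range_mg[2], length.out = n_subjects)
  amps <- pmax((target / 1000) * pi / 2, 0.10)
  speeds <- seq(1.6, 2.4, length.out = n_subjects)
  rows <- lapply(seq_len(n_subjects), function(s) {
    amp_s <- amps[s]
    prof <- gait_profile(
      stages = data.frame(duration_s = duration_s, speed_ms = speeds[s]),
      amp_map = function(v) rep(amp_s, length(v)),
      seed = sub_seed(seed, s))
    feats <- epoch_features(simulate_recording(prof, sample_rate)$recording)
    w <- c(2, duration_s)
    sf <- summarize_features(feats, "floating", window = w)
    xf <- summarize_features(feats, "fixed6s", window = w)
    data.frame(subject = s, amp_g = amp_s,
               mean_mad_fixed_mg = xf$mean_mad_mg,
               mean_mad_floating_mg = sf$mean_mad_mg,
               mean_fs_hz = sf$mean_fs_hz)
  })
  do.call(rbind, rows)
}
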