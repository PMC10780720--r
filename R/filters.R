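#' Fixed-point coefficients of the three recursive filters
#'
#' The three difference equations of the processing chain use fixed-point
#' rational coefficients (exact binary fractions as implemented on the
#' original device firmware). They are stored as exact rationals and
#' evaluated once to double precision; they are deliberately not re-derived
#' from textbook Butterworth designs, whose quantised coefficients would
#' differ in the last bits.
#'
#' * `baseline` (0.12 Hz 2nd-order low-pass): `a = 127/128`.
#' * `lowpass12` (12 Hz 2nd-order Butterworth low-pass):
#'   `a1 = 46/512`, `a2 = 93/512`, `b1 = 125/128`, `b2 = 44/128`.
#' * `bandpass13` (1-3 Hz 2nd-order Butterworth band-pass):
#'   `a1 = 16139/2^22`, `a2 = 32278/2^22`, `b1 = 15565/4096`,
#'   `b2 = 22279/4096`, `b3 = 14239/4096`, `b4 = 3429/4096`.
#'
#' `a2 == 2 * a1` holds exactly for the band-pass numerator, which forces
#' its DC gain to exactly zero.
#'
#' @return Nested named list of filter coefficients (doubles).
#' @export
filter_coefficients <- function() {
  list(
    baseline  = list(a = 127 / 128),
    lowpass12 = list(a1 = 46 / 512, a2 = 93 / 512,
                     b1 = 125 / 128, b2 = 44 / 128),
    bandpass13 = list(a1 = 16139 / 2^22, a2 = 32278 / 2^22,
                      b1 = 15565 / 4096, b2 = 22279 / 4096,
                      b3 = 14239 / 4096, b4 = 3429 / 4096)
  )
}

#' Resultant (vector magnitude) acceleration
#'
#' `r[i] = sqrt(x[i]^2 + y[i]^2 + z[i]^2)` per sample: the Euclidean norm of
#' the three axes, containing both the static (gravity) and dynamic
#' components of acceleration.
#'
#' @param rec A [triaxial_recording()].
#' @return Numeric vector `r` in g, same length as the recording.
#' @export
resultant <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  sqrt(rec$x^2 + rec$y^2 + rec$z^2)
}

# One-sided FIR part u[i] = sum coef[k] * x[i - lag[k]], zeros before start.
fir_part <- function(x, coefs) {
  k <- length(coefs) - 1L
  if (k == 0L) return(coefs[[1]] * x)
  out <- stats::filter(c(rep(0, k), x), coefs, method = "convolution",
                       sides = 1)
  as.numeric(out[(k + 1L):(k + length(x))])
}

#' Baseline low-pass filter (0.12 Hz, 2nd order)
#'
#' The slowly varying reference level used by the MAD deviation:
#' `R_LF[i] = 2a R_LF[i-1] - a^2 R_LF[i-2] + (1 - 2a + a^2) r[i]`
#' with `a = 127/128`. Its DC gain is exactly 1 (the numerator equals the
#' evaluated denominator `(1 - a)^2`).
#'
#' The filter history is initialised to the first input sample: with a
#' 0.12 Hz pole the zero-state startup transient would last minutes, while
#' seeding the state at the first resultant value starts the reference at
#' the local gravity level and makes startup deterministic.
#'
#' @param r Numeric vector, resultant acceleration in g.
#' @return Numeric vector `R_LF`, same length as `r`.
#' @export
baseline_lowpass <- function(r) {
  a <- filter_coefficients()$baseline$a
  out <- stats::filter((1 - 2 * a + a^2) * r, c(2 * a, -a^2),
                       method = "recursive", init = c(r[[1]], r[[1]]))
  as.numeric(out)
}

#' 12 Hz Butterworth low-pass filter (2nd order)
#'
#' First stage of step-cycle extraction; removes high-frequency noise:
#' `R_LF12[i] = a1 r[i] + a2 r[i-1] + a1 r[i-2]
#'             + b1 R_LF12[i-1] - b2 R_LF12[i-2]`
#' with the fixed-point coefficients of [filter_coefficients()].
#' State is initialised to zero (input history before the first sample is
#' taken as zero).
#'
#' @param r Numeric vector, resultant acceleration in g.
#' @return Numeric vector `R_LF12`, same length as `r`.
#' @export
lowpass12 <- function(r) {
  cf <- filter_coefficients()$lowpass12
  u <- fir_part(r, c(cf$a1, cf$a2, cf$a1))
  as.numeric(stats::filter(u, c(cf$b1, -cf$b2), method = "recursive"))
}

#' 1-3 Hz Butterworth band-pass filter (2nd order)
#'
#' Isolates the gait cycle band for step detection:
#' `R_BP[i] = a1 R_LF12[i] - a2 R_LF12[i-2] + a1 R_LF12[i-4]
#'           + b1 R_BP[i-1] - b2 R_BP[i-2] + b3 R_BP[i-3] - b4 R_BP[i-4]`
#' with the fixed-point coefficients of [filter_coefficients()]. Because
#' `a2 = 2 a1` exactly, the DC gain is exactly zero. State is initialised to
#' zero; the first second of output is a startup transient, which the step
#' detector excludes via its warm-up argument.
#'
#' @param rlf12 Numeric vector, output of [lowpass12()].
#' @return Numeric vector `R_BP`, same length as the input.
#' @export
bandpass13 <- function(rlf12) {
  cf <- filter_coefficients()$bandpass13
  u <- fir_part(rlf12, c(cf$a1, 0, -cf$a2, 0, cf$a1))
  as.numeric(stats::filter(u, c(cf$b1, -cf$b2, cf$b3, -cf$b4),
                           method = "recursive"))
}

#' Run the full filter chain on a recording
#'
#' Convenience wrapper computing the resultant and all three filtered
#' traces in one call.
#'
#' @param rec A [triaxial_recording()].
#' @return A list with numeric vectors `r`, `r_lf`, `r_lf12`, `r_bp` (all
#'   the same length as the recording) and `sample_rate`.
#' @export
filter_chain <- function(rec) {
  r <- resultant(rec)
  r_lf12 <- lowpass12(r)
  list(r = r,
       r_lf = baseline_lowpass(r),
       r_lf12 = r_lf12,
       r_bp = bandpass13(r_lf12),
       sample_rate = rec$sample_rate)
}
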