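#' Detect steps by zero crossing with hysteresis
#'
#' Segments the band-passed trace `R_BP` into single steps. A step boundary
#' is emitted at the first sample where `R_BP` rises to or above the
#' positive threshold (+0.05 g) coming from below it, while the detector is
#' armed. Emitting a boundary disarms the detector; it re-arms only once
#' `R_BP` falls to or below the negative threshold (-0.05 g). This
#' hysteresis suppresses noise-induced double counts near the threshold.
#' A step is the half-open interval between consecutive boundaries.
#'
#' Segments shorter than `n_min` or longer than `n_max` samples are rejected
#' as non-gait (at 100 Hz the defaults 20 and 250 samples correspond to step
#' times of 0.2-2.5 s, generously bracketing the 1-3 Hz gait band); a
#' rejected segment breaks contiguity and splits the step sequence into
#' bouts.
#'
#' @param r_bp Numeric vector, band-passed acceleration in g
#'   (see [bandpass13()]).
#' @param sample_rate Sampling frequency in Hz.
#' @param rising,falling Hysteresis thresholds in g (defaults +0.05 and
#'   -0.05). `rising` must be positive and `falling` negative; equality with
#'   a threshold counts as having crossed it, so ties are deterministic.
#' @param n_min,n_max Plausibility bounds on step length in samples.
#' @param warmup_s Seconds at the start of the trace excluded from
#'   detection (filter startup transient; default 1 s).
#'
#' @return A data.frame of class `step_table` with one row per retained
#'   step: `k` (ordinal), `j` (start sample, 1-based), `n` (sample count),
#'   `step_time_s`, `bout` (bout id; steps in one bout are contiguous).
#'   Zero detected steps is a valid result (zero-row table).
#' @export
detect_steps <- function(r_bp, sample_rate,
                         rising = 0.05, falling = -0.05,
                         n_min = 20L, n_max = 250L, warmup_s = 1) {
  stopifnot(rising > 0, falling < 0)
  n <- length(r_bp)
  i0 <- min(n, floor(warmup_s * sample_rate) + 1L)

  empty <- data.frame(k = integer(), j = integer(), n = integer(),
                      step_time_s = numeric(), bout = integer())
  class(empty) <- c("step_table", "data.frame")
  if (n < 2L) return(empty)

  # candidate boundaries: first sample at/above the rising threshold after
  # a sample below it
  above <- r_bp >= rising
  cand <- which(above & !c(TRUE, above[-n]))
  cand <- cand[cand >= i0]
  # cumulative count of re-arm samples (at/below the falling threshold)
  rearm_cum <- cumsum(r_bp <= falling)

  boundaries <- integer(0)
  last_b <- NA_integer_
  for (i in cand) {
    if (is.na(last_b) || rearm_cum[i - 1L] > rearm_cum[last_b]) {
      boundaries <- c(boundaries, i)
      last_b <- i
    }
  }
  if (length(boundaries) < 2L) return(empty)

  j <- boundaries[-length(boundaries)]
  len <- diff(boundaries)
  keep <- len >= n_min & len <= n_max
  if (!any(keep)) return(empty)

  j <- j[keep]; len <- len[keep]
  # a discarded segment leaves a gap: new bout when a step does not start
  # where the previous retained one ended
  gap <- c(TRUE, j[-1] != (j[-length(j)] + len[-length(len)]))
  out <- data.frame(k = seq_along(j), j = j, n = len,
                    step_time_s = len / sample_rate,
                    bout = cumsum(gap))
  class(out) <- c("step_table", "data.frame")
  out
}

#' Group contiguous steps into bouts
#'
#' Returns the index ranges of maximal runs of contiguous steps in a step
#' table. Floating epochs are only formed within a bout, so that "adjacent"
#' steps never straddle a non-gait gap.
#'
#' @param steps A `step_table` from [detect_steps()].
#' @return A data.frame with one row per bout: `bout`, `first_k`, `last_k`,
#'   `n_steps`. Empty input gives an empty table.
#' @export
step_bouts <- function(steps) {
  if (nrow(steps) == 0L)
    return(data.frame(bout = integer(), first_k = integer(),
                      last_k = integer(), n_steps = integer()))
  sp <- split(steps$k, steps$bout)
  data.frame(bout = as.integer(names(sp)),
             first_k = vapply(sp, min, integer(1), USE.NAMES = FALSE),
             last_k = vapply(sp, max, integer(1), USE.NAMES = FALSE),
             n_steps = lengths(sp, use.names = FALSE))
}
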