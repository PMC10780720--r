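#' Per-step mean amplitude deviation (MAD)
#'
#' For step `k` starting at sample `j` with `N` samples, the MAD is the mean
#' absolute deviation of the resultant acceleration about the slowly varying
#' baseline reference over the step:
#' `MAD_k = (1/N) * sum_{i=j}^{j+N-1} |r[i] - R_LF[i]|`, reported in mg
#' (g x 1000), the field's canonical reporting unit.
#'
#' @param r Numeric vector, resultant acceleration in g.
#' @param r_lf Numeric vector, baseline reference (see [baseline_lowpass()]).
#' @param steps A `step_table` from [detect_steps()].
#' @return The step table with an added `mad_mg` column.
#' @export
step_mad <- function(r, r_lf, steps) {
  stopifnot(length(r) == length(r_lf))
  if (nrow(steps) == 0L) {
    steps$mad_mg <- numeric(0)
    return(steps)
  }
  if (any(steps$j < 1L) || any(steps$j + steps$n - 1L > length(r)))
    stop("step segment out of trace bounds")
  csum <- c(0, cumsum(abs(r - r_lf)))
  steps$mad_mg <- 1000 * (csum[steps$j + steps$n] - csum[steps$j]) / steps$n
  steps
}

#' Floating-epoch features: MAD_f, dMAD and step frequency
#'
#' Builds the stride-adaptive "floating" epochs: each epoch spans two
#' adjacent steps within a bout and advances by one step, so consecutive
#' epochs overlap by one step and every interior step is analysed twice.
#' For step `k` (the later of the pair):
#'
#' * `MAD_f,k = (MAD_{k-1} N_{k-1} + MAD_k N_k) / (N_{k-1} + N_k)` — the
#'   sample-count-weighted mean of the two per-step MADs (in mg);
#' * `dMAD_f,k = MAD_f,k - MAD_f,k-1` — the signed change between adjacent
#'   epochs of the same bout (`NA` for the first epoch of a bout); summaries
#'   aggregate its absolute value;
#' * `f_s,k = 2 * sample_rate / (N_{k-1} + N_k)` — the step frequency in Hz.
#'
#' The first step of each bout yields no epoch (it has no predecessor).
#'
#' @param step_features Step table with `mad_mg` (from [step_mad()]).
#' @param sample_rate Sampling frequency in Hz.
#' @return A `feature_table` data.frame with columns `epoch_kind`
#'   ("floating"), `k` (ordinal of the later step), `bout`, `start_sample`,
#'   `end_sample`, `start_s`, `end_s`, `mad_mg`, `dmad_mg_signed`, `fs_hz`.
#' @export
floating_features <- function(step_features, sample_rate) {
  s <- step_features
  out_rows <- vector("list", 0L)
  if (nrow(s) > 0L) {
    for (b in split(seq_len(nrow(s)), s$bout)) {
      if (length(b) < 2L) next
      prev <- b[-length(b)]; cur <- b[-1]
      ntot <- s$n[prev] + s$n[cur]
      mad_f <- (s$mad_mg[prev] * s$n[prev] + s$mad_mg[cur] * s$n[cur]) / ntot
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        epoch_kind = "floating",
        k = s$k[cur],
        bout = s$bout[cur],
        start_sample = s$j[prev],
        end_sample = s$j[cur] + s$n[cur] - 1L,
        mad_mg = mad_f,
        dmad_mg_signed = c(NA_real_, diff(mad_f)),
        fs_hz = 2 * sample_rate / ntot)
    }
  }
  out <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(epoch_kind = character(), k = integer(), bout = integer(),
               start_sample = integer(), end_sample = integer(),
               mad_mg = numeric(), dmad_mg_signed = numeric(),
               fs_hz = numeric())
  out$start_s <- (out$start_sample - 1L) / sample_rate
  out$end_s <- out$end_sample / sample_rate
  out <- out[c("epoch_kind", "k", "bout", "start_sample", "end_sample",
               "start_s", "end_s", "mad_mg", "dmad_mg_signed", "fs_hz")]
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Fixed-epoch MAD (conventional 6 s epochs)
#'
#' Computes the MAD over consecutive, non-overlapping fixed-length epochs
#' (600 samples at 100 Hz for the default 6 s); a trailing partial epoch is
#' dropped.
#'
#' Two deviation references are available. The default, `"baseline"`, uses
#' the same `|r - R_LF|` deviation as the per-step MAD, keeping the two
#' epoch types internally consistent. `"epoch_mean"` is the classical MAD
#' definition, deviation about the epoch's own mean resultant.
#'
#' @param r Numeric vector, resultant acceleration in g.
#' @param r_lf Baseline reference (required for the `"baseline"` reference).
#' @param sample_rate Sampling frequency in Hz.
#' @param epoch_s Epoch length in seconds (default 6).
#' @param reference Deviation reference, `"baseline"` or `"epoch_mean"`.
#' @return A `feature_table` data.frame with columns as in
#'   [floating_features()]; `dmad_mg_signed` and `fs_hz` are `NA` (they are
#'   floating-epoch concepts). A recording shorter than one epoch yields an
#'   empty table with a warning.
#' @export
fixed_epoch_mad <- function(r, r_lf = NULL, sample_rate, epoch_s = 6,
                            reference = c("baseline", "epoch_mean")) {
  reference <- match.arg(reference)
  len <- as.integer(round(epoch_s * sample_rate))
  n_ep <- length(r) %/% len
  if (n_ep == 0L) {
    warning("recording shorter than one ", epoch_s, " s epoch; no epochs")
    mad <- numeric(0)
  } else {
    use <- seq_len(n_ep * len)
    if (reference == "baseline") {
      stopifnot(length(r_lf) == length(r))
      dev <- matrix(abs(r[use] - r_lf[use]), nrow = len)
      mad <- colMeans(dev)
    } else {
      m <- matrix(r[use], nrow = len)
      mad <- colMeans(abs(m - rep(colMeans(m), each = len)))
    }
  }
  idx <- seq_len(n_ep)
  out <- data.frame(
    epoch_kind = rep("fixed6s", n_ep),
    k = idx,
    bout = rep(NA_integer_, n_ep),
    start_sample = (idx - 1L) * len + 1L,
    end_sample = idx * len,
    start_s = (idx - 1L) * len / sample_rate,
    end_s = idx * len / sample_rate,
    mad_mg = 1000 * mad,
    dmad_mg_signed = rep(NA_real_, n_ep),
    fs_hz = rep(NA_real_, n_ep))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Full feature extraction pipeline
#'
#' Runs the filter chain, step detection and feature computation on a raw
#' recording, returning floating-epoch and/or fixed-epoch feature rows in
#' one table.
#'
#' @param rec A [triaxial_recording()].
#' @param epochs Which epoch kinds to compute: `"floating"`, `"fixed6s"`,
#'   or `"both"` (default).
#' @param epoch_s Fixed epoch length in seconds (default 6).
#' @param fixed_reference Deviation reference for fixed epochs
#'   (see [fixed_epoch_mad()]).
#' @param ... Further arguments passed to [detect_steps()].
#' @return A `feature_table` data.frame.
#' @export
epoch_features <- function(rec, epochs = c("both", "floating", "fixed6s"),
                           epoch_s = 6, fixed_reference = "baseline", ...) {
  epochs <- match.arg(epochs)
  ch <- filter_chain(rec)
  parts <- list()
  if (epochs %in% c("both", "floating")) {
    steps <- detect_steps(ch$r_bp, ch$sample_rate, ...)
    steps <- step_mad(ch$r, ch$r_lf, steps)
    parts$floating <- floating_features(steps, ch$sample_rate)
  }
  if (epochs %in% c("both", "fixed6s")) {
    parts$fixed <- fixed_epoch_mad(ch$r, ch$r_lf, ch$sample_rate,
                                   epoch_s = epoch_s,
                                   reference = fixed_reference)
  }
  out <- do.call(rbind, unname(parts))
  class(out) <- c("feature_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Summarise epoch features over a time window
#'
#' Unweighted means of the per-epoch features over all epochs of one kind
#' lying fully inside the window: mean MAD (mg), mean |dMAD| (mg, floating
#' only; the signed per-epoch values are aggregated as absolute values), and
#' mean step frequency (Hz, floating only). These are the stage- or
#' test-level summaries that the VO2 prediction models take as input.
#'
#' @param features A `feature_table`.
#' @param epoch_kind `"floating"` or `"fixed6s"`.
#' @param window Optional `c(start_s, end_s)`; only epochs with
#'   `start_s >= start` and `end_s <= end` contribute. `NULL` uses all.
#' @return An object of class `feature_summary`: a list with `epoch_kind`,
#'   `n_epochs`, `window`, `mean_mad_mg`, `mean_abs_dmad_mg`, `mean_fs_hz`
#'   (the latter two `NA` for fixed epochs).
#' @export
summarize_features <- function(features, epoch_kind = c("floating", "fixed6s"),
                               window = NULL) {
  epoch_kind <- match.arg(epoch_kind)
  f <- features[features$epoch_kind == epoch_kind, , drop = FALSE]
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    f <- f[f$start_s >= window[1] & f$end_s <= window[2], , drop = FALSE]
  }
  if (nrow(f) == 0L)
    stop("no ", epoch_kind, " epochs inside the requested window")
  structure(list(
    epoch_kind = epoch_kind,
    n_epochs = nrow(f),
    window = if (is.null(window)) c(min(f$start_s), max(f$end_s)) else window,
    mean_mad_mg = mean(f$mad_mg),
    mean_abs_dmad_mg = if (epoch_kind == "floating")
      mean(abs(f$dmad_mg_signed), na.rm = TRUE) else NA_real_,
    mean_fs_hz = if (epoch_kind == "floating")
      mean(f$fs_hz) else NA_real_
  ), class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("<feature_summary> %s, %d epochs, window [%.1f, %.1f] s\n",
              x$epoch_kind, x$n_epochs, x$window[1], x$window[2]))
  cat(sprintf("  mean MAD    %8.3f mg\n", x$mean_mad_mg))
  if (x$epoch_kind == "floating") {
    cat(sprintf("  mean |dMAD| %8.3f mg\n", x$mean_abs_dmad_mg))
    cat(sprintf("  mean f_s    %8.4f Hz\n", x$mean_fs_hz))
  }
  invisible(x)
}

#' Write a feature table to CSV
#'
#' One row per epoch, header line with the documented column names, numeric
#' values printed to 6 decimal places so that [read_features()] reproduces
#' them exactly as printed.
#'
#' @param features A non-empty `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (nrow(features) == 0L)
    stop("refusing to write an empty feature table")
  f <- features
  for (col in c("mad_mg", "dmad_mg_signed", "fs_hz", "start_s", "end_s"))
    f[[col]] <- sprintf("%.6f", f[[col]])
  f$dmad_mg_signed[is.na(features$dmad_mg_signed)] <- "NA"
  f$fs_hz[is.na(features$fs_hz)] <- "NA"
  utils::write.csv(f, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return A `feature_table` data.frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file does not exist: ", path)
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_kind", "k", "start_s", "end_s", "mad_mg",
            "dmad_mg_signed", "fs_hz")
  missing <- setdiff(need, names(f))
  if (length(missing))
    stop("feature file lacks column(s): ", paste(missing, collapse = ", "))
  class(f) <- c("feature_table", "data.frame")
  f
}
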