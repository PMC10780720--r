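#' Construct a triaxial accelerometer recording
#'
#' Container for a raw hip-worn accelerometer recording: three equal-length
#' axis signals in g units sampled at a fixed rate. The sample index is the
#' authoritative time base for all downstream computation; an optional
#' start timestamp is carried along as metadata only.
#'
#' @param x,y,z Numeric vectors of equal positive length, acceleration in g.
#' @param sample_rate Sampling frequency in Hz (default 100).
#' @param start_time Optional `POSIXct` start timestamp (metadata only).
#' @param meta Named list of free-form tags (subject id, protocol, ...).
#'
#' @return An object of class `triaxial_recording` with elements `x`, `y`,
#'   `z`, `sample_rate`, `start_time`, `meta`.
#'
#' @details Values beyond the +/-16 g sensor range trigger a warning (the
#'   range of the target device class), never silent clipping.
#'
#' @examples
#' rec <- triaxial_recording(x = rep(0, 100), y = rep(0, 100), z = rep(1, 100))
#' n_samples(rec)
#' duration(rec)
#' @export
triaxial_recording <- function(x, y, z, sample_rate = 100,
                               start_time = NULL, meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  rec <- structure(
    list(x = x, y = y, z = z,
         sample_rate = as.numeric(sample_rate),
         start_time = start_time, meta = meta),
    class = "triaxial_recording"
  )
  validate_recording(rec)
}

#' Validate a triaxial recording
#'
#' Checks the structural invariants: equal, positive axis lengths, positive
#' sample rate, all values finite, and values within the +/-16 g sensor range
#' (a warning, not an error: out-of-range samples are reported, never
#' clipped).
#'
#' @param rec A `triaxial_recording`.
#' @return The validated recording, invisibly usable in pipelines.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  n <- length(rec$x)
  if (n == 0L) stop("recording is empty: axis vectors must have length > 0")
  if (length(rec$y) != n || length(rec$z) != n)
    stop("axis vectors x, y, z must have equal length (got ",
         n, ", ", length(rec$y), ", ", length(rec$z), ")")
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be a positive number, got ", rec$sample_rate)
  vals <- c(rec$x, rec$y, rec$z)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("recording contains non-finite acceleration values")
  n_out <- sum(abs(vals) > 16)
  if (n_out > 0L)
    warning(n_out, " sample value(s) exceed the +/-16 g sensor range")
  rec
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$x), x$sample_rate, length(x$x) / x$sample_rate))
  if (!is.null(x$start_time)) cat("  start:", format(x$start_time), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `triaxial_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$x)

#' Duration of a recording in seconds
#' @param rec A `triaxial_recording`.
#' @return Duration in s (`n_samples / sample_rate`).
#' @export
duration <- function(rec) length(rec$x) / rec$sample_rate

# Guess the field separator of a delimited text file from its first line.
guess_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read a raw acceleration recording from a delimited text file
#'
#' Reads a headerless or single-header-line delimited file with columns
#' x, y, z and an optional fourth timestamp column. The declared
#' `sample_rate` governs all timing; timestamps are never used by the
#' computations.
#'
#' @param path Path to a comma-, tab- or whitespace-delimited text file.
#' @param sample_rate Sampling frequency in Hz (default 100).
#' @param units Input units: `"g"` (default) or `"ms2"`; metre-per-second
#'   squared inputs are converted to g by dividing by 9.81. The default is g
#'   because silent unit mix-ups are the dominant failure mode in raw
#'   accelerometry, so deviating from it requires an explicit flag.
#' @return A [triaxial_recording()] in g units.
#' @export
read_recording <- function(path, sample_rate = 100, units = c("g", "ms2")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("input file is empty: ", path)

  sep <- guess_sep(lines[[1]])
  split1 <- function(ln) {
    if (sep == "") strsplit(trimws(ln), "[[:space:]]+")[[1]]
    else trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
  }
  fields <- lapply(lines, split1)
  ncols <- lengths(fields)
  if (ncols[[1]] < 3L)
    stop("expected at least 3 columns (x, y, z), found ", ncols[[1]],
         " on line 1 of ", path)

  # a non-numeric first line is taken as a header
  first_num <- suppressWarnings(as.numeric(fields[[1]]))
  start_line <- if (anyNA(first_num)) 2L else 1L
  if (start_line > length(fields))
    stop("input file has a header but no data rows: ", path)

  data_idx <- start_line:length(fields)
  bad_width <- data_idx[ncols[data_idx] < 3L]
  if (length(bad_width))
    stop("line ", bad_width[[1]], " of ", path, " has ",
         ncols[[bad_width[[1]]]], " column(s); at least 3 (x,y,z) required")

  mat <- suppressWarnings(
    vapply(fields[data_idx], function(f) as.numeric(f[1:3]), numeric(3))
  )
  if (anyNA(mat)) {
    bad <- data_idx[which(colSums(is.na(mat)) > 0L)[1]]
    stop("non-numeric acceleration value on line ", bad, " of ", path)
  }
  scl <- if (units == "ms2") 1 / 9.81 else 1
  triaxial_recording(x = mat[1, ] * scl, y = mat[2, ] * scl, z = mat[3, ] * scl,
                     sample_rate = sample_rate,
                     meta = list(source = path))
}

#' Write a recording to a delimited text file
#'
#' Writes a CSV with header `x,y,z` and values printed to 6 decimal places,
#' so that `read_recording()` on the output reproduces the samples to that
#' precision.
#'
#' @param rec A `triaxial_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y,z", con)
  writeLines(sprintf("%.6f,%.6f,%.6f", rec$x, rec$y, rec$z), con)
  invisible(path)
}
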