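# Sensor stream / recording containers and multi-rate resampling.

SENSORS <- c("accelerometer", "gyroscope", "barometer")

#' Construct a validated sensor stream
#'
#' Timestamps are seconds relative to session start and must end up strictly
#' increasing: rows with non-finite values are dropped, duplicated timestamps
#' keep their first occurrence, and out-of-order rows are removed (count
#' attached as attribute \code{n_dropped}).
#'
#' @param sensor \code{"accelerometer"}, \code{"gyroscope"} or
#'   \code{"barometer"}.
#' @param timestamps Numeric vector, seconds.
#' @param values Matrix with one row per timestamp: 3 columns for inertial
#'   sensors (m/s^2, rad/s), 1 column for the barometer (hPa).
#' @param nominal_rate Nominal sampling rate, Hz.
#' @return Object of class \code{sensor_stream}.
#' @export
sensor_stream <- function(sensor, timestamps, values, nominal_rate) {
  sensor <- match.arg(sensor, SENSORS)
  values <- as.matrix(values)
  want <- if (sensor == "barometer") 1L else 3L
  stopifnot(ncol(values) == want, nrow(values) == length(timestamps),
            nominal_rate > 0)
  ok <- is.finite(timestamps) & apply(is.finite(values), 1, all)
  ok[ok][duplicated(timestamps[ok])] <- FALSE
  t <- timestamps[ok]; v <- values[ok, , drop = FALSE]
  if (length(t) > 1) {
    keep <- c(TRUE, diff(cummax(t)) > 0)  # drop rows that go backwards
    t <- t[keep]; v <- v[keep, , drop = FALSE]
  }
  structure(list(sensor = sensor, timestamps = t, values = v,
                 nominal_rate = nominal_rate),
            class = "sensor_stream",
            n_dropped = length(timestamps) - length(t))
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples @ %g Hz nominal, span %.1f s\n",
              x$sensor, length(x$timestamps), x$nominal_rate,
              if (length(x$timestamps)) diff(range(x$timestamps)) else 0))
  invisible(x)
}

#' Construct a validated sensor recording
#'
#' Bouts must fall inside the time span covered by every present stream
#' (half-open intervals \code{[start_s, end_s)}) and must not overlap each
#' other; offending bouts are rejected with a warning and counted in attribute
#' \code{n_rejected_bouts}.
#'
#' @param subject_id Subject identifier.
#' @param session \code{"Lab1"}, \code{"Home"} or \code{"Lab2"}.
#' @param streams Named list of \code{\link{sensor_stream}}s (accelerometer
#'   and gyroscope required; barometer optional).
#' @param bouts data.frame with columns \code{bout_id}, \code{activity},
#'   \code{start_s}, \code{end_s}.
#' @param metadata List: \code{cohort}, \code{gait_speed}, optionally
#'   \code{impairment}.
#' @return Object of class \code{sensor_recording}.
#' @export
sensor_recording <- function(subject_id, session, streams, bouts,
                             metadata = list()) {
  stopifnot(session %in% SESSIONS,
            all(names(streams) %in% SENSORS),
            all(c("accelerometer", "gyroscope") %in% names(streams)))
  for (st in streams) stopifnot(inherits(st, "sensor_stream"))
  need <- c("bout_id", "activity", "start_s", "end_s")
  stopifnot(all(need %in% names(bouts)))
  bouts <- bouts[, need]
  ok <- bouts$activity %in% ACTIVITIES & bouts$end_s > bouts$start_s
  # bouts must lie within the span of every stream that has samples
  for (st in streams) {
    if (length(st$timestamps) >= 2) {
      ok <- ok & bouts$start_s >= min(st$timestamps) - 0.5 &
        bouts$end_s <= max(st$timestamps) + 0.5   # allow sub-sample slack
    } else ok <- ok & FALSE
  }
  if (nrow(bouts)) {
    ord <- order(bouts$start_s)
    bouts <- bouts[ord, ]; ok <- ok[ord]
    if (nrow(bouts) > 1) {
      overlap <- c(FALSE, bouts$start_s[-1] < bouts$end_s[-nrow(bouts)] - 1e-9)
      ok <- ok & !overlap
    }
  }
  n_rej <- sum(!ok)
  if (n_rej > 0) warning(sprintf("rejected %d invalid bout(s)", n_rej))
  structure(list(subject_id = as.character(subject_id), session = session,
                 environment = session_environment(session),
                 streams = streams,
                 bouts = bouts[ok, , drop = FALSE],
                 metadata = metadata),
            class = "sensor_recording", n_rejected_bouts = n_rej)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject %s, %s (%s): %s; %d bouts\n",
              x$subject_id, x$session, x$environment,
              paste(names(x$streams), collapse = ", "), nrow(x$bouts)))
  invisible(x)
}

#' Read a recording from per-sensor CSV files
#'
#' Expects the layout written by \code{\link{write_recording}}:
#' \code{<subject>_<session>_<sensor>.csv} for each sensor and
#' \code{<subject>_<session>_labels.csv}. Accelerometer and gyroscope files
#' are required; the barometer file is optional unless
#' \code{require_barometer}. Unparseable or non-monotone rows are dropped with
#' a message; an empty or missing label file yields a recording with zero
#' bouts (with a warning).
#'
#' @param dir Directory holding the CSVs.
#' @param subject_id,session Recording identity (file name prefix).
#' @param require_barometer Error if the barometer file is absent?
#' @param metadata Optional metadata list stored on the recording.
#' @return A \code{\link{sensor_recording}}.
#' @export
read_recording <- function(dir, subject_id, session,
                           require_barometer = FALSE, metadata = list()) {
  base <- file.path(dir, paste(subject_id, session, sep = "_"))
  streams <- list()
  for (s in SENSORS) {
    p <- paste0(base, "_", s, ".csv")
    if (!file.exists(p)) {
      if (s == "barometer" && !require_barometer) next
      stop("missing required sensor file: ", p)
    }
    df <- utils::read.csv(p)
    vals <- if (s == "barometer") as.matrix(df[, "pressure_hPa", drop = FALSE])
            else as.matrix(df[, c("x", "y", "z")])
    st <- sensor_stream(s, df$timestamp_s, vals, if (s == "barometer") 6 else 60)
    if (attr(st, "n_dropped") > 0) {
      message(sprintf("%s: dropped %d invalid row(s)", basename(p),
                      attr(st, "n_dropped")))
    }
    streams[[s]] <- st
  }
  lp <- paste0(base, "_labels.csv")
  if (file.exists(lp) && length(readLines(lp, n = 2)) > 1) {
    bouts <- utils::read.csv(lp)
  } else {
    warning("no labels found for ", basename(base))
    bouts <- data.frame(bout_id = character(0), activity = character(0),
                        start_s = numeric(0), end_s = numeric(0))
  }
  sensor_recording(subject_id, session, streams, bouts, metadata)
}

#' Resample a stream onto a uniform grid by linear interpolation
#'
#' Output timestamps form the uniform grid \code{t0 + k/target_rate} spanning
#' the input range (no extrapolation); values are linearly interpolated per
#' channel.
#'
#' @param stream A \code{\link{sensor_stream}} with at least 2 samples.
#' @param target_rate Target rate, Hz (inertial sensors are analysed at 50 Hz,
#'   the barometer at 6 Hz).
#' @return A \code{sensor_stream} on the uniform grid, with
#'   \code{nominal_rate = target_rate}.
#' @export
resample_stream <- function(stream, target_rate) {
  stopifnot(inherits(stream, "sensor_stream"), target_rate > 0)
  t <- stream$timestamps
  if (length(t) < 2) stop("cannot resample a stream with fewer than 2 samples")
  grid <- seq(t[1], t[length(t)] + 1e-12, by = 1 / target_rate)
  vals <- vapply(seq_len(ncol(stream$values)), function(j) {
    stats::approx(t, stream$values[, j], xout = grid, method = "linear",
                  rule = 1)$y
  }, numeric(length(grid)))
  sensor_stream(stream$sensor, grid, matrix(vals, ncol = ncol(stream$values)),
                target_rate)
}

# Extract the sub-stream inside [from, to); returns NULL if < 2 samples.
slice_stream <- function(stream, from, to) {
  i <- which(stream$timestamps >= from - 1e-9 & stream$timestamps < to - 1e-9)
  if (length(i) < 2) return(NULL)
  sensor_stream(stream$sensor, stream$timestamps[i] - from,
                stream$values[i, , drop = FALSE], stream$nominal_rate)
}
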