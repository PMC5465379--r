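# Artifact trimming, mislabel filtering and overlapping-window segmentation.

#' Trimming configuration
#'
#' Parameters for sample-entropy edge trimming of phone-handling artifacts.
#' Tolerance \code{tolerance_r} is a fraction of a robust bout-level scale
#' (the median SD over non-overlapping subwindows of the accelerometer norm),
#' so the scan keys on signal irregularity at the bout's clean amplitude:
#' smooth postural sway and quasi-periodic gait score low, broadband handling
#' noise scores high. Per-activity thresholds default to 0.5 for stationary
#' and 1.5 for ambulatory activities. The 1-s subwindow matches the shortest
#' handling artifacts so at least one scanned window lies fully inside an
#' artifact.
#'
#' @param subwindow_s Length of the scanned subwindow, seconds.
#' @param hop_s Step between successive subwindow starts, seconds.
#' @param embedding_m SampEn template length m.
#' @param tolerance_r SampEn tolerance as a fraction of the robust bout scale.
#' @param thresholds Named vector: activity -> entropy threshold.
#' @param max_trim_s Maximum seconds trimmed from each bout end.
#' @return Object of class \code{trim_config}.
#' @export
trim_config <- function(subwindow_s = 1, hop_s = 0.25, embedding_m = 2,
                        tolerance_r = 0.2, thresholds = NULL, max_trim_s = 5) {
  if (is.null(thresholds)) {
    thresholds <- stats::setNames(
      ifelse(ACTIVITIES %in% AMBULATORY, 1.5, 0.5), ACTIVITIES)
  }
  stopifnot(subwindow_s > 0, hop_s > 0, embedding_m >= 1, tolerance_r > 0,
            max_trim_s >= 0, all(ACTIVITIES %in% names(thresholds)))
  structure(list(subwindow_s = subwindow_s, hop_s = hop_s,
                 embedding_m = embedding_m, tolerance_r = tolerance_r,
                 thresholds = thresholds, max_trim_s = max_trim_s),
            class = "trim_config")
}

#' Sample entropy of a univariate series
#'
#' SampEn(m, r) = -ln(A/B), where B counts ordered pairs of distinct
#' length-\code{m} templates within Chebyshev distance \code{r} and A counts
#' the same for length \code{m + 1}. Self-matches are excluded. Returns
#' \code{Inf} when no (m+1)-templates match (A = 0) and \code{0} for perfectly
#' regular series (A = B).
#'
#' @param x Numeric series, length >= m + 2.
#' @param m Template length (>= 1).
#' @param r Absolute tolerance (> 0). Scale by \code{sd(x)} for the
#'   conventional relative tolerance.
#' @return Nonnegative real (possibly \code{Inf}).
#' @export
sample_entropy <- function(x, m = 2, r) {
  n <- length(x)
  if (n < m + 2) stop("series too short for sample entropy (need >= m + 2)")
  stopifnot(r > 0, m >= 1)
  d1 <- abs(outer(x, x, "-"))
  nt <- n - m  # both template lengths are counted over the first n - m starts
  cheb <- function(len) {
    dm <- d1[seq_len(nt), seq_len(nt)]
    if (len > 1) {
      for (k in seq_len(len - 1)) {
        dm <- pmax(dm, d1[seq_len(nt) + k, seq_len(nt) + k])
      }
    }
    sum(dm <= r) - nt  # matched ordered pairs, self-matches removed
  }
  b <- cheb(m)
  a <- cheb(m + 1)
  if (a == 0 || b == 0) return(Inf)
  -log(a / b)
}

#' Trim phone-handling artifacts from a bout's edges
#'
#' Scans inward from each bout end over \code{subwindow_s}-second windows of
#' the accelerometer norm (raw rate), advancing by \code{hop_s} up to
#' \code{max_trim_s}. The SampEn tolerance is \code{tolerance_r} times the
#' median subwindow SD of the whole bout, so broadband handling noise scores
#' far above threshold while clean signal stays below at any offset. The end
#' is trimmed to the far edge of the last above-threshold window (capped at
#' \code{max_trim_s}); if no window exceeds the threshold nothing is trimmed,
#' and the interior is never touched. Bouts shorter than two subwindows are
#' returned untrimmed with a warning.
#'
#' @param accel A bout-local accelerometer \code{\link{sensor_stream}} (times
#'   starting at 0).
#' @param activity The bout's activity label.
#' @param cfg A \code{\link{trim_config}}.
#' @return List: \code{trim_lead_s}, \code{trim_trail_s}, and \code{entropy}
#'   (entropies of the scanned lead windows, for audit).
#' @export
trim_bout <- function(accel, activity, cfg = trim_config()) {
  stopifnot(inherits(accel, "sensor_stream"), activity %in% ACTIVITIES,
            inherits(cfg, "trim_config"))
  t <- accel$timestamps
  dur <- if (length(t)) t[length(t)] else 0
  if (dur < 2 * cfg$subwindow_s) {
    warning("bout shorter than two subwindows; returned untrimmed")
    return(list(trim_lead_s = 0, trim_trail_s = 0, entropy = numeric(0)))
  }
  norm <- sqrt(rowSums(accel$values^2))
  thr <- cfg$thresholds[[activity]]
  max_trim <- min(cfg$max_trim_s, dur / 2 - cfg$subwindow_s / 2)

  # robust bout-level amplitude scale: median SD over non-overlapping windows
  n_win <- max(1L, floor(dur / cfg$subwindow_s))
  win_sd <- vapply(seq_len(n_win) - 1L, function(w) {
    stats::sd(norm[t >= w * cfg$subwindow_s & t < (w + 1) * cfg$subwindow_s])
  }, 0)
  r <- cfg$tolerance_r * stats::median(win_sd, na.rm = TRUE)
  if (!is.finite(r) || r <= 0) {
    return(list(trim_lead_s = 0, trim_trail_s = 0, entropy = numeric(0)))
  }

  scan_end <- function(from_tail) {
    offs <- seq(0, max_trim, by = cfg$hop_s)
    ent <- rep(NA_real_, length(offs))
    # an edge artifact >= subwindow_s long must push some window among the
    # first subwindow's worth of offsets above threshold; if none is, stop
    k0 <- min(length(offs), ceiling(cfg$subwindow_s / cfg$hop_s) + 1L)
    for (i in seq_along(offs)) {
      w0 <- offs[i]
      idx <- if (!from_tail) which(t >= w0 & t < w0 + cfg$subwindow_s)
             else which(t > dur - w0 - cfg$subwindow_s & t <= dur - w0)
      if (length(idx) >= cfg$embedding_m + 2) {
        ent[i] <- sample_entropy(norm[idx], cfg$embedding_m, r)
      }
      if (i == k0 && !any(!is.na(ent[1:k0]) & ent[1:k0] > thr)) {
        return(list(trim = 0, ent = ent[1:k0]))
      }
    }
    exceed <- which(!is.na(ent) & ent > thr)
    trim <- if (length(exceed)) {
      min(offs[max(exceed)] + cfg$subwindow_s, max_trim)
    } else 0
    list(trim = trim, ent = ent)
  }
  lead <- scan_end(FALSE)
  trail <- scan_end(TRUE)
  list(trim_lead_s = lead$trim, trim_trail_s = trail$trim, entropy = lead$ent)
}

#' Drop obviously mislabeled ambulatory bouts
#'
#' Bouts labeled Walking, Stairs Up or Stairs Down whose accelerometer-norm SD
#' over the whole bout is below \code{flatness_sd} (near-flat signal,
#' indicating the subject selected the wrong label) are removed. Stationary
#' labels are never touched.
#'
#' @param recording A \code{\link{sensor_recording}}.
#' @param flatness_sd Flatness threshold on the accelerometer-norm SD, m/s^2.
#' @return List: \code{recording} (filtered) and \code{report} (data.frame of
#'   removed bouts with the measured SD).
#' @export
drop_mislabeled <- function(recording, flatness_sd = 0.05) {
  stopifnot(inherits(recording, "sensor_recording"))
  acc <- recording$streams$accelerometer
  bouts <- recording$bouts
  keep <- rep(TRUE, nrow(bouts))
  sds <- rep(NA_real_, nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    if (!(bouts$activity[i] %in% AMBULATORY)) next
    seg <- slice_stream(acc, bouts$start_s[i], bouts$end_s[i])
    if (is.null(seg)) { keep[i] <- FALSE; next }
    sds[i] <- stats::sd(sqrt(rowSums(seg$values^2)))
    if (sds[i] < flatness_sd) keep[i] <- FALSE
  }
  report <- data.frame(bout_id = bouts$bout_id[!keep],
                       activity = bouts$activity[!keep],
                       accel_norm_sd = sds[!keep],
                       reason = rep("flat ambulatory signal", sum(!keep)))
  recording$bouts <- bouts[keep, , drop = FALSE]
  list(recording = recording, report = report)
}

#' Segment a preprocessed bout into overlapping clips
#'
#' Clips start every \code{window_s * (1 - overlap)} seconds from the trimmed
#' bout start; a clip is emitted only if it fits entirely inside the bout's
#' usable duration, so a bout of duration T yields
#' \code{floor((T - window_s)/step) + 1} clips (0 if T < window_s). Each clip
#' spans \code{[s, s + window_s)}: exactly 500 samples per inertial axis at
#' 50 Hz and 60 barometer samples at 6 Hz.
#'
#' @param segment A preprocessed bout segment as produced by
#'   \code{\link{preprocess_recording}} (resampled, grid-aligned streams).
#' @param window_s Clip length, seconds.
#' @param overlap Fractional overlap between consecutive clips in [0, 1).
#' @return data.frame with one row per clip: \code{start_s} (bout-relative),
#'   \code{abs_start_s}, and 1-based sample offsets \code{i_inertial},
#'   \code{i_baro}.
#' @export
segment_clips <- function(segment, window_s = 10, overlap = 0.9) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  step <- window_s * (1 - overlap)
  T_use <- segment$duration_s
  if (T_use < window_s - 1e-9) {
    return(data.frame(start_s = numeric(0), abs_start_s = numeric(0),
                      i_inertial = integer(0), i_baro = integer(0)))
  }
  n_clips <- floor((T_use - window_s) / step + 1e-9) + 1
  starts <- (seq_len(n_clips) - 1) * step
  data.frame(start_s = starts,
             abs_start_s = segment$start_s + starts,
             i_inertial = as.integer(round(starts * segment$rate_inertial)) + 1L,
             i_baro = as.integer(round(starts * segment$rate_baro)) + 1L)
}

#' Preprocess a recording into analysis-ready bout segments
#'
#' For every labeled bout: trims handling artifacts from each end
#' (\code{\link{trim_bout}}), applies the flat-ambulatory mislabel filter,
#' then resamples accelerometer/gyroscope to 50 Hz and barometer to 6 Hz on
#' grids anchored at the trimmed bout start.
#'
#' @param recording A \code{\link{sensor_recording}}.
#' @param trim_cfg A \code{\link{trim_config}}.
#' @param flatness_sd Mislabel flatness threshold, m/s^2 (see
#'   \code{\link{drop_mislabeled}}).
#' @param rate_inertial,rate_baro Analysis rates, Hz.
#' @return List of class \code{preprocessed_recording}: \code{segments} (one
#'   per surviving bout: resampled \code{acc}/\code{gyr} matrices,
#'   \code{baro} vector or NULL, \code{activity}, \code{bout_id},
#'   \code{start_s}, \code{duration_s}, subject metadata),
#'   \code{trim_report}, and \code{rejections}.
#' @export
preprocess_recording <- function(recording, trim_cfg = trim_config(),
                                 flatness_sd = 0.05,
                                 rate_inertial = 50, rate_baro = 6) {
  stopifnot(inherits(recording, "sensor_recording"))
  flt <- drop_mislabeled(recording, flatness_sd)
  rec <- flt$recording
  acc <- rec$streams$accelerometer
  gyr <- rec$streams$gyroscope
  baro <- rec$streams$barometer
  segments <- list()
  trims <- list()
  for (i in seq_len(nrow(rec$bouts))) {
    b <- rec$bouts[i, ]
    acc_seg <- slice_stream(acc, b$start_s, b$end_s)
    gyr_seg <- slice_stream(gyr, b$start_s, b$end_s)
    if (is.null(acc_seg) || is.null(gyr_seg)) next
    tr <- suppressWarnings(trim_bout(acc_seg, b$activity, trim_cfg))
    s0 <- b$start_s + tr$trim_lead_s
    s1 <- b$end_s - tr$trim_trail_s
    trims[[length(trims) + 1L]] <- data.frame(
      bout_id = b$bout_id, activity = b$activity,
      trim_lead_s = tr$trim_lead_s, trim_trail_s = tr$trim_trail_s)
    acc_t <- slice_stream(acc, s0, s1)
    gyr_t <- slice_stream(gyr, s0, s1)
    if (is.null(acc_t) || is.null(gyr_t)) next
    acc_r <- resample_stream(acc_t, rate_inertial)
    gyr_r <- resample_stream(gyr_t, rate_inertial)
    n_in <- min(nrow(acc_r$values), nrow(gyr_r$values))
    dur <- n_in / rate_inertial
    baro_vals <- NULL
    if (!is.null(baro)) {
      baro_t <- slice_stream(baro, s0, s1)
      if (!is.null(baro_t)) {
        baro_r <- resample_stream(baro_t, rate_baro)
        baro_vals <- baro_r$values[, 1]
        dur <- min(dur, length(baro_vals) / rate_baro)
      } else baro <- baro  # too short; treat as absent for this bout
    }
    segments[[length(segments) + 1L]] <- list(
      subject_id = rec$subject_id, session = rec$session,
      environment = rec$environment,
      cohort = rec$metadata$cohort %||% NA_character_,
      impairment = rec$metadata$impairment %||% NA_character_,
      gait_speed = rec$metadata$gait_speed %||% NA_real_,
      bout_id = b$bout_id, activity = b$activity,
      start_s = s0, duration_s = dur,
      rate_inertial = rate_inertial, rate_baro = rate_baro,
      acc = acc_r$values[seq_len(n_in), , drop = FALSE],
      gyr = gyr_r$values[seq_len(n_in), , drop = FALSE],
      baro = baro_vals)
  }
  structure(list(
    segments = segments,
    trim_report = if (length(trims)) do.call(rbind, trims) else
      data.frame(bout_id = character(0), activity = character(0),
                 trim_lead_s = numeric(0), trim_trail_s = numeric(0)),
    rejections = flt$report
  ), class = "preprocessed_recording")
}
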