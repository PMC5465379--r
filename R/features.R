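# The 270-feature catalogue: per-clip time-, derivative- and frequency-domain
# statistics from accelerometer, gyroscope and barometer windows.

zhist_fractions <- function(x) {
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  c(sum(z >= -2 & z < -1), sum(z >= -1 & z < 0),
    sum(z >= 0 & z < 1), sum(z >= 1 & z <= 2)) / length(x)
}

# Vectorized unnamed feature block for one 3-axis inertial window, in
# catalogue order (x block, y block, z block, cross-axis block). Used by the
# per-clip hot path; the exported extract_inertial_features() wraps it with
# validation and names.
inertial_features_fast <- function(mat, rate) {
  n <- nrow(mat)
  m1 <- colMeans(mat)
  cm <- sweep(mat, 2, m1)
  m2 <- colMeans(cm^2)
  sdv <- sqrt(m2 * n / (n - 1))
  skew <- ifelse(m2 > 0, colMeans(cm^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, colMeans(cm^4) / m2^2, 0)

  d <- mat[-1, , drop = FALSE] - mat[-n, , drop = FALSE]
  d <- d * rate
  dm1 <- colMeans(d)
  dcm <- sweep(d, 2, dm1)
  dm2 <- colMeans(dcm^2)
  dsd <- sqrt(dm2 * nrow(d) / (nrow(d) - 1))
  dskew <- ifelse(dm2 > 0, colMeans(dcm^3) / dm2^1.5, 0)
  dkurt <- ifelse(dm2 > 0, colMeans(dcm^4) / dm2^2, 0)

  # one-sided periodogram, all axes at once
  P <- Mod(stats::mvfft(cm))^2 / n
  half <- n %/% 2 + 1L
  P <- P[seq_len(half), , drop = FALSE]
  bins <- band_bin_index(n, rate)          # cached bin id per ordinate
  bp <- rowsum(P[bins$sel, , drop = FALSE], bins$id) / bins$counts
  pos <- P[-1, , drop = FALSE]
  pm1 <- colMeans(pos)
  pcm <- sweep(pos, 2, pm1)
  pm2 <- colMeans(pcm^2)
  psd <- sqrt(pm2 * nrow(pos) / (nrow(pos) - 1))
  pskew <- ifelse(pm2 > 0, colMeans(pcm^3) / pm2^1.5, 0)
  pkurt <- ifelse(pm2 > 0, colMeans(pcm^4) / pm2^2, 0)

  out <- numeric(131)
  pos_i <- 1L
  for (j in 1:3) {
    x <- mat[, j]
    s <- sdv[j]
    z <- if (s > 0) (x - m1[j]) / s else numeric(n)
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    zh <- c(sum(z >= -2 & z < -1), sum(z >= -1 & z < 0),
            sum(z >= 0 & z < 1), sum(z >= 1 & z <= 2)) / n
    out[pos_i:(pos_i + 37L)] <- c(
      m1[j], max(x) - min(x), q[2] - q[1],
      s, skew[j], kurt[j], zh,
      dm1[j], dsd[j], dskew[j], dkurt[j],
      pm1[j], psd[j], pskew[j], pkurt[j], bp[, j])
    pos_i <- pos_i + 38L
  }
  rmsv <- sqrt(colMeans(mat^2))
  cross <- numeric(17)
  ci <- 1L
  pr <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (p in pr) {
    cross[ci] <- if (m2[p[1]] > 0 && m2[p[2]] > 0)
      mean(cm[, p[1]] * cm[, p[2]]) / sqrt(m2[p[1]] * m2[p[2]])
    else 0
    ci <- ci + 1L
  }
  for (p in pr) {
    den <- rmsv[p[1]] * rmsv[p[2]]
    raw <- mean(mat[, p[1]] * mat[, p[2]])
    cross[ci] <- raw
    cross[ci + 1L] <- if (den > 0) raw / den else 0
    ci <- ci + 2L
  }
  for (p in pr) {
    den <- rmsv[p[1]] * rmsv[p[2]]
    araw <- mean(abs(mat[, p[1]] * mat[, p[2]]))
    cross[ci] <- araw
    cross[ci + 1L] <- if (den > 0) araw / den else 0
    ci <- ci + 2L
  }
  cross[16] <- sum(rmsv^2)          # mean squared norm
  cross[17] <- sum(sdv)             # sum of axial SDs
  out[115:131] <- cross
  out
}

# Cached ordinate -> 0.5 Hz band mapping for the one-sided periodogram.
band_bin_index <- function(n, rate, n_bins = 20, bin_hz = 0.5) {
  key <- sprintf("%d_%g", n, rate)
  hit <- .catalog_cache[[key]]
  if (!is.null(hit)) return(hit)
  freq <- (seq_len(n %/% 2 + 1L) - 1L) * rate / n
  id <- floor(freq / bin_hz + 1e-12) + 1L
  sel <- which(id >= 1 & id <= n_bins)
  res <- list(sel = sel, id = id[sel],
              counts = as.vector(table(factor(id[sel], levels = seq_len(n_bins)))))
  .catalog_cache[[key]] <- res
  res
}

barometer_features_fast <- function(p, rate) {
  n <- length(p)
  d <- (p[-1] - p[-n]) * rate
  m <- mean(d)
  dcm <- d - m
  dm2 <- mean(dcm^2)
  t <- (seq_len(n) - 1) / rate
  q <- stats::quantile(p, c(0.25, 0.75), names = FALSE, type = 7)
  c(m, sqrt(dm2 * (n - 1) / (n - 2)),
    if (dm2 > 0) mean(dcm^3) / dm2^1.5 else 0,
    if (dm2 > 0) mean(dcm^4) / dm2^2 else 0,
    stats::sd(p), max(p) - min(p), q[2] - q[1],
    stats::cov(t, p) / stats::var(t))
}

# One-sided periodogram of the mean-removed signal: P_k = |X_k|^2 / n at
# frequencies k * rate / n, k = 0 .. n/2. DC ordinate is 0 by construction.
periodogram <- function(x, rate) {
  n <- length(x)
  xc <- x - mean(x)
  p <- Mod(stats::fft(xc))^2 / n
  k <- 0:(n %/% 2)
  list(freq = k * rate / n, power = p[k + 1])
}

spectral_features <- function(x, rate, n_bins = 20, bin_hz = 0.5) {
  pg <- periodogram(x, rate)
  pos <- pg$power[-1]  # moments over positive-frequency ordinates
  bins <- vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_hz
    mean(pg$power[pg$freq >= lo - 1e-12 & pg$freq < lo + bin_hz - 1e-12])
  }, 0)
  c(spec_mean = mean(pos), spec_sd = stats::sd(pos),
    spec_skew = moment_skew(pos), spec_kurt = moment_kurt(pos),
    stats::setNames(bins, sprintf("bp%02d", seq_len(n_bins))))
}

axis_features <- function(x, rate) {
  d <- diff(x) * rate
  c(mean = mean(x), range = max(x) - min(x),
    iqr = stats::IQR(x),
    sd = stats::sd(x), skew = moment_skew(x), kurt = moment_kurt(x),
    stats::setNames(zhist_fractions(x), paste0("zhist", 1:4)),
    deriv_mean = mean(d), deriv_sd = stats::sd(d),
    deriv_skew = moment_skew(d), deriv_kurt = moment_kurt(d),
    spectral_features(x, rate))
}

safe_cor <- function(a, b) {
  if (stats::sd(a) <= 0 || stats::sd(b) <= 0) return(0)
  stats::cor(a, b)
}

cross_products <- function(a, b) {
  den <- rms(a) * rms(b)
  raw <- mean(a * b)
  araw <- mean(abs(a * b))
  c(raw = raw, norm = if (den > 0) raw / den else 0,
    abs_raw = araw, abs_norm = if (den > 0) araw / den else 0)
}

#' Extract the 131 features of one inertial clip channel
#'
#' Computes, for a 500-sample x 3-axis window at 50 Hz, the full per-axis and
#' cross-axis feature set: per axis, mean/range/IQR, SD/skew/kurtosis, 4
#' z-score histogram fractions on [-2, 2], 4 first-derivative moments, 4
#' power-spectrum moments and 20 band powers (0.5 Hz bins, 0-10 Hz); across
#' axes, the 3 Pearson correlations, raw and normalized mean cross products
#' and their absolute variants for xy/xz/yz, the mean squared norm, and the
#' sum of axial SDs. Skew and kurtosis use population moments (kurtosis
#' non-excess); degenerate (zero-variance) inputs yield 0 by convention. The
#' normalized cross product divides by the product of the axis RMS values.
#'
#' @param mat Numeric matrix, exactly 500 rows x 3 columns (axes x, y, z).
#' @param sensor Name prefix, \code{"acc"} or \code{"gyro"}.
#' @param rate Sampling rate, Hz.
#' @param n_samples Required row count.
#' @return Named numeric vector of length 131, names matching
#'   \code{\link{feature_catalog}}.
#' @export
extract_inertial_features <- function(mat, sensor = c("acc", "gyro"),
                                      rate = 50, n_samples = 500) {
  sensor <- match.arg(sensor)
  mat <- as.matrix(mat)
  if (nrow(mat) != n_samples || ncol(mat) != 3) {
    stop("inertial clip must be exactly ", n_samples, " samples x 3 axes")
  }
  cat270 <- feature_catalog()
  stats::setNames(inertial_features_fast(mat, rate),
                  cat270$name[cat270$sensor == sensor])
}

# Reference (slow, definition-by-definition) implementation kept for clarity;
# inertial_features_fast must agree with it (checked in tests).
extract_inertial_features_ref <- function(mat, sensor = c("acc", "gyro"),
                                          rate = 50, n_samples = 500) {
  sensor <- match.arg(sensor)
  mat <- as.matrix(mat)
  if (nrow(mat) != n_samples || ncol(mat) != 3) {
    stop("inertial clip must be exactly ", n_samples, " samples x 3 axes")
  }
  per_axis <- lapply(1:3, function(j) axis_features(mat[, j], rate))
  names(per_axis) <- c("x", "y", "z")
  out <- numeric(0)
  for (ax in c("x", "y", "z")) {
    v <- per_axis[[ax]]
    names(v) <- paste(sensor, ax, names(v), sep = "_")
    out <- c(out, v)
  }
  pairs <- list(xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  corr <- vapply(pairs, function(p) safe_cor(mat[, p[1]], mat[, p[2]]), 0)
  names(corr) <- paste(sensor, "corr", names(pairs), sep = "_")
  xp <- numeric(0); axp <- numeric(0)
  for (pn in names(pairs)) {
    p <- pairs[[pn]]
    cp <- cross_products(mat[, p[1]], mat[, p[2]])
    xp <- c(xp, stats::setNames(cp[c("raw", "norm")],
                                paste(sensor, "xprod", pn, c("raw", "norm"), sep = "_")))
    axp <- c(axp, stats::setNames(cp[c("abs_raw", "abs_norm")],
                                  paste(sensor, "absxprod", pn, c("raw", "norm"), sep = "_")))
  }
  tail2 <- stats::setNames(
    c(mean(rowSums(mat^2)), sum(apply(mat, 2, stats::sd))),
    paste(sensor, c("msn", "sumsd"), sep = "_"))
  c(out, corr, xp, axp, tail2)
}

#' Extract the 8 barometer features of one clip
#'
#' Derivative (first difference times rate) mean/SD/skew/kurtosis, pressure
#' SD, range and IQR, and the ordinary-least-squares slope of pressure against
#' time (hPa/s).
#'
#' @param p Numeric vector, exactly 60 samples at 6 Hz.
#' @param rate Sampling rate, Hz.
#' @param n_samples Required length.
#' @return Named numeric vector of length 8 (names per
#'   \code{\link{feature_catalog}}); all \code{NA} if \code{p} is NULL
#'   (absent barometer).
#' @export
extract_barometer_features <- function(p, rate = 6, n_samples = 60) {
  nm <- barometer_feature_names()
  if (is.null(p)) return(stats::setNames(rep(NA_real_, 8), nm))
  if (length(p) != n_samples) {
    stop("barometer clip must be exactly ", n_samples, " samples")
  }
  stats::setNames(barometer_features_fast(p, rate), nm)
}

# Features of every clip of one preprocessed bout segment (hot path).
featurize_segment <- function(segment, clips, window_s = 10) {
  n_in <- window_s * segment$rate_inertial
  n_b <- window_s * segment$rate_baro
  out <- matrix(NA_real_, nrow(clips), 270)
  for (k in seq_len(nrow(clips))) {
    ii <- clips$i_inertial[k]
    sl <- ii:(ii + n_in - 1)
    fa <- inertial_features_fast(segment$acc[sl, , drop = FALSE],
                                 segment$rate_inertial)
    fg <- inertial_features_fast(segment$gyr[sl, , drop = FALSE],
                                 segment$rate_inertial)
    fb <- if (is.null(segment$baro)) rep(NA_real_, 8) else
      barometer_features_fast(
        segment$baro[clips$i_baro[k]:(clips$i_baro[k] + n_b - 1)],
        segment$rate_baro)
    out[k, ] <- c(fa, fg, fb)
  }
  colnames(out) <- feature_catalog()$name
  out
}

#' Build the instance table (clips x features) for a cohort or recordings
#'
#' Runs the full preprocessing chain (mislabel filter, entropy trimming,
#' resampling, 10-s / 90%-overlap segmentation) and feature extraction for
#' every recording, returning one row per clip with grouping metadata.
#'
#' @param x An \code{ar_cohort}, a single \code{sensor_recording}, or a list
#'   of recordings.
#' @param trim_cfg A \code{\link{trim_config}}.
#' @param window_s,overlap Clip length (s) and fractional overlap.
#' @param feature_set \code{"all"} or a character subset of catalogue names
#'   (unknown names are an error).
#' @param flatness_sd Mislabel flatness threshold (m/s^2).
#' @return Object of class \code{instance_table}: a data.frame whose metadata
#'   columns are \code{subject_id, session, environment, cohort, impairment,
#'   gait_speed, bout_id, activity, clip_start_s, clip_end_s} followed by one
#'   column per feature; attribute \code{feature_names} lists the feature
#'   columns in catalogue order.
#' @export
build_instance_table <- function(x, trim_cfg = trim_config(), window_s = 10,
                                 overlap = 0.9, feature_set = "all",
                                 flatness_sd = 0.05) {
  recs <- if (inherits(x, "ar_cohort")) x$recordings
          else if (inherits(x, "sensor_recording")) list(x)
          else x
  cat270 <- feature_catalog()
  keep_names <- resolve_feature_set(feature_set, cat270$name)
  meta <- list(); feats <- list()
  for (rec in recs) {
    pp <- preprocess_recording(rec, trim_cfg, flatness_sd)
    for (seg in pp$segments) {
      clips <- segment_clips(seg, window_s, overlap)
      if (!nrow(clips)) next
      fm <- featurize_segment(seg, clips, window_s)
      feats[[length(feats) + 1L]] <- fm
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = seg$subject_id, session = seg$session,
        environment = seg$environment, cohort = seg$cohort,
        impairment = seg$impairment, gait_speed = seg$gait_speed,
        bout_id = seg$bout_id, activity = seg$activity,
        clip_start_s = clips$abs_start_s,
        clip_end_s = clips$abs_start_s + window_s,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(feats)) {
    fm <- matrix(numeric(0), 0, length(keep_names),
                 dimnames = list(NULL, keep_names))
    md <- data.frame(subject_id = character(0), session = character(0),
                     environment = character(0), cohort = character(0),
                     impairment = character(0), gait_speed = numeric(0),
                     bout_id = character(0), activity = character(0),
                     clip_start_s = numeric(0), clip_end_s = numeric(0))
    return(instance_table(md, fm))
  }
  fm <- do.call(rbind, feats)[, keep_names, drop = FALSE]
  instance_table(do.call(rbind, meta), fm)
}

resolve_feature_set <- function(feature_set, all_names) {
  if (identical(feature_set, "all")) return(all_names)
  unknown <- setdiff(feature_set, all_names)
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  all_names[all_names %in% feature_set]  # catalogue order
}

#' Assemble an instance table from metadata and a feature matrix
#'
#' @param meta data.frame of per-clip metadata.
#' @param features Numeric matrix, one row per clip, named columns.
#' @return An \code{instance_table}.
#' @export
instance_table <- function(meta, features) {
  stopifnot(nrow(meta) == nrow(features), !is.null(colnames(features)))
  out <- cbind(meta, as.data.frame(features))
  attr(out, "feature_names") <- colnames(features)
  class(out) <- c("instance_table", "data.frame")
  out
}

#' Feature columns of an instance table
#' @param table An \code{instance_table}.
#' @return Character vector of feature column names, in catalogue order.
#' @export
feature_names <- function(table) attr(table, "feature_names")

#' Restrict an instance table to a feature subset
#' @param table An \code{instance_table}.
#' @param feature_set Character vector of feature names (subset of the
#'   table's features) or \code{"all"}.
#' @return An \code{instance_table} with the projected feature columns.
#' @export
subset_features <- function(table, feature_set) {
  fn <- feature_names(table)
  keep <- resolve_feature_set(feature_set, fn)
  meta_cols <- setdiff(names(table), fn)
  out <- table[, c(meta_cols, keep)]
  attr(out, "feature_names") <- keep
  class(out) <- c("instance_table", "data.frame")
  out
}

#' @export
print.instance_table <- function(x, ...) {
  cat(sprintf("<instance_table> %d instances x %d features (%d subjects, %d classes)\n",
              nrow(x), length(feature_names(x)),
              length(unique(x$subject_id)), length(unique(x$activity))))
  invisible(x)
}
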