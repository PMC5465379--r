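# Synthetic multi-sensor recording generator.
#
# Signals are synthesised in a body frame (x forward, y lateral, z vertical),
# then rotated by the subject's phone orientation (pouch placement is
# unconstrained, so features must cope with arbitrary orientation). Home
# sessions additionally perturb orientation, amplitude and effective gait
# speed per bout, scaled by the subject's environment-variability multiplier.

GRAVITY <- 9.81

# One bout's body-frame signals on jittered ~60 Hz grids plus a 6 Hz barometer.
# Returns accel/gyro (n x 3), shared inertial timestamps, baro times/pressure,
# and the artifact durations actually injected at each end.
simulate_bout_signals <- function(params, duration_s, env_mult = 1,
                                  artifact_rate = 0, rate_hz = 60,
                                  jitter_sd = 0.002, p0 = 1000) {
  n <- round(duration_s * rate_hz)
  dt <- pmax(1 / rate_hz + stats::rnorm(n, 0, jitter_sd), 1 / (2 * rate_hz))
  t <- cumsum(dt) - dt[1]
  t <- t * (duration_s / max(t[n], duration_s))  # keep nominal span
  n <- length(t)

  sway <- cbind(band_sway(t, params$sway_sd * env_mult),
                band_sway(t, params$sway_sd * env_mult),
                band_sway(t, params$sway_sd * env_mult))
  acc <- sway + matrix(stats::rnorm(3 * n, 0, 0.0004), n, 3)
  acc <- sweep(acc, 2, GRAVITY * params$gravity, "+")
  gyr <- cbind(smooth_noise(n, 0.02 * env_mult),
               smooth_noise(n, 0.02 * env_mult),
               smooth_noise(n, 0.015 * env_mult)) +
    matrix(stats::rnorm(3 * n, 0, 0.002), n, 3)

  if (params$cadence > 0) {
    f_inst <- params$cadence * (1 + smooth_noise(n, params$gait_var_sd, phi = 0.9))
    phase <- 2 * pi * cumsum(f_inst * c(dt[-1], dt[n]))
    amp <- params$amplitude * (1 + smooth_noise(n, params$gait_var_sd, phi = 0.9))
    vert <- amp * sin(phase) + 0.35 * amp * sin(2 * phase + 0.7)
    fwd <- 0.6 * amp * sin(phase + 0.9)
    lat <- 0.30 * amp * sin(phase / 2)
    acc <- acc + cbind(fwd, lat, vert)
    gyr <- gyr + cbind(0.5 * params$gyro_amp * sin(phase / 2 + 0.3),
                       0.4 * params$gyro_amp * sin(phase + 1.2),
                       params$gyro_amp * sin(phase / 2))
  }

  # phone-handling artifacts: 1-3 s broadband noise at bout edges
  art <- c(0, 0)
  for (end in 1:2) {
    if (stats::runif(1) < artifact_rate) {
      dur <- stats::runif(1, 1, 3)
      idx <- if (end == 1) which(t < dur) else which(t > t[n] - dur)
      acc[idx, ] <- acc[idx, ] + matrix(stats::rnorm(3 * length(idx), 0, 3), ncol = 3)
      gyr[idx, ] <- gyr[idx, ] + matrix(stats::rnorm(3 * length(idx), 0, 1.5), ncol = 3)
      art[end] <- dur
    }
  }

  nb <- max(2L, floor(duration_s * 6))
  tb <- (seq_len(nb) - 1) / 6 + stats::rnorm(nb, 0, 0.005)
  tb <- sort(pmax(tb, 0))
  baro <- p0 + params$baro_trend * tb + smooth_noise(nb, 0.01) +
    stats::rnorm(nb, 0, params$baro_noise_sd)

  list(t = t, acc = acc, gyr = gyr, tb = tb, baro = as.numeric(baro),
       artifact_lead_s = art[1], artifact_trail_s = art[2])
}

#' Simulate one subject-session recording
#'
#' Generates a labeled multi-sensor recording: tri-axial accelerometer and
#' gyroscope at a jittered ~60 Hz, barometer at 6 Hz, with one labeled bout
#' per planned activity repetition. Gravity (9.81 m/s^2) dominates stationary
#' bouts; gait bouts carry quasi-periodic components at the subject's cadence
#' and harmonics; stair bouts add a signed barometric trend. Bouts may be
#' corrupted at the edges by phone-handling artifacts, mislabeled, or dropped,
#' at the rates in \code{spec}; ground truth for all three is kept in the
#' returned recording for test assertions.
#'
#' @param profile A \code{\link{subject_profile}}.
#' @param spec A \code{\link{cohort_spec}}.
#' @param session \code{"Lab1"}, \code{"Home"} or \code{"Lab2"}.
#' @return A \code{sensor_recording} (see \code{\link{sensor_recording}}) with
#'   an extra \code{ground_truth} bout table (columns: bout_id, activity as
#'   labeled, true_activity, start_s, end_s, artifact_lead_s,
#'   artifact_trail_s, mislabeled, dropped).
#' @export
simulate_subject <- function(profile, spec, session = c("Home", "Lab1", "Lab2")) {
  session <- match.arg(session)
  stopifnot(inherits(profile, "subject_profile"), inherits(spec, "cohort_spec"))
  env <- session_environment(session)
  env_mult <- if (env == "home") profile$environment_variability else 1
  n_bouts <- if (env == "home") spec$bouts_home else spec$bouts_lab
  prev <- if (env == "home") spec$prevalence_home else spec$prevalence_lab

  with_seed(derive_seed(spec$rng_seed, paste(profile$subject_id, session)), {
    counts <- allocate_counts(n_bouts, prev, spec$min_bouts_per_activity)
    plan <- sample(rep(ACTIVITIES, counts))

    t_cursor <- 0
    ts <- list(); acc <- list(); gyr <- list(); tb <- list(); baro <- list()
    gt <- vector("list", length(plan))
    p0 <- 1000 + stats::rnorm(1, 0, 5)
    for (k in seq_along(plan)) {
      true_act <- plan[k]
      dur <- stats::runif(1, spec$duration_range[[true_act]][1],
                          spec$duration_range[[true_act]][2])
      dropped <- stats::runif(1) < spec$drop_rate
      mislab <- stats::runif(1) < spec$mislabel_rate
      label <- true_act
      if (mislab) label <- sample(setdiff(ACTIVITIES, true_act), 1)
      t_cursor <- t_cursor + stats::runif(1, 2, 5)   # unlabeled gap
      start_s <- t_cursor
      if (!dropped) {
        v_b <- profile$gait_speed *
          exp(stats::rnorm(1, 0, 0.08 * max(env_mult - 1, 0)))
        pars <- activity_params(true_act, v_b, spec$signal_coef)
        sig <- simulate_bout_signals(pars, dur, env_mult,
                                     spec$artifact_rate, p0 = p0)
        rot <- profile$phone_orientation
        if (env == "home") {
          rot <- jitter_rotation(0.15 * max(env_mult - 1, 0)) %*% rot
        }
        scale_b <- exp(stats::rnorm(1, 0, 0.10 * max(env_mult - 1, 0)))
        # amplitude jitter affects movement, not gravity
        gvec <- GRAVITY * pars$gravity
        acc_dyn <- sweep(sweep(sig$acc, 2, gvec) * scale_b, 2, gvec, "+")
        ts[[k]] <- sig$t + start_s
        acc[[k]] <- acc_dyn %*% t(rot)
        gyr[[k]] <- (sig$gyr * scale_b) %*% t(rot)
        tb[[k]] <- sig$tb + start_s
        baro[[k]] <- sig$baro
        gt[[k]] <- data.frame(
          activity = label, true_activity = true_act,
          start_s = start_s, end_s = start_s + dur,
          artifact_lead_s = sig$artifact_lead_s,
          artifact_trail_s = sig$artifact_trail_s,
          mislabeled = mislab, dropped = FALSE)
      } else {
        gt[[k]] <- data.frame(
          activity = label, true_activity = true_act,
          start_s = start_s, end_s = start_s + dur,
          artifact_lead_s = 0, artifact_trail_s = 0,
          mislabeled = mislab, dropped = TRUE)
      }
      t_cursor <- start_s + dur
    }
    gt <- do.call(rbind, gt)
    gt$bout_id <- sprintf("%s_%s_b%03d", profile$subject_id, session, seq_len(nrow(gt)))
    gt <- gt[, c("bout_id", setdiff(names(gt), "bout_id"))]

    keep <- !gt$dropped
    bouts <- gt[keep, c("bout_id", "activity", "start_s", "end_s")]
    rownames(bouts) <- NULL

    bind_or_empty <- function(lst, ncol) {
      lst <- lst[!vapply(lst, is.null, TRUE)]
      if (!length(lst)) matrix(numeric(0), 0, ncol) else do.call(rbind, lst)
    }
    t_all <- unlist(ts, use.names = FALSE) %||% numeric(0)
    tb_all <- unlist(tb, use.names = FALSE) %||% numeric(0)
    streams <- list(
      accelerometer = sensor_stream("accelerometer", t_all,
                                    bind_or_empty(acc, 3), 60),
      gyroscope = sensor_stream("gyroscope", t_all, bind_or_empty(gyr, 3), 60),
      barometer = sensor_stream("barometer", tb_all,
                                matrix(unlist(baro, use.names = FALSE) %||% numeric(0),
                                       ncol = 1), 6)
    )
    rec <- sensor_recording(profile$subject_id, session, streams, bouts,
                            metadata = list(cohort = profile$cohort,
                                            gait_speed = profile$gait_speed,
                                            impairment = profile$impairment))
    rec$ground_truth <- gt
    rec
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws subject profiles per stratum (healthy gait speeds from a truncated
#' normal; stroke speeds uniform within each impairment band), then simulates
#' one recording per subject and session. Healthy subjects record a single
#' home session; stroke subjects record the sessions in
#' \code{spec$stroke_sessions}.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return An object of class \code{ar_cohort}: list with \code{recordings}
#'   (named \code{<subject>_<session>}), \code{profiles}, \code{manifest}
#'   (subject, cohort, impairment, gait_speed, session, environment, bout and
#'   loss counts) and \code{bouts} (pooled ground-truth bout table).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_healthy + spec$n_mild + spec$n_moderate + spec$n_severe
  if (n_total == 0) stop("cohort spec requests zero subjects")

  profiles <- with_seed(derive_seed(spec$rng_seed, "profiles"), {
    out <- list()
    draw_speed <- function(stratum, i) {
      switch(stratum,
        none = max(0.3, stats::rnorm(1, spec$healthy_speed_mean, spec$healthy_speed_sd)),
        mild = stats::runif(1, 0.85, 1.15),
        moderate = stats::runif(1, 0.42, 0.78),
        severe = stats::runif(1, 0.18, 0.38))
    }
    k <- 0
    for (stratum in c("none", "mild", "moderate", "severe")) {
      n_s <- switch(stratum, none = spec$n_healthy, mild = spec$n_mild,
                    moderate = spec$n_moderate, severe = spec$n_severe)
      for (i in seq_len(n_s)) {
        k <- k + 1
        cohort <- if (stratum == "none") "healthy" else "stroke"
        id <- sprintf("%s%02d", if (cohort == "healthy") "H" else "S", k)
        out[[id]] <- subject_profile(
          id, cohort, draw_speed(stratum, i),
          environment_variability = spec$environment_variability)
      }
    }
    out
  })

  recordings <- list()
  manifest <- list()
  bouts <- list()
  for (pr in profiles) {
    sessions <- if (pr$cohort == "healthy") "Home" else spec$stroke_sessions
    for (ses in sessions) {
      rec <- simulate_subject(pr, spec, ses)
      key <- paste(pr$subject_id, ses, sep = "_")
      recordings[[key]] <- rec
      gt <- rec$ground_truth
      gt$subject_id <- pr$subject_id
      gt$session <- ses
      gt$environment <- session_environment(ses)
      bouts[[key]] <- gt
      manifest[[key]] <- data.frame(
        subject_id = pr$subject_id, cohort = pr$cohort,
        impairment = pr$impairment, gait_speed = pr$gait_speed,
        session = ses, environment = session_environment(ses),
        n_bouts_planned = nrow(gt), n_bouts = sum(!gt$dropped),
        n_dropped = sum(gt$dropped), n_mislabeled = sum(gt$mislabeled),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    spec = spec, profiles = profiles, recordings = recordings,
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    bouts = do.call(rbind, c(bouts, list(make.row.names = FALSE)))
  ), class = "ar_cohort")
}

#' @export
print.ar_cohort <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic activity-recognition cohort\n")
  cat(sprintf("  %d subjects (%d healthy, %d stroke), %d recordings\n",
              length(x$profiles),
              sum(vapply(x$profiles, function(p) p$cohort == "healthy", TRUE)),
              sum(vapply(x$profiles, function(p) p$cohort == "stroke", TRUE)),
              nrow(m)))
  cat(sprintf("  bouts: %d planned, %d delivered, %d dropped, %d mislabeled\n",
              sum(m$n_bouts_planned), sum(m$n_bouts), sum(m$n_dropped),
              sum(m$n_mislabeled)))
  invisible(x)
}

#' Write a recording (or cohort) as CSV files
#'
#' Writes per-sensor CSVs (\code{<subject>_<session>_<sensor>.csv} with
#' columns \code{timestamp_s, x, y, z} for inertial sensors or
#' \code{timestamp_s, pressure_hPa} for the barometer), a labels CSV
#' (\code{bout_id, activity, start_s, end_s}) and, for cohorts, a
#' \code{manifest.csv}.
#'
#' @param x A \code{sensor_recording} or \code{ar_cohort}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(inherits(x, "sensor_recording"))
  base <- file.path(dir, paste(x$subject_id, x$session, sep = "_"))
  paths <- character(0)
  for (s in names(x$streams)) {
    st <- x$streams[[s]]
    df <- data.frame(timestamp_s = st$timestamps)
    if (s == "barometer") df$pressure_hPa <- st$values[, 1]
    else { df$x <- st$values[, 1]; df$y <- st$values[, 2]; df$z <- st$values[, 3] }
    p <- paste0(base, "_", s, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(base, "_labels.csv")
  utils::write.csv(x$bouts, p, row.names = FALSE)
  invisible(c(paths, p))
}

#' @rdname write_recording
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ar_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- unlist(lapply(x$recordings, write_recording, dir = dir))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(x$manifest, mp, row.names = FALSE)
  invisible(c(paths, mp))
}
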