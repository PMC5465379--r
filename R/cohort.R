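#' Map preferred gait speed to an impairment stratum
#'
#' Uses the conventional 10-meter-walk-test cut points for community
#' ambulation after stroke: mild impairment above 0.8 m/s, moderate between
#' 0.4 and 0.8 m/s (inclusive), severe below 0.4 m/s. Healthy subjects are
#' coded \code{"none"}.
#'
#' @param gait_speed Preferred walking speed in m/s (positive).
#' @param cohort \code{"healthy"} or \code{"stroke"}.
#' @return One of \code{"none"}, \code{"mild"}, \code{"moderate"},
#'   \code{"severe"}.
#' @export
impairment_from_speed <- function(gait_speed, cohort = "stroke") {
  stopifnot(all(gait_speed > 0))
  if (identical(cohort, "healthy")) return(rep("none", length(gait_speed)))
  ifelse(gait_speed > 0.8, "mild",
         ifelse(gait_speed >= 0.4, "moderate", "severe"))
}

#' Construct a subject profile for the synthetic generator
#'
#' @param subject_id Identifier string.
#' @param cohort \code{"healthy"} or \code{"stroke"}.
#' @param gait_speed Preferred gait speed, m/s (> 0).
#' @param environment_variability Multiplier (>= 1) controlling how much more
#'   variable home sessions are than lab sessions (orientation jitter, signal
#'   noise, bout-to-bout amplitude scatter).
#' @param phone_orientation 3x3 rotation matrix applied to body-frame inertial
#'   signals (pouch placement); default a random rotation drawn from the
#'   current RNG stream.
#' @return An object of class \code{subject_profile}.
#' @export
subject_profile <- function(subject_id, cohort = c("stroke", "healthy"),
                            gait_speed, environment_variability = 1.6,
                            phone_orientation = NULL) {
  cohort <- match.arg(cohort)
  stopifnot(is.numeric(gait_speed), length(gait_speed) == 1, gait_speed > 0,
            environment_variability > 0)
  if (is.null(phone_orientation)) phone_orientation <- random_rotation()
  stopifnot(is.matrix(phone_orientation), all(dim(phone_orientation) == 3))
  structure(list(
    subject_id = as.character(subject_id),
    cohort = cohort,
    gait_speed = gait_speed,
    impairment = impairment_from_speed(gait_speed, cohort),
    environment_variability = environment_variability,
    phone_orientation = phone_orientation
  ), class = "subject_profile")
}

#' Per-activity signal model parameters
#'
#' Returns the generative parameters used to synthesise one activity bout for
#' a subject with a given gait speed. Stationary activities are dominated by
#' a gravity orientation plus smooth postural sway; gait activities add
#' quasi-periodic components whose cadence and amplitude increase with gait
#' speed while stride-to-stride variability decreases; stair activities add a
#' signed barometric pressure trend (ascent: pressure falls; descent: rises).
#'
#' All coefficients are synthetic stand-ins (no signal-level measurements are
#' available for the cohorts being emulated); they are exposed here so tests
#' and users can see and override the generative assumptions.
#'
#' @param activity One of the six activity labels.
#' @param gait_speed Gait speed in m/s.
#' @param coef Optional named list overriding default coefficients:
#'   \code{cadence_c0}, \code{cadence_c1} (Hz and Hz per m/s),
#'   \code{amp_per_speed} (m/s^2 per m/s), \code{baro_per_meter} (hPa per
#'   vertical meter), \code{climb_per_speed} (vertical m/s per m/s of gait
#'   speed).
#' @return List with gravity unit vector, sway SD, cadence (Hz), step
#'   amplitude (m/s^2), gait variability SD, gyroscope amplitude (rad/s),
#'   barometric trend (hPa/s) and barometric noise SD (hPa).
#' @export
activity_params <- function(activity, gait_speed, coef = list()) {
  stopifnot(activity %in% ACTIVITIES, gait_speed > 0)
  co <- list(cadence_c0 = 0.5, cadence_c1 = 1.2, amp_per_speed = 1.8,
             baro_per_meter = 0.12, climb_per_speed = 0.25)
  co[names(coef)] <- coef
  grav <- switch(activity,
    Sitting   = c(0.20, 0.10, 0.97),
    Lying     = c(0.05, 0.97, 0.24),
    Standing  = c(0.05, 0.02, 1.00),
    StairsUp  = c(0.12, 0.03, 0.99),
    StairsDown = c(0.10, 0.05, 0.99),
    Walking   = c(0.08, 0.02, 1.00))
  grav <- grav / sqrt(sum(grav^2))
  sway_sd <- switch(activity, Sitting = 0.025, Lying = 0.018, Standing = 0.035,
                    StairsUp = 0.06, StairsDown = 0.06, Walking = 0.05)
  ambulatory <- activity %in% c("Walking", "StairsUp", "StairsDown")
  cad_scale <- if (activity == "Walking") 1 else 0.85   # slower on stairs
  cadence <- if (ambulatory) cad_scale * (co$cadence_c0 + co$cadence_c1 * gait_speed) else 0
  amp <- if (ambulatory) co$amp_per_speed * gait_speed *
    switch(activity, Walking = 1, StairsUp = 0.9, StairsDown = 1.05) else 0
  gait_var <- if (ambulatory) 0.06 / (0.25 + gait_speed) else 0
  gyro_amp <- if (ambulatory) 0.6 * gait_speed else 0
  climb <- co$climb_per_speed * gait_speed
  baro_trend <- switch(activity,
    StairsUp = -co$baro_per_meter * climb,
    StairsDown = co$baro_per_meter * climb,
    0)
  list(activity = activity, gravity = grav, sway_sd = sway_sd,
       cadence = cadence, amplitude = amp, gait_var_sd = gait_var,
       gyro_amp = gyro_amp, baro_trend = baro_trend, baro_noise_sd = 0.03)
}

#' Specify a synthetic cohort
#'
#' Defines the composition of a synthetic study cohort and its recording
#' protocol. Defaults are desk-scale: 8 healthy subjects and 8 stroke subjects
#' per impairment stratum, roughly 40 activity bouts per subject. The original
#' study's size (15 healthy; 8 mild, 13 moderate, 9 severe stroke) is obtained
#' by passing those counts.
#'
#' @param n_healthy Number of healthy subjects (home session only).
#' @param n_mild,n_moderate,n_severe Stroke subjects per gait-impairment
#'   stratum (sessions per \code{stroke_sessions}).
#' @param stroke_sessions Sessions recorded for each stroke subject, a subset
#'   of \code{c("Lab1", "Home", "Lab2")}.
#' @param bouts_lab,bouts_home Number of labeled activity bouts per lab / home
#'   session.
#' @param prevalence_lab,prevalence_home Named numeric vectors over the six
#'   activities, summing to 1: the share of bouts allotted to each activity in
#'   each environment (each activity is guaranteed at least
#'   \code{min_bouts_per_activity} bouts).
#' @param min_bouts_per_activity Minimum bouts of every activity per session.
#' @param duration_range Named list: activity -> c(min_s, max_s) bout duration.
#' @param artifact_rate Probability a bout carries 1-3 s of phone-handling
#'   noise at each end.
#' @param mislabel_rate Probability a bout's stored label is swapped for a
#'   different activity (signal unchanged).
#' @param drop_rate Probability a bout is lost entirely (transmission drop).
#' @param healthy_speed_mean,healthy_speed_sd Gait-speed distribution of the
#'   healthy cohort, truncated positive (m/s).
#' @param environment_variability Home-session variability multiplier given to
#'   every subject profile.
#' @param signal_coef Coefficient overrides forwarded to
#'   \code{\link{activity_params}}.
#' @param rng_seed Integer seed controlling every random choice downstream.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_healthy = 8, n_mild = 8, n_moderate = 8, n_severe = 8,
                        stroke_sessions = c("Lab1", "Home", "Lab2"),
                        bouts_lab = 12, bouts_home = 16,
                        prevalence_lab = NULL, prevalence_home = NULL,
                        min_bouts_per_activity = 1L,
                        duration_range = NULL,
                        artifact_rate = 0.3, mislabel_rate = 0.02,
                        drop_rate = 0.05,
                        healthy_speed_mean = 1.3, healthy_speed_sd = 0.1,
                        environment_variability = 1.6,
                        signal_coef = list(), rng_seed = 1L) {
  if (is.null(prevalence_lab)) {
    prevalence_lab <- stats::setNames(rep(1 / 6, 6), ACTIVITIES)
  }
  if (is.null(prevalence_home)) {
    prevalence_home <- c(Sitting = 0.25, Lying = 0.14, Standing = 0.15,
                         StairsUp = 0.055, StairsDown = 0.055, Walking = 0.35)
  }
  if (is.null(duration_range)) {
    duration_range <- list(
      Sitting = c(15, 30), Lying = c(15, 30), Standing = c(14, 25),
      StairsUp = c(11, 18), StairsDown = c(11, 18), Walking = c(12, 25))
  }
  stopifnot(
    all(ACTIVITIES %in% names(prevalence_lab)),
    all(ACTIVITIES %in% names(prevalence_home)),
    abs(sum(prevalence_lab) - 1) < 1e-6, abs(sum(prevalence_home) - 1) < 1e-6,
    all(stroke_sessions %in% SESSIONS),
    artifact_rate >= 0, artifact_rate <= 1,
    mislabel_rate >= 0, mislabel_rate <= 1,
    drop_rate >= 0, drop_rate <= 1,
    all(vapply(duration_range, min, 0) > 0)
  )
  structure(list(
    n_healthy = n_healthy, n_mild = n_mild, n_moderate = n_moderate,
    n_severe = n_severe, stroke_sessions = stroke_sessions,
    bouts_lab = bouts_lab, bouts_home = bouts_home,
    prevalence_lab = prevalence_lab[ACTIVITIES],
    prevalence_home = prevalence_home[ACTIVITIES],
    min_bouts_per_activity = as.integer(min_bouts_per_activity),
    duration_range = duration_range,
    artifact_rate = artifact_rate, mislabel_rate = mislabel_rate,
    drop_rate = drop_rate,
    healthy_speed_mean = healthy_speed_mean,
    healthy_speed_sd = healthy_speed_sd,
    environment_variability = environment_variability,
    signal_coef = signal_coef, rng_seed = as.integer(rng_seed)
  ), class = "cohort_spec")
}
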