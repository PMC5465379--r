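test_that("identical profile, spec and seed give byte-identical recordings", {
  sp <- tiny_spec(artifact_rate = 0.5, mislabel_rate = 0.1, drop_rate = 0.1)
  p <- with_seed_test(11, subject_profile("S01", "stroke", 0.9))
  r1 <- simulate_subject(p, sp, "Home")
  r2 <- simulate_subject(p, sp, "Home")
  expect_identical(r1$streams, r2$streams)
  expect_identical(r1$ground_truth, r2$ground_truth)
  # a different session draws a different stream
  r3 <- simulate_subject(p, sp, "Lab1")
  expect_false(identical(r1$streams$accelerometer$values[1:10, ],
                         r3$streams$accelerometer$values[1:10, ]))
})

test_that("stationary bouts are gravity-dominated; gait peaks at the cadence", {
  sp <- tiny_spec()
  p <- with_seed_test(2, subject_profile("S01", "stroke", 1.2))
  # lab session: no home-environment speed/orientation jitter on top of the
  # subject's nominal gait speed
  rec <- simulate_subject(p, sp, "Lab1")
  acc <- rec$streams$accelerometer
  gt <- rec$ground_truth

  sit <- gt[gt$true_activity == "Sitting", ][1, ]
  seg <- strokeAR:::slice_stream(acc, sit$start_s, sit$end_s)
  norm <- sqrt(rowSums(seg$values^2))
  expect_lt(abs(mean(norm) - 9.81), 3 * sd(norm))

  walk <- gt[gt$true_activity == "Walking", ][1, ]
  seg <- strokeAR:::slice_stream(acc, walk$start_s, walk$end_s)
  rs <- resample_stream(seg, 50)
  norm <- sqrt(rowSums(rs$values^2))
  n <- length(norm)
  pw <- Mod(fft(norm - mean(norm)))^2 / n
  freq <- (seq_len(n %/% 2) - 1) * 50 / n
  peak <- freq[which.max(pw[seq_len(n %/% 2)])]
  expected <- activity_params("Walking", 1.2)$cadence
  expect_lt(abs(peak - expected), 50 / n + 1e-9)  # within one frequency bin
})

test_that("gait amplitude and cadence increase strictly with gait speed", {
  sp <- tiny_spec()
  amp <- c(); cad <- c()
  for (v in c(0.2, 0.6, 1.0)) {
    p <- with_seed_test(3, subject_profile("S", "stroke", v))
    rec <- simulate_subject(p, sp, "Home")
    gt <- rec$ground_truth
    walks <- gt[gt$true_activity == "Walking", ]
    norms <- c(); peaks <- c()
    for (i in seq_len(nrow(walks))) {
      seg <- strokeAR:::slice_stream(rec$streams$accelerometer,
                                     walks$start_s[i], walks$end_s[i])
      rs <- resample_stream(seg, 50)
      x <- sqrt(rowSums(rs$values^2))
      norms <- c(norms, sd(x))
      n <- length(x)
      pw <- Mod(fft(x - mean(x)))^2 / n
      freq <- (seq_len(n %/% 2) - 1) * 50 / n
      sel <- freq > 0.2   # skip residual drift
      peaks <- c(peaks, freq[sel][which.max(pw[seq_len(n %/% 2)][sel])])
    }
    amp <- c(amp, mean(norms)); cad <- c(cad, mean(peaks))
  }
  expect_true(all(diff(amp) > 0))
  expect_true(all(diff(cad) > 0))
})

test_that("walking-vs-standing feature separation shrinks from mild to severe impairment", {
  sp <- tiny_spec(n_healthy = 0, n_mild = 1, n_moderate = 0, n_severe = 0,
                  bouts_home = 12)
  sep <- c()
  for (v in c(1.0, 0.6, 0.3)) {
    p <- with_seed_test(40, subject_profile("S01", "stroke", v))
    tab <- build_instance_table(simulate_subject(p, sp, "Home"))
    fn <- feature_names(tab)
    x <- scale(as.matrix(tab[, fn]))
    x[!is.finite(x)] <- 0
    mu_w <- colMeans(x[tab$activity == "Walking", , drop = FALSE])
    mu_s <- colMeans(x[tab$activity == "Standing", , drop = FALSE])
    sep <- c(sep, sqrt(sum((mu_w - mu_s)^2)))
  }
  expect_true(all(diff(sep) < 0))
})

test_that("barometer trends: ascent negative, descent positive, walking near zero", {
  sp <- tiny_spec()
  p <- with_seed_test(4, subject_profile("S01", "stroke", 0.9))
  rec <- simulate_subject(p, sp, "Home")
  gt <- rec$ground_truth
  baro <- rec$streams$barometer
  slope_of <- function(act) {
    b <- gt[gt$true_activity == act, ][1, ]
    seg <- strokeAR:::slice_stream(baro, b$start_s, b$end_s)
    mean(diff(seg$values[, 1]) / diff(seg$timestamps))
  }
  expect_lt(slope_of("StairsUp"), 0)
  expect_gt(slope_of("StairsDown"), 0)
  # walking slope bounded by noise scale
  expect_lt(abs(slope_of("Walking")), 0.02)
})

test_that("cohort manifest reproduces requested strata", {
  sp <- cohort_spec(n_healthy = 15, n_mild = 8, n_moderate = 13, n_severe = 9,
                    stroke_sessions = "Home", bouts_home = 2,
                    min_bouts_per_activity = 0L,
                    duration_range = lapply(stats::setNames(
                      nm = c("Sitting", "Lying", "Standing", "StairsUp",
                             "StairsDown", "Walking")), function(a) c(1, 2)),
                    rng_seed = 5)
  coh <- simulate_cohort(sp)
  m <- coh$manifest
  expect_equal(length(unique(m$subject_id)), 45)
  strata <- table(vapply(coh$profiles, function(p) p$impairment, ""))
  expect_equal(unname(strata[c("none", "mild", "moderate", "severe")]),
               c(15, 8, 13, 9), ignore_attr = TRUE)
  for (p in coh$profiles) {
    expect_equal(p$impairment, impairment_from_speed(p$gait_speed, p$cohort))
  }
})

test_that("degenerate rates: full drop empties recordings; mislabel fraction matches binomial CI", {
  sp <- tiny_spec(drop_rate = 1, n_healthy = 1, n_mild = 0, n_moderate = 0,
                  n_severe = 0)
  coh <- simulate_cohort(sp)
  expect_true(all(coh$manifest$n_bouts == 0))
  expect_equal(sum(coh$manifest$n_dropped), sum(coh$manifest$n_bouts_planned))

  # ~1000 bouts with 1-2 s durations keeps this cheap
  short <- lapply(stats::setNames(nm = c("Sitting", "Lying", "Standing",
                                         "StairsUp", "StairsDown", "Walking")),
                  function(a) c(1, 2))
  sp2 <- cohort_spec(n_healthy = 10, n_mild = 0, n_moderate = 0, n_severe = 0,
                     bouts_home = 100, mislabel_rate = 0.1, artifact_rate = 0,
                     drop_rate = 0, duration_range = short,
                     min_bouts_per_activity = 0L, rng_seed = 17)
  coh2 <- simulate_cohort(sp2)
  n <- nrow(coh2$bouts)
  phat <- mean(coh2$bouts$mislabeled)
  ci <- qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(phat - 0.1), ci + 1e-12)
  # mislabeled bouts keep their true signal identity in the ground truth
  mis <- coh2$bouts[coh2$bouts$mislabeled, ]
  expect_true(all(mis$activity != mis$true_activity))
})

test_that("impairment classification follows the 10MWT cut points", {
  expect_equal(impairment_from_speed(c(0.9, 0.8, 0.4, 0.39)),
               c("mild", "moderate", "moderate", "severe"))
  expect_equal(impairment_from_speed(1.3, "healthy"), "none")
  expect_error(impairment_from_speed(0), "gait_speed")
  expect_error(subject_profile("a", "stroke", -1))
})

test_that("recordings round-trip through the CSV layout", {
  sp <- tiny_spec(artifact_rate = 0.3)
  p <- with_seed_test(6, subject_profile("S07", "stroke", 0.7))
  rec <- simulate_subject(p, sp, "Lab1")
  dir <- tempfile("recs")
  write_recording(rec, dir)
  back <- read_recording(dir, "S07", "Lab1")
  expect_equal(length(back$streams), 3)
  expect_equal(nrow(back$bouts), nrow(rec$bouts))
  expect_equal(back$streams$accelerometer$values,
               rec$streams$accelerometer$values, tolerance = 1e-7,
               ignore_attr = TRUE)
  # optional barometer: removing the file is tolerated unless required
  file.remove(file.path(dir, "S07_Lab1_barometer.csv"))
  back2 <- read_recording(dir, "S07", "Lab1")
  expect_equal(length(back2$streams), 2)
  expect_error(read_recording(dir, "S07", "Lab1", require_barometer = TRUE),
               "missing required sensor file")
  # missing inertial file is always fatal
  file.remove(file.path(dir, "S07_Lab1_gyroscope.csv"))
  expect_error(read_recording(dir, "S07", "Lab1"), "missing required")
})
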