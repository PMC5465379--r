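test_that("sample entropy matches brute-force template counting", {
  expect_equal(sample_entropy(rep(2.5, 30), 2, r = 0.1), 0)  # A = B
  x <- rep(c(1, 2), 8)
  expect_equal(sample_entropy(x, 2, 0.5 * sd(x)),
               oracle_sampen(x, 2, 0.5 * sd(x)))
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(40)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5) * sd(x)
    expect_equal(sample_entropy(x, m, r), oracle_sampen(x, m, r),
                 tolerance = 1e-12)
  }
  # A = 0 gives the +Inf sentinel
  x <- c(1, 1, 1, 2, 4, 8, 16)
  expect_identical(sample_entropy(x, 2, 0.01), Inf)
  expect_error(sample_entropy(rnorm(3), 2, 0.1), "too short")
})

test_that("edge artifacts are trimmed, clean signal preserved, caps honored", {
  set.seed(5)
  sp <- tiny_spec(artifact_rate = 1, n_healthy = 1, n_mild = 1,
                  n_moderate = 0, n_severe = 0, bouts_home = 12)
  coh <- simulate_cohort(sp)
  removal <- c(); loss <- c()
  for (rec in coh$recordings) {
    acc <- rec$streams$accelerometer
    gt <- rec$ground_truth
    for (i in seq_len(nrow(rec$bouts))) {
      b <- rec$bouts[i, ]
      g <- gt[gt$bout_id == b$bout_id, ]
      tr <- trim_bout(strokeAR:::slice_stream(acc, b$start_s, b$end_s),
                      b$activity)
      inj <- g$artifact_lead_s + g$artifact_trail_s
      if (inj > 0) {
        removal <- c(removal, (min(tr$trim_lead_s, g$artifact_lead_s) +
                                 min(tr$trim_trail_s, g$artifact_trail_s)) / inj)
      }
      loss <- c(loss, max(tr$trim_lead_s - g$artifact_lead_s, 0) +
                  max(tr$trim_trail_s - g$artifact_trail_s, 0))
    }
  }
  expect_gte(mean(removal), 0.9)
  expect_lte(mean(loss), 0.5)
})

test_that("clean bouts are untouched and trimming is idempotent", {
  set.seed(6)
  sp <- tiny_spec(artifact_rate = 0)
  p <- subject_profile("S01", "stroke", 0.8)
  rec <- simulate_subject(p, sp, "Home")
  acc <- rec$streams$accelerometer
  for (i in seq_len(min(6, nrow(rec$bouts)))) {
    b <- rec$bouts[i, ]
    tr <- trim_bout(strokeAR:::slice_stream(acc, b$start_s, b$end_s),
                    b$activity)
    expect_equal(tr$trim_lead_s + tr$trim_trail_s, 0)
  }
  # artifact bout: a second pass over the trimmed segment trims nothing
  sp2 <- tiny_spec(artifact_rate = 1)
  rec2 <- simulate_subject(p, sp2, "Home")
  acc2 <- rec2$streams$accelerometer
  b <- rec2$bouts[1, ]
  tr1 <- trim_bout(strokeAR:::slice_stream(acc2, b$start_s, b$end_s), b$activity)
  expect_gt(tr1$trim_lead_s + tr1$trim_trail_s, 0)
  seg2 <- strokeAR:::slice_stream(acc2, b$start_s + tr1$trim_lead_s,
                                  b$end_s - tr1$trim_trail_s)
  tr2 <- trim_bout(seg2, b$activity)
  expect_equal(tr2$trim_lead_s + tr2$trim_trail_s, 0)
})

test_that("an all-artifact bout is trimmed at the cap on both ends", {
  set.seed(7)
  t <- seq(0, 20, by = 1 / 60)
  st <- sensor_stream("accelerometer", t,
                      matrix(rnorm(3 * length(t), 0, 3), ncol = 3) + 9.81 / sqrt(3),
                      60)
  tr <- trim_bout(st, "Sitting", trim_config(max_trim_s = 5))
  expect_equal(tr$trim_lead_s, 5)
  expect_equal(tr$trim_trail_s, 5)
  # bouts shorter than two subwindows come back untrimmed, with a warning
  short <- sensor_stream("accelerometer", seq(0, 1.5, by = 1 / 60),
                         matrix(rnorm(273), ncol = 3), 60)
  expect_warning(tr2 <- trim_bout(short, "Sitting"), "untrimmed")
  expect_equal(tr2$trim_lead_s, 0)
})

test_that("flat ambulatory bouts are dropped; stationary and genuine gait kept", {
  set.seed(8)
  sp <- tiny_spec(mislabel_rate = 0)
  p <- subject_profile("S01", "stroke", 1.2)
  rec <- simulate_subject(p, sp, "Lab1")
  # forge a mislabel: relabel one Sitting bout as Walking (signal unchanged)
  i <- which(rec$bouts$activity == "Sitting")[1]
  rec$bouts$activity[i] <- "Walking"
  forged <- rec$bouts$bout_id[i]
  out <- drop_mislabeled(rec)
  expect_true(forged %in% out$report$bout_id)
  expect_false(forged %in% out$recording$bouts$bout_id)
  # genuine walking retained; flat Sitting retained (rule scope is ambulatory)
  expect_true(any(out$recording$bouts$activity == "Walking"))
  expect_true(any(out$recording$bouts$activity == "Sitting"))
})

test_that("clip count follows floor((T - 10)/step) + 1 and clips are exact-length", {
  expect_equal(nrow(segment_clips(make_segment(60))), 51)
  expect_equal(nrow(segment_clips(make_segment(10))), 1)
  expect_equal(nrow(segment_clips(make_segment(9.5))), 0)
  set.seed(9)
  for (T in runif(25, 4, 90)) {
    seg <- make_segment(T)
    cl <- segment_clips(seg)
    T_use <- seg$duration_s
    expected <- if (T_use < 10) 0 else floor((T_use - 10) + 1e-9) + 1
    expect_equal(nrow(cl), expected, label = sprintf("T = %.3f", T))
    if (nrow(cl) > 0) {
      k <- nrow(cl)
      expect_lte(cl$i_inertial[k] + 499, nrow(seg$acc))
      expect_lte(cl$i_baro[k] + 59, length(seg$baro))
    }
  }
})

test_that("emitted clips lie inside their trimmed bout and have exact sample counts", {
  set.seed(10)
  sp <- tiny_spec(artifact_rate = 0.5, n_healthy = 1, n_mild = 1,
                  n_moderate = 0, n_severe = 0)
  p <- subject_profile("S01", "stroke", 1.0)
  rec <- simulate_subject(p, sp, "Home")
  pp <- preprocess_recording(rec)
  for (seg in pp$segments) {
    cl <- segment_clips(seg)
    if (!nrow(cl)) next
    b <- rec$bouts[rec$bouts$bout_id == seg$bout_id, ]
    tr <- pp$trim_report[pp$trim_report$bout_id == seg$bout_id, ]
    expect_gte(seg$start_s, b$start_s + tr$trim_lead_s - 1e-9)
    expect_lte(seg$start_s + seg$duration_s, b$end_s - tr$trim_trail_s + 0.5)
    expect_true(all(cl$abs_start_s + 10 <= seg$start_s + seg$duration_s + 1e-9))
    fm <- featurize_segment(seg, cl)
    expect_equal(ncol(fm), 270)
    expect_false(anyNA(fm))
  }
})
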