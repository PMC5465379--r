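test_that("confusion matrices and recall follow their definitions", {
  truth <- c("a", "a", "b", "b", "c", "c")
  expect_equal(recall_from_confusion(
    confusion_matrix(truth, truth))$mean_recall, 1)

  # per-class recalls {1, 0.5, 0} average to 0.5
  pred <- c("a", "a", "b", "c", "a", "b")
  r <- recall_from_confusion(confusion_matrix(truth, pred))
  expect_equal(unname(r$recall), c(1, 0.5, 0))
  expect_equal(r$mean_recall, 0.5)

  # hand-computed 3-class counts
  cm <- confusion_matrix(rep(c("x", "y", "z"), c(4, 3, 3)),
                         c("x", "x", "y", "z", "y", "y", "x", "z", "z", "y"))
  expect_equal(unname(diag(cm)), c(2, 2, 2))
  expect_equal(unname(rowSums(cm)), c(4, 3, 3))
  expect_equal(unname(recall_from_confusion(cm)$recall), c(0.5, 2 / 3, 2 / 3))

  # classes absent from the test set are omitted from the mean, not scored 0
  cm2 <- confusion_matrix(c("a", "a"), c("a", "b"), classes = c("a", "b", "c"))
  r2 <- recall_from_confusion(cm2)
  expect_equal(r2$classes_present, "a")
  expect_equal(r2$mean_recall, 0.5)
  expect_error(confusion_matrix("a", "d", classes = c("a", "b")), "unknown label")
})

test_that("stationary/ambulatory misclassification rates reduce to count ratios", {
  cls <- c("Sitting", "Lying", "Standing", "StairsUp", "StairsDown", "Walking")
  # all predictions correct: both rates zero
  truth <- rep(cls, 5)
  g0 <- group_misclassification(confusion_matrix(truth, truth, cls))
  expect_equal(g0$amb_to_stat, 0)
  expect_equal(g0$stat_to_amb, 0)
  # every ambulatory instance predicted Sitting: rate 100%
  pred <- ifelse(truth %in% c("StairsUp", "StairsDown", "Walking"),
                 "Sitting", truth)
  g1 <- group_misclassification(confusion_matrix(truth, pred, cls))
  expect_equal(g1$amb_to_stat, 1)
  expect_equal(g1$stat_to_amb, 0)
  expect_error(group_misclassification(confusion_matrix(truth, truth, cls),
                                       stationary = "Sitting",
                                       ambulatory = "Walking"),
               "grouping misses")
})

test_that("the four-class merge combines sedentary postures and stair directions", {
  expect_equal(merge_activity_classes(
    c("Sitting", "Lying", "Standing", "StairsUp", "StairsDown", "Walking")),
    c("Sedentary", "Sedentary", "Standing", "Stairs", "Stairs", "Walking"))
})

test_that("LOSO keeps each test subject out of its own training fold", {
  tab <- make_toy_table(n_subjects = 5, clips_per_class = 8, subject_sd = 0.2,
                        seed = 31)
  rep_ <- eval_population(tab, "stroke", "stroke", algorithm = "rusboost",
                          n_trees = 4, min_leaf = 2, seed = 1)
  expect_equal(nrow(rep_$per_subject), 5)
  expect_setequal(rep_$per_subject$subject_id, unique(tab$subject_id))
  # confusion totals account for every test instance exactly once
  expect_equal(sum(rep_$pooled), nrow(tab))
  # recalls recomputed from the pooled matrix match the matrix itself
  r <- recall_from_confusion(rep_$pooled)
  expect_equal(unname(r$recall), unname(diag(rep_$pooled) / rowSums(rep_$pooled)))
})

test_that("cross-cohort designs train once on the full source cohort", {
  th <- make_toy_table(n_subjects = 3, cohort = "healthy", seed = 32)
  ts <- make_toy_table(n_subjects = 4, cohort = "stroke", seed = 33)
  tab <- instance_table(
    rbind(ts[, setdiff(names(ts), feature_names(ts))],
          th[, setdiff(names(th), feature_names(th))]),
    rbind(as.matrix(ts[, feature_names(ts)]), as.matrix(th[, feature_names(th)])))
  rep_ <- eval_population(tab, "healthy", "stroke", n_trees = 4, min_leaf = 2,
                          seed = 2)
  expect_equal(nrow(rep_$per_subject), 4)
  expect_true(all(rep_$per_subject$cohort == "stroke"))
})

test_that("chronological folds are pairwise time-disjoint after boundary drops", {
  set.seed(34)
  starts <- sort(runif(80, 0, 400))
  tab <- data.frame(clip_start_s = starts, clip_end_s = starts + 10)
  fold <- chronological_folds(tab, k = 4)
  expect_equal(sort(unique(stats::na.omit(fold))), 1:4)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- tab[!is.na(fold) & fold == i, ]
    b <- tab[!is.na(fold) & fold == j, ]
    overlap <- outer(a$clip_start_s, b$clip_end_s, "<") &
      outer(a$clip_end_s, b$clip_start_s, ">")
    expect_false(any(overlap), label = sprintf("folds %d/%d overlap", i, j))
  }
})

test_that("environmental eligibility enforces 60 s of every activity per session", {
  base <- make_toy_table(n_subjects = 2, clips_per_class = 60,
                         activities = c("Sitting", "StairsUp"),
                         sessions = c("Lab1", "Home", "Lab2"), seed = 35)
  expect_setequal(eligible_subjects(base, activities = c("Sitting", "StairsUp")),
                  unique(base$subject_id))
  # cut subject s01's StairsUp Home coverage below 60 s
  cut <- base[!(base$subject_id == "s01" & base$session == "Home" &
                  base$activity == "StairsUp" &
                  base$clip_start_s > min(base$clip_start_s[
                    base$subject_id == "s01" & base$session == "Home" &
                      base$activity == "StairsUp"]) + 40), ]
  cut <- strokeAR:::as_instance_subset(cut, base)
  expect_false("s01" %in% eligible_subjects(
    cut, activities = c("Sitting", "StairsUp")))
  expect_true("s02" %in% eligible_subjects(
    cut, activities = c("Sitting", "StairsUp")))
})

test_that("statistical battery: degenerate paired t, perfect correlation, Tukey layout", {
  tab <- make_toy_table(n_subjects = 6, seed = 36)
  rep_ <- eval_population(tab, "stroke", "stroke", n_trees = 3, min_leaf = 2,
                          seed = 3)
  same <- compare_reports(rep_, rep_)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  rep2 <- rep_
  rep2$per_subject$mean_recall <- rep_$per_subject$mean_recall - 0.1
  t2 <- compare_reports(rep_, rep2)
  expect_equal(unname(t2$estimate), 0.1, tolerance = 1e-12)

  # metric exactly linear in gait speed: Pearson r = 1
  rep3 <- rep_
  rep3$per_subject$amb_recall <- 0.2 + 0.5 * rep3$per_subject$gait_speed
  ct <- correlate_with_speed(rep3, "amb_recall")
  expect_equal(unname(ct$estimate), 1, tolerance = 1e-9)

  # ANOVA + Tukey over impairment strata returns the three pairwise rows
  ps <- data.frame(subject_id = sprintf("s%02d", 1:18),
                   impairment = rep(c("mild", "moderate", "severe"), each = 6),
                   mean_recall = c(rnorm(6, 0.8, 0.03), rnorm(6, 0.6, 0.03),
                                   rnorm(6, 0.4, 0.03)))
  fake <- list(per_subject = ps)
  an <- anova_by_impairment(fake)
  expect_lt(an$p.value, 0.01)
  expect_equal(rownames(an$tukey),
               c("moderate-mild", "severe-mild", "severe-moderate"))
})

test_that("ANOVA on identically distributed strata rejects at about the alpha rate", {
  set.seed(37)
  pvals <- replicate(1000, {
    ps <- data.frame(subject_id = sprintf("s%02d", 1:18),
                     impairment = rep(c("mild", "moderate", "severe"), each = 6),
                     mean_recall = rnorm(18, 0.6, 0.1))
    anova_by_impairment(list(per_subject = ps))$p.value
  })
  rate <- mean(pvals < 0.05)
  # binomial 99.9% band around 0.05 with n = 1000
  expect_lt(abs(rate - 0.05), 3.3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("learning curve holds the training-instance count fixed", {
  tab <- make_toy_table(n_subjects = 8, clips_per_class = 10, subject_sd = 0.4,
                        seed = 38)
  lc <- learning_curve(tab, "stroke", "stroke", sizes = c(2, 6),
                       n_instances = 50, reps = 6, n_trees = 4, min_leaf = 2,
                       seed = 5)
  expect_equal(lc$n_train, c(50, 50))
  expect_equal(lc$reps, c(6, 6))
  # more training subjects should not hurt on a subject-heterogeneous table
  expect_gte(lc$mean_recall[2], lc$mean_recall[1] - 0.05)
  # degenerate CI with a single repetition
  lc1 <- learning_curve(tab, "stroke", "stroke", sizes = 2, n_instances = 40,
                        reps = 1, n_trees = 3, min_leaf = 2, seed = 6)
  expect_equal(lc1$ci_lo, lc1$mean_recall)
  expect_equal(lc1$ci_hi, lc1$mean_recall)
  expect_error(learning_curve(tab, "stroke", "stroke", sizes = 50,
                              n_instances = 10, reps = 1), "exceeds")
})

test_that("barometer ablation changes exactly the 8 barometer features", {
  set.seed(39)
  # stairs vs walking separable only through the barometer slope
  baro_names <- barometer_feature_names()
  acts <- c("StairsUp", "Walking")
  meta <- NULL; feats <- NULL
  for (s in 1:4) {
    for (a in acts) {
      k <- 15
      f <- matrix(rnorm(k * 9), k, 9)
      colnames(f) <- c("acc_x_mean", baro_names)
      f[, "baro_slope"] <- ifelse(a == "StairsUp", -0.03, 0) + rnorm(k, 0, 0.005)
      start <- runif(1, 0, 100) + seq_len(k)
      meta <- rbind(meta, data.frame(
        subject_id = sprintf("s%02d", s), session = "Home",
        environment = "home", cohort = "stroke", impairment = "mild",
        gait_speed = 1, bout_id = paste0(s, a), activity = a,
        clip_start_s = start, clip_end_s = start + 10))
      feats <- rbind(feats, f)
    }
  }
  tab <- instance_table(meta, feats)
  ab <- ablate_barometer(tab, "stroke", "stroke", n_trees = 6, min_leaf = 2,
                         seed = 7)
  expect_equal(unname(ab$n_features["with_baro"] -
                        ab$n_features["without_baro"]), 8)
  expect_lt(mean(ab$paired$stairs_to_walking_with, na.rm = TRUE),
            mean(ab$paired$stairs_to_walking_without, na.rm = TRUE))
})
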