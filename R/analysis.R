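# Learning curves, barometer ablation and the statistical test battery.

#' Learning curve over the number of training subjects
#'
#' For each training-set size, repeatedly samples that many subjects from the
#' source cohort, pools their clips, draws exactly \code{n_instances}
#' instances uniformly at random, trains a classifier and records the mean
#' recall over the held-out test cohort's subjects (per-subject mean recall,
#' averaged). The instance count is held constant across sizes so the curve
#' isolates inter-subject variability rather than data volume.
#'
#' @param table An \code{\link{instance_table}}.
#' @param train_cohort,test_cohort Source and target cohorts. When they are
#'   equal, test subjects are those not sampled for training.
#' @param sizes Integer vector of training-subject counts.
#' @param n_instances Training instances drawn per repetition (default 1200).
#' @param reps Repetitions per size (default 100).
#' @param feature_set,algorithm,n_trees,min_leaf,learn_rate Classifier
#'   settings.
#' @param seed Integer seed.
#' @return data.frame: one row per size with mean recall mean and percentile
#'   95\% CI over repetitions.
#' @export
learning_curve <- function(table, train_cohort, test_cohort,
                           sizes = 2:14, n_instances = 1200, reps = 100,
                           feature_set = "all", algorithm = "rusboost",
                           n_trees = 50, min_leaf = 5, learn_rate = 1,
                           seed = 1L) {
  stopifnot(inherits(table, "instance_table"))
  tr_pool <- sort(unique(table$subject_id[table$cohort == train_cohort]))
  te_all <- table[table$cohort == test_cohort, ]
  if (max(sizes) > length(tr_pool)) {
    stop("requested size exceeds available training subjects (",
         length(tr_pool), ")")
  }
  out <- list()
  for (sz in sizes) {
    vals <- with_seed(derive_seed(seed, paste0("lc", sz)), {
      vapply(seq_len(reps), function(rep) {
        subs <- sample(tr_pool, sz)
        tr <- table[table$subject_id %in% subs & table$cohort == train_cohort, ]
        if (nrow(tr) < n_instances) {
          stop("fewer than n_instances (", n_instances, ") clips available ",
               "for a sample of ", sz, " subjects")
        }
        tr <- tr[sample(nrow(tr), n_instances), ]
        te <- if (train_cohort == test_cohort) {
          te_all[!(te_all$subject_id %in% subs), ]
        } else te_all
        model <- fit_on_table(as_instance_subset(tr, table), feature_set,
                              algorithm, n_trees, min_leaf, learn_rate)
        pred <- predict_on_table(model, as_instance_subset(te, table),
                                 feature_set)
        per_subj <- vapply(split(seq_len(nrow(te)), te$subject_id), function(i) {
          cm <- confusion_matrix(te$activity[i], pred[i],
                                 sort(unique(c(te$activity, pred))))
          recall_from_confusion(cm)$mean_recall
        }, 0)
        mean(per_subj)
      }, 0)
    })
    qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      n_subjects = sz, mean_recall = mean(vals), ci_lo = qs[1], ci_hi = qs[2],
      reps = reps, n_train = n_instances)
  }
  do.call(rbind, out)
}

#' Barometer ablation
#'
#' Runs the same population design twice — once with the full feature set,
#' once with the 8 barometer features removed — and reports the paired
#' per-subject change in stairs-to-walking confusion and mean recall.
#'
#' @param table An \code{\link{instance_table}} whose features include the
#'   barometer columns.
#' @param train_cohort,test_cohort Cohorts, as in
#'   \code{\link{eval_population}}.
#' @param feature_set Base feature set (\code{"all"} or names); the ablated
#'   run removes the barometer names from it.
#' @param ... Classifier settings passed to \code{\link{eval_population}}.
#' @return List of class \code{ar_ablation}: \code{with_baro},
#'   \code{without_baro} (both \code{ar_report}s), and \code{paired}
#'   (per-subject data.frame with stairs-to-walking misclassification rates
#'   and mean recall under both feature sets).
#' @export
ablate_barometer <- function(table, train_cohort, test_cohort,
                             feature_set = "all", ...) {
  fn_all <- resolve_feature_set(feature_set, feature_names(table))
  baro <- barometer_feature_names()
  if (!any(baro %in% fn_all)) stop("table has no barometer features to ablate")
  fn_wo <- setdiff(fn_all, baro)
  with_b <- eval_population(table, train_cohort, test_cohort,
                            feature_set = fn_all, ...)
  without_b <- eval_population(table, train_cohort, test_cohort,
                               feature_set = fn_wo, ...)
  stairs_to_walk <- function(cm) {
    st <- intersect(rownames(cm), c("StairsUp", "StairsDown"))
    n <- sum(cm[st, , drop = FALSE])
    if (n == 0) return(NA_real_)
    sum(cm[st, "Walking"]) / n
  }
  subs <- intersect(names(with_b$confusions), names(without_b$confusions))
  paired <- data.frame(
    subject_id = subs,
    stairs_to_walking_with = vapply(with_b$confusions[subs], stairs_to_walk, 0),
    stairs_to_walking_without = vapply(without_b$confusions[subs], stairs_to_walk, 0),
    mean_recall_with = with_b$per_subject$mean_recall[
      match(subs, with_b$per_subject$subject_id)],
    mean_recall_without = without_b$per_subject$mean_recall[
      match(subs, without_b$per_subject$subject_id)],
    stringsAsFactors = FALSE)
  structure(list(with_baro = with_b, without_baro = without_b,
                 paired = paired,
                 n_features = c(with_baro = length(fn_all),
                                without_baro = length(fn_wo))),
            class = "ar_ablation")
}

#' @export
print.ar_ablation <- function(x, ...) {
  cat(sprintf("<ar_ablation> %d vs %d features\n",
              x$n_features[1], x$n_features[2]))
  cat(sprintf("  stairs->walking: %.1f%% with barometer, %.1f%% without\n",
              100 * mean(x$paired$stairs_to_walking_with, na.rm = TRUE),
              100 * mean(x$paired$stairs_to_walking_without, na.rm = TRUE)))
  invisible(x)
}

#' Statistical comparison of evaluation reports
#'
#' The study's test battery at alpha = 0.05: paired t test between two designs
#' evaluated on the same subjects, two-sample (Welch) t test between designs
#' on different cohorts, one-way ANOVA with Tukey HSD over impairment strata,
#' and Pearson correlation between per-subject gait speed and a per-subject
#' metric.
#'
#' @param a,b \code{ar_report}s (per-subject metric taken from
#'   \code{per_subject}).
#' @param metric Column of \code{per_subject} to compare
#'   (default \code{"mean_recall"}).
#' @param paired Paired on shared subjects (TRUE) or two-sample (FALSE).
#' @return For \code{compare_reports}: \code{htest}-like list with
#'   \code{statistic}, \code{p.value}, \code{estimate}, \code{method}.
#' @export
compare_reports <- function(a, b, metric = "mean_recall", paired = TRUE) {
  pa <- a$per_subject; pb <- b$per_subject
  if (paired) {
    shared <- intersect(pa$subject_id, pb$subject_id)
    if (length(shared) < 2 ||
        length(shared) < max(nrow(pa), nrow(pb))) {
      if (length(shared) < 2) stop("paired comparison needs shared subjects")
    }
    va <- pa[[metric]][match(shared, pa$subject_id)]
    vb <- pb[[metric]][match(shared, pb$subject_id)]
    d <- va - vb
    if (stats::sd(d) == 0) {
      # degenerate paired case (identical vectors): t = 0, p = 1 by convention
      return(structure(list(statistic = c(t = 0), p.value = 1,
                            estimate = c(`mean difference` = mean(d)),
                            method = "Paired t-test (degenerate)",
                            data.name = metric),
                       class = "htest"))
    }
    stats::t.test(va, vb, paired = TRUE)
  } else {
    stats::t.test(pa[[metric]], pb[[metric]])
  }
}

#' @rdname compare_reports
#' @param report An \code{ar_report} over stroke subjects.
#' @return For \code{anova_by_impairment}: list with the ANOVA F statistic and
#'   p value plus the Tukey HSD table over strata.
#' @export
anova_by_impairment <- function(report, metric = "mean_recall") {
  ps <- report$per_subject
  ps <- ps[ps$impairment %in% c("mild", "moderate", "severe") &
             is.finite(ps[[metric]]), ]
  ps$impairment <- factor(ps$impairment, c("mild", "moderate", "severe"))
  fit <- stats::aov(ps[[metric]] ~ ps$impairment)
  an <- summary(fit)[[1]]
  list(F = an$`F value`[1], p.value = an$`Pr(>F)`[1],
       df = an$Df, tukey = stats::TukeyHSD(fit)[[1]])
}

#' @rdname compare_reports
#' @return For \code{correlate_with_speed}: the \code{cor.test} result
#'   (Pearson) between per-subject gait speed and the metric.
#' @export
correlate_with_speed <- function(report, metric = "amb_recall") {
  ps <- report$per_subject
  ok <- is.finite(ps[[metric]]) & is.finite(ps$gait_speed)
  stats::cor.test(ps$gait_speed[ok], ps[[metric]][ok], method = "pearson")
}
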