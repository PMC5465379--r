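# Evaluation designs and metrics: confusion/recall, stationary-ambulatory
# misclassification, LOSO population models, impairment stratification,
# environmental personal/global models with chronological folds.

#' Confusion matrix for multiclass predictions
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Optional class order; defaults to the sorted union. Labels
#'   outside \code{classes} are an error.
#' @return Square integer matrix (true x predicted) of class
#'   \code{ar_confusion}.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  out <- matrix(as.integer(cm), nrow(cm), ncol(cm),
                dimnames = list(true = classes, predicted = classes))
  class(out) <- c("ar_confusion", class(out))
  out
}

#' Per-class recall and unweighted mean recall
#'
#' Recall for class c is the fraction of true-c instances predicted c; the
#' mean is the unweighted average over classes that appear in the test set
#' (classes with zero true instances are omitted, not scored 0).
#'
#' @param cm An \code{\link{ar_confusion}} matrix.
#' @return List: \code{recall} (named vector, NA for absent classes),
#'   \code{mean_recall}, \code{classes_present}.
#' @export
recall_from_confusion <- function(cm) {
  n <- rowSums(cm)
  rec <- ifelse(n > 0, diag(cm) / n, NA_real_)
  names(rec) <- rownames(cm)
  list(recall = rec, mean_recall = mean(rec[n > 0]),
       classes_present = rownames(cm)[n > 0])
}

#' Stationary/ambulatory cross-misclassification rates
#'
#' @param cm An \code{\link{ar_confusion}} matrix.
#' @param stationary,ambulatory Class-name groups covering all of \code{cm}'s
#'   classes between them.
#' @return List: \code{amb_to_stat} and \code{stat_to_amb} (fractions in
#'   [0, 1]; NA when the true group is empty), plus the raw counts.
#' @export
group_misclassification <- function(cm, stationary = STATIONARY,
                                    ambulatory = AMBULATORY) {
  cls <- rownames(cm)
  miss <- setdiff(cls, c(stationary, ambulatory))
  if (length(miss)) stop("grouping misses class(es): ", paste(miss, collapse = ", "))
  st <- intersect(cls, stationary); am <- intersect(cls, ambulatory)
  amb_n <- sum(cm[am, , drop = FALSE])
  sta_n <- sum(cm[st, , drop = FALSE])
  amb_mis <- sum(cm[am, st, drop = FALSE])
  sta_mis <- sum(cm[st, am, drop = FALSE])
  list(amb_to_stat = if (amb_n > 0) amb_mis / amb_n else NA_real_,
       stat_to_amb = if (sta_n > 0) sta_mis / sta_n else NA_real_,
       amb_mis = amb_mis, amb_n = amb_n, sta_mis = sta_mis, sta_n = sta_n)
}

#' Merge the six activities into the four-class grouping
#'
#' Sitting and Lying become \code{"Sedentary"}; Stairs Up and Stairs Down
#' become \code{"Stairs"}; Standing and Walking are unchanged.
#'
#' @param labels Character/factor vector of six-class labels.
#' @return Character vector of merged labels.
#' @export
merge_activity_classes <- function(labels) {
  lab <- as.character(labels)
  lab[lab %in% c("Sitting", "Lying")] <- "Sedentary"
  lab[lab %in% c("StairsUp", "StairsDown")] <- "Stairs"
  lab
}

# Stationary/ambulatory grouping in merged (4-class) label space.
MERGED_STATIONARY <- c("Sedentary", "Standing")
MERGED_AMBULATORY <- c("Stairs", "Walking")

# ---- model plumbing on instance tables --------------------------------------

table_xy <- function(table, feature_set = "all") {
  fn <- resolve_feature_set(feature_set, feature_names(table))
  x <- as.matrix(table[, fn, drop = FALSE])
  x[!is.finite(x)] <- 0
  list(x = x, y = table$activity)
}

fit_on_table <- function(table, feature_set = "all",
                         algorithm = "rusboost", n_trees = 200,
                         min_leaf = 5, learn_rate = 1, seed = NULL,
                         merge_classes = FALSE) {
  d <- table_xy(table, feature_set)
  y <- if (merge_classes) merge_activity_classes(d$y) else d$y
  train_classifier(d$x, y, algorithm, n_trees = n_trees, min_leaf = min_leaf,
                   learn_rate = learn_rate, seed = seed)
}

predict_on_table <- function(model, table, feature_set = "all") {
  d <- table_xy(table, feature_set)
  as.character(stats::predict(model, d$x))
}

# Assemble one test unit's metrics.
unit_metrics <- function(truth, pred, classes, stationary, ambulatory) {
  cm <- confusion_matrix(truth, pred, classes)
  r <- recall_from_confusion(cm)
  g <- group_misclassification(cm, stationary, ambulatory)
  amb_present <- intersect(r$classes_present, ambulatory)
  sta_present <- intersect(r$classes_present, stationary)
  list(cm = cm, mean_recall = r$mean_recall, recall = r$recall,
       amb_recall = if (length(amb_present)) mean(r$recall[amb_present]) else NA_real_,
       stat_recall = if (length(sta_present)) mean(r$recall[sta_present]) else NA_real_,
       amb_to_stat = g$amb_to_stat, stat_to_amb = g$stat_to_amb,
       n_test = length(truth))
}

new_report <- function(design, rows, cms, classes, grouping) {
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  pooled <- Reduce("+", cms)
  class(pooled) <- c("ar_confusion", class(pooled))
  structure(list(design = design, classes = classes, grouping = grouping,
                 per_subject = per_subject, confusions = cms,
                 pooled = pooled),
            class = "ar_report")
}

#' @export
print.ar_report <- function(x, ...) {
  r <- recall_from_confusion(x$pooled)
  g <- group_misclassification(x$pooled, x$grouping$stationary,
                               x$grouping$ambulatory)
  cat(sprintf("<ar_report> %s: %d test units, %d instances\n", x$design,
              nrow(x$per_subject), sum(x$pooled)))
  cat(sprintf("  mean recall (per-subject mean): %.3f; pooled amb->stat %.1f%%, stat->amb %.1f%%\n",
              mean(x$per_subject$mean_recall, na.rm = TRUE),
              100 * g$amb_to_stat, 100 * g$stat_to_amb))
  invisible(x)
}

subject_meta <- function(table) {
  m <- unique(table[, c("subject_id", "cohort", "impairment", "gait_speed")])
  rownames(m) <- NULL
  m
}

# ---- designs ----------------------------------------------------------------

#' Population-model evaluation (within-cohort LOSO or cross-cohort)
#'
#' With \code{train_cohort == test_cohort}, runs leave-one-subject-out
#' cross-validation within the cohort: each subject is tested on a model
#' trained on all other subjects of that cohort. With different cohorts
#' (e.g. healthy-to-stroke), one model is trained on the full source cohort
#' and every target-cohort subject is a test unit.
#'
#' @param table An \code{\link{instance_table}}.
#' @param train_cohort,test_cohort \code{"healthy"} or \code{"stroke"}.
#' @param feature_set Feature subset (\code{"all"} or names).
#' @param algorithm,n_trees,min_leaf,learn_rate Classifier settings (see
#'   \code{\link{rusboost}}).
#' @param seed Integer seed.
#' @return An \code{ar_report}: per-subject metrics (mean recall, ambulatory /
#'   stationary recall, cross-group misclassification rates), per-subject and
#'   pooled confusion matrices.
#' @export
eval_population <- function(table, train_cohort, test_cohort,
                            feature_set = "all", algorithm = "rusboost",
                            n_trees = 200, min_leaf = 5, learn_rate = 1,
                            seed = 1L) {
  stopifnot(inherits(table, "instance_table"))
  tr <- table[table$cohort == train_cohort, ]
  te <- table[table$cohort == test_cohort, ]
  if (!nrow(tr) || !nrow(te)) stop("empty train or test cohort")
  test_subjects <- sort(unique(te$subject_id))
  classes <- sort(unique(c(tr$activity, te$activity)))
  shared_model <- NULL
  if (train_cohort != test_cohort) {
    shared_model <- fit_on_table(as_instance_subset(tr, table), feature_set,
                                 algorithm, n_trees, min_leaf, learn_rate,
                                 seed = seed)
  }
  rows <- list(); cms <- list()
  meta <- subject_meta(te)
  for (s in test_subjects) {
    te_s <- as_instance_subset(te[te$subject_id == s, ], table)
    model <- shared_model
    if (is.null(model)) {
      tr_s <- as_instance_subset(tr[tr$subject_id != s, ], table)
      if (!nrow(tr_s)) stop("LOSO fold for subject ", s, " has no training data")
      model <- fit_on_table(tr_s, feature_set, algorithm, n_trees, min_leaf,
                            learn_rate, seed = derive_seed(seed, s))
    }
    pred <- predict_on_table(model, te_s, feature_set)
    um <- unit_metrics(te_s$activity, pred, classes, STATIONARY, AMBULATORY)
    cms[[s]] <- um$cm
    mi <- meta[meta$subject_id == s, ]
    rows[[s]] <- data.frame(
      subject_id = s, cohort = mi$cohort, impairment = mi$impairment,
      gait_speed = mi$gait_speed, mean_recall = um$mean_recall,
      amb_recall = um$amb_recall, stat_recall = um$stat_recall,
      amb_to_stat = um$amb_to_stat, stat_to_amb = um$stat_to_amb,
      n_test = um$n_test, stringsAsFactors = FALSE)
  }
  new_report(paste0(train_cohort, "-to-", test_cohort), rows, cms, classes,
             list(stationary = STATIONARY, ambulatory = AMBULATORY))
}

# Keep instance_table class/attributes on a row subset.
as_instance_subset <- function(df, parent) {
  attr(df, "feature_names") <- feature_names(parent)
  class(df) <- c("instance_table", "data.frame")
  df
}

#' Aggregate a cross-cohort report by gait-impairment stratum
#'
#' Pools the per-subject confusion matrices of an \code{ar_report} (typically
#' healthy-to-stroke or stroke-to-stroke) within each impairment stratum and
#' recomputes recall and stationary/ambulatory misclassification per stratum.
#'
#' @param report An \code{ar_report} from \code{\link{eval_population}}.
#' @return data.frame: one row per stratum with pooled
#'   \code{amb_to_stat}, \code{stat_to_amb}, mean per-subject mean recall, and
#'   subject count.
#' @export
stratify_by_impairment <- function(report) {
  ps <- report$per_subject
  strata <- intersect(c("mild", "moderate", "severe"), unique(ps$impairment))
  out <- lapply(strata, function(st) {
    ids <- ps$subject_id[ps$impairment == st]
    pooled <- Reduce("+", report$confusions[ids])
    class(pooled) <- c("ar_confusion", class(pooled))
    g <- group_misclassification(pooled, report$grouping$stationary,
                                 report$grouping$ambulatory)
    data.frame(impairment = st, n_subjects = length(ids),
               mean_recall = mean(ps$mean_recall[ps$impairment == st], na.rm = TRUE),
               amb_recall = mean(ps$amb_recall[ps$impairment == st], na.rm = TRUE),
               amb_to_stat = g$amb_to_stat, stat_to_amb = g$stat_to_amb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subjects with enough data for the environmental designs
#'
#' Keeps subjects having at least \code{min_seconds} of every activity in
#' every session listed, measured as summed clip-covered bout spans.
#'
#' @param table An \code{\link{instance_table}}.
#' @param sessions Sessions that must each satisfy the rule.
#' @param min_seconds Minimum seconds per activity per session.
#' @param activities Activities that must be covered.
#' @return Character vector of eligible subject ids.
#' @export
eligible_subjects <- function(table, sessions = c("Lab1", "Home", "Lab2"),
                              min_seconds = 60, activities = ACTIVITIES) {
  ok <- character(0)
  for (s in unique(table$subject_id)) {
    good <- TRUE
    for (ses in sessions) {
      sub <- table[table$subject_id == s & table$session == ses, ]
      secs <- vapply(activities, function(a) {
        b <- sub[sub$activity == a, ]
        if (!nrow(b)) return(0)
        sum(vapply(split(b, b$bout_id),
                   function(d) max(d$clip_end_s) - min(d$clip_start_s), 0))
      }, 0)
      if (any(secs < min_seconds)) { good <- FALSE; break }
    }
    if (good) ok <- c(ok, s)
  }
  ok
}

#' Chronological k-fold assignment with boundary-clip exclusion
#'
#' Orders one subject-session's clips by start time, cuts them into \code{k}
#' contiguous blocks, and drops any clip whose \code{[start, end)} span
#' straddles a block boundary, so no raw sample is shared between folds.
#'
#' @param table Clips of a single subject-session (instance_table rows).
#' @param k Number of folds.
#' @return Integer fold id per row; \code{NA} marks dropped boundary clips.
#' @export
chronological_folds <- function(table, k = 4) {
  n <- nrow(table)
  ord <- order(table$clip_start_s)
  fold <- integer(n)
  fold[ord] <- ceiling(seq_len(n) / (n / k))
  fold[fold > k] <- k
  res <- fold
  for (j in seq_len(k - 1)) {
    later <- table$clip_start_s[fold > j]
    if (!length(later)) next
    tau <- min(later)
    straddle <- table$clip_start_s < tau & table$clip_end_s > tau
    res[straddle] <- NA_integer_
  }
  res
}

#' Environmental model evaluation (personal or global)
#'
#' Reproduces the lab-to-home comparison on the merged four-class problem
#' (Sedentary, Standing, Stairs, Walking) over the eligibility-filtered
#' subject pool. Personal models: per subject, train on Lab1 / test on Lab2,
#' train on Lab1 / test on Home, and Home-to-Home via chronological 4-fold
#' cross-validation with boundary clips dropped. Global models: for each
#' pairing, leave-one-subject-out over the pool (train on the other subjects'
#' source-session clips, test on the held-out subject's target session; for
#' Home-to-Home the subject's own Home data is never in training).
#'
#' @param table An \code{\link{instance_table}} containing Lab1, Home and Lab2
#'   sessions for a stroke cohort.
#' @param scope \code{"personal"} or \code{"global"}.
#' @param min_seconds Eligibility threshold (s per activity per session).
#' @param k Folds for the Home-to-Home personal design.
#' @param feature_set,algorithm,n_trees,min_leaf,learn_rate,seed As in
#'   \code{\link{eval_population}}.
#' @return Named list of \code{ar_report}s: \code{lab1_to_lab2},
#'   \code{lab1_to_home}, \code{home_to_home}.
#' @export
eval_environment <- function(table, scope = c("personal", "global"),
                             min_seconds = 60, k = 4, feature_set = "all",
                             algorithm = "rusboost", n_trees = 200,
                             min_leaf = 5, learn_rate = 1, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "instance_table"))
  pool <- eligible_subjects(table, min_seconds = min_seconds)
  if (!length(pool)) stop("eligibility filter left no subjects")
  tab <- table[table$subject_id %in% pool, ]
  tab <- as_instance_subset(tab, table)
  grouping <- list(stationary = MERGED_STATIONARY, ambulatory = MERGED_AMBULATORY)
  classes <- sort(unique(merge_activity_classes(tab$activity)))
  meta <- subject_meta(tab)

  fit_unit <- function(tr, seed_key) {
    fit_on_table(as_instance_subset(tr, table), feature_set,
                 algorithm, n_trees, min_leaf, learn_rate,
                 seed = derive_seed(seed, seed_key), merge_classes = TRUE)
  }
  test_unit <- function(model, te) {
    pred <- predict_on_table(model, as_instance_subset(te, table), feature_set)
    unit_metrics(merge_activity_classes(te$activity), pred, classes,
                 MERGED_STATIONARY, MERGED_AMBULATORY)
  }
  run_unit <- function(tr, te, seed_key) test_unit(fit_unit(tr, seed_key), te)
  subject_row <- function(s, um) {
    mi <- meta[meta$subject_id == s, ][1, ]
    data.frame(subject_id = s, cohort = mi$cohort, impairment = mi$impairment,
               gait_speed = mi$gait_speed, mean_recall = um$mean_recall,
               amb_recall = um$amb_recall, stat_recall = um$stat_recall,
               amb_to_stat = um$amb_to_stat, stat_to_amb = um$stat_to_amb,
               n_test = um$n_test, stringsAsFactors = FALSE)
  }

  pairings <- c("lab1_to_lab2", "lab1_to_home", "home_to_home")
  rows <- stats::setNames(vector("list", 3), pairings)
  cms <- stats::setNames(vector("list", 3), pairings)
  for (s in pool) {
    # one Lab1-source model per subject serves both Lab2 and Home targets
    lab1_tr <- if (scope == "personal") {
      tab[tab$subject_id == s & tab$session == "Lab1", ]
    } else {
      tab[tab$subject_id != s & tab$session == "Lab1", ]
    }
    lab1_model <- fit_unit(lab1_tr, paste("lab1", s))
    for (dst in c("Lab2", "Home")) {
      te <- tab[tab$subject_id == s & tab$session == dst, ]
      um <- test_unit(lab1_model, te)
      pn <- if (dst == "Lab2") "lab1_to_lab2" else "lab1_to_home"
      cms[[pn]][[s]] <- um$cm
      rows[[pn]][[s]] <- subject_row(s, um)
    }
    # Home-to-Home
    if (scope == "personal") {
      sub <- tab[tab$subject_id == s & tab$session == "Home", ]
      fold <- chronological_folds(sub, k)
      cm_s <- NULL
      for (j in seq_len(k)) {
        tr <- sub[!is.na(fold) & fold != j, ]
        te <- sub[!is.na(fold) & fold == j, ]
        if (!nrow(te) || !nrow(tr)) next
        um <- run_unit(tr, te, paste("home", s, j))
        cm_s <- if (is.null(cm_s)) um$cm else cm_s + um$cm
      }
      if (is.null(cm_s)) next
      class(cm_s) <- c("ar_confusion", class(cm_s))
      r <- recall_from_confusion(cm_s)
      g <- group_misclassification(cm_s, MERGED_STATIONARY, MERGED_AMBULATORY)
      amb_p <- intersect(r$classes_present, MERGED_AMBULATORY)
      sta_p <- intersect(r$classes_present, MERGED_STATIONARY)
      um <- list(cm = cm_s, mean_recall = r$mean_recall,
                 amb_recall = if (length(amb_p)) mean(r$recall[amb_p]) else NA_real_,
                 stat_recall = if (length(sta_p)) mean(r$recall[sta_p]) else NA_real_,
                 amb_to_stat = g$amb_to_stat, stat_to_amb = g$stat_to_amb,
                 n_test = sum(cm_s))
    } else {
      tr <- tab[tab$subject_id != s & tab$session == "Home", ]
      te <- tab[tab$subject_id == s & tab$session == "Home", ]
      um <- run_unit(tr, te, paste("home", s))
    }
    cms$home_to_home[[s]] <- um$cm
    rows$home_to_home[[s]] <- subject_row(s, um)
  }
  out <- list()
  for (pn in pairings) {
    out[[pn]] <- new_report(paste0(scope, ":", pn), rows[[pn]], cms[[pn]],
                            classes, grouping)
  }
  out
}

#' Evaluate one of the named study designs
#'
#' Thin dispatcher over \code{\link{eval_population}},
#' \code{\link{stratify_by_impairment}} and \code{\link{eval_environment}}.
#'
#' @param design One of \code{"population_LOSO"},
#'   \code{"impairment_stratified"}, \code{"environmental_personal"},
#'   \code{"environmental_global"}, \code{"learning_curve"},
#'   \code{"barometer_ablation"}.
#' @param table An \code{\link{instance_table}}.
#' @param train_cohort,test_cohort Cohorts for the population designs.
#' @param ... Passed to the underlying design function.
#' @return An \code{ar_report}, a stratum table, or a list of reports,
#'   depending on the design.
#' @export
evaluate_design <- function(design, table, train_cohort = "stroke",
                            test_cohort = "stroke", ...) {
  switch(design,
    population_LOSO = eval_population(table, train_cohort, test_cohort, ...),
    impairment_stratified = stratify_by_impairment(
      eval_population(table, train_cohort, test_cohort, ...)),
    environmental_personal = eval_environment(table, "personal", ...),
    environmental_global = eval_environment(table, "global", ...),
    learning_curve = learning_curve(table, train_cohort, test_cohort, ...),
    barometer_ablation = ablate_barometer(table, train_cohort, test_cohort, ...),
    stop("unknown design: ", design))
}
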