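# Out-of-bag permutation importance ranking and feature selection.

#' Rank features by out-of-bag permutation importance
#'
#' Trains a bagged-tree ensemble in which every tree sees a random undersample
#' equalizing class counts at the minority-class size (random-undersampling
#' random forest), then scores each feature as the mean over trees of the
#' increase in out-of-bag error after permuting that feature, normalized by
#' the SD of that increase across trees. Backed by
#' \code{randomForest::randomForest} with \code{strata}/\code{sampsize} and
#' \code{importance = TRUE}; deterministic given \code{seed}.
#'
#' @param table An \code{\link{instance_table}} with at least 2 classes.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return data.frame sorted by descending importance: \code{feature},
#'   \code{importance}, \code{rank}.
#' @export
rank_features_oob <- function(table, n_trees = 200, seed = 1L) {
  stopifnot(inherits(table, "instance_table"))
  y <- factor(table$activity)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes to rank features")
  y <- droplevels(y)
  fn <- feature_names(table)
  xm <- as.matrix(table[, fn, drop = FALSE])
  xm[!is.finite(xm)] <- 0  # absent barometer treated as uninformative
  n_min <- min(table(y))
  fit <- with_seed(seed, randomForest::randomForest(
    x = xm, y = y, ntree = n_trees,
    strata = y, sampsize = rep(n_min, nlevels(y)),
    importance = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = fn[ord], importance = unname(imp[ord]),
             rank = seq_along(fn), stringsAsFactors = FALSE)
}

#' Select the top-k features from a ranking
#'
#' @param ranking Output of \code{\link{rank_features_oob}}.
#' @param k Number of features to keep (1 <= k <= nrow(ranking)).
#' @return List of class \code{feature_set}: \code{names} (selected feature
#'   names, ranking order), \code{k}, and \code{provenance}.
#' @export
select_features <- function(ranking, k = 151) {
  stopifnot(is.data.frame(ranking), "feature" %in% names(ranking))
  if (k < 1 || k > nrow(ranking)) stop("k out of range [1, ", nrow(ranking), "]")
  structure(list(names = ranking$feature[seq_len(k)], k = as.integer(k),
                 provenance = list(n_candidates = nrow(ranking),
                                   selected_at = Sys.time())),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d of %d features\n", x$k,
              x$provenance$n_candidates))
  invisible(x)
}
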