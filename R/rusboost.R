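# RUSBoost: AdaBoost.M2 boosting of CART trees where each weak learner is
# trained on a random undersample that equalizes class counts.

#' Fit a RUSBoost ensemble
#'
#' Multiclass AdaBoost.M2 with per-iteration random undersampling. Each
#' boosting round draws, within every class, a weighted random undersample of
#' size \code{sample_size} (the minority-class count by default; with
#' replacement only when a class is smaller than the target), fits a CART tree
#' (Gini, minimum leaf size \code{min_leaf}, no complexity penalty) on the
#' undersample, evaluates the AdaBoost.M2 pseudo-loss on the full weighted
#' training set, and updates the mislabel weight distribution with
#' \code{beta^(learn_rate * ...)}. Boosting stops early when the pseudo-loss
#' reaches 0 (the tree gets a large capped weight) or 0.5 or more (the tree is
#' discarded).
#'
#' @param x Numeric matrix or data.frame of predictors, or a formula.
#' @param y Factor (or coercible) of class labels; at least 2 classes, each
#'   with at least \code{min_leaf} instances.
#' @param n_trees Maximum number of boosting iterations (default 200).
#' @param learn_rate Shrinkage on the weight updates in (0, 1] (default 1).
#' @param min_leaf Minimum observations in a terminal node (default 5).
#' @param sample_size Per-class undersample size; default the minority-class
#'   count.
#' @param seed Integer seed; if NULL, uses the current RNG state.
#' @param ... Passed between methods.
#' @return Object of class \code{rusboost}: weak learners, per-iteration
#'   weights \code{alpha} (= learn_rate * log(1/beta)), class levels, feature
#'   names, and training metadata.
#' @seealso \code{\link{predict.rusboost}}, \code{\link{rf_baseline}}
#' @examples
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
#' y <- rep(c("a", "b"), each = 30)
#' fit <- rusboost(x, y, n_trees = 5, seed = 1)
#' table(predict(fit, x), y)
#' @export
rusboost <- function(x, ...) UseMethod("rusboost")

#' @rdname rusboost
#' @param data data.frame holding the formula variables.
#' @export
rusboost.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  rusboost.default(mf[, -1, drop = FALSE], y, ...)
}

#' @rdname rusboost
#' @export
rusboost.default <- function(x, y, n_trees = 200, learn_rate = 1, min_leaf = 5,
                             sample_size = NULL, seed = NULL, ...) {
  x <- as.data.frame(x)
  y <- factor(y)
  y <- droplevels(y)
  classes <- sort(levels(y))  # fixed alphabetical class order
  y <- factor(as.character(y), levels = classes)
  k <- length(classes)
  n <- nrow(x)
  stopifnot(n == length(y), n_trees >= 1, learn_rate > 0, learn_rate <= 1,
            min_leaf >= 1)
  if (k < 2) stop("rusboost needs at least 2 classes")
  cls_n <- table(y)
  if (any(cls_n < min_leaf)) {
    stop("every class needs at least min_leaf (", min_leaf, ") instances")
  }
  if (is.null(sample_size)) sample_size <- min(cls_n)
  colnames(x) <- make.names(colnames(x) %||% paste0("V", seq_len(ncol(x))),
                            unique = TRUE)
  all_num <- all(vapply(x, is.numeric, TRUE))
  xmat <- if (all_num) as.matrix(x) else NULL
  probs_fun <- if (all_num && !anyNA(xmat)) {
    function(tree) tree_probs_fast(tree, xmat, classes)
  } else {
    function(tree) predict_tree_probs(tree, x, classes)
  }

  fit_fun <- function() {
    yi <- as.integer(y)
    # mislabel weight matrix: w[i, j] over incorrect labels j != y_i
    w <- matrix(1 / (n * (k - 1)), n, k)
    w[cbind(seq_len(n), yi)] <- 0
    trees <- list(); alphas <- numeric(0)
    ctrl <- rpart::rpart.control(minbucket = min_leaf,
                                 minsplit = max(2L, 2L * min_leaf),
                                 cp = 0, xval = 0, maxcompete = 0,
                                 maxsurrogate = 0)
    for (t in seq_len(n_trees)) {
      wi <- rowSums(w)
      idx <- integer(0)
      for (cl in seq_len(k)) {
        pool <- which(yi == cl)
        pr <- wi[pool]
        if (sum(pr) <= 0) pr <- rep(1, length(pool))
        take <- min(sample_size, length(pool))
        sel <- pool[sample.int(length(pool), take, prob = pr)]
        if (take < sample_size) {
          sel <- c(sel, pool[sample.int(length(pool), sample_size - take,
                                        replace = TRUE, prob = pr)])
        }
        idx <- c(idx, sel)
      }
      idx <- sort(idx)
      df <- x[idx, , drop = FALSE]
      df$.y <- y[idx]
      wt <- wi[idx]
      if (sum(wt) <= 0) wt <- rep(1, length(idx))
      tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                           weights = wt / mean(wt), control = ctrl)
      h <- probs_fun(tree)
      h_true <- h[cbind(seq_len(n), yi)]
      eps <- 0.5 * sum(w * (1 - h_true + h))  # w is 0 at the true label
      if (eps <= 0) {
        trees[[length(trees) + 1L]] <- tree
        alphas <- c(alphas, learn_rate * log(1e10))
        break
      }
      if (eps >= 0.5) {
        if (!length(trees)) { trees[[1L]] <- tree; alphas <- 0 }
        break
      }
      beta <- eps / (1 - eps)
      expo <- 0.5 * (1 + h_true - h)  # n x k
      w <- w * beta^(learn_rate * expo)
      w <- w / sum(w)
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, learn_rate * log(1 / beta))
    }
    list(trees = trees, alphas = alphas)
  }
  ens <- if (is.null(seed)) fit_fun() else with_seed(seed, fit_fun())

  structure(list(
    trees = ens$trees, alpha = ens$alphas, classes = classes,
    feature_names = colnames(x),
    config = list(n_trees = n_trees, learn_rate = learn_rate,
                  min_leaf = min_leaf, sample_size = sample_size,
                  seed = seed),
    class_counts = as.integer(cls_n), n = n
  ), class = "rusboost")
}

# Class-probability matrix of one rpart tree on new data, mapped onto the
# global class order (absent classes get probability 0).
predict_tree_probs <- function(tree, newdata, classes) {
  p <- stats::predict(tree, newdata = as.data.frame(newdata), type = "prob")
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

# Fast equivalent of predict(tree, type = "prob") for trees grown with
# maxcompete = maxsurrogate = 0 on all-numeric, NA-free predictors: vectorized
# descent over the rpart frame/splits tables (verified against predict.rpart
# in the test suite). Falls back implicitly via callers for non-numeric input.
tree_probs_fast <- function(tree, xmat, classes) {
  frame <- tree$frame
  nlev <- length(attr(tree, "ylevels"))
  n <- nrow(xmat)
  out <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  prob_cols <- (nlev + 2):(2 * nlev + 1)
  if (nrow(frame) == 1) {  # root-only tree
    pr <- frame$yval2[1, prob_cols]
    for (k in seq_len(nlev)) out[, attr(tree, "ylevels")[k]] <- pr[k]
    return(out)
  }
  nodes <- as.numeric(rownames(frame))  # numeric: ids reach 2^31 at depth 30
  is_leaf <- frame$var == "<leaf>"
  splits <- tree$splits
  split_row <- integer(nrow(frame))      # frame row -> splits row
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  var_idx <- match(rownames(splits), colnames(xmat))
  ylev <- attr(tree, "ylevels")
  left_child <- match(nodes * 2, nodes)
  right_child <- match(nodes * 2 + 1, nodes)

  desc <- function(fr, rows) {
    if (!length(rows)) return(invisible())
    if (is_leaf[fr]) {
      pr <- frame$yval2[fr, prob_cols]
      for (k in seq_len(nlev)) out[rows, ylev[k]] <<- pr[k]
      return(invisible())
    }
    sr <- split_row[fr]
    xv <- xmat[rows, var_idx[sr]]
    thr <- splits[sr, "index"]
    goes_left <- if (splits[sr, "ncat"] < 0) xv < thr else xv >= thr
    desc(left_child[fr], rows[goes_left])
    desc(right_child[fr], rows[!goes_left])
    invisible()
  }
  desc(1L, seq_len(n))
  out
}

#' Predict activity labels from a RUSBoost ensemble
#'
#' The label is the argmax over classes of the alpha-weighted sum of tree
#' class-probability votes; ties break deterministically toward the first
#' class in alphabetical order. Scores are normalized to sum to 1 per
#' instance.
#'
#' @param object A \code{\link{rusboost}} fit.
#' @param newdata Matrix or data.frame carrying the ensemble's features.
#' @param type \code{"class"} for labels, \code{"score"} for the normalized
#'   score matrix.
#' @param ... Ignored.
#' @return Factor of labels, or a numeric matrix of per-class scores.
#' @export
predict.rusboost <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  colnames(newdata) <- make.names(colnames(newdata), unique = TRUE)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks ensemble feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  all_num <- all(vapply(newdata, is.numeric, TRUE))
  xmat <- if (all_num) as.matrix(newdata) else NULL
  fast <- all_num && !anyNA(xmat)
  scores <- matrix(0, nrow(newdata), length(object$classes),
                   dimnames = list(NULL, object$classes))
  for (t in seq_along(object$trees)) {
    h <- if (fast) tree_probs_fast(object$trees[[t]], xmat, object$classes)
         else predict_tree_probs(object$trees[[t]], newdata, object$classes)
    scores <- scores + object$alpha[t] * h
  }
  tot <- rowSums(scores)
  tot[tot <= 0] <- 1
  scores <- scores / tot
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.rusboost <- function(x, ...) {
  cat(sprintf("RUSBoost ensemble: %d trees (requested %d), %d classes, %d features\n",
              length(x$trees), x$config$n_trees, length(x$classes),
              length(x$feature_names)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  trained on %d instances (class counts: %s)\n", x$n,
              paste(x$class_counts, collapse = "/")))
  invisible(x)
}

#' @export
summary.rusboost <- function(object, ...) {
  cat("RUSBoost (AdaBoost.M2 with random undersampling)\n")
  print(object)
  cat(sprintf("  learner weights: min %.3f, median %.3f, max %.3f\n",
              min(object$alpha), stats::median(object$alpha),
              max(object$alpha)))
  cat(sprintf("  config: learn_rate=%g, min_leaf=%d, per-class sample=%d\n",
              object$config$learn_rate, object$config$min_leaf,
              object$config$sample_size))
  invisible(object)
}

#' Plain random-forest baseline
#'
#' Bootstrap-bagged forest (no boosting, no undersampling) used as the
#' comparison model for the class-imbalance analyses. A thin deterministic
#' wrapper around \code{randomForest::randomForest}.
#'
#' @param x Predictor matrix or data.frame.
#' @param y Class labels.
#' @param n_trees Number of trees.
#' @param min_leaf Minimum terminal-node size.
#' @param seed Integer seed.
#' @return Object of class \code{rf_baseline} supporting \code{predict}.
#' @export
rf_baseline <- function(x, y, n_trees = 200, min_leaf = 5, seed = NULL) {
  x <- as.data.frame(x)
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  y <- droplevels(factor(y))
  y <- factor(as.character(y), levels = sort(levels(y)))
  fit_fun <- function() randomForest::randomForest(
    x = x, y = y, ntree = n_trees, nodesize = min_leaf)
  fit <- if (is.null(seed)) fit_fun() else with_seed(seed, fit_fun())
  structure(list(fit = fit, classes = levels(y),
                 feature_names = colnames(x)),
            class = "rf_baseline")
}

#' @export
predict.rf_baseline <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  colnames(newdata) <- make.names(colnames(newdata), unique = TRUE)
  stats::predict(object$fit, newdata[, object$feature_names, drop = FALSE])
}

# Shared trainer used by the evaluation designs.
train_classifier <- function(x, y, algorithm = c("rusboost", "random_forest"),
                             n_trees = 200, min_leaf = 5, learn_rate = 1,
                             seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "rusboost") {
    rusboost(x, y, n_trees = n_trees, learn_rate = learn_rate,
             min_leaf = min_leaf, seed = seed)
  } else {
    rf_baseline(x, y, n_trees = n_trees, min_leaf = min_leaf, seed = seed)
  }
}
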