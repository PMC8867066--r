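#' Fit a regression random forest
#'
#' Bagged CART regression trees with feature subsampling. Importance is the
#' out-of-bag permutation importance (mean increase in OOB MSE when one
#' feature's OOB values are permuted), the standard definition. Hyper-
#' parameters are fixed and recorded in the returned object. The forest is
#' reproducible under `set.seed()`.
#'
#' @param X numeric matrix (n x p), column names required.
#' @param y numeric response.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `max(1, floor(p / 3))`.
#' @param min_node minimum samples per leaf.
#' @param max_depth maximum tree depth.
#' @param importance compute OOB permutation importance.
#' @return object of class `citrus_rf`: trees, OOB predictions, importance.
#' @export
rf_fit <- function(X, y, ntree = 500L, mtry = NULL, min_node = 5L,
                   max_depth = 25L, importance = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  fit <- cpp_rf_fit(X, as.numeric(y), as.integer(ntree), as.integer(mtry),
                    as.integer(min_node), as.integer(max_depth),
                    isTRUE(importance))
  names(fit$importance) <- colnames(X)
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 oob_prediction = fit$oob_prediction,
                 importance = fit$importance,
                 feature_names = colnames(X), n = nrow(X),
                 hyperparameters = list(ntree = ntree, mtry = mtry,
                                        min_node = min_node,
                                        max_depth = max_depth)),
            class = "citrus_rf")
}

#' Predict from a fitted random forest
#' @param object a `citrus_rf`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @export
predict.citrus_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  cpp_rf_predict(object$trees, newdata)
}

#' Partial dependence of a forest prediction on one feature
#'
#' For each grid value v the feature column is set to v over the whole
#' sample and predictions are averaged. The grid is equally spaced
#' quantiles of the observed feature.
#'
#' @param forest a `citrus_rf`.
#' @param X training feature matrix.
#' @param feature feature name.
#' @param grid_size number of grid points.
#' @return data.frame with columns `value` and `prediction`.
#' @export
partial_dependence <- function(forest, X, feature, grid_size = 25L) {
  X <- as.matrix(X)
  if (!feature %in% colnames(X)) stop("unknown feature: ", feature)
  grid <- unique(stats::quantile(X[, feature],
                                 probs = seq(0, 1, length.out = grid_size),
                                 names = FALSE))
  pred <- vapply(grid, function(v) {
    Xv <- X; Xv[, feature] <- v
    mean(predict.citrus_rf(forest, Xv))
  }, numeric(1))
  data.frame(value = grid, prediction = pred)
}

#' Pairwise decision-path interaction scores
#'
#' A light-weight surrogate for iterated-forest interaction discovery: for
#' each tree, root-to-leaf paths ending in large leaves (holding at least
#' `min_leaf_frac` of the tree's training samples) are enumerated, and the
#' score of a feature pair is the fraction of those paths on which both
#' features split, averaged over trees. Depth-1 trees therefore score 0 for
#' every pair, and scores always lie in \[0, 1\].
#'
#' @param forest a `citrus_rf`.
#' @param min_leaf_frac minimum leaf size as a fraction of training n.
#' @return symmetric p x p matrix of co-occurrence scores.
#' @export
path_interactions <- function(forest, min_leaf_frac = 0.02) {
  p <- length(forest$feature_names)
  acc <- matrix(0, p, p, dimnames = list(forest$feature_names,
                                         forest$feature_names))
  min_n <- min_leaf_frac * forest$n
  for (tm in forest$trees) {
    co <- matrix(0, p, p)
    npaths <- 0L
    # depth-first traversal carrying the set of features on the path
    walk <- function(node, feats) {
      f <- tm[node, "feature"]
      if (f == 0) {
        if (tm[node, "n"] >= min_n) {
          npaths <<- npaths + 1L
          u <- unique(feats)
          if (length(u) >= 2) {
            for (a in seq_along(u)[-length(u)])
              for (b in (a + 1):length(u))
                co[u[a], u[b]] <<- co[u[a], u[b]] + 1
          }
        }
        return(invisible())
      }
      walk(tm[node, "left"], c(feats, f))
      walk(tm[node, "right"], c(feats, f))
    }
    walk(1L, integer(0))
    if (npaths > 0L) acc <- acc + (co + t(co)) / npaths
  }
  acc / length(forest$trees)
}
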