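# Shared gradient-boosted-tree fit used by the screening operations.
# Single-threaded with a fixed seed so every report is reproducible.
xgb_fit_multiclass <- function(X, y, seed, nrounds = 50, params = list()) {
  classes <- sort(unique(y))
  yi <- match(y, classes) - 1
  base <- list(max_depth = 4, eta = 0.3, nthread = 1, seed = seed,
               verbosity = 0)
  if (length(classes) > 2) {
    base$objective <- "multi:softprob"
    base$num_class <- length(classes)
  } else {
    base$objective <- "binary:logistic"
  }
  base[names(params)] <- params
  set.seed(seed)
  fit <- xgboost::xgb.train(params = base,
                            data = xgboost::xgb.DMatrix(X, label = yi),
                            nrounds = nrounds, verbose = 0)
  list(model = fit, classes = classes)
}

xgb_predict_prob <- function(fit, X) {
  p <- predict(fit$model, xgboost::xgb.DMatrix(X))
  if (length(fit$classes) == 2) p <- cbind(1 - p, p)
  colnames(p) <- fit$classes
  p
}

#' Rank features by gradient-boosting importance
#'
#' Fits a gradient-boosted tree ensemble and scores each feature by its
#' total gain, normalised to sum to one; features never used in a split
#' score zero. The ranking is stable: descending score, ties broken by
#' feature name.
#'
#' @param table A complete [feature_table()].
#' @param labels A [label_vector()] or integer vector (>= 2 classes).
#' @param seed Integer seed.
#' @param nrounds Boosting rounds.
#' @return An `importance_report`: data frame `(feature, score)` with the
#'   model settings and a data fingerprint as attributes.
#' @export
rank_importance <- function(table, labels, seed = 1L, nrounds = 50) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (any(!is.finite(X))) stop("table contains non-finite values; impute first")
  y <- as_labels(labels)
  if (length(unique(y)) < 2) stop("need at least two classes")
  fit <- xgb_fit_multiclass(X, y, seed, nrounds)
  imp <- xgboost::xgb.importance(model = fit$model)
  score <- stats::setNames(rep(0, ncol(X)), colnames(X))
  score[imp$Feature] <- imp$Gain
  if (sum(score) > 0) score <- score / sum(score)
  ord <- order(-score, names(score))
  out <- data.frame(feature = names(score)[ord], score = unname(score[ord]),
                    row.names = NULL)
  attr(out, "settings") <- list(nrounds = nrounds, seed = seed,
                                importance = "gain")
  attr(out, "fingerprint") <- data_fingerprint(X)
  class(out) <- c("importance_report", "data.frame")
  out
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin across folds.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Mean stratified-CV accuracy of the boosted-tree classifier on a feature
# subset.
xgb_cv_accuracy <- function(X, y, folds, seed, nrounds) {
  fold <- stratified_folds(y, folds, seed)
  correct <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- xgb_fit_multiclass(X[tr, , drop = FALSE], y[tr], seed, nrounds)
    p <- xgb_predict_prob(fit, X[!tr, , drop = FALSE])
    pred <- fit$classes[max.col(p, ties.method = "first")]
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Recursive feature elimination with an accuracy-loss tolerance
#'
#' Starting from the full feature set, repeatedly drops the `step`
#' lowest-importance features (importance refitted at every size) while
#' recording stratified cross-validation accuracy at each visited size, and
#' retains the smallest feature count whose accuracy is at least
#' `(1 - tolerance)` times the full-feature accuracy.
#'
#' @param table A complete [feature_table()].
#' @param labels A [label_vector()] or integer vector.
#' @param tolerance Maximum relative accuracy loss (default 0.001).
#' @param step Features dropped per iteration.
#' @param seed Integer seed.
#' @param folds CV folds inside the elimination loop.
#' @param nrounds Boosting rounds per fit.
#' @return A `selection_result`: `retained` (ordered by importance),
#'   `n_retained`, `accuracy_curve` (data frame `n_features`, `cv_accuracy`),
#'   `full_accuracy`, `selected_accuracy`, `relative_loss`.
#' @export
rfe_select <- function(table, labels, tolerance = 0.001, step = 1, seed = 1L,
                       folds = 5, nrounds = 50) {
  stopifnot(inherits(table, "feature_table"), tolerance >= 0, step >= 1)
  y <- as_labels(labels)
  feats <- table$meta$name
  X <- table$values
  meta <- table$meta

  sizes <- integer(0); accs <- numeric(0); sets <- list()
  current <- feats
  repeat {
    Xc <- X[, current, drop = FALSE]
    tc <- feature_table(Xc, meta[match(current, meta$name), ])
    acc <- xgb_cv_accuracy(Xc, y, folds, seed, nrounds)
    sizes <- c(sizes, length(current)); accs <- c(accs, acc)
    sets[[length(sets) + 1]] <- current
    if (length(current) == 1) break
    imp <- rank_importance(tc, y, seed = seed, nrounds = nrounds)
    keep <- max(1L, length(current) - step)
    current <- imp$feature[seq_len(keep)]
  }

  full_acc <- accs[1]
  ok <- accs >= (1 - tolerance) * full_acc
  if (!any(ok)) {   # unreachable since the full set qualifies; kept defensive
    warning("no subset met the tolerance; returning the full feature set")
    pick <- 1L
  } else pick <- which(ok)[which.min(sizes[ok])]
  sel_acc <- accs[pick]
  res <- list(retained = sets[[pick]],
              n_retained = sizes[pick],
              accuracy_curve = data.frame(n_features = sizes,
                                          cv_accuracy = accs),
              full_accuracy = full_acc,
              selected_accuracy = sel_acc,
              relative_loss = (full_acc - sel_acc) / full_acc)
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> retained", x$n_retained, "features;",
      sprintf("CV accuracy %.4f (full %.4f, relative loss %.4f)\n",
              x$selected_accuracy, x$full_accuracy, x$relative_loss))
  invisible(x)
}

#' Compare two importance reports feature by feature
#'
#' @param before,after `importance_report`s over the same feature universe.
#' @return List with `by_feature` (score delta and rank displacement per
#'   feature) and `rank_correlation` (Spearman correlation of the two
#'   rankings).
#' @export
compare_importance <- function(before, after) {
  if (!setequal(before$feature, after$feature))
    stop("importance reports cover different feature universes")
  m <- merge(data.frame(feature = before$feature,
                        score_before = before$score,
                        rank_before = seq_len(nrow(before))),
             data.frame(feature = after$feature,
                        score_after = after$score,
                        rank_after = seq_len(nrow(after))),
             by = "feature")
  m$score_delta <- m$score_after - m$score_before
  m$rank_displacement <- m$rank_after - m$rank_before
  rho <- stats::cor(m$rank_before, m$rank_after, method = "spearman")
  list(by_feature = m[order(m$rank_before), ], rank_correlation = rho)
}

#' Qualitative LASSO cross-check of a feature selection
#'
#' L1-regularised logistic regression over a penalty path on a binarised
#' (normal vs abnormal) outcome; reports the nonzero-coefficient feature
#' set along the path and at the cross-validated-AUC-maximising penalty.
#' Intended only for overlap reporting against [rfe_select()] results, as a
#' binary-classification sanity check.
#'
#' @param table A complete [feature_table()].
#' @param labels Binary (0/1) labels.
#' @param nlambda Path length.
#' @param nfolds CV folds for the AUC curve.
#' @param seed Integer seed.
#' @return List with `lambda`, `auc`, `nonzero` (list of feature sets along
#'   the path), `selected` (set at the AUC-best penalty) and `best_lambda`.
#' @export
lasso_crosscheck <- function(table, labels, nlambda = 50, nfolds = 5,
                             seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  y <- as_labels(labels)
  if (length(unique(y)) != 2) stop("lasso_crosscheck needs binary labels")
  X <- table$values
  set.seed(seed)
  foldid <- stratified_folds(y, nfolds, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "auc",
                          nlambda = nlambda, foldid = foldid)
  nz <- lapply(seq_along(cv$lambda), function(i) {
    co <- as.matrix(stats::coef(cv$glmnet.fit, s = cv$lambda[i]))[-1, 1]
    names(co)[co != 0]
  })
  best <- which.max(cv$cvm)
  list(lambda = cv$lambda, auc = cv$cvm, nonzero = nz,
       selected = nz[[best]], best_lambda = cv$lambda[best])
}
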