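#' Train/test split specification
#'
#' @param train_fraction Fraction of samples assigned to training (default
#'   0.8, the 8:2 split).
#' @param stratified Preserve per-class proportions (default TRUE).
#' @param seed Integer seed.
#' @return A `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Assigns `round(fraction * n_c)` samples of each class to training (at
#' least one), so per-class training proportions are within one sample of
#' the global fraction; single-member classes go to training with a
#' warning.
#'
#' @param table A [feature_table()] (only its row count is used).
#' @param labels A [label_vector()] or integer vector.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(table, labels, spec = split_spec()) {
  y <- as_labels(labels)
  n <- if (inherits(table, "feature_table")) nrow(table$values) else nrow(table)
  stopifnot(length(y) == n)
  set.seed(spec$seed)
  if (!spec$stratified) {
    tr <- sort(sample.int(n, round(spec$train_fraction * n)))
    return(list(train = tr, test = setdiff(seq_len(n), tr)))
  }
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) == 1) {
      warning("class ", cl, " has a single member; assigned to train")
      train <- c(train, idx)
      next
    }
    m <- max(1L, round(spec$train_fraction * length(idx)))
    m <- min(m, length(idx) - 1L)   # keep at least one test member
    train <- c(train, sample(idx, m))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

subset_table <- function(table, rows) {
  feature_table(table$values[rows, , drop = FALSE], table$meta,
                table$mask[rows, , drop = FALSE])
}

# Micro-averaged one-vs-rest ROC AUC: labels are one-hot binarised, scores
# flattened, and a single binary AUC computed on the pooled vectors.
micro_auc <- function(y_true, scores, classes) {
  onehot <- outer(y_true, classes, "==") * 1
  resp <- as.vector(onehot)
  pred <- as.vector(as.matrix(scores))
  as.numeric(pROC::auc(resp, pred, quiet = TRUE, levels = c(0, 1),
                       direction = "<"))
}

#' Compute the full evaluation report
#'
#' Accuracy, one-vs-rest per-class precision/recall/F1 with supports,
#' macro (unweighted) and weighted (support-weighted) averages, the
#' confusion matrix (rows = true classes), and — when per-class scores are
#' supplied — the micro-averaged one-vs-rest ROC AUC. Classes with zero
#' predicted (or true) positives score 0 for the affected metric, with a
#' warning.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param scores Optional rows-by-classes score matrix (any monotone
#'   ranking; probabilities or negative code distances).
#' @param classes Class set; defaults to the union of labels (and score
#'   columns).
#' @return An `evaluation_report`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(classes)) {
    classes <- sort(unique(c(y_true, y_pred)))
    if (!is.null(scores) && !is.null(colnames(scores)))
      classes <- sort(unique(c(classes, as.integer(colnames(scores)))))
  }
  conf <- table(factor(y_true, levels = classes),
                factor(y_pred, levels = classes))
  conf <- matrix(as.numeric(conf), length(classes), length(classes),
                 dimnames = list(true = classes, pred = classes))
  tp <- diag(conf)
  pred_pos <- colSums(conf)
  support <- rowSums(conf)
  if (any(pred_pos == 0 & support > 0))
    warning("class(es) with zero predicted positives; precision set to 0")
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(label = classes, precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(support), row.names = NULL)
  w <- support / sum(support)
  auc <- if (!is.null(scores)) micro_auc(y_true, scores, classes) else NA_real_
  structure(list(accuracy = sum(tp) / sum(conf),
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 weighted_precision = sum(w * precision),
                 weighted_recall = sum(w * recall),
                 weighted_f1 = sum(w * f1),
                 micro_auc = auc,
                 per_class = per_class,
                 confusion = conf,
                 n = length(y_true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d  accuracy %.4f  macro-F1 %.4f  micro-AUC %s\n",
              x$n, x$accuracy, x$macro_f1,
              ifelse(is.na(x$micro_auc), "-", sprintf("%.4f", x$micro_auc))))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

fit_and_score <- function(spec, ecoc, Xtr, ytr, Xte, code_scheme = "exhaustive") {
  if (ecoc) {
    code <- build_code_matrix(length(unique(ytr)), code_scheme,
                              seed = spec$seed,
                              classes = sort(unique(ytr)))
    model <- ecoc_fit(spec, Xtr, ytr, code)
    ecoc_predict(model, Xte)
  } else {
    native_fit_predict(spec, Xtr, ytr, Xte)
  }
}

#' Stratified k-fold cross-validation of a learner
#'
#' Stratified fold assignment; per fold the model is fitted on the
#' remaining folds and evaluated on the held-out fold. Folds are reduced
#' with a warning when the rarest class has fewer members than requested
#' folds.
#'
#' @param spec A [learner_spec()].
#' @param ecoc Wrap the learner in ECOC?
#' @param table A complete [feature_table()] or matrix.
#' @param labels Training labels.
#' @param folds Fold count (default 10).
#' @param seed Integer seed.
#' @param code_scheme Code-matrix scheme when `ecoc` is TRUE.
#' @return A `cv_result`: `fold_reports` (list of `evaluation_report`s),
#'   `mean_report` (scalar metrics averaged over folds), `mean_confusion`
#'   (elementwise mean), `folds`.
#' @export
cross_validate <- function(spec, ecoc, table, labels, folds = 10, seed = 1L,
                           code_scheme = "exhaustive") {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- as_labels(labels)
  stopifnot(folds >= 2)
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning("rarest class smaller than fold count; folds reduced to ", folds)
  }
  fold <- stratified_folds(y, folds, seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    pred <- fit_and_score(spec, ecoc, X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], code_scheme)
    reports[[f]] <- compute_metrics(y[!tr], pred$labels, pred$scores,
                                    classes = sort(unique(y)))
  }
  scalar <- c("accuracy", "macro_precision", "macro_recall", "macro_f1",
              "weighted_precision", "weighted_recall", "weighted_f1",
              "micro_auc")
  mean_report <- lapply(scalar, function(m)
    mean(vapply(reports, function(r) r[[m]], numeric(1))))
  names(mean_report) <- scalar
  mean_conf <- Reduce(`+`, lapply(reports, `[[`, "confusion")) / folds
  structure(list(fold_reports = reports, mean_report = mean_report,
                 mean_confusion = mean_conf, folds = folds),
            class = "cv_result")
}

#' Compare base learners with and without ECOC wrapping
#'
#' Fits each requested learner on the training partition and evaluates on
#' the test partition, natively (where the family supports multiclass) and
#' ECOC-wrapped, reporting accuracy, macro-F1 and micro-AUC side by side
#' with their deltas. Binary-only max-margin families appear ECOC-only.
#'
#' @param specs List of [learner_spec()]s.
#' @param train,test [feature_table()]s or matrices.
#' @param train_labels,test_labels Labels for the two partitions.
#' @param code_scheme Code-matrix scheme.
#' @return Data frame, one row per family, with `*_native`, `*_ecoc` and
#'   `*_delta` columns (native columns `NA` for binary-only families on
#'   multiclass data).
#' @export
compare_models <- function(specs, train, train_labels, test, test_labels,
                           code_scheme = "exhaustive") {
  stopifnot(length(specs) >= 1)
  ytr <- as_labels(train_labels)
  yte <- as_labels(test_labels)
  Xtr <- if (inherits(train, "feature_table")) train$values else as.matrix(train)
  Xte <- if (inherits(test, "feature_table")) test$values else as.matrix(test)
  multiclass <- length(unique(ytr)) > 2
  rows <- lapply(specs, function(sp) {
    native <- if (!multiclass || learner_is_multiclass(sp)) {
      pred <- fit_and_score(sp, FALSE, Xtr, ytr, Xte, code_scheme)
      compute_metrics(yte, pred$labels, pred$scores, sort(unique(ytr)))
    } else NULL
    pred <- fit_and_score(sp, TRUE, Xtr, ytr, Xte, code_scheme)
    ec <- compute_metrics(yte, pred$labels, pred$scores, sort(unique(ytr)))
    grab <- function(r, m) if (is.null(r)) NA_real_ else r[[m]]
    data.frame(family = sp$family,
               accuracy_native = grab(native, "accuracy"),
               accuracy_ecoc = ec$accuracy,
               macro_f1_native = grab(native, "macro_f1"),
               macro_f1_ecoc = ec$macro_f1,
               micro_auc_native = grab(native, "micro_auc"),
               micro_auc_ecoc = ec$micro_auc)
  })
  out <- do.call(rbind, rows)
  for (m in c("accuracy", "macro_f1", "micro_auc"))
    out[[paste0(m, "_delta")]] <- out[[paste0(m, "_ecoc")]] -
      out[[paste0(m, "_native")]]
  out
}

#' Events per predictor (EPP)
#'
#' Sample-size adequacy heuristic for prediction models:
#' `n_patients * follow_up_years * event_rate / n_predictors`; values of at
#' least 10 are conventionally considered adequate.
#'
#' @param n_patients Cohort size.
#' @param follow_up_years Follow-up duration in years.
#' @param event_rate Event (outcome) rate as a proportion.
#' @param n_predictors Number of modelled predictors.
#' @return The EPP value.
#' @export
epp <- function(n_patients, follow_up_years, event_rate, n_predictors) {
  stopifnot(n_patients > 0, follow_up_years > 0, n_predictors > 0,
            event_rate >= 0, event_rate <= 1)
  n_patients * follow_up_years * event_rate / n_predictors
}
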