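code_matrix_ok <- function(M) {
  if (any(duplicated(M))) return("duplicate class rows")
  cs <- colSums(M)
  if (any(cs == 0) || any(cs == nrow(M))) return("constant column")
  for (a in seq_len(ncol(M) - 1)) for (b in (a + 1):ncol(M)) {
    if (all(M[, a] == M[, b])) return("identical columns")
    if (all(M[, a] == 1 - M[, b])) return("complementary columns")
  }
  NULL
}

#' Build an ECOC code matrix
#'
#' Each class is encoded as a row of M bits; each column defines one binary
#' subproblem. The exhaustive scheme enumerates every non-degenerate
#' bipartition of the classes up to complement, giving `2^(C-1) - 1`
#' columns; the random-dense scheme samples valid columns and keeps, over
#' several trials, the matrix maximising the minimum pairwise row Hamming
#' distance.
#'
#' @param n_classes Number of classes (>= 2).
#' @param scheme `"exhaustive"` or `"random_dense"`.
#' @param M Column count for the random scheme (default `10 * ceil(log2 C)`,
#'   capped at `2^(C-1) - 1`); must be at least `ceil(log2 C)`.
#' @param seed Integer seed (random scheme).
#' @param classes Optional class labels for the rows (default `0:(C-1)`).
#' @return A `code_matrix`: classes-by-M binary matrix with row names the
#'   class labels and the scheme stored as an attribute.
#' @export
build_code_matrix <- function(n_classes, scheme = c("exhaustive", "random_dense"),
                              M = NULL, seed = 1L, classes = NULL) {
  scheme <- match.arg(scheme)
  C <- as.integer(n_classes)
  if (C < 2) stop("n_classes must be >= 2")
  if (is.null(classes)) classes <- 0:(C - 1)
  if (scheme == "exhaustive") {
    Mx <- 2^(C - 1) - 1
    # column j encodes the subset with binary expansion j over classes 2..C
    mat <- matrix(0L, C, Mx)
    for (j in seq_len(Mx))
      mat[2:C, j] <- as.integer(intToBits(j))[seq_len(C - 1)]
  } else {
    if (is.null(M)) M <- min(2^(C - 1) - 1, 10L * as.integer(ceiling(log2(C))))
    if (M < ceiling(log2(C))) stop("M must be at least ceil(log2(n_classes))")
    set.seed(seed)
    best <- NULL; best_sep <- -1
    for (trial in 1:50) {
      mat <- NULL; tries <- 0
      while (is.null(mat) && tries < 200) {
        tries <- tries + 1
        cand <- matrix(sample(0:1, C * M, replace = TRUE), C, M)
        if (is.null(code_matrix_ok(cand))) mat <- cand
      }
      if (is.null(mat)) next
      dH <- as.matrix(stats::dist(mat, method = "manhattan"))
      sep <- min(dH[upper.tri(dH)])
      if (sep > best_sep) { best_sep <- sep; best <- mat }
    }
    if (is.null(best))
      stop("could not sample a valid random_dense code; increase M")
    mat <- best
  }
  err <- code_matrix_ok(mat)
  if (!is.null(err)) stop("invalid code matrix: ", err)
  rownames(mat) <- classes
  structure(mat, scheme = scheme, class = c("code_matrix", class(mat)))
}

#' Decode ECOC bit predictions to class labels and scores
#'
#' Hard decoding by minimum Hamming distance between the thresholded bit
#' vector and each class row; ties are broken by the smaller Euclidean
#' distance between the raw bit probabilities and the class row, then by
#' the lower class index. The per-class score is the negative of
#' `hamming + euclidean / (sqrt(M) + 1)`, a continuous quantity whose
#' argmax always equals the decoded label.
#'
#' @param probs Rows-by-M matrix of bit probabilities (hard 0/1 bits are
#'   fine).
#' @param code A `code_matrix`.
#' @return List with `labels` (decoded class labels) and `scores`
#'   (rows-by-classes matrix).
#' @export
ecoc_decode <- function(probs, code) {
  probs <- as.matrix(probs)
  if (ncol(probs) != ncol(code))
    stop("probs has ", ncol(probs), " bits but the code has ", ncol(code))
  bits <- (probs >= 0.5) * 1
  C <- nrow(code)
  ham <- sapply(seq_len(C), function(c)
    rowSums(bits != matrix(code[c, ], nrow(bits), ncol(code), byrow = TRUE)))
  soft <- sapply(seq_len(C), function(c)
    sqrt(rowSums((probs - matrix(code[c, ], nrow(probs), ncol(code),
                                 byrow = TRUE))^2)))
  ham <- matrix(ham, ncol = C); soft <- matrix(soft, ncol = C)
  combined <- ham + soft / (sqrt(ncol(code)) + 1)
  scores <- -combined
  colnames(scores) <- rownames(code)
  cls <- rownames(code)[max.col(scores, ties.method = "first")]
  labels <- if (!anyNA(suppressWarnings(as.integer(rownames(code)))))
    as.integer(cls) else cls
  list(labels = labels, scores = scores)
}

#' Specify a base learner
#'
#' Families: `"majority"` (modal-class baseline), `"rf"` (random forest),
#' `"xgb"` (depth-wise gradient-boosted trees), `"xgb_hist"` (leaf-wise
#' histogram gradient boosting), `"svc_linear"` (linear support vector
#' classifier) and `"svm_poly"` (polynomial-kernel SVM). The two
#' max-margin families are binary-only and require ECOC wrapping for more
#' than two classes.
#'
#' @param family Registry name.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(family = c("rf", "xgb", "xgb_hist", "svc_linear",
                                    "svm_poly", "majority"),
                         params = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "learner_spec")
}

learner_is_multiclass <- function(spec)
  spec$family %in% c("rf", "xgb", "xgb_hist", "majority")

# Fit any registry family on labels `y` (any number of classes the family
# supports); returns an object predictable via learner_predict.
learner_fit <- function(spec, X, y) {
  y <- as.integer(y)
  classes <- sort(unique(y))
  set.seed(spec$seed)
  model <- switch(spec$family,
    majority = list(freq = table(factor(y, levels = classes)) / length(y)),
    rf = {
      p <- utils::modifyList(list(ntree = 200), spec$params)
      randomForest::randomForest(x = X, y = factor(y, levels = classes),
                                 ntree = p$ntree)
    },
    xgb = xgb_fit_multiclass(X, y, spec$seed,
                             nrounds = spec$params$nrounds %||% 100,
                             params = spec$params[setdiff(names(spec$params),
                                                          "nrounds")]),
    xgb_hist = xgb_fit_multiclass(
      X, y, spec$seed, nrounds = spec$params$nrounds %||% 100,
      params = utils::modifyList(
        list(tree_method = "hist", grow_policy = "lossguide",
             max_leaves = 31, max_depth = 0),
        spec$params[setdiff(names(spec$params), "nrounds")])),
    svc_linear = ,
    svm_poly = {
      if (length(classes) > 2)
        stop("family '", spec$family, "' is binary-only; wrap it in ECOC ",
             "for multiclass prediction")
      p <- utils::modifyList(
        if (spec$family == "svc_linear") list(kernel = "linear", cost = 1)
        else list(kernel = "polynomial", degree = 3, cost = 1, coef0 = 1),
        spec$params)
      do.call(e1071::svm,
              c(list(x = X, y = factor(y, levels = classes),
                     probability = TRUE), p))
    },
    stop("unknown learner family: ", spec$family))
  structure(list(spec = spec, model = model, classes = classes),
            class = "fitted_learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-class probability matrix, columns ordered by `fit$classes`.
learner_predict <- function(fit, X) {
  classes <- fit$classes
  p <- switch(fit$spec$family,
    majority = matrix(as.numeric(fit$model$freq), nrow(X), length(classes),
                      byrow = TRUE),
    rf = {
      pr <- predict(fit$model, X, type = "prob")
      pr[, as.character(classes), drop = FALSE]
    },
    xgb = ,
    xgb_hist = xgb_predict_prob(fit$model, X),
    svc_linear = ,
    svm_poly = {
      pr <- attr(predict(fit$model, X, probability = TRUE), "probabilities")
      pr[, as.character(classes), drop = FALSE]
    })
  p <- matrix(as.numeric(p), nrow(X), length(classes))
  colnames(p) <- classes
  p
}

#' Fit an ECOC-wrapped classifier
#'
#' Trains one binary model per code-matrix column: the column's bit pattern
#' relabels every training sample as positive (bit 1) or negative (bit 0),
#' and the base learner is fitted on the full training set with those
#' targets.
#'
#' @param spec A [learner_spec()].
#' @param table A complete [feature_table()] or numeric matrix.
#' @param labels Labels drawn from the code matrix's class set.
#' @param code A [build_code_matrix()] result; defaults to the exhaustive
#'   code over the observed classes.
#' @return An `ecoc_model`.
#' @export
ecoc_fit <- function(spec, table, labels, code = NULL) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  y <- as_labels(labels)
  classes <- sort(unique(y))
  if (is.null(code))
    code <- build_code_matrix(length(classes), "exhaustive", classes = classes)
  if (!all(y %in% as.integer(rownames(code))))
    stop("labels outside the code matrix's class set")
  ri <- match(y, as.integer(rownames(code)))
  bit_models <- vector("list", ncol(code))
  for (m in seq_len(ncol(code))) {
    y_bit <- code[ri, m]
    if (length(unique(y_bit)) < 2)
      stop("bit ", m, " has single-class targets; invalid code for these labels")
    bspec <- spec
    bspec$seed <- spec$seed * 1000L + m
    bit_models[[m]] <- learner_fit(bspec, X, y_bit)
  }
  structure(list(code = code, bit_models = bit_models, spec = spec,
                 fingerprint = data_fingerprint(X)),
            class = "ecoc_model")
}

#' Predict with an ECOC model
#'
#' Collects the per-bit probability of bit value 1 from every binary model
#' and decodes by minimum distance (see [ecoc_decode()]).
#'
#' @param model An `ecoc_model`.
#' @param table A [feature_table()] or numeric matrix of prediction rows.
#' @return List with `labels` and per-class `scores`.
#' @export
ecoc_predict <- function(model, table) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (any(!is.finite(X))) stop("prediction rows contain non-finite values")
  P <- sapply(model$bit_models, function(bm) learner_predict(bm, X)[, "1"])
  P <- matrix(P, nrow = nrow(X))
  ecoc_decode(P, model$code)
}

#' Fit and predict a base learner natively (no ECOC)
#'
#' Standard multiclass fit/predict for the tree families (and the majority
#' baseline); the max-margin families are binary-only and raise a
#' configuration error for more than two classes.
#'
#' @param spec A [learner_spec()].
#' @param train,test [feature_table()]s or matrices.
#' @param train_labels Labels for the training rows.
#' @return List with `labels` and per-class probability `scores`.
#' @export
native_fit_predict <- function(spec, train, train_labels, test) {
  Xtr <- if (inherits(train, "feature_table")) train$values else as.matrix(train)
  Xte <- if (inherits(test, "feature_table")) test$values else as.matrix(test)
  y <- as_labels(train_labels)
  fit <- learner_fit(spec, Xtr, y)
  p <- learner_predict(fit, Xte)
  list(labels = fit$classes[max.col(p, ties.method = "first")], scores = p)
}
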