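#' Settings for the chained feed-forward-network filler
#'
#' A feed-forward network with skip-layer (direct input-to-output)
#' connections and an optional hidden layer. Skip connections make linear
#' structure in the data exactly representable, so with `size = 0` (the
#' default) the filler is a fully converged linear perceptron; positive
#' widths add logistic hidden units for cohorts with genuinely nonlinear
#' feature relations, at the price of higher variance when the prediction
#' rows carry first-stage fill noise. Any regressor honouring the chaining
#' contract could stand here.
#'
#' @param size Hidden-layer width (0 = skip-layer connections only).
#' @param decay Weight decay.
#' @param maxit Maximum BFGS iterations.
#' @param min_train Minimum observed rows needed to train a per-feature
#'   model; features below it fall back to mean filling with a warning.
#' @param seed Integer seed for weight initialisation.
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(size = 0, decay = 1e-4, maxit = 400, min_train = 10,
                     seed = 1L) {
  structure(list(size = size, decay = decay, maxit = maxit,
                 min_train = min_train, seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Plan which filler handles which feature
#'
#' Low-missingness (not-easy tier) features are filled by K-nearest
#' neighbours using the always-observed columns as the distance space;
#' high-missingness (easy tier) features are then filled by chained MLP
#' prediction, each newly completed feature joining the predictor pool of
#' the next.
#'
#' @param table A [feature_table()].
#' @param k Neighbour count for the KNN stage.
#' @param mlp An [mlp_spec()].
#' @return A `fill_plan` list with `knn_features`, `mlp_features`, `k`,
#'   `mlp`.
#' @export
fill_plan <- function(table, k = 5, mlp = mlp_spec()) {
  stopifnot(inherits(table, "feature_table"))
  structure(list(knn_features = table$meta$name[table$meta$tier == "not_easy"],
                 mlp_features = table$meta$name[table$meta$tier == "easy"],
                 k = as.integer(k), mlp = mlp),
            class = "fill_plan")
}

new_fill_result <- function(table, provenance, method) {
  structure(list(table = table, provenance = provenance, method = method),
            class = "fill_result")
}

#' @export
print.fill_result <- function(x, ...) {
  cat("<fill_result> method:", x$method, "\n")
  print(table(x$provenance))
  invisible(x)
}

empty_provenance <- function(table) {
  pr <- matrix("observed", nrow(table$values), ncol(table$values),
               dimnames = dimnames(table$values))
  pr[table$mask] <- "missing"
  pr
}

#' Fill missing values with column means
#'
#' Continuous features receive the observed column mean; categorical
#' features receive the observed mode (ties broken toward the lowest code).
#'
#' @param table A [feature_table()].
#' @return A `fill_result` whose table is complete on fillable tiers.
#' @export
mean_fill <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  pr <- empty_provenance(table)
  for (j in which(colSums(table$mask) > 0)) {
    obs <- table$values[!table$mask[, j], j]
    if (!length(obs))
      stop("column '", table$meta$name[j], "' has no observed values to fill from")
    fill <- if (table$meta$kind[j] == "categorical") mode_code(obs) else mean(obs)
    miss <- table$mask[, j]
    table$values[miss, j] <- fill
    table$mask[miss, j] <- FALSE
    pr[miss, j] <- "mean"
  }
  new_fill_result(table, pr, "mean")
}

# Neighbour order (by Euclidean distance on z-scored always-observed
# features, ties by row index) for each query row. Returns an n x n matrix
# of row indices, each row sorted nearest-first, self excluded.
knn_reference_order <- function(table, query_rows) {
  nm <- tier_cols(table, "no_missing")
  if (!length(nm)) stop("knn_fill requires at least one no_missing feature")
  Z <- apply_zscore(table$values[, nm, drop = FALSE],
                    zscore_stats(table$values[, nm, drop = FALSE],
                                 table$mask[, nm, drop = FALSE]))
  n <- nrow(Z)
  ord <- matrix(0L, length(query_rows), n - 1)
  for (qi in seq_along(query_rows)) {
    i <- query_rows[qi]
    d <- sqrt(colSums((t(Z) - Z[i, ])^2))
    o <- order(d, seq_len(n))     # ties broken by row index
    ord[qi, ] <- o[o != i]
  }
  ord
}

#' Fill features by K-nearest-neighbour averaging
#'
#' For every missing entry of the listed features, the fill value is the
#' unweighted mean (majority vote for categoricals, ties toward the lowest
#' code) over the `k` rows nearest in Euclidean distance computed on the
#' z-scored always-observed columns — the vertical (same feature, different
#' cases) information of the table.
#'
#' @param table A [feature_table()].
#' @param features Feature names to fill; defaults to every fillable feature
#'   with missing entries.
#' @param k Neighbour count; clamped with a warning when it exceeds the
#'   reference pool.
#' @return A `fill_result`.
#' @export
knn_fill <- function(table, features = NULL, k = 5) {
  stopifnot(inherits(table, "feature_table"), k >= 1)
  if (is.null(features))
    features <- table$meta$name[fillable_cols(table)]
  cols <- match(features, table$meta$name)
  if (anyNA(cols)) stop("unknown feature(s): ",
                        paste(features[is.na(cols)], collapse = ", "))
  cols <- cols[colSums(table$mask[, cols, drop = FALSE]) > 0]
  pr <- empty_provenance(table)
  if (!length(cols)) return(new_fill_result(table, pr, "knn"))

  query_rows <- which(rowSums(table$mask[, cols, drop = FALSE]) > 0)
  ord <- knn_reference_order(table, query_rows)
  clamped <- FALSE
  for (j in cols) {
    miss_rows <- which(table$mask[, j])
    for (i in miss_rows) {
      cand <- ord[match(i, query_rows), ]
      cand <- cand[!table$mask[cand, j]]       # reference rows observe target
      if (!length(cand))
        stop("no reference rows observe '", table$meta$name[j], "'")
      kk <- k
      if (kk > length(cand)) { kk <- length(cand); clamped <- TRUE }
      nb <- table$values[cand[seq_len(kk)], j]
      table$values[i, j] <- if (table$meta$kind[j] == "categorical")
        mode_code(nb) else mean(nb)
      table$mask[i, j] <- FALSE
      pr[i, j] <- "knn"
    }
  }
  if (clamped) warning("k exceeded the reference pool for some entries; clamped")
  new_fill_result(table, pr, "knn")
}

# Fit the per-feature MLP and predict at the missing rows. Categorical
# targets use a softmax head; predictions snap to legal codes.
mlp_fill_one <- function(Xtr, ytr, Xmiss, kind, spec, codes) {
  nw <- (ncol(Xtr) + 1) * spec$size + spec$size + ncol(Xtr) + 1
  if (kind == "categorical") {
    lev <- sort(unique(ytr))
    if (length(lev) == 1) return(rep(lev, nrow(Xmiss)))
    Y <- nnet::class.ind(factor(ytr, levels = lev))
    fit <- nnet::nnet(Xtr, Y, size = spec$size, softmax = TRUE,
                      skip = TRUE, decay = spec$decay, maxit = spec$maxit,
                      trace = FALSE, MaxNWts = max(2000, 5 * nw * length(lev)))
    pr <- predict(fit, Xmiss)
    lev[max.col(pr, ties.method = "first")]
  } else {
    fit <- nnet::nnet(Xtr, ytr, size = spec$size, linout = TRUE,
                      skip = TRUE, decay = spec$decay, maxit = spec$maxit,
                      trace = FALSE, MaxNWts = max(2000, 5 * nw))
    as.numeric(predict(fit, Xmiss))
  }
}

#' Chained (iterative) MLP filling of high-missingness features
#'
#' Features are processed in ascending order of missingness. For the i-th
#' feature a feed-forward network is trained on the rows where it is
#' observed, with predictors the always-observed columns, the (complete)
#' KNN-tier columns and every previously filled feature; its predictions
#' fill the missing rows and the completed column then joins the predictor
#' pool — the horizontal (same case, different features) information of the
#' table.
#'
#' @param table A [feature_table()] whose not-easy tier is complete.
#' @param features Feature names to fill; defaults to the easy tier.
#' @param spec An [mlp_spec()].
#' @return A `fill_result`.
#' @export
mlp_iterative_fill <- function(table, features = NULL, spec = mlp_spec()) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(features))
    features <- table$meta$name[table$meta$tier == "easy"]
  cols <- match(features, table$meta$name)
  if (anyNA(cols)) stop("unknown feature(s): ",
                        paste(features[is.na(cols)], collapse = ", "))
  base_cols <- tier_cols(table, c("no_missing", "not_easy"))
  if (any(table$mask[, setdiff(base_cols, cols)]))
    stop("mlp_iterative_fill requires complete no_missing and not_easy tiers")

  pr <- empty_provenance(table)
  miss_count <- colSums(table$mask[, cols, drop = FALSE])
  cols <- cols[order(miss_count, cols)]        # best-supported first
  pool <- setdiff(base_cols, cols)

  for (step in seq_along(cols)) {
    j <- cols[step]
    miss <- table$mask[, j]
    if (any(miss)) {
      obs <- !miss
      if (sum(obs) < spec$min_train) {
        warning("feature '", table$meta$name[j],
                "' has too few observed rows; falling back to mean fill")
        fill <- if (table$meta$kind[j] == "categorical")
          mode_code(table$values[obs, j]) else mean(table$values[obs, j])
        table$values[miss, j] <- fill
        pr[miss, j] <- "mean"
      } else {
        Xall <- table$values[, pool, drop = FALSE]
        Z <- apply_zscore(Xall, zscore_stats(Xall, matrix(FALSE, nrow(Xall),
                                                          ncol(Xall))))
        set.seed(spec$seed + step)
        pred <- mlp_fill_one(Z[obs, , drop = FALSE], table$values[obs, j],
                             Z[miss, , drop = FALSE],
                             table$meta$kind[j], spec,
                             codes = table$values[obs, j])
        if (table$meta$kind[j] == "categorical")
          pred <- snap_to_codes(pred, table$values[obs, j])
        table$values[miss, j] <- pred
        pr[miss, j] <- "mlp"
      }
      table$mask[miss, j] <- FALSE
    }
    pool <- c(pool, j)                         # completed feature joins pool
  }
  new_fill_result(table, pr, "mlp")
}

#' Fused KNN-then-MLP filling
#'
#' Runs [knn_fill()] on the low-missingness tier, then [mlp_iterative_fill()]
#' on the high-missingness tier, so the neighbour-based stage exploits the
#' table's vertical information and the chained predictive stage its
#' horizontal information.
#'
#' @param table A [feature_table()].
#' @param plan A [fill_plan()]; defaults to the tier assignment of `table`.
#' @return A `fill_result` with per-entry provenance
#'   (`observed`/`knn`/`mlp`/`mean`).
#' @export
fused_fill <- function(table, plan = fill_plan(table)) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "fill_plan"))
  if (length(intersect(plan$knn_features, plan$mlp_features)))
    stop("fill plan assigns features to both stages")
  r1 <- knn_fill(table, plan$knn_features, plan$k)
  r2 <- mlp_iterative_fill(r1$table, plan$mlp_features, plan$mlp)
  pr <- r1$provenance
  upd <- r2$provenance != "observed" & r2$provenance != "missing"
  pr[upd] <- r2$provenance[upd]
  new_fill_result(r2$table, pr, "fused")
}

#' Evaluate a fill against ground truth by mean Euclidean distance
#'
#' For each deleted case, the Euclidean distance between the true and the
#' filled vector restricted to the filled features, computed on z-scored
#' features (statistics from the truth table) so the metric is
#' scale-invariant; the assessment is the mean across deleted cases.
#'
#' @param truth The complete ground-truth [feature_table()].
#' @param filled A `fill_result`.
#' @param deleted_cases Integer row indices that were deleted.
#' @param features Feature names entering the distance; defaults to every
#'   feature filled in at least one deleted case.
#' @return A `fill_assessment` list with `method` and `mean_distance`.
#' @export
evaluate_fill <- function(truth, filled, deleted_cases, features = NULL) {
  stopifnot(inherits(truth, "feature_table"), inherits(filled, "fill_result"))
  if (!length(deleted_cases)) stop("no deleted cases to evaluate")
  pr <- filled$provenance[deleted_cases, , drop = FALSE]
  if (is.null(features)) {
    features <- colnames(pr)[colSums(pr != "observed") > 0]
  }
  cols <- match(features, truth$meta$name)
  if (anyNA(cols)) stop("unknown feature(s) in evaluation")
  st <- zscore_stats(truth$values, truth$mask)
  zt <- apply_zscore(truth$values[deleted_cases, cols, drop = FALSE],
                     list(mean = st$mean[cols], sd = st$sd[cols]))
  zf <- apply_zscore(filled$table$values[deleted_cases, cols, drop = FALSE],
                     list(mean = st$mean[cols], sd = st$sd[cols]))
  d <- sqrt(rowSums((zt - zf)^2))
  structure(list(method = filled$method, mean_distance = mean(d),
                 per_case = d),
            class = "fill_assessment")
}

#' Benchmark the three fillers under worst-case deletion
#'
#' Per seed, deletes a case block via [inject_missingness()] and fills the
#' same masked table with mean filling, KNN-only filling and the fused
#' KNN-then-MLP method, scoring each with [evaluate_fill()]; reports the
#' per-method mean distance averaged over seeds.
#'
#' @param truth A complete [feature_table()].
#' @param case_fraction Deleted-case fraction (default 0.10, the worst-case
#'   benchmark).
#' @param seeds Integer vector of seeds.
#' @param k KNN neighbour count.
#' @param mlp An [mlp_spec()].
#' @return Data frame with columns `method` (`mean`, `knn`, `fused`, in that
#'   fixed order) and `mean_distance`; per-seed distances in
#'   `attr(, "per_seed")`.
#' @export
compare_fill_methods <- function(truth, case_fraction = 0.10, seeds = 1:20,
                                 k = 5, mlp = mlp_spec()) {
  stopifnot(length(seeds) >= 1)
  methods <- c("mean", "knn", "fused")
  per_seed <- matrix(NA_real_, length(seeds), 3,
                     dimnames = list(NULL, methods))
  for (si in seq_along(seeds)) {
    inj <- inject_missingness(truth, case_fraction, seed = seeds[si])
    plan <- fill_plan(inj$table, k = k,
                      mlp = mlp_spec(size = mlp$size, decay = mlp$decay,
                                     maxit = mlp$maxit,
                                     min_train = mlp$min_train,
                                     seed = seeds[si]))
    fills <- list(mean = mean_fill(inj$table),
                  knn = knn_fill(inj$table, k = k),
                  fused = fused_fill(inj$table, plan))
    for (m in methods)
      per_seed[si, m] <- evaluate_fill(truth, fills[[m]],
                                       inj$deleted_rows)$mean_distance
  }
  out <- data.frame(method = methods,
                    mean_distance = colMeans(per_seed),
                    row.names = NULL)
  attr(out, "per_seed") <- per_seed
  out
}
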