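test_that("mean fill uses the observed mean and the categorical mode", {
  meta <- data.frame(name = c("d", "x", "c"),
                     tier = c("no_missing", "not_easy", "easy"),
                     kind = c("continuous", "continuous", "categorical"))
  vals <- cbind(d = 1:4, x = c(1, 3, NA, NA), c = c(0, 0, 1, NA))
  res <- mean_fill(feature_table(vals, meta))
  expect_equal(unname(res$table$values[3:4, "x"]), c(2, 2))
  expect_equal(unname(res$table$values[4, "c"]), 0)       # mode of {0,0,1}
  expect_identical(unname(res$provenance[3, "x"]), "mean")
  # no missing entries -> identity
  complete <- feature_table(cbind(d = 1:4, x = 1:4, c = c(0, 1, 0, 1)), meta)
  expect_identical(mean_fill(complete)$table$values, complete$values)
  # fully-missing column is an error naming the column
  vals2 <- vals; vals2[, "x"] <- NA
  expect_error(mean_fill(feature_table(vals2, meta)), "'x'")
})

test_that("knn fill matches a hand-computed nearest-neighbour oracle", {
  # rows 1 and 2 are near-duplicates in distance space; brute-force check
  tab <- tiny_knn_table()
  res <- knn_fill(tab, "t", k = 1)
  expect_equal(unname(res$table$values[1, "t"]), 3)       # copies its nearest row
  # k = 2: mean of the two nearest rows by explicit distance computation
  res2 <- knn_fill(tab, "t", k = 2)
  Z <- scale(tab$values[, c("d1", "d2")])
  d <- sqrt(colSums((t(Z) - Z[1, ])^2))[-1]
  nb <- order(d)[1:2] + 1
  expect_equal(unname(res2$table$values[1, "t"]), mean(tab$values[nb, "t"]))
})

test_that("knn fill with the full reference pool equals mean fill", {
  co <- small_cohort(seed = 5, n = 40, cat_fraction = 0)
  inj <- inject_missingness(co$table, 0.2, seed = 1)
  expect_warning(knn_fill(inj$table, k = 1e6), "clamped")
  mf <- mean_fill(inj$table)
  expect_equal(suppressWarnings(knn_fill(inj$table, k = 1e6))$table$values,
               mf$table$values, tolerance = 1e-12)
})

test_that("fillers preserve observed entries bit-exactly and complete the table", {
  co <- small_cohort(seed = 6, n = 80)
  inj <- inject_missingness(co$table, 0.15, seed = 2)
  obs <- !inj$table$mask
  for (res in list(mean_fill(inj$table), knn_fill(inj$table, k = 3),
                   fused_fill(inj$table))) {
    expect_identical(res$table$values[obs], co$table$values[obs])
    expect_false(any(res$table$mask))
  }
})

test_that("chained filling reconstructs noiseless rank-1 data", {
  co <- generate_cohort(generator_config(n_samples = 120,
                                         n_features_per_tier = c(4, 4, 6),
                                         latent_rank = 1, noise_sd = 0,
                                         cat_fraction = 0, seed = 8))
  inj <- inject_missingness(co$table, 0.10, seed = 3)
  # not_easy complete via knn first; exact linear relation is learnable
  res <- fused_fill(inj$table)
  ez <- co$table$meta$tier == "easy"
  err <- abs(res$table$values[inj$deleted_rows, ez] -
               co$table$values[inj$deleted_rows, ez])
  sdz <- apply(co$table$values[, ez], 2, sd)
  expect_lt(max(t(t(err) / sdz)), 0.05)
})

test_that("the chained predictor pool grows by one feature per step", {
  co <- small_cohort(seed = 9, n = 60, tiers = c(4, 3, 5), cat_fraction = 0)
  masked <- inject_tiered_missingness(co$table, c(0, 0, 0.3), seed = 1)
  # trace nnet training dimensionality via the mlp stage internals:
  # feature i is trained on base + (i - 1) previously filled columns
  calls <- integer(0)
  trace_fill <- function(table) {
    env <- environment(mlp_iterative_fill)
    local_mocked_bindings(
      mlp_fill_one = function(Xtr, ytr, Xmiss, kind, spec, codes) {
        calls <<- c(calls, ncol(Xtr))
        rep(mean(ytr), nrow(Xmiss))
      },
      .package = "hbpredict"
    )
    mlp_iterative_fill(table)
  }
  trace_fill(masked)
  miss_feats <- sum(colSums(masked$mask) > 0)
  expect_length(calls, miss_feats)
  expect_identical(diff(calls), rep(1L, miss_feats - 1))
})

test_that("stage-restricted tables make fused filling collapse to one stage", {
  co <- small_cohort(seed = 10, n = 60, cat_fraction = 0)
  ne <- co$table$meta$tier == "not_easy"
  ez <- co$table$meta$tier == "easy"
  # only not_easy missing -> identical to knn alone
  t1 <- co$table
  t1$mask[1:5, which(ne)[1:3]] <- TRUE
  t1$values[1:5, which(ne)[1:3]] <- NA
  expect_identical(fused_fill(t1)$table$values,
                   knn_fill(t1, k = 5)$table$values)
  # only easy missing -> identical to the chained mlp alone
  t2 <- co$table
  t2$mask[1:5, which(ez)[1:3]] <- TRUE
  t2$values[1:5, which(ez)[1:3]] <- NA
  expect_identical(fused_fill(t2)$table$values,
                   mlp_iterative_fill(t2)$table$values)
})

test_that("fill evaluation is a mean of per-case z-scored distances", {
  meta <- data.frame(name = c("d", "x"), tier = c("no_missing", "not_easy"),
                     kind = "continuous")
  truth <- feature_table(cbind(d = 1:6, x = c(0, 1, 2, 3, 4, 5)), meta)
  masked <- truth
  masked$mask[1:2, "x"] <- TRUE
  masked$values[1:2, "x"] <- NA
  filled <- mean_fill(masked)
  sdx <- sd(truth$values[, "x"])
  d1 <- abs(filled$table$values[1, "x"] - 0) / sdx
  d2 <- abs(filled$table$values[2, "x"] - 1) / sdx
  ass <- evaluate_fill(truth, filled, deleted_cases = 1:2)
  expect_equal(ass$mean_distance, unname((d1 + d2) / 2))
  # invariant to case order
  expect_equal(evaluate_fill(truth, filled, 2:1)$mean_distance,
               ass$mean_distance)
  # perfect fill -> 0
  perfect <- filled
  perfect$table$values[1:2, "x"] <- c(0, 1)
  expect_equal(evaluate_fill(truth, perfect, 1:2)$mean_distance, 0)
  expect_error(evaluate_fill(truth, filled, integer(0)), "no deleted")
})

test_that("method comparison reports the three fillers in fixed order", {
  co <- small_cohort(seed = 12, n = 80, tiers = c(6, 6, 4))
  cmp <- compare_fill_methods(co$table, 0.10, seeds = 1:2)
  expect_identical(cmp$method, c("mean", "knn", "fused"))
  expect_true(all(is.finite(cmp$mean_distance)))
  expect_identical(dim(attr(cmp, "per_seed")), c(2L, 3L))
})

test_that("no-signal data gives the learning fillers no advantage over the mean", {
  # latent rank = feature count and high noise: features are essentially
  # independent, so the column mean is the best constant fill and neither
  # neighbour averaging (noisier by sqrt(1 + 1/k)) nor chained regression
  # can systematically beat it
  co <- generate_cohort(generator_config(n_samples = 120,
                                         n_features_per_tier = c(6, 6, 6),
                                         latent_rank = 18, noise_sd = 3,
                                         cat_fraction = 0, class_sep = 0,
                                         seed = 13))
  cmp <- compare_fill_methods(co$table, 0.10, seeds = 1:8)
  d <- setNames(cmp$mean_distance, cmp$method)
  expect_gte(d[["knn"]], 0.98 * d[["mean"]])
  expect_gte(d[["fused"]], 0.98 * d[["mean"]])
})
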