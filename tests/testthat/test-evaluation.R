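test_that("stratified split follows exact per-class arithmetic", {
  y <- rep(0:2, times = c(50, 30, 20))
  tab <- matrix(rnorm(100 * 3), 100, 3)
  sp <- stratified_split(tab, y, split_spec(0.8, seed = 1))
  expect_identical(as.integer(table(y[sp$train])), c(40L, 24L, 16L))
  # disjoint and exhaustive
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  # two samples per class at 0.5 -> one each
  y2 <- rep(0:1, each = 2)
  sp2 <- stratified_split(matrix(0, 4, 1), y2, split_spec(0.5, seed = 2))
  expect_identical(as.integer(table(y2[sp2$train])), c(1L, 1L))
  # single-member class goes to train with a warning
  y3 <- c(0L, 0L, 0L, 0L, 1L)
  expect_warning(sp3 <- stratified_split(matrix(0, 5, 1), y3,
                                         split_spec(0.8, seed = 3)),
                 "single member")
  expect_true(5 %in% sp3$train)
})

test_that("metric stack matches hand-computed contingency arithmetic", {
  # 2x2 confusion {{40,10},{20,30}}
  y_true <- rep(c(0, 1), times = c(50, 50))
  y_pred <- c(rep(0, 40), rep(1, 10), rep(0, 20), rep(1, 30))
  r <- compute_metrics(y_true, y_pred)
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$per_class$precision, c(40 / 60, 30 / 40))
  expect_equal(r$per_class$recall, c(0.8, 0.6))
  expect_equal(r$per_class$f1,
               c(2 * (40 / 60) * 0.8 / (40 / 60 + 0.8),
                 2 * 0.75 * 0.6 / (0.75 + 0.6)))
  expect_equal(unname(rowSums(r$confusion)), c(50, 50))
  # macro / weighted identities hold on every report
  expect_equal(r$macro_f1, mean(r$per_class$f1))
  w <- r$per_class$support / sum(r$per_class$support)
  expect_equal(r$weighted_f1, sum(w * r$per_class$f1))
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  y <- rep(0:2, times = c(6, 5, 4))
  scores <- outer(y, 0:2, function(a, b) as.numeric(a == b))
  r <- compute_metrics(y, y, scores)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_f1, 1)
  expect_equal(r$micro_auc, 1)
  expect_true(all(r$confusion[upper.tri(r$confusion)] == 0))
  # constant classifier on a 60/30/10 mix: accuracy 0.6,
  # macro-F1 = mean(0.75, 0, 0) = 0.25
  y2 <- rep(0:2, times = c(60, 30, 10))
  expect_warning(r2 <- compute_metrics(y2, rep(0, 100)), "zero predicted")
  expect_equal(r2$accuracy, 0.6)
  expect_equal(r2$macro_f1, 0.25)
})

test_that("micro-AUC of random scores sits near one half", {
  set.seed(11)
  y <- sample(0:2, 600, replace = TRUE)
  scores <- matrix(runif(1800), 600, 3, dimnames = list(NULL, 0:2))
  r <- compute_metrics(y, sample(0:2, 600, TRUE), scores)
  expect_lt(abs(r$micro_auc - 0.5), 0.05)
})

test_that("cross-validation aggregates folds and is seed-deterministic", {
  pc <- three_blob_cohort(seed = 5, n_per = 30)
  cv <- suppressWarnings(
    cross_validate(learner_spec("majority"), ecoc = FALSE, pc$table,
                   pc$labels, folds = 5, seed = 3))
  expect_length(cv$fold_reports, 5)
  # fold validation sets partition the data: supports sum to n
  total <- sum(vapply(cv$fold_reports, function(r)
    sum(r$per_class$support), numeric(1)))
  expect_equal(total, 90)
  expect_equal(cv$mean_confusion,
               Reduce(`+`, lapply(cv$fold_reports, `[[`, "confusion")) / 5)
  cv2 <- suppressWarnings(
    cross_validate(learner_spec("majority"), ecoc = FALSE, pc$table,
                   pc$labels, folds = 5, seed = 3))
  expect_identical(cv$mean_report, cv2$mean_report)
  # rare class smaller than fold count reduces folds with a warning
  y <- c(rep(0L, 85), rep(1L, 3), rep(2L, 2))
  w <- capture_warnings(
    cv3 <- cross_validate(learner_spec("majority"), FALSE, pc$table, y,
                          folds = 10, seed = 1))
  expect_true(any(grepl("reduced", w)))
  expect_identical(cv3$folds, 2L)
})

test_that("majority-vote cross-validation reproduces the closed form", {
  # constant prediction of the modal class on a 60/30/10 cohort:
  # every fold sees the same distribution, so the mean CV accuracy is 0.6
  # and the mean macro-F1 is 0.25
  set.seed(4)
  y <- rep(0:2, times = c(60, 30, 10))
  tab <- matrix(rnorm(300), 100, 3)
  cv <- suppressWarnings(
    cross_validate(learner_spec("majority"), FALSE, tab, y, folds = 10,
                   seed = 2))
  expect_equal(cv$mean_report$accuracy, 0.6)
  expect_equal(cv$mean_report$macro_f1, 0.25)
})

test_that("model comparison reports native, ECOC and delta columns", {
  pc <- three_blob_cohort(seed = 8, n_per = 40)
  sp <- stratified_split(pc$table, pc$labels, split_spec(0.8, seed = 1))
  tr <- pc$table$values[sp$train, ]
  te <- pc$table$values[sp$test, ]
  cmp <- compare_models(list(learner_spec("xgb", params = list(nrounds = 20)),
                             learner_spec("svc_linear")),
                        tr, pc$labels$labels[sp$train],
                        te, pc$labels$labels[sp$test])
  expect_identical(cmp$family, c("xgb", "svc_linear"))
  # max-margin family has no native multiclass column
  expect_true(is.na(cmp$accuracy_native[2]))
  expect_false(is.na(cmp$accuracy_ecoc[2]))
  # delta column is exactly B - A where both exist
  expect_equal(cmp$accuracy_delta[1],
               cmp$accuracy_ecoc[1] - cmp$accuracy_native[1])
  # separable blobs: tree model accuracy is high both ways
  expect_gte(cmp$accuracy_native[1], 0.9)
})

test_that("events-per-predictor reproduces the cohort worked example", {
  # 854 patients, one year of follow-up, 464 abnormal outcomes, 25
  # predictors: (854 * 1 * 54.33%) / 25 = 18.56
  expect_equal(round(epp(854, 1, 464 / 854, 25), 2), 18.56)
  expect_gte(epp(854, 1, 464 / 854, 25), 10)   # adequacy floor
  expect_error(epp(-1, 1, 0.5, 10))
})
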