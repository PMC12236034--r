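# Brute-force nearest-codeword decoder: minimum Hamming distance, ties to
# the lowest class index. Independent of the package's decoding path.
brute_decode <- function(bits, code) {
  apply(bits, 1, function(b) {
    d <- apply(code, 1, function(row) sum(b != row))
    as.integer(rownames(code)[which.min(d)])
  })
}

test_that("exhaustive codes enumerate all bipartitions up to complement", {
  cm3 <- build_code_matrix(3)
  expect_identical(dim(cm3), c(3L, 3L))
  # rows match (0,0,0),(0,1,1),(1,0,1) up to column order/complement:
  # class 1 all-zero, the others distinct with row distance 2
  expect_true(all(cm3[1, ] == 0))
  dH <- as.matrix(dist(unclass(cm3), method = "manhattan"))
  expect_true(all(dH[upper.tri(dH)] == 2))
  cm2 <- build_code_matrix(2)
  expect_identical(dim(cm2), c(2L, 1L))
  cm4 <- build_code_matrix(4)
  expect_identical(ncol(cm4), 7L)
  for (cm in list(cm2, cm3, cm4)) {
    expect_false(any(duplicated(cm)))
    cs <- colSums(cm)
    expect_true(all(cs > 0 & cs < nrow(cm)))
  }
})

test_that("random dense codes satisfy the structural invariants", {
  cm <- build_code_matrix(5, "random_dense", M = 10, seed = 3)
  expect_identical(dim(cm), c(5L, 10L))
  expect_false(any(duplicated(cm)))
  cs <- colSums(cm)
  expect_true(all(cs > 0 & cs < 5))
  for (a in 1:9) for (b in (a + 1):10) {
    expect_false(all(cm[, a] == cm[, b]))
    expect_false(all(cm[, a] == 1 - cm[, b]))
  }
  expect_error(build_code_matrix(5, "random_dense", M = 2), "at least")
})

test_that("decoding agrees with brute-force search over every codeword", {
  for (C in 2:4) {
    code <- build_code_matrix(C)
    M <- ncol(code)
    all_words <- as.matrix(expand.grid(rep(list(0:1), M)))
    dec <- ecoc_decode(all_words, code)
    expect_identical(dec$labels, brute_decode(all_words, code))
    # per-class scores rank the decoded label first on every row
    expect_identical(as.integer(rownames(code)[max.col(dec$scores,
                                                       ties.method = "first")]),
                     dec$labels)
  }
})

test_that("equidistant codewords resolve by the deterministic tie rule", {
  code <- build_code_matrix(3)
  # codeword (1,1,1): distance 3 to (0,0,0), 1 to (0,1,1), 1 to (1,0,1);
  # brute force and package both take the lowest-index tied class
  dec <- ecoc_decode(matrix(c(1, 1, 1), 1), code)
  expect_identical(dec$labels, 1L)
  expect_identical(brute_decode(matrix(c(1, 1, 1), 1), code), 1L)
})

test_that("binary ECOC reduces to the native binary learner", {
  pc <- three_blob_cohort(seed = 3, n_per = 40)
  y <- as.integer(pc$labels$labels == 2)
  idx <- seq_len(100)
  probe <- pc$table$values[101:120, ]
  spec <- learner_spec("rf", seed = 5)
  em <- ecoc_fit(spec, pc$table$values[idx, ], y[idx])
  native <- native_fit_predict(spec, pc$table$values[idx, ], y[idx], probe)
  expect_identical(ecoc_predict(em, probe)$labels, native$labels)
  spec2 <- learner_spec("svc_linear", seed = 5)
  em2 <- ecoc_fit(spec2, pc$table$values[idx, ], y[idx])
  native2 <- native_fit_predict(spec2, pc$table$values[idx, ], y[idx], probe)
  expect_identical(ecoc_predict(em2, probe)$labels, native2$labels)
})

test_that("ECOC training produces one binary model per code column", {
  pc <- three_blob_cohort(seed = 4, n_per = 30)
  em <- ecoc_fit(learner_spec("xgb", params = list(nrounds = 20)),
                 pc$table, pc$labels)
  expect_length(em$bit_models, 3)
  # refit with the same seed gives identical predictions on a fixed probe
  em2 <- ecoc_fit(learner_spec("xgb", params = list(nrounds = 20)),
                  pc$table, pc$labels)
  expect_identical(ecoc_predict(em, pc$table)$scores,
                   ecoc_predict(em2, pc$table)$scores)
})

test_that("max-margin families are binary-only natively but work under ECOC", {
  pc <- three_blob_cohort(seed = 6, n_per = 30)
  tr <- pc$table$values
  expect_error(native_fit_predict(learner_spec("svc_linear"), tr,
                                  pc$labels, tr),
               "binary-only")
  expect_error(native_fit_predict(learner_spec("svm_poly"), tr,
                                  pc$labels, tr),
               "binary-only")
  em <- ecoc_fit(learner_spec("svc_linear", seed = 2), tr, pc$labels)
  pred <- ecoc_predict(em, tr)
  expect_gt(mean(pred$labels == pc$labels$labels), 0.95)
})

test_that("ECOC-wrapped linear classifiers master separable three-class data", {
  accs <- vapply(1:5, function(s) {
    pc <- three_blob_cohort(seed = s, n_per = 40, sep = 6)
    sp <- stratified_split(pc$table, pc$labels, split_spec(0.8, seed = s))
    em <- ecoc_fit(learner_spec("svc_linear", seed = s),
                   pc$table$values[sp$train, ], pc$labels$labels[sp$train])
    pred <- ecoc_predict(em, pc$table$values[sp$test, ])
    mean(pred$labels == pc$labels$labels[sp$test])
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("native tree predictions yield valid probability vectors", {
  pc <- three_blob_cohort(seed = 7, n_per = 30)
  for (fam in c("rf", "xgb", "xgb_hist", "majority")) {
    out <- native_fit_predict(learner_spec(fam, params =
                                             if (grepl("xgb", fam))
                                               list(nrounds = 20) else list()),
                              pc$table, pc$labels, pc$table)
    expect_equal(rowSums(out$scores), rep(1, nrow(pc$table$values)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(out$labels %in% 0:2))
  }
})
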