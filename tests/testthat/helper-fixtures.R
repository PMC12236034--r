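# Small cohorts shared across tests, built in code.

small_cohort <- function(seed = 7, n = 200, tiers = c(8, 12, 8), ...) {
  generate_cohort(generator_config(n_samples = n,
                                   n_features_per_tier = tiers,
                                   seed = seed, ...))
}

# Hand-built 5-row table for neighbour-search oracles: 2 always-observed
# distance features, 1 fillable feature with one missing entry.
tiny_knn_table <- function(values_d1 = c(0, 0.1, 5, 5.1, 10),
                           values_d2 = c(0, 0.1, 5, 5.1, 10),
                           target = c(1, 3, 10, 30, 100),
                           miss_row = 1) {
  vals <- cbind(d1 = values_d1, d2 = values_d2, t = target)
  meta <- data.frame(name = c("d1", "d2", "t"),
                     tier = c("no_missing", "no_missing", "not_easy"),
                     kind = "continuous")
  vals[miss_row, "t"] <- NA
  feature_table(vals, meta)
}

# Three well-separated Gaussian blobs in feature space with haemoglobin
# values aligned to the 115/150 g/L classes.
three_blob_cohort <- function(seed = 1, n_per = 50, sep = 8, p = 6) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * p), 3, p)
  centers <- sep * centers / sqrt(rowSums(centers^2))
  cls <- rep(0:2, each = n_per)
  X <- centers[cls + 1, ] + matrix(rnorm(3 * n_per * p, sd = 0.5),
                                   3 * n_per, p)
  hb <- c(runif(n_per, 120, 145), runif(n_per, 80, 110),
          runif(n_per, 155, 175))
  meta <- data.frame(name = sprintf("f%02d", seq_len(p)),
                     tier = "no_missing", kind = "continuous")
  list(table = feature_table(X, meta), labels = label_vector(cls, hb))
}
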