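#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with the statistical structure the pipeline assumes:
#' correlated mixed-type features arising from a low-rank latent factor
#' model, three missingness tiers, and a severely imbalanced three-class
#' haemoglobin outcome. Defaults mirror the reference transplant cohort
#' the generator emulates: 854 patients, 95 features across the three tiers, class mix
#' 390:447:17 (normal:low:high) and thresholds 115/150 g/L.
#'
#' @param n_samples Number of patients.
#' @param n_features_per_tier Named or positional vector of three counts:
#'   always-observed, low-missingness (KNN-filled) and high-missingness
#'   (MLP-filled) features.
#' @param latent_rank Number of latent factors; smaller rank means stronger
#'   inter-feature correlation, hence more recoverable signal for predictive
#'   filling.
#' @param noise_sd Standard deviation of feature-level noise on top of the
#'   latent signal (signal loadings are unit-norm, so `noise_sd = 0.5` is a
#'   roughly 4:1 signal:noise variance ratio).
#' @param class_mix Proportions of the normal/low/high outcome classes.
#' @param hb_thresholds Lower/upper bounds of the normal haemoglobin range in
#'   g/L.
#' @param class_sep Magnitude of the class-specific latent mean shift. 0
#'   yields no cluster structure beyond the haemoglobin coupling; large
#'   values yield well-separated (trimodal for three classes) clouds.
#' @param cat_fraction Fraction of features per fillable tier generated as
#'   integer-coded categoricals (quantile-binned latent scores).
#' @param cat_levels Number of levels for categorical features.
#' @param seed Integer seed; every draw in [generate_cohort()] derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 854,
                             n_features_per_tier = c(no_missing = 20,
                                                     not_easy = 45,
                                                     easy = 30),
                             latent_rank = 5,
                             noise_sd = 0.5,
                             class_mix = c(390, 447, 17) / 854,
                             hb_thresholds = c(115, 150),
                             class_sep = 1,
                             cat_fraction = 0.15,
                             cat_levels = 4,
                             seed = 1L) {
  n_features_per_tier <- as.integer(n_features_per_tier)
  if (length(n_features_per_tier) != 3 || any(n_features_per_tier <= 0))
    stop("n_features_per_tier must be three positive counts")
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must be three proportions summing to 1")
  if (n_samples < 1 || latent_rank < 1)
    stop("n_samples and latent_rank must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(hb_thresholds) != 2 || hb_thresholds[1] >= hb_thresholds[2])
    stop("hb_thresholds must be an ordered pair")
  structure(list(n_samples = as.integer(n_samples),
                 n_features_per_tier = stats::setNames(n_features_per_tier, TIERS),
                 latent_rank = as.integer(latent_rank),
                 noise_sd = noise_sd,
                 class_mix = class_mix,
                 hb_thresholds = hb_thresholds,
                 class_sep = class_sep,
                 cat_fraction = cat_fraction,
                 cat_levels = as.integer(cat_levels),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Assign haemoglobin class labels from concentrations
#'
#' Values within the closed normal range map to 0, values below its lower
#' bound to 1 (low), values above its upper bound to 2 (high).
#'
#' @param hb Numeric vector of haemoglobin concentrations (g/L).
#' @param thresholds Ordered pair: lower and upper bound of the normal range
#'   (default 115 and 150 g/L).
#' @return A [label_vector()] carrying both labels and the source
#'   concentrations.
#' @export
assign_labels <- function(hb, thresholds = c(115, 150)) {
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    stop("thresholds must be an ordered pair")
  if (any(!is.finite(hb))) stop("hb contains non-finite values")
  labels <- integer(length(hb))
  labels[hb < thresholds[1]] <- 1L
  labels[hb > thresholds[2]] <- 2L
  label_vector(labels, source_hb = hb)
}

# Draw from a normal truncated to (lo, hi) by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic clinical cohort
#'
#' Samples a complete (no missing values) cohort: class labels from the
#' configured mix; haemoglobin concentrations from class-conditional
#' truncated normals around the 115/150 g/L thresholds; latent factors
#' coupled to the (scaled) haemoglobin value and shifted per class by
#' `class_sep`; features as unit-norm linear combinations of the latent
#' factors plus independent Gaussian noise. A configurable fraction of
#' fillable-tier features is discretised into quantile bins to act as
#' integer-coded categoricals.
#'
#' @param config A [generator_config()].
#' @return List with elements `table` (a [feature_table()], complete) and
#'   `labels` (a [label_vector()] with `source_hb`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples
  r <- config$latent_rank
  p_tier <- config$n_features_per_tier
  p <- sum(p_tier)
  th <- config$hb_thresholds

  cls <- sample(0:2, n, replace = TRUE, prob = config$class_mix)
  hb <- numeric(n)
  mid <- mean(th)
  hb[cls == 0] <- rtruncnorm(sum(cls == 0), mid, 7, th[1], th[2])
  hb[cls == 1] <- rtruncnorm(sum(cls == 1), th[1] - 20, 8, -Inf, th[1] - 1e-9)
  hb[cls == 2] <- rtruncnorm(sum(cls == 2), th[2] + 10, 5, th[2] + 1e-9, Inf)

  Z <- matrix(stats::rnorm(n * r), n, r)
  # couple factor 1 to the outcome so features carry predictive signal
  alpha <- 0.8
  Z[, 1] <- alpha * as.numeric(scale(hb)) + sqrt(1 - alpha^2) * Z[, 1]
  # class-specific latent mean shifts: orthonormal unit directions (when
  # the rank allows) so the three class modes are pairwise equidistant
  if (config$class_sep > 0) {
    if (r >= 3) {
      U <- t(qr.Q(qr(matrix(stats::rnorm(r * 3), r, 3))))
    } else {
      U <- matrix(stats::rnorm(3 * r), 3, r)
      U <- U / sqrt(rowSums(U^2))
    }
    Z <- Z + config$class_sep * U[cls + 1, , drop = FALSE]
  }

  W <- matrix(stats::rnorm(r * p), r, p)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")          # unit-norm loadings
  X <- Z %*% W
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)

  tier <- rep(TIERS, times = p_tier)
  name <- sprintf("%s_%02d", c(no_missing = "nm", not_easy = "ne",
                               easy = "ez")[tier],
                  unlist(lapply(p_tier, seq_len)))
  kind <- rep("continuous", p)
  for (tt in c("not_easy", "easy")) {
    idx <- which(tier == tt)
    ncat <- floor(config$cat_fraction * length(idx))
    if (ncat > 0) {
      ci <- idx[seq_len(ncat)]
      kind[ci] <- "categorical"
      for (j in ci) {
        br <- stats::quantile(X[, j], probs = seq(0, 1, length.out =
                                                    config$cat_levels + 1))
        br[1] <- -Inf; br[length(br)] <- Inf
        X[, j] <- as.numeric(cut(X[, j], breaks = unique(br),
                                 labels = FALSE, include.lowest = TRUE)) - 1
      }
    }
  }

  meta <- data.frame(name = name, tier = tier, kind = kind,
                     stringsAsFactors = FALSE)
  list(table = feature_table(X, meta), labels = label_vector(cls, hb))
}

#' Simulate worst-case missingness by case-block deletion
#'
#' Masks every fillable (not-easy and easy tier) entry of a uniformly random
#' fraction of cases, leaving the always-observed tier untouched. This
#' emulates the worst realistic pattern: a patient record retaining only
#' basic information and preoperative examination values.
#'
#' @param table A complete [feature_table()].
#' @param case_fraction Fraction of rows to delete; the row count is rounded
#'   to the nearest integer, with at least one row when the fraction is
#'   positive.
#' @param seed Integer seed.
#' @return List with elements `table` (masked copy) and `deleted_rows`
#'   (integer indices); the caller keeps the input as ground truth.
#' @export
inject_missingness <- function(table, case_fraction, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_complete(table)) stop("inject_missingness requires a complete table")
  if (case_fraction < 0 || case_fraction > 1)
    stop("case_fraction must be in [0, 1]")
  n <- nrow(table$values)
  m <- round(n * case_fraction)
  if (case_fraction > 0) m <- max(1L, m)
  if (m == 0) return(list(table = table, deleted_rows = integer(0)))
  set.seed(seed)
  rows <- sort(sample.int(n, m))
  cols <- fillable_cols(table)
  table$mask[rows, cols] <- TRUE
  table$values[rows, cols] <- NA_real_
  list(table = table, deleted_rows = rows)
}

#' Inject entrywise missingness at per-tier rates
#'
#' Each fillable entry is masked independently with its tier's probability
#' (missing completely at random); the always-observed tier's rate must be
#' zero.
#'
#' @param table A complete [feature_table()].
#' @param rates Three probabilities ordered no-missing, not-easy, easy.
#' @param seed Integer seed.
#' @return A masked [feature_table()].
#' @export
inject_tiered_missingness <- function(table, rates = c(0, 0.05, 0.25),
                                      seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_complete(table))
    stop("inject_tiered_missingness requires a complete table")
  if (length(rates) != 3 || any(rates < 0) || any(rates > 1))
    stop("rates must be three probabilities in [0, 1]")
  if (rates[1] != 0) stop("the no_missing tier rate must be 0")
  set.seed(seed)
  rate_by_col <- rates[match(table$meta$tier, TIERS)]
  n <- nrow(table$values)
  for (j in which(rate_by_col > 0)) {
    hit <- stats::runif(n) < rate_by_col[j]
    table$mask[hit, j] <- TRUE
    table$values[hit, j] <- NA_real_
  }
  table
}
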