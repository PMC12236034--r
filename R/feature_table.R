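# Recognised missingness tiers, in severity order. NO_MISSING columns are the
# always-observed backbone (demographics, preoperative labs); NOT_EASY columns
# carry a low missing probability and are filled by KNN; EASY columns carry a
# relatively high missing probability and are filled by chained MLP regression.
TIERS <- c("no_missing", "not_easy", "easy")
KINDS <- c("continuous", "categorical")

#' Construct a feature table
#'
#' The universal data container of the pipeline: a samples-by-features numeric
#' matrix (categorical features integer-coded), a same-shape logical
#' missingness mask, and per-feature metadata assigning each feature a
#' missingness tier and a kind. Missing entries are `NA` in `values` and
#' `TRUE` in `mask`; the mask is authoritative, so zero is always a legal
#' observed value.
#'
#' @param values Numeric matrix, one column per feature. Column names, if
#'   present, must match `meta$name`.
#' @param meta Data frame with columns `name`, `tier` (one of `"no_missing"`,
#'   `"not_easy"`, `"easy"`) and `kind` (`"continuous"` or `"categorical"`),
#'   one row per column of `values`.
#' @param mask Logical matrix of the same shape; defaults to `is.na(values)`.
#' @return An object of class `feature_table` with elements `values`, `mask`
#'   and `meta`.
#' @export
feature_table <- function(values, meta, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  if (!is.data.frame(meta) || !all(c("name", "tier", "kind") %in% names(meta)))
    stop("meta must be a data.frame with columns name, tier, kind")
  meta <- data.frame(name = as.character(meta$name),
                     tier = as.character(meta$tier),
                     kind = as.character(meta$kind),
                     stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(values))
    stop("meta has ", nrow(meta), " rows but values has ", ncol(values), " columns")
  if (anyDuplicated(meta$name)) stop("duplicate feature names in meta")
  if (!all(meta$tier %in% TIERS))
    stop("unknown tier(s): ", paste(setdiff(meta$tier, TIERS), collapse = ", "))
  if (!all(meta$kind %in% KINDS))
    stop("unknown kind(s): ", paste(setdiff(meta$kind, KINDS), collapse = ", "))
  colnames(values) <- meta$name
  colnames(mask) <- meta$name
  # mask TRUE => value is the missing sentinel
  values[mask] <- NA_real_
  if (any(mask[, meta$tier == "no_missing", drop = FALSE]))
    stop("no_missing tier columns must have an all-FALSE mask")
  structure(list(values = values, mask = mask, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  tt <- table(factor(x$meta$tier, levels = TIERS))
  cat("  tiers:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat("  missing entries:", sum(x$mask),
      sprintf("(%.1f%%)", 100 * mean(x$mask)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Column indices for one or more tiers.
tier_cols <- function(table, tiers) which(table$meta$tier %in% tiers)

# Fillable = any tier that may legally contain missing entries.
fillable_cols <- function(table) tier_cols(table, c("not_easy", "easy"))

is_complete <- function(table) !any(table$mask)

#' Label vector for the three-class haemoglobin outcome
#'
#' @param labels Integer codes (0 = normal, 1 = low, 2 = high by default
#'   scheme).
#' @param source_hb Optional per-sample haemoglobin concentration (g/L) from
#'   which the labels were derived.
#' @return Object of class `label_vector`.
#' @export
label_vector <- function(labels, source_hb = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be non-missing integers")
  if (!is.null(source_hb)) {
    source_hb <- as.numeric(source_hb)
    if (length(source_hb) != length(labels))
      stop("source_hb length must match labels")
  }
  structure(list(labels = labels, source_hb = source_hb),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat("<label_vector> n =", length(x$labels), "\n")
  print(table(x$labels))
  invisible(x)
}

# Coerce a label_vector or plain vector to an integer vector.
as_labels <- function(labels) {
  if (inherits(labels, "label_vector")) labels$labels else as.integer(labels)
}

# Column z-scoring using observed-value statistics. Constant columns get
# sd = 1 so they contribute nothing to distances instead of NaN.
zscore_stats <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- is.na(values)
  obs <- values
  obs[mask] <- NA_real_
  mu <- colMeans(obs, na.rm = TRUE)
  sd <- apply(obs, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  mu[!is.finite(mu)] <- 0
  list(mean = mu, sd = sd)
}

apply_zscore <- function(values, stats) {
  sweep(sweep(values, 2, stats$mean, "-"), 2, stats$sd, "/")
}

# Majority vote with deterministic ties: lowest code wins.
mode_code <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1])
}

# Round a continuous prediction to the nearest legal categorical code.
snap_to_codes <- function(pred, codes) {
  codes <- sort(unique(codes[!is.na(codes)]))
  codes[max.col(-abs(outer(pred, codes, "-")), ties.method = "first")]
}

# Shared fingerprint for reports/manifests: shape plus a content checksum.
data_fingerprint <- function(values) {
  v <- values[!is.na(values)]
  sprintf("%dx%d:%.10g", nrow(values), ncol(values), sum(v) + sum(v^2) / 1e3)
}
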