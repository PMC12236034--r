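#' Configuration for adaptive synthetic oversampling
#'
#' @param k Neighbour count for density estimation and parent selection.
#' @param beta Target balance ratio in (0, 1]: 1 raises each treated
#'   minority class to (approximately) the majority count.
#' @param strategy `"all"` oversamples every class below the majority count
#'   (the ADASYN default); `"minority"` oversamples only the rarest class.
#' @param seed Integer seed.
#' @return A `balance_config` list.
#' @export
balance_config <- function(k = 5, beta = 1, strategy = c("all", "minority"),
                           seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  structure(list(k = as.integer(k), beta = beta,
                 strategy = match.arg(strategy), seed = as.integer(seed)),
            class = "balance_config")
}

# Largest-remainder apportionment of `total` across weights `w` (sum 1).
largest_remainder <- function(w, total) {
  raw <- w * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Adaptive synthetic oversampling (ADASYN)
#'
#' For each treated minority class, `G = (majority_count - class_count) *
#' beta` synthetic samples are apportioned across the class's members in
#' proportion to their local learning difficulty — the fraction of
#' non-class points among each member's `k` nearest neighbours in the
#' z-scored feature space — so synthesis concentrates near class
#' boundaries. Each synthetic row is a convex combination `x + lambda *
#' (x_nb - x)` (`lambda ~ U(0,1)`) of a member and one of its `k` nearest
#' same-class neighbours; categorical features are copied from the nearer
#' parent.
#'
#' @param table A complete [feature_table()] (run the imputation stage
#'   first).
#' @param labels A [label_vector()] or integer vector.
#' @param config A [balance_config()].
#' @return A `balanced_set` list: `table` (real rows first, unchanged),
#'   `labels`, `origin` (`"real"`/`"synthetic"` per row), `counts_before`,
#'   `counts_after`.
#' @export
adasyn <- function(table, labels, config = balance_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_complete(table)) stop("adasyn requires a complete table")
  y <- as_labels(labels)
  if (length(y) != nrow(table$values)) stop("labels length mismatch")
  counts <- table(y)
  if (length(counts) < 2) stop("adasyn requires at least two classes")
  k <- config$k
  set.seed(config$seed)

  Z <- apply_zscore(table$values,
                    zscore_stats(table$values,
                                 matrix(FALSE, nrow(table$values),
                                        ncol(table$values))))
  n <- nrow(Z)
  maj_count <- max(counts)
  maj_class <- as.integer(names(counts)[which.max(counts)])
  targets <- as.integer(names(counts)[counts < maj_count])
  if (config$strategy == "minority" && length(targets))
    targets <- as.integer(names(counts)[which.min(counts)])

  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  new_rows <- list(); new_y <- integer(0)
  is_cat <- table$meta$kind == "categorical"

  for (cl in targets) {
    idx <- which(y == cl)
    n_c <- length(idx)
    if (n_c <= 1 || n_c < k + 1) {
      warning("class ", cl, " has too few members (", n_c, "); skipped")
      next
    }
    G <- round((maj_count - n_c) * config$beta)
    if (G <= 0) next
    # density weights: share of non-class points among the k nearest
    r <- vapply(idx, function(i) {
      nb <- order(D[i, ], seq_len(n))[seq_len(k)]
      mean(y[nb] != cl)
    }, numeric(1))
    w <- if (sum(r) > 0) r / sum(r) else rep(1 / n_c, n_c)
    quota <- largest_remainder(w, G)
    for (m in seq_along(idx)) {
      if (quota[m] == 0) next
      i <- idx[m]
      same <- idx[idx != i]
      nb_pool <- same[order(D[i, same], same)][seq_len(min(k, length(same)))]
      for (s in seq_len(quota[m])) {
        nb <- nb_pool[sample.int(length(nb_pool), 1)]
        lambda <- stats::runif(1)
        xn <- table$values[i, ] + lambda * (table$values[nb, ] - table$values[i, ])
        if (any(is_cat))
          xn[is_cat] <- if (lambda <= 0.5) table$values[i, is_cat] else
            table$values[nb, is_cat]
        new_rows[[length(new_rows) + 1]] <- xn
        new_y <- c(new_y, cl)
      }
    }
  }

  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    values <- rbind(table$values, add)
  } else values <- table$values
  out_tab <- feature_table(values, table$meta)
  out_y <- c(y, new_y)
  structure(list(table = out_tab,
                 labels = label_vector(out_y),
                 origin = c(rep("real", n), rep("synthetic", length(new_y))),
                 counts_before = counts,
                 counts_after = table(out_y)),
            class = "balanced_set")
}

#' @export
print.balanced_set <- function(x, ...) {
  cat("<balanced_set>\n  before:"); print(x$counts_before)
  cat("  after:"); print(x$counts_after)
  invisible(x)
}

#' Per-class counts and proportions
#'
#' @param labels A [label_vector()] or integer vector.
#' @return Data frame with columns `label`, `count`, `proportion`.
#' @export
class_distribution <- function(labels) {
  y <- as_labels(labels)
  if (!length(y)) stop("labels are empty")
  tab <- table(y)
  data.frame(label = as.integer(names(tab)),
             count = as.integer(tab),
             proportion = as.numeric(tab) / length(y),
             row.names = NULL)
}
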