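#' K-means diagnostics over a range of cluster counts
#'
#' Clusters the z-scored feature matrix for every K in `k_range` with
#' multiple random restarts plus a warm start from the previous K's best
#' centers (augmented with the worst-fit point), which guarantees the
#' within-cluster sum of squares is non-increasing in K. Records the SSE
#' and the mean silhouette width per K.
#'
#' @param table A complete [feature_table()].
#' @param k_range Integer candidates, within `[2, n - 1]`.
#' @param seed Integer seed.
#' @param nstart Random restarts per K.
#' @return A `clustering_diagnostics`: data frame `(K, sse, silhouette)`
#'   plus an `assignments` attribute (list of cluster vectors keyed by K).
#' @export
ideal_clustering <- function(table, k_range = 2:6, seed = 1L, nstart = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (!is_complete(table)) stop("ideal_clustering requires a complete table")
  n <- nrow(table$values)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  Z <- apply_zscore(table$values,
                    zscore_stats(table$values,
                                 matrix(FALSE, n, ncol(table$values))))
  D <- stats::dist(Z)
  res <- data.frame(K = k_range, sse = NA_real_, silhouette = NA_real_)
  assignments <- vector("list", length(k_range))
  names(assignments) <- k_range
  prev_centers <- NULL
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    set.seed(seed + K)
    km <- stats::kmeans(Z, centers = K, nstart = nstart, iter.max = 50)
    if (!is.null(prev_centers) && nrow(prev_centers) == K - 1) {
      # warm start: previous centers plus the point they fit worst
      d2 <- vapply(seq_len(n), function(j)
        min(colSums((t(prev_centers) - Z[j, ])^2)), numeric(1))
      warm <- rbind(prev_centers, Z[which.max(d2), ])
      km2 <- suppressWarnings(stats::kmeans(Z, centers = warm, iter.max = 50))
      if (km2$tot.withinss < km$tot.withinss) km <- km2
    }
    prev_centers <- km$centers
    res$sse[i] <- km$tot.withinss
    sil <- cluster::silhouette(km$cluster, D)
    res$silhouette[i] <- mean(sil[, "sil_width"])
    assignments[[i]] <- km$cluster
  }
  attr(res, "assignments") <- assignments
  class(res) <- c("clustering_diagnostics", "data.frame")
  res
}

#' Elbow criterion for the cluster count
#'
#' Automates the visual "turning point" as the K maximising the discrete
#' second difference `SSE(K-1) - 2 SSE(K) + SSE(K+1)`; ties break toward
#' the smaller K. A curvature-free (e.g. linear) curve triggers a warning
#' and returns the smallest candidate.
#'
#' @param diagnostics A `clustering_diagnostics`.
#' @return The selected K.
#' @export
elbow_k <- function(diagnostics) {
  stopifnot(nrow(diagnostics) >= 3)
  s <- diagnostics$sse
  K <- diagnostics$K
  d2 <- s[-c(length(s) - 1, length(s))] - 2 * s[-c(1, length(s))] +
    s[-c(1, 2)]
  scale <- max(abs(s))
  if (max(d2) - min(d2) <= 1e-12 * max(scale, 1)) {
    warning("SSE curve has no curvature; returning the smallest K")
    return(K[1])
  }
  K[-c(1, length(K))][which.max(d2)]
}

#' Silhouette criterion for the cluster count
#'
#' @param diagnostics A `clustering_diagnostics` with at least two
#'   candidates.
#' @return The K with the highest mean silhouette; ties break toward the
#'   smaller K.
#' @export
silhouette_k <- function(diagnostics) {
  stopifnot(nrow(diagnostics) >= 2)
  diagnostics$K[which.max(diagnostics$silhouette)]
}

# Default clinically-motivated threshold schemes per class count. The
# three-class scheme is the 115/150 g/L normal range; two classes merge the
# abnormal sides; four classes split the low side at a severity threshold.
default_schemes <- function(severity = 80, thresholds = c(115, 150)) {
  list(`2` = list(thresholds = thresholds, type = "binary"),
       `3` = list(thresholds = thresholds, type = "ternary"),
       `4` = list(thresholds = c(severity, thresholds), type = "quaternary"))
}

#' Clinically defined ("actual") partition of a cohort
#'
#' @param hb Haemoglobin concentrations (g/L) or a [label_vector()] with
#'   `source_hb`.
#' @param n_classes 2, 3 or 4.
#' @param schemes Named list of threshold schemes, as produced by the
#'   default; schemes for 2 and 4 classes are explicit configuration since
#'   only the three-class 115/150 g/L thresholds are clinically canonical.
#' @return Integer assignment vector. Two classes: 0 normal / 1 abnormal;
#'   three: 0 normal / 1 low / 2 high; four: additionally 3 = severe low
#'   (below the severity threshold, default 80 g/L).
#' @export
actual_partition <- function(hb, n_classes, schemes = default_schemes()) {
  if (inherits(hb, "label_vector")) {
    if (is.null(hb$source_hb)) stop("label_vector lacks source_hb")
    hb <- hb$source_hb
  }
  if (any(!is.finite(hb))) stop("hb contains non-finite values")
  sc <- schemes[[as.character(n_classes)]]
  if (is.null(sc)) stop("no scheme configured for ", n_classes, " classes")
  if (n_classes == 2) {
    th <- sc$thresholds
    as.integer(hb < th[1] | hb > th[2])
  } else if (n_classes == 3) {
    assign_labels(hb, sc$thresholds)$labels
  } else if (n_classes == 4) {
    th <- sc$thresholds   # (severity, low, high)
    out <- assign_labels(hb, th[2:3])$labels
    out[hb < th[1]] <- 3L
    out
  } else stop("n_classes must be 2, 3 or 4")
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Information-theoretic similarity of two partitions
#'
#' From the contingency table of the two assignment vectors computes
#' normalised mutual information (arithmetic normalisation), homogeneity,
#' completeness, and their harmonic mean (the V-measure). With arithmetic
#' normalisation NMI and V-measure coincide; both are reported.
#'
#' @param ideal Cluster assignment (any label coding).
#' @param actual Reference assignment of equal length.
#' @return A `partition_similarity` list with fields `nmi`, `homogeneity`,
#'   `completeness`, `v_measure`.
#' @export
partition_similarity <- function(ideal, actual) {
  if (length(ideal) != length(actual)) stop("assignments differ in length")
  ct <- table(ideal, actual)
  n <- sum(ct)
  h_i <- entropy_counts(rowSums(ct))
  h_a <- entropy_counts(colSums(ct))
  h_joint <- entropy_counts(as.vector(ct))
  mi <- h_i + h_a - h_joint
  mi <- max(mi, 0)
  homogeneity <- if (h_a == 0) 1 else {
    h_a_given_i <- h_joint - h_i        # H(actual | ideal)
    1 - h_a_given_i / h_a
  }
  completeness <- if (h_i == 0) 1 else {
    h_i_given_a <- h_joint - h_a
    1 - h_i_given_a / h_i
  }
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  nmi <- if ((h_i + h_a) == 0) 1 else 2 * mi / (h_i + h_a)
  structure(list(nmi = nmi, homogeneity = homogeneity,
                 completeness = completeness, v_measure = v),
            class = "partition_similarity")
}

#' Choose the class count by the best-approximation method
#'
#' For each candidate class count, compares the K-means ("ideal") partition
#' at that K with the clinically defined ("actual") partition via
#' [partition_similarity()], and picks the candidate with the highest
#' V-measure; ties prefer the candidate agreeing with the elbow criterion,
#' then the smaller K. The elbow and silhouette diagnostics over
#' `diag_range` are reported alongside.
#'
#' @param table A complete [feature_table()].
#' @param hb Haemoglobin concentrations or a [label_vector()] with
#'   `source_hb`.
#' @param candidates Candidate class counts with configured schemes.
#' @param seed Integer seed.
#' @param schemes Threshold schemes (see [actual_partition()]).
#' @param diag_range K range for the SSE/silhouette diagnostics.
#' @return A `class_count_decision`: `chosen_K`, `elbow_K`, `silhouette_K`,
#'   `similarity` (per-candidate data frame), `diagnostics`.
#' @export
best_approximation <- function(table, hb, candidates = c(2, 3, 4), seed = 1L,
                               schemes = default_schemes(),
                               diag_range = 2:6) {
  diag <- ideal_clustering(table, diag_range, seed = seed)
  assignments <- attr(diag, "assignments")
  need <- setdiff(candidates, as.integer(names(assignments)))
  if (length(need)) {
    extra <- ideal_clustering(table, need, seed = seed)
    assignments <- c(assignments, attr(extra, "assignments"))
  }
  sim <- do.call(rbind, lapply(candidates, function(K) {
    ps <- partition_similarity(assignments[[as.character(K)]],
                               actual_partition(hb, K, schemes))
    data.frame(n_classes = K, nmi = ps$nmi, homogeneity = ps$homogeneity,
               completeness = ps$completeness, v_measure = ps$v_measure)
  }))
  eK <- elbow_k(diag)
  sK <- silhouette_k(diag)
  best_v <- max(sim$v_measure)
  tied <- sim$n_classes[sim$v_measure >= best_v - 1e-12]
  chosen <- if (eK %in% tied) eK else min(tied)
  structure(list(chosen_K = chosen, elbow_K = eK, silhouette_K = sK,
                 similarity = sim, diagnostics = diag),
            class = "class_count_decision")
}

#' @export
print.class_count_decision <- function(x, ...) {
  cat("<class_count_decision> chosen K =", x$chosen_K,
      "(elbow", paste0(x$elbow_K, ","), "silhouette", paste0(x$silhouette_K, ")\n"))
  print(x$similarity, row.names = FALSE)
  invisible(x)
}
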