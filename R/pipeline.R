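#' Write a cohort to plain-text CSV files
#'
#' Values go to `<prefix>_values.csv` (one header row, missing cells
#' empty, full double precision), feature metadata to `<prefix>_meta.csv`
#' (`name,tier,kind`) and, when given, labels to `<prefix>_labels.csv`
#' (`label[,source_hb]`). The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param table A [feature_table()].
#' @param prefix Path prefix (directory must exist).
#' @param labels Optional [label_vector()].
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(table, prefix, labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  paths <- c(values = paste0(prefix, "_values.csv"),
             meta = paste0(prefix, "_meta.csv"))
  vals <- table$values
  chr <- matrix("", nrow(vals), ncol(vals))
  chr[!table$mask] <- sprintf("%.17g", vals[!table$mask])
  colnames(chr) <- colnames(vals)
  utils::write.csv(chr, paths["values"], row.names = FALSE, quote = FALSE)
  utils::write.csv(table$meta, paths["meta"], row.names = FALSE, quote = FALSE)
  if (!is.null(labels)) {
    paths["labels"] <- paste0(prefix, "_labels.csv")
    df <- data.frame(label = labels$labels)
    if (!is.null(labels$source_hb))
      df$source_hb <- sprintf("%.17g", labels$source_hb)
    utils::write.csv(df, paths["labels"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

parse_numeric_col <- function(x, col, file) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  nonempty <- x != ""
  suppressWarnings(out[nonempty] <- as.numeric(x[nonempty]))
  bad <- nonempty & is.na(out)
  if (any(bad))
    stop("malformed numeric value in ", file, ", column '", col,
         "', line ", which(bad)[1] + 1)   # +1 for the header row
  out
}

#' Read a cohort written by [write_cohort()]
#'
#' Empty cells become masked entries; any non-empty cell that does not
#' parse as a number is a format error reported with its line number. The
#' metadata sidecar is required and must cover every value column.
#'
#' @param prefix Path prefix used at write time.
#' @return List with `table` (a [feature_table()]) and `labels` (a
#'   [label_vector()] or `NULL`).
#' @export
read_cohort <- function(prefix) {
  vpath <- paste0(prefix, "_values.csv")
  mpath <- paste0(prefix, "_meta.csv")
  if (!file.exists(mpath))
    stop("missing feature-metadata sidecar: ", mpath)
  if (!file.exists(vpath)) stop("missing values file: ", vpath)
  meta <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  nf <- utils::count.fields(vpath, sep = ",", quote = "\"")
  if (any(nf != nf[1]))
    stop("inconsistent field count in ", vpath, ", line ",
         which(nf != nf[1])[1], " (mixed decimal separators?)")
  raw <- utils::read.csv(vpath, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!identical(sort(names(raw)), sort(meta$name)))
    stop("value columns do not match the metadata sidecar")
  raw <- raw[, meta$name, drop = FALSE]
  vals <- vapply(meta$name, function(cn)
    parse_numeric_col(raw[[cn]], cn, vpath), numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, meta$name))
  tab <- feature_table(vals, meta)
  lpath <- paste0(prefix, "_labels.csv")
  labels <- NULL
  if (file.exists(lpath)) {
    ldf <- utils::read.csv(lpath, stringsAsFactors = FALSE)
    labels <- label_vector(ldf$label,
                           source_hb = if ("source_hb" %in% names(ldf))
                             as.numeric(ldf$source_hb) else NULL)
  }
  list(table = tab, labels = labels)
}

#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's toggles and parameters. Stages execute in the
#' fixed order generate/load, inject missingness (synthetic runs only),
#' impute, split, balance (training partition only by default, to avoid
#' information leakage into the test set), feature selection, class-count
#' report, model training with cross-validation, test-set evaluation.
#'
#' @param generator A [generator_config()], or `NULL` to read `input_prefix`.
#' @param input_prefix Cohort path prefix when `generator` is `NULL`.
#' @param missingness `NULL`, or `list(type = "case_block", fraction =)` /
#'   `list(type = "tiered", rates =)` applied to a generated cohort.
#' @param impute `list(method = "fused"|"knn"|"mean", k =, mlp =)`.
#' @param balance `list(enabled =, beta =, k =, strategy =, train_only =)`.
#' @param select `list(enabled =, tolerance =, step =, nrounds =)`.
#' @param class_count `list(enabled =, candidates =)`.
#' @param model `list(family =, ecoc =, code_scheme =)`.
#' @param split_fraction Training fraction of the 8:2-style split.
#' @param cv_folds Cross-validation folds on the training partition.
#' @param seed Global seed; stage seeds derive from it.
#' @param outdir Output directory for artifacts and the manifest.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_prefix = NULL,
                            missingness = list(type = "case_block",
                                               fraction = 0.10),
                            impute = list(method = "fused", k = 5,
                                          mlp = mlp_spec()),
                            balance = list(enabled = TRUE, beta = 1, k = 5,
                                           strategy = "all",
                                           train_only = TRUE),
                            select = list(enabled = TRUE, tolerance = 0.001,
                                          step = 5, nrounds = 30),
                            class_count = list(enabled = TRUE,
                                               candidates = c(2, 3, 4)),
                            model = list(family = "xgb", ecoc = TRUE,
                                         code_scheme = "exhaustive"),
                            split_fraction = 0.8,
                            cv_folds = 10,
                            seed = 1L,
                            outdir = tempfile("hbrun")) {
  if (is.null(generator) && is.null(input_prefix))
    stop("either a generator config or an input prefix is required")
  if (is.null(generator) && !file.exists(paste0(input_prefix, "_values.csv")))
    stop("input files not found at prefix: ", input_prefix)
  structure(list(generator = generator, input_prefix = input_prefix,
                 missingness = missingness, impute = impute,
                 balance = balance, select = select,
                 class_count = class_count, model = model,
                 split_fraction = split_fraction, cv_folds = cv_folds,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

stage_fingerprint <- function(table, labels = NULL) {
  fp <- list(rows = nrow(table$values), cols = ncol(table$values),
             checksum = data_fingerprint(table$values))
  if (!is.null(labels)) {
    cd <- class_distribution(labels)
    fp$class_counts <- stats::setNames(as.list(cd$count),
                                       as.character(cd$label))
  }
  fp
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, persists every intermediate table
#' as CSV under `config$outdir`, and writes a JSON run manifest (config
#' snapshot, per-stage timings and data fingerprints, artifact paths) plus
#' the final evaluation report.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly; also written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config_snapshot(config), stages = list(),
                   artifacts = list(),
                   versions = list(R = as.character(getRversion()),
                                   hbpredict =
                                     as.character(utils::packageVersion("hbpredict"))))
  tick <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, config$outdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]]$seconds <<-
      round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    out
  }

  # --- cohort -------------------------------------------------------------
  cohort <- tick("cohort", {
    if (!is.null(config$generator)) {
      gc <- config$generator; gc$seed <- config$seed
      generate_cohort(gc)
    } else {
      read_cohort(config$input_prefix)
    }
  })
  truth <- cohort$table
  labels <- cohort$labels
  write_cohort(truth, file.path(config$outdir, "cohort"), labels)
  manifest$stages$cohort$fingerprint <- stage_fingerprint(truth, labels)

  # --- missingness (synthetic runs) ---------------------------------------
  masked <- truth
  if (!is.null(config$missingness) && !is.null(config$generator)) {
    masked <- tick("missingness", {
      m <- config$missingness
      if (m$type == "case_block")
        inject_missingness(truth, m$fraction, seed = config$seed + 1L)$table
      else
        inject_tiered_missingness(truth, m$rates, seed = config$seed + 1L)
    })
    manifest$stages$missingness$fingerprint <- list(
      missing_entries = sum(masked$mask))
  }

  # --- imputation ---------------------------------------------------------
  filled <- tick("impute", {
    if (!any(masked$mask)) {
      new_fill_result(masked, empty_provenance(masked), "none")
    } else {
      switch(config$impute$method,
             mean = mean_fill(masked),
             knn = knn_fill(masked, k = config$impute$k),
             fused = fused_fill(masked,
                                fill_plan(masked, k = config$impute$k,
                                          mlp = config$impute$mlp)),
             stop("unknown impute method"))
    }
  })
  write_cohort(filled$table, file.path(config$outdir, "filled"), labels)
  manifest$stages$impute$fingerprint <- stage_fingerprint(filled$table)
  tab <- filled$table

  # --- split --------------------------------------------------------------
  sp <- tick("split", stratified_split(tab, labels,
                                       split_spec(config$split_fraction,
                                                  seed = config$seed + 2L)))
  manifest$stages$split$fingerprint <- list(train = length(sp$train),
                                            test = length(sp$test))
  ytr <- labels$labels[sp$train]
  train_tab <- subset_table(tab, sp$train)
  test_tab <- subset_table(tab, sp$test)
  yte <- labels$labels[sp$test]

  # --- balancing ----------------------------------------------------------
  if (isTRUE(config$balance$enabled)) {
    bal <- tick("balance", {
      bc <- balance_config(k = config$balance$k, beta = config$balance$beta,
                           strategy = config$balance$strategy,
                           seed = config$seed + 3L)
      if (isTRUE(config$balance$train_only)) adasyn(train_tab, ytr, bc)
      else adasyn(tab, labels, bc)
    })
    if (isTRUE(config$balance$train_only)) {
      train_tab <- bal$table; ytr <- bal$labels$labels
    } else {
      sp2 <- stratified_split(bal$table, bal$labels,
                              split_spec(config$split_fraction,
                                         seed = config$seed + 2L))
      train_tab <- subset_table(bal$table, sp2$train)
      ytr <- bal$labels$labels[sp2$train]
      test_tab <- subset_table(bal$table, sp2$test)
      yte <- bal$labels$labels[sp2$test]
    }
    write_cohort(train_tab, file.path(config$outdir, "balanced_train"))
    manifest$stages$balance$fingerprint <-
      stage_fingerprint(train_tab, ytr)
  }

  # --- feature selection --------------------------------------------------
  if (isTRUE(config$select$enabled)) {
    sel <- tick("select", rfe_select(train_tab, ytr,
                                     tolerance = config$select$tolerance,
                                     step = config$select$step,
                                     seed = config$seed + 4L,
                                     nrounds = config$select$nrounds))
    keep <- match(sel$retained, train_tab$meta$name)
    train_tab <- feature_table(train_tab$values[, keep, drop = FALSE],
                               train_tab$meta[keep, ])
    keep_te <- match(sel$retained, test_tab$meta$name)
    test_tab <- feature_table(test_tab$values[, keep_te, drop = FALSE],
                              test_tab$meta[keep_te, ])
    manifest$stages$select$fingerprint <-
      list(n_retained = sel$n_retained,
           relative_loss = sel$relative_loss)
    jsonlite::write_json(
      list(retained = sel$retained, accuracy_curve = sel$accuracy_curve),
      file.path(config$outdir, "selection.json"), auto_unbox = TRUE,
      digits = NA)
  }

  # --- class count --------------------------------------------------------
  if (isTRUE(config$class_count$enabled) && !is.null(labels$source_hb)) {
    cc <- tick("class_count",
               best_approximation(filled$table, labels,
                                  candidates = config$class_count$candidates,
                                  seed = config$seed + 5L))
    manifest$stages$class_count$fingerprint <- list(chosen_K = cc$chosen_K)
    jsonlite::write_json(
      list(chosen_K = cc$chosen_K, elbow_K = cc$elbow_K,
           silhouette_K = cc$silhouette_K, similarity = cc$similarity),
      file.path(config$outdir, "classcount.json"), auto_unbox = TRUE,
      digits = NA)
  }

  # --- model --------------------------------------------------------------
  spec <- learner_spec(config$model$family, seed = config$seed + 6L)
  cv <- tick("cross_validate",
             cross_validate(spec, isTRUE(config$model$ecoc), train_tab, ytr,
                            folds = config$cv_folds, seed = config$seed + 7L,
                            code_scheme = config$model$code_scheme))
  pred <- tick("evaluate",
               fit_and_score(spec, isTRUE(config$model$ecoc),
                             train_tab$values, ytr, test_tab$values,
                             config$model$code_scheme))
  test_report <- compute_metrics(yte, pred$labels, pred$scores,
                                 classes = sort(unique(c(ytr, yte))))
  eval_out <- list(
    test = list(accuracy = test_report$accuracy,
                macro_f1 = test_report$macro_f1,
                micro_auc = test_report$micro_auc,
                per_class = test_report$per_class,
                confusion = as.data.frame.matrix(test_report$confusion)),
    cv_mean = cv$mean_report,
    cv_mean_confusion = as.data.frame.matrix(cv$mean_confusion))
  jsonlite::write_json(eval_out, file.path(config$outdir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$evaluate$fingerprint <-
    list(test_accuracy = test_report$accuracy,
         cv_accuracy = cv$mean_report$accuracy)

  manifest$artifacts <- as.list(list.files(config$outdir, full.names = TRUE))
  write_manifest(manifest, config$outdir)
  invisible(manifest)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$generator <- if (!is.null(snap$generator)) unclass(snap$generator)
  snap$impute$mlp <- unclass(snap$impute$mlp)
  snap
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
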