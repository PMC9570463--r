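# Evaluation protocols: repeated stratified k-fold cross-validation and
# chromosome-level hold-out. Protocols take a "recipe": a function
# (train_dataset, seed) -> function(windows) -> p_positive, so cheap
# reference models and the full deep classifier share one harness.

#' Stratified fold assignment
#'
#' Per-class shuffle then round-robin assignment, so per-fold class
#' imbalance is at most one record; folds partition the records exactly.
#'
#' @param labels binary label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold ids in `1..k`, parallel to `labels`.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    stop(sprintf("need at least k = %d records per class", k), call. = FALSE)
  }
  fold <- integer(length(labels))
  seeds <- derive_seeds(seed, length(unique(labels)))
  for (ci in seq_along(sort(unique(labels)))) {
    cl <- sort(unique(labels))[ci]
    idx <- which(labels == cl)
    idx <- with_seed(seeds[ci], sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Recipe wrapping the base classifier
#'
#' @param spec a [base_classifier_spec()].
#' @param valid_fraction stratified fraction carved from each training
#'   partition for early stopping.
#' @param scheme [feature_scheme()].
#' @return a recipe function `(train_dataset, seed) -> predictor`.
#' @export
base_classifier_recipe <- function(spec, valid_fraction = 0.15,
                                   scheme = feature_scheme()) {
  force(spec); force(valid_fraction); force(scheme)
  function(train_ds, seed) {
    sp <- spec
    sp$seed <- as.integer(seed %% .Machine$integer.max)
    plan <- train_test_split(train_ds, train_fraction = 1 - valid_fraction,
                             seed = seed)
    parts <- split_dataset(train_ds, plan)
    L <- 2L * train_ds$flank + 1L
    model <- build_base_classifier(sp, c(L, scheme$total_channels), scheme)
    model <- train_base_classifier(model, parts$train, parts$test)
    function(windows) predict_proba(model, windows)[, "p_positive"]
  }
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, records are partitioned into k stratified folds; each
#' fold is scored by a model trained on the remaining folds. Repeats
#' differ only by the fold-shuffling seed. Per-repeat metrics either pool
#' predictions across folds (default, `aggregate = "pool"`) or average
#' per-fold metrics (`"average"`); the report gives mean and SD across
#' repeats.
#'
#' @param dataset an `m6am_dataset` with at least k records per class.
#' @param recipe model recipe (see [base_classifier_recipe()]).
#' @param k folds (default 5).
#' @param repeats repetitions (default 20).
#' @param seed integer master seed.
#' @param aggregate `"pool"` or `"average"`.
#' @param verbose log progress.
#' @return list with `mean`, `sd` (named metric vectors; `sd` is NULL for
#'   a single repeat) and the per-repeat data.frame `per_repeat`.
#' @export
repeated_kfold_cv <- function(dataset, recipe, k = 5L, repeats = 20L,
                              seed = 1L, aggregate = c("pool", "average"),
                              verbose = FALSE) {
  aggregate <- match.arg(aggregate)
  recs <- dataset$records
  seeds <- derive_seeds(seed, repeats * (k + 1L))
  per_repeat <- list()
  si <- 0L
  for (r in seq_len(repeats)) {
    si <- si + 1L
    fold <- make_stratified_folds(recs$label, k, seeds[si])
    fold_metrics <- list()
    y_all <- integer(0); p_all <- numeric(0)
    for (f in seq_len(k)) {
      si <- si + 1L
      train_ds <- new_m6am_dataset(recs[fold != f, , drop = FALSE],
                                   dataset$flank, dataset$provenance)
      test_recs <- recs[fold == f, , drop = FALSE]
      predictor <- recipe(train_ds, seeds[si])
      p <- predictor(setNames(test_recs$window, test_recs$record_id))
      y_all <- c(y_all, test_recs$label)
      p_all <- c(p_all, p)
      if (aggregate == "average") {
        fold_metrics[[f]] <- metrics_report(test_recs$label, p)
      }
    }
    m <- if (aggregate == "pool") {
      metrics_report(y_all, p_all)
    } else {
      as.list(colMeans(do.call(rbind, lapply(fold_metrics, as.data.frame))))
    }
    per_repeat[[r]] <- as.data.frame(m)
    msg("repeat %d/%d: ACC %.4f AUROC %.4f", r, repeats, m$ACC, m$AUROC,
        verbose = verbose)
  }
  df <- do.call(rbind, per_repeat)
  list(mean = colMeans(df),
       sd = if (repeats > 1L) apply(df, 2, stats::sd) else NULL,
       per_repeat = df, k = k, repeats = repeats, aggregate = aggregate)
}

#' Chromosome-level hold-out evaluation
#'
#' Runs one train/evaluate cycle per split plan with an identical recipe
#' (the strict generalization protocol: all windows of the held-out
#' chromosome group are unseen at training time). Training failures are
#' reported per group and do not abort the remaining groups. Groups whose
#' test partition contains a single class get NA AUROC/AUPR; threshold
#' metrics are still reported.
#'
#' @param dataset a chromosome-annotated `m6am_dataset`.
#' @param plans list of plans from [chromosome_holdout_groups()].
#' @param recipe model recipe (see [base_classifier_recipe()]).
#' @param seed integer master seed.
#' @param verbose log progress.
#' @return data.frame: one row per group with n_test and the metrics.
#' @export
holdout_eval <- function(dataset, plans, recipe, seed = 1L,
                         verbose = FALSE) {
  seeds <- derive_seeds(seed, length(plans))
  rows <- lapply(seq_along(plans), function(i) {
    plan <- plans[[i]]
    parts <- split_dataset(dataset, plan)
    res <- tryCatch({
      predictor <- recipe(parts$train, seeds[i])
      te <- parts$test$records
      p <- predictor(setNames(te$window, te$record_id))
      m <- metrics_report(te$label, p, strict = FALSE)
      data.frame(group = plan$name, n_test = nrow(te), as.data.frame(m),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(group = plan$name, n_test = NA_integer_, Sn = NA, Sp = NA,
                 ACC = NA, MCC = NA, AUROC = NA, AUPR = NA,
                 error = conditionMessage(e))
    })
    msg("group %s: ACC %s AUROC %s", plan$name,
        format(res$ACC, digits = 4), format(res$AUROC, digits = 4),
        verbose = verbose)
    res
  })
  do.call(rbind, rows)
}

#' Write a metrics report to TSV and JSON
#'
#' @param metrics named list or data.frame of metric values.
#' @param prefix output prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return invisible named vector of paths.
#' @export
write_metrics <- function(metrics, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(metrics)
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(metrics, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(tsv = paste0(prefix, ".tsv"), json = paste0(prefix, ".json")))
}
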