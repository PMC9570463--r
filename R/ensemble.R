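# Hyper-parameter search, top-k selection and soft-voting aggregation.

#' Default hyper-parameter grid
#'
#' Varies conv filters, LSTM hidden size, attention heads and dropout
#' around the defaults, truncated to keep desk-scale runtime; fully
#' overridable by passing any list of [base_classifier_spec()]s to
#' [hyperparameter_search()].
#'
#' @param n_specs truncate the grid to the first `n_specs` entries.
#' @param seed base seed; spec i uses `seed + i`.
#' @param ... overrides forwarded to every [base_classifier_spec()] call
#'   (e.g. `max_epochs`, `window_length`).
#' @return list of `base_classifier_spec`.
#' @export
default_grid <- function(n_specs = 12L, seed = 1L, ...) {
  combos <- expand.grid(conv = c(32L, 64L), lstm = c(32L, 64L),
                        heads = c(2L, 4L), dropout = c(0.3, 0.5))
  combos <- head(combos, n_specs)
  base <- list(...)
  lapply(seq_len(nrow(combos)), function(i) {
    varied <- list(conv1_filters = combos$conv[i],
                   conv2_filters = combos$conv[i],
                   lstm_hidden = combos$lstm[i],
                   attention_heads = combos$heads[i],
                   dropout_rates = rep(combos$dropout[i], 2),
                   seed = seed + i)
    do.call(base_classifier_spec, utils::modifyList(base, varied))
  })
}

#' Train a grid of specs and rank by validation accuracy
#'
#' Each spec is trained under the stated protocol (by default a single
#' stratified validation split carved from the training data). Selection
#' accuracy is measured on held-out validation data, not training data,
#' to avoid selecting overfit members. A failing member is logged and
#' skipped; it is an error only if all members fail.
#'
#' @param grid non-empty list of [base_classifier_spec()]s.
#' @param train an `m6am_dataset` of training records.
#' @param valid_fraction fraction of `train` carved off (stratified) for
#'   validation when `valid` is NULL.
#' @param valid optional explicit validation `m6am_dataset`.
#' @param seed integer seed for the validation carve.
#' @param scheme [feature_scheme()] for encoding.
#' @param verbose log progress.
#' @return object of class `candidate_pool`: list of entries
#'   `(spec, model, validation_acc)` sorted by validation ACC descending
#'   (ties broken by grid order).
#' @export
hyperparameter_search <- function(grid, train, valid_fraction = 0.2,
                                  valid = NULL, seed = 1L,
                                  scheme = feature_scheme(),
                                  verbose = FALSE) {
  if (!length(grid)) stop("empty spec grid", call. = FALSE)
  if (is.null(valid)) {
    plan <- train_test_split(train, train_fraction = 1 - valid_fraction,
                             seed = seed)
    parts <- split_dataset(train, plan)
    fit_ds <- parts$train; valid <- parts$test
  } else {
    fit_ds <- train
  }
  L <- 2L * fit_ds$flank + 1L
  entries <- list()
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    entry <- tryCatch({
      model <- build_base_classifier(spec,
                                     input_shape = c(L, scheme$total_channels),
                                     scheme = scheme)
      model <- train_base_classifier(model, fit_ds, valid, verbose = FALSE)
      msg("spec %d/%d: val ACC %.4f", i, length(grid),
          model$validation_acc, verbose = verbose)
      list(spec = spec, model = model,
           validation_acc = model$validation_acc, grid_index = i)
    }, error = function(e) {
      msg("spec %d/%d failed: %s", i, length(grid), conditionMessage(e),
          verbose = TRUE)
      NULL
    })
    if (!is.null(entry)) entries[[length(entries) + 1L]] <- entry
  }
  if (!length(entries)) stop("all grid members failed to train",
                             call. = FALSE)
  accs <- vapply(entries, `[[`, numeric(1), "validation_acc")
  idx <- vapply(entries, `[[`, integer(1), "grid_index")
  entries <- entries[order(-accs, idx)]
  structure(entries, class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("<candidate_pool> %d candidates, val ACC %s\n", length(x),
              paste(sprintf("%.3f", vapply(x, `[[`, numeric(1),
                                           "validation_acc")),
                    collapse = ", ")))
  invisible(x)
}

#' Select the top-k members into a soft-voting ensemble
#'
#' Takes the k highest validation-ACC members (default 3; ties broken by
#' earlier grid order, which the pool ordering already encodes) and fixes
#' the aggregation rule to the arithmetic mean of member probability
#' vectors at threshold 0.5.
#'
#' @param pool a `candidate_pool`.
#' @param k ensemble size (default 3).
#' @param voting `"soft"` (probability averaging, canonical) or `"hard"`
#'   (majority vote on member labels).
#' @return object of class `ensemble_model`.
#' @export
select_top_k <- function(pool, k = 3L, voting = c("soft", "hard")) {
  voting <- match.arg(voting)
  if (length(pool) < k) {
    stop(sprintf("pool has %d candidates but k = %d; use a smaller k",
                 length(pool), k), call. = FALSE)
  }
  members <- lapply(pool[seq_len(k)], `[[`, "model")
  accs <- vapply(pool[seq_len(k)], `[[`, numeric(1), "validation_acc")
  structure(list(members = members, member_acc = accs, k = as.integer(k),
                 voting = voting, threshold = 0.5),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members (%s voting), member val ACC %s\n",
              x$k, x$voting,
              paste(sprintf("%.3f", x$member_acc), collapse = ", ")))
  invisible(x)
}

#' Ensemble prediction
#'
#' Soft voting: the final probability vector is the arithmetic mean of the
#' member probability vectors; the hard label is positive iff the mean
#' positive probability is >= the threshold (ties predicted positive).
#'
#' @param model an `ensemble_model`.
#' @param windows character vector of windows or an `m6am_dataset`.
#' @return data.frame with `p_negative`, `p_positive`, `label`
#'   (plus member probabilities as attribute `member_probs`).
#' @export
ensemble_predict <- function(model, windows) {
  stopifnot(inherits(model, "ensemble_model"))
  probs <- lapply(model$members, predict_proba, windows = windows)
  if (model$voting == "soft") {
    P <- Reduce(`+`, probs) / length(probs)
    label <- as.integer(P[, "p_positive"] >= model$threshold)
  } else {
    votes <- Reduce(`+`, lapply(probs, function(p) {
      as.integer(p[, "p_positive"] >= model$threshold)
    }))
    label <- as.integer(votes >= length(probs) / 2)
    P <- Reduce(`+`, probs) / length(probs)  # reported for reference
  }
  out <- data.frame(p_negative = P[, "p_negative"],
                    p_positive = P[, "p_positive"], label = label)
  attr(out, "member_probs") <- probs
  out
}

#' Save an ensemble checkpoint
#'
#' Directory of member checkpoints plus a `manifest.json` recording member
#' order, validation accuracies, aggregation rule and threshold.
#'
#' @param model an `ensemble_model`.
#' @param dir checkpoint directory.
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  member_dirs <- sprintf("member_%02d", seq_len(model$k))
  for (i in seq_len(model$k)) {
    save_classifier(model$members[[i]], file.path(dir, member_dirs[i]))
  }
  manifest <- list(format = "m6amnet-ensemble", format_version = 1L,
                   package_version = .m6amnet_version(),
                   members = member_dirs, member_acc = model$member_acc,
                   voting = model$voting, threshold = model$threshold)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load an ensemble checkpoint
#'
#' @param dir directory written by [save_ensemble()].
#' @return an `ensemble_model`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "m6amnet-ensemble")) {
    stop("not an ensemble checkpoint", call. = FALSE)
  }
  members <- lapply(manifest$members, function(m) {
    load_classifier(file.path(dir, m))
  })
  structure(list(members = members, member_acc = manifest$member_acc,
                 k = length(members), voting = manifest$voting,
                 threshold = manifest$threshold),
            class = "ensemble_model")
}
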