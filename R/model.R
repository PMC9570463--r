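# Base classifier: multi-head self-attention front-end feeding two
# parallel branches (CNN: conv -> conv -> maxpool -> flatten; BiLSTM:
# final states -> FC + ReLU), concatenated into a two-layer softmax head
# with dropout after each head layer.

#' Hyper-parameter specification for one base classifier
#'
#' Defaults are desk-scale standards for 41 x 8 fused-encoding inputs; the
#' originally tuned layer sizes are not public, so every size is exposed
#' here and the ensemble's hyper-parameter search explores a grid around
#' these values.
#'
#' @param attention_heads number of self-attention heads.
#' @param attention_model_dim attention projection width (must be divisible
#'   by `attention_heads`).
#' @param conv1_filters,conv1_kernel,conv2_filters,conv2_kernel the two
#'   convolution layers of the CNN branch.
#' @param pool_size temporal max-pool width (= stride).
#' @param lstm_hidden hidden units per LSTM direction.
#' @param branch_fc_dim width of the FC + ReLU after the BiLSTM.
#' @param head_fc_dims widths of the two head layers (second must be 2).
#' @param dropout_rates dropout after each head layer, in `[0, 1)`.
#' @param learning_rate,batch_size,max_epochs,patience Adam training
#'   schedule; early stopping monitors validation accuracy.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param ablation character subset of
#'   `c("no_attention", "cnn_only", "bilstm_only")`.
#' @param attention_mode `"shared"` (one attention module feeds both
#'   branches) or `"per_branch"` (each branch gets its own module).
#' @param window_length expected input window length (default 41).
#' @return object of class `base_classifier_spec`.
#' @export
base_classifier_spec <- function(attention_heads = 4L,
                                 attention_model_dim = 64L,
                                 conv1_filters = 64L, conv1_kernel = 5L,
                                 conv2_filters = 64L, conv2_kernel = 3L,
                                 pool_size = 2L,
                                 lstm_hidden = 64L,
                                 branch_fc_dim = 64L,
                                 head_fc_dims = c(64L, 2L),
                                 dropout_rates = c(0.5, 0.5),
                                 learning_rate = 1e-3,
                                 batch_size = 64L,
                                 max_epochs = 100L,
                                 patience = 10L,
                                 seed = 1L,
                                 ablation = character(0),
                                 attention_mode = c("shared", "per_branch"),
                                 window_length = 41L) {
  attention_mode <- match.arg(attention_mode)
  spec <- list(attention_heads = as.integer(attention_heads),
               attention_model_dim = as.integer(attention_model_dim),
               conv1_filters = as.integer(conv1_filters),
               conv1_kernel = as.integer(conv1_kernel),
               conv2_filters = as.integer(conv2_filters),
               conv2_kernel = as.integer(conv2_kernel),
               pool_size = as.integer(pool_size),
               lstm_hidden = as.integer(lstm_hidden),
               branch_fc_dim = as.integer(branch_fc_dim),
               head_fc_dims = as.integer(head_fc_dims),
               dropout_rates = as.numeric(dropout_rates),
               learning_rate = learning_rate,
               batch_size = as.integer(batch_size),
               max_epochs = as.integer(max_epochs),
               patience = as.integer(patience),
               seed = as.integer(seed),
               ablation = as.character(ablation),
               attention_mode = attention_mode,
               window_length = as.integer(window_length))
  .validate_spec(spec)
  structure(spec, class = "base_classifier_spec")
}

.validate_spec <- function(s) {
  if (s$attention_model_dim %% s$attention_heads != 0L) {
    stop("attention_model_dim must be divisible by attention_heads",
         call. = FALSE)
  }
  if (any(c(s$attention_heads, s$attention_model_dim, s$conv1_filters,
            s$conv1_kernel, s$conv2_filters, s$conv2_kernel, s$pool_size,
            s$lstm_hidden, s$branch_fc_dim, s$head_fc_dims,
            s$batch_size, s$max_epochs) < 1L)) {
    stop("all layer sizes must be positive", call. = FALSE)
  }
  if (length(s$head_fc_dims) != 2L || s$head_fc_dims[2] != 2L) {
    stop("head_fc_dims must be a pair ending in 2 (binary softmax)",
         call. = FALSE)
  }
  if (length(s$dropout_rates) != 2L ||
      any(s$dropout_rates < 0 | s$dropout_rates >= 1)) {
    stop("dropout_rates must be two fractions in [0, 1)", call. = FALSE)
  }
  bad <- setdiff(s$ablation, c("no_attention", "cnn_only", "bilstm_only"))
  if (length(bad)) stop(sprintf("unknown ablation flag(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  if (all(c("cnn_only", "bilstm_only") %in% s$ablation)) {
    stop("cnn_only and bilstm_only are mutually exclusive", call. = FALSE)
  }
  L <- s$window_length
  if (max(s$conv1_kernel, s$conv2_kernel) > L) {
    stop("kernel sizes must not exceed the window length", call. = FALSE)
  }
  Lc <- L - s$conv1_kernel + 1L - s$conv2_kernel + 1L
  if (Lc < s$pool_size) {
    stop("pool_size larger than the post-convolution length", call. = FALSE)
  }
  invisible(s)
}

.has_cnn <- function(spec) !("bilstm_only" %in% spec$ablation)
.has_lstm <- function(spec) !("cnn_only" %in% spec$ablation)
.has_attn <- function(spec) !("no_attention" %in% spec$ablation)

#' Build an untrained base classifier
#'
#' Instantiates the network topology for `input_shape = c(L, C)` inputs
#' (default 41 x 8 fused encodings) with Glorot-uniform weights drawn
#' under `spec$seed`.
#'
#' @param spec a [base_classifier_spec()].
#' @param input_shape integer pair `c(L, C)`.
#' @param scheme the [feature_scheme()] the model expects at prediction
#'   time.
#' @return object of class `base_classifier` (untrained).
#' @export
build_base_classifier <- function(spec, input_shape = c(41L, 8L),
                                  scheme = feature_scheme()) {
  stopifnot(inherits(spec, "base_classifier_spec"))
  L <- as.integer(input_shape[1]); C <- as.integer(input_shape[2])
  if (L != spec$window_length) {
    stop("input_shape length differs from spec$window_length", call. = FALSE)
  }
  if (!inherits(scheme, "feature_scheme")) scheme <- feature_scheme(scheme)
  if (scheme$total_channels != C) {
    stop("scheme channel count differs from input_shape", call. = FALSE)
  }
  D <- if (.has_attn(spec)) spec$attention_model_dim else C
  params <- with_seed(spec$seed, {
    p <- list()
    if (.has_attn(spec)) {
      if (spec$attention_mode == "shared") {
        p$att <- attn_init(C, spec$attention_model_dim)
      } else {
        if (.has_cnn(spec)) p$att_cnn <- attn_init(C, spec$attention_model_dim)
        if (.has_lstm(spec)) p$att_lstm <- attn_init(C, spec$attention_model_dim)
      }
    }
    feat_dim <- 0L
    if (.has_cnn(spec)) {
      p$conv1 <- conv_init(D, spec$conv1_kernel, spec$conv1_filters)
      p$conv2 <- conv_init(spec$conv1_filters, spec$conv2_kernel,
                           spec$conv2_filters)
      Lc <- L - spec$conv1_kernel + 1L - spec$conv2_kernel + 1L
      Lp <- Lc %/% spec$pool_size
      feat_dim <- feat_dim + Lp * spec$conv2_filters
    }
    if (.has_lstm(spec)) {
      p$lstm_f <- lstm_init(D, spec$lstm_hidden)
      p$lstm_b <- lstm_init(D, spec$lstm_hidden)
      p$lstm_fc <- dense_init(2L * spec$lstm_hidden, spec$branch_fc_dim)
      feat_dim <- feat_dim + spec$branch_fc_dim
    }
    p$fc1 <- dense_init(feat_dim, spec$head_fc_dims[1])
    p$fc2 <- dense_init(spec$head_fc_dims[1], spec$head_fc_dims[2])
    p
  })
  structure(list(spec = spec, params = params, input_shape = c(L, C),
                 scheme = scheme, trained = FALSE,
                 validation_acc = NA_real_, log = NULL),
            class = "base_classifier")
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("<base_classifier> input %d x %d, %s, %d parameters%s\n",
              x$input_shape[1], x$input_shape[2],
              if (length(x$spec$ablation)) paste("ablation:",
                paste(x$spec$ablation, collapse = "+")) else "full",
              n_parameters(x),
              if (x$trained) sprintf(", trained (val ACC %.3f)",
                                     x$validation_acc) else ", untrained"))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `base_classifier`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, numeric(1)))
    else if (is.numeric(x)) length(x)
    else 0
  }
  # conv kernel-size bookkeeping fields are scalars, not weights
  total <- cnt(model$params)
  for (nm in c("conv1", "conv2")) {
    if (!is.null(model$params[[nm]])) total <- total - 1L
  }
  as.integer(total)
}

# Full forward pass. Xm: (n*L) x C sample-major matrix. Returns logits,
# probabilities and caches for backprop.
nn_forward <- function(model, Xm, n, train = FALSE) {
  spec <- model$spec
  p <- model$params
  L <- model$input_shape[1]
  cache <- list()
  feats <- list()
  a_cnn <- Xm; a_lstm <- Xm
  if (.has_attn(spec)) {
    if (spec$attention_mode == "shared") {
      att <- attn_forward(p$att, Xm, n, L, spec$attention_heads)
      cache$att <- att$cache
      a_cnn <- att$out; a_lstm <- att$out
    } else {
      if (.has_cnn(spec)) {
        att <- attn_forward(p$att_cnn, Xm, n, L, spec$attention_heads)
        cache$att_cnn <- att$cache; a_cnn <- att$out
      }
      if (.has_lstm(spec)) {
        att <- attn_forward(p$att_lstm, Xm, n, L, spec$attention_heads)
        cache$att_lstm <- att$cache; a_lstm <- att$out
      }
    }
  }
  if (.has_cnn(spec)) {
    c1 <- conv_forward(p$conv1, a_cnn, n, L)
    L1 <- L - spec$conv1_kernel + 1L
    c2 <- conv_forward(p$conv2, c1$out, n, L1)
    L2 <- L1 - spec$conv2_kernel + 1L
    pl <- pool_forward(c2$out, n, L2, spec$pool_size)
    Lp <- L2 %/% spec$pool_size
    feats$cnn <- flatten_forward(pl$out, n, Lp)
    cache$conv <- list(c1 = c1$cache, c2 = c2$cache, pool = pl$cache,
                       L1 = L1, L2 = L2, Lp = Lp, a_in = a_cnn)
  }
  if (.has_lstm(spec)) {
    lf <- lstm_forward(p$lstm_f, a_lstm, n, L, reverse = FALSE)
    lb <- lstm_forward(p$lstm_b, a_lstm, n, L, reverse = TRUE)
    fc <- dense_forward(p$lstm_fc, cbind(lf$out, lb$out), relu = TRUE)
    feats$lstm <- fc$out
    cache$lstm <- list(f = lf$cache, b = lb$cache, fc = fc$cache,
                       a_in = a_lstm)
  }
  feat <- do.call(cbind, feats)
  h1 <- dense_forward(p$fc1, feat, relu = TRUE)
  d1 <- dropout_forward(h1$out, spec$dropout_rates[1], train)
  h2 <- dense_forward(p$fc2, d1$out)
  d2 <- dropout_forward(h2$out, spec$dropout_rates[2], train)
  cache$head <- list(h1 = h1$cache, d1 = d1$cache, h2 = h2$cache,
                     d2 = d2$cache,
                     dims = vapply(feats, ncol, integer(1)))
  list(logits = d2$out, prob = softmax_rows(d2$out), cache = cache)
}

# Loss + gradients for one batch; labels in {0,1}.
nn_loss_grads <- function(model, Xm, n, labels, train = TRUE) {
  fw <- nn_forward(model, Xm, n, train = train)
  ce <- softmax_ce(fw$logits, labels)
  spec <- model$spec
  p <- model$params
  L <- model$input_shape[1]
  cache <- fw$cache
  g <- list()
  dd2 <- dropout_backward(cache$head$d2, ce$dlogits)
  b2 <- dense_backward(p$fc2, cache$head$h2, dd2)
  g$fc2 <- b2$grads
  dd1 <- dropout_backward(cache$head$d1, b2$dX)
  b1 <- dense_backward(p$fc1, cache$head$h1, dd1)
  g$fc1 <- b1$grads
  dims <- cache$head$dims
  dfeat <- b1$dX
  dX_att_cnn <- NULL; dX_att_lstm <- NULL
  at <- 0L
  for (nm in names(dims)) {
    dpart <- dfeat[, (at + 1L):(at + dims[[nm]]), drop = FALSE]
    at <- at + dims[[nm]]
    if (nm == "cnn") {
      cv <- cache$conv
      dpool_out <- flatten_backward(dpart, n, cv$Lp, spec$conv2_filters)
      dc2_out <- pool_backward(cv$pool, dpool_out)
      bc2 <- conv_backward(p$conv2, cv$c2, dc2_out)
      g$conv2 <- bc2$grads
      bc1 <- conv_backward(p$conv1, cv$c1, bc2$dX)
      g$conv1 <- bc1$grads
      dX_att_cnn <- bc1$dX
    } else {
      ls <- cache$lstm
      bfc <- dense_backward(p$lstm_fc, ls$fc, dpart)
      g$lstm_fc <- bfc$grads
      H <- spec$lstm_hidden
      bf <- lstm_backward(p$lstm_f, ls$f, ls$a_in,
                          bfc$dX[, seq_len(H), drop = FALSE])
      bb <- lstm_backward(p$lstm_b, ls$b, ls$a_in,
                          bfc$dX[, H + seq_len(H), drop = FALSE])
      g$lstm_f <- bf$grads
      g$lstm_b <- bb$grads
      dX_att_lstm <- bf$dX + bb$dX
    }
  }
  if (.has_attn(spec)) {
    if (spec$attention_mode == "shared") {
      dA <- NULL
      if (!is.null(dX_att_cnn)) dA <- dX_att_cnn
      if (!is.null(dX_att_lstm)) {
        dA <- if (is.null(dA)) dX_att_lstm else dA + dX_att_lstm
      }
      g$att <- attn_backward(p$att, cache$att, dA)$grads
    } else {
      if (!is.null(dX_att_cnn)) {
        g$att_cnn <- attn_backward(p$att_cnn, cache$att_cnn, dX_att_cnn)$grads
      }
      if (!is.null(dX_att_lstm)) {
        g$att_lstm <- attn_backward(p$att_lstm, cache$att_lstm,
                                    dX_att_lstm)$grads
      }
    }
  }
  list(loss = ce$loss, prob = ce$prob, grads = g)
}

# Encode a dataset (or window vector) into the sample-major matrix form.
encode_to_mat <- function(windows, scheme) {
  X <- encode_windows(windows, scheme)
  n <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  # rows sample-major, time fastest within sample:
  # M[(i-1)*L + t, ch] == X[i, t, ch]
  M <- matrix(0, n * L, C)
  for (ch in seq_len(C)) M[, ch] <- as.vector(t(X[, , ch]))
  M
}

#' Train a base classifier
#'
#' Minimizes 2-class cross-entropy with Adam, shuffled mini-batches and
#' early stopping on validation accuracy (the model-selection metric);
#' the best-epoch weights are restored. Fully deterministic under
#' `spec$seed`.
#'
#' @param model an untrained [build_base_classifier()] result.
#' @param train,valid disjoint `m6am_dataset`s (or lists with `windows`
#'   and `labels`).
#' @param verbose log per-epoch progress to stderr.
#' @return the trained `base_classifier`, with a `log` data.frame
#'   (epoch, train_loss, val_acc, wall-clock) and `validation_acc` set.
#' @export
train_base_classifier <- function(model, train, valid, verbose = FALSE) {
  stopifnot(inherits(model, "base_classifier"))
  tr <- .as_xy(train)
  va <- .as_xy(valid)
  if (!length(tr$labels) || !length(va$labels)) {
    stop("empty training or validation partition", call. = FALSE)
  }
  if (length(intersect(tr$ids, va$ids)) > 0) {
    stop("train and validation partitions overlap", call. = FALSE)
  }
  spec <- model$spec
  L <- model$input_shape[1]
  if (any(nchar(tr$windows) != L) || any(nchar(va$windows) != L)) {
    stop(sprintf("all windows must have length %d", L), call. = FALSE)
  }
  Xtr <- encode_to_mat(tr$windows, model$scheme)
  Xva <- encode_to_mat(va$windows, model$scheme)
  ntr <- length(tr$labels)
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_acc = numeric(), seconds = numeric())
  t0 <- proc.time()[3]
  with_seed(spec$seed + 1L, {
    wait <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(ntr)
      losses <- numeric(0)
      for (start in seq(1L, ntr, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, ntr)]
        nb <- length(idx)
        rows <- as.vector(outer(seq_len(L), (idx - 1L) * L, `+`))
        res <- nn_loss_grads(model, Xtr[rows, , drop = FALSE], nb,
                             tr$labels[idx], train = TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                       epoch), call. = FALSE)
        }
        st <- adam_step(model$params, res$grads, state, spec$learning_rate)
        model$params <- st$params
        state <- st$state
        losses <- c(losses, res$loss)
      }
      pv <- nn_forward(model, Xva, length(va$labels), train = FALSE)$prob
      val_acc <- mean((pv[, 2] >= 0.5) == (va$labels == 1L))
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_acc = val_acc,
                                   seconds = proc.time()[3] - t0))
      msg("epoch %3d  loss %.4f  val ACC %.4f", epoch, mean(losses),
          val_acc, verbose = verbose)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$validation_acc <- best$acc
  model$log <- log
  attr(model$log, "best_epoch") <- best$epoch
  model
}

.as_xy <- function(x) {
  if (inherits(x, "m6am_dataset")) {
    list(windows = x$records$window, labels = as.integer(x$records$label),
         ids = x$records$record_id)
  } else {
    list(windows = x$windows, labels = as.integer(x$labels),
         ids = x$ids %||% x$windows)
  }
}

#' Predict class probabilities for RNA windows
#'
#' @param model a trained `base_classifier`.
#' @param windows character vector of validated windows matching the
#'   model's window length, or an `m6am_dataset`.
#' @return numeric matrix with columns `p_negative`, `p_positive`; rows
#'   sum to 1.
#' @export
predict_proba <- function(model, windows) {
  stopifnot(inherits(model, "base_classifier"))
  if (inherits(windows, "m6am_dataset")) windows <- windows$records$window
  L <- model$input_shape[1]
  bad <- which(nchar(windows) != L)
  if (length(bad)) {
    stop(sprintf("window length must be %d; offending record(s): %s", L,
                 paste(head(names(windows)[bad] %||% bad, 5),
                       collapse = ", ")), call. = FALSE)
  }
  Xm <- encode_to_mat(windows, model$scheme)
  P <- nn_forward(model, Xm, length(windows), train = FALSE)$prob
  colnames(P) <- c("p_negative", "p_positive")
  rownames(P) <- names(windows)
  P
}

#' Save a base classifier checkpoint
#'
#' A checkpoint is a directory holding the weights plus a JSON sidecar
#' embedding the spec, so it is self-describing.
#'
#' @param model a `base_classifier`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  side <- list(format = "m6amnet-base-classifier", format_version = 1L,
               package_version = .m6amnet_version(),
               spec = unclass(model$spec),
               scheme = model$scheme$encoders,
               input_shape = model$input_shape,
               trained = model$trained,
               validation_acc = model$validation_acc)
  jsonlite::write_json(side, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  saveRDS(model$params, file.path(dir, "weights.rds"))
  if (!is.null(model$log)) {
    write.table(model$log, file.path(dir, "training-log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a base classifier checkpoint
#'
#' @param dir directory written by [save_classifier()].
#' @return a `base_classifier`.
#' @export
load_classifier <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  if (!identical(side$format, "m6amnet-base-classifier")) {
    stop("not a base-classifier checkpoint", call. = FALSE)
  }
  sp <- side$spec
  spec <- base_classifier_spec(
    attention_heads = sp$attention_heads,
    attention_model_dim = sp$attention_model_dim,
    conv1_filters = sp$conv1_filters, conv1_kernel = sp$conv1_kernel,
    conv2_filters = sp$conv2_filters, conv2_kernel = sp$conv2_kernel,
    pool_size = sp$pool_size, lstm_hidden = sp$lstm_hidden,
    branch_fc_dim = sp$branch_fc_dim, head_fc_dims = sp$head_fc_dims,
    dropout_rates = sp$dropout_rates, learning_rate = sp$learning_rate,
    batch_size = sp$batch_size, max_epochs = sp$max_epochs,
    patience = sp$patience, seed = sp$seed,
    ablation = sp$ablation %||% character(0),
    attention_mode = sp$attention_mode, window_length = sp$window_length)
  model <- build_base_classifier(spec, input_shape = side$input_shape,
                                 scheme = feature_scheme(side$scheme))
  model$params <- readRDS(file.path(dir, "weights.rds"))
  model$trained <- isTRUE(side$trained)
  model$validation_acc <- side$validation_acc %||% NA_real_
  lp <- file.path(dir, "training-log.tsv")
  if (file.exists(lp)) model$log <- read.delim(lp)
  model
}
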