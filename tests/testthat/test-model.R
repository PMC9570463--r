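# Base classifier: architecture contracts, gradients, training behavior.

test_that("spec validation rejects inconsistent configurations", {
  expect_error(base_classifier_spec(attention_heads = 3,
                                    attention_model_dim = 64),
               "divisible")
  expect_error(base_classifier_spec(pool_size = 40), "pool_size")
  expect_error(base_classifier_spec(conv1_kernel = 50), "kernel")
  expect_error(base_classifier_spec(dropout_rates = c(1, 0.5)), "dropout")
  expect_error(base_classifier_spec(ablation = "lstm_off"), "unknown ablation")
  expect_error(base_classifier_spec(ablation = c("cnn_only", "bilstm_only")),
               "mutually exclusive")
  expect_error(base_classifier_spec(head_fc_dims = c(64, 3)), "pair")
})

test_that("forward pass returns valid softmax distributions", {
  model <- build_base_classifier(tiny_spec())
  wins <- random_windows(7, 41, seed = 31)
  P <- predict_proba(model, wins)
  expect_equal(dim(P), c(7, 2))
  expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
  # pure function at inference: duplicated window, identical probabilities
  P2 <- predict_proba(model, c(wins[1], wins[1]))
  expect_equal(P2[1, ], P2[2, ])
  expect_error(predict_proba(model, "ACGU"), "length must be 41")
})

test_that("ablations change the parameter set as documented", {
  full <- build_base_classifier(tiny_spec())
  cnn <- build_base_classifier(tiny_spec(ablation = "cnn_only"))
  lstm <- build_base_classifier(tiny_spec(ablation = "bilstm_only"))
  noatt <- build_base_classifier(tiny_spec(ablation = "no_attention"))
  expect_true(all(c("att", "conv1", "lstm_f") %in% names(full$params)))
  expect_false(any(grepl("lstm", names(cnn$params))))   # no recurrent weights
  expect_false(any(grepl("conv", names(lstm$params))))
  expect_false("att" %in% names(noatt$params))
  # per-branch attention instantiates two modules
  pb <- build_base_classifier(tiny_spec(attention_mode = "per_branch"))
  expect_true(all(c("att_cnn", "att_lstm") %in% names(pb$params)))
  # parameter budget under full defaults
  expect_lt(n_parameters(build_base_classifier(base_classifier_spec())),
            1e6)
})

test_that("analytic gradients match finite differences in every variant", {
  wins <- random_windows(3, 11, seed = 32)
  y <- c(0L, 1L, 1L)
  variants <- list(
    tiny_spec(window_length = 11L, dropout_rates = c(0, 0)),
    tiny_spec(window_length = 11L, dropout_rates = c(0, 0),
              ablation = "no_attention"),
    tiny_spec(window_length = 11L, dropout_rates = c(0, 0),
              ablation = "cnn_only"),
    tiny_spec(window_length = 11L, dropout_rates = c(0, 0),
              ablation = "bilstm_only"),
    tiny_spec(window_length = 11L, dropout_rates = c(0, 0),
              attention_mode = "per_branch"))
  for (spec in variants) {
    model <- build_base_classifier(spec, input_shape = c(11L, 8L))
    Xm <- m6amnet:::encode_to_mat(wins, model$scheme)
    expect_lt(check_grads(model, Xm, 3L, y), 1e-4)
  }
})

test_that("attention front-end preserves sequence length", {
  model <- build_base_classifier(tiny_spec())
  wins <- random_windows(2, 41, seed = 33)
  Xm <- m6amnet:::encode_to_mat(wins, model$scheme)
  att <- m6amnet:::attn_forward(model$params$att, Xm, 2L, 41L,
                                model$spec$attention_heads)
  expect_equal(nrow(att$out), 2L * 41L)
  expect_equal(ncol(att$out), model$spec$attention_model_dim)
})

test_that("training learns a strong planted motif and is reproducible", {
  ds <- small_synthetic(150, lambda = 1, seed = 34)
  plan <- train_test_split(ds, 0.8, seed = 1)
  parts <- split_dataset(ds, plan)
  spec <- tiny_spec(max_epochs = 30L, patience = 30L)
  m1 <- train_base_classifier(build_base_classifier(spec),
                              parts$train, parts$test)
  expect_true(m1$trained)
  expect_gt(m1$validation_acc, 0.9)
  P <- predict_proba(m1, parts$test)
  pos <- parts$test$records$label == 1L
  expect_gt(mean(P[pos, "p_positive"] > 0.5), 0.9)
  # identical seed and data -> identical loss trajectory
  m2 <- train_base_classifier(build_base_classifier(spec),
                              parts$train, parts$test)
  expect_identical(m1$log$train_loss, m2$log$train_loss)
  expect_identical(m1$validation_acc, m2$validation_acc)
  # training inputs must be disjoint
  expect_error(train_base_classifier(build_base_classifier(spec),
                                     parts$train, parts$train),
               "overlap")
})

test_that("null-signal data trains to chance accuracy", {
  ds <- small_synthetic(200, lambda = 0, seed = 35)
  plan <- train_test_split(ds, 0.5, seed = 2)
  parts <- split_dataset(ds, plan)
  m <- train_base_classifier(build_base_classifier(tiny_spec(max_epochs = 4L)),
                             parts$train, parts$test)
  P <- predict_proba(m, parts$test)
  auc <- roc_auc(parts$test$records$label, P[, "p_positive"])
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("classifier checkpoints round-trip exactly", {
  ds <- small_synthetic(60, seed = 36)
  plan <- train_test_split(ds, 0.8, seed = 3)
  parts <- split_dataset(ds, plan)
  m <- train_base_classifier(build_base_classifier(tiny_spec(max_epochs = 2L)),
                             parts$train, parts$test)
  dir <- file.path(withr::local_tempdir(), "ckpt")
  save_classifier(m, dir)
  expect_true(file.exists(file.path(dir, "spec.json")))
  m2 <- load_classifier(dir)
  wins <- random_windows(5, 41, seed = 37)
  expect_equal(predict_proba(m2, wins), predict_proba(m, wins))
  expect_equal(m2$validation_acc, m$validation_acc)
})

test_that("attention helps on average across seeds (soft property)", {
  # scaled-down ablation comparison: mean over 5 seeds (independent
  # datasets) of full-minus-no-attention ACC; statistical, so a small
  # noise slack is allowed rather than a hard per-seed assert
  diff_for_seed <- function(s) {
    ds <- small_synthetic(200, lambda = 0.9, seed = 80 + s)
    plan <- train_test_split(ds, 0.6, seed = s)
    parts <- split_dataset(ds, plan)
    acc <- function(spec) {
      m <- train_base_classifier(build_base_classifier(spec),
                                 parts$train, parts$test)
      P <- predict_proba(m, parts$test)
      mean((P[, 2] >= 0.5) == (parts$test$records$label == 1L))
    }
    acc(tiny_spec(seed = 100 + s, max_epochs = 15L, patience = 15L)) -
      acc(tiny_spec(seed = 100 + s, max_epochs = 15L, patience = 15L,
                    ablation = "no_attention"))
  }
  diffs <- vapply(1:5, diff_for_seed, numeric(1))
  expect_gte(mean(diffs), -0.05)
})
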