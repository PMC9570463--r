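# Candidate pools, top-k selection, soft voting and serialization.

test_that("select_top_k picks the highest-ACC members with stable ties", {
  specs <- lapply(1:4, function(i) tiny_spec(seed = i))
  pool <- fake_pool(specs, c(0.80, 0.78, 0.77, 0.70))
  ens <- select_top_k(pool, k = 3)
  expect_equal(ens$member_acc, c(0.80, 0.78, 0.77))
  # boundary tie: earlier-listed spec wins
  pool_tie <- fake_pool(specs, c(0.80, 0.77, 0.77, 0.77))
  ens_tie <- select_top_k(pool_tie, k = 3)
  expect_equal(vapply(ens_tie$members, function(m) m$spec$seed, integer(1)),
               c(1L, 2L, 3L))
  # k = |pool| returns the whole pool; k > |pool| errors helpfully
  expect_equal(select_top_k(pool, k = 4)$k, 4L)
  expect_error(select_top_k(pool, k = 5), "smaller k")
})

test_that("soft voting is the arithmetic mean, bounded by member extremes", {
  specs <- lapply(1:3, function(i) tiny_spec(seed = 10 + i))
  ens <- select_top_k(fake_pool(specs, c(0.7, 0.6, 0.5)), k = 3)
  wins <- random_windows(20, 41, seed = 41)
  pr <- ensemble_predict(ens, wins)
  member <- lapply(ens$members, predict_proba, windows = wins)
  manual <- (member[[1]] + member[[2]] + member[[3]]) / 3
  expect_equal(pr$p_positive, unname(manual[, "p_positive"]))
  expect_equal(pr$p_negative + pr$p_positive, rep(1, 20), tolerance = 1e-12)
  mins <- pmin(member[[1]][, 2], member[[2]][, 2], member[[3]][, 2])
  maxs <- pmax(member[[1]][, 2], member[[2]][, 2], member[[3]][, 2])
  expect_true(all(pr$p_positive >= mins - 1e-12 &
                  pr$p_positive <= maxs + 1e-12))
  expect_equal(pr$label, as.integer(pr$p_positive >= 0.5))

  # identical members: ensemble equals any member
  ens_same <- select_top_k(fake_pool(list(tiny_spec(seed = 9),
                                          tiny_spec(seed = 9)),
                                     c(0.6, 0.6)), k = 2)
  pr_same <- ensemble_predict(ens_same, wins)
  expect_equal(pr_same$p_positive,
               unname(predict_proba(ens_same$members[[1]], wins)[, 2]))
})

test_that("the documented 0.5 tie rule labels positive", {
  # hand-built member probabilities via the documented mean rule
  specs <- lapply(1:3, function(i) tiny_spec(seed = 20 + i))
  ens <- select_top_k(fake_pool(specs, c(0.7, 0.6, 0.5)), k = 3)
  # mean of (0.9, 0.6, 0.3) = 0.6 -> positive
  expect_equal(mean(c(0.9, 0.6, 0.3)), 0.6)
  expect_equal(as.integer(mean(c(0.5, 0.5, 0.5)) >= ens$threshold), 1L)
})

test_that("hyperparameter_search ranks and reproduces on synthetic data", {
  ds <- small_synthetic(80, seed = 42)
  grid <- lapply(1:3, function(i) {
    tiny_spec(seed = 50 + i, max_epochs = 3L,
              lstm_hidden = c(4L, 8L, 12L)[i])
  })
  pool <- hyperparameter_search(grid, ds, seed = 5)
  expect_s3_class(pool, "candidate_pool")
  expect_length(pool, 3)
  accs <- vapply(pool, `[[`, numeric(1), "validation_acc")
  expect_true(all(diff(accs) <= 0))  # sorted descending
  pool2 <- hyperparameter_search(grid, ds, seed = 5)
  expect_equal(accs, vapply(pool2, `[[`, numeric(1), "validation_acc"))
  # grid of one
  expect_length(hyperparameter_search(grid[1], ds, seed = 5), 1)
  expect_error(hyperparameter_search(list(), ds), "empty")
})

test_that("ensemble checkpoints round-trip to identical predictions", {
  specs <- lapply(1:3, function(i) tiny_spec(seed = 30 + i))
  ens <- select_top_k(fake_pool(specs, c(0.7, 0.65, 0.6)), k = 3)
  dir <- file.path(withr::local_tempdir(), "ens")
  save_ensemble(ens, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$voting, "soft")
  expect_length(manifest$members, 3)
  back <- load_ensemble(dir)
  wins <- random_windows(8, 41, seed = 43)
  expect_equal(ensemble_predict(back, wins)$p_positive,
               ensemble_predict(ens, wins)$p_positive)
})

test_that("ensembling does not hurt the best member (soft property)", {
  # mean over 5 seeds: ensemble ACC >= best-member ACC - 0.02 on held-out
  # data; statistical property at desk scale
  diffs <- vapply(1:5, function(s) {
    ds <- small_synthetic(200, lambda = 0.9, seed = 200 + s)
    plan <- train_test_split(ds, 0.6, seed = s)
    parts <- split_dataset(ds, plan)
    grid <- lapply(1:3, function(i) {
      tiny_spec(seed = 10 * s + i, max_epochs = 10L, patience = 10L,
                lstm_hidden = c(6L, 8L, 10L)[i])
    })
    pool <- hyperparameter_search(grid, parts$train, seed = s)
    ens <- select_top_k(pool, k = 3)
    y <- parts$test$records$label
    acc_of <- function(p) mean((p >= 0.5) == (y == 1L))
    member_acc <- vapply(ens$members, function(m) {
      acc_of(predict_proba(m, parts$test)[, 2])
    }, numeric(1))
    acc_of(ensemble_predict(ens, parts$test)$p_positive) - max(member_acc)
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})
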