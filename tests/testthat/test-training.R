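# Training protocol: split arithmetic and leakage guarantees, early
# stopping semantics, learning on solvable problems, fine-tuning splits.

test_that("fivefold splits give the 20/64/16 partition and are seeded", {
  plan <- make_cv_splits(100, k = 5, seed = 3)
  for (f in plan$folds) {
    expect_length(f$test, 20)
    expect_length(f$train, 64)
    expect_length(f$val, 16)
    expect_length(intersect(union(f$train, f$val), f$test), 0)
  }
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(all_test, 1:100)

  expect_identical(make_cv_splits(100, k = 5, seed = 3), plan)
  plan2 <- make_cv_splits(100, k = 5, seed = 4)
  expect_false(identical(plan2$folds[[1]]$test, plan$folds[[1]]$test))
  expect_error(make_cv_splits(3, k = 5), "at least k")
})

test_that("subject-wise splits never place a subject on both sides", {
  subj <- rep(sprintf("s%02d", 1:12), each = 9)
  plan <- make_cv_splits(subj, k = 4, split_mode = "subject", seed = 5)
  for (f in plan$folds) {
    expect_length(intersect(subj[f$test], subj[union(f$train, f$val)]), 0)
    expect_length(intersect(subj[f$train], subj[f$val]), 0)
  }
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(all_test, seq_along(subj))
})

test_that("a constant-label dataset is fitted almost immediately", {
  ws <- tone_window_set(n = 48, seed = 12)
  ws$rr_bpm <- rep(15, 48)
  m <- convmixer_build(tiny_spec(H = 8, depth = 1), seed = 12)
  fit <- train_convmixer(m, ws_subset(ws, 1:36), ws_subset(ws, 37:48),
                         train_config(epochs = 30, batch_size = 12,
                                      patience = 30, seed = 12))
  expect_lt(min(fit$history$train_loss), 0.1)
})

test_that("training reduces held-out error below the label-variance baseline", {
  ws <- tone_window_set(n = 120, seed = 14)
  tr <- ws_subset(ws, 1:80); va <- ws_subset(ws, 81:100)
  te <- ws_subset(ws, 101:120)
  m <- convmixer_build(tiny_spec(H = 16, depth = 2), seed = 14)
  fit <- train_convmixer(m, tr, va,
                         train_config(epochs = 40, batch_size = 32,
                                      learning_rate = 1e-2, patience = 40,
                                      seed = 14))
  mse <- mean((predict(fit$model, te) - te$rr_bpm)^2)
  expect_lt(mse, mean((te$rr_bpm - mean(tr$rr_bpm))^2))
  # history bookkeeping
  expect_named(fit$history, c("epoch", "train_loss", "val_loss"))
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("early stopping halts on patience and restores the best weights", {
  ws <- tone_window_set(n = 60, seed = 15, noise = 0.6)
  m <- convmixer_build(tiny_spec(H = 8, depth = 1), seed = 15)
  fit <- train_convmixer(m, ws_subset(ws, 1:40), ws_subset(ws, 41:60),
                         train_config(epochs = 200, batch_size = 16,
                                      learning_rate = 1e-2, patience = 1,
                                      seed = 15))
  n_run <- nrow(fit$history)
  expect_lt(n_run, 200)
  # best-val restoration: never worse than any recorded epoch or the start
  expect_lte(fit$best_val, min(fit$history$val_loss))
  expect_lte(fit$best_val, fit$history$val_loss[n_run])
  # restored model reproduces the chosen validation loss
  va <- ws_subset(ws, 41:60)
  expect_equal(mean((predict(fit$model, va) - va$rr_bpm)^2), fit$best_val,
               tolerance = 1e-9)
})

test_that("training is reproducible under fixed seeds", {
  ws <- tone_window_set(n = 40, seed = 16)
  run <- function() {
    m <- convmixer_build(tiny_spec(H = 8, depth = 1), seed = 16)
    fit <- train_convmixer(m, ws_subset(ws, 1:30), ws_subset(ws, 31:40),
                           train_config(epochs = 5, batch_size = 10,
                                        patience = 5, seed = 16))
    list(h = fit$history, p = predict(fit$model, ws$windows[1:5, ]))
  }
  a <- run(); b <- run()
  expect_equal(a$h, b$h, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("fine-tuning splits 10/10/80 and rejects bad fractions", {
  ws <- tone_window_set(n = 300, seed = 17)
  m <- convmixer_build(tiny_spec(H = 8, depth = 1), seed = 17)
  fit <- train_convmixer(m, ws_subset(ws, 1:40), ws_subset(ws, 41:60),
                         train_config(epochs = 3, batch_size = 16,
                                      patience = 3, seed = 17))
  ft <- fine_tune(fit$model, ws_subset(ws, 61:300),
                  train_config(epochs = 3, batch_size = 16, patience = 3,
                               seed = 17), seed = 17)
  expect_length(ft$test_idx, 192)           # 80 % of 240
  expect_equal(ft$predictions$n, 192)
  expect_error(fine_tune(fit$model, ws, fractions = c(0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("fine-tuning on the same domain does not catastrophically forget", {
  ws <- tone_window_set(n = 200, seed = 18)
  tr <- ws_subset(ws, 1:100); va <- ws_subset(ws, 101:130)
  rest <- ws_subset(ws, 131:200)
  m <- convmixer_build(tiny_spec(H = 16, depth = 1), seed = 18)
  fit <- train_convmixer(m, tr, va,
                         train_config(epochs = 30, batch_size = 32,
                                      learning_rate = 1e-2, patience = 30,
                                      seed = 18))
  ft <- fine_tune(fit$model, rest,
                  train_config(epochs = 10, batch_size = 8, patience = 10,
                               seed = 18), fractions = c(0.15, 0.15, 0.70),
                  seed = 18)
  te <- ws_subset(rest, ft$test_idx)
  mae_before <- mean(abs(predict(fit$model, te) - te$rr_bpm))
  mae_after <- mean(abs(ft$predictions$rr_pred - ft$predictions$rr_true))
  expect_lt(mae_after, 2 * mae_before + 0.5)
})

test_that("run_experiment orchestrates CV and degenerate cross-dataset", {
  ws <- tone_window_set(n = 90, seed = 19)
  cfg <- train_config(epochs = 4, batch_size = 16, learning_rate = 1e-2,
                      patience = 4, seed = 19)
  res <- run_experiment(ws, "intra_cv", spec = tiny_spec(H = 8, depth = 1),
                        cfg = cfg, k = 3, seed = 19)
  expect_s3_class(res$report, "metrics_report")
  expect_length(res$per_fold, 3)
  expect_equal(res$predictions$n, 90)       # pooled out-of-fold predictions

  # cross-dataset with train == test reduces to self-evaluation
  res2 <- run_experiment(list(ws, ws), "cross_dataset",
                         spec = tiny_spec(H = 8, depth = 1), cfg = cfg,
                         seed = 19)
  self_mae <- mean(abs(predict(res2$model, ws) - ws$rr_bpm))
  expect_equal(res2$report$mae, self_mae, tolerance = 1e-12)

  # combined CV pools all windows
  res3 <- run_experiment(list(ws_subset(ws, 1:45), ws_subset(ws, 46:90)),
                         "combined_cv", spec = tiny_spec(H = 8, depth = 1),
                         cfg = cfg, k = 3, seed = 19)
  expect_equal(res3$predictions$n, 90)

  expect_error(run_experiment(ws, "cross_dataset",
                              spec = tiny_spec(H = 8, depth = 1), cfg = cfg),
               "second dataset")
})
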