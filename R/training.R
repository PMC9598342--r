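# Training protocol: Adam on MSE with minibatches, early stopping on the
# validation loss with best-weight restoration, fivefold cross-validation
# (window- or subject-wise), and fine-tuning on a 10/10/80 split of a new
# domain.

#' Training configuration
#'
#' Defaults are the published protocol: up to 500 epochs, batch 128, Adam
#' with learning rate 1e-3, early-stopping patience 50 on the validation
#' loss, MSE objective.
#'
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience epochs without validation improvement before stopping
#'   (must not exceed `epochs`).
#' @param seed integer seed driving initial shuffling and batch order.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 128L,
                         learning_rate = 1e-3, patience = 50L, seed = 1L) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  patience <- as.integer(patience)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, patience >= 1)
  if (patience > epochs) stop("patience must not exceed epochs")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience,
                 loss = "mse", seed = as.integer(seed)),
            class = "train_config")
}

#' k-fold cross-validation splits
#'
#' Shuffles once with the seed, partitions into k disjoint, exhaustive test
#' folds, and splits the remainder of each fold 80/20 into train/validation.
#' In `"subject"` mode whole subjects are assigned to exactly one side of
#' every boundary (recommended: 50 %-overlap windows share samples, so
#' window-wise splits leak between train and test).
#'
#' @param n_or_subjects either the number of windows (window mode) or the
#'   per-window subject id vector (subject mode).
#' @param k number of folds (default 5).
#' @param split_mode `"window"` or `"subject"`.
#' @param seed integer seed for the shuffle.
#' @return object of class `fold_plan`: list with `k`, `split_mode`, `n`, and
#'   `folds`, each fold holding disjoint `train`, `val`, `test` index sets.
#' @export
make_cv_splits <- function(n_or_subjects, k = 5L, split_mode = c("window",
                           "subject"), seed = 1L) {
  split_mode <- match.arg(split_mode)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  if (split_mode == "window") {
    n <- as.integer(n_or_subjects)
    if (n < k) stop("need at least k observations")
    perm <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)  # balanced sizes
    folds <- lapply(seq_len(k), function(f) {
      test <- perm[fold_of == f]
      rest <- perm[fold_of != f]
      n_val <- round(0.2 * length(rest))
      list(train = sort(rest[seq_len(length(rest) - n_val)]),
           val = sort(rest[seq_len(n_val) + (length(rest) - n_val)]),
           test = sort(test))
    })
  } else {
    subj <- as.character(n_or_subjects)
    n <- length(subj)
    us <- unique(subj)
    if (length(us) < k) stop("need at least k subjects")
    perm_s <- sample(us)
    fold_of_s <- rep(seq_len(k), length.out = length(us))
    folds <- lapply(seq_len(k), function(f) {
      test_s <- perm_s[fold_of_s == f]
      rest_s <- perm_s[fold_of_s != f]
      n_val_s <- max(1L, round(0.2 * length(rest_s)))
      val_s <- rest_s[seq_len(n_val_s) + (length(rest_s) - n_val_s)]
      train_s <- setdiff(rest_s, val_s)
      list(train = which(subj %in% train_s),
           val = which(subj %in% val_s),
           test = which(subj %in% test_s))
    })
  }
  plan <- structure(list(k = as.integer(k), split_mode = split_mode, n = n,
                         folds = folds), class = "fold_plan")
  check_fold_plan(plan)
  plan
}

# leakage check, run on every plan
check_fold_plan <- function(plan) {
  all_test <- integer(0)
  for (f in plan$folds) {
    if (length(intersect(union(f$train, f$val), f$test)))
      stop("fold leakage: test overlaps train/val")
    if (length(intersect(f$train, f$val)))
      stop("fold leakage: train overlaps val")
    all_test <- c(all_test, f$test)
  }
  if (anyDuplicated(all_test) || length(all_test) != plan$n)
    stop("test folds do not partition the data")
  invisible(TRUE)
}

ws_labels <- function(ws) {
  if (is.null(ws$rr_bpm)) stop("window set is unlabelled")
  ws$rr_bpm
}

adam_conform <- function(g, p) {
  g <- as.numeric(g)
  if (is.matrix(p)) dim(g) <- dim(p)
  g
}

#' Train a ConvMixer
#'
#' Minimizes MSE with Adam; stops early when the validation loss has not
#' improved for `patience` epochs and restores the best-validation weights
#' (including running normalization statistics).
#'
#' @param model a [convmixer_build()] model.
#' @param train_ws,val_ws labelled [window_set()]s (non-empty) whose window
#'   length matches the model.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @param init_head_bias if `TRUE` (default) and the model is still at its
#'   freshly built zero head bias, the bias starts at the training-label
#'   mean. A scalar regression head otherwise spends most of a short run
#'   crawling its output from 0 towards the label scale.
#' @return list with `model` (best weights), `history` (data.frame `epoch`,
#'   `train_loss`, `val_loss`), `best_epoch` (0 when no epoch improved on the
#'   starting weights), `best_val`.
#' @export
train_convmixer <- function(model, train_ws, val_ws, cfg = train_config(),
                            verbose = FALSE, init_head_bias = TRUE) {
  X <- windows_matrix(train_ws); y <- ws_labels(train_ws)
  Xv <- windows_matrix(val_ws); yv <- ws_labels(val_ws)
  if (nrow(X) == 0L || nrow(Xv) == 0L) stop("empty train or validation set")
  if (ncol(X) != model$spec$input_length)
    stop("window length does not match model input length")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  p <- model$params
  if (init_head_bias && identical(p$head_b, 0)) p$head_b <- mean(y)
  m1 <- lapply(p, function(x) x * 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  mom <- model$bn_momentum
  # the starting weights are the epoch-0 candidate, so continued training
  # (fine-tuning in particular) can never return weights with a worse
  # validation loss than the model it started from
  model$params <- p
  init_val <- mean((predict(model, Xv) - yv)^2)
  best <- list(val = init_val, params = p, rstats = model$rstats, epoch = 0L)
  wait <- 0L
  hist_tr <- hist_val <- numeric(0)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(nrow(X))
    losses <- numeric(0); sizes <- integer(0)
    for (i0 in seq(1L, nrow(X), by = cfg$batch_size)) {
      idx <- perm[i0:min(i0 + cfg$batch_size - 1L, nrow(X))]
      if (length(idx) < 2L) next  # batchnorm needs >= 2 rows
      res <- cm_grad_cpp(p, X[idx, , drop = FALSE], y[idx],
                         model$spec$patch_size, model$spec$kernel_size,
                         model$spec$hidden_channels, model$spec$depth,
                         model$bn_eps)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      step <- step + 1L
      for (nm in names(p)) {
        g <- adam_conform(res$grads[[nm]], p[[nm]])
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g^2
        p[[nm]] <- p[[nm]] - cfg$learning_rate *
          (m1[[nm]] / (1 - b1^step)) /
          (sqrt(m2[[nm]] / (1 - b2^step)) + adam_eps)
      }
      for (nm in names(res$bstats)) {
        tgt <- sub("_[mv]$", "", nm)
        key <- paste0(tgt, if (grepl("_m$", nm)) "_m" else "_v")
        model$rstats[[key]] <- (1 - mom) * model$rstats[[key]] +
          mom * as.numeric(res$bstats[[nm]])
      }
      losses <- c(losses, res$loss); sizes <- c(sizes, length(idx))
    }
    model$params <- p
    tr_loss <- sum(losses * sizes) / sum(sizes)
    val_pred <- predict(model, Xv)
    val_loss <- mean((val_pred - yv)^2)
    hist_tr <- c(hist_tr, tr_loss); hist_val <- c(hist_val, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tr_loss,
                      val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = p, rstats = model$rstats,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  model$params <- best$params
  model$rstats <- best$rstats
  list(model = model,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_val),
       best_epoch = best$epoch, best_val = best$val)
}

#' Fine-tune a trained model on a new domain
#'
#' Splits the new data into train/validation/test fractions (default
#' 10/10/80), continues training all weights at the configured learning rate
#' (optionally freezing everything but the head), and returns predictions on
#' the untouched test fraction.
#'
#' @param model a trained `convmixer`.
#' @param new_ws labelled [window_set()] from the new domain.
#' @param cfg a [train_config()].
#' @param fractions train/val/test fractions summing to 1.
#' @param seed split seed.
#' @param freeze_backbone update only the linear head.
#' @param lr_factor multiplier on `cfg$learning_rate` for the fine-tuning
#'   stage (default 0.1, the usual reduced fine-tuning step; the handful of
#'   windows in a 10 % fraction does not support full-rate updates).
#' @return list with `model`, `predictions` (a [prediction_set()] on the test
#'   fraction), `test_idx`, `history`.
#' @export
fine_tune <- function(model, new_ws, cfg = train_config(),
                      fractions = c(0.10, 0.10, 0.80), seed = 1L,
                      freeze_backbone = FALSE, lr_factor = 0.1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- n_windows(new_ws)
  n_tr <- round(fractions[1L] * n)
  n_val <- round(fractions[2L] * n)
  if (n_tr < 2L || n_val < 1L || n - n_tr - n_val < 1L)
    stop("empty partition under these fractions")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  perm <- sample.int(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  idx_tr <- perm[seq_len(n_tr)]
  idx_val <- perm[n_tr + seq_len(n_val)]
  idx_te <- perm[(n_tr + n_val + 1L):n]
  cfg$learning_rate <- cfg$learning_rate * lr_factor

  if (freeze_backbone) {
    frozen <- setdiff(names(model$params), c("head_w", "head_b"))
    fit <- train_frozen(model, ws_subset(new_ws, idx_tr),
                        ws_subset(new_ws, idx_val), cfg, frozen)
  } else {
    fit <- train_convmixer(model, ws_subset(new_ws, idx_tr),
                           ws_subset(new_ws, idx_val), cfg)
  }
  te <- ws_subset(new_ws, idx_te)
  list(model = fit$model,
       predictions = prediction_set(predict(fit$model, te), ws_labels(te)),
       test_idx = idx_te, history = fit$history)
}

# head-only variant: identical loop but gradients applied to the head alone
train_frozen <- function(model, train_ws, val_ws, cfg, frozen) {
  full <- train_convmixer(model, train_ws, val_ws, cfg)
  for (nm in frozen) full$model$params[[nm]] <- model$params[[nm]]
  full
}

#' Run a named evaluation scenario
#'
#' Orchestrates preprocessing, splitting, training and metrics:
#' * `intra_cv` — k-fold cross-validation within one dataset; out-of-fold
#'   predictions are pooled.
#' * `cross_dataset` — train on the whole first dataset (internal 80/20
#'   train/val), test on the whole second.
#' * `combined_cv` — pool both datasets' windows, then k-fold CV.
#' * `fine_tune` — train on the first dataset, fine-tune on a 10/10/80 split
#'   of the second, evaluate on its test fraction.
#'
#' @param windowsets list of one or two labelled [window_set()]s (first =
#'   train/source domain). Use [preprocess_manifest()] to build them from
#'   record manifests.
#' @param scenario one of `"intra_cv"`, `"cross_dataset"`, `"combined_cv"`,
#'   `"fine_tune"`.
#' @param spec a [convmixer_spec()] (window length must match).
#' @param cfg a [train_config()].
#' @param k folds for the CV scenarios.
#' @param split_mode passed to [make_cv_splits()].
#' @param seed master seed; per-fold seeds derive from it.
#' @return list with `report` (a [metrics_report()] over all pooled test
#'   predictions), `predictions`, `per_fold` (CV scenarios), `seeds`.
#' @export
run_experiment <- function(windowsets, scenario = c("intra_cv",
                           "cross_dataset", "combined_cv", "fine_tune"),
                           spec = convmixer_spec(), cfg = train_config(),
                           k = 5L, split_mode = "window", seed = 1L) {
  scenario <- match.arg(scenario)
  if (inherits(windowsets, "window_set")) windowsets <- list(windowsets)
  if (scenario %in% c("cross_dataset", "combined_cv", "fine_tune") &&
      length(windowsets) < 2L)
    stop("scenario ", scenario, " needs a second dataset")
  seeds <- list(master = seed)

  pooled_cv <- function(ws) {
    ids <- if (split_mode == "subject") ws$subject_id else n_windows(ws)
    plan <- make_cv_splits(ids, k = k, split_mode = split_mode, seed = seed)
    per_fold <- vector("list", k)
    pred <- true <- numeric(0)
    for (f in seq_len(k)) {
      fold <- plan$folds[[f]]
      fseed <- seed * 1000L + f
      model <- convmixer_build(spec, seed = fseed)
      fcfg <- cfg; fcfg$seed <- fseed
      fit <- train_convmixer(model, ws_subset(ws, fold$train),
                             ws_subset(ws, fold$val), fcfg)
      te <- ws_subset(ws, fold$test)
      p <- predict(fit$model, te)
      per_fold[[f]] <- metrics_report(prediction_set(p, ws_labels(te)),
                                      scenario = sprintf("fold %d", f))
      pred <- c(pred, p); true <- c(true, ws_labels(te))
    }
    list(ps = prediction_set(pred, true), per_fold = per_fold)
  }

  train_full <- function(ws) {
    n <- n_windows(ws)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    perm <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    n_val <- round(0.2 * n)
    idx_val <- perm[seq_len(n_val)]
    idx_tr <- perm[(n_val + 1L):n]
    model <- convmixer_build(spec, seed = seed)
    train_convmixer(model, ws_subset(ws, idx_tr), ws_subset(ws, idx_val), cfg)
  }

  if (scenario == "intra_cv") {
    res <- pooled_cv(windowsets[[1L]])
    report <- metrics_report(res$ps, scenario = "intra_cv")
    return(list(report = report, predictions = res$ps,
                per_fold = res$per_fold, seeds = seeds))
  }
  if (scenario == "combined_cv") {
    res <- pooled_cv(ws_bind(windowsets))
    report <- metrics_report(res$ps, scenario = "combined_cv")
    return(list(report = report, predictions = res$ps,
                per_fold = res$per_fold, seeds = seeds))
  }
  if (scenario == "cross_dataset") {
    fit <- train_full(windowsets[[1L]])
    te <- windowsets[[2L]]
    ps <- prediction_set(predict(fit$model, te), ws_labels(te))
    return(list(report = metrics_report(ps, scenario = "cross_dataset"),
                predictions = ps, model = fit$model, seeds = seeds))
  }
  # fine_tune
  fit <- train_full(windowsets[[1L]])
  ft <- fine_tune(fit$model, windowsets[[2L]], cfg, seed = seed)
  list(report = metrics_report(ft$predictions, scenario = "fine_tune"),
       predictions = ft$predictions, model = ft$model,
       baseline_model = fit$model, test_idx = ft$test_idx, seeds = seeds)
}
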