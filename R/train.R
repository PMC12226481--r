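# Training and evaluation protocols: Adam training with cross-entropy (plus
# an optional auto-encoder denoising MSE term), stratified k-fold
# cross-validation repeated with distinct seeds, leave-one-subject-out
# evaluation, confusion-matrix reports, and the paired t-test used to
# compare decoders across subjects.

#' Training configuration
#'
#' Defaults follow the reference protocol for the force-variation dataset:
#' Adam, learning rate 0.001, batch size 7, 200 epochs (400 with batch 36
#' for the four-class benchmark protocol).
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param lambda_recon weight of the auto-encoder denoising MSE added to the
#'   cross-entropy (0 disables the reconstruction term).
#' @param seed RNG seed controlling weight init, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 200, lr = 0.001, batch_size = 7,
                         lambda_recon = 0.1, seed = 0L, verbose = FALSE) {
  structure(list(epochs = epochs, lr = lr, batch_size = batch_size,
                 lambda_recon = lambda_recon, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

as_inputs <- function(data, model_cfg) {
  if (inherits(data, "model_inputs")) data
  else prepare_model_inputs(data, model_cfg)
}

#' Train the network
#'
#' @param data an [eeg_epochs()] object or a [prepare_model_inputs()] result.
#' @param model_cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @return list of class `fnssir_fit`: `model`, `loss_trace` (per-epoch mean
#'   total loss), `model_cfg`, `tcfg`.
#' @export
train_model <- function(data, model_cfg = model_config(),
                        tcfg = train_config()) {
  inputs <- as_inputs(data, model_cfg)
  with_local_seed(tcfg$seed, {
    model <- build_model(model_cfg)
    st <- adam_state(model$layers)
    n <- inputs$n
    lam <- tcfg$lambda_recon
    trace <- numeric(tcfg$epochs)
    t_adam <- 0L
    for (e in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[b0:min(b0 + tcfg$batch_size - 1L, n)]
        bi <- subset_inputs(inputs, idx)
        fw <- model_forward(model, bi$plane, bi$cae_x, training = TRUE)
        ce <- softmax_xent(fw$logits, bi$labels)
        loss <- ce$loss
        drecon <- NULL
        if (!is.null(fw$recon) && lam > 0) {
          err <- fw$recon - bi$cae_target
          loss <- loss + lam * mean(err^2)
          drecon <- (2 * lam / length(err)) * err
        }
        if (!is.finite(loss))
          stop(sprintf(
            "non-finite loss at epoch %d, batch %d (lr = %g) - aborting",
            e, nb + 1L, tcfg$lr))
        model_backward(model, fw, ce$dlogits, drecon)
        t_adam <- t_adam + 1L
        st <- adam_step(model$layers, st, lr = tcfg$lr, t = t_adam)
        tot <- tot + loss; nb <- nb + 1L
      }
      trace[e] <- tot / nb
      if (tcfg$verbose)
        message(sprintf("epoch %3d/%d  loss %.4f", e, tcfg$epochs, trace[e]))
    }
    structure(list(model = model, loss_trace = trace,
                   model_cfg = model_cfg, tcfg = tcfg),
              class = "fnssir_fit")
  })
}

#' Predict class labels
#'
#' @param fit an [train_model()] result (or an `fnssir_model`).
#' @param data epochs or prepared inputs.
#' @param batch_size inference batch size.
#' @return integer vector of 0-based predicted labels (argmax of the logits,
#'   ties broken toward the lowest class index).
#' @export
predict_classes <- function(fit, data, batch_size = 32L) {
  model <- if (inherits(fit, "fnssir_fit")) fit$model else fit
  inputs <- as_inputs(data, model$cfg)
  n <- inputs$n
  preds <- integer(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    bi <- subset_inputs(inputs, idx)
    fw <- model_forward(model, bi$plane, bi$cae_x, training = FALSE)
    preds[idx] <- max.col(fw$logits, ties.method = "first") - 1L
  }
  preds
}

#' Evaluate a trained model
#'
#' @inheritParams predict_classes
#' @param n_classes number of classes for the confusion matrix.
#' @return an `eval_report`: `accuracy` (%), `confusion`
#'   (`[n_classes x n_classes]` counts, rows = true class, columns =
#'   predicted), `n`, `predictions`, `labels`.
#' @export
evaluate_model <- function(fit, data, n_classes = NULL) {
  model <- if (inherits(fit, "fnssir_fit")) fit$model else fit
  inputs <- as_inputs(data, model$cfg)
  if (inputs$n < 1L) stop("empty test set")
  if (is.null(n_classes)) n_classes <- model$cfg$n_classes
  preds <- predict_classes(model, inputs)
  eval_report(inputs$labels, preds, n_classes)
}

#' Build an evaluation report from labels and predictions
#'
#' @param labels,predictions 0-based integer vectors of equal length.
#' @param n_classes number of classes.
#' @export
eval_report <- function(labels, predictions, n_classes) {
  conf <- table(factor(labels, levels = 0:(n_classes - 1)),
                factor(predictions, levels = 0:(n_classes - 1)))
  conf <- unclass(matrix(conf, n_classes, n_classes,
                         dimnames = list(true = 0:(n_classes - 1),
                                         pred = 0:(n_classes - 1))))
  acc <- 100 * sum(diag(conf)) / sum(conf)
  stopifnot(abs(acc - 100 * mean(labels == predictions)) < 1e-9)
  structure(list(accuracy = acc, confusion = conf, n = length(labels),
                 predictions = predictions, labels = labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.1f%% on %d trials\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold split
#'
#' Shuffles each class with the given seed and deals trials round-robin
#' into `k` folds, so folds are disjoint, cover every trial, and per-class
#' counts across folds differ by at most one.
#'
#' @param labels integer labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` lists with `train` and `test` index vectors.
#' @export
stratified_kfold <- function(labels, k, seed = 0L) {
  n <- length(labels)
  small <- table(labels)
  if (any(small < k))
    stop("class ", names(small)[which.min(small)], " has fewer than k = ",
         k, " trials")
  fold_of <- integer(n)
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Repeated stratified cross-validation
#'
#' Runs `folds`-fold stratified CV `repeats` times with distinct seeds
#' (`base seed + repeat index`). Reports each repeat's fold-mean accuracy,
#' the maximum across repeats (the optimistic single-number convention) and
#' the grand mean (recommended), plus the pooled confusion matrix of the
#' best repeat.
#'
#' @param data epochs or prepared inputs.
#' @param model_cfg a [model_config()].
#' @param tcfg a [train_config()]; its `seed` is the base seed.
#' @param folds,repeats protocol size (default 4-fold x 5 repeats).
#' @return list of class `cv_result`.
#' @export
cv_experiment <- function(data, model_cfg = model_config(),
                          tcfg = train_config(), folds = 4L, repeats = 5L) {
  inputs <- as_inputs(data, model_cfg)
  acc <- matrix(NA_real_, repeats, folds)
  confs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    seed_r <- tcfg$seed + r
    sp <- stratified_kfold(inputs$labels, folds, seed = seed_r)
    conf <- 0
    for (f in seq_len(folds)) {
      stopifnot(length(intersect(sp[[f]]$train, sp[[f]]$test)) == 0L)
      tcf <- tcfg
      tcf$seed <- seed_r * 1000L + f
      fit <- train_model(subset_inputs(inputs, sp[[f]]$train), model_cfg, tcf)
      rep_ <- evaluate_model(fit, subset_inputs(inputs, sp[[f]]$test))
      acc[r, f] <- rep_$accuracy
      conf <- conf + rep_$confusion
    }
    confs[[r]] <- conf
  }
  rm_ <- rowMeans(acc)
  best <- which.max(rm_)
  structure(list(per_fold = acc, repeat_means = rm_,
                 acc_max = max(rm_), acc_mean = mean(rm_),
                 sd_best = stats::sd(acc[best, ]),
                 confusion = confs[[best]], folds = folds,
                 repeats = repeats, base_seed = tcfg$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold x %d repeats: best repeat %.1f%% (sd %.1f), grand mean %.1f%%\n",
    x$folds, x$repeats, x$acc_max, x$sd_best, x$acc_mean))
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' Trains on all subjects but one and tests on the held-out subject, for
#' every subject; no held-out trial ever enters the training set.
#'
#' @param subjects list of [eeg_epochs()], one per subject.
#' @param model_cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @return list of class `loso_result` with per-subject `eval_report`s and
#'   accuracies.
#' @export
loso_experiment <- function(subjects, model_cfg = model_config(),
                            tcfg = train_config()) {
  if (length(subjects) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  for (s in subjects)
    if (n_trials(s) == 0L) stop("subject ", s$subject_id, " has no trials")
  reports <- lapply(seq_along(subjects), function(i) {
    train <- combine_epochs(subjects[-i])
    tcf <- tcfg
    tcf$seed <- tcfg$seed + i
    fit <- train_model(train, model_cfg, tcf)
    evaluate_model(fit, subjects[[i]])
  })
  names(reports) <- vapply(subjects, function(s) s$subject_id, character(1))
  structure(list(reports = reports,
                 accuracy = vapply(reports, function(r) r$accuracy,
                                   numeric(1))),
            class = "loso_result")
}

#' Paired-sample t-test between two decoders
#'
#' Two-sided paired t-test on per-subject accuracies, with an advisory
#' normality check (Shapiro-Wilk on the differences) that warns but does
#' not gate.
#'
#' @param acc_a,acc_b per-subject accuracies (%), equal length >= 3.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("unequal lengths")
  if (length(acc_a) < 3L) stop("need at least 3 paired observations")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0)
    stop("degenerate case: zero variance of paired differences")
  if (length(d) >= 3L && length(d) <= 5000L) {
    swp <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA)
    if (!is.na(swp) && swp < 0.05)
      warning(sprintf(
        "paired differences may be non-normal (Shapiro-Wilk p = %.3g)", swp))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Shuffle labels (chance-level control)
#' @param epochs an [eeg_epochs()] object.
#' @param seed RNG seed.
#' @export
shuffle_labels <- function(epochs, seed = 0L) {
  with_local_seed(seed, {
    epochs$labels <- sample(epochs$labels)
  })
  epochs
}
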