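# The bundled synthetic decoding benchmark: 126 trials (42 per class) from
# the default generator, decoded with the scaled-down network configuration
# via stratified 4-fold cross-validation, plus the label-shuffle chance
# control and the branch-ablation comparison.

#' Generate the default synthetic benchmark dataset
#'
#' @param seed generator seed.
#' @param n_trials_per_class trials per class (default 42).
#' @return an [eeg_epochs()] object (126 trials by default).
#' @export
benchmark_dataset <- function(seed = 42L, n_trials_per_class = 42L) {
  generate_dataset(synthetic_config(seed = seed,
                                    n_trials_per_class = n_trials_per_class))
}

#' Cross-validated decoding on the synthetic benchmark
#'
#' Stratified 4-fold CV of the scaled-down network (100 training epochs,
#' Adam, batch 7) on the benchmark dataset, optionally with shuffled labels
#' as a chance-level control.
#'
#' @param seed seed for the generator, folds and training.
#' @param train_epochs training epochs per fold.
#' @param folds,repeats CV protocol.
#' @param shuffle shuffle labels before CV (chance control).
#' @param data optional pre-generated [eeg_epochs()] or prepared inputs
#'   (skips generation).
#' @param verbose print progress.
#' @return a [cv_experiment()] result.
#' @export
benchmark_cv <- function(seed = 1L, train_epochs = 100L, folds = 4L,
                         repeats = 1L, shuffle = FALSE, data = NULL,
                         verbose = FALSE) {
  mcfg <- benchmark_model_config()
  if (is.null(data)) data <- benchmark_dataset(seed = seed)
  inputs <- as_inputs(data, mcfg)
  if (shuffle)
    inputs$labels <- with_local_seed(seed + 900L, sample(inputs$labels))
  tcfg <- train_config(epochs = train_epochs, batch_size = 7,
                       lambda_recon = 1, seed = seed, verbose = verbose)
  cv_experiment(inputs, mcfg, tcfg, folds = folds, repeats = repeats)
}

#' Branch-ablation comparison on the synthetic benchmark
#'
#' Trains the full model and the three single-branch-removed variants on a
#' stratified 75/25 split of the benchmark dataset and evaluates each on a
#' large freshly generated test set from the same generator configuration
#' (the fine-grained evaluation keeps the comparison above the
#' counting noise of a 32-trial split). All variants share the split and
#' the training protocol.
#'
#' @param seed seed for the generator, split and training.
#' @param train_epochs training epochs.
#' @param data optional pre-generated data or prepared inputs.
#' @param eval_trials_per_class size of the fresh evaluation set.
#' @return named numeric vector of accuracies (%):
#'   `full`, `wo_msstcn`, `wo_cae`, `wo_lstm_sa`.
#' @export
benchmark_ablation <- function(seed = 1L, train_epochs = 100L, data = NULL,
                               eval_trials_per_class = 100L) {
  mcfg <- benchmark_model_config()
  if (is.null(data)) data <- benchmark_dataset(seed = seed)
  inputs <- as_inputs(data, mcfg)
  sp <- stratified_kfold(inputs$labels, 4L, seed = seed)[[1L]]
  tcfg <- train_config(epochs = train_epochs, batch_size = 7,
                       lambda_recon = 1, seed = seed)
  test_ep <- generate_dataset(synthetic_config(
    n_trials_per_class = eval_trials_per_class, seed = seed + 7000L))
  test_inputs <- prepare_model_inputs(test_ep, mcfg)
  variants <- list(
    full = mcfg,
    wo_msstcn = ablate(mcfg, "MSSTCN"),
    wo_cae = ablate(mcfg, "CAE"),
    wo_lstm_sa = ablate(mcfg, "LSTM-SA"))
  vapply(variants, function(cfg) {
    tr <- subset_inputs(inputs, sp$train)
    te <- test_inputs
    tr$cfg <- cfg; te$cfg <- cfg
    if (!cfg$use_msstcn) { tr$plane <- NULL; te$plane <- NULL }
    if (!cfg$use_cae) {
      tr$cae_x <- tr$cae_target <- NULL
      te$cae_x <- te$cae_target <- NULL
    }
    fit <- train_model(tr, cfg, tcfg)
    evaluate_model(fit, te)$accuracy
  }, numeric(1))
}
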