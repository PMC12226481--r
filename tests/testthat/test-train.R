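# Cross-validation machinery, evaluation identities, the paired t-test
# against its closed form, and training-loop contracts.

test_that("stratified folds are disjoint, covering and balanced", {
  labels <- rep(0:2, each = 42)
  sp <- stratified_kfold(labels, 4, seed = 1)
  all_test <- sort(unlist(lapply(sp, `[[`, "test")))
  expect_equal(all_test, seq_along(labels))
  for (f in sp) {
    expect_length(intersect(f$train, f$test), 0)
    counts <- table(labels[f$test])
    expect_true(all(counts %in% c(10L, 11L)))
  }
  expect_equal(sum(lengths(lapply(sp, `[[`, "test"))), 126)
  # leave-one-out on a toy vector: singleton test sets
  lab2 <- rep(0:1, 3)
  sp2 <- stratified_kfold(lab2, 3, seed = 0)
  expect_true(all(lengths(lapply(sp2, `[[`, "test")) == 2))
  expect_error(stratified_kfold(c(0, 0, 1), 2, seed = 0), "fewer than")
  # different seeds permute differently but keep the invariants
  expect_false(identical(stratified_kfold(labels, 4, seed = 1),
                         stratified_kfold(labels, 4, seed = 2)))
})

test_that("fold invariants hold over random label vectors", {
  set.seed(40)
  for (i in 1:250) {
    n_cls <- sample(2:4, 1)
    k <- sample(2:5, 1)
    labels <- sample(0:(n_cls - 1), size = n_cls * k + sample(0:20, 1),
                     replace = TRUE)
    while (any(table(labels) < k))
      labels <- c(labels, 0:(n_cls - 1))
    sp <- stratified_kfold(labels, k, seed = i)
    expect_equal(sort(unlist(lapply(sp, `[[`, "test"))),
                 seq_along(labels))
    for (f in sp) {
      expect_length(intersect(f$train, f$test), 0)
      per <- table(factor(labels[f$test], levels = 0:(n_cls - 1)))
      full <- table(factor(labels, levels = 0:(n_cls - 1)))
      expect_true(all(abs(per - full / k) <= 1))
    }
  }
})

test_that("evaluation reports satisfy their internal identities", {
  r <- eval_report(labels = rep(0:2, 10), predictions = rep(0:2, 10),
                   n_classes = 3)
  expect_equal(r$accuracy, 100)
  expect_true(all(r$confusion[upper.tri(r$confusion)] == 0) &&
                all(r$confusion[lower.tri(r$confusion)] == 0))
  r2 <- eval_report(labels = rep(0:2, each = 10),
                    predictions = rep(0L, 30), n_classes = 3)
  expect_equal(r2$accuracy, 100 / 3, tolerance = 1e-9)
  set.seed(41)
  lab <- sample(0:2, 60, replace = TRUE)
  pred <- sample(0:2, 60, replace = TRUE)
  r3 <- eval_report(lab, pred, 3)
  expect_equal(r3$accuracy,
               100 * sum(diag(r3$confusion)) / sum(r3$confusion))
  expect_equal(unname(rowSums(r3$confusion)),
               as.vector(table(factor(lab, levels = 0:2))))
})

test_that("the paired t-test matches the closed form and flags degeneracy", {
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "degenerate")
  r0 <- paired_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  set.seed(42)
  a <- rnorm(15, 80, 5); b <- rnorm(15, 77, 5)
  r <- suppressWarnings(paired_ttest(a, b))
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(15))
  p_ref <- 2 * stats::pt(-abs(t_ref), 14)
  expect_equal(r$t, t_ref, tolerance = 1e-9)
  expect_equal(r$p, p_ref, tolerance = 1e-9)
  expect_equal(r$df, 14)
  expect_error(paired_ttest(1:2, 1:2), "at least 3")
  expect_error(paired_ttest(1:4, 1:3), "unequal")
})

test_that("training contracts: zero lr freezes, seeds reproduce, loss falls", {
  ep <- subset_trials(benchmark_data_cached(), 1:36)
  mcfg <- benchmark_model_config(msstcn_filters = c(1, 1),
                                 cae_filters = c(2, 2))
  inputs <- prepare_model_inputs(ep, mcfg)
  # lr = 0: weights unchanged; with full batches and no dropout the loss
  # trace is exactly constant (batch statistics then never vary)
  mcfg0 <- benchmark_model_config(msstcn_filters = c(1, 1),
                                  cae_filters = c(2, 2), dropout_p = 0)
  fit0 <- train_model(prepare_model_inputs(ep, mcfg0), mcfg0,
                      train_config(epochs = 3, lr = 0, batch_size = 36,
                                   seed = 3))
  expect_equal(fit0$loss_trace[1], fit0$loss_trace[3], tolerance = 1e-9)
  set.seed(3); ref <- build_model(mcfg0)
  expect_equal(get_weights(fit0$model)$fc$w, ref$layers$fc$params$w,
               tolerance = 1e-12)
  # reproducibility: identical traces for identical seeds
  f1 <- train_model(inputs, mcfg, train_config(epochs = 3, seed = 5))
  f2 <- train_model(inputs, mcfg, train_config(epochs = 3, seed = 5))
  expect_identical(f1$loss_trace, f2$loss_trace)
  # optimisation makes progress on the synthetic task
  f3 <- train_model(inputs, mcfg, train_config(epochs = 20, seed = 7))
  expect_lt(tail(f3$loss_trace, 1), f3$loss_trace[1])
})

test_that("cross-validation keeps folds leak-free and reports sane numbers", {
  ep <- subset_trials(benchmark_data_cached(), 1:36)
  mcfg <- benchmark_model_config(msstcn_filters = c(1, 1),
                                 cae_filters = c(2, 2))
  cv <- cv_experiment(prepare_model_inputs(ep, mcfg), mcfg,
                      train_config(epochs = 4, seed = 1),
                      folds = 3, repeats = 2)
  expect_equal(dim(cv$per_fold), c(2, 3))
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 100))
  expect_equal(cv$acc_max, max(cv$repeat_means))
  expect_equal(cv$acc_mean, mean(cv$repeat_means))
  expect_equal(sum(cv$confusion), 36)
})

test_that("leave-one-subject-out partitions by subject", {
  subs <- simulate_subjects(3, synthetic_config(n_trials_per_class = 6),
                            seed = 13)
  mcfg <- benchmark_model_config(msstcn_filters = c(1, 1),
                                 cae_filters = c(2, 2))
  lo <- loso_experiment(subs, mcfg, train_config(epochs = 6, seed = 2))
  expect_length(lo$reports, 3)
  for (i in 1:3) expect_equal(lo$reports[[i]]$n, 18)
  expect_named(lo$accuracy, c("sim01", "sim02", "sim03"))
  expect_error(loso_experiment(subs[1], mcfg), ">= 2 subjects")
})

test_that("shuffled labels destroy the class structure deterministically", {
  ep <- benchmark_data_cached()
  s1 <- shuffle_labels(ep, seed = 4)
  s2 <- shuffle_labels(ep, seed = 4)
  expect_identical(s1$labels, s2$labels)
  expect_false(identical(s1$labels, ep$labels))
  expect_equal(sort(s1$labels), sort(ep$labels))
})
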