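# Layer-by-layer gradient checks against central finite differences, the
# scalar-loop attention oracle, and the architecture's shape/parameter
# contracts.

test_that("every layer's analytic gradients match finite differences", {
  set.seed(20)
  checks <- list(
    conv3d = list(l = fnssir:::nn_conv3d(c(3, 3, 3), 2L, 2L),
                  x = array(rnorm(10 * 3 * 3 * 2 * 2), c(10, 3, 3, 2, 2))),
    conv1d = list(l = fnssir:::nn_conv1d(3L, 2L, 3L),
                  x = array(rnorm(12 * 2 * 2), c(12, 2, 2))),
    convt1d = list(l = fnssir:::nn_convtranspose1d(4L, 2L, 3L),
                   x = array(rnorm(6 * 2 * 2), c(6, 2, 2))),
    dense = list(l = fnssir:::nn_dense(5L, 3L),
                 x = matrix(rnorm(4 * 5), 4)),
    lstm = list(l = fnssir:::nn_lstm(3L, 4L),
                x = array(rnorm(2 * 5 * 3), c(2, 5, 3))),
    attention = list(l = fnssir:::nn_attention(4L),
                     x = array(rnorm(2 * 3 * 4), c(2, 3, 4))))
  for (nm in names(checks)) {
    l <- checks[[nm]]$l
    for (pn in names(l$params))           # keep pre-activations off kinks
      l$params[[pn]] <- l$params[[pn]] + rnorm(length(l$params[[pn]]),
                                               sd = 0.05)
    x <- checks[[nm]]$x
    y <- l$fwd(x, training = FALSE)
    dout <- array(rnorm(length(y)), dim(y) %||% length(y))
    dx <- expect_grad_match(l, x, dout, tol = 1e-4)
    # input gradients too
    eps <- 1e-6
    idx <- sample(length(x), 5)
    for (i in idx) {
      o <- x[i]
      x[i] <- o + eps; lp <- sum(l$fwd(x) * dout)
      x[i] <- o - eps; lm <- sum(l$fwd(x) * dout)
      x[i] <- o
      expect_equal(dx[i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = paste(nm, "dx"))
    }
  }
})

test_that("batchnorm gradients (training mode) match finite differences", {
  set.seed(21)
  l <- fnssir:::nn_batchnorm3d(2L)
  l$params$gamma <- l$params$gamma + rnorm(2, sd = 0.1)
  l$params$beta <- l$params$beta + rnorm(2, sd = 0.1)
  x <- array(rnorm(6 * 2 * 2 * 2 * 3), c(6, 2, 2, 2, 3))
  dout <- array(rnorm(length(x)), dim(x))
  loss <- function() {
    lc <- fnssir:::nn_batchnorm3d(2L)
    lc$params <- l$params
    sum(lc$fwd(x, training = TRUE) * dout)
  }
  fnssir:::layer_zero_grads(l)
  l$fwd(x, training = TRUE)
  dx <- l$bwd(dout)
  eps <- 1e-6
  for (pn in c("gamma", "beta")) for (i in 1:2) {
    o <- l$params[[pn]][i]
    l$params[[pn]][i] <- o + eps; lp <- loss()
    l$params[[pn]][i] <- o - eps; lm <- loss()
    l$params[[pn]][i] <- o
    expect_equal(l$grads[[pn]][i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(x), 6)) {
    o <- x[i]
    x[i] <- o + eps; lp <- loss()
    x[i] <- o - eps; lm <- loss()
    x[i] <- o
    expect_equal(dx[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("the full model's gradients match finite differences", {
  set.seed(22)
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  randomize_biases(m)
  ti <- tiny_model_inputs(cfg, B = 3)
  tgt <- array(runif(length(ti$cae_x)), dim(ti$cae_x))
  lam <- 0.1
  loss_fn <- function() {
    fw <- model_forward(m, ti$plane, ti$cae_x, training = FALSE)
    ce <- fnssir:::softmax_xent(fw$logits, ti$labels[1:3])
    ce$loss + lam * mean((fw$recon - tgt)^2)
  }
  fw <- model_forward(m, ti$plane, ti$cae_x, training = FALSE)
  ce <- fnssir:::softmax_xent(fw$logits, ti$labels[1:3])
  err <- fw$recon - tgt
  zero_grads(m)
  model_backward(m, fw, ce$dlogits, (2 * lam / length(err)) * err)
  eps <- 1e-5
  for (nm in names(m$layers)) {
    l <- m$layers[[nm]]
    for (pn in names(l$params)) {
      p <- l$params[[pn]]
      for (i in sample(length(p), min(3, length(p)))) {
        o <- p[i]
        l$params[[pn]][i] <- o + eps; lp <- loss_fn()
        l$params[[pn]][i] <- o - eps; lm <- loss_fn()
        l$params[[pn]][i] <- o
        num <- (lp - lm) / (2 * eps)
        expect_equal(l$grads[[pn]][i], num, tolerance = 2e-3,
                     label = sprintf("%s$%s[%d]", nm, pn, i))
      }
    }
  }
})

test_that("attention equals a scalar-loop scaled-dot-product oracle", {
  set.seed(23)
  for (rep in 1:50) {
    d <- sample(2:6, 1); S <- sample(2:5, 1)
    l <- fnssir:::nn_attention(d)
    x <- array(rnorm(1 * S * d), c(1, S, d))
    out <- l$fwd(x)
    X <- matrix(x[1, , ], S, d)
    Q <- X %*% l$params$wq + matrix(l$params$bq, S, d, byrow = TRUE)
    K <- X %*% l$params$wk + matrix(l$params$bk, S, d, byrow = TRUE)
    V <- X %*% l$params$wv + matrix(l$params$bv, S, d, byrow = TRUE)
    ref <- matrix(0, S, d)
    A <- matrix(0, S, S)
    for (i in seq_len(S)) {
      sc <- sapply(seq_len(S), function(j) sum(Q[i, ] * K[j, ]) / sqrt(d))
      w <- exp(sc - max(sc)); w <- w / sum(w)
      A[i, ] <- w
      for (k in seq_len(d)) ref[i, k] <- sum(w * V[, k])
    }
    expect_lt(max(abs(out[1, , ] - ref)), 1e-6)
    expect_equal(rowSums(A), rep(1, S), tolerance = 1e-6)
  }
  # steps = 1: softmax weight 1, output = the V row
  l <- fnssir:::nn_attention(3L)
  x <- array(rnorm(3), c(1, 1, 3))
  v <- matrix(x[1, , ], 1, 3) %*% l$params$wv +
    matrix(l$params$bv, 1, 3, byrow = TRUE)
  expect_equal(matrix(l$fwd(x)[1, , ], 1, 3), v, tolerance = 1e-10)
  # identity projections + identical rows -> rows pass through
  l2 <- fnssir:::nn_attention(3L)
  l2$params$wq <- l2$params$wk <- l2$params$wv <- diag(3)
  l2$params$bq <- l2$params$bk <- l2$params$bv <- numeric(3)
  xr <- array(rep(c(1, -2, 0.5), each = 4), c(1, 4, 3))
  out2 <- l2$fwd(xr)
  expect_equal(out2, xr, tolerance = 1e-10)
})

test_that("the default architecture meets its shape contract", {
  cfg <- model_config()
  expect_equal(model_steps(cfg), 24)
  set.seed(30)
  m <- build_model(cfg)
  plane <- array(rnorm(1200 * 9 * 9 * 2), c(1200, 9, 9, 1, 2))
  cae_x <- array(runif(1200 * 6 * 2), c(1200, 1, 12))
  fw <- model_forward(m, plane, cae_x, training = FALSE)
  expect_equal(dim(fw$seq_m), c(2, 24, 48))
  expect_equal(dim(fw$seq_c), c(2, 24, 300))      # 6 electrodes x 50 samples
  expect_equal(dim(fw$logits), c(2, 3))
  expect_equal(dim(fw$recon), dim(cae_x))
  expect_true(all(fw$recon >= 0 & fw$recon <= 1)) # sigmoid range
  expect_equal(dim(m$layers$fc$params$w), c(24 * 120, 3))
})

test_that("the trainable parameter count matches an independent sum", {
  # computed layer by layer from the architecture table before the model
  kern <- c(3 * 3 * 3, 5 * 5 * 5, 7 * 9 * 7)
  unit1 <- sum(8 * kern) + 3 * 8              # three branches + biases
  bn1 <- 3 * 2 * 8
  unit2 <- sum(16 * 24 * kern) + 3 * 16
  bn2 <- 3 * 2 * 16
  cae <- (8 * 1 * 3 + 8) + (16 * 8 * 3 + 16) +        # encoder convs
    (8 * 16 * 4 + 8) + (1 * 8 * 4 + 1)                # decoder deconvs
  lstm_a <- 4 * 40 * (48 + 40 + 1)
  lstm_b <- 4 * 80 * (300 + 80 + 1)
  att <- 3 * (120 * 120 + 120)
  fc <- 24 * 120 * 3 + 3
  expected <- unit1 + bn1 + unit2 + bn2 + cae + lstm_a + lstm_b + att + fc
  m <- build_model(model_config())
  expect_equal(count_params(m), expected)
})

test_that("zero input propagates to zero through the spatial branch", {
  set.seed(31)
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  plane0 <- array(0, c(20, 3, 3, 1, 2))
  h1 <- fnssir:::msstcn_unit_fwd(m, 1L, plane0, training = FALSE)
  h2 <- fnssir:::msstcn_unit_fwd(m, 2L, h1, training = FALSE)
  expect_equal(max(abs(h2)), 0)
})

test_that("dropout semantics: p = 0 identity, p = 1 zeros in training", {
  x <- array(rnorm(24), c(2, 3, 4))
  d0 <- fnssir:::nn_dropout(0)
  expect_identical(d0$fwd(x, training = TRUE), x)
  d1 <- fnssir:::nn_dropout(1)
  expect_equal(max(abs(d1$fwd(x, training = TRUE))), 0)
  dh <- fnssir:::nn_dropout(0.5)
  expect_identical(dh$fwd(x, training = FALSE), x)  # inference: identity
})

test_that("the auto-encoder halves time twice and restores it exactly", {
  set.seed(32)
  cfg <- model_config()
  m <- build_model(cfg)
  x <- array(runif(1200 * 6), c(1200, 1, 6))
  e <- m$layers$cae_relu1$fwd(m$layers$cae_conv1$fwd(x))
  e <- m$layers$cae_mp1$fwd(e)
  e <- m$layers$cae_relu2$fwd(m$layers$cae_conv2$fwd(e))
  e <- m$layers$cae_mp2$fwd(e)
  expect_equal(dim(e)[1], 300)
  d <- m$layers$cae_relu3$fwd(m$layers$cae_dec1$fwd(e))
  r <- m$layers$cae_sigmoid$fwd(m$layers$cae_dec2$fwd(d))
  expect_equal(dim(r), c(1200, 1, 6))
  expect_true(all(r >= 0 & r <= 1))
  cfgbad <- tiny_model_cfg()
  cfgbad$T_samples <- 18
  expect_error(validate_model_config <- fnssir:::validate_model_config(cfgbad))
})

test_that("the LSTM is order-sensitive", {
  set.seed(33)
  l <- fnssir:::nn_lstm(3L, 4L)
  x <- array(rnorm(1 * 6 * 3), c(1, 6, 3))
  y1 <- l$fwd(x)
  xp <- x[, 6:1, , drop = FALSE]
  y2 <- l$fwd(xp)
  expect_gt(max(abs(y1[, 6, ] - y2[, 6, ])), 1e-6)
})

test_that("ablations change the wiring as specified", {
  cfg <- tiny_model_cfg()
  # w/o CAE: forward succeeds without auto-encoder input
  m1 <- build_model(ablate(cfg, "CAE"))
  ti <- tiny_model_inputs(cfg, B = 2)
  fw <- model_forward(m1, ti$plane, NULL, training = FALSE)
  expect_equal(dim(fw$logits), c(2, 3))
  expect_null(fw$recon)
  # w/o LSTM-SA: no recurrent parameters anywhere
  m2 <- build_model(ablate(cfg, "LSTM-SA"))
  expect_false(any(grepl("lstm|att", names(m2$layers))))
  fw2 <- model_forward(m2, ti$plane, ti$cae_x, training = FALSE)
  expect_equal(dim(fw2$logits), c(2, 3))
  # w/o MSSTCN: CAE branch alone
  m3 <- build_model(ablate(cfg, "MSSTCN"))
  fw3 <- model_forward(m3, NULL, ti$cae_x, training = FALSE)
  expect_equal(dim(fw3$logits), c(2, 3))
  expect_error(ablate(cfg, "nope"))
})

test_that("every trainable tensor receives gradient after one step", {
  set.seed(34)
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  randomize_biases(m)
  ti <- tiny_model_inputs(cfg, B = 4)
  tgt <- array(runif(length(ti$cae_x)), dim(ti$cae_x))
  fw <- model_forward(m, ti$plane, ti$cae_x, training = TRUE)
  ce <- fnssir:::softmax_xent(fw$logits, ti$labels[1:4])
  err <- fw$recon - tgt
  zero_grads(m)
  model_backward(m, fw, ce$dlogits, (0.2 / length(err)) * err)
  for (nm in names(m$layers)) {
    l <- m$layers[[nm]]
    for (pn in names(l$params)) {
      if (grepl("^msconv[12]$", nm) && grepl("^b[123]$", pn)) {
        # a conv bias feeding training-mode batchnorm is absorbed by the
        # per-channel re-centring: its true gradient is identically zero
        expect_lt(max(abs(l$grads[[pn]])), 1e-8)
      } else {
        expect_gt(max(abs(l$grads[[pn]])), 0,
                  label = sprintf("grad norm of %s$%s", nm, pn))
      }
    }
  }
})

test_that("inference is deterministic; the 22-channel plane shape adapts", {
  set.seed(35)
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  ti <- tiny_model_inputs(cfg, B = 2)
  f1 <- model_forward(m, ti$plane, ti$cae_x, training = FALSE)
  f2 <- model_forward(m, ti$plane, ti$cae_x, training = FALSE)
  expect_identical(f1$logits, f2$logits)
  # four-class montage variant: 6 x 7 plane, adapted pools
  cfg2 <- model_config(grid_shape = c(6, 7), T_samples = 1000,
                       msstcn_filters = c(2, 4),
                       pools = list(c(2, 7, 5), c(3, 1, 10)),
                       n_classes = 4, input_fs = 250,
                       grid_channels = montage_channels("bci_iv_2a"))
  expect_equal(model_steps(cfg2), 20)
  m2 <- build_model(cfg2)
  plane <- array(rnorm(1000 * 6 * 7 * 1 * 2), c(1000, 6, 7, 1, 2))
  cae_x <- array(runif(1000 * 6 * 2), c(1000, 1, 12))
  fw <- model_forward(m2, plane, cae_x, training = FALSE)
  expect_equal(dim(fw$logits), c(2, 4))
})

test_that("single-precision conv kernels agree with the double reference", {
  set.seed(36)
  x <- array(rnorm(40 * 4 * 4 * 2 * 3), c(40, 4, 4, 2, 3))
  w <- array(rnorm(3 * 3 * 3 * 2 * 2, sd = 0.3), c(3, 3, 3, 2, 2))
  b <- rnorm(2)
  xd <- as.integer(dim(x)); wd <- as.integer(dim(w))
  yd <- fnssir:::conv3d_fwd(x, w, b, xd, wd, FALSE)
  ys <- fnssir:::conv3d_fwd(x, w, b, xd, wd, TRUE)
  expect_lt(max(abs(yd - ys)) / max(abs(yd)), 1e-5)
  gd <- fnssir:::conv3d_wgrad(x, yd, xd, wd, FALSE)
  gs <- fnssir:::conv3d_wgrad(x, yd, xd, wd, TRUE)
  expect_lt(max(abs(gd$dw - gs$dw)) / max(abs(gd$dw)), 1e-4)
  dd <- fnssir:::conv3d_igrad(yd, w, xd, wd, FALSE)
  ds <- fnssir:::conv3d_igrad(yd, w, xd, wd, TRUE)
  expect_lt(max(abs(dd - ds)) / max(abs(dd)), 1e-5)
})

test_that("a trained auto-encoder denoises toward the low-frequency target", {
  ep <- subset_trials(benchmark_data_cached(), 1:36)
  mcfg <- benchmark_model_config(msstcn_filters = c(1, 1))
  inputs <- prepare_model_inputs(ep, mcfg)
  fit <- train_model(inputs, mcfg,
                     train_config(epochs = 60, lambda_recon = 1, seed = 6))
  fw <- model_forward(fit$model, inputs$plane, inputs$cae_x,
                      training = FALSE)
  mse_recon <- mean((fw$recon - inputs$cae_target)^2)
  mse_raw <- mean((inputs$cae_x - inputs$cae_target)^2)
  expect_lt(mse_recon, mse_raw)
})
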