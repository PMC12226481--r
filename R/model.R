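# The three-branch feature-fusion network:
#   * MSSTCN - two multi-scale spatial-temporal units; each unit runs three
#     parallel same-padded 3D convolutions (small to large kernels) over the
#     interpolated electrode plane, concatenates them channel-wise, then
#     BN / ReLU / average pooling (dropout after the second unit).
#   * CAE - convolutional auto-encoder denoising a frontocentral/sensorimotor
#     electrode subset scaled to [0, 1]: two (1,3) convolutions with ReLU +
#     (1,2) max pooling, then two (1,4) stride-(1,2) transposed convolutions
#     (ReLU, sigmoid) restoring the original length.
#   * LSTM-SA - one LSTM per branch sequence, per-step concatenation, scaled
#     dot-product self-attention, flatten, and a fully connected classifier.

#' Model configuration
#'
#' All architectural constants of the network, with defaults equal to the
#' reference architecture: kernels (3,3,3)/(5,5,5)/(7,9,7), pools
#' (3,3,5)/(3,3,10), dropout 0.5, LSTM sizes 40/80, attention width 120.
#' Kernel and pool shapes are `(height, width, time)` on the electrode
#' plane.
#'
#' @param grid_shape electrode-plane shape `c(H, W)`.
#' @param T_samples input samples per trial (default 1200 = 12 s at 100 Hz).
#' @param msstcn_kernels list of three 3D kernel shapes.
#' @param msstcn_filters filters per branch in unit 1 and unit 2.
#' @param pools two 3D average-pool shapes; they must divide the plane and
#'   collapse it to 1 x 1 spatially.
#' @param dropout_p dropout probability after the second pooling stage.
#' @param cae_channels electrode subset fed to the auto-encoder.
#' @param cae_filters encoder filters of the two convolution stages.
#' @param lstm_a_units,lstm_b_units LSTM sizes for the MSSTCN and CAE branch
#'   sequences.
#' @param attention_dim self-attention width; must equal
#'   `lstm_a_units + lstm_b_units` when both branches are active.
#' @param n_classes number of classes.
#' @param input_fs sampling rate the model consumes, Hz. When lower than the
#'   epochs' rate, inputs are anti-alias decimated during preparation;
#'   `T_samples` must match the epoch duration at this rate.
#' @param grid_channels optional montage subset used for the electrode
#'   plane (`NULL`: all epoch channels).
#' @param precision `"double"` (reference) or `"single"`: arithmetic of the
#'   3D convolution kernels. Single precision roughly doubles training
#'   throughput at float32 accuracy and is the scaled-down benchmark's
#'   default.
#' @param use_msstcn,use_cae,use_lstm_sa branch switches (see [ablate()]).
#' @return a list of class `model_config`.
#' @export
model_config <- function(grid_shape = c(9, 9), T_samples = 1200,
                         msstcn_kernels = list(c(3, 3, 3), c(5, 5, 5),
                                               c(7, 9, 7)),
                         msstcn_filters = c(8, 16),
                         pools = list(c(3, 3, 5), c(3, 3, 10)),
                         dropout_p = 0.5,
                         cae_channels = c("FC3", "FCz", "FC4", "C3", "Cz",
                                          "C4"),
                         cae_filters = c(8, 16),
                         lstm_a_units = 40, lstm_b_units = 80,
                         attention_dim = lstm_a_units + lstm_b_units,
                         n_classes = 3, input_fs = 100,
                         grid_channels = NULL,
                         precision = c("double", "single"),
                         use_msstcn = TRUE, use_cae = TRUE,
                         use_lstm_sa = TRUE) {
  precision <- match.arg(precision)
  cfg <- structure(as.list(environment()), class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  H <- cfg$grid_shape[1L]; W <- cfg$grid_shape[2L]; T <- cfg$T_samples
  p1 <- cfg$pools[[1L]]; p2 <- cfg$pools[[2L]]
  if (length(cfg$msstcn_kernels) != 3L)
    stop("three convolution kernels are required (small/medium/large)")
  if (H %% p1[1L] || W %% p1[2L] || T %% p1[3L])
    stop(sprintf("pool 1 (%s) does not divide the plane (H=%d, W=%d, T=%d)",
                 paste(p1, collapse = ","), H, W, T))
  H2 <- H / p1[1L]; W2 <- W / p1[2L]; T2 <- T / p1[3L]
  if (H2 %% p2[1L] || W2 %% p2[2L] || T2 %% p2[3L])
    stop(sprintf(
      "pool 2 (%s) does not divide the post-pool-1 extents (H=%d, W=%d, T=%d)",
      paste(p2, collapse = ","), H2, W2, T2))
  if (H2 / p2[1L] != 1 || W2 / p2[2L] != 1)
    stop("pools must collapse the plane to 1 x 1 spatially")
  cfg$steps <- T2 / p2[3L]
  if (cfg$use_cae) {
    if (T %% 4L) stop("T_samples must be divisible by 4 for the auto-encoder")
    if (T %% cfg$steps)
      stop("T_samples must be divisible by the step count ", cfg$steps)
  }
  if (cfg$use_msstcn && cfg$use_cae &&
      cfg$attention_dim != cfg$lstm_a_units + cfg$lstm_b_units)
    stop("attention_dim must equal lstm_a_units + lstm_b_units")
  invisible(cfg)
}

#' Number of LSTM steps implied by a model configuration
#' @param cfg a [model_config()].
#' @export
model_steps <- function(cfg) {
  cfg$T_samples / (cfg$pools[[1L]][3L] * cfg$pools[[2L]][3L])
}

#' Remove one branch from the architecture
#'
#' * `"MSSTCN"`: the auto-encoder sequence alone feeds the LSTM-SA stage
#'   (attention width becomes `lstm_b_units`).
#' * `"CAE"`: the spatial-temporal sequence alone feeds LSTM-SA (width
#'   `lstm_a_units`).
#' * `"LSTM-SA"`: both branch sequences are flattened and concatenated
#'   directly into the classifier; the model has no recurrent parameters.
#'
#' @param cfg a [model_config()].
#' @param which one of `"MSSTCN"`, `"CAE"`, `"LSTM-SA"`.
#' @return the modified configuration.
#' @export
ablate <- function(cfg, which = c("MSSTCN", "CAE", "LSTM-SA")) {
  which <- match.arg(which)
  if (which == "MSSTCN") {
    cfg$use_msstcn <- FALSE
    cfg$attention_dim <- cfg$lstm_b_units
  } else if (which == "CAE") {
    cfg$use_cae <- FALSE
    cfg$attention_dim <- cfg$lstm_a_units
  } else {
    cfg$use_lstm_sa <- FALSE
  }
  validate_model_config(cfg)
  cfg
}

#' Build the network
#'
#' Initialises all layers (He-normal convolutions, uniform LSTM weights with
#' forget bias 1, zero biases) using the current RNG state; seed via
#' `set.seed()` or [train_model()] for reproducible weights.
#'
#' @param cfg a [model_config()].
#' @return an object of class `fnssir_model`.
#' @export
build_model <- function(cfg = model_config()) {
  validate_model_config(cfg)
  steps <- model_steps(cfg)
  F1 <- cfg$msstcn_filters[1L]; F2 <- cfg$msstcn_filters[2L]
  L <- list()
  single <- identical(cfg$precision, "single")
  if (cfg$use_msstcn) {
    # per-branch BN before concatenation and one BN on the concatenation are
    # the same per-channel partition; a single merged BN layer is used
    L$msconv1 <- nn_msconv3d(cfg$msstcn_kernels, 1L, F1, single)
    L$bn1 <- nn_bnrelu3d(3L * F1)
    L$msconv2 <- nn_msconv3d(cfg$msstcn_kernels, 3L * F1, F2, single)
    L$bn2 <- nn_bnrelu3d(3L * F2)
    L$pool1 <- nn_avgpool3d(cfg$pools[[1L]])
    L$pool2 <- nn_avgpool3d(cfg$pools[[2L]])
    L$drop <- nn_dropout(cfg$dropout_p)
  }
  if (cfg$use_cae) {
    C1 <- cfg$cae_filters[1L]; C2 <- cfg$cae_filters[2L]
    L$cae_conv1 <- nn_conv1d(3L, 1L, C1)
    L$cae_relu1 <- nn_relu()
    L$cae_mp1 <- nn_maxpool1d(2L)
    L$cae_conv2 <- nn_conv1d(3L, C1, C2)
    L$cae_relu2 <- nn_relu()
    L$cae_mp2 <- nn_maxpool1d(2L)
    L$cae_dec1 <- nn_convtranspose1d(4L, C2, C1, stride = 2L, pad = 1L)
    L$cae_relu3 <- nn_relu()
    L$cae_dec2 <- nn_convtranspose1d(4L, C1, 1L, stride = 2L, pad = 1L)
    L$cae_sigmoid <- nn_sigmoid()
  }
  feat_m <- 3L * F2
  feat_c <- length(cfg$cae_channels) * (cfg$T_samples %/% steps)
  if (cfg$use_lstm_sa) {
    if (cfg$use_msstcn) L$lstm_a <- nn_lstm(feat_m, cfg$lstm_a_units)
    if (cfg$use_cae) L$lstm_b <- nn_lstm(feat_c, cfg$lstm_b_units)
    L$att <- nn_attention(cfg$attention_dim)
    fc_in <- steps * cfg$attention_dim
  } else {
    fc_in <- (if (cfg$use_msstcn) steps * feat_m else 0L) +
      (if (cfg$use_cae) steps * feat_c else 0L)
  }
  L$fc <- nn_dense(fc_in, cfg$n_classes)
  structure(list(cfg = cfg, layers = L, steps = steps,
                 feat_m = feat_m, feat_c = feat_c),
            class = "fnssir_model")
}

#' @export
print.fnssir_model <- function(x, ...) {
  cat(sprintf(
    "<fnssir_model> %s%s%s-> fc; %d steps, %d parameters\n",
    if (x$cfg$use_msstcn) "MSSTCN " else "",
    if (x$cfg$use_cae) "CAE " else "",
    if (x$cfg$use_lstm_sa) "LSTM-SA " else "",
    x$steps, count_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an `fnssir_model`.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

#' Architecture fingerprint
#'
#' Layer list with parameter shapes, as a JSON string, for
#' cross-implementation comparison of checkpoints.
#' @param model an `fnssir_model`.
#' @export
architecture_fingerprint <- function(model) {
  layers <- lapply(model$layers, function(l)
    lapply(l$params, function(p) dim(p) %||% length(p)))
  jsonlite::toJSON(list(steps = model$steps,
                        n_classes = model$cfg$n_classes,
                        layers = layers), auto_unbox = TRUE)
}

#' Extract / restore model weights
#' @param model an `fnssir_model`.
#' @export
get_weights <- function(model) lapply(model$layers, function(l) l$params)

#' @rdname get_weights
#' @param weights a list produced by [get_weights()].
#' @export
set_weights <- function(model, weights) {
  for (nm in names(weights)) model$layers[[nm]]$params <- weights[[nm]]
  invisible(model)
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

msstcn_unit_fwd <- function(model, unit, x, training) {
  L <- model$layers
  y <- L[[paste0("msconv", unit)]]$fwd(x, training)
  y <- L[[paste0("bn", unit)]]$fwd(y, training)   # fused BN + ReLU
  L[[paste0("pool", unit)]]$fwd(y, training)
}

msstcn_unit_bwd <- function(model, unit, dout, need_input_grad) {
  L <- model$layers
  d <- L[[paste0("pool", unit)]]$bwd(dout)
  d <- L[[paste0("bn", unit)]]$bwd(d)
  L[[paste0("msconv", unit)]]$bwd(d, need_input_grad)
}

#' Forward pass
#'
#' @param model an `fnssir_model`.
#' @param plane plane tensor in internal layout `[T, H, W, 1, B]` (see
#'   [prepare_model_inputs()]).
#' @param cae_x auto-encoder input `[T, 1, B * n_cae_channels]`, scaled to
#'   `[0, 1]`; rows ordered channel-fastest.
#' @param training logical; enables dropout and batch statistics.
#' @return list with `logits` `[B x n_classes]`, `recon` (auto-encoder
#'   reconstruction, same shape as `cae_x`), and the branch sequences.
#' @export
model_forward <- function(model, plane, cae_x, training = FALSE) {
  cfg <- model$cfg
  L <- model$layers
  steps <- model$steps
  seq_m <- seq_c <- NULL
  recon <- NULL
  B <- if (cfg$use_msstcn) dim(plane)[5L]
       else dim(cae_x)[3L] / length(cfg$cae_channels)

  if (cfg$use_msstcn) {
    h1 <- msstcn_unit_fwd(model, 1L, plane, training)
    h2 <- msstcn_unit_fwd(model, 2L, h1, training)
    h2 <- L$drop$fwd(h2, training)
    # [steps, 1, 1, C, B] -> [B, steps, C]
    m <- h2; dim(m) <- c(steps, model$feat_m, B)
    seq_m <- aperm(m, c(3L, 1L, 2L))
  }
  if (cfg$use_cae) {
    e <- L$cae_relu1$fwd(L$cae_conv1$fwd(cae_x, training), training)
    e <- L$cae_mp1$fwd(e, training)
    e <- L$cae_relu2$fwd(L$cae_conv2$fwd(e, training), training)
    e <- L$cae_mp2$fwd(e, training)
    d <- L$cae_relu3$fwd(L$cae_dec1$fwd(e, training), training)
    recon <- L$cae_sigmoid$fwd(L$cae_dec2$fwd(d, training), training)
    nc <- length(cfg$cae_channels)
    win <- cfg$T_samples %/% steps
    r <- recon; dim(r) <- c(win, steps, nc, B)     # rows channel-fastest
    seq_c <- aperm(r, c(4L, 2L, 1L, 3L))
    dim(seq_c) <- c(B, steps, model$feat_c)
  }
  if (cfg$use_lstm_sa) {
    parts <- list()
    if (cfg$use_msstcn) parts$a <- L$lstm_a$fwd(seq_m, training)
    if (cfg$use_cae) parts$b <- L$lstm_b$fwd(seq_c, training)
    fused <- if (length(parts) == 2L) {
      arr <- array(0, c(B, steps, cfg$attention_dim))
      arr[, , seq_len(cfg$lstm_a_units)] <- parts$a
      arr[, , cfg$lstm_a_units + seq_len(cfg$lstm_b_units)] <- parts$b
      arr
    } else parts[[1L]]
    att <- L$att$fwd(fused, training)
    flat <- matrix(att, B)                          # [B, steps*d]
  } else {
    flat <- cbind(
      if (cfg$use_msstcn) matrix(seq_m, B) else NULL,
      if (cfg$use_cae) matrix(seq_c, B) else NULL)
  }
  logits <- L$fc$fwd(flat, training)
  list(logits = logits, recon = recon, seq_m = seq_m, seq_c = seq_c,
       B = B)
}

#' Backward pass
#'
#' Accumulates parameter gradients for a loss whose gradients w.r.t. the
#' logits (and optionally the auto-encoder reconstruction) are given.
#'
#' @param model an `fnssir_model` whose layers hold the forward caches.
#' @param fw the [model_forward()] result.
#' @param dlogits gradient at the logits `[B x n_classes]`.
#' @param drecon optional gradient at the reconstruction (same shape), e.g.
#'   from a denoising MSE term.
#' @export
model_backward <- function(model, fw, dlogits, drecon = NULL) {
  cfg <- model$cfg
  L <- model$layers
  steps <- model$steps
  B <- fw$B
  dflat <- L$fc$bwd(dlogits)
  dseq_m <- dseq_c <- NULL
  if (cfg$use_lstm_sa) {
    datt <- array(dflat, c(B, steps, cfg$attention_dim))
    dfused <- L$att$bwd(datt)
    if (cfg$use_msstcn && cfg$use_cae) {
      dseq_m <- L$lstm_a$bwd(dfused[, , seq_len(cfg$lstm_a_units), drop = FALSE])
      dseq_c <- L$lstm_b$bwd(
        dfused[, , cfg$lstm_a_units + seq_len(cfg$lstm_b_units), drop = FALSE])
    } else if (cfg$use_msstcn) {
      dseq_m <- L$lstm_a$bwd(dfused)
    } else {
      dseq_c <- L$lstm_b$bwd(dfused)
    }
  } else {
    at <- 0L
    if (cfg$use_msstcn) {
      n <- steps * model$feat_m
      dseq_m <- array(dflat[, at + seq_len(n)], c(B, steps, model$feat_m))
      at <- at + n
    }
    if (cfg$use_cae) {
      n <- steps * model$feat_c
      dseq_c <- array(dflat[, at + seq_len(n)], c(B, steps, model$feat_c))
    }
  }
  if (cfg$use_cae) {
    nc <- length(cfg$cae_channels)
    win <- cfg$T_samples %/% steps
    dr <- aperm(array(dseq_c, c(B, steps, win, nc)), c(3L, 2L, 4L, 1L))
    dim(dr) <- c(cfg$T_samples, 1L, nc * B)
    if (!is.null(drecon)) dr <- dr + drecon
    dd <- L$cae_sigmoid$bwd(dr)
    dd <- L$cae_dec2$bwd(dd)
    dd <- L$cae_relu3$bwd(dd)
    dd <- L$cae_dec1$bwd(dd)
    de <- L$cae_mp2$bwd(dd)
    de <- L$cae_relu2$bwd(de)
    de <- L$cae_conv2$bwd(de)
    de <- L$cae_mp1$bwd(de)
    de <- L$cae_relu1$bwd(de)
    L$cae_conv1$bwd(de)
  }
  if (cfg$use_msstcn) {
    dm <- aperm(dseq_m, c(2L, 3L, 1L))
    dim(dm) <- c(steps, 1L, 1L, model$feat_m, B)
    dm <- L$drop$bwd(dm)
    dh1 <- msstcn_unit_bwd(model, 2L, dm, need_input_grad = TRUE)
    msstcn_unit_bwd(model, 1L, dh1, need_input_grad = FALSE)
  }
  invisible(NULL)
}

#' Zero all accumulated gradients
#' @param model an `fnssir_model`.
#' @export
zero_grads <- function(model) {
  for (l in model$layers) layer_zero_grads(l)
  invisible(model)
}
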