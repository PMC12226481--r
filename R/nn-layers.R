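# Minimal neural-network layer library with hand-written forward/backward
# passes. Each layer is an environment holding `params` and `grads` (named
# lists of arrays) plus `fwd(x, training)` / `bwd(dout)` closures that cache
# whatever the backward pass needs. Spatial-temporal tensors use the layout
# [T, H, W, C, B] (time fastest); sequence tensors are [B, steps, feat];
# 1D-over-time tensors for the auto-encoder are [L, C, R] with R = batch
# rows. Gradients are accumulated into `grads` by `bwd`; `zero_grads()` and
# the Adam step operate over all layers of a model.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("nn_", kind), "nn_layer")
  e
}

layer_zero_grads <- function(l) {
  l$grads <- lapply(l$params, function(p) p * 0)   # preserves shape exactly
  invisible(l)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- 3D convolution (C++ core) --------------------------------------------

#' @keywords internal
nn_conv3d <- function(kernel_hwt, in_ch, out_ch, single = FALSE) {
  l <- new_layer("conv3d")
  l$single <- single
  kt <- kernel_hwt[3L]; kh <- kernel_hwt[1L]; kw <- kernel_hwt[2L]
  if (any(c(kt, kh, kw) %% 2 == 0))
    stop("conv3d kernels must have odd extents for same padding")
  fan_in <- kt * kh * kw * in_ch
  l$params$w <- array(rnorm(kt * kh * kw * in_ch * out_ch,
                            sd = sqrt(2 / fan_in)),
                      c(kt, kh, kw, in_ch, out_ch))
  l$params$b <- numeric(out_ch)
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    l$cache <- list(x = x, xd = xd)
    out <- conv3d_fwd(x, l$params$w, l$params$b, as.integer(xd),
                      as.integer(dim(l$params$w)), l$single)
    dim(out) <- c(xd[1:3], out_ch, xd[5L])
    out
  }
  l$bwd <- function(dout, need_input_grad = TRUE) {
    xd <- l$cache$xd
    g <- conv3d_wgrad(l$cache$x, dout, as.integer(xd),
                      as.integer(dim(l$params$w)), l$single)
    dim(g$dw) <- dim(l$params$w)
    l$grads$w <- g$dw
    l$grads$b <- g$db
    if (!need_input_grad) return(NULL)
    dx <- conv3d_igrad(dout, l$params$w, as.integer(xd),
                       as.integer(dim(l$params$w)), l$single)
    dim(dx) <- xd
    dx
  }
  l
}

# three parallel same-padded 3D convolutions (small/medium/large kernels)
# writing a channel-concatenated output in one pass
#' @keywords internal
nn_msconv3d <- function(kernels_hwt, in_ch, f_per_branch, single = FALSE) {
  l <- new_layer("msconv3d")
  l$single <- single
  l$ftot <- 3L * f_per_branch
  l$wd <- vector("list", 3L)
  for (i in 1:3) {
    k <- kernels_hwt[[i]]
    kt <- k[3L]; kh <- k[1L]; kw <- k[2L]
    if (any(c(kt, kh, kw) %% 2 == 0))
      stop("conv3d kernels must have odd extents for same padding")
    fan_in <- kt * kh * kw * in_ch
    l$params[[paste0("w", i)]] <-
      array(rnorm(kt * kh * kw * in_ch * f_per_branch,
                  sd = sqrt(2 / fan_in)),
            c(kt, kh, kw, in_ch, f_per_branch))
    l$params[[paste0("b", i)]] <- numeric(f_per_branch)
    l$wd[[i]] <- c(kt, kh, kw, in_ch, f_per_branch)
  }
  l$f <- f_per_branch
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    out <- numeric(prod(xd[1:3]) * l$ftot * xd[5L])
    for (i in 1:3)
      conv3d_fwd_into(out, x, l$params[[paste0("w", i)]],
                      l$params[[paste0("b", i)]], as.integer(xd),
                      as.integer(l$wd[[i]]), l$ftot, (i - 1L) * l$f,
                      l$single)
    dim(out) <- c(xd[1:3], l$ftot, xd[5L])
    l$cache <- list(x = x, xd = xd)
    out
  }
  l$bwd <- function(dout, need_input_grad = TRUE) {
    xd <- l$cache$xd
    for (i in 1:3) {
      g <- conv3d_wgrad(l$cache$x, dout, as.integer(xd),
                        as.integer(l$wd[[i]]), l$single, l$ftot,
                        (i - 1L) * l$f)
      dim(g$dw) <- dim(l$params[[paste0("w", i)]])
      l$grads[[paste0("w", i)]] <- g$dw
      l$grads[[paste0("b", i)]] <- g$db
    }
    if (!need_input_grad) return(NULL)
    dx <- numeric(prod(xd))
    for (i in 1:3)
      conv3d_igrad_into(dx, dout, l$params[[paste0("w", i)]],
                        as.integer(xd), as.integer(l$wd[[i]]), l$ftot,
                        (i - 1L) * l$f, l$single)
    dim(dx) <- xd
    dx
  }
  l
}

# ---- batch normalisation over channels of [T, H, W, C, B] -----------------

#' @keywords internal
nn_batchnorm3d <- function(n_ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm3d")
  l$params$gamma <- rep(1, n_ch)
  l$params$beta <- rep(0, n_ch)
  l$run_mean <- rep(0, n_ch)
  l$run_var <- rep(1, n_ch)
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    n <- prod(xd[1:3]); C <- xd[4L]; B <- xd[5L]
    m_tot <- n * B
    if (training) {
      st <- bn_stats(x, n, C, B)
      mu <- st$sum / m_tot
      va <- pmax(st$sumsq / m_tot - mu^2, 0)
      l$run_mean <- (1 - momentum) * l$run_mean + momentum * mu
      l$run_var <- (1 - momentum) * l$run_var + momentum * va
    } else {
      mu <- l$run_mean; va <- l$run_var
    }
    istd <- 1 / sqrt(va + eps)
    ap <- bn_apply(x, mu, istd, l$params$gamma, l$params$beta, n, C, B)
    out <- ap$y
    dim(out) <- xd
    l$cache <- list(xhat = ap$xhat, istd = istd, xd = xd,
                    training = training)
    out
  }
  l$bwd <- function(dout) {
    xd <- l$cache$xd
    n <- prod(xd[1:3]); C <- xd[4L]; B <- xd[5L]
    m_tot <- n * B
    sums <- bn_bwd_sums(dout, l$cache$xhat, n, C, B)
    l$grads$gamma <- sums$sum_xhat
    l$grads$beta <- sums$sum
    if (l$cache$training) {
      s1 <- sums$sum / m_tot
      s2 <- sums$sum_xhat / m_tot
    } else {
      s1 <- s2 <- numeric(C)
    }
    dx <- bn_bwd_apply(dout, l$cache$xhat, l$params$gamma, l$cache$istd,
                       s1, s2, n, C, B)
    dim(dx) <- xd
    dx
  }
  l
}

# fused batchnorm + ReLU (the unit-level BN -> ReLU sequence in one pass
# over the large feature maps)
#' @keywords internal
nn_bnrelu3d <- function(n_ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bnrelu3d")
  l$params$gamma <- rep(1, n_ch)
  l$params$beta <- rep(0, n_ch)
  l$run_mean <- rep(0, n_ch)
  l$run_var <- rep(1, n_ch)
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    n <- prod(xd[1:3]); C <- xd[4L]; B <- xd[5L]
    m_tot <- n * B
    if (training) {
      st <- bn_stats(x, n, C, B)
      mu <- st$sum / m_tot
      va <- pmax(st$sumsq / m_tot - mu^2, 0)
      l$run_mean <- (1 - momentum) * l$run_mean + momentum * mu
      l$run_var <- (1 - momentum) * l$run_var + momentum * va
    } else {
      mu <- l$run_mean; va <- l$run_var
    }
    istd <- 1 / sqrt(va + eps)
    ap <- bn_relu_apply(x, mu, istd, l$params$gamma, l$params$beta, n, C, B)
    out <- ap$y
    dim(out) <- xd
    l$cache <- list(xhat = ap$xhat, y = ap$y, istd = istd, xd = xd,
                    training = training)
    out
  }
  l$bwd <- function(dout) {
    xd <- l$cache$xd
    n <- prod(xd[1:3]); C <- xd[4L]; B <- xd[5L]
    m_tot <- n * B
    sums <- bn_relu_bwd_sums(dout, l$cache$xhat, l$cache$y, n, C, B)
    l$grads$gamma <- sums$sum_xhat
    l$grads$beta <- sums$sum
    if (l$cache$training) {
      s1 <- sums$sum / m_tot
      s2 <- sums$sum_xhat / m_tot
    } else {
      s1 <- s2 <- numeric(C)
    }
    dx <- bn_relu_bwd_apply(dout, l$cache$xhat, l$cache$y, l$params$gamma,
                            l$cache$istd, s1, s2, n, C, B)
    dim(dx) <- xd
    dx
  }
  l
}

# ---- elementwise layers ----------------------------------------------------

#' @keywords internal
nn_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, training = FALSE) {
    y <- relu_fwd(x)
    dim(y) <- dim(x)
    l$cache <- y
    y
  }
  l$bwd <- function(dout) {
    dx <- relu_bwd(dout, l$cache)
    dim(dx) <- dim(dout)
    dx
  }
  l
}

#' @keywords internal
nn_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$fwd <- function(x, training = FALSE) {
    y <- 1 / (1 + exp(-x))
    l$cache <- y
    y
  }
  l$bwd <- function(dout) dout * l$cache * (1 - l$cache)
  l
}

#' @keywords internal
nn_dropout <- function(p = 0.5) {
  l <- new_layer("dropout")
  l$p <- p
  l$fwd <- function(x, training = FALSE) {
    if (!training || l$p <= 0) {
      l$cache <- NULL
      return(x)
    }
    if (l$p >= 1) {
      l$cache <- array(0, dim(x) %||% length(x))
      return(x * 0)
    }
    m <- (array(runif(length(x)), dim(x) %||% length(x)) >= l$p) / (1 - l$p)
    l$cache <- m
    x * m
  }
  l$bwd <- function(dout) if (is.null(l$cache)) dout else dout * l$cache
  l
}

# ---- pooling ---------------------------------------------------------------

#' @keywords internal
nn_avgpool3d <- function(pool_hwt) {
  l <- new_layer("avgpool3d")
  l$pd <- as.integer(c(pool_hwt[3L], pool_hwt[1L], pool_hwt[2L]))  # (t,h,w)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    l$cache <- xd
    if (xd[1L] %% l$pd[1L] || xd[2L] %% l$pd[2L] || xd[3L] %% l$pd[3L])
      stop(sprintf(
        "pool (%d,%d,%d) does not divide extents (H=%d, W=%d, T=%d)",
        l$pd[2L], l$pd[3L], l$pd[1L], xd[2L], xd[3L], xd[1L]))
    out <- avgpool3d_fwd(x, as.integer(xd), l$pd)
    dim(out) <- c(xd[1L] / l$pd[1L], xd[2L] / l$pd[2L], xd[3L] / l$pd[3L],
                  xd[4L], xd[5L])
    out
  }
  l$bwd <- function(dout) {
    dx <- avgpool3d_bwd(dout, as.integer(l$cache), l$pd)
    dim(dx) <- l$cache
    dx
  }
  l
}

# max pooling over the time axis of [L, C, R], factor q
#' @keywords internal
nn_maxpool1d <- function(q = 2L) {
  l <- new_layer("maxpool1d")
  l$q <- q
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)
    if (xd[1L] %% l$q)
      stop("time length ", xd[1L], " not divisible by pool ", l$q)
    L2 <- xd[1L] %/% l$q
    xr <- x; dim(xr) <- c(l$q, L2 * xd[2L] * xd[3L])
    am <- max.col(t(xr), ties.method = "first")
    mx <- xr[cbind(am, seq_along(am))]
    l$cache <- list(am = am, xd = xd)
    array(mx, c(L2, xd[2L], xd[3L]))
  }
  l$bwd <- function(dout) {
    xd <- l$cache$xd
    L2 <- xd[1L] %/% l$q
    dxr <- matrix(0, l$q, L2 * xd[2L] * xd[3L])
    dxr[cbind(l$cache$am, seq_along(l$cache$am))] <- as.vector(dout)
    dim(dxr) <- xd
    dxr
  }
  l
}

# ---- 1D convolutions over time, [L, C, R] ---------------------------------

#' @keywords internal
nn_conv1d <- function(k, in_ch, out_ch, pad = (k - 1L) %/% 2L, stride = 1L) {
  l <- new_layer("conv1d")
  fan_in <- k * in_ch
  l$params$w <- array(rnorm(k * in_ch * out_ch, sd = sqrt(2 / fan_in)),
                      c(k, in_ch, out_ch))
  l$params$b <- numeric(out_ch)
  l$k <- k; l$pad <- pad; l$stride <- stride
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)  # [L, C, R]
    Lout <- (xd[1L] + 2L * l$pad - l$k) %/% l$stride + 1L
    out <- conv1d_fwd(x, l$params$w, l$params$b, as.integer(xd),
                      as.integer(dim(l$params$w)), l$stride, l$pad)
    dim(out) <- c(Lout, out_ch, xd[3L])
    l$cache <- list(x = x, xd = xd)
    out
  }
  l$bwd <- function(dout) {
    g <- conv1d_bwd(l$cache$x, l$params$w, dout, as.integer(l$cache$xd),
                    as.integer(dim(l$params$w)), l$stride, l$pad)
    dim(g$dw) <- dim(l$params$w)
    l$grads$w <- g$dw
    l$grads$b <- g$db
    dx <- g$dx
    dim(dx) <- l$cache$xd
    dx
  }
  l
}

# transposed 1D convolution: output length = stride * L (k = 4, stride = 2,
# pad = 1 gives exact x2 upsampling)
#' @keywords internal
nn_convtranspose1d <- function(k, in_ch, out_ch, stride = 2L, pad = 1L) {
  l <- new_layer("convtranspose1d")
  fan_in <- k * in_ch
  l$params$w <- array(rnorm(k * in_ch * out_ch, sd = sqrt(2 / fan_in)),
                      c(k, in_ch, out_ch))
  l$params$b <- numeric(out_ch)
  l$k <- k; l$stride <- stride; l$pad <- pad
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    xd <- dim(x)  # [L, C, R]
    Lout <- (xd[1L] - 1L) * l$stride - 2L * l$pad + l$k
    out <- convt1d_fwd(x, l$params$w, l$params$b, as.integer(xd),
                       as.integer(dim(l$params$w)), l$stride, l$pad)
    dim(out) <- c(Lout, out_ch, xd[3L])
    l$cache <- list(x = x, xd = xd)
    out
  }
  l$bwd <- function(dout) {
    g <- convt1d_bwd(l$cache$x, l$params$w, dout, as.integer(l$cache$xd),
                     as.integer(dim(l$params$w)), l$stride, l$pad)
    dim(g$dw) <- dim(l$params$w)
    l$grads$w <- g$dw
    l$grads$b <- g$db
    dx <- g$dx
    dim(dx) <- l$cache$xd
    dx
  }
  l
}

# ---- dense -----------------------------------------------------------------

#' @keywords internal
nn_dense <- function(n_in, n_out) {
  l <- new_layer("dense")
  l$params$w <- matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  l$params$b <- numeric(n_out)
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    sweep(x %*% l$params$w, 2L, l$params$b, "+")
  }
  l$bwd <- function(dout) {
    l$grads$w <- crossprod(l$cache, dout)
    l$grads$b <- colSums(dout)
    tcrossprod(dout, l$params$w)
  }
  l
}

# ---- LSTM over [B, steps, feat] -------------------------------------------

#' @keywords internal
nn_lstm <- function(n_in, n_units) {
  l <- new_layer("lstm")
  s <- 1 / sqrt(n_units)
  l$params$wx <- matrix(runif(n_in * 4 * n_units, -s, s), n_in, 4 * n_units)
  l$params$wh <- matrix(runif(n_units * 4 * n_units, -s, s), n_units,
                        4 * n_units)
  l$params$b <- c(rep(0, n_units), rep(1, n_units), rep(0, 2 * n_units))
  l$n_units <- n_units
  layer_zero_grads(l)
  sig <- function(z) 1 / (1 + exp(-z))
  l$fwd <- function(x, training = FALSE) {
    B <- dim(x)[1L]; S <- dim(x)[2L]
    U <- n_units
    h <- matrix(0, B, U); cc <- matrix(0, B, U)
    out <- array(0, c(B, S, U))
    steps <- vector("list", S)
    ii <- seq_len(U); ff <- U + ii; gg <- 2L * U + ii; oo <- 3L * U + ii
    for (s_ in seq_len(S)) {
      xt <- matrix(x[, s_, ], B)
      z <- xt %*% l$params$wx + h %*% l$params$wh +
        matrix(l$params$b, B, 4 * U, byrow = TRUE)
      gi <- sig(z[, ii, drop = FALSE]); gf <- sig(z[, ff, drop = FALSE])
      gg_ <- tanh(z[, gg, drop = FALSE]); go <- sig(z[, oo, drop = FALSE])
      c_prev <- cc
      cc <- gf * c_prev + gi * gg_
      tc <- tanh(cc)
      h_prev <- h
      h <- go * tc
      out[, s_, ] <- h
      steps[[s_]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                          gi = gi, gf = gf, gg = gg_, go = go, tc = tc)
    }
    l$cache <- list(steps = steps, B = B, S = S)
    out
  }
  l$bwd <- function(dout) {
    B <- l$cache$B; S <- l$cache$S; U <- n_units
    dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
    dx <- array(0, c(B, S, dim(l$params$wx)[1L]))
    gwx <- l$params$wx * 0; gwh <- l$params$wh * 0; gb <- l$params$b * 0
    for (s_ in rev(seq_len(S))) {
      st <- l$cache$steps[[s_]]
      dh <- matrix(dout[, s_, ], B) + dh_next
      dc <- dc_next + dh * st$go * (1 - st$tc^2)
      dgo <- dh * st$tc * st$go * (1 - st$go)
      dgi <- dc * st$gg * st$gi * (1 - st$gi)
      dgf <- dc * st$c_prev * st$gf * (1 - st$gf)
      dgg <- dc * st$gi * (1 - st$gg^2)
      dz <- cbind(dgi, dgf, dgg, dgo)
      gwx <- gwx + crossprod(st$xt, dz)
      gwh <- gwh + crossprod(st$h_prev, dz)
      gb <- gb + colSums(dz)
      dx[, s_, ] <- tcrossprod(dz, l$params$wx)
      dh_next <- tcrossprod(dz, l$params$wh)
      dc_next <- dc * st$gf
    }
    l$grads$wx <- gwx; l$grads$wh <- gwh; l$grads$b <- gb
    dx
  }
  l
}

# ---- scaled dot-product self-attention over [B, steps, d] -----------------

#' @keywords internal
nn_attention <- function(d) {
  l <- new_layer("attention")
  s <- 1 / sqrt(d)
  l$params$wq <- matrix(runif(d * d, -s, s), d, d)
  l$params$wk <- matrix(runif(d * d, -s, s), d, d)
  l$params$wv <- matrix(runif(d * d, -s, s), d, d)
  l$params$bq <- numeric(d); l$params$bk <- numeric(d); l$params$bv <- numeric(d)
  l$d <- d
  layer_zero_grads(l)
  l$fwd <- function(x, training = FALSE) {
    B <- dim(x)[1L]; S <- dim(x)[2L]
    X2 <- matrix(aperm(x, c(2L, 1L, 3L)), B * S, l$d)  # rows: (step, batch)
    Q <- sweep(X2 %*% l$params$wq, 2L, l$params$bq, "+")
    K <- sweep(X2 %*% l$params$wk, 2L, l$params$bk, "+")
    V <- sweep(X2 %*% l$params$wv, 2L, l$params$bv, "+")
    out <- array(0, c(B, S, l$d))
    A <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * S + seq_len(S)
      Sc <- tcrossprod(Q[rows, , drop = FALSE], K[rows, , drop = FALSE]) /
        sqrt(l$d)
      Sc <- sweep(Sc, 1L, apply(Sc, 1L, max), "-")
      E <- exp(Sc)
      Ab <- E / rowSums(E)
      out[b, , ] <- Ab %*% V[rows, , drop = FALSE]
      A[[b]] <- Ab
    }
    l$cache <- list(X2 = X2, Q = Q, K = K, V = V, A = A, B = B, S = S)
    out
  }
  l$bwd <- function(dout) {
    B <- l$cache$B; S <- l$cache$S; d <- l$d
    dQ <- matrix(0, B * S, d); dK <- matrix(0, B * S, d)
    dV <- matrix(0, B * S, d)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * S + seq_len(S)
      dOb <- matrix(dout[b, , ], S, d)
      Ab <- l$cache$A[[b]]
      dV[rows, ] <- crossprod(Ab, dOb)
      dA <- tcrossprod(dOb, l$cache$V[rows, , drop = FALSE])
      dS <- Ab * (dA - rowSums(dA * Ab))
      dQ[rows, ] <- dS %*% l$cache$K[rows, , drop = FALSE] / sqrt(d)
      dK[rows, ] <- crossprod(dS, l$cache$Q[rows, , drop = FALSE]) / sqrt(d)
    }
    X2 <- l$cache$X2
    l$grads$wq <- crossprod(X2, dQ)
    l$grads$wk <- crossprod(X2, dK)
    l$grads$wv <- crossprod(X2, dV)
    l$grads$bq <- colSums(dQ)
    l$grads$bk <- colSums(dK)
    l$grads$bv <- colSums(dV)
    dX2 <- tcrossprod(dQ, l$params$wq) + tcrossprod(dK, l$params$wk) +
      tcrossprod(dV, l$params$wv)
    aperm(array(dX2, c(S, B, d)), c(2L, 1L, 3L))
  }
  l
}

# ---- losses ----------------------------------------------------------------

# softmax cross-entropy; logits [B, n_classes], labels 0-based
softmax_xent <- function(logits, labels) {
  B <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$params)) {
      st <- state[[i]][[nm]]
      adam_update(l$params[[nm]], l$grads[[nm]], st$m, st$v,
                  lr, beta1, beta2, eps, bc1, bc2)
    }
  }
  state
}
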