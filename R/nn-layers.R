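## Neural-network layer primitives with explicit forward/backward passes.
##
## Tensors are column-major R arrays; convolutional activations use layout
## (C, H, W, B) — channel fastest, so per-channel batch-norm arithmetic uses
## plain R recycling and the im2col GEMM output reinterprets as the output
## activation without a copy. Every layer forward returns list(out, cache)
## and every backward consumes (dout, cache) and returns list(dx, grads...).
## This keeps the whole network differentiable without an autodiff framework
## and makes the gradient-reversal contract directly checkable by finite
## differences.

conv_out_hw <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

init_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  fan_in <- kh * kw * cin
  list(
    # flattened row order must match im2col: (cin, kh, kw)
    W = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
              dim = c(cin, kh, kw, cout)),
    b = numeric(cout),
    kh = kh, kw = kw, stride = as.integer(stride), pad = as.integer(pad)
  )
}

conv_fwd <- function(x, p, stride, pad) {
  d <- dim(x)
  kh <- p$kh; kw <- p$kw
  oc <- dim(p$W)[4]
  oh <- conv_out_hw(d[2], kh, stride, pad)
  ow <- conv_out_hw(d[3], kw, stride, pad)
  pointwise <- kh == 1 && kw == 1 && stride == 1 && pad == 0
  if (pointwise) {
    cols <- x
    dim(cols) <- c(d[1], d[2] * d[3] * d[4])
  } else {
    cols <- im2col_cpp(x, kh, kw, stride, stride, pad, pad)
  }
  wmat <- matrix(p$W, nrow = d[1] * kh * kw, ncol = oc)
  # (J x K) GEMM orientation is markedly faster than (K x J) for the small
  # output-channel counts used here; transpose back afterwards
  out <- t.default(crossprod(cols, wmat)) + p$b
  dim(out) <- c(oc, oh, ow, d[4])
  # cache the input, not the lowered columns: x is a shared reference while
  # cols would be a large fresh allocation kept alive until the backward pass
  list(out = out,
       cache = list(x = x, xdim = d, stride = stride, pad = pad,
                    kh = kh, kw = kw, oc = oc, oh = oh, ow = ow,
                    pointwise = pointwise))
}

conv_bwd <- function(dout, p, cache, need_dx = TRUE) {
  cc <- cache
  if (cc$pointwise) {
    cols <- cc$x
    dim(cols) <- c(cc$xdim[1], cc$xdim[2] * cc$xdim[3] * cc$xdim[4])
  } else {
    cols <- im2col_cpp(cc$x, cc$kh, cc$kw, cc$stride, cc$stride,
                       cc$pad, cc$pad)
  }
  dout_mat <- dout
  dim(dout_mat) <- c(cc$oc, cc$oh * cc$ow * cc$xdim[4])
  dW_mat <- tcrossprod(cols, dout_mat)
  db <- rowSums(dout_mat)
  dx <- NULL
  if (need_dx) {
    wmat <- matrix(p$W, nrow = cc$xdim[1] * cc$kh * cc$kw, ncol = cc$oc)
    dcols <- wmat %*% dout_mat
    if (cc$pointwise) {
      dx <- dcols
      dim(dx) <- cc$xdim
    } else {
      dx <- col2im_cpp(dcols, as.integer(cc$xdim), cc$kh, cc$kw,
                       cc$stride, cc$stride, cc$pad, cc$pad)
    }
  }
  list(dx = dx, W = array(dW_mat, dim = dim(p$W)), b = db)
}

init_bn <- function(c_) {
  list(gamma = rep(1, c_), beta = numeric(c_),
       run_mean = numeric(c_), run_var = rep(1, c_))
}

bn_fwd <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  cn <- d[1]
  m <- d[2] * d[3] * d[4]
  if (training) {
    mu <- .rowMeans(x, cn, m)
    xc <- x - mu # channel-first recycling
    var_ <- .rowMeans(xc * xc, cn, m)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var +
      momentum * var_ * m / max(m - 1, 1)
  } else {
    mu <- p$run_mean
    var_ <- p$run_var
    xc <- x - mu
  }
  inv <- 1 / sqrt(var_ + eps)
  xhat <- xc * inv
  out <- xhat * p$gamma + p$beta
  dim(xhat) <- d
  dim(out) <- d
  list(out = out, params = p,
       cache = list(xhat = xhat, inv = inv, d = d, m = m,
                    training = training))
}

bn_bwd <- function(dout, p, cache) {
  d <- cache$d
  cn <- d[1]
  m <- cache$m
  dgamma <- .rowSums(dout * cache$xhat, cn, m)
  dbeta <- .rowSums(dout, cn, m)
  dxhat <- dout * p$gamma
  if (cache$training) {
    sum_dxhat <- .rowSums(dxhat, cn, m)
    sum_dxhat_xhat <- .rowSums(dxhat * cache$xhat, cn, m)
    dx <- cache$inv *
      (dxhat - sum_dxhat / m - cache$xhat * (sum_dxhat_xhat / m))
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, gamma = dgamma, beta = dbeta)
}

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}

relu_bwd <- function(dout, cache) dout * cache

maxpool_fwd <- function(x, k, stride, pad) {
  r <- maxpool_forward_cpp(x, k, k, stride, stride, pad, pad)
  list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
}

maxpool_bwd <- function(dout, cache) {
  maxpool_backward_cpp(dout, cache$argmax, as.integer(cache$xdim))
}

# Adaptive average pooling of a (C, H, W, B) array to spatial size (oh, ow);
# output bin i covers input rows floor(i*H/oh) .. ceil((i+1)*H/oh) - 1
# (0-based). When the input is already (oh, ow) this is the identity.
adaptive_avgpool_fwd <- function(x, oh, ow) {
  d <- dim(x)
  if (d[2] == oh && d[3] == ow) {
    return(list(out = x, cache = list(identity = TRUE, xdim = d)))
  }
  hb <- lapply(seq_len(oh) - 1, function(i) {
    (floor(i * d[2] / oh) + 1):ceiling((i + 1) * d[2] / oh)
  })
  wb <- lapply(seq_len(ow) - 1, function(i) {
    (floor(i * d[3] / ow) + 1):ceiling((i + 1) * d[3] / ow)
  })
  out <- array(0, dim = c(d[1], oh, ow, d[4]))
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      sl <- array(x[, hb[[i]], wb[[j]], , drop = FALSE],
                  dim = c(d[1], length(hb[[i]]) * length(wb[[j]]), d[4]))
      out[, i, j, ] <- apply(sl, c(1, 3), mean)
    }
  }
  list(out = out, cache = list(identity = FALSE, hb = hb, wb = wb, xdim = d))
}

adaptive_avgpool_bwd <- function(dout, cache) {
  if (cache$identity) return(dout)
  d <- cache$xdim
  dx <- array(0, dim = d)
  for (i in seq_along(cache$hb)) {
    for (j in seq_along(cache$wb)) {
      hb <- cache$hb[[i]]; wb <- cache$wb[[j]]
      n <- length(hb) * length(wb)
      g <- dout[, i, j, , drop = FALSE] / n # (C, 1, 1, B)
      for (h in hb) for (w in wb) {
        dx[, h, w, ] <- dx[, h, w, , drop = FALSE] + g
      }
    }
  }
  dx
}

init_linear <- function(d_in, d_out) {
  list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(x, p) {
  list(out = sweep(x %*% p$W, 2, p$b, "+"), cache = x)
}

linear_bwd <- function(dout, p, cache) {
  list(dx = dout %*% t(p$W), W = crossprod(cache, dout), b = colSums(dout))
}

dropout_fwd <- function(x, prob, training) {
  if (!training || prob <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- array(rbinom(length(x), 1, 1 - prob), dim = dim(x)) / (1 - prob)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

## ---- LSTM ----------------------------------------------------------------

init_lstm <- function(d_in, hidden) {
  s <- 1 / sqrt(hidden)
  list(
    Wx = matrix(runif(d_in * 4 * hidden, -s, s), d_in, 4 * hidden),
    Wh = matrix(runif(hidden * 4 * hidden, -s, s), hidden, 4 * hidden),
    b = runif(4 * hidden, -s, s),
    hidden = hidden
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: (B, T, D) array; returns hidden states (B, T, H) with zero initial state.
# The input projection for all timesteps is computed as one large GEMM.
lstm_fwd <- function(x, p) {
  d <- dim(x)
  B <- d[1]; Tn <- d[2]; H <- p$hidden
  xflat <- x
  dim(xflat) <- c(B * Tn, d[3]) # row b + B*(t-1)
  xg_all <- xflat %*% p$Wx
  h <- matrix(0, B, H)
  c_ <- matrix(0, B, H)
  out <- array(0, dim = c(B, Tn, H))
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1) * B + 1):(t * B)
    gates <- xg_all[rows, , drop = FALSE] + h %*% p$Wh
    gates <- sweep(gates, 2, p$b, "+")
    i_ <- sigmoid(gates[, 1:H, drop = FALSE])
    f_ <- sigmoid(gates[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(gates[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(gates[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_ * c_ + i_ * g_
    tc <- tanh(c_new)
    h_new <- o_ * tc
    steps[[t]] <- list(h_prev = h, c_prev = c_, i = i_, f = f_,
                       g = g_, o = o_, c = c_new, tc = tc)
    h <- h_new
    c_ <- c_new
    out[, t, ] <- h
  }
  list(out = out, cache = list(steps = steps, dims = d, xflat = xflat))
}

lstm_bwd <- function(dout, p, cache) {
  d <- cache$dims
  B <- d[1]; Tn <- d[2]; H <- p$hidden
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  dgates_all <- matrix(0, B * Tn, 4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dh <- matrix(dout[, t, ], B) + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dgates <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      dg * (1 - st$g^2),
      do_ * st$o * (1 - st$o)
    )
    dgates_all[((t - 1) * B + 1):(t * B), ] <- dgates
    dWh <- dWh + crossprod(st$h_prev, dgates)
    dh_next <- dgates %*% t(p$Wh)
    dc_next <- dc * st$f
  }
  # input-side gradients batched over all timesteps in two large GEMMs
  dWx <- crossprod(cache$xflat, dgates_all)
  db <- colSums(dgates_all)
  dx <- tcrossprod(dgates_all, p$Wx)
  dim(dx) <- d
  list(dx = dx, Wx = dWx, Wh = dWh, b = db)
}

# Bidirectional LSTM over the channel sequence; output (B, T, 2H) is the
# concatenation [forward_hidden; backward_hidden] per step.
bilstm_fwd <- function(x, p) {
  fw <- lstm_fwd(x, p$fwd)
  xrev <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  bw <- lstm_fwd(xrev, p$bwd)
  H <- p$fwd$hidden
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], 2 * H))
  out[, , 1:H] <- fw$out
  out[, , (H + 1):(2 * H)] <- bw$out[, rev(seq_len(d[2])), , drop = FALSE]
  list(out = out, cache = list(fw = fw$cache, bw = bw$cache, H = H, d = d))
}

bilstm_bwd <- function(dout, p, cache) {
  H <- cache$H
  d <- cache$d
  dfw <- dout[, , 1:H, drop = FALSE]
  dbw <- dout[, rev(seq_len(d[2])), (H + 1):(2 * H), drop = FALSE]
  gfw <- lstm_bwd(dfw, p$fwd, cache$fw)
  gbw <- lstm_bwd(dbw, p$bwd, cache$bw)
  dx <- gfw$dx + gbw$dx[, rev(seq_len(d[2])), , drop = FALSE]
  list(dx = dx,
       fwd = gfw[c("Wx", "Wh", "b")],
       bwd = gbw[c("Wx", "Wh", "b")])
}

## ---- Attention pooling ---------------------------------------------------

init_attention <- function(d_in, hidden) {
  list(W = matrix(rnorm(d_in * hidden, sd = sqrt(1 / d_in)), d_in, hidden),
       b = numeric(hidden),
       v = rnorm(hidden, sd = sqrt(1 / hidden)))
}

softmax_rows <- function(e) {
  e <- e - apply(e, 1, max)
  ex <- exp(e)
  ex / rowSums(ex)
}

# Hs: (B, T, D). Scores e = v' tanh(W h + b); alpha = softmax over T;
# z = sum_t alpha_t h_t.
attention_fwd <- function(hs, p) {
  d <- dim(hs)
  B <- d[1]; Tn <- d[2]; D <- d[3]
  hflat <- matrix(hs, B * Tn, D)
  u <- tanh(sweep(hflat %*% p$W, 2, p$b, "+"))
  e <- matrix(u %*% p$v, B, Tn)
  alpha <- softmax_rows(e)
  z <- matrix(0, B, D)
  for (t in seq_len(Tn)) {
    z <- z + alpha[, t] * matrix(hs[, t, ], B)
  }
  list(out = z, alpha = alpha,
       cache = list(hs = hs, hflat = hflat, u = u, alpha = alpha, d = d))
}

attention_bwd <- function(dz, p, cache) {
  d <- cache$d
  B <- d[1]; Tn <- d[2]; D <- d[3]
  hs <- cache$hs
  alpha <- cache$alpha
  dhs <- array(0, dim = d)
  dalpha <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    ht <- matrix(hs[, t, ], B)
    dhs[, t, ] <- alpha[, t] * dz
    dalpha[, t] <- rowSums(dz * ht)
  }
  de <- alpha * (dalpha - rowSums(dalpha * alpha))
  du <- as.vector(de) %o% p$v            # (B*T, A)
  dpre <- du * (1 - cache$u^2)
  dW <- crossprod(cache$hflat, dpre)
  db <- colSums(dpre)
  dv <- colSums(cache$u * as.vector(de))
  dhflat <- dpre %*% t(p$W)
  dhs <- dhs + array(dhflat, dim = d)
  list(dx = dhs, W = dW, b = db, v = dv)
}

mean_pool_fwd <- function(hs) {
  d <- dim(hs)
  z <- matrix(0, d[1], d[3])
  for (t in seq_len(d[2])) z <- z + matrix(hs[, t, ], d[1])
  list(out = z / d[2], cache = d)
}

mean_pool_bwd <- function(dz, cache) {
  d <- cache
  dhs <- array(0, dim = d)
  for (t in seq_len(d[2])) dhs[, t, ] <- dz / d[2]
  dhs
}
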