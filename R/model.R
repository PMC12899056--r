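## The domain-adversarial spatiotemporal network.
##
## Architecture: channel folding -> channel-independent CNN encoder (ResNet-
## style stem + three residual stages, adaptive average pooling to 3 x 2)
## -> spatial bidirectional LSTM over the 18-channel montage sequence ->
## attention pooling (or mean pooling for ablation) -> two heads: a 2-logit
## seizure classifier and a subject-identity (domain) classifier behind a
## gradient reversal layer.

#' Model configuration
#'
#' @param n_domains number of training-subject domains (0 disables the
#'   domain branch; adversarial training requires >= 2).
#' @param base_width stem width of the convolutional encoder; the three
#'   residual stages use `base_width`, `2*base_width`, `4*base_width`
#'   channels. The default 64 yields the contractual 1536-dimensional
#'   per-channel feature (`4*64` channels x 3 x 2 pooled units).
#' @param blocks_per_stage residual blocks per stage (2 mirrors the first
#'   three stages of ResNet-18; 1 gives the scaled-down demonstration model).
#' @param lstm_hidden hidden size of each LSTM direction; the pooled feature
#'   dimension is `2 * lstm_hidden`.
#' @param attention_hidden hidden size of the attention scorer.
#' @param head_hidden hidden layer size of both MLP heads.
#' @param w_pos positive-class weight in the label loss.
#' @param dropout_p dropout probability in the label head.
#' @param pooling `"attention"` or `"mean"` (ablation).
#' @param grl_lambda constant gradient-reversal coefficient (used when
#'   `lambda_mode = "constant"`; `lambda_mode = "schedule"` ramps
#'   `2/(1+exp(-10 p)) - 1` over training progress `p`).
#' @param lambda_mode `"schedule"` or `"constant"`.
#' @return a `model_config` list (includes derived `cnn_out_dim` and
#'   `pooled_dim`).
#' @export
model_config <- function(n_domains = 0L,
                         base_width = 64L,
                         blocks_per_stage = 2L,
                         lstm_hidden = 256L,
                         attention_hidden = 128L,
                         head_hidden = 128L,
                         w_pos = 2.5,
                         dropout_p = 0.3,
                         pooling = c("attention", "mean"),
                         grl_lambda = 1.0,
                         lambda_mode = c("schedule", "constant")) {
  pooling <- match.arg(pooling)
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(base_width >= 1, blocks_per_stage >= 1, lstm_hidden >= 1,
            w_pos > 0, dropout_p >= 0, dropout_p < 1, grl_lambda >= 0)
  structure(
    list(
      n_channels = 18L,
      n_freq = 33L,
      n_frames = 17L,
      n_domains = as.integer(n_domains),
      base_width = as.integer(base_width),
      blocks_per_stage = as.integer(blocks_per_stage),
      cnn_out_dim = as.integer(4 * base_width * 6), # pooled to 3 x 2
      lstm_hidden = as.integer(lstm_hidden),
      pooled_dim = as.integer(2 * lstm_hidden),
      attention_hidden = as.integer(attention_hidden),
      head_hidden = as.integer(head_hidden),
      w_pos = w_pos,
      dropout_p = dropout_p,
      pooling = pooling,
      grl_lambda = grl_lambda,
      lambda_mode = lambda_mode
    ),
    class = "model_config"
  )
}

## ---- parameter initialization --------------------------------------------

init_res_block <- function(cin, cout, stride) {
  bl <- list(
    conv1 = init_conv(3, 3, cin, cout, stride = stride, pad = 1L),
    bn1 = init_bn(cout),
    conv2 = init_conv(3, 3, cout, cout, stride = 1L, pad = 1L),
    bn2 = init_bn(cout)
  )
  if (stride != 1 || cin != cout) {
    bl$down_conv <- init_conv(1, 1, cin, cout, stride = stride, pad = 0L)
    bl$down_bn <- init_bn(cout)
  }
  bl
}

#' Initialize model parameters
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the parameter draw.
#' @return nested list of parameter arrays.
#' @export
init_model <- function(cfg, seed = 1L) {
  with_seed(seed, {
    w <- cfg$base_width
    widths <- c(w, 2L * w, 4L * w)
    strides <- c(1L, 2L, 2L)
    params <- list(
      stem_conv = init_conv(7, 7, 1, w, stride = 2L, pad = 3L),
      stem_bn = init_bn(w),
      stages = lapply(1:3, function(s) {
        cin <- if (s == 1) w else widths[s - 1]
        lapply(seq_len(cfg$blocks_per_stage), function(b) {
          init_res_block(if (b == 1) cin else widths[s], widths[s],
                         if (b == 1) strides[s] else 1L)
        })
      }),
      bilstm = list(fwd = init_lstm(cfg$cnn_out_dim, cfg$lstm_hidden),
                    bwd = init_lstm(cfg$cnn_out_dim, cfg$lstm_hidden)),
      label_head = list(lin1 = init_linear(cfg$pooled_dim, cfg$head_hidden),
                        lin2 = init_linear(cfg$head_hidden, 2L))
    )
    if (cfg$pooling == "attention") {
      params$attention <- init_attention(cfg$pooled_dim, cfg$attention_hidden)
    }
    if (cfg$n_domains >= 2) {
      params$domain_head <- list(
        lin1 = init_linear(cfg$pooled_dim, cfg$head_hidden),
        lin2 = init_linear(cfg$head_hidden, cfg$n_domains)
      )
    }
    params
  })
}

## ---- channel folding ------------------------------------------------------

#' Fold the 18 electrode channels into the batch dimension
#'
#' Reshapes an `N x 18 x F x T` spectrogram tensor into `(N*18) x 1 x F x T`,
#' where folded row `n*18 + c` (0-based) is channel `c` of sample `n`.
#'
#' @param x an `N x 18 x F x T` array (or a `spectrogram_batch`).
#' @return a `(N*18) x 1 x F x T` array.
#' @export
fold_channels <- function(x) {
  if (inherits(x, "spectrogram_batch")) x <- x$tensor
  d <- dim(x)
  if (length(d) != 4 || d[2] != 18) {
    stop_eegdann("expected an N x 18 x F x T tensor", "eegdann_shape_error")
  }
  array(aperm(x, c(2, 1, 3, 4)), dim = c(d[1] * d[2], 1, d[3], d[4]))
}

#' Invert [fold_channels()]
#' @param folded a `(N*18) x 1 x F x T` array.
#' @param n_channels channel count (18).
#' @return an `N x n_channels x F x T` array.
#' @export
unfold_channels <- function(folded, n_channels = 18L) {
  d <- dim(folded)
  if (length(d) != 4 || d[2] != 1 || d[1] %% n_channels != 0) {
    stop_eegdann("expected a (N*18) x 1 x F x T folded tensor",
                 "eegdann_shape_error")
  }
  n <- d[1] / n_channels
  aperm(array(folded, dim = c(n_channels, n, d[3], d[4])), c(2, 1, 3, 4))
}

## ---- encoder forward/backward ---------------------------------------------

res_block_fwd <- function(x, bl, training) {
  caches <- list()
  c1 <- conv_fwd(x, bl$conv1, bl$conv1$stride, bl$conv1$pad)
  b1 <- bn_fwd(c1$out, bl$bn1, training)
  bl$bn1 <- b1$params
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, bl$conv2, bl$conv2$stride, bl$conv2$pad)
  b2 <- bn_fwd(c2$out, bl$bn2, training)
  bl$bn2 <- b2$params
  if (!is.null(bl$down_conv)) {
    dc <- conv_fwd(x, bl$down_conv, bl$down_conv$stride, bl$down_conv$pad)
    db <- bn_fwd(dc$out, bl$down_bn, training)
    bl$down_bn <- db$params
    short <- db$out
    caches$down <- list(conv = dc$cache, bn = db$cache)
  } else {
    short <- x
  }
  pre <- b2$out + short
  r2 <- relu_fwd(pre)
  caches$conv1 <- c1$cache; caches$bn1 <- b1$cache; caches$relu1 <- r1$cache
  caches$conv2 <- c2$cache; caches$bn2 <- b2$cache; caches$relu2 <- r2$cache
  list(out = r2$out, params = bl, cache = caches)
}

res_block_bwd <- function(dout, bl, cache) {
  g <- list()
  dpre <- relu_bwd(dout, cache$relu2)
  b2 <- bn_bwd(dpre, bl$bn2, cache$bn2)
  g$bn2 <- b2[c("gamma", "beta")]
  c2 <- conv_bwd(b2$dx, bl$conv2, cache$conv2)
  g$conv2 <- c2[c("W", "b")]
  dr1 <- relu_bwd(c2$dx, cache$relu1)
  b1 <- bn_bwd(dr1, bl$bn1, cache$bn1)
  g$bn1 <- b1[c("gamma", "beta")]
  c1 <- conv_bwd(b1$dx, bl$conv1, cache$conv1)
  g$conv1 <- c1[c("W", "b")]
  dx <- c1$dx
  if (!is.null(bl$down_conv)) {
    db <- bn_bwd(dpre, bl$down_bn, cache$down$bn)
    g$down_bn <- db[c("gamma", "beta")]
    dc <- conv_bwd(db$dx, bl$down_conv, cache$down$conv)
    g$down_conv <- dc[c("W", "b")]
    dx <- dx + dc$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = g)
}

encoder_fwd <- function(x_hwcb, params, training) {
  caches <- list()
  st <- conv_fwd(x_hwcb, params$stem_conv, params$stem_conv$stride,
                 params$stem_conv$pad)
  sb <- bn_fwd(st$out, params$stem_bn, training)
  params$stem_bn <- sb$params
  sr <- relu_fwd(sb$out)
  mp <- maxpool_fwd(sr$out, 3L, 2L, 1L)
  caches$stem <- list(conv = st$cache, bn = sb$cache, relu = sr$cache,
                      pool = mp$cache)
  h <- mp$out
  caches$stages <- vector("list", 3)
  for (s in 1:3) {
    caches$stages[[s]] <- vector("list", length(params$stages[[s]]))
    for (b in seq_along(params$stages[[s]])) {
      r <- res_block_fwd(h, params$stages[[s]][[b]], training)
      params$stages[[s]][[b]] <- r$params
      caches$stages[[s]][[b]] <- r$cache
      h <- r$out
    }
  }
  ap <- adaptive_avgpool_fwd(h, 3L, 2L)
  caches$apool <- ap$cache
  d <- dim(ap$out)
  caches$apool_odim <- d
  feat <- t(matrix(ap$out, d[1] * d[2] * d[3], d[4])) # (B, C*6)
  list(feat = feat, params = params, caches = caches,
       pooled_dim = d[1] * d[2] * d[3])
}

encoder_bwd <- function(dfeat, params, caches) {
  g <- list()
  dpool <- array(t(dfeat), dim = caches$apool_odim)
  dh <- adaptive_avgpool_bwd(dpool, caches$apool)
  g$stages <- vector("list", 3)
  for (s in 3:1) {
    g$stages[[s]] <- vector("list", length(params$stages[[s]]))
    for (b in rev(seq_along(params$stages[[s]]))) {
      r <- res_block_bwd(dh, params$stages[[s]][[b]], caches$stages[[s]][[b]])
      g$stages[[s]][[b]] <- r$grads
      dh <- r$dx
    }
  }
  dh <- maxpool_bwd(dh, caches$stem$pool)
  dh <- relu_bwd(dh, caches$stem$relu)
  bb <- bn_bwd(dh, params$stem_bn, caches$stem$bn)
  g$stem_bn <- bb[c("gamma", "beta")]
  # the stem is the first layer: its input gradient is never consumed
  cb <- conv_bwd(bb$dx, params$stem_conv, caches$stem$conv, need_dx = FALSE)
  g$stem_conv <- cb[c("W", "b")]
  g
}

## ---- spec-facing operations ----------------------------------------------

#' Encode folded single-channel spectrograms with the shared CNN
#'
#' @param folded a `(N*18) x 1 x F x T` array from [fold_channels()].
#' @param params model parameters from [init_model()].
#' @param cfg the [model_config()].
#' @param training batch-norm mode flag.
#' @return `N x 18 x cnn_out_dim` channel feature array.
#' @export
cicnn_encode <- function(folded, params, cfg, training = FALSE) {
  d <- dim(folded)
  x_chwb <- aperm(folded, c(2, 3, 4, 1)) # (1, F, T, N*18)
  enc <- encoder_fwd(x_chwb, params, training)
  n <- d[1] / cfg$n_channels
  aperm(array(enc$feat, dim = c(cfg$n_channels, n, ncol(enc$feat))),
        c(2, 1, 3))
}

#' Scan channel features with the spatial bidirectional LSTM
#'
#' @param cf `N x 18 x cnn_out_dim` channel features.
#' @param params model parameters.
#' @return `N x 18 x pooled_dim` spatial features (forward and backward
#'   hidden states concatenated per electrode).
#' @export
spatial_bilstm <- function(cf, params) {
  if (dim(cf)[2] != 18) {
    stop_eegdann("spatial Bi-LSTM expects sequence length 18",
                 "eegdann_shape_error")
  }
  bilstm_fwd(cf, params$bilstm)$out
}

#' Attention pooling over the 18 channels
#'
#' Scores `e = v' tanh(W h + b)`, softmax-normalized weights, weighted sum.
#'
#' @param sf `N x 18 x pooled_dim` spatial features.
#' @param params model parameters (must contain `$attention`).
#' @return list with `z` (`N x pooled_dim`) and `attention` (`N x 18`,
#'   rows non-negative, summing to 1).
#' @export
attention_pool <- function(sf, params) {
  at <- attention_fwd(sf, params$attention)
  list(z = at$out, attention = at$alpha)
}

#' Gradient reversal layer (forward pass)
#'
#' Identity in the forward pass. During backpropagation the gradient through
#' this operation is multiplied by `-lambda` (see [grl_backward()]); the
#' model's backward pass applies exactly that factor to the domain-branch
#' gradient entering the shared backbone.
#'
#' @param x input array.
#' @param lambda non-negative reversal coefficient (unused in forward).
#' @return `x`, unchanged.
#' @export
grad_reverse <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  x
}

#' Gradient reversal layer (backward pass)
#' @param grad upstream gradient.
#' @param lambda non-negative reversal coefficient.
#' @return `-lambda * grad`.
#' @export
grl_backward <- function(grad, lambda) {
  stopifnot(lambda >= 0)
  -lambda * grad
}

#' Seizure probability head
#'
#' MLP `pooled_dim -> head_hidden -> 2` with ReLU and dropout; the seizure
#' probability is the softmax mass of the positive logit.
#'
#' @param z `N x pooled_dim` pooled features.
#' @param params model parameters.
#' @param cfg the [model_config()].
#' @param training dropout mode flag.
#' @return vector of `N` seizure probabilities.
#' @export
predict_label <- function(z, params, cfg, training = FALSE) {
  head_fwd_label(z, params$label_head, cfg, training)$probs[, 2]
}

#' Domain (subject identity) classification head
#'
#' The gradient reversal layer sits at this branch's input: forward identity,
#' backward `-lambda`.
#'
#' @param z `N x pooled_dim` pooled features.
#' @param lambda reversal coefficient.
#' @param params model parameters (must contain `$domain_head`).
#' @param cfg the [model_config()].
#' @return `N x n_domains` logit matrix.
#' @export
classify_domain <- function(z, lambda, params, cfg) {
  if (cfg$n_domains < 2 || is.null(params$domain_head)) {
    stop_eegdann("domain classification requires n_domains >= 2",
                 "eegdann_config_error")
  }
  zr <- grad_reverse(z, lambda)
  head_fwd_domain(zr, params$domain_head)$logits
}

head_fwd_label <- function(z, hp, cfg, training) {
  l1 <- linear_fwd(z, hp$lin1)
  r1 <- relu_fwd(l1$out)
  dr <- dropout_fwd(r1$out, cfg$dropout_p, training)
  l2 <- linear_fwd(dr$out, hp$lin2)
  probs <- softmax_rows(l2$out)
  list(logits = l2$out, probs = probs,
       cache = list(l1 = l1$cache, r1 = r1$cache, dr = dr$cache,
                    l2 = l2$cache))
}

head_bwd_label <- function(dlogits, hp, cache) {
  l2 <- linear_bwd(dlogits, hp$lin2, cache$l2)
  dd <- dropout_bwd(l2$dx, cache$dr)
  dr <- relu_bwd(dd, cache$r1)
  l1 <- linear_bwd(dr, hp$lin1, cache$l1)
  list(dx = l1$dx, lin1 = l1[c("W", "b")], lin2 = l2[c("W", "b")])
}

head_fwd_domain <- function(z, hp) {
  l1 <- linear_fwd(z, hp$lin1)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, hp$lin2)
  list(logits = l2$out,
       cache = list(l1 = l1$cache, r1 = r1$cache, l2 = l2$cache))
}

head_bwd_domain <- function(dlogits, hp, cache) {
  l2 <- linear_bwd(dlogits, hp$lin2, cache$l2)
  dr <- relu_bwd(l2$dx, cache$r1)
  l1 <- linear_bwd(dr, hp$lin1, cache$l1)
  list(dx = l1$dx, lin1 = l1[c("W", "b")], lin2 = l2[c("W", "b")])
}

## ---- losses ----------------------------------------------------------------

#' Weighted binary cross-entropy on seizure probabilities
#'
#' `L = -sum_i [ w_pos * y_i * ln(p_i) + (1 - y_i) * ln(1 - p_i) ]`, with
#' probabilities clamped at `1e-7`. The default reduction is the batch mean
#' (the sum form is recovered with `reduction = "sum"`).
#'
#' @param probs vector of seizure probabilities.
#' @param labels 0/1 vector.
#' @param w_pos positive-class weight.
#' @param reduction `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
weighted_ce_loss <- function(probs, labels, w_pos = 2.5,
                             reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (length(probs) == 0) {
    stop_eegdann("empty batch in loss", "eegdann_validation_error")
  }
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  terms <- -(w_pos * labels * log(p) + (1 - labels) * log(1 - p))
  if (reduction == "mean") mean(terms) else sum(terms)
}

softmax_ce_grad <- function(probs, onehot, weights = NULL) {
  n <- nrow(probs)
  g <- probs - onehot
  if (!is.null(weights)) g <- g * weights
  g / n
}

## ---- full network forward/backward ----------------------------------------

#' Full forward pass of the network
#'
#' @param params parameters from [init_model()].
#' @param cfg the [model_config()].
#' @param x `N x 18 x 33 x 17` tensor or `spectrogram_batch`.
#' @param training training-mode flag (batch-norm statistics, dropout).
#' @param lambda gradient-reversal coefficient recorded for the backward
#'   pass.
#' @param keep_cache retain layer caches for [model_backward()].
#' @return a `model_outputs` list: `seizure_prob`, `label_probs`,
#'   `domain_logits` (or NULL), `attention` (or NULL), `pooled`, `params`
#'   (with updated batch-norm state), and `cache` when requested.
#' @export
model_forward <- function(params, cfg, x, training = FALSE, lambda = 0,
                          keep_cache = FALSE) {
  if (inherits(x, "spectrogram_batch")) x <- x$tensor
  d <- dim(x)
  if (length(d) != 4 || d[2] != cfg$n_channels) {
    stop_eegdann("expected an N x 18 x F x T input tensor",
                 "eegdann_shape_error")
  }
  n <- d[1]
  x_chwb <- array(aperm(x, c(3, 4, 2, 1)),
                  dim = c(1, d[3], d[4], n * cfg$n_channels))
  enc <- encoder_fwd(x_chwb, params, training)
  params <- enc$params
  cf <- aperm(array(enc$feat, dim = c(cfg$n_channels, n, ncol(enc$feat))),
              c(2, 1, 3))
  bl <- bilstm_fwd(cf, params$bilstm)
  alpha <- NULL
  if (cfg$pooling == "attention") {
    pool <- attention_fwd(bl$out, params$attention)
    alpha <- pool$alpha
  } else {
    pool <- mean_pool_fwd(bl$out)
  }
  z <- pool$out
  lh <- head_fwd_label(z, params$label_head, cfg, training)
  dh <- NULL
  if (cfg$n_domains >= 2 && !is.null(params$domain_head)) {
    dh <- head_fwd_domain(grad_reverse(z, lambda), params$domain_head)
  }
  out <- list(
    seizure_prob = lh$probs[, 2],
    label_probs = lh$probs,
    domain_logits = if (!is.null(dh)) dh$logits else NULL,
    domain_probs = if (!is.null(dh)) softmax_rows(dh$logits) else NULL,
    attention = alpha,
    pooled = z,
    params = params
  )
  if (keep_cache) {
    out$cache <- list(enc = enc$caches, bilstm = bl$cache, pool = pool$cache,
                      label = lh$cache, domain = if (!is.null(dh)) dh$cache,
                      n = n, lambda = lambda)
  }
  class(out) <- "model_outputs"
  out
}

#' Backward pass: gradients of the combined loss
#'
#' Label loss: weighted 2-class cross-entropy (batch mean). Domain loss:
#' cross-entropy over training-subject identities (batch mean), weighted by
#' `domain_loss_weight`; its gradient enters the shared backbone through the
#' gradient reversal layer, i.e. multiplied by `-lambda`. Domain-head
#' parameters receive the un-reversed gradient (the head minimizes its loss).
#'
#' @param params model parameters.
#' @param cfg the [model_config()].
#' @param fwd output of [model_forward()] with `keep_cache = TRUE`.
#' @param labels 0/1 window labels.
#' @param domains integer domain indices in `1..n_domains` (or NULL).
#' @param domain_loss_weight scalar weight on the domain loss.
#' @return list with `grads` (mirroring `params`), `loss_label`,
#'   `loss_domain`.
#' @export
model_backward <- function(params, cfg, fwd, labels, domains = NULL,
                           domain_loss_weight = 1.0) {
  cache <- fwd$cache
  if (is.null(cache)) {
    stop_eegdann("model_forward must be called with keep_cache = TRUE",
                 "eegdann_validation_error")
  }
  n <- cache$n
  lambda <- cache$lambda
  grads <- list()
  # label branch
  onehot <- cbind(1 - labels, labels)
  wvec <- ifelse(labels == 1, cfg$w_pos, 1)
  dlogits_y <- softmax_ce_grad(fwd$label_probs, onehot, wvec)
  hb <- head_bwd_label(dlogits_y, params$label_head, cache$label)
  grads$label_head <- hb[c("lin1", "lin2")]
  dz <- hb$dx
  p1 <- pmin(pmax(fwd$seizure_prob, 1e-7), 1 - 1e-7)
  loss_label <- mean(wvec * ifelse(labels == 1, -log(p1), -log(1 - p1)))
  # domain branch through the GRL
  loss_domain <- NA_real_
  if (!is.null(fwd$domain_logits) && !is.null(domains)) {
    donehot <- matrix(0, n, cfg$n_domains)
    donehot[cbind(seq_len(n), domains)] <- 1
    dprobs <- fwd$domain_probs
    loss_domain <- -mean(log(pmax(dprobs[cbind(seq_len(n), domains)], 1e-12)))
    dlogits_d <- softmax_ce_grad(dprobs, donehot) * domain_loss_weight
    db <- head_bwd_domain(dlogits_d, params$domain_head, cache$domain)
    grads$domain_head <- db[c("lin1", "lin2")]
    dz <- dz + grl_backward(db$dx, lambda)
  }
  # pooling
  if (cfg$pooling == "attention") {
    ab <- attention_bwd(dz, params$attention, cache$pool)
    grads$attention <- ab[c("W", "b", "v")]
    dhs <- ab$dx
  } else {
    dhs <- mean_pool_bwd(dz, cache$pool)
  }
  # Bi-LSTM
  bb <- bilstm_bwd(dhs, params$bilstm, cache$bilstm)
  grads$bilstm <- bb[c("fwd", "bwd")]
  # unfold (N, 18, D) -> (B = N*18, D) feature gradient
  dcf <- bb$dx
  dfeat <- matrix(aperm(dcf, c(2, 1, 3)), n * cfg$n_channels, dim(dcf)[3])
  eg <- encoder_bwd(dfeat, params, cache$enc)
  grads$stem_conv <- eg$stem_conv
  grads$stem_bn <- eg$stem_bn
  grads$stages <- eg$stages
  list(grads = grads, loss_label = loss_label, loss_domain = loss_domain)
}
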