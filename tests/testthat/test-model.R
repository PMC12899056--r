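test_that("fold/unfold is an exact round trip with the contracted layout", {
  set.seed(3)
  x <- array(rnorm(3 * 18 * 33 * 17), dim = c(3, 18, 33, 17))
  folded <- fold_channels(x)
  expect_equal(dim(folded), c(54, 1, 33, 17))
  expect_equal(unfold_channels(folded), x)
  # row n*18 + c (0-based): element (n = 2, c = 5) lands at folded row 41
  expect_equal(folded[41 + 1, 1, , ], x[2 + 1, 5 + 1, , ])
  # single sample gives leading dimension 18
  expect_equal(dim(fold_channels(x[1, , , , drop = FALSE]))[1], 18)
  expect_error(fold_channels(array(0, c(2, 5, 33, 17))),
               class = "eegdann_shape_error")
})

test_that("channel-independent encoder shares weights and outputs 1536 dims", {
  cfg <- model_config(base_width = 64, blocks_per_stage = 2)
  expect_equal(cfg$cnn_out_dim, 1536L)
  params <- init_model(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(1 * 18 * 33 * 17), dim = c(1, 18, 33, 17))
  # put the same spectrogram at two different channel positions
  x[1, 7, , ] <- x[1, 2, , ]
  cf <- cicnn_encode(fold_channels(x), params, cfg)
  expect_equal(dim(cf), c(1, 18, 1536))
  expect_equal(cf[1, 7, ], cf[1, 2, ], tolerance = 1e-12)
})

test_that("encoder output is independent of batch composition", {
  cfg <- micro_model_config()
  params <- init_model(cfg, seed = 8)
  set.seed(9)
  x2 <- array(rnorm(2 * 18 * 33 * 17), dim = c(2, 18, 33, 17))
  cf2 <- cicnn_encode(fold_channels(x2), params, cfg)
  cf1 <- cicnn_encode(fold_channels(x2[1, , , , drop = FALSE]), params, cfg)
  expect_equal(cf2[1, , ], cf1[1, , ], tolerance = 1e-10)
})

test_that("spatial Bi-LSTM contract: shape, order sensitivity, recurrence", {
  cfg <- micro_model_config()
  params <- init_model(cfg, seed = 2)
  set.seed(3)
  cf <- array(rnorm(2 * 18 * cfg$cnn_out_dim),
              dim = c(2, 18, cfg$cnn_out_dim))
  sf <- spatial_bilstm(cf, params)
  expect_equal(dim(sf), c(2, 18, cfg$pooled_dim))
  # reversing the channel order changes the output
  sf_rev <- spatial_bilstm(cf[, 18:1, , drop = FALSE], params)
  expect_gt(max(abs(sf_rev - sf)), 1e-3)
  expect_error(spatial_bilstm(cf[, 1:5, , drop = FALSE], params),
               class = "eegdann_shape_error")
})

test_that("LSTM forward matches a hand-unrolled recurrence", {
  set.seed(11)
  p <- eegdann:::init_lstm(3, 2)
  x <- array(rnorm(1 * 3 * 3), dim = c(1, 3, 3)) # B=1, T=3, D=3
  out <- eegdann:::lstm_fwd(x, p)$out
  sig <- function(v) 1 / (1 + exp(-v))
  h <- matrix(0, 1, 2); cc <- matrix(0, 1, 2)
  for (t in 1:3) {
    g <- matrix(x[, t, ], 1) %*% p$Wx + h %*% p$Wh + matrix(p$b, 1)
    i <- sig(g[, 1:2]); f <- sig(g[, 3:4])
    gg <- tanh(g[, 5:6]); o <- sig(g[, 7:8])
    cc <- f * cc + i * gg
    h <- o * tanh(cc)
    expect_equal(as.vector(out[1, t, ]), as.vector(h), tolerance = 1e-12)
  }
  # zeroed forward-direction weights: forward half of the Bi-LSTM output is
  # the zero-input trajectory o*tanh(c) driven by biases alone
  p0 <- p
  p0$Wx[] <- 0; p0$Wh[] <- 0
  out0 <- eegdann:::lstm_fwd(x, p0)$out
  h <- matrix(0, 1, 2); cc <- matrix(0, 1, 2)
  for (t in 1:3) {
    g <- matrix(p0$b, 1)
    cc <- sig(g[, 3:4]) * cc + sig(g[, 1:2]) * tanh(g[, 5:6])
    h <- sig(g[, 7:8]) * tanh(cc)
    expect_equal(as.vector(out0[1, t, ]), as.vector(h), tolerance = 1e-12)
  }
})

test_that("attention pooling implements the gated softmax weighting", {
  cfg <- micro_model_config()
  params <- init_model(cfg, seed = 4)
  # identical electrode vectors -> uniform weights, z = the common vector
  common <- rnorm(cfg$pooled_dim)
  sf <- array(rep(common, each = 2 * 18), dim = c(2, 18, cfg$pooled_dim))
  pool <- attention_pool(sf, params)
  expect_equal(pool$attention, matrix(1 / 18, 2, 18), tolerance = 1e-12)
  expect_equal(pool$z[1, ], common, tolerance = 1e-12)
  # normalization on random input
  set.seed(5)
  sf <- array(rnorm(3 * 18 * cfg$pooled_dim), dim = c(3, 18, cfg$pooled_dim))
  pool <- attention_pool(sf, params)
  expect_equal(rowSums(pool$attention), rep(1, 3), tolerance = 1e-6)
  expect_true(all(pool$attention >= 0))
})

test_that("attention pooling matches manual arithmetic on a tiny example", {
  # 1 sample, 2 channels, 3 feature dims, hand-set parameters
  h1 <- c(0.5, -1.0, 2.0)
  h2 <- c(1.5, 0.25, -0.5)
  W <- matrix(c(0.1, -0.2, 0.3,
                0.4, 0.0, -0.1), nrow = 3) # 3 x 2
  b <- c(0.05, -0.15)
  v <- c(1.2, -0.7)
  e1 <- sum(v * tanh(as.vector(t(W) %*% h1) + b))
  e2 <- sum(v * tanh(as.vector(t(W) %*% h2) + b))
  a <- exp(c(e1, e2)) / sum(exp(c(e1, e2)))
  z_manual <- a[1] * h1 + a[2] * h2
  hs <- array(0, dim = c(1, 2, 3))
  hs[1, 1, ] <- h1; hs[1, 2, ] <- h2
  pool <- eegdann:::attention_fwd(hs, list(W = W, b = b, v = v))
  expect_equal(as.vector(pool$alpha), a, tolerance = 1e-12)
  expect_equal(as.vector(pool$out), z_manual, tolerance = 1e-12)
})

test_that("gradient reversal: identity forward, -lambda backward", {
  set.seed(7)
  z <- matrix(rnorm(12), 3, 4)
  expect_identical(grad_reverse(z, 0.5), z)
  # linear probe: d(sum(grl(z)))/dz = -lambda * 1
  expect_equal(grl_backward(matrix(1, 3, 4), 1), matrix(-1, 3, 4))
  expect_equal(grl_backward(2 * z, 0.37), -0.37 * 2 * z)
})

test_that("GRL contract holds through the full network (finite differences)", {
  cfg <- micro_model_config(n_domains = 3)
  params <- init_model(cfg, seed = 13)
  set.seed(14)
  x <- array(rnorm(2 * 18 * 33 * 17), dim = c(2, 18, 33, 17))
  labels <- c(1, 0)
  domains <- c(1, 3)
  lambda <- 0.37
  fwd <- model_forward(params, cfg, x, training = TRUE, lambda = lambda,
                       keep_cache = TRUE)
  bwd <- model_backward(params, cfg, fwd, labels, domains)
  domain_loss <- function(P) {
    f <- model_forward(P, cfg, x, training = TRUE, lambda = lambda)
    -mean(log(f$domain_probs[cbind(1:2, domains)]))
  }
  label_loss <- function(P) {
    f <- model_forward(P, cfg, x, training = TRUE, lambda = lambda)
    p1 <- pmin(pmax(f$seizure_prob, 1e-7), 1 - 1e-7)
    w <- ifelse(labels == 1, cfg$w_pos, 1)
    mean(w * ifelse(labels == 1, -log(p1), -log(1 - p1)))
  }
  # probes after the max-pool are smooth; the stem probe crosses the pooling
  # argmax kink under finite perturbation, hence its looser tolerance
  probes <- list(
    list(path = list("stem_conv", "W"), idx = c(1, 2, 3, 2), tol = 1e-2),
    list(path = list("bilstm", "fwd", "Wx"), idx = c(4, 3), tol = 1e-5),
    list(path = list("attention", "v"), idx = 2, tol = 1e-5)
  )
  for (pr in probes) {
    g_num <- numeric_grad(params, pr$path, pr$idx, function(P) {
      label_loss(P) - lambda * domain_loss(P)
    })
    g_an <- get_grad_leaf(bwd$grads, pr$path, pr$idx)
    expect_equal(g_an, g_num, tolerance = pr$tol)
  }
  # head parameters are NOT reversed
  g_num_head <- numeric_grad(params, list("domain_head", "lin2", "W"),
                             c(2, 1), domain_loss)
  g_an_head <- get_grad_leaf(bwd$grads, list("domain_head", "lin2", "W"),
                             c(2, 1))
  expect_equal(g_an_head, g_num_head, tolerance = 1e-5)
  # lambda = 0 deactivates the backbone contribution of the domain loss
  fwd0 <- model_forward(params, cfg, x, training = TRUE, lambda = 0,
                        keep_cache = TRUE)
  bwd0 <- model_backward(params, cfg, fwd0, labels, domains)
  cfg_nd <- micro_model_config(n_domains = 0)
  params_nd <- params[setdiff(names(params), "domain_head")]
  fwd_nd <- model_forward(params_nd, cfg_nd, x, training = TRUE,
                          keep_cache = TRUE)
  bwd_nd <- model_backward(params_nd, cfg_nd, fwd_nd, labels)
  expect_equal(bwd0$grads$stem_conv$W, bwd_nd$grads$stem_conv$W,
               tolerance = 1e-12)
})

test_that("label head produces probabilities; zero weights give exactly 0.5", {
  cfg <- micro_model_config()
  params <- init_model(cfg, seed = 3)
  set.seed(4)
  z <- matrix(rnorm(5 * cfg$pooled_dim), 5)
  p1 <- predict_label(z, params, cfg, training = FALSE)
  p2 <- predict_label(z, params, cfg, training = FALSE)
  expect_identical(p1, p2) # eval mode deterministic
  expect_true(all(p1 >= 0 & p1 <= 1))
  params0 <- params
  params0$label_head$lin1$W[] <- 0
  params0$label_head$lin1$b[] <- 0
  params0$label_head$lin2$W[] <- 0
  params0$label_head$lin2$b[] <- 0
  expect_equal(predict_label(z, params0, cfg), rep(0.5, 5))
})

test_that("domain head contract: shape and configuration errors", {
  cfg <- micro_model_config(n_domains = 4)
  params <- init_model(cfg, seed = 3)
  z <- matrix(rnorm(3 * cfg$pooled_dim), 3)
  logits <- classify_domain(z, 0.5, params, cfg)
  expect_equal(dim(logits), c(3, 4))
  cfg1 <- micro_model_config(n_domains = 0)
  expect_error(classify_domain(z, 0.5, init_model(cfg1, 1), cfg1),
               class = "eegdann_config_error")
})

test_that("weighted cross-entropy matches its closed form", {
  # single sample, y = 1, p = 0.5, w = 2.5 -> 2.5 * ln 2
  expect_equal(weighted_ce_loss(0.5, 1, w_pos = 2.5), 2.5 * log(2))
  # w_pos = 1 equals unweighted cross-entropy
  set.seed(8)
  p <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  unweighted <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_ce_loss(p, y, w_pos = 1), unweighted)
  # sum reduction recovers the summed form
  expect_equal(weighted_ce_loss(p, y, 2.5, "sum"),
               20 * weighted_ce_loss(p, y, 2.5, "mean"))
  # perfect predictions give (clamped) near-zero loss
  expect_lt(weighted_ce_loss(ifelse(y == 1, 1, 0), y, 2.5), 1e-5)
  expect_error(weighted_ce_loss(numeric(0), integer(0)),
               class = "eegdann_validation_error")
})

test_that("full forward pass produces the exact shape chain", {
  cfg <- model_config(n_domains = 5, base_width = 64, blocks_per_stage = 2,
                      lstm_hidden = 256)
  params <- init_model(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(4 * 18 * 33 * 17), dim = c(4, 18, 33, 17))
  folded <- fold_channels(x)
  expect_equal(dim(folded), c(72, 1, 33, 17))
  fwd <- model_forward(params, cfg, x, training = FALSE, lambda = 0.3)
  expect_length(fwd$seizure_prob, 4)
  expect_true(all(is.finite(fwd$seizure_prob)))
  expect_equal(dim(fwd$domain_logits), c(4, 5))
  expect_true(all(is.finite(fwd$domain_logits)))
  expect_equal(dim(fwd$pooled), c(4, 512))
  expect_equal(dim(fwd$attention), c(4, 18))
  cf <- cicnn_encode(folded, params, cfg)
  expect_equal(dim(cf), c(4, 18, 1536))
  expect_equal(dim(spatial_bilstm(cf, params)), c(4, 18, 512))
})
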