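test_that("gru_step matches an independent elementwise recomputation", {
  set.seed(42)
  H <- 4; in_dim <- 3
  params <- list(W = matrix(rnorm(3 * H * in_dim), 3 * H, in_dim),
                 U = matrix(rnorm(3 * H * H), 3 * H, H),
                 b = rnorm(3 * H))
  for (i in 1:5) {
    x <- rnorm(in_dim)
    h <- rnorm(H)
    expect_equal(as.numeric(gru_step(x, h, params)),
                 gru_step_scalar(x, h, params), tolerance = 1e-10)
  }
  # gate limits: closed update gate keeps the previous state
  p0 <- params
  p0$b[1:H] <- -50  # z -> 0
  h <- rnorm(H)
  expect_equal(as.numeric(gru_step(rnorm(in_dim), h, p0)), h, tolerance = 1e-10)
  p1 <- params
  p1$b[1:H] <- 50                       # z -> 1
  p1$W[(2 * H + 1):(3 * H), ] <- 0      # zero candidate weights
  p1$U[(2 * H + 1):(3 * H), ] <- 0
  p1$b[(2 * H + 1):(3 * H)] <- 0
  expect_equal(as.numeric(gru_step(rnorm(in_dim), h, p1)), rep(0, H),
               tolerance = 1e-10)
  expect_error(gru_step(rnorm(2), h, params), "shape")
})

test_that("the compiled extractor equals the naive GRU composition", {
  set.seed(7)
  net <- drnn_config(n_layers = 3, hidden_size = 5, dilations = c(1, 2, 4),
                     feature_dim = 3)
  params <- lipdecode:::init_drnn_params(net, 1)
  X <- matrix(rnorm(11 * 4), 11, 4)
  expect_equal(dilated_forward(X, params, net$dilations)$features,
               naive_drnn_forward(X, params, net$dilations, 5),
               tolerance = 1e-8)
  # degenerate dilation: identical to a plain stacked GRU
  expect_equal(dilated_forward(X, params, c(1, 1, 1))$features,
               naive_drnn_forward(X, params, c(1, 1, 1), 5),
               tolerance = 1e-8)
  expect_error(dilated_forward(matrix(rnorm(3 * 2), 3, 2), params,
                               net$dilations), "shorter")
})

test_that("a dilated layer's final state sees only the skip positions", {
  set.seed(8)
  net <- drnn_config(n_layers = 1, hidden_size = 6, dilations = 2,
                     feature_dim = 2)
  params <- lipdecode:::init_drnn_params(net, 1)
  x <- rnorm(4)
  base <- dilated_forward(x, params, 2)$features
  # positions 1 and 3 (odd chain) do not feed the final state at t = 4
  x_mod <- x
  x_mod[c(1, 3)] <- rnorm(2) * 5
  expect_equal(dilated_forward(x_mod, params, 2)$features, base,
               tolerance = 1e-12)
  # positions 2 and 4 do
  x_mod2 <- x
  x_mod2[2] <- x[2] + 1
  expect_gt(max(abs(dilated_forward(x_mod2, params, 2)$features - base)), 1e-6)
})

test_that("dilation changes connectivity, not the parameter count", {
  cfg_dil <- drnn_config(4, 50, c(1, 2, 4, 8), 32)
  cfg_flat <- drnn_config(4, 50, c(1, 1, 1, 1), 32)
  expect_identical(drnn_n_params(cfg_dil), drnn_n_params(cfg_flat))
  set.seed(1)
  p <- lipdecode:::init_drnn_params(cfg_dil, 1)
  expect_identical(length(lipdecode:::flatten_params(p)),
                   as.integer(drnn_n_params(cfg_dil)))
})

test_that("prototype probabilities follow the distance softmax", {
  set.seed(5)
  M <- matrix(rnorm(12), 4, 3)
  p <- prototype_logits(M[3, ], M)
  expect_equal(which.max(p), 3L)
  expect_equal(colSums(p), 1)
  # equidistant prototypes tie
  M2 <- rbind(c(1, 0), c(-1, 0))
  p2 <- prototype_logits(c(0, 0.3), M2)
  expect_equal(p2[1], p2[2])
  # closed form for two prototypes at squared distances 0 and 1
  M3 <- rbind(c(0, 0), c(1, 0))
  p3 <- prototype_logits(c(0, 0), M3, gamma = 1)
  expect_equal(as.numeric(p3), c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  # invariance under a joint rigid rotation of features and prototypes
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  f <- rnorm(3)
  expect_equal(prototype_logits(as.numeric(Q %*% f), M %*% t(Q)),
               prototype_logits(f, M), tolerance = 1e-10)
  expect_error(prototype_logits(f, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("head losses have the stated structure and exact gradients", {
  set.seed(9)
  net <- drnn_config(n_layers = 2, hidden_size = 4, dilations = c(1, 2),
                     feature_dim = 3)
  params <- lipdecode:::init_drnn_params(net, 1)
  X <- matrix(rnorm(8 * 3), 8, 3)
  # a feature sitting on its own prototype with K = 1: zero loss
  cfg <- train_config(head = "prototype", lambda = 0.3)
  f <- dilated_forward(X[, 1], params, net$dilations)$features
  hd <- lipdecode:::proto_head(f, 1L, t(f), cfg$gamma, cfg$lambda)
  expect_equal(hd$loss, 0, tolerance = 1e-12)
  # lambda = 0 reduces to the distance-based cross-entropy alone
  M <- matrix(rnorm(6), 2, 3)
  fm <- matrix(rnorm(6), 3, 2)
  h0 <- lipdecode:::proto_head(fm, c(1L, 2L), M, 1, 0)
  d2 <- lipdecode:::sq_dists(fm, M)
  ce <- -mean(log(lipdecode:::softmax_cols(-d2)[cbind(1:2, 1:2)]))
  expect_equal(h0$loss, ce, tolerance = 1e-12)
  # finite-difference gradient check on every parameter, both heads
  y <- c(1L, 2L, 1L)
  for (head in c("prototype", "softmax")) {
    cfg <- train_config(head = head, gamma = 1.2, lambda = 0.05)
    p <- params
    p$head <- if (head == "prototype") list(M = matrix(rnorm(6), 2, 3))
              else list(W = matrix(rnorm(6), 2, 3), b = rnorm(2))
    lg <- lipdecode:::loss_and_grad(p, X, y, cfg, net)
    expect_gte(lg$loss, 0)
    th <- lipdecode:::flatten_params(p)
    g <- lipdecode:::flatten_params(lg$grad)
    num <- vapply(seq_along(th), function(i) {
      e <- 1e-6
      up <- th; up[i] <- th[i] + e
      dn <- th; dn[i] <- th[i] - e
      (lipdecode:::loss_and_grad(lipdecode:::unflatten_params(up, p), X, y,
                                 cfg, net, want_grad = FALSE)$loss -
       lipdecode:::loss_and_grad(lipdecode:::unflatten_params(dn, p), X, y,
                                 cfg, net, want_grad = FALSE)$loss) /
        (2 * e)
    }, 0)
    expect_lt(max(abs(g - num)), 1e-5)
  }
})

test_that("training separates three synthetic classes and is deterministic", {
  fit <- tiny_trained()
  n <- nrow(fit$curves)
  expect_equal(fit$curves$test_acc[n], 1)
  expect_lte(which(fit$curves$test_acc == 1)[1], 50)
  # loss decreases over the first epochs on separable data
  expect_lt(mean(fit$curves$loss[8:10]), mean(fit$curves$loss[1:3]))
  # same seed, same run
  fit2 <- train_lip_model(tiny_dataset(), tiny_config(epochs = 5), tiny_net())
  fit3 <- train_lip_model(tiny_dataset(), tiny_config(epochs = 5), tiny_net())
  expect_identical(fit2$curves, fit3$curves)
  expect_identical(fit2$params$head$M, fit3$params$head$M)
})

test_that("prediction is order-preserving and supports open-set rejection", {
  fit <- tiny_trained()
  ds <- tiny_dataset()
  tr_ix <- which(ds$manifest$split == "train")[1:6]
  pred <- predict(fit, ds$utterances[tr_ix])
  expect_equal(nrow(pred), 6)
  # an overfit model reproduces its own training labels, in order
  expect_identical(pred$label, ds$manifest$label[tr_ix])
  expect_true(all(pred$prob > 1 / 3))
  # pure noise lands far from every prototype and is rejected
  noise <- waveform(rnorm(1000, sd = 0.3), 1000)
  genuine_d <- pred$dist
  thr <- max(genuine_d) * 1.5
  pn <- predict(fit, noise, reject_threshold = thr)
  expect_true(pn$rejected)
  pg <- predict(fit, ds$utterances[[tr_ix[1]]], reject_threshold = thr)
  expect_false(pg$rejected)
  # untrained models refuse to predict
  broken <- fit
  broken$trained <- FALSE
  expect_error(predict(broken, noise), "trained")
})
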