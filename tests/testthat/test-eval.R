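test_that("confusion analysis summarizes a perfect classifier as identity", {
  fit <- tiny_trained()
  rep <- confusion_report(fit, tiny_dataset())
  expect_equal(unname(rep$confusion), diag(3))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$frac_100, 1)
  expect_equal(rep$frac_gt90, 1)
  expect_equal(rep$frac_gt80, 1)
})

test_that("confusion rows are exact count ratios summing to one", {
  # a deliberately under-trained model still yields a well-formed report
  weak <- train_lip_model(tiny_dataset(), tiny_config(epochs = 1), tiny_net())
  rep <- confusion_report(weak, tiny_dataset())
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 3))
  expect_gte(rep$accuracy, 0)
  expect_lte(rep$accuracy, 1)
  expect_equal(rep$accuracy, mean(diag(rep$confusion)))  # balanced test split
  expect_error(confusion_report(weak, tiny_dataset(), split = "nope"), "split")
})

test_that("confusable classes concentrate off-diagonal mass on each other", {
  ds <- make_dataset(n_classes = 4, n_per_class = 16,
                     templates = builtin_templates("fruits")[c(5, 6, 2, 8)],
                     base_seed = 21, similarity = 0.97)
  cfg <- tiny_config(epochs = 60)
  fit <- train_lip_model(ds, cfg, tiny_net())
  rep <- confusion_report(fit, ds, split = "train")
  off <- rep$confusion
  diag(off) <- 0
  # the blended pair's mutual confusion dominates every other error cell
  pair_max <- max(off[1, 2], off[2, 1])
  off[1, 2] <- off[2, 1] <- 0
  expect_gt(pair_max, max(off))
})

test_that("small-sample sweep reproduces the plain run at fraction one", {
  ds <- tiny_dataset()
  cfg <- tiny_config(epochs = 8)
  sw <- small_sample_sweep(ds, fractions = c(1, 0.5), config = cfg,
                           net = tiny_net(), heads = "prototype", seeds = 1)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$runs), 2)
  # fraction 1 equals a plain training run at the sweep's derived seed
  plain_cfg <- cfg
  plain_cfg$seed <- cfg$seed + 1L
  plain <- train_lip_model(ds, plain_cfg, tiny_net())
  expect_equal(sw$runs$accuracy[sw$runs$fraction == 1],
               plain$curves$test_acc[nrow(plain$curves)])
  # reproducible per seed
  sw2 <- small_sample_sweep(ds, fractions = c(1, 0.5), config = cfg,
                            net = tiny_net(), heads = "prototype", seeds = 1)
  expect_identical(sw$runs, sw2$runs)
  expect_error(small_sample_sweep(ds, fractions = c(0, 0.5), config = cfg),
               "fractions")
})

test_that("feature separability grows from near one to large after training", {
  ds <- tiny_dataset()
  net2 <- tiny_net(feature_dim = 2)
  # untrained extractor: build a model shell around random parameters
  cfg <- tiny_config()
  params <- local({
    set.seed(2)
    p <- lipdecode:::init_drnn_params(net2, 1)
    p$head <- list(M = matrix(rnorm(6), 3, 2))
    p
  })
  untrained <- structure(list(params = params, config = cfg, net = net2,
                              labels = ds$params$labels,
                              curves = data.frame(), trained = TRUE),
                         class = "lip_model")
  r0 <- feature_map_2d(untrained, ds)
  # class-blind null: permuting the labels drives the ratio to one
  feats0 <- t(as.matrix(r0$points[, c("f1", "f2")]))
  set.seed(3)
  perm <- sample(r0$points$label)
  null_ratio <- separability_ratio(feats0, perm)
  expect_gt(null_ratio, 0.9)
  expect_lt(null_ratio, 1.1)
  trained <- train_lip_model(ds, tiny_config(epochs = 40), net2)
  r1 <- feature_map_2d(trained, ds)
  expect_gt(r1$separability, 2)
  expect_gt(r1$separability, r0$separability)
  expect_named(r1$points, c("f1", "f2", "label"))
  # single class: separability undefined
  one <- ds
  keep <- which(one$manifest$label == one$params$labels[1])
  one$manifest <- one$manifest[keep, ]
  one$utterances <- one$utterances[keep]
  expect_warning(r <- feature_map_2d(trained, one), "single")
  expect_true(is.na(r$separability))
})

test_that("identity verification accepts the enrolled speaker only", {
  cmd <- builtin_templates("commands")
  host <- speaker_profile("host", speed_factor = 1, amplitude_jitter_cv = 0.05,
                          duration_jitter_cv = 0.03)
  guest <- speaker_profile("guest", speed_factor = 1.6,
                           initial_trough = TRUE, amplitude_jitter_cv = 0.05,
                           duration_jitter_cv = 0.03)
  host_utts <- lapply(1:8, function(i) {
    synth_word(cmd[["Go forwards"]], host, seed = 600 + i)
  })
  # the impostor's articulation of the passphrase follows their own,
  # structurally different template
  guest_utt <- synth_word(cmd[["Go backwards"]], guest, seed = 700)
  fit <- tiny_trained()
  pol <- enroll_speaker(fit, host_utts[1:6])
  genuine <- verify_identity(fit, pol, host_utts[[7]])
  impostor <- verify_identity(fit, pol, guest_utt)
  expect_true(genuine$accept)
  expect_false(impostor$accept)
  # monotone in tau: reject everything at 0, accept everything at Inf
  expect_false(verify_identity(fit, pol, host_utts[[8]], tau = 0)$accept)
  expect_true(verify_identity(fit, pol, guest_utt, tau = Inf)$accept)
  expect_error(enroll_speaker(fit, host_utts[1]), "two")
})

test_that("command words map bijectively onto action tokens", {
  expect_equal(command_map("Go forwards"), "FORWARD")
  expect_equal(command_map("Left"), "LEFT")
  for (w in c("Go forwards", "Go backwards", "Left", "Right")) {
    expect_identical(command_unmap(command_map(w)), w)
  }
  expect_error(command_map("Jump"), "unknown command")
  expect_error(command_unmap("FLY"), "unknown action")
})
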