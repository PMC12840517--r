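# Loss closed forms, architecture contracts, transfer semantics, training
# determinism and optimizer sanity.

tiny_sizes <- list(lstm_hidden = 8L, mlp_hidden = c(16L, 8L),
                   trunk = 8L, head_hidden = 6L)

test_that("variant grid matches the component table", {
  v <- variant_spec("PT-MLP.LSTM-eICU")
  expect_true(v$pretrain && v$separation)
  expect_equal(v$backbone, "dual")
  expect_equal(v$pretrain_pool, "combined")
  expect_false(variant_spec("MLP.LSTM")$pretrain)
  expect_equal(variant_spec("PT-LSTM-eICU")$backbone, "recurrent_only")
  expect_equal(variant_spec("PT-MLP-eICU")$backbone, "feedforward_only")
  expect_equal(variant_spec("PT-MLP.LSTM")$pretrain_pool, "primary_only")
  expect_equal(variant_spec("PT-MLP·LSTM")$name, "PT-MLP.LSTM")
  expect_error(variant_spec("GRU"), "unknown variant")
})

test_that("training config defaults follow the reference protocol", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-5)
  expect_equal(cfg$weight_decay, 1e-3)
  expect_equal(cfg$batch_size, 4096L)
  expect_equal(cfg$max_epochs, 300L)
  expect_equal(cfg$patience, 30L)
  expect_equal(cfg$seed, 42L)
})

test_that("multi-horizon loss matches closed forms and a naive oracle", {
  expect_equal(multi_horizon_loss(c(0, 0, 0), c(1, 0, 1)), log(2),
               tolerance = 1e-9)
  # hand-computed stable-BCE example
  expect_equal(multi_horizon_loss(c(2, -2, 0), c(1, 0, 1)),
               (0.126928011 + 0.126928011 + 0.693147181) / 3,
               tolerance = 1e-6)
  # saturated logit with matching label drives the loss to zero
  expect_lt(multi_horizon_loss(matrix(30, 1, 3), matrix(1, 1, 3)), 1e-9)
  # agreement with the probability-space oracle on random batches
  set.seed(7)
  for (i in 1:100) {
    z <- matrix(runif(30, -10, 10), 10, 3)
    y <- matrix(rbinom(30, 1, 0.5), 10, 3)
    expect_equal(multi_horizon_loss(z, y), oracle_bce(z, y),
                 tolerance = 1e-6)
  }
})

test_that("backbones accept the documented input layouts", {
  prep <- small_prep()
  ws <- modswarn:::subset_window_set(prep$mods$train, 1:5)
  for (nm in c("PT-MLP.LSTM-eICU", "PT-LSTM-eICU", "PT-MLP-eICU")) {
    spec <- variant_spec(nm)
    net <- build_pretrain_network(spec, tiny_sizes, seed = 1)
    inp <- modswarn:::net_inputs(ws, net$backbone)
    if (net$backbone == "feedforward_only") {
      expect_null(inp$steps)
      expect_equal(ncol(inp$ff), 41L)  # 34 static + 7 vitals at window end
    } else if (net$backbone == "recurrent_only") {
      expect_length(inp$steps, 4L)
      expect_equal(ncol(inp$steps[[1]]), 41L)  # vitals + repeated statics
      expect_equal(inp$steps[[1]][, 8], inp$steps[[4]][, 8])
    } else {
      expect_equal(ncol(inp$steps[[1]]), 7L)
      expect_equal(ncol(inp$ff), 34L)
    }
    p <- predict_risks(net, ws)
    expect_equal(dim(p), c(5L, 1L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("transfer copies every shared parameter and adds a 3-logit head", {
  spec <- variant_spec("PT-MLP.LSTM-eICU")
  pnet <- build_pretrain_network(spec, tiny_sizes, seed = 3)
  mnet <- transfer_to_mods_network(pnet, seed = 9)
  for (part in c("lstm", "mlp", "trunk"))
    expect_identical(mnet$params[[part]], pnet$params[[part]])
  expect_equal(ncol(mnet$params$head$out$W), 3L)
  # checksum of shared layers unchanged by transfer
  shared <- function(net) modswarn:::params_checksum(
    net$params[c("lstm", "mlp", "trunk")])
  expect_identical(shared(mnet), shared(pnet))
  # scratch model under a different seed has different shared weights
  scratch <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes,
                                seed = 4)
  expect_false(isTRUE(all.equal(shared(scratch), shared(pnet))))
  expect_error(transfer_to_mods_network(scratch), "mortality")
})

test_that("one optimizer step decreases the loss on a single sample", {
  prep <- small_prep()
  ws <- modswarn:::subset_window_set(prep$mods$train, 1)
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 5)
  inp <- modswarn:::net_inputs(ws, net$backbone)
  y <- ws$y
  fwd <- modswarn:::net_forward(net, inp, training = TRUE)
  net$bn <- fwd$bn_running
  loss0 <- multi_horizon_loss(fwd$logits, y)
  dlogits <- (modswarn:::sigmoid(fwd$logits) - y) / length(y)
  grads <- modswarn:::net_backward(net, fwd, dlogits)
  st <- modswarn:::adamw_step(net$params, grads, modswarn:::adamw_init(net$params),
                              lr = 1e-3, weight_decay = 0)
  net$params <- st$params
  fwd1 <- modswarn:::net_forward(net, inp, training = TRUE)
  expect_lt(multi_horizon_loss(fwd1$logits, y), loss0)
})

test_that("training is reproducible, bounded and early-stops", {
  prep <- small_prep()
  tr <- modswarn:::subset_window_set(prep$mods$train,
                                     seq_len(min(400, nrow(prep$mods$train$X_hf))))
  va <- modswarn:::subset_window_set(prep$mods$validation,
                                     seq_len(min(150, nrow(prep$mods$validation$X_hf))))
  cfg <- train_config(learning_rate = 1e-3, batch_size = 256,
                      max_epochs = 12, patience = 4, seed = 11)
  run <- function() {
    net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 2)
    train_network(net, tr, va, cfg)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(predict_risks(m1, va), predict_risks(m2, va))
  expect_lte(nrow(m1$history), cfg$max_epochs)
  # the retained checkpoint is at least as good (on validation) as every
  # epoch and as the initialization (the epoch-0 baseline)
  expect_gte(m1$best_val, max(m1$history$val_auc) - 1e-12)
  if (m1$best_epoch > 0)
    expect_equal(m1$best_val, m1$history$val_auc[m1$best_epoch])
  # a model with zero learning rate cannot improve: patience triggers
  cfg0 <- train_config(learning_rate = 1e-30, batch_size = 256,
                       max_epochs = 50, patience = 3, seed = 11)
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 2)
  m0 <- train_network(net, tr, va, cfg0)
  expect_lte(nrow(m0$history), 10L)
  # patient overlap between partitions is refused
  expect_error(train_network(net, tr, tr, cfg), "share patients")
})

test_that("predictions are batch-order invariant and duplicate-consistent", {
  prep <- small_prep()
  ws <- modswarn:::subset_window_set(prep$mods$test, 1:20)
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 6)
  p <- predict_risks(net, ws)
  perm <- rev(seq_len(20))
  p_perm <- predict_risks(net, modswarn:::subset_window_set(ws, perm))
  expect_equal(p_perm, p[perm, ], tolerance = 1e-12)
  dup <- predict_risks(net, modswarn:::subset_window_set(ws, c(1, 1)))
  expect_equal(dup[1, ], dup[2, ])
  # unpreprocessed input is rejected
  raw <- extract_windows(simulate_cohort(sim_config(n_stays = 2, seed = 1))$cohort)
  expect_error(predict_risks(net, raw), "missing values")
})
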