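# Shapley attribution contracts: additivity, linear exactness, symmetry,
# dummy features and determinism.

tiny_sizes <- list(lstm_hidden = 8L, mlp_hidden = c(16L, 8L),
                   trunk = 8L, head_hidden = 6L)

test_that("additivity holds exactly on model explanations", {
  prep <- small_prep()
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 3)
  bg <- modswarn:::subset_window_set(prep$mods$train, 1:40)
  for (i in 1:8) {
    e <- compute_attributions(net, bg, prep$mods$test, i = i, horizon = 12,
                              n_perm = 8, seed = i)
    expect_lt(abs(e$base_value + sum(e$records$phi) - e$f_x), 1e-3)
    expect_equal(nrow(e$records), 62L)  # one record per input component
  }
})

test_that("exact Shapley values are recovered for a linear model", {
  prep <- small_prep()
  # explained sample: component 1 (HR_1) = 2, component 29 (first static
  # feature) = 1, everything else 0; background identically zero
  template <- modswarn:::subset_window_set(prep$mods$test, 1)
  template$X_hf[] <- 0; template$X_lo[] <- 0
  template$X_hf[1, 1] <- 2
  template$X_lo[1, 1] <- 1
  bg <- modswarn:::subset_window_set(prep$mods$train, 1:5)
  bg$X_hf[] <- 0; bg$X_lo[] <- 0
  nh <- ncol(template$X_hf)
  f_lin <- function(Z) Z[, 1] + Z[, nh + 1]
  e <- compute_attributions(f_lin, bg, template, i = 1, n_perm = 10,
                            seed = 4)
  phi <- e$records$phi[match(c(colnames(template$X_hf),
                               colnames(template$X_lo)),
                             e$records$feature)]
  # for a linear model phi_j = x_j - E[b_j] exactly, any permutation count
  expect_equal(phi[1], 2, tolerance = 1e-12)
  expect_equal(phi[nh + 1], 1, tolerance = 1e-12)
  expect_equal(sum(abs(phi[-c(1, nh + 1)])), 0, tolerance = 1e-12)
  expect_equal(e$base_value, 0, tolerance = 1e-12)
  # symmetry: exchangeable inputs with equal values split equally
  template$X_hf[1, 1] <- 1
  e2 <- compute_attributions(f_lin, bg, template, i = 1, n_perm = 10,
                             seed = 4)
  p1 <- e2$records$phi[e2$records$feature == colnames(template$X_hf)[1]]
  p2 <- e2$records$phi[e2$records$feature == colnames(template$X_lo)[1]]
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a feature the model ignores receives zero attribution", {
  prep <- small_prep()
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 7)
  # sever every weight leaving the Lactate input of the static stream
  j <- match("Lactate", colnames(prep$mods$train$X_lo))
  net$params$mlp[[1]]$W[j, ] <- 0
  bg <- modswarn:::subset_window_set(prep$mods$train, 1:30)
  phis <- vapply(1:10, function(i) {
    e <- compute_attributions(net, bg, prep$mods$test, i = i, horizon = 6,
                              n_perm = 6, seed = i)
    e$records$phi[e$records$feature == "Lactate"]
  }, numeric(1))
  expect_lt(max(abs(phis)), 1e-9)
})

test_that("explanations are seed-deterministic", {
  prep <- small_prep()
  net <- build_mods_network(variant_spec("MLP.LSTM"), tiny_sizes, seed = 2)
  bg <- modswarn:::subset_window_set(prep$mods$train, 1:25)
  e1 <- compute_attributions(net, bg, prep$mods$test, i = 2, horizon = 24,
                             n_perm = 6, seed = 99)
  e2 <- compute_attributions(net, bg, prep$mods$test, i = 2, horizon = 24,
                             n_perm = 6, seed = 99)
  expect_identical(e1$records, e2$records)
  r1 <- case_report(e1, top_k = 5)
  r2 <- case_report(e2, top_k = 5)
  expect_identical(r1$text, r2$text)
})

test_that("importance ranking and hourly grid aggregate |phi| faithfully", {
  mk_expl <- function(phis) {
    feats <- c(paste0(rep(c("HR", "SBP"), each = 4), "_", 1:4), "Lactate")
    rec <- data.frame(feature = feats, value = 0, phi = phis)
    rec <- rec[order(-abs(rec$phi), rec$feature), ]
    structure(list(f_x = sum(phis), base_value = 0, horizon = 6,
                   records = rec), class = "case_explanation")
  }
  e1 <- mk_expl(c(0.1, -0.2, 0.3, 0, 0, 0, 0, 0, 0.5))
  e2 <- mk_expl(c(0.3, 0.2, -0.1, 0, 0, 0, 0, 0, 0.1))
  gi <- global_importance(list(e1, e2))
  expect_equal(gi$feature[1], "Lactate")
  expect_equal(gi$mean_abs_phi[gi$feature == "HR_1"], 0.2)
  # zero-attribution features rank last (ties alphabetical)
  expect_true(all(gi$mean_abs_phi[gi$feature %in%
                                    c("SBP_1", "SBP_2")] == 0))
  grid <- hourly_highfreq_summary(list(e1, e2))
  expect_equal(dim(grid), c(2L, 4L))
  expect_equal(grid["HR", "hour2"], 0.2)
  expect_equal(unname(grid["SBP", ]), rep(0, 4))
  # duplicated explanation set keeps the ranking
  expect_identical(global_importance(list(e1, e1))$feature[1], "Lactate")
})

test_that("case reports clamp top_k and mark risk direction", {
  rec <- data.frame(feature = c("A", "B"), value = c(1, 2),
                    phi = c(0.4, -0.3))
  e <- structure(list(f_x = 0.6, base_value = 0.5, horizon = 6,
                      records = rec), class = "case_explanation")
  r <- case_report(e, top_k = 10)
  expect_equal(nrow(r$top), 2L)
  expect_equal(r$top$direction, c("risk-increasing", "risk-decreasing"))
  expect_error(case_report(e, top_k = 0), "at least 1")
})
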