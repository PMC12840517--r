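# Discrimination, bootstrap, calibration, thresholds and learning curves.

test_that("AUC handles separation, ties and label flips", {
  expect_equal(compute_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(compute_auc(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(3)
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  expect_equal(compute_auc(s, y), 1 - compute_auc(s, 1 - y))
  expect_error(compute_auc(s, rep(1, 200)), "single class")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:20) {
    s <- round(runif(150), 2)  # rounding forces ties
    y <- rbinom(150, 1, 0.35)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("weighted AUC equals record duplication", {
  set.seed(8)
  s <- round(runif(60), 1); y <- rbinom(60, 1, 0.5)
  w <- sample(0:3, 60, replace = TRUE)
  keep <- rep(seq_along(s), w)
  expect_equal(compute_auc(s, y, w), compute_auc(s[keep], y[keep]),
               tolerance = 1e-12)
})

test_that("threshold metrics enumerate the confusion matrix", {
  s <- c(0.05, 0.15, 0.25, 0.35); y <- c(0, 0, 1, 1)
  m <- threshold_metrics(s, y, 0.20)
  expect_equal(unlist(m), c(acc = 1, tpr = 1, tnr = 1))
  m2 <- threshold_metrics(s, y, 0.30)
  expect_equal(m2$tpr, 0.5)
  expect_equal(m2$tnr, 1)
  expect_equal(threshold_metrics(c(0.1, 0.2), c(1, 0), 0.9)$tpr, 0)
  expect_error(threshold_metrics(s, c(1, 1, 1, 1), 0.5), "TNR undefined")
  expect_error(threshold_metrics(s, c(0, 0, 0, 0), 0.5), "TPR undefined")
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set.seed(5)
  s <- runif(400); y <- rbinom(400, 1, 0.3)
  res <- sapply(c(0.10, 0.20, 0.30), function(th) {
    m <- threshold_metrics(s, y, th)
    c(m$tpr, m$tnr)
  })
  expect_true(all(diff(res[1, ]) <= 0))
  expect_true(all(diff(res[2, ]) >= 0))
})

test_that("patient bootstrap equals explicit duplication resampling", {
  set.seed(12)
  n_pat <- 50
  pid <- rep(seq_len(n_pat), each = 4)
  s <- runif(length(pid)); y <- rbinom(length(pid), 1, 0.4)
  cfg <- bootstrap_config(B = 200, seed = 31)
  ci <- patient_bootstrap_ci(s, y, pid, "auc", cfg)
  # oracle: duplicate records by patient draw counts, same RNG stream
  oracle <- modswarn:::with_seed(cfg$seed, {
    vapply(seq_len(cfg$B), function(b) {
      draw <- sample.int(n_pat, n_pat, replace = TRUE)
      counts <- tabulate(draw, n_pat)
      idx <- rep(seq_along(pid), counts[pid])
      if (length(unique(y[idx])) < 2) return(NA_real_)
      compute_auc(s[idx], y[idx])
    }, numeric(1))
  })
  expect_equal(ci$values, oracle, tolerance = 1e-12)
  expect_true(ci$lo <= ci$point && ci$point <= ci$hi)
})

test_that("degenerate bootstrap cases behave", {
  pid <- rep(1:10, each = 2)
  y <- rep(c(1, 0), 10)
  s <- ifelse(y == 1, 0.9, 0.1)  # perfect separation
  ci <- patient_bootstrap_ci(s, y, pid, "auc", bootstrap_config(B = 100, seed = 2))
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  ci1 <- patient_bootstrap_ci(s, y, pid, "auc", bootstrap_config(B = 1, seed = 2))
  expect_equal(ci1$lo, ci1$hi)
})

test_that("calibration bins partition [0,1] and Brier has closed forms", {
  expect_equal(calibration_and_brier(c(0, 1, 1, 0), c(0, 1, 1, 0))$brier$point, 0)
  expect_equal(calibration_and_brier(rep(0.5, 8),
                                     rbinom(8, 1, 0.5))$brier$point, 0.25)
  expect_equal(calibration_and_brier(c(0.2, 0.8), c(0, 1))$brier$point, 0.04)
  cal <- calibration_and_brier(seq(0.01, 0.99, length.out = 50),
                               rbinom(50, 1, 0.5))
  expect_equal(nrow(cal$bins), 10L)
  expect_equal(sum(cal$bins$n), 50L)
  expect_equal(cal$bins$lower[1], 0)
  expect_equal(cal$bins$upper[10], 1)
  # constant-predictor decomposition: pi(1-p)^2 + (1-pi)p^2
  set.seed(9)
  y <- rbinom(2000, 1, 0.3)
  p <- 0.4
  expect_equal(calibration_and_brier(rep(p, 2000), y)$brier$point,
               mean(y) * (1 - p)^2 + (1 - mean(y)) * p^2, tolerance = 1e-12)
})

test_that("bootstrap intervals shrink with more patients", {
  width <- function(n_pat, seed) {
    set.seed(seed)
    pid <- rep(seq_len(n_pat), each = 3)
    mu <- rep(runif(n_pat), each = 3)
    y <- rbinom(length(pid), 1, 0.35)
    s <- plogis(qlogis(pmin(pmax(mu, 0.05), 0.95)) + y)
    ci <- patient_bootstrap_ci(s, y, pid, "auc",
                               bootstrap_config(B = 150, seed = seed))
    ci$hi - ci$lo
  }
  small <- mean(vapply(1:5, function(s) width(25, s), numeric(1)))
  big <- mean(vapply(1:5, function(s) width(200, s), numeric(1)))
  expect_lt(big, small)
})

test_that("learning curve uses nested seeded subsets on a fixed pool", {
  pool <- sprintf("S%03d", 1:350)
  seen <- new.env(); seen$sets <- list()
  fn <- function(ids, seed) {
    key <- paste0("s", seed)
    seen$sets[[key]] <- c(seen$sets[[key]], list(ids))
    length(ids) / 1000
  }
  lc <- learning_curve(fn, pool, increment = 100, seeds = c(1, 2))
  expect_equal(lc$n_train, c(100, 200, 300))
  expect_equal(lc$mean_auc, c(0.1, 0.2, 0.3))
  for (key in names(seen$sets)) {
    sets <- seen$sets[[key]]
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
  lc2 <- learning_curve(fn, pool, increment = 100, seeds = c(1, 2))
  expect_identical(lc$mean_auc, lc2$mean_auc)
  expect_error(learning_curve(fn, pool[1:50], increment = 100), "smaller")
})

test_that("metric and threshold reports have coherent intervals", {
  set.seed(77)
  n <- 300
  pid <- rep(sprintf("P%02d", 1:50), each = 6)
  y <- cbind(y6 = rbinom(n, 1, 0.2), y12 = rbinom(n, 1, 0.3))
  probs <- cbind(y6 = plogis(rnorm(n) + 2 * y[, 1]),
                 y12 = plogis(rnorm(n) + 2 * y[, 2]))
  rep_ <- metric_report(probs, y, pid, bootstrap_config(B = 60, seed = 5))
  expect_equal(nrow(rep_), 8L)
  expect_true(all(rep_$lo <= rep_$point + 1e-12))
  expect_true(all(rep_$point <= rep_$hi + 1e-12))
  expect_true(all(rep_$point >= 0 & rep_$point <= 1))
  th <- threshold_report(probs, y, pid, config = bootstrap_config(B = 40, seed = 6))
  expect_equal(nrow(th), 6L)
  for (h in unique(th$horizon)) {
    sub <- th[th$horizon == h, ]
    expect_true(all(diff(sub$sensitivity) <= 1e-12))
    expect_true(all(diff(sub$specificity) >= -1e-12))
  }
})
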