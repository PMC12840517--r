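# Evaluation times, window extraction semantics, labels and splits.

test_that("evaluation times run hourly from hour 4 to the last whole hour", {
  expect_equal(enumerate_eval_times(12), 4:12)
  expect_equal(enumerate_eval_times(4.5), 4L)
  expect_length(enumerate_eval_times(3), 0L)
  expect_equal(enumerate_eval_times(10, stride_h = 2), c(4L, 6L, 8L, 10L))
})

test_that("multi-horizon labels implement the interval rule", {
  # worked case: window (33, 39] catches onset at 37 on the 6-h horizon
  lab <- assign_mods_labels(33, 37)
  expect_equal(unlist(lab[, c("y6", "y12", "y24")]),
               c(y6 = 1L, y12 = 1L, y24 = 1L))
  expect_false(lab$excluded)
  # onset beyond 6 and 12 but within 24
  lab2 <- assign_mods_labels(20, 40)
  expect_equal(unlist(lab2[, c("y6", "y12", "y24")]),
               c(y6 = 0L, y12 = 0L, y24 = 1L))
  # MODS already present: excluded
  expect_true(assign_mods_labels(33, 30)$excluded)
  expect_true(assign_mods_labels(33, 33)$excluded)
  # no MODS in follow-up: all zero
  expect_equal(sum(assign_mods_labels(10, NA)[, 1:3]), 0L)
})

test_that("labels match a brute-force interval evaluation on random pairs", {
  brute <- function(t_k, tm, h) {
    if (is.na(tm)) return(0L)
    as.integer(t_k < tm && tm <= t_k + h)
  }
  set.seed(99)
  t_k <- sample(4:200, 1000, replace = TRUE)
  tm <- ifelse(runif(1000) < 0.2, NA, sample(1:230, 1000, replace = TRUE))
  lab <- assign_mods_labels(t_k, tm)
  for (i in which(!lab$excluded)) {
    expect_identical(lab$y6[i], brute(t_k[i], tm[i], 6))
    expect_identical(lab$y12[i], brute(t_k[i], tm[i], 12))
    expect_identical(lab$y24[i], brute(t_k[i], tm[i], 24))
  }
  # nesting holds everywhere, including excluded rows
  expect_true(all(lab$y6 <= lab$y12 & lab$y12 <= lab$y24))
  # exclusion exactly when onset is at or before the evaluation time
  expect_equal(lab$excluded, !is.na(tm) & tm <= t_k)
})

test_that("mortality label is death within 720 h of ICU admission", {
  expect_equal(assign_mortality_label(c(500, 800, NA, 720)), c(1L, 0L, 0L, 1L))
})

test_that("window boundaries are half-open left, closed right", {
  stays <- make_stay("A", icu_los_h = 40)
  ev <- make_events("A", c(29.0, 30.5, 33.0), "HR", c(60, 80, 100))
  ct <- cohort_table(stays, ev)
  ws <- extract_window(ct, "A", 33)
  hr <- unname(ws$X_hf[1, paste0("HR_", 1:4)])
  # 29.0 is exactly t_k - 4: excluded; 30.5 falls in bin 2; 33.0 in bin 4
  expect_true(is.na(hr[1]))
  expect_equal(hr[2], 80)
  expect_true(is.na(hr[3]))
  expect_equal(hr[4], 100)
})

test_that("two readings in one hour bin are averaged", {
  ct <- cohort_table(make_stay("A", icu_los_h = 12),
                     make_events("A", c(7.2, 7.9), "HR", c(80, 100)))
  ws <- extract_window(ct, "A", 8)
  expect_equal(unname(ws$X_hf[1, "HR_4"]), 90)
})

test_that("low-frequency vector takes the last value within lookback", {
  ev <- rbind(make_events("A", c(2, 20), "Creatinine", c(1.0, 3.0)),
              make_events("A", 1, "Lactate", 2.5),
              make_events("A", 5, "Norepinephrine", 0.2))
  ct <- cohort_table(make_stay("A", age = 61, gender = "female",
                               icu_los_h = 60), ev)
  ws <- extract_window(ct, "A", 28)
  expect_equal(unname(ws$X_lo[1, "Creatinine"]), 3.0)  # 8 h old: kept
  expect_true(is.na(ws$X_lo[1, "Lactate"]))            # 27 h old: stale
  expect_true(is.na(ws$X_lo[1, "Norepinephrine"]))     # dose lookback 4 h
  expect_equal(unname(ws$X_lo[1, "Age"]), 61)
  expect_equal(unname(ws$X_lo[1, "Gender"]), 0)        # male indicator
  # within lookback the same observations are visible
  ws2 <- extract_window(ct, "A", 24)
  expect_equal(unname(ws2$X_lo[1, "Lactate"]), 2.5)    # 23 h old: kept
})

test_that("patient-level split is disjoint, seeded and label-consistent", {
  sim <- simulate_cohort(sim_config(n_stays = 30, seed = 15))
  ds1 <- build_dataset(sim$cohort, task = "mods", seed = 7,
                       onsets = data.frame(stay_id = sim$truth$stay_id,
                                           t_mods_h = sim$truth$t_mods_true))
  ds2 <- build_dataset(sim$cohort, task = "mods", seed = 7,
                       onsets = data.frame(stay_id = sim$truth$stay_id,
                                           t_mods_h = sim$truth$t_mods_true))
  ids <- lapply(ds1, function(ws) unique(ws$meta$stay_id))
  expect_length(Reduce(intersect, ids), 0L)
  expect_identical(ds1$train$y, ds2$train$y)
  expect_identical(ds1$test$meta, ds2$test$meta)
  # exclusion rule: no sample with onset at or before its evaluation time
  for (part in ds1) {
    tm <- sim$truth$t_mods_true[match(part$meta$stay_id, sim$truth$stay_id)]
    expect_true(all(is.na(tm) | tm > part$meta$t_k))
    expect_true(all(part$y[, "y6"] <= part$y[, "y12"]))
    expect_true(all(part$y[, "y12"] <= part$y[, "y24"]))
  }
  tiny <- modswarn:::subset_cohort(sim$cohort,
                                   seq_len(nrow(sim$cohort$stays)) <= 2,
                                   "finetune_cohort")
  expect_error(build_dataset(tiny, task = "mortality"), "at least 3")
})

test_that("a stay with early onset contributes only pre-onset windows", {
  sim <- simulate_cohort(sim_config(n_stays = 6, seed = 21))
  onsets <- data.frame(stay_id = sim$truth$stay_id, t_mods_h = NA_integer_)
  onsets$t_mods_h[1] <- 5L
  ds <- build_dataset(sim$cohort, task = "mods", seed = 1, onsets = onsets)
  for (part in ds) {
    w <- part$meta[part$meta$stay_id == onsets$stay_id[1], ]
    if (nrow(w)) expect_true(all(w$t_k < 5))
  }
})

test_that("mortality task labels every window with the stay outcome", {
  sim <- simulate_cohort(sim_config(n_stays = 12, seed = 31))
  ds <- build_dataset(sim$cohort, task = "mortality", seed = 3)
  for (part in ds) {
    want <- assign_mortality_label(
      sim$cohort$stays$death_time_h[match(part$meta$stay_id,
                                          sim$cohort$stays$stay_id)])
    expect_equal(unname(part$y[, 1]), want)
  }
})
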