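# SOFA sub-scores, carry-forward timelines, MODS onset and sepsis.

test_that("sub-scores match the consensus cut-off table on a dense grid", {
  grids <- list(
    respiration = seq(40, 650, by = 7.3),
    coagulation = seq(1, 900, by = 4.7),
    liver = seq(0.1, 30, by = 0.13),
    cns = 3:15,
    renal = seq(0.1, 12, by = 0.07))
  for (organ in names(grids)) {
    got <- sofa_subscore(organ, grids[[organ]])
    want <- vapply(grids[[organ]], function(x) oracle_sofa(organ, x),
                   integer(1))
    expect_equal(got, want, info = organ)
  }
  # boundary values sit exactly on the published cut-offs
  expect_equal(sofa_subscore("coagulation", c(150, 100, 50, 20)),
               c(0L, 1L, 2L, 3L))
  expect_equal(sofa_subscore("liver", c(1.2, 2, 6, 12)), 1:4)
  expect_equal(sofa_subscore("renal", c(1.2, 2, 3.5, 5)), 1:4)
  expect_equal(sofa_subscore("respiration", c(400, 300, 200, 100)), 0:3)
})

test_that("worked clinical values score as reported", {
  expect_equal(sofa_subscore("coagulation", 141), 1L)
  expect_equal(sofa_subscore("liver", 12.2), 4L)
  expect_equal(sofa_subscore("cns", 15), 0L)
})

test_that("cardiovascular scoring follows the dose hierarchy", {
  expect_equal(sofa_subscore("cardiovascular", map = 80), 0L)
  expect_equal(sofa_subscore("cardiovascular", map = 65), 1L)
  expect_equal(sofa_subscore("cardiovascular", map = 65, dobutamine = 2), 2L)
  expect_equal(sofa_subscore("cardiovascular", dopamine = 4), 2L)
  expect_equal(sofa_subscore("cardiovascular", dopamine = 8), 3L)
  expect_equal(sofa_subscore("cardiovascular", norepinephrine = 0.05), 3L)
  expect_equal(sofa_subscore("cardiovascular", norepinephrine = 0.2), 4L)
  expect_equal(sofa_subscore("cardiovascular", dopamine = 20), 4L)
  # missing inputs: no evidence of dysfunction
  expect_equal(sofa_subscore("cardiovascular", map = NA), 0L)
})

test_that("monotone inputs give monotone sub-scores", {
  plt <- seq(300, 5, by = -2.5)
  expect_true(all(diff(sofa_subscore("coagulation", plt)) >= 0))
  bili <- seq(0.2, 20, by = 0.2)
  expect_true(all(diff(sofa_subscore("liver", bili)) >= 0))
})

test_that("out-of-domain inputs are rejected", {
  expect_error(sofa_subscore("cns", 20), "out-of-domain")
  expect_error(sofa_subscore("coagulation", -5), "out-of-domain")
})

test_that("carry-forward respects the lookback horizon", {
  stays <- make_stay("A", icu_los_h = 40)
  ev <- make_events("A", 2, "Platelet", 90)
  ct <- suppressWarnings(cohort_table(stays, ev))
  tl <- compute_sofa_timeline(ct, stay_id = "A")
  # platelet 90 at hour 2: coagulation 2 for hours 2..26 (24 h lookback)
  expect_equal(tl$coagulation[tl$hour %in% 2:26], rep(2L, 25))
  expect_equal(tl$coagulation[tl$hour %in% c(1, 27:40)], rep(0L, 15))
  expect_equal(tl$total, tl$respiration + tl$coagulation + tl$liver +
                 tl$cardiovascular + tl$cns + tl$renal)
})

test_that("no events yields an all-zero timeline", {
  ct <- cohort_table(make_stay("A", icu_los_h = 24), empty_events())
  tl <- compute_sofa_timeline(ct, stay_id = "A")
  expect_equal(nrow(tl), 24L)
  expect_true(all(tl$total == 0))
})

test_that("MODS onset is the first hour with two organs at 2+", {
  mk <- function(coag, renal) {
    data.frame(stay_id = "A", hour = seq_along(coag),
               respiration = 0L, coagulation = coag, liver = 0L,
               cardiovascular = 0L, cns = 0L, renal = renal,
               total = coag + renal)
  }
  expect_equal(detect_mods_onset(mk(c(1, 2, 2), c(1, 1, 2)))$t_mods_h, 3L)
  expect_true(is.na(detect_mods_onset(mk(c(1, 1, 1), c(1, 1, 1)))$t_mods_h))
  # a single failing organ is not MODS
  expect_true(is.na(detect_mods_onset(mk(c(4, 4, 4), c(0, 0, 0)))$t_mods_h))
})

test_that("MODS onset equals a brute-force scan on random timelines", {
  brute <- function(m) {
    for (h in seq_len(nrow(m))) if (sum(m[h, ] >= 2) >= 2) return(h)
    NA_integer_
  }
  set.seed(2024)
  for (rep in 1:1000) {
    H <- sample(3:30, 1)
    m <- matrix(sample(0:4, H * 6, replace = TRUE,
                       prob = c(0.6, 0.2, 0.1, 0.06, 0.04)), H, 6)
    tl <- data.frame(stay_id = "x", hour = 1:H,
                     respiration = m[, 1], coagulation = m[, 2],
                     liver = m[, 3], cardiovascular = m[, 4],
                     cns = m[, 5], renal = m[, 6], total = rowSums(m))
    expect_identical(detect_mods_onset(tl)$t_mods_h,
                     as.integer(brute(m)))
  }
})

test_that("sepsis requires suspicion plus an acute 2-point SOFA rise", {
  mk_total <- function(tot) {
    data.frame(stay_id = "A", hour = seq_along(tot),
               respiration = tot, coagulation = 0L, liver = 0L,
               cardiovascular = 0L, cns = 0L, renal = 0L, total = tot)
  }
  # baseline 1 before suspicion at 8; rise to 3 at hour 10 qualifies
  tot <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 3, 3, 3)
  res <- detect_sepsis(mk_total(tot), 8)
  expect_true(res$septic)
  expect_equal(res$onset_h, 10L)
  # no suspicion: never septic
  expect_false(detect_sepsis(mk_total(tot), NA)$septic)
  # chronically elevated but flat: no acute rise
  expect_false(detect_sepsis(mk_total(rep(5L, 30)), 10)$septic)
  # rise outside the 48h-before / 24h-after window does not qualify
  tot2 <- c(rep(0L, 80), rep(3L, 10))
  expect_false(detect_sepsis(mk_total(tot2), 10)$septic)
})
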