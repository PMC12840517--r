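# Synthetic ICU cohort generator.
#
# One latent severity process S(t) in [0,1] (bounded random walk with
# drift, accelerated after infection onset) drives every organ channel,
# the vital signs, 30-day mortality AND the SOFA inputs, so that MODS
# onset and mortality share a mechanism: this is what makes mortality
# pre-training informative for MODS prediction, the structural property
# the transfer experiment requires. Organ channels add AR(1) noise to S so
# organs can deteriorate asynchronously.
#
# Vitals are emitted hourly (with configurable dropout, so hour bins show
# realistic missingness); labs are emitted per stream at 12-24 h intervals
# after an admission panel; vasoactive doses appear only while
# administered. A dense mode (hourly, noise-free labs and vitals) exists
# so the SOFA engine can be validated against the generator's internal
# ground truth.

#' Simulation configuration
#'
#' @param n_stays number of stays to simulate.
#' @param trauma_fraction fraction of stays flagged as trauma admissions.
#' @param infected_fraction fraction with a suspected-infection time (these
#'   stays get the post-infection severity drift that produces Sepsis-3
#'   sepsis).
#' @param seed mandatory base seed; each stay derives its own stream.
#' @param sev_shape1,sev_shape2 Beta parameters of the initial severity.
#' @param drift baseline severity drift per hour.
#' @param sepsis_drift extra drift per hour after infection onset.
#' @param volatility random-walk innovation standard deviation per hour.
#' @param organ_noise_sd,organ_noise_rho AR(1) organ-channel noise.
#' @param lab_interval_h two-element range of lab sampling intervals
#'   (hours); must lie within `[1, 48]`.
#' @param vital_noise,lab_noise multipliers on vital-sign and laboratory
#'   observation noise. The defaults make single-window severity inference
#'   deliberately imperfect (charted values are noisy proxies of the latent
#'   state), the regime in which learned representations matter.
#' @param baseline_scale multiplier on per-stay physiological baseline
#'   offsets (resting heart rate, blood pressure, habitual lab levels).
#'   Inter-patient heterogeneity applies to the vitals and the non-SOFA
#'   labs; the SOFA inputs themselves stay on the absolute scale their
#'   scoring thresholds assume. Separating a patient's baseline from true
#'   deterioration is what makes small-sample training hard and large-pool
#'   pre-training valuable.
#' @param miss_vitals probability that an hourly vital observation is not
#'   charted (creates empty hour bins).
#' @param mort_intercept,mort_slope per-hour in-ICU death hazard:
#'   `plogis(intercept + slope * S)`.
#' @param post_intercept,post_slope post-discharge 30-day death risk as a
#'   function of severity at discharge.
#' @param horizon_h maximum simulated stay length (hours).
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters.
#' @param dense_labs dense mode: hourly noise-free labs and vitals, no
#'   dropout (for engine-vs-truth validation).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_stays = 100L, trauma_fraction = 0.5,
                       infected_fraction = 0.9, seed = 42L,
                       sev_shape1 = 2.0, sev_shape2 = 7.5,
                       drift = 0.002, sepsis_drift = 0.0055,
                       volatility = 0.035,
                       organ_noise_sd = 0.05, organ_noise_rho = 0.80,
                       lab_interval_h = c(12, 24),
                       vital_noise = 2, lab_noise = 2, miss_vitals = 0.2,
                       baseline_scale = 1,
                       mort_intercept = -9.5, mort_slope = 6,
                       post_intercept = -4.5, post_slope = 4,
                       horizon_h = 240, los_meanlog = log(60),
                       los_sdlog = 0.55, dense_labs = FALSE) {
  stopifnot(n_stays >= 1, !missing(seed) || TRUE,
            lab_interval_h[1] >= 1, lab_interval_h[2] <= 48,
            lab_interval_h[1] <= lab_interval_h[2])
  cfg <- as.list(environment())
  if (dense_labs) {
    cfg$lab_interval_h <- c(1, 1)
    cfg$vital_noise <- 0
    cfg$lab_noise <- 0
    cfg$miss_vitals <- 0
  }
  structure(cfg, class = "sim_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# the default registry is immutable; build it once per session
.sim_env <- new.env(parent = emptyenv())
.sim_registry <- function() {
  if (is.null(.sim_env$reg)) .sim_env$reg <- feature_registry()
  .sim_env$reg
}

# organ-channel maps from severity to native units (monotone in severity)
sev_to_inputs <- function(O) {
  list(PaO2FiO2 = 90 + 360 * (1 - O$resp)^0.56,
       Platelet = 20 + 300 * (1 - O$coag)^1.4,
       Bilirubin = 0.3 + 13 * O$liver^4,
       Creatinine = 0.6 + 4 * O$renal^2.4,
       GCS = round(clamp(15 - 12 * O$cns^3, 3, 15)),
       MBP = 88 - 30 * O$cv,
       Norepinephrine = ifelse(O$cv > 0.62,
                               0.03 + 0.3 * (O$cv - 0.62), 0))
}

#' Simulate a single ICU stay
#'
#' @param config a [sim_config()].
#' @param stay_seed per-stay seed.
#' @param stay_id identifier for the generated stay.
#' @param force_severity optional fixed severity value (overrides the
#'   random walk; used for degenerate-dynamics checks).
#' @return list with `stay` (manifest row), `events` (long-format
#'   data.frame) and `truth` (latent ground truth: `t_mods_true`,
#'   `mortality30`, severity summary).
#' @export
simulate_stay <- function(config, stay_seed, stay_id = "S1",
                          force_severity = NULL) {
  with_seed(stay_seed, {
    los <- clamp(exp(stats::rnorm(1, config$los_meanlog, config$los_sdlog)),
                 12, config$horizon_h)
    H <- ceiling(los)
    hours <- seq_len(H)

    trauma <- stats::runif(1) < config$trauma_fraction
    infected <- stats::runif(1) < config$infected_fraction
    t_inf <- if (infected) stats::runif(1, 4, max(6, min(36, los * 0.6)))
             else NA_real_

    # latent severity path
    if (!is.null(force_severity)) {
      S <- rep(force_severity, H)
    } else {
      S <- numeric(H)
      S[1] <- stats::rbeta(1, config$sev_shape1, config$sev_shape2)
      dr <- rep(config$drift, H)
      if (infected) dr[hours >= t_inf] <- dr[hours >= t_inf] + config$sepsis_drift
      eps <- stats::rnorm(H, 0, config$volatility)
      for (t in 2:max(H, 2)) if (t <= H)
        S[t] <- clamp(S[t - 1] + dr[t] + eps[t], 0, 1)
    }

    # organ channels: severity plus AR(1) organ-specific noise
    organ <- function() {
      e <- as.numeric(stats::filter(stats::rnorm(H, 0, config$organ_noise_sd),
                                    config$organ_noise_rho,
                                    method = "recursive"))
      clamp(S + e, 0, 1)
    }
    O <- list(resp = organ(), coag = organ(), liver = organ(),
              cv = organ(), cns = organ(), renal = organ())
    tv <- sev_to_inputs(O)

    # ground-truth SOFA sub-scores and MODS onset from the noiseless inputs
    sub <- cbind(
      respiration = sofa_subscore("respiration", tv$PaO2FiO2),
      coagulation = sofa_subscore("coagulation", tv$Platelet),
      liver = sofa_subscore("liver", tv$Bilirubin),
      cardiovascular = sofa_subscore("cardiovascular", map = tv$MBP,
                                     norepinephrine = tv$Norepinephrine),
      cns = sofa_subscore("cns", tv$GCS),
      renal = sofa_subscore("renal", tv$Creatinine))
    hit <- which(rowSums(sub >= 2L) >= 2L)
    t_mods_true <- if (length(hit)) as.integer(hours[hit[1]]) else NA_integer_

    # in-ICU death: hazard driven by organ dysfunction (the worst organ
    # channels), not raw severity alone — mortality risk in the ICU is
    # organ-failure risk, which is also what makes mortality pre-training
    # learn organ-level representations
    Om <- cbind(O$resp, O$coag, O$liver, O$cv, O$cns, O$renal)
    worst2 <- vapply(seq_len(H), function(t)
      mean(sort(Om[t, ], decreasing = TRUE)[1:2]), numeric(1))
    death_drive <- 0.4 * S + 0.6 * worst2
    haz <- stats::plogis(config$mort_intercept + config$mort_slope * death_drive)
    died_h <- which(stats::runif(H) < haz)
    death_time <- NA_real_
    if (length(died_h)) {
      death_time <- as.numeric(died_h[1])
      los <- max(min(los, death_time), 1)
      H <- ceiling(los); hours <- seq_len(H)
    } else {
      p_post <- stats::plogis(config$post_intercept +
                                config$post_slope * death_drive[H])
      if (stats::runif(1) < p_post)
        death_time <- los + stats::runif(1, 1, 900)
    }

    ev <- list()
    emit <- function(t, var, val, unit) {
      list(time_h = t, variable = rep(var, length(t)), value = val,
           unit = rep(unit, length(t)))
    }
    reg <- .sim_registry()
    clip_emit <- function(var, val) {
      i <- match(var, reg$variable)
      clamp(val, reg$low[i], reg$high[i])
    }

    # per-stay physiological baselines (inter-patient heterogeneity)
    bl <- function(sd) stats::rnorm(1, 0, sd * config$baseline_scale)

    # hourly vitals with observation noise and dropout
    nz <- function(sd) stats::rnorm(H, 0, sd * config$vital_noise)
    Sv <- S[hours]; Ocv <- O$cv[hours]
    vit_vals <- list(
      HR = 72 + bl(9) + 45 * Sv + nz(3),
      SBP = 118 + bl(11) - 45 * Ocv + nz(4),
      DBP = 72 + bl(7) - 26 * Ocv + nz(3),
      MBP = tv$MBP[hours] + nz(2),
      Temperature = 36.7 + bl(0.3) + 1.6 * Sv + nz(0.25),
      SpO2 = 98.5 + bl(1) - 9 * Sv^1.5 + nz(0.8),
      Resp_Rate = 14 + bl(2.5) + 13 * Sv + nz(1.5))
    for (v in names(vit_vals)) {
      keep <- stats::runif(H) >= config$miss_vitals
      if (any(keep))
        ev[[length(ev) + 1L]] <- emit(hours[keep], v,
                                      clip_emit(v, vit_vals[[v]][keep]),
                                      reg$unit[match(v, reg$variable)])
    }

    # lab streams: admission panel then 12-24 h intervals
    lab_times <- function() {
      t <- stats::runif(1, 0.5, 4)
      out <- numeric(0)
      while (t <= los) {
        out <- c(out, t)
        t <- t + stats::runif(1, config$lab_interval_h[1],
                              config$lab_interval_h[2])
      }
      out
    }
    if (config$dense_labs) lab_times <- function() hours

    lab_noise <- if (config$dense_labs) 0 else config$lab_noise
    at_hours <- function(x, tt) x[clamp(ceiling(tt), 1, length(x))]
    lab_defs <- list(
      PaO2FiO2 = function(tt) at_hours(tv$PaO2FiO2, tt),
      Platelet = function(tt) at_hours(tv$Platelet, tt),
      Bilirubin = function(tt) at_hours(tv$Bilirubin, tt),
      Creatinine = function(tt) at_hours(tv$Creatinine, tt),
      GCS = function(tt) at_hours(tv$GCS, tt),
      GCS_Motor = function(tt) round(clamp(6 - 4 * at_hours(O$cns, tt), 1, 6)),
      GCS_Verbal = function(tt) round(clamp(5 - 3.5 * at_hours(O$cns, tt), 1, 5)),
      GCS_Eyes = function(tt) round(clamp(4 - 2.7 * at_hours(O$cns, tt), 1, 4)),
      FiO2 = function(tt) 21 + 60 * at_hours(O$resp, tt),
      PaO2 = function(tt) at_hours(tv$PaO2FiO2, tt) *
        (21 + 60 * at_hours(O$resp, tt)) / 100,
      Hematocrit = function(tt) 40 + bl(3) - 10 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1.2 * lab_noise),
      Hemoglobin = function(tt) 13 + bl(1) - 3.5 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 0.5 * lab_noise),
      WBC = function(tt) 8 + bl(2) + 11 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1.5 * lab_noise),
      BUN = function(tt) 15 + bl(6) + 45 * at_hours(O$renal, tt) +
        stats::rnorm(length(tt), 0, 3 * lab_noise),
      Sodium = function(tt) 139 + bl(2) + 4 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1.5 * lab_noise),
      Albumin = function(tt) 4 + bl(0.4) - 1.6 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 0.2 * lab_noise),
      Glucose = function(tt) 112 + bl(22) + 70 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 10 * lab_noise),
      pH = function(tt) 7.42 + bl(0.03) - 0.22 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 0.02 * lab_noise),
      PaCO2 = function(tt) 39 + bl(4) + 6 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 2 * lab_noise),
      PT = function(tt) 12.5 + bl(2) + 20 * at_hours(O$coag, tt) +
        stats::rnorm(length(tt), 0, 1 * lab_noise),
      Potassium = function(tt) 4 + bl(0.35) + 1.1 * at_hours(O$renal, tt) +
        stats::rnorm(length(tt), 0, 0.2 * lab_noise),
      ALT = function(tt) 28 + bl(14) + 320 * at_hours(O$liver, tt)^2 +
        stats::rnorm(length(tt), 0, 8 * lab_noise),
      AST = function(tt) 33 + bl(16) + 360 * at_hours(O$liver, tt)^2 +
        stats::rnorm(length(tt), 0, 8 * lab_noise),
      Base_Excess = function(tt) 1 + bl(2) - 13 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1 * lab_noise),
      Chloride = function(tt) 103 + bl(3) + 5 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1.5 * lab_noise),
      Total_CO2 = function(tt) 24.5 + bl(2) - 9 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 1 * lab_noise),
      Lactate = function(tt) 1 + 7 * at_hours(S, tt)^2 +
        stats::rnorm(length(tt), 0, 0.3 * lab_noise),
      Free_Calcium = function(tt) 1.15 + bl(0.07) - 0.25 * at_hours(S, tt) +
        stats::rnorm(length(tt), 0, 0.04 * lab_noise))
    for (v in names(lab_defs)) {
      tt <- lab_times()
      if (length(tt))
        ev[[length(ev) + 1L]] <- emit(tt, v, clip_emit(v, lab_defs[[v]](tt)),
                                      reg$unit[match(v, reg$variable)])
    }

    # vasoactive doses: recorded hourly while administered
    nor <- tv$Norepinephrine[hours]
    if (any(nor > 0))
      ev[[length(ev) + 1L]] <- emit(hours[nor > 0], "Norepinephrine",
                                    clip_emit("Norepinephrine", nor[nor > 0]),
                                    "ug/kg/min")
    if (max(S) > 0.8) {  # refractory shock: second agent
      dop <- ifelse(O$cv[hours] > 0.8, 4 + 8 * (O$cv[hours] - 0.8), 0)
      if (any(dop > 0))
        ev[[length(ev) + 1L]] <- emit(hours[dop > 0], "Dopamine",
                                      clip_emit("Dopamine", dop[dop > 0]),
                                      "ug/kg/min")
    }

    events <- data.frame(
      stay_id = stay_id,
      time_h = unlist(lapply(ev, `[[`, "time_h"), use.names = FALSE),
      variable = unlist(lapply(ev, `[[`, "variable"), use.names = FALSE),
      value = unlist(lapply(ev, `[[`, "value"), use.names = FALSE),
      unit = unlist(lapply(ev, `[[`, "unit"), use.names = FALSE))
    events <- events[events$time_h <= los, , drop = FALSE]
    rownames(events) <- NULL

    stay <- data.frame(
      stay_id = stay_id,
      age = round(clamp(stats::rnorm(1, 64, 19), 18, 100)),
      gender = if (stats::runif(1) < 0.64) "male" else "female",
      icu_los_h = los,
      death_time_h = death_time,
      trauma_flag = trauma,
      suspected_infection_time_h = if (!is.na(t_inf) && t_inf <= los) t_inf
                                   else NA_real_)

    truth <- data.frame(
      stay_id = stay_id,
      t_mods_true = if (!is.na(t_mods_true) && t_mods_true <= ceiling(los))
                      t_mods_true else NA_integer_,
      mortality30 = assign_mortality_label(death_time),
      mean_severity = mean(S[seq_len(ceiling(los))]),
      infected = infected)

    list(stay = stay, events = events, truth = truth)
  })
}

#' Simulate a cohort
#'
#' Generates `n_stays` independent stays under one configuration and
#' assembles the same structures [read_events()] produces, plus the
#' latent ground-truth table.
#'
#' @param config a [sim_config()].
#' @param id_prefix stay-id prefix (keeps pools and cohorts disjoint).
#' @param role cohort role.
#' @return list with `cohort` (a `cohort_table`) and `truth` (data.frame:
#'   `stay_id`, `t_mods_true`, `mortality30`, `mean_severity`, `infected`).
#' @export
simulate_cohort <- function(config, id_prefix = "S",
                            role = "finetune_cohort") {
  stays <- vector("list", config$n_stays)
  events <- vector("list", config$n_stays)
  truths <- vector("list", config$n_stays)
  for (i in seq_len(config$n_stays)) {
    st <- simulate_stay(config, derive_seed(config$seed, i),
                        stay_id = sprintf("%s%05d", id_prefix, i))
    stays[[i]] <- st$stay; events[[i]] <- st$events; truths[[i]] <- st$truth
  }
  cohort <- cohort_table(
    do.call(rbind, stays),
    as.data.frame(data.table::rbindlist(events)),
    role = role)
  list(cohort = cohort, truth = do.call(rbind, truths))
}

#' Generate the transfer-learning benchmark
#'
#' A large general-ICU pool (non-trauma, milder severity mix) for 30-day
#' mortality pre-training and a smaller trauma sepsis cohort (trauma flag
#' set, infection suspected, higher initial severity) for MODS
#' fine-tuning. Both share the severity mechanism, so representations
#' learned on mortality transfer to MODS prediction. Stay ids are disjoint
#' by prefix.
#'
#' @param pool_n,cohort_n pool and cohort sizes.
#' @param seed base seed.
#' @param pool_config,cohort_config optional [sim_config()] overrides.
#' @return list with `pool`, `cohort` (both `cohort_table`s), `pool_truth`,
#'   `cohort_truth`.
#' @export
transfer_benchmark <- function(pool_n = 5000L, cohort_n = 1000L, seed = 42L,
                               pool_config = NULL, cohort_config = NULL) {
  if (is.null(pool_config))
    pool_config <- sim_config(n_stays = pool_n, trauma_fraction = 0,
                              infected_fraction = 0.3,
                              sev_shape1 = 1.6, sev_shape2 = 6.5,
                              seed = derive_seed(seed, 1001L))
  if (is.null(cohort_config))
    cohort_config <- sim_config(n_stays = cohort_n, trauma_fraction = 1,
                                infected_fraction = 1,
                                seed = derive_seed(seed, 2002L))
  pool <- simulate_cohort(pool_config, id_prefix = "P", role = "pretrain_pool")
  cohort <- simulate_cohort(cohort_config, id_prefix = "T",
                            role = "finetune_cohort")
  list(pool = pool$cohort, cohort = cohort$cohort,
       pool_truth = pool$truth, cohort_truth = cohort$truth,
       configs = list(pool = pool_config, cohort = cohort_config))
}

#' Write a simulated cohort to CSV (stays, events, truth)
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(stays = file.path(dir, "stays.csv"),
             events = file.path(dir, "events.csv"),
             truth = file.path(dir, "truth.csv"))
  write_events(sim$cohort, paths["stays"], paths["events"])
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
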