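# End-to-end orchestration: simulate -> score SOFA -> label -> preprocess
# -> pre-train -> fine-tune -> evaluate -> explain, with seed-controlled
# determinism and JSON artifacts. These functions are also the backing for
# the command-line entry point in inst/cli/.

#' Desk-scale network sizes
#'
#' Smaller layer widths used by the end-to-end pipeline on synthetic
#' cohorts, where the reference sizes ([default_net_sizes()]) buy no
#' additional discrimination but cost wall-clock time.
#'
#' @return a sizes list as accepted by [build_pretrain_network()].
#' @export
desk_net_sizes <- function() {
  list(lstm_hidden = 24L, mlp_hidden = c(48L, 24L),
       trunk = 24L, head_hidden = 16L)
}

#' Desk-scale training protocols
#'
#' The reference optimizer, batch size and stopping rule of
#' [train_config()], with learning rates scaled for networks and cohorts
#' two orders of magnitude smaller than the reference setting:
#' `desk_pretrain_config()` for mortality pre-training,
#' `desk_finetune_config()` for full-network fine-tuning (deliberately
#' small rate: transfer adapts the representation rather than retraining
#' it), and `desk_head_config()` for the head-only warm-up stage of
#' [train_two_stage()] (the head is small, so a larger rate with smaller
#' batches converges in tens of epochs without touching the frozen body).
#'
#' @param seed RNG seed for the returned config.
#' @return a [train_config()].
#' @export
desk_pretrain_config <- function(seed = 42L)
  train_config(learning_rate = 1e-3, weight_decay = 1e-3,
               batch_size = 4096L, max_epochs = 60L, patience = 12L,
               seed = seed)

#' @rdname desk_pretrain_config
#' @export
desk_finetune_config <- function(seed = 42L)
  train_config(learning_rate = 1e-4, weight_decay = 1e-3,
               batch_size = 4096L, max_epochs = 240L, patience = 30L,
               seed = seed)

#' @rdname desk_pretrain_config
#' @export
desk_head_config <- function(seed = 42L)
  train_config(learning_rate = 3e-3, weight_decay = 1e-3,
               batch_size = 512L, max_epochs = 60L, patience = 15L,
               seed = seed)

#' Prepare benchmark data for training
#'
#' Runs the data half of the pipeline on a simulated transfer benchmark:
#' SOFA scoring and sepsis/MODS determination on the trauma cohort,
#' inclusion filtering of both cohorts, window extraction and labeling,
#' patient-level splits, and normalization (statistics fitted on the
#' pre-training pool's training partition and applied to every partition of
#' both tasks, so the transferred representation sees one input scale).
#'
#' @param bench result of [transfer_benchmark()].
#' @param seed split seed.
#' @param registry feature registry.
#' @param max_windows_pool per-stay window cap for the mortality pool.
#' @param stride_h evaluation-time stride.
#' @param verbose print progress.
#' @return list with preprocessed `pool` and `mods` splits (`train`,
#'   `validation`, `test`), the normalization `stats`, the engine-derived
#'   `sofa_summary` of the trauma cohort, and the filtered cohorts.
#' @export
prepare_benchmark_data <- function(bench, seed = 42L,
                                   registry = feature_registry(),
                                   max_windows_pool = 10L, stride_h = 1L,
                                   verbose = FALSE) {
  log_msg("scoring SOFA on the trauma cohort", verbose = verbose)
  summary <- cohort_sofa_summary(bench$cohort, registry)
  flags <- summary[, c("stay_id", "septic")]

  cohort <- filter_finetune_cohort(bench$cohort, sepsis_flags = flags,
                                   registry = registry)
  pool <- filter_pretrain_pool(bench$pool, registry = registry)

  log_msg("building mortality windows (pool of ", nrow(pool$stays),
          " stays)", verbose = verbose)
  pool_split <- build_dataset(pool, task = "mortality",
                              seed = derive_seed(seed, 5L),
                              registry = registry, stride_h = stride_h,
                              max_windows_per_stay = max_windows_pool)
  log_msg("building MODS windows (cohort of ", nrow(cohort$stays),
          " stays)", verbose = verbose)
  mods_split <- build_dataset(cohort, task = "mods",
                              seed = derive_seed(seed, 6L),
                              registry = registry, stride_h = stride_h,
                              onsets = summary[, c("stay_id", "t_mods_h")])

  stats <- suppressWarnings(
    fit_normalization_stats(pool_split$train, registry))
  pp <- function(split) lapply(split, preprocess_windows, stats = stats)
  list(pool = pp(pool_split), mods = pp(mods_split), stats = stats,
       sofa_summary = summary, cohort = cohort, pool_cohort = pool)
}

# restrict a preprocessed split to a set of stays, re-splitting
# train/validation at the patient level
restrict_split <- function(split, stay_ids, val_fraction = 0.2, seed = 1L) {
  ids <- with_seed(seed, sample(stay_ids))
  n_val <- max(1L, round(length(ids) * val_fraction))
  val_ids <- ids[seq_len(n_val)]
  tr_ids <- ids[-seq_len(n_val)]
  pick <- function(ws, keep)
    subset_window_set(ws, ws$meta$stay_id %in% keep)
  pool_all <- list(split$train, split$validation)
  merged <- list(
    X_hf = rbind(split$train$X_hf, split$validation$X_hf),
    X_lo = rbind(split$train$X_lo, split$validation$X_lo),
    meta = rbind(split$train$meta, split$validation$meta),
    y = rbind(split$train$y, split$validation$y),
    hf_vars = split$train$hf_vars, lo_vars = split$train$lo_vars)
  class(merged) <- "window_set"
  list(train = pick(merged, tr_ids), validation = pick(merged, val_ids),
       test = split$test)
}

#' Transfer-benefit experiment
#'
#' Quantifies the value of mortality pre-training in the small-sample
#' regime: a mortality network is pre-trained once on the pool; then, for
#' each seed, `n_finetune` training stays are drawn and two models of
#' identical architecture are trained on them under the IDENTICAL
#' two-stage schedule ([train_two_stage()]): one initialized from the
#' pre-trained parameters, one from random initialization. Both are scored
#' on the fixed test partition, so the per-seed difference isolates the
#' value of the pre-trained initialization. Reported per seed: mean test
#' AUC across the three horizons for both models and their gap.
#'
#' @param prep result of [prepare_benchmark_data()].
#' @param n_finetune number of fine-tuning stays per replicate.
#' @param seeds integer seeds (one replicate each).
#' @param sizes network sizes.
#' @param pretrain_config,finetune_config,head_config training protocols.
#' @param verbose print progress.
#' @return data.frame per seed: `auc_pretrained`, `auc_scratch`, `gap`;
#'   attribute `pretrained_model` holds the shared pre-trained network.
#' @export
transfer_benefit_experiment <- function(prep, n_finetune = 100L,
                                        seeds = c(1L, 2L, 3L),
                                        sizes = desk_net_sizes(),
                                        pretrain_config = desk_pretrain_config(),
                                        finetune_config = desk_finetune_config(),
                                        head_config = desk_head_config(),
                                        verbose = FALSE) {
  log_msg("pre-training mortality network", verbose = verbose)
  spec_pt <- variant_spec("PT-MLP.LSTM-eICU")
  pnet <- build_pretrain_network(spec_pt, sizes,
                                 seed = derive_seed(pretrain_config$seed, 11L))
  pt <- train_network(pnet, prep$pool$train, prep$pool$validation,
                      pretrain_config)

  train_ids <- unique(c(prep$mods$train$meta$stay_id,
                        prep$mods$validation$meta$stay_id))
  if (length(train_ids) < n_finetune)
    stop("training pool has only ", length(train_ids), " stays")
  test_y <- prep$mods$test$y

  mean_auc <- function(model) {
    probs <- predict_risks(model, prep$mods$test)
    mean(vapply(seq_len(ncol(probs)), function(k)
      compute_auc(probs[, k], test_y[, k]), numeric(1)))
  }

  rows <- lapply(seeds, function(sd) {
    subset_ids <- with_seed(derive_seed(sd, 71L),
                            sample(train_ids, n_finetune))
    data_sd <- restrict_split(prep$mods, subset_ids,
                              seed = derive_seed(sd, 72L))
    cfg <- finetune_config; cfg$seed <- derive_seed(sd, 73L)
    hcfg <- head_config; hcfg$seed <- derive_seed(sd, 76L)

    log_msg("seed ", sd, ": fine-tuning on ", n_finetune, " stays",
            verbose = verbose)
    ft_net <- transfer_to_mods_network(pt, seed = derive_seed(sd, 74L))
    ft <- train_two_stage(ft_net, data_sd$train, data_sd$validation,
                          hcfg, cfg)

    sc_net <- build_mods_network(variant_spec("MLP.LSTM"), sizes,
                                 seed = derive_seed(sd, 75L))
    sc <- train_two_stage(sc_net, data_sd$train, data_sd$validation,
                          hcfg, cfg)

    data.frame(seed = sd, auc_pretrained = mean_auc(ft),
               auc_scratch = mean_auc(sc))
  })
  out <- do.call(rbind, rows)
  out$gap <- out$auc_pretrained - out$auc_scratch
  attr(out, "pretrained_model") <- pt
  out
}

#' Run the full pipeline on a synthetic benchmark
#'
#' Simulates the transfer benchmark, prepares the data, pre-trains and
#' fine-tunes the dual-stream model, and evaluates it on the held-out
#' patients: discrimination with patient-level bootstrap CIs, calibration
#' with Brier scores, and the clinical threshold table. Deterministic for
#' a fixed seed.
#'
#' @param pool_n,cohort_n benchmark sizes.
#' @param seed master seed for simulation, splitting and training.
#' @param sizes network sizes.
#' @param boot_B bootstrap resamples for the confidence intervals.
#' @param out_dir optional directory for JSON/CSV artifacts.
#' @param verbose print stage progress.
#' @return list with `metrics`, `calibration` (per horizon), `thresholds`,
#'   `model`, `prep` (prepared data), `ablation = NULL` placeholder.
#' @export
run_full_pipeline <- function(pool_n = 2000L, cohort_n = 600L, seed = 42L,
                              sizes = desk_net_sizes(), boot_B = 200L,
                              out_dir = NULL, verbose = FALSE) {
  log_msg("simulating benchmark (", pool_n, " + ", cohort_n, " stays)",
          verbose = verbose)
  bench <- transfer_benchmark(pool_n = pool_n, cohort_n = cohort_n,
                              seed = seed)
  prep <- prepare_benchmark_data(bench, seed = seed, verbose = verbose)

  spec <- variant_spec("PT-MLP.LSTM-eICU")
  fit <- fit_variant(spec, prep$mods, prep$pool,
                     config = desk_finetune_config(derive_seed(seed, 31L)),
                     pretrain_config = desk_pretrain_config(derive_seed(seed, 32L)),
                     head_config = desk_head_config(derive_seed(seed, 33L)),
                     sizes = sizes, seed = seed, verbose = verbose)

  probs <- predict_risks(fit, prep$mods$test)
  y <- prep$mods$test$y
  pid <- prep$mods$test$meta$stay_id
  bc <- bootstrap_config(B = boot_B, seed = derive_seed(seed, 41L))

  log_msg("evaluating on ", length(unique(pid)), " test stays (",
          nrow(y), " windows)", verbose = verbose)
  metrics <- metric_report(probs, y, pid, config = bc)
  calib <- lapply(seq_len(ncol(probs)), function(k)
    calibration_and_brier(probs[, k], y[, k], patient_ids = pid,
                          config = bc))
  names(calib) <- colnames(probs)
  thresholds <- threshold_report(probs, y, pid, config = bc)

  out <- list(metrics = metrics, calibration = calib,
              thresholds = thresholds, model = fit, prep = prep,
              seed = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           metrics = metrics,
           brier = lapply(calib, function(cc) cc$brier),
           thresholds = thresholds),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Explain test-set predictions of a fitted pipeline
#'
#' @param result output of [run_full_pipeline()].
#' @param n_cases number of test windows to explain.
#' @param n_background background windows drawn from the training split.
#' @param horizon prediction horizon to explain.
#' @param seed RNG seed.
#' @return list with `explanations`, `importance` (global ranking) and
#'   `hourly` (7 x 4 vital-sign grid).
#' @export
explain_pipeline <- function(result, n_cases = 20L, n_background = 100L,
                             horizon = 6L, seed = 7L) {
  train_ws <- result$prep$mods$train
  test_ws <- result$prep$mods$test
  bg_idx <- with_seed(seed, sample(nrow(train_ws$X_hf),
                                   min(n_background, nrow(train_ws$X_hf))))
  bg <- subset_window_set(train_ws, bg_idx)
  case_idx <- with_seed(seed + 1L,
                        sample(nrow(test_ws$X_hf),
                               min(n_cases, nrow(test_ws$X_hf))))
  expl <- lapply(seq_along(case_idx), function(j)
    compute_attributions(result$model, bg, test_ws, i = case_idx[j],
                         horizon = horizon,
                         seed = derive_seed(seed, 100L + j)))
  list(explanations = expl,
       importance = global_importance(expl),
       hourly = hourly_highfreq_summary(expl))
}
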