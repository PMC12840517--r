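# Evaluation suite: discrimination with patient-level bootstrap confidence
# intervals, calibration and Brier score, clinical threshold tables,
# learning curves, and the SOFA feature-subset comparison.

#' Rank-based AUC with midrank tie handling
#'
#' Computes the area under the ROC curve as the normalized Mann-Whitney
#' statistic with ties counted at half weight. Optional non-negative record
#' weights make the statistic identical to computing the unweighted AUC on
#' a dataset in which each record is duplicated `weight` times (the
#' patient-level bootstrap relies on this equivalence).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome labels.
#' @param weights optional non-negative record weights (default 1).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels, weights = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(weights)) weights <- rep(1, length(scores))
  active <- weights > 0
  y <- labels[active]
  if (length(unique(y)) < 2L)
    stop("AUC undefined: labels contain a single class")
  s <- scores[active]; w <- weights[active]
  o <- order(s)
  s <- s[o]; y <- y[o]; w <- w[o]
  grp <- cumsum(!duplicated(s))
  g0 <- rowsum(w * (y == 0), grp)[, 1]
  g1 <- rowsum(w * (y == 1), grp)[, 1]
  W0 <- sum(g0); W1 <- sum(g1)
  below0 <- cumsum(g0) - g0
  U <- sum(g1 * (below0 + 0.5 * g0))
  U / (W0 * W1)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Predictions are positive when `score >= threshold`.
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold in (0, 1).
#' @param weights optional record weights.
#' @return list with `acc`, `tpr` (sensitivity), `tnr` (specificity).
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5,
                              weights = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(weights)) weights <- rep(1, length(scores))
  active <- weights > 0
  s <- scores[active]; y <- labels[active]; w <- weights[active]
  pred <- as.integer(s >= threshold)
  if (sum(w[y == 1]) == 0) stop("TPR undefined: no positive records")
  if (sum(w[y == 0]) == 0) stop("TNR undefined: no negative records")
  list(acc = sum(w * (pred == y)) / sum(w),
       tpr = sum(w[y == 1] * (pred[y == 1] == 1)) / sum(w[y == 1]),
       tnr = sum(w[y == 0] * (pred[y == 0] == 0)) / sum(w[y == 0]))
}

#' Bootstrap configuration
#'
#' @param B number of bootstrap resamples.
#' @param seed RNG seed for the resampling.
#' @param level confidence level.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 2000L, seed = 1L, level = 0.95) {
  stopifnot(B >= 1, level > 0, level < 1)
  structure(list(B = as.integer(B), seed = as.integer(seed), level = level),
            class = "bootstrap_config")
}

resolve_metric <- function(metric, threshold = 0.5) {
  if (is.function(metric)) return(metric)
  switch(metric,
         auc = function(s, y, w) compute_auc(s, y, w),
         acc = function(s, y, w) threshold_metrics(s, y, threshold, w)$acc,
         tpr = function(s, y, w) threshold_metrics(s, y, threshold, w)$tpr,
         tnr = function(s, y, w) threshold_metrics(s, y, threshold, w)$tnr,
         brier = function(s, y, w) sum(w * (s - y)^2) / sum(w),
         stop("unknown metric: ", metric))
}

#' Patient-level bootstrap confidence interval
#'
#' Resamples PATIENTS (not records) with replacement, B times, keeping the
#' number of sampled patients equal to the original cohort size. Each
#' record receives a weight equal to how often its patient was drawn, and
#' the metric is recomputed with those weights (for the AUC, via the
#' weighted rank statistic, which equals explicit record duplication). The
#' interval is the 2.5th/97.5th percentile of the bootstrap distribution
#' (percentile method). Resamples that lose one outcome class are skipped
#' and counted.
#'
#' @param scores,labels record-level predictions and 0/1 outcomes.
#' @param patient_ids patient identifier per record.
#' @param metric `"auc"`, `"acc"`, `"tpr"`, `"tnr"`, `"brier"`, or a
#'   function `(scores, labels, weights) -> numeric`.
#' @param config a [bootstrap_config()].
#' @param threshold threshold used by the confusion-matrix metrics.
#' @return list with `point`, `lo`, `hi`, `n_skipped` and the bootstrap
#'   `values`.
#' @export
patient_bootstrap_ci <- function(scores, labels, patient_ids,
                                 metric = "auc",
                                 config = bootstrap_config(),
                                 threshold = 0.5) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(patient_ids))
  f <- resolve_metric(metric, threshold)
  patients <- unique(patient_ids)
  np <- length(patients)
  rec_pat <- match(patient_ids, patients)
  point <- f(scores, labels, rep(1, length(scores)))
  vals <- with_seed(config$seed, {
    vapply(seq_len(config$B), function(b) {
      draw <- sample.int(np, np, replace = TRUE)
      counts <- tabulate(draw, nbins = np)
      w <- counts[rec_pat]
      if (length(unique(labels[w > 0])) < 2L) return(NA_real_)
      f(scores, labels, w)
    }, numeric(1))
  })
  n_skipped <- sum(is.na(vals))
  vals_ok <- vals[!is.na(vals)]
  a <- (1 - config$level) / 2
  qs <- if (length(vals_ok)) stats::quantile(vals_ok, c(a, 1 - a),
                                             names = FALSE, type = 7)
        else c(NA_real_, NA_real_)
  list(point = point, lo = qs[1], hi = qs[2],
       n_skipped = n_skipped, values = vals)
}

#' Per-horizon metric report with bootstrap confidence intervals
#'
#' AUC, accuracy, sensitivity and specificity for each prediction horizon,
#' each with a patient-level bootstrap CI.
#'
#' @param probs matrix of predicted probabilities (one column per horizon).
#' @param y 0/1 label matrix conformable with `probs`.
#' @param patient_ids patient identifier per row.
#' @param config a [bootstrap_config()].
#' @param threshold operating threshold for ACC/TPR/TNR.
#' @return data.frame with one row per horizon x metric: `point`, `lo`,
#'   `hi`.
#' @export
metric_report <- function(probs, y, patient_ids,
                          config = bootstrap_config(), threshold = 0.5) {
  rows <- list()
  for (k in seq_len(ncol(probs))) {
    hname <- colnames(probs)[k] %||% paste0("out", k)
    for (m in c("auc", "acc", "tpr", "tnr")) {
      ci <- patient_bootstrap_ci(probs[, k], y[, k], patient_ids, m,
                                 config, threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(horizon = hname, metric = m, point = ci$point,
                   lo = ci$lo, hi = ci$hi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibration curve and Brier score
#'
#' Equal-width probability bins over `[0, 1]`; per bin the mean predicted
#' risk and observed event rate. The Brier score is the mean squared
#' difference between predicted probability and outcome, with a
#' patient-level bootstrap CI when patient ids are supplied.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins number of equal-width bins.
#' @param patient_ids optional patient ids for the Brier CI.
#' @param config bootstrap configuration.
#' @return list with `bins` (data.frame: edges, mean predicted, observed
#'   rate, count) and `brier` (`point`, and `lo`/`hi` when patient ids are
#'   given).
#' @export
calibration_and_brier <- function(scores, labels, n_bins = 10L,
                                  patient_ids = NULL,
                                  config = bootstrap_config()) {
  stopifnot(all(scores >= 0 & scores <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  bins <- data.frame(
    bin = seq_len(n_bins),
    lower = edges[-length(edges)], upper = edges[-1],
    mean_pred = as.numeric(tapply(scores, factor(bin, levels = seq_len(n_bins)),
                                  mean)),
    observed = as.numeric(tapply(labels, factor(bin, levels = seq_len(n_bins)),
                                 mean)),
    n = as.integer(table(factor(bin, levels = seq_len(n_bins)))))
  brier_point <- mean((scores - labels)^2)
  brier <- list(point = brier_point)
  if (!is.null(patient_ids)) {
    ci <- patient_bootstrap_ci(scores, labels, patient_ids, "brier", config)
    brier <- list(point = brier_point, lo = ci$lo, hi = ci$hi)
  }
  list(bins = bins, brier = brier)
}

#' Sensitivity/specificity table at clinical risk thresholds
#'
#' @param probs probability matrix (one column per horizon).
#' @param y 0/1 label matrix.
#' @param patient_ids patient ids for the bootstrap CIs.
#' @param thresholds decision thresholds.
#' @param config bootstrap configuration.
#' @return data.frame: horizon, threshold, sensitivity and specificity with
#'   CIs. On a fixed prediction set, sensitivity is non-increasing and
#'   specificity non-decreasing in the threshold.
#' @export
threshold_report <- function(probs, y, patient_ids,
                             thresholds = c(0.10, 0.20, 0.30),
                             config = bootstrap_config()) {
  rows <- list()
  for (k in seq_len(ncol(probs))) {
    hname <- colnames(probs)[k] %||% paste0("out", k)
    for (th in thresholds) {
      se <- patient_bootstrap_ci(probs[, k], y[, k], patient_ids, "tpr",
                                 config, threshold = th)
      sp <- patient_bootstrap_ci(probs[, k], y[, k], patient_ids, "tnr",
                                 config, threshold = th)
      rows[[length(rows) + 1L]] <- data.frame(
        horizon = hname, threshold = th,
        sensitivity = se$point, sens_lo = se$lo, sens_hi = se$hi,
        specificity = sp$point, spec_lo = sp$lo, spec_hi = sp$hi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Learning curve over nested training subsets
#'
#' Expands the training pool in increments of `increment` patients; subsets
#' are nested (each size extends the previous) and the test set is fixed.
#' `train_fn(stay_ids, seed)` must fit a model on the given patients and
#' return the mean test AUC across horizons. Results are averaged over
#' `seeds` (each seed re-draws the nesting order).
#'
#' @param train_fn function `(stay_ids, seed) -> numeric` returning the
#'   mean AUC on the fixed test set.
#' @param pool_ids stay ids available for training.
#' @param increment patients added per curve point.
#' @param seeds integer seeds; one curve per seed, averaged.
#' @return data.frame `n_train`, `mean_auc`; per-seed curves as attribute
#'   `per_seed`.
#' @export
learning_curve <- function(train_fn, pool_ids, increment = 100L,
                           seeds = c(1L, 2L, 3L)) {
  n_pts <- floor(length(pool_ids) / increment)
  if (n_pts < 1L) stop("pool smaller than one increment")
  sizes <- increment * seq_len(n_pts)
  per_seed <- sapply(seeds, function(sd) {
    ord <- with_seed(sd, sample(pool_ids))
    vapply(sizes, function(nsz) train_fn(ord[seq_len(nsz)], sd), numeric(1))
  })
  per_seed <- matrix(per_seed, nrow = length(sizes),
                     dimnames = list(NULL, paste0("seed", seeds)))
  out <- data.frame(n_train = sizes, mean_auc = rowMeans(per_seed))
  attr(out, "per_seed") <- per_seed
  out
}

#' SOFA feature-subset comparison harness
#'
#' Compares four input configurations on the same split:
#' `sofa_only_score` fits a per-horizon logistic regression on the total
#' SOFA score at the evaluation time; `sofa_vars` and `non_sofa_vars`
#' retrain the full pipeline with the complementary registry-tagged feature
#' subsets (excluded columns are masked to the training mean, i.e. zero
#' after standardization); `all_vars` is the unrestricted pipeline.
#'
#' @param subset one of `"sofa_only_score"`, `"sofa_vars"`,
#'   `"non_sofa_vars"`, `"all_vars"`.
#' @param mods_data preprocessed MODS split (`train`/`validation`/`test`).
#' @param registry feature registry (provides the SOFA-related tags).
#' @param sofa_totals data.frame `stay_id`, `t_k`, `total` with the total
#'   SOFA score at each window (required for `sofa_only_score`).
#' @param spec model variant used for the network-based subsets.
#' @param pretrain_data optional preprocessed mortality split when `spec`
#'   pre-trains.
#' @param config,sizes,seed training controls.
#' @return data.frame with per-horizon test AUC and ACC for the subset.
#' @export
feature_subset_harness <- function(subset = c("all_vars", "sofa_vars",
                                              "non_sofa_vars",
                                              "sofa_only_score"),
                                   mods_data,
                                   registry = feature_registry(),
                                   sofa_totals = NULL,
                                   spec = variant_spec("MLP.LSTM"),
                                   pretrain_data = NULL,
                                   config = train_config(),
                                   sizes = default_net_sizes(),
                                   seed = 42L) {
  subset <- match.arg(subset)
  horiz <- paste0("y", HORIZONS_H)

  if (subset == "sofa_only_score") {
    if (is.null(sofa_totals))
      stop("sofa_only_score requires per-window total SOFA scores")
    get_tot <- function(ws) {
      key <- paste(ws$meta$stay_id, ws$meta$t_k)
      sofa_totals$total[match(key, paste(sofa_totals$stay_id,
                                         sofa_totals$t_k))]
    }
    tr_x <- get_tot(mods_data$train); te_x <- get_tot(mods_data$test)
    if (anyNA(tr_x) || anyNA(te_x))
      stop("sofa_totals does not cover every window")
    rows <- lapply(seq_along(horiz), function(k) {
      fit <- stats::glm(mods_data$train$y[, k] ~ tr_x,
                        family = stats::binomial())
      p <- stats::predict(fit, newdata = data.frame(tr_x = te_x),
                          type = "response")
      data.frame(subset = subset, horizon = horiz[k],
                 auc = compute_auc(p, mods_data$test$y[, k]),
                 acc = threshold_metrics(p, mods_data$test$y[, k])$acc,
                 n_features = 1L)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  keep_vars <- switch(subset,
                      all_vars = registry$variable,
                      sofa_vars = sofa_related_vars(registry),
                      non_sofa_vars = setdiff(registry$variable,
                                              sofa_related_vars(registry)))
  if (length(keep_vars) == 0L) stop("empty feature subset")
  mask <- function(ws) {
    drop_hf <- !(sub("_[1-4]$", "", colnames(ws$X_hf)) %in% keep_vars)
    drop_lo <- !(colnames(ws$X_lo) %in% keep_vars)
    ws$X_hf[, drop_hf] <- 0
    ws$X_lo[, drop_lo] <- 0
    ws
  }
  data_m <- list(train = mask(mods_data$train),
                 validation = mask(mods_data$validation),
                 test = mask(mods_data$test))
  pdata_m <- if (!is.null(pretrain_data))
    list(train = mask(pretrain_data$train),
         validation = mask(pretrain_data$validation))
  fit <- fit_variant(spec, data_m, pdata_m, config = config, sizes = sizes,
                     seed = seed)
  probs <- predict_risks(fit, data_m$test)
  out <- do.call(rbind, lapply(seq_along(horiz), function(k)
    data.frame(subset = subset, horizon = horiz[k],
               auc = compute_auc(probs[, k], data_m$test$y[, k]),
               acc = threshold_metrics(probs[, k],
                                       data_m$test$y[, k])$acc,
               n_features = length(keep_vars))))
  rownames(out) <- NULL
  out
}
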