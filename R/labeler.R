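# Rolling-window sample construction and multi-horizon MODS labeling.
#
# Every evaluation time t_k sees only data from the observation window
# (t_k - 4, t_k]  (half-open on the left, closed on the right) and is asked
# whether MODS onset falls in (t_k, t_k + h] for h in {6, 12, 24}. Windows
# where MODS is already present (T_MODS <= t_k) are excluded everywhere to
# avoid label leakage.

HORIZONS_H <- c(6L, 12L, 24L)
OBS_WINDOW_H <- 4L
MORTALITY_CUTOFF_H <- 720  # 30 days after ICU admission

#' Enumerate evaluation times for a stay
#'
#' Evaluation times run at an hourly stride from the first hour with a full
#' 4-h observation history up to the last whole hour of the stay.
#'
#' @param icu_los_h ICU length of stay in hours (a `cohort_table` stay row
#'   may be passed instead).
#' @param stride_h stride between consecutive evaluation times (hours).
#' @return integer vector of evaluation hours (possibly empty).
#' @export
enumerate_eval_times <- function(icu_los_h, stride_h = 1L) {
  if (is.data.frame(icu_los_h)) icu_los_h <- icu_los_h$icu_los_h
  last <- floor(icu_los_h)
  if (last < OBS_WINDOW_H) return(integer(0))
  as.integer(seq(OBS_WINDOW_H, last, by = stride_h))
}

#' Multi-horizon MODS labels for evaluation times
#'
#' For each horizon h, `y_h = 1` exactly when `t_k < T_MODS <= t_k + h`;
#' `y_h = 0` when onset falls beyond the horizon or never occurs in the
#' available follow-up. Windows with `T_MODS <= t_k` are flagged excluded.
#' The horizons are nested, so `y6 <= y12 <= y24` always holds.
#'
#' @param t_k vector of evaluation hours.
#' @param t_mods_h MODS onset hour (scalar or vector recycled against
#'   `t_k`); `NA` when MODS never occurred.
#' @param horizons prediction horizons in hours.
#' @return data.frame with one 0/1 column per horizon (`y6`, `y12`, `y24`)
#'   and a logical `excluded` column.
#' @export
assign_mods_labels <- function(t_k, t_mods_h, horizons = HORIZONS_H) {
  t_mods_h <- rep_len(t_mods_h, length(t_k))
  ys <- lapply(horizons, function(h) {
    as.integer(!is.na(t_mods_h) & t_k < t_mods_h & t_mods_h <= t_k + h)
  })
  names(ys) <- paste0("y", horizons)
  out <- as.data.frame(ys)
  out$excluded <- !is.na(t_mods_h) & t_mods_h <= t_k
  out
}

#' 30-day mortality label
#'
#' @param death_time_h hours from ICU admission to death (`NA` = survived);
#'   a stay manifest data.frame may be passed instead.
#' @return integer 0/1 vector: 1 when death occurred within 720 h of ICU
#'   admission.
#' @export
assign_mortality_label <- function(death_time_h) {
  if (is.data.frame(death_time_h)) death_time_h <- death_time_h$death_time_h
  as.integer(!is.na(death_time_h) & death_time_h <= MORTALITY_CUTOFF_H)
}

# gender encoding used in the low-frequency vector: the first component of
# the {male, female} one-hot pair (the second is collinear and dropped)
encode_gender <- function(gender) {
  v <- tolower(as.character(gender))
  bad <- !(v %in% c("male", "female", "m", "f"))
  if (any(bad)) stop("unknown gender category: ",
                     paste(unique(gender[bad]), collapse = ", "),
                     " (expected male/female)")
  vapply(v, function(g) onehot(if (g %in% c("male", "m")) "male" else "female",
                               c("male", "female"))[1L], numeric(1),
         USE.NAMES = FALSE)
}

#' Extract raw observation windows for a set of evaluation times
#'
#' Builds, for every (stay, t_k) pair, the 4 x 7 high-frequency block
#' (hourly means of the seven vitals over the four bins of
#' `(t_k - 4, t_k]`; events at exactly `t_k - 4` are excluded, at exactly
#' `t_k` included) and the 34-entry low-frequency vector (most recent value
#' at or before t_k within each variable's lookback, plus age and gender
#' from the manifest). Values are plausibility-clipped first; empty bins and
#' unobserved variables are `NA` until imputation.
#'
#' @param cohort a `cohort_table`.
#' @param pairs data.frame with columns `stay_id` and `t_k`; defaults to all
#'   evaluation times of every stay.
#' @param registry feature registry.
#' @param stride_h stride used when `pairs` is derived automatically.
#' @return an object of class `window_set`: list with `X_hf` (n x 28 matrix,
#'   columns grouped by variable as `VAR_1 .. VAR_4`), `X_lo` (n x 34
#'   matrix), `meta` (stay_id, t_k), `hf_vars`, `lo_vars`.
#' @export
extract_windows <- function(cohort, pairs = NULL,
                            registry = feature_registry(), stride_h = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  stays <- cohort$stays
  if (is.null(pairs)) {
    tks <- lapply(seq_len(nrow(stays)), function(i)
      enumerate_eval_times(stays$icu_los_h[i], stride_h))
    pairs <- data.frame(
      stay_id = rep(stays$stay_id, lengths(tks)),
      t_k = unlist(tks, use.names = FALSE))
  }
  if (nrow(pairs) == 0L) stop("no evaluation times to extract")

  hf_vars <- high_frequency_vars(registry)
  lo_all <- low_frequency_vars(registry)
  lo_event_vars <- setdiff(lo_all, c("Age", "Gender"))

  ev <- data.table::as.data.table(cohort$events)
  # plausibility clipping once, per variable
  ev[, value := clip_to_plausible(value, variable[1L], registry),
     by = "variable"]
  ev <- ev[is.finite(value)]

  P <- data.table::as.data.table(pairs[, c("stay_id", "t_k")])
  P[, row := .I]
  n <- nrow(P)

  # ---- high-frequency block: hourly-bin means over (t_k - 4, t_k] ----
  X_hf <- matrix(NA_real_, n, 4L * length(hf_vars),
                 dimnames = list(NULL, paste0(rep(hf_vars, each = 4L), "_", 1:4)))
  hf <- ev[variable %in% hf_vars]
  if (nrow(hf) > 0L) {
    Pj <- data.table::copy(P)
    Pj[, `:=`(lo = t_k - OBS_WINDOW_H, hi = t_k)]
    j <- hf[Pj, on = .(stay_id, time_h > lo, time_h <= hi),
            .(row = i.row, variable = x.variable, t = x.time_h,
              lo = i.lo, value = x.value),
            nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(j) > 0L) {
      j[, bin := pmin(pmax(ceiling(t - lo), 1L), 4L)]
      agg <- j[, .(m = mean(value)), by = .(row, variable, bin)]
      col <- match(paste0(agg$variable, "_", agg$bin), colnames(X_hf))
      X_hf[cbind(agg$row, col)] <- agg$m
    }
  }

  # ---- low-frequency vector: LOCF at t_k within lookback ----
  X_lo <- matrix(NA_real_, n, length(lo_all),
                 dimnames = list(NULL, lo_all))
  lo <- ev[variable %in% lo_event_vars]
  if (nrow(lo) > 0L) {
    data.table::setkey(lo, stay_id, variable, time_h)
    Q <- P[, .(stay_id, row, t_k)][
      , .(variable = lo_event_vars, row = row, time_h = t_k), by = .(stay_id, t_k)]
    data.table::setkey(Q, stay_id, variable, time_h)
    hitcols <- lo[Q, on = .(stay_id, variable, time_h), roll = Inf,
                  .(row = i.row, variable = i.variable, t_k = i.time_h,
                    t_obs = x.time_h, value = x.value)]
    lb <- registry$lookback_h[match(hitcols$variable, registry$variable)]
    ok <- !is.na(hitcols$value) & (hitcols$t_k - hitcols$t_obs) <= lb
    hit <- hitcols[ok]
    if (nrow(hit) > 0L)
      X_lo[cbind(hit$row, match(hit$variable, lo_all))] <- hit$value
  }
  # demographics from the manifest
  si <- match(P$stay_id, stays$stay_id)
  if ("Age" %in% lo_all) X_lo[, "Age"] <- stays$age[si]
  if ("Gender" %in% lo_all) X_lo[, "Gender"] <- encode_gender(stays$gender)[si]

  structure(list(X_hf = X_hf, X_lo = X_lo,
                 meta = data.frame(stay_id = P$stay_id, t_k = P$t_k),
                 hf_vars = hf_vars, lo_vars = lo_all),
            class = "window_set")
}

#' Extract a single observation window
#'
#' @inheritParams extract_windows
#' @param stay_id stay identifier.
#' @param t_k evaluation hour (must be at least 4).
#' @return a `window_set` with one sample.
#' @export
extract_window <- function(cohort, stay_id, t_k,
                           registry = feature_registry()) {
  if (t_k < OBS_WINDOW_H) stop("t_k must be >= ", OBS_WINDOW_H,
                               " so the observation window is complete")
  extract_windows(cohort, data.frame(stay_id = stay_id, t_k = t_k), registry)
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", nrow(x$X_hf), " samples; block ",
      length(x$hf_vars), "x4 + vector ", length(x$lo_vars), sep = "")
  if (!is.null(x$y)) cat("; task:", attr(x, "task") %||% "labeled")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_window_set <- function(ws, idx) {
  out <- ws
  out$X_hf <- ws$X_hf[idx, , drop = FALSE]
  out$X_lo <- ws$X_lo[idx, , drop = FALSE]
  out$meta <- ws$meta[idx, , drop = FALSE]
  if (!is.null(ws$y)) out$y <- ws$y[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Patient-level train / validation / test split and labeling
#'
#' Splits stays (never windows) into train, validation and test partitions,
#' extracts all observation windows and attaches labels. For the `mods`
#' task, labels are the three-horizon onset indicators derived from each
#' stay's MODS onset time (computed by the SOFA engine unless supplied) and
#' windows with `T_MODS <= t_k` are dropped. For the `mortality` task every
#' window of a stay carries the stay's 30-day mortality label.
#'
#' @param cohort a `cohort_table`.
#' @param task `"mods"` or `"mortality"`.
#' @param test_fraction fraction of patients held out for testing.
#' @param val_fraction fraction of the remaining training patients carved
#'   out for validation / early stopping.
#' @param seed integer seed controlling the patient shuffle.
#' @param registry feature registry.
#' @param onsets optional data.frame `stay_id`, `t_mods_h` overriding the
#'   engine-derived onsets (e.g. simulator ground truth).
#' @param stride_h evaluation-time stride.
#' @param max_windows_per_stay optional cap: at most this many windows are
#'   sampled (seed-controlled) from each stay, to bound dataset size in
#'   large pre-training pools.
#' @return list of class `dataset_split` with `window_set` elements `train`,
#'   `validation`, `test`, each carrying a label matrix `y`.
#' @export
build_dataset <- function(cohort, task = c("mods", "mortality"),
                          test_fraction = 0.2, val_fraction = 0.2,
                          seed = 42L, registry = feature_registry(),
                          onsets = NULL, stride_h = 1L,
                          max_windows_per_stay = Inf) {
  task <- match.arg(task)
  stays <- cohort$stays
  if (nrow(stays) < 3L) stop("need at least 3 patients to split")

  ids <- with_seed(seed, sample(stays$stay_id))
  n_test <- max(1L, round(length(ids) * test_fraction))
  test_ids <- ids[seq_len(n_test)]
  rest <- ids[-seq_len(n_test)]
  n_val <- max(1L, round(length(rest) * val_fraction))
  val_ids <- rest[seq_len(n_val)]
  train_ids <- rest[-seq_len(n_val)]

  if (task == "mods" && is.null(onsets)) {
    sm <- cohort_sofa_summary(cohort, registry)
    onsets <- sm[, c("stay_id", "t_mods_h")]
  }

  build_part <- function(part_ids, part_seed) {
    sub <- subset_cohort(cohort, stays$stay_id %in% part_ids, cohort$role)
    tks <- lapply(seq_len(nrow(sub$stays)), function(i)
      enumerate_eval_times(sub$stays$icu_los_h[i], stride_h))
    if (is.finite(max_windows_per_stay)) {
      tks <- with_seed(part_seed, lapply(tks, function(tk) {
        if (length(tk) <= max_windows_per_stay) tk
        else sort(sample(tk, max_windows_per_stay))
      }))
    }
    pairs <- data.frame(stay_id = rep(sub$stays$stay_id, lengths(tks)),
                        t_k = unlist(tks, use.names = FALSE))
    if (nrow(pairs) == 0L) stop("partition has no evaluation times")
    ws <- extract_windows(sub, pairs, registry = registry)
    if (task == "mods") {
      tm <- onsets$t_mods_h[match(ws$meta$stay_id, onsets$stay_id)]
      lab <- assign_mods_labels(ws$meta$t_k, tm)
      ws <- subset_window_set(ws, !lab$excluded)
      lab <- lab[!lab$excluded, , drop = FALSE]
      ws$y <- as.matrix(lab[, paste0("y", HORIZONS_H)])
    } else {
      ml <- assign_mortality_label(stays$death_time_h[
        match(ws$meta$stay_id, stays$stay_id)])
      ws$y <- matrix(ml, ncol = 1L, dimnames = list(NULL, "mortality"))
    }
    rownames(ws$y) <- NULL
    attr(ws, "task") <- task
    ws
  }

  out <- list(train = build_part(train_ids, seed + 1L),
              validation = build_part(val_ids, seed + 2L),
              test = build_part(test_ids, seed + 3L))
  attr(out, "task") <- task
  attr(out, "stay_ids") <- list(train = train_ids, validation = val_ids,
                                test = test_ids)
  class(out) <- "dataset_split"
  out
}

#' Export a labeled window set to CSV
#'
#' One row per sample; the high-frequency block is flattened variable-major
#' (`VAR_1 .. VAR_4` per variable) followed by the low-frequency vector and
#' the labels.
#'
#' @param ws a `window_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_windows <- function(ws, path) {
  df <- cbind(ws$meta, as.data.frame(ws$X_hf), as.data.frame(ws$X_lo))
  if (!is.null(ws$y)) df <- cbind(df, as.data.frame(ws$y))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
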