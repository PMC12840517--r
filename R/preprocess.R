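# Plausibility clipping, imputation, Z-score normalization and the
# high-/low-frequency feature split.
#
# Normalization statistics are fitted on the TRAINING partition only and
# stamped with a fingerprint of the stays they were fitted on, so leakage
# into validation/test statistics is detectable.

#' Plausibility clipping
#'
#' Values outside a variable's registry range `[low, high]` are treated as
#' invalid chart entries and set to missing; in-range values pass through
#' unchanged.
#'
#' @param value numeric vector of raw values.
#' @param variable registry variable name.
#' @param registry feature registry.
#' @return numeric vector with implausible entries replaced by `NA`.
#' @export
clip_to_plausible <- function(value, variable, registry = feature_registry()) {
  i <- match(variable, registry$variable)
  if (is.na(i)) stop("unknown variable: ", variable)
  lo <- registry$low[i]; hi <- registry$high[i]
  if (is.na(lo) || is.na(hi)) return(value)  # categorical: no numeric range
  out <- as.numeric(value)
  out[!is.na(out) & (out < lo | out > hi)] <- NA_real_
  out
}

#' Z-score standardization
#'
#' `z = (x - mu) / alpha` with `mu` the training mean and `alpha` the
#' training standard deviation.
#'
#' @param x numeric vector.
#' @param mu training mean.
#' @param alpha training standard deviation; must be positive.
#' @return standardized values.
#' @export
zscore <- function(x, mu, alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  (x - mu) / alpha
}

#' One-hot encoding
#'
#' @param category a single category value.
#' @param vocabulary character vector of permitted categories.
#' @return a named 0/1 indicator vector with a single 1 at the category's
#'   position.
#' @export
onehot <- function(category, vocabulary) {
  i <- match(category, vocabulary)
  if (is.na(i))
    stop("category '", category, "' not in vocabulary {",
         paste(vocabulary, collapse = ", "),
         "}; extend the vocabulary or recode the input")
  stats::setNames(as.numeric(seq_along(vocabulary) == i), vocabulary)
}

#' Fit normalization and imputation statistics on a training window set
#'
#' Computes, per registry variable, the training mean used for imputation,
#' and per design-matrix column, the post-imputation mean and standard
#' deviation used for Z-scoring. Variables with a `physiologic_default`
#' imputation policy (vasoactive doses, FiO2) are filled with their default
#' rather than the mean. Zero-variance columns receive `alpha = 1` with a
#' warning. Binary columns (gender) are excluded from Z-scoring.
#'
#' @param train_ws the TRAINING `window_set` (raw, possibly with `NA`s).
#' @param registry feature registry.
#' @return an object of class `norm_stats` with elements `impute_mean`
#'   (per variable), `mu`/`alpha` (per column), `continuous` (per-column
#'   flag), and `fingerprint` identifying the fitting partition.
#' @export
fit_normalization_stats <- function(train_ws, registry = feature_registry()) {
  stopifnot(inherits(train_ws, "window_set"))
  cols_hf <- colnames(train_ws$X_hf)
  cols_lo <- colnames(train_ws$X_lo)
  var_of_col <- c(sub("_[1-4]$", "", cols_hf), cols_lo)

  # per-variable imputation values
  vars <- unique(var_of_col)
  impute_mean <- vapply(vars, function(v) {
    i <- match(v, registry$variable)
    if (!is.na(i) && registry$imputation[i] == "physiologic_default" &&
        !is.na(registry$default[i]))
      return(registry$default[i])
    cols <- which(var_of_col == v)
    X <- cbind(train_ws$X_hf, train_ws$X_lo)[, cols, drop = FALSE]
    m <- mean(X, na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    m
  }, numeric(1))

  # per-column post-imputation moments
  X <- cbind(train_ws$X_hf, train_ws$X_lo)
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- impute_mean[[var_of_col[j]]]
  }
  continuous <- var_of_col != "Gender"
  mu <- colMeans(X)
  alpha <- apply(X, 2, stats::sd)
  zero_var <- continuous & (!is.finite(alpha) | alpha <= 0)
  if (any(zero_var)) {
    warning("zero-variance column(s) given alpha = 1: ",
            paste(colnames(X)[zero_var], collapse = ", "))
    alpha[zero_var] <- 1
  }
  mu[!continuous] <- 0
  alpha[!continuous | !is.finite(alpha) | alpha <= 0] <- 1

  structure(list(impute_mean = impute_mean, mu = mu, alpha = alpha,
                 continuous = continuous, var_of_col = var_of_col,
                 n_hf = length(cols_hf),
                 fingerprint = paste0("train:",
                                      length(unique(train_ws$meta$stay_id)),
                                      "stays:", nrow(X), "rows")),
            class = "norm_stats")
}

#' Impute missing values in a window set
#'
#' Missing physiological measurements are replaced by the training mean of
#' their variable; variables with a physiologic default (drug doses -> 0,
#' FiO2 -> 21) get that default. Idempotent: a fully observed set passes
#' through unchanged.
#'
#' @param ws a `window_set`.
#' @param stats `norm_stats` fitted on the training partition.
#' @return the window set with no remaining missing values.
#' @export
impute_windows <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "norm_stats"))
  fill <- function(X, offset) {
    for (j in seq_len(ncol(X))) {
      v <- stats$var_of_col[offset + j]
      if (!v %in% names(stats$impute_mean))
        stop("no imputation statistic for variable: ", v)
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- stats$impute_mean[[v]]
    }
    X
  }
  ws$X_hf <- fill(ws$X_hf, 0L)
  ws$X_lo <- fill(ws$X_lo, stats$n_hf)
  ws
}

#' Apply imputation and Z-score normalization
#'
#' @param ws a `window_set` (any partition).
#' @param stats `norm_stats` fitted on the TRAINING partition.
#' @return the window set with finite, standardized feature matrices.
#' @export
preprocess_windows <- function(ws, stats) {
  ws <- impute_windows(ws, stats)
  nh <- stats$n_hf
  ws$X_hf <- sweep(sweep(ws$X_hf, 2, stats$mu[seq_len(nh)]), 2,
                   stats$alpha[seq_len(nh)], "/")
  lo_idx <- nh + seq_len(ncol(ws$X_lo))
  ws$X_lo <- sweep(sweep(ws$X_lo, 2, stats$mu[lo_idx]), 2,
                   stats$alpha[lo_idx], "/")
  attr(ws, "preprocessed") <- stats$fingerprint
  ws
}

#' Split a sample into its high- and low-frequency components
#'
#' Returns the 4 x 7 sequential block (rows = window hours, columns = the
#' seven vitals) and the 34-entry static vector for one sample, enforcing
#' the tier counts the architecture expects.
#'
#' @param ws a `window_set`.
#' @param i sample index.
#' @param registry feature registry.
#' @return list with `high_block` (4 x 7 matrix) and `low_vector` (length
#'   34, named).
#' @export
split_frequencies <- function(ws, i = 1L, registry = feature_registry()) {
  hf <- high_frequency_vars(registry)
  lo <- low_frequency_vars(registry)
  if (length(hf) != 7L || length(lo) != 34L)
    stop("registry tier counts must be (7, 34), found (",
         length(hf), ", ", length(lo), ")")
  block <- matrix(ws$X_hf[i, ], nrow = 4L, ncol = 7L,
                  dimnames = list(paste0("hour", 1:4), hf))
  list(high_block = block,
       low_vector = stats::setNames(ws$X_lo[i, ], colnames(ws$X_lo)))
}

#' Serialize normalization statistics to JSON
#'
#' @param stats a `norm_stats` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(
    list(impute_mean = as.list(stats$impute_mean),
         mu = as.list(stats$mu), alpha = as.list(stats$alpha),
         fingerprint = stats$fingerprint),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
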