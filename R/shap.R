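# Shapley-value feature attributions.
#
# Estimator: permutation sampling (Castro / Strumbelj-Kononenko). For each
# sampled permutation the marginal contributions telescope, so the sum of
# attributions equals f(x) minus the mean background prediction EXACTLY,
# giving the additivity (local accuracy) guarantee by construction rather
# than by normalization. Attributions are computed per horizon on the
# probability scale.

# flatten one window sample into the 62 input components:
# 28 high-frequency hour-slots (VAR_1..VAR_4) then the 34 static features
flatten_sample <- function(ws, i) {
  c(ws$X_hf[i, ], ws$X_lo[i, ])
}

unflatten_matrix <- function(Z, ws_template) {
  nh <- ncol(ws_template$X_hf)
  out <- ws_template
  out$X_hf <- Z[, seq_len(nh), drop = FALSE]
  out$X_lo <- Z[, nh + seq_len(ncol(ws_template$X_lo)), drop = FALSE]
  out$meta <- data.frame(stay_id = rep("synthetic", nrow(Z)),
                         t_k = rep(0, nrow(Z)))
  out$y <- NULL
  out
}

#' Shapley attributions for one prediction
#'
#' Explains a single window's predicted risk for one horizon against a
#' background set, using sampling-based Shapley value estimation over all
#' 62 input components (28 vital-sign hour-slots plus the 34 low-frequency
#' features). Each of `n_perm` permutations is paired with one background
#' sample (cycled); the attribution of a component is the average change in
#' model output when that component switches from the background value to
#' the explained value, in permutation order. By telescoping,
#' `base_value + sum(phi) == f_x` exactly.
#'
#' @param model a `trained_model`, a `mods_net`, or a plain function
#'   mapping a flattened input matrix (one row per point, 62 columns) to a
#'   numeric output vector (useful for validating the estimator against
#'   models with known Shapley values).
#' @param background_ws preprocessed `window_set` of background samples
#'   (typically ~100 training windows).
#' @param sample_ws preprocessed `window_set` holding the case to explain.
#' @param i row of `sample_ws` to explain.
#' @param horizon 6, 12 or 24 (ignored for mortality models).
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed for permutation and background sampling.
#' @return object of class `case_explanation`: list with `f_x`,
#'   `base_value`, `horizon`, and `records` (feature, value, phi) sorted by
#'   `|phi|` descending.
#' @export
compute_attributions <- function(model, background_ws, sample_ws, i = 1L,
                                 horizon = 6L, n_perm = 25L, seed = 1L) {
  nb <- nrow(background_ws$X_hf)
  if (nb < 1L) stop("background set is empty")
  x <- flatten_sample(sample_ws, i)
  d <- length(x)
  feat_names <- c(colnames(sample_ws$X_hf), colnames(sample_ws$X_lo))

  if (is.function(model)) {
    f_eval <- function(Z) model(Z)
  } else {
    net <- if (inherits(model, "trained_model")) model$net else model
    col <- if (net$task == "mods") match(paste0("y", horizon),
                                         paste0("y", HORIZONS_H))
           else 1L
    if (is.na(col)) stop("horizon must be one of ",
                         paste(HORIZONS_H, collapse = ", "))
    f_eval <- function(Z) {
      ws <- unflatten_matrix(Z, sample_ws)
      predict_risks(net, ws)[, col]
    }
  }

  out <- with_seed(seed, {
    bg_idx <- ((seq_len(n_perm) - 1L) %% nb) + 1L
    # one big batch: for each permutation, the d+1 prefix points
    blocks <- vector("list", n_perm)
    perms <- vector("list", n_perm)
    for (p in seq_len(n_perm)) {
      perm <- sample.int(d)
      b <- flatten_sample(background_ws, bg_idx[p])
      pts <- matrix(b, d + 1L, d, byrow = TRUE)
      z <- b
      for (m in seq_len(d)) {
        z[perm[m]] <- x[perm[m]]
        pts[m + 1L, ] <- z
      }
      blocks[[p]] <- pts
      perms[[p]] <- perm
    }
    fv <- f_eval(do.call(rbind, blocks))
    phi <- numeric(d)
    base_acc <- 0
    for (p in seq_len(n_perm)) {
      off <- (p - 1L) * (d + 1L)
      fp <- fv[off + seq_len(d + 1L)]
      phi[perms[[p]]] <- phi[perms[[p]]] + diff(fp)
      base_acc <- base_acc + fp[1L]
    }
    list(phi = phi / n_perm, base_value = base_acc / n_perm)
  })

  f_x <- f_eval(matrix(x, 1L))
  records <- data.frame(feature = feat_names, value = unname(x),
                        phi = out$phi)
  records <- records[order(-abs(records$phi), records$feature), ]
  rownames(records) <- NULL
  structure(list(f_x = unname(f_x), base_value = out$base_value,
                 horizon = horizon, records = records, seed = seed),
            class = "case_explanation")
}

#' @export
print.case_explanation <- function(x, ...) {
  cat(sprintf("<case_explanation> horizon %dh  f(x) = %.4f  base = %.4f\n",
              x$horizon, x$f_x, x$base_value))
  print(utils::head(x$records, 5))
  invisible(x)
}

#' Global feature importance
#'
#' Mean absolute Shapley attribution per feature across a set of
#' explanations, descending; ties broken alphabetically.
#'
#' @param explanations list of `case_explanation` objects.
#' @return data.frame `feature`, `mean_abs_phi`, ranked.
#' @export
global_importance <- function(explanations) {
  if (length(explanations) < 1L) stop("need at least one explanation")
  phis <- sapply(explanations, function(e)
    e$records$phi[order(e$records$feature)])
  feats <- sort(explanations[[1]]$records$feature)
  imp <- rowMeans(abs(matrix(phis, nrow = length(feats))))
  out <- data.frame(feature = feats, mean_abs_phi = imp)
  out <- out[order(-out$mean_abs_phi, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Hourly attribution summary for the high-frequency block
#'
#' Mean absolute attribution of each vital sign at each hour of the 4-hour
#' observation window, across a set of explanations.
#'
#' @param explanations list of `case_explanation`s computed on 4 x 7
#'   windows.
#' @return a 7 x 4 matrix (variables x window hours) of mean `|phi|`.
#' @export
hourly_highfreq_summary <- function(explanations) {
  stopifnot(length(explanations) >= 1L)
  rec <- explanations[[1]]$records
  hf <- grepl("_[1-4]$", rec$feature)
  vars <- unique(sub("_[1-4]$", "", rec$feature[hf]))
  out <- matrix(0, length(vars), 4L,
                dimnames = list(vars, paste0("hour", 1:4)))
  for (v in vars) for (h in 1:4) {
    nm <- paste0(v, "_", h)
    vals <- vapply(explanations, function(e)
      abs(e$records$phi[match(nm, e$records$feature)]), numeric(1))
    out[v, h] <- mean(vals)
  }
  out
}

#' Force-style case report
#'
#' Lists the model output, the background expectation and the `top_k`
#' features by absolute attribution, marking each as risk-increasing
#' (`+`/arrow up) or risk-decreasing (`-`/arrow down).
#'
#' @param explanation a `case_explanation`.
#' @param top_k number of features to report (clamped to the total).
#' @return list with `f_x`, `base_value`, `horizon`, `top` (data.frame
#'   feature/value/phi/direction) and `text` (printable lines).
#' @export
case_report <- function(explanation, top_k = 10L) {
  if (top_k < 1L) stop("top_k must be at least 1")
  rec <- explanation$records
  top <- utils::head(rec, min(top_k, nrow(rec)))
  top$direction <- ifelse(top$phi >= 0, "risk-increasing", "risk-decreasing")
  text <- c(
    sprintf("f(x) = %.4f  (base value E[f(X)] = %.4f, horizon %d h)",
            explanation$f_x, explanation$base_value, explanation$horizon),
    sprintf("%-14s %9s  phi %+ .5f  %s",
            top$feature, formatC(top$value, digits = 3, format = "g"),
            top$phi, ifelse(top$phi >= 0, "^", "v")))
  list(f_x = explanation$f_x, base_value = explanation$base_value,
       horizon = explanation$horizon, top = top, text = text)
}

#' Serialize explanations to JSON
#'
#' @param explanations list of `case_explanation`s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_explanations <- function(explanations, path) {
  jsonlite::write_json(lapply(explanations, function(e)
    list(f_x = e$f_x, base_value = e$base_value, horizon = e$horizon,
         records = e$records)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
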