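# Dual-stream warning model: variant configuration, mortality pre-training,
# transfer to the three-horizon MODS task, training protocol and prediction.

VARIANT_NAMES <- c("PT-MLP.LSTM-eICU", "MLP.LSTM", "PT-LSTM-eICU",
                   "PT-MLP-eICU", "PT-MLP.LSTM")

#' Model variant specification
#'
#' The five ablation variants differ in whether mortality pre-training is
#' used, whether high- and low-frequency inputs are routed through separate
#' streams, which backbone carries a merged input, and which pool feeds
#' pre-training:
#'
#' * `PT-MLP.LSTM-eICU` — pre-trained on the combined pool; dual-stream.
#' * `MLP.LSTM` — trained from scratch on the target cohort; dual-stream.
#' * `PT-LSTM-eICU` — pre-trained; no separation; recurrent backbone over
#'   the merged 4 x 41 sequence (low-frequency values held constant per bin).
#' * `PT-MLP-eICU` — pre-trained; no separation; feed-forward backbone over
#'   the 41-vector (low-frequency features plus the vitals at window end).
#' * `PT-MLP.LSTM` — dual-stream, pre-trained on the primary pool only.
#'
#' A middle dot in a name may be written as `.` or `·`.
#'
#' @param name one of the five variant names.
#' @return list of class `variant_spec` with fields `name`, `pretrain`,
#'   `separation`, `backbone`, `pretrain_pool`.
#' @export
variant_spec <- function(name) {
  key <- gsub("·", ".", name)
  grid <- list(
    "PT-MLP.LSTM-eICU" = list(pretrain = TRUE,  separation = TRUE,
                              backbone = "dual", pretrain_pool = "combined"),
    "MLP.LSTM"         = list(pretrain = FALSE, separation = TRUE,
                              backbone = "dual", pretrain_pool = "none"),
    "PT-LSTM-eICU"     = list(pretrain = TRUE,  separation = FALSE,
                              backbone = "recurrent_only",
                              pretrain_pool = "combined"),
    "PT-MLP-eICU"      = list(pretrain = TRUE,  separation = FALSE,
                              backbone = "feedforward_only",
                              pretrain_pool = "combined"),
    "PT-MLP.LSTM"      = list(pretrain = TRUE,  separation = TRUE,
                              backbone = "dual", pretrain_pool = "primary_only"))
  if (!key %in% names(grid))
    stop("unknown variant '", name, "'; expected one of: ",
         paste(names(grid), collapse = ", "))
  structure(c(list(name = key), grid[[key]]), class = "variant_spec")
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: AdamW with learning
#' rate 1e-5 and weight decay 1e-3, batch size 4096 (clamped to the dataset
#' size for small cohorts), up to 300 epochs with early stopping at
#' patience 30 on the mean validation AUC across the three horizons, seed
#' 42. Desk-scale runs may pass smaller `max_epochs` / larger
#' `learning_rate`; the defaults are the protocol's reference values.
#'
#' @param learning_rate AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 1e-3,
                         batch_size = 4096L, max_epochs = 300L,
                         patience = 30L, seed = 42L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Multi-horizon binary cross-entropy loss
#'
#' The average, over samples and the three prediction horizons, of binary
#' cross-entropy computed directly on logits in the numerically stable
#' form `max(z, 0) - z * y + log(1 + exp(-|z|))`.
#'
#' @param logits numeric matrix (n x K) of model logits (a vector is
#'   treated as one sample).
#' @param labels 0/1 matrix conformable with `logits`.
#' @return scalar mean loss.
#' @export
multi_horizon_loss <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  stopifnot(all(dim(logits) == dim(labels)), all(labels %in% c(0, 1)))
  l <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  mean(l)
}

#' Build a pre-training (30-day mortality) network
#'
#' Constructs the variant's backbone with a single sigmoid mortality head:
#' the recurrent stream consumes the 4-step vital-sign block and the
#' feed-forward stream the static vector; their outputs are concatenated
#' and passed through a fully connected trunk with batch normalization.
#'
#' @param spec a [variant_spec()].
#' @param sizes layer sizes (see [default_net_sizes()]).
#' @param seed initialization seed.
#' @param d_hf,d_lo input dimensions (vitals per step, static vector).
#' @return a `mods_net` for the mortality task.
#' @export
build_pretrain_network <- function(spec, sizes = default_net_sizes(),
                                   seed = 42L, d_hf = 7L, d_lo = 34L) {
  build_network_core(spec$backbone, "mortality", sizes, seed, d_hf, d_lo)
}

#' Build a MODS network from scratch
#'
#' @inheritParams build_pretrain_network
#' @return a `mods_net` with a three-logit (6/12/24 h) head.
#' @export
build_mods_network <- function(spec, sizes = default_net_sizes(),
                               seed = 42L, d_hf = 7L, d_lo = 34L) {
  build_network_core(spec$backbone, "mods", sizes, seed, d_hf, d_lo)
}

#' Transfer pre-trained parameters into a MODS network
#'
#' Copies every pre-trained stream and trunk parameter verbatim as
#' initialization (the mortality output head is not part of the target
#' network) and appends freshly initialized fully connected layers with a
#' three-logit head for the 6/12/24-hour horizons.
#'
#' @param pretrained a trained mortality `mods_net` (or `trained_model`).
#' @param seed seed for the fresh head initialization.
#' @return a `mods_net` for the MODS task with transferred trunk weights.
#' @export
transfer_to_mods_network <- function(pretrained, seed = 42L) {
  if (inherits(pretrained, "trained_model")) pretrained <- pretrained$net
  stopifnot(inherits(pretrained, "mods_net"))
  if (pretrained$task != "mortality")
    stop("transfer source must be a mortality pre-training network")
  net <- pretrained
  net$task <- "mods"
  net$params$head <- with_seed(seed, init_head("mods", net$sizes)$head)
  net
}

# ordered row indices for one epoch's minibatches
epoch_batches <- function(n, batch_size, seed) {
  ord <- with_seed(seed, sample.int(n))
  bs <- min(batch_size, n)
  split(ord, ceiling(seq_along(ord) / bs))
}

#' Train a network
#'
#' Minibatch AdamW training with per-epoch evaluation on the validation
#' partition. The selection criterion is the mean validation AUC across the
#' network's outputs (the three horizons for MODS, the single mortality
#' output for pre-training); training stops when it fails to improve for
#' `patience` consecutive epochs, and the best checkpoint is retained.
#' Fully reproducible under a fixed config seed.
#'
#' @param net a `mods_net` (freshly built or transferred).
#' @param train_ws,val_ws preprocessed, labeled `window_set`s; the two must
#'   be patient-disjoint.
#' @param config a [train_config()].
#' @param freeze character vector of parameter groups (`"lstm"`, `"mlp"`,
#'   `"trunk"`) held fixed during this call; used for head-only warm-up
#'   phases of transfer fine-tuning.
#' @param verbose print per-epoch progress.
#' @return an object of class `trained_model`: list with `net` (best
#'   checkpoint), `history` (per-epoch loss and validation AUC),
#'   `best_epoch`, `config`.
#' @export
train_network <- function(net, train_ws, val_ws, config = train_config(),
                          freeze = character(), verbose = FALSE) {
  stopifnot(inherits(net, "mods_net"))
  n <- nrow(train_ws$X_hf)
  if (n == 0L) stop("empty training set")
  if (length(intersect(unique(train_ws$meta$stay_id),
                       unique(val_ws$meta$stay_id))) > 0L)
    stop("train and validation partitions share patients")
  y_tr <- train_ws$y
  inputs_val <- net_inputs(val_ws, net$backbone)
  y_val <- val_ws$y

  # a fresh (all-zero) output layer gets its bias set to the training base
  # rate, so probabilities start calibrated and AUC-driven model selection
  # does not freeze an uncalibrated scale
  out <- net$params$head$out
  if (all(out$W == 0) && all(out$b == 0)) {
    prev <- pmin(pmax(colMeans(y_tr), 0.02), 0.98)
    net$params$head$out$b <- stats::qlogis(prev)
  }

  opt <- adamw_init(net$params)
  val_score <- function(net) {
    fwd <- net_forward(net, inputs_val, training = FALSE)
    probs <- sigmoid(fwd$logits)
    aucs <- vapply(seq_len(ncol(probs)), function(k) {
      y <- y_val[, k]
      if (length(unique(y)) < 2L) return(NA_real_)
      compute_auc(probs[, k], y)
    }, numeric(1))
    if (all(is.na(aucs))) -multi_horizon_loss(fwd$logits, y_val)
    else mean(aucs, na.rm = TRUE)
  }
  # the incoming model is the epoch-0 baseline: training never returns a
  # checkpoint with worse validation score than its initialization
  best <- list(score = val_score(net), params = net$params, bn = net$bn,
               epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_auc = numeric())
  stall <- 0L

  inputs_all <- net_inputs(train_ws, net$backbone)
  take_rows <- function(inp, idx) {
    list(steps = if (!is.null(inp$steps))
                   lapply(inp$steps, function(S) S[idx, , drop = FALSE]),
         ff = if (!is.null(inp$ff)) inp$ff[idx, , drop = FALSE])
  }

  for (epoch in seq_len(config$max_epochs)) {
    batches <- epoch_batches(n, config$batch_size,
                             derive_seed(config$seed, epoch))
    ep_loss <- 0
    # a frozen trunk keeps its batch-norm in inference mode: its statistics
    # belong to the (frozen) body and must not drift with the new batches
    bn_training <- !("trunk" %in% freeze)
    for (idx in batches) {
      bi <- take_rows(inputs_all, idx)
      by <- y_tr[idx, , drop = FALSE]
      fwd <- net_forward(net, bi, training = bn_training)
      net$bn <- fwd$bn_running
      loss <- multi_horizon_loss(fwd$logits, by)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; inspect preprocessing or lower the learning rate")
      dlogits <- (sigmoid(fwd$logits) - by) / length(by)
      grads <- net_backward(net, fwd, dlogits)
      kept <- if (length(freeze)) net$params[freeze]
      st <- adamw_step(net$params, grads, opt,
                       config$learning_rate, config$weight_decay)
      net$params <- st$params
      if (length(freeze)) net$params[freeze] <- kept
      opt <- st$state
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / n

    score <- val_score(net)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_auc = score))
    if (verbose)
      log_msg(sprintf("epoch %3d  loss %.5f  val %.4f", epoch, ep_loss, score))
    if (score > best$score + 1e-12) {
      best <- list(score = score, params = net$params, bn = net$bn,
                   epoch = epoch)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience) break
  }

  net$params <- best$params
  net$bn <- best$bn
  structure(list(net = net, history = hist, best_epoch = best$epoch,
                 best_val = best$score, config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> task:", x$net$task, " backbone:", x$net$backbone,
      "\n  epochs:", nrow(x$history), " best:", x$best_epoch,
      sprintf(" (val %.4f)\n", x$best_val))
  invisible(x)
}

#' Two-stage fine-tuning schedule
#'
#' Standard transfer practice for a network whose body is initialized from
#' pre-training but whose task head is fresh: first train the head alone
#' (body parameters frozen) so the model's output reaches the quality its
#' body already supports, then refine the whole network at a small learning
#' rate so the transferred representation is adapted rather than
#' overwritten. The schedule itself carries no knowledge of how the body
#' was initialized, so it applies verbatim to a scratch-initialized network
#' when an initialization-controlled comparison is wanted.
#'
#' @param net a `mods_net`.
#' @param train_ws,val_ws preprocessed, patient-disjoint partitions.
#' @param head_config [train_config()] for the head-only warm-up stage.
#' @param config [train_config()] for the full-network stage.
#' @param verbose print per-epoch progress.
#' @return a `trained_model`; `history` carries a `stage` column.
#' @export
train_two_stage <- function(net, train_ws, val_ws,
                            head_config = train_config(),
                            config = train_config(), verbose = FALSE) {
  body <- intersect(c("lstm", "mlp", "trunk"), names(net$params))
  s1 <- train_network(net, train_ws, val_ws, head_config,
                      freeze = body, verbose = verbose)
  s2 <- train_network(s1$net, train_ws, val_ws, config, verbose = verbose)
  s1$history$stage <- 1L
  s2$history$stage <- 2L
  s2$history$epoch <- s2$history$epoch + nrow(s1$history)
  s2$history <- rbind(s1$history, s2$history)
  s2
}

#' Predict per-horizon risks
#'
#' @param model a `trained_model` or `mods_net`.
#' @param ws a preprocessed `window_set` (must have been normalized with
#'   the training statistics; raw sets with missing values are rejected).
#' @return matrix of probabilities in (0,1), one column per model output
#'   (`y6`, `y12`, `y24` for MODS; `mortality` for pre-training).
#' @export
predict_risks <- function(model, ws) {
  net <- if (inherits(model, "trained_model")) model$net else model
  stopifnot(inherits(net, "mods_net"))
  if (anyNA(ws$X_hf) || anyNA(ws$X_lo))
    stop("window set contains missing values; run preprocess_windows() ",
         "with the training statistics first")
  fwd <- net_forward(net, net_inputs(ws, net$backbone), training = FALSE)
  probs <- sigmoid(fwd$logits)
  colnames(probs) <- if (net$task == "mods") paste0("y", HORIZONS_H)
                     else "mortality"
  probs
}

#' Fit one variant end to end (pre-train, transfer, fine-tune)
#'
#' Runs the variant's full protocol: when the variant pre-trains, fits the
#' mortality network on the pre-training pool, transfers all parameters and
#' fine-tunes on the MODS cohort; otherwise trains the MODS network from
#' scratch. All partitions must already be preprocessed with the relevant
#' training statistics.
#'
#' @param spec a [variant_spec()].
#' @param mods_data list with preprocessed `train` / `validation`
#'   `window_set`s for the MODS task.
#' @param pretrain_data like `mods_data` but for the mortality task; may be
#'   `NULL` for non-pretrained variants. For `pretrain_pool =
#'   "primary_only"` pass the primary pool subset here.
#' @param config fine-tuning [train_config()].
#' @param pretrain_config pre-training config (defaults to `config`).
#' @param head_config optional [train_config()] for a head-only warm-up
#'   stage before full fine-tuning (see [train_two_stage()]); `NULL` means
#'   single-stage fine-tuning.
#' @param sizes layer sizes.
#' @param seed base seed (initialization offsets are derived from it).
#' @param verbose print progress.
#' @return a `trained_model` for the MODS task, with the pre-training
#'   history attached as attribute `pretrain_history` when applicable.
#' @export
fit_variant <- function(spec, mods_data, pretrain_data = NULL,
                        config = train_config(), pretrain_config = config,
                        head_config = NULL,
                        sizes = default_net_sizes(), seed = 42L,
                        verbose = FALSE) {
  stopifnot(inherits(spec, "variant_spec"))
  if (spec$pretrain) {
    if (is.null(pretrain_data))
      stop("variant ", spec$name, " requires a pre-training dataset")
    pnet <- build_pretrain_network(spec, sizes, seed = derive_seed(seed, 11L))
    pt <- train_network(pnet, pretrain_data$train, pretrain_data$validation,
                        pretrain_config, verbose = verbose)
    net <- transfer_to_mods_network(pt, seed = derive_seed(seed, 23L))
    fitted <- if (is.null(head_config))
      train_network(net, mods_data$train, mods_data$validation, config,
                    verbose = verbose)
    else
      train_two_stage(net, mods_data$train, mods_data$validation,
                      head_config, config, verbose = verbose)
    attr(fitted, "pretrain_history") <- pt$history
  } else {
    net <- build_mods_network(spec, sizes, seed = derive_seed(seed, 11L))
    fitted <- train_network(net, mods_data$train, mods_data$validation,
                            config, verbose = verbose)
  }
  fitted$variant <- spec$name
  fitted
}

#' Run the five-variant ablation
#'
#' Trains each requested variant under the shared protocol and evaluates it
#' on the shared test set, returning the component/performance comparison
#' grid.
#'
#' @param mods_data preprocessed MODS split (`train`, `validation`, `test`).
#' @param pretrain_data preprocessed mortality split for the combined pool.
#' @param pretrain_data_primary mortality split restricted to the primary
#'   pool, used by the `PT-MLP.LSTM` variant; defaults to `pretrain_data`.
#' @param variants variant names (default: all five).
#' @param config,pretrain_config,sizes,seed,verbose as in [fit_variant()].
#' @return data.frame with one row per variant: the component flags and the
#'   per-horizon and mean test AUCs; fitted models attached as attribute
#'   `models`.
#' @export
run_ablation <- function(mods_data, pretrain_data,
                         pretrain_data_primary = pretrain_data,
                         variants = VARIANT_NAMES,
                         config = train_config(),
                         pretrain_config = config,
                         sizes = default_net_sizes(), seed = 42L,
                         verbose = FALSE) {
  rows <- list(); models <- list()
  for (nm in variants) {
    spec <- variant_spec(nm)
    pdata <- if (!spec$pretrain) NULL
             else if (spec$pretrain_pool == "primary_only") pretrain_data_primary
             else pretrain_data
    if (verbose) log_msg("ablation: fitting ", spec$name)
    fit <- fit_variant(spec, mods_data, pdata, config, pretrain_config,
                       sizes, seed, verbose = FALSE)
    probs <- predict_risks(fit, mods_data$test)
    aucs <- vapply(seq_len(ncol(probs)), function(k)
      compute_auc(probs[, k], mods_data$test$y[, k]), numeric(1))
    rows[[nm]] <- data.frame(
      variant = spec$name, pretrain = spec$pretrain,
      separation = spec$separation, backbone = spec$backbone,
      pretrain_pool = spec$pretrain_pool,
      auc_6h = aucs[1], auc_12h = aucs[2], auc_24h = aucs[3],
      auc_mean = mean(aucs))
    models[[nm]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' @rdname build_pretrain_network
#' @export
default_net_sizes <- function() {
  list(lstm_hidden = 64L, mlp_hidden = c(128L, 64L),
       trunk = 64L, head_hidden = 32L)
}
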