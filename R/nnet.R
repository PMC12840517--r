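# Internal network core: a single-layer LSTM stream, a feed-forward (MLP)
# stream, a shared fully connected trunk with batch normalization, and task
# heads, with hand-derived backpropagation and an AdamW optimizer.
#
# All operations are dense matrix algebra on CPU (BLAS-backed), which is
# ample for 4-step sequences and desk-scale cohorts, and keeps training
# bit-reproducible under a fixed seed.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# ---- parameter initialization -------------------------------------------

init_lstm <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias init
  list(Wx = glorot(d_in, 4 * h), Wh = glorot(h, 4 * h), b = b)
}

init_mlp <- function(d_in, widths) {
  dims <- c(d_in, widths)
  lapply(seq_along(widths), function(i)
    list(W = glorot(dims[i], dims[i + 1]), b = numeric(dims[i + 1])))
}

# ---- forward passes ------------------------------------------------------

lstm_forward <- function(p, steps) {
  n <- nrow(steps[[1]]); h <- nrow(p$Wh)
  hs <- cs <- gates <- vector("list", length(steps))
  h_t <- c_t <- matrix(0, n, h)
  for (t in seq_along(steps)) {
    A <- steps[[t]] %*% p$Wx + h_t %*% p$Wh +
      matrix(p$b, n, 4 * h, byrow = TRUE)
    i <- sigmoid(A[, 1:h, drop = FALSE])
    f <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
    c_prev <- c_t
    c_t <- f * c_t + i * g
    h_t <- o * tanh(c_t)
    gates[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev)
    hs[[t]] <- h_t; cs[[t]] <- c_t
  }
  list(h_last = h_t, hs = hs, cs = cs, gates = gates, steps = steps)
}

lstm_backward <- function(p, cache, d_hlast) {
  h <- nrow(p$Wh); Tn <- length(cache$steps)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh_next <- d_hlast
  dc_next <- d_hlast * 0
  for (t in rev(seq_len(Tn))) {
    g <- cache$gates[[t]]
    c_t <- cache$cs[[t]]
    tanc <- tanh(c_t)
    dh <- dh_next
    do_ <- dh * tanc
    dc <- dc_next + dh * g$o * (1 - tanc^2)
    di <- dc * g$g; dg <- dc * g$i; df <- dc * g$c_prev
    dc_next <- dc * g$f
    dA <- cbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do_ * g$o * (1 - g$o))
    h_prev <- if (t > 1) cache$hs[[t - 1]] else matrix(0, nrow(dA), h)
    dWx <- dWx + crossprod(cache$steps[[t]], dA)
    dWh <- dWh + crossprod(h_prev, dA)
    db <- db + colSums(dA)
    dh_next <- dA %*% t(p$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    Z <- A %*% layers[[i]]$W + matrix(layers[[i]]$b, nrow(A),
                                      length(layers[[i]]$b), byrow = TRUE)
    A <- relu(Z)
    acts[[i]] <- list(input = if (i == 1) X else NULL, Z = Z, A = A)
  }
  list(out = A, acts = acts, X = X)
}

mlp_backward <- function(layers, cache, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    dZ <- dA * (cache$acts[[i]]$Z > 0)
    inp <- if (i == 1) cache$X else cache$acts[[i - 1]]$A
    grads[[i]] <- list(W = crossprod(inp, dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

BN_EPS <- 1e-5

bn_forward <- function(gamma, beta, Z, running, training, momentum = 0.1) {
  if (training) {
    mb <- colMeans(Z)
    vb <- colMeans(sweep(Z, 2, mb)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mb
    running$var <- (1 - momentum) * running$var + momentum * vb
  } else {
    mb <- running$mean; vb <- running$var
  }
  inv <- 1 / sqrt(vb + BN_EPS)
  Zn <- sweep(sweep(Z, 2, mb), 2, inv, "*")
  Y <- sweep(sweep(Zn, 2, gamma, "*"), 2, beta, "+")
  list(Y = Y, Zn = Zn, inv = inv, running = running, training = training)
}

bn_backward <- function(gamma, cache, dY) {
  dgamma <- colSums(dY * cache$Zn)
  dbeta <- colSums(dY)
  dZn <- sweep(dY, 2, gamma, "*")
  if (!cache$training) {
    # inference-mode normalization: the statistics are constants
    dZ <- sweep(dZn, 2, cache$inv, "*")
  } else {
    m1 <- colMeans(dZn)
    m2 <- colMeans(dZn * cache$Zn)
    dZ <- sweep(sweep(dZn, 2, m1) - sweep(cache$Zn, 2, m2, "*"),
                2, cache$inv, "*")
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# ---- network assembly ----------------------------------------------------

net_input_dims <- function(backbone, d_hf = 7L, d_lo = 34L) {
  switch(backbone,
         dual = list(seq_in = d_hf, ff_in = d_lo),
         recurrent_only = list(seq_in = d_hf + d_lo, ff_in = 0L),
         feedforward_only = list(seq_in = 0L, ff_in = d_hf + d_lo),
         stop("unknown backbone: ", backbone))
}

build_network_core <- function(backbone, task, sizes, seed,
                               d_hf = 7L, d_lo = 34L) {
  dims <- net_input_dims(backbone, d_hf, d_lo)
  with_seed(seed, {
    params <- list()
    concat <- 0L
    if (dims$seq_in > 0L) {
      params$lstm <- init_lstm(dims$seq_in, sizes$lstm_hidden)
      concat <- concat + sizes$lstm_hidden
    }
    if (dims$ff_in > 0L) {
      params$mlp <- init_mlp(dims$ff_in, sizes$mlp_hidden)
      concat <- concat + utils::tail(sizes$mlp_hidden, 1L)
    }
    params$trunk <- list(W = glorot(concat, sizes$trunk),
                         b = numeric(sizes$trunk),
                         gamma = rep(1, sizes$trunk),
                         beta = numeric(sizes$trunk))
    params <- c(params, init_head(task, sizes))
    structure(list(backbone = backbone, task = task, sizes = sizes,
                   dims = c(dims, list(d_hf = d_hf, d_lo = d_lo)),
                   params = params,
                   bn = list(mean = numeric(sizes$trunk),
                             var = rep(1, sizes$trunk)),
                   fingerprint = paste(backbone, sizes$lstm_hidden,
                                       paste(sizes$mlp_hidden, collapse = "x"),
                                       sizes$trunk, sep = "|")),
              class = "mods_net")
  })
}

# the output layer starts at zero so a freshly headed model begins at the
# base rate (logit 0) instead of a random function; hidden head layers are
# glorot-initialized and receive gradient as soon as the output layer moves
init_head <- function(task, sizes) {
  if (task == "mortality") {
    list(head = list(layers = NULL,
                     out = list(W = matrix(0, sizes$trunk, 1L),
                                b = numeric(1L))))
  } else {
    list(head = list(layers = init_mlp(sizes$trunk, sizes$head_hidden),
                     out = list(W = matrix(0, utils::tail(sizes$head_hidden, 1L), 3L),
                                b = numeric(3L))))
  }
}

# assemble the per-backbone input tensors from a preprocessed window_set
net_inputs <- function(ws, backbone) {
  n_var <- length(ws$hf_vars)
  step_cols <- function(t) (seq_len(n_var) - 1L) * 4L + t
  if (backbone == "dual") {
    steps <- lapply(1:4, function(t) ws$X_hf[, step_cols(t), drop = FALSE])
    list(steps = steps, ff = ws$X_lo)
  } else if (backbone == "recurrent_only") {
    # low-frequency values held constant within each bin
    steps <- lapply(1:4, function(t)
      cbind(ws$X_hf[, step_cols(t), drop = FALSE], ws$X_lo))
    list(steps = steps, ff = NULL)
  } else {
    # 34 low-frequency features plus the 7 vitals at the window end
    list(steps = NULL, ff = cbind(ws$X_lo, ws$X_hf[, step_cols(4L), drop = FALSE]))
  }
}

net_forward <- function(net, inputs, training = FALSE) {
  p <- net$params
  parts <- list(); caches <- list()
  if (!is.null(inputs$steps) && !is.null(p$lstm)) {
    caches$lstm <- lstm_forward(p$lstm, inputs$steps)
    parts <- c(parts, list(caches$lstm$h_last))
  }
  if (!is.null(inputs$ff) && !is.null(p$mlp)) {
    caches$mlp <- mlp_forward(p$mlp, inputs$ff)
    parts <- c(parts, list(caches$mlp$out))
  }
  C <- do.call(cbind, parts)
  Zt <- C %*% p$trunk$W + matrix(p$trunk$b, nrow(C), length(p$trunk$b),
                                 byrow = TRUE)
  bn <- bn_forward(p$trunk$gamma, p$trunk$beta, Zt, net$bn, training)
  At <- relu(bn$Y)
  head_cache <- NULL
  H <- At
  if (!is.null(p$head$layers)) {
    head_cache <- mlp_forward(p$head$layers, At)
    H <- head_cache$out
  }
  logits <- H %*% p$head$out$W + matrix(p$head$out$b, nrow(H),
                                        length(p$head$out$b), byrow = TRUE)
  list(logits = logits,
       cache = list(C = C, bn = bn, At = At, Y = bn$Y, H = H,
                    head = head_cache, sub = caches, inputs = inputs),
       bn_running = bn$running)
}

net_backward <- function(net, fwd, dlogits) {
  p <- net$params; cc <- fwd$cache
  g <- list()
  g$head <- list(out = list(W = crossprod(cc$H, dlogits),
                            b = colSums(dlogits)))
  dH <- dlogits %*% t(p$head$out$W)
  if (!is.null(p$head$layers)) {
    hb <- mlp_backward(p$head$layers, cc$head, dH)
    g$head$layers <- hb$grads
    dAt <- hb$dX
  } else dAt <- dH
  dY <- dAt * (cc$Y > 0)
  bb <- bn_backward(p$trunk$gamma, cc$bn, dY)
  g$trunk <- list(W = crossprod(cc$C, bb$dZ), b = colSums(bb$dZ),
                  gamma = bb$dgamma, beta = bb$dbeta)
  dC <- bb$dZ %*% t(p$trunk$W)
  off <- 0L
  if (!is.null(cc$sub$lstm)) {
    h <- nrow(p$lstm$Wh)
    g$lstm <- lstm_backward(p$lstm, cc$sub$lstm,
                            dC[, off + seq_len(h), drop = FALSE])
    off <- off + h
  }
  if (!is.null(cc$sub$mlp)) {
    m <- ncol(cc$sub$mlp$out)
    g$mlp <- mlp_backward(p$mlp, cc$sub$mlp,
                          dC[, off + seq_len(m), drop = FALSE])$grads
  }
  g
}

# ---- flat parameter traversal (optimizer, checksums, copying) ------------

walk_params <- function(params, path = character()) {
  if (is.numeric(params)) return(stats::setNames(list(params),
                                                 paste(path, collapse = "$")))
  out <- list()
  for (nm in names(params)) {
    if (is.null(params[[nm]])) next
    out <- c(out, walk_params(params[[nm]],
                              c(path, nm)))
  }
  out
}

# params lists are name-structured; traverse both params and a parallel
# structure (grads / optimizer state) applying f(leaf, leaf2)
map2_params <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in names(a)) {
    if (is.null(a[[nm]])) next
    out[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
  }
  out
}

zeros_like <- function(params) map2_params(params, params, function(a, b) a * 0)

params_checksum <- function(params)
  sum(vapply(walk_params(params), function(x) sum(abs(x)), numeric(1)))

# ---- AdamW ---------------------------------------------------------------

adamw_init <- function(params)
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u)
    p - lr * u - lr * weight_decay * p)
  list(params = params, state = state)
}
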