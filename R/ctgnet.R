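# Compact three-layer depthwise-separable convolutional classifier for
# two-channel 1 Hz CTG windows, with hand-rolled forward/backward passes
# and an Adam optimizer. The architecture is deliberately tiny (2130
# parameters at defaults): a temporal convolution bank, a depthwise
# convolution across the FHR/UC channel pair, and a separable temporal
# convolution, each followed by batch normalization, with ELU activations,
# average pooling, dropout, and a 2-class softmax head. Convolutions carry
# no biases (each is immediately batch-normalized).

#' CTG-net configuration
#'
#' Architecture and training hyperparameters. The convolution kernels span
#' 30 s at 1 Hz -- the window obstetricians read when classifying
#' decelerations. Filter counts sit in the 4--8 range; the default
#' combination (4 temporal filters, depth multiplier 2, 8 separable
#' filters, kernel 7, two 4-wide poolings) is the unique small
#' configuration whose closed-form parameter count is 2130.
#'
#' @param input_len Samples per channel (1800 = 30 min at 1 Hz).
#' @param n_channels Signal channels (2: FHR and UC).
#' @param k1 Temporal kernel length in samples.
#' @param f1 Temporal filters.
#' @param d Depthwise multiplier of the channel convolution.
#' @param k2 Separable (depthwise) kernel length.
#' @param f2 Separable pointwise filters.
#' @param pool1,pool2 Average-pooling widths.
#' @param dropout Dropout rate.
#' @param lr,adam_eps Adam learning rate and epsilon.
#' @param n_classes Output classes (2: normal / abnormal).
#' @param batch_size,epochs,patience Training schedule: minibatch size,
#'   epoch cap, and early-stopping patience on validation loss.
#' @param bn_momentum Momentum of the batch-norm moving statistics.
#' @param input_center,input_scale Fixed affine input transform: each
#'   channel enters the network as (value - center) / scale. The defaults
#'   center FHR at the 140 bpm mid-band and UC at a 20-unit resting tone,
#'   with a 20-unit spread, so both channels reach the shared temporal
#'   kernels on comparable, roughly unit scales. The constants are fixed
#'   (never estimated from data), so the transform is a reparameterization
#'   of the raw traces, and an input sitting exactly at the reference
#'   levels is the network's zero.
#' @return A list of class `ctgnet_config`.
#' @export
ctgnet_config <- function(input_len = 1800, n_channels = 2,
                          k1 = 30, f1 = 4, d = 2, k2 = 7, f2 = 8,
                          pool1 = 4, pool2 = 4, dropout = 0.25,
                          lr = 1e-3, adam_eps = 1e-5, n_classes = 2,
                          batch_size = 16, epochs = 300, patience = 20,
                          bn_momentum = 0.99,
                          input_center = c(fhr = 140, uc = 20),
                          input_scale = 20) {
  dims <- c(input_len, n_channels, k1, f1, d, k2, f2, pool1, pool2, n_classes)
  if (any(dims < 1)) rlang::abort("All architecture dimensions must be positive.")
  if (dropout < 0 || dropout >= 1) rlang::abort("`dropout` must be in [0, 1).")
  structure(
    list(
      input_len = input_len, n_channels = n_channels, k1 = k1, f1 = f1,
      d = d, k2 = k2, f2 = f2, pool1 = pool1, pool2 = pool2,
      dropout = dropout, lr = lr, adam_eps = adam_eps,
      n_classes = n_classes, batch_size = batch_size, epochs = epochs,
      patience = patience, bn_momentum = bn_momentum,
      input_center = input_center, input_scale = input_scale
    ),
    class = "ctgnet_config"
  )
}

#' Closed-form parameter count of the architecture
#'
#' Term by term: temporal convolution (`k1 * f1`, no bias), first batch
#' norm (4 per feature: scale, shift and the two moving statistics),
#' depthwise channel convolution (`n_channels * f1 * d`), second batch
#' norm, the separable convolution's depthwise (`k2 * f1 * d`) and
#' pointwise (`f1 * d * f2`) parts, third batch norm, and the dense head's
#' weights and biases over the `f2 * floor(floor(input_len / pool1) /
#' pool2)` flattened features. At defaults this is 2130 and always equals
#' the total introspected from a built model.
#'
#' @param config A [ctgnet_config()].
#' @return Integer parameter count.
#' @examples
#' ctgnet_param_count(ctgnet_config())
#' @export
ctgnet_param_count <- function(config) {
  with(config, {
    l2 <- (input_len %/% pool1) %/% pool2
    as.integer(
      k1 * f1 + 4 * f1 +
        n_channels * f1 * d + 4 * f1 * d +
        k2 * f1 * d + f1 * d * f2 + 4 * f2 +
        n_classes * (f2 * l2) + n_classes
    )
  })
}

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Build an untrained CTG-net
#'
#' Initializes all weights (Glorot-uniform convolutions and dense head,
#' unit-scale batch norms) under `seed`. The introspected parameter total
#' of the built model equals [ctgnet_param_count()] by construction and is
#' checked at build time.
#'
#' @param config A [ctgnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ctgnet`.
#' @export
build_ctgnet <- function(config, seed = 0) {
  withr::with_seed(seed, {
    f1 <- config$f1
    m1 <- config$f1 * config$d
    f2 <- config$f2
    l2 <- (config$input_len %/% config$pool1) %/% config$pool2
    bn <- function(k) list(
      gamma = rep(1, k), beta = rep(0, k),
      mean = rep(0, k), var = rep(1, k)
    )
    w <- list(
      W1 = matrix(glorot(config$k1 * f1, config$k1, f1 * config$k1), config$k1, f1),
      bn1 = bn(f1),
      Wd = array(
        glorot(config$n_channels * m1, config$n_channels, config$d),
        dim = c(config$n_channels, f1, config$d)
      ),
      bn2 = bn(m1),
      Wdw = matrix(glorot(config$k2 * m1, config$k2, config$k2), config$k2, m1),
      Wpw = matrix(glorot(m1 * f2, m1, f2), m1, f2),
      bn3 = bn(f2),
      Wfc = matrix(glorot(f2 * l2 * config$n_classes, f2 * l2, config$n_classes),
        f2 * l2, config$n_classes
      ),
      bfc = rep(0, config$n_classes)
    )
    model <- structure(
      list(config = config, weights = w, history = NULL),
      class = "ctgnet"
    )
    stopifnot(model_param_total(model) == ctgnet_param_count(config))
    model
  })
}

#' Introspected parameter total of a built model
#'
#' Sums the lengths of every weight tensor, including the batch-norm
#' moving statistics.
#'
#' @param model A `ctgnet` from [build_ctgnet()].
#' @return Integer parameter count.
#' @export
model_param_total <- function(model) {
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  as.integer(count(model$weights))
}

# ---- low-level numerical machinery ------------------------------------
#
# Activations are held as (B*T) x maps matrices with row index
# b + (t - 1) * B, so batch norm is column-wise, temporal shifts are row
# shifts by multiples of B, and pooling/flattening are array reshapes.
# Everything in the hot path is a BLAS call or a single vectorized op.

kernel_offsets <- function(k) (seq_len(k) - 1L) - (k - 1L) %/% 2L

# Column-wise broadcast helpers (avoid sweep()'s aperm overhead).
col_sub <- function(M, v) M - rep(v, each = nrow(M))
col_mul <- function(M, v) M * rep(v, each = nrow(M))
col_add <- function(M, v) M + rep(v, each = nrow(M))

# im2col for the temporal convolution bank: M is B x T, result (B*T) x k.
im2col <- function(M, k) {
  B <- nrow(M)
  T_ <- ncol(M)
  offsets <- kernel_offsets(k)
  Z <- matrix(0, B * T_, k)
  for (j in seq_len(k)) {
    s <- offsets[j]
    t0 <- max(1L, 1L - s)
    t1 <- min(T_, T_ - s)
    if (t0 <= t1) {
      rows <- ((t0 - 1L) * B + 1L):(t1 * B)
      Z[rows, j] <- as.vector(M[, (t0 + s):(t1 + s), drop = FALSE])
    }
  }
  Z
}

# Shift the time axis of a (B*T) x m stacked matrix by s samples
# (content moves toward earlier rows for positive s; zero fill).
time_shift <- function(X, s, B) {
  n <- nrow(X)
  sB <- s * B
  Y <- matrix(0, n, ncol(X))
  if (sB >= 0) {
    if (sB < n) Y[1:(n - sB), ] <- X[(1 + sB):n, , drop = FALSE]
  } else {
    if (-sB < n) Y[(1 - sB):n, ] <- X[1:(n + sB), , drop = FALSE]
  }
  Y
}

# Per-map same-padded temporal convolution: kernels W is k x m, X is
# (B*T) x m; each column convolved with its own kernel.
dw_conv <- function(X, W, B) {
  offsets <- kernel_offsets(nrow(W))
  Y <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(nrow(W))) {
    Y <- Y + col_mul(time_shift(X, offsets[j], B), W[j, ])
  }
  Y
}

dw_conv_dw <- function(X, dY, k, B) {
  offsets <- kernel_offsets(k)
  t(vapply(seq_len(k), function(j) {
    colSums(dY * time_shift(X, offsets[j], B))
  }, numeric(ncol(X))))
}

dw_conv_dx <- function(dY, W, B) {
  offsets <- kernel_offsets(nrow(W))
  dX <- matrix(0, nrow(dY), ncol(dY))
  for (j in seq_len(nrow(W))) {
    dX <- dX + col_mul(time_shift(dY, -offsets[j], B), W[j, ])
  }
  dX
}

# Non-overlapping average pooling along time; trailing samples that do
# not fill a window are dropped.
pool_fwd <- function(X, p, B) {
  m <- ncol(X)
  T_ <- nrow(X) / B
  T2 <- T_ %/% p
  big <- matrix(as.vector(X[seq_len(B * p * T2), , drop = FALSE]), B, p * T2 * m)
  acc <- big[, seq(1, p * T2 * m, by = p), drop = FALSE]
  for (i in 2:p) acc <- acc + big[, seq(i, p * T2 * m, by = p), drop = FALSE]
  matrix(as.vector(acc / p), B * T2, m)
}

pool_bwd <- function(dY, p, B, T_) {
  m <- ncol(dY)
  T2 <- nrow(dY) / B
  dbig <- matrix(0, B, p * T2 * m)
  dYbig <- matrix(as.vector(dY / p), B, T2 * m)
  for (i in seq_len(p)) dbig[, seq(i, p * T2 * m, by = p)] <- dYbig
  dX <- matrix(0, B * T_, m)
  dX[seq_len(B * p * T2), ] <- matrix(as.vector(dbig), B * p * T2, m)
  dX
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(y) { # in terms of the output
  g <- y + 1
  g[y > 0] <- 1
  g
}

BN_EPS <- 1e-3

# Column-wise batch normalization (one column per feature map).
bn_fwd <- function(M, bn, training) {
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- col_mul(col_sub(M, mu), inv)
  out <- col_add(col_mul(xhat, bn$gamma), bn$beta)
  list(out = out, xhat = xhat, inv = inv, mu = mu, var = v)
}

bn_bwd <- function(dout, cache, gamma) {
  n <- nrow(dout)
  sum_dy <- colSums(dout)
  sum_dyx <- colSums(dout * cache$xhat)
  dx <- col_sub(dout, sum_dy / n) - col_mul(cache$xhat, sum_dyx / n)
  dx <- col_mul(dx, gamma * cache$inv)
  list(dx = dx, dgamma = sum_dyx, dbeta = sum_dy)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# Full forward pass. X is a list(fhr = B x T, uc = B x T). Returns the
# cache needed for backprop when `training`.
ctgnet_forward <- function(model, X, training = FALSE, update_bn = FALSE) {
  cfg <- model$config
  w <- model$weights
  B <- nrow(X[[1]])
  T_ <- cfg$input_len
  f1 <- cfg$f1
  m1 <- cfg$f1 * cfg$d
  f2 <- cfg$f2
  drop_scale <- 1 / (1 - cfg$dropout)
  BT <- B * T_
  cache <- list(B = B)

  # temporal convolution bank (kernels shared across the two channel rows)
  cache$Z <- lapply(X, im2col, k = cfg$k1)
  Y1 <- cache$Z[[1]] %*% w$W1
  Y2 <- cache$Z[[2]] %*% w$W1

  # batch norm 1: statistics per temporal filter over both channel rows
  cache$bn1 <- bn_fwd(rbind(Y1, Y2), w$bn1, training)
  Hn1 <- cache$bn1$out[seq_len(BT), , drop = FALSE]
  Hn2 <- cache$bn1$out[BT + seq_len(BT), , drop = FALSE]
  cache$Hn1 <- Hn1
  cache$Hn2 <- Hn2

  # depthwise convolution across the channel pair, as selection matmuls
  A1 <- matrix(0, f1, m1)
  A2 <- matrix(0, f1, m1)
  for (f in seq_len(f1)) {
    for (j in seq_len(cfg$d)) {
      m <- (f - 1L) * cfg$d + j
      A1[f, m] <- w$Wd[1, f, j]
      A2[f, m] <- w$Wd[2, f, j]
    }
  }
  D <- Hn1 %*% A1 + Hn2 %*% A2

  cache$bn2 <- bn_fwd(D, w$bn2, training)
  Act1 <- elu(cache$bn2$out)
  cache$Act1 <- Act1
  P1 <- pool_fwd(Act1, cfg$pool1, B)
  if (training && cfg$dropout > 0) {
    cache$mask1 <- matrix(
      stats::rbinom(length(P1), 1, 1 - cfg$dropout), nrow(P1)
    ) * drop_scale
    P1 <- P1 * cache$mask1
  }
  cache$P1 <- P1

  # separable convolution: per-map temporal kernels then pointwise mixing
  Ddw <- dw_conv(P1, w$Wdw, B)
  cache$Ddw <- Ddw
  Pp <- Ddw %*% w$Wpw

  cache$bn3 <- bn_fwd(Pp, w$bn3, training)
  Act2 <- elu(cache$bn3$out)
  cache$Act2 <- Act2
  P2 <- pool_fwd(Act2, cfg$pool2, B)
  if (training && cfg$dropout > 0) {
    cache$mask2 <- matrix(
      stats::rbinom(length(P2), 1, 1 - cfg$dropout), nrow(P2)
    ) * drop_scale
    P2 <- P2 * cache$mask2
  }
  cache$P2 <- P2

  l2 <- nrow(P2) / B
  Flat <- matrix(as.vector(P2), B, l2 * f2)
  cache$Flat <- Flat
  logits <- col_add(Flat %*% w$Wfc, w$bfc)
  probs <- softmax_rows(logits)

  if (update_bn) {
    mom <- cfg$bn_momentum
    upd <- function(bn, cc) {
      bn$mean <- mom * bn$mean + (1 - mom) * cc$mu
      bn$var <- mom * bn$var + (1 - mom) * cc$var
      bn
    }
    model$weights$bn1 <- upd(model$weights$bn1, cache$bn1)
    model$weights$bn2 <- upd(model$weights$bn2, cache$bn2)
    model$weights$bn3 <- upd(model$weights$bn3, cache$bn3)
  }
  list(probs = probs, cache = cache, model = model)
}

# Backward pass from softmax cross-entropy. Yhot is B x n_classes.
ctgnet_backward <- function(model, fwd, Yhot) {
  cfg <- model$config
  w <- model$weights
  cache <- fwd$cache
  B <- cache$B
  f1 <- cfg$f1
  m1 <- cfg$f1 * cfg$d
  T_ <- cfg$input_len
  BT <- B * T_
  T1 <- nrow(cache$P1) / B
  l2 <- nrow(cache$P2) / B

  g <- list()
  dlogits <- (fwd$probs - Yhot) / B
  g$Wfc <- crossprod(cache$Flat, dlogits)
  g$bfc <- colSums(dlogits)
  dFlat <- tcrossprod(dlogits, w$Wfc)
  dP2 <- matrix(as.vector(dFlat), B * l2, cfg$f2)

  if (!is.null(cache$mask2)) dP2 <- dP2 * cache$mask2
  dAct2 <- pool_bwd(dP2, cfg$pool2, B, T1) * elu_grad(cache$Act2)
  bb3 <- bn_bwd(dAct2, cache$bn3, w$bn3$gamma)
  g$bn3 <- list(gamma = bb3$dgamma, beta = bb3$dbeta)
  dPp <- bb3$dx

  g$Wpw <- crossprod(cache$Ddw, dPp)
  dDdw <- tcrossprod(dPp, w$Wpw)
  g$Wdw <- dw_conv_dw(cache$P1, dDdw, cfg$k2, B)
  dP1 <- dw_conv_dx(dDdw, w$Wdw, B)

  if (!is.null(cache$mask1)) dP1 <- dP1 * cache$mask1
  dAct1 <- pool_bwd(dP1, cfg$pool1, B, T_) * elu_grad(cache$Act1)
  bb2 <- bn_bwd(dAct1, cache$bn2, w$bn2$gamma)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  dD <- bb2$dx

  # depthwise channel convolution
  A1 <- matrix(0, f1, m1)
  A2 <- matrix(0, f1, m1)
  for (f in seq_len(f1)) {
    for (j in seq_len(cfg$d)) {
      m <- (f - 1L) * cfg$d + j
      A1[f, m] <- w$Wd[1, f, j]
      A2[f, m] <- w$Wd[2, f, j]
    }
  }
  G1 <- crossprod(cache$Hn1, dD) # f1 x m1
  G2 <- crossprod(cache$Hn2, dD)
  g$Wd <- array(0, dim = dim(w$Wd))
  for (f in seq_len(f1)) {
    for (j in seq_len(cfg$d)) {
      m <- (f - 1L) * cfg$d + j
      g$Wd[1, f, j] <- G1[f, m]
      g$Wd[2, f, j] <- G2[f, m]
    }
  }
  dHn1 <- tcrossprod(dD, A1)
  dHn2 <- tcrossprod(dD, A2)

  bb1 <- bn_bwd(rbind(dHn1, dHn2), cache$bn1, w$bn1$gamma)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  dY1 <- bb1$dx[seq_len(BT), , drop = FALSE]
  dY2 <- bb1$dx[BT + seq_len(BT), , drop = FALSE]
  g$W1 <- crossprod(cache$Z[[1]], dY1) + crossprod(cache$Z[[2]], dY2)
  g
}

# Adam state and update over the nested weight/gradient structure. Batch
# norm moving statistics are not gradient-updated.
adam_init <- function(w) rapply(w, function(x) x * 0, how = "replace")

adam_step <- function(w, g, m, v, t, lr, eps, b1 = 0.9, b2 = 0.999) {
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      for (nm in names(w)) {
        if (is.null(g[[nm]])) next
        res <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        w[[nm]] <- res$w
        m[[nm]] <- res$m
        v[[nm]] <- res$v
      }
      return(list(w = w, m = m, v = v))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk(w, g, m, v)
}

# Convert traces (or a precomputed list) into the model input: a list of
# two B x input_len matrices, dropout imputed, 1 Hz enforced, channels
# passed through the config's fixed affine transform.
traces_to_input <- function(traces, config) {
  if (is.list(traces) && !is.null(traces$fhr)) {
    return(traces)
  }
  input_len <- config$input_len
  ctr <- config$input_center
  scl <- config$input_scale
  mats <- purrr::map(traces, function(tr) {
    assert_ctg_trace(tr)
    if (nrow(tr) != input_len) {
      rlang::abort(sprintf(
        "Model input must have exactly %d samples per channel (got %d).",
        input_len, nrow(tr)
      ))
    }
    tr <- impute_trace(tr)
    cbind(
      (tr$fhr_bpm - ctr[["fhr"]]) / scl,
      (tr$uc_units - ctr[["uc"]]) / scl
    )
  })
  list(
    fhr = t(vapply(mats, function(m) m[, 1], numeric(input_len))),
    uc = t(vapply(mats, function(m) m[, 2], numeric(input_len)))
  )
}

labels_to_onehot <- function(labels) {
  y <- factor(labels, levels = c("normal", "abnormal"))
  if (anyNA(y)) rlang::abort("Labels must be 'normal' or 'abnormal'.")
  cbind(normal = as.numeric(y == "normal"), abnormal = as.numeric(y == "abnormal"))
}

ce_loss <- function(probs, Yhot) {
  -mean(log(pmax(rowSums(probs * Yhot), 1e-12)))
}

#' Train CTG-net
#'
#' Minimizes categorical cross-entropy with Adam (learning rate and
#' epsilon from the config), seeded shuffling, dropout and weight
#' initialization, so identical seeds give identical loss histories.
#' Training stops early when validation loss has not improved for
#' `patience` epochs (when a validation set is supplied) and restores the
#' best-validation weights.
#'
#' @param model A `ctgnet` from [build_ctgnet()].
#' @param traces List of 1 Hz, `input_len`-sample [ctg_trace()]s (invalid
#'   samples are linearly interpolated).
#' @param labels Vector of `"normal"`/`"abnormal"` per trace.
#' @param validation Optional `list(traces =, labels =)` for early
#'   stopping.
#' @param epochs Override of the config's epoch cap.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print the loss every 10 epochs.
#' @return The trained `ctgnet`; `$history` holds a tibble of per-epoch
#'   losses, retrievable via [generics::tidy()].
#' @export
train_ctgnet <- function(model, traces, labels, validation = NULL,
                         epochs = NULL, seed = 0, verbose = FALSE) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  X <- traces_to_input(traces, cfg)
  Yhot <- labels_to_onehot(labels)
  n <- nrow(X$fhr)
  Xval <- NULL
  if (!is.null(validation)) {
    Xval <- traces_to_input(validation$traces, cfg)
    Yval <- labels_to_onehot(validation$labels)
  }
  withr::with_seed(seed, {
    m_st <- adam_init(model$weights)
    v_st <- adam_init(model$weights)
    t_step <- 0L
    history <- list()
    best_val <- Inf
    best_w <- NULL
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- list(fhr = X$fhr[idx, , drop = FALSE], uc = X$uc[idx, , drop = FALSE])
        Yb <- Yhot[idx, , drop = FALSE]
        fwd <- ctgnet_forward(model, Xb, training = TRUE, update_bn = TRUE)
        model <- fwd$model
        loss <- ce_loss(fwd$probs, Yb)
        if (!is.finite(loss)) {
          rlang::abort(sprintf("Non-finite training loss at epoch %d.", ep))
        }
        g <- ctgnet_backward(model, fwd, Yb)
        t_step <- t_step + 1L
        res <- adam_step(model$weights, g, m_st, v_st, t_step, cfg$lr, cfg$adam_eps)
        model$weights <- res$w
        m_st <- res$m
        v_st <- res$v
        ep_loss <- ep_loss + loss
        n_batches <- n_batches + 1L
      }
      ep_loss <- ep_loss / n_batches
      val_loss <- NA_real_
      if (!is.null(Xval)) {
        pv <- ctgnet_forward(model, Xval, training = FALSE)$probs
        val_loss <- ce_loss(pv, Yval)
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss, val_loss = val_loss)
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %3d  loss %.4f  val %.4f", ep, ep_loss, val_loss))
      }
      if (!is.null(Xval)) {
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss
          best_w <- model$weights
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (!is.null(best_w)) model$weights <- best_w
    model$history <- dplyr::bind_rows(history)
    model
  })
}

#' Score traces with a (trained) CTG-net
#'
#' Runs the network in inference mode (moving batch-norm statistics, no
#' dropout) and returns the two class probabilities; `abnormality` is the
#' probability of the abnormal class and is the score swept for ROC
#' curves.
#'
#' @param model A `ctgnet`.
#' @param traces A single [ctg_trace()] or a list of them (1 Hz,
#'   `input_len` samples each).
#' @return A tibble with columns `abnormality` and `normality` (rows sum
#'   to 1).
#' @export
score_abnormality <- function(model, traces) {
  if (inherits(traces, "ctg_trace")) traces <- list(traces)
  X <- traces_to_input(traces, model$config)
  n <- nrow(X$fhr)
  out <- vector("list", ceiling(n / 64))
  for (i in seq_along(out)) {
    idx <- ((i - 1) * 64 + 1):min(i * 64, n)
    Xb <- list(fhr = X$fhr[idx, , drop = FALSE], uc = X$uc[idx, , drop = FALSE])
    out[[i]] <- ctgnet_forward(model, Xb, training = FALSE)$probs
  }
  probs <- do.call(rbind, out)
  # class order is (normal, abnormal)
  tibble::tibble(abnormality = probs[, 2], normality = probs[, 1])
}

#' @export
print.ctgnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "CTG-net: input %dx%d, filters %d/%dx/%d, kernels %d/%d, %d parameters%s\n",
    cfg$n_channels, cfg$input_len, cfg$f1, cfg$d, cfg$f2, cfg$k1, cfg$k2,
    model_param_total(x),
    if (is.null(x$history)) " (untrained)" else sprintf(
      " (trained %d epochs)", max(x$history$epoch)
    )
  ))
  invisible(x)
}
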