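# Dual next-step-prediction LSTM and the reconstruction-error risk index.
#
# One two-layer, 40-unit LSTM is trained only on normal traces and a twin
# only on abnormal traces, each to predict the next (FHR, UC) sample from
# the preceding 5. A test trace is scored by the difference of its summed
# absolute prediction errors under the two models: a trace that the
# normal-trained model reconstructs better than the abnormal-trained one
# is presumed normal. Implemented from scratch (BPTT + Adam), like the
# convolutional model.

#' LSTM configuration
#'
#' @param units Recurrent units in each of the two layers.
#' @param window Input time points per prediction (the next point is the
#'   target).
#' @param error_bin_s Width of the error-aggregation bins in seconds
#'   (errors are summed within bins and the bins summed over the trace;
#'   the binning is reported for fidelity but the total equals the plain
#'   sum of absolute errors).
#' @param lr,adam_eps Adam settings.
#' @param epochs,batch_size Training schedule.
#' @param stride Sampling stride (in samples) between training windows
#'   drawn from each trace.
#' @param fhr_scale,uc_scale Channel divisors bringing FHR (bpm) and UC
#'   (units) to a comparable ~\[0, 1\] range before the recurrent model.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(units = 40, window = 5, error_bin_s = 5,
                        lr = 1e-3, adam_eps = 1e-5, epochs = 5,
                        batch_size = 256, stride = 10,
                        fhr_scale = 200, uc_scale = 100) {
  stopifnot(units >= 1, window >= 1, error_bin_s > 0, epochs >= 1)
  structure(
    list(
      units = units, window = window, error_bin_s = error_bin_s,
      lr = lr, adam_eps = adam_eps, epochs = epochs,
      batch_size = batch_size, stride = stride,
      fhr_scale = fhr_scale, uc_scale = uc_scale
    ),
    class = "lstm_config"
  )
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_layer_init <- function(n_in, units) {
  lim_w <- sqrt(6 / (n_in + 4 * units))
  lim_u <- sqrt(6 / (units + 4 * units))
  b <- rep(0, 4 * units)
  b[(units + 1):(2 * units)] <- 1 # forget-gate bias
  list(
    W = matrix(stats::runif(n_in * 4 * units, -lim_w, lim_w), n_in, 4 * units),
    U = matrix(stats::runif(units * 4 * units, -lim_u, lim_u), units, 4 * units),
    b = b
  )
}

build_lstm <- function(config, seed = 0) {
  withr::with_seed(seed, {
    u <- config$units
    w <- list(
      l1 = lstm_layer_init(2, u),
      l2 = lstm_layer_init(u, u),
      Wh = matrix(stats::runif(u * 2, -sqrt(6 / (u + 2)), sqrt(6 / (u + 2))), u, 2),
      bh = rep(0, 2)
    )
    structure(list(config = config, weights = w, history = NULL),
      class = "ctg_lstm"
    )
  })
}

# Forward one layer over the whole window; X is a list of B x n_in
# matrices per timestep. Returns per-step hidden states and caches.
lstm_layer_forward <- function(layer, X, units) {
  B <- nrow(X[[1]])
  h <- matrix(0, B, units)
  cc <- matrix(0, B, units)
  steps <- vector("list", length(X))
  H <- vector("list", length(X))
  for (t in seq_along(X)) {
    z <- X[[t]] %*% layer$W + h %*% layer$U
    z <- sweep(z, 2, layer$b, `+`)
    i <- sigm(z[, 1:units, drop = FALSE])
    f <- sigm(z[, (units + 1):(2 * units), drop = FALSE])
    g <- tanh(z[, (2 * units + 1):(3 * units), drop = FALSE])
    o <- sigm(z[, (3 * units + 1):(4 * units), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    hc <- tanh(cc)
    h_prev <- h
    h <- o * hc
    steps[[t]] <- list(
      i = i, f = f, g = g, o = o, c = cc, hc = hc,
      c_prev = c_prev, h_prev = h_prev, x = X[[t]]
    )
    H[[t]] <- h
  }
  list(H = H, steps = steps)
}

# BPTT through one layer. dH is a list of gradients w.r.t. each step's
# hidden output (zeros where unused). Returns weight grads and dX.
lstm_layer_backward <- function(layer, fwd, dH, units) {
  B <- nrow(dH[[length(dH)]])
  dW <- layer$W * 0
  dU <- layer$U * 0
  db <- layer$b * 0
  dX <- vector("list", length(dH))
  dh_next <- matrix(0, B, units)
  dc_next <- matrix(0, B, units)
  for (t in rev(seq_along(dH))) {
    st <- fwd$steps[[t]]
    dh <- dH[[t]] + dh_next
    dc <- dc_next + dh * st$o * (1 - st$hc^2)
    do_ <- dh * st$hc
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dz <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      dg * (1 - st$g^2),
      do_ * st$o * (1 - st$o)
    )
    dW <- dW + t(st$x) %*% dz
    dU <- dU + t(st$h_prev) %*% dz
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(layer$W)
    dh_next <- dz %*% t(layer$U)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

lstm_forward <- function(model, X) {
  u <- model$config$units
  w <- model$weights
  f1 <- lstm_layer_forward(w$l1, X, u)
  f2 <- lstm_layer_forward(w$l2, f1$H, u)
  h_last <- f2$H[[length(X)]]
  r <- pmax(h_last, 0)
  yhat <- sweep(r %*% w$Wh, 2, w$bh, `+`)
  list(yhat = yhat, f1 = f1, f2 = f2, r = r, h_last = h_last)
}

lstm_backward <- function(model, fwd, dyhat, X) {
  u <- model$config$units
  w <- model$weights
  B <- nrow(dyhat)
  g <- list()
  g$Wh <- t(fwd$r) %*% dyhat
  g$bh <- colSums(dyhat)
  dh_last <- (dyhat %*% t(w$Wh)) * (fwd$h_last > 0)
  dH2 <- lapply(X, function(x) matrix(0, B, u))
  dH2[[length(X)]] <- dh_last
  b2 <- lstm_layer_backward(w$l2, fwd$f2, dH2, u)
  g$l2 <- list(W = b2$dW, U = b2$dU, b = b2$db)
  b1 <- lstm_layer_backward(w$l1, fwd$f1, b2$dX, u)
  g$l1 <- list(W = b1$dW, U = b1$dU, b = b1$db)
  g
}

scale_trace_matrix <- function(trace, config) {
  tr <- impute_trace(trace)
  cbind(tr$fhr_bpm / config$fhr_scale, tr$uc_units / config$uc_scale)
}

# Extract (window, target) pairs from scaled trace matrices.
make_windows <- function(mats, window, stride) {
  xs <- list()
  ys <- list()
  for (m in mats) {
    n <- nrow(m)
    if (n < window + 1L) next
    starts <- seq(1L, n - window, by = stride)
    xs[[length(xs) + 1L]] <- lapply(seq_len(window), function(t) {
      m[starts + t - 1L, , drop = FALSE]
    })
    ys[[length(ys) + 1L]] <- m[starts + window, , drop = FALSE]
  }
  if (length(xs) == 0L) rlang::abort("No trace is long enough to form a prediction window.")
  X <- lapply(seq_len(window), function(t) {
    do.call(rbind, lapply(xs, `[[`, t))
  })
  list(X = X, Y = do.call(rbind, ys))
}

#' Train one next-step LSTM on a group of traces
#'
#' @param traces List of [ctg_trace()]s (1 Hz; invalid samples imputed and
#'   channels scaled per the config).
#' @param config An [lstm_config()].
#' @param seed Integer seed (initialization and shuffling).
#' @return A `ctg_lstm` with a per-epoch loss history.
#' @export
train_lstm <- function(traces, config = lstm_config(), seed = 0) {
  if (length(traces) == 0L) rlang::abort("Cannot train on an empty trace group.")
  mats <- lapply(traces, scale_trace_matrix, config = config)
  dat <- make_windows(mats, config$window, config$stride)
  model <- build_lstm(config, seed)
  n <- nrow(dat$Y)
  withr::with_seed(seed + 1L, {
    m_st <- adam_init(model$weights)
    v_st <- adam_init(model$weights)
    t_step <- 0L
    history <- list()
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        Xb <- lapply(dat$X, function(m) m[idx, , drop = FALSE])
        Yb <- dat$Y[idx, , drop = FALSE]
        fwd <- lstm_forward(model, Xb)
        loss <- mean((fwd$yhat - Yb)^2)
        if (!is.finite(loss)) rlang::abort("Non-finite LSTM training loss.")
        dyhat <- 2 * (fwd$yhat - Yb) / length(Yb)
        g <- lstm_backward(model, fwd, dyhat, Xb)
        t_step <- t_step + 1L
        res <- adam_step(model$weights, g, m_st, v_st, t_step,
          config$lr, config$adam_eps
        )
        model$weights <- res$w
        m_st <- res$m
        v_st <- res$v
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / nb)
    }
    model$history <- dplyr::bind_rows(history)
    model
  })
}

#' Train the normal/abnormal LSTM pair
#'
#' Each model sees only its own group; both start from the same seeded
#' schedule so a run is reproducible end to end.
#'
#' @param normal_traces,abnormal_traces Non-empty lists of traces.
#' @param config An [lstm_config()].
#' @param seed Integer seed.
#' @return An object of class `ctg_lstm_pair`.
#' @export
train_lstm_pair <- function(normal_traces, abnormal_traces,
                            config = lstm_config(), seed = 0) {
  structure(
    list(
      model_normal = train_lstm(normal_traces, config, seed),
      model_abnormal = train_lstm(abnormal_traces, config, seed + 1000L),
      config = config
    ),
    class = "ctg_lstm_pair"
  )
}

# Summed absolute next-step error of one model on one trace, plus the
# per-bin aggregation.
lstm_trace_error <- function(model, trace, stride = 1L) {
  config <- model$config
  m <- scale_trace_matrix(trace, config)
  n <- nrow(m)
  if (n < config$window + 1L) {
    rlang::abort(sprintf(
      "Trace of %d samples is shorter than window + 1 = %d.",
      n, config$window + 1L
    ))
  }
  starts <- seq(1L, n - config$window, by = stride)
  X <- lapply(seq_len(config$window), function(t) m[starts + t - 1L, , drop = FALSE])
  Y <- m[starts + config$window, , drop = FALSE]
  yhat <- lstm_forward(model, X)$yhat
  err <- rowSums(abs(yhat - Y))
  fs <- ctg_fs(trace)
  pred_time_s <- (starts + config$window - 1L) / fs
  bin <- floor(pred_time_s / config$error_bin_s)
  bins <- tapply(err, bin, sum)
  list(total = sum(err), bins = as.numeric(bins))
}

#' Reconstruction-error risk index
#'
#' For each trace, sums absolute next-step prediction errors (aggregated
#' in 5-s bins) under the normal-trained and abnormal-trained models and
#' returns `risk_index = error_normal - error_abnormal`. At the default
#' threshold 0 a trace is called abnormal when its risk index is positive
#' (the abnormal model reconstructs it better); sweeping the threshold
#' yields the model's ROC curve.
#'
#' @param pair A `ctg_lstm_pair` from [train_lstm_pair()].
#' @param traces A [ctg_trace()] or list of them.
#' @param stride Stride between scored windows (1 = every sample).
#' @param threshold Classification threshold on the risk index.
#' @return A tibble with one row per trace: `error_normal`,
#'   `error_abnormal`, `risk_index`, `.pred`.
#' @export
risk_index <- function(pair, traces, stride = 1L, threshold = 0) {
  if (inherits(traces, "ctg_trace")) traces <- list(traces)
  rows <- purrr::map(traces, function(tr) {
    en <- lstm_trace_error(pair$model_normal, tr, stride)$total
    ea <- lstm_trace_error(pair$model_abnormal, tr, stride)$total
    tibble::tibble(
      error_normal = en, error_abnormal = ea, risk_index = en - ea
    )
  })
  out <- dplyr::bind_rows(rows)
  out$.pred <- factor(
    ifelse(out$risk_index > threshold, "abnormal", "normal"),
    levels = c("normal", "abnormal")
  )
  out
}

#' @export
print.ctg_lstm <- function(x, ...) {
  cat(sprintf(
    "Next-step LSTM: 2 layers x %d units, window %d%s\n",
    x$config$units, x$config$window,
    if (is.null(x$history)) " (untrained)" else ""
  ))
  invisible(x)
}

#' @export
print.ctg_lstm_pair <- function(x, ...) {
  cat("LSTM risk-index pair (normal-trained / abnormal-trained):\n")
  print(x$model_normal)
  invisible(x)
}
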