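# Convolutional model: parameter accounting, forward contract, gradient
# correctness, seeded training.

test_that("the closed-form parameter count matches its term expansion", {
  expect_equal(ctgnet_param_count(ctgnet_config()), 2130L)
  # swapping the separable width: 120+16+16+32+56+32+16+2*(4*112)+2
  expect_equal(ctgnet_param_count(ctgnet_config(f2 = 4)), 1186L)
  expect_error(ctgnet_config(f1 = 0), "positive")
})

test_that("formula equals model introspection across random valid configs", {
  set.seed(123)
  for (i in 1:20) {
    cfg <- ctgnet_config(
      input_len = sample(200:600, 1),
      k1 = sample(5:40, 1), f1 = sample(4:8, 1), d = sample(1:3, 1),
      k2 = sample(3:11, 1), f2 = sample(4:8, 1),
      pool1 = sample(2:5, 1), pool2 = sample(2:5, 1)
    )
    expect_equal(model_param_total(build_ctgnet(cfg, seed = i)), ctgnet_param_count(cfg))
  }
})

test_that("pooling arithmetic gives 1800 -> 450 -> 112 temporal positions", {
  cfg <- ctgnet_config()
  m <- build_ctgnet(cfg, seed = 0)
  X <- list(fhr = matrix(140, 1, 1800), uc = matrix(10, 1, 1800))
  fwd <- ctgnet:::ctgnet_forward(m, X, training = FALSE)
  expect_equal(nrow(fwd$cache$P1), 450) # B = 1
  expect_equal(nrow(fwd$cache$P2), 112)
  expect_equal(ncol(fwd$cache$Flat), 8 * 112)
})

test_that("outputs are normalized; zero network input scores exactly 1/2", {
  m <- build_ctgnet(ctgnet_config(), seed = 1)
  tr <- simulate_trace("normal", trace_gen_params(), seed = 2)
  sc <- score_abnormality(m, tr)
  expect_true(sc$abnormality >= 0 && sc$abnormality <= 1)
  expect_equal(sc$abnormality + sc$normality, 1, tolerance = 1e-12)

  # a trace sitting at the input transform's reference levels is the
  # untrained network's zero: by symmetry it scores 1/2
  zero <- constant_trace(1800, fhr = 140, uc = 20)
  expect_equal(score_abnormality(m, zero)$abnormality, 0.5, tolerance = 1e-9)

  expect_error(score_abnormality(m, constant_trace(1200)), "1800")
})

test_that("analytic gradients match finite differences", {
  cfg <- ctgnet_config(
    input_len = 32, k1 = 5, f1 = 2, d = 2, k2 = 3, f2 = 3,
    pool1 = 2, pool2 = 2, dropout = 0
  )
  m <- build_ctgnet(cfg, seed = 2)
  set.seed(3)
  X <- list(fhr = matrix(rnorm(4 * 32), 4), uc = matrix(rnorm(4 * 32), 4))
  Y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  fwd <- ctgnet:::ctgnet_forward(m, X, training = TRUE)
  g <- ctgnet:::ctgnet_backward(m, fwd, Y)
  lossfun <- function(model) {
    ctgnet:::ce_loss(ctgnet:::ctgnet_forward(model, X, training = TRUE)$probs, Y)
  }
  eps <- 1e-5
  assign_in <- function(w, path, i, val) {
    if (length(path) == 1) {
      w[[path]][i] <- val
      return(w)
    }
    w[[path[1]]] <- assign_in(w[[path[1]]], path[-1], i, val)
    w
  }
  get_in <- function(w, path) {
    for (p in path) w <- w[[p]]
    w
  }
  paths <- list(
    "W1", c("bn1", "gamma"), "Wd", c("bn2", "beta"), "Wdw", "Wpw",
    c("bn3", "gamma"), "Wfc", "bfc"
  )
  set.seed(4)
  for (path in paths) {
    gv <- get_in(g, path)
    wv <- get_in(m$weights, path)
    for (i in sample(length(wv), min(3, length(wv)))) {
      mp <- m
      mp$weights <- assign_in(m$weights, path, i, wv[i] + eps)
      mm <- m
      mm$weights <- assign_in(m$weights, path, i, wv[i] - eps)
      num <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
      expect_equal(gv[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seed-deterministic and reduces loss on a learnable set", {
  dat <- simulate_dataset(10, trace_gen_params(duration_s = 1800), seed = 6)
  cfg <- ctgnet_config()
  m1 <- train_ctgnet(build_ctgnet(cfg, seed = 5), dat$ctg, dat$label,
    epochs = 4, seed = 5
  )
  m2 <- train_ctgnet(build_ctgnet(cfg, seed = 5), dat$ctg, dat$label,
    epochs = 4, seed = 5
  )
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  expect_lt(m1$history$loss[4], m1$history$loss[1])
})

test_that("after training, abnormal traces score higher than normal ones", {
  dat <- simulate_dataset(20, trace_gen_params(), seed = 21)
  m <- train_ctgnet(build_ctgnet(ctgnet_config(), seed = 1),
    dat$ctg, dat$label,
    epochs = 25, seed = 1
  )
  test <- simulate_dataset(10, trace_gen_params(), seed = 22)
  sc <- score_abnormality(m, test$ctg)$abnormality
  expect_gt(
    mean(sc[test$label == "abnormal"]),
    mean(sc[test$label == "normal"])
  )
})

test_that("early stopping restores the best-validation weights", {
  dat <- simulate_dataset(8, trace_gen_params(duration_s = 1800), seed = 31)
  val <- simulate_dataset(4, trace_gen_params(duration_s = 1800), seed = 32)
  cfg <- ctgnet_config(patience = 2)
  m <- train_ctgnet(build_ctgnet(cfg, seed = 1), dat$ctg, dat$label,
    validation = list(traces = val$ctg, labels = val$label),
    epochs = 10, seed = 1
  )
  expect_true(all(is.finite(m$history$val_loss)))
  expect_lte(max(m$history$epoch), 10)
})
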