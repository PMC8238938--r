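# Metrics, ROC-AUC, cross-validation protocol and comparison tests.

test_that("confusion counts treat abnormal as positive", {
  truth <- rep(c("abnormal", "normal"), each = 10)
  expect_equal(
    confusion(truth, truth),
    tibble::tibble(tp = 10L, fp = 0L, fn = 0L, tn = 10L)
  )
  expect_equal(
    confusion(truth, rep("abnormal", 20)),
    tibble::tibble(tp = 10L, fp = 10L, fn = 0L, tn = 0L)
  )
  # brute-force tally on a random vector
  set.seed(5)
  t2 <- sample(c("normal", "abnormal"), 40, replace = TRUE)
  p2 <- sample(c("normal", "abnormal"), 40, replace = TRUE)
  cm <- confusion(t2, p2)
  tally <- table(truth = t2, pred = p2)
  expect_equal(cm$tp, tally["abnormal", "abnormal"], ignore_attr = TRUE)
  expect_equal(cm$fp, tally["normal", "abnormal"], ignore_attr = TRUE)
  expect_equal(cm$fn, tally["abnormal", "normal"], ignore_attr = TRUE)
  expect_equal(cm$tn, tally["normal", "normal"], ignore_attr = TRUE)
  expect_equal(sum(cm), 40)
  expect_error(confusion(t2, p2[1:10]), "length")
})

test_that("F1 follows the harmonic-mean definition with a 0/0 guard", {
  expect_equal(
    f1_score(tibble::tibble(tp = 10, fp = 0, fn = 0)),
    tibble::tibble(precision = 1, recall = 1, f1 = 1)
  )
  m <- f1_score(tibble::tibble(tp = 60, fp = 40, fn = 20))
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(
    f1_score(tibble::tibble(tp = 0, fp = 0, fn = 5)),
    tibble::tibble(precision = 0, recall = 0, f1 = 0)
  )
  # harmonic-mean identity whenever defined
  set.seed(8)
  for (i in 1:20) {
    cm <- tibble::tibble(
      tp = sample(0:20, 1), fp = sample(0:20, 1), fn = sample(0:20, 1)
    )
    mm <- f1_score(cm)
    if (mm$precision + mm$recall > 0) {
      expect_equal(
        mm$f1, 2 * mm$precision * mm$recall / (mm$precision + mm$recall)
      )
    }
  }
})

test_that("ROC-AUC equals brute-force pair counting with half-credit ties", {
  expect_equal(
    auc(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("abnormal", "abnormal", "normal", "normal"))),
    1.0
  )
  expect_equal(auc(roc_auc(rep(0.3, 6), rep(c("abnormal", "normal"), 3))), 0.5)
  expect_equal(
    auc(roc_auc(c(0.8, 0.4, 0.6, 0.2), c("abnormal", "abnormal", "normal", "normal"))),
    0.75
  )

  # exhaustive random small cases, with heavy ties
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(
      "abnormal", "normal",
      sample(c("normal", "abnormal"), n - 2, replace = TRUE)
    )
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    r <- roc_auc(scores, labels)
    expect_equal(auc(r), pair_count_auc(scores, labels))
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    expect_true(all(r$tpr >= 0 & r$tpr <= 1 & r$fpr >= 0 & r$fpr <= 1))
  }
  expect_error(roc_auc(1:3, rep("normal", 3)), "both classes")
})

test_that("tenfold CV partitions abnormals and never leaks into training", {
  builder <- function(seed) {
    withr::with_seed(seed, tibble::tibble(
      id = sprintf("R%03d", 1:120),
      label = factor(rep(c("normal", "abnormal"), c(80, 40)),
        levels = c("normal", "abnormal")
      ),
      x = stats::rnorm(120) + 2 * (rep(c(0, 1), c(80, 40)))
    ))
  }
  seen <- new.env()
  seen$test_ids <- character(0)
  oracle_factory <- function(train, seed) {
    train_ids <- train$id
    function(test) {
      expect_length(intersect(train_ids, test$id), 0)
      seen$test_ids <- c(seen$test_ids, test$id[test$label == "abnormal"])
      as.numeric(test$label == "abnormal") # perfect scores
    }
  }
  cv <- tenfold_cv(builder, oracle_factory, n_folds = 10, seed = 3)
  # every abnormal appears in exactly one test fold
  abn_ids <- builder(3)$id[81:120]
  expect_setequal(seen$test_ids, abn_ids)
  expect_equal(anyDuplicated(seen$test_ids), 0)
  expect_true(all(cv$folds$f1 == 1))
  expect_true(all(cv$folds$auc == 1))

  expect_error(
    tenfold_cv(function(seed) builder(seed)[c(1:80, 81:85), ], oracle_factory,
      n_folds = 10, seed = 1
    ),
    "smaller than"
  )
})

test_that("a coin-flip model scores near chance under the CV protocol", {
  builder <- function(seed) {
    withr::with_seed(seed, tibble::tibble(
      id = sprintf("C%03d", 1:200),
      label = factor(rep(c("normal", "abnormal"), each = 100),
        levels = c("normal", "abnormal")
      )
    ))
  }
  coin_factory <- function(train, seed) {
    function(test) withr::with_seed(seed, stats::runif(nrow(test)))
  }
  cv <- tenfold_cv(builder, coin_factory, n_folds = 10, seed = 5)
  # 100 test pairs per fold, 10 folds: SE of the mean AUC ~ 0.03
  expect_lt(abs(cv$summary$mean[cv$summary$metric == "auc"] - 0.5), 0.1)
})

test_that("seed repetition is reproducible and reports mean +/- SD", {
  protocol <- function(seed) {
    withr::with_seed(seed, tibble::tibble(f1 = stats::runif(1), auc = stats::runif(1)))
  }
  r1 <- repeat_with_seeds(protocol, 1:10)
  r2 <- repeat_with_seeds(protocol, 1:10)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10)
  s <- attr(r1, "summary")
  expect_true(all(is.finite(s$sd)))
  expect_match(s$formatted[1], "^0\\.\\d{2} ± 0\\.\\d{2}$")
  expect_equal(format_mean_sd(0.666, 0.031), "0.67 ± 0.03")
  expect_error(repeat_with_seeds(protocol, 1), "two seeds")
})

test_that("summary variability shrinks with protocol sample size", {
  protocol_of <- function(n) {
    function(seed) {
      withr::with_seed(seed, {
        scores <- c(stats::rnorm(n, 1), stats::rnorm(n, 0))
        labels <- rep(c("abnormal", "normal"), each = n)
        tibble::tibble(auc = auc(roc_auc(scores, labels)))
      })
    }
  }
  sd_small <- attr(repeat_with_seeds(protocol_of(25), 1:10), "summary")$sd
  sd_big <- attr(repeat_with_seeds(protocol_of(100), 1:10), "summary")$sd
  expect_lt(sd_big, sd_small)
})

test_that("model comparison reports both t-test variants with df", {
  a <- c(0.6, 0.62, 0.61, 0.63)
  out <- compare_models(a, a)
  expect_equal(out$t[out$method == "two_sample"], 0)
  expect_equal(out$p_value[out$method == "two_sample"], 1)
  expect_equal(out$df[out$method == "two_sample"], 6)

  set.seed(2)
  lo <- stats::rnorm(10, 0, 0.01)
  hi <- stats::rnorm(10, 1, 0.01)
  out2 <- compare_models(lo, hi)
  expect_lt(out2$p_value[1], 0.01)
  expect_equal(out2$df[out2$method == "paired"], 9)

  expect_error(compare_models(rep(1, 4), rep(0, 4)), "zero variance")
  expect_error(compare_models(0.5, 0.7), "at least two")
})

test_that("the two-sample test holds its type-I error rate", {
  set.seed(13)
  rejections <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    p <- compare_models(stats::rnorm(10), stats::rnorm(10))$p_value[1]
    if (p < 0.05) rejections <- rejections + 1L
  }
  # binomial SE at n = 400 is ~0.011
  expect_lt(abs(rejections / n_rep - 0.05), 0.04)
})
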