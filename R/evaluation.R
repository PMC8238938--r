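# Metrics, ROC/AUC, the tenfold cross-validation protocol and model
# comparison tests. The abnormal class is positive throughout.

#' Confusion counts
#'
#' @param truth,estimate Vectors of `"normal"`/`"abnormal"` labels of
#'   equal length; abnormal is the positive class.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    rlang::abort(sprintf(
      "truth (%d) and estimate (%d) differ in length.",
      length(truth), length(estimate)
    ))
  }
  truth <- factor(truth, levels = c("normal", "abnormal"))
  estimate <- factor(estimate, levels = c("normal", "abnormal"))
  tibble::tibble(
    tp = sum(truth == "abnormal" & estimate == "abnormal"),
    fp = sum(truth == "normal" & estimate == "abnormal"),
    fn = sum(truth == "abnormal" & estimate == "normal"),
    tn = sum(truth == "normal" & estimate == "normal")
  )
}

#' Precision, recall and F1
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 is their
#' harmonic mean 2 * precision * recall / (precision + recall). Any 0/0 is
#' defined as 0 (degenerate, e.g. no positive predictions).
#'
#' @param counts A one-row tibble from [confusion()] (or any list with
#'   `tp`, `fp`, `fn`).
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @examples
#' f1_score(tibble::tibble(tp = 60, fp = 40, fn = 20, tn = 80))
#' @export
f1_score <- function(counts) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (plus
#' sentinels), computing the true-positive rate (recall) and
#' false-positive rate at each. The AUC is the trapezoidal integral of
#' the swept curve, which equals the fraction of (abnormal, normal) score
#' pairs ranked correctly with ties counted half.
#'
#' @param scores Numeric abnormality scores (larger = more abnormal).
#' @param labels `"normal"`/`"abnormal"` per score; both classes required.
#' @return An object of class `ctg_roc`: a tibble with `threshold`, `tpr`,
#'   `fpr`, and the AUC as attribute, retrievable via [auc()].
#' @examples
#' auc(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("abnormal", "abnormal", "normal", "normal")))
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels, levels = c("normal", "abnormal"))
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels differ in length.")
  }
  if (anyNA(scores) || anyNA(labels)) rlang::abort("scores/labels contain NA.")
  n_pos <- sum(labels == "abnormal")
  n_neg <- sum(labels == "normal")
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("ROC needs both classes present.")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == "abnormal") / n_pos, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == "normal") / n_neg, numeric(1))
  # trapezoid over the swept staircase; equals midrank pair counting
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  curve <- tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
  structure(curve, auc = auc, class = c("ctg_roc", class(curve)))
}

#' @rdname roc_auc
#' @param x A `ctg_roc`.
#' @export
auc <- function(x) attr(x, "auc")

#' @export
print.ctg_roc <- function(x, ...) {
  cat(sprintf("# ROC curve: %d thresholds, AUC = %.4f\n", nrow(x), auc(x)))
  NextMethod()
}

#' Tenfold cross-validation with normal-group resampling
#'
#' The protocol used for the deep models: the abnormal cases are
#' partitioned into `n_folds` folds, each serving as (half of) the test
#' set exactly once; for every fold a fresh equal-size normal subsample is
#' drawn from the eligible pool and split 9:1 alongside, so the evaluated
#' sets are always balanced. A model factory is fitted on each training
#' split and its scores on the held-out split are turned into confusion
#' counts (threshold 0.5 equivalent: predicted abnormal when the score
#' exceeds `threshold`), F1 and ROC.
#'
#' @param dataset_builder Function `(seed) -> tibble` with columns `id`,
#'   `label`, and whatever the model factory consumes (e.g. a `ctg`
#'   list-column); called once per repetition to supply the abnormal set
#'   and the normal pool.
#' @param model_factory Function `(train_tbl, seed) -> function(test_tbl)
#'   -> numeric scores` (larger = more abnormal).
#' @param n_folds Number of folds (and normal resamples).
#' @param seed Integer seed controlling folds and subsampling.
#' @param threshold Score threshold for the hard classification.
#' @return An object of class `ctg_cv`: per-fold metrics in `$folds`,
#'   mean +/- SD summaries in `$summary`.
#' @export
tenfold_cv <- function(dataset_builder, model_factory, n_folds = 10, seed = 0,
                       threshold = 0.5) {
  data <- dataset_builder(seed)
  abn <- data[data$label == "abnormal", , drop = FALSE]
  pool <- data[data$label == "normal", , drop = FALSE]
  if (nrow(abn) < n_folds) {
    rlang::abort(sprintf(
      "Abnormal class (%d) smaller than the number of folds (%d).",
      nrow(abn), n_folds
    ))
  }
  withr::with_seed(seed, {
    fold_of <- sample(rep(seq_len(n_folds), length.out = nrow(abn)))
    fold_rows <- list()
    for (k in seq_len(n_folds)) {
      test_abn <- abn[fold_of == k, , drop = FALSE]
      train_abn <- abn[fold_of != k, , drop = FALSE]
      nor_idx <- sample.int(nrow(pool), nrow(abn))
      nor <- pool[nor_idx, , drop = FALSE]
      n_test_nor <- nrow(test_abn)
      test_nor <- nor[seq_len(n_test_nor), , drop = FALSE]
      train_nor <- nor[-seq_len(n_test_nor), , drop = FALSE]
      train <- dplyr::bind_rows(train_nor, train_abn)
      test <- dplyr::bind_rows(test_nor, test_abn)
      stopifnot(length(intersect(train$id, test$id)) == 0L)
      scorer <- model_factory(train, seed = seed * 1000L + k)
      scores <- scorer(test)
      cm <- confusion(test$label, ifelse(scores > threshold, "abnormal", "normal"))
      roc <- roc_auc(scores, test$label)
      fold_rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(fold = k), cm, f1_score(cm),
        tibble::tibble(auc = auc(roc), roc = list(roc))
      )
    }
    folds <- dplyr::bind_rows(fold_rows)
    summary <- tibble::tibble(
      metric = c("f1", "auc"),
      mean = c(mean(folds$f1), mean(folds$auc)),
      sd = c(stats::sd(folds$f1), stats::sd(folds$auc)),
      n_folds = n_folds
    )
    structure(list(folds = folds, summary = summary, seed = seed),
      class = "ctg_cv"
    )
  })
}

#' @export
print.ctg_cv <- function(x, ...) {
  cat(sprintf("# %d-fold cross-validation (seed %d)\n", nrow(x$folds), x$seed))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf(
      "  %s: %s\n", x$summary$metric[i],
      format_mean_sd(x$summary$mean[i], x$summary$sd[i])
    ))
  }
  invisible(x)
}

#' Repeat an evaluation protocol across seeds
#'
#' @param protocol Function `(seed) -> one-row data frame` of summary
#'   metrics (any numeric columns).
#' @param seeds Integer vector of seeds (length >= 2).
#' @return A tibble with one row per seed plus the seed column; the
#'   per-metric mean +/- SD is attached as attribute `summary`.
#' @export
repeat_with_seeds <- function(protocol, seeds) {
  if (length(seeds) < 2L) rlang::abort("Need at least two seeds.")
  rows <- purrr::map(seeds, function(s) {
    dplyr::bind_cols(tibble::tibble(seed = s), tibble::as_tibble(protocol(s)))
  })
  out <- dplyr::bind_rows(rows)
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "seed")
  summ <- tibble::tibble(
    metric = num_cols,
    mean = vapply(num_cols, function(cl) mean(out[[cl]]), numeric(1)),
    sd = vapply(num_cols, function(cl) stats::sd(out[[cl]]), numeric(1))
  )
  summ$formatted <- format_mean_sd(summ$mean, summ$sd)
  attr(out, "summary") <- summ
  out
}

#' Format a metric as "mean +/- SD"
#'
#' @param mean,sd Numeric vectors.
#' @param digits Decimal places (default 2, the conventional reporting
#'   precision for F1 and AUC).
#' @return Character vector like `"0.67 ± 0.03"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  sprintf("%.*f ± %.*f", digits, mean, digits, sd)
}

#' Compare two models' per-seed metrics
#'
#' Student's two-sample t-test on per-seed metric values, with the paired
#' variant alongside when lengths match. Degrees of freedom are reported
#' with each statistic.
#'
#' @param metrics_a,metrics_b Numeric vectors (length >= 2) of per-seed
#'   metrics for the two models.
#' @return A tibble with one row per test variant: `method`, `t`, `df`,
#'   `p_value`.
#' @export
compare_models <- function(metrics_a, metrics_b) {
  if (length(metrics_a) < 2L || length(metrics_b) < 2L) {
    rlang::abort("Each metric vector needs at least two values.")
  }
  if (stats::sd(metrics_a) == 0 && stats::sd(metrics_b) == 0) {
    if (all(metrics_a == metrics_b)) {
      # degenerate but well-defined: identical constant samples
      return(tibble::tibble(
        method = c("two_sample", "paired"),
        t = c(0, 0),
        df = c(length(metrics_a) + length(metrics_b) - 2L, length(metrics_a) - 1L),
        p_value = c(1, 1)
      ))
    }
    rlang::abort("Both samples have zero variance; the t statistic is undefined.")
  }
  ts <- stats::t.test(metrics_a, metrics_b, var.equal = TRUE)
  out <- tibble::tibble(
    method = "two_sample",
    t = unname(ts$statistic),
    df = unname(ts$parameter),
    p_value = ts$p.value
  )
  if (length(metrics_a) == length(metrics_b)) {
    d <- metrics_a - metrics_b
    if (stats::sd(d) > 0) {
      tp <- stats::t.test(metrics_a, metrics_b, paired = TRUE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        method = "paired",
        t = unname(tp$statistic),
        df = unname(tp$parameter),
        p_value = tp$p.value
      ))
    }
  }
  out
}
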