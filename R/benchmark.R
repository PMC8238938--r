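# End-to-end synthetic classification benchmark: deep model vs the
# conventional two-feature baselines on the simulator's separable default
# conditions.

#' Synthetic classification benchmark
#'
#' For each seed, simulates a balanced dataset ([simulate_dataset()]),
#' splits it 9:1 stratified by class, trains the requested models on the
#' training split and scores the held-out split, reporting AUC and F1 (at
#' the 0.5 probability / zero risk-index threshold). This reproduces the
#' evaluation protocol -- and, under the simulator's separable default
#' conditions, the deep-model-over-conventional ordering -- at desk
#' scale; it makes no claim about clinical performance values.
#'
#' @param n_per_group Traces per class per seed.
#' @param seeds Integer seeds (one benchmark repetition each).
#' @param models Subset of `"ctgnet"`, `"svm"`, `"kmeans"`, `"lstm"`.
#' @param params A [trace_gen_params()] for the simulator.
#' @param epochs Training epochs for the convolutional model; the
#'   separable benchmark converges quickly so the default is far below
#'   the config cap.
#' @param lstm An [lstm_config()] for the LSTM pair (when requested).
#' @param test_frac Held-out fraction per class.
#' @return A tibble with columns `model`, `seed`, `auc`, `f1`; per-model
#'   mean +/- SD is attached as attribute `summary`.
#' @export
ctg_benchmark <- function(n_per_group = 162, seeds = 1:3,
                          models = c("ctgnet", "svm"),
                          params = trace_gen_params(), epochs = 40,
                          lstm = lstm_config(), test_frac = 0.1) {
  models <- match.arg(models, c("ctgnet", "svm", "kmeans", "lstm"),
    several.ok = TRUE
  )
  rows <- list()
  push <- function(model, seed, scores, truth) {
    roc <- roc_auc(scores$score, truth)
    cm <- confusion(truth, ifelse(scores$score > scores$threshold, "abnormal", "normal"))
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(model = model, seed = seed, auc = auc(roc)),
      f1_score(cm)["f1"]
    )
  }
  for (s in seeds) {
    data <- simulate_dataset(n_per_group, params, seed = s)
    n_test <- max(1L, round(test_frac * n_per_group))
    test_idx <- withr::with_seed(s, {
      c(
        which(data$label == "normal")[sample.int(n_per_group, n_test)],
        which(data$label == "abnormal")[sample.int(n_per_group, n_test)]
      )
    })
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]

    if ("ctgnet" %in% models) {
      net <- build_ctgnet(ctgnet_config(input_len = nrow(data$ctg[[1]])), seed = s)
      net <- train_ctgnet(net, train$ctg, train$label, epochs = epochs, seed = s)
      sc <- score_abnormality(net, test$ctg)$abnormality
      push("ctgnet", s, list(score = sc, threshold = 0.5), test$label)
    }
    if (any(c("svm", "kmeans") %in% models)) {
      feat_train <- ctg_features(train)
      feat_test <- ctg_features(test)
      if ("svm" %in% models) {
        svm_fit <- fit_ctg_svm(feat_train)
        pr <- predict(svm_fit, feat_test)
        push("svm", s, list(score = pr$.score, threshold = 0), test$label)
      }
      if ("kmeans" %in% models) {
        km_fit <- fit_ctg_kmeans(feat_train, seed = s)
        pr <- predict(km_fit, feat_test)
        push("kmeans", s, list(score = pr$.score, threshold = 0), test$label)
      }
    }
    if ("lstm" %in% models) {
      pair <- train_lstm_pair(
        train$ctg[train$label == "normal"],
        train$ctg[train$label == "abnormal"],
        config = lstm, seed = s
      )
      ri <- risk_index(pair, test$ctg, stride = 5L)
      push("lstm", s, list(score = ri$risk_index, threshold = 0), test$label)
    }
  }
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
      mean_f1 = mean(.data$f1), sd_f1 = stats::sd(.data$f1),
      .groups = "drop"
    )
  attr(out, "summary") <- summ
  out
}
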