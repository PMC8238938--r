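# ggplot2 displays for traces, ROC curves and training histories.

#' Plot a CTG trace
#'
#' FHR and UC stacked in the clinical layout, with invalid (dropout)
#' samples blanked and any simulator-planted episodes shaded.
#'
#' @param object A [ctg_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctg_trace
#' @export
autoplot.ctg_trace <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      fhr_bpm = ifelse(.data$valid_fhr, .data$fhr_bpm, NA_real_),
      uc_units = ifelse(.data$valid_uc, .data$uc_units, NA_real_)
    ) |>
    tidyr::pivot_longer(c("fhr_bpm", "uc_units"),
      names_to = "channel", values_to = "value"
    ) |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
      fhr_bpm = "FHR (bpm)", uc_units = "UC (units)"
    ))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 60, .data$value))
  ep <- episodes(object)
  if (!is.null(ep) && nrow(ep) > 0) {
    p <- p + ggplot2::geom_rect(
      data = dplyr::mutate(ep, channel = "FHR (bpm)"),
      ggplot2::aes(
        xmin = .data$onset_s / 60, xmax = .data$offset_s / 60,
        ymin = -Inf, ymax = Inf, fill = .data$kind
      ),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, fill = "Episode") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `ctg_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctg_roc
#' @export
autoplot.ctg_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f", auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A trained `ctgnet` or `ctg_lstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctgnet
#' @export
autoplot.ctgnet <- function(object, ...) {
  if (is.null(object$history)) rlang::abort("Model has no training history yet.")
  df <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "series", values_to = "loss"
  ) |>
    dplyr::filter(is.finite(.data$loss))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ctgnet
#' @method autoplot ctg_lstm
#' @export
autoplot.ctg_lstm <- function(object, ...) {
  if (is.null(object$history)) rlang::abort("Model has no training history yet.")
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean squared error") +
    ggplot2::theme_minimal()
}
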