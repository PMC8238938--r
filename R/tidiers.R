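# broom-style tidiers for fitted objects and result containers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted models and results
#'
#' `tidy()` returns the per-epoch (models), per-fold (cross-validation)
#' or per-threshold (ROC) table; `glance()` a one-row summary.
#'
#' @param x A `ctgnet`, `ctg_lstm`, `ctg_cv` or `ctg_roc`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ctgnet
#' @export
tidy.ctgnet <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric())
}

#' @rdname tidy.ctgnet
#' @method glance ctgnet
#' @export
glance.ctgnet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_params = model_param_total(x),
    epochs = if (is.null(h)) 0L else max(h$epoch),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)]
  )
}

#' @rdname tidy.ctgnet
#' @method tidy ctg_lstm
#' @export
tidy.ctg_lstm <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric())
}

#' @rdname tidy.ctgnet
#' @method glance ctg_lstm
#' @export
glance.ctg_lstm <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    units = x$config$units,
    window = x$config$window,
    epochs = if (is.null(h)) 0L else max(h$epoch),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)]
  )
}

#' @rdname tidy.ctgnet
#' @method tidy ctg_cv
#' @export
tidy.ctg_cv <- function(x, ...) dplyr::select(x$folds, -"roc")

#' @rdname tidy.ctgnet
#' @method glance ctg_cv
#' @export
glance.ctg_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary,
    names_from = "metric", values_from = c("mean", "sd")
  )
}

#' @rdname tidy.ctgnet
#' @method tidy ctg_roc
#' @export
tidy.ctg_roc <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.ctgnet
#' @method glance ctg_roc
#' @export
glance.ctg_roc <- function(x, ...) tibble::tibble(auc = auc(x))
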