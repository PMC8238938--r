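# Conventional feature pipeline: spike removal, moving-average smoothing,
# Hilbert-envelope episode detection, two-feature extraction, and the SVM
# and k-means baselines.

#' Replace physiologically implausible spikes
#'
#' Samples outside the plausible FHR band, or jumping by more than
#' `max_step` bpm from the previous sample, are flagged and replaced by the
#' mean of the nearest preceding and following unflagged samples (the
#' single nearest value at the edges). This operationalizes the manual
#' removal of visually evident recording artifacts.
#'
#' @param x Numeric series (bpm).
#' @param fs Sampling rate in Hz (the slope limit is per sample step).
#' @param range Plausible band in bpm.
#' @param max_step Maximum plausible change per sample step, bpm.
#' @return The cleaned numeric series.
#' @export
remove_spikes <- function(x, fs = 1, range = c(50, 210), max_step = 25) {
  if (length(x) == 0L) rlang::abort("Empty series.")
  bad <- !is.finite(x) | x < range[1] | x > range[2]
  # slope flag relative to the previous not-yet-flagged sample
  prev_ok_val <- NA_real_
  for (i in seq_along(x)) {
    if (bad[i]) next
    if (!is.na(prev_ok_val) && abs(x[i] - prev_ok_val) > max_step) {
      bad[i] <- TRUE
    } else {
      prev_ok_val <- x[i]
    }
  }
  if (all(bad)) rlang::abort("Every sample is flagged as a spike; nothing to interpolate from.")
  if (!any(bad)) return(x)
  idx <- which(!bad)
  at <- which(bad)
  if (length(idx) == 1L) {
    x[at] <- x[idx]
    return(x)
  }
  prev_v <- stats::approx(idx, x[idx], xout = at, method = "constant", f = 0, rule = 2)$y
  next_v <- stats::approx(idx, x[idx], xout = at, method = "constant", f = 1, rule = 2)$y
  x[at] <- (prev_v + next_v) / 2
  x
}

#' Bilateral moving-average smoothing
#'
#' Centered moving average over `width` samples (default 15, i.e. 7 on
#' each side); near the edges the window is truncated to the available
#' samples.
#'
#' @param x Numeric series, length at least `width`.
#' @param width Window width in samples (odd).
#' @return The smoothed series, same length.
#' @export
smooth_ma <- function(x, width = 15) {
  n <- length(x)
  if (n < width) {
    rlang::abort(sprintf("Series of length %d is shorter than the %d-point window.", n, width))
  }
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Magnitude of the analytic signal (FFT construction of the Hilbert
# transform companion).
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Detect acceleration and deceleration episodes
#'
#' Works on a smoothed, spike-free FHR series. The baseline is a centered
#' 10-min running median; the deviation from baseline is enveloped through
#' its analytic signal, and excursions whose envelope reaches `min_amp`
#' seed candidate episodes. Each candidate is refined to the zero
#' crossings of the deviation on either side of its extremum, classified
#' by the sign of the deviation there, and kept when the refined excursion
#' lasts at least `min_dur_s` with extremum at least `min_amp` (the
#' standard 15 bpm / 15 s clinical gate). The unsigned area between signal
#' and baseline is integrated by the trapezoid rule.
#'
#' @param x A [ctg_trace()] (its FHR channel is used) or a numeric series.
#' @param fs Sampling rate in Hz; taken from the trace when omitted.
#' @param min_amp Amplitude gate in bpm.
#' @param min_dur_s Duration gate in seconds.
#' @param baseline_window_s Running-median window; records shorter than
#'   this fall back to a global median baseline.
#' @return A tibble with columns `kind` (`acceleration`/`deceleration`),
#'   `onset_s`, `offset_s`, `extremum_bpm` (signed deviation) and
#'   `area_bpm_s`.
#' @export
detect_episodes <- function(x, fs = NULL, min_amp = 15, min_dur_s = 15,
                            baseline_window_s = 600) {
  if (inherits(x, "ctg_trace")) {
    fs <- fs %||% ctg_fs(x)
    x <- x$fhr_bpm
  }
  fs <- fs %||% 1
  n <- length(x)
  empty <- tibble::tibble(
    kind = character(), onset_s = numeric(), offset_s = numeric(),
    extremum_bpm = numeric(), area_bpm_s = numeric()
  )
  if (n < 3L) return(empty)
  k <- as.integer(round(baseline_window_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  baseline <- if (n <= k) {
    rep(stats::median(x), n)
  } else {
    # constant-extend the interior running median: shrinking end windows
    # would let an episode near the record edge dominate its own baseline
    b <- stats::runmed(x, k, endrule = "keep")
    h <- (k - 1L) %/% 2L
    b[seq_len(h)] <- b[h + 1L]
    b[(n - h + 1L):n] <- b[n - h]
    b
  }
  d <- x - baseline
  env <- analytic_envelope(d)
  over <- env >= min_amp
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  refine <- function(i0, i1) {
    seg <- i0:i1
    ext_i <- seg[which.max(abs(d[seg]))]
    s <- sign(d[ext_i])
    if (s == 0) return(NULL)
    on <- ext_i
    while (on > 1L && sign(d[on - 1L]) == s && d[on - 1L] != 0) on <- on - 1L
    off <- ext_i
    while (off < n && sign(d[off + 1L]) == s && d[off + 1L] != 0) off <- off + 1L
    c(on, off, ext_i)
  }
  out <- list()
  seen <- character(0)
  for (j in seq_len(nrow(runs))) {
    ref <- refine(runs[j, 1], runs[j, 2])
    if (is.null(ref)) next
    key <- paste(ref[1], ref[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    dur_s <- (ref[2] - ref[1]) / fs
    ext <- d[ref[3]]
    if (dur_s < min_dur_s || abs(ext) < min_amp) next
    seg <- ref[1]:ref[2]
    area <- sum(diff((seg - 1) / fs) * (abs(d[seg])[-1] + abs(d[seg])[-length(seg)]) / 2)
    out[[length(out) + 1L]] <- tibble::tibble(
      kind = if (ext > 0) "acceleration" else "deceleration",
      onset_s = (ref[1] - 1) / fs,
      offset_s = (ref[2] - 1) / fs,
      extremum_bpm = ext,
      area_bpm_s = area
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$onset_s)
}

#' Aggregate episodes into the two classifier features
#'
#' The conventional baselines use exactly two hand-crafted features: the
#' number of accelerations and the total unsigned deceleration area.
#'
#' @param episodes A tibble from [detect_episodes()].
#' @return A one-row tibble with `n_accelerations` and `total_decel_area`.
#' @export
extract_features <- function(episodes) {
  tibble::tibble(
    n_accelerations = sum(episodes$kind == "acceleration"),
    total_decel_area = sum(episodes$area_bpm_s[episodes$kind == "deceleration"])
  )
}

#' Full preprocessing + feature extraction over a dataset
#'
#' For each record: impute dropout, remove spikes, smooth with the
#' 15-point bilateral moving average, detect episodes and extract the two
#' features.
#'
#' @param dataset A tibble with a `ctg` list-column (and optionally `id`,
#'   `label`, carried through).
#' @return A tibble with one row per record: `id`, `n_accelerations`,
#'   `total_decel_area`, and `label` when present.
#' @export
ctg_features <- function(dataset) {
  dataset <- tibble::as_tibble(dataset)
  feats <- purrr::map(dataset$ctg, function(tr) {
    fs <- ctg_fs(tr)
    x <- impute_trace(tr)$fhr_bpm
    x <- remove_spikes(x, fs)
    x <- smooth_ma(x)
    extract_features(detect_episodes(x, fs))
  })
  out <- dplyr::bind_rows(feats)
  if ("id" %in% names(dataset)) out <- dplyr::bind_cols(dataset["id"], out)
  if ("label" %in% names(dataset)) out$label <- dataset$label
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, c("n_accelerations", "total_decel_area")])
}

#' Radial-kernel SVM baseline on the two features
#'
#' Standardizes the features with training statistics and fits a
#' radial-basis support vector machine (unit cost; kernel width the
#' inverse feature count on standardized inputs). The decision value is
#' oriented so larger means more abnormal, giving a score for ROC sweeps.
#'
#' @param features A tibble with `n_accelerations`, `total_decel_area` and
#'   a factor `label` column (both classes present).
#' @return An object of class `ctg_svm`.
#' @export
fit_ctg_svm <- function(features) {
  y <- droplevels(factor(features$label, levels = c("normal", "abnormal")))
  if (nlevels(y) < 2L) {
    rlang::abort("Training labels contain a single class; the SVM needs both.")
  }
  x <- feature_matrix(features)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)
  fit <- e1071::svm(
    x = xs, y = y, kernel = "radial", cost = 1, gamma = 1 / ncol(xs),
    scale = FALSE
  )
  structure(
    list(fit = fit, center = center, scale = scale_),
    class = "ctg_svm"
  )
}

#' @rdname fit_ctg_svm
#' @param object A fitted `ctg_svm`.
#' @param new_features A tibble with the two feature columns.
#' @param ... Unused.
#' @return `predict()` returns a tibble with `.pred` (factor label) and
#'   `.score` (signed decision value, larger = more abnormal).
#' @export
predict.ctg_svm <- function(object, new_features, ...) {
  xs <- scale(feature_matrix(new_features),
    center = object$center, scale = object$scale
  )
  pred <- stats::predict(object$fit, xs, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # e1071 orients the decision value toward the first training class
  flip <- if (grepl("^abnormal", colnames(attr(pred, "decision.values"))[1])) 1 else -1
  tibble::tibble(
    .pred = factor(as.character(pred), levels = c("normal", "abnormal")),
    .score = flip * as.numeric(dv)
  )
}

#' k-means clustering baseline on the two features
#'
#' Standard k-means (10 restarts under `seed`) on standardized features.
#' Clusters are mapped to outcome labels by training-set majority vote;
#' a tied cluster maps to abnormal.
#'
#' @param features As in [fit_ctg_svm()].
#' @param k Number of clusters.
#' @param seed Integer seed for the restarts.
#' @return An object of class `ctg_kmeans`.
#' @export
fit_ctg_kmeans <- function(features, k = 2, seed = 0) {
  x <- feature_matrix(features)
  if (nrow(unique(x)) < k) {
    rlang::abort(sprintf(
      "Need at least %d distinct feature rows for %d clusters.", k, k
    ))
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)
  km <- withr::with_seed(seed, stats::kmeans(xs, centers = k, nstart = 10))
  y <- factor(features$label, levels = c("normal", "abnormal"))
  label_map <- vapply(seq_len(k), function(cl) {
    tab <- table(y[km$cluster == cl])
    if (length(tab) == 0 || tab[["abnormal"]] >= tab[["normal"]]) "abnormal" else "normal"
  }, character(1))
  structure(
    list(centers = km$centers, label_map = label_map, center = center, scale = scale_),
    class = "ctg_kmeans"
  )
}

#' @rdname fit_ctg_kmeans
#' @param object A fitted `ctg_kmeans`.
#' @param new_features A tibble with the two feature columns.
#' @param ... Unused.
#' @return `predict()` returns a tibble with `.pred` and `.score` (the
#'   distance margin toward the abnormal-mapped centroids).
#' @export
predict.ctg_kmeans <- function(object, new_features, ...) {
  xs <- scale(feature_matrix(new_features),
    center = object$center, scale = object$scale
  )
  d2 <- vapply(seq_len(nrow(object$centers)), function(cl) {
    rowSums(sweep(xs, 2, object$centers[cl, ])^2)
  }, numeric(nrow(xs)))
  d2 <- matrix(d2, nrow = nrow(xs))
  assign <- max.col(-d2)
  abn <- object$label_map == "abnormal"
  score <- if (any(abn) && any(!abn)) {
    sqrt(apply(d2[, !abn, drop = FALSE], 1, min)) -
      sqrt(apply(d2[, abn, drop = FALSE], 1, min))
  } else {
    rep(0, nrow(xs))
  }
  tibble::tibble(
    .pred = factor(object$label_map[assign], levels = c("normal", "abnormal")),
    .score = score
  )
}
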