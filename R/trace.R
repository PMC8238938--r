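# CTG trace container and quality-control operations.

#' Construct a cardiotocogram trace
#'
#' A CTG trace is the universal unit of signal flow in this package: two
#' synchronized channels, fetal heart rate (FHR, bpm) and uterine contraction
#' (UC, arbitrary tocodynamometer units), sampled at a common rate. It is
#' stored as a tibble with one row per sample and columns `time_s`,
#' `fhr_bpm`, `uc_units`, `valid_fhr`, `valid_uc`, plus attributes `fs`
#' (sampling rate, Hz) and `meta` (free-form identifiers).
#'
#' Clinical recorders emit 4 Hz; the convolutional model consumes 1 Hz
#' (see [downsample_trace()]). An FHR sample is valid when it is finite,
#' non-zero and inside the physiological band 50--210 bpm; zero is the
#' conventional dropout sentinel in intrapartum archives. Invalid samples
#' keep their raw value but are masked, so round-trips preserve the file
#' contents bit-for-bit.
#'
#' @param fhr Numeric vector of fetal heart rate samples (bpm). `NA` marks a
#'   missing sample.
#' @param uc Numeric vector of uterine-contraction samples, same length.
#' @param fs Sampling rate in Hz (> 0).
#' @param valid_fhr,valid_uc Optional logical masks; by default derived from
#'   the samples (FHR: finite, non-zero, in \[50, 210\]; UC: finite).
#' @param meta Named list of record identifiers.
#'
#' @return A tibble of class `ctg_trace`.
#' @examples
#' tr <- ctg_trace(fhr = rep(140, 120), uc = rep(10, 120), fs = 4)
#' signal_loss(tr)
#' @export
ctg_trace <- function(fhr, uc, fs, valid_fhr = NULL, valid_uc = NULL,
                      meta = list()) {
  fhr <- as.numeric(fhr)
  uc <- as.numeric(uc)
  if (length(fhr) < 1L) {
    rlang::abort("A CTG trace needs at least one sample.")
  }
  if (length(uc) != length(fhr)) {
    rlang::abort(sprintf(
      "FHR and UC must have the same length (got %d and %d).",
      length(fhr), length(uc)
    ))
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a single positive sampling rate in Hz.")
  }
  if (is.null(valid_fhr)) valid_fhr <- default_fhr_validity(fhr)
  if (is.null(valid_uc)) valid_uc <- is.finite(uc)
  stopifnot(length(valid_fhr) == length(fhr), length(valid_uc) == length(uc))
  out <- tibble::tibble(
    time_s = (seq_along(fhr) - 1) / fs,
    fhr_bpm = fhr,
    uc_units = uc,
    valid_fhr = as.logical(valid_fhr),
    valid_uc = as.logical(valid_uc)
  )
  new_ctg_trace(out, fs = fs, meta = meta)
}

new_ctg_trace <- function(df, fs, meta = list(), episodes = NULL) {
  structure(
    df,
    fs = fs,
    meta = meta,
    episodes = episodes,
    class = c("ctg_trace", class(tibble::tibble()))
  )
}

default_fhr_validity <- function(fhr) {
  is.finite(fhr) & fhr != 0 & fhr >= 50 & fhr <= 210
}

#' @export
print.ctg_trace <- function(x, ...) {
  cat(sprintf(
    "# CTG trace: %d samples at %g Hz (%.1f min), FHR loss %.1f%%\n",
    nrow(x), ctg_fs(x), ctg_duration(x) / 60, 100 * signal_loss(x)
  ))
  NextMethod()
}

#' Trace accessors
#'
#' `ctg_fs()` returns the sampling rate in Hz, `ctg_duration()` the record
#' duration in seconds, `ctg_meta()` the identifier list, and `episodes()`
#' the annotation table attached by the simulator (or `NULL`).
#'
#' @param trace A [ctg_trace()].
#' @return A scalar (`ctg_fs`, `ctg_duration`), a list (`ctg_meta`) or a
#'   tibble of planted episodes (`episodes`).
#' @export
ctg_fs <- function(trace) attr(trace, "fs")

#' @rdname ctg_fs
#' @export
ctg_duration <- function(trace) nrow(trace) / ctg_fs(trace)

#' @rdname ctg_fs
#' @export
ctg_meta <- function(trace) attr(trace, "meta")

#' @rdname ctg_fs
#' @export
episodes <- function(trace) attr(trace, "episodes")

assert_ctg_trace <- function(trace, arg = "trace") {
  if (!inherits(trace, "ctg_trace")) {
    rlang::abort(sprintf("`%s` must be a ctg_trace.", arg))
  }
  invisible(trace)
}

#' Fraction of the FHR channel lost to dropout
#'
#' Signal loss is the fraction of samples whose FHR is invalid (missing,
#' zero, or outside 50--210 bpm). Only the FHR channel enters the fraction:
#' FHR is the classified signal, and hospital exclusion criteria are stated
#' as a single loss percentage. UC validity is surfaced separately through
#' the `valid_uc` column.
#'
#' @param trace A [ctg_trace()].
#' @return A fraction in \[0, 1\].
#' @export
signal_loss <- function(trace) {
  assert_ctg_trace(trace)
  if (nrow(trace) == 0L) rlang::abort("Cannot compute signal loss of an empty trace.")
  mean(!trace$valid_fhr)
}

#' Record-level quality gate
#'
#' A record passes when it is at least `min_duration_s` long *and* its FHR
#' signal loss does not exceed `max_loss`. Both boundaries are inclusive:
#' exclusion criteria are "shorter than 30 min" and "more than 16% loss",
#' so a 30-min record with exactly 16% loss passes.
#'
#' @param trace A [ctg_trace()].
#' @param min_duration_s Minimum duration in seconds (default 1800 = 30 min).
#' @param max_loss Maximum tolerated FHR signal-loss fraction (default 0.16).
#' @return `TRUE` or `FALSE`.
#' @export
passes_quality <- function(trace, min_duration_s = 1800, max_loss = 0.16) {
  assert_ctg_trace(trace)
  ctg_duration(trace) >= min_duration_s && signal_loss(trace) <= max_loss
}

#' Extract the final window of a record
#'
#' Classification uses the last stretch of monitoring before delivery.
#' Trailing runs of zero (or missing) FHR -- the recorder's post-delivery
#' idle output -- are discarded first, so the window is anchored at the
#' last informative FHR sample. Time is rebased to start at 0. The
#' operation is idempotent.
#'
#' @param trace A [ctg_trace()].
#' @param duration_s Window length in seconds (default 1800 = 30 min).
#' @return A [ctg_trace()] of exactly `duration_s * fs` samples.
#' @export
extract_last_window <- function(trace, duration_s = 1800) {
  assert_ctg_trace(trace)
  if (duration_s <= 0) rlang::abort("`duration_s` must be positive.")
  fs <- ctg_fs(trace)
  informative <- is.finite(trace$fhr_bpm) & trace$fhr_bpm != 0
  last_nz <- if (any(informative)) max(which(informative)) else 0L
  if (last_nz == 0L) {
    rlang::abort("Trace has no nonzero FHR samples; cannot anchor a window.")
  }
  n_keep <- as.integer(round(duration_s * fs))
  if (last_nz < n_keep) {
    rlang::abort(sprintf(
      "Record holds %.1f s of usable signal but the window needs %.1f s (short by %.1f s).",
      last_nz / fs, duration_s, (n_keep - last_nz) / fs
    ))
  }
  idx <- (last_nz - n_keep + 1L):last_nz
  out <- trace[idx, , drop = FALSE]
  out$time_s <- (seq_len(n_keep) - 1) / fs
  new_ctg_trace(out, fs = fs, meta = ctg_meta(trace))
}

#' Downsample a trace by per-bin averaging
#'
#' Each output sample is the mean of the *valid* input samples falling in
#' its bin (half-open bins of `fs / target_fs` input samples); a bin with
#' no valid sample becomes an invalid output sample. Averaging valid
#' samples, rather than decimating, keeps information and degrades
#' gracefully under dropout. The canonical use is 4 Hz clinical input to
#' the 1 Hz, 1800-sample model window.
#'
#' @param trace A [ctg_trace()].
#' @param target_fs Target rate in Hz; `fs` must be an integer multiple.
#' @return A [ctg_trace()] of length `floor(n * target_fs / fs)`.
#' @export
downsample_trace <- function(trace, target_fs = 1) {
  assert_ctg_trace(trace)
  fs <- ctg_fs(trace)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    rlang::abort(sprintf(
      "Sampling rate %g Hz is not an integer multiple of target %g Hz.",
      fs, target_fs
    ))
  }
  ratio <- as.integer(round(ratio))
  n_out <- nrow(trace) %/% ratio
  if (n_out < 1L) rlang::abort("Trace too short to downsample.")
  used <- seq_len(n_out * ratio)
  bin_mean <- function(x, valid) {
    x <- ifelse(valid, x, NA_real_)
    m <- matrix(x[used], nrow = ratio)
    out <- colMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  fhr <- bin_mean(trace$fhr_bpm, trace$valid_fhr)
  uc <- bin_mean(trace$uc_units, trace$valid_uc)
  ctg_trace(
    fhr = fhr, uc = uc, fs = target_fs,
    valid_fhr = !is.na(fhr), valid_uc = !is.na(uc),
    meta = ctg_meta(trace)
  )
}

#' Read and write CTG traces as CSV
#'
#' The on-disk dialect is a plain comma-separated file with header
#' `time_s,fhr_bpm,uc_units` (UTF-8, `.` decimal). Empty cells become
#' invalid samples; the sampling rate is inferred as the reciprocal of the
#' median time step. Round-trips are lossless at the printed precision.
#'
#' @param path File path.
#' @param trace A [ctg_trace()].
#' @return `read_ctg_csv()` returns a [ctg_trace()]; `write_ctg_csv()`
#'   returns `path` invisibly.
#' @export
read_ctg_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "fhr_bpm", "uc_units")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "CSV %s lacks required column(s): %s.", path,
      paste(missing_cols, collapse = ", ")
    ))
  }
  dt <- diff(df$time_s)
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    bad <- which(!is.finite(dt) | dt <= 0)[1] + 1L
    rlang::abort(sprintf(
      "Non-monotone or missing time_s at data row %d of %s.", bad, path
    ))
  }
  fs <- if (nrow(df) > 1L) 1 / stats::median(dt) else 1
  ctg_trace(
    fhr = df$fhr_bpm, uc = df$uc_units, fs = fs,
    meta = list(source = path)
  )
}

#' @rdname read_ctg_csv
#' @export
write_ctg_csv <- function(trace, path) {
  assert_ctg_trace(trace)
  readr::write_csv(
    trace[, c("time_s", "fhr_bpm", "uc_units")], path,
    progress = FALSE
  )
  invisible(path)
}

#' Impute invalid samples by linear interpolation
#'
#' The convolutional and recurrent models have no mask channel, so dropout
#' gaps are filled by linear interpolation between the nearest valid
#' samples; leading/trailing gaps take the nearest valid value. Used by
#' the model input pipelines, exported because it is occasionally useful
#' when plotting.
#'
#' @param trace A [ctg_trace()].
#' @return A [ctg_trace()] with every sample valid.
#' @export
impute_trace <- function(trace) {
  assert_ctg_trace(trace)
  fill <- function(x, valid) {
    if (!any(valid)) rlang::abort("Cannot impute a trace with no valid samples.")
    if (all(valid)) return(x)
    idx <- which(valid)
    stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  fhr <- fill(trace$fhr_bpm, trace$valid_fhr)
  uc <- fill(trace$uc_units, trace$valid_uc)
  ctg_trace(
    fhr = fhr, uc = uc, fs = ctg_fs(trace),
    valid_fhr = rep(TRUE, length(fhr)), valid_uc = rep(TRUE, length(uc)),
    meta = ctg_meta(trace)
  )
}
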