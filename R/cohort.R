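# Cohort sorting: outcome labeling, exclusions, quality filtering, and
# balanced dataset assembly.

registry_outcome_cols <- c("ua_ph", "apgar1")

#' Label deliveries as normal or abnormal by postnatal outcome
#'
#' A delivery is *abnormal* when umbilical-artery pH < 7.20 or the 1-min
#' Apgar score < 7; both thresholds are strict, so a delivery at exactly
#' pH 7.20 and Apgar 7 is normal. The abnormal class is the positive class
#' throughout the package.
#'
#' @param registry A data frame with numeric columns `ua_ph` and `apgar1`
#'   (one row per delivery).
#' @param ph_threshold,apgar_threshold Strict lower cutoffs (defaults 7.20
#'   and 7).
#' @return The registry as a tibble with an added factor column `outcome`
#'   (levels `normal`, `abnormal`).
#' @examples
#' label_outcome(tibble::tibble(ua_ph = c(7.19, 7.31), apgar1 = c(9, 8)))
#' @export
label_outcome <- function(registry, ph_threshold = 7.20, apgar_threshold = 7) {
  registry <- tibble::as_tibble(registry)
  missing_cols <- setdiff(registry_outcome_cols, names(registry))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "Registry lacks outcome column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyNA(registry$ua_ph) || anyNA(registry$apgar1)) {
    rlang::abort(paste(
      "Records with missing ua_ph or apgar1 cannot be labeled;",
      "run apply_exclusions() first (they count as lacking sufficient data)."
    ))
  }
  dplyr::mutate(
    registry,
    outcome = factor(
      ifelse(.data$ua_ph < ph_threshold | .data$apgar1 < apgar_threshold,
        "abnormal", "normal"
      ),
      levels = c("normal", "abnormal")
    )
  )
}

#' Apply registry-level exclusions
#'
#' Removes, in this fixed order, (1) stillbirths, (2) multiple pregnancies
#' (plurality > 1), (3) premature deliveries (gestational age < 37 weeks,
#' the clinical definition of preterm), and (4) records lacking sufficient
#' data (`has_sufficient_data` false, or missing pH/Apgar). Each record is
#' counted at the first stage it fails, so stage counts are disjoint and
#' sum to the total removed.
#'
#' @param registry A data frame with columns `stillbirth` (logical),
#'   `plurality` (integer), `gestational_age_weeks` (numeric),
#'   `has_sufficient_data` (logical), plus outcome columns.
#' @param preterm_weeks Gestational-age cutoff in weeks (default 37).
#' @return The kept records as a tibble; the per-stage removal table is
#'   attached and available via [cohort_summary()].
#' @export
apply_exclusions <- function(registry, preterm_weeks = 37) {
  registry <- tibble::as_tibble(registry)
  insufficient <- !registry$has_sufficient_data
  if (all(registry_outcome_cols %in% names(registry))) {
    insufficient <- insufficient | is.na(registry$ua_ph) | is.na(registry$apgar1)
  }
  fail_stage <- dplyr::case_when(
    registry$stillbirth ~ "stillbirth",
    registry$plurality > 1 ~ "multiple_pregnancy",
    registry$gestational_age_weeks < preterm_weeks ~ "preterm",
    insufficient ~ "insufficient_data",
    TRUE ~ "kept"
  )
  summary <- tibble::tibble(
    stage = c(
      "initial", "stillbirth", "multiple_pregnancy", "preterm",
      "insufficient_data", "kept"
    ),
    n = c(
      nrow(registry),
      sum(fail_stage == "stillbirth"),
      sum(fail_stage == "multiple_pregnancy"),
      sum(fail_stage == "preterm"),
      sum(fail_stage == "insufficient_data"),
      sum(fail_stage == "kept")
    )
  )
  kept <- registry[fail_stage == "kept", , drop = FALSE]
  attr(kept, "cohort_summary") <- summary
  kept
}

#' @rdname apply_exclusions
#' @param x A tibble returned by [apply_exclusions()].
#' @export
cohort_summary <- function(x) attr(x, "cohort_summary")

#' Keep only records whose CTG passes the quality gate
#'
#' Applies [passes_quality()] (default: at least 30 min of record and at
#' most 16% FHR signal loss) to each record's trace.
#'
#' @param registry A tibble with a list-column `ctg` of [ctg_trace()]s.
#' @param min_duration_s,max_loss Passed to [passes_quality()].
#' @return The subset of rows whose trace passes.
#' @export
quality_filter <- function(registry, min_duration_s = 1800, max_loss = 0.16) {
  registry <- tibble::as_tibble(registry)
  if (!"ctg" %in% names(registry)) {
    rlang::abort("Registry has no `ctg` list-column of traces.")
  }
  missing_trace <- vapply(registry$ctg, is.null, logical(1))
  if (any(missing_trace)) {
    rlang::abort(sprintf(
      "%d record(s) lack a loaded trace (first: row %d).",
      sum(missing_trace), which(missing_trace)[1]
    ))
  }
  ok <- vapply(
    registry$ctg, passes_quality, logical(1),
    min_duration_s = min_duration_s, max_loss = max_loss
  )
  registry[ok, , drop = FALSE]
}

#' Assemble a class-balanced labeled dataset
#'
#' Takes all `n_per_group` abnormal records (or errors if there are not
#' exactly enough) and draws `n_per_group` normal records uniformly without
#' replacement under `seed`. Callers are expected to have already applied
#' the emergency-cesarean exclusion and the quality filter to the normal
#' pool.
#'
#' @param normals,abnormals Tibbles of eligible records (any columns; a
#'   `ctg` list-column is carried along if present).
#' @param n_per_group Records per class; defaults to `nrow(abnormals)`.
#' @param seed Integer seed driving the normal subsample.
#' @return A tibble of `2 * n_per_group` rows with a factor column `label`.
#' @export
build_balanced_dataset <- function(normals, abnormals,
                                   n_per_group = nrow(abnormals), seed = 0) {
  normals <- tibble::as_tibble(normals)
  abnormals <- tibble::as_tibble(abnormals)
  if (nrow(abnormals) < n_per_group) {
    rlang::abort(sprintf(
      "Need %d abnormal records but only %d available.",
      n_per_group, nrow(abnormals)
    ))
  }
  if (nrow(normals) < n_per_group) {
    rlang::abort(sprintf(
      "Need %d eligible normal records but only %d available.",
      n_per_group, nrow(normals)
    ))
  }
  abn <- abnormals[seq_len(n_per_group), , drop = FALSE]
  idx <- withr::with_seed(seed, sample.int(nrow(normals), n_per_group))
  nor <- normals[idx, , drop = FALSE]
  abn$label <- factor("abnormal", levels = c("normal", "abnormal"))
  nor$label <- factor("normal", levels = c("normal", "abnormal"))
  dplyr::bind_rows(nor, abn)
}
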