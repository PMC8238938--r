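# Synthetic cardiotocograms and clinical registries.
#
# The simulator targets the statistical and event structure of intrapartum
# monitoring -- baseline, band-limited variability, accelerations and the
# deceleration taxonomy keyed to uterine contractions, contiguous signal
# dropout -- not cardiovascular physiology. Every planted episode is
# returned as ground truth so detection and classification can be scored.

#' Trace generator parameters
#'
#' Defaults describe a 30-min record at the model's 1 Hz scale. Baseline is
#' drawn uniformly from the normocardic band 110--160 bpm unless fixed.
#' Variability is smoothed white noise whose amplitude differs by class
#' (reduced variability is the hallmark of the compromised class). Uterine
#' contractions recur roughly every 3 min with ~70 s width; decelerations
#' are time-locked to contraction peaks at a kind-specific lag (early:
#' |lag| <= 5 s; late: lag >= 30 s). Dropout replaces an exact fraction of
#' samples with zero-valued invalid runs of geometric length.
#'
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz (1 = model scale, 4 = clinical recorders).
#' @param baseline_bpm Fixed FHR baseline, or `NULL` to draw U(110, 160).
#' @param variability_amp_bpm Named amplitudes (bpm) of baseline
#'   variability per class.
#' @param contraction_period_s,contraction_width_s,contraction_amp Uterine
#'   contraction train: mean peak spacing, bump width and amplitude.
#' @param uc_baseline,uc_noise UC resting tone and noise amplitude (units).
#' @param event_rates Named list (`normal`, `abnormal`) of expected episode
#'   counts per record for each kind; counts are Poisson. Abnormal records
#'   are guaranteed at least one late or prolonged deceleration.
#' @param dropout_fraction Fraction of samples lost (exact, in \[0, 1)).
#' @param dropout_mean_run_s Mean length of a contiguous dropout run.
#' @param max_retries Regeneration attempts when planted events collide
#'   into a physiologically impossible (< 50 bpm) trace.
#' @return A list of class `trace_gen_params`.
#' @export
trace_gen_params <- function(duration_s = 1800,
                             fs = 1,
                             baseline_bpm = NULL,
                             variability_amp_bpm = c(normal = 10, abnormal = 3),
                             contraction_period_s = 180,
                             contraction_width_s = 70,
                             contraction_amp = 40,
                             uc_baseline = 10,
                             uc_noise = 1.5,
                             event_rates = list(
                               normal = c(
                                 acceleration = 4, early_decel = 0.8,
                                 variable_decel = 0.8, late_decel = 0,
                                 prolonged_decel = 0
                               ),
                               abnormal = c(
                                 acceleration = 0.5, early_decel = 1,
                                 variable_decel = 1, late_decel = 3,
                                 prolonged_decel = 0.7
                               )
                             ),
                             dropout_fraction = 0.05,
                             dropout_mean_run_s = 30,
                             max_retries = 10) {
  stopifnot(
    duration_s > 0, fs > 0,
    dropout_fraction >= 0, dropout_fraction < 1,
    contraction_period_s > 0, contraction_width_s > 0
  )
  structure(
    list(
      duration_s = duration_s, fs = fs, baseline_bpm = baseline_bpm,
      variability_amp_bpm = variability_amp_bpm,
      contraction_period_s = contraction_period_s,
      contraction_width_s = contraction_width_s,
      contraction_amp = contraction_amp,
      uc_baseline = uc_baseline, uc_noise = uc_noise,
      event_rates = event_rates,
      dropout_fraction = dropout_fraction,
      dropout_mean_run_s = dropout_mean_run_s,
      max_retries = max_retries
    ),
    class = "trace_gen_params"
  )
}

# Raised-cosine (Tukey) pulse over [onset, offset] with unit peak.
# taper_frac 1 is a pure raised cosine; smaller values add a flat core.
episode_pulse <- function(time_s, onset_s, offset_s, taper_frac = 1) {
  dur <- offset_s - onset_s
  u <- (time_s - onset_s) / dur
  w <- numeric(length(time_s))
  inside <- u >= 0 & u <= 1
  a <- taper_frac / 2
  ui <- u[inside]
  wi <- rep(1, length(ui))
  left <- ui < a
  right <- ui > 1 - a
  wi[left] <- 0.5 * (1 - cos(pi * ui[left] / a))
  wi[right] <- 0.5 * (1 - cos(pi * (1 - ui[right]) / a))
  w[inside] <- wi
  w
}

# Draw episode specs for one record. Contractions peaks are supplied so
# decelerations can be locked to them.
draw_episodes <- function(label, params, peaks_s, duration_s) {
  rates <- params$event_rates[[label]]
  counts <- stats::setNames(
    vapply(rates, function(r) stats::rpois(1, r), integer(1)), names(rates)
  )
  if (label == "abnormal" &&
      counts[["late_decel"]] + counts[["prolonged_decel"]] == 0) {
    counts[["late_decel"]] <- 1L
  }
  occupied <- matrix(numeric(0), ncol = 2)
  overlaps <- function(on, off) {
    nrow(occupied) > 0 && any(on < occupied[, 2] & off > occupied[, 1])
  }
  specs <- list()
  free_peaks <- peaks_s
  add <- function(kind, onset, offset, depth, lag) {
    occupied <<- rbind(occupied, c(onset, offset))
    specs[[length(specs) + 1L]] <<- tibble::tibble(
      kind = kind, onset_s = onset, offset_s = offset,
      depth_bpm = depth, lag_s = lag
    )
  }
  place_free <- function(kind, dur, depth) {
    if (dur >= duration_s) return(invisible(FALSE))
    for (try in 1:50) {
      onset <- stats::runif(1, 0, duration_s - dur)
      if (!overlaps(onset, onset + dur)) {
        add(kind, onset, onset + dur, depth, NA_real_)
        return(invisible(TRUE))
      }
    }
    invisible(FALSE)
  }
  place_locked <- function(kind, dur, depth, lag) {
    if (length(free_peaks) == 0 || dur >= duration_s) return(invisible(FALSE))
    for (try in 1:50) {
      pk <- free_peaks[sample.int(length(free_peaks), 1)]
      onset <- pk + lag - dur / 2
      offset <- onset + dur
      if (onset >= 0 && offset <= duration_s && !overlaps(onset, offset)) {
        free_peaks <<- setdiff(free_peaks, pk)
        add(kind, onset, offset, depth, lag)
        return(invisible(TRUE))
      }
    }
    invisible(FALSE)
  }
  for (i in seq_len(counts[["acceleration"]])) {
    place_free("acceleration", stats::runif(1, 20, 60), stats::runif(1, 15, 30))
  }
  for (i in seq_len(counts[["early_decel"]])) {
    place_locked(
      "early_decel", stats::runif(1, 40, 80), -stats::runif(1, 15, 30),
      stats::runif(1, -5, 5)
    )
  }
  for (i in seq_len(counts[["variable_decel"]])) {
    place_locked(
      "variable_decel", stats::runif(1, 20, 60), -stats::runif(1, 20, 55),
      stats::runif(1, -20, 20)
    )
  }
  forced_late <- FALSE
  for (i in seq_len(counts[["late_decel"]])) {
    ok <- place_locked(
      "late_decel", stats::runif(1, 45, 90), -stats::runif(1, 20, 50),
      stats::runif(1, 30, 60)
    )
    forced_late <- forced_late || ok
  }
  for (i in seq_len(counts[["prolonged_decel"]])) {
    ok <- place_free(
      "prolonged_decel", stats::runif(1, 120, 240), -stats::runif(1, 25, 50)
    )
    forced_late <- forced_late || ok
  }
  if (label == "abnormal" && !forced_late) {
    # guarantee the class-defining event even under crowded placement
    half <- min(30, duration_s / 2 - 1)
    add("late_decel", duration_s / 2 - half, duration_s / 2 + half, -30, 40)
  }
  if (length(specs) == 0) {
    return(tibble::tibble(
      kind = character(), onset_s = numeric(), offset_s = numeric(),
      depth_bpm = numeric(), lag_s = numeric()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(specs), .data$onset_s)
}

# Band-limited variability: white noise smoothed by a ~5 s moving average,
# rescaled so its standard deviation is amp / 3 (peak-to-peak roughly amp).
variability_noise <- function(n, fs, amp) {
  if (amp <= 0 || n < 2) return(numeric(n))
  w <- max(3L, as.integer(round(5 * fs)))
  x <- stats::filter(stats::rnorm(n + 2 * w), rep(1 / w, w), sides = 2)
  x <- x[(w + 1):(w + n)]
  x[is.na(x)] <- 0
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * (amp / 3)
}

#' Simulate one annotated CTG trace
#'
#' Generates a two-channel record under [trace_gen_params()]: UC is a
#' resting tone plus a Gaussian-bump contraction train; FHR is baseline
#' plus band-limited variability plus raised-cosine episode pulses, with
#' decelerations time-locked to contraction peaks at their kind-specific
#' lag. An exact `dropout_fraction` of samples is replaced by zero-valued
#' invalid runs. The planted episodes are attached to the result and
#' retrievable with [episodes()].
#'
#' @param label `"normal"` or `"abnormal"`; controls variability amplitude
#'   and event rates. Abnormal records always contain at least one late or
#'   prolonged deceleration.
#' @param params A [trace_gen_params()].
#' @param seed Optional integer; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A [ctg_trace()] with an `episodes` attribute.
#' @examples
#' tr <- simulate_trace("abnormal", seed = 1)
#' episodes(tr)
#' @export
simulate_trace <- function(label = c("normal", "abnormal"),
                           params = trace_gen_params(), seed = NULL) {
  label <- match.arg(label)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_trace(label, params)))
  }
  n <- as.integer(round(params$duration_s * params$fs))
  t_s <- (seq_len(n) - 1) / params$fs

  # uterine contraction channel
  period <- params$contraction_period_s
  first <- stats::runif(1, 0, period)
  k_max <- ceiling(params$duration_s / period) + 1L
  gaps <- period * exp(stats::rnorm(k_max, 0, 0.05))
  peaks <- first + c(0, cumsum(gaps))
  peaks <- peaks[peaks < params$duration_s]
  sigma <- params$contraction_width_s / 4
  uc <- rep(params$uc_baseline, n)
  for (pk in peaks) {
    amp <- params$contraction_amp * stats::runif(1, 0.7, 1.2)
    uc <- uc + amp * exp(-(t_s - pk)^2 / (2 * sigma^2))
  }
  uc <- uc + variability_noise(n, params$fs, 3 * params$uc_noise)
  uc <- pmax(uc, 0)

  baseline <- params$baseline_bpm %||% stats::runif(1, 110, 160)
  amp <- params$variability_amp_bpm[[label]]

  for (attempt in seq_len(params$max_retries)) {
    spec <- draw_episodes(label, params, peaks, params$duration_s)
    fhr <- rep(baseline, n) + variability_noise(n, params$fs, amp)
    if (nrow(spec) > 0) {
      for (i in seq_len(nrow(spec))) {
        taper <- if (spec$kind[i] == "prolonged_decel") 0.4 else 1
        fhr <- fhr + spec$depth_bpm[i] *
          episode_pulse(t_s, spec$onset_s[i], spec$offset_s[i], taper)
      }
    }
    if (min(fhr) >= 50 && max(fhr) <= 210) break
    if (attempt == params$max_retries) {
      rlang::abort("Could not place episodes without leaving 50-210 bpm; lower depths or rates.")
    }
  }

  valid <- rep(TRUE, n)
  n_drop <- as.integer(round(params$dropout_fraction * n))
  if (n_drop > 0) {
    mean_run <- max(1, params$dropout_mean_run_s * params$fs)
    dropped <- 0L
    guard <- 0L
    while (dropped < n_drop && guard < 10000L) {
      guard <- guard + 1L
      len <- min(1L + stats::rgeom(1, 1 / mean_run), n_drop - dropped)
      start <- sample.int(n - len + 1L, 1)
      run <- start:(start + len - 1L)
      fresh <- run[valid[run]]
      valid[fresh] <- FALSE
      dropped <- dropped + length(fresh)
    }
    fhr[!valid] <- 0
  }

  trace <- ctg_trace(
    fhr = fhr, uc = uc, fs = params$fs,
    valid_fhr = valid, valid_uc = rep(TRUE, n),
    meta = list(label = label, baseline_bpm = baseline)
  )
  attr(trace, "episodes") <- spec
  trace
}

#' Cohort generator parameters
#'
#' Stage sizes default to a delivery registry of 5406 records: 15
#' stillbirths, 316 multiple pregnancies, 775 preterm deliveries and 619
#' records lacking sufficient data are excluded, leaving 3681; 298 of the
#' remainder are abnormal by outcome, of which 136 carry planted CTG
#' quality failures (leaving 162); on the normal branch 617 emergency
#' cesareans and 812 quality failures leave 1954 eligible controls.
#' Group-conditional outcomes are Normal(7.31, 0.05) / Normal(7.25, 0.11)
#' for pH and rounded, 0--10-clipped Normal(8.31, 0.65) / Normal(4.30,
#' 1.81) for 1-min Apgar, rejection-sampled so every record's drawn
#' outcome agrees with its intended label (the abnormal pH mean sits above
#' the 7.20 threshold: many abnormals qualify through Apgar alone).
#'
#' @param n_initial,n_stillbirth,n_twins,n_preterm,n_insufficient Registry
#'   stage sizes.
#' @param n_abnormal Abnormal-outcome records among those kept.
#' @param abnormal_quality_fail,normal_quality_fail Planted CTG quality
#'   failures per branch (half too-short records, half excessive loss).
#' @param n_emergency_cs Emergency cesareans among normal-labeled records.
#' @param normal_ph,abnormal_ph,normal_apgar,abnormal_apgar Mean/SD pairs
#'   of the group-conditional outcome distributions.
#' @param trace A [trace_gen_params()] used for generated traces.
#' @return A list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_initial = 5406,
                              n_stillbirth = 15,
                              n_twins = 316,
                              n_preterm = 775,
                              n_insufficient = 619,
                              n_abnormal = 298,
                              abnormal_quality_fail = 136,
                              n_emergency_cs = 617,
                              normal_quality_fail = 812,
                              normal_ph = c(mean = 7.31, sd = 0.05),
                              abnormal_ph = c(mean = 7.25, sd = 0.11),
                              normal_apgar = c(mean = 8.31, sd = 0.65),
                              abnormal_apgar = c(mean = 4.30, sd = 1.81),
                              trace = trace_gen_params()) {
  n_kept <- n_initial - n_stillbirth - n_twins - n_preterm - n_insufficient
  n_normal <- n_kept - n_abnormal
  if (n_kept < 0 || n_abnormal > n_kept) {
    rlang::abort("Inconsistent stage sizes: exclusions exceed the registry.")
  }
  if (abnormal_quality_fail > n_abnormal) {
    rlang::abort("abnormal_quality_fail exceeds the abnormal branch size.")
  }
  if (n_emergency_cs + normal_quality_fail > n_normal) {
    rlang::abort("Normal-branch removals exceed the normal branch size.")
  }
  structure(
    list(
      n_initial = n_initial, n_stillbirth = n_stillbirth, n_twins = n_twins,
      n_preterm = n_preterm, n_insufficient = n_insufficient,
      n_abnormal = n_abnormal, abnormal_quality_fail = abnormal_quality_fail,
      n_emergency_cs = n_emergency_cs,
      normal_quality_fail = normal_quality_fail,
      normal_ph = normal_ph, abnormal_ph = abnormal_ph,
      normal_apgar = normal_apgar, abnormal_apgar = abnormal_apgar,
      trace = trace
    ),
    class = "cohort_gen_params"
  )
}

#' Draw group-conditional delivery outcomes
#'
#' Rejection-samples (pH, Apgar) pairs from the group's distributions until
#' every pair agrees with the intended label under [label_outcome()]'s
#' thresholds, so generated registries are label-consistent by
#' construction.
#'
#' @param n Number of deliveries.
#' @param group `"normal"` or `"abnormal"`.
#' @param params A [cohort_gen_params()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `ua_ph`, `apgar1`.
#' @export
simulate_outcomes <- function(n, group = c("normal", "abnormal"),
                              params = cohort_gen_params(), seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_outcomes(n, group, params)))
  }
  ph_par <- if (group == "normal") params$normal_ph else params$abnormal_ph
  ap_par <- if (group == "normal") params$normal_apgar else params$abnormal_apgar
  ph <- numeric(0)
  ap <- integer(0)
  while (length(ph) < n) {
    m <- 2L * (n - length(ph)) + 10L
    cand_ph <- stats::rnorm(m, ph_par[["mean"]], ph_par[["sd"]])
    cand_ap <- pmin(pmax(round(stats::rnorm(m, ap_par[["mean"]], ap_par[["sd"]])), 0L), 10L)
    abn <- cand_ph < 7.20 | cand_ap < 7
    keep <- if (group == "abnormal") abn else !abn
    ph <- c(ph, cand_ph[keep])
    ap <- c(ap, cand_ap[keep])
  }
  tibble::tibble(ua_ph = ph[seq_len(n)], apgar1 = as.integer(ap[seq_len(n)]))
}

#' Simulate a full delivery registry with CTG traces
#'
#' Emits a registry whose stage sizes match [cohort_gen_params()] exactly
#' (exclusion flags disjoint), with label-consistent outcomes, planted
#' emergency-cesarean flags, and planted CTG quality failures. Traces are
#' generated for every record that faces a quality filter (the abnormal
#' branch and the post-cesarean normal branch); quality failures are
#' realized as genuinely short records or records with excessive planted
#' dropout, so running [quality_filter()] on the generated traces
#' reproduces the planted counts for any seed.
#'
#' @param params A [cohort_gen_params()].
#' @param seed Integer master seed; per-record substreams are derived from
#'   it so subsets regenerate identically.
#' @param traces `"quality"` (default) generates traces for records that
#'   face a quality filter; `"none"` skips trace generation.
#' @return A tibble with one row per delivery: identifiers, outcomes,
#'   exclusion flags, the intended label in `intended_outcome`, and a
#'   `ctg` list-column (`NULL` where no trace was generated).
#' @export
simulate_cohort <- function(params = cohort_gen_params(), seed = 0,
                            traces = c("quality", "none")) {
  traces <- match.arg(traces)
  withr::with_seed(seed, {
    n <- params$n_initial
    n_kept <- n - params$n_stillbirth - params$n_twins - params$n_preterm -
      params$n_insufficient
    category <- sample(rep(
      c("stillbirth", "twins", "preterm", "insufficient", "kept"),
      c(
        params$n_stillbirth, params$n_twins, params$n_preterm,
        params$n_insufficient, n_kept
      )
    ))
    kept_idx <- which(category == "kept")
    intended <- rep(NA_character_, n)
    intended[kept_idx] <- sample(rep(
      c("abnormal", "normal"), c(params$n_abnormal, n_kept - params$n_abnormal)
    ))

    ua_ph <- rep(NA_real_, n)
    apgar1 <- rep(NA_integer_, n)
    abn_idx <- which(!is.na(intended) & intended == "abnormal")
    nor_idx <- which(!is.na(intended) & intended == "normal")
    oc_a <- simulate_outcomes(length(abn_idx), "abnormal", params)
    oc_n <- simulate_outcomes(length(nor_idx), "normal", params)
    ua_ph[abn_idx] <- oc_a$ua_ph
    apgar1[abn_idx] <- oc_a$apgar1
    ua_ph[nor_idx] <- oc_n$ua_ph
    apgar1[nor_idx] <- oc_n$apgar1
    # excluded-but-recorded deliveries get unconstrained normal-group draws
    excl_rec <- which(category %in% c("stillbirth", "twins", "preterm"))
    ua_ph[excl_rec] <- stats::rnorm(
      length(excl_rec), params$normal_ph[["mean"]], params$normal_ph[["sd"]]
    )
    apgar1[excl_rec] <- pmin(pmax(round(stats::rnorm(
      length(excl_rec), params$normal_apgar[["mean"]], params$normal_apgar[["sd"]]
    )), 0L), 10L)

    sample_idx <- function(x, k) x[sample.int(length(x), k)]
    emergency_cs <- rep(FALSE, n)
    emergency_cs[sample_idx(nor_idx, params$n_emergency_cs)] <- TRUE

    # planted CTG quality: pass, short record, or excessive dropout
    quality <- rep(NA_character_, n)
    fail_modes <- function(k) {
      sample(rep(c("short", "loss"), c(k %/% 2, k - k %/% 2)))
    }
    quality[abn_idx] <- "pass"
    abn_fail <- sample_idx(abn_idx, params$abnormal_quality_fail)
    quality[abn_fail] <- fail_modes(params$abnormal_quality_fail)
    nor_branch <- setdiff(nor_idx, which(emergency_cs))
    quality[nor_branch] <- "pass"
    nor_fail <- sample_idx(nor_branch, params$normal_quality_fail)
    quality[nor_fail] <- fail_modes(params$normal_quality_fail)

    gest <- stats::runif(n, 37, 41.5)
    gest[category == "preterm"] <- stats::runif(params$n_preterm, 28, 36.9)

    registry <- tibble::tibble(
      id = sprintf("D%05d", seq_len(n)),
      ua_ph = ua_ph,
      apgar1 = apgar1,
      gestational_age_weeks = gest,
      plurality = ifelse(category == "twins", 2L, 1L),
      stillbirth = category == "stillbirth",
      emergency_cs = emergency_cs,
      has_sufficient_data = category != "insufficient",
      intended_outcome = intended,
      quality = quality
    )

    registry$ctg <- vector("list", n)
    if (traces == "quality") {
      gen_idx <- which(!is.na(quality))
      sub_seeds <- sample.int(.Machine$integer.max - 1L, length(gen_idx))
      registry$ctg[gen_idx] <- purrr::map2(
        gen_idx, sub_seeds,
        function(i, s) {
          tp <- params$trace
          if (quality[i] == "short") tp$duration_s <- 1200
          if (quality[i] == "loss") tp$dropout_fraction <- 0.25
          simulate_trace(intended[i], tp, seed = s)
        }
      )
    }
    registry
  })
}

#' Simulate a balanced, quality-passing benchmark dataset
#'
#' Convenience wrapper producing `n_per_group` normal and abnormal traces
#' at the model scale (defaults: 1 Hz, 30 min, 5% dropout), skipping the
#' registry machinery. This is the dataset the end-to-end classification
#' benchmark runs on.
#'
#' @param n_per_group Traces per class.
#' @param params A [trace_gen_params()].
#' @param seed Integer master seed.
#' @return A tibble with columns `id`, `label` and list-column `ctg`.
#' @export
simulate_dataset <- function(n_per_group = 162, params = trace_gen_params(),
                             seed = 0) {
  withr::with_seed(seed, {
    labels <- rep(c("normal", "abnormal"), each = n_per_group)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
    tibble::tibble(
      id = sprintf("S%04d", seq_along(labels)),
      label = factor(labels, levels = c("normal", "abnormal")),
      ctg = purrr::map2(labels, sub_seeds, function(lb, s) {
        simulate_trace(lb, params, seed = s)
      })
    )
  })
}
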