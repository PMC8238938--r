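# Shared fixture builders: everything is generated in code at test time.

# Generator settings with all stochastic terms off: constant-baseline,
# episode-free, dropout-free records.
quiet_params <- function(duration_s = 1800, fs = 1, baseline = 140) {
  trace_gen_params(
    duration_s = duration_s, fs = fs, baseline_bpm = baseline,
    variability_amp_bpm = c(normal = 0, abnormal = 0),
    dropout_fraction = 0,
    event_rates = list(
      normal = c(
        acceleration = 0, early_decel = 0, variable_decel = 0,
        late_decel = 0, prolonged_decel = 0
      ),
      abnormal = c(
        acceleration = 0, early_decel = 0, variable_decel = 0,
        late_decel = 1, prolonged_decel = 0
      )
    )
  )
}

# Noiseless but fully evented generator settings (for detection oracles).
noiseless_params <- function() {
  trace_gen_params(
    variability_amp_bpm = c(normal = 0, abnormal = 0),
    dropout_fraction = 0
  )
}

constant_trace <- function(n = 1800, fs = 1, fhr = 140, uc = 10) {
  ctg_trace(fhr = rep(fhr, n), uc = rep(uc, n), fs = fs)
}

# Brute-force AUC: fraction of (abnormal, normal) pairs ranked correctly,
# ties counted half. Independent oracle for roc_auc().
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == "abnormal"]
  neg <- scores[labels == "normal"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A tiny registry with all fields the cohort pipeline needs.
toy_registry <- function(n = 6) {
  tibble::tibble(
    id = sprintf("T%02d", seq_len(n)),
    ua_ph = rep(7.31, n),
    apgar1 = rep(9L, n),
    gestational_age_weeks = rep(39, n),
    plurality = rep(1L, n),
    stillbirth = rep(FALSE, n),
    emergency_cs = rep(FALSE, n),
    has_sufficient_data = rep(TRUE, n)
  )
}
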