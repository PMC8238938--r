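# Trace container, signal-loss accounting, windowing, resampling, CSV I/O.

test_that("signal loss counts invalid FHR samples only", {
  expect_equal(signal_loss(constant_trace(100)), 0)

  fhr <- rep(140, 1800)
  fhr[1:288] <- 0
  tr <- ctg_trace(fhr, rep(10, 1800), fs = 1)
  expect_equal(signal_loss(tr), 0.16)

  # UC invalidity does not enter the fraction
  tr2 <- ctg_trace(rep(140, 100), rep(NA_real_, 100), fs = 1)
  expect_equal(signal_loss(tr2), 0)

  # out-of-band and missing FHR both count
  fhr3 <- c(rep(140, 8), 300, NA)
  expect_equal(signal_loss(ctg_trace(fhr3, rep(10, 10), fs = 1)), 0.2)
})

test_that("generator dropout fraction is recovered exactly", {
  for (seed in 1:5) {
    p <- trace_gen_params(dropout_fraction = 0.10)
    tr <- simulate_trace("normal", p, seed = seed)
    expect_equal(signal_loss(tr), 0.10, tolerance = 1 / nrow(tr))
  }
})

test_that("quality gate boundaries are inclusive", {
  fhr <- rep(140, 1800)
  fhr[seq_len(288)] <- 0 # exactly 16%
  tr <- ctg_trace(fhr, rep(10, 1800), fs = 1)
  expect_true(passes_quality(tr))

  expect_false(passes_quality(constant_trace(1799))) # 1 s short
  fhr2 <- rep(140, 3600)
  fhr2[seq_len(580)] <- 0 # 16.1%
  expect_false(passes_quality(ctg_trace(fhr2, rep(10, 3600), fs = 1)))
})

test_that("last-window extraction anchors at the last nonzero FHR", {
  # 60-min record, 30-min window
  tr <- constant_trace(3600)
  w <- extract_last_window(tr, 1800)
  expect_equal(nrow(w), 1800)
  expect_equal(w$fhr_bpm[1800], 140)
  expect_equal(w$time_s, 0:1799)

  # identity on an exact-length record without trailing zeros
  tr30 <- constant_trace(1800)
  w30 <- extract_last_window(tr30, 1800)
  expect_equal(w30$fhr_bpm, tr30$fhr_bpm)

  # 45-min record with a planted 5-min trailing zero run: window covers
  # minutes 10-40
  fhr <- c(seq_len(2400) / 10 + 100, rep(0, 300))
  tr45 <- ctg_trace(fhr, rep(10, 2700), fs = 1)
  w45 <- extract_last_window(tr45, 1800)
  expect_equal(w45$fhr_bpm, fhr[601:2400])

  # idempotent
  expect_equal(
    extract_last_window(w45, 1800)$fhr_bpm,
    w45$fhr_bpm
  )

  expect_error(extract_last_window(constant_trace(1000), 1800), "short")
})

test_that("downsampling averages valid samples per bin", {
  tr <- constant_trace(7200, fs = 4)
  d <- downsample_trace(tr, 1)
  expect_equal(nrow(d), 1800)
  expect_equal(ctg_fs(d), 1)
  expect_equal(d$fhr_bpm, rep(140, 1800))

  # arithmetic mean within a bin
  tr2 <- ctg_trace(c(138, 140, 142, 144), c(1, 2, 3, 4), fs = 4)
  d2 <- downsample_trace(tr2, 1)
  expect_equal(d2$fhr_bpm, 141)
  expect_equal(d2$uc_units, 2.5)

  # a bin whose samples are all invalid yields an invalid sample; a bin
  # with some valid samples averages only those
  fhr <- c(0, 0, 0, 0, 140, 0, 150, 0)
  d3 <- downsample_trace(ctg_trace(fhr, rep(10, 8), fs = 4), 1)
  expect_false(d3$valid_fhr[1])
  expect_equal(d3$fhr_bpm[2], 145)

  # length contract floor(n * target / fs)
  d4 <- downsample_trace(constant_trace(7201, fs = 4), 1)
  expect_equal(nrow(d4), 1800)

  expect_error(downsample_trace(constant_trace(100, fs = 3), 2), "multiple")
})

test_that("CSV round-trip preserves samples and validity", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- simulate_trace("abnormal", trace_gen_params(duration_s = 120), seed = 4)
  write_ctg_csv(tr, path)
  back <- read_ctg_csv(path)
  expect_equal(back$fhr_bpm, tr$fhr_bpm, tolerance = 1e-12)
  expect_equal(back$uc_units, tr$uc_units, tolerance = 1e-12)
  expect_equal(back$valid_fhr, tr$valid_fhr)
  expect_equal(ctg_fs(back), 1)

  # 0.25 s time step implies 4 Hz
  readr::write_csv(
    tibble::tibble(time_s = (0:7) / 4, fhr_bpm = 140, uc_units = 5), path
  )
  expect_equal(ctg_fs(read_ctg_csv(path)), 4)

  # empty cell becomes an invalid sample, length preserved
  writeLines(
    c("time_s,fhr_bpm,uc_units", "0,140,5", "1,,5", "2,141,5"), path
  )
  tr3 <- read_ctg_csv(path)
  expect_equal(nrow(tr3), 3)
  expect_false(tr3$valid_fhr[2])

  writeLines(c("time_s,fhr_bpm", "0,140"), path)
  expect_error(read_ctg_csv(path), "uc_units")
  writeLines(
    c("time_s,fhr_bpm,uc_units", "0,140,5", "2,140,5", "1,140,5"), path
  )
  expect_error(read_ctg_csv(path), "row 3")
})

test_that("imputation fills dropout by interpolation", {
  fhr <- c(140, 0, 0, 146, NA, 150)
  tr <- impute_trace(ctg_trace(fhr, rep(10, 6), fs = 1))
  expect_equal(tr$fhr_bpm, c(140, 142, 144, 146, 148, 150))
  expect_true(all(tr$valid_fhr))
})

test_that("trace constructor enforces its invariants", {
  expect_error(ctg_trace(numeric(0), numeric(0), fs = 1), "at least one")
  expect_error(ctg_trace(1:4, 1:3, fs = 1), "same length")
  expect_error(ctg_trace(1:4, 1:4, fs = 0), "positive")
  expect_error(signal_loss(tibble::tibble(a = 1)), "ctg_trace")
})
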