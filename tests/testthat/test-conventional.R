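# Spike removal, smoothing, Hilbert-envelope episode detection, feature
# extraction and the SVM / k-means baselines.

test_that("spike removal replaces implausible samples by neighbor means", {
  clean <- c(140, 141, 142, 141, 140)
  expect_equal(remove_spikes(clean), clean)

  expect_equal(remove_spikes(c(140, 140, 300, 140)), rep(140, 4))

  # 2-sample +80 bpm spike: both samples replaced, output near pre-spike
  x <- 140 + sin(seq(0, 4 * pi, length.out = 200)) * 5
  xs <- x
  xs[100:101] <- xs[100:101] + 80
  rec <- remove_spikes(xs)
  expect_true(max(abs(rec - x)) < 1)

  # leading flagged run takes the nearest unflagged value
  expect_equal(remove_spikes(c(300, 310, 140, 140)), c(140, 140, 140, 140))
  expect_error(remove_spikes(c(300, 300)), "Every sample")
})

test_that("15-point bilateral moving average behaves as a linear filter", {
  expect_equal(smooth_ma(rep(7, 50)), rep(7, 50))

  # unit impulse spreads to 1/15 over the covered window
  x <- rep(0, 61)
  x[31] <- 1
  s <- smooth_ma(x)
  expect_equal(s[24:38], rep(1 / 15, 15))
  expect_equal(sum(s), 1)

  # white-noise variance shrinks by the window size at interior points
  set.seed(42)
  sims <- replicate(400, smooth_ma(stats::rnorm(61))[31])
  expect_equal(stats::var(sims), 1 / 15, tolerance = 0.2)

  # linear and shift-equivariant away from edges
  set.seed(1)
  a <- stats::rnorm(100)
  b <- stats::rnorm(100)
  expect_equal(smooth_ma(a + 2 * b), smooth_ma(a) + 2 * smooth_ma(b))
  shifted <- smooth_ma(c(a[11:100], stats::rnorm(10)))
  expect_equal(smooth_ma(a)[31:60], shifted[21:50])

  expect_error(smooth_ma(1:10), "shorter")
})

test_that("the analytic-signal envelope of a sinusoid is its amplitude", {
  t <- seq(0, 60, by = 0.25)
  d <- 3.7 * sin(2 * pi * 0.5 * t)
  env <- ctgnet:::analytic_envelope(d)
  interior <- 30:210
  expect_equal(env[interior], rep(3.7, length(interior)), tolerance = 0.02)
})

test_that("a planted raised-cosine deceleration is localized within 5 s", {
  n <- 1800
  t_s <- 0:(n - 1)
  fhr <- 140 - 30 * ctgnet:::episode_pulse(t_s, 700, 760, taper_frac = 1)
  ep <- detect_episodes(fhr, fs = 1)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$kind, "deceleration")
  expect_lt(abs(ep$onset_s - 700), 5)
  expect_lt(abs(ep$offset_s - 760), 5)
  expect_equal(ep$extremum_bpm, -30, tolerance = 0.5)
  expect_equal(ep$area_bpm_s, 30 * 60 / 2, tolerance = 0.1 * 900)

  expect_equal(nrow(detect_episodes(rep(140, 1800), fs = 1)), 0)
})

test_that("planted-episode recovery on noiseless generator output", {
  found <- 0L
  found_5s <- 0L
  total <- 0L
  for (i in 1:12) {
    lb <- if (i %% 2 == 0) "abnormal" else "normal"
    tr <- simulate_trace(lb, noiseless_params(), seed = 100 + i)
    truth <- episodes(tr)
    det <- detect_episodes(tr)
    for (k in seq_len(nrow(truth))) {
      tk <- truth[k, ]
      if (abs(tk$depth_bpm) < 20) next
      total <- total + 1L
      sgn <- if (tk$kind == "acceleration") 1 else -1
      cand <- det[sign(det$extremum_bpm) == sgn &
        det$onset_s < tk$offset_s & det$offset_s > tk$onset_s, ]
      if (nrow(cand) > 0) {
        found <- found + 1L
        berr <- min(pmax(
          abs(cand$onset_s - tk$onset_s), abs(cand$offset_s - tk$offset_s)
        ))
        if (berr <= 5) found_5s <- found_5s + 1L
      }
    }
  }
  expect_gte(found / total, 0.9)
  expect_gte(found_5s / total, 0.85)
})

test_that("features count accelerations and sum deceleration areas", {
  expect_equal(
    extract_features(detect_episodes(rep(140, 1800), fs = 1)),
    tibble::tibble(n_accelerations = 0L, total_decel_area = 0)
  )
  eps <- tibble::tibble(
    kind = c("acceleration", "acceleration", "deceleration"),
    onset_s = c(0, 100, 200), offset_s = c(30, 130, 260),
    extremum_bpm = c(20, 25, -30), area_bpm_s = c(300, 400, 1800)
  )
  expect_equal(
    extract_features(eps),
    tibble::tibble(n_accelerations = 2L, total_decel_area = 1800)
  )

  # end to end against generator ground truth (noiseless, raised cosine:
  # area = depth * duration / 2)
  tr <- simulate_trace("abnormal", noiseless_params(), seed = 55)
  truth <- episodes(tr)
  planted_area <- sum(
    abs(truth$depth_bpm[grepl("decel", truth$kind)]) *
      (truth$offset_s - truth$onset_s)[grepl("decel", truth$kind)] / 2 *
      ifelse(truth$kind[grepl("decel", truth$kind)] == "prolonged_decel", 1.6, 1)
  )
  f <- ctg_features(tibble::tibble(ctg = list(tr)))
  expect_equal(f$total_decel_area, planted_area, tolerance = 0.15)
})

test_that("features are invariant to a pure baseline offset", {
  tr <- simulate_trace("abnormal", noiseless_params(), seed = 77)
  f1 <- extract_features(detect_episodes(tr$fhr_bpm, fs = 1))
  f2 <- extract_features(detect_episodes(tr$fhr_bpm + 12, fs = 1))
  expect_equal(f1, f2)
})

test_that("SVM separates a separable toy problem and rejects one class", {
  set.seed(3)
  feats <- tibble::tibble(
    n_accelerations = c(rnorm(20, 5, 0.3), rnorm(20, 0, 0.3)),
    total_decel_area = c(rnorm(20, 0, 30), rnorm(20, 3000, 30)),
    label = factor(rep(c("normal", "abnormal"), each = 20),
      levels = c("normal", "abnormal")
    )
  )
  fit <- fit_ctg_svm(feats)
  pr <- predict(fit, feats)
  expect_equal(mean(pr$.pred == feats$label), 1)
  # scores orient toward abnormality
  expect_gt(mean(pr$.score[21:40]), mean(pr$.score[1:20]))
  # a point deep inside the normal region
  deep <- tibble::tibble(n_accelerations = 5, total_decel_area = 0)
  expect_equal(as.character(predict(fit, deep)$.pred), "normal")

  expect_error(
    fit_ctg_svm(dplyr::mutate(feats, label = factor("normal"))),
    "single class"
  )
})

test_that("k-means recovers well-separated blobs deterministically", {
  set.seed(4)
  feats <- tibble::tibble(
    n_accelerations = c(rnorm(25, 4, 0.2), rnorm(25, 0.5, 0.2)),
    total_decel_area = c(rnorm(25, 100, 20), rnorm(25, 2500, 20)),
    label = factor(rep(c("normal", "abnormal"), each = 25),
      levels = c("normal", "abnormal")
    )
  )
  fit <- fit_ctg_kmeans(feats, seed = 1)
  pr <- predict(fit, feats)
  expect_equal(mean(pr$.pred == feats$label), 1)
  fit2 <- fit_ctg_kmeans(feats, seed = 1)
  expect_identical(fit$centers, fit2$centers)

  same <- tibble::tibble(
    n_accelerations = rep(1, 5), total_decel_area = rep(2, 5),
    label = factor(rep(c("normal", "abnormal"), c(3, 2)))
  )
  expect_error(fit_ctg_kmeans(same), "distinct")
})

test_that("k-means accuracy on overlapping blobs tracks nearest-centroid", {
  set.seed(9)
  n <- 80
  feats <- tibble::tibble(
    n_accelerations = c(rnorm(n, 3, 1), rnorm(n, 1, 1)),
    total_decel_area = c(rnorm(n, 500, 400), rnorm(n, 2000, 400)),
    label = factor(rep(c("normal", "abnormal"), each = n),
      levels = c("normal", "abnormal")
    )
  )
  fit <- fit_ctg_kmeans(feats, seed = 2)
  acc <- mean(predict(fit, feats)$.pred == feats$label)
  # oracle: assign to the nearer true class centroid (standardized space)
  x <- scale(as.matrix(feats[, 1:2]))
  mu_n <- colMeans(x[seq_len(n), ])
  mu_a <- colMeans(x[n + seq_len(n), ])
  d_n <- rowSums(sweep(x, 2, mu_n)^2)
  d_a <- rowSums(sweep(x, 2, mu_a)^2)
  oracle_acc <- mean((d_a < d_n) == (feats$label == "abnormal"))
  expect_equal(acc, oracle_acc, tolerance = 0.05)
})
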