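# The 37-feature extractor and its independent oracles.

fs <- 125
t30 <- (0:3749) / fs

test_that("the feature vector has exactly the canonical 37 entries", {
  expect_length(feature_names(), 37)
  expect_equal(length(grep("^ratio_", feature_names())), 8)
  expect_equal(length(grep("^(relative_energy|wavelet_)", feature_names())), 20)
  set.seed(1)
  v <- extract_features(rnorm(3750), fs)
  expect_named(v, feature_names())
  expect_true(all(is.finite(v)))
})

test_that("time-domain moments and HFD match their definitions", {
  sine <- sin(2 * pi * 5 * t30)  # integer periods, symmetric
  td <- time_domain_features(sine, 10)
  expect_equal(unname(td["skewness"]), 0, tolerance = 1e-8)
  expect_equal(unname(td["kurtosis"]), 1.5, tolerance = 1e-3)  # Pearson, sine

  set.seed(3)
  gauss <- rnorm(2e4)
  expect_equal(unname(time_domain_features(gauss, 10)["kurtosis"]), 3,
               tolerance = 0.1)

  ramp <- seq(0, 1, length.out = 3750)
  expect_lt(abs(higuchi_fd(ramp, 10) - 1), 0.05)

  set.seed(42)
  noise <- rnorm(3750)
  expect_lt(abs(higuchi_fd(noise, 10) - oracle_higuchi(noise, 10)), 1e-10)
  expect_lt(abs(higuchi_fd(noise, 10) - 2), 0.05)

  expect_error(time_domain_features(rep(1, 100), 10), "degenerate")
})

test_that("Hjorth parameters obey sine closed forms and scale laws", {
  A <- 7
  sine <- A * sin(2 * pi * 5 * t30)
  hj <- hjorth_features(sine)
  expect_equal(unname(hj["activity"]), A^2 / 2, tolerance = 0.02)
  omega <- 2 * pi * 5 / fs  # rad/sample
  expect_equal(unname(hj["mobility"]), 2 * sin(omega / 2), tolerance = 0.02)
  expect_equal(unname(hj["complexity"]), 1, tolerance = 0.02)

  set.seed(8)
  x <- rnorm(1000)
  h1 <- hjorth_features(x)
  h2 <- hjorth_features(3 * x)
  expect_equal(unname(h2["activity"]), 9 * unname(h1["activity"]),
               tolerance = 1e-12)
  expect_equal(unname(h2["mobility"]), unname(h1["mobility"]),
               tolerance = 1e-9)
  expect_equal(unname(h2["complexity"]), unname(h1["complexity"]),
               tolerance = 1e-9)
  expect_error(hjorth_features(rep(2, 50)), "degenerate")
})

test_that("activity z-scoring uses the population convention", {
  expect_equal(zscore_activity_within_subject(c(1, 3)), c(-1, 1))
  set.seed(4)
  v <- rnorm(50, mean = 10, sd = 3)
  z <- zscore_activity_within_subject(v)
  expect_equal(z, (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  expect_equal(zscore_activity_within_subject(2 + 5 * v), z)  # affine invariance
  expect_warning(z0 <- zscore_activity_within_subject(rep(2, 5)),
                 "zero dispersion")
  expect_equal(z0, rep(0, 5))
})

test_that("band powers equal the periodogram-bin-sum oracle", {
  tone2 <- sin(2 * pi * 2 * t30)
  bp <- band_powers(tone2, fs)
  expect_gt(bp[["delta"]] / bp[["full"]], 0.99)

  tone10 <- sin(2 * pi * 10 * t30)
  bp10 <- band_powers(tone10, fs)
  expect_equal(names(which.max(bp10[c("delta", "theta", "alpha", "beta")])),
               "alpha")

  set.seed(12)
  noise <- rnorm(3750)
  bpn <- band_powers(noise, fs)
  for (b in names(eeg_bands())) {
    lohi <- eeg_bands()[[b]]
    expect_equal(bpn[[b]], oracle_band_power(noise, fs, lohi[1], lohi[2]),
                 tolerance = 1e-9)
  }
})

test_that("the eight power ratios follow the fixed definitions", {
  ones <- c(delta = 1, theta = 1, alpha = 1, sigma = 1, beta = 1)
  expect_equal(unname(power_ratios(ones)), c(1, 1, 1, 1, 1, 1, 0.5, 1))

  bp <- c(delta = 4, theta = 2, alpha = 1, sigma = 2, beta = 1)
  expect_equal(unname(power_ratios(bp)), c(4, 4, 2, 2, 2, 0.5, 2, 3))

  expect_equal(power_ratios(2 * bp), power_ratios(bp))  # homogeneity
  w <- capture_warnings(power_ratios(c(delta = 1, theta = 1, alpha = 0,
                                       sigma = 1, beta = 0)))
  expect_gt(length(w), 0)
  expect_true(all(grepl("zero denominator", w)))
})

test_that("spectral shape behaves on line, flat and two-tone spectra", {
  tone <- sin(2 * pi * 10 * t30)
  ss <- spectral_shape(tone, fs)
  expect_equal(unname(ss["spectral_centroid"]), 10, tolerance = 0.05)
  expect_equal(unname(ss["spectral_rolloff"]), 10, tolerance = 0.05)
  expect_lt(unname(ss["spectral_entropy"]), 0.2)

  # exactly flat in-band spectrum via inverse DFT of unit magnitudes
  n <- 3750
  freq <- (0:(n - 1)) * fs / n
  X <- complex(modulus = as.numeric(pmin(freq, fs - freq) >= 0.5 &
                                      pmin(freq, fs - freq) < 30),
               argument = 0)
  flat <- Re(fft(X, inverse = TRUE)) / n
  expect_equal(unname(spectral_shape(flat, fs)["spectral_entropy"]), 1,
               tolerance = 1e-6)

  two <- sin(2 * pi * 5 * t30) + sin(2 * pi * 15 * t30)
  expect_equal(unname(spectral_shape(two, fs)["spectral_centroid"]), 10,
               tolerance = 0.05)
})

test_that("db4 decomposition matches the independent wavelet reference", {
  set.seed(42)
  x <- rnorm(256)
  ref <- pywt_reference()
  dec <- dwt_db4(x, 5)
  E <- sapply(dec$details, function(c) sum(c^2))
  expect_equal(unname(E / sum(E)), ref$rel, tolerance = 1e-12)
  expect_equal(dec$details$d1[1:6], ref$cD1_head, tolerance = 1e-12)
  expect_equal(dec$approximation, ref$cA5, tolerance = 1e-12)
})

test_that("wavelet sub-bands map tones to the expected scales", {
  wf2 <- wavelet_features(sin(2 * pi * 2 * t30) + 1e-8 * sin(2 * pi * 40 * t30))
  rel2 <- wf2[grep("relative_energy", names(wf2))]
  expect_equal(names(which.max(rel2)), "relative_energy_d5")

  wf25 <- wavelet_features(sin(2 * pi * 25 * t30) + 1e-8 * sin(2 * pi * 2 * t30))
  rel25 <- wf25[grep("relative_energy", names(wf25))]
  expect_equal(names(which.max(rel25)), "relative_energy_d2")

  set.seed(9)
  wf <- wavelet_features(rnorm(3750))
  rel <- wf[grep("relative_energy", names(wf))]
  expect_equal(sum(rel), 1, tolerance = 1e-9)
  expect_true(all(rel >= 0 & rel <= 1))
})

test_that("every feature except activity is amplitude-scale invariant", {
  set.seed(33)
  x <- rnorm(3750)
  v1 <- extract_features(x, fs)
  v2 <- extract_features(2 * x, fs)
  expect_equal(unname(v2["hjorth_activity"]),
               4 * unname(v1["hjorth_activity"]), tolerance = 1e-9)
  invariant <- setdiff(feature_names(),
                       c("hjorth_activity",
                         grep("wavelet_entropy", feature_names(),
                              value = TRUE)))
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-6)
  # wavelet entropies are computed on normalized squared coefficients,
  # hence also scale-free
  went <- grep("wavelet_entropy", feature_names(), value = TRUE)
  expect_equal(v2[went], v1[went], tolerance = 1e-6)
})

test_that("determinism and degenerate input handling", {
  set.seed(2)
  x <- rnorm(3750)
  expect_identical(extract_features(x, fs), extract_features(x, fs))
  expect_error(extract_features(rep(1, 3750), fs), "degenerate")
})

test_that("skewness and kurtosis agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  x <- rnorm(2000)
  td <- time_domain_features(x, 10)
  expect_equal(unname(td["skewness"]), e1071::skewness(x, type = 1),
               tolerance = 1e-10)
  # e1071 type-1 kurtosis is excess; ours is the Pearson (non-excess) form
  expect_equal(unname(td["kurtosis"]), e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-10)
})

test_that("study_features z-scores activity within each subject", {
  study <- tiny_study(n_subjects = 2, epochs = 12)
  df <- study_features(study)
  expect_equal(nrow(df), 24)
  expect_named(df, c("subject_id", "epoch_index", "label", feature_names()),
               ignore.order = FALSE)
  for (id in unique(df$subject_id)) {
    a <- df$hjorth_activity[df$subject_id == id]
    expect_equal(mean(a), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((a - mean(a))^2)), 1, tolerance = 1e-9)
  }
  raw <- study_features(study, zscore_activity = FALSE)
  expect_gt(abs(mean(raw$hjorth_activity[raw$subject_id ==
                                           raw$subject_id[1]])), 1e-6)
})
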