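test_that("multitaper PSD satisfies Parseval on white noise", {
  set.seed(21)
  fs <- 250
  m <- make_montage(8)
  x <- matrix(rnorm(8 * fs * 120), 8)
  rec <- eeg_recording(x, fs, m$labels, m$positions, m$roles)
  psd <- multitaper_psd(rec)
  df <- psd$freqs[2] - psd$freqs[1]
  integ <- rowSums(psd$power) * df
  expect_equal(unname(integ), apply(x, 1, var), tolerance = 0.05)
  expect_equal(psd$taper_count, 3L)
})

test_that("a pure sinusoid concentrates its spectral mass near its frequency", {
  fs <- 250
  m <- make_montage(8)
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(rep(sin(2 * pi * 6 * t), each = 8), 8), fs,
                       m$labels, m$positions, m$roles)
  psd <- multitaper_psd(rec, half_bandwidth = 0.5)
  sp <- psd$power[1, ]
  inside <- psd$freqs >= 6 - 1 & psd$freqs <= 6 + 1
  expect_gte(sum(sp[inside]) / sum(sp), 0.95)
})

test_that("zero signal gives an all-zero PSD; too-short input errors", {
  m <- make_montage(8)
  rec <- eeg_recording(matrix(0, 8, 2500), 250, m$labels, m$positions, m$roles)
  expect_equal(max(multitaper_psd(rec)$power), 0)
  shortr <- eeg_recording(matrix(0, 8, 500), 250, m$labels, m$positions,
                          m$roles)
  expect_error(multitaper_psd(shortr), "shorter than one epoch")
})

test_that("global median spectrum is the channelwise median over scalp channels", {
  freqs <- seq(0, 125, by = 0.25)
  base <- exp(-((freqs - 10) / 5)^2)
  pw <- rbind(base, base, base)
  expect_equal(global_median_spectrum(toy_psd(pw, freqs)), base)
  # outlier channel ignored by the median
  pw2 <- rbind(matrix(rep(base, 20), 20, byrow = TRUE), 100 * base)
  expect_equal(global_median_spectrum(toy_psd(pw2, freqs)), base)
  # direct median definition
  pw3 <- matrix(c(1, 2, 9), 3, length(freqs))
  expect_equal(unname(global_median_spectrum(toy_psd(pw3, freqs))[10]), 2)
  # bad and reference channels are excluded
  roles <- c("active", "bad", "reference")
  pw4 <- rbind(base, 50 * base, 99 * base)
  expect_equal(global_median_spectrum(toy_psd(pw4, freqs, roles)), base)
  expect_error(global_median_spectrum(toy_psd(pw4, freqs,
                                              rep("bad", 3))), "active")
})

test_that("band relative power follows the half-open band convention", {
  freqs <- seq(0, 125, by = 0.25)
  spike <- function(f0) { s <- numeric(length(freqs)); s[freqs == f0] <- 1; s }
  g1 <- band_relative_power(spike(6), freqs)
  expect_equal(unname(g1["theta"]), 1)
  expect_equal(sum(g1), 1)
  g2 <- band_relative_power(spike(6) + spike(20), freqs)
  expect_equal(unname(g2[c("theta", "beta")]), c(0.5, 0.5))
  # boundary bin: 10 Hz belongs to alpha2, not alpha1; 8 Hz to alpha1 not theta
  g3 <- band_relative_power(spike(10), freqs)
  expect_equal(unname(g3[c("alpha1", "alpha2")]), c(0, 1))
  g4 <- band_relative_power(spike(8), freqs)
  expect_equal(unname(g4[c("theta", "alpha1")]), c(0, 1))
  expect_error(band_relative_power(numeric(length(freqs)), freqs), "zero total")
  expect_error(band_relative_power(spike(6)[freqs <= 20], freqs[freqs <= 20]),
               "cover")
})

test_that("occipital median frequency matches hand-computable cases", {
  freqs <- seq(0, 125, by = 0.25)
  roles <- c("occipital", "occipital", "active")
  flat <- ifelse(freqs >= 4 & freqs < 14, 1, 0)
  pw <- rbind(flat, flat, 0 * flat)
  mf <- occipital_median_frequency(toy_psd(pw, freqs, roles))
  expect_equal(mf, 9.0, tolerance = 0.25)   # within one bin of the midpoint
  # all mass at a single in-range frequency
  spike <- numeric(length(freqs)); spike[freqs == 7.25] <- 5
  pw2 <- rbind(spike, spike, spike)
  expect_equal(occipital_median_frequency(toy_psd(pw2, freqs, roles)), 7.25,
               tolerance = 0.25)
  # 30% mass at 5 Hz, 70% at 12 Hz -> the 50% crossing sits at 12 Hz
  two <- numeric(length(freqs)); two[freqs == 5] <- 0.3; two[freqs == 12] <- 0.7
  pw3 <- rbind(two, two, two)
  expect_equal(occipital_median_frequency(toy_psd(pw3, freqs, roles)), 12,
               tolerance = 0.25)
  expect_error(occipital_median_frequency(toy_psd(pw3 * 0, freqs, roles)),
               "zero power")
  expect_error(occipital_median_frequency(toy_psd(pw3, freqs,
                                                  rep("active", 3))),
               "occipital")
})

test_that("features are scale-invariant and channel-permutation-invariant", {
  rec <- clean_rec(11)
  f0 <- spectral_features(rec)
  sc <- rec
  sc$data <- 3.3 * sc$data
  expect_equal(spectral_features(sc), f0, tolerance = 1e-10)
  perm <- sample(nrow(rec$data))
  pr <- eeg_recording(rec$data[perm, ], rec$sampling_rate,
                      rec$channel_labels[perm], rec$channel_positions[perm, ],
                      rec$roles[perm])
  expect_equal(spectral_features(pr), f0, tolerance = 1e-10)
})

test_that("measured GRMP theta increases strictly with the generated theta fraction", {
  levels <- c(0.10, 0.16, 0.22, 0.28, 0.34)
  measured <- sapply(levels, function(th) {
    others <- c(delta = 0.242, alpha1 = 0.198, alpha2 = 0.143, beta = 0.219)
    bf <- c(others[c("delta")], theta = th,
            others[c("alpha1", "alpha2", "beta")]) / (sum(others) + th)
    names(bf) <- c("delta", "theta", "alpha1", "alpha2", "beta")
    sp <- eeg_gen_spec(band_fractions = bf, n_channels = 16, duration = 40,
                       blink_rate = 0, n_bad_channels = 0, seed = 77)
    spectral_features(generate_eeg(sp))$grmp_theta
  })
  expect_true(all(diff(measured) > 0))
})
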