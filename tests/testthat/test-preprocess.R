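make_sine_rec <- function(freq, fs = 250, dur = 30, nch = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  m <- make_montage(nch)
  eeg_recording(matrix(rep(x, each = nch), nch), fs, m$labels, m$positions,
                m$roles)
}

test_that("zero-phase filter passes the analysis band and kills the notch", {
  r10 <- apply_filters(make_sine_rec(10))
  mid <- 1000:6500   # away from edges
  amp <- (max(r10$data[1, mid]) - min(r10$data[1, mid])) / 2
  expect_equal(amp, 1, tolerance = 0.06)

  r50 <- apply_filters(make_sine_rec(50))
  expect_lt(sqrt(mean(r50$data[1, mid]^2)) / sqrt(0.5), 0.01)

  z <- make_sine_rec(10)
  z$data[] <- 0
  expect_equal(apply_filters(z)$data, z$data)
})

test_that("filtering rejects recordings shorter than the filter order", {
  short <- make_sine_rec(10, dur = 5)   # 1250 samples < order 2500
  expect_error(apply_filters(short), "too-short")
})

test_that("white noise keeps a flat spectrum through filter + PSD (1-30 Hz)", {
  set.seed(5)
  fs <- 250
  m <- make_montage(8)
  rec <- eeg_recording(matrix(rnorm(8 * fs * 120), 8), fs, m$labels,
                       m$positions, m$roles)
  f <- apply_filters(rec)
  psd <- multitaper_psd(f)
  sp <- colMeans(psd$power)
  inband <- psd$freqs >= 1 & psd$freqs <= 30
  ripple_db <- 10 * log10(range(sp[inband]) / median(sp[inband]))
  expect_lt(ripple_db[2] - ripple_db[1], 2)  # within +-1 dB
})

test_that("bad-channel detection flags flat, scaled and decoupled channels only", {
  rec <- clean_rec(11)
  expect_length(detect_bad_channels(rec), 0)

  flat <- rec
  flat$data[5, ] <- 0
  expect_identical(detect_bad_channels(flat), rec$channel_labels[5])

  scaled <- rec
  scaled$data[7, ] <- 10 * scaled$data[7, ]
  expect_true(rec$channel_labels[7] %in% detect_bad_channels(scaled))

  m8 <- make_montage(8)
  tiny <- eeg_recording(matrix(rnorm(6 * 100), 6), 250, m8$labels[1:6],
                        m8$positions[1:6, ],
                        c("reference", rep("active", 5)))
  expect_error(detect_bad_channels(tiny), "8 channels")
})

test_that("spherical-spline interpolation reproduces constants exactly", {
  m <- make_montage(20)
  rec <- eeg_recording(matrix(3.7, 20, 500), 250, m$labels, m$positions,
                       m$roles)
  out <- interpolate_spherical_spline(rec, m$labels[c(2, 9)])
  expect_equal(out$data[2, ], rep(3.7, 500), tolerance = 1e-6)
  expect_equal(out$data[9, ], rep(3.7, 500), tolerance = 1e-6)
  expect_equal(out$roles[c(2, 9)], c("bad", "bad"))
})

test_that("a smooth dipolar field interpolates with high fidelity", {
  m <- make_montage(32)
  dip <- c(0.3, 0.5, 0.8)
  field <- m$positions %*% dip + 0.5 * (m$positions %*% c(-0.2, 0.7, 0.1))^2
  tt <- seq(0, 2 * pi, length.out = 400)
  data <- outer(drop(field), sin(tt)) + outer(drop(field)^2, 0.3 * cos(2 * tt))
  rec <- eeg_recording(data, 250, m$labels, m$positions, m$roles)
  drop_ch <- 10
  out <- interpolate_spherical_spline(rec, m$labels[drop_ch])
  expect_gte(cor(out$data[drop_ch, ], data[drop_ch, ]), 0.95)
  # good channels untouched
  expect_equal(out$data[-drop_ch, ], data[-drop_ch, ], ignore_attr = TRUE)
})

test_that("interpolation with an empty bad list is the identity", {
  rec <- clean_rec(11)
  expect_identical(interpolate_spherical_spline(rec, character(0)), rec)
})

test_that("interpolation requires enough good channels", {
  m <- make_montage(8)
  rec <- eeg_recording(matrix(rnorm(8 * 100), 8), 250, m$labels, m$positions,
                       m$roles)
  expect_error(interpolate_spherical_spline(rec, m$labels[1:5]), "good channels")
})

test_that("blink-component removal is deterministic and gentle on clean data", {
  rec <- clean_rec(11)
  out1 <- remove_blink_components(rec, seed = 2)
  out2 <- remove_blink_components(rec, seed = 2)
  expect_identical(out1$data, out2$data)
  cors <- sapply(seq_len(nrow(rec$data)),
                 function(i) cor(rec$data[i, ], out1$data[i, ]))
  expect_gte(min(cors), 0.95)
})

test_that("ICA needs at least a minute of data and survives rank deficiency", {
  m <- make_montage(10)
  shortr <- eeg_recording(matrix(rnorm(10 * 250 * 30), 10), 250, m$labels,
                          m$positions, m$roles)
  expect_error(remove_blink_components(shortr), "60 s")

  rankdef <- eeg_recording(matrix(rep(rnorm(250 * 70), each = 10), 10), 250,
                           m$labels, m$positions, m$roles)
  expect_warning(out <- remove_blink_components(rankdef), "rank-deficient")
  expect_identical(out$data, rankdef$data)
})

test_that("full preprocessing is near-idempotent on clean recordings", {
  rec <- generate_eeg(eeg_gen_spec(n_channels = 24, duration = 70,
                                   blink_rate = 0, n_bad_channels = 0,
                                   seed = 13))
  p1 <- preprocess_eeg(rec, seed = 5)
  p2 <- preprocess_eeg(p1, seed = 5)
  rms1 <- apply(p1$data, 1, function(x) sqrt(mean(x^2)))
  rms2 <- apply(p2$data, 1, function(x) sqrt(mean(x^2)))
  expect_lt(max(abs(rms2 - rms1) / rms1), 0.05)
  # sampling rate, channel count and labels never change
  expect_identical(p1$sampling_rate, rec$sampling_rate)
  expect_identical(p1$channel_labels, rec$channel_labels)
  expect_identical(dim(p1$data), dim(rec$data))
})
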