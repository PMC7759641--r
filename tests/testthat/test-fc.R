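test_that("bipolar derivation pairs adjacent contacts within each rod", {
  rec <- sine_recording(paste0("A", 1:5), freqs_hz = c(30, 32, 34, 36, 38))
  bip <- bipolar_derivation(rec)
  expect_equal(bip$channel_labels, c("A1-A2", "A2-A3", "A3-A4", "A4-A5"))

  # two identical contacts difference out exactly
  rec2 <- seizure_recording(rbind(rec$samples[1, ], rec$samples[1, ]),
                            256, c("B1", "B2"))
  expect_true(all(bipolar_derivation(rec2)$samples == 0))

  # no cross-rod pairs: A with 3 contacts + B with 2 -> 2 + 1 channels
  rec3 <- sine_recording(c("A1", "A2", "A3", "B1", "B2"), 25)
  expect_equal(bipolar_derivation(rec3)$channel_labels,
               c("A1-A2", "A2-A3", "B1-B2"))

  # a gap in contact numbering drops the stranded contact with a warning
  rec4 <- sine_recording(c("A1", "A2", "A4", "A5"), 25)
  expect_warning(bip4 <- bipolar_derivation(rec4), "A2")
  expect_equal(bip4$channel_labels, c("A1-A2", "A4-A5"))

  # unparseable label fails naming the label
  bad <- seizure_recording(matrix(rnorm(20), 2), 256, c("A1", "oops"))
  expect_error(bipolar_derivation(bad), "oops")
})

test_that("high-pass filter is -3 dB at the cutoff and flat above", {
  fs <- 256
  gain_db <- function(f_hz, cutoff = 20) {
    rec <- sine_recording("A1", f_hz, fs = fs, dur_s = 8)
    out <- highpass_filter(rec, cutoff)
    # measure away from the edges
    core <- 512:1536
    20 * log10(stats::sd(out$samples[1, core]) /
                 stats::sd(rec$samples[1, core]))
  }
  expect_lt(abs(gain_db(20) - (-3)), 0.5)   # the contractual -3 dB point
  expect_gt(gain_db(40), -1)                # passband preserved within 1 dB
  expect_lt(gain_db(5), -20)                # stopband attenuated >= 20 dB
  # DC removal
  dc <- seizure_recording(matrix(7, 1, 2048), fs, "A1")
  expect_lt(max(abs(highpass_filter(dc, 20)$samples)), 7e-6)
  # cutoff at or above Nyquist is rejected
  expect_error(highpass_filter(dc, 128), "Nyquist")
})

test_that("instantaneous phase tracks the analytic signal of sinusoids", {
  fs <- 256
  rec <- sine_recording("A1", 32, fs = fs, dur_s = 4)
  ph <- instantaneous_phase(rec)$phases[1, ]
  core <- 100:900
  slope <- diff(range(cumsum(c(ph[core][1], diff(ph[core]) %%
                                 (2 * pi))))) / (length(core) - 1) * fs
  expect_equal(slope, 2 * pi * 32, tolerance = 0.01 * 2 * pi * 32)

  # sin lags cos by pi/2 at the same frequency
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec2 <- seizure_recording(rbind(cos(2 * pi * 30 * tt),
                                  sin(2 * pi * 30 * tt)),
                            fs, c("A1", "A2"))
  d <- instantaneous_phase(rec2)$phases
  dphi <- (d[1, 100:900] - d[2, 100:900]) %% (2 * pi)
  expect_true(all(abs(dphi - pi / 2) < 0.02))

  # amplitude invariance
  rec3 <- seizure_recording(rbind(rec$samples[1, ], 17 * rec$samples[1, ]),
                            fs, c("A1", "A2"))
  p3 <- instantaneous_phase(rec3)$phases
  # compare as angles (the +/- pi branch cut is the same phase)
  expect_lt(max(abs(Arg(exp(1i * (p3[1, ] - p3[2, ]))))), 1e-8)

  # all-zero channel flagged, phase zero
  rec4 <- seizure_recording(rbind(rec$samples[1, ], 0 * rec$samples[1, ]),
                            fs, c("A1", "A2"))
  expect_warning(p4 <- instantaneous_phase(rec4), "A2")
  expect_true(all(p4$phases[2, ] == 0))
})

test_that("PLV matches its definition on constructed phase pairs", {
  set.seed(5)
  a <- runif(500, -pi, pi)
  expect_equal(plv_pair(a, a), 1)
  # half the samples at relative phase 0, half at pi: phasors cancel
  b <- a - rep(c(0, pi), each = 250)
  expect_equal(plv_pair(a, b), 0, tolerance = 1e-12)
  # symmetry and common-phase invariance
  c2 <- runif(500, -pi, pi)
  common <- runif(500, -pi, pi)
  expect_equal(plv_pair(a, c2), plv_pair(c2, a))
  expect_equal(plv_pair(a + common, c2 + common), plv_pair(a, c2),
               tolerance = 1e-12)
  expect_error(plv_pair(a, a[-1]), "equal length")
})

test_that("sliding windows follow the closed-form count", {
  w <- sliding_windows(64 * 256, 256, 4, 1)
  expect_equal(nrow(w), 61)
  expect_equal(w$start[1], 0)
  expect_equal(nrow(sliding_windows(4 * 256, 256, 4, 1)), 1)
  w2 <- sliding_windows(10 * 100, 100, 4, 2)
  expect_equal(w2$start, c(0, 200, 400, 600))
  expect_equal(w2$end, c(400, 600, 800, 1000))
  expect_error(sliding_windows(100, 256, 4, 1), "shorter")
  # property: count = floor((n - W)/D) + 1 on random cases
  set.seed(8)
  for (r in 1:25) {
    fs <- sample(c(100, 128, 256, 512), 1)
    n <- sample(2000:20000, 1)
    wl <- sample(1:4, 1); st <- sample(1:3, 1)
    if (n < wl * fs) next
    expect_equal(nrow(sliding_windows(n, fs, wl, st)),
                 floor((n - wl * fs) / (st * fs)) + 1)
  }
})

test_that("windowed PLV series has one row per channel pair", {
  set.seed(12)
  fs <- 128
  smp <- matrix(rnorm(5 * fs * 10), 5)
  rec <- seizure_recording(smp, fs, paste0("A", 1:5))
  fc <- build_fc_series(rec, 4, 1)
  expect_equal(nrow(fc$values), 10)   # 5*4/2
  expect_equal(ncol(fc$values), 7)
  expect_true(all(fc$values >= 0 & fc$values <= 1))
  # a duplicated channel gives a perfectly locked edge
  rec2 <- seizure_recording(rbind(smp[1, ], smp[1, ], smp[2, ]), fs,
                            c("A1", "A2", "A3"))
  fc2 <- build_fc_series(rec2, 4, 1)
  expect_equal(unname(fc2$values[1, ]), rep(1, 7), tolerance = 1e-9)
  # bit-for-bit reproducibility on identical input
  expect_identical(fc$values, build_fc_series(rec, 4, 1)$values)
})
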