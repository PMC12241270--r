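fs <- 125

test_that("band-pass removes DC and matches its frequency-response oracle in the passband", {
  t <- (0:(fs * 30 - 1)) / fs
  mid <- (fs * 10):(fs * 20) # steady-state region

  yc <- bandpass_filter(rep(3.7, length(t)), fs)
  expect_lt(max(abs(yc[mid])), 1e-6 * 3.7)

  y4 <- bandpass_filter(sin(2 * pi * 4 * t), fs)
  amp4 <- max(abs(y4[mid]))
  expect_gt(amp4, 0.95)
  expect_lt(amp4, 1.05)
  expect_lt(abs(amp4 - bandpass_gain(4, fs)), 0.01)

  ylow <- bandpass_filter(sin(2 * pi * 0.05 * t), fs)
  expect_lt(max(abs(ylow[mid])), 0.05)
  expect_lt(bandpass_gain(0.05, fs), 0.05)
})

test_that("zero-phase filtering is passband-idempotent and introduces no lag", {
  t <- (0:(fs * 30 - 1)) / fs
  mid <- (fs * 10):(fs * 20)
  x <- sin(2 * pi * 4 * t)
  once <- bandpass_filter(x, fs)
  twice <- bandpass_filter(once, fs)
  expect_lt(abs(max(abs(twice[mid])) / max(abs(once[mid])) - 1), 0.05)
  cc <- stats::ccf(once[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("filter rejects invalid configurations and too-short signals", {
  expect_error(bandpass_filter(rnorm(1000), 15, filter_spec(highcut = 8)),
               class = "ppgbp_config_error")
  expect_error(filter_spec(lowcut = 9, highcut = 8), class = "ppgbp_config_error")
  expect_error(bandpass_filter(rnorm(5), fs), class = "ppgbp_input_error")
})

test_that("derivatives match analytic oracles", {
  fsd <- 500
  t <- (0:(fsd * 2 - 1)) / fsd
  x <- sin(2 * pi * t)
  d1 <- signal_derivative(x, fsd, 1L)
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(d1[interior] - 2 * pi * cos(2 * pi * t[interior]))), 0.01)

  ramp <- 3.5 * t
  expect_close(signal_derivative(ramp, fsd, 1L)[interior], 3.5, 1e-9)
  expect_close(signal_derivative(ramp, fsd, 2L)[interior], 0, 1e-6)
  expect_close(signal_derivative(rep(2, 100), fsd, 1L), 0, 1e-12)
  expect_close(signal_derivative(rep(2, 100), fsd, 2L), 0, 1e-12)

  # order 2 is the operator applied twice
  expect_identical(signal_derivative(x, fsd, 2L),
                   signal_derivative(signal_derivative(x, fsd, 1L), fsd, 1L))
  expect_error(signal_derivative(1:4, fsd), class = "ppgbp_input_error")
})

test_that("segmentation arithmetic matches the stated formula and an enumeration oracle", {
  seg <- segment_indices(22500, 500, 15, 2 / 3)
  expect_identical(nrow(seg), 7L)
  expect_identical(seg$start[1], 1L)
  # consecutive windows share exactly W - S samples
  expect_identical(seg$end[1] - seg$start[2] + 1L, 7500L - 2500L)

  seg1 <- segment_indices(7500, 500, 15, 2 / 3)
  expect_identical(nrow(seg1), 1L)
  expect_identical(seg1$start, 1L)

  expect_warning(out <- segment_indices(100, 500, 15, 2 / 3))
  expect_identical(nrow(out), 0L)

  withr::with_seed(42, {
    for (i in 1:200) {
      w_s <- runif(1, 1, 20)
      ov <- runif(1, 0, 0.9)
      sr <- sample(25:500, 1)
      w <- round(w_s * sr); s <- round(w * (1 - ov))
      if (s < 1) next
      n <- sample(w:(w * 10), 1)
      expect_identical(nrow(segment_indices(n, sr, w_s, ov)), count_windows_naive(n, w, s))
    }
  })
})

test_that("beat extraction recovers SBP/DBP of a synthetic pressure waveform", {
  t <- (0:(fs * 20 - 1)) / fs
  abp <- 80 + 40 * pmax(0, sin(2 * pi * 1.2 * t))^2
  beats <- abp_to_beats(abp, fs)
  expect_gt(nrow(beats), 15)
  expect_close(beats$sbp, 120, 1)
  expect_close(beats$dbp, 80, 1)
  expect_true(all(beats$sbp > beats$dbp))
  expect_true(all(beats$peak_time >= 0 & beats$peak_time <= 20))

  # recovery across the physiologic heart-rate range
  for (f0 in c(0.8, 1.2, 1.6, 2.0)) {
    abp_f <- 80 + 40 * pmax(0, sin(2 * pi * f0 * t))^2
    b <- abp_to_beats(abp_f, fs)
    expect_close(b$sbp, 120, 1)
    expect_close(b$dbp, 80, 1)
  }

  expect_error(abp_to_beats(rep(100, 1000), fs), class = "ppgbp_input_error")

  two <- 80 + 40 * pmax(0, sin(2 * pi * 1 * (0:(fs * 2.05 - 1)) / fs))^2
  b2 <- abp_to_beats(two, fs)
  expect_equal(b2$sbp[1], b2$sbp[nrow(b2)], tolerance = 1e-6)
  expect_equal(b2$dbp[1], b2$dbp[nrow(b2)], tolerance = 1e-6)
})

test_that("window construction follows filter -> derivative -> segment with constant labels", {
  cfg <- sim_config(n_records = 2, record_duration = 60, sampling_rate = 50, seed = 21)
  recs <- simulate_ppg_dataset(cfg)
  wins <- make_windows(recs)
  expect_identical(nrow(wins), 20L) # floor((60-15)/5)+1 = 10 per record
  expect_true(all(lengths(wins$ppg) == round(15 * 50)))
  expect_true(all(lengths(wins$vppg) == lengths(wins$ppg)))

  # labels propagate unchanged from the record
  for (r in 1:2) {
    sub <- wins[wins$record_id == recs$record_id[r], ]
    expect_true(all(sub$sbp == recs$sbp[r]))
    expect_true(all(sub$dbp == recs$dbp[r]))
  }

  # vPPG windows equal the slice of the full-record derivative (commutation)
  filt <- bandpass_filter(recs$samples[[1]], 50)
  v_full <- signal_derivative(filt, 50, 1L)
  w1 <- wins[wins$record_id == recs$record_id[1], ][3, ]
  i0 <- round(w1$start_time * 50) + 1
  expect_close(w1$vppg[[1]], v_full[i0:(i0 + length(w1$vppg[[1]]) - 1)], 1e-9)
})

test_that("beat-labelled records average beats inside each window and drop empty windows", {
  sr <- 50
  n <- sr * 40
  rec <- tibble::tibble(
    record_id = "r1", subject_id = "s1", sampling_rate = sr,
    sbp = NA_real_, dbp = NA_real_,
    samples = list(sin(2 * pi * (0:(n - 1)) / sr)),
    beats = list(tibble::tibble(
      sbp = c(110, 120, 130, 140), dbp = c(70, 75, 80, 85),
      peak_time = c(1, 2, 16, 39.5)
    ))
  )
  wins <- suppressMessages(make_windows(rec, window_s = 15, overlap_frac = 2 / 3))
  # 6 candidate windows at starts 0,5,...,25 s; the one at 20 s holds no beat
  expect_identical(nrow(wins), 5L)
  expect_equal(wins$sbp[1], 115) # beats at 1 s and 2 s averaged
  expect_equal(wins$dbp[1], 72.5)
  expect_equal(wins$sbp[2], 130) # only the beat at 16 s
  expect_equal(wins$sbp[5], 140) # only the beat at 39.5 s
})
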