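test_that("identical configurations reproduce byte-identical datasets", {
  cfg <- sim_config(n_records = 3, record_duration = 10, sampling_rate = 50, seed = 11)
  a <- simulate_ppg_dataset(cfg)
  b <- simulate_ppg_dataset(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$sbp, b$sbp)
  expect_identical(attr(a, "config_hash"), attr(b, "config_hash"))
})

test_that("with noise, wander and link off, morphology depends only on heart rate", {
  cfg <- sim_config(
    n_records = 2, record_duration = 8, sampling_rate = 50,
    heart_rate_range = c(72, 72), noise_sd = 0, wander_amplitude = 0,
    link_strength = 0, seed = 5
  )
  recs <- simulate_ppg_dataset(cfg)
  # records differ in SBP/DBP draw but share HR; with the link off the
  # waveforms must be identical
  expect_false(isTRUE(all.equal(recs$sbp[1], recs$sbp[2])))
  expect_identical(recs$samples[[1]], recs$samples[[2]])
})

test_that("the planted amplitude-ratio link matches its formula", {
  # at SBP = 120 the pre-clip ratio is exactly 0.8 regardless of link strength
  expect_equal(ppgbp:::ppg_morphology(60, 120, 80, 1)$ratio, 0.8)
  expect_equal(ppgbp:::ppg_morphology(60, 120, 80, 0.3)$ratio, 0.8)
  # linear in SBP inside the clip-free range, with slope -0.004 at full strength
  expect_equal(ppgbp:::ppg_morphology(60, 150, 80, 1)$ratio, 0.8 - 0.004 * 30)
  # clipped at the extremes
  expect_equal(ppgbp:::ppg_morphology(60, 500, 80, 1)$ratio, 0.1)
  # sigma_s widens with DBP
  m1 <- ppgbp:::ppg_morphology(60, 120, 80, 1)
  m2 <- ppgbp:::ppg_morphology(60, 120, 100, 1)
  expect_equal(m2$sigma_s / m1$sigma_s, 1 + 0.005 * 20)
})

test_that("truth parameters expose a monotone non-increasing ratio in SBP", {
  cfg <- sim_config(n_records = 60, record_duration = 2, sampling_rate = 50,
                    noise_sd = 0, wander_amplitude = 0, seed = 3)
  recs <- simulate_ppg_dataset(cfg)
  ord <- order(recs$sbp)
  ratios <- vapply(recs$truth[ord], `[[`, numeric(1), "ratio")
  expect_true(all(diff(ratios) <= 1e-12))
})

test_that("record length, label validity and pulse-pressure floor hold", {
  cfg <- sim_config(n_records = 25, record_duration = 7.3, sampling_rate = 125, seed = 9)
  recs <- simulate_ppg_dataset(cfg)
  expect_true(all(lengths(recs$samples) == round(7.3 * 125)))
  expect_true(all(vapply(recs$samples, function(s) all(is.finite(s)), logical(1))))
  expect_true(all(recs$sbp > recs$dbp))
  expect_true(all(recs$sbp - recs$dbp >= 20))
})

test_that("sampled SBP matches the oracles of the truncated joint uniform", {
  cfg <- sim_config(n_records = 1000, record_duration = 2, sampling_rate = 50,
                    noise_sd = 0, wander_amplitude = 0, seed = 17)
  recs <- simulate_ppg_dataset(cfg)
  # independent oracle 1: rejection-sample the same truncated joint uniform
  mc_oracle <- withr::with_seed(99, {
    s <- runif(2e5, 90, 180); d <- runif(2e5, 55, 110)
    mean(s[s - d >= 20])
  })
  # independent oracle 2: closed form. Acceptance probability given SBP = s is
  # min(max(s - 75, 0), 55)/55, so the truncated mean is the weighted average;
  # pulse-pressure truncation pulls the mean of Uniform(90, 180) up from 135
  # to 141.1 mmHg.
  w <- function(s) pmin(pmax(s - 75, 0), 55) / 55
  exact <- stats::integrate(function(s) s * w(s), 90, 180)$value /
    stats::integrate(w, 90, 180)$value
  expect_lt(abs(mc_oracle - exact), 0.2)
  expect_lt(abs(mean(recs$sbp) - exact), 2)
})

test_that("dataset writer produces a complete manifest and lossless round-trip", {
  cfg <- sim_config(n_records = 3, record_duration = 5, sampling_rate = 50, seed = 2)
  recs <- simulate_ppg_dataset(cfg)
  dir <- withr::local_tempdir()
  write_ppg_dataset(recs, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest$records, 3)
  expect_identical(
    vapply(manifest$records, `[[`, character(1), "record_id"),
    recs$record_id
  )
  back <- read_ppg_dataset(dir)
  expect_equal(back$samples[[2]], recs$samples[[2]], tolerance = 1e-12)
  expect_equal(back$sbp, recs$sbp, tolerance = 1e-12)
})

test_that("baseline wander dominates 5 Hz before filtering and is removed by the band-pass", {
  cfg <- sim_config(n_records = 1, record_duration = 40, sampling_rate = 125,
                    noise_sd = 0, wander_amplitude = 0.3, wander_freq = 0.25, seed = 4)
  rec <- simulate_ppg_record(cfg, 0)
  x <- rec$samples[[1]]
  t <- (seq_along(x) - 1) / 125
  amp_at <- function(sig, f) 2 * Mod(mean(sig * exp(-2i * pi * f * t)))
  expect_gt(amp_at(x, 0.25), amp_at(x, 5))
  y <- bandpass_filter(x, 125)
  expect_lt(amp_at(y, 0.25), 0.05 * amp_at(x, 0.25))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(sampling_rate = 10), class = "ppgbp_config_error")
  expect_error(sim_config(sbp_range = c(120, 90)), class = "ppgbp_config_error")
  expect_error(sim_config(link_strength = 1.5), class = "ppgbp_config_error")
  expect_error(sim_config(sbp_range = c(90, 100), dbp_range = c(85, 110)),
               class = "ppgbp_config_error")
  cfg <- sim_config(n_records = 2)
  expect_error(simulate_ppg_record(cfg, 2), class = "ppgbp_config_error")
})
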