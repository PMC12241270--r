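#' Configuration for the synthetic PPG simulator
#'
#' The simulator produces quasi-periodic pulse waveforms in which each beat is
#' the sum of a systolic and a diastolic (dicrotic) Gaussian component, plus
#' sinusoidal baseline wander and white measurement noise. Blood pressure is
#' planted into the morphology through two documented links:
#'
#' * amplitude ratio: `A_d / A_s = clip(0.8 - link_strength * 0.004 * (SBP - 120), 0.1, 0.95)`
#'   so higher systolic pressure shrinks the diastolic component;
#' * systolic width: `sigma_s = 0.10 * T * (1 + link_strength * 0.005 * (DBP - 80))`
#'   so higher diastolic pressure broadens the systolic peak (`T` is the beat
#'   period in seconds).
#'
#' These coefficients are tunable artifact choices, not physiological claims;
#' `link_strength = 0` removes any morphology--pressure dependence and
#' `link_strength = 1` is the full planted link used in recovery experiments.
#' Reference SBP/DBP are drawn uniformly from their ranges and redrawn until
#' the pulse pressure `SBP - DBP` is at least 20 mmHg.
#'
#' @param sampling_rate Sampling rate in Hz (> 16, i.e. above twice the 8 Hz
#'   passband edge used downstream).
#' @param record_duration Record length in seconds.
#' @param n_records Number of records to simulate.
#' @param heart_rate_range Interval of heart rates in beats per minute; each
#'   record draws one heart rate uniformly from it.
#' @param sbp_range,dbp_range Uniform sampling intervals for reference
#'   systolic/diastolic pressure in mmHg.
#' @param noise_sd Standard deviation of additive white noise (amplitude a.u.).
#' @param wander_amplitude,wander_freq Amplitude (a.u.) and frequency (Hz) of
#'   the sinusoidal baseline wander.
#' @param link_strength Dimensionless link strength in `[0, 1]`.
#' @param records_per_subject Consecutive records sharing one `subject_id`
#'   (used for subject-grouped cross-validation splits).
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_records = 2, record_duration = 20, seed = 1)
#' recs <- simulate_ppg_dataset(cfg)
#' recs$sbp - recs$dbp # pulse pressure >= 20 by construction
#' @export
sim_config <- function(sampling_rate = 125,
                       record_duration = 60,
                       n_records = 10,
                       heart_rate_range = c(55, 95),
                       sbp_range = c(90, 180),
                       dbp_range = c(55, 110),
                       noise_sd = 0.02,
                       wander_amplitude = 0.3,
                       wander_freq = 0.25,
                       link_strength = 1.0,
                       records_per_subject = 1L,
                       seed = 0L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 16) {
    abort_config("`sampling_rate` must exceed 16 Hz (twice the 8 Hz passband edge).")
  }
  if (!is.numeric(record_duration) || record_duration <= 0) {
    abort_config("`record_duration` must be positive.")
  }
  if (!is_count(n_records)) abort_config("`n_records` must be a positive integer.")
  stopifnot_range(heart_rate_range, "heart_rate_range")
  if (heart_rate_range[1] <= 0) abort_config("heart rates must be positive.")
  stopifnot_range(sbp_range, "sbp_range")
  stopifnot_range(dbp_range, "dbp_range")
  if (sbp_range[2] - dbp_range[1] < 20) {
    abort_config("`sbp_range` and `dbp_range` leave no room for a pulse pressure of 20 mmHg.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort_config("`noise_sd` must be >= 0.")
  if (!is.numeric(wander_amplitude) || wander_amplitude < 0) {
    abort_config("`wander_amplitude` must be >= 0.")
  }
  if (!is.numeric(wander_freq) || wander_freq <= 0) abort_config("`wander_freq` must be positive.")
  if (!is.numeric(link_strength) || link_strength < 0 || link_strength > 1) {
    abort_config("`link_strength` must lie in [0, 1].")
  }
  if (!is_count(records_per_subject)) abort_config("`records_per_subject` must be a positive integer.")
  structure(
    list(
      sampling_rate = sampling_rate, record_duration = record_duration,
      n_records = as.integer(n_records), heart_rate_range = heart_rate_range,
      sbp_range = sbp_range, dbp_range = dbp_range, noise_sd = noise_sd,
      wander_amplitude = wander_amplitude, wander_freq = wander_freq,
      link_strength = link_strength,
      records_per_subject = as.integer(records_per_subject),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Morphology parameters implied by (HR, SBP, DBP) under the planted link.
ppg_morphology <- function(hr, sbp, dbp, link_strength) {
  period <- 60 / hr
  ratio <- 0.8 - link_strength * 0.004 * (sbp - 120)
  ratio <- min(max(ratio, 0.1), 0.95)
  list(
    hr = hr, period = period,
    a_s = 1.0,
    a_d = ratio,
    ratio = ratio,
    sigma_s = 0.10 * period * (1 + link_strength * 0.005 * (dbp - 80)),
    sigma_d = 0.12 * period,
    mu_s = 0.30 * period,
    mu_d = 0.65 * period
  )
}

#' Simulate one synthetic PPG record
#'
#' Deterministic given `(config$seed, record_index)`: the record's random draws
#' come from a child seed derived from both, so records can be generated
#' individually or as a dataset with identical results.
#'
#' @param config A [sim_config()].
#' @param record_index Zero-based record index, `< config$n_records`.
#' @return A one-row [tibble::tibble()] with columns `record_id`, `subject_id`,
#'   `sampling_rate`, `sbp`, `dbp`, `hr`, and list-columns `samples` (numeric
#'   vector of length `round(record_duration * sampling_rate)`) and `truth`
#'   (the morphology parameters actually used, for recovery tests).
#' @export
simulate_ppg_record <- function(config, record_index) {
  if (!inherits(config, "sim_config")) abort_config("`config` must be a `sim_config`.")
  if (!is.numeric(record_index) || record_index < 0 || record_index >= config$n_records) {
    abort_config("`record_index` must satisfy 0 <= record_index < n_records.")
  }
  record_index <- as.integer(record_index)
  draws <- with_local_seed(derive_seed(config$seed, record_index), {
    hr <- runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
    sbp <- runif(1, config$sbp_range[1], config$sbp_range[2])
    dbp <- runif(1, config$dbp_range[1], config$dbp_range[2])
    tries <- 0L
    while (sbp - dbp < 20) {
      sbp <- runif(1, config$sbp_range[1], config$sbp_range[2])
      dbp <- runif(1, config$dbp_range[1], config$dbp_range[2])
      tries <- tries + 1L
      if (tries > 10000L) abort_config("could not sample SBP - DBP >= 20 from the given ranges.")
    }
    n <- round(config$record_duration * config$sampling_rate)
    noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
    list(hr = hr, sbp = sbp, dbp = dbp, noise = noise, n = n)
  })

  mor <- ppg_morphology(draws$hr, draws$sbp, draws$dbp, config$link_strength)
  t <- (seq_len(draws$n) - 1) / config$sampling_rate
  tau <- t %% mor$period # time within the current beat
  pulse <- mor$a_s * exp(-(tau - mor$mu_s)^2 / (2 * mor$sigma_s^2)) +
    mor$a_d * exp(-(tau - mor$mu_d)^2 / (2 * mor$sigma_d^2))
  wander <- config$wander_amplitude * sin(2 * pi * config$wander_freq * t)
  samples <- pulse + wander + draws$noise

  subj <- record_index %/% config$records_per_subject
  tibble::tibble(
    record_id = sprintf("rec_%04d", record_index),
    subject_id = sprintf("subj_%04d", subj),
    sampling_rate = config$sampling_rate,
    sbp = draws$sbp, dbp = draws$dbp, hr = draws$hr,
    samples = list(samples),
    truth = list(mor)
  )
}

#' Simulate a dataset of synthetic PPG records
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per record (see [simulate_ppg_record()]),
#'   carrying the generating configuration and its hash as attributes
#'   `sim_config` and `config_hash`.
#' @export
simulate_ppg_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort_config("`config` must be a `sim_config`.")
  recs <- purrr::map(seq_len(config$n_records) - 1L, ~ simulate_ppg_record(config, .x))
  out <- dplyr::bind_rows(recs)
  attr(out, "sim_config") <- config
  attr(out, "config_hash") <- config_hash(unclass(config))
  out
}

#' Write / read a simulated dataset as delimited text plus a JSON manifest
#'
#' Each record becomes `<record_id>.csv` with columns `time_s, ppg`; the
#' manifest (`manifest.json`) lists record ids, subject ids, labels, sampling
#' rate, seed and the configuration hash.
#'
#' @param records Tibble from [simulate_ppg_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ppg_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(list(records$record_id, records$samples, records$sampling_rate), function(id, s, fs) {
    df <- data.frame(time_s = (seq_along(s) - 1) / fs, ppg = s)
    utils::write.csv(df, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  })
  cfg <- attr(records, "sim_config")
  manifest <- list(
    records = purrr::pmap(
      records[c("record_id", "subject_id", "sbp", "dbp", "sampling_rate")],
      function(record_id, subject_id, sbp, dbp, sampling_rate) {
        list(record_id = record_id, subject_id = subject_id, sbp = sbp,
             dbp = dbp, sampling_rate = sampling_rate)
      }
    ),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config_hash = attr(records, "config_hash") %||% NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ppg_dataset
#' @export
read_ppg_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort_input(sprintf("no manifest.json in '%s'.", dir))
  manifest <- jsonlite::read_json(mpath)
  rows <- purrr::map(manifest$records, function(m) {
    sig <- read_signal_file(file.path(dir, paste0(m$record_id, ".csv")))
    tibble::tibble(
      record_id = m$record_id, subject_id = m$subject_id,
      sampling_rate = m$sampling_rate, sbp = m$sbp, dbp = m$dbp,
      samples = list(sig$value)
    )
  })
  dplyr::bind_rows(rows)
}
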