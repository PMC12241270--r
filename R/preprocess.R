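#' Numerical derivative of a sampled signal
#'
#' Central differences in the interior, one-sided differences at the edges;
#' the second derivative is the operator applied twice. Output units are
#' input-units per second (order 1) or per second squared (order 2).
#'
#' @param samples Numeric signal (length >= 5).
#' @param sampling_rate Sampling rate in Hz.
#' @param order 1 (velocity, vPPG) or 2 (acceleration, aPPG).
#' @return Numeric vector, same length as the input.
#' @export
signal_derivative <- function(samples, sampling_rate, order = 1L) {
  if (length(samples) < 5) abort_input("need at least 5 samples to differentiate.")
  if (!order %in% c(1L, 2L)) abort_config("`order` must be 1 or 2.")
  d1 <- function(x) {
    n <- length(x)
    dt <- 1 / sampling_rate
    out <- numeric(n)
    out[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    out[1] <- (x[2] - x[1]) / dt
    out[n] <- (x[n] - x[n - 1]) / dt
    out
  }
  out <- d1(samples)
  if (order == 2L) out <- d1(out)
  out
}

#' Sliding-window segmentation indices
#'
#' Windows of `window_s` seconds with fractional overlap `overlap_frac`
#' (default 2/3, i.e. a 5 s hop for 15 s windows). Window length
#' `W = round(window_s * fs)`, hop `S = round(W * (1 - overlap_frac))`; starts
#' are `0, S, 2S, ...` and trailing samples that do not fill a window are
#' dropped.
#'
#' @param n_samples Signal length in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_s Window duration in seconds.
#' @param overlap_frac Fractional overlap between consecutive windows in `[0, 1)`.
#' @return A tibble with columns `start`, `end` (1-based inclusive sample
#'   indices) and `start_time` (seconds); zero rows (with a warning) if the
#'   signal is shorter than one window.
#' @export
segment_indices <- function(n_samples, sampling_rate, window_s = 15, overlap_frac = 2 / 3) {
  if (overlap_frac < 0 || overlap_frac >= 1) abort_config("`overlap_frac` must lie in [0, 1).")
  w <- round(window_s * sampling_rate)
  s <- round(w * (1 - overlap_frac))
  if (s < 1) abort_config("overlap too large: hop is below one sample.")
  if (n_samples < w) {
    warn("signal shorter than one window; returning zero windows.")
    return(tibble::tibble(start = integer(), end = integer(), start_time = numeric()))
  }
  n_win <- floor((n_samples - w) / s) + 1
  starts <- (seq_len(n_win) - 1) * s
  tibble::tibble(
    start = as.integer(starts + 1),
    end = as.integer(starts + w),
    start_time = starts / sampling_rate
  )
}

# Local-maximum detection with minimum inter-peak distance and prominence,
# in the style of standard peak pickers. Prominence of a peak is its height
# above the higher of the two deepest valleys separating it from higher
# terrain (or the signal edge).
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- i; lmin <- h
    while (left > 1 && x[left] <= h) { left <- left - 1L; lmin <- min(lmin, x[left]) }
    if (x[left] <= h) lmin <- min(lmin, x[left]) # hit the edge
    right <- i; rmin <- h
    while (right < n && x[right] <= h) { right <- right + 1L; rmin <- min(rmin, x[right]) }
    if (x[right] <= h) rmin <- min(rmin, x[right])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(integer())
  # enforce distance, keeping taller peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer()
  for (i in ord) {
    if (all(abs(accepted - i) >= min_distance)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Beat-wise SBP/DBP from an arterial blood-pressure waveform
#'
#' Cardiac cycles are delimited by systolic peaks (minimum inter-peak distance
#' 0.3 s, prominence at least 10 mmHg); within each cycle the systolic value is
#' the maximum and the diastolic value the minimum between successive peaks.
#'
#' @param abp Arterial pressure waveform in mmHg.
#' @param sampling_rate Sampling rate in Hz (>= 25).
#' @param min_distance_s,min_prominence Peak-detection constants.
#' @return A tibble with columns `beat_index`, `sbp`, `dbp`, `peak_time`,
#'   `trough_time` (seconds).
#' @export
abp_to_beats <- function(abp, sampling_rate, min_distance_s = 0.3, min_prominence = 10) {
  if (any(!is.finite(abp))) abort_input("`abp` must be finite.")
  if (sampling_rate < 25) abort_input("`sampling_rate` must be >= 25 Hz for beat detection.")
  peaks <- find_peaks(abp, min_distance = max(1L, round(min_distance_s * sampling_rate)),
                      min_prominence = min_prominence)
  if (length(peaks) < 2) abort_input("no complete cardiac cycle: fewer than 2 systolic peaks detected.")
  beats <- purrr::map(seq_len(length(peaks) - 1), function(k) {
    i0 <- peaks[k]; i1 <- peaks[k + 1]
    cyc <- abp[i0:i1]
    trough_rel <- which.min(cyc)
    tibble::tibble(
      beat_index = k,
      sbp = max(cyc),
      dbp = min(cyc),
      peak_time = (i0 - 1) / sampling_rate,
      trough_time = (i0 + trough_rel - 2) / sampling_rate
    )
  })
  out <- dplyr::bind_rows(beats)
  if (any(out$sbp <= out$dbp)) abort_input("degenerate cycle with SBP <= DBP detected.")
  out
}

#' Preprocess records into labelled analysis windows
#'
#' The fixed pipeline is: band-pass filter the full record, compute vPPG and
#' aPPG on the full filtered record (avoiding per-window edge artifacts), then
#' segment all three traces into overlapping windows. Window labels are the
#' record-level SBP/DBP; if a record carries a per-beat label table (list
#' column `beats` with columns `sbp`, `dbp`, `peak_time`, e.g. from
#' [abp_to_beats()]), labels are the mean over beats whose peak falls inside
#' the window, and windows containing no complete beat are dropped.
#'
#' @param records Tibble of records (from [simulate_ppg_dataset()] or
#'   [read_ppg_dataset()]): columns `record_id`, `subject_id`,
#'   `sampling_rate`, `sbp`, `dbp`, list-column `samples`.
#' @param spec A [filter_spec()].
#' @param window_s,overlap_frac Segmentation parameters, see [segment_indices()].
#' @return A tibble of windows: `window_id`, `record_id`, `subject_id`,
#'   `sampling_rate`, `start_time`, `sbp`, `dbp`, and list-columns `ppg`,
#'   `vppg`, `appg` (equal lengths `round(window_s * sampling_rate)`).
#' @export
make_windows <- function(records, spec = filter_spec(), window_s = 15, overlap_frac = 2 / 3) {
  needed <- c("record_id", "subject_id", "sampling_rate", "sbp", "dbp", "samples")
  if (!all(needed %in% names(records))) {
    abort_input(sprintf("`records` must have columns: %s.", paste(needed, collapse = ", ")))
  }
  has_beats <- "beats" %in% names(records)
  rows <- purrr::map(seq_len(nrow(records)), function(r) {
    rec <- records[r, ]
    fs <- rec$sampling_rate
    x <- bandpass_filter(rec$samples[[1]], fs, spec)
    v <- signal_derivative(x, fs, 1L)
    a <- signal_derivative(x, fs, 2L)
    seg <- segment_indices(length(x), fs, window_s, overlap_frac)
    if (nrow(seg) == 0) return(NULL)
    beats <- if (has_beats) rec$beats[[1]] else NULL
    win <- purrr::map(seq_len(nrow(seg)), function(k) {
      i0 <- seg$start[k]; i1 <- seg$end[k]
      if (!is.null(beats)) {
        t0 <- seg$start_time[k]; t1 <- (i1 - 1) / fs
        inside <- beats$peak_time >= t0 & beats$peak_time <= t1
        if (!any(inside)) return(NULL) # no complete beat in this window
        sbp <- mean(beats$sbp[inside]); dbp <- mean(beats$dbp[inside])
      } else {
        sbp <- rec$sbp; dbp <- rec$dbp
      }
      tibble::tibble(
        window_id = sprintf("%s_w%03d", rec$record_id, k - 1),
        record_id = rec$record_id, subject_id = rec$subject_id,
        sampling_rate = fs, start_time = seg$start_time[k],
        sbp = sbp, dbp = dbp,
        ppg = list(x[i0:i1]), vppg = list(v[i0:i1]), appg = list(a[i0:i1])
      )
    })
    dropped <- sum(vapply(win, is.null, logical(1)))
    if (dropped > 0) inform(sprintf("%s: dropped %d window(s) with no complete beat.", rec$record_id, dropped))
    dplyr::bind_rows(win)
  })
  dplyr::bind_rows(rows)
}
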