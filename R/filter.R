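#' Band-pass filter specification
#'
#' Third-order Butterworth band-pass (0.5--8 Hz by default), realized as a
#' cascade of second-order sections (SOS) for numerical stability. With
#' `zero_phase = TRUE` the cascade is applied forward and backward, so the net
#' phase shift is zero and the magnitude response is squared; band edges are
#' the -3 dB points of the single-pass design in either mode.
#'
#' @param lowcut,highcut Passband edges in Hz, `0 < lowcut < highcut`.
#' @param order Butterworth order of the band-pass design (>= 1).
#' @param zero_phase Apply forward--backward filtering (no phase lag).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(lowcut = 0.5, highcut = 8.0, order = 3L, zero_phase = TRUE) {
  if (!is.numeric(lowcut) || !is.numeric(highcut) || lowcut <= 0 || highcut <= lowcut) {
    abort_config("need 0 < lowcut < highcut.")
  }
  if (!is_count(order)) abort_config("`order` must be a positive integer.")
  structure(
    list(lowcut = lowcut, highcut = highcut, order = as.integer(order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

# Convert a zero/pole/gain design to second-order sections. Conjugate pole
# pairs form one biquad each; real poles are sorted and paired. Zeros are
# paired the same way and padded with trivial numerators; the overall gain
# goes on the first section.
zpg_to_sos <- function(zero, pole, gain, tol = 1e-8) {
  pair_up <- function(roots) {
    cplx <- roots[Im(roots) > tol]
    real <- sort(Re(roots[abs(Im(roots)) <= tol]))
    secs <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
    if (length(real) %% 2 == 1) real <- c(real, 0) # degenerate odd case
    if (length(real) > 0) {
      for (i in seq(1, length(real), by = 2)) {
        r1 <- real[i]; r2 <- real[i + 1]
        secs <- c(secs, list(c(1, -(r1 + r2), r1 * r2)))
      }
    }
    secs
  }
  asec <- pair_up(pole)
  bsec <- pair_up(zero)
  n_sec <- max(length(asec), length(bsec))
  while (length(bsec) < n_sec) bsec <- c(bsec, list(c(1, 0, 0)))
  while (length(asec) < n_sec) asec <- c(asec, list(c(1, 0, 0)))
  sos <- t(mapply(function(b, a) c(b, a), bsec, asec)) # n_sec x 6
  sos[1, 1:3] <- sos[1, 1:3] * Re(gain)
  sos
}

# SOS for a Butterworth band-pass, designed via signal::butter.
butter_bandpass_sos <- function(sampling_rate, spec) {
  nyq <- sampling_rate / 2
  if (spec$highcut >= nyq) {
    abort_config(sprintf("highcut (%g Hz) must be below the Nyquist frequency (%g Hz).",
                         spec$highcut, nyq))
  }
  zpg <- signal::as.Zpg(signal::butter(spec$order, c(spec$lowcut, spec$highcut) / nyq,
                                       type = "pass"))
  zpg_to_sos(zpg$zero, zpg$pole, zpg$gain)
}

# One biquad, direct form II transposed, with optional initial state.
biquad_filter <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; a1 <- a[2]; a2 <- a[3]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b0 * xi + z1
    z1 <- b1 * xi - a1 * yi + z2
    z2 <- b2 * xi - a2 * yi
    y[i] <- yi
  }
  y
}

# Steady-state (unit-step) internal state of a biquad; scaling this by the
# first input sample suppresses the start-up transient, as in standard
# forward-backward filtering practice.
biquad_zi <- function(b, a) {
  y <- sum(b) / sum(a)
  z2 <- b[3] - a[3] * y
  z1 <- b[2] - a[2] * y + z2
  c(z1, z2)
}

sosfilt <- function(sos, x, use_zi = FALSE) {
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi <- if (use_zi) biquad_zi(b, a) * x[1] else c(0, 0)
    x <- biquad_filter(b, a, x, zi)
  }
  x
}

# Zero-phase SOS filtering: odd-reflection padding at both ends, steady-state
# initial conditions, forward pass then reversed backward pass.
sosfiltfilt <- function(sos, x) {
  padlen <- 3L * (2L * nrow(sos) + 1L)
  n <- length(x)
  if (n <= padlen) {
    abort_input(sprintf("signal too short for zero-phase padding (need > %d samples).", padlen))
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sosfilt(sos, ext, use_zi = TRUE)
  y <- rev(sosfilt(sos, rev(y), use_zi = TRUE))
  y[(padlen + 1):(padlen + n)]
}

#' Apply the Butterworth band-pass to a signal
#'
#' @param samples Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as the input.
#' @examples
#' fs <- 125
#' t <- seq(0, 10, by = 1 / fs)
#' x <- sin(2 * pi * 4 * t) + 1 # 4 Hz tone on a DC offset
#' y <- bandpass_filter(x, fs)
#' # DC is removed, the 4 Hz tone passes at unit gain
#' @export
bandpass_filter <- function(samples, sampling_rate, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) abort_config("`spec` must be a `filter_spec`.")
  if (any(!is.finite(samples))) abort_input("`samples` must be finite.")
  if (length(samples) < 3 * spec$order * 2) {
    abort_input("signal too short for the requested filter order.")
  }
  sos <- butter_bandpass_sos(sampling_rate, spec)
  if (spec$zero_phase) sosfiltfilt(sos, samples) else sosfilt(sos, samples, use_zi = TRUE)
}

#' Magnitude response of the band-pass design
#'
#' Evaluates the designed transfer function at given frequencies from its
#' polynomial coefficients; with `zero_phase` the single-pass magnitude is
#' squared. Used as the frequency-response oracle in the test suite.
#'
#' @inheritParams bandpass_filter
#' @param freq_hz Frequencies (Hz) at which to evaluate the gain.
#' @return Numeric vector of linear gains.
#' @export
bandpass_gain <- function(freq_hz, sampling_rate, spec = filter_spec()) {
  sos <- butter_bandpass_sos(sampling_rate, spec)
  z <- exp(-1i * 2 * pi * freq_hz / sampling_rate)
  g <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    g <- g * num / den
  }
  gain <- Mod(g)
  if (spec$zero_phase) gain^2 else gain
}
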