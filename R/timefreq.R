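# Morlet wavelet time-frequency analysis --------------------------------------

# complex Morlet wavelet sampled at `rate`, centre frequency f0, with
# f0/sigma_f = cycles_ratio; scaled so that convolution with a sinusoid of
# amplitude A at f0 yields power A^2/2 (its squared rms, in microvolts^2)
morlet_wavelet <- function(f0, rate, cycles_ratio = 7) {
  sigma_f <- f0 / cycles_ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3.5 * sigma_t * rate)
  t <- (-half:half) / rate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f0 * t)
  w * sqrt(2) / sum(Mod(w))
}

convolve_same <- function(x, w) {
  # linear convolution, central part, via FFT
  nx <- length(x); nw <- length(w)
  n <- stats::nextn(nx + nw - 1L, 2L)
  full <- stats::fft(stats::fft(c(x, rep(0, n - nx))) *
                     stats::fft(c(w, rep(0, n - nw))), inverse = TRUE) / n
  half <- (nw - 1L) %/% 2L
  full[(half + 1L):(half + nx)]
}

#' Morlet wavelet decomposition
#'
#' Convolves each trial and channel with Gaussian Morlet wavelets
#' \eqn{w(t, f_0) = A \exp(-t^2/2\sigma_t^2)\exp(i 2\pi f_0 t)} with
#' \eqn{\sigma_f = f_0 / \mathrm{cycles\_ratio}} (default ratio 7) and unit
#' energy, yielding single-trial power (squared modulus, microvolts squared)
#' of both evoked and induced activity, and retaining the complex
#' coefficients for the phase-locking factor. Samples closer than 3
#' \eqn{\sigma_t} to an epoch edge are contaminated by the edge and set to
#' `NA` rather than zero-padded.
#'
#' @param epochs an `eeg_epochs` (included trials are decomposed).
#' @param freqs frequency grid in Hz (default 4-40 Hz in 1 Hz steps).
#' @param cycles_ratio \eqn{f_0/\sigma_f} (must be >= 5 for admissibility).
#' @param keep_complex retain complex coefficients (needed for
#'   [phase_locking_factor()]).
#' @return An object of class `eeg_tfr`: list with `power` (trials x
#'   channels x freqs x time), optional `coef` (same shape, complex),
#'   `freqs`, `times`, `rate`, `channels`, `categories`, `baseline_state`
#'   (`"raw"`), `layout`.
#' @export
morlet_transform <- function(epochs, freqs = 4:40, cycles_ratio = 7,
                             keep_complex = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (cycles_ratio < 5) stop("cycles_ratio must be >= 5 for admissibility")
  rate <- epochs$rate
  if (any(freqs <= 0 | freqs >= rate / 2)) {
    stop("frequencies must lie in (0, rate/2)")
  }
  keep <- which(epochs$included)
  nt <- length(epochs$times)
  epoch_len <- nt / rate
  sigma_t_max <- cycles_ratio / (2 * pi * min(freqs))
  if (epoch_len < 3 * sigma_t_max) {
    stop("epoch too short for the lowest frequency: need >= 3 sigma_t = ",
         signif(3 * sigma_t_max, 3), " s")
  }
  nch <- length(epochs$channels)
  dims <- c(length(keep), nch, length(freqs), nt)
  power <- array(NA_real_, dims,
                 dimnames = list(NULL, epochs$channels, freqs, NULL))
  coef <- if (keep_complex) array(NA_complex_, dims,
                                  dimnames = dimnames(power)) else NULL
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], rate, cycles_ratio)
    edge <- ceiling(3 * (cycles_ratio / (2 * pi * freqs[fi])) * rate)
    valid <- rep(TRUE, nt)
    if (edge >= 1L) {
      valid[seq_len(min(edge, nt))] <- FALSE
      valid[seq.int(max(nt - edge + 1L, 1L), nt)] <- FALSE
    }
    for (ti in seq_along(keep)) {
      for (ci in seq_len(nch)) {
        z <- convolve_same(epochs$data[keep[ti], ci, ], w)
        z[!valid] <- NA
        power[ti, ci, fi, ] <- Mod(z)^2
        if (keep_complex) coef[ti, ci, fi, ] <- z
      }
    }
  }
  structure(list(power = power, coef = coef, freqs = freqs,
                 times = epochs$times, rate = rate,
                 channels = epochs$channels,
                 categories = epochs$categories[keep],
                 baseline_state = "raw", layout = epochs$layout),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("TFR: %d trials x %d channels x %d freqs (%g-%g Hz) x %d samples, baseline %s%s\n",
              d[1L], d[2L], d[3L], min(x$freqs), max(x$freqs), d[4L],
              x$baseline_state,
              if (!is.null(x$coef)) ", complex coefficients retained" else ""))
  invisible(x)
}

#' Subtract the common S1 baseline power
#'
#' Baseline-corrects time-frequency power by subtracting, per channel and
#' frequency, the scalar mean power over the (-500, -250) ms window before
#' S1 onsets, pooled over all S1 trials (randS1 and predS1). The same scalar
#' is applied to every time point of every stimulus category, so power
#' differences between categories are left untouched.
#'
#' @param tfr an `eeg_tfr` in the raw state.
#' @param s1_tfr an `eeg_tfr` of the pooled S1 trials (same channels and
#'   frequency grid); defaults to `tfr` itself restricted to its S1 trials.
#' @param window baseline window in seconds.
#' @return The corrected `eeg_tfr` (`baseline_state =
#'   "s1_baseline_subtracted"`); corrected power may be negative.
#' @export
subtract_s1_baseline <- function(tfr, s1_tfr = NULL,
                                 window = c(-0.5, -0.25)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$baseline_state != "raw") {
    stop("S1 baseline already subtracted")
  }
  if (is.null(s1_tfr)) {
    s1 <- tfr$categories %in% c("randS1", "predS1")
    if (!any(s1)) stop("no S1 trials available for the baseline")
    bl_pow <- tfr$power[s1, , , , drop = FALSE]
  } else {
    stopifnot(inherits(s1_tfr, "eeg_tfr"),
              identical(s1_tfr$channels, tfr$channels),
              identical(s1_tfr$freqs, tfr$freqs))
    bl_pow <- s1_tfr$power
  }
  tsel <- window_samples(tfr$times, tfr$rate, window)
  if (!any(tsel)) stop("baseline window outside the epoch")
  # channels x freqs scalar baseline
  bl <- apply(bl_pow[, , , tsel, drop = FALSE], c(2L, 3L), mean, na.rm = TRUE)
  tfr$power <- tfr$power - rep(bl, each = dim(tfr$power)[1L])
  tfr$baseline_state <- "s1_baseline_subtracted"
  tfr
}

#' Band power in a time window
#'
#' Mean power over the frequencies of a band (default the 8-14 Hz mu/alpha
#' band) and the samples of a time window, per trial and channel.
#'
#' @param tfr an `eeg_tfr`.
#' @param band length-2 numeric, Hz.
#' @param window length-2 numeric, seconds.
#' @param average average over trials (default `TRUE`).
#' @return If `average`, a named per-channel numeric vector; otherwise a
#'   trials x channels matrix.
#' @export
band_power <- function(tfr, band = c(8, 14), window, average = TRUE) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  fsel <- tfr$freqs >= band[1L] - 1e-9 & tfr$freqs <= band[2L] + 1e-9
  tsel <- window_samples(tfr$times, tfr$rate, window)
  if (!any(fsel)) stop("band outside the frequency grid")
  if (!any(tsel)) stop("window outside the epoch")
  m <- apply(tfr$power[, , fsel, tsel, drop = FALSE], c(1L, 2L), mean)
  colnames(m) <- tfr$channels
  if (average) colMeans(m) else m
}

#' Phase-locking factor
#'
#' At every channel, frequency and time point, the modulus of the across-
#' trial mean of the unit-normalized complex wavelet coefficients:
#' 0 for a uniform phase distribution (high latency jitter), 1 for strict
#' phase-locking to the stimulus. Values above the Rayleigh-derived
#' threshold 0.25 are conventionally taken to indicate a non-uniform phase
#' distribution; the exact Rayleigh p-value \eqn{p = \exp(-n \cdot
#' \mathrm{plf}^2)} is returned alongside.
#'
#' @param tfr an `eeg_tfr` with complex coefficients
#'   (`morlet_transform(..., keep_complex = TRUE)`).
#' @param threshold significance threshold on the PLF (default the fixed
#'   0.25 convention).
#' @return An object of class `plf_map`: list with `plf` (channels x freqs
#'   x time in [0, 1]), `mask` (`plf > threshold`), `rayleigh_p`,
#'   `n_trials`, `n_dropped` (count of zero-modulus coefficients excluded),
#'   `threshold`, `freqs`, `times`, `channels`.
#' @export
phase_locking_factor <- function(tfr, threshold = 0.25) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (is.null(tfr$coef)) stop("complex coefficients not retained; rerun ",
                              "morlet_transform with keep_complex = TRUE")
  n <- dim(tfr$coef)[1L]
  if (n < 2L) stop("phase-locking factor needs >= 2 trials")
  mod <- Mod(tfr$coef)
  zero <- mod == 0
  unit <- tfr$coef / mod
  unit[zero] <- NA
  n_dropped <- sum(zero, na.rm = TRUE)
  n_eff <- apply(!is.na(unit), c(2L, 3L, 4L), sum)
  plf_c <- apply(unit, c(2L, 3L, 4L), mean, na.rm = TRUE)
  plf <- Mod(plf_c)
  plf[n_eff == 0] <- NA
  structure(list(plf = plf, mask = !is.na(plf) & plf > threshold,
                 rayleigh_p = exp(-n_eff * plf^2),
                 n_trials = n, n_dropped = n_dropped,
                 threshold = threshold, freqs = tfr$freqs,
                 times = tfr$times, channels = tfr$channels),
            class = "plf_map")
}

#' @export
print.plf_map <- function(x, ...) {
  cat(sprintf("Phase-locking factor map: %d channels x %d freqs x %d samples, %d trials, threshold %g\n",
              dim(x$plf)[1L], dim(x$plf)[2L], dim(x$plf)[3L], x$n_trials,
              x$threshold))
  if (x$n_dropped > 0)
    cat(" zero-modulus coefficients excluded:", x$n_dropped, "\n")
  invisible(x)
}
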