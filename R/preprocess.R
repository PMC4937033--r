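# Containers -----------------------------------------------------------------

#' Construct a continuous EEG recording
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param layout channel layout data frame (see [standard_layout_64()]);
#'   its `name` column must match `rownames(signal)`.
#' @param reference reference state, `"raw"` or `"earlobe_average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, rate, layout = standard_layout_64(),
                          reference = "raw") {
  stopifnot(is.matrix(signal), rate > 0)
  if (is.null(rownames(signal))) {
    stopifnot(nrow(signal) == nrow(layout))
    rownames(signal) <- layout$name
  }
  missing <- setdiff(rownames(signal), layout$name)
  if (length(missing)) stop("channels missing from layout: ",
                            paste(missing, collapse = ", "))
  reference <- match.arg(reference, c("raw", "earlobe_average"))
  structure(list(signal = signal, rate = rate,
                 layout = layout[match(rownames(signal), layout$name), ],
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate, x$reference))
  invisible(x)
}

#' Re-reference scalp channels to the earlobe average
#'
#' Subtracts the mean of the two earlobe channels `A1` and `A2` from every
#' scalp channel. The operation is recorded in the recording's reference
#' state and can only be applied once (state machine `raw ->
#' earlobe_average`).
#'
#' @param recording an `eeg_recording` in the `raw` state containing both
#'   earlobe channels.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_earlobes <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$reference != "raw") {
    stop("recording is already re-referenced (state: ", recording$reference, ")")
  }
  ch <- rownames(recording$signal)
  if (!all(c("A1", "A2") %in% ch)) stop("earlobe channels A1/A2 not found")
  ref <- 0.5 * (recording$signal["A1", ] + recording$signal["A2", ])
  scalp <- recording$layout$type == "scalp"
  recording$signal[scalp, ] <- sweep(recording$signal[scalp, , drop = FALSE],
                                     2L, ref, "-")
  recording$reference <- "earlobe_average"
  recording
}

# Filtering ------------------------------------------------------------------

# zero-phase band-pass, realized spectrally with the squared-magnitude
# Butterworth response (low-pass order 4, high-pass order 2): identical
# magnitude to cascaded forward-backward IIR passes, exactly zero phase, no
# start-up transients; a time-domain band-pass with a 0.5 Hz corner at
# 512 Hz would be numerically fragile in transfer-function form
bandpass_matrix <- function(x, low, high, rate) {
  nyq <- rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band (", low, ", ", high, ") Hz must satisfy 0 < low < high < ",
         nyq, " (Nyquist)")
  }
  n <- ncol(x)
  n2 <- stats::nextn(n, 2L)
  f <- c(0, seq_len(n2 - 1L)) * rate / n2
  f <- pmin(f, rate - f)                        # two-sided
  g <- 1 / (1 + (f / high)^8) *                 # |H_lp|^2, order 4
    ifelse(f == 0, 0, (f / low)^4 / (1 + (f / low)^4))  # |H_hp|^2, order 2
  xp <- cbind(x, matrix(0, nrow(x), n2 - n))
  y <- Re(stats::mvfft(stats::mvfft(t(xp)) * g, inverse = TRUE)) / n2
  out <- t(y)[, seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

#' Zero-phase band-pass filter
#'
#' Filters a continuous recording or an epoch set with a zero-phase
#' (forward-backward) Butterworth band-pass. Symmetric transients keep their
#' peak latency; attenuation one octave outside the band exceeds 24 dB. The
#' analysis bands of interest are 0.5-30 Hz (slow components such as the CNV
#' and P3) and 4-30 Hz (early transient components with the slow waves
#' filtered out).
#'
#' @param x an `eeg_recording` or `eeg_epochs` object.
#' @param low,high band corner frequencies in Hz.
#' @return Same type as `x`, with the band recorded in its `band` field
#'   (`"band_0p5_30"`, `"band_4_30"`, or `"band_<low>_<high>"`).
#' @export
bandpass <- function(x, low, high) UseMethod("bandpass")

band_tag <- function(low, high) {
  if (isTRUE(all.equal(c(low, high), c(0.5, 30)))) return("band_0p5_30")
  if (isTRUE(all.equal(c(low, high), c(4, 30)))) return("band_4_30")
  paste0("band_", low, "_", high)
}

#' @export
bandpass.eeg_recording <- function(x, low, high) {
  x$signal <- bandpass_matrix(x$signal, low, high, x$rate)
  x$band <- band_tag(low, high)
  x
}

#' @export
bandpass.eeg_epochs <- function(x, low, high) {
  d <- dim(x$data)
  for (i in seq_len(d[1L])) {
    tr <- matrix(x$data[i, , ], nrow = d[2L])
    x$data[i, , ] <- bandpass_matrix(tr, low, high, x$rate)
  }
  x$band <- band_tag(low, high)
  x
}

# Spherical spline interpolation ----------------------------------------------

# Legendre polynomial values P_n(x) for n = 1..nmax via the Bonnet recurrence
legendre_values <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1L] <- p
  if (nmax > 1L) for (n in 2L:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p; p <- pn
  }
  out
}

# Perrin spherical-spline kernel g(cos angle), order m, series truncated at N
spline_g <- function(cosang, m = 4L, nmax = 7L) {
  P <- legendre_values(cosang, nmax)
  n <- seq_len(nmax)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  as.vector(P %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flat or excessively noisy channels by values interpolated from
#' the remaining scalp electrodes with spherical splines (order m = 4,
#' Legendre series truncated at n = 7, ridge regularization 1e-5). The
#' spline reproduces constant fields exactly; good channels are untouched.
#'
#' @param x an `eeg_recording`, or a plain numeric matrix (channels x time)
#'   with row names matching `layout$name`.
#' @param bad character vector of bad channel names (at most 2 in routine
#'   use; must be fewer than half the montage).
#' @param layout layout (used only for the matrix method).
#' @param m,nmax,lambda spline order, series truncation, regularization.
#' @return Same type as `x` with the bad channels replaced.
#' @export
interpolate_bad_channels <- function(x, bad, layout = NULL, m = 4L,
                                     nmax = 7L, lambda = 1e-5) {
  if (inherits(x, "eeg_recording")) {
    x$signal <- interpolate_bad_channels(x$signal, bad, x$layout, m, nmax,
                                         lambda)
    return(x)
  }
  if (!length(bad)) return(x)
  stopifnot(is.matrix(x), !is.null(layout))
  lay <- layout[match(rownames(x), layout$name), ]
  scalp <- which(lay$type == "scalp")
  bad_idx <- match(bad, rownames(x))
  if (anyNA(bad_idx)) stop("unknown channels: ",
                           paste(bad[is.na(bad_idx)], collapse = ", "))
  if (!all(bad_idx %in% scalp)) stop("bad channels must be scalp channels")
  good <- setdiff(scalp, bad_idx)
  if (length(bad_idx) >= length(scalp) / 2) {
    stop("refusing to interpolate ", length(bad_idx),
         " channels from only ", length(good), " good ones")
  }
  pos <- as.matrix(lay[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  cosgg <- tcrossprod(pos[good, , drop = FALSE])
  cosbg <- tcrossprod(pos[bad_idx, , drop = FALSE], pos[good, , drop = FALSE])
  G <- matrix(spline_g(pmin(pmax(as.vector(cosgg), -1), 1), m, nmax),
              length(good))
  Gb <- matrix(spline_g(pmin(pmax(as.vector(cosbg), -1), 1), m, nmax),
               length(bad_idx))
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(x[good, , drop = FALSE], 0)
  cd <- solve(A, rhs)
  x[bad_idx, ] <- Gb %*% cd[seq_len(ng), , drop = FALSE] +
    matrix(cd[ng + 1L, ], length(bad_idx), ncol(x), byrow = TRUE)
  x
}

# Epoching ---------------------------------------------------------------------

#' Extract stimulus-locked epochs
#'
#' Cuts trials around event onsets. Time t maps to sample `round(t * rate)`;
#' the epoch window is inclusive of both endpoint samples, and epoch time 0
#' is the sample at the event onset.
#'
#' @param recording an `eeg_recording`.
#' @param events `stimulus_events` data frame (onsets in seconds on the
#'   recording clock).
#' @param window length-2 numeric, epoch window in seconds relative to onset
#'   (must contain 0).
#' @param channels optional character vector restricting the channels kept.
#' @return An object of class `eeg_epochs`: list with `data` (trials x
#'   channels x time array), `times` (seconds), `rate`, `channels`,
#'   `categories`, `included` (edge-truncated trials are flagged out, not
#'   dropped), `band`, `baseline`, `layout`.
#' @export
epoch_recording <- function(recording, events, window, channels = NULL) {
  stopifnot(inherits(recording, "eeg_recording"),
            window[1L] <= 0, window[2L] >= 0)
  sig <- recording$signal
  if (!is.null(channels)) {
    idx <- match(channels, rownames(sig))
    if (anyNA(idx)) stop("unknown channels: ",
                         paste(channels[is.na(idx)], collapse = ", "))
    sig <- sig[idx, , drop = FALSE]
  }
  rate <- recording$rate
  s0 <- round(window[1L] * rate)
  s1 <- round(window[2L] * rate)
  times <- (s0:s1) / rate
  n_ev <- nrow(events)
  nt <- length(times)
  data <- array(0, dim = c(n_ev, nrow(sig), nt),
                dimnames = list(NULL, rownames(sig), NULL))
  ok <- rep(TRUE, n_ev)
  for (i in seq_len(n_ev)) {
    c0 <- round(events$onset[i] * rate) + 1L   # 1-based sample at onset
    lo <- c0 + s0; hi <- c0 + s1
    if (lo < 1L || hi > ncol(sig)) { ok[i] <- FALSE; next }
    data[i, , ] <- sig[, lo:hi]
  }
  structure(list(data = data, times = times, rate = rate,
                 channels = rownames(sig),
                 categories = events$trial_type,
                 included = ok,
                 band = if (is.null(recording$band)) "broadband"
                        else recording$band,
                 baseline = "none",
                 layout = recording$layout),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG epochs: %d trials x %d channels x %d samples, window (%g, %g) s, band %s, baseline %s\n",
              d[1L], d[2L], d[3L], min(x$times), max(x$times), x$band,
              x$baseline))
  cat(" included:", sum(x$included), "of", d[1L], "\n")
  invisible(x)
}

#' Flag trials with excessive peak-to-peak amplitude
#'
#' A trial is flagged when any scalp channel's peak-to-peak amplitude within
#' the test window (default -700 to 700 ms around stimulus onset) exceeds
#' the threshold. The threshold default of 150 microvolts is a conventional
#' muscular/movement artifact criterion; the window is the one the analysis
#' prescribes.
#'
#' @param epochs an `eeg_epochs` whose window covers `window`.
#' @param window test window in seconds.
#' @param threshold_uV peak-to-peak threshold in microvolts (`Inf` disables).
#' @return Logical vector, one flag per trial.
#' @export
flag_artifacts <- function(epochs, window = c(-0.7, 0.7),
                           threshold_uV = 150) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!covers_window(epochs$times, epochs$rate, window)) {
    stop("epoch window does not cover the artifact test window")
  }
  tsel <- window_samples(epochs$times, epochs$rate, window)
  scalp <- if (!is.null(epochs$layout))
    epochs$channels %in% epochs$layout$name[epochs$layout$type == "scalp"]
  else rep(TRUE, length(epochs$channels))
  apply(epochs$data[, scalp, tsel, drop = FALSE], 1L, function(tr) {
    ptp <- apply(tr, 1L, function(ch) diff(range(ch)))
    any(ptp > threshold_uV)
  })
}

# sample-grid window selection: time t maps to sample round(t * rate) and
# windows include both endpoint samples
window_samples <- function(times, rate, window) {
  s <- round(times * rate)
  s >= round(window[1L] * rate) & s <= round(window[2L] * rate)
}

# does the epoch's sample grid cover the window?
covers_window <- function(times, rate, window) {
  s <- round(times * rate)
  min(s) <= round(window[1L] * rate) && max(s) >= round(window[2L] * rate)
}
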