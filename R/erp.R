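# Evoked responses and ERP measures ------------------------------------------

#' Average epochs into an evoked response
#'
#' Pointwise mean over the included trials of one stimulus category.
#'
#' @param epochs an `eeg_epochs`.
#' @param category stimulus category to average (`NULL` averages all
#'   included trials).
#' @return An object of class `eeg_evoked`: list with `data` (channels x
#'   time), `times`, `rate`, `channels`, `category`, `n_trials`, `band`,
#'   `baseline`, `layout`.
#' @export
average_epochs <- function(epochs, category = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- epochs$included
  if (!is.null(category)) keep <- keep & epochs$categories == category
  if (!any(keep)) {
    stop("no included trials", if (!is.null(category))
      paste0(" for category '", category, "'"))
  }
  dat <- epochs$data[keep, , , drop = FALSE]
  avg <- colMeans(dat)                    # mean over the trial dimension
  structure(list(data = avg, times = epochs$times, rate = epochs$rate,
                 channels = epochs$channels,
                 category = if (is.null(category)) "all" else category,
                 n_trials = sum(keep), band = epochs$band,
                 baseline = epochs$baseline, layout = epochs$layout),
            class = "eeg_evoked")
}

#' @export
print.eeg_evoked <- function(x, ...) {
  cat(sprintf("Evoked response: category %s, %d trials, %d channels, window (%g, %g) s, band %s, baseline %s\n",
              x$category, x$n_trials, length(x$channels), min(x$times),
              max(x$times), x$band, x$baseline))
  invisible(x)
}

#' Pre-stimulus baseline correction
#'
#' Subtracts, per channel (and per trial for epoch sets), the mean over the
#' baseline window. The convention of the analysis: post-stimulus measures
#' use a -100 to 0 ms baseline; pre-stimulus (CNV) measures use no baseline.
#' Applying a baseline twice is a state error.
#'
#' @param x an `eeg_evoked` or `eeg_epochs`.
#' @param window baseline window in seconds (default `c(-0.1, 0)`).
#' @return Same type as `x` with `baseline` set to `"pre_minus100_0"` (or a
#'   descriptive tag for non-default windows).
#' @export
apply_baseline <- function(x, window = c(-0.1, 0)) {
  if (!x$baseline %in% "none") {
    stop("baseline already applied (state: ", x$baseline, ")")
  }
  tsel <- window_samples(x$times, x$rate, window)
  if (!any(tsel)) stop("baseline window outside the epoch")
  tag <- if (isTRUE(all.equal(window, c(-0.1, 0)))) "pre_minus100_0"
         else paste0("pre_", window[1L], "_", window[2L])
  if (inherits(x, "eeg_evoked")) {
    bl <- rowMeans(x$data[, tsel, drop = FALSE])
    x$data <- x$data - bl
  } else if (inherits(x, "eeg_epochs")) {
    bl <- apply(x$data[, , tsel, drop = FALSE], c(1L, 2L), mean)
    x$data <- x$data - as.vector(bl)   # recycles over the time dimension
  } else stop("unsupported type")
  x$baseline <- tag
  x
}

#' Peak latency and amplitude
#'
#' Finds the signed extremum of an evoked waveform at one electrode within a
#' search window (both endpoint samples included). Latency is reported at
#' sample resolution in milliseconds; ties are broken to the earliest
#' sample. Negative components (N1, N2) use `polarity = "negative"`,
#' positive components (P2, P3) `"positive"`.
#'
#' @param evoked an `eeg_evoked`.
#' @param electrode channel name.
#' @param window search window in seconds.
#' @param polarity `"positive"` or `"negative"`.
#' @return List with `electrode`, `polarity`, `latency_ms`, `amplitude_uV`.
#' @export
peak_measure <- function(evoked, electrode, window, polarity) {
  stopifnot(inherits(evoked, "eeg_evoked"))
  polarity <- match.arg(polarity, c("positive", "negative"))
  ci <- match(electrode, evoked$channels)
  if (is.na(ci)) stop("electrode ", electrode, " not present")
  if (!covers_window(evoked$times, evoked$rate, window)) {
    stop("search window outside the epoch")
  }
  tsel <- which(window_samples(evoked$times, evoked$rate, window))
  w <- evoked$data[ci, tsel]
  i <- if (polarity == "positive") which.max(w) else which.min(w)
  list(electrode = electrode, polarity = polarity,
       latency_ms = evoked$times[tsel[i]] * 1000,
       amplitude_uV = w[i])
}

#' Mean amplitude in a time window
#'
#' Inclusive-sample arithmetic mean per electrode, e.g. the CNV measure
#' (mean amplitude in (-150, 0) ms of the non-baselined 0.5-30 Hz evoked
#' response) or the P3 measure ((200, 600) ms, baselined).
#'
#' @param evoked an `eeg_evoked`.
#' @param electrodes character vector of channel names.
#' @param window window in seconds.
#' @param require_baseline optional: `"none"` or `"pre_minus100_0"`; when
#'   given, the evoked's baseline state must match (pre-stimulus windows must
#'   be measured on non-baselined data, post-stimulus windows on baselined
#'   data).
#' @return Named numeric vector of per-electrode means (microvolts).
#' @export
window_mean <- function(evoked, electrodes, window, require_baseline = NULL) {
  stopifnot(inherits(evoked, "eeg_evoked"))
  if (!is.null(require_baseline) && evoked$baseline != require_baseline) {
    stop("baseline state is '", evoked$baseline, "' but '",
         require_baseline, "' is required for this window")
  }
  ci <- match(electrodes, evoked$channels)
  if (anyNA(ci)) stop("unknown electrodes: ",
                      paste(electrodes[is.na(ci)], collapse = ", "))
  if (!covers_window(evoked$times, evoked$rate, window)) {
    stop("window outside the epoch")
  }
  tsel <- window_samples(evoked$times, evoked$rate, window)
  out <- rowMeans(evoked$data[ci, tsel, drop = FALSE])
  names(out) <- electrodes
  out
}

#' Windowed scan grid
#'
#' Splits an analysis interval into successive windows for the
#' mass-univariate scans: contiguous half-open windows `[t, t + width)`
#' (e.g. forty 10 ms windows over (0, 400) ms for the transient ERP scan),
#' or overlapping windows shifted by `step` (e.g. 200 ms windows shifted by
#' 100 ms over (-500, 500) ms for the time-frequency scan).
#'
#' @param interval length-2 numeric, seconds.
#' @param width window width, seconds.
#' @param step shift between window starts (default `width`, i.e.
#'   non-overlapping).
#' @return Matrix with columns `start`, `end` (seconds), one row per window.
#' @export
scan_grid <- function(interval, width, step = width) {
  starts <- seq(interval[1L], interval[2L] - width + 1e-12, by = step)
  cbind(start = starts, end = starts + width)
}

#' Per-subject electrode-by-window measure matrices
#'
#' Applies a scan grid to each subject's evoked response, producing the
#' electrode x window x subject array that feeds the mass-univariate ANOVA.
#' Scan windows are half-open `[start, end)` except the last, which includes
#' its endpoint.
#'
#' @param evokeds list of `eeg_evoked`, one per subject (same channels and
#'   time grid).
#' @param grid matrix from [scan_grid()].
#' @return Numeric array, channels x windows x subjects.
#' @export
scan_windows <- function(evokeds, grid) {
  stopifnot(length(evokeds) >= 1L)
  ref <- evokeds[[1L]]
  nw <- nrow(grid)
  out <- array(NA_real_, dim = c(length(ref$channels), nw, length(evokeds)),
               dimnames = list(ref$channels, NULL, NULL))
  for (s in seq_along(evokeds)) {
    ev <- evokeds[[s]]
    stopifnot(identical(ev$channels, ref$channels),
              length(ev$times) == length(ref$times))
    for (w in seq_len(nw)) {
      last <- w == nw
      tsel <- ev$times >= grid[w, 1L] - 1e-9 &
        (if (last) ev$times <= grid[w, 2L] + 1e-9
         else ev$times < grid[w, 2L] - 1e-9)
      out[, w, s] <- rowMeans(ev$data[, tsel, drop = FALSE])
    }
  }
  out
}

#' Export an evoked response
#'
#' Writes the channel x time matrix as a tab-separated table plus a JSON
#' sidecar recording category, trial count, band and baseline provenance.
#'
#' @param evoked an `eeg_evoked`.
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
export_evoked <- function(evoked, path) {
  m <- as.data.frame(t(evoked$data))
  names(m) <- evoked$channels
  m <- cbind(time_s = evoked$times, m)
  utils::write.table(m, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(category = evoked$category, n_trials = evoked$n_trials,
         band = evoked$band, baseline = evoked$baseline,
         rate_hz = evoked$rate),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
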