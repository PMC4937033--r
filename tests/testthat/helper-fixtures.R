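# shared fixtures: reduced montages, block compositions and event builders
# used across the suite (everything is generated in code)

# montage restricted to the analysis electrodes plus references; keeps the
# injected topography centres (Cz, C3, POz) available
reduced_montage <- function() {
  lay <- standard_layout_64()
  lay[lay$name %in% c("PO3", "PO4", "Pz", "POz", "Fz", "FCz", "Cz",
                      "C3", "C5", "A1", "A2"), ]
}

# down-scaled block composition with the same 15%/85% structure in spirit
reduced_counts <- function() {
  c(randT = 8, randS1 = 12, randS2 = 12, randS3 = 12,
    predT = 6, predS1 = 6, predS2 = 6, predS3 = 6)
}

# a labelled event table from an identity stream, on the standard SOA grid
events_from_identities <- function(ids, soa = 1.15) {
  ev <- data.frame(onset = (seq_along(ids) - 1) * soa,
                   duration = 0.15,
                   identity = ids,
                   trial_type = label_events(ids),
                   block = 1L, stringsAsFactors = FALSE)
  class(ev) <- c("stimulus_events", "data.frame")
  ev
}

# single-channel recording wrapped in the reduced montage (other channels 0)
recording_with_channel <- function(channel, x, rate = 512,
                                   layout = reduced_montage()) {
  sig <- matrix(0, nrow(layout), length(x),
                dimnames = list(layout$name, NULL))
  sig[channel, ] <- x
  eeg_recording(sig, rate, layout)
}

# minimal complex-coefficient TFR container for phase-locking tests
tfr_from_coef <- function(coef, freqs = 10, rate = 512) {
  nt <- dim(coef)[4L]
  structure(list(power = Mod(coef)^2, coef = coef, freqs = freqs,
                 times = (seq_len(nt) - 1) / rate, rate = rate,
                 channels = dimnames(coef)[[2L]] %||% paste0("ch", seq_len(dim(coef)[2L])),
                 categories = rep("randT", dim(coef)[1L]),
                 baseline_state = "raw", layout = NULL),
            class = "eeg_tfr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
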