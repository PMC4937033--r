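# epochs built directly: trials x channels x time with named channels
make_epochs <- function(data, rate = 512, t0 = -0.2, categories = NULL,
                        band = "broadband") {
  nt <- dim(data)[3]
  structure(list(data = data,
                 times = (round(t0 * rate) + seq_len(nt) - 1) / rate,
                 rate = rate,
                 channels = dimnames(data)[[2]],
                 categories = categories %||% rep("randT", dim(data)[1]),
                 included = rep(TRUE, dim(data)[1]),
                 band = band, baseline = "none", layout = NULL),
            class = "eeg_epochs")
}

test_that("averaging uses only included trials and is linear", {
  tmpl <- sin(seq(0, 2 * pi, length.out = 100))
  data <- array(0, c(4, 1, 100), dimnames = list(NULL, "Cz", NULL))
  for (i in 1:4) data[i, 1, ] <- tmpl
  ep <- make_epochs(data)
  av <- average_epochs(ep)
  expect_equal(unname(av$data[1, ]), tmpl)
  expect_equal(av$n_trials, 4L)

  # an excluded outlier trial does not influence the mean
  data2 <- data; data2[3, 1, ] <- 1e6
  ep2 <- make_epochs(data2); ep2$included[3] <- FALSE
  expect_equal(unname(average_epochs(ep2)$data[1, ]), tmpl)

  # linearity in the data
  ep3 <- make_epochs(data * 2.5)
  expect_equal(average_epochs(ep3)$data, av$data * 2.5)

  expect_error(average_epochs(ep, "predT"), "predT")

  # CLT bound: template + noise recovers the template
  set.seed(2)
  n <- 500
  noisy <- array(rep(tmpl, each = n) + rnorm(n * 100, sd = 1),
                 c(n, 1, 100), dimnames = list(NULL, "Cz", NULL))
  avn <- average_epochs(make_epochs(noisy))
  se <- 1 / sqrt(n)
  expect_true(all(abs(avn$data[1, ] - tmpl) < 4 * se))
})

test_that("baseline correction removes the pre-stimulus mean once", {
  rate <- 512
  nt <- round(0.4 * rate)
  data <- array(5, c(2, 1, nt), dimnames = list(NULL, "Pz", NULL))
  ep <- make_epochs(data, rate)
  av <- average_epochs(ep)
  avb <- apply_baseline(av)
  expect_equal(unname(avb$data[1, ]), rep(0, nt))        # constant -> zero
  expect_identical(avb$baseline, "pre_minus100_0")
  expect_error(apply_baseline(avb), "already applied")

  # the baseline-window mean is exactly zero afterwards
  set.seed(3)
  data2 <- array(rnorm(2 * nt), c(2, 1, nt), dimnames = list(NULL, "Pz", NULL))
  av2 <- apply_baseline(average_epochs(make_epochs(data2, rate)))
  bl_sel <- av2$times >= -0.1 & av2$times <= 0
  expect_equal(mean(av2$data[1, bl_sel]), 0)

  # linear ramp keeps its slope, loses its intercept
  ep3 <- make_epochs(data, rate)
  ramp <- 2 + 3 * ep3$times
  ep3$data[1, 1, ] <- ramp; ep3$data[2, 1, ] <- ramp
  av3 <- apply_baseline(average_epochs(ep3))
  fit <- coef(lm(av3$data[1, ] ~ av3$times))
  expect_equal(unname(fit[2]), 3, tolerance = 1e-9)
  # intercept equals minus the slope times the baseline midpoint
  expect_equal(unname(fit[1]), -3 * mean(av3$times[bl_sel]),
               tolerance = 1e-6)

  # epochs are corrected per trial
  ep4 <- make_epochs(array(c(1, 10), c(2, 1, nt),
                           dimnames = list(NULL, "Pz", NULL)), rate)
  ep4b <- apply_baseline(ep4)
  expect_equal(unname(ep4b$data[1, 1, ]), rep(0, nt))
  expect_equal(unname(ep4b$data[2, 1, ]), rep(0, nt))
})

test_that("peak measures find the signed extremum with early ties", {
  rate <- 512
  t0 <- -0.2
  nt <- round(1.0 * rate)
  mk_evoked <- function(wave) {
    data <- array(wave, c(1, 1, nt), dimnames = list(NULL, "Pz", NULL))
    average_epochs(make_epochs(data, rate, t0))
  }
  times <- (round(t0 * rate) + seq_len(nt) - 1) / rate
  bump <- 4 * exp(-(times - 0.3)^2 / (2 * 0.03^2))
  pk <- peak_measure(mk_evoked(bump), "Pz", c(0.25, 0.75), "positive")
  expect_equal(pk$latency_ms, 1000 * times[which.max(bump)])
  expect_lt(abs(pk$latency_ms - 300), 2)     # one-sample resolution
  expect_equal(pk$amplitude_uV, max(bump))

  # two exactly equal maxima: the earlier one wins
  twin <- numeric(nt)
  twin[which.min(abs(times - 0.3))] <- 1
  twin[which.min(abs(times - 0.4))] <- 1
  pk2 <- peak_measure(mk_evoked(twin), "Pz", c(0.25, 0.75), "positive")
  expect_lt(abs(pk2$latency_ms - 300), 3)

  # negative component, and invariance to a constant offset
  pk3 <- peak_measure(mk_evoked(-bump), "Pz", c(0.25, 0.75), "negative")
  expect_equal(pk3$amplitude_uV, -max(bump))
  pk4 <- peak_measure(mk_evoked(-bump + 11), "Pz", c(0.25, 0.75), "negative")
  expect_equal(pk4$latency_ms, pk3$latency_ms)

  expect_error(peak_measure(mk_evoked(bump), "Pz", c(0.5, 2), "positive"),
               "outside")
  expect_error(peak_measure(mk_evoked(bump), "Oz", c(0.25, 0.75),
                            "positive"), "not present")
})

test_that("window means use inclusive sample arithmetic", {
  rate <- 512
  nt <- round(0.9 * rate)
  t0 <- -0.2
  times <- (round(t0 * rate) + seq_len(nt) - 1) / rate
  mk <- function(wave) {
    average_epochs(make_epochs(array(wave, c(1, 1, nt),
                                     dimnames = list(NULL, "PO3", NULL)),
                               rate, t0))
  }
  expect_equal(unname(window_mean(mk(rep(-2, nt)), "PO3", c(-0.15, 0))), -2)
  expect_equal(unname(window_mean(mk(numeric(nt)), "PO3", c(-0.15, 0))), 0)

  # ramp from 0 at -150 ms to -4 at 0 ms: mean is the midpoint -2
  # (windows map to sample indices round(t * rate), both endpoints kept)
  smp <- round(times * rate)
  sel <- smp >= round(-0.15 * rate) & smp <= 0
  ramp <- numeric(nt)
  ramp[sel] <- -4 * (times[sel] + 0.15) / 0.15
  expect_equal(unname(window_mean(mk(ramp), "PO3", c(-0.15, 0))),
               mean(ramp[sel]))
  expect_equal(unname(window_mean(mk(ramp), "PO3", c(-0.15, 0))), -2,
               tolerance = 0.03)

  # mean over the union of two disjoint windows is the count-weighted mean
  w1 <- unname(window_mean(mk(ramp), "PO3", c(-0.15, -0.075)))
  w2 <- unname(window_mean(mk(ramp), "PO3", c(-0.075 + 1 / rate, 0)))
  n1 <- sum(smp >= round(-0.15 * rate) & smp <= round(-0.075 * rate))
  n2 <- sum(smp >= round((-0.075 + 1 / rate) * rate) & smp <= 0)
  expect_equal(unname(window_mean(mk(ramp), "PO3", c(-0.15, 0))),
               (w1 * n1 + w2 * n2) / (n1 + n2))

  # baseline-state guard
  ev <- mk(ramp)
  expect_error(window_mean(ev, "PO3", c(-0.15, 0),
                           require_baseline = "pre_minus100_0"),
               "baseline state")
})

test_that("scan grids have the documented window counts", {
  g1 <- scan_grid(c(0, 0.4), 0.01)
  expect_equal(nrow(g1), 40L)                   # forty 10 ms windows
  expect_equal(0.05 / nrow(g1), 0.00125)        # the corrected threshold
  g2 <- scan_grid(c(-0.5, 0.5), 0.2, 0.1)
  expect_equal(nrow(g2), 9L)                    # nine sliding TF windows
  expect_equal(g2[1, ], c(start = -0.5, end = -0.3))
  expect_equal(g2[9, ], c(start = 0.3, end = 0.5))
})

test_that("scan_windows emits per-subject electrode-by-window means", {
  rate <- 512
  nt <- round(0.9 * rate)
  mk <- function(const) {
    data <- array(const, c(2, 2, nt),
                  dimnames = list(NULL, c("Cz", "Pz"), NULL))
    average_epochs(make_epochs(data, rate, t0 = -0.2))
  }
  evs <- list(mk(1), mk(2), mk(3))
  out <- scan_windows(evs, scan_grid(c(0, 0.4), 0.01))
  expect_equal(dim(out), c(2L, 40L, 3L))
  expect_true(all(out[, , 1] == 1))
  expect_true(all(out[, , 3] == 3))
})
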