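# Synthetic multi-subject task EEG --------------------------------------------
#
# The generator emulates the statistical structure the analysis assumes:
# stimulus-evoked transient components (posterior N1/P2, fronto-central
# P2/N2, centro-parietal P3 growing along the predictive sequence),
# pre-stimulus CNV ramps, a left-central mu rhythm whose 8-14 Hz power is
# modulated before predictable targets, fronto-central background alpha,
# phase-locked post-target alpha, 1/f + broadband noise with spatial
# correlation over the montage, and behavioral responses with a
# predictability benefit. It makes every downstream stage testable without
# recorded data; it is not a biophysical head model.

#' Default ERP component templates
#'
#' Each component is a Gaussian-windowed monophasic deflection (the CNV is a
#' linear ramp ending at stimulus onset) with a spatial topography given by
#' a Gaussian over the flat-projected montage centred on a named electrode.
#' Amplitudes are in microvolts at the centre electrode for gain 1.
#'
#' @return Named list of component definitions (fields `amp`, `latency`,
#'   `width`, `center`, `spread`, `shape`).
#' @export
default_components <- function() {
  list(
    N1     = list(amp = -5, latency = 0.16, width = 0.025, center = "POz",
                  spread = 0.35, shape = "gauss"),
    P2post = list(amp = 4, latency = 0.25, width = 0.035, center = "POz",
                  spread = 0.35, shape = "gauss"),
    P2front = list(amp = 3, latency = 0.20, width = 0.030, center = "FCz",
                   spread = 0.30, shape = "gauss"),
    N2     = list(amp = -4, latency = 0.28, width = 0.035, center = "FCz",
                  spread = 0.30, shape = "gauss"),
    P3     = list(amp = 5, latency = 0.45, width = 0.090, center = "Pz",
                  spread = 0.45, shape = "gauss"),
    CNV    = list(amp = -4, latency = 0, width = NA, center = "Cz",
                  spread = 0.60, shape = "ramp", ramp_start = -0.3))
}

#' Default background-noise model
#'
#' Spectrally shaped 1/f noise plus a weak background alpha oscillation,
#' spatially correlated over the montage by Gaussian mixing.
#'
#' @param one_over_f_exponent spectral exponent of the background.
#' @param sd broadband standard deviation per channel (microvolts).
#' @param alpha_amp,alpha_freq background alpha amplitude (microvolts) and
#'   peak frequency (Hz, within 8-14).
#' @param corr_len spatial correlation length in flat-layout units.
#' @return Named list, validated.
#' @export
noise_model <- function(one_over_f_exponent = 1, sd = 3, alpha_amp = 1,
                        alpha_freq = 10, corr_len = 0.35) {
  stopifnot(sd >= 0, alpha_freq >= 8, alpha_freq <= 14, corr_len > 0)
  list(one_over_f_exponent = one_over_f_exponent, sd = sd,
       alpha_amp = alpha_amp, alpha_freq = alpha_freq, corr_len = corr_len)
}

#' Group effect profile
#'
#' Bundles the condition- and group-dependent effect structure of a
#' simulated population: per-component, per-category gains and latency
#' shifts, the fractional pre-target mu power change at left-central
#' channels, the fronto-central alpha modulation, and the behavioral
#' parameters.
#'
#' @param name group label.
#' @param gains named list: component name -> named numeric vector of gains
#'   per stimulus category (categories missing from the vector get gain 0;
#'   a single unnamed number applies to all categories).
#' @param latency_shift like `gains`, but additive latency shifts in
#'   seconds (missing = 0).
#' @param mu_erd fractional 8-14 Hz mu power change at left-central
#'   channels before predictable targets (e.g. -0.3 = 30% decrease);
#'   applied in the motor-preparation window ending at predT onset.
#' @param frontal_alpha_mod fractional change of fronto-central background
#'   alpha power before predictable targets.
#' @param mu_amp left-central mu rhythm amplitude (microvolts).
#' @param target_alpha_burst amplitude (microvolts) of the phase-locked
#'   fronto-central alpha burst evoked by targets (0 disables it).
#' @param rt_mean_rand,rt_mean_pred,rt_sd reaction-time distribution
#'   (seconds); means must lie within the (0.1, 1.1) s response window.
#' @param fa_rate probability of a false-alarm press per standard.
#' @param miss_rate probability of missing a target.
#' @param gain_sd between-subject lognormal sd of component gains.
#' @param rt_subject_sd between-subject sd of the RT means (seconds).
#' @return Validated list of class `group_profile`.
#' @export
group_profile <- function(name, gains = list(), latency_shift = list(),
                          mu_erd = 0, frontal_alpha_mod = 0, mu_amp = 10,
                          target_alpha_burst = 3,
                          rt_mean_rand = 0.45, rt_mean_pred = 0.40,
                          rt_sd = 0.08, fa_rate = 0.003, miss_rate = 0.03,
                          gain_sd = 0.15, rt_subject_sd = 0.03) {
  p <- list(name = name, gains = gains, latency_shift = latency_shift,
            mu_erd = mu_erd, frontal_alpha_mod = frontal_alpha_mod,
            mu_amp = mu_amp, target_alpha_burst = target_alpha_burst,
            rt_mean_rand = rt_mean_rand,
            rt_mean_pred = rt_mean_pred, rt_sd = rt_sd, fa_rate = fa_rate,
            miss_rate = miss_rate, gain_sd = gain_sd,
            rt_subject_sd = rt_subject_sd)
  validate_profile(p)
  class(p) <- "group_profile"
  p
}

validate_profile <- function(p) {
  gv <- unlist(p$gains)
  if (length(gv) && !all(is.finite(gv))) stop("component gains must be finite")
  if (p$mu_erd < -1) stop("mu_erd below -1 would make power negative")
  for (f in c("rt_mean_rand", "rt_mean_pred")) {
    if (p[[f]] <= 0.1 || p[[f]] >= 1.1) {
      stop(f, " must lie inside the (0.1, 1.1) s response window")
    }
  }
  for (f in c("fa_rate", "miss_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  invisible(TRUE)
}

#' Control-like and autism-like preset profiles
#'
#' `profile_ctrl()` carries the typical-adult effect structure: a CNV ramp
#' mainly before predictable targets, P3 amplitude growing along the
#' predictive sequence, a pre-predT mu power decrease (motor preparation,
#' default -30%) and a fronto-central alpha decrease, and a clear RT benefit
#' of predictability. `profile_asd()` carries the contrasting structure:
#' enhanced CNV before all random stimuli, no pre-predT mu decrease, a
#' slight pre-predT alpha increase, faster responses to random targets and
#' a smaller RT benefit, and a higher false-alarm rate.
#'
#' @param mu_erd,cnv_rand_gain headline effect sizes, exposed for
#'   sensitivity analyses.
#' @return A `group_profile`.
#' @export
profile_ctrl <- function(mu_erd = -0.3) {
  all1 <- function(x) stats::setNames(rep(x, 8L), CATEGORIES)
  group_profile(
    name = "CTRL",
    gains = list(
      N1 = all1(1), P2post = all1(1), P2front = all1(1),
      N2 = c(randT = 1, predT = 1),
      P3 = c(randS1 = 0.3, randS2 = 0.3, randS3 = 0.3,
             predS1 = 0.4, predS2 = 0.7, predS3 = 1.0,
             randT = 1.2, predT = 1.2),
      CNV = c(randS1 = 0.1, randS2 = 0.1, randS3 = 0.1, randT = 0.3,
              predS2 = 0.2, predS3 = 0.4, predT = 1.0)),
    latency_shift = list(N2 = c(predT = -0.02), P3 = c(predT = -0.04)),
    mu_erd = mu_erd, frontal_alpha_mod = -0.2,
    rt_mean_rand = 0.45, rt_mean_pred = 0.40, fa_rate = 0.002)
}

#' @rdname profile_ctrl
#' @export
profile_asd <- function(cnv_rand_gain = 1) {
  all1 <- function(x) stats::setNames(rep(x, 8L), CATEGORIES)
  group_profile(
    name = "ASD",
    gains = list(
      N1 = all1(1), P2post = all1(1), P2front = all1(1),
      N2 = c(randT = 1, predT = 1),
      P3 = c(randS1 = 0.3, randS2 = 0.3, randS3 = 0.3,
             predS1 = 0.4, predS2 = 0.7, predS3 = 1.0,
             randT = 1.2, predT = 1.2),
      CNV = c(randS1 = 0.6 * cnv_rand_gain, randS2 = 0.6 * cnv_rand_gain,
              randS3 = 0.6 * cnv_rand_gain, randT = cnv_rand_gain,
              predS2 = 0.2, predS3 = 0.4, predT = 0.6)),
    latency_shift = list(N2 = c(randT = -0.02), P3 = c(predT = -0.04)),
    mu_erd = 0, frontal_alpha_mod = 0.1,
    rt_mean_rand = 0.41, rt_mean_pred = 0.39, fa_rate = 0.007)
}

# gain of component `comp` for category `categ` under per-subject gains table
lookup_cat <- function(tbl, comp, categ, default = 0) {
  v <- tbl[[comp]]
  if (is.null(v)) return(default)
  if (is.null(names(v))) return(v[1L])
  if (categ %in% names(v)) unname(v[[categ]]) else default
}

# spatial topography: Gaussian over the flat layout centred on an electrode;
# spread 0 gives a one-hot topography
topography <- function(layout, center, spread) {
  ci <- match(center, layout$name)
  if (is.na(ci)) stop("unknown centre electrode ", center)
  if (spread <= 0) {
    w <- numeric(nrow(layout)); w[ci] <- 1
  } else {
    d2 <- (layout$fx - layout$fx[ci])^2 + (layout$fy - layout$fy[ci])^2
    w <- exp(-d2 / (2 * spread^2))
  }
  w[layout$type != "scalp"] <- 0
  w
}

# spectrally shaped Gaussian noise, `nch` independent rows; FFTs are batched
# (mvfft) at a padded power-of-two length, each row sd-normalized
shaped_noise <- function(n, rate, shape_fun, nch = 1L) {
  n2 <- stats::nextn(n, 2L)
  wn <- matrix(stats::rnorm(n2 * nch), n2, nch)
  sp <- stats::mvfft(wn)
  f <- c(0, seq_len(n2 - 1L)) * rate / n2
  f <- pmin(f, rate - f)                       # two-sided
  x <- Re(stats::mvfft(sp * shape_fun(f), inverse = TRUE))[seq_len(n), ,
                                                           drop = FALSE] / n2
  x <- t(x)
  x / apply(x, 1L, stats::sd)
}

# 1/f-shaped noise, sd-normalized rows
one_over_f_noise <- function(n, exponent, rate, nch = 1L) {
  if (exponent == 0) return(matrix(stats::rnorm(n * nch), nch, n))
  shaped_noise(n, rate, function(f) ifelse(f < 0.1, 0, f^(-exponent / 2)),
               nch)
}

# narrowband (Gaussian spectral window) noise: a non-phase-locked rhythm
narrowband_noise <- function(n, f0, bw, rate, nch = 1L) {
  shaped_noise(n, rate, function(f) exp(-(f - f0)^2 / (2 * bw^2)), nch)
}

# truncated-normal reaction time inside the response window
draw_rt <- function(mean, sd, lo = 0.1, hi = 1.1) {
  for (i in 1:1000) {
    r <- stats::rnorm(1L, mean, sd)
    if (r > lo && r < hi) return(r)
  }
  min(max(mean, lo + 1e-3), hi - 1e-3)
}

#' Simulate one subject's recording
#'
#' Generates `n_blocks` stimulus blocks and the corresponding continuous
#' 64+2-channel, 512 Hz EEG: each stimulus evokes the component templates at
#' the profile's per-category gains and latencies on top of spatially
#' correlated 1/f + alpha background noise; a linear CNV ramp precedes
#' stimuli according to the profile's CNV gains; the left-central mu rhythm
#' power is scaled by (1 + `mu_erd`) in the motor-preparation window before
#' predictable targets and fronto-central alpha by
#' (1 + `frontal_alpha_mod`); targets evoke a phase-locked alpha burst;
#' button presses are drawn per target from a truncated normal inside the
#' (0.1, 1.1) s response window with the profile's miss and false-alarm
#' rates. Blocks are concatenated with a 2 s gap; event onsets are on the
#' recording clock.
#'
#' @param profile a `group_profile`.
#' @param n_blocks number of blocks (>= 1).
#' @param seed integer RNG seed.
#' @param counts per-block category counts (default the 127-stimulus block).
#' @param components component templates (default [default_components()]).
#' @param noise background model from [noise_model()].
#' @param rate sampling rate, Hz.
#' @param layout montage (default [standard_layout_64()]).
#' @param subject_jitter apply between-subject gain/RT jitter (disable for
#'   noise-free identity checks).
#' @return List with `recording` (an `eeg_recording`), `events`
#'   (`stimulus_events` on the recording clock) and `responses` (press
#'   times, seconds).
#' @export
simulate_subject <- function(profile, n_blocks = 1L, seed = 1L,
                             counts = DEFAULT_BLOCK_COUNTS,
                             components = default_components(),
                             noise = noise_model(), rate = 512,
                             layout = standard_layout_64(),
                             subject_jitter = TRUE) {
  validate_profile(profile)
  stopifnot(n_blocks >= 1L)
  set.seed(as.integer(seed))
  nch <- nrow(layout)
  pad <- 1.5                                    # s of silence around blocks
  gap <- 2

  # per-subject effect jitter
  gains <- profile$gains
  if (subject_jitter && profile$gain_sd > 0) {
    gains <- lapply(gains, function(v) v * exp(stats::rnorm(1L, 0,
                                                            profile$gain_sd)))
  }
  rt_shift <- if (subject_jitter) stats::rnorm(1L, 0,
                                               profile$rt_subject_sd) else 0
  rt_rand <- min(max(profile$rt_mean_rand + rt_shift, 0.15), 1.05)
  rt_pred <- min(max(profile$rt_mean_pred + rt_shift, 0.15), 1.05)

  topo <- lapply(components, function(cp)
    topography(layout, cp$center, cp$spread))
  mu_topo <- topography(layout, "C3", 0.28)     # left-central motor patch
  mu_topo <- mu_topo + 0.6 * topography(layout, "C5", 0.22)
  alpha_topo <- topography(layout, "FCz", 0.30)

  all_sig <- vector("list", n_blocks)
  all_events <- vector("list", n_blocks)
  all_resp <- list()
  t_offset <- 0

  for (b in seq_len(n_blocks)) {
    ev <- generate_block(counts, seed = sample.int(.Machine$integer.max, 1L))
    ev$block <- b
    n_ev <- nrow(ev)
    dur <- (n_ev - 1L) * SOA_S + 2 * pad
    ns <- ceiling(dur * rate)
    tgrid <- (seq_len(ns) - 1L) / rate
    # presentation is locked to the sampling grid
    onsets <- round((ev$onset + pad) * rate) / rate

    sig <- matrix(0, nch, ns, dimnames = list(layout$name, NULL))
    # --- background noise, spatially correlated over the montage
    if (noise$sd > 0) {
      raw <- one_over_f_noise(ns, noise$one_over_f_exponent, rate, nch)
      d2 <- outer(layout$fx, layout$fx, "-")^2 +
        outer(layout$fy, layout$fy, "-")^2
      W <- exp(-d2 / (2 * noise$corr_len^2))
      W <- W / sqrt(rowSums(W^2))
      nz <- noise$sd * (W %*% raw)
      # earlobe references pick up little neural background
      nz[layout$type == "ref", ] <- 0.3 * nz[layout$type == "ref", ]
      sig <- sig + nz
    }
    if (noise$alpha_amp > 0) {
      # background alpha as a low-rank spatial mixture of a few sources
      n_src <- 6L
      src <- narrowband_noise(ns, noise$alpha_freq, 0.7, rate, n_src)
      mix <- matrix(stats::rnorm(nch * n_src), nch, n_src)
      mix <- mix / sqrt(rowSums(mix^2))
      mix[layout$type != "scalp", ] <- 0
      sig <- sig + noise$alpha_amp / sqrt(2) * (mix %*% src)
    }

    # --- left-central mu rhythm with pre-predT power modulation; constant
    # amplitude with phase diffusion: narrowband (~1.4 Hz linewidth), not
    # phase-locked to stimuli, but with a well-defined band power
    if (profile$mu_amp > 0) {
      dphi <- sqrt(8.7 / rate)            # ~1.4 Hz linewidth at any rate
      mu <- profile$mu_amp *
        cos(2 * pi * 10 * tgrid + stats::runif(1L, 0, 2 * pi) +
            cumsum(stats::rnorm(ns, 0, dphi)))
      env <- rep(1, ns)
      if (profile$mu_erd != 0) {
        fac <- sqrt(1 + profile$mu_erd)
        for (o in onsets[ev$trial_type == "predT"]) {
          w <- tgrid >= o - 0.55 & tgrid <= o + 0.05
          env[w] <- fac
        }
      }
      sig <- sig + mu_topo %o% (mu * env)
      # fronto-central alpha with its own pre-predT modulation
      fa <- profile$mu_amp * 0.6 *
        cos(2 * pi * 10 * tgrid + stats::runif(1L, 0, 2 * pi) +
            cumsum(stats::rnorm(ns, 0, dphi)))
      enva <- rep(1, ns)
      if (profile$frontal_alpha_mod != 0) {
        faca <- sqrt(1 + profile$frontal_alpha_mod)
        for (o in onsets[ev$trial_type == "predT"]) {
          w <- tgrid >= o - 0.55 & tgrid <= o + 0.05
          enva[w] <- faca
        }
      }
      sig <- sig + alpha_topo %o% (fa * enva)
    }

    # --- stimulus-evoked components
    for (i in seq_len(n_ev)) {
      categ <- ev$trial_type[i]
      for (cn in names(components)) {
        cp <- components[[cn]]
        g <- lookup_cat(gains, cn, categ)
        if (g == 0) next
        shift <- lookup_cat(profile$latency_shift, cn, categ, 0)
        if (cp$shape == "ramp") {
          t0 <- onsets[i] + cp$ramp_start
          t1 <- onsets[i]
          idx <- max(1L, ceiling(t0 * rate) + 1L):min(ns, floor(t1 * rate) + 1L)
          wave <- g * cp$amp * (tgrid[idx] - t0) / (t1 - t0)
        } else {
          pk <- onsets[i] + cp$latency + shift
          idx <- max(1L, ceiling((pk - 4 * cp$width) * rate) + 1L):
            min(ns, floor((pk + 4 * cp$width) * rate) + 1L)
          wave <- g * cp$amp * exp(-(tgrid[idx] - pk)^2 / (2 * cp$width^2))
        }
        sig[, idx] <- sig[, idx] + topo[[cn]] %o% wave
      }
      # phase-locked post-target alpha burst (fronto-central)
      if (profile$target_alpha_burst > 0 && categ %in% c("randT", "predT")) {
        t0 <- onsets[i] + 0.05
        idx <- which(tgrid >= t0 & tgrid <= t0 + 0.4)
        if (length(idx)) {
          tt <- tgrid[idx] - t0
          burst <- profile$target_alpha_burst *
            exp(-tt / 0.12) * cos(2 * pi * 10 * tt)
          sig[, idx] <- sig[, idx] + alpha_topo %o% burst
        }
      }
    }

    # --- behavioral responses
    resp <- numeric(0)
    for (i in seq_len(n_ev)) {
      categ <- ev$trial_type[i]
      if (categ %in% c("randT", "predT")) {
        if (stats::runif(1L) >= profile$miss_rate) {
          m <- if (categ == "predT") rt_pred else rt_rand
          resp <- c(resp, onsets[i] + draw_rt(m, profile$rt_sd))
        }
      } else if (profile$fa_rate > 0 && stats::runif(1L) < profile$fa_rate) {
        resp <- c(resp, onsets[i] + stats::runif(1L, 0.3, 0.9))
      }
    }

    ev$onset <- onsets + t_offset
    all_sig[[b]] <- sig
    all_events[[b]] <- ev
    all_resp[[b]] <- resp + t_offset
    # keep the clock aligned with the concatenated sample stream
    t_offset <- t_offset + (ns + ceiling(gap * rate)) / rate
  }

  nsg <- ceiling(gap * rate)
  pieces <- list()
  for (b in seq_len(n_blocks)) {
    pieces[[length(pieces) + 1L]] <- all_sig[[b]]
    if (b < n_blocks) pieces[[length(pieces) + 1L]] <- matrix(0, nch, nsg)
  }
  signal <- do.call(cbind, pieces)
  events <- do.call(rbind, all_events)
  class(events) <- c("stimulus_events", "data.frame")
  list(recording = eeg_recording(signal, rate, layout),
       events = events,
       responses = sort(unlist(all_resp)))
}

#' Simulate a multi-subject study
#'
#' Draws `n_subjects_per_group` subjects from each group profile with
#' per-subject seeds derived deterministically from the master seed, and
#' emits the subject table (subject id, group, handedness; by default one
#' left-handed subject per group of twelve, mirroring typical samples).
#'
#' @param profiles list of `group_profile` objects (one per group).
#' @param n_subjects_per_group subjects per group.
#' @param n_blocks blocks per subject.
#' @param seed master integer seed.
#' @param n_left_handed left-handed subjects per group (the last subjects
#'   of each group; capped at the group size).
#' @param ... passed to [simulate_subject()] (counts, components, noise,
#'   rate, layout).
#' @return An object of class `study_set`: list with `subjects` (data frame
#'   `subject_id`, `group`, `handedness`), `data` (per-subject lists with
#'   `recording`, `events`, `responses`) and `seed`.
#' @export
simulate_study <- function(profiles, n_subjects_per_group, n_blocks = 1L,
                           seed = 1L, n_left_handed = 1L, ...) {
  stopifnot(length(profiles) >= 1L)
  set.seed(as.integer(seed))
  n_tot <- length(profiles) * n_subjects_per_group
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  subjects <- data.frame(subject_id = character(0), group = character(0),
                         handedness = character(0), stringsAsFactors = FALSE)
  data <- list()
  k <- 0L
  for (p in profiles) {
    for (s in seq_len(n_subjects_per_group)) {
      k <- k + 1L
      id <- sprintf("%s%02d", tolower(p$name), s)
      hand <- if (s > n_subjects_per_group - min(n_left_handed,
                                                 n_subjects_per_group))
        "left" else "right"
      subjects <- rbind(subjects, data.frame(
        subject_id = id, group = p$name, handedness = hand,
        stringsAsFactors = FALSE))
      data[[id]] <- simulate_subject(p, n_blocks = n_blocks,
                                     seed = sub_seeds[k], ...)
    }
  }
  structure(list(subjects = subjects, data = data, seed = seed),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat("Synthetic study:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                    table(x$subjects$group)), collapse = ", "),
      "), master seed", x$seed, "\n")
  invisible(x)
}
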