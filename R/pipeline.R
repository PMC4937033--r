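# Pipeline orchestration ------------------------------------------------------

#' Default analysis configuration
#'
#' All analysis windows, bands and thresholds of the study design,
#' pre-filled: ERP bands 0.5-30 Hz (slow) and 4-30 Hz (transient); CNV mean
#' amplitude in (-150, 0) ms (and (-50, 0) ms before random standards) on
#' non-baselined data; P3 mean amplitude in (200, 600) ms on baselined
#' data; peak windows N1 (105, 230) and P2 (205, 310) ms at PO4, P2
#' (155, 255) and N2 (215, 350) ms at FCz, P3 maximum (250, 750) ms at Pz;
#' transient scan of (0, 400) ms in 10 ms windows with corrected threshold
#' alpha/40 = 0.00125; time-frequency scan of (-500, 500) ms in 200 ms
#' windows shifted by 100 ms at threshold 0.005; 8-14 Hz band; PLF
#' threshold 0.25; artifact rejection at 150 microvolts peak-to-peak in
#' (-700, 700) ms; significance on >= 4 adjacent electrodes.
#'
#' @return Nested named list (the `RunConfig`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      profiles = c("ctrl", "asd"),
      n_subjects_per_group = 12L,
      n_blocks = 1L,
      counts = as.list(DEFAULT_BLOCK_COUNTS),
      mu_erd_ctrl = -0.3,
      rate = 512),
    bands = list(slow = c(0.5, 30), transient = c(4, 30)),
    epochs = list(erp = c(-0.7, 0.8), tf = c(-1.05, 1.05)),
    baseline = c(-0.1, 0),
    windows = list(
      cnv = c(-0.15, 0),
      cnv_rand = c(-0.05, 0),
      p3 = c(0.2, 0.6),
      peak_n1_po4 = c(0.105, 0.23),
      peak_p2_po4 = c(0.205, 0.31),
      peak_p2_fcz = c(0.155, 0.255),
      peak_n2_fcz = c(0.215, 0.35),
      peak_p3_pz = c(0.25, 0.75)),
    scan = list(transient_interval = c(0, 0.4), transient_width = 0.01,
                alpha = 0.05, run_mass_univariate = FALSE),
    tf = list(band = c(8, 14), analysis_window = c(-0.5, 0.5),
              scan_width = 0.2, scan_step = 0.1, threshold = 0.005,
              mu_window = c(-0.4, -0.2), plf_threshold = 0.25,
              s1_baseline = c(-0.5, -0.25), right_handed_only = TRUE),
    electrodes = list(cnv = "PO3", cnv_frontal = "Fz", p3 = "Pz",
                      mu = "C5", alpha_frontal = "FCz",
                      measures = c("PO4", "FCz", "Pz", "Fz", "PO3", "C5")),
    artifact = list(window = c(-0.7, 0.7), threshold_uV = 150),
    adjacency = list(mult = 1.5, min_cluster = 4L),
    stats = list(n_rand = 10000L))
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !is.list(user[[k]]) && !is.null(user[[k]])) {
      stop("config key ", full, " must be a mapping")
    }
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' Accepts a config as a named list, a YAML string, or a YAML file path;
#' injects the study defaults ([default_config()]), rejects unknown keys
#' with their full paths, and type-checks the critical fields. An empty
#' input yields the full default configuration.
#'
#' @param config `NULL`, a named list, a YAML string, or a path to a YAML
#'   file.
#' @return The resolved config list (class `run_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.null(config)) {
    user <- list()
  } else if (is.character(config) && length(config) == 1L) {
    user <- if (file.exists(config)) yaml::read_yaml(config)
            else yaml::yaml.load(config)
    if (is.null(user)) user <- list()
  } else if (is.list(config)) {
    user <- config
  } else stop("config must be NULL, a list, or YAML text/path")
  cfg <- merge_config(default_config(), user)
  # coercions and checks
  cfg$seed <- suppressWarnings(as.integer(cfg$seed))
  if (is.na(cfg$seed) || cfg$seed < 0L) stop("seed must be a non-negative integer")
  for (f in c("slow", "transient")) {
    b <- as.numeric(cfg$bands[[f]])
    if (length(b) != 2L || !(b[1L] > 0 && b[1L] < b[2L])) {
      stop("bands.", f, " must be (low, high) with 0 < low < high")
    }
    cfg$bands[[f]] <- b
  }
  ep <- cfg$epochs$erp
  for (w in names(cfg$windows)) {
    win <- as.numeric(cfg$windows[[w]])
    if (length(win) != 2L || win[1L] >= win[2L]) {
      stop("windows.", w, " must be (start, end) with start < end")
    }
    if (win[1L] < ep[1L] - 1e-9 || win[2L] > ep[2L] + 1e-9) {
      stop("windows.", w, " lies outside the ERP epoch (",
           ep[1L], ", ", ep[2L], ")")
    }
    cfg$windows[[w]] <- win
  }
  thr <- cfg$tf$threshold
  if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
    stop("tf.threshold must be in (0, 1)")
  }
  if (cfg$scan$alpha <= 0 || cfg$scan$alpha >= 1) {
    stop("scan.alpha must be in (0, 1)")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

# derive per-subject measure sets from one subject's raw data
analyze_subject <- function(sub, cfg, channels) {
  rec <- rereference_earlobes(sub$recording)
  # trial bookkeeping on broadband epochs
  ep_bb <- epoch_recording(rec, sub$events, cfg$artifact$window,
                           channels = channels)
  art <- flag_artifacts(ep_bb, cfg$artifact$window,
                        cfg$artifact$threshold_uV) | !ep_bb$included
  sel <- select_trials(sub$events, sub$responses, artifact_flags = art)
  sel <- equalize_pairs(sub$events, sel, seed = cfg$seed + 17L)

  # filter only the channels carried into the ERP measures
  rec_sub <- rec
  keep_ch <- rownames(rec$signal) %in% setdiff(channels, c("A1", "A2"))
  rec_sub$signal <- rec$signal[keep_ch, , drop = FALSE]
  rec_sub$layout <- rec$layout[keep_ch, , drop = FALSE]
  slow <- bandpass(rec_sub, cfg$bands$slow[1L], cfg$bands$slow[2L])
  trans <- bandpass(rec_sub, cfg$bands$transient[1L], cfg$bands$transient[2L])
  ch_scalp <- setdiff(channels, c("A1", "A2"))
  ep_slow <- epoch_recording(slow, sub$events, cfg$epochs$erp,
                             channels = ch_scalp)
  ep_trans <- epoch_recording(trans, sub$events, cfg$epochs$erp,
                              channels = ch_scalp)
  ep_slow$included <- ep_slow$included & sel$included
  ep_trans$included <- ep_trans$included & sel$included

  ev_slow <- lapply(CATEGORIES, function(k) {
    if (any(ep_slow$included & ep_slow$categories == k))
      average_epochs(ep_slow, k) else NULL
  })
  names(ev_slow) <- CATEGORIES
  meas <- list()
  # CNV: non-baselined mean amplitudes
  for (k in c("randT", "predT")) {
    if (!is.null(ev_slow[[k]])) {
      meas[[paste0("cnv_", k)]] <- unname(
        window_mean(ev_slow[[k]], cfg$electrodes$cnv, cfg$windows$cnv,
                    require_baseline = "none"))
      meas[[paste0("cnv_frontal_", k)]] <- unname(
        window_mean(ev_slow[[k]], cfg$electrodes$cnv_frontal,
                    cfg$windows$cnv, require_baseline = "none"))
    }
  }
  # pre-stimulus activity before all random standards, (-50, 0) ms
  rs <- which(ep_slow$included &
              ep_slow$categories %in% c("randS1", "randS2", "randS3"))
  if (length(rs)) {
    ep_rs <- ep_slow
    ep_rs$included <- seq_along(ep_slow$included) %in% rs
    ev_rs <- average_epochs(ep_rs)
    meas$cnv_randS <- unname(window_mean(ev_rs, cfg$electrodes$cnv,
                                         cfg$windows$cnv_rand,
                                         require_baseline = "none"))
  }
  # P3: baselined window means and target peak
  for (k in c("randS2", "predS2", "randS3", "predS3", "randT", "predT")) {
    if (!is.null(ev_slow[[k]])) {
      evb <- apply_baseline(ev_slow[[k]], cfg$baseline)
      meas[[paste0("p3_", k)]] <- unname(
        window_mean(evb, cfg$electrodes$p3, cfg$windows$p3,
                    require_baseline = "pre_minus100_0"))
      if (k %in% c("randT", "predT")) {
        pk <- peak_measure(evb, cfg$electrodes$p3, cfg$windows$peak_p3_pz,
                           "positive")
        meas[[paste0("p3lat_", k)]] <- pk$latency_ms
        meas[[paste0("p3amp_", k)]] <- pk$amplitude_uV
      }
    }
  }
  # transient peaks on the 4-30 Hz band, baselined
  for (k in c("randT", "predT")) {
    if (any(ep_trans$included & ep_trans$categories == k)) {
      evt <- apply_baseline(average_epochs(ep_trans, k), cfg$baseline)
      meas[[paste0("n1lat_", k)]] <-
        peak_measure(evt, "PO4", cfg$windows$peak_n1_po4,
                     "negative")$latency_ms
      meas[[paste0("n2lat_", k)]] <-
        peak_measure(evt, "FCz", cfg$windows$peak_n2_fcz,
                     "negative")$latency_ms
    }
  }
  # time-frequency: 8-14 Hz band power around targets
  tf_ch <- unique(c(cfg$electrodes$mu, cfg$electrodes$alpha_frontal))
  for (k in c("randT", "predT")) {
    idx <- which(sel$included & sub$events$trial_type == k)
    if (length(idx)) {
      ev_k <- sub$events[idx, , drop = FALSE]
      ep_tf <- epoch_recording(rec, ev_k, cfg$epochs$tf, channels = tf_ch)
      freqs <- seq(cfg$tf$band[1L], cfg$tf$band[2L])
      tfr <- morlet_transform(ep_tf, freqs = freqs)
      bp <- band_power(tfr, cfg$tf$band, cfg$tf$mu_window, average = TRUE)
      meas[[paste0("mu_", k)]] <- unname(bp[cfg$electrodes$mu])
      meas[[paste0("alpha_frontal_", k)]] <-
        unname(bp[cfg$electrodes$alpha_frontal])
    }
  }
  behav <- score_responses(sub$events, sub$responses)
  list(measures = meas, behavior = behav, selection = sel,
       evoked_slow = ev_slow, epochs_transient = ep_trans)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or accept a supplied study) -> preprocess ->
#' ERP and time-frequency measures -> group statistics -> behavior, in the
#' order of the study's analysis plan. Deterministic given the config seed.
#'
#' @param config anything accepted by [validate_config()].
#' @param study optional `study_set` (from [simulate_study()] or assembled
#'   from recorded data); when missing, one is simulated from
#'   `config$simulate`.
#' @param channels channels carried through the ERP stage (default: the
#'   measure electrodes; use the full montage for mass-univariate scans).
#' @return An object of class `run_report`: list with `config`, `subjects`,
#'   `measures` (subject x measure data frame), `behavior`
#'   (group summary with tests), `anova` (named `mixed_anova` objects for
#'   CNV, P3 latency, N2 latency, mu and frontal alpha power),
#'   `randomization` (named `perm_test` objects), and per-subject trial
#'   accounting.
#' @export
run_pipeline <- function(config = NULL, study = NULL, channels = NULL) {
  cfg <- validate_config(config)
  if (is.null(study)) {
    profs <- lapply(cfg$simulate$profiles, function(p) {
      switch(p,
             ctrl = profile_ctrl(mu_erd = cfg$simulate$mu_erd_ctrl),
             asd = profile_asd(),
             stop("unknown profile preset: ", p))
    })
    study <- simulate_study(profs, cfg$simulate$n_subjects_per_group,
                            n_blocks = cfg$simulate$n_blocks,
                            seed = cfg$seed,
                            counts = unlist(cfg$simulate$counts),
                            rate = cfg$simulate$rate)
  }
  if (is.null(channels)) {
    channels <- unique(c(cfg$electrodes$measures, "A1", "A2"))
  }
  subj <- study$subjects
  res <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    res[[i]] <- tryCatch(
      analyze_subject(study$data[[subj$subject_id[i]]], cfg, channels),
      error = function(e) stop("subject ", subj$subject_id[i],
                               " failed: ", conditionMessage(e)))
  }
  # subject x measure table
  all_meas <- sort(unique(unlist(lapply(res, function(r) names(r$measures)))))
  mtab <- as.data.frame(lapply(all_meas, function(m) {
    vapply(res, function(r) {
      v <- r$measures[[m]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1L))
  }))
  names(mtab) <- all_meas
  mtab <- cbind(subject_id = subj$subject_id, group = subj$group, mtab,
                stringsAsFactors = FALSE)

  g <- factor(subj$group)
  ga <- levels(g)[1L]; gb <- levels(g)[2L]
  run_anova <- function(a, b, rows = TRUE) {
    ok <- rows & !is.na(mtab[[a]]) & !is.na(mtab[[b]])
    if (sum(ok) < 4L || nlevels(droplevels(g[ok])) != 2L) return(NULL)
    mixed_anova_2x2(as.matrix(mtab[ok, c(a, b)]), droplevels(g[ok]))
  }
  rh <- if (isTRUE(cfg$tf$right_handed_only)) subj$handedness == "right"
        else rep(TRUE, nrow(subj))
  anova <- list(
    cnv = run_anova("cnv_randT", "cnv_predT"),
    cnv_frontal = run_anova("cnv_frontal_randT", "cnv_frontal_predT"),
    p3_latency = run_anova("p3lat_randT", "p3lat_predT"),
    n2_latency = run_anova("n2lat_randT", "n2lat_predT"),
    mu_power = run_anova("mu_randT", "mu_predT", rh),
    alpha_frontal = run_anova("alpha_frontal_randT", "alpha_frontal_predT",
                              rh))
  rand_group <- function(col, rows = TRUE, seed_off = 0L) {
    ok <- rows & !is.na(mtab[[col]])
    if (!any(ok & g == ga) || !any(ok & g == gb)) return(NULL)
    randomization_test(mtab[[col]][ok & g == ga], mtab[[col]][ok & g == gb],
                       n_rand = cfg$stats$n_rand, seed = cfg$seed + seed_off)
  }
  randomization <- list(
    cnv_randS = rand_group("cnv_randS", seed_off = 3L),
    cnv_randT = rand_group("cnv_randT", seed_off = 4L),
    mu_predT = rand_group("mu_predT", rh, seed_off = 5L))

  # optional mass-univariate transient scan: 4-30 Hz baselined evoked
  # responses to targets, 10 ms windows over (0, 400) ms, adjacency rule
  scan_transient <- NULL
  if (isTRUE(cfg$scan$run_mass_univariate)) {
    grid <- scan_grid(cfg$scan$transient_interval, cfg$scan$transient_width)
    mk_scan <- function(categ) {
      evs <- lapply(seq_along(res), function(i) {
        ep <- res[[i]]$epochs_transient
        if (is.null(ep) || !any(ep$included & ep$categories == categ)) {
          stop("transient scan: subject ", subj$subject_id[i],
               " has no included ", categ, " trials")
        }
        apply_baseline(average_epochs(ep, categ), cfg$baseline)
      })
      scan_windows(evs, grid)
    }
    adj <- electrode_adjacency(mult = cfg$adjacency$mult)
    scan_transient <- mass_univariate(
      mk_scan("randT"), mk_scan("predT"), subj$group, adj,
      alpha_corrected = cfg$scan$alpha / nrow(grid),
      min_cluster = cfg$adjacency$min_cluster)
  }

  behavior <- summarize_groups(lapply(res, `[[`, "behavior"), subj$group,
                               n_rand = cfg$stats$n_rand,
                               seed = cfg$seed + 29L)
  trial_counts <- t(vapply(res, function(r) {
    c(included = sum(r$selection$included),
      total = nrow(r$selection))
  }, numeric(2L)))
  structure(list(config = cfg, subjects = subj, measures = mtab,
                 behavior = behavior, anova = anova,
                 randomization = randomization,
                 scan_transient = scan_transient,
                 trial_counts = data.frame(subject_id = subj$subject_id,
                                           trial_counts),
                 evoked = lapply(res, `[[`, "evoked_slow")),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", nrow(x$subjects), "subjects, seed", x$config$seed,
      "\n")
  cat("Included trials per subject:",
      paste(range(x$trial_counts$included), collapse = "-"), "\n\n")
  cat("Behavior (predictability x group):\n")
  print(x$behavior$anova_rt)
  cat("RT prediction index randomization: p =",
      format(x$behavior$rand_index$p, digits = 3), "\n\n")
  for (nm in names(x$anova)) {
    if (!is.null(x$anova[[nm]])) {
      cat(nm, ":\n"); print(x$anova[[nm]])
    }
  }
  invisible(x)
}
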