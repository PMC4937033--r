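# Behavioral scoring -----------------------------------------------------------

#' Score button presses against the event stream
#'
#' A press within the half-open interval (100, 1100] ms after a target onset
#' is a correct response (hit); each press is attributed to the most recent
#' unmatched target whose response window contains it. Presses matching no
#' target are false alarms, attributed to the standards. Reaction times are
#' computed for correct trials only, and the fractional reaction-time
#' benefit of the predictive context is summarized by the RT prediction
#' index (RT_randT - RT_predT) / RT_randT.
#'
#' @param events labelled `stimulus_events` data frame.
#' @param responses numeric vector of press times (seconds, sorted; the
#'   first press of a double press counts).
#' @param response_window half-open response interval in seconds.
#' @return An object of class `behavior_score`: list with `table` (one-row
#'   data frame: `hits_randT_pct`, `hits_predT_pct`, `fa_pct`,
#'   `rt_randT_ms`, `rt_predT_ms`, `rt_prediction_index`), `hits`
#'   (per-target logical), `rt` (per-target seconds, NA for misses),
#'   `fa_count`.
#' @export
#' @examples
#' ev <- generate_block(seed = 3)
#' tg <- ev$onset[ev$trial_type %in% c("randT", "predT")]
#' score_responses(ev, tg + 0.4)$table
score_responses <- function(events, responses,
                            response_window = c(0.1, 1.1)) {
  lab <- events$trial_type
  stopifnot(all(lab %in% CATEGORIES))
  responses <- sort(responses)
  is_target <- lab %in% c("randT", "predT")
  t_idx <- which(is_target)
  onset <- events$onset
  hits <- rep(FALSE, length(t_idx))
  rt <- rep(NA_real_, length(t_idx))
  matched <- rep(FALSE, length(t_idx))
  fa <- 0L
  for (p in responses) {
    elig <- which(!matched &
                  p > onset[t_idx] + response_window[1L] &
                  p <= onset[t_idx] + response_window[2L])
    if (length(elig)) {
      j <- elig[which.max(onset[t_idx[elig]])]   # most recent target
      matched[j] <- TRUE
      hits[j] <- TRUE
      rt[j] <- p - onset[t_idx[j]]
    } else {
      fa <- fa + 1L
    }
  }
  n_std <- sum(!is_target)
  cat_t <- lab[t_idx]
  mean_rt_ms <- function(categ) {
    v <- rt[cat_t == categ & hits]
    if (length(v)) mean(v) * 1000 else NA_real_
  }
  rt_rand <- mean_rt_ms("randT")
  rt_pred <- mean_rt_ms("predT")
  tab <- data.frame(
    hits_randT_pct = 100 * mean(hits[cat_t == "randT"]),
    hits_predT_pct = 100 * mean(hits[cat_t == "predT"]),
    fa_pct = if (n_std) 100 * fa / n_std else NA_real_,
    rt_randT_ms = rt_rand,
    rt_predT_ms = rt_pred,
    rt_prediction_index = (rt_rand - rt_pred) / rt_rand)
  structure(list(table = tab, hits = hits, rt = rt, categories = cat_t,
                 fa_count = fa, n_standards = n_std),
            class = "behavior_score")
}

#' @export
print.behavior_score <- function(x, ...) {
  t <- x$table
  cat(sprintf("Behavior: hits randT %.1f%%, predT %.1f%%; FA %.2f%%; RT randT %.0f ms, predT %.0f ms; prediction index %.3f\n",
              t$hits_randT_pct, t$hits_predT_pct, t$fa_pct, t$rt_randT_ms,
              t$rt_predT_ms, t$rt_prediction_index))
  invisible(x)
}

#' Group-level behavior summary and tests
#'
#' Stacks per-subject behavior tables, then feeds the study's tests: the
#' split-plot ANOVA (predictability x group) on percentage of hits and on
#' reaction times, and randomization tests on the false-alarm percentage
#' and the RT prediction index.
#'
#' @param tables list of per-subject `behavior_score` objects (or their
#'   one-row tables).
#' @param group group label per subject (two levels, >= 2 subjects each).
#' @param n_rand,seed randomization-test settings.
#' @return List with `table` (per-subject data frame with group), `anova_hits`
#'   and `anova_rt` (`mixed_anova` objects), `rand_fa` and `rand_index`
#'   (`perm_test` objects).
#' @export
summarize_groups <- function(tables, group, n_rand = 10000L, seed = 1L) {
  rows <- lapply(tables, function(t) {
    if (inherits(t, "behavior_score")) t$table else as.data.frame(t)
  })
  df <- do.call(rbind, rows)
  stopifnot(nrow(df) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) < 2L)) {
    stop("two groups with at least 2 subjects each are required")
  }
  df$group <- g
  ga <- levels(g)[1L]; gb <- levels(g)[2L]
  out <- list(
    table = df,
    anova_hits = mixed_anova_2x2(
      as.matrix(df[, c("hits_randT_pct", "hits_predT_pct")]), g),
    anova_rt = mixed_anova_2x2(
      as.matrix(df[, c("rt_randT_ms", "rt_predT_ms")]), g),
    rand_fa = randomization_test(df$fa_pct[g == ga], df$fa_pct[g == gb],
                                 n_rand = n_rand, seed = seed),
    rand_index = randomization_test(df$rt_prediction_index[g == ga],
                                    df$rt_prediction_index[g == gb],
                                    n_rand = n_rand, seed = seed + 1L))
  out
}
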