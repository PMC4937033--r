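#' @keywords internal
"_PACKAGE"

# Stimulus identities and category labels ------------------------------------

IDENTITIES <- c("left", "up", "right", "down")
CATEGORIES <- c("randS1", "randS2", "randS3", "randT",
                "predS1", "predS2", "predS3", "predT")

# default per-block composition of the target-detection task: 127 stimuli,
# 15% targets, 85% standards in equal thirds, with eight complete 100%
# predictive left-up-right-down sequences
DEFAULT_BLOCK_COUNTS <- c(randT = 11, randS1 = 28, randS2 = 28, randS3 = 28,
                          predT = 8, predS1 = 8, predS2 = 8, predS3 = 8)

#' Paradigm timing constants
#'
#' Stimulus duration is 150 ms with a 1 s inter-stimulus interval, giving a
#' fixed stimulus-onset asynchrony of 1.15 s.
#' @keywords internal
SOA_S <- 1.15

#' Label a stimulus identity stream
#'
#' Deterministically assigns categories to an ordered stream of triangle
#' identities. Any contiguous `(left, up, right, down)` quadruple is the
#' predictive sequence and is labelled `(predS1, predS2, predS3, predT)`;
#' every other downward-facing triangle is a random target `randT`; remaining
#' left/up/right triangles are the random standards `randS1`/`randS2`/
#' `randS3`.
#'
#' @param identities character vector with elements in
#'   `c("left", "up", "right", "down")`.
#' @return Character vector of categories, same length as `identities`.
#' @export
#' @examples
#' label_events(c("left", "up", "right", "down"))   # the predictive sequence
#' label_events(c("left", "up", "right", "up", "down"))
label_events <- function(identities) {
  if (!length(identities)) return(character(0))
  if (!all(identities %in% IDENTITIES)) {
    stop("identities must be in {left, up, right, down}")
  }
  n <- length(identities)
  std_label <- c(left = "randS1", up = "randS2", right = "randS3",
                 down = "randT")
  labels <- unname(std_label[identities])
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (identities[i] == "left" && identities[i + 1L] == "up" &&
          identities[i + 2L] == "right" && identities[i + 3L] == "down") {
        labels[i:(i + 3L)] <- c("predS1", "predS2", "predS3", "predT")
      }
    }
  }
  labels
}

#' Generate one randomized stimulus block
#'
#' Produces a randomized stimulus ordering realizing the requested
#' per-category counts, such that the category labelling recovered from the
#' identity stream alone (via [label_events()]) matches the generator's
#' intent exactly: every intended predictive `(left, up, right, down)`
#' sequence is contiguous, and no accidental predictive quadruple arises from
#' the random standards and targets. Orderings are rejection-sampled.
#'
#' @param counts named integer vector over the eight categories (defaults to
#'   the standard 127-stimulus block). The four `pred*` counts must be equal:
#'   every predictive sequence is complete and fully predictive.
#' @param seed integer RNG seed.
#' @param min_target_gap minimum number of stimuli between consecutive
#'   targets (default 0: unconstrained).
#' @param max_tries rejection-sampling bound before giving up.
#' @return A data.frame of class `stimulus_events` with columns `onset`
#'   (seconds from block start, on the fixed 1.15 s stimulus-onset
#'   asynchrony), `duration` (0.15 s), `identity`, `trial_type` (category)
#'   and `block`.
#' @export
#' @examples
#' ev <- generate_block(seed = 1)
#' nrow(ev)                       # 127
#' table(ev$trial_type)
generate_block <- function(counts = DEFAULT_BLOCK_COUNTS, seed,
                           min_target_gap = 0L, max_tries = 10000L) {
  counts <- counts[CATEGORIES]
  names(counts) <- CATEGORIES
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) stop("counts must be non-negative")
  npred <- counts[["predT"]]
  if (!all(counts[c("predS1", "predS2", "predS3")] == npred)) {
    stop("predS1, predS2, predS3 and predT counts must be equal ",
         "(complete, 100% predictive sequences)")
  }
  set.seed(as.integer(seed))
  # items: singleton standards/targets plus indivisible predictive units
  singles <- rep(c("left", "up", "right", "down"),
                 counts[c("randS1", "randS2", "randS3", "randT")])
  n_items <- length(singles) + npred
  n_total <- length(singles) + 4L * npred

  intended <- character(n_total)
  for (try in seq_len(max_tries)) {
    ord <- sample(n_items)
    items <- c(as.list(singles), rep(list(c("left", "up", "right", "down")),
                                     npred))[ord]
    ids <- unlist(items, use.names = FALSE)
    intended <- unlist(lapply(items, function(it) {
      if (length(it) == 4L) c("predS1", "predS2", "predS3", "predT")
      else unname(c(left = "randS1", up = "randS2", right = "randS3",
                    down = "randT")[it])
    }), use.names = FALSE)
    if (!identical(label_events(ids), intended)) next
    if (min_target_gap > 0L) {
      tpos <- which(intended %in% c("randT", "predT"))
      if (length(tpos) > 1L && min(diff(tpos)) <= min_target_gap) next
    }
    ev <- data.frame(
      onset = round((seq_len(n_total) - 1L) * SOA_S, 6L),
      duration = 0.15,
      identity = ids,
      trial_type = intended,
      block = 1L,
      stringsAsFactors = FALSE)
    attr(ev, "seed") <- as.integer(seed)
    class(ev) <- c("stimulus_events", "data.frame")
    return(ev)
  }
  stop("could not place predictive sequences without accidental ",
       "left-up-right-down quadruples in ", max_tries, " attempts")
}

#' Read/write paradigm event tables
#'
#' Events are exchanged as tab-separated tables with columns `onset`
#' (seconds, 6 decimals), `duration`, `trial_type`, `identity` and `block`,
#' compatible with BIDS `events.tsv` conventions.
#'
#' @param events a `stimulus_events` data frame.
#' @param path file path.
#' @return `read_events` returns a `stimulus_events` data frame;
#'   `write_events` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$onset <- sprintf("%.6f", df$onset)
  utils::write.table(df[, c("onset", "duration", "trial_type", "identity",
                            "block")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$onset <- as.numeric(df$onset)
  class(df) <- c("stimulus_events", "data.frame")
  df
}

# Trial selection --------------------------------------------------------------

EXCLUSION_REASONS <- c("after_target", "near_press", "potential_predS2",
                       "missed_target", "target_short_history", "artifact",
                       "equalization_drop", "none")

#' Apply the trial-exclusion rules
#'
#' Flags events for exclusion following the study's rules, in order of
#' precedence (the first matching rule is recorded as the reason):
#' \enumerate{
#'   \item `after_target`: the standard immediately following any target;
#'   \item `near_press`: a standard whose peri-stimulus window (default
#'     -700 to 700 ms) contains a button press;
#'   \item `potential_predS2`: a `randS2` preceded by a `randS1` but not
#'     followed by a `randS3` (it could have been a `predS2`);
#'   \item `missed_target`: a target with no press within (100, 1100] ms;
#'   \item `target_short_history`: a target preceded by fewer than three
#'     standards;
#'   \item `artifact`: the trial's artifact flag is set.
#' }
#'
#' @param events labelled `stimulus_events` data frame (one block or a
#'   concatenation with strictly increasing onsets).
#' @param responses numeric vector of button-press times (seconds, same
#'   clock as the event onsets).
#' @param artifact_flags optional logical vector, one per event, from
#'   [flag_artifacts()].
#' @param press_window peri-stimulus window (s) within which a press
#'   excludes a standard.
#' @param response_window half-open interval (s) after a target onset in
#'   which a press counts as a hit.
#' @return A `trial_selection` data frame with columns `included` (logical)
#'   and `reason` (one of the exclusion reasons, `"none"` for included
#'   trials).
#' @export
select_trials <- function(events, responses = numeric(0),
                          artifact_flags = NULL,
                          press_window = c(-0.7, 0.7),
                          response_window = c(0.1, 1.1)) {
  lab <- events$trial_type
  if (is.null(lab) || anyNA(lab) || !all(lab %in% CATEGORIES)) {
    stop("events must be fully labelled with the eight stimulus categories")
  }
  n <- nrow(events)
  onset <- events$onset
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, n)
  stopifnot(length(artifact_flags) == n)
  is_target <- lab %in% c("randT", "predT")
  is_standard <- !is_target
  reason <- rep("none", n)

  mark <- function(idx, why) {
    idx <- idx[reason[idx] == "none"]
    reason[idx] <<- why
  }
  # (a) standard immediately after a target
  after <- which(is_target) + 1L
  after <- after[after <= n & is_standard[pmin(after, n)]]
  mark(after, "after_target")
  # (b) standard with a press inside the peri-stimulus window
  if (length(responses)) {
    near <- vapply(seq_len(n), function(i) {
      is_standard[i] && any(responses > onset[i] + press_window[1L] &
                            responses < onset[i] + press_window[2L])
    }, logical(1L))
    mark(which(near), "near_press")
  }
  # (c) potential predS2: randS2 preceded by randS1, not followed by randS3
  pot <- which(lab == "randS2")
  pot <- pot[pot > 1L & lab[pmax(pot - 1L, 1L)] == "randS1"]
  pot <- pot[pot == n | lab[pmin(pot + 1L, n)] != "randS3"]
  mark(pot, "potential_predS2")
  # (d) missed targets: no press in the response window
  hit <- vapply(which(is_target), function(i) {
    any(responses > onset[i] + response_window[1L] &
        responses <= onset[i] + response_window[2L])
  }, logical(1L))
  mark(which(is_target)[!hit], "missed_target")
  # (e) targets preceded by fewer than three standards
  short <- vapply(which(is_target), function(i) {
    i < 4L || any(is_target[(i - 3L):(i - 1L)])
  }, logical(1L))
  mark(which(is_target)[short], "target_short_history")
  # (f) artifacts
  mark(which(artifact_flags), "artifact")

  sel <- data.frame(included = reason == "none", reason = reason,
                    stringsAsFactors = FALSE)
  class(sel) <- c("trial_selection", "data.frame")
  sel
}

#' @export
print.trial_selection <- function(x, ...) {
  cat("Trial selection:", sum(x$included), "of", nrow(x), "trials included\n")
  tab <- table(factor(x$reason[!x$included], levels = EXCLUSION_REASONS))
  tab <- tab[tab > 0]
  if (length(tab)) {
    cat("Exclusions:\n")
    for (r in names(tab)) cat(sprintf("  %-22s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Equalize trial counts within compared pairs
#'
#' For each pair of to-be-compared stimulus categories, randomly drops
#' surviving trials from the larger member until both members contribute the
#' same number of trials to the averages. Never drops from the smaller set.
#'
#' @param events labelled `stimulus_events` data frame.
#' @param selection a `trial_selection` from [select_trials()].
#' @param pairs list of length-2 character vectors; defaults to the four
#'   standard/target pairs `(randS1, predS1)` ... `(randT, predT)`.
#' @param seed integer RNG seed for the random drops.
#' @return Updated `trial_selection`; dropped trials get reason
#'   `"equalization_drop"`. If a pair has zero surviving trials on either
#'   side a warning is issued and the whole pair is left empty.
#' @export
equalize_pairs <- function(events, selection,
                           pairs = list(c("randS1", "predS1"),
                                        c("randS2", "predS2"),
                                        c("randS3", "predS3"),
                                        c("randT", "predT")),
                           seed = 1L) {
  set.seed(as.integer(seed))
  lab <- events$trial_type
  sel <- selection
  for (p in pairs) {
    ia <- which(sel$included & lab == p[1L])
    ib <- which(sel$included & lab == p[2L])
    if (!length(ia) || !length(ib)) {
      if (length(ia) || length(ib)) {
        warning("pair (", p[1L], ", ", p[2L], ") has an empty side; ",
                "dropping the whole pair")
        drop <- c(ia, ib)
        sel$included[drop] <- FALSE
        sel$reason[drop] <- "equalization_drop"
      }
      next
    }
    k <- length(ia) - length(ib)
    if (k > 0L) {
      drop <- if (length(ia) == 1L) ia else sample(ia, k)
    } else if (k < 0L) {
      drop <- if (length(ib) == 1L) ib else sample(ib, -k)
    } else drop <- integer(0)
    sel$included[drop] <- FALSE
    sel$reason[drop] <- "equalization_drop"
  }
  sel
}
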