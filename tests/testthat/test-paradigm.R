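test_that("labelling follows the predictive-sequence rule", {
  expect_identical(label_events(c("left", "up", "right", "down")),
                   c("predS1", "predS2", "predS3", "predT"))
  expect_identical(label_events("down"), "randT")
  # hand-traced: the broken sequence stays random throughout
  expect_identical(label_events(c("left", "up", "right", "up", "down")),
                   c("randS1", "randS2", "randS3", "randS2", "randT"))
  expect_identical(label_events(character(0)), character(0))
  expect_error(label_events(c("left", "sideways")), "identities")
})

test_that("labelling is history-limited to three preceding positions", {
  set.seed(11)
  for (rep in 1:200) {
    n <- 12L
    ids <- sample(c("left", "up", "right", "down"), n, replace = TRUE)
    i <- sample(5:n, 1L)
    lab <- label_events(ids)
    ids2 <- ids
    j <- sample(seq_len(i - 4L), 1L)     # > 3 positions before i
    ids2[j] <- sample(setdiff(c("left", "up", "right", "down"), ids[j]), 1L)
    lab2 <- label_events(ids2)
    expect_identical(lab2[i], lab[i])
  }
})

test_that("generated blocks realize the requested composition exactly", {
  ev <- generate_block(seed = 1)
  expect_equal(nrow(ev), 127L)
  tab <- table(ev$trial_type)
  expect_equal(unname(tab[c("randT", "randS1", "randS2", "randS3")]),
               c(11L, 28L, 28L, 28L), ignore_attr = TRUE)
  expect_equal(unname(tab[c("predT", "predS1", "predS2", "predS3")]),
               rep(8L, 4L), ignore_attr = TRUE)
  # targets are 15%, standards 85%
  expect_equal(sum(tab[c("randT", "predT")]) / 127, 19 / 127)
  # onsets on the fixed 1.15 s asynchrony
  expect_equal(ev$onset, (seq_len(127) - 1) * 1.15, tolerance = 1e-6)
  expect_equal(ev$duration, rep(0.15, 127))
})

test_that("block generation round-trips through the labeller", {
  for (seed in c(1, 2, 7, 19, 101)) {
    ev <- generate_block(seed = seed)
    expect_identical(label_events(ev$identity), ev$trial_type)
  }
  # reduced compositions round-trip as well
  for (seed in 1:5) {
    ev <- generate_block(reduced_counts(), seed = seed)
    expect_identical(label_events(ev$identity), ev$trial_type)
  }
})

test_that("degenerate compositions behave", {
  ev <- generate_block(c(randT = 1), seed = 3)
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$identity, "down")
  expect_identical(ev$trial_type, "randT")
  expect_error(generate_block(c(predT = 2, predS1 = 1, predS2 = 2,
                                predS3 = 2), seed = 1),
               "must be equal")
  expect_error(generate_block(c(randT = -1), seed = 1), "non-negative")
})

test_that("event tables round-trip through the TSV interface", {
  ev <- generate_block(reduced_counts(), seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(ev2$onset, ev$onset, tolerance = 1e-6)
  expect_identical(ev2$trial_type, ev$trial_type)
  expect_identical(ev2$identity, ev$identity)
})

test_that("exclusion rules match hand enumeration on a toy sequence", {
  # down(T) left up down(T) left up right down(predT) up left down(T)
  ids <- c("down", "left", "up", "down", "left", "up", "right", "down",
           "up", "left", "down")
  ev <- events_from_identities(ids)
  expect_identical(ev$trial_type[8], "predT")
  # presses: hit every target 400 ms after onset
  onsets <- ev$onset[ev$trial_type %in% c("randT", "predT")]
  sel <- select_trials(ev, onsets + 0.4)
  # standard immediately after each target is excluded (first rule wins,
  # even for the predS1 that happens to follow a random target)
  expect_identical(sel$reason[2], "after_target")
  expect_identical(sel$reason[5], "after_target")
  expect_identical(sel$reason[9], "after_target")
  # the isolated randS2 surrounded by a randS1 and a target is a
  # potential predS2
  expect_identical(sel$reason[3], "potential_predS2")
  # predT at 8 is preceded by its three standards -> kept; the random
  # targets at 1, 4 and 11 all have another target within their three
  # preceding positions -> short history
  expect_identical(sel$reason[8], "none")
  expect_identical(sel$reason[c(1, 4, 11)],
                   rep("target_short_history", 3))
  # counts by reason sum to total exclusions
  expect_equal(sum(!sel$included),
               sum(table(sel$reason[!sel$included])))
})

test_that("standards near a button press are excluded", {
  ids <- c("left", "up", "down", "right", "up")
  ev <- events_from_identities(ids)
  # press 0.4 s after the target: the following standard (0.75 s before
  # it) is after_target; the press is 1.9 s before 'up' at index 5 -> kept
  sel <- select_trials(ev, ev$onset[3] + 0.4)
  expect_identical(sel$reason[4], "after_target")
  expect_true(sel$included[5])
  # a false-alarm press right on a standard excludes it
  sel2 <- select_trials(ev, c(ev$onset[3] + 0.4, ev$onset[5] + 0.2))
  expect_identical(sel2$reason[5], "near_press")
})

test_that("potential predS2 standards are excluded", {
  ids <- c("left", "up", "down")                # randS1, randS2, then target
  ev <- events_from_identities(ids)
  sel <- select_trials(ev, ev$onset[3] + 0.4)
  expect_identical(sel$reason[2], "potential_predS2")
  # with a randS3 following, the randS2 is kept
  ids2 <- c("left", "up", "right", "up", "down")
  ev2 <- events_from_identities(ids2)
  sel2 <- select_trials(ev2, ev2$onset[5] + 0.4)
  expect_identical(sel2$reason[2], "none")
})

test_that("missed targets and short-history targets are excluded", {
  ev <- generate_block(reduced_counts(), seed = 9)
  sel <- select_trials(ev, numeric(0))
  is_t <- ev$trial_type %in% c("randT", "predT")
  expect_true(all(!sel$included[is_t]))
  expect_true(all(sel$reason[is_t] == "missed_target"))
  # a target too early in the block lacks three preceding standards
  ids <- c("up", "down", "left", "up", "right", "down")
  ev2 <- events_from_identities(ids)
  sel2 <- select_trials(ev2, ev2$onset[c(2, 6)] + 0.4)
  expect_identical(sel2$reason[2], "target_short_history")
  expect_identical(sel2$reason[6], "none")      # predT has full history
  expect_error(select_trials(data.frame(onset = 0, trial_type = NA),
                             numeric(0)), "labelled")
})

test_that("pair equalization drops only from the larger member", {
  ev <- generate_block(seed = 5)
  sel <- select_trials(ev, ev$onset[ev$trial_type %in% c("randT", "predT")] +
                         0.4)
  eq <- equalize_pairs(ev, sel, seed = 2)
  for (p in list(c("randS1", "predS1"), c("randS2", "predS2"),
                 c("randS3", "predS3"), c("randT", "predT"))) {
    na <- sum(eq$included & ev$trial_type == p[1])
    nb <- sum(eq$included & ev$trial_type == p[2])
    expect_equal(na, nb)
    # never drops below the smaller side's surviving count
    expect_equal(nb, min(sum(sel$included & ev$trial_type == p[1]),
                         sum(sel$included & ev$trial_type == p[2])))
  }
  # deterministic under the same seed
  eq2 <- equalize_pairs(ev, sel, seed = 2)
  expect_identical(eq$included, eq2$included)
  # already-equal pairs are untouched
  eq3 <- equalize_pairs(ev, eq, seed = 77)
  expect_identical(eq3$included, eq$included)
})

test_that("an empty pair side empties the pair with a warning", {
  ids <- c("left", "up", "right", "down", "left")   # one pred sequence only
  ev <- events_from_identities(ids)
  sel <- select_trials(ev, ev$onset[4] + 0.4)
  # no randT at all: predT side dropped with a warning (the S2/S3 pairs
  # are empty on both sides and warn as well)
  ws <- capture_warnings(eq <- equalize_pairs(ev, sel, seed = 1))
  expect_true(any(grepl("empty side", ws)))
  expect_false(any(eq$included & ev$trial_type == "predT"))
})
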