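# Session design: tag arithmetic, event scheduling and bookkeeping.

test_that("flicker frequencies map to even frame counts at 120 Hz", {
  expect_identical(frames_per_cycle(c(8.571, 10, 12, 15)),
                   c(14L, 12L, 10L, 8L))
  expect_identical(frames_per_cycle(120 / 14), 14L)
  expect_error(frames_per_cycle(120), "50-50")       # 1 frame, odd
  expect_error(frames_per_cycle(40), "50-50")        # 3 frames, odd
  expect_error(frames_per_cycle(11), "integer")      # 10.9 frames
})

test_that("tag assignment is fixed with the context color at 15 Hz", {
  blue <- assign_tags("blue")
  expect_equal(blue$color, c("red", "green", "yellow", "blue"))
  expect_equal(blue$frequency, c(120 / 14, 10, 12, 15))
  expect_equal(blue$frames_per_cycle, c(14L, 12L, 10L, 8L))
  expect_true(all(blue$frames_on == blue$frames_off))
  lime <- assign_tags("lime")
  expect_equal(lime$frequency[lime$color == "lime"], 15)
  # red's tag is identical across contexts
  for (ctx in c("blue", "orange", "lime")) {
    expect_equal(assign_tags(ctx)$frequency[1], 120 / 14)
  }
  expect_error(assign_tags("purple"))
})

test_that("event roles follow the cued color set", {
  expect_equal(classify_event_role("red", "divided"), "target")
  expect_equal(classify_event_role("green", "red"), "distractor")
  expect_equal(classify_event_role("yellow", "divided"), "distractor")
  expect_equal(classify_event_role(c("red", "green", "yellow", "blue"), "red"),
               c("target", "distractor", "distractor", "distractor"))
  expect_equal(classify_event_role(c("red", "green"), "divided"),
               c("target", "target"))
})

test_that("scheduled onsets respect the head period, gaps and latest onset", {
  par <- design_parameters()
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(0:3, 1)
    on <- schedule_trial_events(n)
    expect_length(on, n)
    if (n > 0) {
      expect_true(all(on >= par$event_free_head_ms))
      expect_true(all(on <= par$latest_onset_ms))
      expect_true(all(diff(on) >= par$min_gap_ms))
      expect_true(!is.unsorted(on))
      # events end before trial end and response windows fit
      expect_true(all(on + par$event_duration_ms <= par$trial_duration_ms))
      expect_true(all(on + par$response_window_ms[2] <= par$trial_duration_ms))
    }
  }
})

test_that("a degenerate scheduling window admits exactly one configuration", {
  set.seed(1)
  on <- schedule_trial_events(3, window = c(500, 1900))
  expect_equal(on, c(500, 1200, 1900))
  expect_error(schedule_trial_events(3, window = c(500, 1800)))
})

test_that("behavioral sessions reproduce the event bookkeeping for any seed", {
  for (seed in c(1, 77, 20240101)) {
    plan <- build_behavioral_session(seed)
    expect_equal(nrow(plan$trials), 270)
    expect_equal(unname(table(paste(plan$trials$focus, plan$trials$context))),
                 rep(30L, 9), ignore_attr = TRUE)
    ev <- plan$events
    expect_equal(nrow(ev), 540)
    tab <- table(ev$role, ev$color)
    expect_equal(sum(tab["target", ]), 180)
    expect_equal(unname(tab["target", c("red", "green")]), c(90L, 90L),
                 ignore_attr = TRUE)
    expect_equal(unname(tab["distractor", c("red", "green")]), c(45L, 45L),
                 ignore_attr = TRUE)
    expect_equal(unname(tab[, "yellow"]), c(135L, 0L), ignore_attr = TRUE)
    # context colors: 45 each, 135 in total
    expect_equal(unname(colSums(tab)[c("blue", "orange", "lime")]),
                 rep(45L, 3), ignore_attr = TRUE)
    # 60 events and 15 per color in every condition
    per_cond <- table(paste(ev$focus, ev$context), ev$color)
    expect_true(all(rowSums(per_cond) == 60))
    expect_true(all(per_cond[per_cond > 0] == 15))
    # response windows within a trial can never overlap
    gaps <- unlist(tapply(ev$onset_ms, ev$trial_id,
                          function(o) diff(sort(o))))
    if (length(gaps)) expect_true(min(gaps) + 250 > 900)
  }
})

test_that("EEG sessions have the specified trial structure", {
  plan <- build_eeg_session(seed = 11)
  expect_equal(nrow(plan$trials), 405)
  expect_equal(nrow(plan$events), 270)
  empty <- table(paste(plan$trials$focus, plan$trials$context)[
    plan$trials$n_events == 0L])
  expect_equal(unname(empty), rep(30L, 9), ignore_attr = TRUE)
  per_cond <- table(paste(plan$events$focus, plan$events$context))
  expect_equal(unname(per_cond), rep(30L, 9), ignore_attr = TRUE)
})

test_that("pooled red+green target counts fluctuate around 90 across seeds", {
  # random color assignment fixes only the totals; the paper-scale spread of
  # the pooled target count (mean 90) spans roughly 81-103 over 20 draws
  counts <- vapply(1:150, function(s) {
    sum(build_eeg_session(s)$events$role == "target")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 90), 2)
  expect_gt(min(counts), 65)
  expect_lt(max(counts), 115)
  # a typical 20-participant draw stays within the reported envelope
  expect_true(all(counts[1:20] >= 75 & counts[1:20] <= 107))
})

test_that("session construction is deterministic in the seed", {
  expect_identical(build_behavioral_session(5), build_behavioral_session(5))
  expect_identical(build_eeg_session(5), build_eeg_session(5))
  expect_false(identical(build_behavioral_session(5)$events,
                         build_behavioral_session(6)$events))
})

test_that("session plans round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  for (plan in list(build_behavioral_session(3), build_eeg_session(3))) {
    write_session(plan, path)
    back <- read_session(path)
    expect_equal(back$kind, plan$kind)
    expect_equal(back$seed, plan$seed)
    ev0 <- plan$events[order(plan$events$trial_id, plan$events$onset_ms), ]
    rownames(ev0) <- NULL
    expect_equal(back$events, ev0, tolerance = 1e-9)
    tr0 <- plan$trials[order(plan$trials$trial_id), ]
    expect_equal(back$trials[c("trial_id", "focus", "context", "n_events")],
                 tr0[c("trial_id", "focus", "context", "n_events")],
                 ignore_attr = TRUE)
  }
})
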