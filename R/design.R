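# Session design: condition grid, flicker-tag assignment and coherent-motion
# event scheduling for the behavioral and EEG sessions.
#
# Timing model (all in ms from motion-interval onset): trials last 3140;
# the first 500 are event-free; coherent-motion events last 400 and their
# onsets are separated by at least 700 within a trial; responses are
# attributed to an event within the closed window [onset+250, onset+900].
# The latest permitted onset, 2240, lets that window close before trial end.

#' Design constants
#'
#' Returns the scheduler/display parameters used throughout the package.
#' Dot-level display parameters (75 squares per color, 0.391 degree squares,
#' 0.061 degree frame displacements, 50% coherence) are carried for
#' documentation; no pixel-level output is produced.
#'
#' @return A named list of design parameters.
#' @export
design_parameters <- function() {
  list(
    refresh_hz = 120,
    trial_duration_ms = 3140,
    event_free_head_ms = 500,
    min_gap_ms = 700,
    event_duration_ms = 400,
    latest_onset_ms = 2240,
    response_window_ms = c(250, 900),
    coherence = 0.5,
    n_dots_per_color = 75,
    dot_size_deg = 0.391,
    dot_step_deg = 0.061
  )
}

.target_colors <- c("red", "green")
.contexts <- c("blue", "orange", "lime")
.foci <- c("red", "green", "divided")
.directions <- c("up", "down", "left", "right")

#' The 3 x 3 condition grid
#'
#' Attentional focus (red, green, or divided between red and green) crossed
#' with color context (which of blue/orange/lime completes the display).
#'
#' @return A 9-row data frame with columns `focus` and `context`.
#' @export
condition_grid <- function() {
  expand.grid(focus = .foci, context = .contexts,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Frames per flicker cycle
#'
#' Converts a flicker frequency to an integer number of monitor frames per
#' on-off cycle. The cycle must be an even number of frames so that the
#' 50-50 on-off duty cycle is realisable.
#'
#' @param frequency Flicker frequency in Hz (vectorised). Rounded printed
#'   values (e.g. 8.571 for 120/14) are accepted: the frame count is taken
#'   from the nearest integer provided the ratio is within `tol` of it.
#' @param refresh Monitor refresh rate in Hz.
#' @param tol Tolerance on `refresh/frequency` against the nearest integer.
#' @return Integer vector of frames per cycle.
#' @examples
#' frames_per_cycle(c(8.571, 10, 12, 15))  # 14 12 10 8
#' @export
frames_per_cycle <- function(frequency, refresh = 120, tol = 1e-3) {
  stopifnot(all(frequency > 0), refresh > 0)
  ratio <- refresh / frequency
  n <- round(ratio)
  bad <- abs(ratio - n) > tol
  if (any(bad)) {
    stop(sprintf("refresh/frequency = %.6f is not an integer frame count",
                 ratio[bad][1]))
  }
  odd <- n %% 2L != 0L
  if (any(odd)) {
    stop(sprintf("%d frames per cycle cannot realise a 50-50 on-off duty",
                 n[odd][1]))
  }
  as.integer(n)
}

#' Assign flicker tags to the four colors of a context
#'
#' Fixed mapping: red 120/14 Hz (printed 8.57), green 10 Hz, yellow 12 Hz,
#' and the context color (blue, orange or lime) 15 Hz. The red frequency is
#' stored exactly as 120/14; the printed 8.57 is its rounding.
#'
#' @param context One of `"blue"`, `"orange"`, `"lime"`.
#' @param refresh Monitor refresh rate in Hz.
#' @return Data frame with columns `color`, `frequency`, `frames_per_cycle`,
#'   `frames_on`, `frames_off`.
#' @examples
#' assign_tags("blue")
#' @export
assign_tags <- function(context, refresh = 120) {
  context <- match.arg(context, .contexts)
  freq <- c(red = refresh / 14, green = 10, yellow = 12, ctx = 15)
  fpc <- frames_per_cycle(freq, refresh)
  data.frame(
    color = c("red", "green", "yellow", context),
    frequency = unname(freq),
    frames_per_cycle = unname(fpc),
    frames_on = unname(fpc %/% 2L),
    frames_off = unname(fpc %/% 2L),
    stringsAsFactors = FALSE
  )
}

#' Classify an event as target or distractor
#'
#' An event is a target iff its color belongs to the cued set: `{red}`,
#' `{green}`, or `{red, green}` for divided attention.
#'
#' @param color Event color(s).
#' @param focus Attentional focus: `"red"`, `"green"` or `"divided"`.
#' @return Character vector, `"target"` or `"distractor"`.
#' @examples
#' classify_event_role("green", "divided")  # target
#' classify_event_role("yellow", "red")     # distractor
#' @export
classify_event_role <- function(color, focus) {
  stopifnot(all(focus %in% .foci))
  cued <- (focus == "divided" | color == focus) & color %in% .target_colors
  ifelse(cued, "target", "distractor")
}

#' Schedule coherent-motion event onsets within a trial
#'
#' Onsets are drawn uniformly over the feasible region of
#' `[window[1], window[2]]` subject to all pairwise gaps being at least
#' `min_gap`, via the spacing transform (uniform order statistics on the
#' gap-collapsed interval). Uses the current RNG state; seed upstream.
#'
#' @param n_events Number of events (0 to 3 in the study design).
#' @param window Earliest and latest permitted onset, ms.
#' @param min_gap Minimum separation of successive onsets, ms.
#' @return Sorted numeric vector of onsets (ms), length `n_events`.
#' @export
schedule_trial_events <- function(n_events,
                                  window = c(design_parameters()$event_free_head_ms,
                                             design_parameters()$latest_onset_ms),
                                  min_gap = design_parameters()$min_gap_ms) {
  stopifnot(length(n_events) == 1L, n_events >= 0)
  n_events <- as.integer(n_events)
  if (n_events == 0L) return(numeric(0))
  span <- window[2] - (n_events - 1L) * min_gap
  if (span < window[1]) {
    stop(sprintf("cannot place %d events with %g ms gaps in [%g, %g]",
                 n_events, min_gap, window[1], window[2]))
  }
  u <- sort(stats::runif(n_events, window[1], span))
  u + (seq_len(n_events) - 1L) * min_gap
}

# Build one session's trials/events. counts_per_bin[k] = number of trials with
# k events (k = 1..3) per condition; n_zero = event-free trials per condition.
# color_mode "balanced": exactly 15 events of each of the 4 colors per
# condition; "random": colors drawn uniformly.
.build_session <- function(kind, counts_per_bin, n_zero, color_mode, seed) {
  grid <- condition_grid()
  par <- design_parameters()
  trials <- list(); events <- list()
  for (i in seq_len(nrow(grid))) {
    focus <- grid$focus[i]; context <- grid$context[i]
    palette4 <- c("red", "green", "yellow", context)
    n_ev_per_trial <- c(rep(0L, n_zero),
                        rep(seq_along(counts_per_bin), counts_per_bin))
    n_ev_per_trial <- sample(n_ev_per_trial)
    n_total_events <- sum(n_ev_per_trial)
    colors <- switch(color_mode,
      balanced = sample(rep(palette4, n_total_events / 4L)),
      random = sample(palette4, n_total_events, replace = TRUE))
    trials[[i]] <- data.frame(focus = focus, context = context,
                              n_events = n_ev_per_trial,
                              stringsAsFactors = FALSE)
    k <- 0L
    ev <- vector("list", sum(n_ev_per_trial > 0L))
    j <- 0L
    for (t in seq_along(n_ev_per_trial)) {
      ne <- n_ev_per_trial[t]
      if (ne == 0L) next
      onsets <- schedule_trial_events(ne)
      cols <- colors[(k + 1L):(k + ne)]
      k <- k + ne
      j <- j + 1L
      ev[[j]] <- data.frame(
        trial_in_condition = t, condition = i,
        event_index = seq_len(ne), color = cols,
        role = classify_event_role(cols, focus),
        onset_ms = onsets,
        duration_ms = par$event_duration_ms,
        direction = sample(.directions, ne, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    events[[i]] <- do.call(rbind, ev)
  }
  trials <- do.call(rbind, trials)
  trials$condition <- rep(seq_len(nrow(grid)), each = nrow(trials) / nrow(grid))
  trials$trial_in_condition <- stats::ave(seq_len(nrow(trials)),
                                          trials$condition, FUN = seq_along)
  # randomise global trial order
  ord <- sample(nrow(trials))
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(nrow(trials))
  events <- do.call(rbind, events)
  key <- paste(trials$condition, trials$trial_in_condition)
  ids <- stats::setNames(trials$trial_id, key)
  events$trial_id <- unname(ids[paste(events$condition, events$trial_in_condition)])
  events <- events[order(events$trial_id, events$onset_ms), ]
  events <- merge(events[, c("trial_id", "event_index", "color", "role",
                             "onset_ms", "duration_ms", "direction")],
                  trials[, c("trial_id", "focus", "context")], by = "trial_id")
  events <- events[order(events$trial_id, events$onset_ms),
                   c("trial_id", "focus", "context", "event_index", "color",
                     "role", "onset_ms", "duration_ms", "direction")]
  rownames(events) <- NULL
  trials <- trials[, c("trial_id", "focus", "context", "n_events")]
  rownames(trials) <- NULL
  structure(list(kind = kind, seed = seed, trials = trials, events = events,
                 config = par),
            class = "session_plan")
}

#' Build a behavioral session plan
#'
#' 270 trials (30 per condition). Each trial carries 1-3 coherent-motion
#' events: per condition, 10 trials with one event, 10 with two and 10 with
#' three (the symmetric split yielding 60 events per condition), with exactly
#' 15 events of each of the condition's four colors.
#'
#' @param seed Integer seed; the plan is a deterministic function of it.
#' @return A `session_plan` object: list with `kind`, `seed`, `trials`
#'   (trial_id, focus, context, n_events), `events` (one row per event) and
#'   `config` (the design parameters).
#' @examples
#' plan <- build_behavioral_session(seed = 1)
#' nrow(plan$events)  # 540
#' @export
build_behavioral_session <- function(seed = 1L) {
  with_seed(seed, .build_session("behavioral", counts_per_bin = c(10L, 10L, 10L),
                                 n_zero = 0L, color_mode = "balanced",
                                 seed = seed))
}

#' Build an EEG session plan
#'
#' 405 trials (45 per condition): 30 event-free trials (the epochs entering
#' the SSVEP analysis) and 15 event-carrying trials per condition (5 each
#' with one, two and three events, i.e. 30 events per condition). Event
#' colors are assigned uniformly at random, so per-color event counts
#' fluctuate between seeds; only the totals are fixed.
#'
#' @inheritParams build_behavioral_session
#' @return A `session_plan` object.
#' @examples
#' plan <- build_eeg_session(seed = 1)
#' nrow(plan$events)  # 270
#' @export
build_eeg_session <- function(seed = 1L) {
  with_seed(seed, .build_session("eeg", counts_per_bin = c(5L, 5L, 5L),
                                 n_zero = 30L, color_mode = "random",
                                 seed = seed))
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("%s session plan (seed %d): %d trials, %d events\n",
              x$kind, x$seed, nrow(x$trials), nrow(x$events)))
  tab <- table(x$events$role)
  cat(sprintf("  targets: %d, distractors: %d, event-free trials: %d\n",
              tab[["target"]], tab[["distractor"]],
              sum(x$trials$n_events == 0)))
  invisible(x)
}

#' Tabulate event counts of a session plan
#'
#' Bookkeeping summary used to verify the design arithmetic: events per
#' role and color, totals per condition.
#'
#' @param plan A `session_plan`.
#' @return A list with `total`, `by_role_color` (table) and `per_condition`
#'   (data frame of event counts per focus x context).
#' @export
session_event_counts <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  ev <- plan$events
  per_cond <- stats::aggregate(list(n_events = ev$trial_id),
                               by = ev[c("focus", "context")], FUN = length)
  list(total = nrow(ev),
       by_role_color = table(ev$role, ev$color),
       per_condition = per_cond)
}

#' Write / read a session plan as TSV
#'
#' One row per event plus one row (with empty event fields) per event-free
#' trial, so the full trial structure round-trips. Metadata (session kind and
#' seed) is stored in `#`-prefixed header comments.
#'
#' @param plan A `session_plan`.
#' @param path File path.
#' @return `read_session()` returns a `session_plan`.
#' @export
write_session <- function(plan, path) {
  stopifnot(inherits(plan, "session_plan"))
  empty <- plan$trials[plan$trials$n_events == 0L, ]
  rows <- plan$events
  if (nrow(empty)) {
    pad <- data.frame(trial_id = empty$trial_id, focus = empty$focus,
                      context = empty$context, event_index = NA_integer_,
                      color = NA_character_, role = NA_character_,
                      onset_ms = NA_real_, duration_ms = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    rows <- rbind(rows, pad)
  }
  rows <- rows[order(rows$trial_id, rows$onset_ms), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_kind=%s", plan$kind), con)
  writeLines(sprintf("# seed=%d", plan$seed), con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  hdr <- readLines(path, n = 2L)
  kind <- sub("^# session_kind=", "", hdr[1])
  seed <- as.integer(sub("^# seed=", "", hdr[2]))
  rows <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  has_ev <- !is.na(rows$event_index)
  events <- rows[has_ev, ]
  rownames(events) <- NULL
  n_ev <- table(factor(events$trial_id, levels = unique(rows$trial_id)))
  first <- rows[!duplicated(rows$trial_id), ]
  trials <- data.frame(trial_id = first$trial_id, focus = first$focus,
                       context = first$context,
                       n_events = as.integer(n_ev[as.character(first$trial_id)]),
                       stringsAsFactors = FALSE)
  structure(list(kind = kind, seed = seed, trials = trials, events = events,
                 config = design_parameters()),
            class = "session_plan")
}
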