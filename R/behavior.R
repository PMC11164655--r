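# Signal-detection scoring of coherent-motion responses.
#
# A response is attributed to an event iff it falls in the closed window
# [onset + 250, onset + 900] ms. Windows within a trial never overlap (the
# scheduler guarantees onset gaps >= 700 ms and 700 + 250 > 900), so each
# response maps to at most one event. Responses outside every window are
# stray presses: logged but excluded from the signal-detection counts.

#' Assign responses to events and score them
#'
#' @param plan A `session_plan` (or a data frame of events with columns
#'   `trial_id`, `focus`, `context`, `color`, `role`, `onset_ms`).
#' @param responses Data frame with columns `trial_id` and `time_ms` (ms from
#'   trial start).
#' @param window Response window relative to event onset, ms (closed
#'   interval).
#' @return An object of class `scored_events`: list with `events` (the event
#'   table plus a logical `responded`), `counts` (per focus x context x
#'   color x role: events and responses), and `stray_presses`.
#' @examples
#' plan <- build_behavioral_session(seed = 1)
#' resp <- simulate_behavior(plan, seed = 2)
#' sc <- assign_responses(plan, resp)
#' sc$stray_presses
#' @export
assign_responses <- function(plan, responses,
                             window = design_parameters()$response_window_ms) {
  events <- if (inherits(plan, "session_plan")) plan$events else plan
  stopifnot(all(c("trial_id", "time_ms") %in% names(responses)))
  known <- if (inherits(plan, "session_plan")) plan$trials$trial_id else
    unique(events$trial_id)
  if (!all(responses$trial_id %in% known)) {
    stop("responses reference unknown trial_id")
  }
  # disjoint closed windows -> interval lookup on a combined trial/time key
  scale <- 10^ceiling(log10(max(events$onset_ms + window[2],
                                responses$time_ms, 1) + 1))
  ev_ord <- order(events$trial_id, events$onset_ms)
  events <- events[ev_ord, ]
  lo <- events$trial_id * scale + events$onset_ms + window[1]
  hi <- events$trial_id * scale + events$onset_ms + window[2]
  rk <- responses$trial_id * scale + responses$time_ms
  idx <- findInterval(rk, lo)
  in_window <- idx > 0 & rk <= hi[pmax(idx, 1L)]
  responded <- rep(FALSE, nrow(events))
  responded[unique(idx[in_window])] <- TRUE
  events$responded <- responded
  counts <- stats::aggregate(
    cbind(n_events = rep(1L, nrow(events)), n_responded = events$responded),
    by = events[c("focus", "context", "color", "role")], FUN = sum)
  structure(list(events = events, counts = counts,
                 stray_presses = sum(!in_window), window = window),
            class = "scored_events")
}

#' @export
print.scored_events <- function(x, ...) {
  tgt <- x$counts$role == "target"
  cat(sprintf("scored events: %d targets (%d hits), %d distractors (%d FAs), %d stray presses\n",
              sum(x$counts$n_events[tgt]), sum(x$counts$n_responded[tgt]),
              sum(x$counts$n_events[!tgt]), sum(x$counts$n_responded[!tgt]),
              x$stray_presses))
  invisible(x)
}

#' Pool false alarms across distractor categories
#'
#' Pooled rate = total false alarms / total distractor events.
#'
#' @param fas Vector of false-alarm counts per category.
#' @param n Vector of distractor event counts per category.
#' @return Pooled false-alarm rate.
#' @examples
#' pool_false_alarms(c(2, 4), c(45, 45))  # 6/90
#' @export
pool_false_alarms <- function(fas, n) {
  stopifnot(length(fas) == length(n), all(fas >= 0), all(fas <= n))
  if (sum(n) == 0) stop("no distractor events to pool over")
  sum(fas) / sum(n)
}

#' Adjust extreme hit / false-alarm rates
#'
#' Perfect rates are pulled off the boundary by the doubling argument: had
#' the number of events been doubled, at least one miss (or false alarm)
#' would have been observed. `k = n` maps to `1 - 1/(2n)`, `k = 0` to
#' `1/(2n)`; interior rates are returned unchanged as `k/n`.
#'
#' @param k Number of responded events (vectorised).
#' @param n Number of events.
#' @return Adjusted rate in (0, 1).
#' @examples
#' adjust_extreme_rate(90, 90)  # 1 - 1/180
#' adjust_extreme_rate(0, 45)   # 1/90
#' @export
adjust_extreme_rate <- function(k, n) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  n <- rep_len(n, length(k))
  rate <- k / n
  hi <- k == n
  lo <- k == 0
  rate[hi] <- 1 - 1 / (2 * n[hi])
  rate[lo] <- 1 / (2 * n[lo])
  rate
}

#' Signal-detection criterion
#'
#' `c = -(z(H) + z(F)) / 2` with `z` the standard-normal quantile. Negative
#' criterion reflects a liberal response pattern (false alarms exceed
#' misses), positive a conservative one; `c = 0` whenever `H + F = 1`.
#'
#' @param H Hit rate(s), strictly inside (0, 1) (adjust extremes first).
#' @param F False-alarm rate(s), strictly inside (0, 1).
#' @return Criterion in z-units.
#' @examples
#' sdt_criterion(0.99, 0.99)  # -2.33
#' sdt_criterion(0.8, 0.2)    # 0
#' @export
sdt_criterion <- function(H, F) {
  stopifnot(all(H > 0 & H < 1), all(F > 0 & F < 1))
  -(stats::qnorm(H) + stats::qnorm(F)) / 2
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(H) - z(F)`. Negative values (F exceeds H) indicate performance
#' below chance, the study's participant-exclusion criterion.
#'
#' @inheritParams sdt_criterion
#' @return Sensitivity in z-units.
#' @examples
#' sdt_dprime(0.99, 0.01)  # ~4.65
#' @export
sdt_dprime <- function(H, F) {
  stopifnot(all(H > 0 & H < 1), all(F > 0 & F < 1))
  stats::qnorm(H) - stats::qnorm(F)
}

#' Score a full session: rates, criterion and d' per condition
#'
#' Computes per-condition (focus x context) hit rates over the condition's
#' target events and a single pooled false-alarm rate over the two
#' always-distractor colors (yellow and the context color); false alarms to
#' the unattended target color are tabulated but excluded from the pooled
#' rate entering criterion and d'. Extreme rates are adjusted per cell with
#' that cell's own event count before the z-transform.
#'
#' @inheritParams assign_responses
#' @return List with `by_color` (counts per focus, context, color, role) and
#'   `sdt` (per condition: hits, misses, fas, crs, H, F, c, dprime), plus
#'   `stray_presses`.
#' @export
score_session <- function(plan, responses,
                          window = design_parameters()$response_window_ms) {
  sc <- assign_responses(plan, responses, window)
  cts <- sc$counts
  grid <- condition_grid()
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    focus <- grid$focus[i]; context <- grid$context[i]
    cell <- cts[cts$focus == focus & cts$context == context, ]
    tgt <- cell[cell$role == "target", ]
    dis <- cell[cell$role == "distractor" &
                  cell$color %in% c("yellow", context), ]
    n_t <- sum(tgt$n_events); hits <- sum(tgt$n_responded)
    n_d <- sum(dis$n_events); fas <- sum(dis$n_responded)
    H <- adjust_extreme_rate(hits, n_t)
    F <- adjust_extreme_rate(fas, n_d)
    out[[i]] <- data.frame(focus = focus, context = context,
                           hits = hits, misses = n_t - hits,
                           fas = fas, crs = n_d - fas,
                           H = H, F = F,
                           c = sdt_criterion(H, F),
                           dprime = sdt_dprime(H, F),
                           stringsAsFactors = FALSE)
  }
  list(by_color = cts, sdt = do.call(rbind, out),
       stray_presses = sc$stray_presses)
}

#' Write the per-condition scoring table as CSV
#'
#' @param scores Result of [score_session()].
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores$sdt, path, row.names = FALSE)
  invisible(path)
}
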