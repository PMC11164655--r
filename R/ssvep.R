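# SSVEP frequency-tagging pipeline: epoch container, preprocessing
# (detrend, artifact rejection, average reference), condition averaging and
# amplitude extraction at the stimulation frequencies.

#' Standard 64-channel montage
#'
#' Channel labels of the 64-electrode 10-10 montage used by Biosemi
#' ActiveTwo caps, including the posterior cluster POz, Oz, O1, O2 and Iz.
#'
#' @return Character vector of 64 channel names.
#' @export
biosemi64_channels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

#' Default occipital electrode cluster
#'
#' The five posterior electrodes over which SSVEP amplitudes are averaged.
#'
#' @return Character vector of channel names.
#' @export
ssvep_cluster <- function() c("POz", "Oz", "O1", "O2", "Iz")

#' Number of samples in an analysis epoch
#'
#' The analysis window spans `window_ms` relative to stimulus onset
#' (default 500-2900 ms, i.e. 2400 ms); at sampling rates where the duration
#' is not an integer number of samples the count is floored (614 samples at
#' 256 Hz).
#'
#' @param sfreq Sampling rate, Hz.
#' @param window_ms Epoch window relative to stimulus onset, ms.
#' @return Integer sample count.
#' @export
n_epoch_samples <- function(sfreq, window_ms = c(500, 2900)) {
  as.integer(floor((window_ms[2] - window_ms[1]) / 1000 * sfreq))
}

#' Epoch container
#'
#' Bundles an `epochs x channels x samples` array (microvolts) with its
#' sampling rate, channel names and condition labels.
#'
#' @param data Numeric array, `epochs x channels x samples`.
#' @param sfreq Sampling rate, Hz.
#' @param channel_names Character vector, one name per channel.
#' @param condition Optional list/row with `focus` and `context`.
#' @param trial_ids Optional integer vector mapping epochs to plan trials.
#' @param window_ms Epoch window relative to stimulus onset, ms.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq = 256, channel_names = biosemi64_channels(),
                      condition = NULL, trial_ids = NULL,
                      window_ms = c(500, 2900)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[2] == length(channel_names))
  if (!is.null(trial_ids)) stopifnot(length(trial_ids) == dim(data)[1])
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names,
                 condition = condition, trial_ids = trial_ids,
                 window_ms = window_ms),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cond <- if (is.null(x$condition)) "" else
    sprintf(" [%s/%s]", x$condition$focus, x$condition$context)
  cat(sprintf("epoch_set%s: %d epochs x %d channels x %d samples @ %g Hz\n",
              cond, d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Extract an analysis epoch from continuous data
#'
#' Returns the samples covering `window_ms` (default 500-2900 ms) after the
#' stimulus-onset sample, discarding the onset-evoked transient before
#' 500 ms and the late interval from 2900 ms on.
#'
#' @param x Numeric matrix, channels x samples of continuous data.
#' @param onset_sample Sample index (1-based) of stimulus onset.
#' @param sfreq Sampling rate, Hz.
#' @param window_ms Epoch window relative to stimulus onset, ms.
#' @return Matrix channels x `n_epoch_samples(sfreq, window_ms)`.
#' @export
extract_epoch <- function(x, onset_sample, sfreq = 256,
                          window_ms = c(500, 2900)) {
  stopifnot(is.matrix(x), onset_sample >= 1)
  n <- n_epoch_samples(sfreq, window_ms)
  start <- onset_sample + floor(window_ms[1] / 1000 * sfreq)
  if (start + n - 1 > ncol(x)) stop("trial too short for the epoch window")
  x[, start:(start + n - 1), drop = FALSE]
}

#' Keep only event-free epochs
#'
#' Epochs from trials containing any coherent-motion event are excluded from
#' the SSVEP analysis so that the averaged signal is uncontaminated by
#' motion- or response-related activity.
#'
#' @param plan A `session_plan`.
#' @param epochs An `epoch_set` with `trial_ids` set.
#' @return The `epoch_set` restricted to event-free trials.
#' @export
select_event_free <- function(plan, epochs) {
  stopifnot(inherits(plan, "session_plan"), inherits(epochs, "epoch_set"),
            !is.null(epochs$trial_ids))
  if (!all(epochs$trial_ids %in% plan$trials$trial_id)) {
    stop("epoch trial_ids not present in the session plan")
  }
  n_ev <- stats::setNames(plan$trials$n_events, plan$trials$trial_id)
  keep <- n_ev[as.character(epochs$trial_ids)] == 0L
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_ids <- epochs$trial_ids[keep]
  epochs
}

#' Remove mean and linear trend from every epoch and channel
#'
#' Least-squares removal of the best-fitting line over time, per epoch and
#' channel; the output has zero mean and zero linear regression slope.
#'
#' @param epochs An `epoch_set`.
#' @return The detrended `epoch_set`.
#' @export
detrend_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  ns <- d[3]
  stopifnot(ns >= 2)
  # flatten to (epochs*channels) x samples, regress on [1, t] in closed form
  m <- matrix(epochs$data, nrow = d[1] * d[2], ncol = ns)
  t0 <- seq_len(ns) - (ns + 1) / 2          # centred time, orthogonal to 1
  denom <- sum(t0^2)
  mu <- rowMeans(m)
  slope <- (m %*% t0) / denom
  m <- m - outer(mu, rep(1, ns)) - outer(as.vector(slope), t0)
  epochs$data <- array(m, dim = d)
  epochs
}

#' Transform epochs to average reference
#'
#' Subtracts, at each sample, the mean over channels, so channel sums vanish.
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  stopifnot(d[2] >= 2)
  m <- matrix(aperm(epochs$data, c(2, 1, 3)), d[2], d[1] * d[3])
  chan_mean <- matrix(colMeans(m), d[1], d[3])     # epochs x samples
  epochs$data <- epochs$data - aperm(
    array(chan_mean, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Drops every epoch whose range (max minus min) on any channel exceeds the
#' threshold. A simple voltage-based stand-in for automated artifact
#' detection: steps, blinks and drifts produce large peak-to-peak values.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Peak-to-peak limit in microvolts.
#' @return The `epoch_set` without the rejected epochs; the attribute
#'   `rejection_fraction` reports the fraction removed.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  d <- dim(epochs$data)
  m <- matrix(epochs$data, d[1] * d[2], d[3])      # rows: epoch x channel
  ptp <- matrix(apply(m, 1, function(v) max(v) - min(v)), d[1], d[2])
  bad <- apply(ptp, 1, max) > threshold
  if (all(bad)) stop("all epochs exceed the artifact threshold")
  epochs$data <- epochs$data[!bad, , , drop = FALSE]
  if (!is.null(epochs$trial_ids)) epochs$trial_ids <- epochs$trial_ids[!bad]
  attr(epochs, "rejection_fraction") <- mean(bad)
  epochs
}

#' Average all epochs of a condition
#'
#' @param epochs An `epoch_set`.
#' @return Matrix channels x samples: the sample-wise mean across epochs.
#' @export
condition_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"), dim(epochs$data)[1] >= 1)
  d <- dim(epochs$data)
  m <- colMeans(array(epochs$data, dim = d))      # channels x samples
  dimnames(m) <- list(epochs$channel_names, NULL)
  m
}

#' SSVEP amplitude at a stimulation frequency
#'
#' Quantifies, per channel, the amplitude (in the input units, microvolts)
#' of the oscillation at frequency `f` in a condition-mean epoch.
#'
#' Method `"projection"` (default) projects the signal onto the sine/cosine
#' quadrature pair at exactly `f`, solving the least-squares problem; a pure
#' sinusoid of amplitude A at `f` is returned as A regardless of whether `f`
#' falls on a Fourier bin. This matters here because 120/14 Hz and 12 Hz are
#' not bin-aligned for a 2400 ms epoch. When `f` is a vector (the four tag
#' frequencies), all quadrature pairs are solved jointly, which removes the
#' mutual spectral leakage between simultaneous non-bin-aligned tones
#' (single-tone projection can pick up several percent of a neighbouring
#' tone 1.4 Hz away over a 2.4 s window).
#' Method `"fft-bin"` returns `2/N` times the FFT magnitude at the bin
#' nearest to each `f` (the classical discrete-spectrum reading). The two
#' agree to numerical precision when `f` is bin-aligned.
#'
#' @param x Matrix channels x samples (a condition average), or an
#'   `epoch_set` (averaged internally).
#' @param f Frequency (Hz, below Nyquist), possibly a vector.
#' @param sfreq Sampling rate, Hz (taken from the `epoch_set` if given).
#' @param method `"projection"` or `"fft-bin"`.
#' @return For scalar `f`, a named numeric vector of per-channel amplitudes
#'   (microvolts); for vector `f`, a matrix frequencies x channels.
#' @examples
#' t <- seq(0, by = 1 / 256, length.out = 614)
#' x <- rbind(3 * sin(2 * pi * 10 * t), 1.5 * cos(2 * pi * 12 * t))
#' amplitude_at_frequency(x, 10, 256)  # c(3, ~0)
#' @export
amplitude_at_frequency <- function(x, f, sfreq = 256,
                                   method = c("projection", "fft-bin")) {
  method <- match.arg(method)
  if (inherits(x, "epoch_set")) {
    sfreq <- x$sfreq
    x <- condition_average(x)
  }
  stopifnot(is.matrix(x), all(f > 0))
  if (any(f >= sfreq / 2)) stop("frequency must be below Nyquist (sfreq/2)")
  n <- ncol(x)
  tt <- (seq_len(n) - 1) / sfreq
  if (method == "projection") {
    D <- do.call(cbind, lapply(f, function(fi) {
      cbind(sin(2 * pi * fi * tt), cos(2 * pi * fi * tt))
    }))
    coefs <- solve(crossprod(D), crossprod(D, t(x)))   # 2k x channels
    amp <- do.call(rbind, lapply(seq_along(f), function(i) {
      sqrt(colSums(coefs[c(2 * i - 1, 2 * i), , drop = FALSE]^2))
    }))
  } else {
    k <- round(f * n / sfreq)                          # nearest bin
    spec <- stats::mvfft(t(x))
    amp <- (2 / n) * Mod(spec[k + 1, , drop = FALSE])
  }
  dimnames(amp) <- list(NULL, rownames(x))
  if (length(f) == 1L) {
    stats::setNames(as.numeric(amp[1, ]), rownames(x))
  } else {
    rownames(amp) <- as.character(f)
    amp
  }
}

#' Average amplitude over an electrode cluster
#'
#' @param amplitudes Named per-channel amplitude vector (from
#'   [amplitude_at_frequency()]).
#' @param cluster Channel names to average over; defaults to the occipital
#'   cluster POz, Oz, O1, O2, Iz.
#' @return Mean amplitude over the cluster (microvolts).
#' @export
cluster_amplitude <- function(amplitudes, cluster = ssvep_cluster()) {
  missing <- setdiff(cluster, names(amplitudes))
  if (length(missing)) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  mean(amplitudes[cluster])
}

#' Data-driven cluster selection
#'
#' Picks the `n` channels with the largest grand-mean amplitude across
#' conditions/frequencies, the data-driven alternative to the fixed
#' occipital cluster.
#'
#' @param amplitude_matrix Matrix with one row per condition/frequency and
#'   one named column per channel.
#' @param n Number of channels to select.
#' @return Character vector of channel names.
#' @export
pick_cluster <- function(amplitude_matrix, n = 5) {
  gm <- colMeans(amplitude_matrix)
  names(sort(gm, decreasing = TRUE))[seq_len(n)]
}

#' Run the SSVEP pipeline over a set of condition epoch sets
#'
#' For each condition: keep event-free epochs (when a plan is supplied),
#' detrend, reject artifacts, transform to average reference, average across
#' epochs, and extract the cluster amplitude at each of the four tag
#' frequencies of the condition's context.
#'
#' @param epoch_sets Named list of `epoch_set` objects, each carrying its
#'   `condition` (focus, context).
#' @param plan Optional `session_plan` for event-free selection.
#' @param threshold Artifact peak-to-peak threshold, microvolts.
#' @param cluster Electrode cluster to average over.
#' @param method Amplitude estimator, see [amplitude_at_frequency()].
#' @return Data frame: `focus`, `context`, `color`, `frequency`,
#'   `amplitude` (cluster mean, microvolts), one row per condition x color.
#' @export
ssvep_amplitudes <- function(epoch_sets, plan = NULL, threshold = 150,
                             cluster = ssvep_cluster(),
                             method = c("projection", "fft-bin")) {
  method <- match.arg(method)
  rows <- lapply(epoch_sets, function(es) {
    stopifnot(inherits(es, "epoch_set"), !is.null(es$condition))
    if (!is.null(plan)) es <- select_event_free(plan, es)
    es <- detrend_epochs(es)
    es <- reject_artifacts(es, threshold)
    es <- rereference_average(es)
    avg <- condition_average(es)
    tags <- assign_tags(es$condition$context)
    amp_mat <- amplitude_at_frequency(avg, tags$frequency, es$sfreq, method)
    amp <- apply(amp_mat, 1, cluster_amplitude, cluster = cluster)
    data.frame(focus = es$condition$focus, context = es$condition$context,
               color = tags$color, frequency = tags$frequency,
               amplitude = amp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attentional effects (attended minus unattended)
#'
#' For each target color (red, green) and context, the unattended amplitude
#' is the amplitude of that color while the *other* target color is
#' attended (red's unattended reference comes from attend-green, and vice
#' versa). Focused and divided effects subtract this same reference.
#'
#' @param amplitudes Data frame from [ssvep_amplitudes()], optionally with a
#'   `participant` column (effects are then computed per participant).
#' @return Data frame per (participant x) context x color with
#'   `amp_focused`, `amp_unattended`, `amp_divided`, `effect_focused`
#'   (A - U, focused), `effect_divided` (A - U, divided), microvolts.
#' @export
attentional_effects <- function(amplitudes) {
  split_cols <- intersect(c("participant"), names(amplitudes))
  groups <- if (length(split_cols)) {
    split(amplitudes, amplitudes[split_cols])
  } else list(amplitudes)
  rows <- lapply(groups, function(g) {
    out <- lapply(unique(g$context), function(ctx) {
      gc <- g[g$context == ctx, ]
      do.call(rbind, lapply(c("red", "green"), function(col) {
        other <- if (col == "red") "green" else "red"
        pick <- function(foc) {
          v <- gc$amplitude[gc$focus == foc & gc$color == col]
          if (length(v) != 1) stop(sprintf(
            "need exactly one amplitude for color %s, focus %s, context %s",
            col, foc, ctx))
          v
        }
        a_att <- pick(col); a_un <- pick(other); a_div <- pick("divided")
        data.frame(context = ctx, color = col,
                   amp_focused = a_att, amp_unattended = a_un,
                   amp_divided = a_div,
                   effect_focused = a_att - a_un,
                   effect_divided = a_div - a_un,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, out)
    if (length(split_cols)) out <- cbind(g[1, split_cols, drop = FALSE], out,
                                         row.names = NULL)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
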