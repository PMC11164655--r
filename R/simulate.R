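# Synthetic behavioral and EEG data with the statistical structure the
# analysis assumes, so that every pipeline stage can be validated
# end-to-end without recorded data.
#
# Behavioral model: equal-variance signal detection. Each event draws
# evidence ~ Normal(d_eff(color, role), 1) and elicits a response iff the
# evidence exceeds the decision threshold c + d_target/2, so that hit rate
# -> Phi(d_target/2 - c) and false-alarm rate -> Phi(-d_target/2 - c +
# d_distractor).
#
# EEG model: each color contributes a stimulus-locked sinusoid at its tag
# frequency with a posterior-weighted topography; attention scales its
# amplitude (focused gain 1 + delta, unattended 1, divided gain
# p_true * (2 + delta), which makes the resource-split multiplier exactly
# recoverable and reduces to 1 + delta/2 at p_true = 0.5). 1/f^alpha
# Gaussian noise is added per epoch and channel.

#' Behavioral generator configuration
#'
#' Defaults are chosen to reproduce group-level performance typical of this
#' task: with `d_target = 2.26` and `criterion = 0.36` the expected hit rate
#' is 78% and the expected false-alarm rate about 6%.
#'
#' @param d_target Sensitivity (z-units) for target-color coherent motion.
#' @param d_distractor Sensitivity leakage on distractor colors (0 = no
#'   color confusion); scalar or named by color.
#' @param criterion Decision criterion c (z-units); positive = conservative.
#' @param stray_rate Rate of stray presses outside all response windows,
#'   presses per second.
#' @param rt_window Response-time window after event onset, ms.
#' @return A list of class `behavior_gen_config`.
#' @export
behavior_gen_config <- function(d_target = 2.26, d_distractor = 0,
                                criterion = 0.36, stray_rate = 0.002,
                                rt_window = c(250, 900)) {
  stopifnot(d_target >= 0, all(d_distractor >= 0), stray_rate >= 0)
  structure(list(d_target = d_target, d_distractor = d_distractor,
                 criterion = criterion, stray_rate = stray_rate,
                 rt_window = rt_window),
            class = "behavior_gen_config")
}

#' Simulate button-press responses for a session plan
#'
#' Draws one evidence sample per event from the signal-detection model and
#' emits a response (uniformly timed inside the response window) when the
#' evidence crosses the decision threshold; stray presses arise from a
#' homogeneous Poisson process over the trial, thinned to the complement of
#' all response windows.
#'
#' @param plan A `session_plan`.
#' @param cfg A [behavior_gen_config()].
#' @param seed Integer seed; output is a deterministic function of it.
#' @return Data frame with columns `trial_id`, `time_ms`, sorted.
#' @examples
#' plan <- build_behavioral_session(seed = 1)
#' resp <- simulate_behavior(plan, seed = 2)
#' @export
simulate_behavior <- function(plan, cfg = behavior_gen_config(), seed = 1L) {
  stopifnot(inherits(plan, "session_plan") || is.data.frame(plan),
            inherits(cfg, "behavior_gen_config"))
  events <- if (inherits(plan, "session_plan")) plan$events else plan
  trials <- if (inherits(plan, "session_plan")) plan$trials else
    data.frame(trial_id = unique(events$trial_id))
  dur <- design_parameters()$trial_duration_ms
  with_seed(seed, {
    d_dis <- cfg$d_distractor
    d_eff <- ifelse(events$role == "target", cfg$d_target,
                    if (length(d_dis) == 1L) d_dis else
                      unname(d_dis[events$color]))
    thresh <- cfg$criterion + cfg$d_target / 2
    responded <- stats::rnorm(nrow(events), mean = d_eff) > thresh
    rt <- stats::runif(nrow(events), cfg$rt_window[1], cfg$rt_window[2])
    resp <- data.frame(trial_id = events$trial_id[responded],
                       time_ms = events$onset_ms[responded] + rt[responded])
    # stray presses: homogeneous process thinned to outside all windows
    n_stray <- stats::rpois(nrow(trials), cfg$stray_rate * dur / 1000)
    if (sum(n_stray) > 0) {
      stray <- data.frame(
        trial_id = rep(trials$trial_id, n_stray),
        time_ms = stats::runif(sum(n_stray), 0, dur))
      lo <- events$onset_ms + cfg$rt_window[1]
      hi <- events$onset_ms + cfg$rt_window[2]
      inside <- vapply(seq_len(nrow(stray)), function(i) {
        j <- events$trial_id == stray$trial_id[i]
        any(stray$time_ms[i] >= lo[j] & stray$time_ms[i] <= hi[j])
      }, logical(1))
      resp <- rbind(resp, stray[!inside, ])
    }
    resp <- resp[order(resp$trial_id, resp$time_ms), ]
    rownames(resp) <- NULL
    resp
  })
}

#' EEG generator configuration
#'
#' Base amplitudes are per-color microvolt amplitudes of the cluster-peak
#' channels; attention multiplies them by 1 + `attended_gain` (focused), 1
#' (unattended) or `p_true * (2 + attended_gain)` (divided). Between-subject
#' variability multiplies base amplitudes and the attended gain by
#' log-normal factors with log-SD `subject_sdlog`.
#'
#' @param base_amplitude Named microvolt amplitudes per color.
#' @param attended_gain Fractional amplitude gain delta when a color is the
#'   single attended target.
#' @param p_true True resource-split multiplier of the generator (0.5 =
#'   exact halving).
#' @param noise_sd Per-sample noise standard deviation, microvolts.
#' @param noise_alpha Spectral exponent of the 1/f^alpha noise (0 = white).
#' @param sfreq Sampling rate, Hz.
#' @param harmonic Second-harmonic amplitude as a fraction of the
#'   fundamental (0 disables it).
#' @param subject_sdlog Log-SD of the between-subject log-normal jitter.
#' @param channels Channel names.
#' @param topography Named per-channel weights (>= 0) applied to every
#'   color's sinusoid.
#' @return A list of class `eeg_gen_config`.
#' @export
eeg_gen_config <- function(base_amplitude = c(red = 1.2, green = 1.0,
                                              yellow = 0.8, blue = 0.6,
                                              orange = 0.6, lime = 0.6),
                           attended_gain = 0.5, p_true = 0.5,
                           noise_sd = 10, noise_alpha = 1, sfreq = 256,
                           harmonic = 0, subject_sdlog = 0.2,
                           channels = biosemi64_channels(),
                           topography = posterior_topography(channels)) {
  stopifnot(all(base_amplitude > 0), attended_gain >= 0, noise_sd >= 0,
            all(topography >= 0), length(topography) == length(channels))
  structure(list(base_amplitude = base_amplitude,
                 attended_gain = attended_gain, p_true = p_true,
                 noise_sd = noise_sd, noise_alpha = noise_alpha,
                 sfreq = sfreq, harmonic = harmonic,
                 subject_sdlog = subject_sdlog, channels = channels,
                 topography = topography),
            class = "eeg_gen_config")
}

#' Posterior-peaked topography weights
#'
#' Weight 1 at the occipital cluster (POz, Oz, O1, O2, Iz), 0.5 over the
#' remaining parieto-occipital sites, 0.1 elsewhere — a coarse stand-in for
#' the posterior SSVEP scalp distribution.
#'
#' @param channels Channel names.
#' @return Named numeric weight vector.
#' @export
posterior_topography <- function(channels = biosemi64_channels()) {
  w <- rep(0.1, length(channels))
  names(w) <- channels
  posterior <- grepl("^(P|PO|O|I)", channels)
  w[posterior] <- 0.5
  w[names(w) %in% ssvep_cluster()] <- 1
  w
}

# 1/f^alpha Gaussian noise: ncols independent series of length ns with
# per-sample SD `sd`. Frequency-domain synthesis with a symmetric
# f^(-alpha/2) amplitude profile; the DC component is zero.
.pink_noise <- function(ns, ncols, sd, alpha, sfreq) {
  if (sd == 0) return(matrix(0, ns, ncols))
  # synthesise at the next fast FFT length and truncate (the process is
  # stationary, so truncation preserves the per-sample distribution)
  nf <- stats::nextn(ns, c(2, 3, 5))
  k <- seq_len(nf) - 1
  fk <- pmin(k, nf - k) * sfreq / nf
  s <- c(0, fk[-1]^(-alpha / 2))
  s <- s * sd / sqrt(sum(s^2))
  z <- matrix(stats::rnorm(nf * ncols), nf, ncols) +
    1i * matrix(stats::rnorm(nf * ncols), nf, ncols)
  Re(stats::mvfft(z * s, inverse = TRUE))[seq_len(ns), , drop = FALSE]
}

# attention gain for one color under a condition
.attn_gain <- function(color, focus, delta, p_true) {
  if (!color %in% c("red", "green")) return(1)
  if (focus == "divided") return(p_true * (2 + delta))
  if (focus == color) return(1 + delta)
  1
}

#' Simulate frequency-tagged EEG epochs for one participant
#'
#' For each of the nine conditions, generates epochs (event-free trials by
#' default — the ones the SSVEP analysis uses) containing the four tagged
#' sinusoids with condition-dependent attention gains, a posterior-weighted
#' topography and additive 1/f noise. Sinusoid phases are drawn once per
#' color and kept constant across epochs and conditions (the SSVEP is
#' stimulus-locked; averaging across epochs must preserve it).
#'
#' @param plan A `session_plan` from [build_eeg_session()].
#' @param cfg An [eeg_gen_config()].
#' @param seed Integer seed; output is a deterministic function of it.
#' @param which `"event_free"` (default) to generate only the event-free
#'   trials per condition, or `"all"` for every trial.
#' @return Named list (`"focus.context"`) of `epoch_set` objects.
#' @examples
#' plan <- build_eeg_session(seed = 1)
#' cfg <- eeg_gen_config(noise_sd = 0, subject_sdlog = 0)
#' eps <- simulate_eeg_epochs(plan, cfg, seed = 1)
#' @export
simulate_eeg_epochs <- function(plan, cfg = eeg_gen_config(), seed = 1L,
                                which = c("event_free", "all")) {
  stopifnot(inherits(plan, "session_plan"), inherits(cfg, "eeg_gen_config"))
  which <- match.arg(which)
  ns <- n_epoch_samples(cfg$sfreq)
  tt <- (seq_len(ns) - 1) / cfg$sfreq
  nch <- length(cfg$channels)
  grid <- condition_grid()
  with_seed(seed, {
    colors_all <- names(cfg$base_amplitude)
    amp_mult <- stats::setNames(
      exp(stats::rnorm(length(colors_all), 0, cfg$subject_sdlog)), colors_all)
    delta <- cfg$attended_gain * exp(stats::rnorm(1, 0, cfg$subject_sdlog))
    phase <- stats::setNames(
      stats::runif(length(colors_all), 0, 2 * pi), colors_all)
    out <- vector("list", nrow(grid))
    names(out) <- paste(grid$focus, grid$context, sep = ".")
    for (i in seq_len(nrow(grid))) {
      focus <- grid$focus[i]; context <- grid$context[i]
      sel <- plan$trials$focus == focus & plan$trials$context == context
      if (which == "event_free") sel <- sel & plan$trials$n_events == 0L
      ids <- plan$trials$trial_id[sel]
      ne <- length(ids)
      tags <- assign_tags(context)
      sig <- matrix(0, nch, ns)
      for (j in seq_len(nrow(tags))) {
        col <- tags$color[j]
        a <- cfg$base_amplitude[[col]] * amp_mult[[col]] *
          .attn_gain(col, focus, delta, cfg$p_true)
        wave <- a * sin(2 * pi * tags$frequency[j] * tt + phase[[col]])
        if (cfg$harmonic > 0 && 2 * tags$frequency[j] < cfg$sfreq / 2) {
          wave <- wave + cfg$harmonic * a *
            sin(4 * pi * tags$frequency[j] * tt + 2 * phase[[col]])
        }
        sig <- sig + cfg$topography %o% wave
      }
      noise <- .pink_noise(ns, nch * ne, cfg$noise_sd, cfg$noise_alpha,
                           cfg$sfreq)
      arr <- array(noise, dim = c(ns, nch, ne)) + as.vector(t(sig))
      out[[i]] <- epoch_set(aperm(arr, c(3, 2, 1)), sfreq = cfg$sfreq,
                            channel_names = cfg$channels,
                            condition = list(focus = focus, context = context),
                            trial_ids = ids)
    }
    out
  })
}

#' Inject a step artifact into one epoch
#'
#' Adds a square step (0 before the epoch midpoint, `amplitude` after) to a
#' single channel of a single epoch — a minimal blink/movement stand-in for
#' exercising peak-to-peak artifact rejection.
#'
#' @param epochs An `epoch_set`.
#' @param epoch,channel Indices of the epoch and channel to contaminate.
#' @param amplitude Step height, microvolts.
#' @return The modified `epoch_set`.
#' @export
add_step_artifact <- function(epochs, epoch = 1L, channel = 1L,
                              amplitude = 500) {
  stopifnot(inherits(epochs, "epoch_set"))
  ns <- dim(epochs$data)[3]
  step <- c(rep(0, ns %/% 2), rep(amplitude, ns - ns %/% 2))
  epochs$data[epoch, channel, ] <- epochs$data[epoch, channel, ] + step
  epochs
}

#' Simulate a multi-participant SSVEP study and extract amplitudes
#'
#' Convenience wrapper for full-stack validation: per participant, builds an
#' EEG session plan, simulates its event-free epochs, runs the SSVEP
#' pipeline and returns the tidy amplitude table.
#'
#' @param n_participants Number of simulated participants.
#' @param cfg An [eeg_gen_config()].
#' @param seed Integer seed; participant-level seeds are derived from it.
#' @param threshold Artifact rejection threshold passed to the pipeline.
#' @param method Amplitude estimator, see [amplitude_at_frequency()].
#' @return Data frame: `participant`, `focus`, `context`, `color`,
#'   `frequency`, `amplitude`.
#' @export
simulate_ssvep_study <- function(n_participants = 20,
                                 cfg = eeg_gen_config(), seed = 1L,
                                 threshold = 150,
                                 method = c("projection", "fft-bin")) {
  method <- match.arg(method)
  seeds <- child_seeds(seed, 2L * n_participants)
  rows <- lapply(seq_len(n_participants), function(i) {
    plan <- build_eeg_session(seed = seeds[2L * i - 1L])
    eps <- simulate_eeg_epochs(plan, cfg, seed = seeds[2L * i])
    amp <- ssvep_amplitudes(eps, plan = plan, threshold = threshold,
                            method = method)
    cbind(participant = sprintf("P%02d", i), amp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
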