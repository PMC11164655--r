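# Shared fixtures for the test suite. Everything is generated in code.

# A reduced montage that keeps the occipital cluster plus a few frontal
# sites, so pipeline unit tests run fast while exercising re-referencing
# and cluster averaging.
mini_channels <- function() c("POz", "Oz", "O1", "O2", "Iz", "Pz", "Cz", "Fz")

mini_topography <- function() {
  w <- c(1, 1, 1, 1, 1, 0.5, 0.2, 0.1)
  names(w) <- mini_channels()
  w
}

mini_eeg_cfg <- function(...) {
  eeg_gen_config(channels = mini_channels(), topography = mini_topography(),
                 ...)
}

# epoch_set holding identical copies of a deterministic channels x samples
# matrix builder applied per epoch
make_epochs <- function(n_epochs, signal_fun, sfreq = 256,
                        channels = mini_channels(),
                        n_samples = n_epoch_samples(sfreq)) {
  tt <- (seq_len(n_samples) - 1) / sfreq
  data <- array(0, dim = c(n_epochs, length(channels), n_samples))
  for (e in seq_len(n_epochs)) {
    data[e, , ] <- signal_fun(tt, e)
  }
  epoch_set(data, sfreq = sfreq, channel_names = channels)
}

# minimal hand-built event table (one target and one distractor per trial)
# for scoring tests: windows [onset+250, onset+900] are disjoint
two_event_trials <- function(n_trials, onsets = c(500, 1500),
                             focus = "red", context = "blue") {
  data.frame(
    trial_id = rep(seq_len(n_trials), each = 2),
    focus = focus, context = context,
    event_index = rep(1:2, n_trials),
    color = rep(c("red", "yellow"), n_trials),
    role = rep(c("target", "distractor"), n_trials),
    onset_ms = rep(onsets, n_trials),
    duration_ms = 400,
    direction = "up",
    stringsAsFactors = FALSE
  )
}
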