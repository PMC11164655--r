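# SSVEP pipeline: epoching, preprocessing and amplitude extraction.

test_that("epoch sample counts follow the floored 2400 ms window", {
  expect_equal(n_epoch_samples(256), 614L)
  expect_equal(n_epoch_samples(500), 1200L)
  expect_equal(n_epoch_samples(256, c(500, 2900)), 614L)
})

test_that("epochs are cut 500-2900 ms after stimulus onset", {
  x <- matrix(seq_len(2 * 2000), nrow = 2, byrow = TRUE)  # 2 channels, ramps
  ep <- extract_epoch(x, onset_sample = 100, sfreq = 256)
  expect_equal(dim(ep), c(2, 614))
  expect_equal(ep[1, 1], x[1, 100 + 128])   # 500 ms = 128 samples at 256 Hz
  expect_error(extract_epoch(x, onset_sample = 1500, sfreq = 256), "short")
})

test_that("event-free selection keeps exactly the no-event trials", {
  plan <- build_eeg_session(seed = 21)
  cfg <- mini_eeg_cfg(noise_sd = 0, subject_sdlog = 0)
  eps <- simulate_eeg_epochs(plan, cfg, seed = 1, which = "all")
  es <- eps[["red.blue"]]
  expect_equal(dim(es$data)[1], 45)
  kept <- select_event_free(plan, es)
  expect_equal(dim(kept$data)[1], 30)
  n_ev <- setNames(plan$trials$n_events, plan$trials$trial_id)
  expect_true(all(n_ev[as.character(kept$trial_ids)] == 0))
  # a plan where every trial has events leaves nothing
  bplan <- build_behavioral_session(seed = 21)
  es$trial_ids <- bplan$trials$trial_id[seq_len(45)]
  expect_equal(dim(select_event_free(bplan, es)$data)[1], 0)
})

test_that("detrending removes means and linear trends but keeps sinusoids", {
  # constant and pure ramp channels vanish
  es <- make_epochs(2, function(tt, e) {
    rbind(rep(5, length(tt)), 3 + 2 * tt,
          matrix(0, 6, length(tt)))
  })
  de <- detrend_epochs(es)
  expect_lt(max(abs(de$data)), 1e-9)
  # any signal orthogonal to {1, t} passes through unchanged, and adding a
  # line back on top of it changes nothing after detrending
  sfreq <- 256; ns <- 512
  tt <- (seq_len(ns) - 1) / sfreq
  tc <- seq_len(ns) - (ns + 1) / 2
  s <- sin(2 * pi * 8 * tt)
  s <- s - mean(s) - sum(s * tc) / sum(tc^2) * tc
  es2 <- make_epochs(1, function(t, e) {
    matrix(rep(s + 4 + 3 * t, each = 8), nrow = 8)
  }, sfreq = sfreq, n_samples = ns)
  de2 <- detrend_epochs(es2)
  expect_lt(max(abs(de2$data[1, 1, ] - s)), 1e-9)
  # idempotence
  expect_equal(detrend_epochs(de2)$data, de2$data, tolerance = 1e-12)
})

test_that("average reference zeroes channel sums and fixes balanced inputs", {
  es <- make_epochs(3, function(tt, e) {
    matrix(rnorm(8 * length(tt)), 8)
  })
  rr <- rereference_average(es)
  sums <- apply(rr$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  # identical channels go to zero; a (+v, -v) pair is left unchanged
  v <- sin(2 * pi * 10 * (0:613) / 256)
  same <- epoch_set(array(rep(v, each = 2), c(1, 2, 614)),
                    channel_names = c("A", "B"))
  expect_lt(max(abs(rereference_average(same)$data)), 1e-12)
  pair <- epoch_set(array(c(rbind(v, -v)), c(1, 2, 614)),
                    channel_names = c("A", "B"))
  expect_equal(rereference_average(pair)$data, pair$data, tolerance = 1e-12)
})

test_that("peak-to-peak rejection removes exactly the contaminated epochs", {
  set.seed(5)
  es <- make_epochs(10, function(tt, e) {
    matrix(rnorm(8 * length(tt), sd = 5), 8)
  })
  clean <- reject_artifacts(es, threshold = 200)
  expect_equal(dim(clean$data)[1], 10)
  expect_equal(attr(clean, "rejection_fraction"), 0)
  dirty <- add_step_artifact(es, epoch = 4, channel = 2, amplitude = 500)
  kept <- reject_artifacts(dirty, threshold = 200)
  expect_equal(dim(kept$data)[1], 9)
  expect_equal(attr(kept, "rejection_fraction"), 0.1)
  # the surviving epochs are the uncontaminated ones, in order
  expect_equal(kept$data, es$data[-4, , , drop = FALSE])
  expect_error(reject_artifacts(es, threshold = 0.001), "all epochs")
})

test_that("condition averaging is the sample-wise mean", {
  es <- make_epochs(1, function(tt, e) matrix(seq_along(tt), 8, length(tt),
                                              byrow = TRUE))
  expect_equal(unname(condition_average(es)), es$data[1, , ])
  # an epoch and its negation average to zero
  d <- array(0, c(2, 8, 614))
  d[1, , ] <- es$data[1, , ]; d[2, , ] <- -es$data[1, , ]
  two <- epoch_set(d, channel_names = mini_channels())
  expect_lt(max(abs(condition_average(two))), 1e-12)
})

test_that("averaging N noisy epochs shrinks residual noise power like 1/N", {
  sfreq <- 256; ns <- 614
  tt <- (seq_len(ns) - 1) / sfreq
  truth <- sin(2 * pi * 10 * tt)
  set.seed(31)
  resid_var <- vapply(c(5, 20, 80), function(N) {
    es <- make_epochs(N, function(tt, e) {
      matrix(truth + rnorm(ns), 1)
    }, channels = "Oz", n_samples = ns)
    mean((condition_average(es)[1, ] - truth)^2)
  }, numeric(1))
  ratios <- resid_var[-3] / resid_var[-1]
  expect_true(all(ratios > 2 & ratios < 8))   # nominal 4x per 4x epochs
})

test_that("projection amplitudes recover pure tones at any tag frequency", {
  sfreq <- 256; ns <- 614
  tt <- (seq_len(ns) - 1) / sfreq
  for (f in c(120 / 14, 10, 12, 15)) {
    x <- matrix(3 * sin(2 * pi * f * tt + 0.7), 1,
                dimnames = list("Oz", NULL))
    expect_equal(unname(amplitude_at_frequency(x, f, sfreq)), 3,
                 tolerance = 1e-3 / 3)
  }
  zero <- matrix(0, 1, ns, dimnames = list("Oz", NULL))
  expect_equal(unname(amplitude_at_frequency(zero, 10, sfreq)), 0)
  expect_error(amplitude_at_frequency(zero, 128, sfreq), "Nyquist")
})

test_that("projection equals the FFT bin when the frequency is bin-aligned", {
  sfreq <- 256; ns <- 614
  tt <- (seq_len(ns) - 1) / sfreq
  set.seed(12)
  x <- matrix(rnorm(2 * ns), 2, dimnames = list(c("Oz", "POz"), NULL))
  for (k in c(24, 29, 36)) {
    f <- k * sfreq / ns
    expect_equal(amplitude_at_frequency(x, f, sfreq, "projection"),
                 amplitude_at_frequency(x, f, sfreq, "fft-bin"),
                 tolerance = 1e-9)
  }
})

test_that("joint estimation separates simultaneous non-bin-aligned tones", {
  sfreq <- 256; ns <- 614
  tt <- (seq_len(ns) - 1) / sfreq
  freqs <- c(120 / 14, 10, 12, 15)
  amps <- c(1.2, 1.0, 0.8, 0.6)
  x <- matrix(colSums(amps * t(sapply(seq_along(freqs), function(i) {
    sin(2 * pi * freqs[i] * tt + i)
  }))), 1, dimnames = list("Oz", NULL))
  est <- amplitude_at_frequency(x, freqs, sfreq)
  expect_equal(unname(est[, "Oz"]), amps, tolerance = 5e-3)
  # single-tone projection on the same mixture shows the leakage the joint
  # solve removes
  single <- vapply(freqs, function(f) {
    unname(amplitude_at_frequency(x, f, sfreq))
  }, numeric(1))
  expect_gt(max(abs(single - amps)), max(abs(est[, "Oz"] - amps)))
})

test_that("cluster averaging uses the named occipital electrodes", {
  amps <- setNames(runif(8, 1, 2), mini_channels())
  expect_equal(cluster_amplitude(amps),
               mean(amps[c("POz", "Oz", "O1", "O2", "Iz")]))
  uniform <- setNames(rep(1.5, 8), mini_channels())
  expect_equal(cluster_amplitude(uniform), 1.5)
  expect_error(cluster_amplitude(amps[1:3]), "unknown channel")
  # data-driven pick finds the peak channel
  m <- matrix(runif(16, 0, 0.1), 2, 8, dimnames = list(NULL, mini_channels()))
  m[, "Oz"] <- c(2, 2.1)
  expect_true("Oz" %in% pick_cluster(m, n = 5))
})

test_that("the pipeline is linear and order-invariant", {
  plan <- build_eeg_session(seed = 4)
  cfg <- mini_eeg_cfg(noise_sd = 1, subject_sdlog = 0)
  eps <- simulate_eeg_epochs(plan, cfg, seed = 6)
  amp1 <- ssvep_amplitudes(eps, plan = plan)
  scaled <- lapply(eps, function(es) { es$data <- 3 * es$data; es })
  amp3 <- ssvep_amplitudes(scaled, plan = plan)
  expect_equal(amp3$amplitude, 3 * amp1$amplitude, tolerance = 1e-9)
  eff1 <- attentional_effects(amp1); eff3 <- attentional_effects(amp3)
  expect_equal(eff3$effect_focused, 3 * eff1$effect_focused,
               tolerance = 1e-9)
  # permuting epochs within a condition changes nothing
  perm <- lapply(eps, function(es) {
    o <- rev(seq_len(dim(es$data)[1]))
    es$data <- es$data[o, , , drop = FALSE]
    es$trial_ids <- es$trial_ids[o]
    es
  })
  expect_equal(ssvep_amplitudes(perm, plan = plan)$amplitude,
               amp1$amplitude, tolerance = 1e-12)
})

test_that("noiseless generator amplitudes are recovered within 0.5%", {
  plan <- build_eeg_session(seed = 14)
  cfg <- mini_eeg_cfg(noise_sd = 0, subject_sdlog = 0)
  eps <- simulate_eeg_epochs(plan, cfg, seed = 2)
  amp <- ssvep_amplitudes(eps, plan = plan)
  w <- mini_topography()
  # average reference shifts every channel by the weighted mean; cluster
  # channels all carry weight 1
  expected_gain <- mean(w[ssvep_cluster()]) - mean(w)
  base <- cfg$base_amplitude
  for (i in seq_len(nrow(amp))) {
    g <- if (amp$color[i] %in% c("red", "green")) {
      if (amp$focus[i] == amp$color[i]) 1.5
      else if (amp$focus[i] == "divided") 0.5 * 2.5 else 1
    } else 1
    truth <- base[[amp$color[i]]] * g * expected_gain
    expect_lt(abs(amp$amplitude[i] - truth) / truth, 0.005)
  }
})

test_that("epoch sets round-trip through HDF5", {
  plan <- build_eeg_session(seed = 2)
  cfg <- mini_eeg_cfg(noise_sd = 0.5, subject_sdlog = 0)
  eps <- simulate_eeg_epochs(plan, cfg, seed = 3)[c("red.blue", "divided.lime")]
  path <- withr::local_tempfile(fileext = ".h5")
  write_epochs_h5(eps, path, participant = "P01")
  back <- read_epochs_h5(path, participant = "P01")
  expect_setequal(names(back), names(eps))
  for (nm in names(eps)) {
    expect_equal(back[[nm]]$data, eps[[nm]]$data, tolerance = 1e-12)
    expect_equal(back[[nm]]$sfreq, eps[[nm]]$sfreq)
    expect_equal(back[[nm]]$channel_names, eps[[nm]]$channel_names)
    expect_equal(back[[nm]]$condition$focus, eps[[nm]]$condition$focus)
    expect_equal(back[[nm]]$trial_ids, eps[[nm]]$trial_ids)
  }
})
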