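test_that("simulator is seed-reproducible and respects degenerate inputs", {
  sched <- build_trial_schedule(tiny_design_cfg(n_reps = 2L), seed = 1)
  a <- simulate_epochs(sched, seed = 5, n_participants = 2L)
  b <- simulate_epochs(sched, seed = 5, n_participants = 2L)
  expect_identical(a, b)
  c <- simulate_epochs(sched, seed = 6, n_participants = 2L)
  expect_false(identical(a[[1]]$data, c[[1]]$data))
  # no sources -> all-zero epochs
  z <- simulate_epochs(sched, effect_spec(),
                       noise_spec(background_sd_uV = 0), n_participants = 1L,
                       seed = 1)
  expect_true(all(z[[1]]$data == 0))
  expect_equal(dim(z[[1]]$data), c(8L, 2L, 3001L))
  # burst at/above Nyquist is rejected
  expect_error(simulate_epochs(sched, effect_spec(gaze_burst(center_freq_hz = 480)),
                               seed = 1), "Nyquist")
})

test_that("background spectrum follows the requested 1/f slope", {
  set.seed(11)
  x <- tfspm:::colored_noise(60000, 1, exponent = 1, sd_uV = 40, fs_hz = 1000)
  expect_equal(sd(x), 40, tolerance = 0.1)
  sp <- spec.pgram(ts(x[, 1], frequency = 1000), spans = 31, plot = FALSE,
                   taper = 0)
  keep <- sp$freq > 2 & sp$freq < 300
  slope <- coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("an injected burst's wavelet power localizes at its locus", {
  sched <- build_trial_schedule(tiny_design_cfg(n_reps = 2L), seed = 2)
  burst <- gaze_burst(amplitude_uV = 20)
  eps <- simulate_epochs(sched, effect_spec(burst),
                         noise_spec(background_sd_uV = 0),
                         n_participants = 1L, seed = 3)[[1]]
  p <- wavelet_params(freqs_hz = seq(4, 300, by = 8), fs_hz = 1000)
  st <- tf_power(eps, p, out_times_ms = seq(-200, 500, by = 4),
                 spectrum_eps = 1e-6)
  eyes <- which(st$obs$stimulus_type == "eyes")
  pw <- apply(st$power[, , eyes], c(1, 2), mean)
  dt <- diff(st$times_ms[1:2])
  box_t <- abs(st$times_ms - burst$center_time_ms) <= 2 * burst$time_fwhm_ms
  box_f <- abs(st$freqs_hz - burst$center_freq_hz) <=
    burst$freq_bandwidth_hz   # +-2 x half-bandwidth
  frac <- sum(pw[box_t, box_f]) / sum(pw)
  expect_gt(frac, 0.8)
  # mosaics trials received nothing
  expect_true(all(st$power[, , st$obs$stimulus_type == "mosaic"] == 0))
})

test_that("random-phase bursts are induced, not evoked", {
  # averaging many burst trials cancels the carrier: evoked energy is tiny
  sched <- build_trial_schedule(
    stimulus_set_config(n_models_female = 7L, n_models_male = 7L,
                        n_repetitions = 3L, n_target_trials = 0L), seed = 4)
  eps <- simulate_epochs(sched, effect_spec(gaze_burst(amplitude_uV = 20)),
                         noise_spec(background_sd_uV = 0),
                         n_participants = 1L, seed = 5)[[1]]
  eyes <- eps$events$stimulus_type == "eyes"
  avg <- colMeans(eps$data[eyes, 1, ])
  per_trial_peak <- mean(apply(abs(eps$data[eyes, 1, ]), 1, max))
  expect_lt(max(abs(avg)), 0.2 * per_trial_peak)
  # an evoked component survives averaging
  eps2 <- simulate_epochs(sched, effect_spec(evoked = evoked_component(
    amplitude_uV = 5, condition = list(stimulus_type = "eyes"))),
    noise_spec(background_sd_uV = 0), n_participants = 1L, seed = 6)[[1]]
  avg2 <- colMeans(eps2$data[eps2$events$stimulus_type == "eyes", 1, ])
  times <- epoch_times(eps2)
  expect_gt(max(avg2), 4)
  expect_lt(abs(times[which.max(avg2)] - 350), 10)
})

test_that("artifact injection marks exactly the chosen trials", {
  sched <- build_trial_schedule(tiny_design_cfg(n_reps = 3L), seed = 7)
  eps <- simulate_epochs(sched, seed = 8, n_participants = 1L)[[1]]
  spiked <- inject_artifacts(eps, n_trials = 3L, peak_uV = 900, seed = 9)
  ids <- attr(spiked, "artifact_trials")
  expect_length(ids, 3L)
  peaks <- apply(abs(spiked$data), 1, max)
  expect_true(all(peaks[ids] > 800))
  expect_true(all(peaks[-ids] < 800))
  # peak 0 and n_trials 0 are identities
  expect_equal(inject_artifacts(eps, 3L, peak_uV = 0, seed = 1)$data, eps$data)
  expect_equal(inject_artifacts(eps, 0L, peak_uV = 900, seed = 1)$data, eps$data)
  expect_error(inject_artifacts(eps, nrow(sched) + 1L, 900, 1), "exceeds")
})
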