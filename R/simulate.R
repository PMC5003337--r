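#' Background-noise specification for the synthetic iEEG generator
#'
#' The background is 1/f ("pink-like") noise synthesized by spectral shaping
#' of Gaussian white noise: the amplitude spectrum is scaled by
#' `f^(-exponent/2)` so the power spectrum falls off as `f^(-exponent)`.
#' Optional mains line noise can be superimposed.
#'
#' @param one_over_f_exponent Spectral slope of the background power
#'   spectrum (0 = white). Default 1.
#' @param background_sd_uV Marginal standard deviation of the background in
#'   microvolts. Default 40, a typical intracranial background amplitude.
#' @param line_noise Optional `list(freq_hz=, amplitude_uV=)`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, background_sd_uV = 40,
                       line_noise = NULL) {
  if (!is.finite(one_over_f_exponent) || one_over_f_exponent < 0)
    stop_cfg("one_over_f_exponent must be >= 0")
  if (!is.finite(background_sd_uV) || background_sd_uV < 0)
    stop_cfg("background_sd_uV must be >= 0")
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 background_sd_uV = background_sd_uV,
                 line_noise = line_noise),
            class = "noise_spec")
}

#' Condition-dependent oscillatory burst
#'
#' A burst is a Gaussian-windowed sinusoid added to selected trials: the
#' carrier frequency is drawn per trial and channel uniformly within
#' `center_freq_hz +- freq_bandwidth_hz/2`, the carrier phase is drawn
#' uniformly (so the burst is *induced*: it raises trial-wise spectral power
#' but cancels from the stimulus-locked average), and the amplitude is
#' jittered log-normally with coefficient of variation
#' `amplitude_jitter_cv` of the enclosing [effect_spec()].
#'
#' The defaults place an eyes-selective gamma burst at 226 ms / 121 Hz with
#' ~21 ms temporal FWHM and 50 Hz bandwidth, the locus used throughout the
#' package's recovery tests. The default amplitude (13 uV against the
#' default 40 uV 1/f background) produces a log-power elevation of ~0.5 at
#' the locus of the wavelet maps (calibrated by simulation).
#'
#' @param center_time_ms,center_freq_hz Burst locus.
#' @param time_fwhm_ms Full width at half maximum of the Gaussian envelope.
#' @param freq_bandwidth_hz Full width of the uniform carrier-frequency draw.
#' @param amplitude_uV Envelope peak amplitude in microvolts.
#' @param condition Named list of factor levels the burst applies to, e.g.
#'   `list(stimulus_type = "eyes")`; fields may reference `stimulus_type`,
#'   `first_direction`, `second_direction`.
#' @param hemisphere `NULL` for both hemispheres, else `"left"`/`"right"`.
#' @return A `tf_burst` list.
#' @export
gaze_burst <- function(center_time_ms = 226, center_freq_hz = 121,
                       time_fwhm_ms = 21, freq_bandwidth_hz = 50,
                       amplitude_uV = 13,
                       condition = list(stimulus_type = "eyes"),
                       hemisphere = NULL) {
  if (amplitude_uV < 0) stop_cfg("burst amplitude must be >= 0")
  structure(list(center_time_ms = center_time_ms,
                 center_freq_hz = center_freq_hz,
                 time_fwhm_ms = time_fwhm_ms,
                 freq_bandwidth_hz = freq_bandwidth_hz,
                 amplitude_uV = amplitude_uV,
                 condition = condition, hemisphere = hemisphere),
            class = "tf_burst")
}

#' Phase-locked evoked component
#'
#' A Gaussian voltage deflection with fixed polarity and latency, added to
#' selected trials. Unlike [gaze_burst()] it survives trial averaging and is
#' therefore visible to the ERP arm of the pipeline.
#'
#' @param latency_ms Peak latency.
#' @param width_ms FWHM of the deflection.
#' @param amplitude_uV Peak amplitude (signed).
#' @param condition,hemisphere As in [gaze_burst()].
#' @return An `evoked_component` list.
#' @export
evoked_component <- function(latency_ms = 350, width_ms = 100,
                             amplitude_uV = 3,
                             condition = list(stimulus_type = "eyes"),
                             hemisphere = NULL) {
  structure(list(latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uV = amplitude_uV, condition = condition,
                 hemisphere = hemisphere),
            class = "evoked_component")
}

#' Collection of injectable effects
#'
#' @param bursts List of [gaze_burst()] objects.
#' @param evoked List of [evoked_component()] objects.
#' @param amplitude_jitter_cv Coefficient of variation of the log-normal
#'   per-trial amplitude jitter shared by all effects. Default 0.2.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(bursts = list(), evoked = list(),
                        amplitude_jitter_cv = 0.2) {
  if (inherits(bursts, "tf_burst")) bursts <- list(bursts)
  if (inherits(evoked, "evoked_component")) evoked <- list(evoked)
  if (amplitude_jitter_cv < 0) stop_cfg("amplitude_jitter_cv must be >= 0")
  ok <- c("stimulus_type", "first_direction", "second_direction")
  for (b in c(bursts, evoked)) {
    bad <- setdiff(names(b$condition), ok)
    if (length(bad))
      stop_cfg("unknown condition selector field(s): ", paste(bad, collapse = ", "))
  }
  structure(list(bursts = bursts, evoked = evoked,
                 amplitude_jitter_cv = amplitude_jitter_cv),
            class = "effect_spec")
}

# 1/f^a noise by spectral shaping: returns n x nseries matrix, marginal sd
# as requested (analytic normalization, so trial-to-trial variance is real).
# The shaped Hermitian spectrum is synthesized directly from white Gaussian
# coefficients, so only one (inverse) FFT per series is needed.
colored_noise <- function(n, nseries, exponent, sd_uV, fs_hz) {
  if (sd_uV == 0 || nseries == 0L) return(matrix(0, n, nseries))
  N <- nextn(n, 2)
  k <- seq_len(N) - 1L
  f <- pmin(k, N - k) * fs_hz / N   # two-sided frequency axis
  shape <- c(0, f[-1]^(-exponent / 2))
  half <- N / 2
  X <- matrix(0i, N, nseries)
  z <- matrix(complex(real = rnorm((half - 1L) * nseries),
                      imaginary = rnorm((half - 1L) * nseries)),
              half - 1L, nseries) * sqrt(N / 2)
  X[2:half, ] <- z * shape[2:half]
  X[half + 1L, ] <- rnorm(nseries) * sqrt(N) * shape[half + 1L]
  X[N:(half + 2L), ] <- Conj(X[2:half, ])
  x <- Re(mvfft(X, inverse = TRUE)) / N
  x <- x[seq_len(n), , drop = FALSE]
  x * (sd_uV / sqrt(mean(shape^2)))
}

match_trials <- function(events, condition) {
  keep <- rep(TRUE, nrow(events))
  for (nm in names(condition))
    keep <- keep & (events[[nm]] %in% condition[[nm]])
  which(keep)
}

#' Simulate epoched iEEG for a trial schedule
#'
#' Per trial and channel the signal is the sum of 1/f background noise,
#' any matching evoked components (phase-locked Gaussian deflections) and
#' any matching oscillatory bursts (Gaussian-windowed sinusoids with random
#' carrier phase), each with log-normal amplitude jitter. One temporal-pole
#' channel per hemisphere is simulated per participant; each participant
#' receives an independently shuffled copy of the schedule when
#' `reshuffle_schedule` is `TRUE`.
#'
#' @param schedule An `event_table` (see [build_trial_schedule()]).
#' @param effects An [effect_spec()].
#' @param noise A [noise_spec()].
#' @param n_participants Number of virtual participants. Default 6.
#' @param fs_hz Sampling rate. Default 1000 Hz.
#' @param window_ms Epoch window relative to first-stimulus onset.
#'   Default `c(-1000, 2000)`.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param reshuffle_schedule Re-randomize trial order per participant.
#' @return List of [ieeg_epochs()] objects, one per participant.
#' @export
simulate_epochs <- function(schedule, effects = effect_spec(),
                            noise = noise_spec(), n_participants = 6L,
                            fs_hz = 1000, window_ms = c(-1000, 2000),
                            seed = NULL, reshuffle_schedule = TRUE) {
  stopifnot(nrow(schedule) > 0L)
  for (b in effects$bursts)
    if (b$center_freq_hz + b$freq_bandwidth_hz / 2 >= fs_hz / 2)
      stop_cfg("burst frequency reaches Nyquist (", fs_hz / 2, " Hz)")
  times <- seq(window_ms[1], window_ms[2], by = 1000 / fs_hz)
  nsamp <- length(times)
  channels <- data.frame(label = c("LTP1", "RTP1"),
                         hemisphere = c("left", "right"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(n_participants), function(p) {
    with_seed(child_seed(seed, p), {
      ev <- schedule
      if (reshuffle_schedule && nrow(ev) > 1L) {
        ord <- sample.int(nrow(ev))
        onset <- sort(ev$onset_ms)
        ev <- ev[ord, , drop = FALSE]
        ev$onset_ms <- onset
        ev$trial_id <- seq_len(nrow(ev))
        rownames(ev) <- NULL
        class(ev) <- c("event_table", "data.frame")
      }
      ntrial <- nrow(ev)
      dat <- array(0, c(ntrial, 2L, nsamp))
      for (ch in 1:2) {
        x <- t(colored_noise(nsamp, ntrial, noise$one_over_f_exponent,
                             noise$background_sd_uV, fs_hz))
        if (!is.null(noise$line_noise)) {
          ln <- noise$line_noise
          ph <- runif(ntrial, 0, 2 * pi)
          x <- x + ln$amplitude_uV *
            sin(outer(ph, 2 * pi * ln$freq_hz * times / 1000, `+`))
        }
        for (b in effects$bursts) {
          if (!is.null(b$hemisphere) &&
              !identical(b$hemisphere, channels$hemisphere[ch])) next
          idx <- match_trials(ev, b$condition)
          if (!length(idx) || b$amplitude_uV == 0) next
          sig_t <- b$time_fwhm_ms / (2 * sqrt(2 * log(2)))
          env <- exp(-(times - b$center_time_ms)^2 / (2 * sig_t^2))
          fcar <- runif(length(idx), b$center_freq_hz - b$freq_bandwidth_hz / 2,
                        b$center_freq_hz + b$freq_bandwidth_hz / 2)
          phase <- runif(length(idx), 0, 2 * pi)
          cv <- effects$amplitude_jitter_cv
          amp <- b$amplitude_uV *
            exp(rnorm(length(idx), -cv^2 / 2, cv))
          carrier <- cos(outer(fcar, 2 * pi * (times - b$center_time_ms) / 1000) +
                           phase)
          x[idx, ] <- x[idx, , drop = FALSE] +
            (amp * carrier) * rep(env, each = length(idx))
        }
        for (e in effects$evoked) {
          if (!is.null(e$hemisphere) &&
              !identical(e$hemisphere, channels$hemisphere[ch])) next
          idx <- match_trials(ev, e$condition)
          if (!length(idx) || e$amplitude_uV == 0) next
          sig_t <- e$width_ms / (2 * sqrt(2 * log(2)))
          env <- exp(-(times - e$latency_ms)^2 / (2 * sig_t^2))
          cv <- effects$amplitude_jitter_cv
          amp <- e$amplitude_uV * exp(rnorm(length(idx), -cv^2 / 2, cv))
          x[idx, ] <- x[idx, , drop = FALSE] + outer(amp, env)
        }
        dat[, ch, ] <- x
      }
      ieeg_epochs(dat, fs_hz = fs_hz, t0_ms = window_ms[1],
                  channels = channels,
                  participant_id = sprintf("S%02d", p), events = ev)
    })
  })
}

#' Inject high-amplitude transient artifacts into chosen trials
#'
#' Adds a Gaussian-envelope voltage spike (sigma = 15 ms, random latency,
#' random polarity) of the given peak amplitude to `n_trials` randomly
#' chosen trials on one random channel each. The modified trial ids are
#' attached as attribute `"artifact_trials"`.
#'
#' @param epochs An `ieeg_epochs` object.
#' @param n_trials Number of trials to contaminate.
#' @param peak_uV Spike peak amplitude (microvolts); 0 leaves data unchanged.
#' @param seed Integer seed.
#' @return The modified `ieeg_epochs`.
#' @export
inject_artifacts <- function(epochs, n_trials, peak_uV = 900, seed = NULL) {
  stopifnot(inherits(epochs, "ieeg_epochs"), peak_uV >= 0)
  ntrial <- dim(epochs$data)[1]
  if (n_trials > ntrial)
    stop_cfg("n_trials (", n_trials, ") exceeds available trials (", ntrial, ")")
  if (n_trials == 0L || peak_uV == 0) {
    attr(epochs, "artifact_trials") <- integer(0)
    return(epochs)
  }
  times <- epoch_times(epochs)
  with_seed(seed, {
    ids <- sort(sample.int(ntrial, n_trials))
    for (i in ids) {
      ch <- sample.int(dim(epochs$data)[2], 1L)
      tc <- runif(1, times[1] + 100, times[length(times)] - 100)
      sgn <- sample(c(-1, 1), 1L)
      epochs$data[i, ch, ] <- epochs$data[i, ch, ] +
        sgn * peak_uV * exp(-(times - tc)^2 / (2 * 15^2))
    }
    attr(epochs, "artifact_trials") <- ids
    epochs
  })
}
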