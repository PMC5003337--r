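#' Morlet wavelet decomposition parameters
#'
#' @param n_cycles Number of cycles of the Morlet family; fixes the
#'   time/frequency trade-off via `sigma_t = n_cycles / (2*pi*f)`. Default 7.
#' @param freqs_hz Frequency grid in Hz. Default 4--300 Hz in 1 Hz steps.
#' @param fs_hz Sampling rate of the data the wavelets will be applied to.
#' @return A `wavelet_params` object.
#' @export
wavelet_params <- function(n_cycles = 7, freqs_hz = 4:300, fs_hz = 1000) {
  if (n_cycles < 1) stop_cfg("n_cycles must be >= 1")
  if (max(freqs_hz) >= fs_hz / 2)
    stop_cfg("max frequency must be below Nyquist (", fs_hz / 2, " Hz)")
  if (any(diff(freqs_hz) <= 0)) stop_cfg("freqs_hz must be increasing")
  structure(list(n_cycles = n_cycles, freqs_hz = as.numeric(freqs_hz),
                 fs_hz = fs_hz), class = "wavelet_params")
}

#' Discrete Morlet wavelet kernel
#'
#' Complex Gaussian-windowed exponential with temporal spread
#' `sigma_t = n_cycles / (2*pi*f)`, truncated at `+-5 sigma_t` and
#' normalized to unit L2 norm (`sum(|w|^2) * dt = 1`).
#'
#' @param f Center frequency (Hz), below Nyquist.
#' @param p A [wavelet_params()] object.
#' @return Complex vector with attributes `sigma_t_ms` and `times_ms`
#'   (sample times of the kernel, centered on 0).
#' @export
morlet_kernel <- function(f, p) {
  if (f >= p$fs_hz / 2)
    stop_cfg("wavelet frequency ", f, " Hz is at or above Nyquist")
  sigma_t <- p$n_cycles / (2 * pi * f)            # seconds
  dt <- 1 / p$fs_hz
  h <- ceiling(5 * sigma_t / dt)
  t <- (-h:h) * dt
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w <- w / sqrt(sum(Mod(w)^2) * dt)
  attr(w, "sigma_t_ms") <- sigma_t * 1000
  attr(w, "times_ms") <- t * 1000
  w
}

# Spectrum of the kernel on an N-point grid, with t=0 at index 1 and
# negative lags wrapped; scaled by dt so the convolution approximates the
# continuous integral, and phase-rotated by `offset` samples so that the
# decimated output frame starts at that sample.
kernel_spectrum <- function(w, N, fs_hz, offset = 0L) {
  h <- (length(w) - 1L) %/% 2L
  if (length(w) > N) stop_cfg("FFT length shorter than kernel support")
  v <- complex(length.out = N)
  v[1:(h + 1L)] <- w[(h + 1L):length(w)]
  if (h > 0) v[(N - h + 1L):N] <- w[1:h]
  K <- fft(v) / fs_hz
  if (offset != 0L) {
    k <- seq_len(N) - 1L
    K <- K * exp(2i * pi * k * offset / N)
  }
  K
}

# Contiguous circular band of the spectrum with |K| >= eps * max|K|.
# Returns list(k1 = 0-based start, kv = values). eps = 0 keeps everything.
spectral_band <- function(K, eps) {
  N <- length(K)
  if (eps <= 0) return(list(k1 = 0L, kv = K))
  a <- Mod(K)
  keep <- which(a >= eps * max(a))
  if (length(keep) == N) return(list(k1 = 0L, kv = K))
  gaps <- diff(c(keep, keep[1] + N))
  g <- which.max(gaps)
  start <- if (g == length(keep)) keep[1] else keep[g + 1L]
  len <- N - max(gaps) + 1L
  idx <- ((start - 1L) + seq_len(len) - 1L) %% N + 1L
  list(k1 = start - 1L, kv = K[idx])
}

#' Per-trial Morlet wavelet power maps
#'
#' Computes, for every trial and channel of an epochs object, the squared
#' magnitude of the convolution with the Morlet kernel at every frequency of
#' the grid. The convolution is exact linear convolution over the
#' zero-padded epoch, evaluated in the Fourier domain; edge-contaminated
#' samples are expected to be discarded later by [tf_crop()].
#'
#' @param epochs An [ieeg_epochs()] object spanning the full analysis epoch.
#' @param p A [wavelet_params()] object (its `fs_hz` must match the epochs).
#' @param out_times_ms Optional evenly spaced subset of sample times at
#'   which power is returned (decimated output); `NULL` keeps every sample.
#' @param spectrum_eps Relative threshold below which kernel spectrum bins
#'   are dropped; 0 (default) keeps the computation exact, small values
#'   (e.g. 1e-7) speed up batch analyses with negligible error.
#' @param chunk Number of observations transformed per FFT block.
#' @return A `tf_stack`: list with `power` array `[time, freq, obs]`,
#'   `times_ms`, `freqs_hz`, an `obs` data frame (participant, trial,
#'   channel, hemisphere and condition factors), and `stage = "raw_power"`.
#' @export
tf_power <- function(epochs, p = wavelet_params(), out_times_ms = NULL,
                     spectrum_eps = 0, chunk = 512L) {
  stopifnot(inherits(epochs, "ieeg_epochs"))
  if (!isTRUE(all.equal(p$fs_hz, epochs$fs_hz)))
    stop_cfg("wavelet_params fs_hz does not match the epochs")
  times <- epoch_times(epochs)
  n <- length(times)
  dms <- 1000 / epochs$fs_hz
  if (is.null(out_times_ms)) out_times_ms <- times
  idx0 <- round((out_times_ms - times[1]) / dms)
  if (any(abs(times[1] + idx0 * dms - out_times_ms) > 1e-6) ||
      any(idx0 < 0 | idx0 >= n))
    stop_cfg("out_times_ms must be sample times inside the epoch")
  m <- 1L
  if (length(idx0) > 1L) {
    steps <- unique(diff(idx0))
    if (length(steps) != 1L)
      stop_cfg("out_times_ms must be evenly spaced")
    m <- as.integer(steps)
  }
  offset <- as.integer(idx0[1] %% m)
  kernels <- lapply(p$freqs_hz, morlet_kernel, p = p)
  klen <- vapply(kernels, length, 1L)
  if (max(klen) > n)
    stop_cfg("epoch (", n, " samples) shorter than kernel support (",
             max(klen), " samples) at ", p$freqs_hz[which.max(klen)], " Hz")
  # FFT length: smallest m * 2^k that holds the full linear convolution,
  # so the decimated frame length N/m is integral and N stays FFT-friendly.
  Nf <- m * vapply(klen, function(L) nextn(as.integer(ceiling((n + L - 1L) / m)), 2), 1)
  ntrial <- dim(epochs$data)[1]
  nchan <- dim(epochs$data)[2]
  nobs <- ntrial * nchan
  nout <- length(idx0)
  nfreq <- length(p$freqs_hz)
  pow <- array(NA_real_, c(nout, nfreq, nobs))

  for (N in sort(unique(Nf))) {
    fi <- which(Nf == N)
    bands <- lapply(fi, function(i) {
      spectral_band(kernel_spectrum(kernels[[i]], N, p$fs_hz, offset), spectrum_eps)
    })
    k1 <- vapply(bands, `[[`, 0L, "k1")
    kv <- lapply(bands, `[[`, "kv")
    out_idx <- as.integer((idx0 - offset) / m)
    for (j0 in seq(1L, nobs, by = chunk)) {
      j1 <- min(j0 + chunk - 1L, nobs)
      sig <- matrix(0, N, j1 - j0 + 1L)
      for (j in j0:j1) {
        tr <- (j - 1L) %% ntrial + 1L
        ch <- (j - 1L) %/% ntrial + 1L
        sig[seq_len(n), j - j0 + 1L] <- epochs$data[tr, ch, ]
      }
      res <- tf_power_core(sig, k1, kv, m, out_idx)
      dim(res) <- c(nout, length(fi), j1 - j0 + 1L)
      pow[, fi, j0:j1] <- res
    }
  }
  obs <- data.frame(
    participant = epochs$participant_id,
    trial_id = rep(if (!is.null(epochs$events)) epochs$events$trial_id
                   else seq_len(ntrial), nchan),
    channel = rep(epochs$channels$label, each = ntrial),
    hemisphere = rep(epochs$channels$hemisphere, each = ntrial),
    stringsAsFactors = FALSE)
  if (!is.null(epochs$events)) {
    for (colnm in c("stimulus_type", "first_direction", "second_direction",
                    "is_target"))
      obs[[colnm]] <- rep(epochs$events[[colnm]], nchan)
  }
  structure(list(power = pow, times_ms = out_times_ms, freqs_hz = p$freqs_hz,
                 obs = obs, stage = "raw_power"),
            class = "tf_stack")
}

#' @export
print.tf_stack <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("tf_stack [%s]: %d times x %d freqs x %d observations\n",
              x$stage, d[1], d[2], d[3]))
  invisible(x)
}

#' Crop a time-frequency stack in time
#'
#' Restricts the maps to `[t_lo, t_hi]`, the standard way of discarding
#' wavelet edge effects after a full-epoch decomposition.
#'
#' @param stack A `tf_stack`.
#' @param t_lo,t_hi Crop window in ms (inclusive). Defaults -200 and 500.
#' @return The cropped `tf_stack`.
#' @export
tf_crop <- function(stack, t_lo = -200, t_hi = 500) {
  if (t_lo < min(stack$times_ms) - 1e-9 || t_hi > max(stack$times_ms) + 1e-9)
    stop_cfg("crop window outside the computed time range")
  keep <- which(stack$times_ms >= t_lo - 1e-9 & stack$times_ms <= t_hi + 1e-9)
  if (!length(keep)) stop_cfg("empty crop window")
  stack$power <- stack$power[keep, , , drop = FALSE]
  stack$times_ms <- stack$times_ms[keep]
  stack
}

#' Log transform and per-frequency baseline correction
#'
#' Converts each map to log power expressed relative to its own pre-stimulus
#' baseline, separately for each frequency. With `method = "log_mean"` (the
#' default) the corrected value is `ln(power) - ln(mean baseline power)`,
#' i.e. the log power ratio against the mean baseline power of that trial
#' and frequency. `method = "mean_log"` subtracts the mean of the log
#' baseline power instead, which makes corrected stationary noise exactly
#' zero-mean (the log-of-mean form carries a common negative offset from
#' Jensen's inequality that cancels in condition contrasts).
#'
#' @param stack A raw-power `tf_stack`.
#' @param baseline_ms Baseline window, default `c(-200, 0)`.
#' @param method `"log_mean"` (default) or `"mean_log"`.
#' @return The corrected stack, `stage = "log_baseline_corrected"`.
#' @export
log_baseline_correct <- function(stack, baseline_ms = c(-200, 0),
                                 method = c("log_mean", "mean_log")) {
  method <- match.arg(method)
  if (!identical(stack$stage, "raw_power"))
    stop_cfg("stack is not raw power (stage = ", stack$stage, ")")
  bidx <- which(stack$times_ms >= baseline_ms[1] - 1e-9 &
                  stack$times_ms <= baseline_ms[2] + 1e-9)
  if (!length(bidx)) stop_cfg("baseline window outside the time axis")
  d <- dim(stack$power)
  bl <- stack$power[bidx, , , drop = FALSE]
  if (any(bl == 0) && method == "mean_log")
    stop_cfg("zero baseline power; add a noise floor before log correction")
  lbl <- if (method == "log_mean") {
    mb <- colMeans(matrix(bl, length(bidx), d[2] * d[3]))
    if (any(mb == 0))
      stop_cfg("zero mean baseline power at some frequency; ",
               "add a noise floor before log correction")
    log(mb)
  } else {
    colMeans(matrix(log(bl), length(bidx), d[2] * d[3]))
  }
  stack$power <- log(stack$power) - rep(lbl, each = d[1])
  dim(stack$power) <- d
  stack$stage <- "log_baseline_corrected"
  stack
}

# Concatenate per-participant stacks along the observation axis.
tf_bind <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  s1 <- stacks[[1]]
  if (length(stacks) == 1L) return(s1)
  for (s in stacks[-1]) {
    stopifnot(isTRUE(all.equal(s$times_ms, s1$times_ms)),
              isTRUE(all.equal(s$freqs_hz, s1$freqs_hz)),
              identical(s$stage, s1$stage))
  }
  d <- dim(s1$power)
  s1$power <- array(unlist(lapply(stacks, function(s) as.vector(s$power))),
                    c(d[1], d[2],
                      sum(vapply(stacks, function(s) dim(s$power)[3], 1L))))
  s1$obs <- do.call(rbind, lapply(stacks, `[[`, "obs"))
  rownames(s1$obs) <- NULL
  s1
}
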