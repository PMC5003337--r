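test_that("Morlet kernels have the closed-form spread and unit energy", {
  p <- wavelet_params(fs_hz = 1000)
  w <- morlet_kernel(100, p)
  expect_equal(attr(w, "sigma_t_ms"), 7000 / (2 * pi * 100), tolerance = 1e-12)
  for (f in c(4, 55, 121, 299)) {
    wf <- morlet_kernel(f, p)
    expect_equal(sum(Mod(wf)^2) / 1000, 1, tolerance = 1e-12)
    expect_lt(Mod(sum(wf)), 1e-3 * sum(Mod(wf)))
  }
  expect_error(morlet_kernel(500, p), "Nyquist")
  expect_error(wavelet_params(freqs_hz = c(10, 600)), "Nyquist")
})

test_that("a pure sinusoid peaks at its own frequency", {
  fs <- 1000
  t <- seq(0, 0.999, by = 1 / fs)
  x <- sin(2 * pi * 50 * t)
  eps <- make_epochs(1L, 1L, length(t), t0 = 0,
                     fill = function(n) rep(x, length.out = n))
  p <- wavelet_params(freqs_hz = seq(20, 120, by = 2), fs_hz = fs)
  st <- tf_power(eps, p)
  mid <- st$times_ms > 200 & st$times_ms < 800   # away from edges
  prof <- colMeans(st$power[mid, , 1])
  expect_equal(st$freqs_hz[which.max(prof)], 50)
  # scaling the signal by c scales power by c^2
  eps2 <- eps; eps2$data <- eps$data * 3
  st2 <- tf_power(eps2, p)
  expect_equal(st2$power, st$power * 9, tolerance = 1e-12)
  # zero signal -> zero power
  eps0 <- eps; eps0$data[] <- 0
  expect_true(all(tf_power(eps0, p)$power == 0))
})

test_that("impulse response width matches the time-frequency uncertainty", {
  fs <- 1000
  eps <- make_epochs(1L, 1L, 1200L, t0 = -600,
                     fill = function(n) {x <- rep(0, n); x[600] <- 1; x})
  p <- wavelet_params(freqs_hz = c(40, 100, 200), fs_hz = fs)
  st <- tf_power(eps, p)
  for (fi in seq_along(p$freqs_hz)) {
    prof <- st$power[, fi, 1]
    half <- prof >= max(prof) / 2
    fwhm_obs <- diff(range(st$times_ms[half])) + 1
    sigma_t <- 1000 * p$n_cycles / (2 * pi * p$freqs_hz[fi])
    fwhm_theory <- 2 * sqrt(2 * log(2)) * sigma_t / sqrt(2)
    expect_equal(fwhm_obs, fwhm_theory, tolerance = 0.05)
  }
})

test_that("cropping counts samples and rejects bad windows", {
  st <- as_tf_stack(array(1, c(3001, 2, 1)), seq(-1000, 2000), c(10, 20))
  cr <- tf_crop(st)
  expect_equal(dim(cr$power)[1], 701L)
  expect_equal(range(cr$times_ms), c(-200, 500))
  expect_equal(tf_crop(st, -1000, 2000)$power, st$power)
  expect_error(tf_crop(st, -1500, 500), "outside")
})

test_that("decimated output equals subsampled exact output", {
  set.seed(8)
  eps <- make_epochs(2L, 1L, 801L, t0 = -400)
  p <- wavelet_params(freqs_hz = c(30, 80, 150), fs_hz = 1000)
  full <- tf_power(eps, p)
  dec <- tf_power(eps, p, out_times_ms = seq(-200, 392, by = 4))
  keep <- match(dec$times_ms, full$times_ms)
  expect_equal(dec$power, full$power[keep, , , drop = FALSE], tolerance = 1e-12)
})

test_that("log baseline correction has the closed-form values", {
  # power doubled after stimulus -> ln 2 exactly under log_mean
  pw <- array(1, c(10, 3, 2))
  pw[6:10, , ] <- 2
  st <- as_tf_stack(pw, times_ms = seq(-200, 250, by = 50), freqs_hz = c(5, 10, 20))
  cor <- log_baseline_correct(st, baseline_ms = c(-200, 0))
  expect_equal(cor$power[6, 2, 1], log(2))
  expect_true(all(abs(cor$power[1:5, , ]) < 1e-12))
  expect_equal(cor$stage, "log_baseline_corrected")
  # equal power everywhere -> 0 everywhere
  st0 <- as_tf_stack(array(3.7, c(10, 2, 1)), seq(-200, 250, 50), c(5, 10))
  expect_true(all(log_baseline_correct(st0)$power == 0))
  # zero baseline power errors with guidance
  stz <- as_tf_stack(array(0, c(10, 1, 1)), seq(-200, 250, 50), 5)
  expect_error(log_baseline_correct(stz), "noise floor")
  # double correction is refused
  expect_error(log_baseline_correct(cor), "not raw power")
})

test_that("corrected stationary noise is zero-mean under mean_log and has
          unbiased condition differences under log_mean", {
  set.seed(9)
  n <- 500L
  eps <- make_epochs(n, 1L, 600L, t0 = -300,
                     fill = function(k) rnorm(k, sd = 20))
  p <- wavelet_params(freqs_hz = c(30, 90, 180), fs_hz = 1000)
  st <- tf_power(eps, p, out_times_ms = seq(-200, 296, by = 4))
  ml <- log_baseline_correct(st, method = "mean_log")
  post <- ml$times_ms > 50
  for (fi in 1:3) {
    v <- apply(ml$power[post, fi, ], 2, mean)   # per-trial mean post-stim
    se <- sd(v) / sqrt(n)
    expect_lt(abs(mean(v)), 3 * se + 0.02)
  }
  # under the default log-mean rule, two halves of the trials (a null
  # condition split) differ by ~0 even though the grand mean is offset
  lm_ <- log_baseline_correct(st, method = "log_mean")
  v <- apply(lm_$power[post, 2, ], 2, mean)
  g1 <- v[1:250]; g2 <- v[251:500]
  se <- sd(v) * sqrt(2 / 250)
  expect_lt(abs(mean(g1) - mean(g2)), 3 * se)
  expect_lt(mean(v), 0)   # Jensen offset of the log-of-mean baseline
})

test_that("smoothing preserves constants and localizes mass", {
  st <- as_tf_stack(array(2.5, c(30, 10, 2)), seq(0, 290, 10), seq(10, 100, 10),
                    stage = "log_baseline_corrected")
  sm <- smooth_images(st, fwhm_ms = 30, fwhm_hz = 20)
  expect_equal(sm$power, st$power, tolerance = 1e-12)
  imp <- st; imp$power[] <- 0; imp$power[15, 5, ] <- 1
  smi <- smooth_images(imp, fwhm_ms = 30, fwhm_hz = 20)
  expect_equal(sum(smi$power[, , 1]), 1, tolerance = 1e-6)
  expect_equal(which.max(smi$power[, 5, 1]), 15L)
})
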