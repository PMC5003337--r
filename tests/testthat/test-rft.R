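# Residual images with a known Gaussian smoothness, wrapped as a fitted
# model so the smoothness estimator can be checked against ground truth.
smooth_noise_fit <- function(nimg, nt, nf, fwhm_px, seed = 1) {
  set.seed(seed)
  U <- matrix(rnorm(nimg * nt * nf), nimg, nt * nf)
  if (fwhm_px > 0) {
    G1 <- tfspm:::gauss_smoother(seq_len(nt), fwhm_px)
    G2 <- tfspm:::gauss_smoother(seq_len(nf), fwhm_px)
    for (i in seq_len(nimg)) {
      img <- matrix(U[i, ], nt, nf)
      U[i, ] <- as.vector(G1 %*% img %*% t(G2))
    }
  }
  nrm <- sqrt(colSums(U^2))
  U <- U / rep(nrm, each = nimg)
  structure(list(resid_std = U,
                 geom = list(times_ms = seq_len(nt), freqs_hz = seq_len(nf),
                             dims = c(nt, nf))),
            class = "tf_glm")
}

test_that("smoothness estimation recovers a known applied FWHM", {
  fit <- smooth_noise_fit(60, 120, 100, fwhm_px = 20)
  sm <- estimate_smoothness(fit)
  expect_lt(abs(sm$fwhm_px[1] - 20) / 20, 0.15)
  expect_lt(abs(sm$fwhm_px[2] - 20) / 20, 0.15)
  # unsmoothed white noise: FWHM in the 1-2 pixel range (clamped at 1)
  fit0 <- smooth_noise_fit(60, 80, 80, fwhm_px = 0)
  sm0 <- estimate_smoothness(fit0)
  expect_true(all(sm0$fwhm_px >= 1 & sm0$fwhm_px <= 2))
  # resel count follows the box formula
  expect_equal(unname(sm$resels["R2"]),
               (119 / sm$fwhm_px[1]) * (99 / sm$fwhm_px[2]))
  expect_error(estimate_smoothness(
    structure(list(resid_std = matrix(0, 4, 9),
                   geom = list(times_ms = 1:3, freqs_hz = 1:3,
                               dims = c(3L, 3L))), class = "tf_glm")),
    "constant")
})

test_that("pixel size cancels out of physical smoothness and resels", {
  fit <- smooth_noise_fit(40, 100, 80, fwhm_px = 10)
  sm1 <- estimate_smoothness(fit)
  fit2 <- fit
  fit2$geom$times_ms <- fit$geom$times_ms * 2   # coarser physical sampling
  sm2 <- estimate_smoothness(fit2)
  expect_equal(sm2$fwhm_physical[1], 2 * sm1$fwhm_physical[1])
  expect_equal(sm2$resels, sm1$resels)
})

test_that("cluster-level p is monotone in extent and the table is ordered", {
  df <- 500
  u <- qt(0.999, df)
  resels <- c(R0 = 1, R1 = 30, R2 = 200)
  ks <- c(0.1, 0.5, 1, 2, 5)
  ps <- vapply(ks, tfspm:::rft_cluster_p, 0, u = u, df = df, resels = resels)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
  # EC densities approach the Gaussian forms at large df
  for (d in 0:2)
    expect_equal(tfspm:::ec_density_t(3, 1e7, d),
                 c(pnorm(3, lower.tail = FALSE),
                   sqrt(4 * log(2)) / (2 * pi) * exp(-4.5),
                   4 * log(2) / (2 * pi)^1.5 * 3 * exp(-4.5))[d + 1],
                 tolerance = 1e-3)
})

test_that("cluster tables report peaks, extents and sizes consistently", {
  tvals <- matrix(0, 30, 20)
  tvals[10:14, 5:8] <- 5          # one block cluster
  tvals[12, 6] <- 7               # interior peak
  tvals[25, 15] <- 6              # isolated pixel cluster
  stat <- structure(list(values = tvals, times_ms = seq(0, 290, 10),
                         freqs_hz = seq(10, 200, 10), df = 1000,
                         label = "demo"), class = "stat_image")
  sm <- list(fwhm_px = c(3, 3), resels = c(R0 = 1, R1 = 29 / 3 + 19 / 3,
                                           R2 = (29 * 19) / 9))
  tab <- cluster_inference(stat, sm, height_p = 0.001)
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$p_fwe) >= 0))
  big <- tab[tab$n_pixels == 20, ]
  expect_equal(big$peak_time_ms, 110)   # row 12 -> time 110
  expect_equal(big$peak_freq_hz, 60)
  expect_equal(big$peak_T, 7)
  expect_equal(c(big$time_lo_ms, big$time_hi_ms), c(90, 130))
  expect_equal(c(big$freq_lo_hz, big$freq_hi_hz), c(50, 80))
  expect_equal(big$cluster_size_ms_hz, 20 * 10 * 10)
  # all-zero map: empty table, no error
  stat0 <- stat; stat0$values[] <- 0
  expect_equal(nrow(cluster_inference(stat0, sm)), 0L)
  # pre-window pixels (NA-masked) never enter clusters
  stat$values[1:5, ] <- NA
  tab2 <- cluster_inference(stat, sm)
  expect_true(all(tab2$time_lo_ms >= 50))
  stat2 <- stat; stat2$df <- 2
  expect_error(cluster_inference(stat2, sm), "exceed")
})

test_that("connectivity choice changes diagonal cluster merging", {
  tvals <- matrix(0, 6, 6)
  tvals[cbind(1:4, 1:4)] <- 9     # diagonal line
  lab8 <- label_components(tvals, 3, 8L)
  lab4 <- label_components(tvals, 3, 4L)
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 4L)
  expect_equal(max_cluster_extent(tvals, 3, 8L), 4L)
  expect_equal(max_cluster_extent(tvals, 3, 4L), 1L)
})

test_that("report rendering matches the peak/extent table layout", {
  tab <- data.frame(peak_time_ms = 226, peak_freq_hz = 121, peak_T = 5.36,
                    time_lo_ms = 215, time_hi_ms = 236, freq_lo_hz = 101,
                    freq_hi_hz = 150, n_pixels = 705,
                    cluster_size_ms_hz = 705, p_fwe = 0.001,
                    significant = TRUE)
  class(tab) <- c("cluster_table", "data.frame")
  out <- format_cluster_report(tab, "Main effect of stimulus type")
  expect_match(out, "215-236")
  expect_match(out, "101-150")
  expect_match(out, "226\t121\t5.36")
  empty <- tab[0, ]
  expect_match(format_cluster_report(empty, "Interaction"), "none")
})

test_that("the permutation oracle is seed-stable and degenerate-safe", {
  set.seed(31)
  sched <- build_trial_schedule(tiny_design_cfg(n_reps = 6L), seed = 1)
  eps <- simulate_epochs(sched, seed = 2, n_participants = 2L)[[1]]
  st <- erp_images(eps, out_times_ms = seq(-200, 500, 20))
  st <- apply_explicit_mask(st, c(0, 500))
  des <- build_design(st$obs, "first")
  ctr <- table_contrasts()$main_type
  a <- permutation_oracle(st, des, ctr, n_perm = 120, seed = 7)
  b <- permutation_oracle(st, des, ctr, n_perm = 120, seed = 7)
  expect_identical(a$max_extent_null, b$max_extent_null)
  expect_warning(permutation_oracle(st, des, ctr, n_perm = 50, seed = 1),
                 "coarse")
  # p-values obey the add-one rank formula against the returned null
  if (nrow(a$observed) > 0) {
    recomputed <- vapply(a$observed$n_pixels, function(k)
      (1 + sum(a$max_extent_null >= k)) / 121, 0)
    expect_equal(a$observed$p_fwe_perm, recomputed)
  }
  # permutations that cannot alter any label reproduce the observed field:
  # identical trial data make every relabelled statistic identical, so no
  # permuted maximum can fall below the observed one
  wave <- sin(seq_len(400) / 20)
  eps1 <- ieeg_epochs(array(rep(wave, each = 32L), c(16L, 2L, 400L)),
                      1000, -100,
                      data.frame(label = c("L", "R"),
                                 hemisphere = c("left", "right")),
                      events = build_trial_schedule(tiny_design_cfg(n_reps = 4L),
                                                    seed = 3))
  st1 <- erp_images(eps1, out_times_ms = seq(0, 296, 8))
  des1 <- build_design(st1$obs, "first")
  o <- permutation_oracle(st1, des1, ctr, n_perm = 100, seed = 5)
  expect_true(all(o$max_extent_null == max(o$max_extent_null)))
  if (nrow(o$observed) > 0)
    expect_true(all(o$observed$p_fwe_perm == 1))
})
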