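test_that("the factorial design expands to the expected cell structure", {
  # 42 trials x 4 sequences x 2 hemispheres x 6 participants
  obs <- expand.grid(
    trial = 1:42,
    stimulus_type = c("eyes", "mosaic"),
    first_direction = c("averted", "straight"),
    hemisphere = c("left", "right"),
    participant = sprintf("S%02d", 1:6),
    stringsAsFactors = FALSE)
  obs$second_direction <- ifelse(obs$first_direction == "averted",
                                 "straight", "averted")
  # two hemisphere observations share a trial id within participant
  obs$trial_id <- rep(rep(1:168, times = 2), times = 6)
  des <- build_design(obs, "first")
  expect_equal(dim(des$X), c(2016L, 8L))
  expect_equal(unname(colSums(des$X)), rep(252, 8))
  expect_equal(unname(colSums(des$X)), as.numeric(des$n_per_cell))
  expect_equal(sum(!is.na(des$pair)), 2016L)
  # a single condition leaves other cells empty
  solo <- obs[obs$stimulus_type == "eyes" & obs$first_direction == "averted", ]
  expect_error(build_design(solo, "first"), "empty design cell")
  expect_error(build_design(within(obs, stimulus_type <- "target"), "first"),
               "target")
})

test_that("identity-covariance contrast T equals the classical pooled t", {
  set.seed(21)
  obs <- full_cell_obs(n_per_cell = 12L)
  des <- build_design(obs, "first")
  Y <- matrix(rnorm(nrow(obs) * 4), nrow(obs), 4)
  fit <- glm_fit(as_erp_stack(t(Y), 1:4, obs), des)
  # eyes vs mosaic within (averted, left): classical two-sample t with the
  # pooled 8-cell error variance
  w <- c(1, -1, rep(0, 6))
  tm <- contrast_map(fit, tf_contrast(w))
  i1 <- des$cell_of == 1; i2 <- des$cell_of == 2
  for (px in 1:4) {
    num <- mean(Y[i1, px]) - mean(Y[i2, px])
    se <- sqrt(fit$sigma2[px] * (1 / sum(i1) + 1 / sum(i2)))
    expect_equal(tm$values[px, 1], num / se, tolerance = 1e-8)
  }
  # literal two-cell design through the same fit path: equals t.test
  keep <- des$cell_of %in% 1:2
  g <- des$cell_of[keep]
  des2 <- two_cell_design(g, obs[keep, ])
  fit2 <- glm_fit(as_erp_stack(t(Y[keep, , drop = FALSE]), 1:4, obs[keep, ]),
                  des2)
  t2 <- contrast_map(fit2, tf_contrast(c(1, -1)))
  tt <- t.test(Y[keep, 2][g == 1], Y[keep, 2][g == 2], var.equal = TRUE)
  expect_equal(t2$values[2, 1], unname(tt$statistic), tolerance = 1e-10)
})

test_that("contrast maps obey linearity and degenerate guards", {
  set.seed(22)
  obs <- full_cell_obs(6L)
  des <- build_design(obs, "first")
  Y <- matrix(rnorm(nrow(obs) * 6), nrow(obs), 6)
  fit <- glm_fit(as_erp_stack(t(Y), 1:6, obs), des)
  w <- table_contrasts()$main_type$weights
  tp <- contrast_map(fit, tf_contrast(w))
  tn <- contrast_map(fit, tf_contrast(-w))
  expect_equal(tp$values, -tn$values)
  expect_true(all(contrast_map(fit, tf_contrast(rep(0, 8)))$values == 0))
  # all-zero data: betas 0 and T defined as 0
  fit0 <- glm_fit(as_erp_stack(t(Y * 0), 1:6, obs), des)
  expect_true(all(fit0$beta == 0))
  expect_true(all(contrast_map(fit0, tf_contrast(w))$values == 0))
  expect_equal(contrast_map(fit0, tf_contrast(w))$n_flagged_zero_variance, 6L)
  # adding a constant shifts betas but not zero-sum contrasts
  fitc <- glm_fit(as_erp_stack(t(Y + 10), 1:6, obs), des)
  expect_equal(fitc$beta, fit$beta + 10)
  expect_equal(contrast_map(fitc, tf_contrast(w))$values, tp$values,
               tolerance = 1e-10)
})

test_that("ReML recovers designed heteroscedasticity and dependence", {
  set.seed(23)
  obs <- full_cell_obs(25L)                      # 200 obs, unpaired
  des <- build_design(obs, "first")
  # equal variances: ratios near 1
  Y <- matrix(rnorm(nrow(obs) * 300), nrow(obs), 300)
  ns <- estimate_nonsphericity(Y, des, n_pixels = 300)
  expect_true(all(ns$lambda / mean(ns$lambda) > 0.8 &
                    ns$lambda / mean(ns$lambda) < 1.25))
  expect_lt(abs(ns$rho), 0.1)
  # 4x variance in one cell
  Y4 <- Y * ifelse(des$cell_of == 3, 2, 1)
  ns4 <- estimate_nonsphericity(Y4, des, n_pixels = 300)
  ratio <- ns4$lambda[3] / mean(ns4$lambda[-3])
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)
  expect_lte(ns4$df_effective, nrow(obs) - 8)
})

test_that("whitening with a single identity-like component is a no-op fit", {
  set.seed(24)
  obs <- full_cell_obs(10L)
  des <- build_design(obs, "first")
  Y <- matrix(rnorm(nrow(obs) * 8), nrow(obs), 8)
  stack <- as_erp_stack(t(Y), 1:8, obs)
  ns <- estimate_nonsphericity(Y, des, n_pixels = 8)
  f_ols <- glm_fit(stack, des)
  f_wht <- glm_fit(stack, des, nonsph = ns)
  # homoscedastic data: whitening rescales but T statistics agree closely
  w <- table_contrasts()$main_type
  expect_equal(contrast_map(f_wht, w)$values, contrast_map(f_ols, w)$values,
               tolerance = 0.05)
  expect_equal(f_wht$df, nrow(Y) - 8)
})

test_that("Satterthwaite df decreases monotonically with heterogeneity", {
  obs <- full_cell_obs(10L)
  des <- build_design(obs, "first")
  ratios <- c(1, 2, 4, 8, 16)
  dfs <- vapply(ratios, function(r) {
    lam <- rep(1, 8); lam[1] <- r
    names(lam) <- des$cells$label
    ns <- structure(list(lambda = lam, rho = 0), class = "nonsphericity")
    satterthwaite_df(des, ns)
  }, 0)
  expect_equal(dfs[1], nrow(obs) - 8, tolerance = 1e-8)
  expect_true(all(diff(dfs) < 0))
  expect_true(all(dfs <= nrow(obs) - 8 + 1e-8))
})

test_that("explicit masking restricts the search region", {
  pw <- array(rnorm(20 * 10 * 3), c(20, 10, 3))
  st <- as_tf_stack(pw, seq(-45, 430, by = 25), seq(10, 100, by = 10),
                    stage = "log_baseline_corrected")
  m <- apply_explicit_mask(st, c(0, 500), c(4, 300))
  expect_true(all(m$times_ms >= 0))
  expect_equal(attr(m, "mask_n_pixels"), length(m$times_ms) * 10L)
  full <- apply_explicit_mask(st, c(-45, 430), c(10, 100))
  expect_equal(full$power, st$power)
  expect_error(apply_explicit_mask(st, c(600, 700)), "empty explicit mask")
})
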