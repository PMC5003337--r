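#' Estimate field smoothness from standardized residuals
#'
#' Residual-gradient estimator: the variance of the spatial partial
#' derivatives of the pixel-wise standardized residual images gives the
#' roughness per dimension, converted to FWHM via
#' `FWHM = sqrt(4 ln 2 / lambda)`. FWHM is clamped below at 1 pixel (an
#' unsmoothed field cannot be resolved below the grid). Resel counts use the
#' box formula for the rectangular search region.
#'
#' @param fit A [glm_fit()] with retained residuals.
#' @param max_images Residual images used (deterministic stride subsample);
#'   gradients from a few hundred images estimate roughness stably.
#' @return A `smoothness_estimate`: `fwhm_px` per dimension (time, and
#'   frequency for 2-D images), `fwhm_physical` (ms, Hz), `resels`
#'   (`R0..RD`), and the search-region size.
#' @export
estimate_smoothness <- function(fit, max_images = 512L) {
  if (is.null(fit$resid_std)) stop_cfg("fit has no retained residuals")
  if (nrow(fit$resid_std) < 2L) stop_cfg("need >= 2 residual images")
  dims <- fit$geom$dims
  nt <- dims[1]; nf <- dims[2]
  U <- fit$resid_std                       # obs x pixels, unit SS per pixel
  if (nrow(U) > max_images) {
    U <- U[round(seq(1L, nrow(U), length.out = max_images)), , drop = FALSE]
    # renormalize to unit sum of squares per pixel
    nrm <- sqrt(colSums(U^2))
    nrm[nrm == 0] <- 1
    U <- U / rep(nrm, each = nrow(U))
  }
  if (all(abs(U) < 1e-14)) stop_cfg("constant residuals; smoothness undefined")
  # time derivative: difference along rows of each [nt, nf] image
  A <- array(t(U), c(nt, nf, nrow(U)))
  dt <- A[-1, , , drop = FALSE] - A[-nt, , , drop = FALSE]
  g_t <- sum(dt^2) / ((nt - 1) * nf)     # summed over obs: unit-SS pixels
  fwhm_t <- max(1, sqrt(4 * log(2) / grad_to_lambda(g_t)))
  fwhm <- fwhm_t
  if (nf > 1L) {
    df_ <- A[, -1, , drop = FALSE] - A[, -nf, , drop = FALSE]
    g_f <- sum(df_^2) / (nt * (nf - 1))
    fwhm_f <- max(1, sqrt(4 * log(2) / grad_to_lambda(g_f)))
    fwhm <- c(fwhm_t, fwhm_f)
  }
  dt_ms <- if (nt > 1) diff(fit$geom$times_ms[1:2]) else 1
  df_hz <- if (nf > 1) diff(fit$geom$freqs_hz[1:2]) else NA_real_
  phys <- fwhm * c(dt_ms, df_hz)[seq_along(fwhm)]
  resels <- if (nf > 1L) {
    L1 <- (nt - 1) / fwhm[1]; L2 <- (nf - 1) / fwhm[2]
    c(R0 = 1, R1 = L1 + L2, R2 = L1 * L2)
  } else {
    c(R0 = 1, R1 = (nt - 1) / fwhm[1])
  }
  structure(list(fwhm_px = fwhm, fwhm_physical = phys, resels = resels,
                 dims = dims, method = "residual-gradient"),
            class = "smoothness_estimate")
}

# Pipeline-safe smoothness: degenerate (all-zero-residual) fits fall back
# to a unit-FWHM field, under which no suprathreshold pixels can exist
# anyway (all statistics are 0).
smoothness_or_unit <- function(fit) {
  if (all(fit$sigma2 == 0)) {
    dims <- fit$geom$dims
    fwhm <- if (dims[2] > 1L) c(1, 1) else 1
    resels <- if (dims[2] > 1L)
      c(R0 = 1, R1 = (dims[1] - 1) + (dims[2] - 1),
        R2 = (dims[1] - 1) * (dims[2] - 1))
    else c(R0 = 1, R1 = dims[1] - 1)
    return(structure(list(fwhm_px = fwhm, fwhm_physical = fwhm,
                          resels = resels, dims = dims, method = "degenerate"),
                     class = "smoothness_estimate"))
  }
  estimate_smoothness(fit)
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("smoothness_estimate: FWHM (px) =", paste(round(x$fwhm_px, 2), collapse = " x "),
      "; resels =", round(x$resels[length(x$resels)], 2), "\n")
  invisible(x)
}

# Unbias the forward-difference gradient variance g = E[(u(x+1)-u(x))^2]
# into the derivative variance lambda of the continuous process: under a
# Gaussian autocorrelation, g = 2(1 - exp(-lambda/2)), so the naive
# identification lambda ~ g underestimates roughness for smooth fields.
grad_to_lambda <- function(g) {
  if (g >= 2 - 1e-8) return(max(g, 1e-12))
  max(-2 * log(1 - g / 2), 1e-12)
}

# Euler characteristic densities of a T field (Worsley), d = 0, 1, 2.
ec_density_t <- function(u, df, d) {
  if (d == 0) return(pt(u, df, lower.tail = FALSE))
  base <- (1 + u^2 / df)^(-(df - 1) / 2)
  if (d == 1) return(sqrt(4 * log(2)) / (2 * pi) * base)
  if (d == 2) {
    cst <- exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2)
    return(4 * log(2) / (2 * pi)^1.5 * cst * u * base)
  }
  stop_cfg("EC density implemented for d <= 2 only")
}

# Cluster-level FWE p for an excursion of k_resels at height u (T field),
# via the Poisson clumping heuristic with RFT expected cluster counts.
rft_cluster_p <- function(k_resels, u, df, resels) {
  D <- length(resels) - 1L
  Em <- sum(resels * vapply(0:D, function(d) ec_density_t(u, df, d), 0))
  EN <- ec_density_t(u, df, 0) * resels[length(resels)]
  if (Em <= 0 || EN <= 0) return(1)
  beta <- (gamma(D / 2 + 1) * Em / EN)^(2 / D)
  Pnk <- exp(-beta * k_resels^(2 / D))
  1 - exp(-Em * Pnk)
}

#' Cluster-level random-field-theory inference on a statistic image
#'
#' Thresholds the T image at the value whose upper-tail probability under
#' Student t(df) equals `height_p`, labels connected suprathreshold
#' components, and assigns each cluster a family-wise-error-corrected
#' p-value from the random-field-theory cluster-extent distribution for a T
#' field with the estimated smoothness. Works on 2-D time-frequency and 1-D
#' sensor-time images.
#'
#' @param stat A [contrast_map()] `stat_image` (NA pixels are outside the
#'   search region).
#' @param smoothness An [estimate_smoothness()] result.
#' @param height_p Cluster-forming (uncorrected) threshold. Default 0.001.
#' @param extent_fwe_p Cluster-level FWE threshold. Default 0.05.
#' @param connectivity 8 (default) or 4.
#' @return A `cluster_table` data frame (possibly 0-row): peak time,
#'   frequency and T, extent ranges, size in pixels and in ms x Hz,
#'   `p_fwe`, and `significant`; sorted by `p_fwe`. Attributes carry the
#'   threshold and smoothness used.
#' @export
cluster_inference <- function(stat, smoothness, height_p = 0.001,
                              extent_fwe_p = 0.05, connectivity = 8L) {
  stopifnot(inherits(stat, "stat_image"))
  if (stat$df <= 2) stop_cfg("degrees of freedom must exceed 2")
  u <- qt(1 - height_p, stat$df)
  vals <- stat$values
  vals[is.na(vals)] <- -Inf
  lab <- label_components(vals, u, as.integer(connectivity))
  nclus <- max(lab)
  is2d <- !is.null(stat$freqs_hz) && length(stat$freqs_hz) > 1L
  dt_ms <- if (length(stat$times_ms) > 1) diff(stat$times_ms[1:2]) else 1
  df_hz <- if (is2d) diff(stat$freqs_hz[1:2]) else 1
  fwhm_prod <- prod(smoothness$fwhm_px)
  rows <- lapply(seq_len(nclus), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    tv <- vals[px]
    pk <- which(tv == max(tv))
    # tie-break: earliest time, then lowest frequency
    pk <- pk[order(px[pk, 1], px[pk, 2])][1]
    k_res <- nrow(px) / fwhm_prod
    data.frame(
      peak_time_ms = stat$times_ms[px[pk, 1]],
      peak_freq_hz = if (is2d) stat$freqs_hz[px[pk, 2]] else NA_real_,
      peak_T = max(tv),
      time_lo_ms = min(stat$times_ms[px[, 1]]),
      time_hi_ms = max(stat$times_ms[px[, 1]]),
      freq_lo_hz = if (is2d) min(stat$freqs_hz[px[, 2]]) else NA_real_,
      freq_hi_hz = if (is2d) max(stat$freqs_hz[px[, 2]]) else NA_real_,
      n_pixels = nrow(px),
      cluster_size_ms_hz = nrow(px) * dt_ms * df_hz,
      p_fwe = rft_cluster_p(k_res, u, stat$df, smoothness$resels))
  })
  tab <- if (nclus) do.call(rbind, rows) else data.frame(
    peak_time_ms = numeric(0), peak_freq_hz = numeric(0), peak_T = numeric(0),
    time_lo_ms = numeric(0), time_hi_ms = numeric(0), freq_lo_hz = numeric(0),
    freq_hi_hz = numeric(0), n_pixels = integer(0),
    cluster_size_ms_hz = numeric(0), p_fwe = numeric(0))
  tab$significant <- tab$p_fwe < extent_fwe_p
  tab <- tab[order(tab$p_fwe), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "height_threshold_T") <- u
  attr(tab, "height_p") <- height_p
  attr(tab, "extent_fwe_p") <- extent_fwe_p
  attr(tab, "smoothness") <- smoothness
  attr(tab, "label") <- stat$label
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' Permutation oracle for cluster-level inference
#'
#' Non-parametric validation of the analytic cluster inference: condition
#' labels (stimulus type x direction) are permuted across trials within each
#' participant (both hemisphere observations of a trial keep a common
#' label), the T image is recomputed under each relabelling, and the null
#' distribution of the maximum suprathreshold cluster extent yields
#' family-wise-corrected cluster p-values by rank.
#'
#' @param stack Masked, baseline-corrected `tf_stack` or `erp_stack`.
#' @param design A [build_design()] for the observed labels.
#' @param contrast A [tf_contrast()].
#' @param nonsph Optional non-sphericity estimate (whitening is held fixed
#'   across permutations).
#' @param n_perm Number of permutations. Default 199; fewer than 100 draws
#'   a warning.
#' @param height_p Cluster-forming threshold. Default 0.001.
#' @param connectivity 8 or 4.
#' @param seed Integer seed.
#' @return List: `max_extent_null` (pixel counts, one per permutation),
#'   `observed` cluster table with permutation `p_fwe_perm`, and the
#'   T threshold used.
#' @export
permutation_oracle <- function(stack, design, contrast, nonsph = NULL,
                               n_perm = 199L, height_p = 0.001,
                               connectivity = 8L, seed = NULL) {
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  if (!inherits(contrast, "tf_contrast")) contrast <- tf_contrast(contrast)
  Y <- stack_matrix(stack)
  Yw <- whiten_rows(Y, design, nonsph)
  dims <- if (inherits(stack, "erp_stack"))
    c(length(stack$times_ms), 1L) else dim(stack$power)[1:2]
  obs <- design$obs
  df <- if (is.null(nonsph)) nrow(Y) - ncol(design$X) else nonsph$df_effective
  u <- qt(1 - height_p, df)
  w <- contrast$weights

  tmap_for <- function(cell_of) {
    X <- matrix(0, nrow(obs), 8L)
    X[cbind(seq_len(nrow(obs)), cell_of)] <- 1
    Xw <- whiten_rows(X, design, nonsph)
    XtXi <- solve(crossprod(Xw))
    beta <- XtXi %*% crossprod(Xw, Yw)
    tot <- colSums(Yw^2)
    Rss <- tot - colSums((crossprod(Xw, Yw)) * beta)
    Rss[Rss <= 1e-12 * pmax(tot, 1e-300)] <- 0
    sigma2 <- pmax(Rss, 0) / df
    num <- as.vector(crossprod(w, beta))
    den <- sqrt(sigma2 * as.numeric(t(w) %*% XtXi %*% w))
    tv <- ifelse(den > 0, num / den, 0)
    matrix(tv, dims[1], dims[2])
  }

  t_obs <- tmap_for(design$cell_of)
  lab <- label_components(t_obs, u, as.integer(connectivity))
  obs_sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)

  # trial-level label permutation within participant: permute the condition
  # (type x direction) carried by each trial, holding hemisphere fixed.
  trial_key <- paste(obs$participant, obs$trial_id)
  first_of_trial <- !duplicated(trial_key)
  trial_part <- obs$participant[first_of_trial]
  trial_cell <- design$cell_of[first_of_trial]          # includes hemisphere
  trial_cond <- (trial_cell - 1L) %% 4L                 # type x direction part
  obs_trial <- match(trial_key, trial_key[first_of_trial])
  hemi_part <- (design$cell_of - 1L) %/% 4L             # 0 left, 1 right

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm_cond <- trial_cond
      for (pp in unique(trial_part)) {
        ix <- which(trial_part == pp)
        perm_cond[ix] <- perm_cond[sample(ix)]
      }
      cell_perm <- perm_cond[obs_trial] + 4L * hemi_part + 1L
      max_cluster_extent(tmap_for(cell_perm), u, as.integer(connectivity))
    }, 0L)
  })
  p_perm <- vapply(obs_sizes, function(k)
    (1 + sum(null_max >= k)) / (n_perm + 1), 0)
  list(max_extent_null = null_max,
       observed = data.frame(n_pixels = obs_sizes, p_fwe_perm = p_perm),
       height_threshold_T = u)
}

#' Render a cluster table in the style of a peak/extent results table
#'
#' One row per significant cluster with peak time, frequency and T-value,
#' extent ranges and cluster size (ms x Hz); "none" when no cluster survives.
#'
#' @param tab A [cluster_inference()] `cluster_table`.
#' @param label Contrast label printed as the row header.
#' @return Character vector of report lines.
#' @export
format_cluster_report <- function(tab, label = attr(tab, "label") %||% "contrast") {
  sig <- tab[tab$significant, , drop = FALSE]
  if (!nrow(sig)) return(sprintf("%s\tnone", label))
  fmt_rng <- function(lo, hi) sprintf("%g-%g", lo, hi)
  lines <- sprintf("%s\t%g\t%g\t%.2f\t%s\t%s\t%g",
                   c(label, rep("", nrow(sig) - 1L)),
                   sig$peak_time_ms, sig$peak_freq_hz, sig$peak_T,
                   fmt_rng(sig$time_lo_ms, sig$time_hi_ms),
                   fmt_rng(sig$freq_lo_hz, sig$freq_hi_hz),
                   sig$cluster_size_ms_hz)
  lines
}

#' Write a cluster table as TSV
#' @param tab A `cluster_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
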