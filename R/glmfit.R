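#' Restrict a stack to the analysis search window (explicit mask)
#'
#' Keeps only the pixels inside the post-stimulus time window and frequency
#' band over which statistical inference is performed; everything outside is
#' excluded from estimation and from the cluster search region.
#'
#' @param stack A `tf_stack` (or an `erp_stack`, time window only).
#' @param time_window Analysis window in ms, default `c(0, 500)`.
#' @param freq_window Analysis band in Hz, default `c(4, 300)`.
#' @return The masked object; attribute `"mask_n_pixels"` records the
#'   search-region size.
#' @export
apply_explicit_mask <- function(stack, time_window = c(0, 500),
                                freq_window = c(4, 300)) {
  ti <- which(stack$times_ms >= time_window[1] - 1e-9 &
                stack$times_ms <= time_window[2] + 1e-9)
  if (!length(ti)) stop_cfg("empty explicit mask (time window)")
  if (inherits(stack, "erp_stack")) {
    stack$values <- stack$values[ti, , drop = FALSE]
    stack$times_ms <- stack$times_ms[ti]
    attr(stack, "mask_n_pixels") <- length(ti)
    return(stack)
  }
  fi <- which(stack$freqs_hz >= freq_window[1] - 1e-9 &
                stack$freqs_hz <= freq_window[2] + 1e-9)
  if (!length(fi)) stop_cfg("empty explicit mask (frequency window)")
  stack$power <- stack$power[ti, fi, , drop = FALSE]
  stack$times_ms <- stack$times_ms[ti]
  stack$freqs_hz <- stack$freqs_hz[fi]
  attr(stack, "mask_n_pixels") <- length(ti) * length(fi)
  stack
}

# Observations x pixels data matrix of a stack (pixels in time-major order
# within frequency blocks, i.e. column-major over the [time, freq] image).
stack_matrix <- function(stack) {
  if (inherits(stack, "erp_stack")) return(t(stack$values))
  d <- dim(stack$power)
  t(matrix(stack$power, d[1] * d[2], d[3]))
}

# Drop observations (e.g. target trials) from a stack.
stack_subset_obs <- function(stack, keep) {
  if (inherits(stack, "erp_stack")) {
    stack$values <- stack$values[, keep, drop = FALSE]
  } else {
    stack$power <- stack$power[, , keep, drop = FALSE]
  }
  stack$obs <- stack$obs[keep, , drop = FALSE]
  rownames(stack$obs) <- NULL
  stack
}

#' Fit the mass-univariate GLM over a stack of images
#'
#' Pixel-wise (weighted) least squares of the cell-means model. When a
#' non-sphericity estimate is supplied and `whiten = TRUE` (the default),
#' data and design are pre-multiplied by `W = V^(-1/2)` so the error is
#' rendered i.i.d. and the pooled trial-level degrees of freedom apply; with
#' `whiten = FALSE` an ordinary fit is returned and the Satterthwaite
#' effective degrees of freedom under the estimated covariance are used.
#'
#' @param stack A masked, baseline-corrected `tf_stack` (or `erp_stack`).
#' @param design A [build_design()] aligned with the stack observations.
#' @param nonsph Optional [estimate_nonsphericity()] result.
#' @param whiten Pre-whiten with the estimated covariance. Default TRUE.
#' @param keep_residuals Retain standardized residuals for smoothness
#'   estimation. Default TRUE.
#' @return A `tf_glm` object: `beta` (cells x pixels), `sigma2`, `df`,
#'   `XtXi`, image geometry, and standardized residuals.
#' @export
glm_fit <- function(stack, design, nonsph = NULL, whiten = TRUE,
                    keep_residuals = TRUE) {
  Y <- stack_matrix(stack)
  stopifnot(nrow(Y) == nrow(design$X))
  if (qr(design$X)$rank < ncol(design$X))
    stop_cfg("design matrix is rank deficient")
  if (whiten && !is.null(nonsph)) {
    Yw <- whiten_rows(Y, design, nonsph)
    Xw <- whiten_rows(design$X, design, nonsph)
    df <- nonsph$df_effective
  } else {
    Yw <- Y
    Xw <- design$X
    df <- if (is.null(nonsph)) nrow(Y) - ncol(design$X)
          else satterthwaite_df(design, nonsph)
  }
  XtXi <- solve(crossprod(Xw))
  beta <- XtXi %*% crossprod(Xw, Yw)
  R <- Yw - Xw %*% beta
  rss <- colSums(R^2)
  # pixels the model fits perfectly (to rounding) have no usable error
  # variance: their statistics are defined as 0 and flagged
  rss[rss <= 1e-12 * pmax(colSums(Yw^2), 1e-300)] <- 0
  sigma2 <- rss / df
  resid_std <- NULL
  if (keep_residuals) {
    nrm <- sqrt(rss)
    nrm[nrm == 0] <- 1
    resid_std <- R / rep(nrm, each = nrow(R))
  }
  geom <- if (inherits(stack, "erp_stack"))
    list(times_ms = stack$times_ms, freqs_hz = NULL,
         dims = c(length(stack$times_ms), 1L))
  else list(times_ms = stack$times_ms, freqs_hz = stack$freqs_hz,
            dims = c(length(stack$times_ms), length(stack$freqs_hz)))
  structure(list(beta = beta, sigma2 = sigma2, df = df, XtXi = XtXi,
                 design = design, nonsph = nonsph, whitened = whiten,
                 resid_std = resid_std, geom = geom),
            class = "tf_glm")
}

#' @export
print.tf_glm <- function(x, ...) {
  cat(sprintf("tf_glm: %d obs, %d x %d image, df = %.1f, %s\n",
              nrow(x$design$X), x$geom$dims[1], x$geom$dims[2], x$df,
              if (x$whitened && !is.null(x$nonsph)) "ReML-whitened"
              else "OLS"))
  invisible(x)
}

#' Statistic image for a T contrast
#'
#' `T = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` pixel-wise; zero-variance
#' pixels yield T = 0 and are flagged. If the contrast carries an inclusive
#' mask, pixels failing the one-sided uncorrected mask test are set to `NA`
#' (removed from the search region).
#'
#' @param fit A [glm_fit()] object.
#' @param contrast A [tf_contrast()] (or a bare length-8 weight vector).
#' @return A `stat_image`: `values` (time x frequency T matrix), axes,
#'   `df` and the contrast label.
#' @export
contrast_map <- function(fit, contrast) {
  if (!inherits(contrast, "tf_contrast")) contrast <- tf_contrast(contrast)
  tvals <- contrast_t(fit, contrast$weights)
  if (!is.null(contrast$mask)) {
    tmask <- contrast_t(fit, contrast$mask$weights)
    thr <- qt(1 - contrast$mask$p, fit$df)
    tvals[tmask <= thr] <- NA_real_
  }
  structure(list(values = matrix(tvals, fit$geom$dims[1], fit$geom$dims[2]),
                 times_ms = fit$geom$times_ms, freqs_hz = fit$geom$freqs_hz,
                 df = fit$df, label = contrast$label,
                 n_flagged_zero_variance = sum(fit$sigma2 == 0)),
            class = "stat_image")
}

contrast_t <- function(fit, w) {
  stopifnot(length(w) == nrow(fit$beta))
  num <- as.vector(crossprod(w, fit$beta))
  den <- sqrt(fit$sigma2 * as.numeric(t(w) %*% fit$XtXi %*% w))
  tv <- ifelse(den > 0, num / den, 0)
  tv
}

#' @export
print.stat_image <- function(x, ...) {
  cat(sprintf("stat_image '%s': %d x %d, df = %.1f, max T = %.2f\n",
              x$label, nrow(x$values), ncol(x$values), x$df,
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}
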