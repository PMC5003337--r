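#' Baseline-corrected single-trial ERP line images
#'
#' Converts each trial and channel into a one-dimensional voltage trace with
#' the mean over the baseline window subtracted, the input of the
#' sensor-time (1-D) SPM analysis.
#'
#' @param epochs An [ieeg_epochs()] object.
#' @param baseline_ms Baseline window, default `c(-200, 0)`.
#' @param out_times_ms Optional evenly spaced subset of sample times kept in
#'   the images (e.g. a decimated 0--500 ms grid plus baseline).
#' @return An `erp_stack`: `values` matrix `[time, obs]` (microvolts),
#'   `times_ms`, `baseline_ms` and the observation table.
#' @export
erp_images <- function(epochs, baseline_ms = c(-200, 0), out_times_ms = NULL) {
  stopifnot(inherits(epochs, "ieeg_epochs"))
  times <- epoch_times(epochs)
  bidx <- which(times >= baseline_ms[1] - 1e-9 & times <= baseline_ms[2] + 1e-9)
  if (!length(bidx)) stop_cfg("baseline window outside the epoch")
  ntrial <- dim(epochs$data)[1]
  nchan <- dim(epochs$data)[2]
  keep <- if (is.null(out_times_ms)) seq_along(times)
          else match(round(out_times_ms, 6), round(times, 6))
  if (anyNA(keep)) stop_cfg("out_times_ms must be sample times inside the epoch")
  vals <- matrix(NA_real_, length(keep), ntrial * nchan)
  for (ch in seq_len(nchan)) {
    x <- matrix(aperm(epochs$data[, ch, , drop = FALSE], c(3, 1, 2)),
                length(times), ntrial)                   # samples x trials
    x <- x - rep(colMeans(x[bidx, , drop = FALSE]), each = nrow(x))
    vals[, (ch - 1L) * ntrial + seq_len(ntrial)] <- x[keep, , drop = FALSE]
  }
  obs <- data.frame(
    participant = epochs$participant_id,
    trial_id = rep(if (!is.null(epochs$events)) epochs$events$trial_id
                   else seq_len(ntrial), nchan),
    channel = rep(epochs$channels$label, each = ntrial),
    hemisphere = rep(epochs$channels$hemisphere, each = ntrial),
    stringsAsFactors = FALSE)
  if (!is.null(epochs$events))
    for (colnm in c("stimulus_type", "first_direction", "second_direction",
                    "is_target"))
      obs[[colnm]] <- rep(epochs$events[[colnm]], nchan)
  structure(list(values = vals, times_ms = times[keep],
                 baseline_ms = baseline_ms, obs = obs),
            class = "erp_stack")
}

#' @export
print.erp_stack <- function(x, ...) {
  cat(sprintf("erp_stack: %d times x %d observations\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Concatenate per-participant ERP stacks.
erp_bind <- function(stacks) {
  s1 <- stacks[[1]]
  if (length(stacks) == 1L) return(s1)
  s1$values <- do.call(cbind, lapply(stacks, `[[`, "values"))
  s1$obs <- do.call(rbind, lapply(stacks, `[[`, "obs"))
  rownames(s1$obs) <- NULL
  s1
}

#' Grand-average ERP traces by condition
#'
#' @param stack An `erp_stack`.
#' @param by Observation columns defining the averaging cells.
#' @return Data frame in long format: condition columns, `time_ms`,
#'   `mean_uV`, `n_obs`.
#' @export
erp_grand_average <- function(stack,
                              by = c("stimulus_type", "first_direction")) {
  g <- interaction(stack$obs[by], drop = TRUE, sep = ".")
  out <- lapply(levels(g), function(lev) {
    ix <- which(g == lev)
    cbind(stack$obs[rep(ix[1], length(stack$times_ms)), by, drop = FALSE],
          data.frame(time_ms = stack$times_ms,
                     mean_uV = rowMeans(stack$values[, ix, drop = FALSE]),
                     n_obs = length(ix), row.names = NULL))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-dimensional sensor-time SPM on ERP images
#'
#' Runs the same GLM machinery as the time-frequency arm on 1-D line
#' images: explicit 0--500 ms mask, optional ReML non-sphericity with
#' whitening, contrast T lines, 1-D random-field-theory cluster inference.
#'
#' @param stack An `erp_stack` (all participants bound together).
#' @param direction Which presentation's direction factor to use.
#' @param contrasts List of [tf_contrast()]; default [table_contrasts()].
#' @param time_window Explicit mask, default `c(0, 500)` ms.
#' @param use_nonsphericity Estimate and whiten by ReML covariance
#'   components. Default TRUE.
#' @param height_p,extent_fwe_p,connectivity Inference settings.
#' @return List with one `cluster_table` per contrast, plus the fit and
#'   smoothness estimate.
#' @export
erp_spm <- function(stack, direction = c("first", "second"),
                    contrasts = table_contrasts(), time_window = c(0, 500),
                    use_nonsphericity = TRUE, height_p = 0.001,
                    extent_fwe_p = 0.05, connectivity = 8L) {
  direction <- match.arg(direction)
  keep <- !stack$obs$is_target
  stack <- stack_subset_obs(stack, which(keep))
  masked <- apply_explicit_mask(stack, time_window = time_window)
  design <- build_design(masked$obs, direction = direction)
  nonsph <- if (use_nonsphericity)
    estimate_nonsphericity(stack_matrix(masked), design) else NULL
  fit <- glm_fit(masked, design, nonsph = nonsph)
  sm <- smoothness_or_unit(fit)
  tables <- lapply(contrasts, function(cn) {
    cluster_inference(contrast_map(fit, cn), sm, height_p = height_p,
                      extent_fwe_p = extent_fwe_p,
                      connectivity = connectivity)
  })
  list(tables = tables, fit = fit, smoothness = sm, design = design)
}
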