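#' Analysis configuration
#'
#' Collects every tunable of the time-frequency and ERP SPM pipeline.
#' Defaults: 7-cycle Morlet wavelets on a
#' 4--300 Hz grid over the full -1000--2000 ms epoch, maps cropped to
#' -200--500 ms, log baseline correction against the 200 ms pre-stimulus
#' mean, explicit 0--500 ms x 4--300 Hz mask, ReML non-sphericity with
#' whitening, cluster-forming p = 0.001 and cluster FWE p = 0.05.
#'
#' `time_step_ms` and `freq_step_hz` control the resolution of the computed
#' maps; [batch_profile()] returns a coarser, faster profile for
#' calibration batches.
#'
#' @param n_cycles,freq_range_hz,freq_step_hz Wavelet grid.
#' @param time_step_ms Output time resolution of the maps (ms).
#' @param crop_ms Cropped analysis window around the locked onset.
#' @param baseline_ms,baseline_method Baseline correction settings.
#' @param mask_time_ms,mask_freq_hz Explicit search mask.
#' @param smooth_fwhm_ms,smooth_fwhm_hz Gaussian image smoothing applied to
#'   the corrected maps before the GLM (see [smooth_images()]); 0 disables.
#' @param abs_thresh_uV,sd_thresh,reject_center Artifact rejection rules.
#' @param height_p,extent_fwe_p,mask_p,connectivity Inference settings.
#' @param use_nonsphericity Estimate ReML covariance components and whiten.
#' @param include_masked_followups Add masked simple-effect contrasts.
#' @param presentation `"first"`, `"second"` or `"both"`.
#' @param second_onset_ms Onset of the second stimulus relative to the
#'   first (ms); second-presentation epochs are re-locked here.
#' @param spectrum_eps Wavelet spectral truncation (0 = exact).
#' @param seed Seed recorded with the run.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_cycles = 7, freq_range_hz = c(4, 300),
                            freq_step_hz = 1, time_step_ms = 1,
                            crop_ms = c(-200, 500),
                            baseline_ms = c(-200, 0),
                            baseline_method = "log_mean",
                            mask_time_ms = c(0, 500),
                            mask_freq_hz = c(4, 300),
                            smooth_fwhm_ms = 24, smooth_fwhm_hz = 36,
                            abs_thresh_uV = 800, sd_thresh = 5,
                            reject_center = "both",
                            height_p = 0.001, extent_fwe_p = 0.05,
                            mask_p = 0.05, connectivity = 8L,
                            use_nonsphericity = TRUE,
                            include_masked_followups = FALSE,
                            presentation = "first", second_onset_ms = 500,
                            spectrum_eps = 0, seed = NULL) {
  stopifnot(presentation %in% c("first", "second", "both"),
            height_p > 0, height_p < 1, extent_fwe_p > 0, extent_fwe_p < 1)
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Fast coarse-resolution profile for calibration batches
#'
#' Same pipeline with maps computed on an 8 ms x 12 Hz grid and a mildly
#' truncated kernel spectrum, the resolution used for the package's
#' Monte-Carlo calibration and power runs.
#'
#' @param ... Overrides passed to [analysis_config()].
#' @return An `analysis_config`.
#' @export
batch_profile <- function(...) {
  args <- list(time_step_ms = 8, freq_step_hz = 12, spectrum_eps = 1e-5)
  override <- list(...)
  args[names(override)] <- override
  do.call(analysis_config, args)
}

#' Load an analysis configuration from YAML or JSON
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_cfg("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

tf_params_of <- function(cfg, fs_hz) {
  wavelet_params(n_cycles = cfg$n_cycles,
                 freqs_hz = seq(cfg$freq_range_hz[1], cfg$freq_range_hz[2],
                                by = cfg$freq_step_hz),
                 fs_hz = fs_hz)
}

# Time-frequency SPM for one presentation over a list of epochs objects.
analyze_tf_arm <- function(epochs_list, cfg, direction = c("first", "second")) {
  direction <- match.arg(direction)
  shift <- if (direction == "second") cfg$second_onset_ms else 0
  fs <- epochs_list[[1]]$fs_hz
  p <- tf_params_of(cfg, fs)
  out_rel <- seq(cfg$crop_ms[1], cfg$crop_ms[2], by = cfg$time_step_ms)
  stacks <- lapply(epochs_list, function(ep) {
    s <- tf_power(ep, p, out_times_ms = out_rel + shift,
                  spectrum_eps = cfg$spectrum_eps)
    s$times_ms <- s$times_ms - shift     # re-lock to the analyzed onset
    s
  })
  stack <- tf_bind(stacks)
  stack <- log_baseline_correct(stack, cfg$baseline_ms,
                                method = cfg$baseline_method)
  stack <- smooth_images(stack, cfg$smooth_fwhm_ms, cfg$smooth_fwhm_hz)
  stack <- stack_subset_obs(stack, which(!stack$obs$is_target))
  masked <- apply_explicit_mask(stack, cfg$mask_time_ms, cfg$mask_freq_hz)
  design <- build_design(masked$obs, direction = direction)
  nonsph <- if (cfg$use_nonsphericity)
    estimate_nonsphericity(stack_matrix(masked), design) else NULL
  fit <- glm_fit(masked, design, nonsph = nonsph)
  sm <- smoothness_or_unit(fit)
  contrasts <- table_contrasts(cfg$include_masked_followups, cfg$mask_p)
  tables <- lapply(contrasts, function(cn)
    cluster_inference(contrast_map(fit, cn), sm, height_p = cfg$height_p,
                      extent_fwe_p = cfg$extent_fwe_p,
                      connectivity = cfg$connectivity))
  list(tables = tables, fit = fit, smoothness = sm, design = design,
       stack = masked, direction = direction)
}

analyze_erp_arm <- function(epochs_list, cfg, direction = c("first", "second")) {
  direction <- match.arg(direction)
  shift <- if (direction == "second") cfg$second_onset_ms else 0
  out_rel <- seq(cfg$crop_ms[1], cfg$crop_ms[2], by = cfg$time_step_ms)
  stacks <- lapply(epochs_list, function(ep) {
    s <- erp_images(ep, baseline_ms = cfg$baseline_ms + shift,
                    out_times_ms = out_rel + shift)
    s$times_ms <- s$times_ms - shift
    s
  })
  stack <- erp_bind(stacks)
  stack <- smooth_images(stack, cfg$smooth_fwhm_ms, 0)
  stack <- stack_subset_obs(stack, which(!stack$obs$is_target))
  erp_spm(stack, direction = direction,
          contrasts = table_contrasts(cfg$include_masked_followups, cfg$mask_p),
          time_window = cfg$mask_time_ms,
          use_nonsphericity = cfg$use_nonsphericity,
          height_p = cfg$height_p, extent_fwe_p = cfg$extent_fwe_p,
          connectivity = cfg$connectivity)
}

#' Run the full analysis pipeline
#'
#' Artifact rejection, then the time-frequency SPM (and optionally the ERP
#' SPM) for the requested stimulus presentations, with cluster tables,
#' rejection report, text report and provenance written to a run directory
#' when `out_dir` is given. The run is deterministic given the epochs and
#' configuration.
#'
#' @param epochs_list List of [ieeg_epochs()] (one per participant), or a
#'   single epochs object.
#' @param cfg An [analysis_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param include_erp Also run the ERP arm. Default TRUE.
#' @return A `tfspm_run`: per-presentation TF and ERP results, rejection
#'   reports, and the configuration.
#' @export
run_pipeline <- function(epochs_list, cfg = analysis_config(),
                         out_dir = NULL, include_erp = TRUE) {
  if (inherits(epochs_list, "ieeg_epochs")) epochs_list <- list(epochs_list)
  cleaned <- lapply(epochs_list, function(ep)
    reject_artifacts(ep, cfg$abs_thresh_uV, cfg$sd_thresh, cfg$reject_center))
  kept <- lapply(cleaned, `[[`, "epochs")
  reports <- lapply(cleaned, `[[`, "report")
  names(reports) <- vapply(kept, `[[`, "", "participant_id")
  pres <- if (cfg$presentation == "both") c("first", "second") else cfg$presentation
  tf <- lapply(pres, function(d) analyze_tf_arm(kept, cfg, d))
  names(tf) <- pres
  erp <- NULL
  if (include_erp) {
    erp <- lapply(pres, function(d) analyze_erp_arm(kept, cfg, d))
    names(erp) <- pres
  }
  run <- structure(list(tf = tf, erp = erp, rejection = reports, config = cfg),
                   class = "tfspm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.tfspm_run <- function(x, ...) {
  for (d in names(x$tf)) {
    cat(sprintf("== %s presentation (time-frequency SPM) ==\n", d))
    for (nm in names(x$tf[[d]]$tables))
      cat(format_cluster_report(x$tf[[d]]$tables[[nm]]), sep = "\n")
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- character(0)
  for (d in names(run$tf)) {
    arm <- run$tf[[d]]
    lines <- c(lines, sprintf("# %s presentation, time-frequency SPM", d),
               "contrast\tpeak_time_ms\tpeak_freq_hz\tpeak_T\textent_time_ms\textent_freq_hz\tcluster_size_ms_hz")
    for (nm in names(arm$tables)) {
      write_cluster_table(arm$tables[[nm]],
                          file.path(out_dir, sprintf("clusters_tf_%s_%s.tsv", d, nm)))
      lines <- c(lines, format_cluster_report(arm$tables[[nm]]))
    }
    if (!is.null(run$erp)) {
      lines <- c(lines, sprintf("# %s presentation, ERP SPM", d))
      for (nm in names(run$erp[[d]]$tables)) {
        write_cluster_table(run$erp[[d]]$tables[[nm]],
                            file.path(out_dir, sprintf("clusters_erp_%s_%s.tsv", d, nm)))
        lines <- c(lines, format_cluster_report(run$erp[[d]]$tables[[nm]]))
      }
    }
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  for (pid in names(run$rejection))
    write_rejection_report(run$rejection[[pid]],
                           file.path(out_dir, sprintf("rejection_%s.json", pid)))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(run$config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  prov <- list(package = "tfspm",
               version = as.character(utils::packageVersion("tfspm")),
               r_version = R.version.string,
               config_md5 = unname(tools::md5sum(cfg_path)),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

# Jaccard overlap of a detected cluster rectangle with an injected locus.
locus_overlap <- function(row, locus) {
  it <- max(0, min(row$time_hi_ms, locus$time_ms[2]) -
              max(row$time_lo_ms, locus$time_ms[1]))
  jf <- max(0, min(row$freq_hi_hz, locus$freq_hz[2]) -
              max(row$freq_lo_hz, locus$freq_hz[1]))
  inter <- it * jf
  a1 <- (row$time_hi_ms - row$time_lo_ms) * (row$freq_hi_hz - row$freq_lo_hz)
  a2 <- diff(locus$time_ms) * diff(locus$freq_hz)
  if (a1 + a2 - inter <= 0) return(as.numeric(inter > 0))
  inter / (a1 + a2 - inter)
}

burst_locus <- function(b) {
  list(time_ms = b$center_time_ms + c(-1, 1) * b$time_fwhm_ms / 2,
       freq_hz = b$center_freq_hz + c(-1, 1) * b$freq_bandwidth_hz / 2)
}

#' Simulate and analyze a batch of synthetic datasets
#'
#' The calibration/power harness: for each of `n_datasets` seeds it builds a
#' schedule, simulates epochs, runs the time-frequency (and optionally ERP)
#' analysis for the first presentation, and records, per contrast, whether
#' any cluster is FWE-significant, the detected peak, and the overlap of the
#' best significant cluster with the injected burst locus. With
#' `permutation_contrast` set, a label-permutation test is run for that
#' contrast as well, so analytic and non-parametric significance calls can
#' be compared.
#'
#' @param n_datasets Number of datasets.
#' @param design_cfg [stimulus_set_config()] for the schedules.
#' @param effects [effect_spec()] injected into every dataset (empty spec =
#'   null datasets).
#' @param noise [noise_spec()].
#' @param cfg [analysis_config()]; [batch_profile()] is the intended choice.
#' @param n_participants Virtual participants per dataset. Default 6.
#' @param include_erp Run the ERP arm too. Default FALSE.
#' @param permutation_contrast Optional contrast name (e.g. `"main_type"`).
#' @param n_perm Permutations per dataset when enabled.
#' @param seed Master seed; dataset `d` derives its own stream.
#' @param progress Print one line per dataset.
#' @return Data frame with one row per dataset x contrast.
#' @export
simulate_and_analyze <- function(n_datasets, design_cfg = stimulus_set_config(),
                                 effects = effect_spec(), noise = noise_spec(),
                                 cfg = batch_profile(), n_participants = 6L,
                                 include_erp = FALSE,
                                 permutation_contrast = NULL, n_perm = 199L,
                                 seed = NULL, progress = FALSE) {
  stopifnot(n_datasets >= 1L)
  loci <- lapply(effects$bursts, burst_locus)
  out <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    sd_d <- child_seed(seed, d)
    sched <- build_trial_schedule(design_cfg, seed = sd_d)
    eps <- simulate_epochs(sched, effects, noise,
                           n_participants = n_participants,
                           seed = child_seed(sd_d, 1L))
    cleaned <- lapply(eps, function(ep)
      reject_artifacts(ep, cfg$abs_thresh_uV, cfg$sd_thresh,
                       cfg$reject_center)$epochs)
    arm <- analyze_tf_arm(cleaned, cfg, "first")
    erp_arm <- if (include_erp) analyze_erp_arm(cleaned, cfg, "first")
    perm_sig <- NA
    if (!is.null(permutation_contrast)) {
      po <- permutation_oracle(
        arm$stack, arm$design,
        table_contrasts(TRUE, cfg$mask_p)[[permutation_contrast]],
        nonsph = arm$fit$nonsph, n_perm = n_perm,
        height_p = cfg$height_p, connectivity = cfg$connectivity,
        seed = child_seed(sd_d, 2L))
      perm_sig <- any(po$observed$p_fwe_perm < cfg$extent_fwe_p)
    }
    rows <- lapply(names(arm$tables), function(nm) {
      tab <- arm$tables[[nm]]
      sig <- tab[tab$significant, , drop = FALSE]
      ov <- if (nrow(sig) && length(loci))
        max(vapply(seq_len(nrow(sig)), function(i)
          max(vapply(loci, function(L) locus_overlap(sig[i, ], L), 0)), 0))
      else NA_real_
      data.frame(dataset = d, contrast = nm,
                 n_sig_clusters = nrow(sig),
                 any_sig = nrow(sig) > 0,
                 peak_time_ms = if (nrow(sig)) sig$peak_time_ms[1] else NA_real_,
                 peak_freq_hz = if (nrow(sig)) sig$peak_freq_hz[1] else NA_real_,
                 peak_T = if (nrow(sig)) sig$peak_T[1] else NA_real_,
                 locus_overlap = ov,
                 erp_any_sig = if (include_erp)
                   any(erp_arm$tables[[nm]]$significant) else NA,
                 perm_any_sig = if (nm == (permutation_contrast %||% ""))
                   perm_sig else NA,
                 stringsAsFactors = FALSE)
    })
    out[[d]] <- do.call(rbind, rows)
    if (progress)
      message(sprintf("dataset %d/%d: %s", d, n_datasets,
                      paste(vapply(out[[d]]$any_sig, isTRUE, TRUE), collapse = " ")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
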