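#' Extract epochs from a continuous recording
#'
#' Cuts one epoch per event out of a continuous multi-channel recording,
#' locked to the event onset.
#'
#' @param signal Numeric matrix `samples x channels` (or a vector for a
#'   single channel), in microvolts.
#' @param fs_hz Sampling rate of `signal`.
#' @param events `event_table` with `onset_ms` relative to recording start.
#' @param window_ms Epoch window relative to each onset.
#'   Default `c(-1000, 2000)`.
#' @param channels Channel metadata data frame (`label`, `hemisphere`).
#' @param participant_id Identifier stored in the result.
#' @return An [ieeg_epochs()] object.
#' @export
extract_epochs <- function(signal, fs_hz, events,
                           window_ms = c(-1000, 2000),
                           channels = NULL, participant_id = "P01") {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  nchan <- ncol(signal)
  if (is.null(channels))
    channels <- data.frame(label = paste0("CH", seq_len(nchan)),
                           hemisphere = NA_character_,
                           stringsAsFactors = FALSE)
  step <- 1000 / fs_hz
  nsamp <- round((window_ms[2] - window_ms[1]) / step) + 1L
  dat <- array(NA_real_, c(nrow(events), nchan, nsamp))
  for (i in seq_len(nrow(events))) {
    i0 <- round((events$onset_ms[i] + window_ms[1]) / step)  # 0-based sample
    if (i0 < 0 || i0 + nsamp > nrow(signal))
      stop_cfg("epoch window for trial ", events$trial_id[i],
               " overruns the recording edge")
    dat[i, , ] <- t(signal[i0 + seq_len(nsamp), , drop = FALSE])
  }
  ieeg_epochs(dat, fs_hz = fs_hz, t0_ms = window_ms[1], channels = channels,
              participant_id = participant_id, events = events)
}

#' Artifact rejection by absolute and distributional amplitude rules
#'
#' Applies the two epoch-rejection rules in one pass:
#' \describe{
#'   \item{Rule 1 (absolute)}{a trial is rejected if any sample on any
#'     channel exceeds `abs_thresh_uV` in absolute value.}
#'   \item{Rule 2 (distributional)}{per electrode, the per-trial peak
#'     absolute amplitude is collected across the rule-1 survivors; a trial
#'     is rejected if its peak exceeds `center + sd_thresh * SD` of that
#'     distribution, where the center is the mean, the median, or (default)
#'     either of the two. A degenerate distribution (SD = 0) rejects
#'     nothing.}
#' }
#' Rejection removes the whole trial (all channels), preserving the paired
#' cross-hemisphere structure. Rule 2 is applied once, not iterated.
#'
#' @param epochs An `ieeg_epochs` object.
#' @param abs_thresh_uV Absolute-amplitude threshold. Default 800.
#' @param sd_thresh Number of SDs for rule 2. Default 5.
#' @param center `"both"` (reject if beyond either mean- or median-centered
#'   bound), `"mean"`, or `"median"`.
#' @return `list(epochs=, report=)` where `report` is a `rejection_report`
#'   with the rejected ids per rule, per-condition rejection fractions, and
#'   the thresholds used.
#' @export
reject_artifacts <- function(epochs, abs_thresh_uV = 800, sd_thresh = 5,
                             center = c("both", "mean", "median")) {
  stopifnot(inherits(epochs, "ieeg_epochs"))
  center <- match.arg(center)
  ntrial <- dim(epochs$data)[1]
  if (ntrial == 0L) stop_cfg("no trials to screen")
  # per-trial, per-channel peak absolute amplitude
  d <- dim(epochs$data)
  peak <- matrix(row_abs_max(matrix(epochs$data, d[1] * d[2], d[3])),
                 d[1], d[2])
  rej1 <- which(apply(peak, 1, max) > abs_thresh_uV)
  keep1 <- setdiff(seq_len(ntrial), rej1)
  rej2 <- integer(0)
  for (ch in seq_len(ncol(peak))) {
    p <- peak[keep1, ch]
    s <- sd(p)
    if (!is.finite(s) || s == 0) next
    lim <- c(
      if (center %in% c("both", "mean")) mean(p) + sd_thresh * s,
      if (center %in% c("both", "median")) median(p) + sd_thresh * s)
    rej2 <- union(rej2, keep1[p > min(lim)])
  }
  rej2 <- sort(rej2)
  rejected <- sort(union(rej1, rej2))
  kept <- setdiff(seq_len(ntrial), rejected)
  if (!length(kept)) stop_cfg("all trials rejected; empty after rejection")
  frac <- NULL
  if (!is.null(epochs$events)) {
    cond <- interaction(epochs$events$stimulus_type,
                        epochs$events$first_direction, drop = TRUE)
    frac <- tapply(seq_len(ntrial) %in% rejected, cond, mean)
  }
  report <- structure(list(
    rejected_ids = list(absolute = rej1, sd_rule = rej2),
    rejected_all = rejected,
    n_in = ntrial, n_kept = length(kept),
    rejection_fraction = length(rejected) / ntrial,
    rejection_fraction_by_condition = frac,
    thresholds = list(abs_thresh_uV = abs_thresh_uV, sd_thresh = sd_thresh,
                      center = center)), class = "rejection_report")
  list(epochs = subset_trials(epochs, kept), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf(
    "rejection_report: %d/%d trials rejected (%.1f%%); rule1 %d, rule2 %d\n",
    x$n_in - x$n_kept, x$n_in, 100 * x$rejection_fraction,
    length(x$rejected_ids$absolute), length(x$rejected_ids$sd_rule)))
  invisible(x)
}

#' Serialize a rejection report to JSON
#' @param report A `rejection_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rejection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
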