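#' Configuration of the two-stimulus gaze stimulus set
#'
#' Describes the stimulus set and trial timing of a two-stimulus gaze
#' paradigm: on each non-target trial a first stimulus (eyes or an
#' eye-derived mosaic, gaze averted or straight) is shown briefly and then
#' replaced by a second stimulus of the same type whose direction always
#' differs from the first, so that the second presentation carries a
#' directional change. Rare target trials (a red cross requiring a button
#' press) keep attention on the display.
#'
#' The defaults reproduce the paradigm the synthetic generator emulates:
#' 7 female + 7 male stimulus models, 3 repetitions of each of the 4
#' condition sequences, 15 target trials (42 trials per sequence, 183 trials
#' in total), 500 ms fixation, 500 ms first stimulus, 1000 ms second
#' stimulus, inter-trial interval drawn uniformly from 2000--5000 ms.
#'
#' @param n_models_female,n_models_male Number of distinct stimulus
#'   identities of each sex.
#' @param n_repetitions Presentations of each (model, sequence) combination.
#' @param n_target_trials Number of target-detection trials.
#' @param condition_sequences Data frame with columns `stimulus_type`,
#'   `first_direction`, `second_direction`; defaults to the four sequences
#'   eyes/mosaic x averted-then-straight/straight-then-averted.
#' @param iti_range_ms Inter-trial interval range in ms (uniform draw,
#'   integer ms).
#' @param fixation_ms,first_ms,second_ms Trial timing in ms.
#' @return An object of class `stimulus_set_config`.
#' @export
stimulus_set_config <- function(n_models_female = 7L, n_models_male = 7L,
                                n_repetitions = 3L, n_target_trials = 15L,
                                condition_sequences = default_sequences(),
                                iti_range_ms = c(2000, 5000),
                                fixation_ms = 500, first_ms = 500,
                                second_ms = 1000) {
  counts <- c(n_models_female = n_models_female, n_models_male = n_models_male,
              n_repetitions = n_repetitions, n_target_trials = n_target_trials)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_cfg("stimulus_set_config: counts must be non-negative")
  cs <- as.data.frame(condition_sequences, stringsAsFactors = FALSE)
  need <- c("stimulus_type", "first_direction", "second_direction")
  if (!all(need %in% names(cs)))
    stop_cfg("condition_sequences needs columns: ", paste(need, collapse = ", "))
  if (any(cs$first_direction == cs$second_direction))
    stop_cfg("first and second direction must differ within a sequence")
  if (length(iti_range_ms) != 2L || iti_range_ms[1] > iti_range_ms[2])
    stop_cfg("iti_range_ms must be (min, max)")
  structure(list(
    n_models_female = as.integer(n_models_female),
    n_models_male = as.integer(n_models_male),
    n_repetitions = as.integer(n_repetitions),
    n_target_trials = as.integer(n_target_trials),
    condition_sequences = cs,
    iti_range_ms = as.numeric(iti_range_ms),
    fixation_ms = fixation_ms, first_ms = first_ms, second_ms = second_ms
  ), class = "stimulus_set_config")
}

default_sequences <- function() {
  data.frame(
    stimulus_type = rep(c("eyes", "mosaic"), each = 2L),
    first_direction = rep(c("averted", "straight"), 2L),
    second_direction = rep(c("straight", "averted"), 2L),
    stringsAsFactors = FALSE
  )
}

#' Build a randomized trial schedule
#'
#' Expands the stimulus-set configuration into one trial per
#' (model, repetition, condition sequence), appends target trials, shuffles
#' the order uniformly, and assigns cumulative first-stimulus onsets using
#' the trial timing and uniform integer-ms inter-trial intervals.
#'
#' @param cfg A [stimulus_set_config()].
#' @param seed Integer seed controlling shuffle, ITI draws and target order.
#' @return An `event_table` data frame with columns `trial_id`,
#'   `stimulus_type` (`"eyes"`, `"mosaic"` or `"target"`), `first_direction`,
#'   `second_direction` (`"none"` on target trials), `model_id`, `onset_ms`
#'   (first-stimulus onset) and `is_target`.
#' @export
build_trial_schedule <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "stimulus_set_config"))
  n_models <- cfg$n_models_female + cfg$n_models_male
  cs <- cfg$condition_sequences
  rows <- expand.grid(model_id = seq_len(n_models),
                      rep = seq_len(cfg$n_repetitions),
                      seq = seq_len(nrow(cs)))
  tab <- data.frame(
    stimulus_type = if (nrow(rows)) cs$stimulus_type[rows$seq] else character(0),
    first_direction = if (nrow(rows)) cs$first_direction[rows$seq] else character(0),
    second_direction = if (nrow(rows)) cs$second_direction[rows$seq] else character(0),
    model_id = if (nrow(rows)) as.integer(rows$model_id) else integer(0),
    is_target = logical(nrow(rows)),
    stringsAsFactors = FALSE
  )
  if (cfg$n_target_trials > 0L) {
    tab <- rbind(tab, data.frame(
      stimulus_type = rep("target", cfg$n_target_trials),
      first_direction = "none", second_direction = "none",
      model_id = NA_integer_, is_target = TRUE, stringsAsFactors = FALSE))
  }
  n <- nrow(tab)
  tab <- with_seed(seed, {
    if (n > 1L) tab <- tab[sample.int(n), , drop = FALSE]
    iti <- if (n > 0L)
      round(runif(n, cfg$iti_range_ms[1], cfg$iti_range_ms[2])) else numeric(0)
    trial_len <- cfg$first_ms + cfg$second_ms
    # first-stimulus onset: fixation precedes each first stimulus
    onset <- cfg$fixation_ms + c(0, cumsum(trial_len + iti[-n] + cfg$fixation_ms))[seq_len(n)]
    tab$onset_ms <- if (n > 0L) onset else numeric(0)
    tab
  })
  tab <- cbind(trial_id = seq_len(n), tab)
  rownames(tab) <- NULL
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d trials (%d targets)\n",
              nrow(x), sum(x$is_target)))
  print.data.frame(head(as.data.frame(x), 8L), ...)
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Write / read an events table as tab-separated text
#'
#' The on-disk layout is a BIDS-style events TSV: `onset` and `duration` in
#' seconds followed by `trial_type` (the condition sequence collapsed to one
#' label) and the factor columns. `onset_ms` is carried as an explicit
#' integer-ms column so the round trip is lossless.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `read_events` returns the `event_table`; `write_events` its path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  out <- data.frame(
    onset = events$onset_ms / 1000,
    duration = ifelse(events$is_target, NA_real_, 1.5),
    trial_type = ifelse(events$is_target, "target",
                        paste(events$stimulus_type, events$first_direction,
                              events$second_direction, sep = "_")),
    trial_id = events$trial_id,
    onset_ms = events$onset_ms,
    stimulus_type = events$stimulus_type,
    first_direction = events$first_direction,
    second_direction = events$second_direction,
    model_id = events$model_id,
    is_target = events$is_target,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "n/a"),
    error = function(e) stop_cfg("failed to parse events TSV '", path, "': ",
                                 conditionMessage(e)))
  need <- c("trial_id", "onset_ms", "stimulus_type", "first_direction",
            "second_direction", "model_id", "is_target")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_cfg("events TSV '", path, "' lacks columns: ",
             paste(miss, collapse = ", "))
  bad <- which(!tab$is_target &
                 (is.na(tab$first_direction) | is.na(tab$second_direction) |
                    tab$first_direction == tab$second_direction))
  if (length(bad))
    stop_cfg("events TSV '", path, "': invalid directions at line ",
             bad[1] + 1L)
  out <- data.frame(
    trial_id = as.integer(tab$trial_id),
    stimulus_type = as.character(tab$stimulus_type),
    first_direction = as.character(tab$first_direction),
    second_direction = as.character(tab$second_direction),
    model_id = as.integer(tab$model_id),
    is_target = as.logical(tab$is_target),
    onset_ms = as.numeric(tab$onset_ms),
    stringsAsFactors = FALSE
  )
  # column order as produced by build_trial_schedule
  out <- out[, c("trial_id", "stimulus_type", "first_direction",
                 "second_direction", "model_id", "is_target", "onset_ms")]
  class(out) <- c("event_table", "data.frame")
  out
}
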