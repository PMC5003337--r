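#' Epoched iEEG container
#'
#' Holds a trials x channels x samples voltage array (microvolts) together
#' with its sampling rate, the time of the first sample relative to the
#' locking event, channel labels with hemisphere tags, a participant id and
#' the event table the epochs were locked to.
#'
#' @param data Numeric array `[trial, channel, sample]`, in microvolts.
#' @param fs_hz Sampling rate (Hz).
#' @param t0_ms Time of the first sample relative to the locked onset (ms).
#' @param channels Data frame with columns `label` and `hemisphere`.
#' @param participant_id Identifier.
#' @param events `event_table` with one row per trial (same order as `data`).
#' @return An object of class `ieeg_epochs`.
#' @export
ieeg_epochs <- function(data, fs_hz, t0_ms, channels, participant_id = "P01",
                        events = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "hemisphere") %in% names(channels)),
            nrow(channels) == dim(data)[2], nrow(channels) >= 1L)
  if (!all(is.finite(data))) stop_cfg("epoch data must be finite")
  if (!is.null(events)) stopifnot(nrow(events) == dim(data)[1])
  structure(list(data = data, fs_hz = fs_hz, t0_ms = t0_ms,
                 channels = channels, participant_id = participant_id,
                 events = events),
            class = "ieeg_epochs")
}

#' @export
print.ieeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ieeg_epochs [%s]: %d trials x %d channels x %d samples, %g Hz, t0 = %g ms\n",
    x$participant_id, d[1], d[2], d[3], x$fs_hz, x$t0_ms))
  invisible(x)
}

#' Epoch time axis in ms
#' @param epochs An `ieeg_epochs` object.
#' @return Numeric vector of sample times relative to the locked onset.
#' @export
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$t0_ms + (seq_len(n) - 1L) * 1000 / epochs$fs_hz
}

# Keep a subset of trials, preserving event rows.
subset_trials <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  if (!is.null(epochs$events)) {
    epochs$events <- epochs$events[keep, , drop = FALSE]
    class(epochs$events) <- c("event_table", "data.frame")
  }
  epochs
}

#' Write / read epochs as a raw binary + JSON sidecar container
#'
#' The container is a pair of files: `<path>.dat` holding the voltage array
#' as little-endian float64 in trial-major order, and `<path>.json` holding
#' dimensions, sampling rate, time origin, channel table, participant id and
#' the events table. Everything needed to reconstruct the object is in the
#' sidecar, so the format is self-describing.
#'
#' @param epochs An `ieeg_epochs` object.
#' @param path Path stem (without extension).
#' @return `read_epochs` returns the `ieeg_epochs`; `write_epochs` the path
#'   stem, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "ieeg_epochs"))
  sidecar <- list(
    format = "tfspm-epochs-v1", dims = dim(epochs$data),
    fs_hz = epochs$fs_hz, t0_ms = epochs$t0_ms,
    channels = epochs$channels, participant_id = epochs$participant_id,
    events = if (!is.null(epochs$events)) as.data.frame(epochs$events))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(paste0(path, ".json")))
    stop_cfg("no epochs container at ", path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sc$format, "tfspm-epochs-v1"))
    stop_cfg("not a tfspm epochs container: ", path)
  dims <- as.integer(sc$dims)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  events <- NULL
  if (!is.null(sc$events)) {
    events <- as.data.frame(sc$events, stringsAsFactors = FALSE)
    class(events) <- c("event_table", "data.frame")
  }
  ieeg_epochs(array(x, dims), fs_hz = sc$fs_hz, t0_ms = sc$t0_ms,
              channels = sc$channels, participant_id = sc$participant_id,
              events = events)
}
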