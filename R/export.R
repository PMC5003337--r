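#' Export maps, statistic images and designs as plain text
#'
#' `write_stat_image` writes a T image as TSV (long format: time_ms,
#' freq_hz, value). `write_tf_mean_map` averages a stack's maps over a
#' subset of observations (e.g. one condition) and writes the mean map the
#' same way -- the raw material of time-frequency plots.
#' `write_design_json` serializes the design matrix, cell table and
#' optional contrast definitions for provenance.
#'
#' @param stat A `stat_image`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stat_image <- function(stat, path) {
  stopifnot(inherits(stat, "stat_image"))
  freqs <- stat$freqs_hz %||% NA_real_
  out <- data.frame(time_ms = rep(stat$times_ms, times = ncol(stat$values)),
                    freq_hz = rep(freqs, each = nrow(stat$values)),
                    value = as.vector(stat$values))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stat_image
#' @param stack A `tf_stack`.
#' @param keep Logical or integer index over observations; default all.
#' @export
write_tf_mean_map <- function(stack, path, keep = NULL) {
  stopifnot(inherits(stack, "tf_stack"))
  d <- dim(stack$power)
  if (is.null(keep)) keep <- seq_len(d[3])
  m <- rowMeans(matrix(stack$power[, , keep, drop = FALSE],
                       d[1] * d[2], length(keep)))
  out <- data.frame(time_ms = rep(stack$times_ms, times = d[2]),
                    freq_hz = rep(stack$freqs_hz, each = d[1]),
                    value = m)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stat_image
#' @param design A [build_design()] object.
#' @param contrasts Optional list of [tf_contrast()] objects.
#' @export
write_design_json <- function(design, path, contrasts = NULL) {
  stopifnot(inherits(design, "tf_design"))
  payload <- list(
    cells = design$cells,
    n_per_cell = as.integer(design$n_per_cell),
    cell_of = as.integer(design$cell_of),
    n_pairs = sum(!is.na(design$pair)) %/% 2L,
    contrasts = lapply(contrasts, function(cn)
      list(label = cn$label, weights = cn$weights,
           mask = cn$mask)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
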