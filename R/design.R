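#' Build the factorial cell-means design
#'
#' Constructs the 2 x 2 x 2 cell-means design (stimulus type x stimulus
#' direction x hemisphere) over trial-level observations: every artifact-free
#' non-target trial contributes one observation per temporal-pole electrode.
#' The relevant direction factor is the first- or second-presentation
#' direction depending on which presentation is analyzed.
#'
#' @param obs Data frame with one row per observation, containing
#'   `stimulus_type`, `first_direction`, `second_direction`, `hemisphere`,
#'   `participant` and `trial_id` (the `obs` table of a `tf_stack`).
#' @param direction `"first"` or `"second"`: which presentation's direction
#'   labels the direction factor.
#' @return A `tf_design`: list with the indicator matrix `X`
#'   (observations x 8 cells), the `cells` table, the per-cell counts, the
#'   observation table, and `pair`, the index pairing the two hemisphere
#'   observations of the same trial (NA when unpaired).
#' @export
build_design <- function(obs, direction = c("first", "second")) {
  direction <- match.arg(direction)
  dir_col <- paste0(direction, "_direction")
  need <- c("stimulus_type", dir_col, "hemisphere", "participant", "trial_id")
  stopifnot(all(need %in% names(obs)))
  if (any(obs$stimulus_type == "target"))
    stop_cfg("target trials must be removed before building the design")
  cells <- expand.grid(stimulus_type = c("eyes", "mosaic"),
                       direction = c("averted", "straight"),
                       hemisphere = c("left", "right"),
                       stringsAsFactors = FALSE)
  cell_lab <- function(ty, di, he) paste(ty, di, he, sep = ".")
  cells$label <- cell_lab(cells$stimulus_type, cells$direction, cells$hemisphere)
  cell_of <- match(cell_lab(obs$stimulus_type, obs[[dir_col]], obs$hemisphere),
                   cells$label)
  if (anyNA(cell_of))
    stop_cfg("observations with factor levels outside the 2x2x2 design")
  n_per_cell <- tabulate(cell_of, nbins = 8L)
  if (any(n_per_cell == 0L))
    stop_cfg("empty design cell(s): ",
             paste(cells$label[n_per_cell == 0L], collapse = ", "))
  X <- matrix(0, nrow(obs), 8L, dimnames = list(NULL, cells$label))
  X[cbind(seq_len(nrow(obs)), cell_of)] <- 1
  trial_key <- paste(obs$participant, obs$trial_id)
  pair <- rep(NA_integer_, nrow(obs))
  dup <- split(seq_len(nrow(obs)), trial_key)
  pid <- 0L
  for (ix in dup) {
    if (length(ix) == 2L) {
      pid <- pid + 1L
      pair[ix] <- pid
    } else if (length(ix) > 2L) {
      stop_cfg("more than two observations for one trial; ",
               "one observation per hemisphere is expected")
    }
  }
  structure(list(X = X, cells = cells, cell_of = cell_of,
                 n_per_cell = n_per_cell, obs = obs, pair = pair),
            class = "tf_design")
}

#' @export
print.tf_design <- function(x, ...) {
  cat(sprintf("tf_design: %d observations x %d cells; per-cell n: %s\n",
              nrow(x$X), ncol(x$X), paste(x$n_per_cell, collapse = " ")))
  invisible(x)
}

#' T contrast over the eight design cells
#'
#' @param weights Numeric vector of length 8, in the cell order of
#'   [build_design()] (`eyes/mosaic` fastest, then direction, then
#'   hemisphere); must sum to 0 for a difference contrast.
#' @param label Human-readable contrast name.
#' @param mask Optional inclusive mask: `list(weights=, p=0.05)`; pixels
#'   whose one-sided uncorrected p on the masking contrast exceeds `p` are
#'   excluded from the search region.
#' @return A `tf_contrast` object.
#' @export
tf_contrast <- function(weights, label = "contrast", mask = NULL) {
  stopifnot(length(weights) >= 2L)
  if (!is.null(mask)) {
    stopifnot(length(mask$weights) == length(weights))
    mask$p <- mask$p %||% 0.05
  }
  structure(list(weights = as.numeric(weights), label = label, mask = mask),
            class = "tf_contrast")
}

#' The standard contrast set of the factorial gaze analysis
#'
#' Main effect of stimulus type (eyes - mosaics), the three interactions
#' involving stimulus type, and (optionally) the hemisphere-wise simple main
#' effects of stimulus type inclusively masked by a positive main effect of
#' type at uncorrected p < `mask_p` -- the follow-up used to resolve a
#' type x hemisphere interaction.
#'
#' Cell order is `eyes/mosaic` x `averted/straight` x `left/right` with type
#' varying fastest. All contrasts are one-sided (positive).
#'
#' @param include_masked_followups Add the masked simple-effect contrasts.
#' @param mask_p Uncorrected one-sided p threshold of the inclusive mask.
#' @return Named list of [tf_contrast()] objects.
#' @export
table_contrasts <- function(include_masked_followups = FALSE, mask_p = 0.05) {
  e <- c(1, 0, 1, 0, 1, 0, 1, 0) / 4   # eyes cells
  m <- c(0, 1, 0, 1, 0, 1, 0, 1) / 4   # mosaic cells
  av <- c(1, 1, 0, 0, 1, 1, 0, 0)      # averted
  lf <- c(1, 1, 1, 1, 0, 0, 0, 0)      # left hemisphere
  type_me <- e - m
  txd <- 2 * ((e - m) * av - (e - m) * (1 - av))
  txh_l <- 2 * ((e - m) * lf - (e - m) * (1 - lf))
  txh_r <- -txh_l
  threeway <- 4 * ((e - m) * av * lf - (e - m) * av * (1 - lf) -
                     (e - m) * (1 - av) * lf + (e - m) * (1 - av) * (1 - lf))
  out <- list(
    main_type = tf_contrast(type_me, "Main effect of stimulus type (eyes - mosaics)"),
    type_x_direction = tf_contrast(txd, "Interaction of stimulus type x stimulus direction"),
    type_x_hemisphere = tf_contrast(txh_l, "Interaction of stimulus type x hemisphere"),
    type_x_direction_x_hemisphere = tf_contrast(
      threeway, "Interaction of stimulus type x stimulus direction x hemisphere"))
  if (include_masked_followups) {
    mask <- list(weights = type_me, p = mask_p)
    out$simple_type_left <- tf_contrast(
      2 * (e - m) * lf, "Eyes - mosaics, left hemisphere (masked)", mask = mask)
    out$simple_type_right <- tf_contrast(
      2 * (e - m) * (1 - lf), "Eyes - mosaics, right hemisphere (masked)", mask = mask)
    out$txh_right_gt_left <- tf_contrast(
      txh_r, "Interaction of stimulus type x hemisphere (right > left, masked)",
      mask = mask)
  }
  out
}
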