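# Droplet segmentation and per-cell intensity scoring: green-channel
# thresholding, per-pixel Oil Red O ratio, GFP auto-contrast normalization,
# and per-cell maxima over a label mask.

#' Segment lipid droplets by thresholding the Nile Red green channel
#'
#' The droplet mask is `green >= threshold` (the threshold value itself is
#' included) with connected components smaller than `min_droplet_area`
#' removed. The threshold is an explicit input and is echoed in the result so
#' the same value can be reused across all wells of one experiment.
#'
#' @param green Numeric matrix, non-polar-lipid (green) channel.
#' @param threshold Intensity threshold, or `"auto"` for Otsu.
#' @param min_droplet_area Minimum droplet component area in pixels
#'   (default 4; 0 disables the filter).
#' @param bit_depth Bit depth used to validate a numeric threshold.
#' @return An object of class `"droplet_mask"`: list with `mask` (logical
#'   matrix), `threshold` (the value applied) and `min_droplet_area`.
#' @export
segment_droplets <- function(green, threshold = "auto", min_droplet_area = 4,
                             bit_depth = 8) {
  green <- as_numeric_matrix(green, "green")
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(green)
  } else {
    thr <- as.numeric(threshold)
    if (thr < 0 || thr > 2^bit_depth - 1) {
      stop(sprintf("threshold %s outside the %d-bit range [0, %d]",
                   format(thr), bit_depth, 2^bit_depth - 1))
    }
  }
  mask <- green >= thr
  if (min_droplet_area > 0 && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    mask[lab > 0 & sizes[pmax(lab, 1)] < min_droplet_area] <- FALSE
  }
  structure(list(mask = mask, threshold = thr,
                 min_droplet_area = min_droplet_area),
            class = "droplet_mask")
}

#' @export
print.droplet_mask <- function(x, ...) {
  cat(sprintf("<droplet_mask> %dx%d, %d droplet px, threshold %.3f, min area %d px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold,
              x$min_droplet_area))
  invisible(x)
}

droplet_mask_matrix <- function(droplets) {
  if (inherits(droplets, "droplet_mask")) droplets <- droplets$mask
  if (!is.matrix(droplets)) stop("droplets must be a matrix or droplet_mask")
  droplets > 0
}

#' Per-pixel Oil Red O positivity ratio
#'
#' For every pixel of a brightfield RGB image, the red value divided by the
#' sum of the green and blue values; ratios strictly greater than 1 are Oil
#' Red O positive. A pixel with `G + B = 0` is positive when `R > 0`
#' (`Inf` sentinel: pure red signal is maximally positive) and negative when
#' `R = 0` (ratio 0).
#'
#' @param rgb A `h x w x 3` array of nonnegative values.
#' @return A list with `ratio` (numeric matrix) and `positive` (logical
#'   matrix, `ratio > 1`).
#' @export
oro_ratio_image <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("rgb must be a height x width x 3 array")
  }
  if (any(rgb < 0)) stop("rgb values must be nonnegative")
  r <- rgb[, , 1]; den <- rgb[, , 2] + rgb[, , 3]
  ratio <- r / den
  ratio[den == 0 & r == 0] <- 0        # 0/0: no signal, negative
  ratio[den == 0 & r > 0] <- Inf       # pure red: positive
  list(ratio = ratio, positive = ratio > 1)
}

#' Auto-contrast normalization of a channel to the 0-255 scale
#'
#' Linearly rescales so the brightest pixel maps to 255, as in auto-contrast
#' display normalization; values stay floating point (no rounding). An
#' all-zero channel is returned unchanged with a warning (there is no signal
#' to normalize to).
#'
#' @param channel Numeric matrix of nonnegative intensities.
#' @return Numeric matrix with maximum 255 (or all zeros).
#' @export
normalize_autocontrast <- function(channel) {
  channel <- as_numeric_matrix(channel, "channel")
  m <- max(channel)
  if (m == 0) {
    warning("all-zero channel: auto-contrast normalization is a no-op")
    return(channel)
  }
  channel * (255 / m)
}

#' Per-cell measurements over a label mask
#'
#' For each cell instance: area, droplet-pixel overlap, and the maxima of the
#' normalized GFP and Oil Red O ratio images over the cell's pixels. Channels
#' not provided yield `NA` columns (Nile Red experiments carry no GFP/ORO).
#'
#' @param cells Integer label matrix (0 = background).
#' @param droplets A [segment_droplets()] result, a logical matrix, or `NULL`.
#' @param gfp_norm Normalized GFP matrix (from [normalize_autocontrast()]) or
#'   `NULL`.
#' @param oro_ratio Oil Red O ratio matrix (from [oro_ratio_image()]) or
#'   `NULL`.
#' @param droplet_overlap_min Minimum droplet-pixel overlap for
#'   `has_droplets` (default 1 px).
#' @return A tibble with one row per cell: `label`, `area_px`,
#'   `n_droplet_px`, `has_droplets`, `max_gfp_norm`, `max_oro_ratio`.
#' @export
per_cell_stats <- function(cells, droplets = NULL, gfp_norm = NULL,
                           oro_ratio = NULL, droplet_overlap_min = 1) {
  if (!is.matrix(cells)) stop("cells must be an integer label matrix")
  shape_check <- function(x, nm) {
    if (!is.null(x) && !all(dim(x)[1:2] == dim(cells))) {
      stop(nm, " shape differs from the cell mask")
    }
  }
  dmask <- if (is.null(droplets)) NULL else droplet_mask_matrix(droplets)
  shape_check(dmask, "droplets"); shape_check(gfp_norm, "gfp_norm")
  shape_check(oro_ratio, "oro_ratio")

  idx <- which(cells > 0)
  labels <- sort(unique(cells[idx]))
  out <- tibble::tibble(
    label = as.integer(labels),
    area_px = NA_integer_, n_droplet_px = NA_integer_, has_droplets = NA,
    max_gfp_norm = NA_real_, max_oro_ratio = NA_real_
  )
  if (length(idx) == 0) return(out[0, ])

  g <- factor(cells[idx], levels = labels)
  out$area_px <- as.integer(tapply(idx, g, length))
  if (!is.null(dmask)) {
    out$n_droplet_px <- as.integer(tapply(dmask[idx], g, sum))
    out$has_droplets <- out$n_droplet_px >= droplet_overlap_min
  }
  if (!is.null(gfp_norm)) out$max_gfp_norm <- as.numeric(tapply(gfp_norm[idx], g, max))
  if (!is.null(oro_ratio)) out$max_oro_ratio <- as.numeric(tapply(oro_ratio[idx], g, max))
  out
}
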