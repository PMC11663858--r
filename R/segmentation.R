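# Instance segmentation: nuclei detection ("bright spots"), nuclei-seeded
# watershed, and a classical lipid-red-channel segmenter with the same
# input/output contract as a learned segmenter (a binary mask split into
# instances), so one can be swapped in later.

as_numeric_matrix <- function(x, arg = "image") {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x)) stop(arg, " must be a numeric matrix")
  x
}

#' Detect nuclei as bright spots in a DAPI image
#'
#' Gaussian smoothing followed by local-maximum detection above a threshold:
#' the standard deterministic blob detector. With `threshold = "auto"` the
#' threshold is Otsu's method on the smoothed image. Plateaus collapse to
#' their centroid; remaining peaks are greedily thinned (strongest first, ties
#' broken by scan order, lowest row then column) so that retained seeds are at
#' least `min_distance` apart.
#'
#' @param dapi Numeric matrix of nuclear-stain intensities.
#' @param min_distance Minimum distance between seeds, pixels.
#' @param threshold Intensity threshold, or `"auto"` for Otsu on the smoothed
#'   image.
#' @param sigma Gaussian smoothing sigma, pixels.
#' @return A tibble with columns `row`, `col` (seed coordinates, 1-based) and
#'   `score` (smoothed intensity at the seed). A constant image yields zero
#'   rows.
#' @export
detect_nuclei <- function(dapi, min_distance = 8, threshold = "auto", sigma = 2) {
  dapi <- as_numeric_matrix(dapi, "dapi")
  empty <- tibble::tibble(row = numeric(0), col = numeric(0), score = numeric(0))
  rng <- range(dapi)
  if (diff(rng) == 0) return(empty)

  sm <- smooth_image(dapi, sigma)
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(sm)
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- sm > thr
  if (!any(mask)) return(empty)

  # local maxima (8-neighborhood plateaus allowed) via grayscale dilation
  size <- 2L * ceiling(min_distance) + 1L
  brush <- EBImage::makeBrush(size, shape = "box")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(sm), brush))
  peaks <- mask & (sm >= dil)
  if (!any(peaks)) return(empty)

  # collapse plateaus to centroids
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(peaks * 1)))
  idx <- which(lab > 0)
  rr <- ((idx - 1L) %% nrow(sm)) + 1L
  cc <- ((idx - 1L) %/% nrow(sm)) + 1L
  g <- lab[idx]
  cent_r <- tapply(rr, g, mean)
  cent_c <- tapply(cc, g, mean)
  score <- tapply(sm[idx], g, max)

  ord <- order(-score, cent_r, cent_c)
  cr <- cent_r[ord]; cc2 <- cent_c[ord]; sc <- score[ord]
  keep <- logical(length(cr))
  for (i in seq_along(cr)) {
    if (i == 1L || all((cr[keep] - cr[i])^2 + (cc2[keep] - cc2[i])^2 >= min_distance^2)) {
      keep[i] <- TRUE
    }
  }
  out <- tibble::tibble(row = as.numeric(cr[keep]), col = as.numeric(cc2[keep]),
                        score = as.numeric(sc[keep]))
  dplyr::arrange(out, row, col)
}

# Separable Gaussian smoothing with replicate (edge-extend) padding. The
# replicate boundary avoids wrap-around artifacts at image borders that would
# otherwise seed spurious detections.
smooth_image <- function(x, sigma) {
  if (sigma <= 0) return(x)
  hw <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(m) {
    mp <- rbind(m[rep(1L, hw), , drop = FALSE], m,
                m[rep(nrow(m), hw), , drop = FALSE])
    r <- stats::filter(mp, k, sides = 2)
    matrix(r[(hw + 1):(nrow(mp) - hw), ], nrow(m), ncol(m))
  }
  t(conv_cols(t(conv_cols(x))))
}

# Otsu on an arbitrary-range image: scale into [0,1] for EBImage::otsu, then
# map the threshold back to the original scale.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xs <- (x - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1), levels = levels)
  rng[1] + t01 * diff(rng)
}

#' Seeded watershed segmentation of cells
#'
#' Partitions the foreground among nucleus seeds by seeded region growing
#' (watershed on the seed-distance landscape via `EBImage::propagate`). With
#' `on = "distance"` (default) the partition follows geometric distance to the
#' seeds within the foreground; with `on = "intensity"` the support image also
#' steers the boundaries. Seeds falling outside the foreground are dropped
#' with a warning. Label `k` of the output is seed `k` (row order of `seeds`).
#'
#' @param seeds Tibble or data frame with `row`, `col` seed coordinates (e.g.
#'   from [detect_nuclei()]).
#' @param support Numeric matrix used when `on = "intensity"`; may be `NULL`
#'   for pure distance-based growth.
#' @param foreground_mask Logical or 0/1 matrix delimiting the region to
#'   partition; defaults to the whole image (confluent monolayer).
#' @param on `"distance"` or `"intensity"`.
#' @return An integer label matrix (0 = background); every foreground pixel
#'   belongs to exactly one retained seed.
#' @export
segment_cells_watershed <- function(seeds, support = NULL, foreground_mask = NULL,
                                    on = c("distance", "intensity")) {
  on <- match.arg(on)
  if (is.null(foreground_mask)) {
    if (is.null(support)) stop("need `support` or `foreground_mask` to fix the image size")
    foreground_mask <- matrix(TRUE, nrow(support), ncol(support))
  }
  fg <- as_numeric_matrix(foreground_mask * 1, "foreground_mask") > 0
  h <- nrow(fg); w <- ncol(fg)
  out <- matrix(0L, h, w)
  if (nrow(seeds) == 0) return(out)

  sr <- round(seeds$row); sc <- round(seeds$col)
  if (any(sr < 1 | sr > h | sc < 1 | sc > w)) stop("seed coordinates outside image bounds")
  inside <- fg[cbind(sr, sc)]
  if (any(!inside)) {
    warning(sum(!inside), " seed(s) outside the foreground were dropped")
  }
  keep <- which(inside)
  if (length(keep) == 0) return(out)

  seed_img <- matrix(0L, h, w)
  seed_img[cbind(sr[keep], sc[keep])] <- keep

  x <- if (on == "intensity") {
    s <- as_numeric_matrix(support, "support")
    if (!all(dim(s) == dim(fg))) stop("support and foreground_mask shapes differ")
    rngs <- range(s)
    if (diff(rngs) > 0) (s - rngs[1]) / diff(rngs) else matrix(0, h, w)
  } else {
    matrix(0, h, w)  # flat support: growth by geometric distance only
  }
  lab <- EBImage::propagate(EBImage::Image(x), seeds = EBImage::Image(seed_img),
                            mask = EBImage::Image(fg * 1), lambda = 1e-4)
  out <- EBImage::imageData(lab)
  storage.mode(out) <- "integer"
  out
}

#' Segment cell instances from the Nile Red red channel
#'
#' A deterministic classical stand-in for a trained cell segmenter operating
#' on the total-lipid (red) channel: global threshold (Otsu by default), hole
#' filling, removal of objects below `min_area`, then instance splitting by
#' watershed on the smoothed distance transform of the foreground.
#'
#' @param lipid_red Numeric intensity matrix.
#' @param threshold Intensity threshold or `"auto"` (Otsu).
#' @param min_area Minimum object area in pixels; smaller components are
#'   removed as debris.
#' @param split Split touching cells by distance-transform watershed
#'   (`TRUE`, default) or return connected components as instances.
#' @param tolerance Watershed tolerance (minimum depth separating two
#'   instances on the distance transform); larger values merge shallow maxima.
#' @param smooth_sigma Gaussian sigma applied to the distance transform before
#'   the watershed, suppressing spurious maxima from boundary roughness.
#' @return An integer label matrix (0 = background).
#' @export
segment_cells_from_lipid_red <- function(lipid_red, threshold = "auto",
                                         min_area = 30, split = TRUE,
                                         tolerance = 2, smooth_sigma = 2) {
  img <- as_numeric_matrix(lipid_red, "lipid_red")
  if (diff(range(img)) == 0) return(matrix(0L, nrow(img), ncol(img)))
  thr <- if (identical(threshold, "auto")) otsu_threshold(img) else as.numeric(threshold)
  fg <- img >= thr
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  if (min_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    fg[lab > 0 & sizes[pmax(lab, 1)] < min_area] <- FALSE
  }
  if (!any(fg)) return(matrix(0L, nrow(img), ncol(img)))

  if (!split) {
    out <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
    storage.mode(out) <- "integer"
    return(out)
  }
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg * 1)))
  dms <- smooth_image(dm, smooth_sigma)
  dms[!fg] <- 0
  ws <- EBImage::watershed(EBImage::Image(dms), tolerance = tolerance, ext = 1)
  out <- EBImage::imageData(ws)
  storage.mode(out) <- "integer"
  out
}

#' Centroid table of a label mask
#'
#' @param mask Integer label matrix (0 = background).
#' @return A tibble with `label`, `row`, `col` (centroids) and `area_px`.
#' @export
label_centroids <- function(mask) {
  idx <- which(mask > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(0), row = numeric(0),
                          col = numeric(0), area_px = integer(0)))
  }
  g <- mask[idx]
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  tibble::tibble(
    label = as.integer(names(tapply(rr, g, mean))) ,
    row = as.numeric(tapply(rr, g, mean)),
    col = as.numeric(tapply(cc, g, mean)),
    area_px = as.integer(tapply(rr, g, length))
  ) |> dplyr::arrange(.data$label)
}
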