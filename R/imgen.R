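#' Configuration for a synthetic well
#'
#' Builds and validates the parameter set for [generate_well()]. The generator
#' emulates a confluent monolayer of mesenchymal stem cells imaged in four
#' fluorescence channels (DAPI nuclei, Nile Red red = total lipids, Nile Red
#' green = non-polar lipids, GFP) plus a brightfield RGB Oil Red O image, with
#' a controllable fraction of droplet-containing (differentiated) cells and of
#' GFP-transduced cells, and additive Gaussian noise.
#'
#' @param height,width Image size in pixels.
#' @param bit_depth Fluorescence channel bit depth, 8 or 16. The Oil Red O RGB
#'   image is always 8-bit.
#' @param n_cells Number of cells to place.
#' @param adipocyte_fraction Fraction of cells carrying lipid droplets, in
#'   `[0, 1]`.
#' @param droplet_regime `"small"` (several small droplets per adipocyte, the
#'   homogeneous phenotype), `"large"` (a single droplet about half the cell
#'   radius), or `"mixed"` (each adipocyte drawn from one of the two regimes
#'   at random).
#' @param gfp_fraction Fraction of cells expressing GFP, in `[0, 1]`.
#' @param gfp_suppresses_adipogenesis If `TRUE`, GFP-positive cells never
#'   receive droplets (the transgene-rescue scenario); droplet-bearing cells
#'   are then drawn from the GFP-negative pool.
#' @param noise_sd Standard deviation of additive Gaussian noise, in intensity
#'   units of the channel bit depth.
#' @param seed Integer RNG seed; `generate_well()` is a pure function of the
#'   configuration including this seed.
#' @param cell_radius Length-2 numeric, min/max cell radius in pixels.
#' @param nucleus_radius Nucleus radius in pixels.
#' @param min_center_dist Minimum distance between cell centers; defaults to
#'   `1.7 * mean(cell_radius)`, which keeps nuclei disjoint while letting
#'   neighboring cell bodies touch as in a confluent monolayer.
#' @param droplet_small_n Length-2 integer, min/max droplet count per
#'   adipocyte in the small regime.
#' @param droplet_small_radius Length-2 numeric, min/max droplet radius in the
#'   small regime (pixels).
#' @param large_droplet_scale Droplet radius as a fraction of the cell radius
#'   in the large regime.
#' @param intensity Named list of intensity levels; missing entries are filled
#'   with defaults scaled to `bit_depth`. Entries: `background`, `dapi_fg`,
#'   `lipid_red_fg`, `lipid_red_droplet`, `lipid_green_fg`, `gfp_fg` (scalar
#'   levels) and `oro_droplet`, `oro_background` (RGB triplets on the 8-bit
#'   scale; droplet triplets must satisfy R > G + B and background triplets
#'   R <= G + B).
#'
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(height = 512, width = 512, bit_depth = 8,
                         n_cells = 150, adipocyte_fraction = 0.1,
                         droplet_regime = c("small", "large", "mixed"),
                         gfp_fraction = 0.1,
                         gfp_suppresses_adipogenesis = FALSE,
                         noise_sd = 5, seed = 1L,
                         cell_radius = c(10, 16), nucleus_radius = 5,
                         min_center_dist = NULL,
                         droplet_small_n = c(3L, 8L),
                         droplet_small_radius = c(2, 4),
                         large_droplet_scale = 0.5,
                         intensity = list()) {
  droplet_regime <- match.arg(droplet_regime)
  stopifnot(
    height >= 1, width >= 1,
    bit_depth %in% c(8L, 16L),
    n_cells >= 0,
    adipocyte_fraction >= 0, adipocyte_fraction <= 1,
    gfp_fraction >= 0, gfp_fraction <= 1,
    noise_sd >= 0,
    length(cell_radius) == 2, all(cell_radius >= 1),
    cell_radius[1] <= cell_radius[2],
    nucleus_radius >= 1, nucleus_radius < cell_radius[1],
    length(droplet_small_n) == 2, droplet_small_n[1] >= 1,
    length(droplet_small_radius) == 2, all(droplet_small_radius >= 1),
    large_droplet_scale > 0, large_droplet_scale < 1
  )
  if (is.null(min_center_dist)) min_center_dist <- 1.7 * mean(cell_radius)
  if (min_center_dist < 2 * nucleus_radius + 1) {
    stop("`min_center_dist` must exceed 2 * nucleus_radius so nuclei cannot overlap")
  }

  scale <- if (bit_depth == 8L) 1 else 257  # 255 * 257 = 65535
  defaults <- list(
    background       = 10 * scale,
    dapi_fg          = 200 * scale,
    lipid_red_fg     = 120 * scale,
    lipid_red_droplet = 160 * scale,
    lipid_green_fg   = 180 * scale,
    gfp_fg           = 220 * scale,
    oro_droplet      = c(200, 55, 55),
    oro_background   = c(170, 110, 100)
  )
  intensity <- utils::modifyList(defaults, intensity)
  maxval <- 2^bit_depth - 1
  scalars <- c("background", "dapi_fg", "lipid_red_fg", "lipid_red_droplet",
               "lipid_green_fg", "gfp_fg")
  for (nm in scalars) {
    v <- intensity[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > maxval) {
      stop(sprintf("intensity$%s must be a scalar in [0, %d]", nm, maxval))
    }
  }
  for (nm in c("oro_droplet", "oro_background")) {
    v <- intensity[[nm]]
    if (!is.numeric(v) || length(v) != 3 || any(v < 0) || any(v > 255)) {
      stop(sprintf("intensity$%s must be an RGB triplet in [0, 255]", nm))
    }
  }
  if (intensity$oro_droplet[1] <= sum(intensity$oro_droplet[2:3])) {
    stop("intensity$oro_droplet must satisfy R > G + B")
  }
  if (intensity$oro_background[1] > sum(intensity$oro_background[2:3])) {
    stop("intensity$oro_background must satisfy R <= G + B")
  }

  structure(
    list(height = as.integer(height), width = as.integer(width),
         bit_depth = as.integer(bit_depth), n_cells = as.integer(n_cells),
         adipocyte_fraction = adipocyte_fraction,
         droplet_regime = droplet_regime, gfp_fraction = gfp_fraction,
         gfp_suppresses_adipogenesis = isTRUE(gfp_suppresses_adipogenesis),
         noise_sd = noise_sd, seed = as.integer(seed),
         cell_radius = cell_radius, nucleus_radius = nucleus_radius,
         min_center_dist = min_center_dist,
         droplet_small_n = as.integer(droplet_small_n),
         droplet_small_radius = droplet_small_radius,
         large_droplet_scale = large_droplet_scale,
         intensity = intensity),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %dx%d %d-bit | %d cells | adipocyte %.3f | gfp %.3f (%s) | %s droplets | noise_sd %.1f | seed %d\n",
    x$height, x$width, x$bit_depth, x$n_cells, x$adipocyte_fraction,
    x$gfp_fraction,
    if (x$gfp_suppresses_adipogenesis) "suppressing" else "neutral",
    x$droplet_regime, x$noise_sd, x$seed))
  invisible(x)
}

# Dart-throwing placement of cell centers with a minimum pairwise distance.
# Errors out (rather than silently truncating) when the requested density
# cannot be packed.
place_centers <- function(n, height, width, min_dist, max_tries = 200L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  min_d2 <- min_dist^2
  tries <- 0L
  while (placed < n) {
    m <- max(64L, (n - placed) * 4L)
    cand <- cbind(stats::runif(m, 1, height), stats::runif(m, 1, width))
    for (i in seq_len(m)) {
      if (placed == 0L ||
          min((centers[seq_len(placed), 1] - cand[i, 1])^2 +
              (centers[seq_len(placed), 2] - cand[i, 2])^2) >= min_d2) {
        placed <- placed + 1L
        centers[placed, ] <- cand[i, ]
        if (placed == n) break
      }
    }
    tries <- tries + 1L
    if (tries >= max_tries && placed < n) {
      stop(sprintf(
        "packing failure: placed only %d of %d cells at min_center_dist %.1f in a %dx%d image",
        placed, n, min_dist, height, width))
    }
  }
  centers
}

# Radius of a perturbed ellipse as a function of polar angle. Amplitudes are
# clamped so the boundary always clears the nucleus.
cell_radius_fun <- function(base_r, a1, a2, phi1, phi2, min_r) {
  amp_max <- max(0, 1 - min_r / base_r)
  s <- a1 + a2
  if (s > amp_max && s > 0) {
    a1 <- a1 * amp_max / s
    a2 <- a2 * amp_max / s
  }
  function(theta) base_r * (1 + a1 * cos(theta - phi1) + a2 * cos(2 * (theta - phi2)))
}

clip_round <- function(x, maxval) {
  round(pmin(pmax(x, 0), maxval))
}

add_noise <- function(mat, sd, maxval) {
  if (sd > 0) mat <- mat + stats::rnorm(length(mat), 0, sd)
  clip_round(mat, maxval)
}

disk_indices <- function(cr, cc, radius, height, width) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(height, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(width, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cr
  dx <- cols - cc
  inside <- outer(dy^2, dx^2, `+`) <= radius^2
  rr <- rep(rows, times = length(cols))[inside]
  cc2 <- rep(cols, each = length(rows))[inside]
  (cc2 - 1L) * height + rr
}

#' Generate a synthetic multichannel well with ground truth
#'
#' Renders a confluent monolayer of perturbed-ellipse cells, each with a
#' circular nucleus, assigns lipid droplets to a controlled fraction of cells
#' and GFP expression to another, and synthesizes the five images used by the
#' quantification workflows: DAPI, Nile Red red (total lipids, whole-cell
#' signal), Nile Red green (non-polar lipids, droplet-only signal), GFP, and a
#' brightfield-style Oil Red O RGB image in which droplet pixels satisfy
#' R > G + B and all other pixels R <= G + B (before noise).
#'
#' Identical configurations (including the seed) yield bit-identical wells;
#' the caller's RNG state is left untouched.
#'
#' @param config A [synth_config()].
#' @return An object of class `"synth_well"`: a list with elements `channels`
#'   (`dapi`, `lipid_red`, `lipid_green`, `gfp` numeric matrices and `oro_rgb`,
#'   a `height x width x 3` array), `truth` (list with `cells` — a tibble with
#'   columns `label`, `row`, `col`, `is_adipocyte`, `n_droplet_px`, `gfp_on` —
#'   plus `cell_mask` and `droplet_mask` integer matrices in which droplet
#'   pixels carry the owning cell's label), and `config`.
#' @export
generate_well <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_well_impl(config))
}

generate_well_impl <- function(cfg) {
  h <- cfg$height; w <- cfg$width
  maxval <- 2^cfg$bit_depth - 1
  n <- cfg$n_cells

  cell_mask <- matrix(0L, h, w)
  droplet_mask <- matrix(0L, h, w)
  nucleus_px <- integer(0)

  if (n > 0) {
    centers <- place_centers(n, h, w, cfg$min_center_dist)
    base_r <- stats::runif(n, cfg$cell_radius[1], cfg$cell_radius[2])
    a1 <- stats::runif(n, 0, 0.12); a2 <- stats::runif(n, 0, 0.10)
    phi1 <- stats::runif(n, 0, 2 * pi); phi2 <- stats::runif(n, 0, 2 * pi)

    # competitive rasterization: a pixel belongs to the cell whose boundary
    # it sits deepest inside (smallest normalized radial distance)
    best_rho <- matrix(Inf, h, w)
    for (k in seq_len(n)) {
      rf <- cell_radius_fun(base_r[k], a1[k], a2[k], phi1[k], phi2[k],
                            cfg$nucleus_radius + 2)
      rmax <- base_r[k] * 1.25
      r0 <- max(1L, floor(centers[k, 1] - rmax))
      r1 <- min(h, ceiling(centers[k, 1] + rmax))
      c0 <- max(1L, floor(centers[k, 2] - rmax))
      c1 <- min(w, ceiling(centers[k, 2] + rmax))
      if (r0 > r1 || c0 > c1) next
      rows <- r0:r1; cols <- c0:c1
      dy <- matrix(rows - centers[k, 1], length(rows), length(cols))
      dx <- matrix(cols - centers[k, 2], length(rows), length(cols), byrow = TRUE)
      d <- sqrt(dy^2 + dx^2)
      theta <- atan2(dx, dy)
      rho <- d / rf(theta)
      win_idx <- as.vector(outer(rows, (cols - 1L) * h, `+`))
      take <- rho <= 1 & rho < best_rho[win_idx]
      idx <- win_idx[take]
      best_rho[idx] <- rho[take]
      cell_mask[idx] <- k
    }

    # assignment of phenotypes
    n_adipo <- round(cfg$adipocyte_fraction * n)
    n_gfp <- round(cfg$gfp_fraction * n)
    gfp_on <- logical(n)
    if (n_gfp > 0) gfp_on[sample.int(n, n_gfp)] <- TRUE
    is_adipo <- logical(n)
    pool <- if (cfg$gfp_suppresses_adipogenesis) which(!gfp_on) else seq_len(n)
    if (n_adipo > length(pool)) {
      stop("adipocyte_fraction too high for the GFP-negative pool under suppression")
    }
    if (n_adipo > 0) is_adipo[sample(pool, n_adipo)] <- TRUE

    # droplets
    cell_px <- split(seq_len(h * w)[cell_mask > 0L],
                     cell_mask[cell_mask > 0L])
    for (k in which(is_adipo)) {
      px <- cell_px[[as.character(k)]]
      regime <- cfg$droplet_regime
      if (regime == "mixed") regime <- if (stats::runif(1) < 0.5) "small" else "large"
      if (regime == "large") {
        dr <- cfg$large_droplet_scale * base_r[k]
        dpx <- disk_indices(centers[k, 1], centers[k, 2], dr, h, w)
        dpx <- intersect(dpx, px)
      } else {
        nd <- sample(seq(cfg$droplet_small_n[1], cfg$droplet_small_n[2]), 1)
        # droplet centers drawn from the cell interior
        interior <- px[best_rho[px] <= 0.7]
        if (length(interior) == 0) interior <- px
        cent <- interior[sample.int(length(interior), min(nd, length(interior)),
                                    replace = length(interior) < nd)]
        dpx <- integer(0)
        for (ci in cent) {
          rr <- ((ci - 1L) %% h) + 1L
          cc <- ((ci - 1L) %/% h) + 1L
          dr <- stats::runif(1, cfg$droplet_small_radius[1], cfg$droplet_small_radius[2])
          dpx <- c(dpx, disk_indices(rr, cc, dr, h, w))
        }
        dpx <- intersect(unique(dpx), px)
      }
      if (length(dpx) == 0) dpx <- px[which.min(best_rho[px])]  # guarantee >= 1 px
      droplet_mask[dpx] <- k
    }

    for (k in seq_len(n)) {
      nucleus_px <- c(nucleus_px,
                      disk_indices(centers[k, 1], centers[k, 2],
                                   cfg$nucleus_radius, h, w))
    }

    truth <- tibble::tibble(
      label = seq_len(n),
      row = centers[, 1],
      col = centers[, 2],
      is_adipocyte = is_adipo,
      n_droplet_px = as.integer(tabulate(droplet_mask[droplet_mask > 0L], nbins = n)),
      gfp_on = gfp_on
    )
  } else {
    truth <- tibble::tibble(
      label = integer(0), row = numeric(0), col = numeric(0),
      is_adipocyte = logical(0), n_droplet_px = integer(0), gfp_on = logical(0)
    )
  }

  ints <- cfg$intensity
  bg <- ints$background
  dapi <- matrix(bg, h, w)
  dapi[nucleus_px] <- ints$dapi_fg
  lipid_red <- matrix(bg, h, w)
  lipid_red[cell_mask > 0L] <- ints$lipid_red_fg
  lipid_red[droplet_mask > 0L] <- ints$lipid_red_droplet
  lipid_green <- matrix(bg, h, w)
  lipid_green[droplet_mask > 0L] <- ints$lipid_green_fg
  gfp <- matrix(bg, h, w)
  if (n > 0 && any(truth$gfp_on)) {
    gfp[cell_mask %in% truth$label[truth$gfp_on]] <- ints$gfp_fg
  }

  oro <- array(0, dim = c(h, w, 3))
  for (p in 1:3) {
    plane <- matrix(ints$oro_background[p], h, w)
    plane[droplet_mask > 0L] <- ints$oro_droplet[p]
    oro[, , p] <- plane
  }

  dapi <- add_noise(dapi, cfg$noise_sd, maxval)
  lipid_red <- add_noise(lipid_red, cfg$noise_sd, maxval)
  lipid_green <- add_noise(lipid_green, cfg$noise_sd, maxval)
  gfp <- add_noise(gfp, cfg$noise_sd, maxval)
  oro_sd <- cfg$noise_sd * if (cfg$bit_depth == 16L) 1 / 257 else 1
  for (p in 1:3) oro[, , p] <- add_noise(oro[, , p], oro_sd, 255)

  structure(
    list(channels = list(dapi = dapi, lipid_red = lipid_red,
                         lipid_green = lipid_green, gfp = gfp, oro_rgb = oro),
         truth = list(cells = truth, cell_mask = cell_mask,
                      droplet_mask = droplet_mask),
         config = cfg),
    class = "synth_well"
  )
}

#' @export
print.synth_well <- function(x, ...) {
  cat(sprintf(
    "<synth_well> %dx%d, %d cells (%d with droplets, %d GFP+), seed %d\n",
    x$config$height, x$config$width, nrow(x$truth$cells),
    sum(x$truth$cells$is_adipocyte), sum(x$truth$cells$gfp_on),
    x$config$seed))
  invisible(x)
}

#' Write a synthetic well to disk as TIFFs plus ground-truth CSV
#'
#' Writes one grayscale TIFF per fluorescence channel at the configured bit
#' depth, the Oil Red O image as an 8-bit RGB TIFF, the ground-truth cell
#' table as CSV, and the configuration as YAML. Reading the TIFFs back
#' reproduces the in-memory arrays exactly.
#'
#' @param well A `"synth_well"` from [generate_well()].
#' @param directory Output directory; created if absent.
#' @return A tibble manifest with columns `file` and `kind`, invisibly usable
#'   as the inventory of written paths.
#' @export
write_fixture <- function(well, directory) {
  stopifnot(inherits(well, "synth_well"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  bits <- well$config$bit_depth
  maxval <- 2^bits - 1
  files <- character(0); kinds <- character(0)
  for (ch in c("dapi", "lipid_red", "lipid_green", "gfp")) {
    path <- file.path(directory, paste0(ch, ".tif"))
    ok <- try(tiff::writeTIFF(well$channels[[ch]] / maxval, path,
                              bits.per.sample = bits), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write ", path)
    files <- c(files, path); kinds <- c(kinds, "channel_tiff")
  }
  path <- file.path(directory, "oro_rgb.tif")
  tiff::writeTIFF(well$channels$oro_rgb / 255, path, bits.per.sample = 8L)
  files <- c(files, path); kinds <- c(kinds, "rgb_tiff")

  path <- file.path(directory, "truth.csv")
  readr::write_csv(well$truth$cells, path)
  files <- c(files, path); kinds <- c(kinds, "truth_csv")

  path <- file.path(directory, "config.yaml")
  cfg <- unclass(well$config)
  yaml::write_yaml(cfg, path)
  files <- c(files, path); kinds <- c(kinds, "config_yaml")

  tibble::tibble(file = files, kind = kinds)
}

#' Read a well fixture written by [write_fixture()]
#'
#' @param directory Directory containing the channel TIFFs (and optionally
#'   `truth.csv` / `config.yaml`).
#' @return A list with `channels` (integer-valued matrices / RGB array on the
#'   original intensity scale), and, when present on disk, `truth$cells` and
#'   `config`.
#' @export
read_well <- function(directory) {
  cfg_path <- file.path(directory, "config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  bits <- if (!is.null(config)) config$bit_depth else 8L
  maxval <- 2^bits - 1
  channels <- list()
  for (ch in c("dapi", "lipid_red", "lipid_green", "gfp")) {
    path <- file.path(directory, paste0(ch, ".tif"))
    if (file.exists(path)) {
      channels[[ch]] <- round(tiff::readTIFF(path) * maxval)
    }
  }
  path <- file.path(directory, "oro_rgb.tif")
  if (file.exists(path)) channels$oro_rgb <- round(tiff::readTIFF(path) * 255)
  truth_path <- file.path(directory, "truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- list(cells = readr::read_csv(truth_path, show_col_types = FALSE))
  }
  list(channels = channels, truth = truth, config = config)
}
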