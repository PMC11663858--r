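# Headline quantification: droplet-containing cell selection ("Having"),
# differentiated-cell fractions, GFP/ORO double-positive gating, scatter
# export, field-of-view sampling, and fold-change arithmetic.

#' Gating thresholds for droplet, Oil Red O and GFP classification
#'
#' @param gfp_threshold Normalized GFP gate; cells with `max_gfp_norm`
#'   strictly above it are GFP-positive (default 127 on the 0-255 scale).
#' @param oro_threshold Oil Red O ratio line; cells with `max_oro_ratio`
#'   strictly above it are positive (default 1).
#' @param droplet_overlap_min Minimum droplet-pixel overlap for a cell to
#'   count as droplet-containing (default 1 px).
#' @return A list of class `"gate_config"`.
#' @export
gate_config <- function(gfp_threshold = 127, oro_threshold = 1,
                        droplet_overlap_min = 1) {
  stopifnot(gfp_threshold >= 0, gfp_threshold <= 255,
            oro_threshold >= 0, droplet_overlap_min >= 0)
  structure(list(gfp_threshold = gfp_threshold, oro_threshold = oro_threshold,
                 droplet_overlap_min = droplet_overlap_min),
            class = "gate_config")
}

#' Select cells whose region intersects the droplet mask
#'
#' The "Having" operation: a cell is retained when at least `overlap_min` of
#' its pixels fall on the droplet mask. Returns both the selected label ids
#' and the filtered label mask in which all other cells are zeroed.
#'
#' @param cells Integer label matrix.
#' @param droplets A [segment_droplets()] result or logical matrix, same
#'   shape.
#' @param overlap_min Minimum overlap in pixels (default 1).
#' @return A list with `labels` (sorted integer vector) and `mask` (filtered
#'   label matrix).
#' @export
cells_having_droplets <- function(cells, droplets, overlap_min = 1) {
  dmask <- droplet_mask_matrix(droplets)
  if (!all(dim(dmask) == dim(cells))) stop("cell and droplet masks differ in shape")
  idx <- which(cells > 0 & dmask)
  if (length(idx) == 0 || overlap_min == 0) {
    labels <- if (overlap_min == 0) sort(unique(cells[cells > 0])) else integer(0)
  } else {
    counts <- table(cells[idx])
    labels <- sort(as.integer(names(counts)[counts >= overlap_min]))
  }
  mask <- cells
  mask[!(mask %in% labels)] <- 0L
  list(labels = as.integer(labels), mask = mask)
}

#' Percentage of differentiated (droplet-containing) cells
#'
#' @param n_pos Number of droplet-containing cells.
#' @param n_total Total cell count; must be positive.
#' @return `100 * n_pos / n_total` (full precision; reports round to one
#'   decimal).
#' @export
differentiated_fraction <- function(n_pos, n_total) {
  if (n_total <= 0) stop("undefined result: total cell count is zero")
  if (n_pos < 0 || n_pos > n_total) stop("n_pos must lie in [0, n_total]")
  100 * n_pos / n_total
}

#' Classify cells into GFP/Oil-Red-O gate quadrants
#'
#' GFP-positive means `max_gfp_norm` strictly above the GFP gate; Oil Red O
#' positive means `max_oro_ratio` strictly above the ratio line. The four
#' class counts always partition the total.
#'
#' @param records Tibble from [per_cell_stats()] carrying `max_gfp_norm` and
#'   `max_oro_ratio`.
#' @param gates A [gate_config()].
#' @return A list with `records` (input plus `gfp_pos`, `oro_pos`, `class`
#'   columns), `counts` (tibble of the four classes), `n_total`,
#'   `n_gfp_pos`, `n_oro_pos`, `n_double_pos` and the `gates` used.
#' @export
gate_cells <- function(records, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  need <- c("max_gfp_norm", "max_oro_ratio")
  if (!all(need %in% names(records)) ||
      anyNA(records$max_gfp_norm) || anyNA(records$max_oro_ratio)) {
    stop("records must carry non-missing max_gfp_norm and max_oro_ratio")
  }
  rec <- dplyr::mutate(
    tibble::as_tibble(records),
    gfp_pos = .data$max_gfp_norm > gates$gfp_threshold,
    oro_pos = .data$max_oro_ratio > gates$oro_threshold,
    class = dplyr::case_when(
      gfp_pos & oro_pos ~ "GFP+ORO+",
      gfp_pos & !oro_pos ~ "GFP+ORO-",
      !gfp_pos & oro_pos ~ "GFP-ORO+",
      TRUE ~ "GFP-ORO-"
    )
  )
  lev <- c("GFP+ORO+", "GFP+ORO-", "GFP-ORO+", "GFP-ORO-")
  counts <- tibble::tibble(
    class = lev,
    n = as.integer(table(factor(rec$class, levels = lev)))
  )
  list(records = rec, counts = counts, n_total = nrow(rec),
       n_gfp_pos = sum(rec$gfp_pos), n_oro_pos = sum(rec$oro_pos),
       n_double_pos = sum(rec$gfp_pos & rec$oro_pos), gates = gates)
}

#' Per-cell scatter table of GFP versus Oil Red O maxima
#'
#' One row per cell with its gate class; plot it with
#' [plot_gate_scatter()].
#'
#' @param records Tibble carrying `label`, `max_gfp_norm`, `max_oro_ratio`.
#' @param gates A [gate_config()].
#' @return A tibble with columns `label`, `gfp`, `oro`, `class`.
#' @export
scatter_table <- function(records, gates = gate_config()) {
  if (nrow(records) == 0) stop("records must be non-empty")
  g <- gate_cells(records, gates)
  tibble::tibble(label = g$records$label, gfp = g$records$max_gfp_norm,
                 oro = g$records$max_oro_ratio, class = g$records$class)
}

#' Scatterplot of per-cell GFP versus Oil Red O maxima with gate lines
#'
#' Draws each cell as a point, the Oil Red O positivity line (horizontal) and
#' the GFP gate (vertical); the upper-right quadrant holds the double-positive
#' cells.
#'
#' @param records Tibble from [per_cell_stats()] (or a [scatter_table()]).
#' @param gates A [gate_config()].
#' @return A ggplot object.
#' @export
plot_gate_scatter <- function(records, gates = gate_config()) {
  tab <- if (all(c("gfp", "oro", "class") %in% names(records))) {
    tibble::as_tibble(records)
  } else {
    scatter_table(records, gates)
  }
  oro_cap <- max(tab$oro[is.finite(tab$oro)], gates$oro_threshold * 2)
  tab$oro_plot <- pmin(tab$oro, oro_cap)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$gfp, y = .data$oro_plot,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = gates$oro_threshold,
                        colour = "red", linetype = 2) +
    ggplot2::geom_vline(xintercept = gates$gfp_threshold,
                        colour = "darkgreen", linetype = 2) +
    ggplot2::labs(x = "max GFP intensity (auto-contrast, 0-255)",
                  y = "max Oil Red O ratio R/(G+B)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Estimate the differentiated fraction from random fields of view
#'
#' Emulates manual counting in which a number of rectangular fields of view
#' are sampled per well: fields are placed uniformly at random (they may
#' overlap), cells are assigned to a field by their centroid, and the pooled
#' percentage over all sampled cells is the estimate.
#'
#' @param records Tibble with one row per cell carrying centroid coordinates
#'   `row`, `col` and a logical `has_droplets` column.
#' @param image_dim `c(height, width)` of the well image.
#' @param n_fields Number of fields (default 10).
#' @param field_size `c(height, width)` of each field in pixels.
#' @param seed RNG seed; placement is deterministic given it.
#' @return A list with `estimate` (pooled percent), `n_cells_sampled`,
#'   `n_pos_sampled` and `fields` (tibble of per-field placements and
#'   counts).
#' @export
field_sample_estimate <- function(records, image_dim, n_fields = 10,
                                  field_size, seed = 1L) {
  stopifnot(length(image_dim) == 2, length(field_size) == 2, n_fields >= 1)
  if (any(field_size > image_dim)) stop("field larger than the image")
  need <- c("row", "col", "has_droplets")
  if (!all(need %in% names(records))) {
    stop("records must carry row, col and has_droplets")
  }
  withr::with_seed(seed, {
    top <- stats::runif(n_fields, 1, image_dim[1] - field_size[1] + 1)
    left <- stats::runif(n_fields, 1, image_dim[2] - field_size[2] + 1)
  })
  per_field <- purrr::map_dfr(seq_len(n_fields), function(i) {
    inside <- records$row >= top[i] & records$row < top[i] + field_size[1] &
      records$col >= left[i] & records$col < left[i] + field_size[2]
    tibble::tibble(field = i, top = top[i], left = left[i],
                   n_cells = sum(inside),
                   n_pos = sum(inside & records$has_droplets))
  })
  n_sampled <- sum(per_field$n_cells)
  if (n_sampled == 0) stop("undefined result: no cells fell in the sampled fields")
  n_pos <- sum(per_field$n_pos)
  list(estimate = differentiated_fraction(n_pos, n_sampled),
       n_cells_sampled = n_sampled, n_pos_sampled = n_pos,
       fields = per_field)
}

#' Fold change between two percentages
#'
#' The ratio of two (typically one-decimal) percentages, rounded half away
#' from zero to one decimal — the convention used when reporting fold
#' increases/decreases of differentiated-cell percentages.
#'
#' @param percent_a Numerator percentage.
#' @param percent_b Denominator percentage; must be nonzero.
#' @return The one-decimal fold change.
#' @export
fold_change <- function(percent_a, percent_b) {
  if (any(percent_b == 0)) stop("fold change undefined: zero denominator")
  x <- percent_a / percent_b
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Summarize a well into droplet-positive counts and percentage
#'
#' @param condition Condition label.
#' @param n_total Total cell count.
#' @param n_droplet_pos Droplet-containing cell count.
#' @param n_gfp_pos,n_double_pos Optional gated counts.
#' @return A one-row tibble with `percent_droplet_pos` rounded to one
#'   decimal.
#' @export
quant_result <- function(condition, n_total, n_droplet_pos,
                         n_gfp_pos = NA_integer_, n_double_pos = NA_integer_) {
  tibble::tibble(
    condition = condition,
    n_total = as.integer(n_total),
    n_droplet_pos = as.integer(n_droplet_pos),
    percent_droplet_pos = round(differentiated_fraction(n_droplet_pos, n_total), 1),
    n_gfp_pos = as.integer(n_gfp_pos),
    n_double_pos = as.integer(n_double_pos)
  )
}
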