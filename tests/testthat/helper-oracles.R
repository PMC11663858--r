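# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the package's vectorized code paths.

# Per-cell statistics by explicit per-pixel iteration.
oracle_per_cell_stats <- function(cells, dmask = NULL, gfp = NULL, oro = NULL,
                                  overlap_min = 1) {
  labels <- sort(unique(cells[cells > 0]))
  rows <- lapply(labels, function(k) {
    area <- 0L; ndp <- 0L
    mg <- -Inf; mo <- -Inf
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(ncol(cells))) {
        if (cells[i, j] == k) {
          area <- area + 1L
          if (!is.null(dmask) && dmask[i, j]) ndp <- ndp + 1L
          if (!is.null(gfp)) mg <- max(mg, gfp[i, j])
          if (!is.null(oro)) mo <- max(mo, oro[i, j])
        }
      }
    }
    data.frame(label = k, area_px = area,
               n_droplet_px = if (is.null(dmask)) NA_integer_ else ndp,
               has_droplets = if (is.null(dmask)) NA else ndp >= overlap_min,
               max_gfp_norm = if (is.null(gfp)) NA_real_ else mg,
               max_oro_ratio = if (is.null(oro)) NA_real_ else mo)
  })
  do.call(rbind, rows)
}

# "Having" selection by explicit set intersection per label.
oracle_having <- function(cells, dmask, overlap_min = 1) {
  labels <- sort(unique(cells[cells > 0]))
  keep <- vapply(labels, function(k) {
    sum(dmask[cells == k]) >= overlap_min
  }, logical(1))
  as.integer(labels[keep])
}

# Kruskal-Wallis H by direct rank-sum arithmetic (tie-corrected).
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  rk <- rank(values)
  groups <- factor(groups)
  rsum <- tapply(rk, groups, sum)
  nsz <- tapply(rk, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / nsz) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Classical balanced two-way ANOVA sums of squares from cell means.
oracle_anova2_f <- function(df) {
  gm <- mean(df$value)
  a_means <- tapply(df$value, df$A, mean)
  b_means <- tapply(df$value, df$B, mean)
  cell_means <- tapply(df$value, list(df$A, df$B), mean)
  n_cell <- length(df$value) / (length(a_means) * length(b_means))
  ss_a <- n_cell * length(b_means) * sum((a_means - gm)^2)
  ss_b <- n_cell * length(a_means) * sum((b_means - gm)^2)
  ss_cells <- n_cell * sum((cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((df$value - cell_means[cbind(df$A, df$B)])^2)
  df_a <- length(a_means) - 1; df_b <- length(b_means) - 1
  df_ab <- df_a * df_b
  df_err <- length(df$value) - length(a_means) * length(b_means)
  ms_err <- ss_err / df_err
  c(A = (ss_a / df_a) / ms_err, B = (ss_b / df_b) / ms_err,
    `A:B` = (ss_ab / df_ab) / ms_err)
}

# Random label mask: nearest-seed (Voronoi) assignment over a small grid,
# with a background margin of unassigned pixels.
random_label_mask <- function(h = 64, w = 64, n_seeds = 5, bg_frac = 0.3) {
  sr <- runif(n_seeds, 1, h); sc <- runif(n_seeds, 1, w)
  mask <- matrix(0L, h, w)
  maxd <- sqrt(h * w / n_seeds / pi / bg_frac)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      d <- sqrt((sr - i)^2 + (sc - j)^2)
      k <- which.min(d)
      if (d[k] <= maxd) mask[i, j] <- k
    }
  }
  mask
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small well presets used in several files.
quick_well <- function(seed = 1, n_cells = 60, ...) {
  generate_well(synth_config(height = 320, width = 320, n_cells = n_cells,
                             seed = seed, ...))
}
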