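# Group statistics and tabular calculations: Kruskal-Wallis with Dunn
# pairwise comparisons, two-way ANOVA with Tukey HSD, 2^-ddCt relative
# expression, and dye-elution normalization with a Bradford standard curve.

#' Kruskal-Wallis test with Dunn pairwise comparisons
#'
#' Rank-based comparison of two or more groups (tie-corrected H via
#' `stats::kruskal.test`), followed by Dunn's pairwise z-tests on the mean
#' ranks with Holm adjustment of the pairwise p-values.
#'
#' @param data A data frame.
#' @param value Column of observations (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param p_adjust Adjustment method for the pairwise p-values (default
#'   `"holm"`; any method of [stats::p.adjust()]).
#' @return An object of class `"kw_multi"`: list with `statistic` (H), `df`,
#'   `p_value`, `pairwise` (tibble: `group1`, `group2`, `z`, `p_value`,
#'   `p_adj`), `group_summary`, and `n`.
#' @export
kruskal_wallis_multi <- function(data, value, group, p_adjust = "holm") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    stop("group(s) with fewer than 2 observations: ", paste(small, collapse = ", "))
  }
  all_tied <- length(unique(v)) == 1
  if (all_tied) {
    # fully degenerate data: no evidence of any group effect
    kt <- list(statistic = 0, parameter = nlevels(g) - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(v, g)
  }

  # Dunn's z statistics on mean ranks with tie correction
  n <- length(v)
  rk <- rank(v)
  mean_rank <- tapply(rk, g, mean)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- if (se > 0) (mean_rank[[a]] - mean_rank[[b]]) / se else 0
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adj <- stats::p.adjust(pw$p_value, method = p_adjust)

  structure(list(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, pairwise = pw,
    group_summary = tibble::tibble(group = lev,
                                   n = as.integer(sizes[lev]),
                                   mean_rank = as.numeric(mean_rank[lev])),
    n = n, p_adjust = p_adjust
  ), class = "kw_multi")
}

#' @export
print.kw_multi <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  cat(sprintf("Dunn pairwise comparisons (%s-adjusted):\n", x$p_adjust))
  print(as.data.frame(x$pairwise), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy kw_multi
#' @export
tidy.kw_multi <- function(x, ...) {
  dplyr::mutate(x$pairwise, method = "Dunn", .before = 1)
}

#' @method glance kw_multi
#' @export
glance.kw_multi <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = x$n, method = "Kruskal-Wallis")
}

#' Two-way ANOVA with Tukey HSD post hoc tests
#'
#' Fits `value ~ A * B`, reports type-II sums of squares (which coincide with
#' the classical decomposition for balanced designs) and Tukey HSD pairwise
#' comparisons.
#'
#' @param data A data frame.
#' @param value Observation column (tidy-eval).
#' @param factor_a,factor_b The two crossed factor columns (tidy-eval).
#' @return An object of class `"anova2"`: list with `table` (tibble of term,
#'   sum of squares, df, F, p), `tukey` (tibble of pairwise comparisons) and
#'   the fitted `aov` object in `fit`.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  df <- tibble::tibble(
    value = rlang::eval_tidy(rlang::enquo(value), data),
    A = factor(rlang::eval_tidy(rlang::enquo(factor_a), data)),
    B = factor(rlang::eval_tidy(rlang::enquo(factor_b), data))
  )
  cells <- table(df$A, df$B)
  if (any(cells == 0)) stop("empty design cell(s): every A x B combination needs data")
  if (any(cells < 2)) stop("need at least 2 replicates per design cell")
  fit <- stats::aov(value ~ A * B, data = df)
  a2 <- car::Anova(fit, type = 2)
  tab <- tibble::tibble(
    term = trimws(rownames(a2)),
    sumsq = a2[["Sum Sq"]], df = a2[["Df"]],
    statistic = a2[["F value"]], p_value = a2[["Pr(>F)"]]
  )
  tuk <- stats::TukeyHSD(fit)
  tukey <- purrr::map_dfr(names(tuk), function(term) {
    m <- tuk[[term]]
    tibble::tibble(term = term, contrast = rownames(m),
                   estimate = m[, "diff"], conf_low = m[, "lwr"],
                   conf_high = m[, "upr"], p_adj = m[, "p adj"])
  })
  structure(list(table = tab, tukey = tukey, fit = fit), class = "anova2")
}

#' @export
print.anova2 <- function(x, ...) {
  cat("Two-way ANOVA (type II):\n")
  print(as.data.frame(x$table), digits = 4)
  cat("Tukey HSD:\n")
  print(as.data.frame(x$tukey), digits = 4)
  invisible(x)
}

#' @method tidy anova2
#' @export
tidy.anova2 <- function(x, ...) x$table

#' @method glance anova2
#' @export
glance.anova2 <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble::tibble(df_residual = stats::df.residual(x$fit),
                 sigma = sqrt(s[["Mean Sq"]][nrow(s)]),
                 method = "two-way ANOVA + Tukey HSD")
}

#' Relative gene expression by the 2^-ddCt method
#'
#' For every sample and target gene, the cycle-threshold difference to the
#' reference gene is exponentiated (fold = 2^-dCt) and normalized so that the
#' mean relative expression of the control group is exactly 1 for each
#' transcript.
#'
#' @param data Tidy Ct table with one row per (sample, gene) measurement.
#' @param sample,gene,ct Columns naming the sample id, gene, and Ct value
#'   (tidy-eval).
#' @param reference_gene Name of the reference (housekeeping) gene.
#' @param group Column with the group of each sample (tidy-eval).
#' @param control_group Level of `group` used as the control.
#' @return A tibble with one row per (sample, target gene): `sample`,
#'   `group`, `gene`, `dct`, `fold` (2^-dCt) and `rel_expr` (control mean
#'   normalized to 1).
#' @export
ddct <- function(data, sample, gene, ct, reference_gene, group, control_group) {
  tab <- tibble::tibble(
    sample = rlang::eval_tidy(rlang::enquo(sample), data),
    gene = rlang::eval_tidy(rlang::enquo(gene), data),
    ct = rlang::eval_tidy(rlang::enquo(ct), data),
    group = rlang::eval_tidy(rlang::enquo(group), data)
  )
  if (any(tab$ct <= 0)) stop("Ct values must be positive")
  ref <- dplyr::filter(tab, .data$gene == reference_gene)
  if (nrow(ref) == 0) stop("reference gene not found: ", reference_gene)
  targets <- dplyr::filter(tab, .data$gene != reference_gene)
  joined <- dplyr::left_join(targets,
                             dplyr::select(ref, "sample", ct_ref = "ct"),
                             by = "sample")
  if (anyNA(joined$ct_ref)) {
    miss <- unique(joined$sample[is.na(joined$ct_ref)])
    stop("missing reference Ct for sample(s): ", paste(miss, collapse = ", "))
  }
  if (!control_group %in% tab$group) stop("control group not present: ", control_group)
  out <- joined |>
    dplyr::mutate(dct = .data$ct - .data$ct_ref, fold = 2^(-.data$dct)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(rel_expr = .data$fold /
                    mean(.data$fold[.data$group == control_group])) |>
    dplyr::ungroup()
  dplyr::select(out, "sample", "group", "gene", "dct", "fold", "rel_expr")
}

#' Fit a protein standard curve by ordinary least squares
#'
#' Fits `absorbance ~ concentration` to standards (duplicate concentrations
#' are averaged first), as for a Bradford assay with BSA dilutions, and
#' supports inverse prediction of concentration from absorbance.
#'
#' @param standards Data frame with columns `conc` and `abs`.
#' @return An object of class `"standard_curve"` with `slope`, `intercept`,
#'   `r_squared` and the averaged standards.
#' @export
fit_standard_curve <- function(standards) {
  if (!all(c("conc", "abs") %in% names(standards))) {
    stop("standards must have columns `conc` and `abs`")
  }
  avg <- standards |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(abs = mean(.data$abs), .groups = "drop")
  if (nrow(avg) < 2) stop("need at least 2 distinct standard concentrations")
  fit <- stats::lm(abs ~ conc, data = avg)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps^0.5) {
    stop("degenerate standards: zero slope, curve cannot be inverted")
  }
  # collinear standards are legal input; silence lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, standards = avg,
                 fit = fit),
            class = "standard_curve")
}

#' Predict concentration from absorbance on a standard curve
#'
#' @param curve A [fit_standard_curve()] object.
#' @param absorbance Absorbance value(s).
#' @return Predicted concentration(s) by linear inversion.
#' @export
predict_conc <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Normalize eluted-dye absorbance to protein content
#'
#' @param a500 Absorbance of the eluate at 500 nm.
#' @param protein Protein concentration (from the standard curve); must be
#'   positive.
#' @return `a500 / protein`.
#' @export
normalize_eluate <- function(a500, protein) {
  if (any(protein <= 0)) stop("protein concentration must be positive")
  a500 / protein
}
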