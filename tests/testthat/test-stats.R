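test_that("Kruskal-Wallis H agrees with direct rank-sum arithmetic", {
  df <- data.frame(v = c(1, 2, 3, 101, 102, 103, 201, 202, 203),
                   g = rep(c("a", "b", "c"), each = 3))
  res <- kruskal_wallis_multi(df, v, g)
  expect_equal(res$statistic, oracle_kw_h(df$v, df$g))
  expect_equal(res$df, 2)
  expect_equal(nrow(res$pairwise), 3)

  # shuffling observation order leaves H unchanged
  set.seed(2)
  perm <- sample(nrow(df))
  res_p <- kruskal_wallis_multi(df[perm, ], v, g)
  expect_equal(res_p$statistic, res$statistic)

  # identical values in all groups: no group effect at all
  flat <- data.frame(v = rep(5, 6), g = rep(c("a", "b"), each = 3))
  res0 <- kruskal_wallis_multi(flat, v, g)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_true(all(res0$pairwise$p_adj == 1))

  expect_error(
    kruskal_wallis_multi(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")), v, g),
    "fewer than 2")
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$statistic, res$statistic)
})

test_that("two-way ANOVA matches closed-form balanced sums of squares", {
  set.seed(14)
  df <- expand.grid(A = c("WT", "KO"), B = c("standard", "adipogenic"),
                    rep = 1:4)
  df$value <- 2 + (df$A == "KO") * 1.5 + (df$B == "adipogenic") * 3 +
    (df$A == "KO" & df$B == "adipogenic") * 0.8 + rnorm(nrow(df), 0, 0.5)
  res <- two_way_anova(df, value, A, B)
  want <- oracle_anova2_f(df)
  got <- setNames(res$table$statistic[match(c("A", "B", "A:B"), res$table$term)],
                  c("A", "B", "A:B"))
  expect_equal(got, want, tolerance = 1e-10)

  # scale invariance of F
  df2 <- df; df2$value <- df2$value * 2
  res2 <- two_way_anova(df2, value, A, B)
  expect_equal(res2$table$statistic, res$table$statistic)

  # zero between-group variance: all F are zero
  dff <- df
  dff$value <- as.numeric(dff$rep)  # identical replicate pattern in every cell
  resf <- two_way_anova(dff, value, A, B)
  f <- resf$table$statistic[resf$table$term %in% c("A", "B", "A:B")]
  expect_true(all(abs(f) < 1e-20))

  # structural errors
  bad <- df[!(df$A == "KO" & df$B == "adipogenic"), ]
  expect_error(two_way_anova(bad, value, A, B), "empty design cell")
  expect_s3_class(tidy(res), "tbl_df")
  expect_gt(nrow(res$tukey), 0)
})

test_that("relative expression follows the 2^-ddCt rule with exact control mean 1", {
  ct <- tibble::tibble(
    sample = c("t1", "t1", "c1", "c1"),
    gene = c("Cdh13", "ref", "Cdh13", "ref"),
    ct = c(25, 20, 24, 20),
    grp = c("treated", "treated", "control", "control"))
  out <- ddct(ct, sample, gene, ct, reference_gene = "ref",
              group = grp, control_group = "control")
  expect_equal(out$rel_expr[out$sample == "t1"], 0.5)
  expect_equal(out$rel_expr[out$sample == "c1"], 1)

  # a ddCt of -2 gives 4-fold expression
  ct2 <- tibble::tibble(
    sample = c("t1", "t1", "c1", "c1"),
    gene = rep(c("g", "ref"), 2),
    ct = c(18, 20, 20, 20),
    grp = c("treated", "treated", "control", "control"))
  out2 <- ddct(ct2, sample, gene, ct, "ref", grp, "control")
  expect_equal(out2$rel_expr[out2$sample == "t1"], 4)

  # control-group mean is exactly 1 for arbitrary control Ct values
  set.seed(8)
  ct3 <- tibble::tibble(
    sample = rep(sprintf("s%d", 1:6), each = 2),
    gene = rep(c("g", "ref"), 6),
    ct = runif(12, 18, 30),
    grp = rep(c("control", "treated"), each = 6))
  out3 <- ddct(ct3, sample, gene, ct, "ref", grp, "control")
  expect_identical(mean(out3$rel_expr[out3$group == "control"]), 1)

  # invariance to shifting target and reference Ct together
  ct4 <- ct3; ct4$ct <- ct4$ct + 3.25
  out4 <- ddct(ct4, sample, gene, ct, "ref", grp, "control")
  expect_equal(out4$rel_expr, out3$rel_expr)

  expect_error(ddct(ct3, sample, gene, ct, "nope", grp, "control"),
               "reference gene not found")
  missing_ref <- ct3[ct3$gene != "ref" | ct3$sample != "s2", ]
  expect_error(ddct(missing_ref, sample, gene, ct, "ref", grp, "control"),
               "missing reference")
})

test_that("standard curves invert linearly and eluate normalization divides", {
  std <- data.frame(conc = c(1, 2, 3, 4), abs = 0.1 * c(1, 2, 3, 4))
  curve <- fit_standard_curve(std)
  expect_equal(predict_conc(curve, 0.35), 3.5)
  expect_equal(curve$r_squared, 1)

  # duplicate standards are averaged before fitting
  dup <- data.frame(conc = c(1, 1, 2, 2), abs = c(0.09, 0.11, 0.19, 0.21))
  cd <- fit_standard_curve(dup)
  expect_equal(cd$slope, 0.1)

  flat <- data.frame(conc = c(1, 2, 3), abs = c(0.2, 0.2, 0.2))
  expect_error(fit_standard_curve(flat), "zero slope")

  expect_equal(normalize_eluate(0.5, 2.0), 0.25)
  expect_error(normalize_eluate(0.5, 0), "positive")
})
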