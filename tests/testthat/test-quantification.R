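test_that("droplet-containing cell selection matches set-intersection semantics", {
  cells <- matrix(0L, 12, 12)
  cells[1:4, 1:4] <- 1L; cells[1:4, 6:9] <- 2L; cells[7:10, 1:4] <- 3L
  dm <- matrix(FALSE, 12, 12)

  dm[2, 7] <- TRUE  # droplets only inside cell 2
  expect_equal(cells_having_droplets(cells, dm)$labels, 2L)

  expect_equal(cells_having_droplets(cells, matrix(FALSE, 12, 12))$labels,
               integer(0))

  # one droplet blob straddling cells 1 and 3 selects both
  dm2 <- matrix(FALSE, 12, 12)
  dm2[4:7, 2] <- TRUE
  expect_setequal(cells_having_droplets(cells, dm2)$labels, c(1L, 3L))

  # the filtered mask zeroes unselected labels and keeps selected ones intact
  flt <- cells_having_droplets(cells, dm)$mask
  expect_true(all(flt[cells == 2L] == 2L))
  expect_true(all(flt[cells != 2L] == 0L))

  expect_error(cells_having_droplets(cells, matrix(FALSE, 5, 5)), "shape")
})

test_that("selection equals a brute-force intersection oracle on random masks", {
  set.seed(123)
  for (rep in 1:100) {
    m <- random_label_mask(20, 20, n_seeds = sample(2:6, 1))
    dm <- matrix(runif(400) < 0.1, 20, 20)
    omin <- sample(1:3, 1)
    expect_identical(cells_having_droplets(m, dm, overlap_min = omin)$labels,
                     oracle_having(m, dm, overlap_min = omin))
  }
})

test_that("differentiated fraction is a guarded percentage", {
  expect_equal(differentiated_fraction(16, 200), 8.0)
  expect_equal(differentiated_fraction(0, 500), 0.0)
  expect_equal(differentiated_fraction(37, 37), 100.0)
  expect_error(differentiated_fraction(0, 0), "undefined")
  expect_error(differentiated_fraction(5, 3), "n_pos")
})

test_that("gate classification uses strict thresholds and partitions the cells", {
  rec <- tibble::tibble(label = 1:4,
                        max_gfp_norm = c(200, 127, 130, 50),
                        max_oro_ratio = c(1.4, 2.0, 0.5, 1.0))
  g <- gate_cells(rec, gate_config())
  expect_equal(g$records$class,
               c("GFP+ORO+", "GFP-ORO+", "GFP+ORO-", "GFP-ORO-"))
  expect_equal(sum(g$counts$n), 4)
  expect_equal(g$n_double_pos, 1)

  expect_error(gate_cells(tibble::tibble(label = 1), gate_config()), "records")

  # random records always partition into the four classes
  set.seed(5)
  r <- tibble::tibble(label = 1:200,
                      max_gfp_norm = runif(200, 0, 255),
                      max_oro_ratio = c(runif(199, 0, 3), Inf))
  gr <- gate_cells(r)
  expect_equal(sum(gr$counts$n), 200)
  expect_equal(gr$n_gfp_pos, sum(r$max_gfp_norm > 127))
})

test_that("scatter table and plot mirror the gated records", {
  rec <- tibble::tibble(label = 1:3,
                        max_gfp_norm = c(10, 140, 250),
                        max_oro_ratio = c(0.2, 0.9, 1.7))
  tab <- scatter_table(rec)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("label", "gfp", "oro", "class"))
  expect_equal(nrow(tab), gate_cells(rec)$n_total)
  expect_error(scatter_table(rec[0, ]), "non-empty")

  p <- plot_gate_scatter(rec)
  expect_s3_class(p, "ggplot")
  # all-negative records still draw, with nothing above the ORO line
  neg <- tibble::tibble(label = 1:5, max_gfp_norm = runif(5, 0, 100),
                        max_oro_ratio = runif(5, 0, 0.9))
  expect_s3_class(plot_gate_scatter(neg), "ggplot")
  expect_equal(gate_cells(neg)$n_oro_pos, 0)
})

test_that("field sampling is exhaustive when the field covers the well", {
  rec <- tibble::tibble(row = runif(50, 1, 100), col = runif(50, 1, 100),
                        has_droplets = rep(c(TRUE, FALSE), c(10, 40)))
  est <- field_sample_estimate(rec, image_dim = c(100, 100), n_fields = 1,
                               field_size = c(100, 100), seed = 3)
  expect_equal(est$estimate, 20)
  expect_equal(est$n_cells_sampled, 50)

  expect_error(field_sample_estimate(rec, c(100, 100), 1, c(200, 100)),
               "larger")
  expect_error(field_sample_estimate(rec[0, ], c(100, 100), 2, c(10, 10)),
               "undefined")
})

test_that("ten-field estimates are unbiased for the whole-well percentage", {
  w <- generate_well(synth_config(n_cells = 300, adipocyte_fraction = 0.15,
                                  height = 640, width = 640, seed = 31))
  rec <- dplyr::mutate(w$truth$cells, has_droplets = .data$n_droplet_px > 0)
  whole <- 100 * mean(rec$has_droplets)
  ests <- vapply(1:200, function(s) {
    field_sample_estimate(rec, image_dim = c(640, 640), n_fields = 10,
                          field_size = c(160, 160), seed = s)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - whole), 1)
  # determinism in the seed
  e1 <- field_sample_estimate(rec, c(640, 640), 10, c(160, 160), seed = 8)
  e2 <- field_sample_estimate(rec, c(640, 640), 10, c(160, 160), seed = 8)
  expect_identical(e1, e2)
})

test_that("fold changes reproduce one-decimal percentage arithmetic", {
  expect_equal(fold_change(8.5, 5.6), 1.5)
  expect_equal(fold_change(3.1, 0.6), 5.2)
  expect_equal(fold_change(4.2, 4.2), 1.0)
  # half away from zero
  expect_equal(fold_change(1.25, 1), 1.3)
  expect_equal(fold_change(-1.25, 1), -1.3)
  expect_error(fold_change(1, 0), "zero")
})
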