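make_nilered_experiment <- function(root, seeds = 1:4,
                                    fractions = c(0.25, 0.25, 0.05, 0.05)) {
  conds <- rep(c("LDL", "none"), each = 2)
  wells <- purrr::map_dfr(seq_along(seeds), function(i) {
    dir <- file.path(root, sprintf("well%d", i))
    w <- generate_well(synth_config(height = 320, width = 320, n_cells = 60,
                                    adipocyte_fraction = fractions[i],
                                    seed = seeds[i]))
    write_fixture(w, dir)
    tibble::tibble(well_id = sprintf("w%d", i), path = dir,
                   condition = conds[i])
  })
  experiment_config(wells)
}

test_that("the Nile Red pipeline summarizes wells, conditions and a group test", {
  root <- withr::local_tempdir()
  cfg <- make_nilered_experiment(root)
  res <- run_nilered_pipeline(cfg)
  expect_equal(nrow(res$per_well), 4)
  expect_equal(nrow(res$summary), 2)
  expect_setequal(res$summary$condition, c("LDL", "none"))
  expect_s3_class(res$stats, "kw_multi")
  expect_equal(nrow(res$stats$pairwise), 1)
  expect_equal(nrow(res$errors), 0)
  # the shared droplet threshold is a single echoed number
  expect_length(res$droplet_threshold, 1)
  expect_true(is.numeric(res$droplet_threshold))
  # percentages track the generator fractions by condition
  ldl <- res$per_well$percent_droplet_pos[res$per_well$condition == "LDL"]
  none <- res$per_well$percent_droplet_pos[res$per_well$condition == "none"]
  expect_true(mean(ldl) > mean(none))
})

test_that("reruns of the same configuration write byte-identical outputs", {
  root <- withr::local_tempdir()
  cfg <- make_nilered_experiment(root)
  out1 <- file.path(root, "run1"); out2 <- file.path(root, "run2")
  run_nilered_pipeline(cfg, output_dir = out1)
  run_nilered_pipeline(cfg, output_dir = out2)
  for (f in c("per_well.csv", "condition_summary.csv", "report.txt")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6),
                     label = f)
  }
})

test_that("missing channels fail validation and per-well errors are isolated", {
  root <- withr::local_tempdir()
  cfg <- make_nilered_experiment(root)
  file.remove(file.path(cfg$wells$path[2], "lipid_green.tif"))
  expect_error(run_nilered_pipeline(cfg), "w2")

  # a corrupt (but present) channel only fails its own well
  writeLines("not a tiff", file.path(cfg$wells$path[2], "lipid_green.tif"))
  res <- run_nilered_pipeline(
    experiment_config(cfg$wells[c(3, 4, 2), ]))  # corrupt well last
  expect_equal(nrow(res$errors), 1)
  expect_equal(res$errors$well_id, "w2")
  expect_equal(nrow(res$per_well), 2)
})

test_that("the rescue pipeline scores cells per well and echoes its gates", {
  root <- withr::local_tempdir()
  dirs <- file.path(root, c("ctrl", "resc"))
  w_ctrl <- generate_well(synth_config(height = 512, width = 512, n_cells = 150,
                                       adipocyte_fraction = 0.4,
                                       gfp_fraction = 0.1, seed = 41))
  w_resc <- generate_well(synth_config(height = 512, width = 512, n_cells = 150,
                                       adipocyte_fraction = 0.4,
                                       gfp_fraction = 0.1,
                                       gfp_suppresses_adipogenesis = TRUE,
                                       seed = 42))
  write_fixture(w_ctrl, dirs[1]); write_fixture(w_resc, dirs[2])
  cfg <- experiment_config(tibble::tibble(
    well_id = c("ctrl", "resc"), path = dirs,
    condition = c("control-virus", "tcad-virus")))
  out <- file.path(root, "out")
  res <- run_rescue_pipeline(cfg, output_dir = out)

  # one record per truth cell, within 2% segmentation error
  for (i in 1:2) {
    n_truth <- 150
    n_seen <- res$gate_counts$n_total[i]
    expect_lte(abs(n_seen - n_truth), 0.02 * n_truth)
  }
  # double positives: present without suppression, fewer with it
  expect_gt(res$gate_counts$n_double_pos[1], 0)
  expect_lt(res$gate_counts$n_double_pos[2], res$gate_counts$n_double_pos[1])

  # report embeds the gate thresholds (audit trail)
  report <- readLines(file.path(out, "report.txt"))
  expect_true(any(grepl("gfp_threshold: 127", report)))
  expect_true(any(grepl("oro_threshold: 1", report)))
  expect_true(file.exists(file.path(out, "cell_records.csv")))
  expect_true(file.exists(file.path(out, "scatter_ctrl.png")))
})

test_that("a well with no GFP signal yields no cells above the GFP gate", {
  root <- withr::local_tempdir()
  w <- generate_well(synth_config(height = 320, width = 320, n_cells = 60,
                                  adipocyte_fraction = 0.3, gfp_fraction = 0,
                                  noise_sd = 0,
                                  intensity = list(background = 0), seed = 5))
  dir <- file.path(root, "neg")
  write_fixture(w, dir)
  cfg <- experiment_config(tibble::tibble(well_id = "neg", path = dir,
                                          condition = "none"))
  res <- suppressWarnings(run_rescue_pipeline(cfg))
  expect_equal(res$gate_counts$n_gfp_pos, 0)
  expect_equal(res$gate_counts$n_double_pos, 0)
})
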