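test_that("stack generation is deterministic and honours the empty case", {
  cfg <- image_sim_config(seed = 5)
  a <- generate_image_stack(cfg)
  b <- generate_image_stack(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)

  cfg2 <- image_sim_config(seed = 6)
  expect_false(identical(generate_image_stack(cfg2)$stack$voxels,
                         a$stack$voxels))

  # no swellings, no noise, flat illumination: additive rendering peaks at
  # fibre intensity over the background level
  cfg0 <- image_sim_config(n_swellings_large = 0, n_swellings_small = 0,
                           noise_sd = 0, background_gradient_amplitude = 0,
                           mode = "fluorescence", background_level = 10,
                           n_fibres = 3, fibre_intensity = 40, seed = 2)
  sim0 <- generate_image_stack(cfg0)
  expect_equal(max(sim0$stack$voxels), 10 + 40)
  expect_equal(nrow(sim0$truth), 0)
})

test_that("ground-truth size classes match the particle filters by construction", {
  sim <- generate_image_stack(image_sim_config(n_swellings_large = 12,
                                               n_swellings_small = 5,
                                               seed = 9))
  expect_equal(sum(sim$truth$passes_filter), 12)
  expect_equal(sum(!sim$truth$passes_filter), 5)
  expect_equal(sim$truth$size_class[sim$truth$passes_filter],
               rep("large", 12))

  # flags recomputed from geometry agree with the stored flags
  flags <- recompute_filter_flags(sim$truth, sim$stack$pixel_size,
                                  sim$stack$z_step)
  expect_identical(flags, sim$truth$passes_filter)

  # analytic volumes are the truncated-ellipsoid volumes of the sigmas used
  expect_equal(sim$truth$volume_um3,
               4 / 3 * pi * sim$truth$radius_xy_um^2 * sim$truth$radius_z_um)
})

test_that("config validation rejects degenerate geometry", {
  expect_error(image_sim_config(swelling_radius_range = c(1, 0.5)), "ordered")
  expect_error(image_sim_config(pixel_size = 0), "pixel_size")
  expect_error(cohort_sim_config(n_per_cell = 1))
  expect_error(cohort_sim_config(swelling_peak_time_male = 120,
                                 swelling_peak_time_female = 60),
               "peak")
})

test_that("cohort generation has the designed layout and determinism", {
  cfg <- cohort_sim_config(seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 2 * 2 * 2 * 5)  # sex x group x time x n
  expect_identical(co, generate_cohort(cfg))
  expect_false(identical(co, generate_cohort(cohort_sim_config(seed = 5))))

  # empty-vector animals never carry swellings and keep baseline TH
  ev <- co[co$group == "empty", ]
  expect_true(all(ev$swelling_count == 0))
  expect_true(abs(mean(ev$th_od) - cfg$th_baseline) <
                3 * cfg$od_noise_sd / sqrt(nrow(ev)))
})

test_that("null cohort configuration makes the groups exchangeable", {
  cfg <- cohort_sim_config(th_decline_male = c(0, 0),
                           th_decline_female = c(0, 0),
                           swelling_peak_mean = 0, n_per_cell = 30, seed = 8)
  co <- generate_cohort(cfg)
  expect_true(all(co$swelling_count == 0))
  d <- abs(mean(co$th_od[co$group == "a53t"]) -
             mean(co$th_od[co$group == "empty"]))
  expect_lt(d, 4 * cfg$od_noise_sd / sqrt(sum(co$group == "a53t")))
})

test_that("stage-score reconstruction matches exhaustive tuple enumeration", {
  # printed summaries of the study's 60- and 120-day groups
  expect_equal(best_stage_scores(2.2, 0.8, 5), c(3, 3, 2, 2, 1))
  expect_equal(best_stage_scores(2.5, 0.6, 4), c(3, 3, 2, 2))
  expect_equal(best_stage_scores(1.0, 0.0, 3), c(1, 1, 1))

  rec <- reconstruct_stage_scores(2.6, 0.6, 5)
  expect_equal(rec$candidates[[1]], c(3, 3, 3, 2, 2))
  expect_equal(rec$sd[1], sd(c(3, 3, 3, 2, 2)), tolerance = 1e-12)
  expect_equal(rec$candidates[[2]], c(3, 3, 3, 3, 1))
  expect_false(rec$tie)

  # impossible summary: explicit empty result
  none <- reconstruct_stage_scores(2.13, 0.1, 5, digits = 2)
  expect_length(none$candidates, 0)

  # cross-check against the 3^n brute force on assorted summaries
  cases <- list(c(2.6, 0.6, 5), c(1.6, 0.6, 5), c(2.2, 0.8, 5),
                c(2.5, 0.6, 4), c(2.0, 1.0, 6), c(1.8, 0.4, 7))
  key <- function(v) paste(sort(v), collapse = ",")
  for (cs in cases) {
    mine <- reconstruct_stage_scores(cs[1], cs[2], cs[3])$candidates
    ref <- oracle_scores(cs[1], cs[2], cs[3])
    expect_setequal(vapply(mine, key, ""), vapply(ref, key, ""))
    if (length(mine)) expect_equal(key(mine[[1]]), key(ref[[1]]))
  }
})

test_that("stacks survive a TIFF round-trip with calibration", {
  sim <- generate_image_stack(image_sim_config(width = 32, height = 32,
                                               depth = 4,
                                               n_swellings_large = 2,
                                               n_swellings_small = 1,
                                               min_separation = 1, seed = 3))
  path <- file.path(tempdir(), "roundtrip.tif")
  write_stack_tiff(sim$stack, path, extra = list(truth = sim$truth))
  back <- read_stack_tiff(path)
  expect_equal(back$voxels, sim$stack$voxels)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$z_step, sim$stack$z_step)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(nrow(meta$truth), nrow(sim$truth))
  unlink(c(path, paste0(path, ".json")))
})
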