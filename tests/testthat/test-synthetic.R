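# Synthetic generator: determinism, ground-truth structure, geometry, and
# trace construction.

test_that("identical config and seed give bit-identical explants", {
  cfg <- explant_sim_config(n_cells = 20, seed = 77)
  e1 <- generate_explant(cfg)
  e2 <- generate_explant(cfg)
  expect_identical(e1, e2)
  cfg2 <- calcium_sim_config(n_rois = 8, seed = 12)
  expect_identical(generate_calcium_recording(cfg2),
                   generate_calcium_recording(cfg2))
})

test_that("noise-free control cell peaks where configured", {
  cfg <- explant_sim_config(n_cells = 1, group = "control", noise_sd = 0,
                            phase_sd_h = 0, spatial_gradient_h_per_unit = 0,
                            damping_per_cycle = 0, base_peak_time_h = 12,
                            period_mean_h = 24, period_sd_h = 0,
                            duration_h = 96, sampling_interval_min = 1,
                            seed = 1)
  e <- generate_explant(cfg)
  cell <- e$cells[[1]]
  first_cycle <- cell$t_min < 24 * 60
  argmax_h <- cell$t_min[first_cycle][which.max(cell$intensity[first_cycle])] / 60
  expect_equal(argmax_h, 12, tolerance = 1 / 60)
  expect_equal(e$truth$true_peak_h, 12)
})

test_that("truth labels follow the configured rapid fraction", {
  cfg <- explant_sim_config(n_cells = 1000, group = "delay",
                            rapid_fraction = 0.3, seed = 31)
  e <- generate_explant(cfg)
  n_rapid <- sum(e$truth$population == "rapid")
  # 300 +/- 4 binomial SDs (sqrt(1000 * .3 * .7) ~ 14.5)
  expect_gt(n_rapid, 300 - 58)
  expect_lt(n_rapid, 300 + 58)
})

test_that("degenerate shift SDs give exactly two shift values", {
  cfg <- explant_sim_config(n_cells = 50, group = "delay",
                            rapid_fraction = 0.4, rapid_shift_h = 6,
                            slow_shift_h = 0, rapid_shift_sd_h = 0,
                            slow_shift_sd_h = 0, seed = 2)
  e <- generate_explant(cfg)
  expect_setequal(unique(e$truth$true_shift_h), c(0, 6))
  expect_true(all(e$truth$true_shift_h[e$truth$population == "rapid"] == 6))
})

test_that("cells lie inside the lobe outline; rapid cells sit ventrolaterally", {
  e <- generate_explant(explant_sim_config(n_cells = 400, group = "delay",
                                           rapid_fraction = 0.3,
                                           ventrolateral_prob = 1, seed = 9))
  expect_true(all(in_scn_outline(e$truth$x, e$truth$y)))
  rapid <- e$truth$population == "rapid"
  expect_true(all(in_ventrolateral_sector(e$truth$x[rapid], e$truth$y[rapid])))
  expect_setequal(unique(e$truth$population), c("rapid", "slow"))
})

test_that("noise-free traces have cycle intervals equal to the period", {
  cfg <- explant_sim_config(n_cells = 3, noise_sd = 0, phase_sd_h = 0,
                            period_sd_h = 0, period_mean_h = 24.5,
                            duration_h = 120, seed = 5)
  e <- process_explant(generate_explant(cfg))
  iv <- unlist(e$intervals)
  expect_true(all(abs(iv - 24.5) < 1 / 60))
})

test_that("config invariants are enforced", {
  expect_error(explant_sim_config(rapid_fraction = 1.2), "rapid_fraction")
  expect_error(explant_sim_config(period_mean_h = 30), "period_mean_h")
  expect_error(explant_sim_config(duration_h = 40), "duration_h")
  expect_error(explant_sim_config(sampling_interval_min = 0),
               "sampling_interval")
  expect_error(calcium_sim_config(class_probs = c(excitatory = 0.5,
                                                  inhibitory = 0.5,
                                                  null = 0.5)), "sum to 1")
  expect_error(calcium_sim_config(stim_times_s = c(80, 20)), "increasing")
  expect_error(calcium_sim_config(transient_amplitude_rel = 1.5), "negative")
})

test_that("rendered stack puts each cell's light at its center", {
  cell <- make_cosine_series(dur_h = 75, dt_min = 29, x = -0.4, y = 0.4)
  e <- make_explant(list(cell))
  st <- render_image_stack(e, width = 40, height = 30, cell_radius_px = 2,
                           background_sd = 0)
  ctr <- attr(st, "centers")
  for (k in c(1, 50, dim(st)[3])) {
    idx <- which(st[, , k] == max(st[, , k]), arr.ind = TRUE)
    expect_lt(abs(idx[1, 1] - ctr[1, "row"]), 1)
    expect_lt(abs(idx[1, 2] - ctr[1, "col"]), 1)
  }
  expect_equal(dim(st)[3], length(cell$t_min))
})

test_that("empty explant renders as pure noise and small grids error", {
  e <- make_explant(list())
  st <- render_image_stack(e, width = 16, height = 16, background_sd = 1,
                           seed = 3)
  expect_equal(dim(st), c(16, 16, 3))
  expect_lt(abs(mean(st)), 0.1)
  cell <- make_cosine_series(dur_h = 75, dt_min = 29)
  expect_error(render_image_stack(make_explant(list(cell)), width = 6,
                                  height = 6, cell_radius_px = 2),
               "grid too small")
})

test_that("null-class calcium ROI stays at baseline; excitatory doubles it", {
  cfg <- calcium_sim_config(n_rois = 4, noise_sd_nM = 0,
                            class_probs = c(excitatory = 0, inhibitory = 0,
                                            null = 1), seed = 8)
  rois <- generate_calcium_recording(cfg)
  ca <- roi_ca_series(rois[[1]])
  expect_true(all(abs(ca - cfg$baseline_nM) < 1e-9))

  cfg2 <- calcium_sim_config(n_rois = 4, noise_sd_nM = 0,
                             transient_amplitude_rel = 1,
                             class_probs = c(excitatory = 1, inhibitory = 0,
                                             null = 0), seed = 8)
  ca2 <- roi_ca_series(generate_calcium_recording(cfg2)[[1]])
  expect_equal(max(ca2), 2 * cfg2$baseline_nM, tolerance = 1e-9)
})

test_that("population shift draws converge to the configured mixture", {
  sh <- draw_population_shifts(explant_sim_config(
    n_cells = 10000, group = "delay", rapid_fraction = 0.29, seed = 13))
  pop <- attr(sh, "population")
  p <- mean(pop == "rapid")
  ci <- 4 * sqrt(0.29 * 0.71 / 10000)
  expect_gt(p, 0.29 - ci)
  expect_lt(p, 0.29 + ci)
  expect_equal(mean(sh[pop == "rapid"]), 4, tolerance = 0.05)
})
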