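# Template maps and per-cell phase shifts: standard size, alignment,
# mirroring, gap handling, control self-test, recovery.

test_that("standard size is the mean bounding extent", {
  mk <- function(w, h) {
    cells <- list(cell_series("a", -w / 2, 0, 0:2, 1:3),
                  cell_series("b", w / 2, h, 0:2, 1:3),
                  cell_series("c", 0, h / 2, 0:2, 1:3))
    make_explant(cells)
  }
  expect_equal(unname(standardize_size(list(mk(100, 50)))), c(100, 50))
  expect_equal(unname(standardize_size(list(mk(100, 50), mk(200, 70)))),
               c(150, 60))
  expect_error(standardize_size(list()), "no explants")
})

test_that("an explant already in the standard frame aligns to itself", {
  e <- fx_controls()[[1]]
  a <- align_explant(e)
  expect_equal(a$metrics$x, e$metrics$x, tolerance = 1e-9)
  expect_equal(a$metrics$y, e$metrics$y, tolerance = 1e-9)
  expect_equal(unname(a$transform$scale_x), c(1, 1), tolerance = 1e-9)
})

test_that("a scaled, rotated, translated explant is recovered exactly", {
  e <- fx_controls()[[1]]
  warped <- transform_explant(e, scale = 2, rotate_rad = 0.4,
                              translate = c(5, -3))
  back <- align_explant(warped)
  expect_equal(back$metrics$x, e$metrics$x, tolerance = 1e-6)
  expect_equal(back$metrics$y, e$metrics$y, tolerance = 1e-6)
  expect_equal(unname(back$transform$scale_x), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("landmark problems raise alignment errors", {
  e <- fx_controls()[[1]]
  e_bad <- e
  e_bad$landmarks$v3 <- NULL
  expect_error(align_explant(e_bad), "missing landmarks")
  e_deg <- e
  e_deg$landmarks$v3 <- e_deg$landmarks$oc
  expect_error(align_explant(e_deg), "degenerate")
  e_chk <- e
  e_chk$check_landmarks <- list(list(at = c(0.5, 0.5), expect = c(0.9, 0.9)))
  expect_error(align_explant(e_chk), "mismatch beyond tolerance")
  # a correct check landmark passes
  e_ok <- e
  e_ok$check_landmarks <- list(list(at = c(0, 0.5), expect = c(0, 0.5)))
  expect_silent(align_explant(e_ok))
})

test_that("single-cell template mirrors the entry across the midline", {
  e <- make_explant(list(cell_series("a", 0.5, 0.25, 0:2, 1:3)))
  e$metrics <- data.frame(cell_id = "a", x = 0.5, y = 0.25, peak1_h = 12,
                          period_h = 24, n_cycles = 3, included = TRUE)
  tm <- build_template(list(e))
  expect_equal(nrow(tm$entries), 2)
  expect_setequal(tm$entries$x, c(-0.5, 0.5))
  expect_true(all(tm$entries$peak_h == 12))
  expect_true(all(tm$entries$y == 0.25))
})

test_that("overlapping cells average their peak times", {
  e <- make_explant(list())
  e$metrics <- data.frame(cell_id = c("a", "b"), x = c(0.501, 0.499),
                          y = 0.25, peak1_h = c(12, 14), period_h = 24,
                          n_cycles = 3, included = TRUE)
  tm <- build_template(list(e))
  expect_true(all(tm$entries$peak_h == 13))
  expect_true(all(tm$entries$n == 2))
})

test_that("templates are mirror-symmetric with gaps recorded", {
  tm <- fx_template()
  key <- function(x, y) paste(round(x * tm$grid_n), round(y * tm$grid_n))
  m <- match(key(-tm$entries$x, tm$entries$y),
             key(tm$entries$x, tm$entries$y))
  expect_false(anyNA(m))
  expect_equal(tm$entries$peak_h[m], tm$entries$peak_h, tolerance = 1e-12)
  expect_gt(nrow(tm$gaps), 0)
  expect_true(all(in_scn_outline(tm$entries$x, tm$entries$y)))
  expect_error(build_template(list()), "no cells")
})

test_that("template recovers the ventral-dorsal peak-time gradient", {
  tm <- fx_template()
  slope <- coef(lm(peak_h ~ y, data = tm$entries, weights = tm$entries$n))[2]
  expect_equal(unname(slope), 4, tolerance = 0.4)  # configured gradient
})

test_that("shifts subtract the template peak; gap cells are dropped", {
  tm <- structure(list(
    entries = data.frame(x = 0.5, y = 0.25, peak_h = 12, n = 1),
    gaps = data.frame(x = numeric(0), y = numeric(0)),
    spacing = 0.025, grid_n = 40, region = "central"),
    class = "template_map")
  e <- make_explant(list())
  e$metrics <- data.frame(cell_id = c("a", "b"), x = c(0.5, -0.8),
                          y = c(0.26, 0.1), peak1_h = c(15, 13),
                          period_h = 24, n_cycles = 3, included = TRUE)
  cs <- compute_cell_shifts(e, tm)
  expect_equal(cs$shifts$shift_h, 3)
  expect_equal(cs$n_dropped, 1L)
  expect_error(compute_cell_shifts(e, structure(list(entries =
    tm$entries[0, ]), class = "template_map")), "empty")
})

test_that("control explants score near zero against the control template", {
  tm <- fx_template()
  for (e in fx_controls()) {
    cs <- compute_cell_shifts(e, tm)
    expect_lt(mean(abs(cs$shifts$shift_h)), 0.25)
  }
})

test_that("delay-cohort shifts are recovered with small error", {
  # tightly synchronized configuration: per-cell jitter enters measured
  # shifts one-to-one, so recovery of the mapping itself is assessed at low
  # jitter
  ctrl <- lapply(1:4, function(i) align_explant(process_explant(
    generate_explant(explant_sim_config(n_cells = 200, group = "control",
                                        phase_sd_h = 0.25, seed = 300 + i),
                     sprintf("c%d", i)))))
  tm <- build_template(ctrl)
  d <- align_explant(process_explant(generate_explant(
    explant_sim_config(n_cells = 300, group = "delay", phase_sd_h = 0.25,
                       rapid_shift_h = 4, slow_shift_h = 1, seed = 55), "d")))
  cs <- compute_cell_shifts(d, tm)
  m <- merge(cs$shifts, d$truth[, c("cell_id", "true_shift_h")],
             by = "cell_id")
  expect_gt(nrow(m), 200)
  expect_lt(mean(abs(m$shift_h - m$true_shift_h)), 0.5)
})
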