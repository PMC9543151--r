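# Gaussian bimodality analysis: binning, component fits, model selection,
# population fractions, intersection cutoff, exact signed-rank test.

test_that("histogram uses 15-min bins on quarter-hour boundaries", {
  h <- make_histogram(c(1.0, 1.1, 1.2))
  expect_equal(h$bin_width, 0.25)
  expect_equal(sum(h$counts), 3)
  expect_equal(sum(h$counts > 0), 1)
  occupied <- h$mids[h$counts > 0]
  expect_equal(occupied, 1.125)  # bin [1.0, 1.25)
  expect_error(make_histogram(numeric(0)), "no shifts")
})

test_that("histogram counts match an independent tally", {
  set.seed(14)
  x <- runif(500, -2, 7)
  h <- make_histogram(x)
  expect_equal(sum(h$counts), 500)
  for (i in sample(seq_along(h$counts), 10)) {
    lo <- h$bin_edges[i]
    hi <- h$bin_edges[i + 1]
    expect_equal(h$counts[i], sum(x >= lo & x < hi))
  }
})

test_that("component density integrates to its area A", {
  for (p in list(c(100, 2, 3), c(7, 0.5, -1), c(250, 4.2, 10))) {
    q <- integrate(function(x) scnshift:::gauss_component(x, p[1], p[2], p[3]),
                   -Inf, Inf, rel.tol = 1e-10)
    expect_equal(q$value, p[1], tolerance = 1e-6)
  }
})

test_that("a noise-free single component is recovered within 1%", {
  A <- 100; w <- 2; xc <- 3
  edges <- seq(-3, 9, by = 0.25)
  mids <- edges[-length(edges)] + 0.125
  counts <- scnshift:::gauss_component(mids, A, w, xc) * 0.25
  h <- structure(list(bin_edges = edges, mids = mids, counts = counts,
                      n_total = round(sum(counts)), bin_width = 0.25),
                 class = "shift_histogram")
  f1 <- fit_gaussians(h, 1)
  expect_equal(f1$components$A, A, tolerance = 0.01)
  expect_equal(f1$components$w, w, tolerance = 0.01)
  expect_equal(f1$components$xc, xc, tolerance = 0.01)
  f2 <- fit_gaussians(h, 2)
  expect_lte(f2$rss, f1$rss + 1e-8)  # nested models
})

test_that("well-separated mixture components are localized within one bin", {
  set.seed(23)
  x <- c(rnorm(250, 1, 0.5), rnorm(250, 4, 0.5))  # w = 1 components
  h <- make_histogram(x)
  f2 <- fit_gaussians(h, 2)
  expect_equal(f2$components$xc, c(1, 4), tolerance = 0.25)
  expect_equal(f2$components$A / sum(f2$components$A), c(0.5, 0.5),
               tolerance = 0.05)
  expect_error(fit_gaussians(make_histogram(c(1, 1.1)), 2), "occupied bins")
})

test_that("model selection follows the delta-AIC rule with overrides", {
  sep <- data.frame(A = c(100, 50), w = c(1, 1), xc = c(1, 4))
  f2 <- function(aic, chi = 5, comp = sep) make_fit(2, aic, chi, comp)
  f1 <- make_fit(1, 100, 10, data.frame(A = 150, w = 2, xc = 2))
  expect_equal(select_model(f1, f2(98))$selected, "bimodal")
  expect_equal(select_model(f1, f2(99))$selected, "unimodal")
  # nested override: smaller-area component entirely within the larger
  nested <- data.frame(A = c(150, 20), w = c(3, 0.5), xc = c(2, 2.5))
  expect_equal(select_model(f1, f2(90, comp = nested))$selected, "unimodal")
  # chi-square must not worsen
  expect_equal(select_model(f1, f2(90, chi = 11))$selected, "unimodal")
  expect_error(select_model(f1, NULL), "missing fit")
})

test_that("population fractions come from the component areas", {
  f2 <- make_fit(2, 0, 0, data.frame(A = c(63, 37), w = c(1, 1),
                                     xc = c(0.88, 2.65)))
  ps <- population_stats(f2)
  expect_equal(ps$fractions, c(0.63, 0.37))
  expect_equal(ps$mean_shifts_h, c(0.88, 2.65))
  ps2 <- population_stats(make_fit(2, 0, 0, data.frame(A = c(5, 5),
                                                       w = c(1, 1),
                                                       xc = c(1, 3))))
  expect_equal(ps2$fractions, c(0.5, 0.5))
})

test_that("intersection cutoff solves the equal-density point", {
  eq <- intersection_cutoff(list(A = 10, w = 1, xc = 1),
                            list(A = 10, w = 1, xc = 3))
  expect_equal(eq, 2)
  shifted <- intersection_cutoff(list(A = 20, w = 1, xc = 1),
                                 list(A = 10, w = 1, xc = 3))
  expect_gt(shifted, 2)  # pushed toward the smaller component
  # closed form for equal widths: x = midpoint + w^2 ln(A1/A2) / (4 dx)
  expect_equal(shifted, 2 + log(2) / (4 * 2), tolerance = 1e-9)
  # residual property for arbitrary parameters
  set.seed(31)
  for (i in 1:20) {
    c1 <- list(A = runif(1, 10, 200), w = runif(1, 0.5, 2),
               xc = runif(1, 0, 1))
    c2 <- list(A = runif(1, 10, 200), w = runif(1, 0.5, 2),
               xc = c1$xc + runif(1, 1, 4))
    cut <- suppressWarnings(intersection_cutoff(c1, c2))
    g <- scnshift:::gauss_component
    if (cut > c1$xc && cut < c2$xc &&
        abs(cut - (c1$xc + c2$xc) / 2) > 1e-9) {
      expect_lt(abs(g(cut, c1$A, c1$w, c1$xc) - g(cut, c2$A, c2$w, c2$xc)),
                1e-9)
    }
  }
  expect_error(intersection_cutoff(list(A = 1, w = 1, xc = 3),
                                   list(A = 1, w = 1, xc = 1)), "ordered")
})

test_that("cells are classified rapid strictly above the cutoff", {
  expect_equal(classify_cells(c(1, 2, 2.5), 2.5), rep("slow", 3))
  expect_equal(classify_cells(c(2.5, 2.51), 2.5), c("slow", "rapid"))
})

test_that("exact signed-rank test enumerates all sign assignments", {
  expect_equal(paired_population_test(1, 5)$p_value, 1)
  # nine all-positive distinct differences: only the two extreme assignments
  p9 <- paired_population_test(1:9, 1:9 + (1:9) / 10)
  expect_equal(p9$p_value, 2 / 512)
  expect_error(paired_population_test(numeric(0), numeric(0)), "no pairs")
  expect_error(paired_population_test(1:2, 1:3), "paired")
})

test_that("exact signed-rank p matches the reference implementation", {
  set.seed(51)
  for (i in 1:5) {
    x <- round(rnorm(8), 3)
    y <- round(rnorm(8, 0.5), 3)
    ours <- paired_population_test(x, y)$p_value
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the two reference populations differ significantly", {
  tbl <- delay_population_table()
  res <- paired_population_test(tbl$shift_pop1_h, tbl$shift_pop2_h)
  expect_equal(res$n_pairs, 9L)
  expect_lt(res$p_value, 0.01)
})

test_that("full shift analysis labels a clear mixture consistently", {
  sh <- as.numeric(draw_population_shifts(explant_sim_config(
    n_cells = 400, group = "delay", rapid_fraction = 0.3, slow_shift_h = 1,
    rapid_shift_h = 4, seed = 61)))
  res <- analyze_shifts(sh)
  expect_equal(res$selected, "bimodal")
  truth <- attr(draw_population_shifts(explant_sim_config(
    n_cells = 400, group = "delay", rapid_fraction = 0.3, slow_shift_h = 1,
    rapid_shift_h = 4, seed = 61)), "population")
  acc <- mean(res$labels == truth)
  expect_gt(acc, 0.85)
  expect_true(res$cutoff_h > res$mean_shifts_h[1] &&
                res$cutoff_h < res$mean_shifts_h[2])
  expect_equal(sum(res$fractions), 1)
})
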