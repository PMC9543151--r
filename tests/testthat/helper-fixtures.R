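# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# three processed, aligned control explants (shared by phasemap/synchrony)
fx_controls <- function() fx("controls", function() {
  lapply(1:3, function(i) {
    align_explant(process_explant(generate_explant(
      explant_sim_config(n_cells = 120, group = "control", seed = 100 + i),
      sprintf("ctrl%d", i))))
  })
})

fx_template <- function() fx("template", function() {
  build_template(fx_controls(), region = "central")
})

fx_delay <- function() fx("delay", function() {
  align_explant(process_explant(generate_explant(
    explant_sim_config(n_cells = 200, group = "delay", seed = 42), "delay1")))
})

# noise-free sampled cosine as a cell_series
make_cosine_series <- function(tau = 24, peak_h = 18, dur_h = 72,
                               dt_min = 1, mesor = 100, amp = 50,
                               id = "cos", x = 0, y = 0.5) {
  t <- seq(0, dur_h * 60, by = dt_min)
  cell_series(id, x, y, t, mesor + amp * cos(2 * pi * (t / 60 - peak_h) / tau))
}

# hand-built explant from a list of cell_series (standard frame)
make_explant <- function(cells, explant_id = "manual", region = "central",
                         group = "control") {
  structure(list(explant_id = explant_id, region = region, group = group,
                 cells = cells, truth = NULL,
                 landmarks = list(oc = c(0, 0), v3 = c(0, 1)),
                 lobe_extent = c(left = 1, right = 1)),
            class = "scn_explant")
}

# synthetic gaussian_model_fit for select_model tests
make_fit <- function(n_components, aic, chi_square, comp) {
  structure(list(components = comp, rss = 1, chi_square = chi_square,
                 aic = aic, n_bins = 40L, k_params = 3L * n_components,
                 n_components = n_components),
            class = "gaussian_model_fit")
}
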