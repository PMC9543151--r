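# Synthetic SCN explant and calcium-recording generator.
#
# The generator is first-class, tested code: it emulates the statistical
# structure that the downstream analysis assumes (damped noisy ~24-h
# single-cell oscillations, a two-population phase-shift structure with the
# rapid population placed ventrolaterally, and calcium recordings with
# excitatory/inhibitory/null transients at two stimulations 60 s apart), and
# carries per-cell ground truth for recovery tests.

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Is a point inside the normalized SCN lobe outline?
#'
#' The SCN cross-section is modelled as a unit half-ellipse in a normalized
#' frame: x in \[-1, 1\] (midline at x = 0, lateral positive/negative for the
#' right/left lobe), y in \[0, 1\] (ventral y = 0 to dorsal y = 1); a point is
#' inside when x^2 + y^2 <= 1. The "ventrolateral sector" used for rapid-cell
#' placement is y < 0.5 and |x| > 0.3.
#'
#' @param x,y numeric vectors of normalized coordinates.
#' @return logical vector.
#' @export
in_scn_outline <- function(x, y) {
  x^2 + y^2 <= 1 & y >= 0 & y <= 1 & abs(x) <= 1
}

#' @rdname in_scn_outline
#' @export
in_ventrolateral_sector <- function(x, y) {
  in_scn_outline(x, y) & y < 0.5 & abs(x) > 0.3
}

# rejection-sample one point from the outline (optionally the VL sector)
sample_lobe_point <- function(ventrolateral = FALSE) {
  repeat {
    x <- runif(1, -1, 1)
    y <- runif(1, 0, 1)
    ok <- if (ventrolateral) in_ventrolateral_sector(x, y) else in_scn_outline(x, y)
    if (ok) return(c(x = x, y = y))
  }
}

#' Configuration for a synthetic SCN explant
#'
#' Defaults reproduce the study conditions: ~24.2-h mean period, recordings
#' of several circadian cycles sampled every 29 min, and for delay explants a
#' two-population phase-shift structure in which ~29% of cells (the rapid
#' population, preferentially ventrolateral) are delayed by ~4 h and the rest
#' by ~1.5 h.
#'
#' @param n_cells number of cells in the explant.
#' @param region one of `"anterior"`, `"central"`, `"posterior"`.
#' @param group `"control"` (no shift) or `"delay"` (6-h light-cycle delay).
#' @param rapid_fraction proportion of cells in the rapid-shifting
#'   population (delay group only).
#' @param rapid_shift_h,slow_shift_h mean phase delay (hours) of the rapid
#'   and slow populations.
#' @param rapid_shift_sd_h,slow_shift_sd_h within-population SD of the shift
#'   (hours).
#' @param base_peak_time_h control peak time (hours from recording start) at
#'   the map origin (ventral midline).
#' @param spatial_gradient_h_per_unit ventral-to-dorsal gradient in control
#'   peak time, hours per normalized y unit.
#' @param phase_sd_h per-cell peak-time dispersion (hours) around the
#'   spatial mean field.
#' @param period_mean_h,period_sd_h per-cell free-running period mean and SD
#'   (hours).
#' @param damping_per_cycle fractional amplitude loss per cycle; mesor and
#'   amplitude are both multiplied by `(1 - damping_per_cycle)^(t/tau)`.
#' @param amplitude,mesor,noise_sd oscillation amplitude, mean level and
#'   additive Gaussian noise SD, in arbitrary luminescence units.
#' @param duration_h recording length (hours); must be at least three mean
#'   periods so the inclusion filter is testable.
#' @param sampling_interval_min acquisition interval (minutes); 29 min
#'   matches the camera exposure regime.
#' @param ventrolateral_prob probability that a rapid cell is placed in the
#'   ventrolateral sector.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return an object of class `explant_sim_config`.
#' @export
explant_sim_config <- function(n_cells = 200,
                               region = c("central", "anterior", "posterior"),
                               group = c("control", "delay"),
                               rapid_fraction = 0.29,
                               rapid_shift_h = 4,
                               slow_shift_h = 1.5,
                               rapid_shift_sd_h = 0.5,
                               slow_shift_sd_h = 1,
                               base_peak_time_h = 26,
                               spatial_gradient_h_per_unit = 4,
                               phase_sd_h = 0.5,
                               period_mean_h = 24.2,
                               period_sd_h = 0.3,
                               damping_per_cycle = 0.15,
                               amplitude = 100,
                               mesor = 150,
                               noise_sd = 10,
                               duration_h = 120,
                               sampling_interval_min = 29,
                               ventrolateral_prob = 0.9,
                               seed = 1L) {
  region <- match.arg(region)
  group <- match.arg(group)
  cfg <- list(
    n_cells = as.integer(n_cells), region = region, group = group,
    rapid_fraction = rapid_fraction, rapid_shift_h = rapid_shift_h,
    slow_shift_h = slow_shift_h, rapid_shift_sd_h = rapid_shift_sd_h,
    slow_shift_sd_h = slow_shift_sd_h, base_peak_time_h = base_peak_time_h,
    spatial_gradient_h_per_unit = spatial_gradient_h_per_unit,
    phase_sd_h = phase_sd_h, period_mean_h = period_mean_h,
    period_sd_h = period_sd_h, damping_per_cycle = damping_per_cycle,
    amplitude = amplitude, mesor = mesor, noise_sd = noise_sd,
    duration_h = duration_h, sampling_interval_min = sampling_interval_min,
    ventrolateral_prob = ventrolateral_prob, seed = as.integer(seed)
  )
  class(cfg) <- "explant_sim_config"
  validate_explant_sim_config(cfg)
  cfg
}

validate_explant_sim_config <- function(cfg) {
  if (cfg$n_cells < 1) stop("configuration error: n_cells must be >= 1")
  if (cfg$rapid_fraction < 0 || cfg$rapid_fraction > 1)
    stop("configuration error: rapid_fraction must be in [0, 1]")
  if (cfg$period_mean_h < 20 || cfg$period_mean_h > 28)
    stop("configuration error: period_mean_h must be in [20, 28]")
  if (cfg$sampling_interval_min <= 0)
    stop("configuration error: sampling_interval_min must be > 0")
  if (cfg$duration_h < 3 * cfg$period_mean_h)
    stop("configuration error: duration_h must be >= 3 * period_mean_h")
  if (cfg$damping_per_cycle < 0 || cfg$damping_per_cycle >= 1)
    stop("configuration error: damping_per_cycle must be in [0, 1)")
  invisible(cfg)
}

#' Single-cell bioluminescence series
#'
#' @param cell_id identifier.
#' @param x,y cell coordinates (normalized explant frame or pixels).
#' @param t_min sampling times, minutes since recording start, strictly
#'   increasing.
#' @param intensity luminescence values (finite).
#' @return an object of class `cell_series`.
#' @export
cell_series <- function(cell_id, x, y, t_min, intensity) {
  stopifnot(length(t_min) == length(intensity))
  if (any(diff(t_min) <= 0)) stop("t_min must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(list(cell_id = unname(cell_id), x = unname(x), y = unname(y),
                 t_min = as.numeric(t_min), intensity = as.numeric(intensity)),
            class = "cell_series")
}

#' @export
print.cell_series <- function(x, ...) {
  cat(sprintf("<cell_series %s at (%.3f, %.3f): %d samples, %.1f h>\n",
              x$cell_id, x$x, x$y, length(x$t_min),
              (max(x$t_min) - min(x$t_min)) / 60))
  invisible(x)
}

#' Generate a synthetic SCN explant
#'
#' Each cell's trace is a damped noisy cosine
#' `B(t) = mesor * d(t) + amplitude * d(t) * cos(2*pi*(t - tp)/tau) + eps(t)`
#' with geometric damping `d(t) = (1 - damping_per_cycle)^(t/tau)` and
#' Gaussian noise `eps`. Control peak times follow a ventral-to-dorsal
#' spatial gradient plus per-cell jitter; in the delay group a
#' `rapid_fraction` subset — preferentially placed in the ventrolateral
#' sector — is further delayed by `rapid_shift_h` (+/- SD) and the remainder
#' by `slow_shift_h` (+/- SD).
#'
#' @param config an [explant_sim_config()].
#' @param explant_id identifier stored on the result.
#' @return an object of class `scn_explant`: a list with `cells` (list of
#'   [cell_series()]), `truth` (data frame: cell_id, population, x, y,
#'   true_peak_h, true_shift_h, true_period_h), `landmarks` (optic chiasm and
#'   third ventricle in the explant frame), and `region`, `group`,
#'   `explant_id`, `config`.
#' @export
generate_explant <- function(config, explant_id = "explant1") {
  validate_explant_sim_config(config)
  local_seed(config$seed, {
    n <- config$n_cells
    pop <- if (config$group == "delay") {
      ifelse(runif(n) < config$rapid_fraction, "rapid", "slow")
    } else rep("slow", n)

    xy <- t(vapply(seq_len(n), function(i) {
      vl <- pop[i] == "rapid" && runif(1) < config$ventrolateral_prob
      sample_lobe_point(ventrolateral = vl)
    }, numeric(2)))

    peak0 <- config$base_peak_time_h +
      config$spatial_gradient_h_per_unit * xy[, 2] +
      rnorm(n, 0, config$phase_sd_h)
    shift <- if (config$group == "delay") {
      ifelse(pop == "rapid",
             rnorm(n, config$rapid_shift_h, config$rapid_shift_sd_h),
             rnorm(n, config$slow_shift_h, config$slow_shift_sd_h))
    } else rep(0, n)
    period <- rnorm(n, config$period_mean_h, config$period_sd_h)
    tp <- peak0 + shift

    t_min <- seq(0, config$duration_h * 60, by = config$sampling_interval_min)
    t_h <- t_min / 60
    cells <- lapply(seq_len(n), function(i) {
      d <- (1 - config$damping_per_cycle)^(t_h / period[i])
      b <- config$mesor * d +
        config$amplitude * d * cos(2 * pi * (t_h - tp[i]) / period[i]) +
        rnorm(length(t_h), 0, config$noise_sd)
      cell_series(sprintf("c%03d", i), xy[i, 1], xy[i, 2], t_min, b)
    })

    truth <- data.frame(
      cell_id = vapply(cells, `[[`, "", "cell_id"),
      population = pop, x = xy[, 1], y = xy[, 2],
      true_peak_h = tp, true_shift_h = shift, true_period_h = period,
      stringsAsFactors = FALSE
    )
    structure(list(explant_id = explant_id, region = config$region,
                   group = config$group, cells = cells, truth = truth,
                   landmarks = list(oc = c(0, 0), v3 = c(0, 1)),
                   lobe_extent = c(left = 1, right = 1),
                   config = config),
              class = "scn_explant")
  })
}

#' @export
print.scn_explant <- function(x, ...) {
  cat(sprintf("<scn_explant %s: %s %s, %d cells%s>\n", x$explant_id,
              x$region, x$group, length(x$cells),
              if (!is.null(x$metrics)) ", processed" else ""))
  invisible(x)
}

#' Draw per-cell phase shifts from the two-population model
#'
#' The population-assignment and shift-drawing machinery of
#' [generate_explant()], without trace synthesis: returns the true per-cell
#' shifts of a delay explant. Used for mixture-detection power studies where
#' trace extraction is exercised elsewhere.
#'
#' @inheritParams generate_explant
#' @return numeric vector of `n_cells` shifts (hours) with a `"population"`
#'   attribute of truth labels.
#' @export
draw_population_shifts <- function(config) {
  validate_explant_sim_config(config)
  local_seed(config$seed, {
    n <- config$n_cells
    pop <- ifelse(runif(n) < config$rapid_fraction, "rapid", "slow")
    shift <- ifelse(pop == "rapid",
                    rnorm(n, config$rapid_shift_h, config$rapid_shift_sd_h),
                    rnorm(n, config$slow_shift_h, config$slow_shift_sd_h))
    structure(shift, population = pop)
  })
}

#' Render a synthetic explant as a bioluminescence image stack
#'
#' Each frame is the sum of per-cell Gaussian-profile spots scaled by that
#' cell's trace value at the frame time, plus Gaussian background noise.
#' Overlapping cells simply add. Normalized cell coordinates are mapped into
#' the pixel grid leaving a margin of `2 * cell_radius_px` so every spot fits.
#'
#' @param explant an [scn_explant()].
#' @param width,height pixel grid dimensions.
#' @param cell_radius_px spot radius in pixels (Gaussian sigma =
#'   `cell_radius_px / 2`).
#' @param background_sd SD of additive background noise.
#' @param seed RNG seed for the background noise.
#' @return numeric array `[height, width, n_frames]` with attributes `t_min`
#'   (frame times) and `centers` (per-cell pixel centers, rows = cells).
#' @export
render_image_stack <- function(explant, width = 64, height = 48,
                               cell_radius_px = 2, background_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(explant, "scn_explant"))
  margin <- 2 * cell_radius_px
  if (width - 2 * margin < 1 || height - 2 * margin < 1)
    stop("grid too small for the requested cell radius")
  n_cells <- length(explant$cells)
  t_min <- if (n_cells > 0) explant$cells[[1]]$t_min else seq(0, 60, by = 30)
  nt <- length(t_min)
  stack <- array(0, dim = c(height, width, nt))

  centers <- NULL
  if (n_cells > 0) {
    xs <- vapply(explant$cells, `[[`, 0, "x")
    ys <- vapply(explant$cells, `[[`, 0, "y")
    col0 <- margin + 1 + (xs + 1) / 2 * (width - 2 * margin - 1)
    row0 <- margin + 1 + (1 - ys) * (height - 2 * margin - 1)
    centers <- cbind(row = row0, col = col0)
    sigma <- cell_radius_px / 2
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (i in seq_len(n_cells)) {
      if (length(explant$cells[[i]]$t_min) != nt)
        stop("all cells must share the same time grid")
      profile <- exp(-((rr - row0[i])^2 + (cc - col0[i])^2) / (2 * sigma^2))
      trace <- explant$cells[[i]]$intensity
      for (k in seq_len(nt)) stack[, , k] <- stack[, , k] + profile * trace[k]
    }
  }
  if (background_sd > 0) {
    local_seed(seed, {
      stack <- stack + array(rnorm(length(stack), 0, background_sd), dim(stack))
    })
  }
  attr(stack, "t_min") <- t_min
  attr(stack, "centers") <- centers
  stack
}

#' Fura-2 calibration constants
#'
#' Calibration for converting the background-subtracted F340/F380 excitation
#' ratio into an approximate calcium concentration,
#' `Ca = beta * Kd * (r - r_min) / (r_max - r)`. Defaults are the
#' experimentally determined constants of the recordings this package
#' models: beta 7.48, Kd 230 nM, r_min 149, r_max 5262.
#'
#' @param beta dimensionless calibration factor.
#' @param Kd Fura-2 dissociation constant (nM).
#' @param r_min,r_max minimum and maximum ratio values.
#' @return an object of class `calcium_calibration`.
#' @export
calcium_calibration <- function(beta = 7.48, Kd = 230, r_min = 149,
                                r_max = 5262) {
  if (r_min >= r_max) stop("r_min must be < r_max")
  if (Kd <= 0 || beta <= 0) stop("beta and Kd must be > 0")
  structure(list(beta = beta, Kd = Kd, r_min = r_min, r_max = r_max),
            class = "calcium_calibration")
}

#' Configuration for a synthetic calcium recording
#'
#' Emulates ~120-s Fura-2 recordings sampled every 2 s with two 10-s
#' stimulus trains 60 s apart; each ROI responds with an excitatory
#' (transient increase), inhibitory (transient decrease) or null transient
#' after each stimulus. ROIs carry standard-frame coordinates; excitatory
#' ROIs are preferentially ventrolateral, mirroring the spatial pattern of
#' light-responsive cells.
#'
#' @param n_rois number of ROIs (cells).
#' @param class_probs named probabilities for excitatory/inhibitory/null.
#' @param baseline_nM resting calcium concentration.
#' @param transient_amplitude_rel transient amplitude as a proportion of the
#'   baseline (must be < 1 so inhibitory transients stay positive).
#' @param transient_duration_s transient duration in seconds.
#' @param stim_times_s two stimulation onsets (seconds), 60 s apart.
#' @param stim_duration_s stimulus train duration (10 s).
#' @param noise_sd_nM additive concentration noise SD.
#' @param calibration a [calcium_calibration()].
#' @param duration_s,sample_interval_s record length and sampling interval.
#' @param region explant region label carried to the summary.
#' @param ventrolateral_prob probability an excitatory ROI is placed
#'   ventrolaterally.
#' @param seed integer RNG seed.
#' @return an object of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_rois = 30,
                               class_probs = c(excitatory = 0.35,
                                               inhibitory = 0.05,
                                               null = 0.60),
                               baseline_nM = 150,
                               transient_amplitude_rel = 0.5,
                               transient_duration_s = 20,
                               stim_times_s = c(20, 80),
                               stim_duration_s = 10,
                               noise_sd_nM = 5,
                               calibration = calcium_calibration(),
                               duration_s = 130,
                               sample_interval_s = 2,
                               region = "central",
                               ventrolateral_prob = 0.9,
                               seed = 1L) {
  cfg <- list(n_rois = as.integer(n_rois), class_probs = class_probs,
              baseline_nM = baseline_nM,
              transient_amplitude_rel = transient_amplitude_rel,
              transient_duration_s = transient_duration_s,
              stim_times_s = stim_times_s, stim_duration_s = stim_duration_s,
              noise_sd_nM = noise_sd_nM, calibration = calibration,
              duration_s = duration_s, sample_interval_s = sample_interval_s,
              region = region, ventrolateral_prob = ventrolateral_prob,
              seed = as.integer(seed))
  class(cfg) <- "calcium_sim_config"
  validate_calcium_sim_config(cfg)
  cfg
}

validate_calcium_sim_config <- function(cfg) {
  if (abs(sum(cfg$class_probs) - 1) > 1e-8)
    stop("configuration error: class_probs must sum to 1")
  if (!all(c("excitatory", "inhibitory", "null") %in% names(cfg$class_probs)))
    stop("configuration error: class_probs must name excitatory/inhibitory/null")
  if (length(cfg$stim_times_s) != 2 || diff(cfg$stim_times_s) <= 0)
    stop("configuration error: stim_times_s must be two increasing onsets")
  if (cfg$baseline_nM * (1 - cfg$transient_amplitude_rel) < 0)
    stop("configuration error: transient amplitude would make [Ca2+] negative")
  if (!inherits(cfg$calibration, "calcium_calibration"))
    stop("configuration error: calibration must be a calcium_calibration")
  if (cfg$stim_times_s[1] < 10)
    stop("configuration error: need >= 10 s of pre-stimulus baseline")
  invisible(cfg)
}

# trapezoidal pulse: 0 outside [onset, onset+dur], 1 on the plateau, with
# one-sample linear flanks so the transient leaves and re-enters the
# baseline band smoothly
pulse_shape <- function(t_s, onset, dur, ramp) {
  up <- pmin(pmax((t_s - onset) / ramp, 0), 1)
  down <- pmin(pmax((onset + dur - t_s) / ramp, 0), 1)
  pmin(up, down)
}

#' Generate a synthetic Fura-2 calcium recording
#'
#' Per ROI, a calcium time course (baseline plus class-dependent transient
#' after each stimulus) is inverted through the calibration equation into
#' consistent F340/F380 pairs (F380 held at a constant reference level).
#' Truth classes and coordinates are stored on each ROI.
#'
#' @param config a [calcium_sim_config()].
#' @return list of `calcium_roi_series` objects: each has `roi_id`, `t_s`,
#'   `F340`, `F380`, `stim_epochs` (list of `c(onset_s, duration_s)`),
#'   `calibration`, `region`, `x`, `y`, `truth_class`.
#' @export
generate_calcium_recording <- function(config) {
  validate_calcium_sim_config(config)
  local_seed(config$seed, {
    t_s <- seq(0, config$duration_s, by = config$sample_interval_s)
    classes <- sample(names(config$class_probs), config$n_rois,
                      replace = TRUE, prob = config$class_probs)
    ramp <- config$sample_interval_s
    lapply(seq_len(config$n_rois), function(i) {
      cls <- classes[i]
      vl <- cls == "excitatory" && runif(1) < config$ventrolateral_prob
      xy <- sample_lobe_point(ventrolateral = vl)
      amp <- switch(cls,
                    excitatory = config$transient_amplitude_rel,
                    inhibitory = -config$transient_amplitude_rel,
                    null = 0)
      ca <- rep(config$baseline_nM, length(t_s))
      for (onset in config$stim_times_s) {
        ca <- ca + config$baseline_nM * amp *
          pulse_shape(t_s, onset, config$transient_duration_s, ramp)
      }
      ca <- ca + rnorm(length(t_s), 0, config$noise_sd_nM)
      ca <- pmax(ca, 0.1)  # noise floor: concentrations stay positive
      r <- ca_to_ratio(ca, config$calibration)
      F380 <- rep(1000, length(t_s))
      structure(list(roi_id = sprintf("roi%03d", i), t_s = t_s,
                     F340 = r * F380, F380 = F380,
                     stim_epochs = lapply(config$stim_times_s, function(o)
                       c(onset_s = o, duration_s = config$stim_duration_s)),
                     calibration = config$calibration,
                     region = config$region, x = xy[1], y = xy[2],
                     truth_class = cls),
                class = "calcium_roi_series")
    })
  })
}
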