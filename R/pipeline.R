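# End-to-end orchestration on synthetic cohorts: simulate -> traces ->
# synchrony -> template -> shifts -> bimodality, and simulate -> calcium,
# with a manifest and a summary comparing the rapid-shift and excited-cell
# spatial maps.

#' Pipeline configuration
#'
#' @param seed master seed; all per-explant and calcium seeds are derived
#'   from it deterministically.
#' @param regions SCN regions to simulate.
#' @param n_control,n_delay explants per region and group.
#' @param n_cells cells per explant.
#' @param n_calcium_rois ROIs per simulated calcium recording (one recording
#'   per region).
#' @param explant_overrides named list of [explant_sim_config()] arguments
#'   applied to every explant (e.g. `list(noise_sd = 5)`).
#' @param calcium_overrides named list of [calcium_sim_config()] arguments.
#' @param grid_n,match_radius template grid nodes per lobe and matching
#'   radius (grid units).
#' @param window_h trace smoothing window (hours).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            regions = c("anterior", "central", "posterior"),
                            n_control = 3, n_delay = 2, n_cells = 120,
                            n_calcium_rois = 40,
                            explant_overrides = list(),
                            calcium_overrides = list(),
                            grid_n = 40, match_radius = 1.5, window_h = 2) {
  structure(list(seed = as.integer(seed), regions = regions,
                 n_control = n_control, n_delay = n_delay, n_cells = n_cells,
                 n_calcium_rois = n_calcium_rois,
                 explant_overrides = explant_overrides,
                 calcium_overrides = calcium_overrides,
                 grid_n = grid_n, match_radius = match_radius,
                 window_h = window_h),
            class = "pipeline_config")
}

# small deterministic sub-seed scheme (stays far below 2^31)
derive_seed <- function(seed, i, j = 0) {
  (seed * 1009L + i * 131L + j * 7L) %% 2000000011L
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: explant simulation (control and delay cohorts per
#' region), trace processing, per-explant synchrony reports, control
#' template construction, per-cell phase shifts for delay explants,
#' bimodality analysis per delay explant with a two-population summary
#' table, calcium simulation and response summary, and the spatial-overlap
#' comparison between rapid-shifting and stimulus-excited cells. All
#' artifacts are written under `out_dir` and listed in a JSON manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: a list with `seed`, `parameters`,
#'   `artifacts` (paths), and in-memory `results` (synchrony, population
#'   table + summary, calcium summary, overlap).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    artifacts[[name]] <<- p
    p
  }

  ## stage: simulate + traces
  make_explant <- function(region, group, i) {
    args <- c(list(n_cells = config$n_cells, region = region, group = group,
                   seed = derive_seed(config$seed,
                                      match(region, config$regions) * 10 + i,
                                      j = as.integer(group == "delay"))),
              config$explant_overrides)
    cfg <- do.call(explant_sim_config, args)
    e <- generate_explant(cfg, explant_id = sprintf("%s_%s_%d", region, group, i))
    process_explant(e, window_h = config$window_h)
  }
  controls <- list(); delays <- list()
  for (rg in config$regions) {
    for (i in seq_len(config$n_control))
      controls[[length(controls) + 1]] <- make_explant(rg, "control", i)
    for (i in seq_len(config$n_delay))
      delays[[length(delays) + 1]] <- make_explant(rg, "delay", i)
  }
  all_metrics <- do.call(rbind, lapply(c(controls, delays), function(e)
    cbind(explant_id = e$explant_id, region = e$region, group = e$group,
          e$metrics)))
  save_csv(all_metrics, "cell_metrics.csv")

  ## stage: synchrony
  sync <- do.call(rbind, lapply(c(controls, delays), synchrony_report))
  save_csv(sync, "synchrony.csv")

  ## stage: templates + shifts + bimodality
  ## Control explants are also scored against the template: their shifts
  ## should be near zero (the control map self-test); bimodality analysis
  ## runs on delay explants only.
  pop_rows <- list(); shift_rows <- list(); bim <- list()
  for (rg in config$regions) {
    ctrl_rg <- Filter(function(e) e$region == rg, controls)
    ctrl_rg <- lapply(ctrl_rg, align_explant)
    template <- build_template(ctrl_rg, region = rg, grid_n = config$grid_n)
    write_template(template, file.path(out_dir, sprintf("template_%s.csv", rg)))
    artifacts[[sprintf("template_%s.csv", rg)]] <-
      file.path(out_dir, sprintf("template_%s.csv", rg))
    delay_rg <- lapply(Filter(function(d) d$region == rg, delays),
                       align_explant)
    for (e in c(ctrl_rg, delay_rg)) {
      cs <- compute_cell_shifts(e, template,
                                match_radius = config$match_radius)
      sh <- cs$shifts
      if (nrow(sh) < 10) next
      sh$explant_id <- e$explant_id
      sh$region <- rg
      sh$group <- e$group
      if (e$group == "control") {
        sh$population <- "slow"
        shift_rows[[e$explant_id]] <- sh
        next
      }
      res <- analyze_shifts(sh$shift_h)
      sh$population <- res$labels
      shift_rows[[e$explant_id]] <- sh
      bim[[e$explant_id]] <- res
      if (res$selected == "bimodal") {
        pop_rows[[e$explant_id]] <- data.frame(
          region = rg, explant_id = e$explant_id,
          shift_pop1_h = res$mean_shifts_h[1],
          shift_pop2_h = res$mean_shifts_h[2],
          cells_pop1_pct = 100 * res$fractions[1],
          cells_pop2_pct = 100 * res$fractions[2],
          cutoff_h = res$cutoff_h, n_dropped = cs$n_dropped,
          stringsAsFactors = FALSE)
      }
    }
  }
  shifts_df <- do.call(rbind, shift_rows)
  if (!is.null(shifts_df)) {
    rownames(shifts_df) <- NULL
    save_csv(shifts_df, "cell_shifts.csv")
  }
  pop_tbl <- do.call(rbind, pop_rows)
  pop_summary <- NULL
  if (!is.null(pop_tbl)) {
    rownames(pop_tbl) <- NULL
    save_csv(pop_tbl, "population_table.csv")
    pop_summary <- summarize_population_table(pop_tbl)
    save_csv(pop_summary, "population_summary.csv")
  }

  ## stage: calcium
  ca_rois <- list()
  for (rg in config$regions) {
    args <- c(list(n_rois = config$n_calcium_rois, region = rg,
                   seed = derive_seed(config$seed,
                                      match(rg, config$regions), j = 99)),
              config$calcium_overrides)
    cfg <- do.call(calcium_sim_config, args)
    ca_rois <- c(ca_rois, generate_calcium_recording(cfg))
  }
  ca_df <- analyze_calcium_recording(ca_rois)
  save_csv(ca_df, "calcium_rois.csv")
  ca_summary <- gate_and_summarize(ca_df)
  save_csv(ca_summary, "calcium_summary.csv")

  ## stage: spatial overlap between rapid-shift and excited maps
  overlap <- NULL
  delay_sh <- if (!is.null(shifts_df)) shifts_df[shifts_df$group == "delay", ]
  if (!is.null(delay_sh) && nrow(delay_sh) > 0) {
    rapid_map <- data.frame(x = delay_sh$x, y = delay_sh$y,
                            flag = delay_sh$population == "rapid")
    inc <- ca_df[ca_df$final_class != "excluded", ]
    excite_map <- data.frame(x = inc$x, y = inc$y,
                             flag = inc$final_class == "excitatory")
    overlap <- spatial_overlap_summary(rapid_map, excite_map)
    save_csv(overlap$sectors, "overlap_sectors.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("scnshift")),
    seed = config$seed,
    parameters = unclass(config),
    artifacts = artifacts,
    overlap_spearman_rho = if (!is.null(overlap)) overlap$spearman_rho else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(manifest, list(results = list(
    synchrony = sync, population_table = pop_tbl,
    population_summary = pop_summary, calcium_summary = ca_summary,
    overlap = overlap, bimodality = bim, out_dir = out_dir))))
}

#' Spatial overlap between two cell populations
#'
#' Divides the standard frame into a coarse sector grid (default 4 x 4),
#' computes per sector the fraction of flagged cells in each map, and
#' reports the Spearman rank correlation of the two fractions across
#' sectors occupied by both maps.
#'
#' @param map1,map2 data frames with columns `x`, `y` (standard frame) and
#'   logical `flag` (e.g. rapid-shifting; excitatory).
#' @param nx,ny sector grid dimensions over x in \[-1, 1\] and y in \[0, 1\].
#' @return list with `sectors` (per-sector fractions and counts) and
#'   `spearman_rho`.
#' @export
spatial_overlap_summary <- function(map1, map2, nx = 4, ny = 4) {
  if (nx < 1 || ny < 1) stop("empty sector grid")
  sector_of <- function(df) {
    ix <- pmin(pmax(findInterval(df$x, seq(-1, 1, length.out = nx + 1),
                                 rightmost.closed = TRUE), 1), nx)
    iy <- pmin(pmax(findInterval(df$y, seq(0, 1, length.out = ny + 1),
                                 rightmost.closed = TRUE), 1), ny)
    (iy - 1) * nx + ix
  }
  frac <- function(df) {
    s <- sector_of(df)
    vapply(seq_len(nx * ny), function(k) {
      sel <- s == k
      if (!any(sel)) NA_real_ else mean(df$flag[sel])
    }, numeric(1))
  }
  f1 <- frac(map1); f2 <- frac(map2)
  sectors <- data.frame(sector = seq_len(nx * ny), frac_map1 = f1,
                        frac_map2 = f2)
  ok <- complete.cases(sectors)
  rho <- if (sum(ok) >= 3) {
    tryCatch(
      suppressWarnings(cor.test(f1[ok], f2[ok], method = "spearman"))$estimate,
      error = function(e) NA_real_)
  } else NA_real_
  list(sectors = sectors, spearman_rho = unname(rho))
}
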