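# Reading and writing the package's plain-text interchange formats:
# long-format trace CSV, per-cell metrics CSV, template CSV + JSON metadata,
# calcium CSV + JSON sidecar, and multi-page TIFF stacks.

#' Write / read an explant as long-format CSV
#'
#' Columns: explant_id, cell_id, x, y, t_min, intensity. Truth labels (when
#' present) go to a companion `<path>_truth.csv`.
#'
#' @param explant an [scn_explant()].
#' @param path CSV path.
#' @param write_truth also write the simulation truth, if present.
#' @return `path`, invisibly.
#' @export
write_explant_csv <- function(explant, path, write_truth = TRUE) {
  long <- do.call(rbind, lapply(explant$cells, function(cell) {
    data.frame(explant_id = explant$explant_id, cell_id = cell$cell_id,
               x = cell$x, y = cell$y, t_min = cell$t_min,
               intensity = cell$intensity, stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE)
  if (write_truth && !is.null(explant$truth)) {
    write.csv(explant$truth, sub("\\.csv$", "_truth.csv", path),
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_explant_csv
#' @param region,group,landmarks metadata not carried by the CSV itself.
#' @return `read_explant_csv()`: an [scn_explant()].
#' @export
read_explant_csv <- function(path, region = "central", group = "control",
                             landmarks = list(oc = c(0, 0), v3 = c(0, 1))) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("explant_id", "cell_id", "x", "y", "t_min", "intensity")
  if (!all(need %in% names(long)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  cells <- lapply(split(long, long$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    cell_series(d$cell_id[1], d$x[1], d$y[1], d$t_min, d$intensity)
  })
  names(cells) <- NULL
  structure(list(explant_id = long$explant_id[1], region = region,
                 group = group, cells = cells, truth = NULL,
                 landmarks = landmarks),
            class = "scn_explant")
}

#' Write per-cell metrics of a processed explant
#'
#' Columns: cell_id, x, y, peak1_h, period_h, n_cycles, included.
#'
#' @param explant a processed [scn_explant()].
#' @param path CSV path.
#' @export
write_metrics_csv <- function(explant, path) {
  if (is.null(explant$metrics)) stop("explant must be processed first")
  write.csv(explant$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a template map (CSV entries + JSON metadata)
#'
#' @param template a [build_template()] result.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_template <- function(template, path) {
  write.csv(template$entries, path, row.names = FALSE)
  jsonlite::write_json(list(region = template$region,
                            grid_n = template$grid_n,
                            spacing = template$spacing),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  entries <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid_n <- meta$grid_n
  spacing <- meta$spacing
  nodes <- expand.grid(x = seq(-1, 1, by = spacing),
                       y = seq(0, 1, by = spacing))
  nodes <- nodes[in_scn_outline(nodes$x, nodes$y), ]
  key <- function(x, y) paste(round(x * grid_n), round(y * grid_n))
  gaps <- nodes[!(key(nodes$x, nodes$y) %in% key(entries$x, entries$y)), ]
  rownames(gaps) <- NULL
  structure(list(entries = entries, gaps = gaps, spacing = spacing,
                 grid_n = grid_n, region = meta$region),
            class = "template_map")
}

#' Write / read a calcium recording (CSV + JSON sidecar)
#'
#' The CSV holds roi_id, t_s, F340, F380; the sidecar `<path>.json` holds
#' stimulation epochs, calibration constants, region, coordinates and truth
#' classes.
#'
#' @param rois list of `calcium_roi_series`.
#' @param path CSV path.
#' @export
write_calcium_csv <- function(rois, path) {
  long <- do.call(rbind, lapply(rois, function(roi) {
    data.frame(roi_id = roi$roi_id, t_s = roi$t_s, F340 = roi$F340,
               F380 = roi$F380, stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE)
  r1 <- rois[[1]]
  side <- list(
    stim_epochs = lapply(r1$stim_epochs, as.list),
    calibration = unclass(r1$calibration),
    rois = lapply(rois, function(roi)
      list(roi_id = roi$roi_id, region = roi$region, x = roi$x, y = roi$y,
           truth_class = roi$truth_class))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calcium_csv
#' @export
read_calcium_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  calib <- do.call(calcium_calibration, side$calibration)
  epochs <- lapply(side$stim_epochs, function(e)
    c(onset_s = e$onset_s, duration_s = e$duration_s))
  meta <- setNames(side$rois,
                   vapply(side$rois, function(r) r$roi_id, ""))
  lapply(split(long, long$roi_id), function(d) {
    d <- d[order(d$t_s), ]
    m <- meta[[d$roi_id[1]]]
    structure(list(roi_id = d$roi_id[1], t_s = d$t_s, F340 = d$F340,
                   F380 = d$F380, stim_epochs = epochs, calibration = calib,
                   region = m$region, x = m$x, y = m$y,
                   truth_class = m$truth_class),
              class = "calcium_roi_series")
  })
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages; intensities are rescaled to
#' \[0, 1\] on write (the scale factor is not preserved — use for fixtures,
#' not calibrated data).
#'
#' @param stack array `[height, width, frames]`.
#' @param path TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  rng <- range(stack)
  denom <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    (stack[, , k] - rng[1]) / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param t_min frame times to attach (minutes).
#' @export
read_stack_tiff <- function(path, t_min = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                            length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]]
  attr(stack, "t_min") <- if (is.null(t_min)) seq_len(length(pages)) else t_min
  stack
}
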