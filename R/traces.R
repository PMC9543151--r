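# Bioluminescence trace processing: ROI detection on the peak-expression
# map, trace extraction, smoothing/resampling to a 1-min grid, per-cycle
# peak detection, half-maximum cycle intervals, and the inclusion filter
# (>= 3 cycles with period 20-28 h).

#' Detect cell-sized ROIs in a bioluminescence image stack
#'
#' Builds a per-pixel peak-expression map (maximum over time), thresholds it
#' at `median + k * MAD` of the map, labels 4-connected components, and keeps
#' components of 3-9 pixels (cell-sized groups brighter than noise). ROIs are
#' fixed for the whole recording.
#'
#' @param stack numeric array `[height, width, n_frames]`.
#' @param k MAD multiplier for the noise threshold.
#' @param min_px,max_px component size bounds in pixels.
#' @return list of ROIs; each is a list with `pixels` (matrix of row, col)
#'   and `centroid` (`c(row, col)`).
#' @export
detect_rois <- function(stack, k = 5, min_px = 3, max_px = 9) {
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("stack must be a [height, width, frames] array with >= 1 frame")
  peak_map <- apply(stack, c(1, 2), max)
  thr <- median(peak_map) + k * mad(peak_map)
  mask <- peak_map > thr
  labels <- label_components_4(mask)
  if (max(labels) == 0) return(list())
  rois <- list()
  for (lab in seq_len(max(labels))) {
    idx <- which(labels == lab, arr.ind = TRUE)
    if (nrow(idx) >= min_px && nrow(idx) <= max_px) {
      colnames(idx) <- c("row", "col")
      rois[[length(rois) + 1]] <- list(
        pixels = idx,
        centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2]))
      )
    }
  }
  rois
}

# 4-connected component labelling of a logical matrix by breadth-first
# search; returns an integer matrix of labels (0 = background)
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
          q <- (d[2] - 1L) * nr + d[1]
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- current
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

#' Extract the average trace of an ROI from an image stack
#'
#' `intensity(t)` is the mean over the ROI's pixels at each frame.
#'
#' @param stack numeric array `[height, width, n_frames]` with a `t_min`
#'   attribute (frame times in minutes; defaults to frame index).
#' @param roi an ROI from [detect_rois()].
#' @param cell_id identifier for the resulting series.
#' @return a [cell_series()] with pixel-centroid coordinates.
#' @export
extract_trace <- function(stack, roi, cell_id = "roi") {
  d <- dim(stack)
  px <- roi$pixels
  if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2]))
    stop("ROI pixel out of frame bounds")
  t_min <- attr(stack, "t_min")
  if (is.null(t_min)) t_min <- seq_len(d[3])
  vals <- vapply(seq_len(d[3]), function(k) {
    mean(stack[cbind(px[, 1], px[, 2], k)])
  }, numeric(1))
  cell_series(cell_id, x = roi$centroid["col"], y = roi$centroid["row"],
              t_min = t_min, intensity = vals)
}

#' Smooth a trace and resample it to one point per minute
#'
#' Linear interpolation onto a 1-min grid spanning the input range, followed
#' by a centered moving average (window `window_h` hours; shrinking windows
#' at the record ends so the output spans the full input range).
#'
#' @param series a [cell_series()] with >= 2 samples.
#' @param window_h smoothing window in hours (default 2 h).
#' @return a smoothed [cell_series()] sampled at exactly 1-min intervals,
#'   with the window stored in attribute `window_h`.
#' @export
smooth_resample <- function(series, window_h = 2) {
  if (length(series$t_min) < 2) stop("need >= 2 samples")
  span_min <- max(series$t_min) - min(series$t_min)
  if (window_h * 60 > span_min) stop("smoothing window longer than record")
  grid <- seq(ceiling(min(series$t_min)), floor(max(series$t_min)), by = 1)
  y <- approx(series$t_min, series$intensity, xout = grid)$y
  half <- round(window_h * 60 / 2)
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- cell_series(series$cell_id, series$x, series$y, grid, sm)
  attr(out, "window_h") <- window_h
  out
}

#' Find per-cycle peak times of a smoothed trace
#'
#' Local maxima with a minimum separation (default 16 h, under half the
#' shortest admissible circadian period times two); maxima within one
#' smoothing window of either record end are discarded to avoid boundary
#' artifacts.
#'
#' Around each retained maximum the peak time is refined to the vertex of a
#' local quadratic fit (window `refine_h` hours each side): near its peak a
#' circadian waveform is locally parabolic, and the fit pools many samples,
#' which makes the peak time far less sensitive to noise than the raw argmax.
#'
#' @param series a smoothed 1-min [cell_series()] (from [smooth_resample()]).
#' @param min_separation_h minimum peak separation in hours.
#' @param edge_window_h exclusion zone at each record end (defaults to the
#'   series' smoothing window, else 2 h).
#' @param refine_h half-width (hours) of the quadratic refinement window;
#'   0 disables refinement.
#' @return numeric vector of peak times in hours from recording start
#'   (possibly empty).
#' @export
find_peak_times <- function(series, min_separation_h = 16,
                            edge_window_h = NULL, refine_h = 3) {
  if (is.null(edge_window_h))
    edge_window_h <- if (!is.null(attr(series, "window_h")))
      attr(series, "window_h") else 2
  y <- series$intensity
  t <- series$t_min
  n <- length(y)
  if (n < 3) return(numeric(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  edge <- edge_window_h * 60
  cand <- cand[t[cand] - t[1] >= edge & t[n] - t[cand] >= edge]
  if (length(cand) == 0) return(numeric(0))
  # greedy selection by height with minimum separation
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_separation_h * 60)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  peaks_h <- t[kept] / 60
  if (refine_h > 0) {
    for (j in seq_along(kept)) {
      i <- kept[j]
      sel <- which(t >= t[i] - refine_h * 60 & t <= t[i] + refine_h * 60)
      if (length(sel) < 5) next
      tt <- (t[sel] - t[i]) / 60
      X <- cbind(1, tt, tt^2)
      cf <- tryCatch(qr.coef(qr(X), y[sel]), error = function(e) NULL)
      if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) next
      vertex <- -cf[2] / (2 * cf[3])
      if (abs(vertex) <= refine_h) peaks_h[j] <- t[i] / 60 + vertex
    }
  }
  peaks_h
}

#' Cycle-to-cycle intervals from half-maximum rising-edge crossings
#'
#' For each detected cycle, the half-maximum level is
#' `(cycle max + preceding trough) / 2`, where the trough is the minimum
#' between the previous and current peak (the record start for the first
#' cycle). The crossing time on the rising flank is found by linear
#' interpolation, and intervals are consecutive differences of crossing
#' times.
#'
#' @param series a smoothed 1-min [cell_series()].
#' @param peak_times_h optional precomputed peak times (hours); computed via
#'   [find_peak_times()] otherwise.
#' @return numeric vector of intervals in hours (empty when fewer than two
#'   rising edges are present).
#' @export
cycle_intervals <- function(series, peak_times_h = NULL) {
  if (is.null(peak_times_h)) peak_times_h <- find_peak_times(series)
  crossings <- half_max_crossings(series, peak_times_h)
  if (length(crossings) < 2) return(numeric(0))
  diff(crossings)
}

#' @rdname cycle_intervals
#' @return `half_max_crossings()`: the rising-edge crossing times themselves
#'   (hours).
#' @export
half_max_crossings <- function(series, peak_times_h = NULL) {
  if (is.null(peak_times_h)) peak_times_h <- find_peak_times(series)
  if (length(peak_times_h) == 0) return(numeric(0))
  t <- series$t_min
  y <- series$intensity
  peak_idx <- vapply(peak_times_h * 60, function(pt) which.min(abs(t - pt)),
                     integer(1))
  crossings <- numeric(0)
  prev <- 1L
  for (j in seq_along(peak_idx)) {
    pk <- peak_idx[j]
    seg <- prev:pk
    tr <- seg[which.min(y[seg])]
    half <- (y[pk] + y[tr]) / 2
    rise <- tr:pk
    above <- which(y[rise] >= half)
    if (length(above) > 0 && above[1] > 1) {
      i2 <- rise[above[1]]
      i1 <- i2 - 1L
      tc <- t[i1] + (half - y[i1]) / (y[i2] - y[i1]) * (t[i2] - t[i1])
      crossings <- c(crossings, tc / 60)
    } else if (length(above) > 0 && above[1] == 1 && j > 1) {
      # flank already above half at the trough: degenerate cycle, skip
    }
    prev <- pk
  }
  crossings
}

#' Inclusion filter for single-cell traces
#'
#' A trace is included when at least three cycle-to-cycle intervals were
#' detected and every one of the first three lies within the admissible
#' circadian period band (20-28 h).
#'
#' @param intervals_h cycle intervals in hours (from [cycle_intervals()]).
#' @param n_required number of cycles required.
#' @param period_range admissible period band in hours.
#' @return logical scalar.
#' @export
inclusion_filter <- function(intervals_h, n_required = 3,
                             period_range = c(20, 28)) {
  if (length(intervals_h) < n_required) return(FALSE)
  first <- intervals_h[seq_len(n_required)]
  all(first >= period_range[1] & first <= period_range[2])
}

#' Process every cell of an explant into per-cell rhythm metrics
#'
#' Runs [smooth_resample()], [find_peak_times()] and [cycle_intervals()] on
#' each cell and applies the [inclusion_filter()]. The result is attached to
#' the explant as `$metrics` (a data frame with one row per cell) and
#' `$peaks` / `$intervals` (lists keyed by cell).
#'
#' The recording captures a partial cycle before the first full cycle in
#' vitro (explants are cut a few hours before the reporter's peak), so the
#' per-cycle analysis starts at the first peak inside `first_cycle_window_h`:
#' `peak1_h` is the first peak within that window, and earlier (partial)
#' peaks are excluded from the cycle-interval computation.
#'
#' @param explant an [scn_explant()].
#' @param window_h smoothing window (hours).
#' @param intervals_per_cell how many leading intervals enter `period_h`.
#' @param first_cycle_window_h window (hours from recording start) in which
#'   the first full cycle's peak must fall; the default matches a reporter
#'   peaking about a day after cutting.
#' @return the explant with `metrics` (cell_id, x, y, peak1_h, period_h,
#'   n_cycles, included), `peaks` and `intervals` added.
#' @export
process_explant <- function(explant, window_h = 2, intervals_per_cell = 2,
                            first_cycle_window_h = c(12, 36)) {
  stopifnot(inherits(explant, "scn_explant"))
  res <- lapply(explant$cells, function(cell) {
    sm <- smooth_resample(cell, window_h = window_h)
    pk_all <- find_peak_times(sm)
    pk <- pk_all[pk_all >= first_cycle_window_h[1]]
    iv <- cycle_intervals(sm, pk)
    first <- pk[pk <= first_cycle_window_h[2]]
    list(cell = cell, peaks = pk, intervals = iv,
         peak1 = if (length(first) > 0) first[1] else NA_real_)
  })
  metrics <- do.call(rbind, lapply(res, function(r) {
    iv_head <- head(r$intervals, intervals_per_cell)
    data.frame(
      cell_id = r$cell$cell_id, x = r$cell$x, y = r$cell$y,
      peak1_h = r$peak1,
      period_h = if (length(iv_head) > 0) mean(iv_head) else NA_real_,
      n_cycles = length(r$intervals),
      included = inclusion_filter(r$intervals),
      stringsAsFactors = FALSE
    )
  }))
  rownames(metrics) <- NULL
  explant$metrics <- metrics
  explant$peaks <- setNames(lapply(res, `[[`, "peaks"), metrics$cell_id)
  explant$intervals <- setNames(lapply(res, `[[`, "intervals"),
                                metrics$cell_id)
  explant
}
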