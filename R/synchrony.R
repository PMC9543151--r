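# Per-explant synchronization measures: phase distribution (SD of peak
# times), period variability (mean per-cell SD of cycle intervals), period
# length, and the Kuramoto-style order parameter R.

#' Phase distribution of an explant
#'
#' The standard deviation (sample SD, N-1 denominator) of the peak times of
#' the individual cells for one specified cycle.
#'
#' @param peak_times_h per-cell peak times in hours (N >= 2).
#' @return SD in hours.
#' @export
phase_distribution <- function(peak_times_h) {
  if (length(peak_times_h) < 2) stop("need >= 2 peak times")
  sd(peak_times_h)
}

#' Period variability of an explant
#'
#' Per-cell sample SD of the leading cycle-to-cycle intervals (the first
#' three cycles yield two half-maximum intervals), averaged over the cells of
#' the explant. Cells with fewer than two eligible intervals are skipped.
#'
#' @param per_cell_intervals list of per-cell interval vectors (hours).
#' @param intervals_per_cell number of leading intervals per cell to use.
#' @return mean per-cell SD in hours.
#' @export
period_variability <- function(per_cell_intervals, intervals_per_cell = 2) {
  sds <- vapply(per_cell_intervals, function(iv) {
    iv <- head(iv, intervals_per_cell)
    if (length(iv) < 2) NA_real_ else sd(iv)
  }, numeric(1))
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) stop("no cells with >= 2 cycle intervals")
  mean(sds)
}

#' Period length of an explant
#'
#' Mean of the leading cycle-to-cycle (half-maximum rising-edge) intervals
#' across all cells.
#'
#' @inheritParams period_variability
#' @return mean period in hours.
#' @export
period_length <- function(per_cell_intervals, intervals_per_cell = 2) {
  iv <- unlist(lapply(per_cell_intervals, head, intervals_per_cell))
  if (length(iv) == 0) stop("no cycle intervals available")
  mean(iv)
}

#' Order parameter R of an explant
#'
#' Each cell's relative peak time is converted to a relative phase
#' `theta_j = (mean(tp) - tp_j) / tau * 2 * pi` and transformed with Euler's
#' formula; R is the magnitude of the mean resultant,
#' `R = |sum_j exp(i * theta_j)| / N`. R = 1 indicates perfect synchrony and
#' R = 0 uniform dispersion. Phases are taken directly from the linear
#' formula (not wrapped); with peak-time spreads well under half a period
#' this is immaterial.
#'
#' @param peak_times_h per-cell peak times in hours (N >= 1).
#' @param tau_h period used for the phase conversion (hours, > 0); the
#'   explant's ensemble period estimate is the conventional choice.
#' @return R in \[0, 1\].
#' @export
order_parameter <- function(peak_times_h, tau_h) {
  if (length(peak_times_h) < 1) stop("need >= 1 peak time")
  if (tau_h <= 0) stop("tau must be > 0")
  theta <- (mean(peak_times_h) - peak_times_h) / tau_h * 2 * pi
  Mod(mean(exp(1i * theta)))
}

#' Synchronization report for a processed explant
#'
#' Computes all four per-explant synchrony measures from the per-cell
#' metrics of [process_explant()], restricted to included cells. The first
#' detected peak per cell is the "specified cycle" for the phase measures;
#' the period measures use the leading cycle intervals.
#'
#' @param explant a processed [scn_explant()] (see [process_explant()]).
#' @param intervals_per_cell leading intervals per cell for the period
#'   measures.
#' @return data frame with explant_id, region, group, n_cells_included,
#'   phase_distribution_sd_h, period_variability_h, period_length_h,
#'   order_parameter_R.
#' @export
synchrony_report <- function(explant, intervals_per_cell = 2) {
  if (is.null(explant$metrics))
    stop("explant must be processed first (process_explant)")
  keep <- explant$metrics$included & !is.na(explant$metrics$peak1_h)
  if (sum(keep) < 2) stop("fewer than 2 included cells")
  peaks <- explant$metrics$peak1_h[keep]
  ivs <- explant$intervals[keep]
  tau <- period_length(ivs, intervals_per_cell)
  data.frame(
    explant_id = explant$explant_id,
    region = explant$region,
    group = explant$group,
    n_cells_included = sum(keep),
    phase_distribution_sd_h = phase_distribution(peaks),
    period_variability_h = period_variability(ivs, intervals_per_cell),
    period_length_h = tau,
    order_parameter_R = order_parameter(peaks, tau),
    stringsAsFactors = FALSE
  )
}
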