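# Published per-explant summaries of the delay experiment, embedded as
# reference data: the bimodal explants' two-population shifts and fractions,
# and the per-region response counts of the RHT stimulation experiment.
# These printed values are inputs for desk-scale re-analysis (regional and
# grand averages, the paired population test, and response percentages).

#' Per-explant two-population phase-shift summary (reference data)
#'
#' The nine delay explants with a bimodal phase-shift distribution: mean
#' shift of the first (slow) and second (rapid) population and the
#' percentage of cells in each, per explant, with the SCN region.
#'
#' @return data frame: region, shift_pop1_h, shift_pop2_h, cells_pop1_pct,
#'   cells_pop2_pct.
#' @export
delay_population_table <- function() {
  data.frame(
    region = c(rep("anterior", 3), rep("central", 4), rep("posterior", 2)),
    shift_pop1_h = c(0.88, 2.13, 1.13, 2.32, 1.26, 3.49, 0.67, 2.76, 1.12),
    shift_pop2_h = c(2.65, 6.23, 3.12, 4.33, 2.62, 5.43, 3.15, 4.94, 3.88),
    cells_pop1_pct = c(63.0, 94.4, 26.5, 59.2, 38.9, 71.6, 59.7, 96.2, 91.7),
    cells_pop2_pct = c(37.0, 5.6, 73.5, 40.8, 61.1, 28.4, 40.3, 3.8, 8.3),
    stringsAsFactors = FALSE
  )
}

#' Regional and grand averages of a two-population summary table
#'
#' Averages the per-explant rows within each region; the grand average is
#' the unweighted mean of the regional averages (i.e. corrected for the
#' unequal numbers of explants per region).
#'
#' @param tbl a table in the layout of [delay_population_table()].
#' @return data frame of regional rows plus a `"grand"` row, with the same
#'   value columns.
#' @export
summarize_population_table <- function(tbl) {
  vals <- c("shift_pop1_h", "shift_pop2_h", "cells_pop1_pct", "cells_pop2_pct")
  regions <- unique(tbl$region)
  reg <- do.call(rbind, lapply(regions, function(rg) {
    sub <- tbl[tbl$region == rg, vals]
    cbind(data.frame(region = rg, n_explants = nrow(sub)),
          as.data.frame(as.list(colMeans(sub))))
  }))
  grand <- cbind(data.frame(region = "grand", n_explants = nrow(tbl)),
                 as.data.frame(as.list(colMeans(reg[, vals]))))
  out <- rbind(reg, grand)
  rownames(out) <- NULL
  out
}

#' Per-region RHT stimulation response counts (reference data)
#'
#' Counts of SCN neurons with excitatory, inhibitory and null calcium
#' responses to electrical stimulation of the retinohypothalamic tract, per
#' region.
#'
#' @return data frame: region, n_slices, excitatory_n, inhibitory_n, null_n.
#' @export
rht_response_counts <- function() {
  data.frame(
    region = c("anterior", "central", "posterior"),
    n_slices = c(2L, 8L, 6L),
    excitatory_n = c(20L, 90L, 17L),
    inhibitory_n = c(1L, 11L, 5L),
    null_n = c(9L, 106L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Response percentages from per-region counts
#'
#' Recomputes class percentages per region (denominator: all counted cells
#' in the region) and a total row across regions.
#'
#' @param tbl a table in the layout of [rht_response_counts()].
#' @return data frame: region, n_total, per-class counts and percentages.
#' @export
summarize_response_counts <- function(tbl) {
  tbl$n_total <- tbl$excitatory_n + tbl$inhibitory_n + tbl$null_n
  tot <- data.frame(region = "total",
                    excitatory_n = sum(tbl$excitatory_n),
                    inhibitory_n = sum(tbl$inhibitory_n),
                    null_n = sum(tbl$null_n))
  tot$n_total <- tot$excitatory_n + tot$inhibitory_n + tot$null_n
  cols <- c("region", "n_total", "excitatory_n", "inhibitory_n", "null_n")
  out <- rbind(tbl[, cols], tot[, cols])
  for (cls in c("excitatory", "inhibitory", "null")) {
    out[[paste0(cls, "_pct")]] <- 100 * out[[paste0(cls, "_n")]] / out$n_total
  }
  rownames(out) <- NULL
  out
}
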