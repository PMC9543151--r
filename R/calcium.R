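# Fura-2 calcium response analysis: ratio-to-concentration conversion,
# baseline and transient metrics, normalized-AUC classification,
# reproducibility gating across the two stimulations, basal exclusion, and
# per-region summaries.

#' Convert a Fura-2 excitation ratio to a calcium concentration
#'
#' `Ca = beta * Kd * (r - r_min) / (r_max - r)` (nM). Ratios below `r_min`
#' are clamped to 0 nM with a warning; ratios at or above `r_max` are outside
#' the calibration range and raise an error.
#'
#' @param r ratio values (F340 / F380, background-subtracted).
#' @param calib a [calcium_calibration()].
#' @return concentrations in nM, strictly increasing in `r`.
#' @export
ratio_to_ca <- function(r, calib = calcium_calibration()) {
  if (any(r >= calib$r_max))
    stop("ratio at or above r_max: outside calibration range")
  if (any(r < calib$r_min)) {
    warning("ratio below r_min clamped to 0 nM")
    r <- pmax(r, calib$r_min)
  }
  calib$beta * calib$Kd * (r - calib$r_min) / (calib$r_max - r)
}

#' @rdname ratio_to_ca
#' @param ca_nM concentrations in nM (>= 0).
#' @return `ca_to_ratio()`: the algebraic inverse,
#'   `r = (r_max * ca + beta * Kd * r_min) / (ca + beta * Kd)`.
#' @export
ca_to_ratio <- function(ca_nM, calib = calcium_calibration()) {
  if (any(ca_nM < 0)) stop("concentration must be >= 0")
  (calib$r_max * ca_nM + calib$beta * calib$Kd * calib$r_min) /
    (ca_nM + calib$beta * calib$Kd)
}

#' Calcium concentration series of an ROI
#'
#' @param roi a `calcium_roi_series` (see [generate_calcium_recording()] or
#'   [read_calcium_csv()]).
#' @return numeric vector of concentrations (nM) at `roi$t_s`.
#' @export
roi_ca_series <- function(roi) {
  if (any(roi$F380 <= 0)) stop("F380 must be > 0 wherever the ratio is computed")
  ratio_to_ca(roi$F340 / roi$F380, roi$calibration)
}

#' Baseline calcium concentration before a stimulus
#'
#' Mean concentration over the 10-s window immediately preceding the
#' stimulus onset.
#'
#' @param t_s sample times (seconds).
#' @param ca_nM concentration series.
#' @param stim_onset_s stimulus onset (seconds).
#' @param window_s baseline window length (seconds).
#' @return baseline in nM.
#' @export
compute_baseline <- function(t_s, ca_nM, stim_onset_s, window_s = 10) {
  sel <- t_s >= stim_onset_s - window_s & t_s < stim_onset_s
  if (!any(sel) || min(t_s) > stim_onset_s - window_s)
    stop("insufficient pre-stimulus data for the baseline window")
  mean(ca_nM[sel])
}

#' Transient metrics after one stimulus
#'
#' The transient starts at the stimulation onset; its end is the first
#' sample at which the concentration has returned to within 10% of the
#' baseline — tested only after the trace has left the +/-10% band for at
#' least `min_excursion_samples` consecutive samples, so the duration can
#' neither collapse to a single sample nor be triggered by an isolated noise
#' blip. If the trace never leaves the band that long, the response is a
#' null shortcut (`auc_n = 1`); if it never returns, the duration is capped
#' at the next stimulus onset or the record end, with a warning. The AUC is the trapezoidal integral of
#' `ca - bl` over the transient (positive for increases, negative for
#' decreases) and `auc_n = 1 + auc / (bl * td)` — equivalently the mean of
#' `ca / bl` over the transient, which reconciles the signed AUC with
#' thresholds that straddle 1.
#'
#' @param t_s,ca_nM sample times and concentrations.
#' @param stim_onset_s stimulus onset (seconds).
#' @param bl baseline from [compute_baseline()].
#' @param cap_s latest admissible transient end (defaults to record end; use
#'   the next stimulus onset for the first transient).
#' @param band_rel return band as a fraction of baseline.
#' @param min_excursion_samples how many consecutive out-of-band samples
#'   constitute a transient; shorter blips are noise, not a response
#'   (evoked calcium transients last tens of seconds).
#' @return list with `bl`, `td` (s), `auc` (nM s), `auc_n`.
#' @export
transient_metrics <- function(t_s, ca_nM, stim_onset_s, bl,
                              cap_s = max(t_s), band_rel = 0.1,
                              min_excursion_samples = 3) {
  if (stim_onset_s < min(t_s) || stim_onset_s > max(t_s))
    stop("stimulus onset outside record")
  band <- band_rel * bl
  win <- which(t_s >= stim_onset_s & t_s <= cap_s)
  outb <- abs(ca_nM[win] - bl) > band
  dt <- median(diff(t_s))
  runs <- rle(outb)
  run_end <- cumsum(runs$lengths)
  k <- which(runs$values & runs$lengths >= min_excursion_samples)[1]
  if (is.na(k)) {
    return(list(bl = bl, td = dt, auc = 0, auc_n = 1, capped = FALSE,
                left_band = any(outb)))
  }
  if (run_end[k] < length(win)) {
    end_t <- t_s[win[run_end[k] + 1]]  # first in-band sample after the run
    capped <- FALSE
  } else {
    end_t <- cap_s
    capped <- TRUE
    warning("transient did not return to baseline; duration capped")
  }
  td <- end_t - stim_onset_s
  if (td <= dt) {
    return(list(bl = bl, td = dt, auc = 0, auc_n = 1, capped = capped,
                left_band = TRUE))
  }
  seg <- t_s >= stim_onset_s & t_s <= end_t
  auc <- pracma::trapz(t_s[seg], ca_nM[seg] - bl)
  list(bl = bl, td = td, auc = auc, auc_n = 1 + auc / (bl * td),
       capped = capped, left_band = TRUE)
}

#' Classify a transient from its normalized AUC
#'
#' `auc_n < 0.9` is inhibitory, `auc_n > 1.1` excitatory, and values in
#' `[0.9, 1.1]` (boundaries inclusive) are null responses.
#'
#' @param auc_n normalized AUC (finite).
#' @return `"inhibitory"`, `"excitatory"` or `"null"`.
#' @export
classify_transient <- function(auc_n) {
  if (!all(is.finite(auc_n))) stop("auc_n must be finite")
  ifelse(auc_n < 0.9, "inhibitory",
         ifelse(auc_n > 1.1, "excitatory", "null"))
}

#' Analyze one calcium ROI: both stimulations
#'
#' Converts the ROI to concentrations, computes the baseline and transient
#' metrics for each stimulation epoch (the first transient capped at the
#' second onset), and classifies each transient.
#'
#' @param roi a `calcium_roi_series`.
#' @return one-row data frame: roi_id, region, x, y, basal_nM, and per
#'   stimulus bl/td/auc/auc_n/class.
#' @export
analyze_calcium_roi <- function(roi) {
  ca <- roi_ca_series(roi)
  onsets <- vapply(roi$stim_epochs, `[[`, 0, "onset_s")
  if (length(onsets) != 2) stop("expected exactly 2 stimulation epochs")
  caps <- c(onsets[2], max(roi$t_s))
  res <- lapply(1:2, function(i) {
    bl <- compute_baseline(roi$t_s, ca, onsets[i])
    m <- suppressWarnings(
      transient_metrics(roi$t_s, ca, onsets[i], bl, cap_s = caps[i]))
    m$class <- classify_transient(m$auc_n)
    m
  })
  data.frame(roi_id = roi$roi_id,
             region = if (is.null(roi$region)) NA_character_ else roi$region,
             x = if (is.null(roi$x)) NA_real_ else roi$x,
             y = if (is.null(roi$y)) NA_real_ else roi$y,
             basal_nM = res[[1]]$bl,
             bl1 = res[[1]]$bl, td1 = res[[1]]$td, auc1 = res[[1]]$auc,
             auc_n1 = res[[1]]$auc_n, class1 = res[[1]]$class,
             bl2 = res[[2]]$bl, td2 = res[[2]]$td, auc2 = res[[2]]$auc,
             auc_n2 = res[[2]]$auc_n, class2 = res[[2]]$class,
             stringsAsFactors = FALSE)
}

#' Analyze a whole calcium recording
#'
#' @param rois list of `calcium_roi_series`.
#' @return data frame with one row per ROI (see [analyze_calcium_roi()]),
#'   plus `final_class`: the per-stimulus class when both stimulations agree,
#'   `"excluded"` otherwise or when the basal concentration exceeds the
#'   cutoff.
#' @param basal_cutoff_nM basal concentration exclusion threshold.
#' @export
analyze_calcium_recording <- function(rois, basal_cutoff_nM = 300) {
  df <- do.call(rbind, lapply(rois, analyze_calcium_roi))
  df$final_class <- ifelse(df$basal_nM > basal_cutoff_nM, "excluded",
                           ifelse(df$class1 == df$class2, df$class1,
                                  "excluded"))
  df
}

#' Gate ROIs and summarize responses per region
#'
#' Excludes ROIs with basal concentration above the cutoff, keeps a final
#' class only when both stimulations agree, and tabulates counts and
#' percentages of excitatory/inhibitory/null responses per region (the
#' denominator is the included ROIs), plus a total row.
#'
#' @param rois list of `calcium_roi_series` (or a precomputed data frame
#'   from [analyze_calcium_recording()]).
#' @param basal_cutoff_nM basal exclusion threshold (nM).
#' @return data frame: region, n_total, excitatory_n, excitatory_pct,
#'   inhibitory_n, inhibitory_pct, null_n, null_pct, n_excluded.
#' @export
gate_and_summarize <- function(rois, basal_cutoff_nM = 300) {
  df <- if (is.data.frame(rois)) rois
  else analyze_calcium_recording(rois, basal_cutoff_nM)
  inc <- df[df$final_class != "excluded", ]
  if (nrow(inc) == 0) stop("zero included ROIs")
  summarize_region <- function(sub, label) {
    n <- nrow(sub)
    cnt <- function(cls) sum(sub$final_class == cls)
    data.frame(region = label, n_total = n,
               excitatory_n = cnt("excitatory"),
               excitatory_pct = 100 * cnt("excitatory") / n,
               inhibitory_n = cnt("inhibitory"),
               inhibitory_pct = 100 * cnt("inhibitory") / n,
               null_n = cnt("null"),
               null_pct = 100 * cnt("null") / n,
               stringsAsFactors = FALSE)
  }
  regions <- unique(inc$region)
  out <- do.call(rbind, lapply(regions, function(rg)
    summarize_region(inc[inc$region == rg, ], rg)))
  out <- rbind(out, summarize_region(inc, "total"))
  out$n_excluded <- c(vapply(regions, function(rg)
    sum(df$region == rg & df$final_class == "excluded"), 0),
    sum(df$final_class == "excluded"))
  rownames(out) <- NULL
  out
}
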