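# scnshift

Single-cell analysis of circadian re-entrainment in the suprachiasmatic
nucleus (SCN). After a 6-h delay of the light–dark cycle, SCN neurons do not
shift as one: a ventrolateral subpopulation (~29% of cells) delays its
PER2 rhythm by ~4–6 h within the first cycle while the rest move only
~1–2 h, producing a *bimodal* distribution of single-cell phase shifts —
and the rapid shifters coincide spatially with the cells excited by
retinohypothalamic (RHT) input. `scnshift` is for chronobiologists who want
to quantify that structure in PER2::LUC bioluminescence recordings of SCN
explants and in Fura-2 calcium recordings of RHT stimulation, or to study
the method's behavior on simulated data.

The package implements, end to end:

- **Trace processing** — ROI detection on the peak-expression map
  (cell-sized 3–9 px components above median + 5 MAD), trace extraction,
  smoothing/resampling to 1 min, per-cycle peak detection with quadratic
  refinement, half-maximum rising-edge cycle intervals, and the inclusion
  filter (≥ 3 cycles of 20–28 h).
- **Synchronization measures** — phase distribution (SD of peak times),
  period variability, period length, and the order parameter
  `R = |Σ_j exp(iθ_j)| / N` with `θ_j = 2π (t̄_p − t_p,j) / τ`.
- **Spatiotemporal phase maps** — landmark alignment into a normalized
  bilateral frame, mirrored control template maps on a discrete grid, and
  per-cell shifts of delay explants (`shift = cell peak − template peak`).
- **Bimodality detection** — 15-min shift histograms fitted with one- and
  two-component Gaussians `y = A/(w√(π/2)) · exp(−2(x−x_c)²/w²)`; the
  two-component model is selected when it lowers both the Pearson
  chi-square and the AIC (by ≥ 2), unless one component nests inside the
  other; population fractions from component areas, cutoff at the curve
  intersection, and an exact paired Wilcoxon signed-rank test by full
  enumeration.
- **Calcium classification** — Fura-2 ratio → concentration via
  `Ca = β·K_d·(r − r_min)/(r_max − r)`; baseline, transient duration, AUC
  and normalized AUC `AUC_n = 1 + AUC/(bl·t_d)`; excitatory (> 1.1),
  inhibitory (< 0.9) or null, gated on agreement across two stimulations
  and basal `[Ca²⁺] ≤ 300 nM`.
- **Synthetic data** — a seeded generator for explants (damped noisy
  cosines with a two-population shift structure and ventrolateral rapid
  cells), image stacks, and calcium recordings, with per-cell ground truth.

## Worked example

Simulate one delay explant at the recording's scale (220 cells, 120 h at
29-min sampling), process the traces, and summarize its synchrony:

```r
library(scnshift)
e <- process_explant(generate_explant(
  explant_sim_config(n_cells = 220, group = "delay", seed = 8), "demo"))
synchrony_report(e)
#>   explant_id  region group n_cells_included phase_distribution_sd_h
#> 1       demo central delay              220                    1.54
#>   period_variability_h period_length_h order_parameter_R
#> 1                0.428            24.2             0.923
```

The phase distribution (1.54 h) is the SD of the first-full-cycle peak
times across cells — delay explants are visibly less synchronized than
controls (~1.1 h under the same settings); the order parameter 0.92 says
the ensemble is still strongly phase-clustered; the period length (24.2 h)
is the mean half-maximum cycle interval.

The bundled per-explant population table (nine bimodal delay explants)
reproduces the published averages and the paired test:

```r
tbl <- delay_population_table()
summarize_population_table(tbl)
#>      region n_explants shift_pop1_h shift_pop2_h cells_pop1_pct cells_pop2_pct
#> 1  anterior          3     1.380000       4.0000       61.30000       38.70000
#> 2   central          4     1.935000       3.8825       57.35000       42.65000
#> 3 posterior          2     1.940000       4.4100       93.95000        6.05000
#> 4     grand          9     1.751667       4.0975       70.86667       29.13333
paired_population_test(tbl$shift_pop1_h, tbl$shift_pop2_h)$p_value
#> [1] 0.00390625
```

The grand row says the slow population shifted 1.75 h and the rapid
population 4.10 h, with 29.1% of cells in the rapid population; the exact
two-sided signed-rank p (2/2⁹) confirms the two populations differ.

The whole chain — simulate control and delay cohorts, build templates,
compute shifts, fit bimodality, analyze calcium, compare the rapid and
excited maps — runs from one call:

```r
res <- run_pipeline(pipeline_config(seed = 11, n_cells = 220, n_delay = 3),
                    out_dir = "run")
res$results$population_table[, c("region", "shift_pop1_h", "shift_pop2_h",
                                 "cells_pop2_pct")]
#>     region shift_pop1_h shift_pop2_h cells_pop2_pct
#> 1 anterior     1.124212     3.868751       45.62634
#> 2  central     2.004473     4.441489       19.95311
res$overlap_spearman_rho
#> [1] 0.6877251
```

Two of the nine simulated delay explants are detected as bimodal (as with
real explants, detection is not guaranteed at this size), with slow/rapid
shifts near the generator's 1.5 h / 4 h truth; the positive Spearman
correlation says sectors rich in rapid-shifting cells are also rich in
stimulus-excited cells. A shell wrapper for the same call is in
`inst/scripts/run_pipeline.R`.

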