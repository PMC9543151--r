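---
title: "Single-cell phase-shift analysis in SCN explants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell phase-shift analysis in SCN explants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After an abrupt delay in the light–dark cycle, the neurons of the
suprachiasmatic nucleus (SCN) do not re-entrain as a rigid unit: a
subpopulation — concentrated ventrolaterally, where retinohypothalamic
(RHT) input is densest — shifts its PER2 expression rhythm within the first
cycle, while the remaining cells lag. `scnshift` implements the analysis
chain needed to quantify this at single-cell resolution in PER2::LUC
bioluminescence recordings of organotypic SCN explants, and the companion
analysis of Fura-2 calcium responses to electrical RHT stimulation that
identifies the light-responsive cells.

Because no public single-cell recordings exist for this preparation, the
package ships a seeded synthetic generator that reproduces the statistical
structure of the recordings; every stage of the pipeline is tested against
that generator's ground truth.

## Trace model and processing

Each synthetic cell's bioluminescence is a damped, noisy cosine:

$$B(t) = M\,d(t) + A\,d(t)\cos\!\big(2\pi (t - t_p)/\tau\big) + \varepsilon(t),
\qquad d(t) = (1 - \delta)^{t/\tau},$$

with mesor $M$, amplitude $A$, per-cell peak time $t_p$, per-cell period
$\tau \sim N(24.2, 0.3^2)$ h, fractional amplitude loss per cycle
$\delta = 0.15$, and white noise $\varepsilon \sim N(0, 10^2)$ (arbitrary
luminescence units, $A = 100$). Organotypic PER2::LUC rhythms damp over
days; a geometric per-cycle factor applied to both mesor and amplitude is
the simplest form with that property, and it has a useful exact consequence:
scaling the whole waveform by a constant per cycle leaves the half-maximum
crossing interval exactly $\tau$, so the period estimator is unbiased under
damping by construction.

Processing follows the recording conventions: traces acquired every 29 min
are linearly interpolated to a 1-min grid and smoothed with a centered
moving average (default window 2 h; shrinking windows at the record ends so
the output spans the input). Peaks are local maxima separated by at least
16 h, excluding maxima within one smoothing window of either record end,
and each peak time is refined to the vertex of a local quadratic fit
(±3 h). The refinement matters: near its peak a cosine is flat, so a raw
argmax has ≈0.75 h SD at the default noise, whereas the quadratic vertex —
which pools six hours of data — achieves ≈0.3 h.

Cycle-to-cycle intervals are measured between consecutive half-maximum
crossings of the rising edge: per cycle the half-maximum is
(cycle max + preceding trough)/2, with the trough taken as the minimum
between the previous and current peak (record start for the first cycle),
and the crossing located by linear interpolation. A cell is included when
at least three such intervals exist and the first three all lie in
20–28 h.

One subtlety: explants are cut a few hours before the reporter's peak, so
recordings begin inside a partial cycle. `process_explant()` therefore
anchors the analysis at the first peak inside a configurable window
(default 12–36 h from the recording start — "the first full cycle in
vitro") and excludes the partial peak from interval estimation; without
this the first-cycle peak and the first interval are inconsistent across
cells.

## Synchronization measures

For each explant the package reports, over included cells:

- **phase distribution** — sample SD (N−1, the conventional choice, used
  consistently throughout) of the first-full-cycle peak times;
- **period variability** — per-cell SD of the leading cycle intervals,
  averaged over cells. "The first 3 cycles" yield two half-maximum
  intervals, so two intervals per cell is the default
  (`intervals_per_cell = 2`, exposed as an argument);
- **period length** — mean of those intervals across cells;
- **order parameter** $R = \big|\tfrac1N \sum_j e^{i\theta_j}\big|$ with
  $\theta_j = 2\pi(\bar t_p - t_{p,j})/\tau$. $\tau$ is the explant's own
  period-length estimate (an ensemble value is stabler than per-cell
  periods), and phases are deliberately not wrapped: with peak-time spreads
  well below $\tau/2$ wrapping is immaterial, and the unwrapped form matches
  the defining equation.

## Template maps and per-cell shifts

Control explants define a spatial reference for what each location's peak
time should be. Coordinates live in a normalized bilateral frame: the SCN
cross-section is a unit half-ellipse, midline at $x = 0$, $x \in [-1, 1]$
lateral, $y \in [0, 1]$ ventral→dorsal; the "ventrolateral sector" is
$y < 0.5,\ |x| > 0.3$. Alignment is a similarity transform fixed by two
landmarks — the optic chiasm maps to the origin and the third ventricle to
$(0, 1)$ — with each lobe scaled separately along the lateral axis (lobe
extents from metadata when available, else from the outermost cell).

The template is a discrete grid (default 40 nodes per lobe per axis; the
spatial granularity of such maps is a free choice, and a grid makes gap
semantics explicit). Cells are assigned to the nearest inside-outline node,
overlapping contributions are averaged (cell-count weighted), and the map is
finalized by mirroring each lobe onto the other and averaging coincident
nodes — retinal input is bilaterally symmetric, and mirroring both reduces
outlier influence and fills gaps. Peak times are averaged arithmetically,
not circularly; valid while within-region spreads are far below half a
period, which holds for all configurations here (documented limitation).

A delay cell's shift is its peak time minus the template peak at the
nearest entry within 1.5 grid units (positive = delayed); cells whose
neighbourhood holds only gaps are dropped and counted. Scoring the control
explants against their own template gives mean |shift| well under one
histogram bin (the tests assert < 0.25 h), as it must.

Per-cell biological phase jitter enters a measured shift one-to-one: the
delay cells are different cells from those that built the template, so
their private deviation from the local mean field cannot be subtracted.
The parameter-recovery test therefore uses a tightly synchronized
configuration (`phase_sd_h = 0.25`) so that it measures the mapping
machinery's error (< 0.5 h mean absolute error) rather than biological
dispersion; at the default dispersion the same machinery shows ≈1.1 h MAE,
nearly all of it jitter.

## Bimodality detection

Shifts are binned at 15 min and fitted with one- and two-component curves
of the form

$$y(x) = \frac{A}{w\sqrt{\pi/2}}\; e^{-2 (x - x_c)^2 / w^2},$$

where $A$ is the component's area (cells), $w$ its width (implied SD
$w/2$) and $x_c$ its center. Fits are bounded nonlinear least squares
(Levenberg–Marquardt) against count density at the bin centers; density
scaling keeps $A$ in cell units, and the choice does not affect model
selection since the AIC difference is scale-invariant. The one-component
fit starts from moment estimates; the two-component fit is deterministic
multi-start (five quantile-pair centers plus a one-dimensional k-means-style
split), keeping the lowest-RSS converged fit. Amplitudes must be positive
and widths at least one bin width, which excludes degenerate spike
solutions.

Model selection requires the two-component model to win on **both**
statistics: Pearson chi-square over occupied bins
($\sum (O - E)^2 / \max(E, 0.5)$) must not increase, and the least-squares
AIC ($n \ln(\mathrm{RSS}/n) + 2k$, $k = 3$ or $6$) must drop by at least 2.
The chi-square condition is not redundant: the RSS of the nested
two-component model never increases, but the Pearson statistic — computed
on the counts scale with small-expectation guards — often does when the
second component is a spurious tail shoulder. On 200 unimodal synthetic
histograms (n = 300 cells, SD 1 h) the AIC-only rule calls 11.5% bimodal
while the dual rule calls 4%, with no loss of power on 70/30 mixtures
separated by 3 h (the acceptance tests compute these rates). Finally, when
the smaller-area component lies entirely within the other (interval
containment of $x_c \pm w$ — one reasonable operationalization of "located
entirely within"), the one-component model is kept regardless.

For a bimodal explant, population fractions are $A_i / (A_1 + A_2)$ and the
cutoff separating the populations is the intersection of the two component
curves between the centers — the root of the log-density difference, a
quadratic in $x$ (the midpoint is used with a warning in the degenerate
no-root case). Cells strictly above the cutoff are "rapid"; a cell exactly
at the cutoff is "slow" (closed lower side).

The paired comparison of the two populations across explants uses an exact
two-sided Wilcoxon signed-rank test by full enumeration of all $2^n$ sign
assignments (midranks for ties, zero differences dropped, $n \le 15$),
cross-checked against the reference implementation in the tests.

## Calcium response classification

The Fura-2 excitation ratio $r = F_{340}/F_{380}$ (background-subtracted)
converts to concentration via
$\mathrm{Ca} = \beta K_d (r - r_\min)/(r_\max - r)$ with $\beta = 7.48$,
$K_d = 230$ nM, $r_\min = 149$, $r_\max = 5262$. Ratios at or above
$r_\max$ are outside the calibration range (error); ratios below $r_\min$
clamp to 0 nM with a warning.

Per stimulus: the baseline is the mean concentration over the 10 s before
onset; the transient runs from stimulation onset until the first sample
back within ±10% of baseline; the AUC is the trapezoidal integral of
$\mathrm{Ca} - bl$ over the transient (signed); and the normalized AUC is
$\mathrm{AUC}_n = 1 + \mathrm{AUC}/(bl \cdot t_d)$ — equivalently the mean
of $\mathrm{Ca}/bl$ over the transient. This definition reconciles two
facts that a single naive formula cannot: the AUC is signed (negative for
decreases), yet the classification thresholds straddle 1.
$\mathrm{AUC}_n < 0.9$ is inhibitory, $> 1.1$ excitatory, and the closed
interval $[0.9, 1.1]$ null.

Two guards make the duration well-defined on noisy data: the return test
only starts once the trace has left the band for at least 3 consecutive
samples (6 s at 2-s sampling; evoked transients last tens of seconds, so
shorter blips are noise and the response is null), and if the trace never
returns, the duration caps at the next stimulus onset or the record end
with a warning. ROIs with basal concentration above 300 nM are excluded,
and a final class is assigned only when both stimulations agree, otherwise
the ROI is excluded; summary percentages use included ROIs as denominator.
Whether the AUC integrand should be $\mathrm{Ca}$ or $\mathrm{Ca} - bl$ is
a genuine modelling fork; the baseline-relative form is the default because
it is the one consistent with thresholds straddling 1, and the absolute
form is recoverable from the returned pieces.

## What the generator emulates — and what it does not

The generator reproduces: 100–400 cells per explant with damped noisy
~24-h oscillations sampled every 29 min for 120 h; a two-population shift
structure for delay explants (29% rapid at ~4 h vs ~1.5 h, within-population
SDs 0.5/1.0 h — placeholders for quantities no published measurement pins
down, exposed in the config); rapid cells placed ventrolaterally with probability 0.9; a
ventral→dorsal peak-time gradient of 4 h per normalized unit plus 0.5 h
per-cell jitter, a decomposition chosen so the control-explant phase
distribution comes out ≈1.1 h while remaining mostly spatial structure (a
jitter-dominated decomposition matches the dispersion number but would make
the measured shift histograms unimodal, contrary to the delay-group
observations); optional image stacks of Gaussian spots for the ROI-detection
path; and 130-s calcium recordings at 2-s sampling with two 10-s stimulation
epochs 60 s apart.

It does **not** emulate: molecular feedback-loop dynamics (phenomenological
cosine only), cell movement or focus drift (ROIs are static, as the
analysis assumes), photobleaching beyond geometric damping, inter-explant
anatomical variability beyond similarity transforms, electrode artifacts,
or dye bleaching. Passing tests therefore demonstrate correctness of the
measurement and inference machinery under the stated statistical structure,
not robustness to every artifact of real recordings.

## Numerical choices and problem sizes

Quarter-hour histogram bins are half-open on the left, spanning the data
range on quarter-hour boundaries. Ties at the bimodal cutoff go to the slow
side. ROI detection thresholds the per-pixel peak map at median + 5 MAD and
keeps 4-connected components of 3–9 pixels. Sub-seeds for cohort simulation
are derived linearly from the master seed modulo a large prime, keeping all
seeds within 32-bit integer range. The test and acceptance suites use
explants of 120–300 cells, cohorts of 3–4 control explants, 100 fit
replicates per power study, and 200 replicates for the false-positive rate
— sizes at which every stochastic assertion has comfortable margin while
the whole suite runs in well under a minute per file.

## Known limitations

- Arithmetic (non-circular) averaging of peak times breaks down if
  within-region spreads approach half a period.
- The template has no elastic registration; anatomically distorted explants
  would need nonlinear alignment upstream.
- The exact signed-rank enumeration is limited to 15 pairs.
- The two-component fit assumes at most two populations; the nested-model
  override makes three-population data collapse to one or two components.
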