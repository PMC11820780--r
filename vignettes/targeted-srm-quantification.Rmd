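---
title: "Models and methods behind srmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srmquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmquant)
```

srmquant implements the post-acquisition computational workflow of a
dual-method (HILIC + reversed-phase) scheduled-SRM targeted metabolomics
assay on a polarity-switching triple quadrupole: the assay definition and
its scheduling arithmetic, weighted calibration with quantification
limits, the validation statistics (carryover, standard-addition recovery,
repeatability), and recovery-corrected two-dilution quantification with
ion-ratio confirmation.  This vignette explains the models, their
assumptions, the defaults and the deliberate design choices.

## The assay model

The assay is described by a flat transition registry: one row per SRM
transition, two transitions (quantifier + qualifier) per analyte, with a
small number of documented exceptions (single-transition analytes where
only one reliable fragmentation exists, and both-polarity analytes that
carry one transition per polarity because two reliable transitions could
not be found in a single polarity).  A full 235-analyte panel built this
way carries $235 \times 2 - 3 = 467$ transitions; `synthetic_full_registry()`
reconstructs a panel with exactly this structure.  The reconciliation of
the both-polarity analytes (exactly two transitions, one per polarity) is
an inference from the transition count, and is documented as such.

Each LC method is a gradient program; the run ends with the last
programmed segment, so `run_duration()` is simply the final segment time
(23.0 min for the built-in RP program, 16.5 min for HILIC — 39.5 min of
instrument time per sample).

## Scheduled-SRM dwell-time budgeting

In scheduled SRM each transition is only monitored inside a retention-time
window (`|t - rt| <= window/2`, closed interval, 30 s wide by default, 60 s
for compounds whose plasma isomer envelopes shift retention time).  At any
instant the active transitions share one duty cycle:

$$\mathrm{dwell}(t) = \frac{T_\mathrm{cycle} - \mathrm{overhead}(t) - n(t)\,
t_\mathrm{pause}}{n(t)}$$

with $T_\mathrm{cycle}$ = 1000 ms, $t_\mathrm{pause}$ = 5 ms per
transition, and an overhead of two polarity-switch settling events
(2 x 15 ms) whenever both polarities are active, zero otherwise.  Dwell is
floored at 3 ms — the smallest value modern instruments quantify reliably —
and when the floor binds, the realized cycle stretches to
$\mathrm{overhead} + n\,(3 + t_\mathrm{pause})$ ms and the grid point is
flagged infeasible.  Points per chromatographic peak are
`peak_width * 1000 / cycle`.

The equal split across concurrent transitions is a model choice: vendor
schedulers do not disclose their allocation rule, and an equal split under
the stated budget is the simplest allocation consistent with published
dwell-time profiles.  The rule lives behind `allocate_dwell()` so an
alternative (e.g. intensity-proportional) allocation can be slotted in.
Time is discretized on a 1 s grid by default.

## Weighted calibration and quantification limits

Calibration uses external standards fitted by $1/x$-weighted least
squares, where $x$ is the nominal concentration.  Peak-area variance in
LC-MS/MS grows roughly with the signal, so over ranges spanning several
orders of magnitude an unweighted fit is dominated by the top levels and
back-calculates poorly at the bottom; $1/x$ is the standard bioanalytical
compromise.  The zero-concentration standard is excluded (its weight is
undefined); it only informs noise assessment.  With `model = "auto"` the
linear model is kept when its weighted $r^2 \ge 0.995$, otherwise a
quadratic accommodates detector saturation.  $r^2$ is computed on the
weighted residuals.

Quantification limits follow signal-to-noise rules on a 14-level series
(0.1 ... 50000 ug/L plus a zero level): the LOD is the lowest level with
S/N >= 3, the LLOQ the lowest with S/N >= 10.  S/N is defined as peak
apex height divided by the standard deviation of baseline noise — the
most common convention; the assay data (and the synthetic generator)
supply both per measurement, and the definition is isolated in
`determine_lod_lloq()`.  Injector carryover can leave a constant residual
peak at the bottom of the series; when the series *starts* with
consecutive levels whose areas fail to grow by at least a factor 2
(the grids are roughly 3x-spaced), the LOD is reported undetermined and
the LLOQ moves to the lowest level where the area clearly increases and
S/N >= 10.  A flat stretch in the middle of a series does not trigger
this fallback — the carryover floor is a low-end phenomenon.  Because the
trigger depends only on areas, scaling the noise up can never lower the
LOD or LLOQ (a property the tests assert).

The ULOQ is found by descending search: the largest level $L$ such that
the curve refitted on $[\mathrm{LLOQ}, L]$ keeps $r^2 > 0.995$ *and*
back-calculates $L$ within 95–105% of nominal.  With ~5% single-injection
measurement noise the 95–105% check at the top level fails with
appreciable probability even for a perfectly linear analyte, so the
determined ULOQ can sit one or two levels below the top of the range;
this conservatism is inherent to the rule, not a defect.

Back-calculation inverts the curve; for a saturating quadratic only the
root on the monotone branch (below the parabola vertex) within
$[0, 1.05\,\mathrm{ULOQ}]$ is admissible, which rejects the spurious high
root beyond the saturation turnover.  The reference ion ratio is the mean
qualifier/quantifier area ratio at three representative levels within the
quantifiable range (`calibrate_analyte()` picks the three closest to the
geometric mid-range).

## Carryover, recovery and repeatability

Carryover is the trailing-blank area as a percentage of the preceding
high standard (the 1 mg/L level, or the highest validation level for
high-LLOQ analytes), binned at 1% and 5%.

Apparent recovery ($R_A$) comes from standard addition: six spiking
levels at 0.5–3x the predetermined native concentration (or 12.5–75x the
LLOQ for analytes undetected in the QC pool; one high level only for
poorly soluble compounds), each in triplicate ($n = 18$).  Two estimators
are provided:

* **Slope ratio** — $R_A = 100 \cdot s_\mathrm{spiked}/s_\mathrm{neat}$,
  for analytes with linear response.  The regression lines are fitted by
  *ordinary* least squares: the spiking range spans less than one order
  of magnitude, so calibration-style $1/x$ weighting is unnecessary
  here — and actively harmful, because the zero-spike sample still
  carries the full native signal, so a variance model keyed to the spike
  amount mis-weights the series and inflates the slope variance.
* **Level-wise** — per observation
  $R_A = 100\,(c_\mathrm{sp} - c_\mathrm{NS})/c_A$, with $c_\mathrm{sp}$
  back-calculated through the analyte's wide-range neat-solvent
  calibration curve.  $c_\mathrm{NS}$ is the *measured* native
  concentration, which makes the two estimators exactly equal on
  noiseless linear data with a constant matrix factor (an identity the
  tests assert on random parameter draws).

`estimate_recovery()` chooses between them by the analyte's response
shape, not by the raw $r^2$ of the narrow spiking series: with realistic
5% multiplicative noise the $r^2$ of a 6-level, 0.5–3x regression is
~0.97–0.99 for a *perfectly linear* analyte, so a hard 0.995 gate there
would misroute every analyte into the noisier level-wise path.  When the
wide-range calibration curve is available, its auto-selected model
(linear vs quadratic) decides the route; otherwise a curvature
significance test (p < 0.05 by default) on the neat series does.  An
$r^2 > 0.9$ gross-failure guard on the slope fits still catches erratic
series.  Back-calculating the level-wise route through the wide-range
curve rather than the narrow comparison series avoids extrapolation
(spiked samples reach native + 3x native, beyond the spike-only range)
and matches how quantification actually works.

Repeatability is the RSD (sample SD, $n-1$) of the 18 per-observation
recoveries; negative recoveries are retained so the RSD reflects the raw
dispersion.  Acceptance: 70–130% is acceptable; outside the band the
analyte's quantification is corrected by its recovery; an out-of-band
recovery that is *also* erratic (RSD > 25%, the reporting convention's
bound, configurable) marks the analyte unreliable ("reject").

## Quantification

Samples are injected at two dilutions (1:5 and 1:100 overall, i.e.
plasma + 4 volumes of precipitant, then 1 + 19).  Each dilution is
back-calculated; among dilutions whose measurement lies within
[LLOQ, ULOQ] the *most dilute* wins, because matrix effects shrink with
dilution.  For low-abundance compound classes that drop below the LLOQ
at 1:100, `prefer = "least_dilute"` pins them to 1:5.  If nothing is in
range the result is censored (`>ULOQ` with an advisory that a higher
dilution — e.g. 1:500 — is required, or `<LLOQ`).

Recovery correction applies
$c_\mathrm{corrected} = c \cdot 100 / R_A$ using the RA of the *matching
dilution* when it lies outside 70–130% (the `"threshold"` policy, the
validated-assay rule).  Correction with $R_A = 100$ is the identity.  Two
further policies are exposed: `"always"` and `"never"`.  The end-to-end
simulation checks in this package run `"always"`: with true matrix
factors spanning [0.7, 1.3], the threshold policy deliberately leaves
in-band analytes uncorrected (and hence up to 30% biased against ground
truth), so a parameter-recovery claim like "within 15% of truth" is only
meaningful for the always-corrected pipeline.  What that check
demonstrates is that the *estimated* recoveries are accurate enough to
reconstruct true concentrations; it does not claim the threshold policy
yields 15% accuracy.

Duplicate injections are averaged after censoring resolution (a
quantified result beats a censored one, flagged).  Ion ratios confirm
identity within a +-30% relative tolerance — a conventional confirmatory
band, configurable, not an assay-derived value.  Co-eluting isomers with
a shared and a unique transition (the leucine/isoleucine case) are
resolved by subtraction, with negative differences censored at zero and
flagged; the subtraction conserves the sum pre-censoring.

Trueness against certified reference values is the integer percentage
`round(100 * measured / certified)`, ties away from zero — the convention
every printed trueness table uses; below-LOD analytes are excluded from
the "within 70–130%" summary count.

## The synthetic-data generator

`synthetic_truth()` + `simulate_peak_table()` stand in for the
instrument.  The realized quantifier area at measurement-solution
concentration $c$ is

$$A = d(i)\; m(\mathrm{dilution})\; (a c + b c^2)\;
\varepsilon_\mathrm{ln} + \varepsilon_\mathrm{base}, \qquad
A \ge 0$$

with $d(i)$ a piecewise-linear multiplicative drift in injection index
(default 100% to 80% across a sequence — the minimal model matching
bracket-calibration drift correction), $m$ a per-analyte, per-dilution
matrix factor, $\varepsilon_\mathrm{ln}$ a mean-1 lognormal factor with
CV = `rsd` (default 5%, a validated assay's typical mid-range
repeatability), and $\varepsilon_\mathrm{base}$ additive Gaussian
baseline noise.  The lognormal-plus-baseline structure reproduces the two
empirical regimes: S/N limits quantification at the low end, while RSD is
roughly level-independent at the high end.  Matrix factors at 1:5 are
drawn uniformly (default [0.7, 1.3]); at 1:100 only 40% of the deviation
from unity persists, emulating the observed improvement of recoveries
upon dilution.  Native plasma concentrations are log-uniform over
50–20000 ug/L.  Blanks inherit `carryover_fraction` of the previous
injection's area, so consecutive blanks decay geometrically.  Qualifier
transitions respond at the true ion ratio with independent noise draws.
The emitted height is area/4 (a fixed area-to-height proxy; no peak
shapes are simulated) and the emitted noise estimate is on the same
height scale, so the expected S/N at concentration $c$ is
$a c / \sigma_\mathrm{base}$.

What the generator does *not* emulate: chromatographic peak shapes,
retention-time drift, ionization physics, interferences from unmodeled
isobars, and work-up losses distinct from matrix effects.  Tests passing
on this generator therefore demonstrate the correctness of the
*arithmetic and estimators* under the stated statistical model, not the
chromatographic robustness of a real assay.

Calibration standards are simulated as single injections per level
(replicate counts for standards are not specified by the protocol; single
injection with bracketing is the documented default), while spiked
samples and their neat comparison standards are in triplicate per level,
mirroring the standard-addition protocol in which the comparison
solutions are processed identically to the spikes.

## Problem sizes and numerical choices

The simulation studies shipped with the package use 100 synthetic
analytes for the recovery and end-to-end checks, 100 random registries
for the scheduler properties, and 200 random datasets for the
weighted-least-squares oracle comparison — sizes at which the checked
means and fractions are stable to well under their acceptance margins.
At the default design (6 levels x 3 replicates, 5% CV), the mean
absolute error of the slope-ratio recovery estimate sits near 3
percentage points — close to the information limit of an 18-point
regression over a 0.5–3x range — and the end-to-end always-corrected
pipeline recovers 94–100% of analytes within 15% of truth across seeds.

Ties in rounding are away from zero wherever a percentage or index is
printed (integers for percentages, one decimal for polarity indices).
Weighted $r^2$ uses the weighted mean of the response.  Quadratic
back-calculation rejects roots off the monotone branch.  Degenerate
inputs (all-identical levels, empty gradient programs, non-positive
areas where positives are required) raise errors rather than propagate
NaNs; infeasible dwell allocations are reported, not raised.

## Known limitations

* The dwell allocation is a model of an undisclosed vendor algorithm;
  only its budget arithmetic, not its exact output, can be compared.
* The LLOQ carryover fallback keys on an initial flat run of the area
  series; pathological series that are flat only mid-range pass through
  the plain S/N rules.
* The registry validation covers structural rules; it does not check
  chemical plausibility of m/z values.
* Standard additions assume spiking does not perturb the matrix; the
  generator enforces this by construction.
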