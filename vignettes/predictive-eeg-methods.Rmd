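---
title: "Methods: analysing EEG markers of prediction under certainty and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing EEG markers of prediction under certainty and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the paradigm and trial logic, the measures, the inference layer, the
synthetic-data generator that stands in for recorded EEG, and the
numerical and design choices that a maintainer would want spelled out.

## The paradigm and its trial logic

Stimuli are triangles shown for 150 ms every 1.15 s (a 1 s inter-stimulus
interval). A block holds 127 stimuli: 15% targets (downward-facing) and
85% standards in equal thirds of leftward-, upward- and rightward-facing
triangles. A target is either *random* (`randT`, uncertain context) or
*predictable* (`predT`), announced by the fully predictive contiguous
sequence left → up → right. Stimuli inside the sequence are `predS1..3`;
the physically identical stimuli outside it are `randS1..3`. The labelling
rule is purely local — any contiguous (left, up, right, down) quadruple is
a predictive sequence — so a generated identity stream can be relabelled
from scratch, and `generate_block()` rejection-samples orderings until the
relabelling reproduces its intent exactly. That constructive check is what
makes the labels unambiguous: no accidental quadruple can arise.

Trial exclusion mirrors standard practice for this paradigm, applied in a
fixed order of precedence (the first matching rule is recorded): the
standard immediately following a target; standards with a button press
inside a ±700 ms peri-stimulus window (the same window as the artifact
check — the phrase "before or after a button press" is interpreted as this
symmetric window, configurable); a `randS2` preceded by a `randS1` but not
followed by a `randS3` (it could have been a `predS2`); targets with no
press in (100, 1100] ms; targets whose three immediately preceding events
are not all standards; and artifact-flagged trials. Trial counts are then
equalized within each compared pair by random subsampling of the larger
member, never the smaller.

## Preprocessing

* **Reference.** Scalp channels are re-referenced to the average of the
  two earlobe electrodes; the operation is a one-way state transition so
  it cannot be applied twice. Pairwise scalp differences are unaffected.
* **Filtering.** Two analysis bands: 0.5–30 Hz for slow components (CNV,
  P3) and 4–30 Hz for early transients with the slow waves removed. The
  filter is zero-phase by construction: the squared-magnitude Butterworth
  response (low-pass order 4, high-pass order 2) is applied in the
  frequency domain. This is the magnitude response a forward–backward
  (filtfilt) cascade would have, with exactly zero phase and no start-up
  transients; a time-domain band-pass with a 0.5 Hz corner at 512 Hz is
  numerically fragile in transfer-function form. The response meets the
  usual ERP requirements: monotone passband (ripple well under 1 dB) and
  more than 24 dB attenuation one octave outside the band.
* **Bad channels.** Spherical-spline interpolation with the conventional
  reference values: order m = 4, Legendre series truncated at n = 7, ridge
  regularization 1e-5. The spline reproduces constant fields exactly;
  interpolation of more than half the montage is refused.
* **Epoching convention.** Time t maps to sample `round(t * rate)`;
  windows include both endpoint samples. Every window-based measure in the
  package (baselines, peak searches, window means, artifact checks, band
  power) uses this one convention, tested explicitly. Stated windows such
  as (−150, 0) ms are treated as closed intervals; scan grids are
  half-open `[t, t + w)` except the last window.
* **Artifacts.** A trial is flagged when any scalp channel exceeds a
  peak-to-peak threshold within (−700, 700) ms. The threshold default is
  150 µV — a conventional value, since the criterion is otherwise
  qualitative — and is configurable. Ocular ICA is deliberately out of
  scope: the pipeline accepts externally cleaned recordings, and the
  synthetic data are blink-free by default.

## ERP and time-frequency measures

Evoked responses are pointwise means over included trials per category.
Post-stimulus measures use a (−100, 0) ms baseline; pre-stimulus (CNV)
measures use *no* baseline, and the baseline state is carried on the
object so a mismatch is an error rather than a silent bias. Peaks are the
signed extremum in the stated window (N1 (105, 230) and P2 (205, 310) ms
at PO4; P2 (155, 255) and N2 (215, 350) ms at FCz; P3 maximum (250, 750)
ms at Pz), reported at sample resolution (≈1.95 ms at 512 Hz) with ties
broken to the earliest sample — no interpolation, because latency
differences of interest here are tens of milliseconds.

Time-frequency power comes from Gaussian Morlet wavelets with
f₀/σ_f = 7 (the convention of the method this analysis cites; the grid
default is 1 Hz steps). The wavelet is scaled so that a sinusoid of
amplitude A at the centre frequency yields power A²/2 — its squared rms,
in µV² — which makes band power directly interpretable. Samples closer
than 3σ_t to an epoch edge are set to `NA` rather than zero-padded, so
edge contamination surfaces as missing data instead of biased numbers;
consequently time-frequency epochs are cut wider (±1.05 s) than the
(−500, 500) ms analysis window. Power is baseline-corrected by
subtracting, per channel and frequency, one scalar: the mean power in
(−500, −250) ms before all S1 stimuli (randS1 and predS1 pooled), applied
identically to every stimulus category so that category contrasts are
untouched. The phase-locking factor is the modulus of the across-trial
mean of unit-normalized complex coefficients; the significance mask uses
the fixed threshold 0.25 as stated for this analysis, *not* recomputed per
trial count. That constant corresponds to α = 0.05 only near n ≈ 48
trials, while realistic clean-trial counts are higher; the exact Rayleigh
p-value exp(−n·PLF²) is therefore returned alongside the mask.

## The inference layer

The split-plot 2×2 ANOVA is computed from scratch: between-subject
variation splits into group and subject-within-group (the error term for
the group effect); within-subject variation into predictability,
predictability × group, and their residual (the error term for both
within-subject effects). With two levels per factor no sphericity
correction exists to make. Two numerical guards matter in the
mass-univariate setting: the subtractively computed error sums of squares
are clamped at zero (catastrophic cancellation can drive them slightly
negative), a zero effect SS reports F = 0, and a positive effect SS over a
zero error term reports F = ∞ (p = 0).

The paired permutation test enumerates all 2ⁿ within-pair swaps (n ≤ 20;
4096 for 12 subjects) of the statistic T = (Σ sample₁)² + (Σ sample₂)².
Because the pair totals are fixed under swapping, T is a monotone function
of the squared difference of condition sums, so the test is the two-sided
test of zero mean difference; the enumeration is compared against an
independently coded enumerator in the tests. Tie comparison uses a 1e-9
relative tolerance so that mathematically equal statistics reached by
different floating-point paths count as ties. The randomization test
shuffles group labels 10,000 times and uses the add-one rule
p = (1 + #{T ≥ T_obs}) / (1 + n_rand), which cannot report zero.

Mass-univariate scans run the ANOVA in every electrode × window cell. The
corrected threshold is the base α divided by the number of windows —
0.05/40 = 0.00125 for the 10 ms transient grid over (0, 400) ms. For the
200 ms / 100 ms time-frequency grid (9 windows) the stated constant 0.005
is used verbatim rather than 0.05/9 ≈ 0.0056. An effect is retained only
where sub-threshold electrodes form a connected set of at least 4 on the
adjacency graph, within one window; clustering across windows is not
required by the rule and not implemented. "Adjacent" is not defined by the
design, so the package constructs the graph explicitly — electrodes closer
than 1.5× the median nearest-neighbour spacing in the flat-projected
montage are neighbours — and exports it for inspection; both the
multiplier and the whole graph are replaceable.

Spearman correlation uses average ranks; its p-value is delegated to
`stats::cor.test` (exact null distribution for n ≤ 10 without ties, the
t-approximation otherwise) since it is a standard step, not part of the
bespoke machinery.

## The synthetic-data generator

The generator produces what the analysis *assumes*: 64 scalp channels plus
two earlobe references at 512 Hz (both reducible for small studies —
analyses are rate- and montage-agnostic), with

* Gaussian-windowed monophasic component templates (posterior N1/P2,
  fronto-central P2/N2, centro-parietal P3) whose per-category gains and
  latency shifts live in a `group_profile`; the P3 gain grows along the
  predictive sequence;
* a linear CNV ramp from −300 ms to stimulus onset, with per-category
  gains (the control-like preset ramps mainly before predictable targets;
  the autism-like preset before all random stimuli);
* a left-central mu rhythm modelled as a constant-amplitude 10 Hz
  oscillation with phase diffusion (≈1.4 Hz linewidth): narrowband and not
  phase-locked to stimuli, but with a well-defined band power, so that a
  programmed fractional power change is recovered precisely. Its
  amplitude is scaled by √(1 + mu_erd) in the motor-preparation window
  before predictable targets (−30% power for the control-like preset,
  none for the autism-like preset); a fronto-central alpha rhythm is
  modulated analogously;
* a phase-locked post-target alpha burst (decaying 10 Hz cosine at
  fronto-central channels) to exercise the phase-locking factor;
* 1/f background noise (exponent 1, 3 µV per channel) mixed over the
  montage with a Gaussian spatial kernel, plus a weak low-rank background
  alpha; earlobe channels carry 30% of the scalp background, since a
  quiet reference is what earlobe referencing presumes;
* behavioral responses from a truncated normal inside the (0.1, 1.1) s
  response window, with group-specific means (control-like 450/400 ms for
  random/predictable targets; autism-like 410/390 ms), miss and
  false-alarm rates, and between-subject jitter of component gains
  (lognormal, sd 0.15) and RT means (sd 30 ms).

Absolute µV effect sizes are free parameters of the simulation — the
defaults are ordinary ERP magnitudes, not claims about any particular
dataset. Event onsets are snapped to the sampling grid, and all
randomness derives from one master seed with per-subject seeds drawn
deterministically from it, so studies are bit-reproducible.

What the generator does **not** emulate: volume conduction from a head
model, ocular or muscular artifacts (an amplitude criterion is exercised
with injected spikes instead), non-stationary drifts, electrode
impedance differences, or any coupling between behavior and single-trial
EEG. Passing tests therefore demonstrate that the pipeline recovers the
statistical structure it is designed for; they are not evidence about
artifact robustness on recorded data.

## Problem sizes used by the tests and the acceptance script

These are the package's chosen reduced scales, set once by a pilot power
analysis before the checks were frozen:

* **Null calibration** (500 datasets): subject-level measures simulated at
  the measure level — 12 + 12 subjects, 40 trials/condition averaged to
  subject means, identical group distributions — feeding the real
  permutation and ANOVA code. Rejection at α = 0.05 must sit within ±2
  standard errors of 0.05. The exhaustive permutation p is discrete
  (multiples of 1/4096), so its attainable level is ⌊0.05·4096⌋/4096 ≈
  0.0498; rejection is `p ≤ 0.05`.
* **Parameter recovery** (50 studies): 12 + 12 subjects, 2 blocks of 68
  stimuli, 256 Hz, an 11-channel montage containing the injected and
  analysis electrodes. Endpoints: the predictability × group interaction
  in 8–14 Hz power at C5 in (−400, −200) ms (right-handed subjects only),
  and the group difference in the pre-randT CNV mean read at Cz — the
  centre of the injected CNV topography. At PO3, further down the
  topography, the 0.5 Hz high-pass leaves little of the contrast, because
  the autism-like profile ramps before nearly every stimulus and that
  quasi-DC structure is removed by design; reading the injected channel is
  the honest recovery check.
* The mu-desynchronization oracle runs at 60 trials/condition with the
  rhythm isolated (no noise), where the measured power ratio must match
  1 + mu_erd within 10%.

## Known limitations

* The ANOVA partition assumes a balanced or near-balanced two-group
  design; grossly unbalanced groups would need a cell-means (Type III)
  formulation.
* The adjacency graph is geometric, not anatomical, and the minimum
  cluster rule is within-window only.
* The spherical-spline layout is constructed from the 10-10 geometric
  convention, not digitized positions; it is adequate for interpolation
  and adjacency but not for source analysis.
* EDF/BDF file ingestion is not implemented — recordings enter as
  in-memory containers (or from the generator) and events as
  tab-separated tables compatible with BIDS `events.tsv`.
* The fixed 0.25 phase-locking threshold is honoured as a constant; its
  nominal level varies with trial count (see above).
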