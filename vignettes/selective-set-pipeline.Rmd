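---
title: "Methods: vincentized selective-set ERP analysis and forward simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vincentized selective-set ERP analysis and forward simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpactr)
```

This vignette documents the models, assumptions and numerical choices behind
`erpactr`. The package targets go/no-go target-detection ERP experiments on
a 12-channel 10–20 montage: a block of 150 picture trials (37 targets, 113
distractors; 500 ms stimulus + 500 ms fixation), epochs of −200…+1000 ms at
1000 Hz (1200 samples), and 13 subjects as the reference design.

## Vincentized quantile bins

Each epoch is cut into twelve half-open 100 ms bins. Within a bin, the
amplitude sample of one subject/condition/electrode is summarized by its
left-continuous empirical quantile function evaluated at the mid-points
`α_j = (j − ½)/q`, with `q` equal to the within-bin sample count — i.e. the
sorted sample itself, which keeps data density equal across bins. The
Vincent average across subjects is the pointwise weighted mean of these
quantile functions; because averaging quantiles commutes with affine maps,
distribution shape is preserved exactly within any location-scale family
(property-tested at 1e-9).

Choices made where the procedure was underdetermined:

* **Weights** default to `1/n`; they are configurable but equal weights
  reproduce the arithmetic mean of quantiles.
* **The variate being vincentized** is the within-bin amplitude
  distribution per subject. A competing reading (quantiles of a time
  distribution over the epoch) is inconsistent with sorting amplitudes
  within bins, and is not implemented.
* **No baseline correction** is applied by default; pre-stimulus mean
  subtraction is available behind `vincentize_epochs(..., baseline = TRUE)`.
* The cell summary (mean of the mid-point quantiles) is algebraically the
  within-bin mean; the quantile machinery matters for shape-sensitive uses
  and is exposed (`quantile_midpoints`, `vincent_average`) rather than
  hidden.

## Omnibus ANOVA and focused contrasts

The stated design — interval bin as a *between* factor, electrode and
condition *within* — implies the observational unit is the subject × bin
"case". `omnibus_anova()` computes the classical balanced split-plot
decomposition from first principles (verified against R's projection-based
`aov` on random designs at 1e-8) and exposes the error mean square of the
electrode × condition stratum, `mse_within()`. Treating the same 13
subjects in every bin as independent cases is statistically odd but is the
design as stated; published error df on raw-EEG scale (13068) cannot be
reconstructed from any binned layout and our df follow the data shape.

The minimum significant difference is `t_crit · sqrt(MSE · Σ λ²/n)`. The
critical t defaults to the two-tailed quantile at the already-corrected
p = 1e-4 with df = 12 (5.694). Dividing a 0.05 family alpha by 12
electrodes would give 0.0042, not 1e-4; the printed corrected level is taken
at face value and both the family size and df are arguments.

**Classification polarity.** A signed cell difference alone cannot say which
condition had the *larger* peak when the dominant peak is negative-going:
−1.6 µV at a negativity means the target was more negative, i.e. larger.
Classification therefore requires polarity metadata (sign of the dominant
peak per cell): advantage goes to the target iff `sign(diff) == polarity`.
For synthetic runs the generator's enhancement table supplies the polarity;
for the shipped reference table the polarity is derived from its printed
advantage labels.

**Enhancement χ².** The 2×2 table {(n_T, N−n_T), (n_D, N−n_D)} is tested
with the Yates continuity correction (clamped at zero): the corrected
statistic on (46, 5, 84) is 45.05 whereas the uncorrected one is ≈47.3, so
correction is the default.

## Activity paths

Per analysis bin (1–7, 0–700 ms: up to the approximate manual-response
time), the flagged cells of a condition contribute their electrode of
maximum |difference|; electrodes within a *simultaneity tolerance* of the
maximum (capped at three) are treated as co-active. The tolerance is a
prominent parameter: "non-significantly different maxima" is not a formula,
and the natural default is the minimum-significant-difference threshold.

Orderings within a step are chosen by exhaustive permutation search under
the wiring-minimization movement rules (occipital only forward/lateral,
frontal only backward/lateral, left-column laterals rightward, right-column
laterals leftward, midline unrestricted), minimizing total chord distance.
On this 4×3 grid the stated rules are in fact never violated by any
two-electrode move (a left-column electrode cannot move further left, etc.),
so the practical discriminator is the deterministic tie-break: prefer the
ordering starting at the most posterior row (matching the
posterior-to-anterior flow of target activity), then label order. The
replay validator and the constraint-violating annotation are retained for
richer montages where the rules do bind. Between-step transitions are
annotated with their legality but never filtered.

## Head model and forward simulation

Electrode positions use a fixed geometric 10–20 convention (unit sphere, Cz
at the pole, the circumferential ring at 72° inclination, F3/F4 and friends
as great-circle midpoints). Only relative field magnitudes are used, so any
fixed convention is equivalent; note that under true 10–20 geometry Fz
mirrors Pz about the coronal plane (Oz sits lower on the ring).

Each production drives a current dipole: potential `k·p·cosθ/r²` with k = 1,
radial moments by default, positions from an editable synthetic coordinate
table (approximate stereotaxic positions normalized by a nominal 90 mm head
radius — they are configuration, not computed facts). The spike time course
is triangular with a 100 ms default width, so consecutive productions
(100 ms apart) have marginally touching, non-overlapping supports and at
most one dipole is active at any instant.

The production engine is a purpose-built minimal cycle: one chunk per
buffer, serial firing, if-pattern matching against buffer contents, stall
errors when nothing matches. The schedule completes production k at
`k·100 + 50` ms. Target runs traverse visual → spatial → declarative →
executive → procedural → manual and release the motor program; distractor
runs withhold it and carry dipoles only at 250 ms (middle temporal) and
550 ms (claustrum) — firings without a mapped dipole contribute background
field only. Activation profiles (ex-Gaussian rise µ = 30, σ = 10, τ = 40 ms;
decay half-life 50 ms; rest level 0.1 × task) are package defaults, not
measured facts; "faster productions are more intense and decay faster" is
honored by scaling intensity with the inverse inter-firing duration and the
decay rate with intensity. A narrated target time of "45 ms" for the insula
in the source material is treated as a typo for 450 ms, consistent with the
production schedule.

Polyspiking evaluates, at every production time and electrode, the sum of
task-level, decaying and resting dipole contributions; coarse coding maps
amplitudes onto 13 ordered intensity categories spanning −6…+6 µV (odd count
so zero is the middle category) via a symmetric gain that sends the largest
absolute amplitude to the bound. Topographic map values are the continuous
rescaled field; the quantized category is carried alongside, so the
noise-free map-vs-map regression identity (R² = 1 at 1e-9) holds exactly.

## Homology tests

Functional: OLS of the actual per-bin map on the simulated one (12
electrodes per fit; published F(1,11) would imply 13 points — documented
mismatch, electrode count configurable), summarized by min/max R². R² is
computed in closed form for the simple regression; it is invariant to
affine rescaling of either map. Structural: localization search ranges
(1–5 mm grey-matter search) are z-scored; since standardizing each group
separately would make any location test vacuous, `homology_report()`
standardizes both groups against the pooled mean and sd before the Welch t
(Mann-Whitney optional). The published R²/F pairs are mutually inconsistent
under F = R²(n−2)/(1−R²) and are not used as exact targets.

## Synthetic-data generator

The generator states the experiment's world: 13 subjects, 150 trials with
37 targets, hit rate 0.775, false-alarm rate 0.0607, ex-Gaussian RTs with
mean 685 ms (µ = 485, σ = 50, τ = 200 — the split between components is a
documented choice, only the mean is stated), 1000 Hz epochs. Epoch noise is
Gaussian AR(1) (φ = 0.95, innovation sd 2 µV) plus a 1 µV-sd subject offset;
the AR model is a pragmatic stand-in for EEG background, not a fitted
spectrum. Condition structure comes either from per-bin raised-cosine
enhancement bumps whose within-bin means equal a configurable electrode ×
bin offset table (default: the shipped reference difference table), or from
the dipole forward model for recovery tests.

What a green test does *not* establish: the default AR(1) noise has a
marginal sd of ≈6.4 µV, which is realistic for a light average but makes
the data-driven significance threshold (~9 µV) larger than the configured
effects — so a blind run at stock noise flags nothing, and the
46-vs-5-style asymmetry only emerges at reduced noise (as exercised in the
parameter-recovery and calibration tests via the exposed config). The
generator also omits blinks, drift, artifact rejection (a `reject_fraction`
knob exists but defaults to 0) and pediatric head-geometry differences.

## Numerical and degenerate-input decisions

* Extreme hit/false-alarm rates use the 1/(2N) correction when trial counts
  are supplied, otherwise error.
* Zero-spread inputs: z-ranges return zeros with a `degenerate` flag;
  `compare_z_ranges` on two zero-spread equal groups reports p = 1.
* `enhancement_test` clamps the corrected |ad−bc| − N/2 at zero and rejects
  zero margins.
* Quantile functions are validated to share one α grid (1e-12); Vincent
  weights must sum to 1 within 1e-9.
* Unbalanced ANOVA input errors rather than silently reweighting.
* All generators take explicit seeds; `with_seed` restores the caller's RNG
  state, so no hidden global-state coupling.

## Scaling in the test suite

The default test run scales simulations down (e.g. 100–250 Hz sampling,
4–8 subjects) wherever a property does not depend on the within-bin sample
count; the full-scale 13 × 2 × 12 × 1200 grid is generated once to verify
the documented record count. The type-I calibration runs the whole
vincentize → ANOVA → threshold → classify chain on 200 seeded null data
sets at reduced scale.
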