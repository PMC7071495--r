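# erpactr

Analysis and simulation toolkit for **selective-set attention ERP
experiments** — go/no-go target-detection designs in which a stream of
pictures (25% targets, 75% distractors) is presented while EEG is recorded
from a 12-channel 10–20 montage (F3, Fz, F4, Cz, T7, T8, P7, Pz, P8, O1, Oz,
O2). It is written for cognitive-neurophysiology researchers who want a
reproducible, scriptable version of the full chain from epoched amplitudes to
topographic-map homology statistics, including a seeded synthetic-data
generator so every stage can be exercised without any recording.

## What it computes

**Vincentized bin statistics.** Each −200…+1000 ms epoch is divided into
twelve 100 ms bins. Within each bin the amplitude sample of each subject is
summarized by its mid-point quantile function
`F_i^-1(α) = inf{v : F_i(v) ≥ α}` and averaged across subjects as the Vincent
average `Σ w_i F_i^-1(α)` (`Σ w_i = 1`), which preserves distribution shape
across individuals.

**Focused contrasts.** A split-plot ANOVA (interval bin between cases,
electrode × condition within) supplies the error mean square `MSE_within`
for the electrode × condition interaction; the minimum significant
target−distractor amplitude difference is

```
Amp_diff = t_crit * sqrt( MSE_within * Σ λ_j² / n_j )
```

with a Bonferroni-corrected two-tailed critical t. Cells at or above the
threshold are classified as target (T) or distractor (D) advantage using the
dominant-peak polarity, and the T-vs-D proportion asymmetry is tested with a
Yates-corrected χ² on the 2×2 counts table.

**Activity paths.** Per bin, the electrode(s) of maximum significant
difference (up to three "simultaneous" ones within a tolerance) are ordered
by exhaustive search under neural-wiring-minimization movement constraints
(occipital moves forward, frontal backward, left laterals rightward, right
laterals leftward) and concatenated into a per-condition path.

**Forward simulation.** A production-cycle (ACT–R style) model fires six
productions at `k·100 + 50` ms (visual 150, spatial attention 250,
declarative 350, executive 450, procedural 550, manual 650). Each firing
drives a current dipole whose scalp potential is `k·p·cosθ / r²` on a
unit-sphere head, with a triangular spike time course; per-electrode
polyspiking patterns are coarse-coded onto a relative −6…+6 µV scale and
assembled into per-bin topographic maps.

**Homology tests.** Structural: z-scores of grey-matter localization search
ranges (mm) compared between sources (Welch t). Functional: per-bin OLS
regression of actual maps on simulated maps, summarized by min/max R².

## Worked example

```r
library(erpactr)

# behavioral summary statistics from the published rates
sdt_metrics(0.775, 0.0607)
#> $d_prime        $c
#> [1] 2.304339    [1] 0.3967545

# the significance threshold from the focused-contrast formula
t_crit <- bonferroni_tcrit(1e-4, m = 1, df = 12)   # 5.694466
min_sig_diff(t_crit, 0.132, c(1, -1), c(13, 13))   # 0.8115 uV
min_sig_diff(5.69, 0.132, c(1, -1), c(13, 13))     # 0.8109 uV (printed t)

# classify the shipped reference difference table at 0.80 uV
sig <- classify_cells(reference_differences(), 0.80)
table(sig$flag)
#>        D  T
#> 29  5 50
enhancement_test(46, 5, 84)$chisq                  # 45.04634

# first target activity: parietal central/right electrodes
max_diff_electrodes(sig, 1, "target", 0.80)
#> [1] "P8" "Pz"

# full synthetic pipeline, deterministic under the seed
res <- run_pipeline(generator_config(seed = 1))
res$threshold        # data-driven threshold on this synthetic set
path_narration(res$paths)
```

`sdt_metrics` returns the equal-variance signal-detection sensitivity d′ and
criterion c; the 0.81 µV value is the smallest cell difference that survives
the Bonferroni-corrected contrast; the `classify_cells` table reproduces the
five distractor-advantage cells of the reference table; the χ² of 45.05
(1 df) shows the 46-vs-5 target/distractor asymmetry is far beyond chance.

## Command line

```sh
Rscript -e 'erpactr::erp_cli()' run-all --seed 1 --out out_dir
# subcommands: synth behavior vincentize contrasts paths simulate homology run-all
```

## Layout

- `R/` — montage/forward model, synthetic generator, behavior, vincentized
  binning, split-plot ANOVA + contrasts, activity paths, production-cycle
  simulator, homology, IO/pipeline/CLI
- `inst/extdata/` — reference difference table; synthetic dipole coordinates
- `vignettes/selective-set-pipeline.Rmd` — methods notes: model assumptions,
  parameter choices, numerical decisions, limitations
- `tests/testthat/` — unit, property and acceptance suites
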