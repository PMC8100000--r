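---
title: "Seed-based hippocampal connectivity and subfield volumetry with hippoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based hippocampal connectivity and subfield volumetry with hippoconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoconn)
```

## Scope and model

`hippoconn` implements a native-space analysis of hippocampal function and
structure in two arms:

1. **Functional arm.** Seed-based resting-state connectivity of the
   hippocampal head. Because the hippocampus is thin and undulating,
   a fixed anatomical seed risks sampling non-brain signal; the seed is
   instead *selected functionally*: every voxel in the anatomically defined
   hippocampal head is cross-correlated with every grey-matter voxel of the
   posterior cingulate (PCC) — the default-mode hub with the strongest and
   best-replicated hippocampal coupling — and the hippocampal voxel with the
   highest correlation becomes the center of a 9-voxel in-plane (axial)
   seed ROI. The seed's detrended mean series is correlated with every
   brain voxel, each `r` is converted to a Student `t`
   (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`), and the whole-brain `t`
   distribution is normalized to zero mean and unit variance, yielding a
   `z` map comparable across subjects despite global-signal differences.
   Group-average maps are thresholded voxelwise (one-sample t across
   subjects, two-sided `p < 0.0005` by default), cluster-extent filtered,
   and their union defines ROIs over which per-subject mean `z` is compared
   between groups with Benjamini–Hochberg FDR adjustment.

2. **Volumetric arm.** Hippocampal subfield volumes (ERC, SUB, CA1, CA2,
   CA3, DG, tail per hemisphere) are corrected for head size as
   `100 * volume / ICV`, composites are derived as `CAt = CA1 + CA2 + CA3`
   and `HIP = SUB + CAt + DG + tail`, and groups are compared by
   pooled-variance t-tests with FDR adjustment. Hemispheric asymmetry uses
   the index `AI = 100 * (L - R) / (L + R)` on uncorrected volumes
   (negative = rightward asymmetry), compared within group by paired t and
   between groups by unpaired t.

The HIP composite deliberately **excludes** the entorhinal cortex: ERC is a
parahippocampal region reported as a separate measure, and the published
group-mean totals are consistent only with the ERC-free sum — an identity
the test suite asserts exactly (2292, 2415, 3115, 3156 mm³ and the
left-hemisphere %ICV totals 0.1903 and 0.2192).

## Preprocessing chain

The functional chain runs in a fixed order, enforced by `preprocessBold()`:

| step | default | notes |
|---|---|---|
| `dropInitialVolumes` | k = 4 | discards pre-steady-state volumes (132 → 128) |
| `regressConfounds` | order-2 Fourier basis | RETROICOR-style `sin/cos(m·φ)` of measured cardiac and respiratory phase |
| `spatialSmooth` | FWHM 2 mm | separable Gaussian, `sigma = FWHM/2.3548` per axis in voxels |
| `temporalDetrend` | linear | per-voxel OLS line removal |
| `lowpassFilter` | 0.08 Hz | ideal DFT cutoff; frequencies > cutoff zeroed |

Numerical choices worth stating:

- **"2 mm filter" is interpreted as FWHM**, the dominant fMRI convention;
  a sigma interpretation can be had by passing `fwhmMm = 2.3548 * sigma`.
- **Smoothing boundary** is half-sample reflection, which for a symmetric
  kernel preserves the volume sum (hence mean) exactly; an impulse response
  reproduces the closed-form Gaussian with `sigma = 0.8493` voxels at
  2 mm FWHM / 1 mm voxels to better than 1e-3.
- **The low-pass is an ideal DFT cutoff**, not a Butterworth: it exactly
  matches "remove fluctuations above 0.08 Hz", is idempotent, and is
  unit-testable against DFT identities. On-grid sinusoids below the cutoff
  pass with < 1e-6 relative RMS error; above, they are annihilated. For
  132-volume runs at TR = 2.8 s the 0.02/0.10 Hz test frequencies are
  realized at the nearest DFT grid frequencies (k = 7 and k = 36 of an
  n = 128 transform: 0.0195 and 0.1004 Hz).
- **Motion exclusion** is one-pass and upper-tailed: a subject is dropped
  if mean *or* maximum slice-wise motion exceeds the group mean by more
  than 2.5 sample standard deviations. Thresholds are not recomputed after
  removal, and low movers are never excluded. The either-exceeds reading
  was chosen because the source procedure does not state whether the two
  summaries were tested jointly.
- **Detrending** is linear by default (`detrendOrder` raises the
  polynomial order).

## Seed selection details

- "Highest correlation to the PCC" aggregates each hippocampal voxel's
  correlations over PCC voxels by the **row maximum** (`aggregate = "max"`),
  matching a selection rule phrased as "the voxel with the highest
  cross-correlation"; the row mean is available as a config alternative.
- Argmax ties break to the lowest linear (x-fastest) voxel index, so
  selection is deterministic.
- "In-plane" is the axial (z) slice, matching axial acquisition.
- ROI members falling outside the hippocampal mask are kept with a warning;
  constraining them is not part of the selection contract.
- The **seed search runs on confound-regressed, detrended but unsmoothed,
  unfiltered series**. This is a deliberate design choice: smoothing blurs
  the voxelwise argmax across neighbors and the low-pass discards about
  half of the effective degrees of freedom, both of which degrade exact
  single-voxel recovery. The connectivity *maps* are computed from the
  fully preprocessed (smoothed, detrended, filtered) data.
- `df` for the r→t conversion is the post-drop time-point count minus 2
  (126 by default). No autocorrelation or filtering correction is applied
  to `df`; the resulting `t` values are therefore not nominally calibrated,
  which is harmless here because the whole-brain normalization to `z`
  absorbs any common scale factor.
- The voxelwise threshold statistic behind the group maps is a two-sided
  one-sample t-test across subjects' normalized z values — the standard
  choice for group-average seed maps where the generating procedure is
  unstated. Thresholding the group-mean map at a z cutoff can be emulated
  by `groupMeanMap()` + a comparison.
- "Conjunction" of the four thresholded group maps is implemented as their
  **union** (regions connected to either hippocampus in either group),
  then 26-connected component labeling defines ROIs.

## The synthetic-data generators

Participant data for this kind of study are typically available only on
request, so the package ships generators that emulate the study conditions
and give every operator a planted ground truth.

**BOLD phantoms** (`phantomSpec()`, `makePhantomAnatomy()`,
`simulateBold()`): a 32 × 32 × 24 grid (0.75 × 0.75 × 1.5 mm voxels,
TR = 2.8 s, 132 volumes) holding a brain ellipsoid, box-shaped left/right
hippocampal heads, and a PCC box nested in a larger DMN box. A
standard-normal latent signal drives every PCC voxel (weight 0.85,
i.e. the regional SNR of the PCC signal) and exactly one designated voxel
per hippocampal head, mixed as `r·latent + sqrt(1 - r²)·noise` so the
expected sample correlation equals the target `r`. Cardiac (1 Hz, aliased
by the 2.8 s sampling) and respiratory (0.3 Hz) cosine confounds with
recorded phase and amplitude 0.3 are added to all brain voxels, plus a
baseline of 100. The geometry is boxes and an ellipsoid — not anatomy —
because every pipeline operator consumes only aligned masks; grid size was
chosen so a full phantom simulates in ~0.1 s.

What the phantom does *not* emulate: hemodynamic response convolution,
spatial autocorrelation of physiological noise, susceptibility dropout,
slice timing, motion-induced signal changes, or extended (multi-voxel)
hippocampal source regions. Passing tests therefore demonstrate
algorithmic correctness and calibration of the operators, not robustness
to real acquisition artifacts.

**Motion summaries** (`simulateMotion()`): per-subject mean and maximum
motion drawn around 0.12 ± 0.03 mm, with an optional fraction of planted
outliers at 10 base-sd above the mean — far enough above the bulk that the
2.5-SD rule should flag exactly the planted subjects even though outliers
inflate the estimated sd.

**Volumetric cohorts** (`cohortSpec()`, `simulateCohortVolumes()`):
group sizes 34 (DS) / 27 (HC), ages uniform on 15–35 years, sex ratio
≈ 0.65/0.63 male, and per-measure normal distributions truncated at zero
whose means and sds reproduce published group-averaged subfield volumes.
Two generator parameters are not printed in any table and were derived or
chosen once: ICV (backed out of the mm³ and %ICV columns of the same
table: ≈ 1.204 × 10⁶ mm³ DS, 1.421 × 10⁶ mm³ HC, sd set to 8% of the
mean, a realistic between-subject ICV spread) and the CA2/CA3 means
(the published CAt − CA1 remainders, split evenly, with generous sds —
these fields exist only to form CAt, mirroring their reported
high variability). Measures are drawn independently by default;
`volumeCorrelation` adds a shared per-subject factor for
volume–connectivity correlation experiments. Connectivity effect sizes
between groups are *not* calibrated to any published table (none reports
them); they are user-set through `rTargets` in `runPipeline()`.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to balance statistical
resolution against desk-scale runtimes: 100 phantoms per condition for
seed-recovery rates (132 volumes, full grid), 100 seeds for null-coupling
calibration, 2000 replicates for t-test type-I calibration, 10⁴ voxels ×
22 subjects for voxelwise threshold calibration, 1000 random p-vectors for
the FDR oracle, 100 random 20³ masks for the connected-component oracle,
and 500 replicates for interaction-slope recovery. End-to-end pipeline
tests use 4–6 subjects per group with 48–96 volumes and a proportionally
reduced cluster-extent threshold (the default 500 refers to high-resolution
acquisition voxels; on a 32³ phantom grid the planted PCC region itself is
only ~100 voxels).

## Degenerate inputs and tie-breaks

- Zero-variance voxels: flagged `NA` in correlation matrices (excluded
  from maxima), excluded with a warning by `thresholdMap()`, and an error
  where a defined result is impossible (zero-variance seed, constant map
  normalization, zero pooled variance).
- `|r| = 1` maps to ±∞ under r→t and is excluded from normalization
  statistics.
- Motion rule with zero spread excludes nobody.
- All argmax/labeling ties resolve by lowest linear index; component
  labels are numbered by smallest member index, so outputs are
  permutation-stable and reproducible.

## Known limitations

- No spatial normalization: all subjects must share a grid (synthetic data
  are generated co-registered; real data must be pre-registered).
- No segmentation: hippocampal masks and subfield volumes are inputs.
- No slice-timing or motion *correction*; motion enters only through
  summary-based exclusion.
- FDR families follow the analysis groupings (volumes, AI, connectivity
  ROIs per hemisphere) at q = 0.05; family membership is an analysis-level
  choice, not enforced by the functions.
- Welch's t is available (`equalVar = FALSE`) but the default is the
  pooled-variance Student test, matching the reporting convention the
  package follows.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(pThresh = 0.005, minCluster = 10L, seed = 8L)
res <- runPipeline(cfg,
                   phantomTemplate = phantomSpec(nVolumes = 96L),
                   nPerGroup = c(DS = 6L, HC = 6L),
                   rTargets = c(DS = 0.25, HC = 0.8))
res$log$seedRecoveryRate   # fraction of seeds landing on the planted voxel
head(res$connStats)        # per-ROI group comparisons with FDR
head(res$volumeStats)      # subfield group comparisons on %ICV values
```

The same bundle carries the union `RoiMask`, per-subject ROI mean-z table,
motion screening decisions, and a provenance log from which every output
is regenerable given the seed.
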