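---
title: "Quantifying coilin-positive nuclear bodies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coilin-positive nuclear bodies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbquant)
```

## The problem

Cajal bodies and related coilin-containing nuclear bodies are sub-micron
punctate structures whose number and size respond to the functional state of
the cell. Counting them by eye across hundreds of nuclei in 3D confocal
stacks is slow and subjective; `nbquant` automates the task for two-channel
acquisitions (channel 1: immunostained protein such as coilin; channel 2:
DAPI) and pairs the imaging pipeline with the nonparametric statistics
appropriate for ordered experimental groups (such as animal age classes)
whose distributions are far from normal.

The pipeline has three stages:

1. **Nucleus identification and cropping** (`segment_nuclei()`,
   `crop_nuclei()`). The DAPI channel is thresholded at 12 a.u. (whole
   nucleus) and 28 a.u. (dense chromatin) on the 8-bit scale; thresholds
   are inclusive. 26-connected components whose physical volume reaches
   50 µm³ become nucleus candidates; each is cropped with a 1 µm margin.
2. **Body segmentation** (`gaussian_blur_3d()`, `detect_maxima_3d()`,
   `segment_bodies()`). The protein channel is smoothed with an
   anisotropy-aware 3D Gaussian (σ = 1 µm physical, so the voxel-space
   kernel differs per axis), local maxima are detected with a prominence
   rule (noise tolerance 0.25 a.u.) and a minimum seed separation
   (0.5 µm in XY and Z), and bodies are grown from the seeds over the
   super-threshold domain (16 a.u.) by smallest anisotropy-weighted
   geodesic distance. Objects with mean XY bounding-box extent below
   0.1 µm are removed.
3. **Morphometry** (`measure_bodies()`, `summarize_nucleus()`). Per body:
   inclusive bounding-box extents, diameter = mean of the X and Y extents
   (deliberately ignoring the poorer axial resolution), and maximum raw
   gray value (peak intensity is a robust readout for small high-contrast
   foci). Per nucleus: body count and, when bodies exist, the arithmetic
   means of the per-body diameter and peak intensity; a nucleus with no
   bodies has *absent* means, never zeros.

`run_pipeline()` orchestrates the stages deterministically: identical
inputs, configuration and seed give byte-identical CSV output.

## Which image is thresholded, and why

The 16 a.u. segmentation threshold is applied to the **raw** protein image
(`threshold_on = "raw"`, the default), while maxima detection and the
prominence rule operate on the **blurred** image. The reasoning is
quantitative. Blurring a Gaussian spot of physical width σ~s~ with a σ~b~
kernel scales its peak by (σ~s~²/(σ~s~²+σ~b~²))^3/2^. For σ~b~ = 1 µm and the
0.2–1 µm diameters typical of these bodies this factor is 0.008–0.06: even a
saturated 255 a.u. spot retains at most a few a.u. above background after
smoothing and could never clear a 16 a.u. threshold on the blurred image.
Conversely the strikingly small noise tolerance (0.25 a.u., on a scale of
255) makes sense only on the blurred image, where genuine spots survive as
bumps of one to ten a.u. The package therefore reads the two parameters on
the two different grids; the all-blurred variant remains available behind
`threshold_on = "blurred"`.

Two further interpretation choices: the "minimum object size of 0.1 µm" is
dimensionally a length and is read as a minimum *mean XY bounding-box
extent*, the same size definition used for the diameter metric, keeping one
size concept throughout; and "0–256 a.u." is taken as the standard 8-bit
range [0, 255] with 256 an exclusive bound.

## Maxima detection: prominence and tie-breaking

A voxel is a candidate seed when it is ≥ all of its 26 neighbours inside
the nucleus mask (a flat plateau contributes one candidate, its
lexicographically-first voxel in (z, y, x) order). A candidate is
suppressed when its blurred value does not exceed its highest saddle toward
any higher maximum by at least the noise tolerance — computed exactly by a
union–find flood in decreasing intensity (the persistence construction),
with saddle paths confined to the nucleus mask. Of any two survivors closer
than 0.5 µm in XY *and* 0.5 µm in Z, only the brighter survives; ties
resolve lexicographically. The test suite checks this implementation
against an independent brute-force oracle that enumerates saddle levels by
level-set connectivity on small grids.

Seeded assignment uses multi-source Dijkstra over the threshold domain with
26-neighbour steps weighted by their physical length, so the partition
between two seeds falls on the geodesic midline even on anisotropic grids.
Domain voxels unreachable from every seed (isolated noise voxels above
threshold) are dropped. A seeded-watershed alternative
(`assignment = "watershed"`) floods the domain in decreasing blurred
intensity instead.

One practical lesson is baked into `run_pipeline()`: the blur is computed
once per field of view and then cropped, never per nucleus crop. Blurring a
tight crop truncates the smoothing context at the crop faces; with
replicated borders this measurably distorts the field up to 4σ inside the
crop and can displace or destroy maxima near the nucleus surface.

## The statistical battery

All tests are two-sided and nonparametric; cohorts of body counts are
heavily tied, so every statistic carries tie corrections.

- **Exact r×c contingency test** (`fisher_exact_rxc()`): the two-sided p is
  the total probability of all tables with the observed margins whose
  hypergeometric probability does not exceed the observed one (comparison
  tolerance 10⁻¹²), by exhaustive enumeration. Pairwise 2×2 follow-ups are
  Bonferroni-multiplied by K(K−1)/2 and capped at 1.
- **Mann–Whitney** (`mann_whitney()`): U counts first-sample wins plus half
  ties (U + U′ = n₁n₂). The p-value is exact — a tie-aware dynamic program
  over the permutation distribution of the rank sum — whenever
  n₁·n₂ ≤ 400, and otherwise uses the tie-corrected normal approximation
  with continuity correction.
- **Jonckheere–Terpstra** (`jonckheere_terpstra()`): JT = Σ~i<j~ U~ij~ over
  ordered group pairs, with the tie-corrected null mean and variance giving
  z and a two-sided p; a seeded permutation mode is available. A decreasing
  trend across the declared order yields z < 0. In `cohort_report()` the
  trend test runs only when the group medians are monotone in the declared
  order — the "pattern consistent with an ordered trend" gate — with
  `always_jt = TRUE` to override.
- **Kendall τ** (`kendall_tau()`): τ-b on (group rank, value) pairs — the
  three-level group variable makes ties pervasive, so the b variant is the
  only defensible choice — delegated to `stats::cor.test()` with the
  tie-corrected normal p.
- **Shapiro–Wilk** (`normality_screen()`): delegated to
  `stats::shapiro.test()`; cohorts that fail it (these invariably do) are
  summarized by medians.

Calibration is tested by simulation: under an exchangeable Poisson(6) null
at group sizes 54/33/42 the trend test rejects at the nominal 5% ± 1.5%
(2000 seeded cohorts), and under a planted decreasing trend (means
8/6/4.5) it returns z < 0 in over 99% of 200 cohorts.

## The synthetic-data generator

Real acquisitions of this kind are rarely deposited, so validation uses
`synthetic_spec()` / `generate_cohort()`: ellipsoidal nuclei (DAPI 120 a.u.
with embedded dense-chromatin blobs at 160 a.u.) rendered into fields of
view, protein-channel bodies as isotropic 3D Gaussian spots over a diffuse
nucleoplasmic background (8 a.u. inside, 2 a.u. outside), a perinuclear
haze (+10 a.u.) for cytoplasmic-positive cells, and additive Gaussian noise
(σ = 2 a.u.), clipped to [0, 255]. The default cohort mirrors the study
design this package was built for: three ordered age groups of 54/33/42
nuclei across 18 images, Poisson body counts with decreasing means
8/6/4.5, and per-group cytoplasmic-labeling probabilities 0.167/0.152/0.

The geometric defaults follow from a detectability analysis rather than
from biology, and this is worth stating plainly. Under a σ = 1 µm
smoothing scale, two spots produce separate maxima only when roughly 3σ
apart, and the blurred amplitude of a spot scales with σ~s~³ — so a wide
size range lets a small spot vanish into the shoulder of a large
neighbour. The generator therefore plants spots of 0.85–1.0 µm FWHM and
peak 150–200 a.u. at pairwise spacing ≥ 3.5 µm, and sizes nuclei
(semi-axes ~4 × 12.5 × 12.5 µm, larger in the stress tests that plant up
to 33 bodies) so such packings exist; body counts are capped at the
packing capacity. The planted "diameter" recorded in the ground truth is
the spot's analytic super-threshold XY extent at the default 16 a.u.
threshold — exactly the quantity a threshold segmentation measures — and
the recovery tests demand agreement within two lateral voxels.

What passing these tests shows: the chain blur → prominence maxima →
geodesic segmentation → bounding-box morphometry is internally correct,
recovers every planted object at realistic noise (peak SNR ≫ 5), assigns
no false positives, and feeds the statistics exactly the counts it
detected. What it does not show: performance on real microscope data with
optical PSFs, autofluorescence, spot sizes below ~0.5 µm or spacings below
~3 µm — in that crowded regime the fixed 1 µm smoothing scale *cannot*
resolve neighbours, real counts will be underestimated, and no parameter
setting of this pipeline avoids it. Synthetic nuclei are also larger than
typical somatic nuclei for the high-count stress tests, a geometric
necessity at the resolvable spacing, not a biological claim.

## Numerical conventions and degenerate inputs

- Axis order (z, y, x) everywhere; R-style 1-based voxel indices;
  `crop_origin + local − 1` recovers parent coordinates.
- Threshold comparisons are inclusive (≥); a voxel equal to the threshold
  is kept.
- 16-bit input is linearly min–max rescaled to [0, 255] per stack (the
  scale is recorded in the run log); 8-bit input is never altered.
- Nucleus masks are hole-filled slice-wise and then in 3D, because
  nucleoli are DAPI-dark but belong to the nucleus.
- Empty results are legal everywhere: an all-zero stack yields zero
  nuclei; a nucleus with no seeds yields zero bodies and absent means;
  statistics refuse (with errors, not NAs) samples that cannot support
  them.
- Touching nuclei merge into one component and are expected to be removed
  by QC — there is no watershed splitting of nuclei, mirroring the manual
  selection step of the workflow this automates.
- CSV output is written with fixed LF line endings; identical inputs and
  seed reproduce it byte-for-byte.

## Problem sizes used by the test suite

The suite validates at deliberately scaled sizes: the full-cohort nucleus
count test renders 18 images / 129 nuclei without bodies; spot-count
recovery runs 100 single-nucleus renders spanning 0–33 planted bodies;
pipeline end-to-end tests use a 10-nucleus cohort; oracle equivalences run
on grids ≤ 16³ and samples ≤ 8 per group, where exhaustive enumeration is
feasible; calibration uses 2000 null and 200 power cohorts at the study's
group sizes.

## Known limitations

- No point-spread-function simulation, deconvolution, illumination
  correction or spectral crosstalk; the generator's Gaussian spots are a
  model of segmentable signal, not of optics.
- The cytoplasmic-labeling flag is a reproducible surrogate (shell/interior
  median ratio, default 0.5) for a judgment made visually in the original
  workflow; it feeds the categorical analysis only and never excludes a
  nucleus automatically.
- Sub-resolution and sub-spacing objects are invisible by design of the
  fixed smoothing scale (see above); `rayleigh_limit()` documents the
  optical floor (~0.26 µm for a 530 nm emitter at NA 1.25) below which
  measured diameters reflect the instrument, not the object.
- The exact r×c enumeration is exponential in table size; it is meant for
  the small group-by-category tables of cohort analysis.
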