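---
title: "Mesenteric artery calcium scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesenteric artery calcium scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macscore)
```

## The score

The mesenteric artery calcium score (MACS) transfers the coronary Agatston
principle to the celiac (CA), superior mesenteric (SMA) and inferior
mesenteric (IMA) arteries. Inside an artery's scoring territory, every
voxel at or above a 130 HU threshold is a calcium candidate; candidates are
grouped per axial slice into 8-connected lesions; each lesion scores

$$ s = A \cdot w \cdot \frac{t}{3\,\mathrm{mm}}, $$

with $A$ the in-plane lesion area in mm², $t$ the slice thickness, and the
density weight $w \in \{1,2,3,4\}$ determined by the lesion's peak
attenuation (130–199, 200–299, 300–399, ≥ 400 HU). The artery's MACS is the
sum over its lesions; CA+SMA and the total over all three arteries are
plain sums of artery scores.

Two phrasings of the Agatston definition circulate: "per-slice area times a
density factor" (the classic rule, defined on 3 mm acquisitions) and
"lesion volume times a density factor". The thickness factor $t/3$
reconciles them: at $t = 3$ mm it is exactly the classic score, and at any
other thickness the per-slice sum becomes volume-proportional, so a lesion
spanning two 1.5 mm slices scores the same as it would on one 3 mm slice.
This keeps scores computed on modern thin-slice CTA on the same scale as
the classic definition. It also makes explicit that the score *depends* on
slice thickness through partial-volume effects — which is why no volume is
ever resampled implicitly, and why a dedicated slab-averaging simulator
exists (below).

Assumptions worth stating: lesions are weighted by their **per-slice** peak
HU (the classic rule; a per-lesion 3D maximum is a defensible alternative
that we do not use), the threshold is **inclusive** (a voxel at exactly
130 HU counts), and connectivity is 8-neighbour within a slice with no
merging across slices.

## Scoring territories

A territory is the union of:

* an **origin region** — all voxels whose centers lie within a distance of
  *one origin diameter* of the ostium center. The radius equals the
  measured diameter, not its half. By default this is a 3D ball, because
  ostial lesions span slices; a per-slice 2D disc mode is available for
  users who read the region strictly in-plane. The choice is recorded in
  the annotation file.
* an operator-drawn **distal extent** — per-slice simple polygons out to
  the artery's anatomical endpoint (CA bifurcation, first large jejunal
  branch, left colic artery). These are clinical landmarks that observers
  identify by eye; the package deliberately does not attempt vessel
  segmentation or automatic ostium detection.

Rasterization is by pixel center: a pixel belongs to a polygon iff its
center is inside under the even-odd rule, so vertex orientation is
irrelevant and self-intersecting outlines are rejected as ambiguous.
Degenerate origin regions smaller than a voxel still contain the voxel
nearest the ostium, so a territory is never silently empty. Annotations are
stored in world millimetres (JSON, versioned schema, with a volume
checksum), so they survive resampling of the underlying grid.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `threshold` | 130 | HU | classic calcium attenuation threshold; may be *raised*, never lowered |
| `min_area` | 1 | mm² | classic minimum lesion footprint; suppresses single-pixel noise on fine grids |
| `mode` | `"ball"` | — | volumetric reading of the origin-region circle |
| origin radius | 1 × diameter | mm | scoring circle of radius one origin-diameter |
| `adaptive_threshold` | off | — | raises the threshold to the measured aortic contrast density, `max(130, mean + 2·sd)` |

On contrast-enhanced scans the hand-drawn region is primarily responsible
for excluding lumen. The adaptive threshold is a guard, not a substitute:
it is off by default, it reports the threshold actually used, and it will
also suppress genuinely low-attenuation calcium hidden inside enhancement —
the same trade-off a human reader faces. The aortic **contrast density** is
defined as mean + 2 × sample standard deviation (n−1; the ROI is a finite
sample) of the HU values in a circular ROI at the center of the aorta at
the artery-origin level.

## Statistical machinery

* **ICC.** Interobserver agreement uses the two-way random-effects,
  single-rater, absolute-agreement form ICC(2,1) by default — the form that
  answers "would another observer produce the same score", which is the
  right question when regions are drawn by hand. Consistency (ICC(3,1)) and
  one-way forms are available. Confidence intervals use the McGraw–Wong
  F-distribution method. Bands: poor < 0.5 ≤ moderate < 0.75 ≤ good <
  0.9 ≤ excellent. A table with no between-subject variance has no defined
  ICC and errors explicitly.
* **ROC/AUC.** Thresholds sit at the unique observed scores with
  "positive ⇔ score ≥ threshold"; the trapezoidal AUC then equals the
  Mann–Whitney probability with ties counted ½ (verified against exhaustive
  pair enumeration in the tests). The DeLong CI comes from pROC. AUC bands:
  < 0.7 poor, 0.7–0.8 acceptable, 0.8–0.9 excellent, ≥ 0.9 outstanding.
* **Cutoff selection** maximises Youden's J over midpoints between
  consecutive unique scores (plus sentinels beyond both extremes), so
  perfectly separated classes return the midpoint of the separating gap.
  Ties in J break toward higher sensitivity — in a rule-out screen the
  false negative is the costly error. All-equal scores return the minimum
  with a warning.
* **Screening metrics** are kept unrounded internally and rounded to one
  decimal for display; the "test-negative and disease-free" fraction
  (TN / N) is reported as an integer percentage. Positivity is
  score ≥ cutoff.
* **Group comparisons**: Wilcoxon rank-sum (exact for small tie-free
  samples, tie-corrected normal approximation otherwise — MACS data are
  heavily tied at zero) for continuous variables; chi-square for
  categorical tables, switching to Fisher's exact when any expected cell is
  below 5 (Cochran's rule).
* **Sign test** for paired protocol comparisons: exact two-sided binomial
  on the signs of the differences; zero differences carry no directional
  information and are dropped, with their count reported.
* **Quartiles** everywhere use R's default linear-interpolation convention
  (`quantile` type 7).

## The digital phantom

The phantom generator emulates the geometry that matters to the scorer and
nothing else: a soft-tissue background (40 HU), a contrast-filled aorta
cylinder along the slice axis, one tube per artery, and uniform-HU lesions
(balls or boxes). Uniform lesions keep the ground truth **analytic**: per
slice center the exact cross-section area (disc or rectangle) is known in
closed form, so the continuous-geometry score
$\sum_z A(z)\, w \, t/3$ is computed without any rasterization. Overlapping
lesions of different HU are rejected because their ground truth would be
ambiguous.

Two deliberate simplifications:

* **Default enhancement is 100 HU — below the calcium threshold.** The
  phantom's auto-generated territories are schematic balls that include the
  vessel lumen, whereas clinical observers exclude lumen when drawing
  regions. Sub-threshold enhancement keeps "scored = analytic" exact. The
  contrast-leak scenario is exercised separately by raising the lumen HU
  and enabling the adaptive threshold.
* **Thicker-slice acquisition is modelled as slab averaging** (mean over
  `round(new/native)` consecutive slices, then additive Gaussian noise).
  This is a first-order partial-volume model: adequate to reproduce the
  *direction* of protocol effects on sub-slice lesions, but it does not
  model beam hardening, reconstruction kernels, blooming, or any tube
  voltage physics (kVp enters only as metadata). Non-integer slab ratios
  snap to the nearest integer and say so.

Passing phantom tests therefore show that the scorer is geometrically and
arithmetically correct and that protocol effects propagate with the right
sign — they do not show robustness to real-scanner texture, motion, or
observer variability in drawing regions.

## Synthetic cohorts

Per-artery scores are drawn independently per patient from zero-inflated
log-normal distributions — MACS is non-negative, has a large point mass at
zero in non-diseased patients, and is strongly right-skewed. The default
parameters (`cohort_distribution_defaults()`) were calibrated once,
analytically, against published per-artery median (IQR) summaries of a CMI
screening cohort: where all three quartiles are positive, the zero mass
$p_0$ is root-found so that the three quartile equations are mutually
consistent; where the median is zero, $p_0$ is fixed at a plausible value
(0.55–0.6) with $\sigma = 1.5$ and $\mu$ solved from Q3. Two caveats are
documented rather than hidden: the printed CMI-CA quartiles are slightly
left-skewed relative to any log-normal (the implied median overshoots by
~18%), and per-artery independence understates the correlation of
atherosclerosis across arteries, so simulated *combined* scores are
somewhat less extreme than a correlated model would give. Both are
immaterial for exercising rank-based machinery, which is what the
simulated cohorts are for.

## Numerical choices and degenerate inputs

* Voxel membership is always by center (balls, discs, polygons, lesions) —
  one convention, applied everywhere, tested by brute-force enumeration.
* The calcium threshold is inclusive; weight-bin edges are inclusive on the
  left (exactly 200 HU → weight 2).
* Components are compared against `min_area` with strict `<`, so a
  1 mm² lesion survives the 1 mm² default.
* NIfTI stores spacing and origin as float32, so geometry round-trips to
  ~1e-7 relative precision; the NRRD writer stores them as decimal text and
  round-trips exactly. Voxel values round-trip exactly in both (float64).
* NIfTI has a single per-axis spacing, so slice thickness is assumed equal
  to slice spacing on load and flagged; supply the true thickness through
  `acquisition_meta()` when they differ.
* All simulations take explicit integer seeds; identical spec + seed
  reproduces volumes bit for bit.

## Problem sizes used by the test-suite

The suite favours many small, exhaustively checkable instances over few
large ones: oracle equivalence runs the scorer against an independent
flood-fill implementation on fifty random volumes up to 16³ voxels, AUC and
cutoff selection against exhaustive enumeration on fifty 20-point samples;
the resolution study uses a 5 mm lesion at 1.0 / 0.5 / 0.25 mm pixels; the
paired-protocol experiment uses 29 phantom pairs at 48 × 48 × 40 voxels;
cohort calibration checks use 500 patients per group.

## Known limitations

* No DICOM series reader: convert series to NIfTI first. Rescale
  slope/intercept arithmetic is available as `hu_rescale()`.
* No vessel segmentation, centerline extraction, or automatic ostium and
  diameter measurement — territories are operator input, as in the clinical
  workflow the score comes from.
* No mass/volume score variants, no stent or metal-artifact handling, and
  no model of calcium concealed by strong enhancement beyond the adaptive
  threshold guard.
* Phantom realism is bounded as described above; conclusions about real
  scanners require real scans.
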