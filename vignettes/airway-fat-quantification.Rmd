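---
title: "Quantifying upper-airway intra-tissue fat and volumetrics from Dixon MRI"
author: "airwayDixon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying upper-airway intra-tissue fat and volumetrics from Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayDixon)
```

## The measurement problem

Obstructive sleep apnoea is driven in part by the anatomy of the pharynx:
the size of the airway lumen and the bulk and composition of the soft
tissues that surround it (tongue, tongue base, soft palate, lateral
pharyngeal walls, parapharyngeal fat pads). Interventions such as surgical
weight loss are expected to change both *how much* tissue surrounds the
airway and *how fatty* that tissue is. Modified Dixon (mDixon) MRI
separates fat and water signal by chemical shift, producing four
co-registered image sets per session — in-phase, out-of-phase,
fat-saturated and water-saturated — from which fat content can be
quantified voxel by voxel inside anatomical boundaries drawn on the
anatomical scan.

This package implements that analysis pipeline end to end:

1. voxelwise fat-signal-fraction mapping from the fat (F) and water (W)
   channels,
2. restriction of the map to expert-drawn 3-D label masks and derivation
   of per-structure volume, intra-tissue fat volume and percentage, and
   voxel fat-fraction histograms,
3. landmark-based subdivision of the airway into velopharynx, oropharynx
   and hypopharynx with per-slice cross-sectional areas and slice-span
   lengths, and
4. paired baseline/follow-up cohort statistics (paired t-tests and
   repeated-measures Cohen's d with bootstrap confidence intervals).

Manual segmentation itself, MRI acquisition and Dixon reconstruction from
raw data are upstream of the package: inputs are co-registered NIfTI-1
volumes plus an integer label mask and per-subject landmark slices.

## The fat-signal fraction

For a voxel with fat-saturated magnitude F and water-saturated magnitude
W, the two-point Dixon fat-signal fraction is

$$\mathrm{FSF} = 100 \cdot \frac{F}{F + W} \; [\%].$$

The map is computed wherever $F + W$ exceeds a background threshold
(default 0, i.e. only zero-signal voxels such as the airway lumen are
undefined); undefined voxels are excluded from every aggregate. The
threshold is configurable because, in noisy magnitude images, near-zero
total signal makes the ratio meaningless — but inside anatomical
soft-tissue masks the default affects essentially no voxels. No T2\* or
multi-peak spectral correction is applied: the pipeline consumes the
reconstructed fat/water magnitudes as provided.

**Tissue fat percent.** Two aggregations of the voxelwise map to a tissue
are defensible: the mean of voxel fractions, and the ratio of summed
signals $100\,\Sigma F / (\Sigma F + \Sigma W)$. The package defaults to
the *mean of voxel fractions*, because the per-voxel percentage is the
primitive quantity (it is what the histograms aggregate), and fat volume
then equals the sum of fraction × voxel volume. The ratio-of-sums variant
is exposed (`method = "ratio_of_sums"` in `tissueFatMetrics()`) as a
sensitivity check; the two coincide exactly on homogeneous tissue.

**Histograms.** Voxel fractions are binned over 0–100% into equal-width
bins, by default 50 bins of 2 percentage points. Bins are half-open
$[lo, hi)$ except the last, $[98, 100]$, so a pure-fat voxel is in range.
The median is computed on raw voxel values, never on binned values. The
bin width is a reporting convention, not an estimate — any fixed choice
gives reproducible counts.

## Volumetrics and airway subdivision

All volumes are voxel counts × voxel volume (mm³, reported in cm³); this
makes partition identities exact rather than approximate. The airway is
subdivided at four anatomist-supplied axial landmark slices (0-based,
superior → inferior): velopharynx = [hard palate, uvula tip), oropharynx =
[uvula tip, epiglottis base), hypopharynx = [epiglottis base, vocal fold].
Half-open intervals with the final boundary closed make the three regions
disjoint with union equal to the airway over the landmark span — the
partition is testable to machine precision. Landmarks are user-supplied
per subject and session, mirroring the manual, anatomy-guided protocol;
automatic landmark detection is out of scope.

Per-slice cross-sectional area is the in-plane labelled voxel count ×
pixel area. Slices without any labelled voxel are excluded from the mean
and minimum (they contribute zero volume): this keeps an obstructed slice
inside a region distinguishable from slices outside the region's span.

Length is the centre-to-centre distance between the first and last
occupied slice, `(last − first) × axial spacing`. A single-slice region
therefore has length 0. The alternative convention (count × spacing,
giving one slice thickness) is plausible; the span convention was chosen
because the quantity is described as a distance *between* slices, and it
is stated prominently in the documentation because the two differ by
exactly one slice thickness.

## Paired cohort statistics

Changes are follow-up − baseline per subject; percent change is
100 × change / baseline per subject, and the cohort percent change is the
mean ± SD of those per-subject values (not the ratio of means — each
subject's percent change is a datum with its own dispersion). Pairs are
dropped listwise per metric; a baseline of exactly zero flags that
subject/metric as having an undefined percent change rather than failing
the run.

The paired t-test is the standard one on differences. Effect sizes come
in three repeated-measures variants:

- $d_z = \bar d / SD_d$ (change-score standardization),
- $d_{rm} = \dfrac{\bar d}{\sqrt{SD_1^2 + SD_2^2 - 2 r\, SD_1 SD_2}}
  \cdot \sqrt{2(1-r)}$, which rescales $d_z$ by the pre/post correlation
  $r$ so that the denominator is comparable to a between-subject SD,
- $d_{av} = \bar d / ((SD_1 + SD_2)/2)$.

The default is $d_{rm}$. No single variant reproduces every published
repeated-measures effect size from summary statistics alone, so reports
always state the variant and the choice is switchable. Magnitudes are
classed by the usual thresholds (|d| > 0.2 small, > 0.5 medium,
> 0.8 large).

Confidence intervals are seeded nonparametric percentile bootstraps over
subjects (default 10,000 resamples), resampling pairs together. The
percentile bootstrap was chosen because it applies uniformly to all three
variants without variant-specific analytic derivations. Its known cost is
anti-conservatism for standardized mean differences at small n: in the
package's own calibration (also recomputed by `scripts/acceptance.R`),
95% intervals for $d_z$ cover a true standardized change of −1.5 in
roughly 87–89% of replicates at n = 18, while coverage is nominal at
n = 18 for small effects and approaches 95% by n ≈ 150. Intervals on
large effects from small cohorts should therefore be read as optimistic.
No multiple-comparison adjustment is applied — the analysis is
exploratory by design, and rows are simply flagged at p < 0.05.

As an analysis-stage package there is no registration step: baseline and
follow-up sessions are analyzed independently and compared only through
their per-structure metrics.

## The synthetic phantom

Because clinical upper-airway MRI with segmentations is not freely
distributable, every pipeline stage is validated on synthetic Dixon
phantoms with known ground truth (`phantomSpec()` /
`generatePhantom()`). The default phantom is a 64³ grid at 1 mm isotropic
spacing containing all seven structures as geometric primitives: an axial
airway tube flanked by lateral-wall boxes and ellipsoidal fat pads, a
soft-palate box at the velopharyngeal level, and tongue / tongue-base
ellipsoids. Overlaps after voxelization are resolved by a fixed priority
order (airway > fat pads > velopharyngeal lateral walls > oropharyngeal
lateral walls > soft palate > tongue base > tongue), so masks are always
disjoint. Default true fat fractions are tongue 30%, tongue base 23%,
soft palate 30%, lateral walls 20% — the 15–30% range typical of
pharyngeal soft tissue — plus near-pure fat pads at 80% and a zero-signal
airway.

Signals follow the two-point model the pipeline consumes: water =
amplitude (1 − f/100), fat = amplitude f/100, in-phase = fat + water,
out-of-phase = |water − fat|, amplitude 1000 arbitrary units. Noise is
Rician — each magnitude voxel s becomes $\sqrt{(s+g_1)^2 + g_2^2}$ with
independent zero-mean Gaussians of SD σ — the correct model for magnitude
MRI. All generators are bit-reproducible under a fixed seed.

Paired cohorts are simulated either from (change mean, change SD) with
the change drawn independently of baseline, from (follow-up SD, pre/post
correlation) via the bivariate-Normal conditional, or as a deterministic
multiplicative factor; the generator records the implied true effects for
recovery tests. The study-scale default is 18 subjects with
tongue-volume-like parameters (baseline 89.2 ± 18.2 cm³, change
−9.0 ± 7.0 cm³).

**What the phantom does and does not show.** Noiseless phantoms make
recovery exact: fat fractions to 1e-9 percentage points and volumes to
the voxel count identically, so those tests verify the arithmetic, not
robustness. The phantom's geometry is deliberately simple — convex
primitives, homogeneous tissue, perfect co-registration, no bias field,
no chemical-shift artefacts, no partial-volume mixing at boundaries, no
motion. Passing tests therefore demonstrate correctness of the
computation under the stated signal model, not segmentation quality or
robustness to acquisition artefacts on real scans.

## Numerical choices and calibrated tolerances

- **Background threshold** default 0 signal units; configurable.
- **Histogram** default 50 bins; last bin right-closed.
- **Landmark intervals** half-open, final boundary closed; landmark
  slices 0-based (the NIfTI voxel convention), validated as strictly
  increasing and in range.
- **Noise tolerance.** Recovery under Rician noise at σ = 2% of tissue
  amplitude was calibrated by a 100-replicate Monte-Carlo run on the 64³
  phantom before the assertion was written: the largest observed error in
  any tissue's fat percent was 0.19 percentage points (mean 0.086),
  dominated by the small positive Rician bias at finite SNR. The frozen
  test tolerance is 0.5 points. The bias shrinks monotonically as σ
  falls; the suite asserts the monotone trend across σ = 4, 2, 1, 0.5%
  of amplitude.
- **Voxelization bound.** Recovered volume ratios of isotropically
  shrunken structures deviate from the prescribed factor by surface
  discretization. A resolution sweep (N = 32…128) bounded the error of a
  0.9 tongue-volume factor by 2/N; the frozen bound at the 64³ study
  scale is 0.031.
- **Problem sizes.** The unit suite uses 32³ phantoms; the acceptance
  suite uses the 64³ study scale, 100 noise replicates, 1000-replicate
  statistical calibrations and 500-replicate bootstrap coverage at 1000
  resamples — sizes at which Monte-Carlo error is small relative to the
  asserted margins while the suite stays fast.
- **Degenerate inputs.** Zero-variance differences raise a
  degenerate-test error at the function level and become annotated row
  statuses (not failures) in cohort summaries; empty structures and
  structures with no defined voxels raise empty-structure errors;
  |r| = 1 makes d_rm undefined and is reported as such.

## Known limitations

- The two-point F/(F+W) fraction is a *signal* fat fraction: without T2\*
  and multi-peak correction it is not a proton-density fat fraction, and
  absolute values carry sequence-dependent bias common to both sessions.
- Percentile bootstrap CIs on large standardized effects at n ≈ 18 are
  anti-conservative (above).
- Airway length is a slice-span measure along the scanner axis, not a
  curved centerline length.
- Labels are mutually exclusive; partial-volume voxels are assigned
  wholly to one structure.
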