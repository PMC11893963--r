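---
title: "Quantifying the lung shunt fraction from SPECT/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lung shunt fraction from SPECT/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungshunt)
```

## The quantity and the three estimators

Before selective internal radiation therapy (SIRT) with ⁹⁰Y microspheres,
⁹⁹ᵐTc-labelled macroaggregated albumin (MAA) is injected into the hepatic
artery and imaged. The **lung shunt fraction** (LSF) — the percentage of the
injected particles that bypass the liver capillary bed through arteriovenous
shunts and lodge in the lungs — gates the prescribed activity, because an
excessive shunt risks radiation pneumonitis.

`lungshunt` implements three estimators of the same quantity:

* **3D SPECT count ratio.** With volumes of interest (VOIs) for the lungs and
  the liver on the attenuation-corrected SPECT volume,

  $$\mathrm{LSF}\% = \frac{C_\text{lung}}{C_\text{lung} + C_\text{liver}}
  \times 100,$$

  where $C$ are summed voxel counts under each VOI (`organ_counts()` +
  `lsf_3d()`).

* **Planar geometric mean.** With anterior ($A$) and posterior ($P$) planar
  organ totals, $G = \sqrt{A \cdot P}$ per organ and
  $\mathrm{LSF}\% = G_\text{lung} / (G_\text{lung} + G_\text{liver}) \times
  100$ (`planar_organ_counts()` + `lsf_planar()`). The geometric mean is
  taken of the organ *totals* per view, the standard clinical practice, not
  pixelwise. The posterior image is mirrored left–right exactly once, inside
  `planar_organ_counts()`, so ROIs are always drawn in the anterior frame.
  No background ROI subtraction is applied: the planar estimator is kept
  exactly as the conventional clinical computation it stands in for.

* **Assay ground truth** (phantoms only). From syringe activities $RLA, LLA,
  LA$ and residuals $rlr, llr, lr$,

  $$\mathrm{LSF}\% = \frac{(RLA - rlr) + (LLA - llr)}
  {(RLA - rlr) + (LLA - llr) + (LA - lr)} \times 100,$$

  with every activity decay-corrected to a common reference time using the
  ⁹⁹ᵐTc half-life of 6.0067 h (`lsf_ground_truth()`).

Cohort comparisons use the signed percentage difference
$PD = (PL - TF)/TF \times 100$ between the planar ($PL$) and SPECT ($TF$)
estimates, and quartiles at ranks $(n+1)/4$ and $3(n+1)/4$ with linear
interpolation between order statistics and ranks clipped to $[1, n]$
(`quartile_summary()`; this is the classical quartile definition, equivalent
to `quantile(type = 6)` away from the clipped edges). Because "average
percentage difference" admits two readings, `cohort_summary()` reports both
the mean of per-case PDs and the PD of the cohort means.

## Geometry conventions

All patient coordinates are DICOM LPS millimetres; NIfTI input (RAS) is
converted on read. Voxel indices are 0-based, the grid origin is the
*centre* of voxel $(0,0,0)$, and extents are half-open. These conventions
are fixed so that resampling is exactly testable: `resample_mask()` is pure
nearest-neighbour through the two affines, and a voxel-centre loop oracle
must reproduce it bit for bit.

SPECT and CT are assumed hardware-fused: a frame-of-reference mismatch is a
hard error, never a registration problem to be solved. Multi-field
acquisitions are accepted only as already-stitched volumes. DICOM series
are expected to be converted to NIfTI upstream; the normalisation such a
converter must perform (slice ordering independent of storage direction,
uniform-gap check at 1% tolerance, rescale slope/intercept, right-handed
index-to-patient transform) is available and tested as `assemble_slices()`.

## Mask providers

Masks can come from files (binarised at 0.5, so probabilistic outputs are
accepted), from an external ML segmenter invoked out of process through a
command template (`run_external_segmenter()`; the tool is configuration, not
a dependency), or from `threshold_segment_ct()` for phantom and synthetic
data. The threshold segmenter uses conventional CT windows — lungs
(−950, −300) HU, liver (−50, 200) HU — keeps the two largest lung components
(each at least 50 cm³) and the largest liver component, fills interior
holes, and assigns left/right by the component centroid's sign on the
patient left–right axis, the larger component taken as right on a tie.
All three choices are deterministic so repeated runs are identical.

## VOI augmentation and the precedence order

Respiratory motion smears counts across the CT-derived organ boundaries, so
each VOI is dilated by a margin specified in millimetres and converted to
voxel offsets through the grid spacing — on a coarse anisotropic SPECT grid
a voxel-based margin would be direction-biased, a metric one is not. The
structuring element is a ball, stretched along the patient
superior–inferior axis by `extra_cranio_caudal_mm` because that is the
dominant direction of breathing displacement. Defaults are liver 10 mm,
lung 5 mm, extra cranio-caudal 5 mm; they are tunable per case and every
applied value is echoed into the report.

Where dilated VOIs collide, voxels are resolved by the precedence

> original lung > original liver > augmented lung > augmented liver,

which encodes two rules: the liver margin must never encroach on lung
evidence (lungs hold few counts, so misassigning high-concentration liver
counts into them would inflate the LSF), and augmentation must never remove
an original voxel of either organ. Voxels contested between the two
augmented lungs go to the right lung — an arbitrary but fixed tie-break.
The finalised VOI set is disjoint by construction and carries per-organ
provenance arrays marking exactly which voxels the augmentation added.

## Cropped lung apex

When the SPECT field of view cuts the lung apex (detected as the lung mask
touching the superior volume face), the missing volume is the supplied
reference lung volume minus the imaged volume, and the imputed counts are

$$\Delta C = \bar c_\text{apex} \times V_\text{missing},$$

with $\bar c_\text{apex}$ the mean count concentration over the most
superior 20 mm of imaged lung (window configurable). Only *counts* are
imputed, never mask voxels, so reported organ volumes stay honest; the
correction is recorded in the report and folded into the lung total by
`organ_counts()`. If the reference volume exceeds the imaged volume by more
than 25% yet the lung does not touch the face, a warning is logged and no
correction is applied — that discrepancy is a segmentation problem, not a
cropping one.

## The digital phantom

`build_phantom()` is an in-silico stand-in for a fillable anthropomorphic
liver/lung phantom: three ellipsoidal compartments (liver 1785 cm³, left
lung 883 cm³, right lung 1308 cm³ by default, semi-axes scaled to hit the
configured volumes within 1%) inside a water-equivalent elliptical body, on
a 64×64×88 SPECT grid at 4.8 mm and a 128×128×176 CT grid at 2.4 mm. The
lungs are filled either with water or with a bead/water mixture (−700 HU
with seeded speckle, attenuation 0.05 cm⁻¹ at 140 keV versus 0.154 cm⁻¹
for water); default activities (liver 150 MBq, lungs 23.41 MBq split by
volume) give a ground-truth LSF of 13.5%. A configurable liver–lung gap
reproduces the separated bench configuration (10 cm) next to the patient
configuration (0).

The simulator emulates a *reconstructed* attenuation-corrected SPECT
directly — activity map, optional respiratory blur, Gaussian PSF
(default FWHM 12 mm), scaling to 2×10⁶ total counts, optional Poisson
draw — rather than projecting and running an OSEM reconstruction. The LSF
is a count ratio and is empirically robust to reconstruction corrections,
so the quantification layer can be validated without a reconstruction
engine. Respiratory motion is an equal-weight average over a symmetric
arcsine dwell kernel (21 bins), the stationary distribution of sinusoidal
motion: the count centroid is unchanged and the axial variance grows by the
kernel variance ($\approx A^2/8$ for peak-to-peak amplitude $A$). The
default acquisition is static, like a phantom on the couch.

Planar views are attenuated parallel projections: each voxel contributes
$a \, e^{-\int \mu \, dl}$ along the anterior (or posterior) ray, with
half-voxel self-attenuation, followed by in-plane PSF blur, a common scale
factor bringing the mean view total to 10⁶ counts, and optional Poisson
noise. The posterior view is returned as the posterior camera records it
(mirrored), which `planar_organ_counts()` undoes — so the simulator and the
quantifier together exercise the mirroring convention end to end.

What the phantom does *not* emulate: Monte-Carlo photon transport, scatter
windows, collimator septal penetration, deformable breathing (organs move
rigidly and together), inter-organ background activity, and real anatomy
(compartments are ellipsoids). Passing the phantom tests therefore shows
that the mask-transfer, augmentation and count arithmetic are correct under
controlled degradations — not that the pipeline is validated on patients.

## Numerical choices and degenerate inputs

* Blur kernels are truncated at 4σ and renormalised; edges are zero-padded,
  so counts are conserved except for losses off the volume faces (tested to
  0.1% on interior sources).
* Fractional motion shifts use linear interpolation between integer voxel
  shifts.
* An LSF is only defined when the denominator is positive; both-zero counts
  raise an error rather than returning NaN. Zero lung counts give 0%.
* A zero anterior or posterior organ total makes that organ's geometric
  mean zero, with a warning — a common situation for faint shunts.
* Empty-after-resampling masks warn and stay empty rather than erroring, so
  a partially out-of-field organ degrades visibly, not silently.
* Reported LSF values are rounded to 2 decimals in rendered reports;
  internal values keep full precision, and a report's recorded LSF must
  reproduce from its own recorded counts to 1e-9 relative or the report
  refuses to build.

## A limitation found by the phantom

With the symmetric (zero-mean) motion kernel and masks derived from a CT
aligned with the time-averaged count distribution, the count-*ratio* LSF is
remarkably insensitive to uncompensated blur: lung and liver lose nearly
equal fractions of their counts, and the ratio cancels most of the loss.
In this idealised geometry the augmented VOIs are not measurably more
accurate than the unaugmented ones (both land within ~0.3% absolute of the
truth in the shipped acceptance checks, with the unaugmented masks slightly
closer). The clinical benefit of margin augmentation arises when the CT
snapshot is *offset* from the SPECT time-average — a breath-hold CT against
free-breathing SPECT — which a zero-mean kernel excludes by construction.
The simulator keeps the zero-mean kernel (it is the correct stationary
model of the acquisition itself), and we record this cancellation property
explicitly rather than engineering the phantom to flatter the margins.

## Problem sizes used by the shipped tests

Unit tests run on small synthetic arrays (≤ 40³) against brute-force
oracles; pipeline and acceptance checks use the default phantom grids above
(64×64×88 SPECT / 128×128×176 CT), five seeds for the motion comparison,
and 100 fuzzed mask pairs for the precedence oracle — sizes chosen so the
whole suite exercises realistic grids while staying quick on one CPU.
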