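# lungshunt

Quantification of the **lung shunt fraction (LSF)** for ⁹⁰Y radioembolization
(SIRT) planning from ⁹⁹ᵐTc-MAA studies.

Before delivering ⁹⁰Y microspheres to a liver tumour, clinicians measure how
much of a surrogate tracer injected into the hepatic artery shunts through to
the lungs: too high a shunt risks radiation pneumonitis, and the LSF directly
gates the prescribed activity. The conventional estimate comes from planar
scintigraphy; this package implements the 3D SPECT/CT alternative — organ
masks derived from CT, transferred onto the attenuation-corrected SPECT grid,
augmented with millimetre-metric margins to compensate respiratory motion —
together with the planar estimator and a phantom ground truth for comparison,
and a seeded digital liver/lung phantom so the whole pipeline can be
exercised and validated without scanner data.

The three estimators, in the field's standard notation:

* 3D SPECT: `LSF% = TotalLungCount / (TotalLungCount + TotalLiverCount) × 100`
* 2D planar: `LSF% = Geomean_lung / (Geomean_lung + Geomean_liver) × 100`,
  with `Geomean = √(anterior × posterior)` organ totals and the posterior
  view mirrored once
* Ground truth from syringe assays:
  `LSF% = ((RLA − rlr) + (LLA − llr)) / ((RLA − rlr) + (LLA − llr) + (LA − lr)) × 100`,
  decay-corrected to a common reference time (⁹⁹ᵐTc T½ = 6.0067 h)

plus cohort statistics: signed percentage difference
`PD = (PL − TF)/TF × 100` and quartiles/IQR at ranks `(n+1)/4` and
`3(n+1)/4`.

Intended users: medical physicists and imaging researchers working on
SIRT treatment planning, VOI-based dosimetry, or phantom validation of
quantitative SPECT pipelines.

## Worked example

Build a digital phantom with the default configuration (liver 1785 cm³,
lungs 883 + 1308 cm³, ground-truth LSF 13.5%, bead-filled lungs, 12 mm
system PSF, Poisson noise at 2×10⁶ counts), run the full 3D pipeline and
the planar estimator:

```r
library(lungshunt)

study <- build_phantom(phantom_spec(seed = 1))
vois  <- augment_vois(study$masks_spect$liver,
                      study$masks_spect$lung_left,
                      study$masks_spect$lung_right)
vois
#> voi_set on dim [64,64,88] spacing [4.8,4.8,4.8] origin [2.4,2.4,2.4]
#>   liver       2713.3 cm^3 (24534 voxels, 8434 added by augmentation)
#>   lung_left   1136.4 cm^3 (10276 voxels, 2286 added by augmentation)
#>   lung_right  1632.8 cm^3 (14764 voxels, 2934 added by augmentation)
#>   margins: liver 10 mm, lung 5 mm, extra cranio-caudal 5 mm

counts <- organ_counts(study$spect, vois)
counts
#> count_summary: lung 263015 (L 104756 + R 158259 + crop 0), liver 1.72578e+06

lsf_3d(counts)
#> LSF = 13.22% [SPECT_3D]

rois <- planar_rois_from_masks(study$masks_spect)
lsf_planar(planar_organ_counts(study$planar_ant, study$planar_post, rois))
#> LSF = 19.04% [PLANAR_2D]

lsf_ground_truth(study$truth)
#> LSF = 13.50% [GROUND_TRUTH]
```

Reading the numbers: the 3D count-ratio estimate (13.22%) lands close to
the assayed truth (13.50%), while the planar geometric-mean estimate
(19.04%) overshoots substantially — the lungs attenuate far less than the
water-equivalent liver, so planar views over-represent lung counts. That
systematic planar overestimation is exactly the clinical motivation for the
3D method.

For clinical data the same pipeline starts from files:
`read_volume()` (NIfTI; convert DICOM series upstream), `load_masks()` or
`threshold_segment_ct()`, `resample_mask()` onto the SPECT grid,
`augment_vois()`, optionally `correct_cropped_lung()`, then `organ_counts()`
and `lsf_3d()`. `build_report()` / `render_report()` produce a JSON or text
report that records every applied parameter and is self-consistent by
construction. A command-line wrapper with `lsf3d`, `lsfplanar`, `phantom`
and `cohort` subcommands is installed at `inst/cli/lungshunt`.

## Layout

* `R/` — implementation: image containers and NIfTI I/O, geometry,
  segmentation providers, mask transfer/augmentation, quantification,
  phantom simulator, reports, CLI
* `tests/testthat/` — unit, property (oracle-backed) and acceptance tests
* `vignettes/lsf-quantification.Rmd` — the methods vignette: models,
  parameters, simulator scope, numerical choices, known limitations
* `scripts/acceptance.R` — see above
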