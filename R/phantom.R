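#' Specification of a digital liver/lung phantom and its acquisition
#'
#' Digital stand-in for a fillable anthropomorphic liver/lung phantom: one
#' unit-density liver compartment and two low-density lung compartments inside
#' a water-equivalent body, with configurable activities, attenuation, system
#' blur, cranio-caudal respiratory motion and Poisson counting noise. Default
#' compartment volumes are liver 1785 cm^3, left lung 883 cm^3, right lung
#' 1308 cm^3, and default activities give a ground-truth LSF of 13.5%.
#' The default acquisition is static (`motion_amplitude_mm = 0`), like a
#' physical phantom on the couch; motion is an option used to emulate a
#' breathing patient.
#'
#' @param spect_dim,spect_spacing SPECT grid (voxels, mm).
#' @param ct_dim,ct_spacing CT grid (voxels, mm); must share the SPECT frame.
#' @param liver_volume_cm3,lung_left_volume_cm3,lung_right_volume_cm3
#'   compartment volumes; ellipsoid semi-axes are scaled to hit them.
#' @param liver_lung_gap_mm extra liver-lung separation (0 = patient
#'   configuration; 100 reproduces the separated bench configuration).
#' @param lung_fill `"BEADS"` (water + polystyrene beads, approx. -700 HU with
#'   speckle, attenuation `mu_lung`) or `"WATER"` (unit density).
#' @param liver_activity_MBq,lung_activity_MBq total compartment activities;
#'   the lung activity is split between left and right in proportion to their
#'   volumes.
#' @param bead_hu,bead_hu_sd mean and speckle SD of the bead-fill HU.
#' @param mu_water,mu_lung,mu_air linear attenuation coefficients (cm^-1) at
#'   140 keV.
#' @param psf_fwhm_mm isotropic system resolution (Gaussian FWHM).
#' @param motion_amplitude_mm peak-to-peak cranio-caudal respiratory
#'   excursion; counts are averaged over a symmetric sinusoidal dwell kernel.
#' @param motion_bins number of displacement bins of the dwell kernel.
#' @param noise `"POISSON"` or `"NONE"`.
#' @param spect_total_counts,planar_total_counts target pre-noise totals.
#' @param seed RNG seed for every stochastic option.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(spect_dim = c(64, 64, 88),
                         spect_spacing = c(4.8, 4.8, 4.8),
                         ct_dim = c(128, 128, 176),
                         ct_spacing = c(2.4, 2.4, 2.4),
                         liver_volume_cm3 = 1785,
                         lung_left_volume_cm3 = 883,
                         lung_right_volume_cm3 = 1308,
                         liver_lung_gap_mm = 0,
                         lung_fill = c("BEADS", "WATER"),
                         liver_activity_MBq = 150,
                         lung_activity_MBq = 23.41,
                         bead_hu = -700, bead_hu_sd = 60,
                         mu_water = 0.154, mu_lung = 0.05, mu_air = 0,
                         psf_fwhm_mm = 12,
                         motion_amplitude_mm = 0,
                         motion_bins = 21,
                         noise = c("POISSON", "NONE"),
                         spect_total_counts = 2e6,
                         planar_total_counts = 1e6,
                         seed = 1) {
  lung_fill <- match.arg(lung_fill)
  noise <- match.arg(noise)
  stopifnot(liver_activity_MBq >= 0, lung_activity_MBq >= 0,
            liver_lung_gap_mm >= 0, psf_fwhm_mm >= 0,
            motion_amplitude_mm >= 0)
  structure(
    list(spect_dim = as.integer(spect_dim), spect_spacing = spect_spacing,
         ct_dim = as.integer(ct_dim), ct_spacing = ct_spacing,
         liver_volume_cm3 = liver_volume_cm3,
         lung_left_volume_cm3 = lung_left_volume_cm3,
         lung_right_volume_cm3 = lung_right_volume_cm3,
         liver_lung_gap_mm = liver_lung_gap_mm,
         lung_fill = lung_fill,
         liver_activity_MBq = liver_activity_MBq,
         lung_activity_MBq = lung_activity_MBq,
         bead_hu = bead_hu, bead_hu_sd = bead_hu_sd,
         mu_water = mu_water, mu_lung = mu_lung, mu_air = mu_air,
         psf_fwhm_mm = psf_fwhm_mm,
         motion_amplitude_mm = motion_amplitude_mm,
         motion_bins = as.integer(motion_bins),
         noise = noise,
         spect_total_counts = spect_total_counts,
         planar_total_counts = planar_total_counts,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Anatomy template: ellipsoid centres (LPS mm) and semi-axis RATIOS; the
# ratios are scaled per compartment so the analytic volume (4/3)pi*a*b*c hits
# the configured target. Lungs are prolate along S-I (as real lungs are),
# the liver a flatter blob crossing the midline from the patient's right.
phantom_anatomy <- function(spec) {
  scale_semi <- function(ratio, vol_cm3) {
    u <- (vol_cm3 * 1000 / (4 / 3 * pi * prod(ratio)))^(1 / 3)
    ratio * u
  }
  gap <- spec$liver_lung_gap_mm
  list(
    liver = list(center = c(115, 155, 100),
                 semi = scale_semi(c(1.5, 1.1, 0.8), spec$liver_volume_cm3)),
    lung_left = list(center = c(215, 150, 255 + gap),
                     semi = scale_semi(c(0.55, 0.95, 1.5),
                                       spec$lung_left_volume_cm3)),
    lung_right = list(center = c(90, 150, 270 + gap),
                      semi = scale_semi(c(0.55, 0.95, 1.5),
                                        spec$lung_right_volume_cm3)),
    body = list(center = c(153.6, 153.6, NA), semi = c(145, 120, NA))
  )
}

# Rasterize an axis-aligned ellipsoid (centre/semi in mm) on a grid: voxel
# centre inside <=> sum((x-c)/a)^2 <= 1.
rasterize_ellipsoid <- function(geom, center, semi) {
  w <- grid_world_coords(geom)
  q <- ((w[, 1] - center[1]) / semi[1])^2 +
    ((w[, 2] - center[2]) / semi[2])^2 +
    ((w[, 3] - center[3]) / semi[3])^2
  array(q <= 1, geom$dim)
}

# Infinite elliptical cylinder along z (the phantom body).
rasterize_cylinder_z <- function(geom, center_xy, semi_xy) {
  w <- grid_world_coords(geom)
  q <- ((w[, 1] - center_xy[1]) / semi_xy[1])^2 +
    ((w[, 2] - center_xy[2]) / semi_xy[2])^2
  array(q <= 1, geom$dim)
}

#' Build a digital phantom study
#'
#' Generates the CT volume, truth organ masks on both the CT and SPECT grids,
#' the voxel activity map, assayed ground-truth activities, and then runs
#' [simulate_spect()] and [simulate_planar()] to produce the emulated
#' attenuation-corrected SPECT and the attenuated anterior/posterior planar
#' pair. Everything stochastic is driven by `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_study` with elements `ct`, `masks_ct`,
#'   `masks_spect`, `activity` (MBq per SPECT voxel), `materials` (0 air,
#'   1 water-equivalent, 2 lung fill), `spect`, `planar_ant`, `planar_post`,
#'   `truth` ([ground_truth_activities()]), `true_lsf_percent` and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  g_sp <- affine_geometry(spec$spect_spacing, spec$spect_spacing / 2,
                          diag(3), spec$spect_dim)
  g_ct <- affine_geometry(spec$ct_spacing, spec$ct_spacing / 2,
                          diag(3), spec$ct_dim)
  ana <- phantom_anatomy(spec)
  ras <- function(g, part) rasterize_ellipsoid(g, ana[[part]]$center,
                                               ana[[part]]$semi)
  organs <- c("liver", "lung_left", "lung_right")
  m_ct <- lapply(organs, function(p) ras(g_ct, p))
  m_sp <- lapply(organs, function(p) ras(g_sp, p))
  names(m_ct) <- names(m_sp) <- organs
  for (ms in list(m_ct, m_sp)) {
    if (any(ms$liver & (ms$lung_left | ms$lung_right)) ||
        any(ms$lung_left & ms$lung_right)) {
      stop("phantom compartments overlap; adjust volumes/gap")
    }
  }
  body_ct <- rasterize_cylinder_z(g_ct, ana$body$center[1:2], ana$body$semi[1:2])
  body_sp <- rasterize_cylinder_z(g_sp, ana$body$center[1:2], ana$body$semi[1:2])

  # CT in Hounsfield units
  hu <- array(-1000, g_ct$dim)
  hu[body_ct] <- 0
  lung_ct <- m_ct$lung_left | m_ct$lung_right
  if (spec$lung_fill == "BEADS") {
    n_lung <- sum(lung_ct)
    speckle <- with_seed(spec$seed + 2L, stats::rnorm(n_lung, 0, spec$bead_hu_sd))
    hu[lung_ct] <- pmin(pmax(spec$bead_hu + speckle, -1000), 100)
  }  # WATER fill stays at 0 HU
  ct <- image_volume(hu, g_ct$spacing, g_ct$origin, g_ct$orientation,
                     modality = "CT", frame_of_reference = "phantom")

  # material labels on the SPECT grid (for the attenuation model)
  materials <- array(0L, g_sp$dim)
  materials[body_sp] <- 1L
  lung_sp <- m_sp$lung_left | m_sp$lung_right
  materials[lung_sp] <- if (spec$lung_fill == "BEADS") 2L else 1L

  # activity: uniform concentration per compartment, MBq per SPECT voxel
  vol_ll <- spec$lung_left_volume_cm3
  vol_lr <- spec$lung_right_volume_cm3
  act_ll <- spec$lung_activity_MBq * vol_ll / (vol_ll + vol_lr)
  act_lr <- spec$lung_activity_MBq * vol_lr / (vol_ll + vol_lr)
  activity <- array(0, g_sp$dim)
  activity[m_sp$liver] <- spec$liver_activity_MBq / sum(m_sp$liver)
  activity[m_sp$lung_left] <- act_ll / sum(m_sp$lung_left)
  activity[m_sp$lung_right] <- act_lr / sum(m_sp$lung_right)

  truth <- ground_truth_activities(RLA = act_lr, LLA = act_ll,
                                   LA = spec$liver_activity_MBq)
  if (spec$liver_activity_MBq + spec$lung_activity_MBq <= 0) {
    stop("undefined true LSF: phantom has zero activity everywhere")
  }
  true_lsf <- lsf_ground_truth(truth)$lsf_percent

  mk <- function(ms, g, lab_r) {
    organ_mask(c(liver = "LIVER", lung_left = "LUNG_LEFT",
                 lung_right = "LUNG_RIGHT")[[lab_r]],
               ms[[lab_r]], g, source = "FILE")
  }
  study <- structure(
    list(ct = ct,
         masks_ct = stats::setNames(lapply(organs, function(p) mk(m_ct, g_ct, p)), organs),
         masks_spect = stats::setNames(lapply(organs, function(p) mk(m_sp, g_sp, p)), organs),
         activity = activity, materials = materials,
         spect = NULL, planar_ant = NULL, planar_post = NULL,
         truth = truth, true_lsf_percent = true_lsf, spec = spec),
    class = "phantom_study"
  )
  study$spect <- simulate_spect(study, spec)
  pl <- simulate_planar(study, spec)
  study$planar_ant <- pl$ant
  study$planar_post <- pl$post
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("phantom_study: true LSF", sprintf("%.2f%%", x$true_lsf_percent), "\n")
  cat("  lung fill", x$spec$lung_fill,
      "| gap", x$spec$liver_lung_gap_mm, "mm",
      "| PSF", x$spec$psf_fwhm_mm, "mm",
      "| motion", x$spec$motion_amplitude_mm, "mm",
      "| noise", x$spec$noise, "| seed", x$spec$seed, "\n")
  for (nm in names(x$masks_ct)) {
    cat(sprintf("  %-10s %7.1f cm^3 (CT grid)\n", nm,
                mask_volume(x$masks_ct[[nm]])))
  }
  invisible(x)
}

#' Symmetric respiratory dwell kernel
#'
#' Equal-weight displacement samples of sinusoidal cranio-caudal motion with
#' peak-to-peak amplitude `amplitude_mm`: `d_i = (A/2) cos(pi (i - 1/2) / n)`.
#' The kernel has exactly zero mean (the count centroid is unchanged by the
#' motion blur) and variance close to `A^2 / 8`, the dwell variance of a
#' sinusoid.
#'
#' @param amplitude_mm peak-to-peak amplitude.
#' @param n_bins number of displacement samples.
#' @return numeric vector of displacements in mm.
#' @export
respiratory_kernel <- function(amplitude_mm, n_bins = 21) {
  (amplitude_mm / 2) * cos(pi * (seq_len(n_bins) - 0.5) / n_bins)
}

#' Emulate a reconstructed attenuation-corrected SPECT volume
#'
#' The activity map is degraded in the order a reconstructed AC SPECT would
#' be: respiratory blur (average over the symmetric sinusoidal dwell kernel
#' along the patient S-I axis), isotropic Gaussian system PSF, global scaling
#' to the target total count, and an optional seeded Poisson draw. Blurring
#' conserves total counts except for losses off the volume edge.
#'
#' @param study a `phantom_study` (its `activity` map is used).
#' @param spec the [phantom_spec()] describing the acquisition.
#' @return an [image_volume()] with modality `SPECT_AC`.
#' @export
simulate_spect <- function(study, spec = study$spec) {
  img <- study$activity
  sp <- spec$spect_spacing
  if (spec$motion_amplitude_mm > 0) {
    kern <- respiratory_kernel(spec$motion_amplitude_mm, spec$motion_bins)
    acc <- array(0, dim(img))
    for (d in kern) acc <- acc + shift_fractional(img, 3L, d / sp[3])
    img <- acc / length(kern)
  }
  if (spec$psf_fwhm_mm > 0) {
    img <- gaussian_blur(img, spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))), sp)
  }
  if (!is.null(spec$spect_total_counts) && sum(img) > 0) {
    img <- img * (spec$spect_total_counts / sum(img))
  }
  if (spec$noise == "POISSON") {
    img <- array(as.double(with_seed(spec$seed, stats::rpois(length(img), img))),
                 dim(img))
  }
  image_volume(img, sp, spec$spect_spacing / 2, diag(3),
               modality = "SPECT_AC", frame_of_reference = "phantom")
}

#' Emulate attenuated anterior/posterior planar projections
#'
#' Each voxel contributes `activity x exp(-integral of mu dl)` along the
#' anterior (respectively posterior) ray to the exit face, accumulated into
#' the detector pixel above it; self-attenuation over half the voxel's own
#' thickness is included. The in-plane PSF blur is applied, both views are
#' scaled by one common factor so their mean total equals
#' `planar_total_counts`, and optional Poisson noise is drawn (seeded). The
#' posterior image is returned as the posterior camera records it
#' (left-right mirrored); [planar_organ_counts()] undoes the mirroring.
#'
#' @inheritParams simulate_spect
#' @return list with [planar_image()]s `ant` and `post`.
#' @export
simulate_planar <- function(study, spec = study$spec) {
  act <- study$activity
  mu_lut <- c(spec$mu_air, spec$mu_water, spec$mu_lung)
  mu <- array(mu_lut[study$materials + 1L], dim(act))
  sp <- spec$spect_spacing
  dy_cm <- sp[2] / 10
  dm <- dim(act)
  # cumulative attenuation along the A-P axis (axis 2; +y is posterior)
  cs <- aperm(apply(mu, c(1, 3), cumsum), c(2, 1, 3))
  att_ant <- exp(-(cs - mu / 2) * dy_cm)
  tot <- cs[, dm[2], , drop = TRUE]                       # full path integral
  tot3 <- aperm(array(tot, c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  att_post <- exp(-(tot3 - cs + mu / 2) * dy_cm)
  ant2d <- apply(act * att_ant, c(1, 3), sum)
  post2d <- apply(act * att_post, c(1, 3), sum)
  if (spec$psf_fwhm_mm > 0) {
    sg <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
    ant2d <- gaussian_blur(ant2d, sg, sp[c(1, 3)])
    post2d <- gaussian_blur(post2d, sg, sp[c(1, 3)])
  }
  if (!is.null(spec$planar_total_counts)) {
    m <- (sum(ant2d) + sum(post2d)) / 2
    if (m > 0) {
      s <- spec$planar_total_counts / m
      ant2d <- ant2d * s
      post2d <- post2d * s
    }
  }
  if (spec$noise == "POISSON") {
    ant2d <- matrix(as.double(with_seed(spec$seed + 1L,
                              stats::rpois(length(ant2d), ant2d))), dm[1], dm[3])
    post2d <- matrix(as.double(with_seed(spec$seed + 3L,
                               stats::rpois(length(post2d), post2d))), dm[1], dm[3])
  }
  post2d <- post2d[rev(seq_len(nrow(post2d))), , drop = FALSE]  # camera mirror
  list(ant = planar_image(ant2d, sp[c(1, 3)], "ANTERIOR"),
       post = planar_image(post2d, sp[c(1, 3)], "POSTERIOR"))
}

#' Project 3D organ masks into anterior-frame planar ROIs
#'
#' Each mask is collapsed along the anterior-posterior axis; pixels where the
#' projected liver overlaps a projected lung are assigned to the lung (the
#' same lung-priority rule the 3D augmentation uses).
#'
#' @param masks named list of [organ_mask()]s (`liver`, `lung_left`,
#'   `lung_right`) on the SPECT grid.
#' @return named list of 2D logical ROIs: `liver`, `lung_left`, `lung_right`.
#' @export
planar_rois_from_masks <- function(masks) {
  proj <- function(m) apply(m$mask, c(1, 3), any)
  ll <- proj(masks$lung_left)
  lr <- proj(masks$lung_right)
  lv <- proj(masks$liver) & !(ll | lr)
  list(liver = lv, lung_left = ll, lung_right = lr)
}

#' Crop the superior end of a study's field of view
#'
#' Utility for emulating an acquisition whose field of view cuts the lung
#' apex: keeps axial slices `1..n_keep` of a volume or mask (identity
#' orientation grids).
#'
#' @param x an [image_volume()] or [organ_mask()].
#' @param n_keep number of axial slices to keep.
#' @return the cropped object on its reduced grid.
#' @export
crop_superior <- function(x, n_keep) {
  if (inherits(x, "image_volume")) {
    image_volume(x$voxels[, , seq_len(n_keep), drop = FALSE],
                 x$geometry$spacing, x$geometry$origin,
                 x$geometry$orientation, x$modality, x$frame_of_reference)
  } else if (inherits(x, "organ_mask")) {
    g <- x$geometry
    g2 <- affine_geometry(g$spacing, g$origin, g$orientation,
                          c(g$dim[1:2], n_keep))
    organ_mask(x$label, x$mask[, , seq_len(n_keep), drop = FALSE], g2,
               x$source, allow_empty = TRUE)
  } else {
    stop("crop_superior expects an image_volume or organ_mask")
  }
}

#' Write a phantom study to disk
#'
#' CT, SPECT, truth masks (CT grid) and planar views are written as NIfTI,
#' plus `truth.json` with the assayed activities, the true LSF and the
#' phantom configuration.
#'
#' @param study a `phantom_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(study$ct, file.path(dir, "ct.nii.gz"))
  write_volume(study$spect, file.path(dir, "spect.nii.gz"))
  for (nm in names(study$masks_ct)) {
    m <- study$masks_ct[[nm]]
    write_volume(array(as.double(m$mask), dim(m$mask)),
                 file.path(dir, paste0("mask_", nm, ".nii.gz")),
                 geometry = m$geometry)
  }
  for (v in c("planar_ant", "planar_post")) {
    img <- RNifti::asNifti(study[[v]]$pixels)
    RNifti::writeNifti(img, file.path(dir, paste0(v, ".nii.gz")))
  }
  truth <- list(
    activities_MBq = study$truth[c("RLA", "LLA", "LA", "rlr", "llr", "lr")],
    true_lsf_percent = study$true_lsf_percent,
    config = unclass(study$spec)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read/write a phantom configuration file
#'
#' Flat key/value YAML serialization of a [phantom_spec()].
#'
#' @param path file path.
#' @return [read_phantom_config()] returns a `phantom_spec`.
#' @export
read_phantom_config <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

#' @rdname read_phantom_config
#' @param spec a [phantom_spec()] to serialize.
#' @export
write_phantom_config <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
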