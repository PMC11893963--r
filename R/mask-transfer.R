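#' Augmentation parameters for VOI margins
#'
#' Margins are specified in millimetres and converted to voxel offsets through
#' the grid spacing, so anisotropic SPECT grids dilate isotropically in
#' patient space. `extra_cranio_caudal_mm` widens the structuring element
#' along the patient superior-inferior axis only, the direction respiratory
#' motion displaces counts.
#'
#' @param liver_radius_mm isotropic liver margin (default 10).
#' @param lung_radius_mm isotropic lung margin (default 5).
#' @param extra_cranio_caudal_mm additional S-I margin for both organs
#'   (default 5).
#' @return object of class `augmentation_params`.
#' @export
augmentation_params <- function(liver_radius_mm = 10, lung_radius_mm = 5,
                                extra_cranio_caudal_mm = 5) {
  if (liver_radius_mm < 0 || lung_radius_mm < 0 || extra_cranio_caudal_mm < 0) {
    stop("augmentation radii must be non-negative")
  }
  structure(list(liver_radius_mm = liver_radius_mm,
                 lung_radius_mm = lung_radius_mm,
                 extra_cranio_caudal_mm = extra_cranio_caudal_mm),
            class = "augmentation_params")
}

#' Volume of an organ mask in cm^3
#'
#' True-voxel count times the voxel volume.
#'
#' @param mask an [organ_mask()] (or logical array with `geometry` supplied).
#' @param geometry required when `mask` is a bare array.
#' @return volume in cm^3.
#' @export
mask_volume <- function(mask, geometry = NULL) {
  if (inherits(mask, "organ_mask")) {
    geometry <- mask$geometry
    mask <- mask$mask
  }
  sum(mask) * voxel_cm3(geometry)
}

#' Resample a mask onto a target grid (nearest neighbour)
#'
#' For each target voxel centre, the patient-space position is mapped through
#' the inverse source affine; the voxel is true iff the continuous source
#' index rounds to a true source voxel inside bounds. Both grids must share a
#' frame of reference (checked by the callers that know it); no registration
#' is applied.
#'
#' @param mask an [organ_mask()].
#' @param target target [affine_geometry()].
#' @return an [organ_mask()] on the target grid (possibly empty, with a
#'   warning logged).
#' @export
resample_mask <- function(mask, target) {
  src <- mask$geometry
  M <- solve(src$affine) %*% target$affine  # target index -> source index
  dm <- target$dim
  n <- prod(dm)
  i <- rep.int(seq.int(0L, dm[1] - 1L), times = dm[2] * dm[3])
  j <- rep.int(rep(seq.int(0L, dm[2] - 1L), each = dm[1]), times = dm[3])
  k <- rep(seq.int(0L, dm[3] - 1L), each = dm[1] * dm[2])
  sidx <- cbind(i, j, k, 1) %*% t(M[1:3, ])
  ridx <- round(sidx)
  sdm <- src$dim
  inb <- ridx[, 1] >= 0 & ridx[, 1] < sdm[1] &
    ridx[, 2] >= 0 & ridx[, 2] < sdm[2] &
    ridx[, 3] >= 0 & ridx[, 3] < sdm[3]
  out <- logical(n)
  lin <- 1L + ridx[inb, 1] + sdm[1] * (ridx[inb, 2] + sdm[2] * ridx[inb, 3])
  out[inb] <- mask$mask[lin]
  if (!any(out)) {
    lsf_log("WARN", "mask ", mask$label,
            " is empty after resampling onto the target grid")
  }
  organ_mask(mask$label, array(out, dm), target, source = mask$source,
             allow_empty = TRUE)
}

#' Augment organ VOIs with metric margins and lung-priority overlap rules
#'
#' Each organ is dilated by a millimetre-metric ball (ellipsoidal when an
#' extra cranio-caudal margin is set). Voxels claimed by more than one organ
#' are resolved by precedence: original lung > original liver > augmented
#' lung > augmented liver, so the augmented liver is adjusted to avoid any
#' overlap with the lung VOIs and no original voxel is ever discarded. Voxels
#' contested between the two augmented lungs go to the right lung
#' (deterministic tie-break).
#'
#' @param liver,lung_left,lung_right [organ_mask()]s on the SPECT grid,
#'   pairwise disjoint.
#' @param params an [augmentation_params()].
#' @return object of class `voi_set` with elements `liver`, `lung_left`,
#'   `lung_right` (augmented masks), `augmentation` (the params applied),
#'   `provenance` (per-organ logical arrays marking voxels added by
#'   augmentation) and `crop_correction` (NULL until
#'   [correct_cropped_lung()]).
#' @export
augment_vois <- function(liver, lung_left, lung_right,
                         params = augmentation_params()) {
  g <- liver$geometry
  if (!same_grid(g, lung_left$geometry) || !same_grid(g, lung_right$geometry)) {
    stop("all organ masks must share the SPECT grid")
  }
  if (any(liver$mask & (lung_left$mask | lung_right$mask)) ||
      any(lung_left$mask & lung_right$mask)) {
    stop("input organ masks overlap; upstream segmentation/resampling bug")
  }
  sp <- g$spacing
  si_axis <- which.max(abs(g$orientation[3, ]))  # index axis along patient S-I
  semi <- function(r) {
    s <- rep(r, 3)
    s[si_axis] <- r + params$extra_cranio_caudal_mm
    s
  }
  dil_ll <- dilate_mm(lung_left$mask, semi(params$lung_radius_mm), sp)
  dil_lr <- dilate_mm(lung_right$mask, semi(params$lung_radius_mm), sp)
  dil_lv <- dilate_mm(liver$mask, semi(params$liver_radius_mm), sp)

  orig_lung <- lung_left$mask | lung_right$mask
  orig_any <- orig_lung | liver$mask
  # precedence: original lung > original liver > augmented lung > augmented liver
  aug_lr <- dil_lr & !orig_any
  aug_ll <- dil_ll & !orig_any & !aug_lr  # right lung wins the contested tier
  aug_lv <- dil_lv & !orig_any & !aug_lr & !aug_ll

  fin_ll <- lung_left$mask | aug_ll
  fin_lr <- lung_right$mask | aug_lr
  fin_lv <- liver$mask | aug_lv

  structure(
    list(
      liver = organ_mask("LIVER", fin_lv, g, "AUGMENTED"),
      lung_left = organ_mask("LUNG_LEFT", fin_ll, g, "AUGMENTED"),
      lung_right = organ_mask("LUNG_RIGHT", fin_lr, g, "AUGMENTED"),
      augmentation = params,
      provenance = list(liver = aug_lv, lung_left = aug_ll,
                        lung_right = aug_lr),
      crop_correction = NULL
    ),
    class = "voi_set"
  )
}

#' @export
print.voi_set <- function(x, ...) {
  cat("voi_set on", format_geometry(x$liver$geometry), "\n")
  for (nm in c("liver", "lung_left", "lung_right")) {
    m <- x[[nm]]
    cat(sprintf("  %-10s %7.1f cm^3 (%d voxels, %d added by augmentation)\n",
                nm, mask_volume(m), sum(m$mask), sum(x$provenance[[nm]])))
  }
  p <- x$augmentation
  cat(sprintf("  margins: liver %g mm, lung %g mm, extra cranio-caudal %g mm\n",
              p$liver_radius_mm, p$lung_radius_mm, p$extra_cranio_caudal_mm))
  if (!is.null(x$crop_correction)) {
    cc <- x$crop_correction
    cat(sprintf("  crop correction: %.1f%% of lung missing, %.4g counts imputed\n",
                100 * cc$estimated_missing_fraction, cc$added_counts))
  }
  invisible(x)
}

#' Impute counts for a lung apex cropped by the SPECT field of view
#'
#' Cropping is detected when the lung mask touches the superior face of the
#' volume. The missing lung volume is `reference - imaged`; the counts imputed
#' for it equal the mean count concentration over the most superior
#' `apex_window_mm` of imaged lung times the missing volume. Only COUNTS are
#' imputed (stored in a `crop_correction` record and folded into lung totals
#' by [organ_counts()]); the organ masks and their reported volumes are left
#' untouched.
#'
#' @param voiset a [augment_vois()] result.
#' @param spect the SPECT [image_volume()] on the same grid.
#' @param reference_lung_volume_cm3 expected full (uncropped) lung volume.
#' @param apex_window_mm thickness of the apical sampling window (default 20).
#' @return the `voi_set` with its `crop_correction` field populated (or left
#'   NULL when no cropping is detected).
#' @export
correct_cropped_lung <- function(voiset, spect, reference_lung_volume_cm3,
                                 apex_window_mm = 20) {
  g <- spect$geometry
  lung <- voiset$lung_left$mask | voiset$lung_right$mask
  imaged_cm3 <- sum(lung) * voxel_cm3(g)
  if (reference_lung_volume_cm3 < imaged_cm3 * (1 - 1e-6)) {
    stop("reference lung volume is smaller than the imaged lung volume")
  }
  z <- grid_world_coords(g)[, 3]
  touches <- any(lung & array(z >= max(z) - max(g$spacing) / 2 - 1e-6, dim(lung)))
  if (!touches) {
    if (reference_lung_volume_cm3 > 1.25 * imaged_cm3) {
      lsf_log("WARN", "reference lung volume exceeds imaged volume by >25% ",
              "but the lung does not touch the superior face; ",
              "no crop correction applied")
    }
    voiset$crop_correction <- NULL
    return(voiset)
  }
  missing_cm3 <- max(0, reference_lung_volume_cm3 - imaged_cm3)
  zmax_lung <- max(z[as.vector(lung)])
  window <- lung & array(z >= zmax_lung - apex_window_mm, dim(lung))
  conc <- sum(spect$voxels[window]) / (sum(window) * voxel_cm3(g))
  added <- conc * missing_cm3
  voiset$crop_correction <- structure(
    list(reference_lung_volume_cm3 = reference_lung_volume_cm3,
         imaged_lung_volume_cm3 = imaged_cm3,
         estimated_missing_fraction = missing_cm3 / reference_lung_volume_cm3,
         apex_window_mm = apex_window_mm,
         added_counts = added),
    class = "crop_correction"
  )
  voiset
}

#' Export a VOI set as a single label volume
#'
#' Background 0, liver 1, left lung 2, right lung 3 (disjoint by
#' construction), written as NIfTI on the SPECT grid.
#'
#' @param voiset a `voi_set`.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_voiset <- function(voiset, path) {
  lab <- array(0, dim(voiset$liver$mask))
  lab[voiset$liver$mask] <- 1
  lab[voiset$lung_left$mask] <- 2
  lab[voiset$lung_right$mask] <- 3
  write_volume(lab, path, geometry = voiset$liver$geometry)
}
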