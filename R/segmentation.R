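#' Binary organ mask on a stated grid
#'
#' @param label one of `"LIVER"`, `"LUNG_LEFT"`, `"LUNG_RIGHT"`.
#' @param mask 3D logical array.
#' @param geometry the [affine_geometry()] of the grid the mask lives on.
#' @param source provenance: `"FILE"`, `"THRESHOLD"`, `"EXTERNAL_ML"` or
#'   `"AUGMENTED"`.
#' @param allow_empty set TRUE to permit a mask with no true voxel (e.g. after
#'   resampling outside the field of view).
#' @return object of class `organ_mask`.
#' @export
organ_mask <- function(label, mask, geometry, source = "FILE",
                       allow_empty = FALSE) {
  label <- match.arg(label, c("LIVER", "LUNG_LEFT", "LUNG_RIGHT"))
  source <- match.arg(source, c("FILE", "THRESHOLD", "EXTERNAL_ML", "AUGMENTED"))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), as.integer(geometry$dim))) {
    stop("mask shape does not match its grid: ",
         paste(dim(mask), collapse = "x"), " vs ",
         paste(geometry$dim, collapse = "x"))
  }
  if (!any(mask) && !allow_empty) {
    stop("organ mask for ", label, " is empty")
  }
  structure(list(label = label, mask = mask, geometry = geometry,
                 source = source),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("organ_mask [%s, %s] %s: %d voxels, %.1f cm^3\n",
              x$label, x$source, paste(x$geometry$dim, collapse = "x"),
              sum(x$mask), mask_volume(x)))
  invisible(x)
}

#' Load organ masks from files onto the CT grid
#'
#' Each mask file must live on the CT grid (spacing/origin within 1e-3 mm);
#' values are binarised at 0.5, so probabilistic masks are accepted.
#'
#' @param paths named list/vector mapping labels (`liver`, `lung_left`,
#'   `lung_right`) to NIfTI files.
#' @param ct the CT [image_volume()] defining the reference grid.
#' @return named list of [organ_mask()] objects.
#' @export
load_masks <- function(paths, ct) {
  labels <- c(liver = "LIVER", lung_left = "LUNG_LEFT",
              lung_right = "LUNG_RIGHT")
  out <- list()
  for (nm in names(paths)) {
    if (!nm %in% names(labels)) stop("unknown mask label: ", nm)
    vol <- read_volume(paths[[nm]], "NIFTI", modality = "CT",
                       frame_of_reference = ct$frame_of_reference)
    if (!same_grid(vol$geometry, ct$geometry, tol = 1e-3)) {
      stop(sprintf("mask grid for '%s' does not match the CT grid:\n  mask %s\n  CT   %s",
                   nm, format_geometry(vol$geometry),
                   format_geometry(ct$geometry)))
    }
    out[[nm]] <- organ_mask(labels[[nm]], vol$voxels > 0.5, ct$geometry,
                            source = "FILE")
  }
  out
}

#' Threshold-based liver/lung segmentation of a CT volume
#'
#' A deterministic stand-in segmenter for phantom and synthetic studies, so no
#' machine-learning model is needed: voxels inside the lung HU window are
#' connected-component filtered to the two largest components (left/right
#' assigned by the component centroid's sign on the patient left-right axis;
#' on a tie the larger component is RIGHT), voxels inside the liver window are
#' reduced to the largest component, and interior holes are filled per organ.
#'
#' @param ct CT [image_volume()].
#' @param lung_hu_window,liver_hu_window length-2 `(low, high)` HU windows;
#'   defaults (-950, -300) and (-50, 200).
#' @param min_lung_cm3 minimum size for a lung component (default 50 cm^3).
#' @return named list of [organ_mask()]s: `liver`, `lung_left`, `lung_right`.
#' @export
threshold_segment_ct <- function(ct, lung_hu_window = c(-950, -300),
                                 liver_hu_window = c(-50, 200),
                                 min_lung_cm3 = 50) {
  if (ct$modality != "CT") stop("threshold segmentation requires a CT volume")
  g <- ct$geometry
  vx_cm3 <- voxel_cm3(g)

  lung_bin <- ct$voxels >= lung_hu_window[1] & ct$voxels <= lung_hu_window[2]
  lab <- label_components(lung_bin)
  sizes <- tabulate(lab)
  big <- which(sizes * vx_cm3 >= min_lung_cm3)
  if (length(big) < 2L) {
    stop("fewer than two lung components above ", min_lung_cm3,
         " cm^3 in the lung HU window; supply mask files instead")
  }
  big <- big[order(sizes[big], decreasing = TRUE)][1:2]
  m1 <- fill_holes(lab == big[1])
  m2 <- fill_holes(lab == big[2])
  # patient L-R axis: +x is LEFT in LPS
  coords_x <- grid_world_coords(g)[, 1]
  cx <- function(m) mean(coords_x[as.vector(m)])
  c1 <- cx(m1); c2 <- cx(m2)
  if (abs(c1 - c2) < 1e-9) {
    # tie: larger component is RIGHT
    left <- if (sizes[big[1]] >= sizes[big[2]]) m2 else m1
    right <- if (sizes[big[1]] >= sizes[big[2]]) m1 else m2
  } else if (c1 > c2) {
    left <- m1; right <- m2
  } else {
    left <- m2; right <- m1
  }

  liver_bin <- ct$voxels >= liver_hu_window[1] & ct$voxels <= liver_hu_window[2]
  # exclude anything already claimed as lung (interior bead speckle can enter
  # the liver window but lung holes were filled above)
  liver_bin <- liver_bin & !left & !right
  liver_lab <- label_components(liver_bin)
  if (max(liver_lab) == 0L) {
    stop("no voxels in the liver HU window; liver mask would be empty")
  }
  liver <- fill_holes(liver_lab == which.max(tabulate(liver_lab)))
  liver <- liver & !left & !right

  list(liver = organ_mask("LIVER", liver, g, "THRESHOLD"),
       lung_left = organ_mask("LUNG_LEFT", left, g, "THRESHOLD"),
       lung_right = organ_mask("LUNG_RIGHT", right, g, "THRESHOLD"))
}

#' Run an external ML organ segmenter out of process
#'
#' Adapter for an external command-line segmenter (e.g. a TotalSegmentator
#' wrapper). The command template is expanded with `{input}` and `{outdir}`
#' placeholders and executed; the adapter then collects
#' `liver.nii.gz`, `lung_left.nii.gz` and `lung_right.nii.gz` from the output
#' directory (filenames configurable). The segmenter itself is never bundled
#' nor required by any other part of the pipeline.
#'
#' @param ct_path path to the CT volume handed to the external tool.
#' @param command_template shell command with `{input}` and `{outdir}`.
#' @param outdir output directory (created if missing).
#' @param filenames named character vector mapping `liver`, `lung_left`,
#'   `lung_right` to the file names the tool writes.
#' @return named list of file paths (same names as `filenames`).
#' @export
run_external_segmenter <- function(ct_path, command_template,
                                   outdir = tempfile("seg"),
                                   filenames = c(liver = "liver.nii.gz",
                                                 lung_left = "lung_left.nii.gz",
                                                 lung_right = "lung_right.nii.gz")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cmd <- gsub("{input}", shQuote(ct_path),
              gsub("{outdir}", shQuote(outdir), command_template,
                   fixed = TRUE), fixed = TRUE)
  log <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  status <- attr(log, "status") %||% 0L
  if (status != 0L) {
    stop("external segmenter exited with status ", status, ":\n",
         paste(log, collapse = "\n"))
  }
  paths <- file.path(outdir, filenames)
  names(paths) <- names(filenames)
  missing <- names(paths)[!file.exists(paths)]
  if (length(missing)) {
    stop("external segmenter did not produce: ",
         paste(missing, collapse = ", "), "\nprocess log:\n",
         paste(log, collapse = "\n"))
  }
  as.list(paths)
}
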