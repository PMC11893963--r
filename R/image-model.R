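#' Spatially-aware image volume
#'
#' The container every volumetric input lives in: a 3D voxel array (counts for
#' SPECT, Hounsfield units for CT) together with its full grid geometry in the
#' DICOM LPS patient frame.
#'
#' @param voxels 3D numeric array.
#' @param spacing,origin,orientation grid geometry, see [affine_geometry()].
#' @param modality one of `"CT"`, `"SPECT_AC"`, `"SPECT_NC"`.
#' @param frame_of_reference opaque identifier string; volumes are only
#'   combined when their frames of reference match (hardware-fused
#'   acquisition; no registration is ever performed).
#' @return object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         orientation = diag(3), modality = "CT",
                         frame_of_reference = "unknown") {
  modality <- match.arg(modality, c("CT", "SPECT_AC", "SPECT_NC"))
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  geom <- affine_geometry(spacing, origin, orientation, dim(voxels))
  if (modality != "CT" && any(voxels < 0)) {
    stop("SPECT voxel values must be non-negative")
  }
  structure(
    list(voxels = voxels, geometry = geom, modality = modality,
         frame_of_reference = as.character(frame_of_reference)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s] %s, frame of reference '%s'\n",
              x$modality, format_geometry(x$geometry), x$frame_of_reference))
  cat(sprintf("  voxel values: min %.4g, max %.4g, total %.6g\n",
              min(x$voxels), max(x$voxels), sum(x$voxels)))
  invisible(x)
}

#' Planar scintigraphy image
#'
#' One member of an anterior/posterior planar pair. The posterior image is
#' stored as acquired (un-mirrored); left-right mirroring is applied exactly
#' once, by [planar_organ_counts()].
#'
#' @param pixels 2D numeric array of counts (non-negative).
#' @param pixel_spacing length-2 pixel size in mm.
#' @param view `"ANTERIOR"` or `"POSTERIOR"`.
#' @return object of class `planar_image`.
#' @export
planar_image <- function(pixels, pixel_spacing, view) {
  view <- match.arg(view, c("ANTERIOR", "POSTERIOR"))
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("planar counts must be non-negative")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing, view = view),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image [%s] %d x %d px @ %s mm, total counts %.6g\n",
              x$view, nrow(x$pixels), ncol(x$pixels),
              paste(signif(x$pixel_spacing, 4), collapse = " x "),
              sum(x$pixels)))
  invisible(x)
}

# NIfTI stores index->RAS; the package works in LPS. Flip the first two
# patient axes on the way in/out.
RAS_TO_LPS <- diag(c(-1, -1, 1, 1))

#' Read an image volume from disk
#'
#' Native support is NIfTI (.nii/.nii.gz); geometry is taken from the sform
#' (or qform) and converted from the NIfTI RAS convention to LPS. DICOM series
#' input is not read natively: convert to NIfTI first (the slice-stack
#' normalisation such a converter must perform is available as
#' [assemble_slices()]).
#'
#' @param path file path.
#' @param format `"NIFTI"` or `"DICOM_SERIES"`.
#' @param modality modality tag to attach, see [image_volume()].
#' @param frame_of_reference identifier to attach; defaults to one stored in a
#'   sidecar (none for NIfTI), else `"unknown"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, format = c("NIFTI", "DICOM_SERIES"),
                        modality = "CT", frame_of_reference = NULL) {
  format <- match.arg(format)
  if (format == "DICOM_SERIES") {
    stop("DICOM series input is not read natively; convert the series to ",
         "NIfTI and pass format = 'NIFTI'")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop RNifti header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  aff_ras <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- RAS_TO_LPS %*% aff_ras[1:4, 1:4]
  g <- decompose_affine(aff)
  image_volume(arr, g$spacing, g$origin, g$orientation, modality = modality,
               frame_of_reference = frame_of_reference %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a 4x4 index->mm affine into (orthonormal orientation, spacing, origin).
decompose_affine <- function(aff) {
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("degenerate affine: zero-length direction")
  list(orientation = sweep(M, 2, spacing, "/"), spacing = spacing,
       origin = aff[1:3, 4])
}

#' Write an image volume (or mask) to NIfTI
#'
#' @param vol an [image_volume()] or a 3D array paired with `geometry`.
#' @param path output path, `.nii` or `.nii.gz`.
#' @param geometry required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, geometry = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$voxels
    geom <- vol$geometry
  } else {
    arr <- vol
    geom <- geometry
    if (is.null(geom)) stop("geometry required when writing a bare array")
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  aff_ras <- RAS_TO_LPS %*% geom$affine  # LPS -> RAS (involution)
  img <- RNifti::`sform<-`(img, structure(aff_ras, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff_ras, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an anterior/posterior planar pair
#'
#' Both images must exist and share matrix size and pixel spacing. Accepts 2D
#' NIfTI files (spacing from the header) or plain CSV count matrices (spacing
#' from `pixel_spacing`). The posterior image is returned unflipped.
#'
#' @param path_ant,path_post file paths for the anterior and posterior views.
#' @param pixel_spacing length-2 mm, required for CSV input and used as
#'   override for NIfTI.
#' @return list with elements `ant` and `post`, both [planar_image()]s.
#' @export
read_planar_pair <- function(path_ant, path_post, pixel_spacing = NULL) {
  ant <- read_planar_one(path_ant, pixel_spacing)
  post <- read_planar_one(path_post, pixel_spacing)
  if (!identical(dim(ant$pixels), dim(post$pixels))) {
    stop(sprintf("planar matrix size mismatch: anterior %s vs posterior %s",
                 paste(dim(ant$pixels), collapse = "x"),
                 paste(dim(post$pixels), collapse = "x")))
  }
  if (max(abs(ant$spacing - post$spacing)) > 1e-6) {
    stop("planar pixel spacing mismatch between views")
  }
  list(ant = planar_image(ant$pixels, ant$spacing, "ANTERIOR"),
       post = planar_image(post$pixels, post$spacing, "POSTERIOR"))
}

read_planar_one <- function(path, pixel_spacing) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "csv") {
    if (is.null(pixel_spacing)) {
      stop("pixel_spacing is required for CSV planar input")
    }
    px <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(px) <- NULL
    return(list(pixels = px, spacing = rep_len(pixel_spacing, 2L)))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  if (length(dim(arr)) != 2L) stop("expected a 2D planar image: ", path)
  sp <- pixel_spacing %||% RNifti::pixdim(img)[1:2]
  list(pixels = arr, spacing = rep_len(sp, 2L))
}

#' Assemble a volume from a stack of axial slices
#'
#' The normalisation a DICOM-series front-end must apply: slices sharing an
#' in-plane orientation and frame of reference are sorted along the slice
#' normal regardless of their stored order (superior-first or inferior-first),
#' the inter-slice gap is checked for uniformity (1% tolerance), rescale
#' slope/intercept are applied, and the slice axis is oriented so the
#' index-to-patient transform is right-handed. The result is therefore
#' identical for both storage orders of the same acquisition.
#'
#' @param slices list of 2D arrays (stored pixel values).
#' @param positions list/matrix of LPS mm positions of each slice's first
#'   pixel centre (DICOM ImagePositionPatient).
#' @param row_dir,col_dir length-3 LPS direction cosines of pixel rows and
#'   columns (DICOM ImageOrientationPatient).
#' @param pixel_spacing length-2 in-plane spacing, mm.
#' @param frames_of_reference character vector (one per slice or length 1).
#' @param slope,intercept rescale applied as `slope * stored + intercept`.
#' @param modality passed to [image_volume()].
#' @return an [image_volume()].
#' @export
assemble_slices <- function(slices, positions, row_dir, col_dir,
                            pixel_spacing, frames_of_reference = "unknown",
                            slope = 1, intercept = 0, modality = "CT") {
  n <- length(slices)
  stopifnot(n >= 2L)
  frames_of_reference <- rep_len(frames_of_reference, n)
  if (length(unique(frames_of_reference)) > 1L) {
    u <- unique(frames_of_reference)
    stop(sprintf("mixed frames of reference in one series: '%s' vs '%s'",
                 u[1], u[2]))
  }
  if (is.list(positions)) positions <- do.call(rbind, positions)
  row_dir <- row_dir / sqrt(sum(row_dir^2))
  col_dir <- col_dir / sqrt(sum(col_dir^2))
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- as.numeric(positions %*% normal)
  ord <- order(proj)  # ascending along +normal => right-handed transform
  gaps <- diff(proj[ord])
  if (any(gaps <= 0)) stop("duplicate slice positions in series")
  if ((max(gaps) - min(gaps)) / mean(gaps) > 0.01) {
    stop(sprintf(
      "non-uniform slice gap beyond 1%% tolerance (min %.4f, max %.4f mm)",
      min(gaps), max(gaps)))
  }
  dz <- mean(gaps)
  dm2 <- dim(slices[[1]])
  vox <- array(0, c(dm2, n))
  for (s in seq_len(n)) {
    sl <- slices[[ord[s]]]
    if (!identical(dim(sl), dm2)) stop("slice matrix size varies within series")
    vox[, , s] <- slope * sl + intercept
  }
  image_volume(vox,
               spacing = c(pixel_spacing, dz),
               origin = positions[ord[1], ],
               orientation = cbind(row_dir, col_dir, normal),
               modality = modality,
               frame_of_reference = frames_of_reference[1])
}

# Hard check used wherever two volumes are combined.
check_same_frame <- function(a, b) {
  if (!identical(a$frame_of_reference, b$frame_of_reference)) {
    stop(sprintf(
      "frame-of-reference mismatch: '%s' vs '%s' (images must be hardware-fused; no registration is performed)",
      a$frame_of_reference, b$frame_of_reference))
  }
  invisible(TRUE)
}
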