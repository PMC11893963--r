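#' Affine voxel geometry
#'
#' Describes the grid of an image or mask: the homogeneous 4x4 transform
#' from continuous 0-based voxel index to patient-space millimetres, plus the
#' grid dimensions. Patient coordinates follow the DICOM LPS convention
#' (+x left, +y posterior, +z superior); `origin` is the patient-space
#' position of the CENTRE of voxel (0,0,0), and voxel extents are half-open.
#'
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, mm position of the centre of voxel (0,0,0).
#' @param orientation 3x3 direction matrix mapping index axes to patient axes;
#'   must be orthonormal to within 1e-4.
#' @param dim integer length-3 grid dimensions.
#' @return an object of class `affine_geometry` with elements `spacing`,
#'   `origin`, `orientation`, `dim`, and `affine` (the 4x4 matrix).
#' @export
affine_geometry <- function(spacing, origin = c(0, 0, 0),
                            orientation = diag(3), dim) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  stopifnot(length(spacing) == 3L, length(origin) == 3L, length(dim) == 3L)
  if (any(spacing <= 0)) {
    stop("voxel spacing must be strictly positive on all axes")
  }
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-4) {
    stop("orientation matrix is not orthonormal (tolerance 1e-4)")
  }
  affine <- rbind(
    cbind(orientation %*% diag(spacing), origin),
    c(0, 0, 0, 1)
  )
  structure(
    list(spacing = spacing, origin = origin, orientation = orientation,
         dim = as.integer(dim), affine = affine),
    class = "affine_geometry"
  )
}

#' Map 0-based voxel indices to patient-space mm
#'
#' @param geom an [affine_geometry()].
#' @param idx numeric matrix (n x 3) or length-3 vector of continuous 0-based
#'   voxel indices.
#' @return n x 3 matrix of LPS mm coordinates.
#' @export
index_to_world <- function(geom, idx) {
  idx <- to_coord_matrix(idx)
  t(geom$orientation %*% (t(idx) * geom$spacing) + geom$origin)
}

#' Map patient-space mm to continuous 0-based voxel indices
#'
#' @inheritParams index_to_world
#' @param world numeric matrix (n x 3) or length-3 vector of LPS mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
world_to_index <- function(geom, world) {
  world <- to_coord_matrix(world)
  t((t(geom$orientation) %*% (t(world) - geom$origin)) / geom$spacing)
}

to_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(x) == 3L)
  x
}

#' @export
print.affine_geometry <- function(x, ...) {
  cat("affine_geometry:", paste(x$dim, collapse = " x "), "voxels, spacing",
      paste(signif(x$spacing, 6), collapse = " x "), "mm\n")
  cat("  origin (LPS mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  invisible(x)
}

# Geometry equality within tolerance (mm on spacing/origin, abs on direction).
same_grid <- function(a, b, tol = 1e-3) {
  identical(a$dim, b$dim) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= 1e-6 + tol / 1e3
}

format_geometry <- function(g) {
  sprintf("dim [%s] spacing [%s] origin [%s]",
          paste(g$dim, collapse = ","),
          paste(signif(g$spacing, 6), collapse = ","),
          paste(signif(g$origin, 6), collapse = ","))
}

# World-space mm coordinates of every voxel centre, as an n x 3 matrix in
# column-major voxel order (the storage order of R arrays).
grid_world_coords <- function(geom) {
  dm <- geom$dim
  i <- rep.int(seq.int(0L, dm[1] - 1L), times = dm[2] * dm[3])
  j <- rep.int(rep(seq.int(0L, dm[2] - 1L), each = dm[1]), times = dm[3])
  k <- rep(seq.int(0L, dm[3] - 1L), each = dm[1] * dm[2])
  index_to_world(geom, cbind(i, j, k))
}

# Volume of one voxel in cm^3.
voxel_cm3 <- function(geom) prod(geom$spacing) / 1000
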