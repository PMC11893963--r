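#' Build a structured LSF report
#'
#' Collects everything a reviewer needs to reproduce the number: study
#' metadata, per-organ volumes before and after augmentation, the count
#' summary, every augmentation/crop parameter applied, and the LSF result(s).
#' The recorded LSF is re-derived from the recorded counts and must agree to
#' 1e-9 relative, so a report is self-consistent by construction.
#'
#' @param metadata named list of study metadata (ids, series descriptions,
#'   times); free-form.
#' @param voiset the final [augment_vois()] VOI set (optional for
#'   planar-only reports).
#' @param counts a `count_summary` or `planar_count_summary`.
#' @param results a single `lsf_result` or list of them.
#' @param software_version package version string.
#' @return object of class `lsf_report`.
#' @export
build_report <- function(metadata = list(), voiset = NULL, counts,
                         results,
                         software_version = as.character(utils::packageVersion("lungshunt"))) {
  if (missing(counts) || is.null(counts)) stop("mandatory field missing: counts")
  if (missing(results) || is.null(results)) stop("mandatory field missing: results")
  if (inherits(results, "lsf_result")) results <- list(results)
  for (r in results) {
    recomputed <- switch(r$method,
      SPECT_3D = 100 * counts$total_lung_count /
        (counts$total_lung_count + counts$total_liver_count),
      PLANAR_2D = 100 * counts$geomean_lung_count /
        (counts$geomean_lung_count + counts$geomean_liver_count),
      GROUND_TRUTH = r$lsf_percent)
    if (abs(recomputed - r$lsf_percent) > 1e-9 * max(1, abs(r$lsf_percent))) {
      stop("report inconsistency: recorded LSF does not reproduce from its counts")
    }
  }
  volumes <- NULL
  augmentation <- NULL
  crop <- NULL
  if (!is.null(voiset)) {
    volumes <- lapply(c(liver = "liver", lung_left = "lung_left",
                        lung_right = "lung_right"), function(nm) {
      m <- voiset[[nm]]
      vx <- voxel_cm3(m$geometry)
      list(original_cm3 = (sum(m$mask) - sum(voiset$provenance[[nm]])) * vx,
           augmented_cm3 = sum(m$mask) * vx)
    })
    augmentation <- unclass(voiset$augmentation)
    if (!is.null(voiset$crop_correction)) crop <- unclass(voiset$crop_correction)
  }
  structure(
    list(metadata = metadata,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         software_version = software_version,
         organ_volumes = volumes,
         augmentation = augmentation,
         crop_correction = crop,
         counts = unclass(counts),
         results = lapply(results, function(r)
           list(method = r$method, lsf_percent = r$lsf_percent,
                inputs = r$inputs))),
    class = "lsf_report"
  )
}

#' Render an LSF report
#'
#' JSON rendering is schema-stable and round-trips losslessly through
#' [parse_report()]; TEXT is a human-readable summary with the LSF to two
#' decimals.
#'
#' @param report an [build_report()] result.
#' @param format `"JSON"` or `"TEXT"`.
#' @return a character scalar (the document).
#' @export
render_report <- function(report, format = c("JSON", "TEXT")) {
  if (!format[1] %in% c("JSON", "TEXT")) {
    stop("unknown report format: ", format[1])
  }
  format <- match.arg(format)
  if (format == "JSON") {
    return(as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE,
                                         null = "null")))
  }
  lines <- c("Lung shunt fraction report",
             sprintf("generated %s by lungshunt %s", report$created,
                     report$software_version))
  for (nm in names(report$metadata)) {
    lines <- c(lines, sprintf("  %s: %s", nm, report$metadata[[nm]]))
  }
  if (!is.null(report$organ_volumes)) {
    for (nm in names(report$organ_volumes)) {
      v <- report$organ_volumes[[nm]]
      lines <- c(lines, sprintf("  %-10s %8.1f cm^3 original, %8.1f cm^3 augmented",
                                nm, v$original_cm3, v$augmented_cm3))
    }
  }
  if (!is.null(report$augmentation)) {
    a <- report$augmentation
    lines <- c(lines, sprintf(
      "  augmentation: liver %g mm, lung %g mm, extra cranio-caudal %g mm",
      a$liver_radius_mm, a$lung_radius_mm, a$extra_cranio_caudal_mm))
  }
  if (!is.null(report$crop_correction)) {
    cc <- report$crop_correction
    lines <- c(lines, sprintf(
      "  crop correction: %.1f%% of reference lung volume missing, %.6g counts imputed",
      100 * cc$estimated_missing_fraction, cc$added_counts))
  }
  for (r in report$results) {
    lines <- c(lines, sprintf("  LSF [%s] = %.2f%%", r$method, r$lsf_percent))
  }
  paste(lines, collapse = "\n")
}

#' Parse a JSON report back into an `lsf_report`
#'
#' @param json character scalar or path to a JSON report file.
#' @return an `lsf_report`.
#' @export
parse_report <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                          simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  structure(x, class = "lsf_report")
}

#' @export
print.lsf_report <- function(x, ...) {
  cat(render_report(x, "TEXT"), "\n")
  invisible(x)
}
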