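#' Sum SPECT counts under each organ VOI
#'
#' Per-organ sums of voxel values under the (augmented) masks; counts imputed
#' by a crop correction are folded into the lung total.
#'
#' @param spect SPECT [image_volume()].
#' @param voiset a [augment_vois()] result on the same grid.
#' @return object of class `count_summary` with per-organ counts,
#'   `total_lung_count` (left + right + crop-imputed) and
#'   `total_liver_count`.
#' @export
organ_counts <- function(spect, voiset) {
  if (spect$modality == "CT") stop("organ_counts expects a SPECT volume")
  if (!same_grid(spect$geometry, voiset$liver$geometry)) {
    stop("VOI set and SPECT volume are on different grids:\n  SPECT ",
         format_geometry(spect$geometry), "\n  VOIs  ",
         format_geometry(voiset$liver$geometry))
  }
  liver <- sum(spect$voxels[voiset$liver$mask])
  ll <- sum(spect$voxels[voiset$lung_left$mask])
  lr <- sum(spect$voxels[voiset$lung_right$mask])
  crop <- if (is.null(voiset$crop_correction)) 0 else
    voiset$crop_correction$added_counts
  structure(
    list(liver_count = liver, lung_left_count = ll, lung_right_count = lr,
         crop_added_counts = crop,
         total_lung_count = ll + lr + crop, total_liver_count = liver),
    class = "count_summary"
  )
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("count_summary: lung %.6g (L %.6g + R %.6g + crop %.6g), liver %.6g\n",
              x$total_lung_count, x$lung_left_count, x$lung_right_count,
              x$crop_added_counts, x$total_liver_count))
  invisible(x)
}

new_lsf_result <- function(lsf_percent, method, inputs, parameters = list()) {
  if (is.nan(lsf_percent) || lsf_percent < 0 || lsf_percent > 100) {
    stop("LSF is undefined or outside [0, 100]")
  }
  structure(list(lsf_percent = lsf_percent, method = method, inputs = inputs,
                 parameters = parameters),
            class = "lsf_result")
}

#' @export
print.lsf_result <- function(x, ...) {
  cat(sprintf("LSF = %.2f%% [%s]\n", x$lsf_percent, x$method))
  invisible(x)
}

#' Lung shunt fraction from 3D SPECT organ counts
#'
#' `LSF% = TotalLungCount / (TotalLungCount + TotalLiverCount) x 100`.
#'
#' @param counts a `count_summary` from [organ_counts()], or a list with
#'   `total_lung_count` and `total_liver_count`.
#' @param parameters optional list echoed into the result (augmentation, crop
#'   correction, ...).
#' @return an `lsf_result` with `method = "SPECT_3D"`.
#' @export
lsf_3d <- function(counts, parameters = list()) {
  lung <- counts$total_lung_count
  liver <- counts$total_liver_count
  if (lung < 0 || liver < 0) stop("counts must be non-negative")
  if (lung + liver <= 0) stop("undefined LSF: total lung and liver counts are both zero")
  new_lsf_result(100 * lung / (lung + liver), "SPECT_3D",
                 inputs = list(total_lung_count = lung,
                               total_liver_count = liver),
                 parameters = parameters)
}

#' Organ counts from an anterior/posterior planar pair
#'
#' The posterior image is mirrored left-right once, here, so that both views
#' share the anterior ROI frame; per-organ totals are computed per view and
#' combined as the geometric mean `sqrt(ant * post)` of the organ TOTALS.
#'
#' @param ant,post [planar_image()]s (same matrix).
#' @param rois named list of 2D logical ROI masks in the anterior frame:
#'   `liver` plus either `lung` or `lung_left`/`lung_right`.
#' @return object of class `planar_count_summary`.
#' @export
planar_organ_counts <- function(ant, post, rois) {
  if (ant$view != "ANTERIOR" || post$view != "POSTERIOR") {
    stop("planar_organ_counts expects an (ANTERIOR, POSTERIOR) pair")
  }
  if (!identical(dim(ant$pixels), dim(post$pixels))) {
    stop("anterior/posterior matrix size mismatch")
  }
  if ("lung" %in% names(rois)) {
    lung_roi <- rois$lung
  } else {
    lung_roi <- rois$lung_left | rois$lung_right
  }
  liver_roi <- rois$liver
  if (!identical(dim(lung_roi), dim(ant$pixels)) ||
      !identical(dim(liver_roi), dim(ant$pixels))) {
    stop("ROI matrix size does not match the planar images")
  }
  post_px <- post$pixels[rev(seq_len(nrow(post$pixels))), , drop = FALSE]
  tot <- function(px, roi) as.numeric(sum(as.numeric(px[roi])))
  ant_lung <- tot(ant$pixels, lung_roi); post_lung <- tot(post_px, lung_roi)
  ant_liver <- tot(ant$pixels, liver_roi); post_liver <- tot(post_px, liver_roi)
  if (post_lung == 0 || post_liver == 0 || ant_lung == 0 || ant_liver == 0) {
    lsf_log("WARN", "zero organ total in one planar view; geometric mean is 0")
  }
  structure(
    list(geomean_lung_count = sqrt(ant_lung * post_lung),
         geomean_liver_count = sqrt(ant_liver * post_liver),
         ant_lung_count = ant_lung, post_lung_count = post_lung,
         ant_liver_count = ant_liver, post_liver_count = post_liver),
    class = "planar_count_summary"
  )
}

#' Lung shunt fraction from planar geometric-mean counts
#'
#' `LSF% = GeomeanLung / (GeomeanLung + GeomeanLiver) x 100`.
#'
#' @param counts a `planar_count_summary` (or list with `geomean_lung_count`
#'   and `geomean_liver_count`).
#' @param parameters optional list echoed into the result.
#' @return an `lsf_result` with `method = "PLANAR_2D"`.
#' @export
lsf_planar <- function(counts, parameters = list()) {
  lung <- counts$geomean_lung_count
  liver <- counts$geomean_liver_count
  if (lung < 0 || liver < 0) stop("geomean counts must be non-negative")
  if (lung + liver <= 0) stop("undefined LSF: both geometric means are zero")
  new_lsf_result(100 * lung / (lung + liver), "PLANAR_2D",
                 inputs = list(geomean_lung_count = lung,
                               geomean_liver_count = liver),
                 parameters = parameters)
}

#' Assayed syringe activities defining the phantom ground truth
#'
#' @param RLA,LLA,LA assayed right-lung, left-lung and liver activities (MBq).
#' @param rlr,llr,lr residual activities left in the syringes (MBq).
#' @param assay_time,reference_time numeric hours (or POSIXct) used for decay
#'   correction; equal by default.
#' @return object of class `ground_truth_activities`.
#' @export
ground_truth_activities <- function(RLA, LLA, LA, rlr = 0, llr = 0, lr = 0,
                                    assay_time = 0, reference_time = assay_time) {
  vals <- c(RLA = RLA, LLA = LLA, LA = LA, rlr = rlr, llr = llr, lr = lr)
  if (any(vals < 0)) stop("activities and residuals must be non-negative")
  if (rlr > RLA || llr > LLA || lr > LA) {
    stop("a residual exceeds its assayed activity")
  }
  structure(as.list(c(vals, list(assay_time = assay_time,
                                 reference_time = reference_time))),
            class = "ground_truth_activities")
}

# Physical decay of Tc-99m between two times; accepts numeric hours or POSIXct.
TC99M_HALF_LIFE_H <- 6.0067

decay_correct <- function(activity, from_time, to_time,
                          half_life_h = TC99M_HALF_LIFE_H) {
  if (inherits(from_time, "POSIXt")) {
    dt_h <- as.numeric(difftime(to_time, from_time, units = "hours"))
  } else {
    dt_h <- as.numeric(to_time) - as.numeric(from_time)
  }
  activity * 2^(-dt_h / half_life_h)
}

#' Ground-truth lung shunt fraction from syringe assays
#'
#' All six activities are decay-corrected to the reference time
#' (Tc-99m half-life 6.0067 h), then
#' `LSF% = ((RLA - rlr) + (LLA - llr)) /
#'   ((RLA - rlr) + (LLA - llr) + (LA - lr)) x 100`.
#'
#' @param a a [ground_truth_activities()].
#' @return an `lsf_result` with `method = "GROUND_TRUTH"`.
#' @export
lsf_ground_truth <- function(a) {
  dc <- function(x) decay_correct(x, a$assay_time, a$reference_time)
  net_rl <- dc(a$RLA) - dc(a$rlr)
  net_ll <- dc(a$LLA) - dc(a$llr)
  net_lv <- dc(a$LA) - dc(a$lr)
  if (net_rl < 0 || net_ll < 0 || net_lv < 0) {
    stop("negative net activity after decay correction; assay inconsistency")
  }
  lung <- net_rl + net_ll
  if (lung + net_lv <= 0) stop("undefined LSF: all net activities are zero")
  new_lsf_result(100 * lung / (lung + net_lv), "GROUND_TRUTH",
                 inputs = list(net_right_lung_MBq = net_rl,
                               net_left_lung_MBq = net_ll,
                               net_liver_MBq = net_lv))
}

#' Percentage difference between planar and SPECT LSF
#'
#' `PD = (PL - TF) / TF x 100`, signed; `PL` is the planar LSF and `TF` the
#' 3D SPECT LSF, both in percent.
#'
#' @param PL,TF LSF percentages (TF must be > 0).
#' @return signed percentage difference.
#' @export
percentage_difference <- function(PL, TF) {
  if (any(TF <= 0)) stop("percentage difference undefined for TF <= 0")
  (PL - TF) / TF * 100
}

#' Accuracy of a measured LSF against the ground truth
#'
#' `(measured - truth) / truth x 100`, signed.
#'
#' @param measured,truth `lsf_result`s (or plain percentages).
#' @return signed accuracy percentage.
#' @export
accuracy_vs_truth <- function(measured, truth) {
  m <- if (inherits(measured, "lsf_result")) measured$lsf_percent else measured
  t <- if (inherits(truth, "lsf_result")) truth$lsf_percent else truth
  if (t <= 0) stop("accuracy undefined for zero ground truth")
  (m - t) / t * 100
}

#' Quartiles and interquartile range by the (n+1)/4 rank rule
#'
#' Q1 sits at rank `(n+1)/4` and Q3 at rank `3(n+1)/4` over the sorted
#' values, with linear interpolation between adjacent order statistics for
#' fractional ranks and ranks clipped to `[1, n]`; `IQR = Q3 - Q1`.
#'
#' @param values numeric vector (n >= 1).
#' @return object of class `quartile_summary` with `n`, `q1`, `q3`, `iqr`.
#' @export
quartile_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    stop("quartile_summary needs at least one finite value")
  }
  s <- sort(values)
  n <- length(s)
  at_rank <- function(r) {
    r <- min(max(r, 1), n)
    lo <- floor(r); hi <- ceiling(r)
    s[lo] + (r - lo) * (s[hi] - s[lo])
  }
  q1 <- at_rank((n + 1) / 4)
  q3 <- at_rank(3 * (n + 1) / 4)
  structure(list(n = n, q1 = q1, q3 = q3, iqr = q3 - q1),
            class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(sprintf("n = %d, Q1 = %.2f, Q3 = %.2f, IQR = %.2f\n",
              x$n, x$q1, x$q3, x$iqr))
  invisible(x)
}

#' Cohort comparison of planar versus 3D SPECT LSF
#'
#' Reads per-case planar and SPECT LSF percentages, computes the per-case
#' percentage difference (defined only where the SPECT LSF is positive) and
#' quartile summaries. Because "average percentage difference" is ambiguous,
#' both readings are reported: the mean of the per-case PDs and the PD of the
#' cohort means.
#'
#' @param cohort data frame with columns `case_id`, `planar_lsf_percent`,
#'   `spect_lsf_percent`, or a path to such a CSV.
#' @return list with the per-case table (`cases`, including a `pd_percent`
#'   column), `planar` and `spect` [quartile_summary()]s, means, and both PD
#'   summaries (`mean_pd_percent`, `pd_of_means_percent`).
#' @export
cohort_summary <- function(cohort) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  need <- c("case_id", "planar_lsf_percent", "spect_lsf_percent")
  if (!all(need %in% names(cohort))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  pl <- cohort$planar_lsf_percent
  tf <- cohort$spect_lsf_percent
  pd <- ifelse(tf > 0, (pl - tf) / tf * 100, NA_real_)
  cohort$pd_percent <- pd
  list(
    cases = cohort,
    planar = quartile_summary(pl),
    spect = quartile_summary(tf),
    mean_planar_lsf = mean(pl),
    mean_spect_lsf = mean(tf),
    mean_pd_percent = mean(pd, na.rm = TRUE),
    pd_of_means_percent = if (mean(tf) > 0)
      percentage_difference(mean(pl), mean(tf)) else NA_real_
  )
}
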