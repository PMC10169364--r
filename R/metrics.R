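#' Dice similarity coefficient
#'
#' Spatial overlap between two binary segmentations:
#' `2|A intersect B| / (|A| + |B|)`, 0 for disjoint masks, 1 for identical
#' ones. Symmetric. Undefined (an error) when both masks are empty.
#'
#' @param a,b Congruent [mask_volume()]s (or binary 3D arrays).
#' @return A scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  av <- mask_vox(a)
  bv <- mask_vox(b)
  if (inherits(a, "mask_volume") && inherits(b, "mask_volume")) {
    stopifnot_congruent(a, b)
  } else if (!identical(dim(av), dim(bv))) {
    stop("masks are not congruent", call. = FALSE)
  }
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0) {
    stop("DSC undefined: both masks are empty", call. = FALSE)
  }
  2 * sum(av * bv) / (na + nb)
}

mask_vox <- function(m) if (inherits(m, "image_volume")) m$voxels else m

#' Border voxels of a binary mask
#'
#' A foreground voxel is a border voxel when at least one of its six
#' face-neighbours is background; neighbours outside the array count as
#' background, so foreground touching the grid boundary is border.
#'
#' @param m A nonempty [mask_volume()] (or binary 3D array).
#' @return Integer matrix of 1-based voxel coordinates, one row per border
#'   voxel.
#' @export
surface_voxels <- function(m) {
  v <- mask_vox(m)
  if (sum(v) == 0) stop("surface undefined: mask is empty", call. = FALSE)
  b <- border_voxels(v)
  which(b != 0, arr.ind = TRUE)
}

# directed surface distances (mm) from every border voxel of `from` to the
# border surface of `to`, via an anisotropic Euclidean distance transform
directed_surface_distances <- function(from, to, spacing) {
  bf <- border_voxels(from)
  bt <- border_voxels(to)
  dt <- edt3d(bt, spacing)
  dt[bf != 0]
}

check_distance_args <- function(a, b) {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  stopifnot_congruent(a, b)
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0) {
    stop("surface distance undefined: a mask is empty (missed tumor)",
         call. = FALSE)
  }
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The outlier-robust maximal boundary error: the larger of the two
#' directed 95th-percentile border-voxel distances (each the 95th
#' percentile, by linear interpolation between order statistics, of the
#' Euclidean mm distances from the border voxels of one mask to the border
#' surface of the other). Distances are voxel-centre to voxel-centre,
#' scaled per axis by the voxel spacing.
#'
#' @param a,b Congruent nonempty [mask_volume()]s.
#' @return Distance in mm.
#' @export
hd95 <- function(a, b) {
  check_distance_args(a, b)
  d_ab <- directed_surface_distances(a$voxels, b$voxels, a$spacing)
  d_ba <- directed_surface_distances(b$voxels, a$voxels, a$spacing)
  max(stats::quantile(d_ab, 0.95, type = 7, names = FALSE),
      stats::quantile(d_ba, 0.95, type = 7, names = FALSE))
}

#' Average symmetric surface distance (mm)
#'
#' The mean of the pooled directed border-voxel distances of both masks:
#' all distances from border voxels of `a` to the surface of `b` together
#' with all distances from border voxels of `b` to the surface of `a`.
#'
#' @inheritParams hd95
#' @return Distance in mm.
#' @export
assd <- function(a, b) {
  check_distance_args(a, b)
  d_ab <- directed_surface_distances(a$voxels, b$voxels, a$spacing)
  d_ba <- directed_surface_distances(b$voxels, a$voxels, a$spacing)
  mean(c(d_ab, d_ba))
}

#' Relative absolute volume difference
#'
#' `|V_pred - V_gt| / V_gt` with volumes measured as foreground voxel
#' count times voxel volume. Not symmetric: the ground truth provides the
#' denominator. An empty prediction against a nonempty truth gives 1.
#'
#' @param pred Predicted [mask_volume()].
#' @param gt Nonempty ground-truth [mask_volume()].
#' @return A nonnegative scalar.
#' @export
ravd <- function(pred, gt) {
  stopifnot(inherits(pred, "mask_volume"), inherits(gt, "mask_volume"))
  stopifnot_congruent(pred, gt)
  vg <- volume_cm3(gt)
  if (vg == 0) stop("RAVD undefined: ground truth mask is empty",
                    call. = FALSE)
  abs(volume_cm3(pred) - vg) / vg
}

#' All four metrics for one predicted/truth mask pair
#'
#' Computes DSC, HD95 (mm), ASSD (mm) and RAVD, plus the two volumes and a
#' detection flag. When the prediction is empty the tumor counts as missed:
#' `detected` is `FALSE`, DSC is 0, RAVD is 1 and the surface distances are
#' `NA` (they are undefined without a predicted surface).
#'
#' @param pred Predicted [mask_volume()].
#' @param gt Nonempty ground-truth [mask_volume()].
#' @return A one-row data frame (class `case_metrics`).
#' @export
case_metrics <- function(pred, gt) {
  stopifnot_congruent(pred, gt)
  detected <- sum(pred$voxels) > 0
  if (detected) {
    out <- data.frame(dsc = dsc(pred, gt), hd95_mm = hd95(pred, gt),
                      assd_mm = assd(pred, gt), ravd = ravd(pred, gt))
  } else {
    out <- data.frame(dsc = 0, hd95_mm = NA_real_, assd_mm = NA_real_,
                      ravd = 1)
  }
  out$pred_volume_cm3 <- volume_cm3(pred)
  out$gt_volume_cm3 <- volume_cm3(gt)
  out$detected <- detected
  class(out) <- c("case_metrics", "data.frame")
  out
}

#' Evaluate a cohort of predictions
#'
#' Computes [case_metrics()] for every pair, then summarizes each metric —
#' mean, SD, median and interquartile range — overall and within
#' ground-truth volume strata (default `< 0.1`, `[0.1, 6]` and `> 6` cm^3).
#' Cases with an empty prediction are counted as missed tumors and excluded
#' from the surface-distance summaries (their DSC 0 and RAVD 1 still
#' contribute).
#'
#' @param pairs List of `list(pred =, gt =)` mask pairs; names become case
#'   ids.
#' @param strata_bounds_cm3 Two ascending volume bounds (cm^3) defining the
#'   three strata.
#' @return A `cohort_report`: `per_case` data frame, `summary` data frame
#'   (one row per stratum x metric), `n_cases`, `n_detected`.
#' @export
evaluate_cohort <- function(pairs, strata_bounds_cm3 = c(0.1, 6.0)) {
  stopifnot(length(pairs) >= 1, length(strata_bounds_cm3) == 2L,
            strata_bounds_cm3[1] < strata_bounds_cm3[2])
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(pairs))
  per_case <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    cm <- case_metrics(pairs[[i]]$pred, pairs[[i]]$gt)
    cbind(data.frame(case_id = ids[i]), cm)
  }))
  lo <- strata_bounds_cm3[1]
  hi <- strata_bounds_cm3[2]
  per_case$stratum <- cut(per_case$gt_volume_cm3,
                          c(-Inf, lo, hi, Inf),
                          labels = c(sprintf("<%g", lo),
                                     sprintf("%g-%g", lo, hi),
                                     sprintf(">%g", hi)),
                          right = TRUE)
  summarize <- function(df, label) {
    met <- c("dsc", "hd95_mm", "assd_mm", "ravd")
    do.call(rbind, lapply(met, function(m) {
      x <- df[[m]]
      x <- x[!is.na(x)]
      data.frame(stratum = label, metric = m, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 median = if (length(x)) stats::median(x) else NA_real_,
                 q25 = if (length(x)) stats::quantile(x, 0.25, names = FALSE)
                       else NA_real_,
                 q75 = if (length(x)) stats::quantile(x, 0.75, names = FALSE)
                       else NA_real_)
    }))
  }
  summ <- summarize(per_case, "all")
  for (s in levels(per_case$stratum)) {
    sub <- per_case[per_case$stratum == s, ]
    if (nrow(sub)) summ <- rbind(summ, summarize(sub, s))
  }
  structure(list(per_case = per_case, summary = summ,
                 n_cases = nrow(per_case),
                 n_detected = sum(per_case$detected)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d cases, %d detected (%d missed)\n",
              x$n_cases, x$n_detected, x$n_cases - x$n_detected))
  overall <- x$summary[x$summary$stratum == "all", ]
  for (i in seq_len(nrow(overall))) {
    r <- overall[i, ]
    cat(sprintf("  %-8s mean %.3f +/- %.3f  median %.3f (%.3f-%.3f)  n=%d\n",
                r$metric, r$mean, ifelse(is.na(r$sd), 0, r$sd), r$median,
                r$q25, r$q75, r$n))
  }
  invisible(x)
}
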