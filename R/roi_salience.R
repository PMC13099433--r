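# Per-subject functional ROI selection inside a target mask: coactivation
# with a spherical salience-network seed, then percentile + floor rules
# defining salience-related and non-salience voxel clusters.

#' Spherical seed specification
#'
#' @param center_mm `(x, y, z)` seed center in mm (the study uses a right
#'   anterior-insula seed at MNI 36, 18, 4).
#' @param radius_mm sphere radius in mm (default 4).
#' @param label seed label.
#' @return an object of class `SeedSpec`.
#' @export
seed_spec <- function(center_mm, radius_mm = 4, label = "seed") {
  if (length(center_mm) != 3L || !all(is.finite(center_mm))) {
    stopf("center_mm must be three finite coordinates")
  }
  if (!is_scalar_num(radius_mm) || radius_mm <= 0) {
    stopf("radius_mm must be > 0")
  }
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 label = label),
            class = "SeedSpec")
}

#' ROI selection configuration
#'
#' Salience cluster: correlation strictly above the `high_pctile`
#' percentile of valid voxel correlations AND strictly above `high_floor`.
#' Non-salience cluster: strictly below the `low_pctile` percentile AND
#' strictly below `low_ceiling`.
#'
#' @param high_pctile,low_pctile percentile thresholds (defaults 85, 15).
#' @param high_floor absolute floor for the salience cluster (default 0.2).
#' @param low_ceiling absolute ceiling for the non-salience cluster
#'   (default 0.2, reading "at least below 0.2" as `r < 0.2`; set to -0.2
#'   for the stricter sign reading).
#' @param target_mask_label mask over which voxels are selected
#'   (default `"target"`).
#' @return an object of class `ROISelectionConfig`.
#' @export
roi_config <- function(high_pctile = 85, low_pctile = 15, high_floor = 0.2,
                       low_ceiling = 0.2, target_mask_label = "target") {
  if (!(0 < low_pctile && low_pctile < high_pctile && high_pctile < 100)) {
    stopf("need 0 < low_pctile < high_pctile < 100")
  }
  if (high_floor < 0) stopf("high_floor must be >= 0")
  structure(list(high_pctile = high_pctile, low_pctile = low_pctile,
                 high_floor = high_floor, low_ceiling = low_ceiling,
                 target_mask_label = target_mask_label),
            class = "ROISelectionConfig")
}

#' Mean time-course of a spherical seed region
#'
#' Averages, per volume, all voxels whose centers lie within
#' `radius_mm` of the seed center (boundary inclusive).
#'
#' @param bold a `BOLDDataset`.
#' @param seed a `SeedSpec`.
#' @return numeric vector, one value per volume, with attribute
#'   `n_voxels` (sphere membership count).
#' @export
seed_timecourse <- function(bold, seed) {
  stopifnot(inherits(bold, "BOLDDataset"), inherits(seed, "SeedSpec"))
  d2 <- rowSums(sweep(bold$coords, 2, seed$center_mm, `-`)^2)
  idx <- which(sqrt(d2) <= seed$radius_mm + 1e-9)
  if (length(idx) == 0L) {
    stopf("seed '%s' (radius %g mm) contains no voxel centers",
          seed$label, seed$radius_mm)
  }
  ts <- colMeans(bold$data[idx, , drop = FALSE])
  attr(ts, "n_voxels") <- length(idx)
  attr(ts, "voxel_idx") <- idx
  ts
}

#' Correlation of every target voxel with a seed time-course
#'
#' Pearson correlation per voxel of the target mask; voxels with zero
#' variance get `NA` (recorded as missing, excluded from later selection).
#'
#' @param bold a `BOLDDataset`.
#' @param seed_ts numeric seed time-course, one value per volume.
#' @param target_mask_label mask to correlate over (default `"target"`).
#' @return named numeric vector of per-voxel r (names = voxel indices).
#' @export
voxelwise_seed_correlation <- function(bold, seed_ts,
                                       target_mask_label = "target") {
  stopifnot(inherits(bold, "BOLDDataset"))
  if (length(seed_ts) != ncol(bold$data)) {
    stopf("seed time-course length (%d) does not match volumes (%d)",
          length(seed_ts), ncol(bold$data))
  }
  idx <- bold$mask_labels[[target_mask_label]]
  if (is.null(idx) || length(idx) == 0L) {
    stopf("target mask '%s' is empty or absent", target_mask_label)
  }
  y <- bold$data[idx, , drop = FALSE]
  sds <- apply(y, 1, stats::sd)
  r <- rep(NA_real_, length(idx))
  ok <- sds > 0 & stats::sd(seed_ts) > 0
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(t(y[ok, , drop = FALSE]), seed_ts))
  }
  names(r) <- as.character(idx)
  r
}

#' Select salience-related and non-salience clusters from voxel correlations
#'
#' Applies the percentile + floor rules of [roi_config()] over the valid
#' (non-missing) correlations.  Percentiles use linear interpolation;
#' both rules are strict inequalities, so ties at a threshold are
#' excluded and the two clusters are disjoint by construction.
#'
#' @param voxel_r named numeric vector of per-voxel correlations (as
#'   returned by [voxelwise_seed_correlation()]); `NA` entries are
#'   excluded from both percentile computation and membership.
#' @param cfg an `ROISelectionConfig`.
#' @return an object of class `ROISelectionResult`: list with `voxel_r`,
#'   `salience_voxels` / `nonsalience_voxels` (integer voxel indices),
#'   `n_salience`, `n_nonsalience` and the realized `thresholds`.
#' @export
select_salience_clusters <- function(voxel_r, cfg = roi_config()) {
  stopifnot(inherits(cfg, "ROISelectionConfig"))
  valid <- !is.na(voxel_r)
  if (!any(valid)) stopf("all voxel correlations are missing")
  if (sum(valid) < 7L) {
    stopf("need at least 7 valid voxels for meaningful percentiles (have %d)",
          sum(valid))
  }
  rv <- voxel_r[valid]
  hi_cut <- pctile(rv, cfg$high_pctile)
  lo_cut <- pctile(rv, cfg$low_pctile)
  vox_ids <- if (is.null(names(voxel_r))) {
    seq_along(voxel_r)
  } else {
    as.integer(names(voxel_r))
  }
  sal <- valid & voxel_r > hi_cut & voxel_r > cfg$high_floor
  non <- valid & voxel_r < lo_cut & voxel_r < cfg$low_ceiling
  structure(list(voxel_r = voxel_r,
                 salience_voxels = vox_ids[which(sal)],
                 nonsalience_voxels = vox_ids[which(non)],
                 n_salience = sum(sal), n_nonsalience = sum(non),
                 thresholds = c(high_cut = hi_cut, low_cut = lo_cut,
                                high_floor = cfg$high_floor,
                                low_ceiling = cfg$low_ceiling)),
            class = "ROISelectionResult")
}

#' @export
print.ROISelectionResult <- function(x, ...) {
  cat(sprintf(paste0("ROISelectionResult: %d salience / %d non-salience of ",
                     "%d voxels (cuts: > %.3f & > %.2f ; < %.3f & < %.2f)\n"),
              x$n_salience, x$n_nonsalience, length(x$voxel_r),
              x$thresholds["high_cut"], x$thresholds["high_floor"],
              x$thresholds["low_cut"], x$thresholds["low_ceiling"]))
  invisible(x)
}

#' One-call ROI selection from a BOLD run and a seed
#'
#' Convenience wrapper: seed time-course, voxel-wise correlation, cluster
#' selection.  The selection run (the study uses the fear-clips block) is
#' intentionally a different dataset handle than the testing run.
#'
#' @param bold a `BOLDDataset` (the selection run).
#' @param seed a `SeedSpec`.
#' @param cfg an `ROISelectionConfig`.
#' @return an `ROISelectionResult`.
#' @export
select_rois <- function(bold, seed, cfg = roi_config()) {
  ts <- seed_timecourse(bold, seed)
  r <- voxelwise_seed_correlation(bold, ts, cfg$target_mask_label)
  select_salience_clusters(r, cfg)
}
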