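# Voxel-wise first-level regression of BOLD on an EFP regressor, group
# one-sample and paired tests, and Benjamini-Hochberg FDR correction.

#' Construct a BOLD dataset
#'
#' @param data numeric matrix, voxels x volumes (arbitrary units).
#' @param tr repetition time in seconds (> 0).
#' @param coords numeric matrix, voxels x 3, voxel-center coordinates in mm.
#' @param spacing_mm isotropic voxel spacing in mm.
#' @param mask_labels named list mapping a label to a voxel index vector
#'   (e.g. `list(target = 1:60, seed = 61:67)`).
#' @param subject_id label.
#' @return an object of class `BOLDDataset`.
#' @export
bold_dataset <- function(data, tr, coords, spacing_mm = 2.2,
                         mask_labels = list(target = seq_len(nrow(data))),
                         subject_id = "sub") {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stopf("need at least 2 volumes")
  if (!is_scalar_num(tr) || tr <= 0) stopf("tr must be > 0")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(data) || ncol(coords) != 3L) {
    stopf("coords must be voxels x 3")
  }
  if (!all(is.finite(data))) stopf("BOLD data must be finite")
  for (lb in names(mask_labels)) {
    idx <- mask_labels[[lb]]
    if (any(idx < 1 | idx > nrow(data))) {
      stopf("mask label '%s' indexes voxels outside the dataset", lb)
    }
  }
  structure(list(data = data, tr = tr, coords = coords,
                 spacing_mm = spacing_mm, mask_labels = mask_labels,
                 subject_id = subject_id),
            class = "BOLDDataset")
}

#' @export
print.BOLDDataset <- function(x, ...) {
  cat(sprintf("BOLDDataset '%s': %d voxels x %d volumes, TR %g s; masks: %s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              paste(sprintf("%s (%d)", names(x$mask_labels),
                            lengths(x$mask_labels)), collapse = ", ")))
  invisible(x)
}

#' First-level GLM configuration
#'
#' @param highpass_hz high-pass cutoff in Hz (default 0.001); drifts slower
#'   than this are removed by discrete-cosine regression.
#' @param detrend remove a per-voxel linear trend first (default TRUE).
#' @param demean subtract the per-voxel mean last (default TRUE).
#' @param efp_convolve_hrf convolve the EFP regressor with the canonical
#'   HRF before regression (default FALSE: the regression runs on the raw
#'   EFP, which is itself an estimate of BOLD).
#' @param standardize_efp z-score the EFP regressor so betas are
#'   comparable across models (default TRUE).
#' @return an object of class `GLMConfig`.
#' @export
glm_config <- function(highpass_hz = 0.001, detrend = TRUE, demean = TRUE,
                       efp_convolve_hrf = FALSE, standardize_efp = TRUE) {
  if (!is_scalar_num(highpass_hz) || highpass_hz < 0) {
    stopf("highpass_hz must be >= 0")
  }
  structure(list(highpass_hz = highpass_hz, detrend = detrend,
                 demean = demean, efp_convolve_hrf = efp_convolve_hrf,
                 standardize_efp = standardize_efp),
            class = "GLMConfig")
}

# Residualize the rows of y against the columns of basis (plus intercept).
.residualize_rows <- function(y, basis) {
  X <- cbind(1, basis)
  qx <- qr(X)
  t(qr.resid(qx, t(y)))
}

#' Prepare voxel signals for regression
#'
#' Per voxel, in order: remove a linear trend, remove discrete-cosine
#' drift components slower than `highpass_hz`, subtract the mean.
#'
#' @param bold a `BOLDDataset`.
#' @param cfg a `GLMConfig`.
#' @return a `BOLDDataset` with filtered data.
#' @export
prepare_voxel_signals <- function(bold, cfg = glm_config()) {
  stopifnot(inherits(bold, "BOLDDataset"), inherits(cfg, "GLMConfig"))
  n_vol <- ncol(bold$data)
  if (n_vol < 4L) stopf("need at least 4 volumes to filter")
  y <- bold$data
  tt <- seq_len(n_vol)
  if (isTRUE(cfg$detrend)) {
    y <- .residualize_rows(y, cbind(tt))
  }
  if (cfg$highpass_hz > 0) {
    run_s <- n_vol * bold$tr
    k_max <- floor(2 * run_s * cfg$highpass_hz)
    if (k_max >= 1) {
      dct <- vapply(seq_len(k_max), function(k) {
        cos(pi * k * (2 * (tt - 1) + 1) / (2 * n_vol))
      }, numeric(n_vol))
      y <- .residualize_rows(y, dct)
    }
  }
  if (isTRUE(cfg$demean)) y <- y - rowMeans(y)
  out <- bold
  out$data <- y
  out
}

#' Align an EFP time-course to volume acquisition times
#'
#' Volume `k` is acquired at `(k - 1) * tr`; each EFP timestamp is mapped
#' to the nearest volume.  Volumes earlier than the first EFP value (the
#' warm-up before one full EEG segment) are dropped.
#'
#' @param efp an `EFPTimecourse`.
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @return list with `values` (EFP regressor) and `volume_idx` (the
#'   matched volume indices), equal lengths.
#' @export
align_efp_to_volumes <- function(efp, n_volumes, tr) {
  stopifnot(inherits(efp, "EFPTimecourse"))
  t_e <- efp_times(efp)
  idx <- round(t_e / tr) + 1L
  keep <- idx >= 1L & idx <= n_volumes & !duplicated(idx)
  if (!any(keep)) stopf("no EFP values fall inside the run")
  list(values = efp$values[keep], volume_idx = idx[keep])
}

#' Per-subject effect map container
#' @keywords internal
effect_map <- function(beta, tstat, dof, subject_id, regressor_name) {
  structure(list(beta = beta, tstat = tstat, dof = dof,
                 subject_id = subject_id, regressor_name = regressor_name),
            class = "EffectMap")
}

#' Voxel-wise first-level regression of BOLD on an EFP regressor
#'
#' Prepares the voxel signals (detrend, high-pass, demean), aligns the EFP
#' to the volume grid, then fits per voxel the ordinary least-squares model
#' `BOLD ~ intercept + EFP` along the full time-course, returning the
#' per-voxel slope and its t statistic.
#'
#' @param bold a `BOLDDataset`.
#' @param efp an `EFPTimecourse` (or numeric vector already aligned one
#'   value per volume).
#' @param cfg a `GLMConfig`.
#' @param mask_label which mask to regress over (default `"target"`).
#' @return an `EffectMap` with `beta`, `tstat` (one per masked voxel,
#'   named by voxel index), and `dof = volumes - 2`.
#' @export
first_level_glm <- function(bold, efp, cfg = glm_config(),
                            mask_label = "target") {
  stopifnot(inherits(bold, "BOLDDataset"))
  idx <- bold$mask_labels[[mask_label]]
  if (is.null(idx)) stopf("no mask labelled '%s'", mask_label)
  prepared <- prepare_voxel_signals(bold, cfg)
  if (inherits(efp, "EFPTimecourse")) {
    if (isTRUE(cfg$efp_convolve_hrf)) {
      ker <- hrf_kernel(dt = efp$dt)
      full <- stats::convolve(efp$values, rev(ker$values), type = "open")
      efp$values <- full[seq_along(efp$values)] * efp$dt
    }
    al <- align_efp_to_volumes(efp, ncol(prepared$data), prepared$tr)
    x <- al$values
    y <- prepared$data[idx, al$volume_idx, drop = FALSE]
  } else {
    x <- as.numeric(efp)
    if (length(x) != ncol(prepared$data)) {
      stopf("regressor length (%d) does not match volumes (%d)",
            length(x), ncol(prepared$data))
    }
    y <- prepared$data[idx, , drop = FALSE]
  }
  if (stats::sd(x) == 0) stopf("EFP regressor has zero variance")
  if (isTRUE(cfg$standardize_efp)) x <- as.numeric(scale(x))
  n_t <- length(x)
  if (n_t < 4L) stopf("too few aligned volumes (%d) for regression", n_t)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- y - rowMeans(y)
  beta <- as.numeric(yc %*% xc) / sxx
  rss <- rowSums(yc^2) - beta^2 * sxx
  dof <- n_t - 2L
  sigma2 <- pmax(rss, 0) / dof
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, beta / se, 0)
  names(beta) <- names(tstat) <- as.character(idx)
  effect_map(beta, tstat, dof, bold$subject_id,
             if (inherits(efp, "EFPTimecourse")) efp$model_name else "efp")
}

# Shared machinery for the group tests: one-sample t on the columns of a
# subjects x voxels matrix, two-tailed p, BH-adjusted q, significance mask.
.group_t <- function(B, test, alpha) {
  n <- nrow(B)
  m <- colMeans(B)
  s2 <- (colSums(B^2) - n * m^2) / (n - 1)
  s2 <- pmax(s2, 0)
  s <- sqrt(s2)
  tol <- 1e-12
  degenerate <- s < tol
  tstat <- ifelse(degenerate, 0, m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  # degenerate across-subject variance: conservative convention, never
  # significant, flagged
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "BH")
  structure(list(t = tstat, p = p, q = q,
                 sig_mask = q <= alpha & !degenerate,
                 degenerate = degenerate,
                 test = test, alpha = alpha, n_subjects = n,
                 dof = n - 1L),
            class = "GroupStats")
}

#' @export
print.GroupStats <- function(x, ...) {
  cat(sprintf("GroupStats (%s, n = %d): %d voxels, %d significant at FDR %g\n",
              x$test, x$n_subjects, length(x$t), sum(x$sig_mask), x$alpha))
  invisible(x)
}

.beta_matrix <- function(maps) {
  vox <- names(maps[[1]]$beta)
  for (m in maps) {
    if (!identical(names(m$beta), vox)) {
      stopf("all effect maps must cover the same voxels in the same order")
    }
  }
  do.call(rbind, lapply(maps, function(m) m$beta))
}

#' Group-level one-sample t-test of effect maps
#'
#' Per voxel, a two-tailed one-sample t-test of the subject betas against
#' zero, with Benjamini-Hochberg FDR across voxels.  Voxels with zero
#' across-subject variance are flagged and never significant.
#'
#' @param maps list of `EffectMap` objects (>= 3 subjects) over a common
#'   voxel set.
#' @param alpha FDR level (default 0.05).
#' @return a `GroupStats` object with per-voxel `t`, `p`, `q`, `sig_mask`.
#' @export
group_one_sample <- function(maps, alpha = 0.05) {
  if (length(maps) < 3L) stopf("need at least 3 subjects")
  B <- .beta_matrix(maps)
  out <- .group_t(B, "one-sample", alpha)
  names(out$t) <- names(out$p) <- names(out$q) <- names(out$sig_mask) <-
    names(maps[[1]]$beta)
  out
}

#' Group-level paired contrast between two EFP effect maps
#'
#' Per voxel, a two-tailed paired t-test on the per-subject difference
#' `a - b` (e.g. Amyg-EFP minus VS-EFP maps), with BH FDR across voxels.
#' Directional masks are additionally thresholded at `alpha / 2` per
#' direction (0.025 at the default alpha), honoring the two-tailed display
#' convention.
#'
#' @param maps_a,maps_b lists of `EffectMap` objects from the same subjects
#'   in the same order.
#' @param alpha FDR level (default 0.05).
#' @return a `GroupStats` object with extra fields `sig_a_gt_b` and
#'   `sig_b_gt_a`.
#' @export
group_paired_contrast <- function(maps_a, maps_b, alpha = 0.05) {
  if (length(maps_a) != length(maps_b)) {
    stopf("the two map lists must have the same length")
  }
  if (length(maps_a) < 3L) stopf("need at least 3 subjects")
  ids_a <- vapply(maps_a, function(m) m$subject_id, character(1))
  ids_b <- vapply(maps_b, function(m) m$subject_id, character(1))
  if (!identical(ids_a, ids_b)) {
    stopf("subject ids differ between the two map lists")
  }
  D <- .beta_matrix(maps_a) - .beta_matrix(maps_b)
  out <- .group_t(D, "paired", alpha)
  out$sig_a_gt_b <- out$q <= alpha / 2 & out$t > 0
  out$sig_b_gt_a <- out$q <= alpha / 2 & out$t < 0
  names(out$t) <- names(out$p) <- names(out$q) <- names(out$sig_mask) <-
    names(maps_a[[1]]$beta)
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR over a p-value vector, optionally restricted to a subset of
#' entries (e.g. correcting only among amygdala voxels) -- entries outside
#' the subset are never rejected and get `NA` adjusted values.
#'
#' @param p p-values in [0, 1].
#' @param q_level FDR level (default 0.05).
#' @param subset optional index vector restricting the correction.
#' @return list with `reject` (logical) and `q` (BH-adjusted values).
#' @export
fdr_bh <- function(p, q_level = 0.05, subset = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  reject <- rep(FALSE, length(p))
  idx <- if (is.null(subset)) seq_along(p) else subset
  q[idx] <- stats::p.adjust(p[idx], method = "BH")
  reject[idx] <- q[idx] <= q_level
  list(reject = reject, q = q)
}
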