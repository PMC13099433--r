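# Nonparametric sliding-window correlation test: per-voxel window-averaged
# Pearson correlations between the EFP time-course and ROI BOLD, compared
# against a shuffled-window permutation null, with the per-subject
# above-chance decision (median of real > 95th percentile of null).

#' Sliding-window test configuration
#'
#' @param window_trs window length in TRs (the study sweeps 10, 20, 30,
#'   40, 50; default 30).
#' @param step_trs window step in TRs (default 1).
#' @param n_perm number of shuffled-window permutations (default 100).
#' @param chance_pctile percentile of the null defining chance level
#'   (default 95).
#' @param rng_seed master seed for the permutations.
#' @return an object of class `SWConfig`.
#' @export
sw_config <- function(window_trs = 30, step_trs = 1, n_perm = 100,
                      chance_pctile = 95, rng_seed = 1) {
  if (window_trs <= 2) stopf("window_trs must be > 2")
  if (step_trs < 1) stopf("step_trs must be >= 1")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  structure(list(window_trs = as.integer(window_trs),
                 step_trs = as.integer(step_trs),
                 n_perm = as.integer(n_perm),
                 chance_pctile = chance_pctile,
                 rng_seed = rng_seed),
            class = "SWConfig")
}

.as_efp_values <- function(efp) {
  if (inherits(efp, "EFPTimecourse")) efp$values else as.numeric(efp)
}

# Window start indices for a series of length n_t.
.window_starts <- function(n_t, w, step) {
  if (n_t < w) {
    stopf("series (%d TRs) shorter than the window (%d TRs)", n_t, w)
  }
  seq.int(1L, n_t - w + 1L, by = step)
}

# Matrix of standardized windows: column i holds the z-scored window
# starting at starts[i], divided by sqrt(w - 1) so that crossprod of two
# such columns is their Pearson r.  Zero-variance windows become all-zero
# columns (their r contributes 0) and are counted in attr "n_degenerate".
.window_zmat <- function(x, starts, w) {
  m <- vapply(starts, function(s) x[s:(s + w - 1L)], numeric(w))
  mu <- colMeans(m)
  m <- sweep(m, 2, mu, `-`)
  ss <- sqrt(colSums(m^2))
  degen <- ss < 1e-12
  ss[degen] <- 1
  m <- sweep(m, 2, ss, `/`)
  m[, degen] <- 0
  attr(m, "n_degenerate") <- sum(degen)
  m
}

#' Window-averaged sliding correlations per voxel
#'
#' For each voxel, Pearson correlations between the EFP and the voxel
#' series over every full window (starts 1, 1 + step, ...; e.g. window 1:
#' TRs 1-10, window 2: 2-11 at step 1), averaged across windows.
#' Zero-variance windows contribute r = 0 with a warning, identically in
#' the real and null computations.
#'
#' @param efp an `EFPTimecourse` or numeric vector, one value per TR,
#'   already aligned with the columns of `voxel_ts`.
#' @param voxel_ts numeric matrix, voxels x TRs.
#' @param cfg an `SWConfig`.
#' @return numeric vector of per-voxel window-mean r.
#' @export
sliding_window_corr <- function(efp, voxel_ts, cfg = sw_config()) {
  x <- .as_efp_values(efp)
  voxel_ts <- as.matrix(voxel_ts)
  if (length(x) != ncol(voxel_ts)) {
    stopf("EFP length (%d) does not match voxel series length (%d)",
          length(x), ncol(voxel_ts))
  }
  w <- cfg$window_trs
  starts <- .window_starts(length(x), w, cfg$step_trs)
  E <- .window_zmat(x, starts, w)
  n_degen <- attr(E, "n_degenerate")
  r <- vapply(seq_len(nrow(voxel_ts)), function(v) {
    Vz <- .window_zmat(voxel_ts[v, ], starts, w)
    n_degen <<- n_degen + attr(Vz, "n_degenerate")
    mean(colSums(E * Vz))
  }, numeric(1))
  if (n_degen > 0) {
    warning(sprintf("%d zero-variance window(s) contributed r = 0", n_degen),
            call. = FALSE)
  }
  r
}

#' Shuffled-window permutation null distribution
#'
#' Each permutation reassigns the intact EFP windows to the BOLD window
#' positions: the BOLD window at start `i` is paired with the unbroken EFP
#' window starting at `perm[i]`, where `perm` is a seeded random
#' permutation (without replacement) of all valid window starts -- windows
#' are shuffled, never the repetitions within a window.  Window-mean r per
#' voxel is computed exactly as in the real case, and all
#' `n_perm x n_voxels` values are pooled.
#'
#' @param efp an `EFPTimecourse` or numeric vector.
#' @param voxel_ts numeric matrix, voxels x TRs.
#' @param cfg an `SWConfig` (`n_perm`, `rng_seed` control the null).
#' @param perms optional list of explicit permutations of the window-start
#'   positions (test hook; overrides `n_perm` and the RNG).
#' @return numeric matrix, `n_perm` rows x `n_voxels` columns, of
#'   permuted window-mean r values.
#' @export
shuffle_windows_null <- function(efp, voxel_ts, cfg = sw_config(),
                                 perms = NULL) {
  x <- .as_efp_values(efp)
  voxel_ts <- as.matrix(voxel_ts)
  if (length(x) != ncol(voxel_ts)) {
    stopf("EFP length (%d) does not match voxel series length (%d)",
          length(x), ncol(voxel_ts))
  }
  w <- cfg$window_trs
  starts <- .window_starts(length(x), w, cfg$step_trs)
  n_s <- length(starts)
  if (is.null(perms)) {
    # one substream per permutation, derived from the master seed, so any
    # permutation can be regenerated independently
    perms <- lapply(seq_len(cfg$n_perm), function(k) {
      with_rng_seed(derive_seed(cfg$rng_seed, k), sample.int(n_s))
    })
  }
  E <- .window_zmat(x, starts, w)
  n_vox <- nrow(voxel_ts)
  null <- matrix(NA_real_, length(perms), n_vox)
  for (v in seq_len(n_vox)) {
    Vz <- .window_zmat(voxel_ts[v, ], starts, w)
    M <- crossprod(E, Vz)  # M[j, i] = r(EFP window j, voxel window i)
    for (k in seq_along(perms)) {
      null[k, v] <- mean(M[cbind(perms[[k]], seq_len(n_s))])
    }
  }
  null
}

#' Run the sliding-window test for one subject-ROI
#'
#' Computes the real distribution (window-mean r across ROI voxels), the
#' shuffled-window null of size `n_perm x n_voxels`, the chance level
#' (95th percentile of the pooled null) and the above-chance decision
#' (median of the real distribution strictly above chance level).
#'
#' @param efp an `EFPTimecourse` or numeric vector, one value per TR.
#' @param voxel_ts numeric matrix, ROI voxels x TRs.
#' @param cfg an `SWConfig`.
#' @return an object of class `SWTestResult`: list with `real_dist`,
#'   `null_dist` (length `n_perm * n_voxels`), `real_median`,
#'   `chance_level`, `above_chance`, `window_trs`, `n_voxels`, `n_perm`,
#'   and `display_real_scale = 100` (the factor applied to real-frequency
#'   histograms for display only; it never enters the decision).
#' @export
sw_test <- function(efp, voxel_ts, cfg = sw_config()) {
  real <- suppressWarnings(sliding_window_corr(efp, voxel_ts, cfg))
  null <- shuffle_windows_null(efp, voxel_ts, cfg)
  res <- structure(list(real_dist = real,
                        null_dist = as.numeric(null),
                        real_median = stats::median(real),
                        chance_level = pctile(as.numeric(null),
                                              cfg$chance_pctile),
                        above_chance = NA,
                        window_trs = cfg$window_trs,
                        n_voxels = nrow(as.matrix(voxel_ts)),
                        n_perm = nrow(null),
                        chance_pctile = cfg$chance_pctile,
                        display_real_scale = 100L),
                   class = "SWTestResult")
  res$above_chance <- above_chance_decision(res)
  res
}

#' Above-chance decision for a sliding-window test result
#'
#' `TRUE` when the median of the real distribution exceeds the
#' `chance_pctile` (default 95th) percentile of the null distribution.
#'
#' @param result an `SWTestResult` with populated distributions.
#' @return logical.
#' @export
above_chance_decision <- function(result) {
  stopifnot(inherits(result, "SWTestResult"))
  if (length(result$real_dist) == 0L || length(result$null_dist) == 0L) {
    stopf("real and null distributions must be non-empty")
  }
  stats::median(result$real_dist) >
    pctile(result$null_dist, result$chance_pctile)
}

#' @export
print.SWTestResult <- function(x, ...) {
  cat(sprintf(paste0("SWTestResult (w = %d TR, %d voxels, %d perms): ",
                     "median r = %.4f, chance = %.4f -> %s\n"),
              x$window_trs, x$n_voxels, x$n_perm, x$real_median,
              x$chance_level,
              if (x$above_chance) "above chance" else "not above chance"))
  invisible(x)
}

#' Sliding-window test across a sweep of window sizes
#'
#' @param efp an `EFPTimecourse` or numeric vector.
#' @param voxel_ts numeric matrix, ROI voxels x TRs.
#' @param windows integer vector of window sizes in TRs
#'   (default `c(10, 20, 30, 40, 50)`).
#' @param cfg an `SWConfig` supplying step, permutation count and seed.
#' @return named list mapping each window size to its `SWTestResult`.
#' @export
window_sweep <- function(efp, voxel_ts, windows = c(10, 20, 30, 40, 50),
                         cfg = sw_config()) {
  out <- lapply(windows, function(w) {
    cfg_w <- cfg
    cfg_w$window_trs <- as.integer(w)
    sw_test(efp, voxel_ts, cfg_w)
  })
  names(out) <- as.character(windows)
  out
}

#' Fraction of subjects above chance, per window size
#'
#' Cohort-level summary of [window_sweep()] results: the proportion of
#' subjects whose ROI was above chance at each window size (the quantity
#' reported per functional cluster in the study).
#'
#' @param sweeps list (one element per subject) of [window_sweep()] results.
#' @return named numeric vector, one fraction per window size.
#' @export
above_chance_fraction <- function(sweeps) {
  if (length(sweeps) == 0L) stopf("no subjects supplied")
  windows <- names(sweeps[[1]])
  vapply(windows, function(w) {
    mean(vapply(sweeps, function(s) s[[w]]$above_chance, logical(1)))
  }, numeric(1))
}
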