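# Cohort-level validation utilities: recovery of planted coupling by the
# GLM chain, discrimination of coupled vs null ROIs by the sliding-window
# test, calibration of the permutation null, and recovery of the
# behavioral reactivity coupling.  These drive the package's self-checks
# and are exported so users can benchmark alternative settings.

#' GLM recovery on a synthetic cohort
#'
#' Runs the full chain -- EFP from each subject's EEG, first-level GLM,
#' group one-sample test with FDR -- and scores it against the generator's
#' ground truth: sensitivity is the fraction of truly coupled voxels in
#' the significance mask, the false-positive rate the fraction of
#' uncoupled voxels flagged.
#'
#' @param cohort a list of `SyntheticSubject` objects
#'   (see [simulate_cohort()]).
#' @param model an `EFPModel` (default: the bundled demo model).
#' @param cfg a `GLMConfig`.
#' @param alpha FDR level (default 0.05).
#' @return list with `sensitivity`, `false_positive_rate`, `group` (the
#'   `GroupStats`), and `efps` (per-subject EFP time-courses, reusable by
#'   [sw_discrimination()]).
#' @export
glm_recovery <- function(cohort, model = demo_efp_model(),
                         cfg = glm_config(), alpha = 0.05) {
  efps <- lapply(cohort, function(s) {
    compute_efp_timecourse(s$eeg, model, stride_s = s$bold$tr)
  })
  maps <- lapply(seq_along(cohort), function(i) {
    first_level_glm(cohort[[i]]$bold, efps[[i]], cfg)
  })
  group <- group_one_sample(maps, alpha = alpha)
  coupled <- as.character(cohort[[1]]$truth$coupled)
  target <- as.character(cohort[[1]]$bold$mask_labels$target)
  uncoupled <- setdiff(target, coupled)
  list(sensitivity = mean(group$sig_mask[coupled]),
       false_positive_rate = mean(group$sig_mask[uncoupled]),
       group = group, efps = efps)
}

#' Sliding-window discrimination of coupled vs null ROIs
#'
#' For each subject, runs the sliding-window permutation test over the
#' truth-coupled voxel set and over an equally sized uncoupled (null) set,
#' for every requested window size, and reports the cohort above-chance
#' fractions per window and ROI type.
#'
#' @param cohort a list of `SyntheticSubject` objects.
#' @param efps per-subject `EFPTimecourse` list (e.g. from
#'   [glm_recovery()]).
#' @param windows window sizes in TRs (default `c(10, 20, 30, 40, 50)`).
#' @param n_perm permutations per test (default 100).
#' @param rng_seed master seed for the permutation substreams.
#' @return list with `frac_coupled` and `frac_null`, named numeric vectors
#'   over window sizes.
#' @export
sw_discrimination <- function(cohort, efps,
                              windows = c(10, 20, 30, 40, 50),
                              n_perm = 100, rng_seed = 1) {
  sweeps <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    al <- align_efp_to_volumes(efps[[i]], ncol(s$bold$data), s$bold$tr)
    coupled <- s$truth$coupled
    uncoupled <- setdiff(s$bold$mask_labels$target, coupled)
    null_set <- uncoupled[seq_len(min(length(coupled), length(uncoupled)))]
    cfg <- sw_config(n_perm = n_perm,
                     rng_seed = derive_seed(rng_seed, i))
    list(coupled = window_sweep(al$values,
                                s$bold$data[coupled, al$volume_idx,
                                            drop = FALSE],
                                windows = windows, cfg = cfg),
         null = window_sweep(al$values,
                             s$bold$data[null_set, al$volume_idx,
                                         drop = FALSE],
                             windows = windows, cfg = cfg))
  })
  list(frac_coupled = above_chance_fraction(lapply(sweeps, `[[`, "coupled")),
       frac_null = above_chance_fraction(lapply(sweeps, `[[`, "null")))
}

#' Empirical false-positive rate of the sliding-window decision
#'
#' Monte-Carlo calibration of the above-chance decision under the null:
#' ROIs of `n_voxels` independent white-noise voxels tested against a
#' white-noise EFP that is independent of them.  The nominal rate of the
#' median-vs-95th-percentile rule is 5%; the empirical rate also depends
#' on the ROI size (see the methods vignette).
#'
#' @param n_rois number of null ROIs (default 200).
#' @param n_voxels voxels per ROI (default 40, the scale of a functional
#'   amygdala cluster).
#' @param n_volumes series length in TRs (default 400).
#' @param window_trs window size (default 30).
#' @param n_perm permutations per ROI (default 100).
#' @param rng_seed master seed.
#' @return the empirical above-chance rate (scalar in [0, 1]).
#' @export
sw_null_calibration <- function(n_rois = 200, n_voxels = 40,
                                n_volumes = 400, window_trs = 30,
                                n_perm = 100, rng_seed = 1) {
  decisions <- vapply(seq_len(n_rois), function(i) {
    dat <- with_rng_seed(derive_seed(rng_seed, i), {
      list(vox = matrix(stats::rnorm(n_voxels * n_volumes), n_voxels),
           efp = stats::rnorm(n_volumes))
    })
    sw_test(dat$efp, dat$vox,
            sw_config(window_trs = window_trs, n_perm = n_perm,
                      rng_seed = derive_seed(rng_seed, 100000 + i))
    )$above_chance
  }, logical(1))
  mean(decisions)
}

#' Recovery rate of the reactivity-EFP coupling across cohorts
#'
#' Simulates `n_cohorts` behavioral cohorts with a positive rating slope
#' and shared scene-arousal gains, runs the reactivity chain on each, and
#' reports the fraction of cohorts in which the cross-subject
#' reactivity-EFP correlation comes out positive.
#'
#' @param n_cohorts number of cohorts (default 100).
#' @param n_subjects subjects per cohort (default 60).
#' @param spec a `CouplingSpec` with `rating_slope > 0`.
#' @param rng_seed master seed.
#' @return list with `frac_positive` and `r` (the per-cohort correlations).
#' @export
reactivity_recovery <- function(n_cohorts = 100, n_subjects = 60,
                                spec = coupling_spec(), rng_seed = 1) {
  r <- vapply(seq_len(n_cohorts), function(i) {
    beh <- simulate_reactivity_cohort(n_subjects, spec = spec,
                                      rng_seed = derive_seed(rng_seed, i))
    correlate_reactivity_efp(reactivity_cohort_table(beh))$r
  }, numeric(1))
  list(frac_positive = mean(r > 0), r = r)
}
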