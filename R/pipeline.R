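# End-to-end orchestration: simulate (optional) -> EFP -> GLM -> ROI
# selection -> sliding-window test -> reactivity, with a JSON manifest
# recording seeds, configuration and per-stage outputs.

#' Pipeline configuration
#'
#' @param n_subjects cohort size for the simulation stage (default 6).
#' @param duration_s main-run duration in seconds (default 300).
#' @param n_voxels target-mask voxels per subject (default 40).
#' @param fs EEG sampling rate in Hz (default 125; the EFP band span ends
#'   at 40 Hz, well under Nyquist).
#' @param tr repetition time in seconds (default 1.5).
#' @param master_seed master integer seed for every random stage.
#' @param template a `CouplingSpec` for the simulated cohort.
#' @param model an `EFPModel`, or a path to a model JSON file, or `NULL`
#'   for the bundled demo model.
#' @param glm a `GLMConfig`.
#' @param roi an `ROISelectionConfig`.
#' @param sw an `SWConfig` (its `rng_seed` is re-derived from
#'   `master_seed` per subject).
#' @param sw_windows window sizes for the sweep (default 30).
#' @param out_dir output directory (`NULL`: nothing written).
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(n_subjects = 6, duration_s = 300, n_voxels = 40,
                            fs = 125, tr = 1.5, master_seed = 1,
                            template = coupling_spec(), model = NULL,
                            glm = glm_config(), roi = roi_config(),
                            sw = sw_config(), sw_windows = 30,
                            out_dir = NULL) {
  structure(list(n_subjects = n_subjects, duration_s = duration_s,
                 n_voxels = n_voxels, fs = fs, tr = tr,
                 master_seed = master_seed, template = template,
                 model = model, glm = glm, roi = roi, sw = sw,
                 sw_windows = sw_windows, out_dir = out_dir),
            class = "PipelineConfig")
}

.resolve_model <- function(model) {
  if (is.null(model)) return(demo_efp_model())
  if (inherits(model, "EFPModel")) return(model)
  if (is.character(model)) {
    if (!file.exists(model)) {
      stopf("EFP model file '%s' does not exist", model)
    }
    return(read_efp_model(model))
  }
  stopf("model must be an EFPModel, a file path, or NULL")
}

#' Run the full coupling pipeline on a simulated cohort
#'
#' Stages: simulate the cohort; compute each subject's EFP time-course
#' from their EEG; first-level GLM of BOLD on the EFP with a group
#' one-sample test and FDR; per-subject ROI selection from seed
#' coactivation; sliding-window permutation tests in the salience and
#' non-salience clusters; behavioral reactivity coupling on a matching
#' rating cohort.  Any stage failure aborts with the failing stage named.
#'
#' @param cfg a `PipelineConfig`.
#' @return a run manifest: list with per-stage results (`cohort_betas`,
#'   `group`, `roi`, `sw_fractions`, `reactivity`) and `meta` (seed,
#'   config hash, package version, timing).  Written as
#'   `manifest.json` plus per-stage TSV/JSON files when `out_dir` is set.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  t_start <- Sys.time()
  model <- .resolve_model(cfg$model)   # validated before any computation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  subjects <- stage("simulate", {
    simulate_cohort(cfg$n_subjects, template = cfg$template,
                    rng_seed = cfg$master_seed,
                    duration_s = cfg$duration_s, n_voxels = cfg$n_voxels,
                    fs = cfg$fs, tr = cfg$tr)
  })

  efps <- stage("efp", {
    lapply(subjects, function(s) {
      compute_efp_timecourse(s$eeg, model, stride_s = cfg$tr)
    })
  })

  maps <- stage("glm", {
    lapply(seq_along(subjects), function(i) {
      first_level_glm(subjects[[i]]$bold, efps[[i]], cfg$glm)
    })
  })
  group <- stage("glm", group_one_sample(maps))

  rois <- stage("roi", {
    lapply(subjects, function(s) {
      seed <- seed_spec(s$truth$seed_center_mm, s$truth$seed_radius_mm,
                        label = "salience-seed")
      select_rois(s$bold, seed, cfg$roi)
    })
  })

  sw_res <- stage("swtest", {
    lapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      al <- align_efp_to_volumes(efps[[i]], ncol(s$bold$data), s$bold$tr)
      cfg_sw <- cfg$sw
      cfg_sw$rng_seed <- derive_seed(cfg$master_seed, 500 + i)
      lapply(list(salience = rois[[i]]$salience_voxels,
                  nonsalience = rois[[i]]$nonsalience_voxels),
             function(vox) {
               if (length(vox) == 0L) return(NULL)
               window_sweep(al$values,
                            s$bold$data[vox, al$volume_idx, drop = FALSE],
                            windows = cfg$sw_windows, cfg = cfg_sw)
             })
    })
  })
  sw_fractions <- lapply(c(salience = "salience", nonsalience = "nonsalience"),
                         function(cl) {
    sweeps <- Filter(Negate(is.null), lapply(sw_res, `[[`, cl))
    if (length(sweeps) == 0L) return(NULL)
    above_chance_fraction(sweeps)
  })

  reactivity <- stage("reactivity", {
    beh <- simulate_reactivity_cohort(
      n_subjects = max(cfg$n_subjects, 4L),
      spec = cfg$template,
      rng_seed = derive_seed(cfg$master_seed, 900))
    tab <- reactivity_cohort_table(beh)
    list(tests = scene_difference_tests(tab),
         coupling = correlate_reactivity_efp(tab))
  })

  manifest <- list(
    meta = list(package = "efpcouple",
                version = as.character(utils::packageVersion("efpcouple")),
                master_seed = cfg$master_seed,
                config_hash = rlang::hash(cfg),
                model_name = model$name,
                elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                units = "secs"))),
    cohort_betas = as.numeric(attr(subjects, "subject_betas")),
    group = list(n_sig = sum(group$sig_mask),
                 n_voxels = length(group$sig_mask),
                 mean_beta_sig = if (any(group$sig_mask)) {
                   mean(colMeans(.beta_matrix(maps))[group$sig_mask])
                 } else NA_real_),
    roi = list(n_salience = vapply(rois, function(r) r$n_salience,
                                   numeric(1)),
               n_nonsalience = vapply(rois, function(r) r$n_nonsalience,
                                      numeric(1))),
    sw_fractions = sw_fractions,
    reactivity = list(
      rating_t = reactivity$tests$paired_t_ratings$t,
      rating_p = reactivity$tests$paired_t_ratings$p,
      efp_t = reactivity$tests$paired_t_efp$t,
      efp_p = reactivity$tests$paired_t_efp$p,
      r = reactivity$coupling$r,
      r_p = reactivity$coupling$p))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    utils::write.table(
      data.frame(voxel = names(group$t), t = group$t, p = group$p,
                 q = group$q, significant = group$sig_mask),
      file.path(cfg$out_dir, "group_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(efps)) {
      write_efp_tsv(efps[[i]], file.path(
        cfg$out_dir, sprintf("%s_efp.tsv", subjects[[i]]$subject_id)))
    }
  }
  manifest
}
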