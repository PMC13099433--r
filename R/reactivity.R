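# Emotional-reactivity indices from continuous 1-7 ratings and their
# cross-subject coupling with EFP amplitude differences between scenes.

#' Construct a continuous rating trace
#'
#' @param t sample times in seconds, ascending.
#' @param values ratings on the 1-7 scale (4 = no emotional reaction).
#' @param scene scene label.
#' @param subject_id subject label.
#' @return an object of class `RatingTrace`.
#' @export
rating_trace <- function(t, values, scene = "scene", subject_id = "sub") {
  if (length(t) != length(values) || length(t) == 0L) {
    stopf("t and values must be equal-length, non-empty")
  }
  if (any(diff(t) <= 0)) stopf("t must be strictly ascending")
  if (any(!is.finite(values)) || any(values < 1 | values > 7)) {
    stopf("ratings must lie within [1, 7]")
  }
  structure(list(t = as.numeric(t), values = as.numeric(values),
                 scene = scene, subject_id = subject_id),
            class = "RatingTrace")
}

#' Emotional reactivity index of a rating trace
#'
#' Ratings are centered at the neutral anchor 4, converted to absolute
#' emotional reactivity (absolute distance from neutral) and averaged
#' across the timeline.  Irregularly sampled traces are first
#' step-resampled onto a uniform grid (sample-and-hold at the smallest
#' sampling interval) so that long-held ratings weigh by their duration;
#' uniformly sampled traces are used as-is.
#'
#' @param trace a `RatingTrace`.
#' @return scalar reactivity index (>= 0).
#' @export
reactivity_index <- function(trace) {
  stopifnot(inherits(trace, "RatingTrace"))
  v <- trace$values
  t <- trace$t
  if (length(v) > 2L) {
    d <- diff(t)
    if (max(d) - min(d) > 1e-9 * stats::median(d)) {
      span <- t[length(t)] - t[1]
      dt <- max(min(d), span / 1e5)
      grid <- seq(t[1], t[length(t)], by = dt)
      v <- stats::approx(t, v, xout = grid, method = "constant",
                         rule = 2)$y
    }
  }
  mean(abs(v - 4))
}

#' Mean EFP amplitude over a scene window
#'
#' Mean of the EFP values whose timestamps fall inside
#' `[window[1], window[2]]` (raw mean; `absolute = TRUE` averages
#' magnitudes instead).
#'
#' @param efp an `EFPTimecourse`.
#' @param window `c(t_start, t_end)` in seconds.
#' @param absolute average `|value|` instead of the raw values
#'   (default FALSE).
#' @return scalar mean amplitude.
#' @export
efp_amplitude <- function(efp, window, absolute = FALSE) {
  stopifnot(inherits(efp, "EFPTimecourse"))
  if (length(window) != 2L || window[2] < window[1]) {
    stopf("window must be c(t_start, t_end) with t_end >= t_start")
  }
  tt <- efp_times(efp)
  idx <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  if (!any(idx)) stopf("no EFP values fall inside the window")
  v <- efp$values[idx]
  if (absolute) mean(abs(v)) else mean(v)
}

# Assemble the per-subject, per-scene table the cohort tests consume.
.complete_scene_table <- function(cohort, scene_a, scene_b) {
  stopifnot(is.data.frame(cohort),
            all(c("subject", "scene", "rating_index", "efp_amp") %in%
                  names(cohort)))
  have <- table(cohort$subject[cohort$scene %in% c(scene_a, scene_b)])
  complete <- names(have)[have == 2L]
  dropped <- setdiff(unique(cohort$subject), complete)
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d subject(s) missing a scene: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  a <- cohort[cohort$scene == scene_a & cohort$subject %in% complete, ]
  b <- cohort[cohort$scene == scene_b & cohort$subject %in% complete, ]
  a <- a[order(a$subject), ]
  b <- b[order(b$subject), ]
  data.frame(subject = a$subject,
             rating_diff = b$rating_index - a$rating_index,
             efp_diff = b$efp_amp - a$efp_amp,
             stringsAsFactors = FALSE)
}

# Paired t via stats::t.test, with a defined convention when all
# differences are identical (zero variance): t = 0 / p = 1 if the common
# difference is 0, otherwise an infinite statistic with p = 0.
.paired_t <- function(d) {
  n <- length(d)
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) return(list(t = 0, p = 1, dof = n - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, dof = n - 1))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       dof = unname(tt$parameter))
}

#' Paired scene-difference tests across subjects
#'
#' Two-tailed paired t-tests, across subjects, of (i) the reactivity-index
#' difference and (ii) the EFP-amplitude difference between two scenes
#' (convention: `scene_b` minus `scene_a`, i.e. Snakes minus Farewell by
#' default).  Subjects missing a scene are dropped with a warning.
#'
#' @param cohort a `data.frame` with columns `subject`, `scene`,
#'   `rating_index`, `efp_amp` (one row per subject x scene; see
#'   [reactivity_cohort_table()]).
#' @param scene_a,scene_b scene labels (defaults `"farewell"`, `"snakes"`).
#' @return an object of class `ReactivityResult`: list with `diffs` (the
#'   per-subject difference table), `paired_t_ratings` and `paired_t_efp`
#'   (each `list(t, p, dof)`), and `n_subjects`.
#' @export
scene_difference_tests <- function(cohort, scene_a = "farewell",
                                   scene_b = "snakes") {
  d <- .complete_scene_table(cohort, scene_a, scene_b)
  if (nrow(d) < 3L) stopf("need at least 3 subjects with both scenes")
  structure(list(diffs = d,
                 paired_t_ratings = .paired_t(d$rating_diff),
                 paired_t_efp = .paired_t(d$efp_diff),
                 scene_a = scene_a, scene_b = scene_b,
                 n_subjects = nrow(d)),
            class = "ReactivityResult")
}

#' @export
print.ReactivityResult <- function(x, ...) {
  cat(sprintf(paste0("ReactivityResult (%s - %s, n = %d): ratings ",
                     "T = %.2f (p = %.3g); EFP amplitude T = %.2f ",
                     "(p = %.3g)\n"),
              x$scene_b, x$scene_a, x$n_subjects,
              x$paired_t_ratings$t, x$paired_t_ratings$p,
              x$paired_t_efp$t, x$paired_t_efp$p))
  invisible(x)
}

#' Cross-subject correlation of reactivity and EFP scene differences
#'
#' Pearson correlation, across subjects, between the per-subject
#' reactivity-index difference and EFP-amplitude difference between the
#' two scenes, with its two-tailed p-value.
#'
#' @param cohort a cohort table as in [scene_difference_tests()], or a
#'   `ReactivityResult`.
#' @param scene_a,scene_b scene labels (ignored when a `ReactivityResult`
#'   is given).
#' @return list with `r`, `p`, `n_subjects`.
#' @export
correlate_reactivity_efp <- function(cohort, scene_a = "farewell",
                                     scene_b = "snakes") {
  d <- if (inherits(cohort, "ReactivityResult")) {
    cohort$diffs
  } else {
    .complete_scene_table(cohort, scene_a, scene_b)
  }
  if (nrow(d) < 4L) stopf("need at least 4 subjects with complete data")
  if (stats::sd(d$rating_diff) == 0 || stats::sd(d$efp_diff) == 0) {
    stopf("zero variance in a difference vector; correlation undefined")
  }
  ct <- stats::cor.test(d$rating_diff, d$efp_diff)
  list(r = unname(ct$estimate), p = ct$p.value, n_subjects = nrow(d))
}

#' Build the cohort table from simulated (or loaded) subject data
#'
#' Computes, per subject and scene, the reactivity index of the rating
#' trace and the mean EFP amplitude over the scene (full trace by default,
#' or a scene window per scene).
#'
#' @param subjects list with per-subject `ratings` and `efp` named lists
#'   over scenes, as produced by [simulate_reactivity_cohort()].
#' @param windows optional named list mapping scene to a
#'   `c(t_start, t_end)` window for the EFP amplitude; by default each
#'   scene's full EFP trace is averaged.
#' @param absolute passed to [efp_amplitude()].
#' @return a `data.frame` with columns `subject`, `scene`, `rating_index`,
#'   `efp_amp`.
#' @export
reactivity_cohort_table <- function(subjects, windows = NULL,
                                    absolute = FALSE) {
  rows <- lapply(subjects, function(s) {
    scenes <- names(s$ratings)
    do.call(rbind, lapply(scenes, function(sc) {
      efp <- s$efp[[sc]]
      win <- if (!is.null(windows) && !is.null(windows[[sc]])) {
        windows[[sc]]
      } else {
        range(efp_times(efp))
      }
      data.frame(subject = s$subject_id, scene = sc,
                 rating_index = reactivity_index(s$ratings[[sc]]),
                 efp_amp = efp_amplitude(efp, win, absolute = absolute),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
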