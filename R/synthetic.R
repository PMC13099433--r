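# Synthetic EEG-fMRI cohort generator.  Emulates the statistical structure
# the analysis assumes -- a slow latent arousal drive, EEG whose band power
# tracks it, BOLD voxels coupled to its HRF convolution with AR(1) noise,
# an insula-like seed co-fluctuating with a salience subset of target
# voxels, and 1-7 ratings tied to the latent -- with known ground truth for
# recovery tests.

#' Latent arousal trace
#'
#' Low-pass-filtered Gaussian noise, demeaned and scaled to unit variance:
#' a stand-in for the slow emotional drive evoked by naturalistic stimuli.
#'
#' @param duration_s trace duration in seconds (>= 10 * dt).
#' @param dt seconds per sample (default 0.25).
#' @param cutoff_hz low-pass cutoff in Hz (default 0.1); lower cutoffs give
#'   smoother, more autocorrelated traces.
#' @param rng_seed integer seed; identical arguments give identical traces.
#' @param label trace label.
#' @return an object of class `LatentTrace`: list with `values`, `dt`,
#'   `label`.
#' @export
make_latent <- function(duration_s, dt = 0.25, cutoff_hz = 0.1, rng_seed = 1,
                        label = "latent") {
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stopf("duration_s must be > 0")
  }
  if (!is_scalar_num(dt) || dt <= 0) stopf("dt must be > 0")
  if (duration_s < 10 * dt) stopf("duration_s must be at least 10 * dt")
  fs <- 1 / dt
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stopf("cutoff_hz must lie inside (0, 1/(2 dt))")
  }
  n <- round(duration_s / dt)
  v <- with_rng_seed(rng_seed, {
    lp <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
    .butter_filtfilt(stats::rnorm(n), lp)
  })
  v <- v - mean(v)
  s <- stats::sd(v)
  if (s > 0) v <- v / s
  structure(list(values = v, dt = dt, label = label), class = "LatentTrace")
}

#' Coupling specification (synthetic ground truth)
#'
#' The effect sizes the downstream analysis should recover.
#'
#' @param beta_bold BOLD units per unit of HRF-convolved latent (default 0.5).
#' @param ar1_phi lag-1 autoregression of voxel noise, in (-1, 1)
#'   (default 0.3).
#' @param noise_sd marginal standard deviation of voxel noise (default 1).
#' @param frac_coupled_voxels fraction of target voxels coupled to the
#'   latent, in [0, 1] (default 0.3).
#' @param seed_coupling_r amplitude (in SD units) of the shared
#'   salience-network fluctuation linking coupled voxels to the seed
#'   region, in [-1, 1] (default 0.6).
#' @param rating_slope rating units per latent unit (default 1).
#' @param rating_noise_sd rating noise SD (default 0.5).
#' @return an object of class `CouplingSpec`.
#' @export
coupling_spec <- function(beta_bold = 0.5, ar1_phi = 0.3, noise_sd = 1,
                          frac_coupled_voxels = 0.3, seed_coupling_r = 0.6,
                          rating_slope = 1, rating_noise_sd = 0.5) {
  vals <- c(beta_bold, ar1_phi, noise_sd, frac_coupled_voxels,
            seed_coupling_r, rating_slope, rating_noise_sd)
  if (!all(is.finite(vals))) stopf("all coupling fields must be finite")
  if (abs(ar1_phi) >= 1) stopf("ar1_phi must lie inside (-1, 1)")
  if (noise_sd < 0 || rating_noise_sd < 0) stopf("noise SDs must be >= 0")
  if (frac_coupled_voxels < 0 || frac_coupled_voxels > 1) {
    stopf("frac_coupled_voxels must lie in [0, 1]")
  }
  if (abs(seed_coupling_r) > 1) stopf("seed_coupling_r must lie in [-1, 1]")
  structure(list(beta_bold = beta_bold, ar1_phi = ar1_phi,
                 noise_sd = noise_sd,
                 frac_coupled_voxels = frac_coupled_voxels,
                 seed_coupling_r = seed_coupling_r,
                 rating_slope = rating_slope,
                 rating_noise_sd = rating_noise_sd),
            class = "CouplingSpec")
}

#' Canonical double-gamma HRF kernel
#'
#' Difference of two gamma densities (response peak ~6 s, undershoot ~16 s,
#' undershoot ratio 1/6) on a 32-s support, scaled to unit area so that
#' convolution preserves the scale of a slow input.
#'
#' @param dt kernel sampling interval in seconds (default 0.25).
#' @param peak,undershoot gamma shape parameters (rate 1) for response and
#'   undershoot (defaults 6 and 16).
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @param duration_s kernel support in seconds (default 32).
#' @return list of class `HRFKernel` with `values` and `dt`.
#' @export
hrf_kernel <- function(dt = 0.25, peak = 6, undershoot = 16, ratio = 1 / 6,
                       duration_s = 32) {
  t <- seq(0, duration_s, by = dt)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h <- h / (sum(h) * dt)
  structure(list(values = h, dt = dt), class = "HRFKernel")
}

#' Convolve a latent trace with an HRF kernel
#'
#' @param latent a `LatentTrace`.
#' @param hrf an `HRFKernel` sampled at the latent's `dt`.
#' @return numeric vector, same length as the latent.
#' @export
hrf_convolve <- function(latent, hrf = hrf_kernel(dt = latent$dt)) {
  stopifnot(inherits(latent, "LatentTrace"), inherits(hrf, "HRFKernel"))
  if (abs(latent$dt - hrf$dt) > 1e-9) {
    stopf("HRF kernel dt (%g) must match the latent dt (%g)",
          hrf$dt, latent$dt)
  }
  n <- length(latent$values)
  full <- stats::convolve(latent$values, rev(hrf$values), type = "open")
  full[seq_len(n)] * latent$dt
}

# Resample an HRF-convolved latent at volume acquisition times k * tr.
.latent_to_volumes <- function(latent, n_volumes, tr,
                               hrf = hrf_kernel(dt = latent$dt)) {
  x <- hrf_convolve(latent, hrf)
  t_lat <- (seq_along(x) - 1) * latent$dt
  t_vol <- (seq_len(n_volumes) - 1) * tr
  stats::approx(t_lat, x, xout = t_vol, rule = 2)$y
}

# Stationary AR(1) noise with marginal sd `sd` and lag-1 coefficient `phi`
# (uses the ambient RNG stream).
.ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, sd = sd))
  burn <- 50L
  e <- stats::rnorm(n + burn, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))[(burn + 1):(burn + n)]
}

# Analytic signal via FFT (for envelope normalization of the EEG carrier).
.analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Simulate EEG whose band power tracks a latent trace
#'
#' The carrier is band-limited Gaussian noise in `carrier_band`, normalized
#' to constant instantaneous envelope, then amplitude-modulated by
#' `1 + mod_depth * latent` (floored at a small positive value), so the
#' quarter-second power envelope in the carrier band follows the latent.
#' Broadband white noise is added on top.  Two channels are emitted: the
#' active derivation channel carrying the signal and a reference channel
#' carrying only weak noise, matching the bipolar derivation the EFP uses.
#'
#' @param latent a `LatentTrace`.
#' @param fs EEG sampling rate in Hz (default 250).
#' @param carrier_band `[f_lo, f_hi]` Hz, inside `(0, fs/2)` (default 4-8).
#' @param noise_sd broadband noise SD relative to unit carrier amplitude
#'   (default 0.5).
#' @param mod_depth amplitude-modulation depth per latent unit (default 0.5).
#' @param rng_seed integer seed.
#' @param channels labels for the two emitted channels
#'   (default `c("Pz", "FCz")`).
#' @return an `EEGRecording`.
#' @export
simulate_eeg <- function(latent, fs = 250, carrier_band = c(4, 8),
                         noise_sd = 0.5, mod_depth = 0.5, rng_seed = 1,
                         channels = c("Pz", "FCz")) {
  stopifnot(inherits(latent, "LatentTrace"))
  if (carrier_band[1] <= 0 || carrier_band[2] >= fs / 2 ||
      carrier_band[1] >= carrier_band[2]) {
    stopf("carrier band must lie inside (0, fs/2)")
  }
  dur <- length(latent$values) * latent$dt
  n <- round(dur * fs)
  t_sig <- (seq_len(n) - 1) / fs
  t_lat <- (seq_along(latent$values) - 1) * latent$dt
  lat_up <- stats::approx(t_lat, latent$values, xout = t_sig, rule = 2)$y
  with_rng_seed(rng_seed, {
    bp <- signal::butter(4, carrier_band / (fs / 2), type = "pass")
    carrier <- .butter_filtfilt(stats::rnorm(n), bp)
    env <- Mod(.analytic_signal(carrier))
    carrier <- carrier / pmax(env, 1e-12)   # constant-envelope band noise
    amp <- pmax(1 + mod_depth * lat_up, 0.05)
    active <- amp * carrier + noise_sd * stats::rnorm(n)
    ref <- 0.1 * noise_sd * stats::rnorm(n)
    eeg_recording(rbind(active, ref), fs, channels, reference = channels[2])
  })
}

#' Simulate a BOLD dataset coupled to a latent trace
#'
#' The first `floor(frac_coupled_voxels * n_voxels)` voxels equal
#' `beta_bold` times the HRF-convolved latent resampled to the TR grid,
#' plus stationary AR(1) noise; the remaining voxels are pure AR(1) noise.
#' Voxels sit on a 3-D integer lattice with isotropic mm spacing so that
#' mm-radius seed spheres are well-defined.
#'
#' @param latent a `LatentTrace`.
#' @param n_voxels number of target voxels (>= 2).
#' @param spec a `CouplingSpec`.
#' @param tr repetition time in seconds (default 1.5).
#' @param hrf an `HRFKernel` at the latent's `dt`.
#' @param rng_seed integer seed.
#' @param spacing_mm lattice spacing (default 2.2).
#' @param origin_mm lattice origin (default `c(0, 0, 0)`).
#' @param subject_id label.
#' @return a `BOLDDataset` (see [bold_dataset()]) with mask label
#'   `"target"` covering all voxels and a `truth` field listing the coupled
#'   voxel indices and the coupling spec used.
#' @export
simulate_bold <- function(latent, n_voxels, spec = coupling_spec(), tr = 1.5,
                          hrf = hrf_kernel(dt = latent$dt), rng_seed = 1,
                          spacing_mm = 2.2, origin_mm = c(0, 0, 0),
                          subject_id = "sim") {
  stopifnot(inherits(latent, "LatentTrace"), inherits(spec, "CouplingSpec"))
  if (n_voxels < 2) stopf("n_voxels must be >= 2")
  if (!is_scalar_num(tr) || tr <= 0) stopf("tr must be > 0")
  dur <- length(latent$values) * latent$dt
  n_vol <- max(2L, round(dur / tr))
  x <- .latent_to_volumes(latent, n_vol, tr, hrf)
  n_coupled <- floor(spec$frac_coupled_voxels * n_voxels)
  data <- with_rng_seed(rng_seed, {
    m <- matrix(0, n_voxels, n_vol)
    for (v in seq_len(n_voxels)) {
      m[v, ] <- .ar1_noise(n_vol, spec$ar1_phi, spec$noise_sd)
      if (v <= n_coupled) m[v, ] <- m[v, ] + spec$beta_bold * x
    }
    m
  })
  coords <- .lattice_coords(n_voxels, spacing_mm, origin_mm)
  bd <- bold_dataset(data, tr, coords, spacing_mm,
                     mask_labels = list(target = seq_len(n_voxels)),
                     subject_id = subject_id)
  bd$truth <- list(coupled = seq_len(n_coupled), spec = spec,
                   signal = x)
  bd
}

# Coordinates of the first n points of a cubic lattice.
.lattice_coords <- function(n, spacing, origin) {
  side <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  grid <- cbind(idx %% side,
                (idx %/% side) %% side,
                idx %/% (side * side))
  sweep(grid * spacing, 2, origin, `+`)
}

#' Simulate continuous emotion ratings from per-scene latents
#'
#' Ratings are `4 + rating_slope * latent + noise`, saturated into the 1-7
#' scale, so the expected absolute deviation from the neutral anchor 4
#' grows with `rating_slope * |latent|`.
#'
#' @param latent_per_scene named list of `LatentTrace` objects, one per
#'   scene (at least two scenes).
#' @param spec a `CouplingSpec` (uses `rating_slope`, `rating_noise_sd`).
#' @param rng_seed integer seed.
#' @param subject_id label.
#' @return named list of `RatingTrace` objects (see [rating_trace()]).
#' @export
simulate_ratings <- function(latent_per_scene, spec = coupling_spec(),
                             rng_seed = 1, subject_id = "sim") {
  if (length(latent_per_scene) < 2L || is.null(names(latent_per_scene))) {
    stopf("latent_per_scene must be a named list with at least two scenes")
  }
  with_rng_seed(rng_seed, {
    out <- lapply(names(latent_per_scene), function(sc) {
      lt <- latent_per_scene[[sc]]
      stopifnot(inherits(lt, "LatentTrace"))
      v <- 4 + spec$rating_slope * lt$values +
        stats::rnorm(length(lt$values), sd = spec$rating_noise_sd)
      v <- pmin(pmax(v, 1), 7)
      rating_trace(t = (seq_along(v) - 1) * lt$dt, values = v,
                   scene = sc, subject_id = subject_id)
    })
    names(out) <- names(latent_per_scene)
    out
  })
}

#' Attach seed-coupled voxels to a time-series matrix
#'
#' Returns an `n_voxels x length(seed_ts)` matrix in which the rows listed
#' in `coupled_idx` equal `r * z(seed_ts) + sqrt(1 - r^2) * noise` (so
#' their expected Pearson correlation with the seed is `r`) and all other
#' rows are pure noise.  Used to build ground-truth fixtures for the
#' seed-coactivation ROI selection.
#'
#' @param seed_ts numeric seed time-course.
#' @param n_voxels total rows.
#' @param coupled_idx indices of the coupled rows.
#' @param r target correlation in [-1, 1].
#' @param rng_seed integer seed.
#' @return numeric matrix.
#' @export
simulate_seed_coupled_voxels <- function(seed_ts, n_voxels, coupled_idx, r,
                                         rng_seed = 1) {
  if (abs(r) > 1) stopf("r must lie in [-1, 1]")
  z <- as.numeric(scale(seed_ts))
  n_t <- length(seed_ts)
  with_rng_seed(rng_seed, {
    m <- matrix(stats::rnorm(n_voxels * n_t), n_voxels, n_t)
    for (v in coupled_idx) {
      m[v, ] <- r * z + sqrt(1 - r^2) * m[v, ]
    }
    m
  })
}

#' Simulate one fully self-consistent subject
#'
#' Generates a latent arousal trace over the task, EEG tracking it, and a
#' BOLD dataset containing (i) target voxels -- a coupled subset carrying
#' `beta_bold` times the HRF-convolved latent plus a shared
#' salience-network fluctuation of amplitude `seed_coupling_r`, and
#' uncoupled pure-noise voxels -- and (ii) a small spherical seed region
#' driven by the latent and the same network fluctuation, mimicking an
#' anterior-insula salience seed.  Per-scene ratings are generated from
#' scene latents scaled by per-scene arousal gains (higher for the aversive
#' scene) that also scale the subject's EFP-band modulation depth, linking
#' behavioral reactivity and EFP amplitude across subjects.
#'
#' @param duration_s main task duration in seconds (default 450).
#' @param n_voxels target-mask voxels (default 60).
#' @param spec a `CouplingSpec`.
#' @param tr repetition time (default 1.5 s).
#' @param fs EEG sampling rate (default 250 Hz).
#' @param carrier_band EEG band carrying the latent (default 4-8 Hz).
#' @param eeg_noise_sd broadband EEG noise SD (default 0.5).
#' @param rng_seed integer seed.
#' @param subject_id label.
#' @param seed_center_mm mm center of the synthetic seed sphere (default
#'   `c(28.6, 28.6, 0)`, a lattice point away from the target block).
#' @param seed_radius_mm seed sphere radius (default 4).
#' @return an object of class `SyntheticSubject`: list with `eeg`, `bold`,
#'   `ratings`, `truth` (spec, coupled voxel indices, arousal gains,
#'   latent) and `rng_seed`.
#' @export
simulate_subject <- function(duration_s = 450, n_voxels = 60,
                             spec = coupling_spec(), tr = 1.5, fs = 250,
                             carrier_band = c(4, 8), eeg_noise_sd = 0.5,
                             rng_seed = 1, subject_id = "sub-01",
                             seed_center_mm = c(28.6, 28.6, 0),
                             seed_radius_mm = 4) {
  latent <- make_latent(duration_s, dt = 0.25, rng_seed = derive_seed(rng_seed, 1))
  eeg <- simulate_eeg(latent, fs = fs, carrier_band = carrier_band,
                      noise_sd = eeg_noise_sd,
                      rng_seed = derive_seed(rng_seed, 2))
  bold <- simulate_bold(latent, n_voxels, spec, tr = tr,
                        rng_seed = derive_seed(rng_seed, 3),
                        subject_id = subject_id)
  n_vol <- ncol(bold$data)
  x_z <- as.numeric(scale(bold$truth$signal))

  # shared salience-network fluctuation (independent of the latent) tying
  # coupled voxels to the seed beyond their common latent drive
  extra <- with_rng_seed(derive_seed(rng_seed, 4), {
    nu <- as.numeric(scale(.ar1_noise(n_vol, 0.5, 1)))
    coupled <- bold$truth$coupled
    for (v in coupled) {
      bold$data[v, ] <- bold$data[v, ] + spec$seed_coupling_r * nu
    }
    seed_drive <- as.numeric(scale(x_z + nu))
    seed_coords <- .seed_sphere_coords(seed_center_mm, seed_radius_mm,
                                       bold$spacing_mm)
    seed_data <- t(vapply(seq_len(nrow(seed_coords)), function(i) {
      seed_drive + 0.3 * stats::rnorm(n_vol)
    }, numeric(n_vol)))
    list(seed_coords = seed_coords, seed_data = seed_data)
  })
  seed_idx <- nrow(bold$data) + seq_len(nrow(extra$seed_coords))
  bold$data <- rbind(bold$data, extra$seed_data)
  bold$coords <- rbind(bold$coords, extra$seed_coords)
  bold$mask_labels$seed <- seed_idx

  # per-scene arousal gains: aversive scene stronger on average, with
  # subject-level variation shared between ratings and EFP modulation
  scenes <- with_rng_seed(derive_seed(rng_seed, 5), {
    gains <- c(farewell = max(0.1, 0.5 + stats::rnorm(1, sd = 0.25)),
               snakes = max(0.1, 1.2 + stats::rnorm(1, sd = 0.25)))
    lat <- list(
      farewell = make_latent(501, dt = 0.5,
                             rng_seed = derive_seed(rng_seed, 6),
                             label = "farewell"),
      snakes = make_latent(321, dt = 0.5,
                           rng_seed = derive_seed(rng_seed, 7),
                           label = "snakes"))
    for (sc in names(lat)) lat[[sc]]$values <- gains[[sc]] * lat[[sc]]$values
    list(gains = gains, lat = lat)
  })
  ratings <- simulate_ratings(scenes$lat, spec,
                              rng_seed = derive_seed(rng_seed, 8),
                              subject_id = subject_id)
  structure(list(eeg = eeg, bold = bold, ratings = ratings,
                 truth = list(spec = spec, coupled = bold$truth$coupled,
                              scene_gains = scenes$gains, latent = latent,
                              seed_center_mm = seed_center_mm,
                              seed_radius_mm = seed_radius_mm),
                 rng_seed = rng_seed, subject_id = subject_id),
            class = "SyntheticSubject")
}

.seed_sphere_coords <- function(center, radius, spacing) {
  k <- ceiling(radius / spacing)
  offs <- expand.grid(x = -k:k, y = -k:k, z = -k:k) * spacing
  keep <- sqrt(rowSums(offs^2)) <= radius + 1e-9
  as.matrix(sweep(offs[keep, , drop = FALSE], 2, center, `+`))
}

#' Simulate a cohort of subjects
#'
#' Per-subject coupling specs are drawn around a template (normal jitter on
#' `beta_bold`, truncated at 0); the master seed reproduces the whole
#' cohort.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param template a `CouplingSpec` giving the cohort means.
#' @param between_subject_sd SD of subject-level `beta_bold` around the
#'   template (default 0.1; the study does not characterize inter-subject
#'   coupling variability, so this default is a documented convention).
#' @param rng_seed master integer seed.
#' @param ... further arguments passed to [simulate_subject()]
#'   (`duration_s`, `n_voxels`, `fs`, ...).
#' @return a list of `SyntheticSubject` objects with attribute
#'   `subject_betas`.
#' @export
simulate_cohort <- function(n_subjects, template = coupling_spec(),
                            between_subject_sd = 0.1, rng_seed = 1, ...) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (between_subject_sd < 0) stopf("between_subject_sd must be >= 0")
  betas <- with_rng_seed(rng_seed, {
    pmax(0, template$beta_bold +
           stats::rnorm(n_subjects, sd = between_subject_sd))
  })
  subs <- lapply(seq_len(n_subjects), function(i) {
    sp <- template
    sp$beta_bold <- betas[i]
    simulate_subject(spec = sp, rng_seed = derive_seed(rng_seed, 100 + i),
                     subject_id = sprintf("sub-%02d", i), ...)
  })
  attr(subs, "subject_betas") <- betas
  class(subs) <- "SyntheticCohort"
  subs
}

#' Lightweight behavioral cohort for the reactivity chain
#'
#' Generates, per subject, per-scene rating traces and per-scene EFP
#' time-courses that share the subject's scene arousal gains (ratings
#' scale with `rating_slope * gain`; the EFP trace's mean level scales
#' with the same gain), without simulating raw EEG -- the construction the
#' reactivity analysis assumes, at cohort scale.
#'
#' @param n_subjects cohort size (default 60, the scale of the study's
#'   rating sample).
#' @param spec a `CouplingSpec` (uses `rating_slope`, `rating_noise_sd`).
#' @param efp_gain EFP level change per unit arousal gain (default 0.5).
#' @param efp_noise_sd SD of AR(1) noise on the EFP traces (default 0.3).
#' @param rng_seed master integer seed.
#' @return a list with one element per subject: `ratings` and `efp` (named
#'   lists over scenes `farewell`, `snakes`), `gains`, `subject_id`.
#' @export
simulate_reactivity_cohort <- function(n_subjects = 60,
                                       spec = coupling_spec(),
                                       efp_gain = 0.5, efp_noise_sd = 0.3,
                                       rng_seed = 1) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  durations <- c(farewell = 501, snakes = 321)
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("sub-%02d", i)
    s_i <- derive_seed(rng_seed, i)
    gains <- with_rng_seed(s_i, {
      c(farewell = max(0.1, 0.5 + stats::rnorm(1, sd = 0.25)),
        snakes = max(0.1, 1.2 + stats::rnorm(1, sd = 0.25)))
    })
    lat <- lapply(names(durations), function(sc) {
      l <- make_latent(durations[[sc]], dt = 0.5,
                       rng_seed = derive_seed(s_i, match(sc, names(durations))),
                       label = sc)
      l$values <- gains[[sc]] * l$values
      l
    })
    names(lat) <- names(durations)
    ratings <- simulate_ratings(lat, spec, rng_seed = derive_seed(s_i, 11),
                                subject_id = sid)
    efp <- with_rng_seed(derive_seed(s_i, 12), {
      out <- lapply(names(durations), function(sc) {
        n <- floor(durations[[sc]] / 1.5)
        efp_timecourse(efp_gain * gains[[sc]] +
                         .ar1_noise(n, 0.3, efp_noise_sd),
                       dt = 1.5, t0 = 0, model_name = "synthetic-efp")
      })
      names(out) <- names(durations)
      out
    })
    list(ratings = ratings, efp = efp, gains = gains, subject_id = sid)
  })
}
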