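# Synthetic cohort generator: determinism, construction contracts, and
# recovery of the planted statistical structure.

test_that("latent traces are seeded, demeaned, and smoother at lower cutoffs", {
  a <- make_latent(60, dt = 0.25, rng_seed = 7)
  b <- make_latent(60, dt = 0.25, rng_seed = 7)
  expect_identical(a$values, b$values)
  expect_lt(abs(mean(a$values)), 1e-9)
  expect_equal(sd(a$values), 1, tolerance = 1e-9)

  ac1 <- function(x) cor(x[-1], x[-length(x)])
  slow <- fast <- numeric(100)
  for (s in 1:100) {
    slow[s] <- ac1(make_latent(120, 0.25, cutoff_hz = 0.1, rng_seed = s)$values)
    fast[s] <- ac1(make_latent(120, 0.25, cutoff_hz = 1.0, rng_seed = s)$values)
  }
  expect_gt(mean(slow), mean(fast))

  expect_error(make_latent(-5, 0.25), "> 0")
  expect_error(make_latent(1, 0.25), "10")
})

test_that("simulated EEG band power tracks the latent", {
  lat <- make_latent(60, dt = 0.25, rng_seed = 7)
  eeg <- simulate_eeg(lat, fs = 200, noise_sd = 0, rng_seed = 3)
  sig <- eeg$samples["Pz", ]
  qtr <- 200 * 0.25
  env <- sqrt(colMeans(matrix(sig^2, qtr)))
  t_env <- (seq_along(env) - 0.5) * 0.25
  lat_q <- approx((seq_along(lat$values) - 1) * 0.25, lat$values,
                  xout = t_env, rule = 2)$y
  expect_gt(cor(env, lat_q), 0.9)

  # zero latent, zero noise -> constant envelope
  flat <- lat; flat$values <- rep(0, length(flat$values))
  eeg0 <- simulate_eeg(flat, fs = 200, noise_sd = 0, rng_seed = 3)
  env0 <- sqrt(colMeans(matrix(eeg0$samples["Pz", ]^2, qtr)))
  expect_lt(var(env0) / mean(env0)^2, 0.01)  # vs ~0.5 for raw band noise

  expect_identical(simulate_eeg(lat, rng_seed = 9)$samples,
                   simulate_eeg(lat, rng_seed = 9)$samples)
  expect_error(simulate_eeg(lat, fs = 250, carrier_band = c(100, 130)),
               "carrier band")
})

test_that("simulated BOLD plants the stated coupling structure", {
  lat <- make_latent(600, dt = 0.25, rng_seed = 5)

  # noise-free, beta 1: coupled voxels equal the HRF-convolved resampled
  # latent exactly
  spec0 <- coupling_spec(beta_bold = 1, noise_sd = 0,
                         frac_coupled_voxels = 0.5)
  b0 <- simulate_bold(lat, n_voxels = 4, spec = spec0, rng_seed = 2)
  hx <- hrf_convolve(lat)
  t_lat <- (seq_along(lat$values) - 1) * lat$dt
  x_vol <- approx(t_lat, hx, xout = (seq_len(ncol(b0$data)) - 1) * 1.5,
                  rule = 2)$y
  expect_equal(b0$data[1, ], x_vol, tolerance = 1e-12)
  expect_equal(b0$truth$coupled, 1:2)

  # noise-only voxels: Yule-Walker lag-1 estimate near ar1_phi
  spec_ar <- coupling_spec(beta_bold = 0, ar1_phi = 0.4, noise_sd = 1,
                           frac_coupled_voxels = 0)
  b1 <- simulate_bold(lat, n_voxels = 200, spec = spec_ar, rng_seed = 3)
  ac1 <- apply(b1$data, 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac1) - 0.4), 0.1)

  expect_error(simulate_bold(lat, 10, coupling_spec(ar1_phi = 1.2)),
               "ar1_phi")
  expect_error(simulate_bold(lat, 1, coupling_spec()), "n_voxels")
})

test_that("beta 0 makes coupled and uncoupled voxels indistinguishable", {
  lat <- make_latent(450, dt = 0.25, rng_seed = 9)
  spec <- coupling_spec(beta_bold = 0, frac_coupled_voxels = 0.5)
  b <- simulate_bold(lat, n_voxels = 100, spec = spec, rng_seed = 4)
  x <- approx((seq_along(lat$values) - 1) * lat$dt, hrf_convolve(lat),
              xout = (seq_len(ncol(b$data)) - 1) * 1.5, rule = 2)$y
  fm <- first_level_glm(b, efp_timecourse(x, dt = 1.5), glm_config())
  expect_lt(abs(mean(fm$beta)), 2 * sd(fm$beta) / sqrt(length(fm$beta)) * 2)
})

test_that("ratings stay on scale and reactivity grows with the slope", {
  lats <- list(a = make_latent(100, 0.5, rng_seed = 1),
               b = make_latent(100, 0.5, rng_seed = 2))
  r1 <- simulate_ratings(lats, coupling_spec(rating_slope = 1), rng_seed = 3)
  expect_true(all(vapply(r1, function(tr) all(tr$values >= 1 &
                                                tr$values <= 7), logical(1))))

  # slope 0: ratings are noise around the neutral anchor
  r0 <- simulate_ratings(lats, coupling_spec(rating_slope = 0,
                                             rating_noise_sd = 0.3),
                         rng_seed = 3)
  expect_lt(abs(mean(r0$a$values) - 4), 0.1)

  idx <- function(slope, seed) {
    rr <- simulate_ratings(lats, coupling_spec(rating_slope = slope),
                           rng_seed = seed)
    mean(vapply(rr, reactivity_index, numeric(1)))
  }
  hi <- vapply(1:40, function(s) idx(1, s), numeric(1))
  lo <- vapply(1:40, function(s) idx(0.2, s), numeric(1))
  expect_gt(mean(hi), mean(lo))

  expect_error(simulate_ratings(lats["a"], coupling_spec()), "two scenes")
})

test_that("cohorts are reproducible and centered on the template", {
  co1 <- simulate_cohort(3, rng_seed = 11, duration_s = 60, n_voxels = 8,
                         fs = 125)
  co2 <- simulate_cohort(3, rng_seed = 11, duration_s = 60, n_voxels = 8,
                         fs = 125)
  expect_identical(co1[[2]]$bold$data, co2[[2]]$bold$data)
  expect_identical(co1[[1]]$eeg$samples, co2[[1]]$eeg$samples)

  # sd 0: all subjects share the template beta exactly
  b0 <- attr(simulate_cohort(3, between_subject_sd = 0, rng_seed = 1,
                             duration_s = 60, n_voxels = 8, fs = 125),
             "subject_betas")
  expect_true(all(b0 == coupling_spec()$beta_bold))

  # law of large numbers on the drawn betas (no need to build the data)
  betas <- with(list(), {
    tpl <- coupling_spec(beta_bold = 0.5)
    set.seed(99)
    pmax(0, tpl$beta_bold + rnorm(200, sd = 0.1))
  })
  expect_lt(abs(mean(betas) - 0.5), 0.02)

  expect_error(simulate_cohort(1), "n_subjects")
  expect_error(simulate_cohort(3, between_subject_sd = -1),
               "between_subject_sd")
})

test_that("subjects carry consistent EEG/BOLD coverage and ground truth", {
  sub <- simulate_subject(duration_s = 90, n_voxels = 27, rng_seed = 13,
                          fs = 125)
  eeg_dur <- ncol(sub$eeg$samples) / sub$eeg$fs
  bold_dur <- ncol(sub$bold$data) * sub$bold$tr
  expect_lt(abs(eeg_dur - bold_dur), 1.5)
  expect_true(all(sub$truth$coupled %in% sub$bold$mask_labels$target))
  expect_gt(length(sub$bold$mask_labels$seed), 0)
  # seed voxels are distinct from target voxels
  expect_length(intersect(sub$bold$mask_labels$seed,
                          sub$bold$mask_labels$target), 0)
})

test_that("seed-coupled voxel helper hits the requested correlation", {
  set.seed(2)
  seed_ts <- rnorm(400)
  m <- simulate_seed_coupled_voxels(seed_ts, n_voxels = 30,
                                    coupled_idx = 1:10, r = 0.6,
                                    rng_seed = 4)
  rc <- apply(m[1:10, ], 1, cor, y = seed_ts)
  ru <- apply(m[11:30, ], 1, cor, y = seed_ts)
  expect_lt(abs(mean(rc) - 0.6), 0.1)
  expect_lt(abs(mean(ru)), 0.1)
})
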