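# EFP signal path: filtering, Stockwell transform, binning, weighted
# summation, and the end-to-end time-course.

test_that("preprocessing attenuates the notch band and preserves the passband", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  steady <- seq(5 * fs, 15 * fs)  # avoid filter edge transients
  rms <- function(x) sqrt(mean(x^2))

  rec33 <- eeg_recording(rbind(sin(2 * pi * 33 * t)), fs, "Pz")
  out33 <- preprocess_eeg(rec33, band = c(0.75, 70), notches = list(c(33, 4)))
  expect_lt(rms(out33$samples[1, steady]) / rms(rec33$samples[1, steady]),
            0.05)

  rec10 <- eeg_recording(rbind(sin(2 * pi * 10 * t)), fs, "Pz")
  out10 <- preprocess_eeg(rec10, band = c(0.75, 70), notches = list(c(33, 4)))
  expect_equal(rms(out10$samples[1, steady]) / rms(rec10$samples[1, steady]),
               1, tolerance = 0.05)

  zero <- eeg_recording(matrix(0, 1, fs * 2), fs, "Pz")
  expect_equal(max(abs(preprocess_eeg(zero)$samples)), 0)
  expect_error(preprocess_eeg(rec10, band = c(0.75, 200)), "fs/2")
})

test_that("Stockwell transform matches the direct Gaussian-windowed DFT oracle", {
  set.seed(11)
  for (n in c(64, 128)) {
    fs <- n / 2  # 2-s signals
    x <- rnorm(n)
    freqs <- c(2, 5, 9, fs / 4)
    S <- stockwell_transform(x, fs, freqs)
    S0 <- oracle_stockwell(x, fs, freqs)
    expect_lt(max(Mod(S - S0)) / max(Mod(S0)), 1e-6)
  }
})

test_that("Stockwell transform is linear and localizes a pure tone", {
  fs <- 250
  t <- (0:(12 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  S <- stockwell_transform(x, fs, 1:40)
  expect_identical(which.max(colMeans(Mod(S)^2)), 10L)

  y <- rnorm(512)
  expect_lt(max(Mod(stockwell_transform(3.7 * y, fs, c(5, 20)) -
                      3.7 * stockwell_transform(y, fs, c(5, 20)))), 1e-9)

  expect_equal(max(Mod(stockwell_transform(numeric(64), 32, c(2, 5)))), 0)
  expect_error(stockwell_transform(rnorm(64), 32, c(-1, 5)), "inside")
  expect_error(stockwell_transform(rnorm(64), 32, 20), "inside")
})

test_that("time-frequency binning equals brute-force rectangle means", {
  # 1-s toy grid at 8 Hz sampling, 2 bands, hand-filled 8 x 4 matrix
  p <- matrix(seq_len(32), 8, 4)
  freqs <- c(1, 2, 5, 6)
  bands <- rbind(c(0.5, 3), c(3, 8))
  g <- bin_time_frequency(p, fs = 8, time_bin_s = 0.25, band_edges = bands,
                          freqs = freqs)
  expect_equal(dim(g$power), c(4L, 2L))
  brute <- matrix(0, 4, 2)
  for (tb in 1:4) {
    rows <- ((tb - 1) * 2 + 1):(tb * 2)
    brute[tb, 1] <- mean(p[rows, freqs >= 0.5 & freqs < 3])
    brute[tb, 2] <- mean(p[rows, freqs >= 3 & freqs <= 8])
  }
  expect_equal(g$power, brute, tolerance = 1e-12)

  # constant input -> constant cells
  gc <- bin_time_frequency(matrix(3.3, 8, 4), fs = 8, time_bin_s = 0.25,
                           band_edges = bands, freqs = freqs)
  expect_true(all(abs(gc$power - 3.3) < 1e-12))

  # 12-s input at the default geometry -> 48 x 10
  p12 <- matrix(abs(rnorm(48 * 40)), 48, 40)
  g12 <- bin_time_frequency(p12, fs = 4, time_bin_s = 0.25,
                            freqs = efp_analysis_freqs(demo_efp_model()))
  expect_equal(dim(g12$power), c(48L, 10L))

  expect_error(bin_time_frequency(p[1:7, ], fs = 8, time_bin_s = 0.25,
                                  band_edges = bands, freqs = freqs),
               "integer multiple")
})

test_that("EFP value is the weighted sum plus intercept", {
  bands <- default_band_edges()
  zero_grid <- bin_time_frequency(matrix(0, 48, 40), fs = 4,
                                  time_bin_s = 0.25, band_edges = bands,
                                  freqs = efp_analysis_freqs(demo_efp_model()))
  m0 <- efp_model(matrix(0, 48, 10), intercept = 0.3, band_edges = bands)
  expect_equal(compute_efp_value(zero_grid, m0), 0.3)

  w <- matrix(0, 48, 10); w[5, 2] <- 1
  g <- zero_grid; g$power[5, 2] <- 4.2
  m1 <- efp_model(w, intercept = 0.1, band_edges = bands)
  expect_equal(compute_efp_value(g, m1), 0.1 + 4.2)

  set.seed(21)
  wr <- matrix(rnorm(480), 48, 10)
  gr <- zero_grid; gr$power <- matrix(abs(rnorm(480)), 48, 10)
  mr <- efp_model(wr, intercept = -0.7, band_edges = bands)
  brute <- -0.7
  for (i in 1:48) for (j in 1:10) brute <- brute + gr$power[i, j] * wr[i, j]
  expect_equal(compute_efp_value(gr, mr), brute, tolerance = 1e-12)

  bad <- zero_grid; bad$power <- bad$power[1:24, ]
  expect_error(compute_efp_value(bad, mr), "model expects")
})

test_that("EFP time-course emits one value per stride from segment end", {
  fs <- 125
  rec <- eeg_recording(matrix(rnorm(2 * 60 * fs), 2), fs, c("Pz", "FCz"))
  m <- demo_efp_model()
  efp <- compute_efp_timecourse(rec, m, stride_s = 1.5)
  expect_length(efp$values, 33)             # t = 12.0, 13.5, ..., 60.0
  expect_equal(efp_times(efp)[1], 12)
  expect_equal(efp_times(efp)[33], 60)
  expect_identical(efp$warmup_volumes, 8L)  # TR-length steps before t0

  zero <- eeg_recording(matrix(0, 2, 20 * fs), fs, c("Pz", "FCz"))
  expect_equal(max(abs(compute_efp_timecourse(zero, m)$values)), 0)

  short <- eeg_recording(matrix(rnorm(2 * 10 * fs), 2), fs, c("Pz", "FCz"))
  expect_error(compute_efp_timecourse(short, m), "shorter than one")
  no_ch <- eeg_recording(matrix(0, 1, 20 * fs), fs, "Cz")
  expect_error(compute_efp_timecourse(no_ch, m), "derivation channel")
})

test_that("EFP map is linear in the input power for a fixed model", {
  set.seed(5)
  bands <- default_band_edges()
  m <- demo_efp_model()
  p <- matrix(abs(rnorm(48 * 40)), 48, 40)
  freqs <- efp_analysis_freqs(m)
  v1 <- compute_efp_value(bin_time_frequency(p, 4, 0.25, bands, freqs), m)
  v2 <- compute_efp_value(bin_time_frequency(2.5 * p, 4, 0.25, bands, freqs), m)
  expect_equal(v2, 2.5 * v1, tolerance = 1e-12)
})

test_that("EFP recovers the latent drive from synthetic EEG", {
  # carrier-band power tracks the latent; the EFP integrates the trailing
  # 12-s window, so it is compared at the window's effective (center) lag
  lat <- make_latent(180, dt = 0.25, rng_seed = 7)
  eeg <- simulate_eeg(lat, fs = 250, carrier_band = c(4, 8), noise_sd = 0.5,
                      rng_seed = 3)
  m <- demo_efp_model(carrier_band = c(4, 8))
  efp <- compute_efp_timecourse(eeg, m, stride_s = 1.5)
  t_lat <- (seq_along(lat$values) - 1) * lat$dt
  lat_mid <- approx(t_lat, lat$values,
                    xout = efp_times(efp) - m$segment_s / 2, rule = 2)$y
  expect_gt(cor(efp$values, lat_mid), 0.5)
})

test_that("EFP model JSON round-trips exactly", {
  m <- demo_efp_model()
  path <- tempfile(fileext = ".json")
  write_efp_model(m, path)
  back <- read_efp_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$band_edges, m$band_edges)
  expect_equal(back$intercept, m$intercept)
  expect_identical(back$derivation, m$derivation)
  writeLines('{"foo": 1}', path)
  expect_error(read_efp_model(path), "format")
})
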