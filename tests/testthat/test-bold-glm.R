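# Voxel-wise GLM, group tests, FDR.

make_bold <- function(data, tr = 1.5, subject_id = "sub") {
  bold_dataset(data, tr, coords = cbind(seq_len(nrow(data)) * 2.2, 0, 0),
               subject_id = subject_id)
}

test_that("signal preparation removes trends, drifts, and means", {
  n <- 400
  ramp <- seq(0, 10, length.out = n)
  slow <- sin(2 * pi * 0.0005 * (0:(n - 1)) * 1.5)
  fast <- sin(2 * pi * 0.05 * (0:(n - 1)) * 1.5)
  b <- make_bold(rbind(ramp, slow, fast))
  out <- prepare_voxel_signals(b, glm_config())
  expect_lt(max(abs(out$data[1, ])), 1e-9)          # pure ramp removed
  expect_lt(max(abs(rowMeans(out$data))), 1e-9)     # demeaned
  expect_lt(var(out$data[2, ]) / var(out$data[3, ]), 0.25)  # slow suppressed
  expect_error(prepare_voxel_signals(make_bold(matrix(1, 2, 3))), "volumes")
})

test_that("first-level GLM recovers exact and orthogonal slopes", {
  set.seed(31)
  x <- rnorm(120)
  cfg_raw <- glm_config(highpass_hz = 0, detrend = FALSE,
                        standardize_efp = FALSE)
  y1 <- 2 * x + 5
  # voxel orthogonal to the regressor by residualization
  z <- rnorm(120)
  y2 <- residuals(lm(z ~ x))
  fm <- first_level_glm(make_bold(rbind(y1, y2), tr = 1.5), x, cfg_raw)
  expect_equal(unname(fm$beta[1]), 2, tolerance = 1e-9)
  expect_lt(abs(fm$beta[2]), 1e-9)
  expect_identical(fm$dof, 118L)
  expect_error(first_level_glm(make_bold(rbind(y1)), rep(1, 120), cfg_raw),
               "zero variance")
  expect_error(first_level_glm(make_bold(rbind(y1)), x[1:50], cfg_raw),
               "does not match")
})

test_that("first-level beta and t match the normal-equation oracle", {
  set.seed(33)
  cfg <- glm_config(highpass_hz = 0, detrend = FALSE, demean = FALSE,
                    standardize_efp = FALSE)
  for (rep in 1:5) {
    x <- rnorm(50)
    y <- rnorm(50)
    fm <- first_level_glm(make_bold(rbind(y)), x, cfg)
    o <- oracle_ols(y, x)
    expect_equal(unname(fm$beta[1]), o$beta, tolerance = 1e-10)
    expect_equal(unname(fm$tstat[1]), o$t, tolerance = 1e-10)
  }
})

test_that("EFP warm-up volumes are dropped by nearest-sample alignment", {
  efp <- efp_timecourse(seq_len(20), dt = 1.5, t0 = 12)
  al <- align_efp_to_volumes(efp, n_volumes = 30, tr = 1.5)
  expect_equal(al$volume_idx[1], 9)   # volumes 1..8 precede the first value
  expect_equal(length(al$values), 20)
  al2 <- align_efp_to_volumes(efp, n_volumes = 15, tr = 1.5)
  expect_equal(length(al2$values), 7)  # truncated to the run
})

test_that("group one-sample test matches the t oracle and handles degeneracy", {
  mk_map <- function(betas, id) {
    m <- list(beta = betas, tstat = betas, dof = 98L, subject_id = id,
              regressor_name = "efp")
    names(m$beta) <- names(m$tstat) <- as.character(seq_along(betas))
    class(m) <- "EffectMap"
    m
  }
  # symmetric betas -> t = 0, p = 1
  maps <- list(mk_map(c(1, 2), "a"), mk_map(c(-1, -2), "b"),
               mk_map(c(0.5, 1), "c"), mk_map(c(-0.5, -1), "d"))
  g0 <- group_one_sample(maps)
  expect_equal(unname(g0$t), c(0, 0))
  expect_equal(unname(g0$p), c(1, 1))

  set.seed(41)
  B <- matrix(rnorm(20 * 6, mean = 0.5, sd = 0.1), 20, 6)
  maps <- lapply(1:20, function(i) mk_map(B[i, ], paste0("s", i)))
  g <- group_one_sample(maps)
  for (v in 1:6) {
    o <- oracle_t_one_sample(B[, v])
    expect_equal(unname(g$t[v]), o$t, tolerance = 1e-10)
    expect_equal(unname(g$p[v]), o$p, tolerance = 1e-10)
  }

  # n = 3 identical values: degenerate-variance branch, never significant
  mapsd <- lapply(1:3, function(i) mk_map(c(1.0, rnorm(1)), paste0("d", i)))
  gd <- group_one_sample(mapsd)
  expect_true(gd$degenerate[1])
  expect_equal(unname(gd$p[1]), 1)
  expect_false(gd$sig_mask[1])
  expect_error(group_one_sample(maps[1:2]), "at least 3")
})

test_that("paired contrast matches its oracle and negates under swap", {
  mk_map <- function(betas, id) {
    m <- list(beta = betas, tstat = betas, dof = 98L, subject_id = id,
              regressor_name = "efp")
    names(m$beta) <- names(m$tstat) <- as.character(seq_along(betas))
    class(m) <- "EffectMap"
    m
  }
  set.seed(43)
  A <- matrix(rnorm(10 * 4, 0.3, 0.2), 10, 4)
  B <- A - 0.2 + rnorm(40, sd = 0.01)
  maps_a <- lapply(1:10, function(i) mk_map(A[i, ], paste0("s", i)))
  maps_b <- lapply(1:10, function(i) mk_map(B[i, ], paste0("s", i)))

  gab <- group_paired_contrast(maps_a, maps_b)
  for (v in 1:4) {
    o <- oracle_t_one_sample(A[, v] - B[, v])
    expect_equal(unname(gab$t[v]), o$t, tolerance = 1e-10)
  }
  gba <- group_paired_contrast(maps_b, maps_a)
  expect_equal(unname(gab$t), -unname(gba$t))

  gaa <- group_paired_contrast(maps_a, maps_a)
  expect_true(all(gaa$t == 0))

  # directional masks thresholded at alpha/2 per direction
  expect_true(all(gab$sig_a_gt_b == (gab$q <= 0.025 & gab$t > 0)))

  maps_x <- maps_b
  maps_x[[1]]$subject_id <- "other"
  expect_error(group_paired_contrast(maps_a, maps_x), "subject ids")
})

test_that("BH FDR matches the brute-force step-up oracle", {
  expect_false(any(fdr_bh(0.06, 0.05)$reject))
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject))
  expect_true(all(fdr_bh(rep(0, 5), 0.05)$reject))
  set.seed(47)
  for (rep in 1:20) {
    p <- runif(40)^2
    expect_identical(fdr_bh(p, 0.05)$reject, oracle_bh_reject(p, 0.05))
  }
  # restriction to a subset corrects only within it
  p <- c(0.001, 0.5, 0.002, 0.9)
  res <- fdr_bh(p, 0.05, subset = c(1, 3))
  expect_true(all(res$reject[c(1, 3)]))
  expect_false(any(res$reject[c(2, 4)]))
  expect_true(all(is.na(res$q[c(2, 4)])))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("voxelwise type-I error is nominal under the null at group level", {
  # 20 subjects, 600 null voxels, betas from first-level fits on AR(1) noise
  set.seed(53)
  n_sub <- 20; n_vox <- 600; n_vol <- 200
  x <- rnorm(n_vol)
  cfg <- glm_config(highpass_hz = 0, detrend = FALSE)
  maps <- lapply(1:n_sub, function(i) {
    noise <- matrix(rnorm(n_vox * (n_vol + 20)), n_vox)
    noise <- t(apply(noise, 1, function(e)
      as.numeric(stats::filter(e, 0.3, method = "recursive"))))
    first_level_glm(make_bold(noise[, 21:(n_vol + 20)],
                              subject_id = paste0("s", i)), x, cfg)
  })
  g <- group_one_sample(maps)
  rate <- mean(g$p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  # FDR keeps the false-discovery count near zero under the global null
  expect_lt(sum(g$sig_mask) / max(1, n_vox), 0.01)
})
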