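# Reactivity indices, EFP amplitudes, and their cross-subject coupling.

test_that("reactivity index is the mean absolute deviation from neutral", {
  tr4 <- rating_trace(0:9, rep(4, 10))
  expect_equal(reactivity_index(tr4), 0)
  tr <- rating_trace(0:2, c(1, 7, 4))
  expect_equal(reactivity_index(tr), 2)

  set.seed(81)
  v <- pmin(pmax(4 + rnorm(500), 1), 7)
  trr <- rating_trace(seq(0, 499), v)
  brute <- 0
  for (x in v) brute <- brute + abs(x - 4)
  expect_equal(reactivity_index(trr), brute / 500, tolerance = 1e-12)

  # invariance under reflection about the neutral anchor
  refl <- rating_trace(seq(0, 499), 8 - v)
  expect_equal(reactivity_index(refl), reactivity_index(trr),
               tolerance = 1e-12)

  expect_error(rating_trace(0:2, c(0.5, 4, 4)), "1, 7")
  expect_error(rating_trace(c(0, 0, 1), c(4, 4, 4)), "ascending")
})

test_that("irregular traces are duration-weighted by step resampling", {
  # value 7 held for 8 s then 4 for 2 s: index ~ (8*3 + 2*0)/10
  tr <- rating_trace(c(0, 8, 9, 10), c(7, 4, 4, 4))
  expect_equal(reactivity_index(tr), (8 * 3) / 10, tolerance = 0.15)
})

test_that("EFP amplitude averages the windowed values", {
  efp <- efp_timecourse(c(1, 2, 3), dt = 1.5, t0 = 0)
  expect_equal(efp_amplitude(efp, c(0, 3)), 2)
  efp_c <- efp_timecourse(rep(2.5, 10), dt = 1.5, t0 = 0)
  expect_equal(efp_amplitude(efp_c, c(3, 9)), 2.5)

  set.seed(83)
  v <- rnorm(200)
  efp_r <- efp_timecourse(v, dt = 1.5, t0 = 0)
  w <- c(30, 150)
  tt <- efp_times(efp_r)
  keep <- tt >= w[1] & tt <= w[2]
  brute <- 0
  for (x in v[keep]) brute <- brute + x
  expect_equal(efp_amplitude(efp_r, w), brute / sum(keep), tolerance = 1e-12)
  expect_equal(efp_amplitude(efp_r, w, absolute = TRUE), mean(abs(v[keep])))
  expect_error(efp_amplitude(efp_r, c(1000, 1001)), "no EFP values")
})

test_that("scene-difference tests match the paired-t oracle", {
  mk_cohort <- function(rating_a, rating_b, efp_a, efp_b) {
    n <- length(rating_a)
    data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
               scene = rep(c("farewell", "snakes"), each = n),
               rating_index = c(rating_a, rating_b),
               efp_amp = c(efp_a, efp_b))
  }
  set.seed(85)
  ra <- runif(30, 0.5, 1.5)
  rb <- ra + rnorm(30, 0.5, 0.1)
  ea <- rnorm(30)
  eb <- ea + rnorm(30, 0.3, 0.1)
  res <- scene_difference_tests(mk_cohort(ra, rb, ea, eb))
  o_r <- oracle_t_one_sample(rb - ra)
  o_e <- oracle_t_one_sample(eb - ea)
  expect_equal(res$paired_t_ratings$t, o_r$t, tolerance = 1e-10)
  expect_equal(res$paired_t_ratings$p, o_r$p, tolerance = 1e-10)
  expect_equal(res$paired_t_efp$t, o_e$t, tolerance = 1e-10)

  # identical scenes -> t = 0, p = 1; swapped scene order negates t
  res0 <- scene_difference_tests(mk_cohort(ra, ra, ea, ea))
  expect_equal(res0$paired_t_ratings$t, 0)
  expect_equal(res0$paired_t_ratings$p, 1)
  swapped <- scene_difference_tests(mk_cohort(rb, ra, eb, ea))
  expect_equal(swapped$paired_t_ratings$t, -res$paired_t_ratings$t,
               tolerance = 1e-12)

  # a subject missing one scene is dropped without touching the others
  cohort <- mk_cohort(ra, rb, ea, eb)
  cohort_miss <- cohort[-1, ]  # drop subject 1's farewell row
  expect_warning(res_m <- scene_difference_tests(cohort_miss), "dropping")
  expect_equal(res_m$n_subjects, 29)
  full_d <- res$diffs[res$diffs$subject != "s01", "rating_diff"]
  expect_equal(res_m$diffs$rating_diff, full_d)
})

test_that("reactivity-EFP correlation matches the Pearson oracle", {
  set.seed(87)
  n <- 20
  rd <- rnorm(n)
  ed <- 0.5 * rd + rnorm(n, sd = 0.5)
  cohort <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                       scene = rep(c("farewell", "snakes"), each = n),
                       rating_index = c(abs(rnorm(n)), abs(rnorm(n))),
                       efp_amp = rnorm(2 * n))
  cohort$rating_index[(n + 1):(2 * n)] <- cohort$rating_index[1:n] + rd
  cohort$efp_amp[(n + 1):(2 * n)] <- cohort$efp_amp[1:n] + ed
  res <- correlate_reactivity_efp(cohort)
  o <- oracle_pearson(rd, ed)
  expect_equal(res$r, o$r, tolerance = 1e-10)
  expect_equal(res$p, o$p, tolerance = 1e-10)

  # exact proportionality -> r = 1
  cohort2 <- cohort
  cohort2$efp_amp[(n + 1):(2 * n)] <- cohort2$efp_amp[1:n] + 2 * rd
  expect_equal(correlate_reactivity_efp(cohort2)$r, 1, tolerance = 1e-12)

  # independence at large n -> |r| small
  set.seed(88)
  big <- data.frame(subject = rep(sprintf("s%05d", 1:10000), 2),
                    scene = rep(c("farewell", "snakes"), each = 10000),
                    rating_index = abs(rnorm(20000)),
                    efp_amp = rnorm(20000))
  expect_lt(abs(correlate_reactivity_efp(big)$r), 0.05)

  cohort3 <- cohort
  cohort3$efp_amp <- rep(1, 2 * n)
  expect_error(correlate_reactivity_efp(cohort3), "zero variance")
})

test_that("synthetic behavioral cohorts recover positive coupling", {
  beh <- simulate_reactivity_cohort(n_subjects = 60, rng_seed = 42)
  tab <- reactivity_cohort_table(beh)
  expect_equal(nrow(tab), 120)
  res <- scene_difference_tests(tab)
  # the aversive scene is built to evoke stronger reactivity and EFP
  expect_gt(res$paired_t_ratings$t, 0)
  expect_gt(res$paired_t_efp$t, 0)
  expect_gt(correlate_reactivity_efp(tab)$r, 0)
})
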