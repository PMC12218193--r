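test_that("with identity lenses the perceived mean is the Euclidean mean", {
  w <- opinion_wave(tibble::tibble(group = c("A", "A"),
                                   x = c(0, 0.3), y = c(0, 0.4)))
  r <- mean_disagreement(w, identity_lens_set(w))
  expect_equal(r$population_mean, 0.5, tolerance = 1e-14)
  expect_identical(r$population_mean, r$objective_mean)

  # a larger heterogeneous wave: still exact agreement
  w2 <- random_wave(n_per_group = 30, m = 3, n_groups = 3, seed = 2)
  r2 <- mean_disagreement(w2, identity_lens_set(w2))
  expect_equal(r2$population_mean, r2$objective_mean, tolerance = 1e-12)
})

test_that("a unanimous wave has zero disagreement under any lens set", {
  w <- opinion_wave(tibble::tibble(group = c("A", "A", "B", "B"),
                                   x = rep(0.4, 4), y = rep(0.7, 4)))
  ls1 <- build_lens_set(w, quiet = TRUE) # degenerate, ridge keeps it finite
  expect_equal(mean_disagreement(w, ls1)$population_mean, 0,
               tolerance = 1e-12)
  expect_equal(mean_disagreement(w, identity_lens_set(w))$population_mean, 0,
               tolerance = 1e-14)
})

test_that("a perceiver with a lens half as wide sees twice the distance", {
  # one red and one blue respondent; red's in-group variance is a quarter
  # of blue's on each axis, so red's axis scale is half of blue's
  w <- opinion_wave(tibble::tibble(group = c("red", "blue"),
                                   x = c(0.8, 0.2), y = c(0.8, 0.3)))
  lenses <- structure(list(
    fitted_on = wave_label(w),
    lenses = list(
      None = build_lens(diag(c(0.04, 0.04)), "None", ridge_epsilon = 0),
      red = build_lens(diag(c(0.01, 0.01)), "red", ridge_epsilon = 0),
      blue = build_lens(diag(c(0.04, 0.04)), "blue", ridge_epsilon = 0)
    ),
    fallbacks = tibble::tibble(group = character(), n = integer())
  ), class = "lens_set")
  r <- mean_disagreement(w, lenses)
  d_red <- r$per_group$mean[r$per_group$group == "red"]
  d_blue <- r$per_group$mean[r$per_group$group == "blue"]
  expect_equal(d_red / d_blue, 2, tolerance = 1e-12)
  # oracle check of the actual magnitudes
  expect_equal(d_blue, oracle_distance(c(0.8, 0.8), c(0.2, 0.3),
                                       diag(c(0.04, 0.04))),
               tolerance = 1e-10)
})

test_that("per-group means aggregate back to the population mean", {
  w <- random_wave(n_per_group = 40, m = 2, n_groups = 3, seed = 9)
  r <- mean_disagreement(w, build_lens_set(w, quiet = TRUE))
  agg <- sum(r$per_group$mean * r$per_group$mass) / sum(r$per_group$mass)
  expect_equal(r$population_mean, agg, tolerance = 1e-10)
  expect_equal(r$n_pairs_effective, sum(r$per_group$mass), tolerance = 1e-10)

  # perceiver_filter reproduces the per-group entry
  for (g in unique(w$group)) {
    rf <- mean_disagreement(w, build_lens_set(w, quiet = TRUE),
                            perceiver_filter = g)
    expect_equal(rf$population_mean,
                 r$per_group$mean[r$per_group$group == g], tolerance = 1e-12)
  }
  expect_error(mean_disagreement(w, build_lens_set(w, quiet = TRUE),
                                 perceiver_filter = "nope"), "not a group")
})

test_that("pair weighting uses the product w_i w_j over ordered pairs", {
  # 3 respondents in 1D with distinct weights; hand-computed oracle
  tb <- tibble::tibble(group = "A", weight = c(1, 2, 3),
                       x = c(0, 0.5, 1))
  w <- opinion_wave(tb)
  r <- mean_disagreement(w, identity_lens_set(w))
  d <- as.matrix(stats::dist(tb$x))
  wt <- outer(tb$weight, tb$weight); diag(wt) <- 0
  expect_equal(r$population_mean, sum(wt * d) / sum(wt), tolerance = 1e-12)
})

test_that("the subsampled estimator converges to the exact mean", {
  w <- random_wave(n_per_group = 60, m = 2, n_groups = 2, seed = 31)
  ls1 <- build_lens_set(w, quiet = TRUE)
  exact <- mean_disagreement(w, ls1)
  approx <- mean_disagreement(w, ls1, subsample_pairs = 60000, seed = 1)
  expect_equal(approx$population_mean, exact$population_mean,
               tolerance = 0.05)
  # seeded: same call twice gives the identical estimate
  approx2 <- mean_disagreement(w, ls1, subsample_pairs = 60000, seed = 1)
  expect_identical(approx$population_mean, approx2$population_mean)
})

test_that("perceived polarization is the difference of disagreement means", {
  w1 <- random_wave(seed = 1, wave_label = "t1")
  w2 <- random_wave(seed = 2, wave_label = "t2")
  ls1 <- build_lens_set(w1, quiet = TRUE)
  r1 <- mean_disagreement(w1, ls1)
  r2 <- mean_disagreement(w2, ls1)
  expect_identical(perceived_polarization(r1, r1), 0)
  expect_equal(perceived_polarization(r1, r2),
               r2$population_mean - r1$population_mean, tolerance = 1e-15)
  expect_equal(perceived_polarization(r2, r1),
               -perceived_polarization(r1, r2), tolerance = 1e-15)

  w3 <- opinion_wave(tibble::tibble(group = c("A", "A"), z = c(0, 1)))
  r3 <- mean_disagreement(w3, identity_lens_set(w3))
  expect_error(perceived_polarization(r1, r3), "different item sets")
})

test_that("P telescopes exactly into P1 + P2 and fixed lenses kill P2", {
  w1 <- random_wave(seed = 5, wave_label = "t1")
  w2 <- random_wave(seed = 6, wave_label = "t2")
  ls1 <- build_lens_set(w1, quiet = TRUE)
  ls2 <- build_lens_set(w2, quiet = TRUE)

  dec <- decompose(w1, w2, ls1, ls2)
  expect_lt(abs(dec$P - (dec$P1 + dec$P2)), 1e-12)
  # independent recomputation of P as d(X2, L2) - d(X1, L1)
  p_indep <- mean_disagreement(w2, ls2)$population_mean -
    mean_disagreement(w1, ls1)$population_mean
  expect_lt(abs(dec$P - p_indep), 1e-12)

  # holding the lenses fixed: P2 is exactly zero, P = P1
  fixed <- decompose(w1, w2, ls1)
  expect_identical(fixed$P2, 0)
  expect_identical(fixed$P, fixed$P1)
  expect_identical(fixed$mode, "fixed")
  same <- decompose(w1, w2, ls1, ls1)
  expect_identical(same$P2, 0)

  # no change at all: everything is zero
  null_dec <- decompose(w1, w1, ls1, ls1)
  expect_identical(null_dec$P, 0)
  expect_identical(null_dec$P1, 0)
  expect_identical(null_dec$P2, 0)
})

test_that("per-group decomposition rows are internally consistent", {
  w1 <- random_wave(n_per_group = 35, seed = 7, wave_label = "t1")
  w2 <- random_wave(n_per_group = 35, seed = 8, wave_label = "t2")
  dec <- decompose_instantaneous(w1, w2)
  expect_equal(dec$per_group$P, dec$per_group$P1 + dec$per_group$P2,
               tolerance = 1e-12)
  expect_equal(dec$per_group$rel_P1,
               dec$per_group$P1 / dec$per_group$baseline, tolerance = 1e-12)
  expect_identical(dec$mode, "instantaneous")
  # tidy/glance expose the same numbers
  td <- tidy(dec)
  expect_identical(td$P[td$group == "(all)"], dec$P)
  expect_identical(glance(dec)$P2, dec$P2)
})

test_that("deterministic in-place contraction splits P into opposing halves", {
  # one-group society; wave 2 is wave 1 with opinions pulled toward the
  # mean by factor 0.5. Through the frozen lens distances halve (P1 =
  # -d1/2); the refitted lens rescales them back (P2* = +d1/2), so the
  # perceivers notice nothing: P* = 0 in the ridge-free limit.
  set.seed(17)
  w1 <- opinion_wave(tibble::tibble(group = "G",
                                    x = stats::runif(60, 0.2, 0.8),
                                    y = stats::runif(60, 0.2, 0.8)),
                     wave = "t1")
  w2 <- contract_wave(w1, 0.5, label = "t2")
  dec <- decompose_instantaneous(w1, w2, ridge_epsilon = 0)
  d1 <- dec$baseline
  expect_equal(dec$P1, -d1 / 2, tolerance = 1e-10)
  expect_equal(dec$P2, d1 / 2, tolerance = 1e-10)
  expect_equal(dec$P, 0, tolerance = 1e-10)
})

test_that("contracting only one group's covariance yields lens-specific polarization", {
  sc <- contraction_scenario(two_lenses_spec(n = 400, seed = 3), "red", 0.5)
  waves <- generate_scenario(sc)
  dec <- decompose_instantaneous(waves[[1]], waves[[2]])
  red <- dec$per_group[dec$per_group$group == "red", ]
  expect_gt(red$P2, 0) # the contracted group's lens narrows
  expect_gt(abs(red$P2), 5 * abs(red$P1)) # and dominates the opinion shift
  blue <- dec$per_group[dec$per_group$group == "blue", ]
  expect_lt(abs(blue$P2), red$P2 / 5) # the unchanged group barely moves
})

test_that("waves with different item sets refuse to decompose", {
  w1 <- random_wave(seed = 1, m = 2)
  w3 <- opinion_wave(tibble::tibble(group = c("A", "A", "B"),
                                    z = c(0, 1, 0.5)))
  expect_error(decompose(w1, w3, build_lens_set(w1, quiet = TRUE)),
               "different item sets")
})

test_that("cross-wave lens gaps fall back to the old 'None' lens and are logged", {
  w1 <- opinion_wave(tibble::tibble(group = rep(c("A", "B"), each = 10),
                                    x = stats::runif(20), y = stats::runif(20)),
                     wave = "t1")
  w2 <- opinion_wave(tibble::tibble(group = rep(c("A", "C"), each = 10),
                                    x = stats::runif(20), y = stats::runif(20)),
                     wave = "t2")
  ls1 <- build_lens_set(w1, quiet = TRUE) # knows A, B, None - not C
  r <- mean_disagreement(w2, ls1)
  expect_true("C" %in% r$fallbacks)
  # C's perceivers used the full-sample lens of t1: same mean as filtering
  # through an explicit None lens
  c_mean <- r$per_group$mean[r$per_group$group == "C"]
  expect_true(is.finite(c_mean) && c_mean > 0)
})
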