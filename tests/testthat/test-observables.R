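test_that("gyration radius matches hand-computed geometries", {
  expect_equal(gyration_radius(matrix(c(1, 2, 3), 1)), 0)
  d <- 3.2
  expect_equal(gyration_radius(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  rod3 <- cbind(0:2, 0, 0)
  expect_equal(gyration_radius(rod3), sqrt(2 / 3))
})

test_that("contact maps are symmetric with the advertised entries", {
  # 3 beads pairwise within threshold, one snapshot
  close3 <- array(cbind(c(0, 1, 0.5), c(0, 0, 0.8), c(0, 0, 0)), c(3, 3, 1))
  cm <- contact_map(close3, threshold = 2, min_image = FALSE)
  expect_true(all(unclass(cm) == 1))
  far <- array(cbind(c(0, 10, 20), c(0, 0, 0), c(0, 0, 0)), c(3, 3, 1))
  cm2 <- contact_map(far, threshold = 2, min_image = FALSE)
  expect_equal(sum(unclass(cm2)) , 3) # diagonal only
  expect_symmetric(cm2)
  expect_error(contact_map(array(0, c(3, 3, 0))), "empty-input")
})

test_that("P_c(s) from the map and the trajectory agree exactly", {
  arr <- oracle_ensemble(n = 15, t = 20)
  cm <- contact_map(arr, threshold = 2, min_image = FALSE)
  ps1 <- contact_probability_vs_separation(cm)
  ps2 <- contact_probability_vs_separation(arr, threshold = 2)
  expect_equal(ps1$p, ps2$p, tolerance = 1e-15)
  # monotone-nonincreasing trend (allowing noise): binned means decrease
  b <- with(ps1[ps1$p > 0, ], tapply(p, cut(s, c(0, 3, 7, 14)), mean))
  expect_true(all(diff(na.omit(b)) <= 0))
})

test_that("power-law fitting recovers known exponents", {
  s <- 1:400
  exact <- ps_curve(s, s^(-2))
  expect_equal(fit_power_law_exponent(exact, n_boot = 0)$alpha, 2,
               tolerance = 1e-9)
  flat <- ps_curve(s, rep(0.4, 400))
  expect_equal(fit_power_law_exponent(flat, n_boot = 0)$alpha, 0,
               tolerance = 1e-9)
  set.seed(11)
  noisy <- ps_curve(s, 0.5 * s^(-1.5) * exp(rnorm(400, sd = 0.05)))
  fit <- fit_power_law_exponent(noisy, window = c(4, 300))
  expect_lt(abs(fit$alpha - 1.5), 0.1)
  expect_true(fit$ci[1] < fit$alpha && fit$alpha < fit$ci[2])
  expect_error(fit_power_law_exponent(ps_curve(1:20, rep(0, 20)), c(5, 15)),
               "fit-domain")
})

test_that("plateau detection brackets the onset and the pre-plateau fit works", {
  s <- 1:500
  curve <- ps_curve(s, pmin(s, 40)^(-1))
  # the onset marks the start of the crossover, at or before the true break
  onset <- plateau_onset(curve)
  expect_gte(onset, 10)
  expect_lte(onset, 40)
  fit <- fit_preplateau_exponent(curve, n_boot = 0)
  expect_lt(abs(fit$alpha - 1), 0.1)
  # no plateau: onset is Inf, window falls back to [3, N/4]
  expect_equal(plateau_onset(ps_curve(s, s^(-2.1))), Inf)
})

test_that("R^2(s) matches rod and ideal-chain closed forms", {
  rod <- array(cbind(0:9 * 1.1, 0, 0), c(10, 3, 1))
  r2 <- mean_square_distance_vs_separation(rod)
  expect_equal(r2$r2, 1.1^2 * (1:9)^2, tolerance = 1e-12)

  b <- 1.7
  g <- sample_gaussian_chain(40, b = b, n_samples = 400, seed = 21)
  r2g <- mean_square_distance_vs_separation(g)
  for (s in c(5, 15, 30)) {
    vals <- r2g$r2[r2g$s == s]
    # relative 3-sigma band: var of chi2_3-like distances across samples
    expect_lt(abs(vals / (b^2 * s) - 1), 3 * sqrt(2 / 3) / sqrt(400 * 40 / s))
  }
})

test_that("structure factor limits: single particle, coincident pair, ideal gas", {
  box <- simulation_box(10)
  s1 <- structure_factor(matrix(c(3, 3, 3), 1), box)
  expect_true(all(abs(s1$sk - 1) < 1e-9))
  s2 <- structure_factor(rbind(c(2, 2, 2), c(2, 2, 2)), box)
  expect_true(all(abs(s2$sk - 2) < 1e-9))
  set.seed(4)
  gas <- matrix(runif(3000) * 10, ncol = 3)
  sg <- structure_factor(gas, box)
  expect_lt(abs(mean(sg$sk) - 1), 0.15)
  expect_false(has_sharp_peak(sg))
  expect_error(structure_factor(gas, box, k_max = 0.1), "wavevector")
})

test_that("a crystalline binder arrangement shows sharp peaks (order call)", {
  box <- simulation_box(12)
  g <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5)) * 1.1
  sc <- structure_factor(g, box, k_max = 8)
  expect_true(has_sharp_peak(sc))
  expect_gt(max_peak_prominence(sc), 3)
})

test_that("observables agree with the brute-force oracle on small ensembles", {
  for (seed in c(1, 2, 3)) {
    arr <- oracle_ensemble(n = 10, t = 30, seed = seed)
    thr <- 1.8
    oracle <- brute_force_contact_oracle(arr, thr, n_max = 6, s_max = 6)
    ps <- contact_probability_vs_separation(arr, threshold = thr)
    expect_equal(ps$p, oracle$ps$p, tolerance = 1e-12)
    trip <- triplet_contact_probability(arr, threshold = thr, s_max = 6)
    expect_equal(unname(trip), oracle$triplet, tolerance = 1e-12)
    mb <- many_body_contact_frequency(arr, threshold = thr, n_max = 6,
                                      site_stride = 1)
    expect_equal(mb$frequency, oracle$manybody$frequency[2:6],
                 tolerance = 1e-12)
  }
})

test_that("triplet probabilities obey their marginal bound and hand cases", {
  three <- array(cbind(c(0, 0.9, 0.5), c(0, 0, 0.7), c(0, 0, 0)), c(3, 3, 1))
  tp <- triplet_contact_probability(three, threshold = 1.5, s_max = 1)
  expect_equal(tp[1, 1], 1)
  far <- array(cbind(c(0, 5, 10, 15), 0, 0), c(4, 3, 1))
  expect_true(all(triplet_contact_probability(far, 1.5, s_max = 2) == 0))
  # a triplet contact implies each pairwise contact
  arr <- oracle_ensemble(n = 14, t = 25, seed = 5)
  ps <- contact_probability_vs_separation(arr, threshold = 2)
  tp2 <- triplet_contact_probability(arr, threshold = 2, s_max = 5)
  for (s1 in 1:5) for (s2 in 1:5)
    expect_lte(tp2[s1, s2], min(ps$p[s1], ps$p[s2]) + 1e-12)
  expect_error(triplet_contact_probability(array(0, c(2, 3, 1)), 1), "domain")
})

test_that("many-body counting handles degenerate inputs", {
  three <- array(cbind(c(0, 0.9, 0.5), c(0, 0, 0.7), c(0, 0, 0)), c(3, 3, 1))
  mb <- many_body_contact_frequency(three, 1.5, n_max = 3, site_stride = 1)
  expect_equal(mb$frequency[mb$n == 3], 1)
  expect_equal(mb$frequency[mb$n == 2], 0)
  far <- array(cbind(c(0, 5, 10, 15), 0, 0), c(4, 3, 1))
  mbf <- many_body_contact_frequency(far, 1.5, n_max = 4, site_stride = 1)
  expect_true(all(mbf$frequency == 0))
})

test_that("state classification: coil at zero affinity, globule when collapsed", {
  tr <- tiny_globule_traj()
  cls <- classify_state(4.1, 54, tr)
  expect_match(cls$state, "^globule")
  expect_lt(cls$evidence$ratio, 0.8)
  # synthetic coil diagnostics straight from the SAW reference ensemble
  st <- saw_reference_stats(40, 60, seed = 12)
  cls0 <- classify_state(0, 54, list(rg = st$rg, n_beads = 40, sk = NULL))
  expect_equal(cls0$state, "coil")
  # a visibly drifting Rg series is refused
  expect_error(classify_state(2, 54, list(rg = seq(10, 5, length.out = 20),
                                          n_beads = 40)),
               "not-converged")
})

test_that("boundary pair comparison is a null test against itself", {
  tr <- tiny_globule_traj()
  # treat the chain midpoint as a mock boundary; offset 0 compares the
  # symmetric pair with itself
  res <- boundary_pair_distance_test(tr, boundary = 20, separation = 8,
                                     offset = 0)
  expect_equal(res$median_diff, 0)
  res2 <- boundary_pair_distance_test(tr, boundary = 20, separation = 8)
  expect_equal(length(res2$d_sym), length(tr$times))
  expect_error(boundary_pair_distance_test(tr, boundary = 20,
                                           separation = 200),
               "domain")
})
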