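test_that("pivot SAW samples are hard-core and deterministic", {
  arr <- sample_saw_pivot(30, 20, seed = 6)
  for (t in 1:20) {
    d <- stats::dist(arr[, , t])
    expect_gte(min(d), 1)
  }
  arr2 <- sample_saw_pivot(30, 20, seed = 6)
  expect_identical(arr, arr2)
  expect_false(identical(arr, sample_saw_pivot(30, 20, seed = 7)))
  expect_error(sample_saw_pivot(4, 5), ">= 8")
})

test_that("SAW ensembles scale with the Flory exponent", {
  # end-to-end scaling over chain lengths: 2*nu in [1.1, 1.25]
  ns <- c(64, 128, 256, 512)
  e2 <- vapply(ns, function(n)
    mean(saw_reference_stats(n, 400, seed = 31)$e2e^2), numeric(1))
  fit <- stats::coef(stats::lm(log(e2) ~ log(ns)))
  expect_gt(fit[2], 1.1)
  expect_lt(fit[2], 1.25)
})

test_that("SAW contact decay sits in the coil universality class", {
  st <- saw_reference_stats(256, 3000, threshold = 2, s_max = 64, seed = 8)
  fit <- fit_power_law_exponent(st$ps, window = c(10, 64), n_boot = 0)
  expect_gt(fit$alpha, 1.9)
  expect_lt(fit$alpha, 2.3)
})

test_that("Gaussian chains reproduce ideal statistics", {
  b <- 2
  st <- gaussian_reference_stats(256, 3000, b = b, threshold = 2,
                                 s_max = 64, seed = 9)
  # R^2(s) = b^2 s within 3 standard errors
  for (s in c(8, 32, 64)) {
    v <- st$r2$r2[st$r2$s == s]
    n_eff <- 3000 * 256 / s
    expect_lt(abs(v / (b^2 * s) - 1), 3 * sqrt(2 / 3) / sqrt(n_eff) + 0.01)
  }
  fit <- fit_power_law_exponent(st$ps, window = c(10, 64), n_boot = 0)
  expect_gt(fit$alpha, 1.4)
  expect_lt(fit$alpha, 1.6)
  # seeded determinism
  st2 <- gaussian_reference_stats(256, 50, b = b, seed = 9)
  st3 <- gaussian_reference_stats(256, 50, b = b, seed = 9)
  expect_identical(st2$ps$p, st3$ps$p)
})

test_that("block fixtures are deterministic, and the truth scores 100%", {
  fx <- make_block_fixture(n_beads = 40,
                           blocks = data.frame(length = c(10, 10, 10, 10),
                                               color = c(1, 2, 1, 2)),
                           n_traj = 2, n_relax = 5000, n_sample = 5000,
                           sample_interval = 1000, seed = 3)
  fx2 <- make_block_fixture(n_beads = 40,
                            blocks = data.frame(length = c(10, 10, 10, 10),
                                                color = c(1, 2, 1, 2)),
                            n_traj = 2, n_relax = 5000, n_sample = 5000,
                            sample_interval = 1000, seed = 3)
  expect_identical(unclass(fx$target), unclass(fx2$target))
  expect_equal(profile_agreement(fx$profile, fx$profile), 1)
  expect_symmetric(fx$target)

  # multiplicative noise preserves symmetry and the diagonal
  fxn <- make_block_fixture(n_beads = 40,
                            blocks = data.frame(length = c(20, 20),
                                                color = c(1, 2)),
                            n_traj = 2, n_relax = 5000, n_sample = 5000,
                            sample_interval = 1000, noise_cv = 0.1, seed = 4)
  expect_symmetric(fxn$target, tol = 1e-12)
  expect_true(all(diag(unclass(fxn$target)) == 1))
})

test_that("the brute-force oracle guards its scope and degenerate thresholds", {
  arr <- oracle_ensemble(n = 8, t = 10)
  zero <- brute_force_contact_oracle(arr, threshold = 0)
  expect_true(all(zero$ps$p == 0))
  expect_error(brute_force_contact_oracle(array(0, c(60, 3, 2)), 1),
               "oracle-scope")
  expect_error(brute_force_contact_oracle(array(0, c(10, 3, 2000)), 1),
               "oracle-scope")
})
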