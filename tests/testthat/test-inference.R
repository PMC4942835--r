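toy_baseline <- function(n) c(1, (1:(n - 1))^(-1.2))

test_that("surrogate map: inert exactness, colour boost, monotonicity", {
  n <- 30
  p0 <- toy_baseline(n)
  inert <- binding_profile(matrix(0L, n, 2))
  sur0 <- unclass(surrogate_contact_matrix(inert, p0, kappa = 3))
  expect_equal(sur0[1, ], p0, tolerance = 1e-12)
  expect_symmetric(sur0)

  m <- matrix(0L, n, 2)
  m[5, 1] <- 1L; m[20, 1] <- 1L
  one <- binding_profile(m)
  sur1 <- unclass(surrogate_contact_matrix(one, p0, kappa = 3))
  expect_gt(sur1[5, 20], sur0[5, 20])

  # adding a shared colour to a pair never decreases their surrogate contact
  m2 <- m; m2[5, 2] <- 1L; m2[20, 2] <- 1L
  sur2 <- unclass(surrogate_contact_matrix(binding_profile(m2), p0, kappa = 3))
  expect_gt(sur2[5, 20] / sum(sur2), sur1[5, 20] / sum(sur1))
})

test_that("annealing degenerate limits behave", {
  n <- 24
  p0 <- toy_baseline(n)
  m_true <- matrix(0L, n, 1)
  m_true[5:12, 1] <- 1L
  truth <- binding_profile(m_true)
  target <- surrogate_contact_matrix(truth, p0, kappa = 3)

  # huge parsimony price: the all-inert profile wins
  pr <- anneal_binding_profile(target, 1, anneal_schedule(sweeps = 5,
                                                          n_levels = 8),
                               lambda = 100, kappa = 3, baseline = p0,
                               coarse_n = 64, seed = 2)
  expect_equal(sum(pr$multiplicities), 0)

  # zero temperature, initialised at the truth: nothing changes
  pr2 <- suppressWarnings(
    anneal_binding_profile(target, 1,
                           anneal_schedule(t0 = 1e-12, sweeps = 3,
                                           n_levels = 2),
                           lambda = 0, kappa = 3, baseline = p0,
                           init = truth, seed = 3))
  expect_equal(pr2$multiplicities, truth$multiplicities)

  expect_error(anneal_binding_profile(matrix(1:9, 3), 1), "symmetric")
})

test_that("annealing recovers a known one-colour arrangement from its surrogate", {
  n <- 40
  p0 <- toy_baseline(n)
  m_true <- matrix(0L, n, 1)
  m_true[c(6:15, 26:35), 1] <- 1L
  truth <- binding_profile(m_true)
  target <- surrogate_contact_matrix(truth, p0, kappa = 3)
  pr <- anneal_binding_profile(target, 1, anneal_schedule(),
                               lambda = 1e-6, kappa = 3, baseline = p0,
                               seed = 4)
  expect_gte(profile_agreement(pr, truth), 0.9)
  # best-ever cost trace is non-increasing within each resolution
  tr <- attr(pr, "cost_trace")
  for (res in unique(tr$resolution))
    expect_true(all(diff(tr$best_cost[tr$resolution == res]) <= 1e-15))
})

test_that("parsimony removes spurious sites before true block sites", {
  n <- 40
  p0 <- toy_baseline(n)
  m_true <- matrix(0L, n, 1)
  m_true[c(6:15, 26:35), 1] <- 1L
  truth <- binding_profile(m_true)
  set.seed(9)
  tm <- unclass(surrogate_contact_matrix(truth, p0, kappa = 3))
  noise <- matrix(rlnorm(n * n, 0, 0.05), n)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  target <- tm * noise
  tot <- sapply(c(0, 2e-5, 2e-3), function(lam) {
    pr <- anneal_binding_profile(target, 1, anneal_schedule(sweeps = 20,
                                                            n_levels = 25),
                                 lambda = lam, kappa = 3, baseline = p0,
                                 seed = 5)
    sum(pr$multiplicities)
  })
  expect_true(all(diff(tot) <= 0))
  expect_gt(tot[1], 0)
})

test_that("matrix Pearson correlations: identity, sign flip, null", {
  set.seed(31)
  a <- matrix(rnorm(100 * 100), 100)
  a <- a + t(a)
  expect_equal(matrix_pearson(a, a), 1)
  expect_equal(matrix_pearson(a, -a), -1)
  b <- matrix(rnorm(100 * 100), 100)
  b <- b + t(b)
  expect_lt(abs(matrix_pearson(a, b)), 0.05)
  strat <- matrix_pearson(a, a, "distance_stratified")
  expect_equal(strat$mean, 1, tolerance = 1e-12)
  expect_error(matrix_pearson(a, b[1:50, 1:50]), "alignment")
})

test_that("profile agreement is permutation-invariant and exact on itself", {
  m <- matrix(0L, 20, 2)
  m[1:10, 1] <- 1L; m[11:20, 2] <- 1L
  p <- binding_profile(m)
  expect_equal(profile_agreement(p, p), 1)
  swapped <- binding_profile(m[, c(2, 1)])
  expect_equal(profile_agreement(p, swapped), 1)
})
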