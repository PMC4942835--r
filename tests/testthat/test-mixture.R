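test_that("the analytic library has the advertised pure-state shapes", {
  lib <- synthetic_state_library()
  expect_named(lib$curves,
               c("coil", "theta", "globule_disordered", "globule_ordered"))
  a_coil <- fit_power_law_exponent(lib$curves$coil, n_boot = 0)$alpha
  expect_equal(a_coil, 2.1, tolerance = 1e-6)
  a_theta <- fit_power_law_exponent(lib$curves$theta, n_boot = 0)$alpha
  expect_equal(a_theta, 1.5, tolerance = 1e-6)
  # disordered globule: slope over the last decade is flatter than -0.3
  dis <- lib$curves$globule_disordered
  last_dec <- fit_power_law_exponent(dis, window = c(100, 1000), n_boot = 0)
  expect_lt(last_dec$alpha, 0.3)
  # ordered globule decays ~ s^-1 before its plateau
  pre <- fit_preplateau_exponent(lib$curves$globule_ordered, n_boot = 0)
  expect_lt(abs(pre$alpha - 1), 0.1)
})

test_that("mixture evaluation is linear, convex and anchored", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5, 7.5, by = 0.1)
  coil_only <- evaluate_mixture(c(1, 0, 0, 0), 1e5, lib, sg)
  expect_equal(coil_only$p, (sg / 1e5)^(-2.1), tolerance = 1e-6)

  half <- evaluate_mixture(c(0.5, 0, 0, 0.5), 1e5, lib, sg)
  ordr <- evaluate_mixture(c(0, 0, 0, 1), 1e5, lib, sg)
  expect_equal(half$p, (coil_only$p + ordr$p) / 2, tolerance = 1e-9)

  set.seed(3)
  for (k in 1:10) {
    w <- rexp(4); w <- w / sum(w)
    mx <- evaluate_mixture(w, 1e5, lib, sg)
    lo <- pmin(coil_only$p, ordr$p,
               evaluate_mixture(c(0, 1, 0, 0), 1e5, lib, sg)$p,
               evaluate_mixture(c(0, 0, 1, 0), 1e5, lib, sg)$p)
    hi <- pmax(coil_only$p, ordr$p,
               evaluate_mixture(c(0, 1, 0, 0), 1e5, lib, sg)$p,
               evaluate_mixture(c(0, 0, 1, 0), 1e5, lib, sg)$p)
    expect_true(all(mx$p >= lo - 1e-12 & mx$p <= hi + 1e-12))
  }
  expect_error(evaluate_mixture(c(1, 0, 0, 0), 10, lib, c(1, 1e6)),
               "extrapolation")
  expect_error(evaluate_mixture(c(2, 0, 0, 0), 1e5, lib, sg), "sum to 1")
})

test_that("self-fits recover vertices with near-zero chi^2", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5.1, 7.6, by = 0.05)
  obs <- evaluate_mixture(c(1, 0, 0, 0), 1e5, lib, sg)
  fit <- fit_mixture(obs, lib, n_boot = 0)
  expect_lt(abs(fit$weights["coil"] - 1), 0.02)
  expect_lt(fit$chi2, 1e-4)
})

test_that("mixture fits recover known compositions and scale factors", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5.1, 7.6, by = 0.05)
  cases <- list(c(0.4, 0, 0, 0.6),
                c(0.3, 0.3, 0.4, 0),
                c(0.25, 0.25, 0.25, 0.25))
  for (w in cases) {
    obs <- evaluate_mixture(w, 1e5, lib, sg)
    fit <- fit_mixture(obs, lib, n_boot = 0)
    expect_lt(max(abs(fit$weights - w)), 0.05)
    expect_lt(abs(log10(fit$g / 1e5)), log10(1.2))
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  }
})

test_that("round-trip recovery holds on random simplex points (property)", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5.1, 7.6, by = 0.05)
  sg2 <- 10^seq(5.4, 7.6, by = 0.05)
  set.seed(17)
  for (k in 1:6) {
    w <- rexp(4); w <- w / sum(w)
    obs <- evaluate_mixture(w, 2e5, lib, sg2)
    fit <- fit_mixture(obs, lib, n_boot = 0)
    expect_lt(max(abs(fit$weights - w)), 0.05)
  }
})

test_that("chi^2 does not increase when the generating state is available", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5.1, 7.6, by = 0.05)
  obs <- evaluate_mixture(c(0.2, 0, 0, 0.8), 1e5, lib, sg)
  fit_full <- fit_mixture(obs, lib, n_boot = 0)
  # cripple the library: replace the generating ordered state by a coil copy
  lib2 <- lib
  lib2$curves$globule_ordered <- lib$curves$coil
  fit_crip <- fit_mixture(obs, lib2, n_boot = 0)
  expect_lte(fit_full$chi2, fit_crip$chi2 + 1e-12)
})

test_that("noisy observations stay within the stated tolerance", {
  lib <- synthetic_state_library()
  sg <- 10^seq(5.1, 7.6, by = 0.05)
  truth <- c(0.4, 0, 0.2, 0.4)  # 3-component mixture
  clean <- evaluate_mixture(truth, 1e5, lib, sg)
  set.seed(23)
  sdlog <- sqrt(log(1 + 0.05^2))
  errs <- vapply(1:5, function(k) {
    noisy <- ps_curve(clean$s, clean$p * rlnorm(length(clean$p),
                                                -sdlog^2 / 2, sdlog))
    fit <- fit_mixture(noisy, lib, n_boot = 0)
    max(abs(fit$weights - truth))
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
  expect_lt(max(errs), 0.15)
})

test_that("the simulated library builds at smoke scale", {
  # N = 340 is the smallest chain giving the required >= 2.5 decades of
  # support; one short trajectory per globular state, no phase gate (the
  # mislabeled-state branch is a one-line classify_state dispatch, and
  # classify_state itself is tested in test-observables)
  lib <- build_pure_state_library(n_beads = 340, n_samples = 200,
                                  n_traj = 1, n_relax = 50000,
                                  n_sample = 25000, sample_interval = 2500,
                                  verify_phase = FALSE, seed = 5)
  expect_s3_class(lib, "sbs_state_library")
  expect_named(lib$curves,
               c("coil", "theta", "globule_disordered", "globule_ordered"))
  for (cv in lib$curves) expect_true(all(cv$p > 0))
})

test_that("the observed support must overlap the library", {
  lib <- synthetic_state_library()
  short <- ps_curve(c(10, 20, 50, 100), c(1, 0.5, 0.2, 0.1))
  expect_error(fit_mixture(short, lib), "fit-domain")
})
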