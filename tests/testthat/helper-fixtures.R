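# Shared fixtures, built in code and memoised per test session so the
# heavier simulation-backed objects are paid for once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# a small polymer+binder system in the deep-attraction regime
tiny_system <- function(n = 40, e_int = 4.1, edge = 14, binders = 40) {
  sbs_system(build_homopolymer(n), simulation_box(edge),
             force_field(e_int = e_int), binders = binders)
}

# short collapsed trajectory of the tiny system
tiny_globule_traj <- function() {
  memo("tiny_globule", function()
    run_trajectory(tiny_system(), 20000, sample_interval = 2000, seed = 3,
                   n_relax = 40000))
}

# random loose ensemble (Gaussian chains) for oracle comparisons
oracle_ensemble <- function(n = 12, t = 40, seed = 7) {
  sample_gaussian_chain(n, b = 1.2, n_samples = t, seed = seed)
}

expect_symmetric <- function(m, tol = 1e-12) {
  v <- unclass(m)
  expect_lt(max(abs(v - t(v))), tol)
}
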