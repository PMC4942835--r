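test_that("pair energies match their closed forms", {
  ff <- force_field(e_int = 2.5)
  # WCA: zero at its cutoff, eps at r = sigma
  expect_equal(pair_energy(2^(1 / 6), "wca", ff), 0)
  expect_equal(pair_energy(1, "wca", ff), ff$eps_rep)
  expect_equal(pair_energy(3, "wca", ff), 0)
  # FENE diverges at r0
  expect_error(pair_energy(1.5, "fene", ff), "overstretch")
  expect_equal(pair_energy(0.5, "fene", ff),
               -0.5 * 30 * 1.5^2 * log(1 - (0.5 / 1.5)^2))
  # attraction: zero at/beyond cutoff, scaled by the colour affinity
  expect_equal(pair_energy(1.5, "attract", ff), 0)
  expect_equal(pair_energy(1.6, "attract", ff), 0)
  r <- 1.1
  shift <- 4 * 2.5 * ((1 / 1.5)^12 - (1 / 1.5)^6)
  expect_equal(pair_energy(r, "attract", ff),
               4 * 2.5 * ((1 / r)^12 - (1 / r)^6) - shift)
  expect_error(pair_energy(0, "wca", ff), "singularity")
})

test_that("compiled energy matches R closed forms on dimers", {
  ff <- force_field(e_int = 3)
  box <- simulation_box(20)
  # bead-bead dimer at r: FENE + WCA
  for (r in c(0.9, 1.0, 1.2)) {
    ch <- build_homopolymer(2)
    ch$positions <- rbind(c(5, 5, 5), c(5 + r, 5, 5))
    sys <- sbs_system(ch, box, ff, binders = 0)
    expect_equal(total_energy(sys, ch$positions),
                 pair_energy(r, "fene", ff) + pair_energy(r, "wca", ff),
                 tolerance = 1e-12)
  }
  # bead-binder pair of matching colour: attraction only (not WCA + LJ)
  ch <- build_homopolymer(2)
  ch$positions <- rbind(c(5, 5, 5), c(6, 5, 5))
  sys <- sbs_system(ch, box, ff, binders = 1)
  pos <- rbind(ch$positions, c(5, 5 + 1.2, 5))
  e_binder <- total_energy(sys, pos) -
    (pair_energy(1, "fene", ff) + pair_energy(1, "wca", ff) +
       pair_energy(sqrt(1 + 1.2^2), "attract", ff))
  expect_equal(e_binder, pair_energy(1.2, "attract", ff), tolerance = 1e-12)
})

test_that("forces are the exact gradient of the energy (finite differences)", {
  set.seed(42)
  box <- simulation_box(12)
  ch <- build_homopolymer(6)
  ch <- initialize_saw_configuration(ch, box, seed = 9)
  sys <- sbs_system(ch, box, force_field(e_int = 2), binders = 3)
  pos <- init_pos <- rbind(ch$positions,
                           cpp_place <- matrix(c(2, 2, 2, 9, 9, 9, 5, 2, 8),
                                               ncol = 3, byrow = TRUE))
  f <- total_forces(sys, pos)
  # Newton's third law
  expect_lt(max(abs(colSums(f))), 1e-10)
  h <- 1e-6
  for (k in sample(length(pos), 12)) {
    pp <- pos; pp[k] <- pp[k] + h
    pm <- pos; pm[k] <- pm[k] - h
    fd <- -(total_energy(sys, pp) - total_energy(sys, pm)) / (2 * h)
    expect_equal(f[k], fd, tolerance = 1e-5)
  }
})

test_that("free flight and energy conservation in the deterministic limit", {
  box <- simulation_box(20)
  # fene_k = 0 and separation beyond the WCA cutoff: no force at all
  ff0 <- force_field(e_int = 0, fene_k = 0)
  ch <- build_homopolymer(2)
  ch$positions <- rbind(c(5, 5, 5), c(6.3, 5, 5))
  sys <- sbs_system(ch, box, ff0, binders = 0)
  v <- rbind(c(0.3, -0.2, 0.1), c(-0.1, 0.2, 0.05))
  st <- langevin_step(sys, ch$positions, v, dt = 0.01, gamma = 0, seed = 1)
  expect_equal(st$positions, ch$positions + v * 0.01, tolerance = 1e-12)
  expect_equal(st$velocities, v, tolerance = 1e-12)

  # FENE dimer, gamma = 0: total energy drift < 1e-4 relative over 1e4 steps
  ff <- force_field(e_int = 0)
  ch$positions <- rbind(c(5, 5, 5), c(6.2, 5, 5))
  sys <- sbs_system(ch, box, ff, binders = 0)
  v0 <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0))
  etot <- function(pos, vel) total_energy(sys, pos) + 0.5 * sum(vel^2)
  e0 <- etot(ch$positions, v0)
  tr <- run_trajectory(sys, 10000, sample_interval = 10000, dt = 0.001,
                       gamma = 0,
                       init = list(positions = ch$positions, velocities = v0))
  e1 <- etot(tr$final$positions, tr$final$velocities)
  expect_lt(abs(e1 - e0) / abs(e0), 1e-4)
})

test_that("thermostatted runs satisfy equipartition within 3 standard errors", {
  sys <- tiny_system(n = 20, e_int = 1, edge = 12, binders = 20)
  tr <- run_trajectory(sys, 30000, sample_interval = 1000, dt = 0.003,
                       gamma = 1, seed = 8, n_relax = 2000)
  ke <- tr$kinetic_per_dof[-1]
  se <- sd(ke) / sqrt(length(ke))
  expect_lt(abs(mean(ke) - 0.5), 3 * se + 0.005)
})

test_that("trajectories are reproducible and sampled per contract", {
  sys <- tiny_system(n = 10, e_int = 1, edge = 10, binders = 5)
  t0 <- run_trajectory(sys, 0, sample_interval = 100, seed = 5)
  expect_equal(length(t0$times), 1)

  t1 <- run_trajectory(sys, 1000, sample_interval = 100, seed = 5)
  t2 <- run_trajectory(sys, 1000, sample_interval = 100, seed = 5)
  expect_identical(t1$beads, t2$beads)
  expect_identical(t1$binders, t2$binders)
  expect_equal(length(t1$times), 11)
  t3 <- run_trajectory(sys, 1000, sample_interval = 100, seed = 6)
  expect_false(identical(t1$beads, t3$beads))

  # bond-length bound holds in every snapshot
  for (s in seq_along(t1$times)) {
    b <- t1$beads[, , s]
    bl <- sqrt(rowSums((b[-1, ] - b[-nrow(b), ])^2))
    expect_lt(max(bl), 1.5)
  }
})

test_that("overstretched configurations are rejected with a diagnostic", {
  box <- simulation_box(20)
  ch <- build_homopolymer(2)
  ch$positions <- rbind(c(5, 5, 5), c(6.49, 5, 5))
  sys <- sbs_system(ch, box, force_field(e_int = 0), binders = 0)
  expect_error(total_forces(sys, ch$positions), "overstretch")
  expect_error(total_energy(sys, ch$positions), "overstretch")
})
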