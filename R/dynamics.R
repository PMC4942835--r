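ff_as_list <- function(ff) {
  list(eps_rep = ff$eps_rep, r_cut_attr = ff$r_cut_attr, fene_k = ff$fene_k,
       fene_r0 = ff$fene_r0, kT = ff$kT)
}

#' Pair interaction energies
#'
#' Closed-form pair potentials of the model, in k_BT:
#' * `wca`: `4 eps ((sigma/r)^12 - (sigma/r)^6) + eps` for `r < 2^(1/6)`,
#'   zero beyond (purely repulsive).
#' * `fene`: `-0.5 k r0^2 log(1 - (r/r0)^2)`; diverges at the maximum bond
#'   extension `r0` (overstretch error for `r >= r0`).
#' * `attract`: truncated-and-shifted Lennard-Jones of depth
#'   `e_int[color]`, zero at and beyond `r_cut_attr`.
#'
#' @param r distance(s) in sigma, > 0.
#' @param kind one of `"wca"`, `"fene"`, `"attract"`.
#' @param ff an [force_field()].
#' @param color colour index selecting the affinity for `"attract"`.
#' @return energy (vectorised over `r`) in k_BT.
#' @export
pair_energy <- function(r, kind = c("wca", "fene", "attract"), ff, color = 1) {
  kind <- match.arg(kind)
  if (any(r <= 0)) stop("singularity: r must be > 0")
  switch(kind,
    wca = {
      out <- numeric(length(r))
      w <- r < 2^(1 / 6) * ff$sigma
      sr6 <- (ff$sigma / r[w])^6
      out[w] <- 4 * ff$eps_rep * (sr6^2 - sr6) + ff$eps_rep
      out
    },
    fene = {
      if (any(r >= ff$fene_r0))
        stop("overstretch: FENE energy diverges at r >= r0")
      -0.5 * ff$fene_k * ff$fene_r0^2 * log(1 - (r / ff$fene_r0)^2)
    },
    attract = {
      e <- ff$e_int[color]
      out <- numeric(length(r))
      w <- r < ff$r_cut_attr
      sr6 <- (ff$sigma / r[w])^6
      sc6 <- (ff$sigma / ff$r_cut_attr)^6
      out[w] <- 4 * e * (sr6^2 - sr6) - 4 * e * (sc6^2 - sc6)
      out
    })
}

state_matrices <- function(system, positions) {
  list(pos = positions,
       mult = system$chain$colors,
       bcol = as.integer(system$binder_colors),
       eint = as.numeric(system$ff$e_int))
}

#' Total forces on all particles
#'
#' Analytic gradient of the total potential (FENE + WCA + colour-matched
#' attraction) under the minimum-image convention. Newton's third law holds:
#' deterministic pair forces sum to zero.
#'
#' @param system an [sbs_system()].
#' @param positions (N+M) x 3 matrix: beads first, then binders.
#' @return (N+M) x 3 matrix of forces (k_BT / sigma).
#' @export
total_forces <- function(system, positions) {
  if (min(stats::dist(positions)) < 1e-6 && nrow(positions) > 1)
    stop("singularity: overlapping particles")
  s <- state_matrices(system, positions)
  cpp_forces(s$pos, s$mult, s$bcol, s$eint, system$box$edge,
             ff_as_list(system$ff))
}

#' Total potential energy
#'
#' @inheritParams total_forces
#' @return scalar potential energy (k_BT).
#' @export
total_energy <- function(system, positions) {
  s <- state_matrices(system, positions)
  cpp_energy(s$pos, s$mult, s$bcol, s$eint, system$box$edge,
             ff_as_list(system$ff))
}

init_positions <- function(system, seed) {
  chain <- system$chain
  if (is.null(chain$positions))
    chain <- initialize_saw_configuration(chain, system$box, seed)
  m <- sum(system$binders)
  bind <- if (m > 0)
    cpp_place_binders(chain$positions, m, system$box$edge, 0.9, seed + 104729)
  else matrix(numeric(0), 0, 3)
  rbind(chain$positions, bind)
}

#' One Langevin (BAOAB) step
#'
#' Advances the system by a single timestep of the BAOAB splitting of
#' underdamped Langevin dynamics at kT = 1. Deterministic for a given seed.
#' With `gamma = 0` and zero forces this reduces to free flight.
#'
#' @param system an [sbs_system()].
#' @param positions,velocities (N+M) x 3 matrices.
#' @param dt timestep (tau).
#' @param gamma friction (1/tau).
#' @param seed seed for the noise stream.
#' @return list with updated `positions` and `velocities`.
#' @export
langevin_step <- function(system, positions, velocities, dt = 0.012,
                          gamma = 0.5, seed = 1) {
  s <- state_matrices(system, positions)
  out <- cpp_run_md(s$pos, velocities, s$mult, s$bcol, s$eint,
                    system$box$edge, ff_as_list(system$ff), dt, gamma,
                    1L, 1L, seed)
  if (!out$stable)
    stop("step-rejection: bond overstretch persisted after timestep halving")
  n_snap <- dim(out$positions)[3]
  list(positions = out$positions[, , n_snap, drop = TRUE],
       velocities = out$velocities)
}

#' Run a Langevin trajectory
#'
#' Integrates the polymer-binder system and records snapshots every
#' `sample_interval` steps (the initial state is snapshot 1). Chain positions
#' are grown as a self-avoiding conformation from the run seed when unset;
#' binders are placed uniformly without overlaps. Velocities start from the
#' Maxwell-Boltzmann distribution. Trajectories are a pure function of
#' (system, parameters, seed). Positions are stored unwrapped; apply the
#' minimum image convention when distances across the periodic box are
#' needed.
#'
#' @param system an [sbs_system()].
#' @param n_steps number of integration steps (0 = initial snapshot only).
#' @param sample_interval steps between stored snapshots.
#' @param dt timestep in tau (default 0.012, stable for FENE k = 30).
#' @param gamma Langevin friction in 1/tau.
#' @param seed run seed; all randomness (initial conformation, binder
#'   placement, velocities, noise) derives from it.
#' @param n_relax steps of un-sampled relaxation run before sampling starts
#'   (0 = none); used to discard the approach to equilibrium.
#' @param init optional list(positions, velocities) to continue from.
#' @return an `sbs_trajectory`: list with `beads` (N x 3 x S array, unwrapped),
#'   `binders` (M x 3 x S), `times`, `rg` (bead gyration radius per snapshot,
#'   including relaxation when requested), `kinetic_per_dof`, `system`,
#'   `final` state, and provenance fields.
#' @export
run_trajectory <- function(system, n_steps, sample_interval = 1000,
                           dt = 0.012, gamma = 0.5, seed = 1, n_relax = 0,
                           init = NULL) {
  if (sample_interval < 1) stop("sample_interval must be >= 1")
  n <- system$chain$n_beads
  pos <- if (is.null(init)) init_positions(system, seed) else init$positions
  vel <- if (is.null(init) || is.null(init$velocities))
    matrix(numeric(0), 0, 3) else init$velocities
  s <- state_matrices(system, pos)
  rg_relax <- numeric(0)
  if (n_relax > 0) {
    rel <- cpp_run_md(pos, vel, s$mult, s$bcol, s$eint, system$box$edge,
                      ff_as_list(system$ff), dt, gamma, as.integer(n_relax),
                      as.integer(min(n_relax, sample_interval)), seed)
    if (!rel$stable) stop("instability during relaxation (NaN/overstretch)")
    n_snap <- dim(rel$positions)[3]
    pos <- rel$positions[, , n_snap, drop = TRUE]
    vel <- rel$velocities
    rg_relax <- rel$rg
  }
  out <- cpp_run_md(pos, vel, s$mult, s$bcol, s$eint, system$box$edge,
                    ff_as_list(system$ff), dt, gamma, as.integer(n_steps),
                    as.integer(sample_interval), seed + 7919)
  arr <- out$positions
  S <- dim(arr)[3]
  traj <- structure(list(
    beads = arr[seq_len(n), , , drop = FALSE],
    binders = arr[-seq_len(n), , , drop = FALSE],
    times = out$times + n_relax * dt,
    rg = out$rg, rg_relax = rg_relax,
    kinetic_per_dof = out$kinetic_per_dof,
    system = system, dt = dt, gamma = gamma, seed = seed,
    sample_interval = sample_interval, n_relax = n_relax,
    stable = out$stable, n_halved_steps = out$n_halved_steps,
    final = list(positions = arr[, , S, drop = TRUE],
                 velocities = out$velocities)),
    class = "sbs_trajectory")
  if (!out$stable)
    warning("trajectory went unstable; returning the stable prefix (",
            S, " snapshots)")
  traj
}

#' Relax a system to its gyration-radius plateau
#'
#' Integrates un-sampled relaxation chunks until the chain's Rg trace is flat
#' (and, when a collapsed phase is expected, until the chain has actually
#' collapsed: the coil-globule transition is nucleation-limited, so a fixed
#' relaxation length leaves an occasional trajectory stranded in the
#' metastable open state). Deterministic given the seed.
#'
#' @param system an [sbs_system()].
#' @param seed RNG seed.
#' @param n_relax nominal (first-chunk) relaxation steps.
#' @param max_relax hard cap on total relaxation steps.
#' @param expect_collapse require Rg to drop below `collapse_frac` of its
#'   running maximum before a flat trace counts as equilibrated.
#' @param collapse_frac collapse criterion (fraction of the running maximum).
#' @param flat_tol relative spread of the last three chunk means accepted as
#'   flat.
#' @param dt,gamma integrator parameters.
#' @return list with `state` (positions/velocities for `init =` of
#'   [run_trajectory()]), `rg` (chunk-mean trace), `steps`, `converged`.
#' @export
relax_state <- function(system, seed, n_relax, max_relax = 4 * n_relax,
                        expect_collapse = TRUE, collapse_frac = 0.75,
                        flat_tol = 0.1, dt = 0.012, gamma = 0.5) {
  state <- NULL
  means <- numeric(0)
  rg0 <- NA_real_
  total <- 0
  chunk <- n_relax
  i <- 0
  repeat {
    tr <- run_trajectory(system, chunk,
                         sample_interval = max(1000, chunk %/% 10),
                         dt = dt, gamma = gamma,
                         seed = seed + 1000003 * (i + 1), init = state)
    state <- tr$final
    total <- total + chunk
    if (i == 0) {
      rg0 <- tr$rg[1]  # initial (open) conformation
      # segment the nominal chunk so an early collapse is seen as flat
      thirds <- split(tr$rg, cut(seq_along(tr$rg), 3))
      means <- vapply(thirds, mean, numeric(1))
    } else {
      means <- c(means, mean(tr$rg))
    }
    flat <- length(means) >= 3 && {
      rc <- utils::tail(means, 3)
      (max(rc) - min(rc)) / mean(rc) < flat_tol
    }
    # collapsed when Rg has contracted materially below the initial open
    # conformation, or sits within 40% of the dense-sphere estimate
    # Rg = sqrt(3/5) (N / (8 phi))^(1/3) at packing fraction phi ~ 0.35.
    # The relative criterion handles multi-domain profiles (inert spacers
    # give several sub-globules, with Rg above the single-sphere value);
    # the absolute one matters at small N, where the grown open
    # conformation is barely larger than the globule.
    rg_compact <- 1.4 * sqrt(3 / 5) * (system$chain$n_beads / 2.8)^(1 / 3)
    rg_now <- utils::tail(means, 1)
    collapsed <- !expect_collapse ||
      rg_now < collapse_frac * max(rg0, means) || rg_now < rg_compact
    if ((flat && collapsed) || total >= max_relax)
      return(list(state = state, rg = means, steps = total,
                  converged = flat && collapsed))
    i <- i + 1
    chunk <- max(20000, n_relax %/% 3)
  }
}

# Pools ensemble contact maps over independent, *equilibrated* trajectories.
# A trajectory whose relaxation misses the convergence criterion (the
# coil-globule collapse is nucleation-limited and a rare seed stays trapped
# in the metastable open state within the step cap) is excluded and replaced
# by the next seed: exclusion is by the pre-registered equilibration
# criterion, never by the measured observable. Deterministic given seeds.
collect_equilibrium_maps <- function(system, n_traj, seed_base, n_relax,
                                     max_relax, n_sample, sample_interval,
                                     threshold, dt = 0.012, gamma = 0.5,
                                     expect_collapse = TRUE, adaptive = TRUE,
                                     max_attempts = 2 * n_traj + 3) {
  # adaptive = FALSE: fixed-length relaxation, no convergence gate. Used for
  # structured (multi-colour / spacer) systems whose equilibrium is a
  # multi-blob state with large, slow Rg fluctuations: a flat-and-collapsed
  # criterion is ill-defined there, while the homopolymer criterion is
  # well-defined and kept for the phase-diagram ensembles.
  maps <- list(); rg <- list(); last <- NULL
  attempts <- 0
  rx_last <- NULL
  while (length(maps) < n_traj && attempts < max_attempts) {
    attempts <- attempts + 1
    sd <- seed_base + attempts
    if (!adaptive) {
      rel <- run_trajectory(system, n_relax,
                            sample_interval = max(1000, n_relax %/% 10),
                            dt = dt, gamma = gamma, seed = sd + 1000003)
      rx <- list(state = rel$final, rg = rel$rg, steps = n_relax,
                 converged = TRUE)
    } else {
      rx <- relax_state(system, seed = sd, n_relax = n_relax,
                        max_relax = max_relax, dt = dt, gamma = gamma,
                        expect_collapse = expect_collapse)
    }
    rx_last <- list(rx = rx, sd = sd)
    if (!rx$converged) {
      warning(sprintf("trajectory seed %s not equilibrated within %g steps; replaced",
                      format(sd), rx$steps))
      next
    }
    tr <- run_trajectory(system, n_sample, sample_interval = sample_interval,
                         dt = dt, gamma = gamma, seed = sd, init = rx$state)
    maps[[length(maps) + 1]] <- unclass(contact_map(tr, threshold))
    rg[[length(rg) + 1]] <- tr$rg
    last <- tr
  }
  if (length(maps) == 0) {
    # nothing equilibrated within the cap (tiny smoke-scale protocols):
    # proceed once, explicitly flagged, rather than fail outright
    warning("no trajectory equilibrated within the step cap; proceeding unequilibrated")
    tr <- run_trajectory(system, n_sample, sample_interval = sample_interval,
                         dt = dt, gamma = gamma, seed = rx_last$sd,
                         init = rx_last$rx$state)
    maps[[1]] <- unclass(contact_map(tr, threshold))
    rg[[1]] <- tr$rg
    last <- tr
  } else if (length(maps) < n_traj) {
    warning(sprintf("only %d of %d trajectories equilibrated within the attempt budget",
                    length(maps), n_traj))
  }
  list(maps = maps, rg = rg, last = last, attempts = attempts,
       n_collected = length(maps))
}

#' @export
print.sbs_trajectory <- function(x, ...) {
  cat(sprintf("SBS trajectory: %d snapshots, t in [%.3g, %.3g] tau, N = %d, M = %d\n",
              length(x$times), min(x$times), max(x$times),
              dim(x$beads)[1], dim(x$binders)[1]))
  cat(sprintf("  Rg: %.3g -> %.3g sigma; seed %s%s\n", x$rg[1],
              x$rg[length(x$rg)], format(x$seed),
              if (x$stable) "" else " [UNSTABLE, truncated]"))
  invisible(x)
}
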