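# Default surrogate contrast, calibrated once against molecular dynamics on
# the two-colour block reference system (N = 200, calibrate_kappa() gave
# kappa = 2.19, surrogate-vs-MD Pearson 0.93; see the methods vignette).
# Not tuned per target.
KAPPA_DEFAULT <- 2.2

#' Binding-site profile
#'
#' Per-bead assignment of binding-site colours and multiplicities (a row of
#' zeros = inert bead), plus the per-colour binder concentration and affinity
#' used when the profile is simulated.
#'
#' @param multiplicities N x n_colors matrix of nonnegative integers.
#' @param e_int affinity per colour (k_BT).
#' @param concentration binder concentration per colour (nmol/l).
#' @param m_max largest allowed multiplicity (validation only).
#' @return an `sbs_binding_profile`.
#' @export
binding_profile <- function(multiplicities, e_int = 4.1, concentration = 54,
                            m_max = 3) {
  m <- as.matrix(multiplicities)
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("multiplicities must be nonnegative integers")
  if (any(m > m_max)) stop("multiplicities exceed m_max")
  nc <- ncol(m)
  structure(list(multiplicities = m, n_beads = nrow(m), n_colors = nc,
                 e_int = rep_len(e_int, nc),
                 concentration = rep_len(concentration, nc), m_max = m_max),
            class = "sbs_binding_profile")
}

#' @export
print.sbs_binding_profile <- function(x, ...) {
  inert <- sum(rowSums(x$multiplicities) == 0)
  cat(sprintf("SBS binding profile: N = %d beads, %d colours, %d inert beads, total multiplicity %d\n",
              x$n_beads, x$n_colors, inert, sum(x$multiplicities)))
  invisible(x)
}

#' Distance-decay baseline of a contact matrix
#'
#' Mean over each diagonal |i - j|, with non-positive diagonals floored to
#' half the smallest positive value (the surrogate needs a strictly positive
#' baseline).
#'
#' @param target square contact matrix.
#' @return numeric vector of length N: P0 at separations 0..N-1.
#' @export
profile_baseline <- function(target) {
  n <- nrow(target)
  v <- unclass(target)
  p0 <- vapply(0:(n - 1), function(s)
    mean(v[cbind(seq_len(n - s), seq_len(n - s) + s)]), numeric(1))
  pos <- p0[p0 > 0]
  if (length(pos) == 0) stop("target matrix has no positive entries")
  p0[p0 <= 0] <- min(pos) / 2
  p0
}

#' Fast surrogate contact matrix of a binding profile
#'
#' `M_ij = P0(|i - j|) * (1 + kappa * sum_c min(m_ic, m_jc)) / Z`: the
#' distance-decay baseline boosted by the shared binding valence of each
#' bead pair, with `Z` restoring the baseline's total contact mass, so the
#' all-inert profile returns the baseline exactly. A cheap stand-in for the
#' MD-generated map used inside the annealing loop only; `kappa` was
#' calibrated once against MD on the two-colour block system.
#'
#' @param profile an `sbs_binding_profile`.
#' @param baseline distance decay: an `sbs_ps_curve` (bead units, covering
#'   1..N-1; the s = 0 diagonal value is taken as 1) or a numeric vector of
#'   length N giving P0 at separations 0..N-1.
#' @param kappa contrast of the valence boost.
#' @return an `sbs_contact_matrix`.
#' @export
surrogate_contact_matrix <- function(profile, baseline, kappa = KAPPA_DEFAULT) {
  n <- profile$n_beads
  p0 <- baseline_vector(baseline, n)
  raw <- cpp_surrogate(p0, profile$multiplicities, kappa)
  base_mass <- sum(p0 * c(n, 2 * (n - seq_len(n - 1))))
  out <- raw * (base_mass / sum(raw))
  new_contact_matrix(out, normalization = "surrogate")
}

baseline_vector <- function(baseline, n) {
  if (inherits(baseline, "sbs_ps_curve")) {
    if (max(baseline$s) < n - 1)
      stop("baseline curve must cover separations 1..N-1")
    p0 <- c(1, interp_loglog(baseline, seq_len(n - 1)))
  } else {
    p0 <- as.numeric(baseline)
    if (length(p0) != n) stop("baseline vector must have length N")
  }
  if (any(p0 <= 0)) stop("baseline must be strictly positive")
  p0
}

#' Annealing schedule
#'
#' @param t0 initial Monte Carlo temperature; `NA` picks it automatically so
#'   the initial uphill acceptance is about one half.
#' @param cool geometric cooling factor per level (strictly < 1).
#' @param sweeps sweeps (N attempted moves each) per temperature level.
#' @param n_levels temperature levels.
#' @return an `sbs_anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = NA, cool = 0.9, sweeps = 50, n_levels = 40) {
  if (!is.na(t0) && t0 <= 0) stop("t0 must be positive")
  if (!(cool > 0 && cool < 1)) stop("cooling factor must be in (0, 1)")
  if (sweeps < 1 || n_levels < 1) stop("sweeps and n_levels must be >= 1")
  structure(list(t0 = t0, cool = cool, sweeps = as.integer(sweeps),
                 n_levels = as.integer(n_levels)),
            class = "sbs_anneal_schedule")
}

coarsen_matrix <- function(m, fac = 2) {
  n <- nrow(m)
  nn <- ceiling(n / fac)
  idx <- rep(seq_len(nn), each = fac)[seq_len(n)]
  agg <- rowsum(t(rowsum(m, idx)), idx)
  cnt <- tabulate(idx)
  agg / outer(cnt, cnt)
}

#' Infer a binding profile from a contact matrix by simulated annealing
#'
#' Metropolis Monte Carlo over per-bead colour multiplicities (moves:
#' single-bead multiplicity +-1, two-bead profile swap) with geometric
#' cooling, minimising
#' `cost = mean((rownorm(target) - rownorm(surrogate))^2) + lambda * sum(m)`.
#' The `lambda` term operationalises the "minimal arrangement": it prices
#' every binding site, so spurious low-multiplicity sites are removed first.
#' Optimisation is recursive across resolutions: the target is pooled by
#' factors of two down to <= `coarse_n` bins, solved there, and the solution
#' upsampled to seed each finer level. Deterministic given `seed`.
#'
#' @param target a symmetric nonnegative contact matrix
#'   (`sbs_contact_matrix` or plain matrix).
#' @param n_colors number of binding-site colours to infer.
#' @param schedule an [anneal_schedule()].
#' @param lambda parsimony price per unit multiplicity.
#' @param kappa surrogate contrast (see [surrogate_contact_matrix()]).
#' @param baseline optional baseline P0; defaults to the target's own
#'   diagonal means.
#' @param m_max largest multiplicity per bead and colour.
#' @param init optional initial profile (skips the coarse recursion).
#' @param coarse_n resolution at which the recursion bottoms out.
#' @param seed RNG seed.
#' @return an `sbs_binding_profile` with attributes `cost_trace`
#'   (per-level best cost, non-increasing), `best_cost`, `provenance`.
#'   A non-convergence warning is raised when no move was accepted in the
#'   final three temperature levels.
#' @export
anneal_binding_profile <- function(target, n_colors, schedule = anneal_schedule(),
                                   lambda = 0, kappa = KAPPA_DEFAULT,
                                   baseline = NULL, m_max = 3, init = NULL,
                                   coarse_n = 64, seed = 1) {
  tm <- unclass(target)
  if (nrow(tm) != ncol(tm) || any(tm < 0) ||
      max(abs(tm - t(tm))) > 1e-6 * max(abs(tm)))
    stop("target must be square, symmetric and nonnegative")
  if (n_colors < 1) stop("n_colors must be >= 1")
  n <- nrow(tm)
  p0 <- if (is.null(baseline)) profile_baseline(tm) else baseline_vector(baseline, n)

  run_level <- function(tmat, p0v, init_m, sweeps, n_levels, lseed,
                        diag_weights = NULL) {
    cpp_anneal_profile(tmat, p0v, init_m, kappa, lambda, as.integer(m_max),
                       if (is.na(schedule$t0)) -1 else schedule$t0,
                       schedule$cool, as.integer(sweeps),
                       as.integer(n_levels), lseed, diag_weights)
  }

  if (is.null(init)) {
    # recursive coarse-to-fine: list of (matrix, baseline) per resolution
    mats <- list(tm)
    while (nrow(mats[[length(mats)]]) > coarse_n)
      mats[[length(mats) + 1]] <- coarsen_matrix(mats[[length(mats)]])
    mats <- rev(mats)  # coarsest first
    m_cur <- matrix(0L, nrow(mats[[1]]), n_colors)
    trace <- NULL
    for (li in seq_along(mats)) {
      tmat <- mats[[li]]
      p0v <- if (li == length(mats)) p0 else profile_baseline(tmat)
      sw <- if (li == length(mats)) schedule$sweeps else max(10, schedule$sweeps %/% 2)
      nl <- if (li == 1) schedule$n_levels else max(10, schedule$n_levels %/% 2)
      res <- run_level(tmat, p0v, m_cur, sw, nl, seed + li)
      trace <- rbind(trace, cbind(resolution = nrow(tmat), res$trace))
      m_cur <- res$multiplicities
      if (li < length(mats)) {
        nn <- nrow(mats[[li + 1]])
        m_cur <- m_cur[rep(seq_len(nrow(m_cur)), each = 2)[seq_len(nn)], ,
                       drop = FALSE]
      }
    }
    res_final <- res
  } else {
    m0 <- if (inherits(init, "sbs_binding_profile")) init$multiplicities else init
    res_final <- run_level(tm, p0, m0, schedule$sweeps, schedule$n_levels, seed)
    trace <- cbind(resolution = n, res_final$trace)
  }
  if (res_final$stalled_final_levels)
    warning("non-convergence: no accepted move in the final 3 temperature levels")
  prof <- binding_profile(res_final$multiplicities, m_max = m_max)
  attr(prof, "cost_trace") <- trace
  attr(prof, "best_cost") <- res_final$best_cost
  attr(prof, "provenance") <- list(kappa = kappa, lambda = lambda,
                                   schedule = schedule, seed = seed,
                                   t0_used = res_final$t0,
                                   distance = "mean squared difference of row-normalised matrices",
                                   moves = "multiplicity +-1 (70%), profile swap (30%)")
  prof
}

#' Choose the parsimony price by the L-curve elbow
#'
#' Operationalises the "minimal arrangement": anneals the profile over an
#' increasing grid of `lambda` (warm-starting each fit from the previous
#' solution) and returns the most parsimonious profile whose unpenalised
#' distance to the target stays within `distance_tol` of the best fit.
#' Without a parsimony price the surrogate rewards multiplicity inflation
#' (extra valence compensates the surrogate's contrast shortfall without
#' improving the arrangement), so the elbow sits where redundant
#' multiplicity has been priced out but the block structure still explains
#' the data.
#'
#' @inheritParams anneal_binding_profile
#' @param lambdas candidate prices; by default auto-scaled to the target
#'   (`d0 / N * c(0.03, 0.1, 0.3, 1, 3)` with `d0` the lambda = 0 distance),
#'   since lambda * sum(m) competes with a distance of order `d0`.
#' @param distance_tol acceptable relative excess distance over the best
#'   fit.
#' @return list with `lambda`, `profile` (the selected fit), and `scores`
#'   (data.frame `lambda`, `distance`, `total_multiplicity`).
#' @export
select_lambda_elbow <- function(target, n_colors, lambdas = NULL,
                                schedule = anneal_schedule(),
                                distance_tol = 0.1, kappa = KAPPA_DEFAULT,
                                m_max = 3, seed = 1) {
  tm <- unclass(target)
  n <- nrow(tm)
  p0 <- profile_baseline(tm)
  tn <- tm / rowSums(tm)
  distance_of <- function(prof) {
    s <- cpp_surrogate(p0, prof$multiplicities, kappa)
    sn <- s / rowSums(s)
    mean((tn - sn)^2)
  }
  base <- anneal_binding_profile(target, n_colors, schedule = schedule,
                                 lambda = 0, kappa = kappa, m_max = m_max,
                                 seed = seed)
  d0 <- distance_of(base)
  if (is.null(lambdas)) lambdas <- d0 / n * c(0.03, 0.1, 0.3, 1, 3)
  lambdas <- sort(lambdas)
  fits <- list(base)
  scores <- data.frame(lambda = 0, distance = d0,
                       total_multiplicity = sum(base$multiplicities))
  prev <- base
  # warm-started continuation fits need a fraction of the full schedule
  sched2 <- anneal_schedule(t0 = schedule$t0, cool = schedule$cool,
                            sweeps = max(10, schedule$sweeps %/% 2),
                            n_levels = max(10, schedule$n_levels %/% 2))
  for (lam in lambdas) {
    pr <- suppressWarnings(
      anneal_binding_profile(target, n_colors, schedule = sched2,
                             lambda = lam, kappa = kappa, m_max = m_max,
                             init = prev, seed = seed + 1))
    fits[[length(fits) + 1]] <- pr
    scores <- rbind(scores,
                    data.frame(lambda = lam, distance = distance_of(pr),
                               total_multiplicity = sum(pr$multiplicities)))
    prev <- pr
  }
  ok <- scores$distance <= (1 + distance_tol) * min(scores$distance)
  pick <- which(ok)[which.min(scores$total_multiplicity[ok])]
  list(lambda = scores$lambda[pick], profile = fits[[pick]], scores = scores)
}

#' Choose the parsimony price by diagonal cross-validation
#'
#' Two-fold matrix cross-validation of `lambda`: for each candidate, the
#' profile is annealed with the cost restricted to odd diagonals of the
#' target, and scored by the (unpenalised) row-normalised squared error on
#' the even diagonals. Returns the candidate with the smallest held-out
#' error.
#'
#' @inheritParams anneal_binding_profile
#' @param lambdas candidate parsimony prices.
#' @return list with `lambda` (the winner), and `scores` (data.frame
#'   `lambda`, `heldout_error`, `total_multiplicity`).
#' @export
select_lambda_cv <- function(target, n_colors,
                             lambdas = c(0, 1e-9, 1e-8, 1e-7, 1e-6),
                             schedule = anneal_schedule(sweeps = 25,
                                                        n_levels = 25),
                             kappa = KAPPA_DEFAULT, m_max = 3, seed = 1) {
  tm <- unclass(target)
  n <- nrow(tm)
  p0 <- profile_baseline(tm)
  w_odd <- as.numeric(seq_len(n) %% 2 == 0)  # separations 1, 3, 5, ...
  even_idx <- outer(seq_len(n), seq_len(n),
                    function(i, j) abs(i - j) %% 2 == 0 & i != j)
  tn <- tm / rowSums(tm)
  scores <- lapply(lambdas, function(lam) {
    res <- cpp_anneal_profile(tm, p0, matrix(0L, n, n_colors), kappa, lam,
                              as.integer(m_max),
                              if (is.na(schedule$t0)) -1 else schedule$t0,
                              schedule$cool, schedule$sweeps,
                              schedule$n_levels, seed, w_odd)
    sur <- unclass(surrogate_contact_matrix(
      binding_profile(res$multiplicities, m_max = m_max), p0, kappa))
    sn <- sur / rowSums(sur)
    data.frame(lambda = lam,
               heldout_error = mean((tn[even_idx] - sn[even_idx])^2),
               total_multiplicity = sum(res$multiplicities))
  })
  scores <- do.call(rbind, scores)
  list(lambda = scores$lambda[which.min(scores$heldout_error)],
       scores = scores)
}

#' Calibrate the surrogate contrast against molecular dynamics
#'
#' Finds the `kappa` minimising the row-normalised mean squared difference
#' between the surrogate map of a known profile and its MD ensemble map.
#' Run once on the two-colour block reference fixture; the result is frozen
#' as the package default.
#'
#' @param profile the generating `sbs_binding_profile`.
#' @param md_map the MD ensemble `sbs_contact_matrix` of that profile.
#' @param baseline optional baseline; defaults to the MD map's diagonal
#'   means.
#' @param interval search interval for kappa.
#' @return list with `kappa`, `objective`, `pearson`.
#' @export
calibrate_kappa <- function(profile, md_map, baseline = NULL,
                            interval = c(0.1, 100)) {
  tm <- unclass(md_map)
  p0 <- if (is.null(baseline)) profile_baseline(tm)
        else baseline_vector(baseline, nrow(tm))
  tn <- tm / rowSums(tm)
  obj <- function(kap) {
    s <- cpp_surrogate(p0, profile$multiplicities, kap)
    sn <- s / rowSums(s)
    mean((tn - sn)^2)
  }
  op <- stats::optimize(function(k) obj(exp(k)), log(interval))
  kap <- exp(op$minimum)
  s <- surrogate_contact_matrix(profile, p0, kap)
  list(kappa = kap, objective = op$objective,
       pearson = matrix_pearson(md_map, s))
}

#' Pearson correlation between contact matrices
#'
#' @param a,b matrices of equal size (`sbs_contact_matrix` or plain).
#' @param mode `"global"`: correlation over the strict upper triangle;
#'   `"distance_stratified"`: one correlation per diagonal `|i - j|` plus
#'   their mean.
#' @return for `"global"` a scalar; otherwise a list with `per_distance`
#'   (data.frame `s`, `r`, `n`) and `mean` over valid diagonals.
#' @export
matrix_pearson <- function(a, b, mode = c("global", "distance_stratified")) {
  mode <- match.arg(mode)
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) stop("alignment: matrices differ in shape")
  n <- nrow(a)
  if (mode == "global") {
    ut <- upper.tri(a)
    ok <- is.finite(a[ut]) & is.finite(b[ut])
    return(stats::cor(a[ut][ok], b[ut][ok]))
  }
  rows <- lapply(seq_len(n - 2), function(s) {
    i <- seq_len(n - s)
    av <- a[cbind(i, i + s)]; bv <- b[cbind(i, i + s)]
    ok <- is.finite(av) & is.finite(bv)
    av <- av[ok]; bv <- bv[ok]
    r <- if (length(av) >= 3 && stats::sd(av) > 0 && stats::sd(bv) > 0)
      stats::cor(av, bv) else NA_real_
    data.frame(s = s, r = r, n = length(av))
  })
  per <- do.call(rbind, rows)
  list(per_distance = per, mean = mean(per$r, na.rm = TRUE))
}

#' Validate an inferred profile with full dynamics
#'
#' Simulates the profile's strings-and-binders system over independent
#' Langevin trajectories, pools the ensemble contact map, and reports its
#' global and distance-stratified Pearson correlation with the target.
#' Equilibration is checked on the pooled Rg of the sampling windows; a
#' drifting ensemble raises a validation-incomplete error.
#'
#' @param profile an `sbs_binding_profile`.
#' @param target the target `sbs_contact_matrix` (optional; correlations are
#'   skipped when absent).
#' @param n_traj independent trajectories (>= 20 recommended for production;
#'   scale down for smoke tests).
#' @param n_relax,n_sample,sample_interval integration protocol per
#'   trajectory.
#' @param threshold contact threshold for the map (sigma).
#' @param box_edge box side; defaults to volume fraction 0.02.
#' @param dt,gamma integrator parameters.
#' @param seed master seed (trajectory k uses `seed * 1000 + k`).
#' @param drift_tol relative Rg drift tolerance across sampling windows.
#' @param bin_factor beads pooled per bin before computing correlations
#'   (uniform k-beads-per-bin mapping). Matches the practice of comparing
#'   at contact-map bin resolution, with the simulation run at finer bead
#'   resolution; 1 compares raw bead maps.
#' @return list with `map` (bead resolution), `pearson`, `stratified`,
#'   `rg`, `provenance`.
#' @export
validate_profile_with_dynamics <- function(profile, target = NULL,
                                           n_traj = 20, n_relax = 120000,
                                           n_sample = 60000,
                                           sample_interval = 3000,
                                           threshold = 3.5, box_edge = NULL,
                                           dt = 0.012, gamma = 0.5, seed = 1,
                                           drift_tol = 0.1, bin_factor = 1) {
  chain <- new_bead_chain(profile$multiplicities)
  box <- simulation_box(if (is.null(box_edge))
    default_box_edge(2 * profile$n_beads, phi = 0.02) else box_edge)
  sys <- sbs_system(chain, box, force_field(e_int = profile$e_int),
                    concentration = profile$concentration)
  expect_collapse <- any(profile$e_int > 0) && any(profile$multiplicities > 0)
  col <- collect_equilibrium_maps(sys, n_traj, seed_base = seed * 1000,
                                  n_relax = n_relax,
                                  max_relax = max(4 * n_relax, 500000),
                                  n_sample = n_sample,
                                  sample_interval = sample_interval,
                                  threshold = threshold, dt = dt,
                                  gamma = gamma,
                                  expect_collapse = expect_collapse,
                                  adaptive = FALSE)
  maps <- col$maps
  rg_all <- do.call(rbind, lapply(col$rg, function(v)
    v[seq_len(1 + n_sample %/% sample_interval)]))
  rg_mean <- colMeans(rg_all, na.rm = TRUE)
  # drifting = the two halves of the pooled Rg trace differ both materially
  # and significantly (same rule as classify_state)
  first <- rg_mean[seq_len(floor(length(rg_mean) / 2))]
  second <- rg_mean[seq.int(ceiling(length(rg_mean) / 2), length(rg_mean))]
  se_diff <- sqrt(stats::var(first) / length(first) +
                    stats::var(second) / length(second))
  drift <- abs(mean(second) - mean(first)) / mean(rg_mean)
  if (drift > drift_tol && abs(mean(second) - mean(first)) > 3 * se_diff)
    stop(sprintf("validation-incomplete: ensemble Rg still drifting (%.2g > %.2g); extend n_relax",
                 drift, drift_tol))
  map <- new_contact_matrix(Reduce(`+`, maps) / length(maps),
                            threshold = threshold,
                            n_snapshots = length(maps))
  out <- list(map = map, rg = rg_mean,
              provenance = list(n_traj = col$n_collected, n_relax = n_relax,
                                n_sample = n_sample,
                                sample_interval = sample_interval,
                                threshold = threshold, seed = seed,
                                box_edge = box$edge, drift = drift))
  if (!is.null(target)) {
    mp <- unclass(map); tg <- unclass(target)
    if (bin_factor > 1) {
      mp <- coarsen_matrix(mp, bin_factor)
      tg <- coarsen_matrix(tg, bin_factor)
    }
    out$pearson <- matrix_pearson(mp, tg)
    out$stratified <- matrix_pearson(mp, tg, "distance_stratified")
    out$provenance$bin_factor <- bin_factor
  }
  out
}

#' Bead-wise dominant-colour agreement between two profiles
#'
#' Fraction of beads whose dominant colour (argmax multiplicity; inert when
#' all zero) matches, maximised over global colour permutations (colour
#' labels are exchangeable in both the surrogate and the dynamics).
#'
#' @param a,b `sbs_binding_profile`s over the same beads.
#' @return agreement fraction in `[0, 1]`.
#' @export
profile_agreement <- function(a, b) {
  dom <- function(m) {
    d <- max.col(m, ties.method = "first")
    d[rowSums(m) == 0] <- 0L
    d
  }
  da <- dom(a$multiplicities); db <- dom(b$multiplicities)
  nc <- max(a$n_colors, b$n_colors)
  perms <- perm_all(seq_len(nc))
  best <- 0
  for (p in perms) {
    map <- c(0L, p)  # inert stays inert
    best <- max(best, mean(map[da + 1L] == db))
  }
  best
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}
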