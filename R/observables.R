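#' Gyration radius
#'
#' `Rg = sqrt(mean(|r_i - r_cm|^2))` from unwrapped coordinates.
#'
#' @param positions N x 3 matrix (or an `sbs_trajectory`, averaged over
#'   snapshots).
#' @return scalar Rg in sigma (for a trajectory, the per-snapshot vector is
#'   in `attr(, "per_snapshot")`).
#' @export
gyration_radius <- function(positions) {
  if (inherits(positions, "sbs_trajectory")) {
    out <- mean(positions$rg)
    attr(out, "per_snapshot") <- positions$rg
    return(out)
  }
  p <- as.matrix(positions)
  cm <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, cm)^2)))
}

bead_array <- function(x) {
  if (inherits(x, "sbs_trajectory")) return(x$beads)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, c(nrow(x), 3, 1)))
  stop("empty-input: expected a trajectory, an N x 3 x T array or an N x 3 matrix")
}

new_contact_matrix <- function(values, threshold = NA, n_snapshots = NA,
                               normalization = "raw", bin_size = 1) {
  structure(values, class = c("sbs_contact_matrix", "matrix"),
            threshold = threshold, n_snapshots = n_snapshots,
            normalization = normalization, bin_size = bin_size)
}

#' Ensemble contact map
#'
#' Entry (i, j) is the fraction of snapshots in which beads i and j are
#' within `threshold` (minimum image when the trajectory has a periodic box).
#'
#' @param x an `sbs_trajectory`, or an N x 3 x T array of bead positions.
#' @param threshold contact distance in sigma. The package default is 3.5
#'   sigma for locus-style maps; use 2.0 for scaling-exponent estimation.
#' @param min_image use the minimum-image convention (needs a box; default
#'   TRUE for trajectories).
#' @return an `sbs_contact_matrix` (symmetric, diagonal 1 in raw mode).
#' @export
contact_map <- function(x, threshold = 3.5, min_image = inherits(x, "sbs_trajectory")) {
  arr <- bead_array(x)
  if (dim(arr)[3] < 1) stop("empty-input: trajectory has no snapshots")
  edge <- if (min_image && inherits(x, "sbs_trajectory")) x$system$box$edge else -1
  new_contact_matrix(cpp_contact_map(arr, threshold, edge),
                     threshold = threshold, n_snapshots = dim(arr)[3])
}

new_ps_curve <- function(s, p, n_pairs = rep(NA_real_, length(s)),
                         units = "beads") {
  stopifnot(length(s) == length(p), !is.unsorted(s))
  structure(data.frame(s = s, p = p, n_pairs = n_pairs),
            class = c("sbs_ps_curve", "data.frame"), units = units)
}

#' Construct a contact-probability curve
#'
#' @param s separations (beads or bp), strictly increasing.
#' @param p contact probabilities in `[0, 1]` (relative frequencies allowed
#'   for experimental curves).
#' @param n_pairs optional pair counts per separation (for error bars).
#' @param units `"beads"` or `"bp"`.
#' @return an `sbs_ps_curve` data frame with columns `s`, `p`, `n_pairs`.
#' @export
ps_curve <- function(s, p, n_pairs = rep(NA_real_, length(s)), units = "beads") {
  if (any(p < 0)) stop("invalid curve: probabilities must be >= 0")
  new_ps_curve(as.numeric(s), as.numeric(p), as.numeric(n_pairs), units)
}

#' Mean contact probability versus contour separation
#'
#' P_c(s): the probability that two beads a contour distance `s` apart are in
#' contact, averaged over all pairs at that separation and over snapshots.
#' Computed from the ensemble contact map, so the two routes agree exactly.
#'
#' @param x an `sbs_trajectory`, bead array, or an `sbs_contact_matrix`.
#' @param threshold contact distance in sigma (ignored when `x` is already a
#'   contact matrix). Default 2.0, the exponent-estimation threshold.
#' @return an `sbs_ps_curve`.
#' @export
contact_probability_vs_separation <- function(x, threshold = 2.0) {
  cm <- if (inherits(x, "sbs_contact_matrix")) x else contact_map(x, threshold)
  n <- nrow(cm)
  v <- unclass(cm)
  p <- vapply(seq_len(n - 1), function(s)
    mean(v[cbind(seq_len(n - s), seq_len(n - s) + s)]), numeric(1))
  n_pairs <- (n - seq_len(n - 1)) *
    if (is.na(attr(cm, "n_snapshots"))) 1 else attr(cm, "n_snapshots")
  new_ps_curve(seq_len(n - 1), p, n_pairs)
}

log_binned <- function(s, y, bins_per_decade = 8) {
  lb <- log10(s)
  breaks <- seq(min(lb), max(lb) + 1e-9, by = 1 / bins_per_decade)
  if (length(breaks) < 3) breaks <- range(lb) + c(-1e-9, 1e-9)
  bin <- cut(lb, breaks, include.lowest = TRUE)
  x <- tapply(lb, bin, mean)
  yy <- tapply(y, bin, mean)
  ok <- !is.na(x) & !is.na(yy)
  list(x = as.numeric(x[ok]), y = as.numeric(yy[ok]))
}

#' Fit the power-law decay exponent of a P_c(s) curve
#'
#' Least-squares slope of `log10 P` versus `log10 s` over log-spaced bins in
#' the fit window. The decay exponent alpha is the negated slope
#' (`P ~ s^-alpha`). A bootstrap over bins gives the confidence interval.
#'
#' @param curve an `sbs_ps_curve`.
#' @param window `c(s_min, s_max)`; the default `[10, N/4]` avoids
#'   short-range stiffness and chain-end effects.
#' @param bins_per_decade log-binning density (default 8).
#' @param n_boot bootstrap replicates for the CI.
#' @param seed seed for the bootstrap.
#' @return list with `alpha`, `ci` (95%), `window`, `n_points`.
#' @export
fit_power_law_exponent <- function(curve, window = NULL, bins_per_decade = 8,
                                   n_boot = 200, seed = 1) {
  s <- curve$s; p <- curve$p
  if (is.null(window)) window <- c(10, (max(s) + 1) / 4)
  w <- s >= window[1] & s <= window[2]
  if (sum(w) < 5) stop("fit-domain: fewer than 5 points in the fit window")
  if (any(p[w] <= 0)) {
    w <- w & p > 0
    if (sum(w) < 5) stop("fit-domain: nonpositive values in the fit window")
  }
  b <- log_binned(s[w], log10(p[w]), bins_per_decade)
  if (length(b$x) < 3) stop("fit-domain: fit window spans too few bins")
  slope <- stats::coef(stats::lm(b$y ~ b$x))[[2]]
  boots <- numeric(0)
  if (n_boot > 0 && length(b$x) >= 4) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(k) {
      idx <- sample(length(b$x), replace = TRUE)
      if (length(unique(b$x[idx])) < 2) return(NA_real_)
      stats::coef(stats::lm(b$y[idx] ~ b$x[idx]))[[2]]
    }, numeric(1))
    boots <- boots[is.finite(boots)]
  }
  ci <- if (length(boots) > 10)
    -rev(stats::quantile(boots, c(0.025, 0.975), names = FALSE))
  else c(NA_real_, NA_real_)
  list(alpha = -slope, ci = ci, window = window, n_points = sum(w))
}

#' Detect the plateau onset of a contact-decay curve
#'
#' A curve has a plateau when it decays by less than `decay_ratio` across
#' its outer half (median around mid-curve versus median near the end); a
#' ratio is robust both to the sampling noise of the plateau, where local
#' slopes fluctuate wildly, and to the chain-end depletion that bends the
#' very tail down. The onset is then the smallest separation at which the
#' curve first comes within `level_factor` times its terminal level (median
#' over the outer half). The default factor 2 marks the start of the
#' decay-to-plateau crossover: the crossover is broad in log space (the
#' curve sits within 2x of its plateau throughout), so a smaller factor
#' would place the onset mid-crossover and contaminate a pre-plateau fit
#' window with non-power-law points. Returns `Inf` when there is no
#' plateau.
#'
#' @param curve an `sbs_ps_curve`.
#' @param decay_ratio mid-curve to end decay ratio below which a plateau is
#'   declared (a pure power law `s^-alpha` has ratio `~2^alpha` here, so 2
#'   separates plateaued curves from decays with `alpha >~ 1`).
#' @param level_factor multiple of the terminal level taken as the onset.
#' @param s_min smallest separation considered.
#' @return plateau onset separation (possibly `Inf`).
#' @export
plateau_onset <- function(curve, decay_ratio = 2, level_factor = 2,
                          s_min = 3) {
  cv <- curve[curve$p > 0, ]
  if (nrow(cv) < 8) return(Inf)
  smax <- max(cv$s)
  mid <- stats::median(cv$p[cv$s >= 0.4 * smax & cv$s <= 0.6 * smax])
  end <- stats::median(cv$p[cv$s >= 0.8 * smax])
  if (!is.finite(mid) || !is.finite(end) || mid / end >= decay_ratio)
    return(Inf)  # still decaying: no plateau
  level <- stats::median(cv$p[cv$s >= smax / 2])
  hit <- cv$s[cv$s >= s_min & cv$p <= level_factor * level]
  if (length(hit) == 0) return(Inf)
  min(hit)
}

#' Fit the pre-plateau decay exponent
#'
#' For globular states P_c(s) decays and then flattens into a plateau; this
#' fits the decade preceding the plateau onset. The onset is detected from
#' the curve by [plateau_onset()], or — preferably, when the ensemble's
#' gyration radius is known — set to the Gaussian-saturation scale
#' `s* = Rg^2`: inside an equilibrium globule `R^2(s) ~ s` until it
#' saturates at the globule size, which is where contacts stop decaying.
#' The physical scale is stable across ensembles, while curve-based
#' detection is sensitive to sampling noise in the shallow crossover.
#'
#' @inheritParams fit_power_law_exponent
#' @param s_star optional plateau onset (e.g. `mean(rg)^2` of the same
#'   ensemble); overrides detection.
#' @param ... passed to [fit_power_law_exponent()].
#' @return as [fit_power_law_exponent()], plus `plateau_at`.
#' @export
fit_preplateau_exponent <- function(curve, s_star = NULL, ...) {
  if (is.null(s_star)) s_star <- plateau_onset(curve)
  top <- if (is.finite(s_star)) s_star else (max(curve$s) + 1) / 4
  # floor at s = 4: with the 2-sigma contact threshold, separations below ~4
  # are dominated by local chain stiffness (P_c ~ 1), not by the fold
  window <- c(max(4, top / 10), top)
  out <- fit_power_law_exponent(curve, window = window, ...)
  out$plateau_at <- s_star
  out
}

#' Mean-square spatial distance versus contour separation
#'
#' `R^2(s)` averaged over pairs and snapshots, from unwrapped coordinates
#' (the FISH-accessible counterpart of P_c(s)).
#'
#' @param x an `sbs_trajectory` or bead array.
#' @return data.frame with columns `s`, `r2`.
#' @export
mean_square_distance_vs_separation <- function(x) {
  arr <- bead_array(x)
  if (dim(arr)[3] < 1) stop("empty-input: no snapshots")
  data.frame(s = seq_len(dim(arr)[1] - 1), r2 = cpp_r2_vs_s(arr))
}

#' Structure factor of the binder cloud
#'
#' `S(k) = <|sum_j exp(i k . r_j)|^2> / M` over wavevectors commensurate with
#' the periodic box (`k = 2 pi n / L`), spherically averaged in shells. A
#' flat S(k) signals a disordered (homogeneous or liquid-like) binder
#' arrangement; sharp peaks signal ordered aggregation.
#'
#' @param x an `sbs_trajectory` (binder positions, averaged over the last
#'   half of the snapshots) or an M x 3 matrix of positions.
#' @param box an `sbs_box` (taken from the trajectory when omitted).
#' @param k_max largest wavenumber (sigma^-1).
#' @param bins number of k shells.
#' @param bound_only for trajectories: restrict each snapshot to binders
#'   within the attraction cutoff of some bead. The free-binder gas is an
#'   ideal-gas background (S ~ 1) that dilutes the aggregate's order signal;
#'   the order-disorder transition lives in the bound fraction.
#' @return an `sbs_sk_curve`: data.frame `k`, `sk` with a `peaks` attribute
#'   (k*, height, prominence relative to the median S(k) over k in [0.5, 2]).
#' @export
structure_factor <- function(x, box = NULL, k_max = 8, bins = 60,
                             bound_only = TRUE) {
  if (inherits(x, "sbs_trajectory")) {
    box <- x$system$box
    S <- dim(x$binders)[3]
    keep <- seq.int(max(1, floor(S / 2)), S)
    mats <- lapply(keep, function(t) {
      b <- x$binders[, , t, drop = TRUE]
      if (!bound_only || nrow(b) == 0) return(b)
      L <- box$edge
      mi <- function(d) d - L * round(d / L)
      p <- x$beads[, , t, drop = TRUE]
      rc <- x$system$ff$r_cut_attr
      dmin <- apply(b, 1, function(r)
        min(mi(p[, 1] - r[1])^2 + mi(p[, 2] - r[2])^2 + mi(p[, 3] - r[3])^2))
      b[dmin <= rc^2, , drop = FALSE]
    })
    mats <- Filter(function(m) nrow(m) >= 1, mats)
    if (length(mats) == 0) stop("need at least 1 bound binder")
  } else {
    mats <- list(as.matrix(x))
    if (is.null(box)) stop("wavevector: a box is required for commensurate k")
  }
  m <- nrow(mats[[1]])
  if (m < 1) stop("need at least 1 particle")
  L <- box$edge
  nmax <- floor(k_max * L / (2 * pi))
  if (nmax < 1) stop("wavevector: k_max below the smallest commensurate k")
  g <- expand.grid(nx = 0:nmax, ny = -nmax:nmax, nz = -nmax:nmax)
  g <- g[!(g$nx == 0 & g$ny == 0 & g$nz == 0), ]
  g <- g[!(g$nx == 0 & (g$ny < 0 | (g$ny == 0 & g$nz < 0))), ] # half space
  kvec <- 2 * pi / L * as.matrix(g)
  kk <- sqrt(rowSums(kvec^2))
  sel <- kk <= k_max
  kvec <- kvec[sel, , drop = FALSE]; kk <- kk[sel]
  acc <- numeric(length(kk))
  for (r in mats) {
    ph <- kvec %*% t(r)             # nk x M
    re <- rowSums(cos(ph)); im <- rowSums(sin(ph))
    acc <- acc + (re^2 + im^2) / nrow(r)
  }
  acc <- acc / length(mats)
  shell <- cut(kk, breaks = seq(0, k_max, length.out = bins + 1),
               include.lowest = TRUE)
  kmid <- tapply(kk, shell, mean)
  sk <- tapply(acc, shell, mean)
  ok <- !is.na(kmid)
  out <- data.frame(k = as.numeric(kmid[ok]), sk = as.numeric(sk[ok]))
  ref <- stats::median(out$sk[out$k >= 0.5 & out$k <= 2])
  pk <- which(diff(sign(diff(out$sk))) == -2) + 1
  peaks <- data.frame(k = out$k[pk], height = out$sk[pk],
                      prominence = out$sk[pk] / ref)
  peaks <- peaks[order(-peaks$prominence), ]
  structure(out, class = c("sbs_sk_curve", "data.frame"), peaks = peaks,
            reference_level = ref)
}

#' Sharp-peak test of the binder structure factor
#'
#' A peak counts as sharp when its height exceeds `factor` times the median
#' S(k) over k in `[0.5, 2]` sigma^-1 (a scale-free version of the
#' flat-versus-peaked dichotomy). Peaks are searched above k = 2.5 sigma^-1,
#' beyond the cluster form-factor rise of a compact aggregate.
#'
#' @param sk an `sbs_sk_curve`.
#' @param factor prominence threshold (default 3).
#' @return logical.
#' @export
has_sharp_peak <- function(sk, factor = 3) {
  peaks <- attr(sk, "peaks")
  peaks <- peaks[peaks$k > 2.5, , drop = FALSE]
  nrow(peaks) > 0 && any(peaks$prominence > factor)
}

#' @rdname has_sharp_peak
#' @param k_min peaks below this wavenumber are ignored (cluster form-factor
#'   region).
#' @return `max_peak_prominence`: the largest peak prominence (0 when no
#'   peak).
#' @export
max_peak_prominence <- function(sk, k_min = 2.5) {
  peaks <- attr(sk, "peaks")
  peaks <- peaks[peaks$k > k_min, , drop = FALSE]
  if (nrow(peaks) == 0) return(0)
  max(peaks$prominence)
}

#' Many-body contact frequencies
#'
#' Per snapshot, builds the contact graph over probe sites (every
#' `site_stride`-th bead) at `threshold` and counts its connected components
#' (components, not cliques: cliques are threshold-brittle and costly).
#' Probe sites rather than all beads keep the statistic non-degenerate: the
#' full-bead graph is connected through backbone neighbours whenever the
#' threshold exceeds the bond length. Reports per order n both the mean
#' number of components of size exactly n (`frequency`) and of size at least
#' n (`frequency_geq`); enrichment relative to the pivot-SAW reference at
#' equal N uses the cumulative counts, the quantity that grows exponentially
#' with n upon collapse.
#'
#' @param x an `sbs_trajectory` or bead array.
#' @param threshold contact distance (sigma).
#' @param n_max largest order reported.
#' @param site_stride contour spacing of probe sites (1 = all beads).
#' @param saw_baseline compute the pivot-SAW baseline and ratios?
#' @param n_saw_samples SAW ensemble size for the baseline.
#' @param seed seed for the SAW baseline.
#' @return data.frame `n`, `frequency`, `frequency_geq`, and when requested
#'   `frequency_saw`, `frequency_geq_saw`, `ratio`
#'   (= `frequency_geq / frequency_geq_saw`).
#' @export
many_body_contact_frequency <- function(x, threshold = 3.5, n_max = 8,
                                        site_stride = 10,
                                        saw_baseline = FALSE,
                                        n_saw_samples = 200, seed = 1) {
  if (n_max < 2) stop("n_max must be >= 2")
  arr <- bead_array(x)
  n <- dim(arr)[1]
  sites <- as.integer(seq.int(1, n, by = site_stride) - 1L)
  if (length(sites) < n_max)
    stop("domain: fewer probe sites than n_max; lower site_stride")
  edge <- if (inherits(x, "sbs_trajectory")) x$system$box$edge else -1
  freq <- as.numeric(cpp_manybody_components(arr, threshold, edge, sites))
  cum <- rev(cumsum(rev(freq)))
  out <- data.frame(n = seq_len(n_max), frequency = freq[seq_len(n_max)],
                    frequency_geq = cum[seq_len(n_max)])
  if (saw_baseline) {
    saw <- sample_saw_pivot(n, n_saw_samples, seed = seed)
    fsaw <- as.numeric(cpp_manybody_components(saw, threshold, -1, sites))
    csaw <- rev(cumsum(rev(fsaw)))
    out$frequency_saw <- fsaw[seq_len(n_max)]
    out$frequency_geq_saw <- csaw[seq_len(n_max)]
    out$ratio <- out$frequency_geq / out$frequency_geq_saw
  }
  attr(out, "counting") <-
    sprintf("connected components over probe sites (stride %d)", site_stride)
  out[out$n >= 2, , drop = FALSE]
}

#' Triplet contact probability
#'
#' Probability that beads (i, i+s1, i+s1+s2) are pairwise in contact,
#' averaged over i and snapshots.
#'
#' @param x an `sbs_trajectory` or bead array (N >= 3).
#' @param threshold contact distance (sigma).
#' @param s_max largest separation per leg.
#' @return an `s_max` x `s_max` matrix, entry (s1, s2).
#' @export
triplet_contact_probability <- function(x, threshold = 3.5, s_max = NULL) {
  arr <- bead_array(x)
  n <- dim(arr)[1]
  if (n < 3) stop("domain: need at least 3 beads")
  if (is.null(s_max)) s_max <- min(n - 2, 50)
  if (s_max + 1 >= n) stop("domain: s1 + s2 must stay below N")
  edge <- if (inherits(x, "sbs_trajectory")) x$system$box$edge else -1
  g <- cpp_triplet_grid(arr, threshold, as.integer(s_max), edge)
  dimnames(g) <- list(s1 = seq_len(nrow(g)), s2 = seq_len(ncol(g)))
  g
}

# cached SAW gyration-radius reference per chain length
.saw_rg_cache <- new.env(parent = emptyenv())

saw_rg_reference <- function(n, n_samples = 150, seed = 99) {
  key <- sprintf("n%d", n)
  if (!is.null(.saw_rg_cache[[key]])) return(.saw_rg_cache[[key]])
  st <- cpp_saw_pivot_stats(as.integer(n), as.integer(n_samples),
                            as.integer(n), as.integer(20 * n), 2.0, 1L, seed)
  ref <- list(mean = mean(st$rg), sd = stats::sd(st$rg))
  .saw_rg_cache[[key]] <- ref
  ref
}

#' Classify the thermodynamic state of a run
#'
#' Decides coil / disordered globule / ordered globule from equilibrium
#' diagnostics: the chain is a coil when its equilibrium Rg is compatible
#' with the SAW reference at equal N (lattice-pivot ensemble), a globule
#' otherwise; a globule is ordered when the binder structure factor has a
#' sharp peak. A theta-proximity flag is raised when Rg sits near the ideal
#' chain value `sqrt(N/6)`.
#'
#' @param e_int affinity used for the run (k_BT); `e_int = 0` is always a
#'   coil.
#' @param c_nmol binder concentration (nmol/l), reported in the evidence.
#' @param diagnostics list with `rg` (per-snapshot gyration radii of the
#'   equilibrated window), `n_beads`, and optionally `sk`
#'   (an `sbs_sk_curve`). Supplying an `sbs_trajectory` also works.
#' @param drift_tol maximal relative Rg drift across the window before the
#'   run counts as unequilibrated.
#' @return list with `state` (one of `"coil"`, `"globule_disordered"`,
#'   `"globule_ordered"`), `theta_proximal`, and the `evidence` used.
#' @export
classify_state <- function(e_int, c_nmol, diagnostics, drift_tol = 0.1) {
  if (inherits(diagnostics, "sbs_trajectory")) {
    traj <- diagnostics
    diagnostics <- list(rg = traj$rg, n_beads = dim(traj$beads)[1],
                        sk = tryCatch(structure_factor(traj),
                                      error = function(e) NULL))
  }
  rg <- diagnostics$rg
  n <- diagnostics$n_beads
  if (length(rg) < 4) stop("not-converged: too few equilibrium snapshots")
  first <- rg[seq_len(floor(length(rg) / 2))]
  half <- rg[seq.int(ceiling(length(rg) / 2), length(rg))]
  # drifting = the two halves differ both materially and significantly
  se_diff <- sqrt(stats::var(first) / length(first) +
                    stats::var(half) / length(half))
  drift <- abs(mean(half) - mean(first)) / mean(rg)
  if (drift > drift_tol && abs(mean(half) - mean(first)) > 3 * se_diff)
    stop(sprintf("not-converged: Rg still drifting (relative drift %.2g > %.2g)",
                 drift, drift_tol))
  rg_eq <- mean(half)
  ref <- saw_rg_reference(n)
  ratio <- rg_eq / ref$mean
  rg_theta <- sqrt(n / 6)
  theta_proximal <- abs(rg_eq - rg_theta) / rg_theta < 0.2
  if (e_int == 0 || ratio > 0.8) {
    state <- "coil"
  } else {
    ordered <- !is.null(diagnostics$sk) && has_sharp_peak(diagnostics$sk)
    state <- if (ordered) "globule_ordered" else "globule_disordered"
  }
  list(state = state, theta_proximal = theta_proximal,
       evidence = list(rg_eq = rg_eq, rg_saw = ref$mean, rg_saw_sd = ref$sd,
                       ratio = ratio, rg_theta = rg_theta, drift = drift,
                       e_int = e_int, c_nmol = c_nmol,
                       sk_peaks = if (!is.null(diagnostics$sk))
                         attr(diagnostics$sk, "peaks") else NULL))
}

#' Symmetry breaking of physical distances across a block boundary
#'
#' Compares the spatial distance distribution of a bead pair straddling a
#' block boundary symmetrically against a pair at the same contour
#' separation placed asymmetrically (shifted by a quarter separation), as a
#' probe of the insulating effect of domain boundaries.
#'
#' @param traj an `sbs_trajectory` of a block copolymer.
#' @param boundary 0-based bead index at which the second block starts
#'   (defaults to the chain's first recorded block boundary).
#' @param separation contour separation of the pairs (even, >= 4).
#' @param offset contour shift of the asymmetric pair (default a quarter
#'   separation; 0 compares the symmetric pair with itself, a zero-effect
#'   control).
#' @return list with the two distance samples (`d_sym`, `d_asym`), their
#'   medians, `median_diff` (symmetric minus asymmetric), and the Wilcoxon
#'   rank-sum statistic and p-value.
#' @export
boundary_pair_distance_test <- function(traj, boundary = NULL, separation = 20,
                                        offset = floor(separation / 4)) {
  n <- dim(traj$beads)[1]
  if (is.null(boundary)) boundary <- traj$system$chain$block_bounds[1]
  if (is.null(boundary)) stop("domain: no block boundary available")
  h <- floor(separation / 2); q <- offset
  i_s <- boundary - h; j_s <- boundary + h
  i_a <- boundary - h - q; j_a <- boundary + h - q
  if (i_a < 0 || j_s >= n || separation < 4)
    stop("domain: separation too large for this boundary")
  pdist <- function(i, j) {
    # 1-based indexing into the bead array; unwrapped coordinates
    sqrt(colSums((traj$beads[i + 1, , ] - traj$beads[j + 1, , ])^2))
  }
  d_sym <- pdist(i_s, j_s)
  d_asym <- pdist(i_a, j_a)
  wt <- stats::wilcox.test(d_sym, d_asym, exact = FALSE)
  list(d_sym = d_sym, d_asym = d_asym,
       median_sym = stats::median(d_sym), median_asym = stats::median(d_asym),
       median_diff = stats::median(d_sym) - stats::median(d_asym),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       pairs = list(symmetric = c(i_s, j_s), asymmetric = c(i_a, j_a)))
}
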