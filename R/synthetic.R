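#' Sample self-avoiding walks by pivot Monte Carlo
#'
#' Cubic-lattice pivot sampler with hard-core exclusion (one bead per site,
#' lattice spacing = sigma): the reference ensemble of the coil (SAW
#' universality) class. Samples are taken every `stride` attempted pivot
#' moves (default N, enough to decorrelate global observables) after
#' `burnin` moves from a rod start. Deterministic given the seed.
#'
#' @param n_beads chain length (>= 8).
#' @param n_samples number of conformations.
#' @param seed RNG seed.
#' @param stride attempted pivot moves between samples.
#' @param burnin attempted moves discarded before sampling.
#' @return an `n_beads` x 3 x `n_samples` array of coordinates.
#' @export
sample_saw_pivot <- function(n_beads, n_samples, seed = 1, stride = n_beads,
                             burnin = 20 * n_beads) {
  if (n_beads < 8) stop("n_beads must be >= 8 for pivot sampling")
  cpp_saw_pivot_sample(as.integer(n_beads), as.integer(n_samples),
                       as.integer(stride), as.integer(burnin), seed)
}

#' Streamed statistics of a pivot-SAW ensemble
#'
#' Runs the pivot sampler without materialising conformations and
#' accumulates P_c(s) (contacts at `threshold`), R^2(s), per-sample Rg and
#' end-to-end distance. Intended for large ensembles (e.g. 1e4 samples of an
#' N = 512 chain).
#'
#' @inheritParams sample_saw_pivot
#' @param threshold contact distance (sigma).
#' @param s_max largest separation tracked.
#' @return list with `ps` (an `sbs_ps_curve`), `r2` (data.frame `s`, `r2`),
#'   `rg`, `e2e`.
#' @export
saw_reference_stats <- function(n_beads, n_samples, threshold = 2.0,
                                s_max = floor(n_beads / 2), seed = 1,
                                stride = n_beads, burnin = 20 * n_beads) {
  st <- cpp_saw_pivot_stats(as.integer(n_beads), as.integer(n_samples),
                            as.integer(stride), as.integer(burnin),
                            threshold, as.integer(s_max), seed)
  list(ps = new_ps_curve(st$s, st$contacts / st$pairs, st$pairs),
       r2 = data.frame(s = st$s, r2 = st$r2),
       rg = st$rg, e2e = st$e2e)
}

#' Sample ideal (Gaussian) chains
#'
#' Cumulative sums of isotropic Gaussian steps with mean bond length `b`
#' (per-axis standard deviation `b / sqrt(3)`), the theta-point reference
#' class with `R^2(s) = b^2 s` exactly in expectation. The default bond
#' `b = 2` sigma is the smallest for which the default 2-sigma contact
#' threshold stays inside the asymptotic `s^(-3/2)` regime over the standard
#' fit window (see the methods vignette).
#'
#' @param n_beads chain length (>= 3).
#' @param b bond length (sigma).
#' @param n_samples number of chains.
#' @param seed RNG seed (uses R's RNG; an independent path from the C++
#'   streaming sampler).
#' @return an `n_beads` x 3 x `n_samples` array.
#' @export
sample_gaussian_chain <- function(n_beads, b = 2, n_samples = 1, seed = 1) {
  if (n_beads < 3) stop("n_beads must be >= 3")
  set.seed(seed)
  out <- array(0, c(n_beads, 3, n_samples))
  for (k in seq_len(n_samples)) {
    steps <- matrix(stats::rnorm(3 * (n_beads - 1), sd = b / sqrt(3)),
                    ncol = 3)
    out[, , k] <- rbind(0, apply(steps, 2, cumsum))
  }
  out
}

#' @rdname sample_gaussian_chain
#' @inheritParams saw_reference_stats
#' @return for `gaussian_reference_stats`: as [saw_reference_stats()] minus
#'   `e2e`.
#' @export
gaussian_reference_stats <- function(n_beads, n_samples, b = 2,
                                     threshold = 2.0,
                                     s_max = floor(n_beads / 2), seed = 1) {
  st <- cpp_gaussian_chain_stats(as.integer(n_beads), b,
                                 as.integer(n_samples), threshold,
                                 as.integer(s_max), seed)
  list(ps = new_ps_curve(st$s, st$contacts / st$pairs, st$pairs),
       r2 = data.frame(s = st$s, r2 = st$r2),
       rg = st$rg)
}

#' Ground-truth block-copolymer fixture
#'
#' Simulates the full strings-and-binders dynamics of a known block
#' profile and emits its ensemble contact matrix as a synthetic Hi-C-like
#' target, optionally with entrywise log-normal multiplicative noise
#' (distance-preserving mean). The generating profile is returned so
#' inference can be scored against the truth.
#'
#' @param n_beads chain length (default 200, sized so the full
#'   infer/validate/mutate loop runs in minutes on one CPU).
#' @param blocks block layout as in [build_block_copolymer()]; the default is
#'   two pairs of alternating 50-bead red/green blocks.
#' @param e_int affinity per colour (k_BT); default 4.1, the deep ordered
#'   phase.
#' @param c_nmol binder concentration per colour (nmol/l); default 54.
#' @param n_traj independent trajectories pooled into the target map.
#' @param n_relax,n_sample,sample_interval integration protocol per
#'   trajectory (defaults pass the collapse plateau at N = 200).
#' @param threshold contact threshold for the map (sigma).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise on matrix entries (0 = noiseless).
#' @param box_edge box side; default sized by [default_box_edge()] at
#'   volume fraction 0.02 to match the production setup.
#' @param seed seed controlling trajectories and noise.
#' @return list with `profile` (truth, an `sbs_binding_profile`), `target`
#'   (`sbs_contact_matrix`), `system`, and provenance.
#' @export
make_block_fixture <- function(n_beads = 200,
                               blocks = data.frame(length = c(50, 50, 50, 50),
                                                   color = c(1, 2, 1, 2)),
                               e_int = 4.1, c_nmol = 54, n_traj = 20,
                               n_relax = 120000, n_sample = 60000,
                               sample_interval = 3000, threshold = 3.5,
                               noise_cv = 0, box_edge = NULL, seed = 1) {
  chain <- build_block_copolymer(blocks)
  if (sum(blocks$length) != n_beads)
    stop("blocks must sum to n_beads")
  n_colors <- chain$n_colors
  ff <- force_field(e_int = rep_len(e_int, n_colors))
  box <- simulation_box(if (is.null(box_edge))
    default_box_edge(2 * n_beads, phi = 0.02) else box_edge)
  sys <- sbs_system(chain, box, ff, concentration = rep_len(c_nmol, n_colors))
  expect_collapse <- any(e_int > 0) && any(chain$colors > 0)
  col <- collect_equilibrium_maps(sys, n_traj, seed_base = seed * 1000,
                                  n_relax = n_relax,
                                  max_relax = max(4 * n_relax, 500000),
                                  n_sample = n_sample,
                                  sample_interval = sample_interval,
                                  threshold = threshold,
                                  expect_collapse = expect_collapse,
                                  adaptive = FALSE)
  maps <- col$maps
  target <- Reduce(`+`, maps) / length(maps)
  if (noise_cv > 0) {
    set.seed(seed + 271828)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(target), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nrow = nrow(target))
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    target <- target * noise
    diag(target) <- 1
  }
  profile <- binding_profile(chain$colors, e_int = rep_len(e_int, n_colors),
                             concentration = rep_len(c_nmol, n_colors))
  list(profile = profile,
       target = new_contact_matrix(target, threshold = threshold,
                                   n_snapshots = n_traj *
                                     (1 + n_sample %/% sample_interval)),
       system = sys,
       provenance = list(n_traj = n_traj, n_relax = n_relax,
                         n_sample = n_sample,
                         sample_interval = sample_interval,
                         noise_cv = noise_cv, seed = seed))
}

#' Brute-force contact oracle
#'
#' Independent O(N^3) reference implementation of the contact observables
#' for small ensembles (N <= 50, snapshots <= 1000): P_c(s), the triplet
#' grid, and many-body component counts via igraph. Shares no kernels with
#' the production code paths.
#'
#' @param arr N x 3 x T array of positions (no periodic wrapping).
#' @param threshold contact distance.
#' @param n_max largest many-body order.
#' @param s_max triplet grid extent.
#' @return list with `ps` (data.frame `s`, `p`), `triplet` (matrix), and
#'   `manybody` (data.frame `n`, `frequency`).
#' @export
brute_force_contact_oracle <- function(arr, threshold, n_max = 8,
                                       s_max = NULL) {
  d <- dim(arr)
  if (d[1] > 50 || d[3] > 1000)
    stop("oracle-scope: brute-force oracle limited to N <= 50, T <= 1000")
  n <- d[1]; nt <- d[3]
  if (is.null(s_max)) s_max <- n - 2
  adj_of <- function(t) {
    m <- as.matrix(stats::dist(arr[, , t])) <= threshold
    diag(m) <- FALSE
    m
  }
  psum <- numeric(n - 1)
  trip <- matrix(0, s_max, s_max)
  comp <- numeric(n_max)
  for (t in seq_len(nt)) {
    a <- adj_of(t)
    for (s in seq_len(n - 1)) {
      hits <- 0
      for (i in seq_len(n - s)) hits <- hits + a[i, i + s]
      psum[s] <- psum[s] + hits / (n - s)
    }
    for (s1 in seq_len(s_max)) for (s2 in seq_len(s_max)) {
      if (s1 + s2 >= n) next
      hits <- 0; tot <- n - s1 - s2
      for (i in seq_len(tot))
        hits <- hits + (a[i, i + s1] && a[i + s1, i + s1 + s2] &&
                          a[i, i + s1 + s2])
      trip[s1, s2] <- trip[s1, s2] + hits / tot
    }
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    cs <- igraph::components(g)$csize
    for (k in cs) if (k <= n_max) comp[k] <- comp[k] + 1
  }
  list(ps = data.frame(s = seq_len(n - 1), p = psum / nt),
       triplet = trip / nt,
       manybody = data.frame(n = seq_len(n_max), frequency = comp / nt))
}
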