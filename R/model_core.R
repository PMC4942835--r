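#' Force field of the strings-and-binders system
#'
#' Bundles the interaction parameters of the coarse-grained model in reduced
#' units (bead diameter `sigma = 1`, thermal energy `kT = 1`, bead mass 1).
#' Chain beads are connected by FENE bonds; all bead-bead and binder-binder
#' pairs repel through a WCA (purely repulsive, truncated-shifted
#' Lennard-Jones) potential; bead-binder pairs of matching colour attract
#' through a truncated-and-shifted Lennard-Jones well of depth
#' `e_int[colour] * multiplicity`.
#'
#' @param e_int numeric vector of bead-binder affinities, one per colour
#'   (k_BT units). Values must be >= 0.
#' @param eps_rep repulsive (WCA) energy scale in k_BT.
#' @param r_cut_attr cutoff of the attractive well, in sigma. Must exceed the
#'   WCA cutoff 2^(1/6).
#' @param fene_k FENE bond stiffness (k_BT / sigma^2).
#' @param fene_r0 maximum FENE bond extension (sigma). Must exceed sigma.
#' @param sigma bead/binder diameter. The simulation core works in reduced
#'   units, so this must be 1; physical sizes enter only through
#'   [simulation_box()] unit mapping.
#' @param kT thermal energy (reduced; must be 1 for the shipped integrator).
#' @return an object of class `sbs_force_field`.
#' @export
force_field <- function(e_int = 0, eps_rep = 1, r_cut_attr = 1.5,
                        fene_k = 30, fene_r0 = 1.5, sigma = 1, kT = 1) {
  e_int <- as.numeric(e_int)
  if (any(!is.finite(e_int)) || any(e_int < 0))
    stop("invalid-model: affinities e_int must be finite and >= 0")
  if (sigma != 1)
    stop("unit-mapping: the core works in reduced units, sigma must be 1")
  if (!(fene_r0 > sigma))
    stop("invalid-model: fene_r0 must exceed sigma")
  if (!(r_cut_attr > 2^(1 / 6) * sigma))
    stop("invalid-model: r_cut_attr must exceed the WCA cutoff 2^(1/6) sigma")
  if (eps_rep < 0 || fene_k < 0)
    stop("invalid-model: energies must be >= 0")
  structure(list(sigma = sigma, eps_rep = eps_rep, e_int = e_int,
                 r_cut_attr = r_cut_attr, fene_k = fene_k, fene_r0 = fene_r0,
                 kT = kT),
            class = "sbs_force_field")
}

#' Periodic cubic simulation box
#'
#' @param edge box side in sigma.
#' @param physical_sigma optional physical bead diameter in nanometres used by
#'   the concentration/coordinate unit mapping (87 nm corresponds to a
#'   100 kb-per-bead coarse graining of a 100 Mb chromosome modelled with
#'   1000 beads).
#' @return an object of class `sbs_box`.
#' @export
simulation_box <- function(edge, physical_sigma = 87) {
  if (!is.numeric(edge) || length(edge) != 1 || !(edge > 3))
    stop("invalid-model: box edge must exceed 2 * fene_r0 (= 3 sigma)")
  structure(list(edge = as.numeric(edge), periodic = TRUE,
                 physical_sigma = physical_sigma),
            class = "sbs_box")
}

#' Default box edge for a target packing fraction
#'
#' Picks the smallest edge such that the combined volume fraction of beads and
#' binders (spheres of diameter sigma) does not exceed `phi`.
#'
#' @param n_particles total number of beads plus binders.
#' @param phi maximum volume fraction (default 0.1 per the model contract;
#'   production runs in this package use more dilute boxes).
#' @return box edge in sigma.
#' @export
default_box_edge <- function(n_particles, phi = 0.1) {
  max(4, ceiling((n_particles * pi / 6 / phi)^(1 / 3)))
}

new_bead_chain <- function(colors, positions = NULL, block_bounds = NULL) {
  storage.mode(colors) <- "integer"
  structure(list(n_beads = nrow(colors), n_colors = ncol(colors),
                 colors = colors, positions = positions,
                 block_bounds = block_bounds),
            class = "sbs_bead_chain")
}

#' Build a homopolymer chain
#'
#' Linear chain of `n_beads` identical beads, each carrying one binding site
#' of the given colour.
#'
#' @param n_beads chain length N (>= 2).
#' @param color colour index of the binding sites (>= 1), or 0 for a fully
#'   inert chain.
#' @param n_colors total number of colours carried by the chain (defaults to
#'   `max(color, 1)`).
#' @return an `sbs_bead_chain` (positions unset; see
#'   [initialize_saw_configuration()]).
#' @export
build_homopolymer <- function(n_beads, color = 1, n_colors = max(color, 1)) {
  if (!is.numeric(n_beads) || n_beads < 2)
    stop("invalid-model: a chain needs at least 2 beads")
  m <- matrix(0L, nrow = n_beads, ncol = n_colors)
  if (color >= 1) m[, color] <- 1L
  new_bead_chain(m)
}

#' Build a block copolymer chain
#'
#' @param blocks a data.frame with columns `length` and `color` (colour 0 =
#'   inert spacer), or a list of `c(length, color)` pairs. Blocks are laid
#'   down in order.
#' @param multiplicity binding-site multiplicity given to every bead of a
#'   non-inert block.
#' @return an `sbs_bead_chain`; block boundaries (0-based bead indices at
#'   which a new block starts, excluding 0) are kept in `$block_bounds` for
#'   boundary symmetry-breaking analyses.
#' @export
build_block_copolymer <- function(blocks, multiplicity = 1) {
  if (is.list(blocks) && !is.data.frame(blocks))
    blocks <- do.call(rbind.data.frame,
                      lapply(blocks, function(b) list(length = b[1], color = b[2])))
  if (!all(c("length", "color") %in% names(blocks)) || nrow(blocks) < 1)
    stop("invalid-model: blocks need `length` and `color`")
  if (any(blocks$length < 1))
    stop("invalid-model: zero-length block")
  n <- sum(blocks$length)
  if (n < 2) stop("invalid-model: a chain needs at least 2 beads")
  n_colors <- max(1, blocks$color)
  m <- matrix(0L, nrow = n, ncol = n_colors)
  at <- 0
  for (k in seq_len(nrow(blocks))) {
    idx <- at + seq_len(blocks$length[k])
    if (blocks$color[k] >= 1) m[idx, blocks$color[k]] <- as.integer(multiplicity)
    at <- at + blocks$length[k]
  }
  bounds <- cumsum(blocks$length)
  new_bead_chain(m, block_bounds = bounds[-length(bounds)])
}

#' Map a molar binder concentration to a binder count (and back)
#'
#' Converts a concentration in nmol/l to the number of binders the periodic
#' box holds, using the box's physical bead diameter:
#' `count = round(c * N_A * V)` with `V = (edge * physical_sigma)^3` in litres.
#'
#' @param c_nmol concentration in nmol per litre (>= 0).
#' @param box an [simulation_box()] with `physical_sigma` set (nm).
#' @return integer binder count.
#' @export
binder_count_from_concentration <- function(c_nmol, box) {
  if (is.null(box$physical_sigma) || !is.finite(box$physical_sigma))
    stop("unit-mapping: box$physical_sigma (nm) is required")
  if (c_nmol < 0) stop("invalid-model: concentration must be >= 0")
  v_litres <- (box$edge * box$physical_sigma * 1e-9)^3 * 1e3
  as.integer(round(c_nmol * 1e-9 * 6.02214076e23 * v_litres))
}

#' @rdname binder_count_from_concentration
#' @param count binder count.
#' @return for `concentration_from_binder_count`, the concentration in nmol/l.
#' @export
concentration_from_binder_count <- function(count, box) {
  if (is.null(box$physical_sigma) || !is.finite(box$physical_sigma))
    stop("unit-mapping: box$physical_sigma (nm) is required")
  v_litres <- (box$edge * box$physical_sigma * 1e-9)^3 * 1e3
  count / (6.02214076e23 * v_litres) / 1e-9
}

#' Self-avoiding initial configuration
#'
#' Grows a random self-avoiding conformation with unit bonds inside the
#' periodic box: no pair of beads closer than sigma under the minimum-image
#' convention. Deterministic for a given seed.
#'
#' @param chain an `sbs_bead_chain`.
#' @param box an `sbs_box`.
#' @param seed RNG seed (positive integer).
#' @return the chain with `$positions` set (N x 3 matrix).
#' @export
initialize_saw_configuration <- function(chain, box, seed = 1) {
  pos <- tryCatch(
    cpp_grow_saw(chain$n_beads, box$edge, seed, 1.0, 1.0, 25L),
    error = function(e) stop("congestion: ", conditionMessage(e), call. = FALSE))
  chain$positions <- pos
  chain
}

#' Assemble a polymer-binder system
#'
#' @param chain an `sbs_bead_chain` (positions may be unset; they are then
#'   grown at simulation time from the run seed).
#' @param box an `sbs_box`.
#' @param ff an `sbs_force_field` whose `e_int` covers the chain's colours.
#' @param binders either an integer vector of binder counts per colour or the
#'   result of [binder_count_from_concentration()] recycled across colours.
#' @param concentration alternatively, a per-colour concentration in nmol/l
#'   converted through the box unit mapping.
#' @return an object of class `sbs_system`.
#' @export
sbs_system <- function(chain, box, ff, binders = NULL, concentration = NULL) {
  stopifnot(inherits(chain, "sbs_bead_chain"), inherits(box, "sbs_box"),
            inherits(ff, "sbs_force_field"))
  if (box$edge <= 2 * ff$fene_r0)
    stop("invalid-model: box edge must exceed 2 * fene_r0")
  n_colors <- chain$n_colors
  if (length(ff$e_int) < n_colors)
    stop("invalid-model: force field covers fewer colours than the chain")
  if (is.null(binders)) {
    if (is.null(concentration)) stop("give binder counts or a concentration")
    binders <- vapply(rep_len(concentration, n_colors),
                      binder_count_from_concentration, integer(1), box = box)
  }
  binders <- as.integer(rep_len(binders, n_colors))
  if (any(binders < 0)) stop("invalid-model: binder counts must be >= 0")
  structure(list(chain = chain, box = box, ff = ff, binders = binders,
                 binder_colors = rep(seq_len(n_colors), binders)),
            class = "sbs_system")
}

#' @export
print.sbs_system <- function(x, ...) {
  cat(sprintf("SBS system: N = %d beads (%d colour%s), %d binders, box edge %.4g sigma\n",
              x$chain$n_beads, x$chain$n_colors,
              if (x$chain$n_colors == 1) "" else "s",
              sum(x$binders), x$box$edge))
  cat(sprintf("  e_int = %s k_BT; c = %s nmol/l\n",
              paste(signif(x$ff$e_int, 3), collapse = ", "),
              paste(signif(vapply(x$binders, concentration_from_binder_count,
                                  numeric(1), box = x$box), 3), collapse = ", ")))
  invisible(x)
}
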