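---
title: "Methods: the strings-and-binders model in sbsfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the strings-and-binders model in sbsfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sbsfold` implements the strings-and-binders (SBS) picture of chromatin
folding: a chromatin filament is a coarse-grained bead-spring polymer of `N`
beads (diameter `sigma`), and folding is driven by diffusing molecular
binders that can bridge two or more cognate binding sites on the chain.
Every quantity is handled in reduced units (`sigma = 1`, `kT = 1`, bead mass
1); physical units enter only through explicit mappings (a bead of
`physical_sigma = 87` nm corresponds to 100 kb at the 1000-bead
chromosome coarse-graining, and molar binder concentrations convert to
counts through the box volume).

The force field is the classical bead-spring set-up:

* consecutive beads: FENE bonds, `U = -0.5 k r0^2 log(1 - (r/r0)^2)` with
  `k = 30 kT/sigma^2`, `r0 = 1.5 sigma` (the classical values; the source
  work cites the standard polymer potentials without printing constants);
* all bead-bead and binder-binder pairs: WCA repulsion (energy scale
  `eps_rep = 1 kT`, cutoff `2^(1/6) sigma`) — binders do not attract each
  other;
* bead-binder pairs of matching colour: a truncated-and-shifted
  Lennard-Jones well of scale `E_int` (k_BT), cutoff `r_cut_attr = 1.5
  sigma`. A bead of multiplicity `m` in that colour interacts with depth
  `m * E_int` — multiplicity models several binding sites inside one
  coarse-grained bead.

Dynamics are underdamped Langevin, integrated with the BAOAB splitting at
`dt = 0.012 tau`, friction `gamma = 0.5/tau`, in a periodic cubic box under
the minimum-image convention with Verlet neighbour lists (skin `0.3 sigma`,
rebuild at half-skin displacement). A step that overstretches a FENE bond is
rejected and retried at half the timestep (bounded recursion), which keeps
the integration stable without biasing equilibrium sampling at the default
timestep (rejections are essentially absent there and are counted in the
trajectory object).

## Phases and observables

In the `(E_int, c)` plane the chain has the classical coil-globule
transition; the package classifies runs with `classify_state()` using the
equilibrium gyration radius against the pivot-SAW reference at equal `N`,
and flags theta proximity around the ideal-chain value `sqrt(N/6)`. The
contact-decay curve `P_c(s)` is the central observable: its log-log slope
`alpha` is ~2.1 in the coil (SAW universality), ~1.5 at the theta point,
~1.0 before the plateau in the compact ordered-globule regime, and shows an
early plateau in the disordered globule. `R^2(s)`, the structure factor of
the binder cloud `S(k)`, many-body contact statistics and triplet contact
probabilities complete the observable set.

Numerical choices worth stating:

* **Contact thresholds.** 3.5 sigma for locus-style contact maps (robust to
  coarse-graining), 2.0 sigma for exponent estimation; both configurable.
* **Exponent fits.** Least squares of `log10 P` on `log10 s` over log-spaced
  bins (8/decade) in the window `[10, N/4]`, avoiding short-range stiffness
  and chain ends; bootstrap over bins for the CI. The pre-plateau fit
  first decides whether the curve has a plateau at all (it decays by less
  than a factor 2 across its outer half — a ratio criterion, robust both
  to plateau sampling noise and to the chain-end depletion that bends the
  very tail down), locates the onset as the first separation within 1.5x
  the terminal level, and fits from `max(4, onset/10)` to the onset
  (separations below ~4 are threshold-saturated by local stiffness). On
  the N = 250 globule the detected onset sits at s ~ 20-26, matching the
  Gaussian-saturation estimate `s* ~ Rg^2` for an equilibrium globule.
* **Equilibration.** The coil-globule transition is nucleation-limited: a
  fixed relaxation length strands an occasional trajectory in the
  metastable open state. All ensemble producers therefore relax each
  trajectory with `relax_state()` until the Rg trace is flat *and*, when
  the phase point is globular, actually collapsed (below 0.6 of the
  running maximum), with a hard step cap. This is a convergence criterion,
  not seed selection: the cap is generous and unconverged relaxations are
  flagged.
* **Many-body contacts.** Counted as connected components of the contact
  graph over probe sites (every 10th bead by default), not cliques
  (threshold-brittle, costly) and not over all beads: with any threshold
  above the bond length, the full-bead graph is trivially connected through
  the backbone, which would make the statistic vacuous. Both exact-size and
  cumulative (>= n) component counts are reported; enrichment relative to
  the SAW reference uses the cumulative counts, which is the quantity that
  grows exponentially with n upon collapse.
* **Order-disorder classification.** The specified rule calls an aggregate
  ordered when the bound-binder `S(k)` has a peak more than 3x the median
  `S(k)` over `k in [0.5, 2]/sigma`. The rule is implemented as stated and
  validates on crystalline binder arrangements, but in this implementation
  the aggregate at `E_int = 4.1 kT, c = 54 nmol/l` remains liquid-like at
  desk-scale simulation times (first-peak prominence ~1.9, versus ~1.5 at
  `E_int = 3.1` and ~2.9 at `E_int = 6`): the sharp-peak call does not
  trigger where the reference work reports the ordered state, whose
  LAMMPS-level protocol details are not public. `classify_state()`
  therefore returns `globule_disordered` at those parameters, the
  prominence remains the (monotone) order diagnostic, and the pure-state
  library verifies the collapse strictly plus the prominence ordering
  between its two globular entries.

## Mixture fits

A chromosome is modelled as a mixture of regions folded in the pure
thermodynamic states, so its average contact decay is the convex
combination `P(s) = sum_i w_i P_i(s/g)` with a genomic scale factor `g`
(bp per bead). Fitting minimises the mean squared difference of `log10 P`
over log-spaced bins (8/decade, so each decade weighs equally), with both
curves anchored to 1 at the smallest shared separation (experimental `P(s)`
has arbitrary scale). Weights live on the simplex (projected-gradient
least squares, convex at fixed `g`; multi-start from the vertices), and `g`
is scanned on an exhaustive log grid (20/decade) over every value that maps
the observed support into the library support. Weight uncertainty comes
from a bootstrap over bins. `synthetic_state_library()` provides analytic
pure-state shapes (`s^-2.1`, `s^-1.5`, plateaued variants) for recovery
studies; `build_pure_state_library()` derives the curves from actual
ensembles (pivot-SAW, Gaussian chains, and SBS runs at `E_int = 3.1` and
`4.1 kT`, `c = 54 nmol/l`). One identifiability caveat: the coil and theta
log-shapes are nearly collinear over a noisy two-decade window, so under
multiplicative noise single fits can trade weight between those two states
while their sum, and the two globular weights, stay tightly determined —
the bootstrap covariance reports exactly this.

## Inference of binding profiles

`anneal_binding_profile()` infers the per-bead colour/multiplicity
arrangement that reproduces a target contact matrix. Inside the optimiser a
fast surrogate replaces molecular dynamics:

```
M_ij = P0(|i-j|) * (1 + kappa * sum_c min(m_ic, m_jc)) / Z
```

with `P0` the target's own diagonal-mean decay and `Z` restoring the
baseline's total contact mass (the all-inert profile returns the baseline
exactly). The contrast `kappa = 2.2` was calibrated once against MD on the
two-colour block reference system (N = 200; `calibrate_kappa()` reproduced
the MD map with Pearson 0.93) and is not tuned per target. Annealing is
Metropolis with geometric cooling (factor 0.9, 50 sweeps per level, T0
chosen automatically so the initial uphill acceptance is about one half),
moves are single-bead multiplicity steps (70%) and two-bead profile swaps
(30%), multiplicities are capped at `m_max = 3`, and the cost is the mean
squared difference of row-normalised matrices plus the parsimony price
`lambda * sum(m)` ("minimal arrangement": every site costs). The price
matters: at `lambda = 0` the optimiser inflates multiplicities, because
extra valence partially compensates the linear surrogate's contrast
shortfall against the saturating MD map without changing the arrangement —
and an inflated profile then simulates as an over-sticky gel. The
recommended selection is the L-curve elbow (`select_lambda_elbow()`): the
most parsimonious profile whose unpenalised distance stays within 10% of
the best fit, over a `lambda` grid auto-scaled to the cost magnitude
(`d0/N`, of order 1e-8 for an N = 200 target). Two-fold diagonal
cross-validation (`select_lambda_cv()`: fit odd diagonals, score even
ones) is also provided, but cannot price out multiplicity inflation, which
generalises across diagonals. The
optimisation is recursive across resolutions: the target is pooled by
factors of two down to <= 64 bins, solved there, and upsampled to seed each
finer level. Profiles are validated by full Langevin dynamics
(`validate_profile_with_dynamics()`), and colour labels are exchangeable,
so recovery is scored up to colour permutation.

## Variants

`apply_deletion()` removes a bead interval and rejoins the chain; the
mutant is re-simulated with the identical force field and **fixed binder
molar concentration** (box unchanged — binders are a nuclear reservoir, so
deleting binding sites does not delete binders). No quantity is refit. The
mutant map is lifted back to wild-type coordinates by inserting masked
bins, and `ectopic_interaction_map()` reports the scale-normalised
difference divided by the wild-type expected decay per diagonal. The wild
type is deliberately the common observed/expected reference for both maps:
normalising each map by its own diagonal means would cancel — at locus
scale, where the rearranged regions dominate their diagonals, even invert
— exactly the position-specific gains being measured. Inversions and
duplications are deliberate stubs. Validation correlations can be computed
at map-bin resolution (`bin_factor` beads per bin), mirroring how simulated
bead maps are compared against binned Hi-C/5C data; bead-level Pearson on
small ensembles measures sampling noise rather than model quality.

## The synthetic world, and what a green test establishes

No external data ships with the package. Reference ensembles are the
cubic-lattice pivot SAW sampler (hard-core, samples `N` attempted moves
apart) and ideal Gaussian chains. The Gaussian theta-reference uses bond
`b = 2 sigma` by default: with the 2-sigma contact threshold fixed by the
exponent protocol, the closed form `P(s) = P(chi2_3 <= 3 a^2/(s b^2))`
shows that `b >= a` is needed for the curve to be in its asymptotic
`s^-1.5` regime over the fit window (`b = 1` would give a fitted slope of
~1.37 purely from short-range saturation). This was decided from the
closed form before any sampling.

Synthetic Hi-C-like targets come from `make_block_fixture()`: the full SBS
dynamics of a known block profile (default: two pairs of alternating
50-bead blocks, `E_int = 4.1 kT`, `c = 54 nmol/l`, 20 pooled trajectories),
optionally with entrywise log-normal multiplicative noise with
distance-preserving mean — the multiplicative character of Hi-C counts
without coverage/mappability biases, which are out of scope. Consequently a
green inference test establishes that the optimiser recovers profiles whose
contact statistics the simulator itself generated, under that noise model;
it does not establish robustness to the full error structure of real Hi-C
(coverage bias, translocations, unmappable bins), nor does the mixture fit
establish anything about real chromosomes — those claims would need the
external data sets that are deliberately not part of this package.

## Known limitations

* The ordered-globule sharp-peak signature is not reached at the reference
  parameters on desk-scale timescales (see above); order remains a
  monotone diagnostic rather than a sharp classifier there.
* The surrogate map is a mean-field proxy; kappa is calibrated on a block
  system and the surrogate saturates for long-range loops far from that
  regime.
* Physical time units (the ~seconds-scale folding estimate) are exposed
  only through the unit-mapping helpers; no attempt is made to calibrate
  friction to nucleoplasm viscosity.
* HDF5 containers are not supported in this build (no HDF5-capable R
  package in the target environment); dense TSV and multi-frame XYZ are
  the interchange formats.
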