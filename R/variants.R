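#' Apply a deletion to a binding profile
#'
#' Removes the beads in `[start, end)` (0-based, half-open) and re-joins the
#' chain with a bond between the former neighbours. Binder concentrations
#' are left unchanged (fixed-concentration convention: binders are a nuclear
#' reservoir, so removing binding sites does not remove binders; the box is
#' unchanged too, hence binder counts are identical).
#'
#' @param profile an `sbs_binding_profile`.
#' @param interval `c(start, end)` in bead coordinates, `0 <= start < end <=
#'   N`; `start == end` is the identity.
#' @return the mutant profile, with `attr(, "coordinate_map")`: a data.frame
#'   `old` (0-based WT bead), `new` (0-based mutant bead or NA when
#'   deleted), and `attr(, "deletion")`.
#' @export
apply_deletion <- function(profile, interval) {
  n <- profile$n_beads
  start <- interval[1]; end <- interval[2]
  if (start < 0 || end > n || start > end)
    stop("invalid-variant: need 0 <= start <= end <= N")
  keep <- setdiff(seq_len(n) - 1L, seq.int(start, length.out = end - start))
  if (length(keep) < 2)
    stop("invalid-variant: deletion leaves fewer than 2 beads")
  mut <- binding_profile(profile$multiplicities[keep + 1L, , drop = FALSE],
                         e_int = profile$e_int,
                         concentration = profile$concentration,
                         m_max = profile$m_max)
  map <- data.frame(old = seq_len(n) - 1L, new = NA_integer_)
  map$new[keep + 1L] <- seq_along(keep) - 1L
  attr(mut, "coordinate_map") <- map
  attr(mut, "deletion") <- c(start = start, end = end)
  attr(mut, "binder_convention") <- "fixed molar concentration, box unchanged"
  mut
}

#' Not-implemented structural variants
#'
#' Only deletions are supported; the coordinate-lifting contract is general,
#' but inversions and duplications are deliberate stubs.
#'
#' @param profile an `sbs_binding_profile`.
#' @param interval bead interval.
#' @export
apply_inversion <- function(profile, interval) {
  stop("not-implemented: only deletions are supported")
}

#' @rdname apply_inversion
#' @export
apply_duplication <- function(profile, interval) {
  stop("not-implemented: only deletions are supported")
}

#' Predict the contact map of a deletion variant
#'
#' Simulates the mutant profile with the identical force field, binder
#' concentrations and integration protocol as the wild type -- no refitting,
#' no adjustable parameters -- and lifts the resulting map back to wild-type
#' coordinates by inserting masked (NA) rows/columns at the deletion.
#'
#' @param profile the wild-type `sbs_binding_profile`.
#' @param interval deletion `c(start, end)` in bead coordinates.
#' @param ... simulation protocol passed to
#'   [validate_profile_with_dynamics()] (`n_traj`, `n_relax`, `n_sample`,
#'   `sample_interval`, `threshold`, `box_edge`, `seed`, ...).
#' @return list with `mutant_profile`, `map` (mutant coordinates), `lifted`
#'   (WT coordinates, deleted bins NA), and the simulation provenance.
#' @export
predict_variant_map <- function(profile, interval, ...) {
  mut <- apply_deletion(profile, interval)
  sim <- validate_profile_with_dynamics(mut, target = NULL, ...)
  map <- sim$map
  lifted <- lift_matrix_to_wt(unclass(map), attr(mut, "coordinate_map"))
  list(mutant_profile = mut, map = map,
       lifted = new_contact_matrix(lifted,
                                   threshold = attr(map, "threshold"),
                                   n_snapshots = attr(map, "n_snapshots")),
       provenance = c(sim$provenance,
                      list(deletion = attr(mut, "deletion"),
                           binder_convention = attr(mut, "binder_convention"))))
}

lift_matrix_to_wt <- function(m, coordinate_map) {
  n_wt <- nrow(coordinate_map)
  out <- matrix(NA_real_, n_wt, n_wt)
  kept <- !is.na(coordinate_map$new)
  out[kept, kept] <- m[coordinate_map$new[kept] + 1L,
                       coordinate_map$new[kept] + 1L]
  out
}

#' Drop masked bins from a lifted matrix
#'
#' Inverse of the coordinate lifting: removing the masked rows/columns
#' recovers the mutant-coordinate matrix exactly.
#'
#' @param lifted matrix in WT coordinates with NA-masked deleted bins.
#' @return matrix over the unmasked bins.
#' @export
drop_masked_bins <- function(lifted) {
  m <- unclass(lifted)
  keep <- !apply(m, 1, function(r) all(is.na(r)))
  m[keep, keep]
}

#' Ectopic interaction map
#'
#' Signed mutant-minus-wild-type comparison in wild-type coordinates. Both
#' maps are first scaled to unit mean over their commonly valid entries
#' (removing the global contact-level change a deletion induces), then their
#' difference is divided, diagonal by diagonal, by the wild-type expected
#' decay (the WT diagonal means). The wild type serves as the common
#' reference for both maps: normalising each map by its own diagonal means
#' would cancel -- or at locus scale even invert -- exactly the signal of
#' interest whenever the rearranged regions dominate their diagonals.
#' Positive entries are ectopic gains; masked bins stay masked.
#'
#' @param wt wild-type map (WT coordinates).
#' @param mut_lifted mutant map lifted to WT coordinates (deleted bins NA).
#' @return signed matrix in WT coordinates, class `sbs_contact_matrix` with
#'   normalization `"obs_exp_difference"`.
#' @export
ectopic_interaction_map <- function(wt, mut_lifted) {
  a <- unclass(wt); b <- unclass(mut_lifted)
  if (!all(dim(a) == dim(b))) stop("alignment: matrices differ in shape")
  mask_a <- apply(a, 1, function(r) all(is.na(r)))
  mask_b <- apply(b, 1, function(r) all(is.na(r)))
  if (any(mask_a & !mask_b)) stop("alignment: masks disagree")
  valid <- is.finite(a) & is.finite(b)
  if (!any(valid)) stop("alignment: no commonly valid entries")
  a_s <- a / mean(a[valid])
  b_s <- b / mean(b[valid])
  n <- nrow(a)
  out <- matrix(NA_real_, n, n)
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    idx <- cbind(i, i + s)
    mu <- mean(a_s[idx], na.rm = TRUE)   # wild-type expected at separation s
    v <- if (is.finite(mu) && mu > 0) (b_s[idx] - a_s[idx]) / mu else NA_real_
    out[idx] <- v
    out[idx[, c(2, 1), drop = FALSE]] <- v
  }
  new_contact_matrix(out, normalization = "obs_exp_difference")
}
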