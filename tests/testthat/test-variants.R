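block_profile <- function() {
  ch <- build_block_copolymer(data.frame(length = c(40, 20, 40),
                                         color = c(1, 0, 1)))
  binding_profile(ch$colors)
}

test_that("deletions rejoin the chain and map coordinates", {
  m <- matrix(1L, 100, 1)
  p <- binding_profile(m)
  mut <- apply_deletion(p, c(40, 60))
  expect_equal(mut$n_beads, 80)
  map <- attr(mut, "coordinate_map")
  expect_equal(map$new[map$old == 39], 39)
  expect_true(is.na(map$new[map$old == 45]))
  expect_equal(map$new[map$old == 60], 40) # old bead 60 follows old bead 39

  # empty interval is the identity
  id <- apply_deletion(p, c(50, 50))
  expect_equal(id$multiplicities, p$multiplicities)

  expect_error(apply_deletion(p, c(0, 100)), "invalid-variant")
  expect_error(apply_deletion(p, c(-1, 10)), "invalid-variant")

  # the multiset of multiplicities outside the interval is preserved
  p2 <- block_profile()
  mut2 <- apply_deletion(p2, c(40, 60))
  keep <- c(1:40, 61:100)
  expect_equal(sort(mut2$multiplicities[, 1]),
               sort(p2$multiplicities[keep, 1]))
})

test_that("inversions and duplications are explicit stubs", {
  p <- block_profile()
  expect_error(apply_inversion(p, c(1, 5)), "not-implemented")
  expect_error(apply_duplication(p, c(1, 5)), "not-implemented")
})

test_that("coordinate lifting round-trips through masked bins", {
  p <- block_profile()
  mut <- apply_deletion(p, c(40, 60))
  m <- matrix(seq_len(80 * 80) / 6400, 80)
  m <- (m + t(m)) / 2
  ns <- asNamespace("sbsfold")
  lifted <- ns$lift_matrix_to_wt(m, attr(mut, "coordinate_map"))
  expect_equal(dim(lifted), c(100, 100))
  expect_true(all(is.na(lifted[41:60, ])))
  expect_equal(drop_masked_bins(lifted), m)
})

test_that("ectopic maps vanish for identical inputs and keep masks", {
  set.seed(2)
  a <- matrix(rexp(50 * 50), 50)
  a <- a + t(a)
  z <- ectopic_interaction_map(a, a)
  expect_lt(max(abs(unclass(z)), na.rm = TRUE), 1e-12)

  b <- a
  b[10, ] <- NA; b[, 10] <- NA
  z2 <- ectopic_interaction_map(a, b)
  expect_true(all(is.na(unclass(z2)[10, ])))
  expect_error(ectopic_interaction_map(a, a[1:10, 1:10]), "alignment")
})
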