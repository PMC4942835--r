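test_that("homopolymer construction follows the contract", {
  ch <- build_homopolymer(1000, color = 1)
  expect_equal(ch$n_beads, 1000)
  expect_true(all(ch$colors[, 1] == 1L))

  ch2 <- build_homopolymer(2, color = 1)
  expect_equal(ch2$n_beads, 2)

  ch3 <- build_homopolymer(2250)
  expect_equal(ch3$n_beads, 2250)

  expect_error(build_homopolymer(1), "invalid-model")
})

test_that("block copolymers lay down blocks in order and record boundaries", {
  ch <- build_block_copolymer(data.frame(length = c(250, 250, 250, 250),
                                         color = c(1, 2, 1, 2)))
  expect_equal(ch$n_beads, 1000)
  expect_equal(ch$n_colors, 2)
  expect_equal(ch$block_bounds, c(250, 500, 750))
  expect_true(all(ch$colors[1:250, 1] == 1L) && all(ch$colors[1:250, 2] == 0L))
  expect_true(all(ch$colors[251:500, 2] == 1L))

  # single block reduces to a homopolymer
  single <- build_block_copolymer(data.frame(length = 10, color = 1))
  expect_equal(single$colors, build_homopolymer(10)$colors)

  # inert spacer: all-zero rows
  spc <- build_block_copolymer(data.frame(length = c(5, 5, 5),
                                          color = c(1, 0, 1)))
  expect_true(all(rowSums(spc$colors[6:10, , drop = FALSE]) == 0))

  expect_error(build_block_copolymer(data.frame(length = c(5, 0),
                                                color = c(1, 2))),
               "invalid-model")
})

test_that("force field invariants are enforced", {
  expect_error(force_field(e_int = -1), "invalid-model")
  expect_error(force_field(r_cut_attr = 1.05), "invalid-model")
  expect_error(force_field(fene_r0 = 0.9), "invalid-model")
  ff <- force_field(e_int = c(3.1, 4.1))
  expect_equal(ff$fene_k, 30)
  expect_equal(ff$fene_r0, 1.5)
  expect_equal(ff$kT, 1)
})

test_that("concentration mapping matches Avogadro arithmetic and round-trips", {
  # 1 cubic micron of physical volume: edge * physical_sigma = 1000 nm
  box <- simulation_box(10, physical_sigma = 100)
  expect_equal(binder_count_from_concentration(0, box), 0L)
  # 54 nmol/l * N_A * 1e-15 l = 32.5 -> 33
  expect_equal(binder_count_from_concentration(54, box), 33L)

  for (c0 in c(5, 54, 500)) {
    cnt <- binder_count_from_concentration(c0, box)
    back <- concentration_from_binder_count(cnt, box)
    quantum <- concentration_from_binder_count(1, box)
    expect_lt(abs(back - c0), quantum)
  }
  expect_error(binder_count_from_concentration(54, simulation_box(10, NA)),
               "unit-mapping")
})

test_that("SAW initial configurations respect hard core and bond bounds", {
  box <- simulation_box(20)
  ch <- initialize_saw_configuration(build_homopolymer(100), box, seed = 1)
  pos <- ch$positions
  # bonds
  bl <- sqrt(rowSums((pos[-1, ] - pos[-100, ])^2))
  expect_true(all(bl > 0.8 & bl < 1.2))
  # minimum-image pair distances
  mi <- function(d) d - box$edge * round(d / box$edge)
  dmin <- Inf
  for (i in 1:99) {
    d2 <- mi(pos[(i + 1):100, 1] - pos[i, 1])^2 +
      mi(pos[(i + 1):100, 2] - pos[i, 2])^2 +
      mi(pos[(i + 1):100, 3] - pos[i, 3])^2
    dmin <- min(dmin, d2)
  }
  expect_gte(sqrt(dmin), 1 - 1e-9)

  # determinism and seed sensitivity
  ch2 <- initialize_saw_configuration(build_homopolymer(100), box, seed = 1)
  expect_identical(pos, ch2$positions)
  ch3 <- initialize_saw_configuration(build_homopolymer(100), box, seed = 2)
  expect_false(identical(pos, ch3$positions))

  two <- initialize_saw_configuration(build_homopolymer(2), box, seed = 5)
  expect_equal(sqrt(sum(diff(two$positions)^2)), 1, tolerance = 1e-9)
})

test_that("system assembly checks boxes, colours and binder counts", {
  expect_error(simulation_box(2), "invalid-model")
  ch <- build_block_copolymer(data.frame(length = c(10, 10), color = c(1, 2)))
  expect_error(sbs_system(ch, simulation_box(10), force_field(e_int = c(1, 2))),
               "counts or a concentration")
  expect_error(sbs_system(ch, simulation_box(10),
                          force_field(e_int = c(1)), binders = c(5, 5)),
               "fewer colours")
  sys <- sbs_system(ch, simulation_box(10), force_field(e_int = c(1, 2)),
                    binders = c(5, 3))
  expect_equal(sys$binder_colors, rep(c(1L, 2L), c(5, 3)))
  # default edge keeps the volume fraction at or under target
  edge <- default_box_edge(400, phi = 0.1)
  expect_lte(400 * pi / 6 / edge^3, 0.1)
})
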