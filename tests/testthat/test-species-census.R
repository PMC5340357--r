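test_that("the O-H cutoff boundary at 1.2 A is sharp", {
  mk <- function(d) xyz_frame(c("O", "H"), rbind(c(5, 5, 5), c(5 + d, 5, 5)),
                              c(12, 12, 12))
  expect_identical(nrow(neighbor_pairs(mk(1.19))), 1L)
  expect_identical(nrow(neighbor_pairs(mk(1.21))), 0L)
})

test_that("minimum image sees pairs across the periodic boundary", {
  fr <- xyz_frame(c("O", "H"), rbind(c(0.1, 5, 5), c(9.9, 5, 5)),
                  c(10, 10, 10))
  p <- neighbor_pairs(fr)
  expect_identical(nrow(p), 1L)
  expect_equal(p$dist, 0.2, tolerance = 1e-12)
})

test_that("cutoffs at or above half the box edge are rejected", {
  fr <- water_frame(box = c(2.2, 10, 10))
  expect_error(neighbor_pairs(fr), "half the smallest")
})

test_that("neighbor search equals the 27-image brute-force oracle", {
  set.seed(101)
  cuts <- cutoff_table("peroxide")
  for (rep in 1:30) {
    fr <- random_frame(n = 50)
    got <- neighbor_pairs(fr, cuts)
    want <- brute_pairs(fr, cuts)
    want <- want[order(want$i, want$j), ]
    expect_identical(got$i, want$i)
    expect_identical(got$j, want$j)
    expect_equal(got$dist, want$dist, tolerance = 1e-9)
  }
})

test_that("coordination numbers follow the taxonomy fixtures", {
  mono <- water_frame()
  Z <- coordination_table(mono)
  expect_identical(Z$nH[Z$symbol == "O"], 2L)
  expect_identical(Z$nO[Z$symbol == "H"], c(1L, 1L))

  hydronium <- xyz_frame(c("O", "H", "H", "H"),
                         rbind(c(5, 5, 5), c(5.98, 5, 5),
                               c(4.51, 5.85, 5), c(4.51, 4.15, 5)),
                         c(12, 12, 12))
  Zh <- coordination_table(hydronium)
  expect_identical(Zh$nH[Zh$symbol == "O"], 3L)
  expect_identical(classify_species(hydronium)$counts[["H3O_plus"]], 1L)

  h2 <- xyz_frame(c("H", "H"), rbind(c(5, 5, 5), c(5.74, 5, 5)),
                  c(12, 12, 12))
  Z2 <- coordination_table(h2)
  expect_identical(Z2$nH, c(1L, 1L))
  expect_identical(classify_species(h2)$counts[["H2"]], 1L)
})

test_that("species classification covers isolated atoms and pristine slabs", {
  slab <- build_slab(tiny_params(), snapshot_seed = 9)
  inv <- classify_species(slab)
  expect_identical(inv$counts[["H2O"]], 20L)
  expect_identical(sum(inv$counts[species_labels() != "H2O"]), 0L)

  lone <- xyz_frame(c("O", "H"), rbind(c(1, 1, 1), c(6, 6, 6)),
                    c(12, 12, 12))
  invl <- classify_species(lone)
  expect_identical(invl$counts[["O_isolated"]], 1L)
  expect_identical(invl$counts[["H_isolated"]], 1L)
})

test_that("every atom carries exactly one label (conservation)", {
  set.seed(7)
  for (rep in 1:5) {
    fr <- random_frame(n = 40, box = c(9, 9, 9))
    inv <- classify_species(fr)
    expect_length(inv$labels, 40L)
    expect_false(anyNA(inv$labels))
    # label-weighted atom counts: every atom appears once
    expect_identical(length(inv$labels), length(fr$symbols))
  }
})

test_that("molecular components get Hill formulas", {
  # peroxide: O-O 1.47 A, H on each O
  h2o2 <- xyz_frame(c("O", "O", "H", "H"),
                    rbind(c(5, 5, 5), c(6.47, 5, 5),
                          c(4.68, 5.9, 5), c(6.79, 4.1, 5)),
                    c(12, 12, 12))
  comp <- molecular_components(h2o2, cutoff_table("peroxide"))
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$formula, "H2O2")
  # with the standard preset the O-O bond is invisible
  comp2 <- molecular_components(h2o2, cutoff_table("standard"))
  expect_identical(sort(comp2$formula), c("HO", "HO"))

  ch <- xyz_frame(c("C", "H"), rbind(c(5, 5, 5), c(6.1, 5, 5)),
                  c(12, 12, 12))
  expect_identical(molecular_components(ch)$formula, "CH")

  slab <- build_slab(tiny_params(), snapshot_seed = 4)
  comps <- molecular_components(slab)
  expect_identical(nrow(comps), 20L)
  expect_true(all(comps$formula == "H2O"))
})

test_that("census along a static trajectory is constant and conserving", {
  slab <- build_slab(tiny_params(), snapshot_seed = 3)
  fr1 <- slab; fr1$projectile <- 1L
  fr2 <- fr1; fr2$time <- 1
  tr <- md_trajectory(list(fr1, fr2), slab_interval = c(0, 9.5))
  cs <- census_vs_projectile(tr)
  expect_identical(cs$H2O, c(20L, 20L))
  expect_identical(cs$cum_H_isolated, c(0L, 0L))
  labs <- attr(cs, "labels")
  expect_false(anyNA(labs))
})

test_that("census recovers ground-truth creations near the event site", {
  p <- tiny_params(p_single = 0, p_double = 1, encounter_spacing = 6,
                   continuous_loss_rate = 0)
  res <- generate_track(p, speed = 2, entry = c(5, 5), seed = 31)
  ev <- res$events[res$events$channel == "double_dissociation", ]
  expect_gte(nrow(ev), 1L)
  cs <- census_vs_projectile(res$trajectory)
  n <- nrow(cs)
  n_double <- nrow(ev)
  # cumulative creations match the ledger within one
  expect_lte(abs(cs$cum_O_isolated[n] - n_double), 1)
  expect_lte(abs(cs$cum_H_isolated[n] - 2 * n_double), 1)
  # the first isolated O appears within 2 A of the first event
  k0 <- which(cs$cum_O_isolated > 0)[1]
  expect_lte(abs(cs$projectile_x[k0] - ev$x[1]), 2)
  # atom conservation on every frame
  labs <- attr(cs, "labels")
  expect_true(all(rowSums(!is.na(labs)) == ncol(labs)))
})
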