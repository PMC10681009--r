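test_that("Moore neighbourhoods have the right size, content and order", {
  n2 <- neighbor_sites(c(0, 0))
  expect_equal(nrow(n2), 8)
  expect_false(any(n2[, 1] == 0 & n2[, 2] == 0))
  expect_true(all(pmax(abs(n2[, 1]), abs(n2[, 2])) == 1))
  expect_identical(n2, neighbor_sites(c(0, 0)))  # deterministic order

  n57 <- neighbor_sites(c(5, 7))
  expect_true(any(n57[, 1] == 4 & n57[, 2] == 6))
  expect_true(any(n57[, 1] == 6 & n57[, 2] == 8))

  expect_equal(nrow(neighbor_sites(c(0, 0, 0))), 26)
  expect_error(neighbor_sites(c(0, 0, 0, 0)), "dimension")
})

test_that("p = 1 gives exact doubling, and identical seeds replay bit-identically", {
  cfg <- sim_config(push_rate = 1, mutation_rate = 1, target_size = 2^10,
                    seed = 42)
  tum <- grow_tumour(cfg)
  expect_equal(tum$generations, 10)
  expect_equal(tum$n_alive, 1024)
  # every cell divides each generation: 2^g cells are born at generation g
  born <- tabulate(tum$cells$birth_generation, nbins = 10)
  expect_equal(born, 2^(1:10))
  expect_true(all(tum$cells$birth_generation[tum$cells$alive] == 10))
  # cell ids encode birth order
  expect_true(all(diff(tum$cells$birth_generation) >= 0))
  expect_identical(grow_tumour(cfg), tum)
})

test_that("occupancy is conserved: one cell per site, exact cell counts", {
  for (p in c(0, 0.5, 1)) {
    tum <- grown_fixture(paste0("p", p, "_1k"), push_rate = p,
                         mutation_rate = 1, target_size = 2^10,
                         seed = 7)
    cc <- tum$cells[tum$cells$alive, ]
    expect_equal(anyDuplicated(cc[, c("x", "y")]), 0)
    expect_equal(nrow(cc), tum$n_alive)
    # one net birth per division: cells ever = 2 * divisions + 1
    expect_equal(nrow(tum$cells), 2 * (tum$n_alive - 1) + 1)
  }
})

test_that("p = 0 is surface growth: no pushes, daughters adjacent to parents", {
  tum <- grown_fixture("p0_1k", push_rate = 0, mutation_rate = 1,
                       target_size = 2^10, seed = 7)
  # without pushing no cell ever moves, so every daughter must still lie
  # within one Moore step of its parent's recorded position
  cc <- tum$cells
  kids <- cc[cc$parent_id > 0L, ]
  par <- cc[kids$parent_id, ]
  cheb <- pmax(abs(kids$x - par$x), abs(kids$y - par$y))
  expect_true(all(cheb <= 1))
  expect_gte(tum$n_alive, 1024)
})

test_that("random-direction push shifts the ray and conserves occupants", {
  # [C1][C2][empty] along +x from the origin; +x is direction 7 in the
  # lexicographic Moore order
  coords <- rbind(c(0L, 0L), c(1L, 0L), c(2L, 0L))
  res <- spatialith:::.push_harness(coords, origin = 1L, algorithm = 0L,
                                    direction = 7L, pad = 3L)
  expect_equal(res$freed, c(1L, 0L))
  expect_equal(res$coords[1, ], c(0L, 0L))   # origin stays
  expect_equal(res$coords[2, ], c(2L, 0L))   # both ray cells shift by one
  expect_equal(res$coords[3, ], c(3L, 0L))

  # empty at distance 3: exactly 2 cells shifted, occupant count conserved
  coords <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 2L))
  res <- spatialith:::.push_harness(coords, origin = 1L, algorithm = 0L,
                                    direction = 5L, pad = 4L)  # +y
  expect_equal(res$coords[, 2], c(0L, 2L, 3L))
  expect_equal(nrow(unique(res$coords)), 3)
})

test_that("shortest-path push finds the nearest empty site and breaks ties uniformly", {
  # 3x3 block fully occupied: single blocker between centre and any
  # nearest empty site two steps away
  blk <- as.matrix(expand.grid(x = -1:1, y = -1:1))
  origin <- which(blk[, 1] == 0 & blk[, 2] == 0)
  res <- spatialith:::.push_harness(blk, origin = origin, algorithm = 1L,
                                    direction = 0L, pad = 4L)
  expect_equal(nrow(unique(res$coords)), 9)       # occupancy conserved
  expect_equal(max(abs(res$freed)), 1)            # freed site adjacent
  # exactly one cell moved, onto a site at Euclidean distance 2
  moved <- which(rowSums(res$coords != blk) > 0)
  expect_length(moved, 1)
  expect_equal(sqrt(sum(res$coords[moved, ]^2)), 2)

  # 3x5 block: exactly two equidistant nearest empties at (+-2, 0)
  blk2 <- as.matrix(expand.grid(x = -1:1, y = -2:2))
  origin2 <- which(blk2[, 1] == 0 & blk2[, 2] == 0)
  set.seed(99)
  side <- replicate(1500, {
    r <- spatialith:::.push_harness(blk2, origin2, 1L, 0L, 4L)
    moved <- which(rowSums(r$coords != blk2) > 0)
    sign(r$coords[moved, 1])
  })
  expect_true(all(side %in% c(-1, 1)))
  phat <- mean(side == 1)
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / 1500))
})

test_that("tumour radius: degenerate cases and area oracle for compact growth", {
  tum1 <- grow_tumour(sim_config(push_rate = 0, target_size = 1, seed = 1))
  expect_equal(tumour_radius(tum1), 0)
  expect_equal(tum1$generations, 0)

  tum2 <- grow_tumour(sim_config(push_rate = 0, target_size = 2, seed = 1))
  r2 <- tumour_radius(tum2)
  expect_gte(r2, 1)
  expect_lte(r2, sqrt(2))

  # compact surface-growth cluster: radius within 15% of the value a
  # filled disc of the same area would have (the cluster is slightly
  # squarer than a disc, so the ratio sits a little above 1)
  tum <- grown_fixture("p0_4k", push_rate = 0, mutation_rate = 1,
                       target_size = 2^12, seed = 11)
  expect_lt(abs(tumour_radius(tum) / sqrt(tum$n_alive / pi) - 1), 0.15)
})

test_that("mean generations to a fixed size is non-increasing in push rate", {
  gens <- sapply(c(0, 0.25, 1), function(p) {
    mean(sapply(1:5, function(s)
      grow_tumour(sim_config(push_rate = p, mutation_rate = 0,
                             target_size = 2^10,
                             seed = 1000 + s))$generations))
  })
  expect_true(all(diff(gens) <= 0))
})
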