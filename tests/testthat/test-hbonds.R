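# a water whose O sits at `o` with one H aimed along `dir`
aimed_water <- function(o, dir) {
  dir <- dir / sqrt(sum(dir^2))
  th <- 104.52 * pi / 180
  # second H in the plane spanned by dir and a perpendicular
  perp <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- perp - sum(perp * dir) * dir
  perp <- perp / sqrt(sum(perp^2))
  h2 <- cos(th) * dir + sin(th) * perp
  rbind(o, o + 0.9572 * dir, o + 0.9572 * h2)
}

# trajectory from explicit per-water coordinate blocks (3 rows per water)
waters_explicit <- function(blocks, box, solute = NULL) {
  n <- length(blocks)
  top <- cavsolv:::make_water_topology(n, solute)
  X <- do.call(rbind, blocks)
  X <- rbind(if (is.null(solute)) NULL else solute$coords, X)
  trajectory(top, X, box)
}

test_that("the distance and angle inequalities gate detection as printed", {
  box <- c(30, 30, 30)
  # donor water aimed straight at an acceptor water 2.8 A away: angle 0
  don <- aimed_water(c(10, 10, 10), c(1, 0, 0))
  acc <- aimed_water(c(12.8, 10, 10), c(0, 0, 1))
  tr <- waters_explicit(list(don, acc), box)
  hb <- detect_hbonds(tr)
  expect_true(any(hb$donor == 1 & hb$acceptor == 4))
  expect_equal(unique(hb$class), "water-water")

  # same distance but acceptor at 90 degrees from both O-H directions
  # (donor hydrogens lie in the xy-plane): no bond
  acc90 <- aimed_water(c(10, 10, 12.8), c(0, 1, 0))
  hb90 <- detect_hbonds(waters_explicit(list(don, acc90), box))
  expect_false(any(hb90$donor == 1 & hb90$acceptor == 4))

  # boundary cases are strict ("less than"): at/just past 3.6 A or 30 deg
  # no bond is recorded
  acc_far <- aimed_water(c(13.601, 10, 10), c(0, 0, 1))
  expect_false(any(detect_hbonds(waters_explicit(list(don, acc_far),
                                                 box))$donor == 1))
  ang <- 30 * pi / 180
  acc_ang <- aimed_water(c(10, 10, 10) + 2.8 * c(cos(ang), sin(ang), 0),
                         c(0, 0, 1))
  hb_ang <- detect_hbonds(waters_explicit(list(don, acc_ang), box))
  expect_false(any(hb_ang$donor == 1 & hb_ang$acceptor == 4))
  just_in <- aimed_water(c(10, 10, 10) + 2.8 * c(cos(ang * 0.99),
                                                 sin(ang * 0.99), 0),
                         c(0, 0, 1))
  hb_in <- detect_hbonds(waters_explicit(list(don, just_in), box))
  expect_true(any(hb_in$donor == 1 & hb_in$acceptor == 4))
})

test_that("random configurations match the all-triples brute-force oracle", {
  set.seed(17)
  box <- c(11, 11, 11)
  for (rep in 1:3) {
    cfg <- generator_config(50, box, 1, seed = 17 + rep, mode = "ideal_gas")
    tr <- gen_ideal_gas(cfg)
    for (conv in c("acceptor_donor_hydrogen", "donor_hydrogen_acceptor")) {
      hb <- detect_hbonds(tr, hbond_criteria(angle_convention = conv))
      got <- as.matrix(hb[order(hb$donor, hb$hydrogen, hb$acceptor),
                          c("donor", "hydrogen", "acceptor")])
      want <- oracle_hbonds(tr, 1, convention = conv)
      expect_equal(unname(got), unname(want), ignore_attr = TRUE)
    }
  }
})

test_that("solute-water bonds are classified and counted per group", {
  box <- c(20, 20, 20)
  # acceptor-only solute atom; donor water aimed at it
  sol <- point_solute(c(10, 10, 10), charge = -0.5, sigma = 2.96,
                      epsilon = 0.21, name = "OA1", element = "O")
  don <- aimed_water(c(12.8, 10, 10), c(-1, 0, 0))
  far <- aimed_water(c(3, 3, 3), c(1, 0, 0))
  tr <- waters_explicit(list(don, far), box, solute = sol)
  hb <- detect_hbonds(tr)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$class, "solute-water")

  g <- functional_group("LIG-OA1", atoms = 1, capability = "acceptor")
  gs <- group_stats(tr, list(g))
  expect_equal(gs$mean_water_hbonds[gs$label == "LIG-OA1"], 1)
  expect_equal(gs$mean_water_hbonds[gs$label == "total"], 1)
  # one neighbor within 3.6 (the bonded water), the far water is not
  expect_equal(gs$mean_water_neighbors[gs$label == "LIG-OA1"], 1)
  # totals row is the exact column sum
  expect_equal(gs$mean_water_neighbors[gs$label == "total"],
               sum(gs$mean_water_neighbors[gs$label != "total"]))
  # donor capability demands hydrogens
  expect_error(functional_group("bad", 1, capability = "donor"), "hydrogens")
})

test_that("neighbor counts match a brute-force double loop", {
  set.seed(23)
  box <- c(11, 11, 11)
  sol3 <- point_solute(c(5, 5, 5))
  sol3$topology <- dplyr::bind_rows(sol3$topology, sol3$topology, sol3$topology)
  sol3$topology$index <- 1:3
  sol3$topology$name <- c("C1", "C2", "C3")
  sol3$coords <- rbind(c(5, 5, 5), c(7, 5, 5), c(5, 7.5, 5))
  cfg <- generator_config(100, box, 2, seed = 29, mode = "ideal_gas")
  gas <- gen_ideal_gas(cfg)
  tr <- waters_explicit(split.data.frame(
    frame_coords(gas, 1)[, , drop = FALSE],
    rep(1:100, each = 3)), box, solute = sol3)
  got <- count_neighbors(tr, 1:3, cutoff = 3.6)$n_neighbors
  at <- frame_atoms(tr, 1)
  ox <- at[at$role == "solvent_oxygen", c("x", "y", "z")]
  want <- sum(apply(ox, 1, function(o) {
    any(vapply(1:3, function(i) {
      oracle_min_image(unlist(o), sol3$coords[i, ], box) <= 3.6
    }, logical(1)))
  }))
  expect_equal(got, want)
  # trivial cases
  one <- waters_explicit(list(aimed_water(c(7, 5, 5), c(1, 0, 0)),
                              aimed_water(c(9.2, 5, 5), c(1, 0, 0))),
                         box, solute = point_solute(c(5, 5, 5)))
  expect_equal(count_neighbors(one, 1, cutoff = 3.6)$n_neighbors, 1)
  expect_error(count_neighbors(one, integer(0)), "empty")
})

test_that("an H-bond partner is always a neighbor at matching cutoffs", {
  cfg <- generator_config(60, c(11, 11, 11), 3, seed = 41, mode = "ideal_gas")
  tr <- gen_ideal_gas(cfg)
  sol <- point_solute(c(5.5, 5.5, 5.5), charge = -0.5, sigma = 2.96,
                      epsilon = 0.21, name = "OA1", element = "O")
  tr2 <- waters_explicit(split.data.frame(frame_coords(tr, 1),
                                          rep(1:60, each = 3)),
                         c(11, 11, 11), solute = sol)
  g <- functional_group("acc", 1, capability = "acceptor")
  gs <- group_stats(tr2, list(g), neighbor_cutoff = 3.6)
  expect_lte(gs$mean_water_hbonds[1], gs$mean_water_neighbors[1])
})

test_that("water-water detection is invariant under rotation of the frame", {
  cfg <- generator_config(40, c(11, 11, 11), 1, seed = 53, mode = "ideal_gas")
  tr <- gen_ideal_gas(cfg)
  n0 <- nrow(detect_hbonds(tr))
  # rotate all coordinates about the box center (box is cubic)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ctr <- c(5.5, 5.5, 5.5)
  tr$coords[, , 1] <- sweep(sweep(tr$coords[, , 1], 2, ctr) %*% t(Rz), 2,
                            ctr, "+")
  expect_equal(nrow(detect_hbonds(tr)), n0)
})

test_that("conformer occupancy counts nearest-reference assignments", {
  box <- c(20, 20, 20)
  w <- aimed_water(c(5, 5, 5), c(1, 0, 0))
  tr4 <- waters_explicit(list(w), box)
  # four frames: probe (the oxygen) near A, A, A, then B
  coords <- array(NA_real_, c(3, 3, 4))
  for (f in 1:4) coords[, , f] <- w
  coords[1, , 4] <- c(11.8, 5, 5)
  tr4 <- trajectory(tr4$topology, coords, box)
  refs <- rbind(A = c(5.2, 5, 5), B = c(12, 5, 5))
  occ <- conformer_occupancy(tr4, 1, refs)
  expect_equal(occ$fraction, c(0.75, 0.25))
  expect_equal(sum(occ$fraction), 1, tolerance = 1e-12)
  # all frames at A
  occA <- conformer_occupancy(tr4, 1, refs, frames = 1:3)
  expect_equal(occA$fraction, c(1, 0))
  # rigid translation of coordinates and references together changes nothing
  tr5 <- tr4; tr5$coords <- tr5$coords + 2.5
  occ5 <- conformer_occupancy(tr5, 1, refs + 2.5)
  expect_equal(occ5$fraction, occ$fraction)
})
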