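test_that("all generators are seed-deterministic end to end", {
  cfg <- generator_config(20, 10, 4, seed = 5, mode = "ideal_gas")
  expect_identical(gen_ideal_gas(cfg)$coords, gen_ideal_gas(cfg)$coords)
  cfgl <- generator_config(27, 12, 3, seed = 5, mode = "lattice")
  expect_identical(gen_lattice(cfgl, 3.1)$coords, gen_lattice(cfgl, 3.1)$coords)
  cfgm <- generator_config(15, 10, 5, seed = 5, mode = "metropolis")
  m <- ideal_model(4.5)
  a <- gen_mc_water(cfgm, model = m, burnin_sweeps = 10, sweeps_per_frame = 1)
  b <- gen_mc_water(cfgm, model = m, burnin_sweeps = 10, sweeps_per_frame = 1)
  expect_identical(a$coords, b$coords)
  expect_identical(attr(a, "energy"), attr(b, "energy"))
})

test_that("ideal-gas sphere occupancy matches the binomial expectation", {
  box <- c(10, 10, 10)
  n_wat <- 50; n_frames <- 400
  cfg <- generator_config(n_wat, box, n_frames, seed = 31, mode = "ideal_gas")
  tr <- gen_ideal_gas(cfg)
  wi <- cavsolv:::water_index(tr$topology)
  centers <- rbind(c(3, 3, 3), c(7, 6, 5), c(5, 5, 5))
  p <- (4 / 3) * pi / prod(box)  # per-water probability of a 1 A sphere
  for (k in seq_len(nrow(centers))) {
    hits <- 0
    for (f in seq_len(n_frames)) {
      o <- tr$coords[wi$o_rows, , f]
      hits <- hits + sum(minimum_image_distance(o, centers[k, ], box) <= 1)
    }
    mean_occ <- hits / n_frames
    se <- sqrt(n_wat * p * (1 - p) / n_frames)
    expect_lt(abs(mean_occ - n_wat * p), 3 * se + 1e-9)
  }
  # zero-parameter model: every energy identically zero
  we <- water_energies(strip_interactions(tr), ideal_model(), frames = 1:5)
  expect_true(all(we$e_tot_ref == 0))
})

test_that("ideal-gas density is uniform by a chi-square test", {
  box <- c(10, 10, 10)
  cfg <- generator_config(60, box, 200, seed = 37, mode = "ideal_gas")
  tr <- gen_ideal_gas(cfg)
  wi <- cavsolv:::water_index(tr$topology)
  ox <- matrix(aperm(tr$coords[wi$o_rows, , ], c(1, 3, 2)), ncol = 3)
  cell <- pmin(floor(ox / 2.5), 3)  # 4^3 coarse histogram
  idx <- cell[, 1] + 4 * cell[, 2] + 16 * cell[, 3] + 1
  counts <- tabulate(idx, 64)
  chi <- chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
})

test_that("lattice fixtures are static with symmetric interior energies", {
  cfg <- generator_config(27, 12.4, 3, seed = 1, mode = "lattice")
  tr <- gen_lattice(cfg, 3.1)
  # identical frames: zero variance in every coordinate
  expect_equal(tr$coords[, , 1], tr$coords[, , 3])
  m <- interaction_model(cutoff = 6, e_neat = 0, rho0 = 0.0334)
  we <- water_energies(tr, m, frames = 1)
  # 27 waters at 3.1 A spacing fill the 12.4 A box periodically (4 cells per
  # axis would be 12.4): every site is lattice-equivalent once wrapped; with
  # 3 cells occupied of 4, corner/edge classes emerge - instead check the
  # strict per-frame invariance and g support
  g <- gist_finalize(gist_accumulate(tr, m, grid_spec_for_box(c(12.4, 12.4,
                                                                12.4), 0.5),
                                     criteria = NULL), m)
  occupied <- which(as.vector(g$n_wat) > 0)
  expect_length(occupied, 27)  # one voxel per lattice site
  expect_true(all(as.vector(g$g)[occupied] > 0))
  expect_true(all(as.vector(g$g)[-occupied] == 0))
  # full-lattice case: all interior-equivalent sites share one e_ww value
  cfg64 <- generator_config(64, 12.4, 1, seed = 1, mode = "lattice")
  tr64 <- gen_lattice(cfg64, 3.1)
  we64 <- water_energies(tr64, m)
  expect_lt(diff(range(we64$e_ww)), 1e-9)
})

test_that("saved Metropolis frames re-evaluate to the sampler's energies", {
  m <- interaction_model(cutoff = 4.5, e_neat = 0, rho0 = 0.0334)
  sol <- point_solute(c(5, 5, 5), charge = -0.3, sigma = 3.2, epsilon = 0.12)
  cfg <- generator_config(18, 10, 6, seed = 11, mode = "metropolis")
  tr <- gen_mc_water(cfg, solute = sol, model = m, burnin_sweeps = 25,
                     sweeps_per_frame = 1)
  for (f in seq_len(n_frames(tr))) {
    expect_equal(frame_total_energy(tr, m, f), attr(tr, "energy")[f],
                 tolerance = 1e-10)
  }
})

test_that("the infinite-temperature limit flattens the radial profile", {
  box <- c(11, 11, 11)
  m <- interaction_model(cutoff = 4.5, e_neat = 0, rho0 = 0.0334)
  sol <- point_solute(c(5.5, 5.5, 5.5), charge = -0.8, sigma = 3.2,
                      epsilon = 0.15, name = "OS1", element = "O")
  shell_frac <- function(tr) {
    wi <- cavsolv:::water_index(tr$topology)
    vapply(seq_len(n_frames(tr)), function(f) {
      mean(minimum_image_distance(tr$coords[wi$o_rows, , f],
                                  c(5.5, 5.5, 5.5), box) < 3.6)
    }, numeric(1))
  }
  # at infinite temperature every proposal is accepted, so large steps give
  # essentially independent uniform configurations
  cfg_hot <- generator_config(40, box, 80, temperature = Inf, seed = 3,
                              mode = "metropolis")
  hot <- shell_frac(gen_mc_water(cfg_hot, sol, m, burnin_sweeps = 60,
                                 sweeps_per_frame = 3, trans_step = 3))
  gas <- shell_frac(gen_ideal_gas(generator_config(40, box, 80, seed = 3,
                                                   mode = "ideal_gas")))
  cfg_cold <- generator_config(40, box, 80, temperature = 200, seed = 3,
                               mode = "metropolis")
  cold <- shell_frac(gen_mc_water(cfg_cold, sol, m, burnin_sweeps = 60,
                                  sweeps_per_frame = 3))
  se <- sqrt(glance(block_average(hot, 4))$sem^2 +
               glance(block_average(gas, 4))$sem^2)
  # hot matches the ideal gas within 3 SE; the cold run deviates more
  expect_lt(abs(mean(hot) - mean(gas)), 3 * se + 1e-9)
  expect_gt(abs(mean(cold) - mean(gas)), abs(mean(hot) - mean(gas)))
})

test_that("the mean energy is stable over the second half of a run", {
  # supercritical temperature avoids the slow vapor-droplet condensation of
  # small ambient systems, and widely spaced frames decorrelate the blocks
  m <- interaction_model(cutoff = 4.5, e_neat = 0, rho0 = 0.0334)
  cfg <- generator_config(25, 10, 320, temperature = 500, seed = 23,
                          mode = "metropolis")
  tr <- gen_mc_water(cfg, model = m, burnin_sweeps = 1000,
                     sweeps_per_frame = 15)
  u <- attr(tr, "energy")
  h1 <- u[1:160]; h2 <- u[161:320]
  # correlation-aware block SEMs on each half
  se <- sqrt(glance(block_average(h1, 8))$sem^2 +
               glance(block_average(h2, 8))$sem^2)
  expect_lt(abs(mean(h1) - mean(h2)), 3 * se)
})

test_that("the enclosed bidentate pocket admits only one bridging water", {
  sol <- build_bidentate_pocket(2.3, "enclosed")
  # geometric scan: feasible oxygen positions in hydrogen-bond range of the
  # acceptors never admit two oxygens at water-water contact or more apart
  scan <- pocket_throat_scan(sol)
  expect_gt(nrow(scan$feasible), 0)      # one water does fit
  expect_lt(scan$max_separation, 2.4)    # two cannot
  # solvated run: no frame has two distinct waters in the throat
  box <- c(16, 16, 16)
  solc <- build_bidentate_pocket(2.3, "enclosed", center = c(8, 8, 6))
  m <- synthetic_model(); m$cutoff <- 7.5
  cfg <- generator_config(90, box, 60, seed = 41, mode = "metropolis")
  tr <- gen_mc_water(cfg, solc, m, burnin_sweeps = 80, sweeps_per_frame = 1)
  wi <- cavsolv:::water_index(tr$topology)
  accs <- solc$coords[solc$acceptor_atoms, ]
  worst <- 0
  for (f in seq_len(n_frames(tr))) {
    o <- tr$coords[wi$o_rows, , f]
    near <- minimum_image_distance(o, accs[1, ], box) <= 3.6 |
      minimum_image_distance(o, accs[2, ], box) <= 3.6
    worst <- max(worst, sum(near))
  }
  expect_lte(worst, 1)
  # a single water can donate to at most both acceptors (2 bonds)
  hb <- detect_hbonds(tr)
  sw <- hb[hb$class == "solute-water", ]
  if (nrow(sw) > 0) {
    per <- table(paste(sw$frame, sw$donor))
    expect_lte(max(per), 2)
  }
  # the solute is rigid: identical coordinates in every frame
  srows <- wi$solute_rows
  expect_equal(tr$coords[srows, , 1], tr$coords[srows, , n_frames(tr)])
})

test_that("a widely spaced open pocket develops two acceptor-bound sites", {
  box <- c(16, 16, 16)
  sol <- build_bidentate_pocket(6, "open", center = c(8, 8, 7))
  m <- synthetic_model(); m$cutoff <- 7.5
  cfg <- generator_config(90, box, 150, seed = 43, mode = "metropolis")
  tr <- gen_mc_water(cfg, sol, m, burnin_sweeps = 120, sweeps_per_frame = 2)
  accs <- sol$coords[sol$acceptor_atoms, ]
  region <- list(min = c(8 - 5.5, 8 - 2.5, 7 - 0.5), max = c(8 + 5.5, 8 + 2.5, 7 + 3.5))
  s <- site_thermo(find_sites(tr, m, region, min_occupancy_ratio = 2),
                   tr, m)
  expect_gte(nrow(s$sites), 2)
  # at least one site hydrogen-bonds each acceptor
  near_each <- vapply(1:2, function(k) {
    any(sqrt((s$sites$x - accs[k, 1])^2 + (s$sites$y - accs[k, 2])^2 +
               (s$sites$z - accs[k, 3])^2) <= 3.6)
  }, logical(1))
  expect_true(all(near_each))
})

test_that("a symmetric two-state group is occupied half the time", {
  box <- c(10, 10, 10)
  # a group with no interactions at all: the two states are exactly degenerate
  sol <- point_solute(c(5, 5, 3), charge = 0, sigma = 0, epsilon = 0)
  m <- interaction_model(cutoff = 4.5, e_neat = 0, rho0 = 0.0334)
  cfg <- generator_config(15, box, 400, seed = 47, mode = "metropolis")
  tr <- gen_mc_water(cfg, sol, m, burnin_sweeps = 30, sweeps_per_frame = 1,
                     flexible_group = 1, alternate_position = matrix(c(5, 5, 7), 1))
  st <- attr(tr, "state")
  # states decorrelate every sweep (swap acceptance 1), so a binomial SE
  expect_lt(abs(mean(st) - 0.5), 3 * sqrt(0.25 / length(st)))
  # rigid runs stay at the cognate position
  trr <- gen_mc_water(generator_config(15, box, 10, seed = 47,
                                       mode = "metropolis"),
                      sol, m, burnin_sweeps = 10, sweeps_per_frame = 1)
  occ <- conformer_occupancy(trr, 1, rbind(cognate = c(5, 5, 3),
                                           alternate = c(5, 5, 7)))
  expect_equal(occ$fraction, c(1, 0))
})

test_that("alternate overlap with the static solute is rejected", {
  sol <- build_bidentate_pocket(2.3, "enclosed", center = c(8, 8, 8))
  cfg <- generator_config(30, 16, 5, seed = 3, mode = "metropolis")
  m <- synthetic_model(); m$cutoff <- 7.5
  bad_alt <- sol$coords[5, , drop = FALSE] + 0.1  # on top of a cage atom
  expect_error(gen_mc_water(cfg, sol, m, flexible_group = 1,
                            alternate_position = bad_alt, burnin_sweeps = 5,
                            sweeps_per_frame = 1), "overlap")
})
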