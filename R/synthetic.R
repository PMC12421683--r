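# ---------------------------------------------------------------------------
# synthetic water/solute ensembles with known statistical structure
# ---------------------------------------------------------------------------

# rigid 3-site water template (TIP3P-like geometry and parameters):
# O-H 0.9572 A, H-O-H 104.52 deg; qO -0.834 e, qH +0.417 e;
# LJ on oxygen only (sigma 3.15061 A, epsilon 0.1521 kcal/mol)
water_template <- function() {
  th <- 104.52 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(0.9572, 0, 0),
        H2 = c(0.9572 * cos(th), 0.9572 * sin(th), 0))
}

water_param_rows <- function() {
  tibble(residue_name = "WAT", atom_name = c("O", "H1", "H2"),
         charge = c(-0.834, 0.417, 0.417),
         sigma = c(3.15061, 0, 0), epsilon = c(0.1521, 0, 0),
         role = c("solvent_oxygen", "solvent_hydrogen", "solvent_hydrogen"))
}

#' Interaction model of the packaged synthetic water
#'
#' Constants of the rigid 3-site synthetic solvent: 9 A cutoff (compatible
#' with the neat calibration box), neat reference energy measured once from a
#' long neat Metropolis run of 216 waters at 298 K and frozen here, and the
#' ambient water number density 0.0334 molecules/A^3 set by construction of
#' the neat box.
#'
#' @param ww_split Water-water energy split (see [interaction_model()]).
#' @return A `cav_model`.
#' @export
synthetic_model <- function(ww_split = 0.5) {
  interaction_model(cutoff = 9, e_neat = E_NEAT_SYNTHETIC, rho0 = 0.0334,
                    ww_split = ww_split)
}

# measured by scripts/calibrate_neat.R (seed 42); see the methods vignette
E_NEAT_SYNTHETIC <- -9.702

#' Generator configuration
#'
#' @param n_waters Number of water molecules.
#' @param box Orthorhombic box lengths, Angstrom (scalar recycled).
#' @param n_frames Number of frames to generate (>= 1).
#' @param temperature Temperature, K (`Inf` gives the ideal-gas limit in the
#'   Metropolis generator).
#' @param seed RNG seed; a fixed seed makes every generator bit-reproducible.
#' @param mode `"ideal_gas"`, `"lattice"` or `"metropolis"`.
#' @return A `cav_genconfig` list.
#' @export
generator_config <- function(n_waters, box, n_frames, temperature = 298,
                             seed = 1, mode = c("ideal_gas", "lattice",
                                                "metropolis")) {
  mode <- match.arg(mode)
  if (n_frames < 1) abort("n_frames must be >= 1")
  structure(list(n_waters = as.integer(n_waters),
                 box = rep(as.numeric(box), length.out = 3),
                 n_frames = as.integer(n_frames),
                 temperature = temperature, seed = as.integer(seed),
                 mode = mode), class = "cav_genconfig")
}

# uniform random rotation via normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# topology for n waters, optionally preceded by a rigid solute
make_water_topology <- function(n_waters, solute = NULL) {
  wt <- water_param_rows()
  sol <- if (!is.null(solute)) solute$topology
  ns <- if (is.null(sol)) 0L else nrow(sol)
  wat <- tibble(
    index = ns + seq_len(3 * n_waters),
    name = rep(wt$atom_name, n_waters),
    residue_name = "WAT",
    residue_id = (if (is.null(sol)) 0L else max(sol$residue_id)) +
      rep(seq_len(n_waters), each = 3),
    element = rep(c("O", "H", "H"), n_waters),
    charge = rep(wt$charge, n_waters),
    lj_sigma = rep(wt$sigma, n_waters),
    lj_epsilon = rep(wt$epsilon, n_waters),
    molecule_id = (if (is.null(sol)) 0L else max(sol$molecule_id)) +
      rep(seq_len(n_waters), each = 3),
    role = rep(wt$role, n_waters)
  )
  if (is.null(sol)) wat else dplyr::bind_rows(sol, wat)
}

# place water template at positions (n x 3) with given rotations (list or NULL)
assemble_waters <- function(positions, rotations = NULL) {
  tmpl <- water_template()
  n <- nrow(positions)
  out <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    R <- if (is.null(rotations)) diag(3) else rotations[[i]]
    out[(3 * i - 2):(3 * i), ] <- tmpl %*% t(R) +
      matrix(positions[i, ], 3, 3, byrow = TRUE)
  }
  out
}

#' Ideal-gas water frames
#'
#' Each frame places the waters uniformly at random in the box with uniform
#' random orientations; no interactions are implied (pair with a
#' zero-parameter model for null tests). An optional hard-sphere exclusion
#' rejects oxygen positions within `exclude_radius` of `exclude_center`.
#'
#' @param config A [generator_config()] with `mode = "ideal_gas"`.
#' @param exclude_center Optional length-3 center of a hard-sphere solute.
#' @param exclude_radius Exclusion radius, Angstrom.
#' @return A `cav_trajectory`.
#' @export
gen_ideal_gas <- function(config, exclude_center = NULL, exclude_radius = 0) {
  stopifnot(config$mode == "ideal_gas")
  set.seed(config$seed)
  top <- make_water_topology(config$n_waters)
  coords <- array(NA_real_, c(3 * config$n_waters, 3, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    pos <- matrix(NA_real_, config$n_waters, 3)
    n <- 0L
    while (n < config$n_waters) {
      p <- runif(3) * config$box
      if (!is.null(exclude_center) &&
          minimum_image_distance(p, exclude_center, config$box) < exclude_radius) next
      n <- n + 1L
      pos[n, ] <- p
    }
    rots <- replicate(config$n_waters, random_rotation(), simplify = FALSE)
    coords[, , f] <- assemble_waters(pos, rots)
  }
  trajectory(top, coords, config$box)
}

#' Lattice water frames
#'
#' Waters on a cubic lattice with a fixed orientation, identical in every
#' frame: a fully deterministic fixture.
#'
#' @param config A [generator_config()] with `mode = "lattice"`.
#' @param spacing Lattice constant, Angstrom.
#' @return A `cav_trajectory`.
#' @export
gen_lattice <- function(config, spacing) {
  stopifnot(config$mode == "lattice")
  if (spacing < 2.5) abort("lattice spacing too small for the water molecule")
  m <- ceiling(config$n_waters^(1 / 3))
  if (m * spacing > min(config$box)) abort("lattice does not fit in the box")
  pts <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m)))
  pos <- (pts[seq_len(config$n_waters), , drop = FALSE] - 0.5) * spacing
  frame <- assemble_waters(pos)
  coords <- array(rep(frame, config$n_frames),
                  c(3 * config$n_waters, 3, config$n_frames))
  trajectory(make_water_topology(config$n_waters), coords, config$box)
}

# lattice candidate points clear of the solute, for MC initialization
initial_positions <- function(config, solute_coords = NULL, clearance = 2.6,
                              exclude_spheres = NULL) {
  m <- ceiling((2 * config$n_waters)^(1 / 3))
  sp <- min(config$box) / m
  if (sp < 2.45) {
    m <- floor(min(config$box) / 2.45)
    sp <- min(config$box) / m
  }
  pts <- (as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m))) - 0.5) * sp
  if (!is.null(solute_coords) && nrow(solute_coords) > 0) {
    ok <- apply(pts, 1, function(p) {
      all(minimum_image_distance(solute_coords, p, config$box) >= clearance)
    })
    pts <- pts[ok, , drop = FALSE]
  }
  if (!is.null(exclude_spheres)) {
    for (i in seq_len(nrow(exclude_spheres))) {
      ok <- apply(pts, 1, function(p) {
        minimum_image_distance(exclude_spheres[i, 1:3], p, config$box) >=
          exclude_spheres[i, 4]
      })
      pts <- pts[ok, , drop = FALSE]
    }
  }
  if (nrow(pts) < config$n_waters) {
    abort("box too small to place the requested number of waters")
  }
  pts[sample.int(nrow(pts), config$n_waters), , drop = FALSE]
}

#' Metropolis Monte Carlo water ensembles
#'
#' Rigid-water translations and rotations (solute fixed) sampled with the
#' Metropolis criterion at `config$temperature`, using exactly the analysis
#' energy function (molecule-based water-water cutoff, per-atom-pair
#' solute-water cutoff). Frames are saved every `sweeps_per_frame` sweeps
#' after `burnin_sweeps` equilibration sweeps. When `flexible_group` is
#' given, an additional Metropolis move swaps those solute atoms between
#' their cognate coordinates and `alternate_position`, so state occupancies
#' reflect the energy difference.
#'
#' @param config A [generator_config()] with `mode = "metropolis"`.
#' @param solute Optional `cav_solute` (see [build_bidentate_pocket()]).
#' @param model A [interaction_model()]; defaults to [synthetic_model()].
#' @param burnin_sweeps Equilibration sweeps discarded before saving.
#' @param sweeps_per_frame Sweeps between saved frames.
#' @param trans_step Maximum translation per move, Angstrom.
#' @param rot_step Maximum rotation per move, degrees.
#' @param flexible_group Integer solute atom indices of the two-state group.
#' @param alternate_position Matrix of alternate coordinates for the group.
#' @param swap_attempts Group-swap attempts per sweep.
#' @param exclude_spheres Optional matrix with rows (x, y, z, radius): regions
#'   kept free of waters at initialization (e.g. sealed solute interiors that
#'   the equilibrium dynamics could never populate or vacate).
#' @return A `cav_trajectory` with attributes `acceptance`,
#'   `swap_acceptance`, `state` (0 cognate / 1 alternate per saved frame) and
#'   `energy` (total energy per saved frame, kcal/mol).
#' @export
gen_mc_water <- function(config, solute = NULL, model = synthetic_model(),
                         burnin_sweeps = 200, sweeps_per_frame = 2,
                         trans_step = 0.18, rot_step = 20,
                         flexible_group = integer(0),
                         alternate_position = NULL, swap_attempts = 1,
                         exclude_spheres = NULL) {
  stopifnot(config$mode == "metropolis")
  if (model$cutoff > min(config$box) / 2) {
    abort("cutoff exceeds half the box length; shrink the cutoff or grow the box")
  }
  set.seed(config$seed)
  top <- make_water_topology(config$n_waters, solute)
  solute_coords <- if (!is.null(solute)) solute$coords
  pos <- initial_positions(config, solute_coords, exclude_spheres = exclude_spheres)
  rots <- replicate(config$n_waters, random_rotation(), simplify = FALSE)
  X0 <- rbind(if (is.null(solute_coords)) NULL else solute_coords,
              assemble_waters(pos, rots))
  wi <- water_index(top)
  if (length(flexible_group) > 0) {
    stopifnot(!is.null(alternate_position),
              nrow(alternate_position) == length(flexible_group))
    static_rows <- setdiff(wi$solute_rows, flexible_group)
    if (length(static_rows) > 0) {
      dmin <- min(apply(alternate_position, 1, function(p) {
        minimum_image_distance(X0[static_rows, , drop = FALSE], p, config$box)
      }))
      if (dmin < 0.8) abort("alternate position overlaps the static solute")
    }
  }
  res <- cpp_mc_run(X0, top$charge, top$lj_sigma, top$lj_epsilon,
                    wi$watoms, wi$o_rows, wi$solute_rows, config$box,
                    model$cutoff, model$coulomb_constant, config$temperature,
                    burnin_sweeps, config$n_frames, sweeps_per_frame,
                    trans_step, rot_step,
                    as.integer(flexible_group),
                    if (is.null(alternate_position)) matrix(0, 0, 3) else
                      as.matrix(alternate_position),
                    swap_attempts)
  if (!is.na(res$acceptance) && res$acceptance == 0) {
    abort("no Monte Carlo move was accepted; adjust trans_step / rot_step")
  }
  tr <- trajectory(top, res$coords, config$box)
  attr(tr, "acceptance") <- res$acceptance
  attr(tr, "swap_acceptance") <- res$swap_acceptance
  attr(tr, "state") <- res$state
  attr(tr, "energy") <- res$energy
  tr
}

# standard cage atom parameters (apolar carbon-like LJ sphere)
cage_atom <- function(name, xyz, charge = 0, sigma = 3.4, epsilon = 0.086,
                      element = "C") {
  tibble(name = name, x = xyz[1], y = xyz[2], z = xyz[3], charge = charge,
         sigma = sigma, epsilon = epsilon, element = element)
}

ring_atoms <- function(prefix, n, radius, z, ...) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    cage_atom(paste0(prefix, i), c(radius * cos(ang[i]), radius * sin(ang[i]), z),
              ...)
  }))
}

solute_from_atoms <- function(atoms, acceptor_names, enclosure,
                              separation = NA) {
  topology <- tibble(
    index = seq_len(nrow(atoms)), name = atoms$name, residue_name = "LIG",
    residue_id = 1L, element = atoms$element, charge = atoms$charge,
    lj_sigma = atoms$sigma, lj_epsilon = atoms$epsilon, molecule_id = 1L,
    role = "solute")
  structure(list(topology = topology,
                 coords = as.matrix(atoms[, c("x", "y", "z")]),
                 acceptor_atoms = match(acceptor_names, atoms$name),
                 enclosure = enclosure, acceptor_separation = separation),
            class = "cav_solute")
}

#' @export
print.cav_solute <- function(x, ...) {
  cat(sprintf("<cav_solute> %d atoms, %s, acceptor separation %.2f A\n",
              nrow(x$topology), x$enclosure, x$acceptor_separation))
  invisible(x)
}

#' Rigid bidentate pocket solute
#'
#' A rigid cage of apolar Lennard-Jones spheres presenting two closely
#' spaced acceptor oxygens (a carboxylate-like pair) at the bottom of a
#' pocket. The `enclosed` variant wraps the acceptors in a narrow vertical
#' shaft (inner free radius about 1.3 A) so water reaches them single file
#' from above and at most one water oxygen fits in hydrogen-bond range at a
#' time; the `open` variant exposes the acceptors on a flat shelf so each
#' can be solvated independently. Each acceptor carries -0.60 e, compensated
#' by buried +0.60 e carriers, so the solute is neutral.
#'
#' Coordinates are centered so the acceptor midpoint sits at `center`.
#'
#' @param separation Acceptor-acceptor distance, Angstrom (2.3 for the
#'   carboxylate-like pocket; use ~6 with `open` for independent sites).
#' @param enclosure `"enclosed"` or `"open"`.
#' @param center Position of the acceptor midpoint in the box.
#' @return A `cav_solute` with `acceptor_atoms` recording the acceptor rows.
#' @export
build_bidentate_pocket <- function(separation = 2.3,
                                   enclosure = c("enclosed", "open"),
                                   center = c(0, 0, 0)) {
  enclosure <- match.arg(enclosure)
  if (separation <= 0) abort("separation must be > 0")
  s2 <- separation / 2
  acc <- dplyr::bind_rows(
    cage_atom("OA1", c(-s2, 0, 0), charge = -0.60, sigma = 2.96,
              epsilon = 0.21, element = "O"),
    cage_atom("OA2", c(s2, 0, 0), charge = -0.60, sigma = 2.96,
              epsilon = 0.21, element = "O"),
    cage_atom("CP1", c(-s2, 0, -1.3), charge = 0.60, sigma = 2.0,
              epsilon = 0.05),
    cage_atom("CP2", c(s2, 0, -1.3), charge = 0.60, sigma = 2.0,
              epsilon = 0.05))
  if (enclosure == "enclosed") {
    cage <- dplyr::bind_rows(
      ring_atoms("CW", 8, 3.95, 1.0),
      ring_atoms("CX", 8, 3.95, 2.6),
      ring_atoms("CY", 8, 3.95, 4.2),
      ring_atoms("CF", 8, 3.0, -1.0),
      ring_atoms("CG", 6, 1.6, -2.2),
      cage_atom("CZ", c(0, 0, -2.6)))
  } else {
    cage <- dplyr::bind_rows(
      ring_atoms("CF", 10, max(4.5, s2 + 2.2), -1.4),
      ring_atoms("CG", 6, 2.2, -1.8),
      cage_atom("CZ", c(0, 0, -2.0)))
  }
  atoms <- dplyr::bind_rows(acc, cage)
  atoms$x <- atoms$x + center[1]
  atoms$y <- atoms$y + center[2]
  atoms$z <- atoms$z + center[3]
  solute_from_atoms(atoms, c("OA1", "OA2"), enclosure, separation)
}

#' Geometric scan of the pocket throat
#'
#' Scans a fine grid for positions where a water oxygen fits (no overlap
#' with the solute core, approach limited to `approach` times the combined
#' Lennard-Jones sigma) while lying within `hb_range` of at least one
#' acceptor, and reports the maximum pairwise distance among feasible
#' positions. If that maximum is below 2.4 A, two waters cannot
#' simultaneously occupy the throat.
#'
#' @param solute A `cav_solute` from [build_bidentate_pocket()].
#' @param hb_range Heavy-atom hydrogen-bond range, Angstrom.
#' @param approach Minimum approach as a fraction of the combined sigma.
#' @param resolution Scan grid resolution, Angstrom.
#' @return List: `feasible` (matrix of positions), `max_separation`.
#' @export
pocket_throat_scan <- function(solute, hb_range = 3.6, approach = 0.90,
                               resolution = 0.25) {
  accs <- solute$coords[solute$acceptor_atoms, , drop = FALSE]
  mid <- colMeans(accs)
  rng <- hb_range + 0.5
  gx <- seq(mid[1] - rng, mid[1] + rng, by = resolution)
  gy <- seq(mid[2] - rng, mid[2] + rng, by = resolution)
  gz <- seq(mid[3] - rng, mid[3] + rng, by = resolution)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sig_w <- 3.15061
  min_app <- approach * 0.5 * (solute$topology$lj_sigma + sig_w)
  min_app[solute$topology$lj_sigma == 0] <- 1.5
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(solute$coords))) {
    d <- sqrt(colSums((t(pts) - solute$coords[i, ])^2))
    keep <- keep & d >= min_app[i]
  }
  near_acc <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(accs))) {
    d <- sqrt(colSums((t(pts) - accs[i, ])^2))
    near_acc <- near_acc | d <= hb_range
  }
  feas <- pts[keep & near_acc, , drop = FALSE]
  maxsep <- if (nrow(feas) < 2) 0 else {
    md <- 0
    for (i in seq_len(nrow(feas) - 1)) {
      d <- sqrt(colSums((t(feas[(i + 1):nrow(feas), , drop = FALSE]) -
                           feas[i, ])^2))
      md <- max(md, max(d))
    }
    md
  }
  list(feasible = feas, max_separation = maxsep)
}

#' Matched rigid and flexible ensembles of one solute
#'
#' Runs the Metropolis generator twice on the same solvated solute: the
#' rigid trajectory holds `flexible_group` at its cognate coordinates; the
#' flexible trajectory lets the group hop between the cognate and
#' `alternate_position` with Metropolis acceptance, so state occupancies
#' reflect the energy difference. Both runs are solvated identically
#' otherwise (same water count, box and temperature; seeds derived from
#' `config$seed`).
#'
#' @param solute A `cav_solute`.
#' @param flexible_group Integer solute atom indices of the two-state group.
#' @param alternate_position Matrix of alternate coordinates (one row per
#'   group atom).
#' @param config A [generator_config()] with `mode = "metropolis"`.
#' @param model A [interaction_model()].
#' @param ... Passed to [gen_mc_water()] (burn-in, step sizes, ...).
#' @return List with `rigid` and `flexible` trajectories; the flexible one
#'   carries the `state` attribute (0 cognate / 1 alternate per frame).
#' @export
make_rigid_flexible_pair <- function(solute, flexible_group,
                                     alternate_position, config,
                                     model = synthetic_model(), ...) {
  cfg_r <- config; cfg_r$seed <- config$seed
  cfg_f <- config; cfg_f$seed <- config$seed + 1L
  rigid <- gen_mc_water(cfg_r, solute, model, ...)
  flexible <- gen_mc_water(cfg_f, solute, model,
                           flexible_group = flexible_group,
                           alternate_position = alternate_position, ...)
  list(rigid = rigid, flexible = flexible)
}

#' Demonstration two-state system: buried vs window-exposed acceptor
#'
#' A compact solute for rigid-vs-flexible comparisons: a near-spherical
#' shell of apolar carbons (radius 4 A) whose top pole is a "grate" of
#' small, soft atoms that water cannot pass but can hydrogen-bond through.
#' A single acceptor oxygen (-1 e) sits on the shell axis: in the cognate
#' state it is held deep in the interior (4 A or more from any water, out of
#' hydrogen-bond range) against a small strain atom; in the alternate state
#' it sits just beneath the grate, where the nearest allowed water position
#' is about 2.9 A away and waters donate hydrogen bonds through the window.
#' Both sites are permanently water-inaccessible, so the two-state swap
#' move never collides with solvent; the mild cognate-site strain makes the
#' initial barrier crossing downhill, and the hydration of the exposed
#' state (hydrogen bonds worth far more than the strain) then locks the
#' flexible ensemble in the exposed state, while the rigid run keeps the
#' acceptor buried.
#'
#' @param center Shell center position in the box.
#' @return List: `solute` (`cav_solute`), `flexible_group`,
#'   `alternate_position`, `ligand_ref` (pseudo-ligand tibble over the
#'   window solvation shell, for subvolume definitions), and
#'   `exclude_spheres` (keep the sealed interior water-free at
#'   initialization; pass to [gen_mc_water()]).
#' @export
demo_two_state_system <- function(center = c(0, 0, 0)) {
  n <- 32; r <- 4.0
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta),
               r * cos(phi))
  window <- pts[, 3] > r * cos(40 * pi / 180)
  shell <- dplyr::bind_rows(lapply(which(!window), function(i) {
    cage_atom(paste0("CC", i), pts[i, ])
  }))
  grate <- dplyr::bind_rows(lapply(which(window), function(i) {
    cage_atom(paste0("GR", i), pts[i, ], sigma = 1.8, epsilon = 0.05)
  }))
  atoms <- dplyr::bind_rows(
    cage_atom("OA1", c(0, 0, 1.0), charge = -1.0, sigma = 2.96,
              epsilon = 0.21, element = "O"),
    cage_atom("GB1", c(0, 0, -0.82), sigma = 1.8, epsilon = 0.05),
    shell, grate)
  atoms$x <- atoms$x + center[1]
  atoms$y <- atoms$y + center[2]
  atoms$z <- atoms$z + center[3]
  solute <- solute_from_atoms(atoms, "OA1", "open", NA)
  list(solute = solute, flexible_group = 1L,
       alternate_position = matrix(center + c(0, 0, 2.2), 1, 3),
       ligand_ref = tibble(atom_name = "L1", x = center[1], y = center[2],
                           z = center[3] + 2.8),
       exclude_spheres = matrix(c(center, 5.0), 1))
}
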