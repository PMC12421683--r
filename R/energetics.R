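#' Nonbonded interaction model
#'
#' Point-charge Coulomb plus Lennard-Jones with Lorentz-Berthelot combination
#' (arithmetic-mean sigma, geometric-mean epsilon) and plain truncation at the
#' cutoff. Per-water totals are referenced to `e_neat`, the mean potential
#' energy of one water molecule in the neat liquid under the same conditions;
#' `rho0` is the neat-liquid number density used to normalize voxel densities.
#'
#' @param cutoff Interaction cutoff, Angstrom.
#' @param e_neat Neat-water reference energy, kcal/mol per molecule.
#' @param rho0 Bulk number density of the water model, molecules/Angstrom^3.
#' @param ww_split Fraction of each water-water pair energy credited to each
#'   partner. The default 0.5 shares pair energies evenly so grid and
#'   subvolume totals are additive without double counting.
#' @param coulomb_constant Coulomb constant, kcal*A/(mol*e^2).
#' @return A `cav_model` object.
#' @export
interaction_model <- function(cutoff = 10, e_neat = -12.259, rho0 = 0.0334,
                              ww_split = 0.5, coulomb_constant = COULOMB_KCAL) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (ww_split <= 0 || ww_split > 1) abort("ww_split must be in (0, 1]")
  if (rho0 <= 0) abort("rho0 must be > 0")
  structure(list(cutoff = cutoff, e_neat = e_neat, rho0 = rho0,
                 ww_split = ww_split, coulomb_constant = coulomb_constant),
            class = "cav_model")
}

#' @export
print.cav_model <- function(x, ...) {
  cat(sprintf(paste0("<cav_model> cutoff %.1f A, e_neat %.4f kcal/mol, ",
                     "rho0 %.5f /A^3, ww_split %.2f\n"),
              x$cutoff, x$e_neat, x$rho0, x$ww_split))
  invisible(x)
}

# atoms: tibble/data.frame with x, y, z, charge, lj_sigma, lj_epsilon
atom_group <- function(atoms) {
  atoms <- as.data.frame(atoms)
  list(X = as.matrix(atoms[, c("x", "y", "z")]),
       q = atoms$charge, s = atoms$lj_sigma, e = atoms$lj_epsilon)
}

#' Interaction energy between two atom groups
#'
#' Sum over cross pairs of the Coulomb + Lennard-Jones energy with a
#' per-atom-pair minimum-image cutoff. Pairs beyond the cutoff contribute 0.
#'
#' @param group_a,group_b Data frames with columns x, y, z, charge, lj_sigma,
#'   lj_epsilon (the groups must be disjoint atom sets).
#' @param model A [interaction_model()].
#' @param box Orthorhombic box lengths, Angstrom.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(group_a, group_b, model, box) {
  a <- atom_group(group_a); b <- atom_group(group_b)
  cpp_pair_energy(a$X, a$q, a$s, a$e, b$X, b$q, b$s, b$e,
                  as.numeric(box), model$cutoff, model$coulomb_constant,
                  strict = TRUE)
}

#' Per-water interaction energies for every frame
#'
#' For each solvent molecule w: `e_sw` is its interaction energy with all
#' solute atoms, where each solute atom is included against the whole water
#' molecule when its distance to the water oxygen is within the cutoff;
#' `e_ww` is `ww_split` times the sum of its full molecular pair energies
#' with every other water whose oxygen lies within the cutoff. In both terms
#' the water molecule is all-or-nothing at the cutoff - molecules are never
#' split, which would leave spurious monopoles at the cutoff sphere.
#' `e_tot_ref = e_sw + e_ww - e_neat`.
#'
#' @param trajectory A `cav_trajectory`.
#' @param model A [interaction_model()].
#' @param frames Optional integer frame positions to restrict to.
#' @return Tibble: frame, molecule_id, e_sw, e_ww, e_tot_ref.
#' @export
water_energies <- function(trajectory, model, frames = NULL) {
  wi <- water_index(trajectory$topology)
  if (length(wi$o_rows) == 0) abort("trajectory has no solvent molecules")
  frames <- frames %||% seq_len(n_frames(trajectory))
  em <- traj_water_energy_matrices(trajectory, model, frames)
  M <- length(wi$o_rows)
  tibble(
    frame = rep(trajectory$frame_index[frames], each = M),
    molecule_id = rep(wi$water_molecule, length(frames)),
    e_sw = as.vector(em$e_sw),
    e_ww = as.vector(em$e_ww),
    e_tot_ref = as.vector(em$e_sw + em$e_ww - model$e_neat)
  )
}

# e_sw, e_ww as M x n_frames matrices (internal workhorse)
traj_water_energy_matrices <- function(trajectory, model, frames) {
  wi <- water_index(trajectory$topology)
  top <- trajectory$topology
  M <- length(wi$o_rows)
  e_sw <- matrix(0, M, length(frames))
  e_ww <- matrix(0, M, length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    pe <- cpp_frame_water_energies(
      frame_coords(trajectory, f), top$charge, top$lj_sigma, top$lj_epsilon,
      wi$watoms, wi$o_rows, wi$solute_rows, trajectory$box[f, ],
      model$cutoff, model$coulomb_constant, model$ww_split, strict = TRUE)
    e_sw[, i] <- pe$e_sw
    e_ww[, i] <- pe$e_ww
  }
  list(e_sw = e_sw, e_ww = e_ww, o_rows = wi$o_rows)
}

#' Total nonbonded energy of one frame
#'
#' Unique-pair total under the analysis convention: all water-water molecular
#' pair energies (molecule-based cutoff) plus all solute-water interactions
#' (per-atom-pair cutoff). Equals `sum(e_sw) + sum(e_ww)` of [water_energies()]
#' when `ww_split = 0.5`.
#'
#' @param trajectory A `cav_trajectory`.
#' @param model A [interaction_model()].
#' @param frame Frame position.
#' @return Energy in kcal/mol.
#' @export
frame_total_energy <- function(trajectory, model, frame = 1) {
  wi <- water_index(trajectory$topology)
  top <- trajectory$topology
  cpp_frame_total_energy(
    frame_coords(trajectory, frame), top$charge, top$lj_sigma, top$lj_epsilon,
    wi$watoms, wi$o_rows, wi$solute_rows, trajectory$box[frame, ],
    model$cutoff, model$coulomb_constant, strict = TRUE)
}
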