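#' Geometric hydrogen-bond criteria
#'
#' A noncovalent polar contact counts as a hydrogen bond when the
#' donor-acceptor heavy-atom distance is strictly less than
#' `heavy_distance_max` and the angle criterion is strictly met.
#'
#' The default convention measures the angle at the donor heavy atom between
#' the donor->hydrogen and donor->acceptor vectors (the
#' acceptor-donor-hydrogen angle); the alternative measures the deviation
#' from donor-hydrogen-acceptor linearity (180 degrees minus the angle at the
#' hydrogen). Both use the same `angle_max`.
#'
#' @param heavy_distance_max Heavy-atom distance bound, Angstrom.
#' @param angle_max Angle bound, degrees.
#' @param angle_convention `"acceptor_donor_hydrogen"` (default) or
#'   `"donor_hydrogen_acceptor"`.
#' @return A `cav_hbond_criteria` object.
#' @export
hbond_criteria <- function(heavy_distance_max = 3.6, angle_max = 30,
                           angle_convention = c("acceptor_donor_hydrogen",
                                                "donor_hydrogen_acceptor")) {
  if (heavy_distance_max <= 0) abort("heavy_distance_max must be > 0")
  if (angle_max <= 0 || angle_max > 180) abort("angle_max must be in (0, 180]")
  angle_convention <- match.arg(angle_convention)
  structure(list(heavy_distance_max = heavy_distance_max,
                 angle_max = angle_max, angle_convention = angle_convention),
            class = "cav_hbond_criteria")
}

# Identify polar heavy atoms and their covalent hydrogens from the topology
# and one set of coordinates. A hydrogen belongs to the nearest polar heavy
# atom of its own molecule within `bond_max` Angstrom.
hbond_topology <- function(topology, coords, polar_elements = c("N", "O", "S"),
                           bond_max = 1.25) {
  polar <- which(topology$element %in% polar_elements &
                   topology$role != "solvent_virtual")
  hyd <- which(topology$element == "H")
  donor_heavy <- integer(0); donor_h <- integer(0)
  if (length(hyd) > 0 && length(polar) > 0) {
    for (h in hyd) {
      same <- polar[topology$molecule_id[polar] == topology$molecule_id[h]]
      if (length(same) == 0) next
      d <- sqrt(rowSums((coords[same, , drop = FALSE] -
                           matrix(coords[h, ], length(same), 3, byrow = TRUE))^2))
      j <- which.min(d)
      if (d[j] <= bond_max) {
        donor_heavy <- c(donor_heavy, same[j])
        donor_h <- c(donor_h, h)
      }
    }
  }
  list(donor_heavy = donor_heavy, donor_h = donor_h, acceptors = polar)
}

#' Detect hydrogen bonds in trajectory frames
#'
#' Enumerates all (donor-hydrogen, acceptor) pairs among polar heavy atoms
#' (N, O, S by default) and applies the geometric criteria under the
#' minimum-image convention. Intramolecular pairs are skipped. Each
#' (donor-hydrogen, acceptor) pair is reported at most once per frame.
#'
#' @param trajectory A `cav_trajectory`.
#' @param criteria A [hbond_criteria()].
#' @param frames Optional frame positions to restrict to.
#' @param polar_elements Elements eligible as donors/acceptors.
#' @return Tibble: frame, donor, hydrogen, acceptor (atom indices), class
#'   (`"solute-water"`, `"water-water"` or `"solute-solute"`).
#' @export
detect_hbonds <- function(trajectory, criteria = hbond_criteria(),
                          frames = NULL, polar_elements = c("N", "O", "S")) {
  top <- trajectory$topology
  ht <- hbond_topology(top, frame_coords(trajectory, 1), polar_elements)
  frames <- frames %||% seq_len(n_frames(trajectory))
  conv <- if (criteria$angle_convention == "acceptor_donor_hydrogen") 0L else 1L
  solute <- top$role == "solute"
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    tri <- cpp_frame_hbonds(frame_coords(trajectory, f), ht$donor_heavy,
                            ht$donor_h, ht$acceptors, top$molecule_id,
                            trajectory$box[f, ], criteria$heavy_distance_max,
                            criteria$angle_max, conv)
    if (nrow(tri) == 0) next
    ns <- solute[tri[, 1]] + solute[tri[, 3]]
    out[[i]] <- tibble(frame = trajectory$frame_index[f],
                       donor = tri[, 1], hydrogen = tri[, 2],
                       acceptor = tri[, 3],
                       class = c("water-water", "solute-water",
                                 "solute-solute")[ns + 1L])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(frame = integer(), donor = integer(), hydrogen = integer(),
                  acceptor = integer(), class = character())
  }
  res
}

#' Define a functional group of solute heavy atoms
#'
#' @param label Group label (e.g. `"SER289-OG"`).
#' @param atoms Integer atom indices of the group's heavy atoms.
#' @param donor_hydrogens Integer indices of hydrogens the group can donate.
#' @param capability `"donor"`, `"acceptor"` or `"both"`.
#' @return A `cav_group` object.
#' @export
functional_group <- function(label, atoms, donor_hydrogens = integer(0),
                             capability = c("acceptor", "donor", "both")) {
  capability <- match.arg(capability)
  if (length(atoms) == 0) abort("functional group must contain atoms")
  if (capability %in% c("donor", "both") && length(donor_hydrogens) == 0) {
    abort(paste0("group '", label, "' has donor capability but no hydrogens"))
  }
  structure(list(label = label, atoms = as.integer(atoms),
                 donor_hydrogens = as.integer(donor_hydrogens),
                 capability = capability),
            class = "cav_group")
}

#' Count water-oxygen neighbors of a functional group
#'
#' A water is a neighbor when its oxygen lies within `cutoff` (inclusive) of
#' any heavy atom of the group, under the minimum-image convention.
#'
#' @param trajectory A `cav_trajectory`.
#' @param group A [functional_group()] (or integer atom indices).
#' @param cutoff Neighbor cutoff, Angstrom (3.6 by default; 3.5 is the
#'   common table-caption variant).
#' @param frames Optional frame positions.
#' @return Tibble: frame, n_neighbors.
#' @export
count_neighbors <- function(trajectory, group, cutoff = 3.6, frames = NULL) {
  atoms <- if (inherits(group, "cav_group")) group$atoms else as.integer(group)
  if (length(atoms) == 0) abort("empty group")
  wi <- water_index(trajectory$topology)
  frames <- frames %||% seq_len(n_frames(trajectory))
  n <- vapply(frames, function(f) {
    cpp_frame_neighbors(frame_coords(trajectory, f), atoms, wi$o_rows,
                        trajectory$box[f, ], cutoff)
  }, integer(1))
  tibble(frame = trajectory$frame_index[frames], n_neighbors = n)
}

#' Per-group solvation statistics
#'
#' For each functional group, the mean number of water neighbors per frame
#' and the mean number of group-water hydrogen bonds per frame, with a
#' `total` row summing the per-group means (the layout of per-group
#' solvation tables).
#'
#' @param trajectory A `cav_trajectory`.
#' @param groups List of [functional_group()] objects.
#' @param criteria A [hbond_criteria()].
#' @param neighbor_cutoff Neighbor cutoff, Angstrom.
#' @param frames Optional frame positions.
#' @return Tibble: label, mean_water_neighbors, mean_water_hbonds.
#' @export
group_stats <- function(trajectory, groups, criteria = hbond_criteria(),
                        neighbor_cutoff = 3.6, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(trajectory))
  hb <- detect_hbonds(trajectory, criteria, frames)
  top <- trajectory$topology
  solute <- top$role == "solute"
  nf <- length(frames)
  rows <- lapply(groups, function(g) {
    nb <- count_neighbors(trajectory, g, neighbor_cutoff, frames)
    gw <- (hb$donor %in% g$atoms & !solute[hb$acceptor]) |
      (hb$acceptor %in% g$atoms & !solute[hb$donor])
    tibble(label = g$label,
           mean_water_neighbors = mean(nb$n_neighbors),
           mean_water_hbonds = sum(gw) / nf)
  })
  group_totals(dplyr::bind_rows(rows))
}

#' Conformer occupancy of a probe atom against labeled reference positions
#'
#' Each frame is assigned to the label whose reference position is nearest to
#' the probe atom (minimum image); exact ties go to the first label in input
#' order (and are reported via a message).
#'
#' @param trajectory A `cav_trajectory`.
#' @param probe_atom Integer atom index followed across frames.
#' @param reference_positions `m x 3` matrix of reference positions (m >= 2)
#'   with rownames as labels, or a named list of length-3 positions.
#' @param frames Optional frame positions.
#' @return Tibble: label, n_frames, fraction (fractions sum to 1).
#' @export
conformer_occupancy <- function(trajectory, probe_atom, reference_positions,
                                frames = NULL) {
  if (is.list(reference_positions)) {
    reference_positions <- do.call(rbind, reference_positions)
  }
  if (nrow(reference_positions) < 2) abort("need >= 2 labeled reference positions")
  labels <- rownames(reference_positions) %||%
    paste0("state", seq_len(nrow(reference_positions)))
  frames <- frames %||% seq_len(n_frames(trajectory))
  assign <- integer(length(frames))
  ties <- 0L
  for (i in seq_along(frames)) {
    f <- frames[i]
    p <- trajectory$coords[probe_atom, , f]
    d <- minimum_image_distance(reference_positions, p, trajectory$box[f, ])
    if (sum(d == min(d)) > 1) ties <- ties + 1L
    assign[i] <- which.min(d)
  }
  if (ties > 0) message(ties, " frame(s) had exact distance ties; assigned to first label")
  counts <- tabulate(assign, nbins = nrow(reference_positions))
  tibble(label = labels, n_frames = counts,
         fraction = counts / length(frames))
}
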