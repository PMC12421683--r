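#' Find hydration sites by greedy high-density clustering
#'
#' Candidate centers are all observed water-oxygen positions in the region,
#' pooled over frames. Repeatedly, the candidate whose 1 A sphere contains
#' the most observations becomes a site (ties to the lowest observation
#' index), its observations are removed, and candidates closer than
#' `min_separation` to an accepted center become ineligible. Clustering stops
#' when the best remaining sphere's occupancy per frame falls below
#' `min_occupancy_ratio` times the bulk expectation
#' `rho0 * (4/3) * pi * radius^3`.
#'
#' @param trajectory A `cav_trajectory` (aligned).
#' @param model A [interaction_model()] (supplies `rho0`).
#' @param region Bounding box `list(min = c(x,y,z), max = c(x,y,z))`, or a
#'   [subvolume_spec()] (ligand-proximity region), or `NULL` for the whole box.
#' @param min_occupancy_ratio Density enrichment required of a site (default
#'   2: a site must be at least twice bulk density).
#' @param radius Site sphere radius, Angstrom (1 A).
#' @param min_separation Minimum distance between accepted centers (2 A).
#' @param frames Optional frame positions.
#' @return A `cav_sites` object: tibble (site, x, y, z, n_obs, occupancy)
#'   with the per-observation bookkeeping needed by [site_thermo()] attached.
#' @export
find_sites <- function(trajectory, model, region = NULL,
                       min_occupancy_ratio = 2, radius = 1,
                       min_separation = 2, frames = NULL) {
  wi <- water_index(trajectory$topology)
  frames <- frames %||% seq_len(n_frames(trajectory))
  M <- length(wi$o_rows)
  obs <- matrix(NA_real_, M * length(frames), 3)
  obs_frame <- integer(M * length(frames)); obs_water <- integer(M * length(frames))
  n <- 0L
  for (i in seq_along(frames)) {
    f <- frames[i]
    P <- trajectory$coords[wi$o_rows, , f, drop = FALSE]
    dim(P) <- c(M, 3)
    keep <- in_region(P, region, trajectory$box[f, ])
    nk <- sum(keep)
    if (nk == 0) next
    obs[n + seq_len(nk), ] <- P[keep, , drop = FALSE]
    obs_frame[n + seq_len(nk)] <- i
    obs_water[n + seq_len(nk)] <- which(keep)
    n <- n + nk
  }
  empty <- structure(list(sites = tibble(site = integer(), x = numeric(),
                                         y = numeric(), z = numeric(),
                                         n_obs = integer(), occupancy = numeric()),
                          radius = radius, n_frames = length(frames),
                          frames = frames,
                          occupants = tibble(site = integer(), frame_pos = integer(),
                                             water = integer())),
                     class = "cav_sites")
  if (n == 0) return(empty)
  obs <- obs[seq_len(n), , drop = FALSE]
  obs_frame <- obs_frame[seq_len(n)]; obs_water <- obs_water[seq_len(n)]
  min_count <- min_occupancy_ratio * model$rho0 * (4 / 3) * pi * radius^3 *
    length(frames)
  res <- cpp_greedy_sites(obs, trajectory$box[frames[1], ], radius,
                          min_separation, min_count)
  S <- nrow(res$centers)
  if (S == 0) return(empty)
  sites <- tibble(site = seq_len(S),
                  x = res$centers[, 1], y = res$centers[, 2],
                  z = res$centers[, 3], n_obs = res$counts,
                  occupancy = res$counts / length(frames))
  occ <- res$assignment > 0
  structure(list(sites = sites, radius = radius, n_frames = length(frames),
                 frames = frames,
                 occupants = tibble(site = res$assignment[occ],
                                    frame_pos = obs_frame[occ],
                                    water = obs_water[occ])),
            class = "cav_sites")
}

in_region <- function(P, region, box) {
  if (is.null(region)) return(rep(TRUE, nrow(P)))
  if (inherits(region, "cav_subvolume")) {
    lig <- as.matrix(region$ligand[, c("x", "y", "z")])
    apply(P, 1, function(p) any(minimum_image_distance(lig, p, box) <= region$distance))
  } else {
    P[, 1] >= region$min[1] & P[, 1] <= region$max[1] &
      P[, 2] >= region$min[2] & P[, 2] <= region$max[2] &
      P[, 3] >= region$min[3] & P[, 3] <= region$max[3]
  }
}

#' @export
print.cav_sites <- function(x, ...) {
  cat(sprintf("<cav_sites> %d site(s) over %d frames (radius %.1f A)\n",
              nrow(x$sites), x$n_frames, x$radius))
  print(x$sites)
  invisible(x)
}

#' @export
tidy.cav_sites <- function(x, ...) x$sites

#' Per-site thermodynamics and donor/acceptor classification
#'
#' Averages the per-water energies over each site's occupying waters
#' (`e_tot_ref = mean(e_sw) + mean(e_ww) - e_neat`), computes the fraction of
#' occupants donating / accepting at least one hydrogen bond to the solute,
#' mean solute-water hydrogen bonds, mean water neighbors, and classifies
#' each site with the 60% rule of [classify_site()].
#'
#' @param sites A `cav_sites` from [find_sites()].
#' @param trajectory The same trajectory.
#' @param model A [interaction_model()].
#' @param criteria A [hbond_criteria()].
#' @param neighbor_cutoff Water-neighbor cutoff, Angstrom.
#' @param threshold Donor/acceptor classification threshold (0.60).
#' @return The `cav_sites` object with columns e_sw, e_ww, e_tot_ref,
#'   donor_fraction, acceptor_fraction, hb_sw, water_neighbors,
#'   classification added to its site table.
#' @export
site_thermo <- function(sites, trajectory, model, criteria = hbond_criteria(),
                        neighbor_cutoff = 3.6, threshold = 0.60) {
  if (nrow(sites$sites) == 0) return(sites)
  if (any(tabulate(sites$occupants$site, nrow(sites$sites)) == 0)) {
    abort("site with zero occupancy")
  }
  frames <- sites$frames
  wi <- water_index(trajectory$topology)
  em <- traj_water_energy_matrices(trajectory, model, frames)
  hm <- traj_water_hb_matrices(trajectory, criteria, frames)
  nb <- matrix(0L, length(wi$o_rows), length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    nb[, i] <- cpp_frame_ww_neighbors(frame_coords(trajectory, f), wi$o_rows,
                                      trajectory$box[f, ], neighbor_cutoff)
  }
  occ <- sites$occupants
  lin <- cbind(occ$water, occ$frame_pos)
  per <- tibble(site = occ$site,
                e_sw = em$e_sw[lin], e_ww = em$e_ww[lin],
                don = hm$hb_don_sw[lin] > 0, acc = hm$hb_acc_sw[lin] > 0,
                hb_sw = hm$hb_sw[lin], neigh = nb[lin])
  agg <- per |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(e_sw = mean(.data$e_sw), e_ww = mean(.data$e_ww),
                     donor_fraction = mean(.data$don),
                     acceptor_fraction = mean(.data$acc),
                     hb_sw = mean(.data$hb_sw),
                     water_neighbors = mean(.data$neigh), .groups = "drop")
  agg$e_tot_ref <- referenced_total(agg$e_sw, agg$e_ww, 1, model$e_neat)
  agg$classification <- classify_site(agg$donor_fraction,
                                      agg$acceptor_fraction, threshold)
  sites$sites <- dplyr::left_join(sites$sites, agg, by = "site")
  sites
}

#' Classify a hydration site as donor/acceptor/both/neither
#'
#' A site is a donor (acceptor) when 60% or more of its occupying waters
#' donate (accept) a hydrogen bond to the solute; `both` when both fractions
#' meet the threshold; `neither` otherwise. The threshold comparison is `>=`.
#'
#' @param donor_fraction,acceptor_fraction Fractions in `[0, 1]` (vectorized).
#' @param threshold Classification threshold (default 0.60).
#' @return Character vector: `"donor"`, `"acceptor"`, `"both"` or `"neither"`.
#' @export
classify_site <- function(donor_fraction, acceptor_fraction, threshold = 0.60) {
  stopifnot(all(donor_fraction >= 0 & donor_fraction <= 1),
            all(acceptor_fraction >= 0 & acceptor_fraction <= 1))
  d <- donor_fraction >= threshold
  a <- acceptor_fraction >= threshold
  dplyr::case_when(d & a ~ "both", d ~ "donor", a ~ "acceptor",
                   .default = "neither")
}

#' Write hydration sites as a pseudo-atom PDB plus a sidecar TSV
#'
#' One oxygen pseudo-atom per site; the occupancy column carries the site
#' occupancy (capped at 9.99) and the B-factor a classification code
#' (1 donor, 2 acceptor, 3 both, 0 neither or unclassified).
#'
#' @param sites A `cav_sites`.
#' @param path Output PDB path; the TSV is written next to it (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  st <- sites$sites
  code <- if ("classification" %in% names(st)) {
    c(donor = 1, acceptor = 2, both = 3, neither = 0)[st$classification]
  } else rep(0, nrow(st))
  lines <- vapply(seq_len(nrow(st)), function(i) {
    sprintf("HETATM%5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
            i, " O", "HST", i, st$x[i], st$y[i], st$z[i],
            min(st$occupancy[i], 9.99), code[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  write.table(st, sub("\\.pdb$", ".tsv", path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
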