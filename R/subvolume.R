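#' Ligand-proximity subvolume specification
#'
#' A subvolume is the set of voxels whose center lies within `distance`
#' (inclusive) of any heavy atom of the reference ligand. The conventional
#' choices are 3 A (the displacement region) and 10 A (the full binding-site
#' solvation region), scanned in 0.5 A steps.
#'
#' @param ligand Data frame of ligand heavy-atom coordinates (columns x, y, z;
#'   e.g. from [read_reference_pdb()]).
#' @param distance Inclusion distance, Angstrom.
#' @return A `cav_subvolume` object.
#' @export
subvolume_spec <- function(ligand, distance) {
  if (distance <= 0) abort("distance must be > 0")
  ligand <- as_tibble(as.data.frame(ligand))
  stopifnot(all(c("x", "y", "z") %in% names(ligand)))
  structure(list(ligand = ligand, distance = distance), class = "cav_subvolume")
}

#' Select the voxels of a subvolume
#'
#' @param grid A `cav_gist` (or a bare [grid_spec()]).
#' @param subvolume A [subvolume_spec()].
#' @return Integer vector of 1-based linear voxel indices whose center lies
#'   within the subvolume distance of any ligand atom (no periodic wrapping;
#'   empty, with a warning, when the ligand lies outside the grid reach).
#' @export
select_voxels <- function(grid, subvolume) {
  spec <- if (inherits(grid, "cav_grid_spec")) grid else grid$spec
  ctr <- voxel_centers(spec)
  lig <- as.matrix(subvolume$ligand[, c("x", "y", "z")])
  d2max <- subvolume$distance^2
  hit <- rep(FALSE, nrow(ctr))
  for (i in seq_len(nrow(lig))) {
    d2 <- (ctr[, 1] - lig[i, 1])^2 + (ctr[, 2] - lig[i, 2])^2 +
      (ctr[, 3] - lig[i, 3])^2
    hit <- hit | d2 <= d2max
  }
  if (!any(hit)) warn("ligand lies entirely outside the grid; empty subvolume")
  which(hit)
}

#' Integrate grid quantities over a voxel set
#'
#' Integrated quantities are sums of the additive per-frame voxel quantities
#' over the set: mean water count per frame, total solute-water, water-water
#' and referenced total energies per frame, and mean hydrogen-bond counts.
#' Per-water values divide by the mean water count (0 when empty). The
#' identity `e_tot = e_sw + e_ww - n_water * e_neat` holds by construction.
#'
#' @param grid A finalized `cav_gist`.
#' @param voxels Integer linear voxel indices (from [select_voxels()]).
#' @return One-row tibble: n_voxels, volume, n_water, e_sw, e_ww, e_tot,
#'   hb_sw, hb_ww, e_sw_per_water, e_ww_per_water, e_tot_per_water.
#' @export
integrate_subvolume <- function(grid, voxels) {
  if (!grid$finalized) abort("finalize the grid first")
  nw <- sum(grid$n_wat[voxels]) / grid$n_frames
  e_sw <- sum(grid$e_sw_per_frame[voxels])
  e_ww <- sum(grid$e_ww_per_frame[voxels])
  e_tot <- sum(grid$e_per_frame[voxels])
  tibble(
    n_voxels = length(voxels),
    volume = length(voxels) * grid$spec$spacing^3,
    n_water = nw, e_sw = e_sw, e_ww = e_ww, e_tot = e_tot,
    hb_sw = sum(grid$hb_sw_per_frame[voxels]),
    hb_ww = sum(grid$hb_ww_per_frame[voxels]),
    e_sw_per_water = if (nw > 0) e_sw / nw else 0,
    e_ww_per_water = if (nw > 0) e_ww / nw else 0,
    e_tot_per_water = if (nw > 0) e_tot / nw else 0
  )
}

#' Total energy referenced to neat water
#'
#' The reporting identity used throughout: `e_sw + e_ww - n_water * e_neat`.
#' With `e_neat = 0` this is the plain solute-water + water-water sum, the
#' form in which per-site totals are usually printed.
#'
#' @param e_sw,e_ww Solute-water and water-water energies, kcal/mol.
#' @param n_water Number of water molecules being referenced.
#' @param e_neat Neat-water reference energy per molecule.
#' @return `e_sw + e_ww - n_water * e_neat` (vectorized).
#' @export
referenced_total <- function(e_sw, e_ww, n_water = 1, e_neat = 0) {
  e_sw + e_ww - n_water * e_neat
}

#' Add a total row to a per-group table
#'
#' The layout of per-functional-group solvation tables: one row per group
#' plus a `total` row holding the column sums of every numeric column.
#'
#' @param stats Tibble with a `label` column and numeric columns.
#' @return The tibble with a `total` row appended.
#' @export
group_totals <- function(stats) {
  num <- vapply(stats, is.numeric, logical(1))
  tot <- stats[1, ]
  tot$label <- "total"
  for (cl in names(stats)[num]) tot[[cl]] <- sum(stats[[cl]])
  dplyr::bind_rows(stats, tot)
}

#' Block averaging of a per-frame series
#'
#' Splits the series into `n_blocks` contiguous equal blocks (trailing frames
#' beyond an even split are dropped, with a message), and reports the mean of
#' block means and their standard error `sd(block_means) / sqrt(n_blocks)`.
#'
#' @param series Numeric per-frame series (length >= n_blocks).
#' @param n_blocks Number of blocks (default 4).
#' @return A `cav_blockstats` list: block_means, mean, sem.
#' @export
block_average <- function(series, n_blocks = 4) {
  n <- length(series)
  if (n < n_blocks) abort("series shorter than the number of blocks")
  bl <- n %/% n_blocks
  drop <- n - bl * n_blocks
  if (drop > 0) message("dropping ", drop, " trailing frame(s) for even blocks")
  bm <- vapply(seq_len(n_blocks), function(b) {
    mean(series[((b - 1) * bl + 1):(b * bl)])
  }, numeric(1))
  structure(list(block_means = bm, mean = mean(bm),
                 sem = sd(bm) / sqrt(n_blocks)),
            class = "cav_blockstats")
}

#' @export
print.cav_blockstats <- function(x, ...) {
  cat(sprintf("<cav_blockstats> mean %.4f +/- %.4f (SEM over %d blocks)\n",
              x$mean, x$sem, length(x$block_means)))
  invisible(x)
}

#' @export
tidy.cav_blockstats <- function(x, ...) {
  tibble(block = seq_along(x$block_means), block_mean = x$block_means)
}

#' @export
glance.cav_blockstats <- function(x, ...) {
  tibble(mean = x$mean, sem = x$sem, n_blocks = length(x$block_means))
}

#' Integrated subvolume quantities with block-averaged errors
#'
#' Splits the trajectory into `n_blocks` contiguous blocks, accumulates and
#' integrates the grid within each block, and block-averages every
#' integrated quantity.
#'
#' @param trajectory A `cav_trajectory`.
#' @param model A [interaction_model()].
#' @param spec A [grid_spec()].
#' @param subvolume A [subvolume_spec()].
#' @param criteria A [hbond_criteria()].
#' @param n_blocks Number of blocks (default 4).
#' @return Tibble: quantity, mean, sem and one column per block. The mean
#'   equals the average of block means (identical to the full-trajectory
#'   value when frame counts divide evenly).
#' @export
integrate_blocks <- function(trajectory, model, spec, subvolume,
                             criteria = hbond_criteria(), n_blocks = 4) {
  nf <- n_frames(trajectory)
  if (nf < n_blocks) abort("trajectory shorter than the number of blocks")
  bl <- nf %/% n_blocks
  vox <- NULL
  rows <- lapply(seq_len(n_blocks), function(b) {
    fr <- ((b - 1) * bl + 1):(b * bl)
    g <- gist_finalize(gist_accumulate(trajectory, model, spec, criteria,
                                       frames = fr), model)
    if (is.null(vox)) vox <<- select_voxels(g, subvolume)
    integrate_subvolume(g, vox)
  })
  per_block <- dplyr::bind_rows(rows)
  quantities <- c("n_water", "e_sw", "e_ww", "e_tot", "hb_sw", "hb_ww",
                  "e_sw_per_water", "e_ww_per_water", "e_tot_per_water")
  out <- lapply(quantities, function(q) {
    bm <- per_block[[q]]
    tibble(quantity = q, mean = mean(bm), sem = sd(bm) / sqrt(n_blocks),
           !!!setNames(as.list(bm), paste0("block", seq_len(n_blocks))))
  })
  dplyr::bind_rows(out)
}

#' Rigid-vs-flexible comparison of integrated quantities
#'
#' Deltas are `rigid - flexible` for every shared numeric quantity; with the
#' total-energy sign convention used throughout (energies referenced to neat
#' water), a positive energy delta means the flexible system is more
#' favorable.
#'
#' @param rigid,flexible Either one-row tibbles of quantities (e.g. from
#'   [integrate_subvolume()]) or long tibbles with `quantity` and `mean`
#'   columns (e.g. from [integrate_blocks()], in which case block SEMs are
#'   propagated as `sqrt(sem_r^2 + sem_f^2)`).
#' @return A `cav_comparison` tibble: quantity, rigid, flexible, delta (and
#'   delta_sem when SEMs are available).
#' @export
compare_integrated <- function(rigid, flexible) {
  long <- is.data.frame(rigid) && "quantity" %in% names(rigid)
  if (long) {
    stopifnot("quantity" %in% names(flexible))
    j <- dplyr::inner_join(
      dplyr::select(rigid, "quantity", rigid = "mean",
                    dplyr::any_of(c(rigid_sem = "sem"))),
      dplyr::select(flexible, "quantity", flexible = "mean",
                    dplyr::any_of(c(flexible_sem = "sem"))),
      by = "quantity")
    if (nrow(j) == 0) abort("no shared quantities to compare")
    out <- tibble(quantity = j$quantity, rigid = j$rigid,
                  flexible = j$flexible, delta = j$rigid - j$flexible)
    if (all(c("rigid_sem", "flexible_sem") %in% names(j))) {
      out$delta_sem <- sqrt(j$rigid_sem^2 + j$flexible_sem^2)
    }
  } else {
    shared <- intersect(names(rigid), names(flexible))
    shared <- shared[vapply(rigid[shared], is.numeric, logical(1))]
    if (length(shared) == 0) abort("no shared quantities to compare")
    out <- tibble(quantity = shared,
                  rigid = as.numeric(rigid[1, shared]),
                  flexible = as.numeric(flexible[1, shared]))
    out$delta <- out$rigid - out$flexible
  }
  class(out) <- c("cav_comparison", class(out))
  out
}
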