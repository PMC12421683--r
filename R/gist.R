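#' Voxel grid specification
#'
#' @param origin Corner of voxel (0,0,0), Angstrom.
#' @param shape Integer voxel counts per axis.
#' @param spacing Voxel edge length, Angstrom (0.5 by default, giving a
#'   voxel volume of 0.125 A^3).
#' @return A `cav_grid_spec` object.
#' @export
grid_spec <- function(origin, shape, spacing = 0.5) {
  if (spacing <= 0) abort("spacing must be > 0")
  shape <- as.integer(shape)
  if (any(shape < 1)) abort("shape must be >= 1 on every axis")
  structure(list(origin = as.numeric(origin), shape = shape, spacing = spacing),
            class = "cav_grid_spec")
}

#' Grid spec covering a whole box
#' @param box Box lengths, Angstrom.
#' @param spacing Voxel edge length, Angstrom.
#' @return A `cav_grid_spec` with origin at (0,0,0).
#' @export
grid_spec_for_box <- function(box, spacing = 0.5) {
  grid_spec(c(0, 0, 0), floor(box / spacing), spacing)
}

#' Assign positions to voxels
#'
#' Half-open voxel intervals: a position maps to
#' `floor((position - origin) / spacing)` (0-based triplets), so boundary
#' points are assigned upward; positions outside `[0, shape)` get `NA`.
#' A voxel's center is `origin + (i + 0.5) * spacing`.
#'
#' @param positions `n x 3` matrix (or length-3 vector) of positions.
#' @param spec A [grid_spec()].
#' @return Tibble: ix, iy, iz (0-based voxel triplet, `NA` when outside) and
#'   `voxel` (1-based linear index into the grid arrays, x fastest).
#' @export
assign_voxel <- function(positions, spec) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  idx <- floor(sweep(sweep(positions, 2, spec$origin), 2, spec$spacing, "/"))
  outside <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
    idx[, 1] >= spec$shape[1] | idx[, 2] >= spec$shape[2] | idx[, 3] >= spec$shape[3]
  idx[outside, ] <- NA
  lin <- idx[, 1] + spec$shape[1] * (idx[, 2] + spec$shape[2] * idx[, 3]) + 1
  tibble(ix = as.integer(idx[, 1]), iy = as.integer(idx[, 2]),
         iz = as.integer(idx[, 3]), voxel = as.integer(lin))
}

#' Voxel center coordinates
#' @param spec A [grid_spec()].
#' @param voxels Optional 1-based linear voxel indices (default: all).
#' @return `n x 3` matrix of voxel centers.
#' @export
voxel_centers <- function(spec, voxels = NULL) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  voxels <- voxels %||% seq_len(nx * ny * nz)
  v0 <- voxels - 1
  ix <- v0 %% nx
  iy <- (v0 %/% nx) %% ny
  iz <- v0 %/% (nx * ny)
  cbind(x = spec$origin[1] + (ix + 0.5) * spec$spacing,
        y = spec$origin[2] + (iy + 0.5) * spec$spacing,
        z = spec$origin[3] + (iz + 0.5) * spec$spacing)
}

# per-frame per-water hydrogen-bond counts (matrices M x n_frames).
# hb_ww credits each water-water bond to both participating waters;
# hb_don_sw / hb_acc_sw count solute-directed donations/acceptances.
traj_water_hb_matrices <- function(trajectory, criteria, frames) {
  top <- trajectory$topology
  wi <- water_index(top)
  M <- length(wi$o_rows)
  wnum <- integer(nrow(top))  # water ordinal per atom, 0 for solute
  solv <- top$role != "solute"
  wnum[solv] <- match(top$molecule_id[solv], wi$water_molecule)
  ht <- hbond_topology(top, frame_coords(trajectory, 1))
  conv <- if (criteria$angle_convention == "acceptor_donor_hydrogen") 0L else 1L
  F <- length(frames)
  hb_don_sw <- matrix(0L, M, F); hb_acc_sw <- matrix(0L, M, F)
  hb_ww <- matrix(0L, M, F)
  n_ww_bonds <- integer(F); n_sw_bonds <- integer(F)
  for (i in seq_along(frames)) {
    f <- frames[i]
    tri <- cpp_frame_hbonds(frame_coords(trajectory, f), ht$donor_heavy,
                            ht$donor_h, ht$acceptors, top$molecule_id,
                            trajectory$box[f, ], criteria$heavy_distance_max,
                            criteria$angle_max, conv)
    if (nrow(tri) == 0) next
    wd <- wnum[tri[, 1]]; wa <- wnum[tri[, 3]]
    # water donates to solute
    ds <- wd > 0 & wa == 0
    if (any(ds)) hb_don_sw[, i] <- hb_don_sw[, i] + tabulate(wd[ds], M)
    # water accepts from solute
    as_ <- wd == 0 & wa > 0
    if (any(as_)) hb_acc_sw[, i] <- hb_acc_sw[, i] + tabulate(wa[as_], M)
    ww <- wd > 0 & wa > 0
    if (any(ww)) {
      hb_ww[, i] <- hb_ww[, i] + tabulate(wd[ww], M) + tabulate(wa[ww], M)
    }
    n_ww_bonds[i] <- sum(ww)
    n_sw_bonds[i] <- sum(ds) + sum(as_)
  }
  list(hb_sw = hb_don_sw + hb_acc_sw, hb_don_sw = hb_don_sw,
       hb_acc_sw = hb_acc_sw, hb_ww = hb_ww,
       n_ww_bonds = n_ww_bonds, n_sw_bonds = n_sw_bonds)
}

#' Accumulate a solvation grid from a trajectory
#'
#' For every frame and every water whose oxygen falls inside the grid, the
#' water's voxel receives one occupancy count and the water's solute-water
#' energy, water-water energy, referenced total `e_sw + e_ww - e_neat`, and
#' solute-water / water-water hydrogen-bond counts. Voxel assignment uses the
#' water oxygen position only. Waters outside the grid are counted in
#' `n_outside` and otherwise ignored.
#'
#' @param trajectory A `cav_trajectory` with at least one solvent molecule.
#' @param model A [interaction_model()].
#' @param spec A [grid_spec()].
#' @param criteria A [hbond_criteria()]; `NULL` skips hydrogen-bond mapping.
#' @param frames Optional frame positions.
#' @return A `cav_gist` object (finalize with [gist_finalize()]).
#' @export
gist_accumulate <- function(trajectory, model, spec,
                            criteria = hbond_criteria(), frames = NULL) {
  if (n_frames(trajectory) == 0) abort("empty trajectory")
  wi <- water_index(trajectory$topology)
  if (length(wi$o_rows) == 0) abort("trajectory has no solvent molecules")
  frames <- frames %||% seq_len(n_frames(trajectory))
  if (length(frames) == 0) abort("empty trajectory (no frames selected)")
  nvox <- prod(spec$shape)
  acc <- matrix(0, nvox, 6)  # n_wat, e_sw, e_ww, e_ref, hb_sw, hb_ww
  em <- traj_water_energy_matrices(trajectory, model, frames)
  hm <- if (!is.null(criteria)) traj_water_hb_matrices(trajectory, criteria, frames)
  n_outside <- 0L
  for (i in seq_along(frames)) {
    f <- frames[i]
    opos <- trajectory$coords[wi$o_rows, , f, drop = FALSE]
    dim(opos) <- c(length(wi$o_rows), 3)
    vox <- assign_voxel(opos, spec)$voxel
    ok <- !is.na(vox)
    n_outside <- n_outside + sum(!ok)
    if (!any(ok)) next
    e_ref <- em$e_sw[ok, i] + em$e_ww[ok, i] - model$e_neat
    vals <- cbind(1, em$e_sw[ok, i], em$e_ww[ok, i], e_ref,
                  if (is.null(hm)) 0 else hm$hb_sw[ok, i],
                  if (is.null(hm)) 0 else hm$hb_ww[ok, i])
    rs <- rowsum(vals, vox[ok])
    rows <- as.integer(rownames(rs))
    acc[rows, ] <- acc[rows, ] + rs
  }
  dims <- spec$shape
  structure(list(
    spec = spec, n_frames = length(frames), n_outside = n_outside,
    n_wat = array(acc[, 1], dims), sum_e_sw = array(acc[, 2], dims),
    sum_e_ww = array(acc[, 3], dims), sum_e_ref = array(acc[, 4], dims),
    n_hb_sw = array(acc[, 5], dims), n_hb_ww = array(acc[, 6], dims),
    finalized = FALSE), class = "cav_gist")
}

#' Finalize a solvation grid
#'
#' Computes per-voxel derived fields: number density `rho_vox =
#' n_wat / (n_frames * voxel_volume)`; normalized density `g = rho_vox /
#' rho0`; the density-weighted energy density `e_dens = g * mean(e_ref)`
#' (the printed grid formula, kcal/mol scaled by local enrichment); and the
#' additive per-frame energy `e_per_frame = sum_e_ref / n_frames` (kcal/mol
#' per frame, which sums over voxels to the trajectory total and is the
#' quantity used for subvolume integration). Voxels never visited have all
#' derived fields 0.
#'
#' @param grid A `cav_gist` from [gist_accumulate()].
#' @param model The [interaction_model()] used for accumulation.
#' @return The grid with derived fields and `finalized = TRUE`.
#' @export
gist_finalize <- function(grid, model) {
  vvol <- grid$spec$spacing^3
  n <- grid$n_wat
  occ <- n > 0
  mean_ref <- array(0, dim(n)); mean_ref[occ] <- grid$sum_e_ref[occ] / n[occ]
  grid$rho_vox <- n / (grid$n_frames * vvol)
  grid$g <- grid$rho_vox / model$rho0
  grid$e_dens <- grid$g * mean_ref
  grid$e_per_frame <- grid$sum_e_ref / grid$n_frames
  grid$e_sw_per_frame <- grid$sum_e_sw / grid$n_frames
  grid$e_ww_per_frame <- grid$sum_e_ww / grid$n_frames
  grid$hb_sw_per_frame <- grid$n_hb_sw / grid$n_frames
  grid$hb_ww_per_frame <- grid$n_hb_ww / grid$n_frames
  grid$mean_e_sw <- array(0, dim(n)); grid$mean_e_sw[occ] <- grid$sum_e_sw[occ] / n[occ]
  grid$mean_e_ww <- array(0, dim(n)); grid$mean_e_ww[occ] <- grid$sum_e_ww[occ] / n[occ]
  grid$model <- model
  grid$finalized <- TRUE
  grid
}

#' @export
print.cav_gist <- function(x, ...) {
  cat(sprintf("<cav_gist> %d x %d x %d voxels (%.2f A), %d frames, %s\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$shape[3],
              x$spec$spacing, x$n_frames,
              if (x$finalized) "finalized" else "raw accumulators"))
  invisible(x)
}

gist_fields <- function(grid) {
  f <- c("n_wat", "sum_e_sw", "sum_e_ww", "sum_e_ref", "n_hb_sw", "n_hb_ww")
  if (grid$finalized) {
    f <- c(f, "rho_vox", "g", "e_dens", "e_per_frame", "e_sw_per_frame",
           "e_ww_per_frame", "hb_sw_per_frame", "hb_ww_per_frame",
           "mean_e_sw", "mean_e_ww")
  }
  f
}

#' Tidy a solvation grid into a voxel table
#'
#' @param x A finalized `cav_gist`.
#' @param drop_empty Keep only visited voxels.
#' @param ... Unused.
#' @return Tibble with voxel indices, centers and all per-voxel fields.
#' @export
tidy.cav_gist <- function(x, drop_empty = TRUE, ...) {
  ctr <- voxel_centers(x$spec)
  keep <- if (drop_empty) which(as.vector(x$n_wat) > 0) else
    seq_len(prod(x$spec$shape))
  nx <- x$spec$shape[1]; ny <- x$spec$shape[2]
  v0 <- keep - 1
  out <- tibble(voxel = keep,
                ix = as.integer(v0 %% nx),
                iy = as.integer((v0 %/% nx) %% ny),
                iz = as.integer(v0 %/% (nx * ny)),
                x = ctr[keep, 1], y = ctr[keep, 2], z = ctr[keep, 3])
  for (f in gist_fields(x)) out[[f]] <- as.vector(x[[f]])[keep]
  out
}

#' One-row summary of a solvation grid
#'
#' @param x A finalized `cav_gist`.
#' @param ... Unused.
#' @return Tibble: n_voxels, n_frames, n_observations, n_outside,
#'   mean_g_occupied, e_total_per_frame.
#' @export
glance.cav_gist <- function(x, ...) {
  tibble(n_voxels = prod(x$spec$shape), n_frames = x$n_frames,
         n_observations = sum(x$n_wat), n_outside = x$n_outside,
         mean_g_occupied = if (x$finalized) mean(x$g[x$n_wat > 0]) else NA_real_,
         e_total_per_frame = if (x$finalized) sum(x$e_per_frame) else NA_real_)
}

#' Write a grid field as an OpenDX scalar file
#'
#' Standard "regular positions, regular connections" OpenDX dialect: grid
#' positions are voxel centers, the last (z) index varies fastest in the
#' data block.
#'
#' @param grid A `cav_gist`.
#' @param field Field name (see [tidy.cav_gist()] columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, field, path) {
  ok <- gist_fields(grid)
  if (!field %in% ok) {
    abort(paste0("unknown field '", field, "'; available: ",
                 paste(ok, collapse = ", ")))
  }
  a <- grid[[field]]
  sh <- grid$spec$shape
  org <- grid$spec$origin + grid$spec$spacing / 2  # first voxel center
  s <- grid$spec$spacing
  # z fastest: permute so that writing in R's column-major order emits z first
  vals <- as.vector(aperm(a, c(3, 2, 1)))
  n <- length(vals)
  pad <- (3 - n %% 3) %% 3
  m <- matrix(c(vals, rep(NA, pad)), nrow = 3)
  lines <- apply(m, 2, function(v) paste(formatC(v[!is.na(v)], format = "g",
                                                 digits = 10), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("origin %.6f %.6f %.6f", org[1], org[2], org[3]),
    sprintf("delta %.6f 0 0", s), sprintf("delta 0 %.6f 0", s),
    sprintf("delta 0 0 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    lines,
    "attribute \"dep\" string \"positions\"",
    "object \"regular positions regular connections\" class field",
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar file
#'
#' @param path Path to a `.dx` file written by [write_dx()] (or compatible).
#' @return List: `spec` (a [grid_spec()], origin shifted back to the voxel
#'   corner), `values` (3D array).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "",
                                 grep("^origin", lines, value = TRUE)[1]), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- do.call(rbind, lapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), " +")[[1]])))
  spacing <- dmat[1, 1]
  istart <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > istart]) - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1):iend]), " +")))
  a <- aperm(array(vals, rev(counts)), c(3, 2, 1))
  list(spec = grid_spec(org - spacing / 2, counts, spacing), values = a)
}

# 3^3 box-mean smoothing with edge truncation (mean over available neighbors)
smooth_field <- function(a) {
  d <- dim(a)
  num <- array(0, d); den <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    xt <- xs - dx; yt <- ys - dy; zt <- zs - dz
    num[xt, yt, zt] <- num[xt, yt, zt] + a[xs, ys, zs]
    den[xt, yt, zt] <- den[xt, yt, zt] + 1
  }
  num / den
}

#' Solvent-accessible surface area from the water density field
#'
#' Extracts the isosurface of the (optionally smoothed) normalized density
#' `g` at `g_threshold` by marching tetrahedra and returns its area; a
#' voxel-face approximation (count of faces between voxels straddling the
#' threshold times spacing^2) is returned alongside as a cross-check.
#'
#' @param grid A finalized `cav_gist`.
#' @param g_threshold Iso level on `g` (default 0.5).
#' @param smooth Apply a 3^3 box-mean filter before surfacing.
#' @return Tibble: area (marching tetrahedra, A^2), area_voxel_faces (A^2).
#' @export
sasa_from_density <- function(grid, g_threshold = 0.5, smooth = TRUE) {
  if (!grid$finalized) abort("finalize the grid first")
  g <- if (smooth) smooth_field(grid$g) else grid$g
  if (all(g >= g_threshold) || all(g < g_threshold)) {
    warn("density field does not cross the threshold; area is 0")
    return(tibble(area = 0, area_voxel_faces = 0))
  }
  area <- cpp_isosurface_area(as.vector(g), dim(g), g_threshold,
                              grid$spec$spacing)
  d <- dim(g)
  inside <- g >= g_threshold
  faces <- 0L
  faces <- faces + sum(inside[-d[1], , ] != inside[-1, , ])
  faces <- faces + sum(inside[, -d[2], ] != inside[, -1, ])
  faces <- faces + sum(inside[, , -d[3]] != inside[, , -1])
  tibble(area = area, area_voxel_faces = faces * grid$spec$spacing^2)
}
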