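#' Read a nonbonded parameter table
#'
#' The sidecar table maps `(residue_name, atom_name)` pairs to a partial
#' charge, Lennard-Jones parameters and a role. It is a TSV file with header
#' `residue_name, atom_name, charge, sigma, epsilon, role`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per `(residue_name, atom_name)` pair.
#' @export
read_atom_params <- function(path) {
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  need <- c("residue_name", "atom_name", "charge", "sigma", "epsilon", "role")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("parameter table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ok_roles <- c("solute", "solvent_oxygen", "solvent_hydrogen", "solvent_virtual")
  bad <- setdiff(unique(tab$role), ok_roles)
  if (length(bad) > 0) abort(paste0("unknown role(s) in parameter table: ",
                                    paste(bad, collapse = ", ")))
  if (any(tab$sigma < 0) || any(tab$epsilon < 0)) {
    abort("lj sigma and epsilon must be >= 0")
  }
  tab
}

#' Write a nonbonded parameter table
#'
#' @param params Tibble as returned by [read_atom_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atom_params <- function(params, path) {
  write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# parse fixed-column ATOM/HETATM records; returns a data frame + coordinates
parse_pdb_atoms <- function(lines, path = "<pdb>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) == 0) abort(paste0("no ATOM/HETATM records in ", path))
  at <- lines[idx]
  num <- function(sub, what) {
    v <- suppressWarnings(as.numeric(sub))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(paste0("malformed PDB ", what, " field in ", path, " at line ",
                   idx[bad[1]], ": '", at[bad[1]], "'"))
    }
    v
  }
  short <- which(nchar(at) < 54)
  if (length(short) > 0) {
    abort(paste0("malformed (truncated) PDB line in ", path, " at line ",
                 idx[short[1]]))
  }
  data.frame(
    name = trimws(substr(at, 13, 16)),
    residue_name = trimws(substr(at, 18, 20)),
    residue_id = as.integer(num(substr(at, 23, 26), "residue id")),
    x = num(substr(at, 31, 38), "x"),
    y = num(substr(at, 39, 46), "y"),
    z = num(substr(at, 47, 54), "z"),
    element = trimws(substr(at, 77, 78)),
    stringsAsFactors = FALSE
  )
}

parse_cryst1 <- function(line) {
  c(a = as.numeric(substr(line, 7, 15)),
    b = as.numeric(substr(line, 16, 24)),
    c = as.numeric(substr(line, 25, 33)))
}

infer_element <- function(name, element) {
  out <- element
  blank <- is.na(out) | out == ""
  # fall back on the first alphabetic character of the atom name
  out[blank] <- toupper(substr(gsub("[^A-Za-z].*$", "", name[blank]), 1, 1))
  out
}

#' Read a topology from a PDB file and a parameter table
#'
#' Every atom of the PDB is matched against the parameter table by
#' `(residue_name, atom_name)`; water residues are recognized by residue name.
#' Each water residue becomes one solvent molecule and must contain exactly
#' one `solvent_oxygen`; the partial charges of each solvent molecule must sum
#' to zero. Non-water residues are solute, one molecule per residue.
#'
#' @param pdb_path Path to a PDB file (ATOM/HETATM records; first MODEL used).
#' @param params_path Path to the parameter TSV (see [read_atom_params()]).
#' @param water_residues Residue names recognized as water.
#' @return A list with `topology` (tibble: index, name, residue_name,
#'   residue_id, element, charge, lj_sigma, lj_epsilon, molecule_id, role) and
#'   `coords` (n x 3 matrix, Angstrom) and `box` (lengths if a CRYST1 record
#'   is present, else `NULL`).
#' @export
read_topology <- function(pdb_path, params_path,
                          water_residues = c("WAT", "HOH", "SOL", "TIP", "OPC")) {
  lines <- readLines(pdb_path)
  # first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) lines <- lines[seq_len(endm[1])]
  atoms <- parse_pdb_atoms(lines, pdb_path)
  params <- read_atom_params(params_path)

  key <- paste(atoms$residue_name, atoms$name, sep = "|")
  pkey <- paste(params$residue_name, params$atom_name, sep = "|")
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    miss <- which(is.na(hit))[1]
    abort(paste0("no parameter row for atom '", atoms$name[miss],
                 "' of residue '", atoms$residue_name[miss], "'"))
  }

  is_water <- atoms$residue_name %in% water_residues
  role <- params$role[hit]
  if (any(is_water & role == "solute")) {
    warn("water residue carries a 'solute' role in the parameter table")
  }

  # new molecule whenever (residue_id, residue_name) changes along the file
  runs <- paste(atoms$residue_id, atoms$residue_name)
  molecule_id <- cumsum(c(TRUE, runs[-1] != runs[-length(runs)]))

  topology <- tibble(
    index = seq_len(nrow(atoms)),
    name = atoms$name,
    residue_name = atoms$residue_name,
    residue_id = atoms$residue_id,
    element = infer_element(atoms$name, atoms$element),
    charge = params$charge[hit],
    lj_sigma = params$sigma[hit],
    lj_epsilon = params$epsilon[hit],
    molecule_id = molecule_id,
    role = role
  )
  validate_topology(topology)

  cl <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cl) > 0) unname(parse_cryst1(cl[1])) else NULL
  list(topology = topology,
       coords = unname(as.matrix(atoms[, c("x", "y", "z")])),
       box = box)
}

validate_topology <- function(topology) {
  solv <- topology[topology$role != "solute", ]
  if (nrow(solv) > 0) {
    n_ox <- tapply(solv$role == "solvent_oxygen", solv$molecule_id, sum)
    if (any(n_ox != 1)) {
      abort("every solvent molecule must contain exactly one solvent_oxygen")
    }
    qs <- tapply(solv$charge, solv$molecule_id, sum)
    if (any(abs(qs) > 1e-6)) {
      abort("solvent molecule charges must sum to 0 (within 1e-6 e)")
    }
  }
  if (any(topology$lj_sigma < 0) || any(topology$lj_epsilon < 0)) {
    abort("lj_sigma and lj_epsilon must be >= 0")
  }
  invisible(topology)
}

#' Assemble a trajectory object
#'
#' A trajectory bundles one topology with an ordered stack of frames. Frames
#' share the topology; coordinates are in Angstrom and boxes are orthorhombic
#' box lengths per frame.
#'
#' @param topology Topology tibble (see [read_topology()]).
#' @param coords Numeric array `n_atoms x 3 x n_frames` (a single `n x 3`
#'   matrix is promoted to one frame).
#' @param box Numeric length-3 vector (constant box) or `n_frames x 3` matrix.
#' @param frame_interval Time between frames, ps (metadata only).
#' @param frame_index Optional strictly increasing integer frame labels.
#' @return A `cav_trajectory` object.
#' @export
trajectory <- function(topology, coords, box, frame_interval = 1,
                       frame_index = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology)) {
    abort("coordinate count does not match topology atom count")
  }
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (any(box <= 0)) abort("box lengths must be > 0")
  if (is.null(frame_index)) frame_index <- seq_len(nf)
  if (any(diff(frame_index) <= 0)) abort("frame_index must be strictly increasing")
  structure(list(topology = topology, coords = coords, box = box,
                 frame_index = as.integer(frame_index),
                 frame_interval = frame_interval),
            class = "cav_trajectory")
}

#' @export
print.cav_trajectory <- function(x, ...) {
  nw <- sum(x$topology$role == "solvent_oxygen")
  cat(sprintf("<cav_trajectory> %d atoms (%d waters), %d frames, box %s A\n",
              nrow(x$topology), nw, n_frames(x),
              paste(sprintf("%.2f", x$box[1, ]), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `cav_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory A `cav_trajectory`.
#' @param frame Frame position (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(trajectory, frame) trajectory$coords[, , frame, drop = TRUE]

# index bookkeeping shared by the kernels: oxygen rows, per-water atom rows,
# solute rows. Waters must all have the same atom count.
water_index <- function(topology) {
  o_rows <- which(topology$role == "solvent_oxygen")
  solute_rows <- which(topology$role == "solute")
  if (length(o_rows) == 0) {
    return(list(o_rows = integer(), watoms = matrix(integer(), 0, 0),
                solute_rows = solute_rows))
  }
  wmol <- topology$molecule_id[o_rows]
  rows_by_mol <- split(which(topology$role != "solute"),
                       topology$molecule_id[topology$role != "solute"])
  rows_by_mol <- rows_by_mol[as.character(wmol)]
  k <- lengths(rows_by_mol)
  if (length(unique(k)) != 1) {
    abort("all solvent molecules must have the same number of atoms")
  }
  watoms <- do.call(rbind, rows_by_mol)
  list(o_rows = o_rows, watoms = watoms, solute_rows = solute_rows,
       water_molecule = wmol)
}

#' Convert a trajectory to a long tibble of coordinates
#'
#' @param x A `cav_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per (frame, atom): frame, index, name,
#'   residue_name, residue_id, role, x, y, z.
#' @export
tidy.cav_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$topology)
  tibble(
    frame = rep(x$frame_index, each = na),
    index = rep(x$topology$index, nf),
    name = rep(x$topology$name, nf),
    residue_name = rep(x$topology$residue_name, nf),
    residue_id = rep(x$topology$residue_id, nf),
    role = rep(x$topology$role, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}

pdb_atom_line <- function(serial, name, resname, resid, xyz, element) {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, resname, resid %% 10000,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

pdb_cryst1 <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1], box[2], box[3], 90, 90, 90)
}

#' Write a trajectory as a multi-model PDB
#'
#' Each frame is one MODEL; the per-frame box is written as a CRYST1 record
#' immediately before each MODEL record.
#'
#' @param trajectory A `cav_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  top <- trajectory$topology
  nf <- n_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    X <- frame_coords(trajectory, f)
    writeLines(pdb_cryst1(trajectory$box[f, ]), con)
    writeLines(sprintf("MODEL     %4d", trajectory$frame_index[f]), con)
    lines <- vapply(seq_len(nrow(top)), function(i) {
      pdb_atom_line(top$index[i], top$name[i], top$residue_name[i],
                    top$residue_id[i], X[i, ], top$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single structure as a PDB file
#'
#' @param topology Topology tibble.
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param path Output path.
#' @param box Optional box lengths for a CRYST1 record.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, coords, path, box = NULL) {
  tr <- trajectory(topology, coords, box %||% c(1e6, 1e6, 1e6))
  if (is.null(box)) {
    top <- topology
    lines <- vapply(seq_len(nrow(top)), function(i) {
      pdb_atom_line(top$index[i], top$name[i], top$residue_name[i],
                    top$residue_id[i], coords[i, ], top$element[i])
    }, character(1))
    writeLines(c(lines, "END"), path)
    return(invisible(path))
  }
  writeLines(c(pdb_cryst1(box),
               vapply(seq_len(nrow(topology)), function(i) {
                 pdb_atom_line(topology$index[i], topology$name[i],
                               topology$residue_name[i], topology$residue_id[i],
                               coords[i, ], topology$element[i])
               }, character(1)), "END"), path)
  invisible(path)
}

#' Read trajectory frames from a multi-model PDB
#'
#' Reads the dialect written by [write_trajectory_pdb()]: one MODEL per frame
#' with a CRYST1 record per frame (a single leading CRYST1 is also accepted
#' and reused for every frame).
#'
#' @param path Path to the multi-model PDB.
#' @param topology Topology tibble the frames refer to.
#' @param frame_interval Time between frames, ps.
#' @return A `cav_trajectory`.
#' @export
read_trajectory_pdb <- function(path, topology, frame_interval = 1) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  crysts <- grep("^CRYST1", lines)
  if (length(starts) == 0) { starts <- 1; ends <- length(lines) }
  if (length(starts) != length(ends)) abort("unbalanced MODEL/ENDMDL records")
  nf <- length(starts)
  na <- nrow(topology)
  coords <- array(NA_real_, c(na, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  frame_index <- integer(nf)
  for (f in seq_len(nf)) {
    blk <- lines[starts[f]:ends[f]]
    atoms <- parse_pdb_atoms(blk, path)
    if (nrow(atoms) != na) {
      abort(sprintf("frame %d has %d atoms; topology has %d", f, nrow(atoms), na))
    }
    coords[, , f] <- as.matrix(atoms[, c("x", "y", "z")])
    prev <- crysts[crysts < starts[f]]
    if (length(prev) == 0) abort("no CRYST1 box record preceding a MODEL")
    box[f, ] <- parse_cryst1(lines[max(prev)])
    mi <- suppressWarnings(as.integer(substr(lines[starts[f]], 11, 14)))
    frame_index[f] <- if (is.na(mi)) f else mi
  }
  trajectory(topology, coords, box, frame_interval, frame_index)
}

#' Read a reference structure (e.g. aligned cocrystal ligand heavy atoms)
#'
#' @param path PDB file with the reference coordinates.
#' @param heavy_only Drop hydrogens (by element).
#' @return Tibble: atom_name, residue_name, residue_id, element, x, y, z.
#' @export
read_reference_pdb <- function(path, heavy_only = TRUE) {
  atoms <- parse_pdb_atoms(readLines(path), path)
  atoms$element <- infer_element(atoms$name, atoms$element)
  if (heavy_only) atoms <- atoms[atoms$element != "H", ]
  tibble(atom_name = atoms$name, residue_name = atoms$residue_name,
         residue_id = atoms$residue_id, element = atoms$element,
         x = atoms$x, y = atoms$y, z = atoms$z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
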