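# shared fixtures and independent oracles

# --- minimum image by explicit enumeration of the 27 periodic images ---
oracle_min_image <- function(a, b, box) {
  a <- a %% box; b <- b %% box  # reduce into the primary cell first
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

oracle_min_image_vec <- function(a, b, box) {
  # displacement a - b with the smallest norm over the 27 images
  a <- a %% box; b <- b %% box
  best <- NULL; bn <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    n <- sqrt(sum(d * d))
    if (n < bn) { bn <- n; best <- d }
  }
  best
}

# --- independently coded double-loop pair-energy evaluator ---
oracle_pair_energy <- function(A, B, model, box) {
  A <- as.data.frame(A); B <- as.data.frame(B)
  e <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- oracle_min_image(unlist(A[i, c("x", "y", "z")]),
                          unlist(B[j, c("x", "y", "z")]), box)
    if (r > model$cutoff) next
    e <- e + model$coulomb_constant * A$charge[i] * B$charge[j] / r
    if (A$lj_epsilon[i] > 0 && B$lj_epsilon[j] > 0) {
      s <- (A$lj_sigma[i] + B$lj_sigma[j]) / 2
      eps <- sqrt(A$lj_epsilon[i] * B$lj_epsilon[j])
      e <- e + 4 * eps * ((s / r)^12 - (s / r)^6)
    }
  }
  e
}

# per-frame atom table (topology + coordinates of one frame)
frame_atoms <- function(traj, f) {
  X <- frame_coords(traj, f)
  cbind(traj$topology, data.frame(x = X[, 1], y = X[, 2], z = X[, 3]))
}

# unique water-pair total plus solute-water total for one frame:
# molecule-based O-O cutoff for water pairs, atom-pair cutoff solute-water
oracle_frame_total <- function(traj, model, f) {
  at <- frame_atoms(traj, f)
  box <- traj$box[f, ]
  omask <- at$role == "solvent_oxygen"
  wmols <- at$molecule_id[omask]
  e <- 0
  nocut <- model; nocut$cutoff <- Inf
  if (length(wmols) > 1) {
    for (i in seq_len(length(wmols) - 1)) for (j in (i + 1):length(wmols)) {
      oi <- at[omask & at$molecule_id == wmols[i], c("x", "y", "z")]
      oj <- at[omask & at$molecule_id == wmols[j], c("x", "y", "z")]
      if (oracle_min_image(unlist(oi), unlist(oj), box) > model$cutoff) next
      e <- e + oracle_pair_energy(at[at$molecule_id == wmols[i] & at$role != "solute", ],
                                  at[at$molecule_id == wmols[j] & at$role != "solute", ],
                                  nocut, box)
    }
  }
  sol <- at[at$role == "solute", ]
  if (nrow(sol) > 0) {
    # solute atoms are gated on their distance to the water OXYGEN; the
    # water molecule is never split at the cutoff
    for (m in wmols) {
      wat <- at[at$molecule_id == m & at$role != "solute", ]
      o <- unlist(wat[wat$role == "solvent_oxygen", c("x", "y", "z")])
      for (s in seq_len(nrow(sol))) {
        if (oracle_min_image(o, unlist(sol[s, c("x", "y", "z")]), box) >
            model$cutoff) next
        e <- e + oracle_pair_energy(wat, sol[s, , drop = FALSE], nocut, box)
      }
    }
  }
  e
}

# --- brute-force hydrogen-bond oracle (all donor-H x acceptor triples) ---
oracle_hbonds <- function(traj, f, dist_max = 3.6, angle_max = 30,
                          convention = "acceptor_donor_hydrogen",
                          polar = c("N", "O", "S")) {
  at <- frame_atoms(traj, f)
  box <- traj$box[f, ]
  X <- as.matrix(at[, c("x", "y", "z")])
  heavy <- which(at$element %in% polar & at$role != "solvent_virtual")
  hyd <- which(at$element == "H")
  pairs <- NULL
  for (h in hyd) {
    cand <- heavy[at$molecule_id[heavy] == at$molecule_id[h]]
    if (length(cand) == 0) next
    dd <- vapply(cand, function(d) sqrt(sum((X[d, ] - X[h, ])^2)), 0)
    if (min(dd) <= 1.25) pairs <- rbind(pairs, c(cand[which.min(dd)], h))
  }
  out <- NULL
  for (p in seq_len(NROW(pairs))) {
    d <- pairs[p, 1]; h <- pairs[p, 2]
    for (a in heavy) {
      if (a == d || at$molecule_id[a] == at$molecule_id[d]) next
      v_da <- oracle_min_image_vec(X[a, ], X[d, ], box)
      if (sqrt(sum(v_da^2)) >= dist_max) next
      if (convention == "acceptor_donor_hydrogen") {
        v_dh <- oracle_min_image_vec(X[h, ], X[d, ], box)
        ang <- acos(sum(v_da * v_dh) /
                      (sqrt(sum(v_da^2)) * sqrt(sum(v_dh^2)))) * 180 / pi
      } else {
        v_hd <- oracle_min_image_vec(X[d, ], X[h, ], box)
        v_ha <- oracle_min_image_vec(X[a, ], X[h, ], box)
        ang <- 180 - acos(sum(v_hd * v_ha) /
                            (sqrt(sum(v_hd^2)) * sqrt(sum(v_ha^2)))) * 180 / pi
      }
      if (ang < angle_max) out <- rbind(out, c(d, h, a))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 3) else out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# --- independent minimal OpenDX parser (z varies fastest) ---
oracle_read_dx <- function(path) {
  ln <- readLines(path)
  counts <- as.integer(strsplit(sub(".*counts +", "", ln[grep("gridpositions", ln)[1]]), " +")[[1]])
  origin <- as.numeric(strsplit(sub("origin +", "", ln[grep("^origin", ln)[1]]), " +")[[1]])
  delta <- as.numeric(strsplit(sub("delta +", "", ln[grep("^delta", ln)[1]]), " +")[[1]])[1]
  i0 <- grep("data follows", ln)[1]
  i1 <- grep("^attribute", ln)[1] - 1
  vals <- as.numeric(unlist(strsplit(trimws(ln[(i0 + 1):i1]), " +")))
  arr <- array(NA_real_, counts)
  n <- 0
  for (i in seq_len(counts[1])) for (j in seq_len(counts[2])) for (k in seq_len(counts[3])) {
    n <- n + 1
    arr[i, j, k] <- vals[n]
  }
  list(counts = counts, origin = origin, spacing = delta, values = arr)
}

# --- small topology/trajectory builders ---

# a zero-interaction variant of a trajectory's topology (ideal-gas analysis)
strip_interactions <- function(traj) {
  traj$topology$charge <- 0
  traj$topology$lj_epsilon <- 0
  traj
}

ideal_model <- function(cutoff = 9) {
  interaction_model(cutoff = cutoff, e_neat = 0, rho0 = 0.0334)
}

# a tiny solute: one LJ/charged atom at a position
point_solute <- function(xyz, charge = 0, sigma = 3.4, epsilon = 0.086,
                         name = "CS1", element = "C") {
  topology <- tibble::tibble(index = 1L, name = name, residue_name = "LIG",
                             residue_id = 1L, element = element,
                             charge = charge, lj_sigma = sigma,
                             lj_epsilon = epsilon, molecule_id = 1L,
                             role = "solute")
  structure(list(topology = topology, coords = matrix(xyz, 1, 3),
                 acceptor_atoms = integer(0), enclosure = "open",
                 acceptor_separation = NA), class = "cav_solute")
}

# trajectory with explicit water positions/orientations (identical each frame
# unless `coords_by_frame` given); positions = n x 3 oxygen positions
waters_at <- function(positions, box, n_frames = 1, solute = NULL,
                      jitter = 0) {
  n <- nrow(positions)
  top <- cavsolv:::make_water_topology(n, solute)
  ns <- if (is.null(solute)) 0 else nrow(solute$topology)
  coords <- array(NA_real_, c(ns + 3 * n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    pos <- positions + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    wat <- cavsolv:::assemble_waters(pos)
    coords[, , f] <- rbind(if (is.null(solute)) NULL else solute$coords, wat)
  }
  trajectory(top, coords, box)
}

# write the packaged synthetic parameter table (plus optional solute rows)
write_params_fixture <- function(path, solute = NULL) {
  tab <- cavsolv:::water_param_rows()
  if (!is.null(solute)) {
    st <- solute$topology
    tab <- rbind(data.frame(residue_name = st$residue_name,
                            atom_name = st$name, charge = st$charge,
                            sigma = st$lj_sigma, epsilon = st$lj_epsilon,
                            role = st$role), as.data.frame(tab))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
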