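#' Read functional-group definitions from a TSV file
#'
#' Columns: `label`, `residue_id`, `atom_names` (comma-separated heavy-atom
#' names), `capability`. Donor hydrogens are located from the coordinates
#' (hydrogens of the same molecule within 1.25 A of a group atom).
#'
#' @param path TSV path.
#' @param topology Topology tibble.
#' @param coords `n x 3` coordinates used to attach hydrogens.
#' @return List of [functional_group()] objects.
#' @export
read_groups_tsv <- function(path, topology, coords) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    names_i <- trimws(strsplit(tab$atom_names[i], ",")[[1]])
    atoms <- which(topology$residue_id == tab$residue_id[i] &
                     topology$name %in% names_i)
    if (length(atoms) == 0) {
      abort(paste0("group '", tab$label[i], "': no matching atoms"))
    }
    hyd <- which(topology$element == "H" &
                   topology$molecule_id %in% topology$molecule_id[atoms])
    dh <- hyd[vapply(hyd, function(h) {
      any(sqrt(rowSums((coords[atoms, , drop = FALSE] -
                          matrix(coords[h, ], length(atoms), 3,
                                 byrow = TRUE))^2)) <= 1.25)
    }, logical(1))]
    functional_group(tab$label[i], atoms, dh, tab$capability[i])
  })
}

pipeline_require <- function(config, keys, stage) {
  for (k in keys) {
    if (is.null(config[[k]])) {
      abort(paste0("[", stage, "] missing required input '", k, "'"))
    }
    if (is.character(config[[k]]) && grepl("\\.(pdb|tsv|yaml|yml)$", config[[k]]) &&
        !file.exists(config[[k]])) {
      abort(paste0("[", stage, "] input file not found: '", k, "' = ",
                   config[[k]]))
    }
  }
}

#' Run the full solvation-mapping pipeline on a rigid/flexible pair
#'
#' Orchestrates energetics, grid accumulation, hydrogen-bond mapping,
#' hydration-site analysis, subvolume integration with block errors, and the
#' rigid-vs-flexible comparison; writes OpenDX grids, TSV tables, site PDBs
#' and a run log of all resolved parameters.
#'
#' @param config A named list or path to a YAML file with keys: `topology`
#'   (PDB), `params` (TSV), `rigid` and `flexible` (multi-model PDB
#'   trajectories), `ligand` (PDB of reference ligand heavy atoms),
#'   `out_dir`, and optional `grid` (origin/shape/spacing), `model`,
#'   `criteria`, `distances`, `n_blocks`, `hsa`, `groups` blocks.
#' @return Invisibly, a list with the comparison report, per-system
#'   integrated profiles, hydration sites, and (if requested) group stats.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  pipeline_require(config, c("topology", "params", "rigid", "flexible",
                             "ligand", "out_dir"), "setup")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  topo <- read_topology(config$topology, config$params)
  ligand <- read_reference_pdb(config$ligand)
  model <- do.call(interaction_model, config$model %||% list())
  criteria <- do.call(hbond_criteria, config$criteria %||% list())
  n_blocks <- config$n_blocks %||% 4
  distances <- config$distances %||% seq(3, 10, 0.5)

  systems <- list(
    rigid = read_trajectory_pdb(config$rigid, topo$topology),
    flexible = read_trajectory_pdb(config$flexible, topo$topology))

  spec <- if (!is.null(config$grid)) {
    grid_spec(config$grid$origin, config$grid$shape,
              config$grid$spacing %||% 0.5)
  } else {
    grid_spec_for_box(systems$rigid$box[1, ], 0.5)
  }

  results <- list()
  profiles <- list()
  blocks <- list()
  for (sys in names(systems)) {
    tr <- systems[[sys]]
    grid <- gist_finalize(gist_accumulate(tr, model, spec, criteria), model)
    for (field in c("g", "e_per_frame", "hb_sw_per_frame")) {
      write_dx(grid, field, file.path(config$out_dir,
                                      paste0(sys, "_", field, ".dx")))
    }
    prof <- dplyr::bind_rows(lapply(distances, function(d) {
      vox <- select_voxels(grid, subvolume_spec(ligand, d))
      dplyr::mutate(integrate_subvolume(grid, vox), distance = d,
                    system = sys, .before = 1)
    }))
    profiles[[sys]] <- prof
    # block errors at the widest distance (the cavity subvolume)
    blocks[[sys]] <- integrate_blocks(tr, model, spec,
                                      subvolume_spec(ligand, max(distances)),
                                      criteria, n_blocks)
    hsa_cfg <- config$hsa %||% list()
    sites <- find_sites(tr, model,
                        region = subvolume_spec(ligand, hsa_cfg$distance %||%
                                                  max(distances)),
                        min_occupancy_ratio = hsa_cfg$min_occupancy_ratio %||% 2)
    sites <- site_thermo(sites, tr, model, criteria)
    write_sites(sites, file.path(config$out_dir, paste0("sites_", sys, ".pdb")))
    results[[sys]] <- list(grid = grid, sites = sites)
    if (!is.null(config$groups)) {
      gr <- read_groups_tsv(config$groups, topo$topology, topo$coords)
      gs <- group_stats(tr, gr, criteria,
                        config$neighbor_cutoff %||% 3.6)
      write.table(gs, file.path(config$out_dir, paste0("groups_", sys, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results[[sys]]$group_stats <- gs
    }
  }

  profile <- dplyr::bind_rows(profiles)
  write.table(profile, file.path(config$out_dir, "subvolume_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- compare_integrated(blocks$rigid, blocks$flexible)
  write.table(tidy(comparison), file.path(config$out_dir, "table1_totals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log <- list(model = unclass(model), criteria = unclass(criteria),
              grid = list(origin = spec$origin, shape = spec$shape,
                          spacing = spec$spacing),
              distances = distances, n_blocks = n_blocks,
              inputs = config[c("topology", "params", "rigid", "flexible",
                                "ligand")])
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))

  invisible(list(comparison = comparison, profile = profile,
                 blocks = blocks, systems = results))
}
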