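#' Trajectory sets: multi-run coordinate ensembles with chain roles
#'
#' A `trajectory_set` bundles one shared atom topology with one or more runs of
#' frame coordinates, plus a mapping from chain identifiers to their role in
#' the complex (`"inhibitor"`, `"protease"`, or `"other"`). It is the substrate
#' of all structural statistics in the package: hydrogen-bond occupancy
#' analysis and binding-loop rigidity profiles.
#'
#' @param topology A data frame with one row per atom and columns `serial`,
#'   `name`, `element`, `residue_number`, `residue_name`, `chain_id`.
#' @param runs A list of numeric arrays, one per run, each of dimension
#'   `c(n_atoms, 3, n_frames)` holding coordinates in Angstrom.
#' @param chain_roles Named character vector mapping chain id to role, e.g.
#'   `c(I = "inhibitor", E = "protease")`. Chains not listed are `"other"`.
#'
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(topology, runs, chain_roles = character()) {
  topology <- as_tibble(topology)
  required <- c("serial", "name", "element", "residue_number", "residue_name",
                "chain_id")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0) {
    abort(paste0("topology is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  key <- paste(topology$chain_id, topology$residue_number, topology$name)
  if (anyDuplicated(key)) {
    abort("topology has duplicate (chain_id, residue_number, name) atoms")
  }
  if (!is.list(runs) || length(runs) < 1) {
    abort("`runs` must be a non-empty list of coordinate arrays")
  }
  n_atoms <- nrow(topology)
  runs <- lapply(runs, function(xyz) {
    xyz <- as_coord_array(xyz, n_atoms)
    if (!all(is.finite(xyz))) abort("coordinates must be finite")
    xyz
  })
  if (length(chain_roles) > 0 &&
      !all(chain_roles %in% c("inhibitor", "protease", "other"))) {
    abort("chain roles must be one of 'inhibitor', 'protease', 'other'")
  }
  structure(
    list(topology = topology, runs = runs, chain_roles = chain_roles),
    class = "trajectory_set"
  )
}

as_coord_array <- function(xyz, n_atoms) {
  if (is.matrix(xyz)) {
    # a single frame as an n x 3 matrix
    xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  }
  if (!is.array(xyz) || length(dim(xyz)) != 3L || dim(xyz)[2] != 3L) {
    abort("each run must be an array of dimension (n_atoms, 3, n_frames)")
  }
  if (dim(xyz)[1] != n_atoms) {
    abort("run coordinate array does not match the topology atom count")
  }
  xyz
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d atoms, %d run(s) x %d frame(s)\n",
    nrow(x$topology), n_runs(x), n_frames(x)
  ))
  chains <- unique(x$topology$chain_id)
  roles <- vapply(chains, function(ch) chain_role(x, ch), character(1))
  cat("  chains:", paste(sprintf("%s (%s)", chains, roles), collapse = ", "),
      "\n")
  invisible(x)
}

#' Trajectory dimensions
#'
#' @param traj A [trajectory_set()].
#' @return An integer count.
#' @export
n_runs <- function(traj) length(traj$runs)

#' @rdname n_runs
#' @export
n_frames <- function(traj) dim(traj$runs[[1]])[3]

#' @rdname n_runs
#' @export
n_atoms <- function(traj) nrow(traj$topology)

chain_role <- function(traj, chain_id) {
  role <- traj$chain_roles[chain_id]
  ifelse(is.na(role), "other", unname(role))
}

#' Assign chain roles on an existing trajectory
#'
#' @param traj A [trajectory_set()].
#' @param inhibitor,protease Chain id(s) carrying each role.
#' @return The trajectory with updated `chain_roles`.
#' @export
set_chain_roles <- function(traj, inhibitor, protease = character()) {
  roles <- c(
    setNames(rep("inhibitor", length(inhibitor)), inhibitor),
    setNames(rep("protease", length(protease)), protease)
  )
  known <- unique(traj$topology$chain_id)
  unknown <- setdiff(names(roles), known)
  if (length(unknown) > 0) {
    abort(paste0("chains not present in topology: ",
                 paste(unknown, collapse = ", ")))
  }
  traj$chain_roles <- roles
  traj
}

#' Combine single-run trajectories into a replicate set
#'
#' All runs must share an identical topology (same atoms in the same order).
#'
#' @param ... `trajectory_set` objects.
#' @return A `trajectory_set` whose runs are the concatenated runs.
#' @export
bind_runs <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1 && is.list(trajs[[1]]) &&
      !inherits(trajs[[1]], "trajectory_set")) {
    trajs <- trajs[[1]]
  }
  if (length(trajs) == 0) abort("no trajectories supplied")
  ref <- trajs[[1]]
  for (tr in trajs[-1]) {
    if (!identical(ref$topology[c("name", "residue_number", "chain_id")],
                   tr$topology[c("name", "residue_number", "chain_id")])) {
      abort("all runs must share one topology")
    }
  }
  roles <- ref$chain_roles
  trajectory_set(ref$topology, unlist(lapply(trajs, `[[`, "runs"),
                                      recursive = FALSE), roles)
}

#' Read a multi-model PDB file as a single-run trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records is read
#' as a single frame. Coordinates are in Angstrom and residue numbering is
#' preserved as written (1-based, as in the PDB). The first alternate location
#' is kept; insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @param inhibitor,protease Optional chain id(s) to label with roles.
#' @return A single-run [trajectory_set()].
#' @export
read_multimodel_pdb <- function(path, inhibitor = NULL, protease = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  atom <- pdb$atom
  element <- atom$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(atom))
  element <- ifelse(is.na(element) | element == "",
                    guess_element(atom$elety), element)
  chain <- ifelse(is.na(atom$chain), " ", atom$chain)
  topology <- tibble(
    serial = atom$eleno,
    name = atom$elety,
    element = trimws(element),
    residue_number = atom$resno,
    residue_name = atom$resid,
    chain_id = chain
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_fr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(topology), 3L, n_fr))
  for (f in seq_len(n_fr)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  traj <- trajectory_set(topology, list(coords))
  if (!is.null(inhibitor)) {
    traj <- set_chain_roles(traj, inhibitor, protease %||% character())
  }
  traj
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed ATOM record at line %d: too short", i))
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(coords)) {
      abort(sprintf("malformed ATOM record at line %d: non-numeric coordinates",
                    i))
    }
    if (substr(ln, 27, 27) != " ") {
      abort(sprintf("insertion codes are not supported (line %d)", i))
    }
  }
  # topology consistency: every MODEL block must contain the same atom count
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_of <- findInterval(idx, model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts)) != 1) {
      abort("inconsistent atom sets across MODEL blocks")
    }
  }
  invisible(TRUE)
}

guess_element <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  first <- substr(stripped, 1, 1)
  # two-letter elements common in PDB protein records
  ifelse(substr(stripped, 1, 2) %in% c("CL", "NA", "MG", "ZN", "FE", "SE"),
         substr(stripped, 1, 2), first)
}

#' Write a single-run trajectory as a multi-model PDB file
#'
#' One MODEL block per frame, standard fixed-column ATOM records, coordinates
#' rounded to 3 decimals. Multi-run sets must be written one run per file.
#'
#' @param traj A single-run [trajectory_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (!inherits(traj, "trajectory_set")) abort("`traj` must be a trajectory_set")
  if (n_runs(traj) > 1) {
    abort("trajectory has multiple runs; write one file per run")
  }
  if (n_frames(traj) < 1 || n_atoms(traj) < 1) abort("empty trajectory")
  coords <- traj$runs[[1]]
  if (any(abs(coords) > 9999.999)) {
    abort("coordinate magnitude exceeds the PDB field width (|x| > 9999.999)")
  }
  n_fr <- dim(coords)[3]
  xyz <- t(vapply(seq_len(n_fr),
                  function(f) as.vector(t(coords[, , f])),
                  numeric(3L * n_atoms(traj))))
  top <- traj$topology
  bio3d::write.pdb(
    file = path, xyz = xyz,
    eleno = top$serial, elety = top$name, resid = top$residue_name,
    chain = top$chain_id, resno = top$residue_number, elesy = top$element
  )
  invisible(path)
}

#' Extract coordinates of one frame
#'
#' @param traj A [trajectory_set()].
#' @param run,frame 1-based run and frame indices.
#' @return An `n_atoms` x 3 matrix.
#' @export
frame_coords <- function(traj, run = 1, frame = 1) {
  if (run < 1 || run > n_runs(traj)) abort("run index out of range")
  if (frame < 1 || frame > n_frames(traj)) abort("frame index out of range")
  m <- traj$runs[[run]][, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Select C-alpha coordinates of a chain in one frame
#'
#' Returns one coordinate per residue possessing a CA atom, in residue-number
#' order. Residues lacking a CA atom are skipped with a warning.
#'
#' @inheritParams frame_coords
#' @param chain_id Chain to select.
#' @return A matrix with one row per CA atom, rownames = residue numbers.
#' @export
select_calpha <- function(traj, chain_id, run = 1, frame = 1) {
  idx <- calpha_indices(traj, chain_id)
  coords <- frame_coords(traj, run, frame)[idx, , drop = FALSE]
  rownames(coords) <- traj$topology$residue_number[idx]
  coords
}

calpha_indices <- function(traj, chain_id) {
  top <- traj$topology
  in_chain <- top$chain_id == chain_id
  if (!any(in_chain)) abort(paste0("chain not found: ", chain_id))
  is_ca <- in_chain & top$name == "CA"
  if (!any(is_ca)) abort(paste0("chain ", chain_id, " has no CA atoms"))
  residues <- sort(unique(top$residue_number[in_chain]))
  ca_res <- top$residue_number[is_ca]
  missing <- setdiff(residues, ca_res)
  if (length(missing) > 0) {
    warn(paste0("residues without CA skipped: ",
                paste(missing, collapse = ", ")))
  }
  which(is_ca)[order(ca_res)]
}

#' @export
as_tibble.trajectory_set <- function(x, ...) {
  purrr::map_dfr(seq_len(n_runs(x)), function(r) {
    purrr::map_dfr(seq_len(n_frames(x)), function(f) {
      m <- frame_coords(x, r, f)
      dplyr::mutate(x$topology, run = r, frame = f,
                    x = m[, 1], y = m[, 2], z = m[, 3])
    })
  })
}
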