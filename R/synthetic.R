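#' Deterministic sub-stream seed derivation
#'
#' Hashes a base seed together with any number of labels (run index, variant
#' name, ...) into a reproducible 31-bit seed, so that independent generator
#' sub-streams can be derived per (run, variant) without manual bookkeeping.
#' Identical inputs give identical seeds on every platform.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "\r")
  m <- 2147480009  # prime below 2^31
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

#' Specification of a synthetic two-chain trajectory
#'
#' Describes a toy inhibitor-protease system whose hydrogen bonds are placed
#' by construction rather than physics: a poly-alanine-like backbone for a
#' cyclic-peptide-sized inhibitor chain `I` and a dummy protease chain `E`,
#' with a list of programmed donor-acceptor contacts that are switched on
#' independently each frame with the stated occupancy probability. Defaults
#' mirror the analysed study conditions: a 14-residue inhibitor, three
#' replicate runs of 5000 frames.
#'
#' @param n_residues_inhibitor,n_residues_protease Chain lengths.
#' @param programmed_bonds Data frame with columns `donor_resno`,
#'   `acceptor_resno`, `class` (`"internal"` or `"intermolecular"`), and
#'   `occupancy` in `[0, 1]`. Donors sit on the inhibitor chain; acceptors on
#'   the inhibitor chain for internal bonds and on the protease chain for
#'   intermolecular ones. Acceptor residues must be distinct across bonds (a
#'   carbonyl oxygen can only be in one place per frame).
#' @param n_frames,n_runs Frames per run and number of replicate runs.
#' @param jitter_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Base seed; all runs derive sub-streams from it.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues_inhibitor = 14,
                            n_residues_protease = 20,
                            programmed_bonds = NULL,
                            n_frames = 5000, n_runs = 3,
                            jitter_sigma = 0.05, seed = 1) {
  if (n_frames < 1 || n_runs < 1) abort("n_frames and n_runs must be >= 1")
  if (is.null(programmed_bonds)) {
    programmed_bonds <- tibble(donor_resno = integer(),
                               acceptor_resno = integer(),
                               class = character(), occupancy = numeric())
  }
  programmed_bonds <- as_tibble(programmed_bonds)
  check_cols(programmed_bonds,
             c("donor_resno", "acceptor_resno", "class", "occupancy"))
  if (nrow(programmed_bonds) > 0) {
    if (!all(programmed_bonds$class %in% c("internal", "intermolecular"))) {
      abort("bond class must be 'internal' or 'intermolecular'")
    }
    if (any(programmed_bonds$occupancy < 0 | programmed_bonds$occupancy > 1)) {
      abort("occupancies must be in [0, 1]")
    }
    bad_d <- programmed_bonds$donor_resno > n_residues_inhibitor |
      programmed_bonds$donor_resno < 1
    max_acc <- ifelse(programmed_bonds$class == "internal",
                      n_residues_inhibitor, n_residues_protease)
    bad_a <- programmed_bonds$acceptor_resno > max_acc |
      programmed_bonds$acceptor_resno < 1
    if (any(bad_d) || any(bad_a)) {
      abort("programmed bond references a residue outside the chain")
    }
    acc_key <- paste(ifelse(programmed_bonds$class == "internal", "I", "E"),
                     programmed_bonds$acceptor_resno)
    if (anyDuplicated(acc_key)) {
      abort("acceptor residues must be distinct across programmed bonds")
    }
    same <- programmed_bonds$class == "internal" &
      programmed_bonds$donor_resno == programmed_bonds$acceptor_resno
    if (any(same)) abort("donor and acceptor cannot be the same residue")
  }
  structure(
    list(n_residues_inhibitor = n_residues_inhibitor,
         n_residues_protease = n_residues_protease,
         programmed_bonds = programmed_bonds,
         n_frames = n_frames, n_runs = n_runs,
         jitter_sigma = jitter_sigma, seed = seed),
    class = "trajectory_spec"
  )
}

# Base (bond-free) topology and coordinates for a spec. Residues are spaced
# 6 A along x; the protease chain is offset 25 A in y. Per residue: backbone
# N (donor), its amide H pointing +y, CA, C, and carbonyl O (acceptor) parked
# 3 A off the backbone so no bond is satisfied by default.
synthetic_topology <- function(spec) {
  template <- tibble(
    name = c("N", "H", "CA", "C", "O"),
    element = c("N", "H", "C", "C", "O"),
    dx = c(0, 0, 1.5, 2.6, 2.6),
    dy = c(0, 1.0, 0, 0, -3.0),
    dz = c(0, 0, 0.9, 0.3, 0.5)
  )
  build_chain <- function(chain_id, n_res, y_offset) {
    purrr::map_dfr(seq_len(n_res), function(i) {
      # stagger CA positions so the trace is not collinear (degenerate for
      # least-squares superposition); CA takes no part in bond placement
      ca_kink <- ifelse(template$name == "CA", 1.2 * ((i %% 3) - 1), 0)
      dplyr::mutate(template, residue_number = i, residue_name = "ALA",
                    chain_id = chain_id,
                    x = 6 * i + .data$dx, y = y_offset + .data$dy + ca_kink,
                    z = .data$dz + ca_kink)
    })
  }
  atoms <- dplyr::bind_rows(
    build_chain("I", spec$n_residues_inhibitor, 0),
    build_chain("E", spec$n_residues_protease, 25)
  )
  atoms$serial <- seq_len(nrow(atoms))
  topology <- atoms[c("serial", "name", "element", "residue_number",
                      "residue_name", "chain_id")]
  coords <- as.matrix(atoms[c("x", "y", "z")])
  list(topology = topology, coords = coords)
}

#' Generate a synthetic trajectory with programmed bond occupancies
#'
#' For each programmed bond and frame, with probability equal to the bond's
#' occupancy the acceptor carbonyl oxygen is moved collinear with the donor
#' N-H at a donor-acceptor distance of 2.9 Angstrom (D-H...A = 180 degrees),
#' which satisfies the default detection criteria; otherwise it stays parked
#' more than 5 Angstrom from any donor. Frames are independent; each run uses
#' a seed derived from `(seed, run)`. Gaussian jitter of `jitter_sigma` is
#' then added to every coordinate. The realised per-bond occupancies and
#' per-frame class counts are returned as ground truth so downstream checks
#' never re-derive them.
#'
#' @param spec A [trajectory_spec()].
#' @return A list: `trajectory` (a [trajectory_set()] with chain roles
#'   `I` = inhibitor, `E` = protease) and `truth` (list with tibbles
#'   `bond_occupancy` and `per_frame_counts`).
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  base <- synthetic_topology(spec)
  top <- base$topology
  bonds <- spec$programmed_bonds
  n_b <- nrow(bonds)
  atom_row <- function(chain, resno, name) {
    which(top$chain_id == chain & top$residue_number == resno &
            top$name == name)
  }
  donor_idx <- if (n_b > 0) {
    vapply(seq_len(n_b), function(b) atom_row("I", bonds$donor_resno[b], "N"),
           integer(1))
  } else integer(0)
  acceptor_idx <- if (n_b > 0) {
    vapply(seq_len(n_b), function(b) {
      atom_row(ifelse(bonds$class[b] == "internal", "I", "E"),
               bonds$acceptor_resno[b], "O")
    }, integer(1))
  } else integer(0)

  runs <- vector("list", spec$n_runs)
  occ_truth <- vector("list", spec$n_runs)
  count_truth <- vector("list", spec$n_runs)
  n_at <- nrow(top)
  for (r in seq_len(spec$n_runs)) {
    set.seed(derive_seed(spec$seed, "run", r))
    coords <- array(rep(base$coords, spec$n_frames),
                    dim = c(n_at, 3, spec$n_frames))
    if (n_b > 0) {
      on <- matrix(stats::runif(n_b * spec$n_frames), nrow = n_b) <=
        bonds$occupancy
      for (b in seq_len(n_b)) {
        frames_on <- which(on[b, ])
        if (length(frames_on) > 0) {
          # collinear with the donor N-H (+y): D...A = 2.9 A, angle 180
          coords[acceptor_idx[b], 1, frames_on] <-
            base$coords[donor_idx[b], 1]
          coords[acceptor_idx[b], 2, frames_on] <-
            base$coords[donor_idx[b], 2] + 2.9
          coords[acceptor_idx[b], 3, frames_on] <-
            base$coords[donor_idx[b], 3]
        }
      }
    } else {
      on <- matrix(logical(0), nrow = 0, ncol = spec$n_frames)
    }
    if (spec$jitter_sigma > 0) {
      coords <- coords + stats::rnorm(length(coords), sd = spec$jitter_sigma)
    }
    runs[[r]] <- coords
    occ_truth[[r]] <- dplyr::mutate(bonds, run = r,
                                    realized_occupancy = rowMeans(on))
    count_truth[[r]] <- tibble(
      run = r, frame = seq_len(spec$n_frames),
      internal = colSums(on[bonds$class == "internal", , drop = FALSE]),
      intermolecular = colSums(on[bonds$class == "intermolecular", ,
                                  drop = FALSE])
    )
  }
  traj <- trajectory_set(top, runs,
                         c(I = "inhibitor", E = "protease"))
  list(
    trajectory = traj,
    truth = list(
      bond_occupancy = dplyr::bind_rows(occ_truth),
      per_frame_counts = dplyr::bind_rows(count_truth)
    )
  )
}

#' Generate a panel of variant trajectories
#'
#' One synthetic trajectory per variant with a shared topology; each
#' variant's seed is derived deterministically from the base seed and the
#' variant name, so panels are reproducible regardless of generation order.
#'
#' @param base A [trajectory_spec()] providing everything except occupancies.
#' @param variant_occupancies Named list: variant label -> numeric vector of
#'   occupancies, one per row of `base$programmed_bonds`.
#' @param dir Optional directory; if given, each run of each variant is also
#'   written as `<variant>_run<r>.pdb` plus a `<variant>_truth.json` sidecar.
#' @return A named list of [make_trajectory()] results.
#' @export
make_variant_panel <- function(base, variant_occupancies, dir = NULL) {
  stopifnot(inherits(base, "trajectory_spec"))
  if (length(variant_occupancies) == 0) abort("variant map is empty")
  nms <- names(variant_occupancies)
  if (is.null(nms) || any(nms == "")) abort("variants must be named")
  if (anyDuplicated(nms)) abort("duplicate variant names")
  out <- purrr::imap(variant_occupancies, function(occ, nm) {
    if (length(occ) != nrow(base$programmed_bonds)) {
      abort(paste0("variant '", nm, "' occupancy vector length mismatch"))
    }
    spec <- base
    spec$programmed_bonds$occupancy <- occ
    spec$seed <- derive_seed(base$seed, "variant", nm)
    make_trajectory(spec)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::iwalk(out, function(res, nm) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
      for (r in seq_len(n_runs(res$trajectory))) {
        one <- trajectory_set(res$trajectory$topology,
                              res$trajectory$runs[r],
                              res$trajectory$chain_roles)
        write_multimodel_pdb(one, file.path(dir, sprintf("%s_run%d.pdb",
                                                         safe, r)))
      }
      jsonlite::write_json(res$truth, file.path(dir, paste0(safe,
                                                            "_truth.json")),
                           dataframe = "columns", digits = NA)
    })
  }
  out
}

#' Specification of a simulated kinetic dataset
#'
#' @param model One of `"competitive"`, `"morrison"`, `"slow_binding"`,
#'   `"decay"`.
#' @param true_params Named list of generating parameters; required names per
#'   model: competitive `Vmax, Km_uM, Ki_nM`; morrison
#'   `Ki_nM, enzyme_nM, substrate_uM, Km_uM`; slow_binding
#'   `k_on_M_s, k_off_s, enzyme_nM, inhibitor_nM, substrate_uM, Km_uM, v0`;
#'   decay `A0, t_half`.
#' @param design Named list of design grids: competitive `substrate_uM`,
#'   `inhibitor_nM` (crossed); morrison `inhibitor_nM`; slow_binding
#'   `time_s`; decay `time`.
#' @param noise_sigma Gaussian noise, as a fraction of the uninhibited signal
#'   scale (0 = noiseless).
#' @param seed Seed for the noise stream.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(model, true_params, design, noise_sigma = 0,
                          seed = 1) {
  model <- match.arg(model, c("competitive", "morrison", "slow_binding",
                              "decay"))
  required <- switch(model,
    competitive = list(params = c("Vmax", "Km_uM", "Ki_nM"),
                       design = c("substrate_uM", "inhibitor_nM")),
    morrison = list(params = c("Ki_nM", "enzyme_nM", "substrate_uM", "Km_uM"),
                    design = "inhibitor_nM"),
    slow_binding = list(params = c("k_on_M_s", "k_off_s", "enzyme_nM",
                                   "inhibitor_nM", "substrate_uM", "Km_uM",
                                   "v0"),
                        design = "time_s"),
    decay = list(params = c("A0", "t_half"), design = "time")
  )
  missing_p <- setdiff(required$params, names(true_params))
  if (length(missing_p) > 0) {
    abort(paste0("missing true_params for ", model, ": ",
                 paste(missing_p, collapse = ", ")))
  }
  missing_d <- setdiff(required$design, names(design))
  if (length(missing_d) > 0) {
    abort(paste0("missing design grid(s): ",
                 paste(missing_d, collapse = ", ")))
  }
  if (any(lengths(design[required$design]) == 0)) {
    abort("design grids must be non-empty")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(list(model = model, true_params = true_params, design = design,
                 noise_sigma = noise_sigma, seed = seed),
            class = "kinetics_spec")
}

#' Simulate a kinetic dataset from a known model
#'
#' Evaluates the named model at the design points, adds seeded Gaussian noise
#' scaled to the uninhibited signal, and returns the dataset in the column
#' schema the corresponding fitter reads, together with the generating truth.
#' For the slow-binding model the result is the three-curve design used for
#' dissociation-rate analysis: an uninhibited progress curve, a co-addition
#' curve (substrate and inhibitor added together), and a preformed-complex
#' curve, with `k_obs = k_off + k_on * [I] / (1 + S/Km)` and
#' `vs = v0 * k_off / k_obs`.
#'
#' @param spec A [kinetics_spec()].
#' @param path Optional file path (or directory for `slow_binding`) to write
#'   the dataset(s) as CSV.
#' @return A list `data` (tibble, or named list of the three curve tibbles)
#'   and `truth` (the generating parameters, including derived quantities).
#' @export
make_kinetics <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "kinetics_spec"))
  p <- spec$true_params
  d <- spec$design
  set.seed(derive_seed(spec$seed, "kinetics", spec$model))
  noisy <- function(y, scale) {
    if (spec$noise_sigma == 0) y
    else y + stats::rnorm(length(y), sd = spec$noise_sigma * scale)
  }
  out <- switch(spec$model,
    competitive = {
      grid <- tidyr::expand_grid(substrate_uM = d$substrate_uM,
                                 inhibitor_nM = d$inhibitor_nM)
      v <- competitive_velocity(grid$substrate_uM, grid$inhibitor_nM,
                                p$Vmax, p$Km_uM, p$Ki_nM)
      list(data = dplyr::mutate(grid, velocity = noisy(v, p$Vmax)),
           truth = p)
    },
    morrison = {
      ki_app <- ki_apparent(p$Ki_nM, p$substrate_uM, p$Km_uM)
      fv <- morrison_fraction(p$enzyme_nM, d$inhibitor_nM, ki_app)
      list(data = tibble(inhibitor_nM = d$inhibitor_nM,
                         frac_velocity = noisy(fv, 1)),
           truth = c(p, list(Ki_app_nM = ki_app)))
    },
    slow_binding = {
      I_M <- p$inhibitor_nM * 1e-9
      k_obs <- p$k_off_s + p$k_on_M_s * I_M / (1 + p$substrate_uM / p$Km_uM)
      vs <- p$v0 * p$k_off_s / k_obs
      t <- d$time_s
      scale <- p$v0 * max(t)
      curves <- list(
        uninhibited = tibble(time_s = t, signal = noisy(p$v0 * t, scale)),
        coadd = tibble(time_s = t,
                       signal = noisy(slow_binding_progress(t, p$v0, vs,
                                                            k_obs), scale)),
        preformed = tibble(time_s = t,
                           signal = noisy(slow_binding_progress(t, 0, vs,
                                                                k_obs),
                                          scale))
      )
      list(data = curves, truth = c(p, list(k_obs = k_obs, vs = vs)))
    },
    decay = {
      lambda <- log(2) / p$t_half
      a <- p$A0 * exp(-lambda * d$time)
      list(data = tibble(time = d$time, activity = noisy(a, p$A0)),
           truth = c(p, list(decay_rate = lambda)))
    }
  )
  if (!is.null(path)) {
    if (spec$model == "slow_binding") {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      purrr::iwalk(out$data, function(df, nm) {
        readr::write_csv(df, file.path(path, paste0(nm, ".csv")))
      })
    } else {
      readr::write_csv(out$data, path)
    }
  }
  out
}
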