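#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is accepted when the donor-heavy to acceptor distance is at
#' most `max_da_distance` and, when hydrogens are required, at least one
#' attached hydrogen gives a D-H...A angle within `max_angle_deviation` of
#' linear (i.e. angle >= 180 - max_angle_deviation degrees). The defaults
#' (3.3 Angstrom, 40 degrees) are the cutoffs conventionally used when
#' post-processing explicit-hydrogen MD trajectories.
#'
#' @param max_da_distance Donor-acceptor distance cutoff, Angstrom.
#' @param max_angle_deviation Allowed deviation of D-H...A from linear,
#'   degrees, in (0, 90).
#' @param require_hydrogens If `FALSE`, accept on distance alone. Intended for
#'   hydrogen-free toy structures; summaries produced under this mode are
#'   flagged.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.3, max_angle_deviation = 40,
                           require_hydrogens = TRUE) {
  if (!is.numeric(max_da_distance) || max_da_distance <= 0) {
    abort("max_da_distance must be > 0")
  }
  if (!is.numeric(max_angle_deviation) ||
      max_angle_deviation <= 0 || max_angle_deviation >= 90) {
    abort("max_angle_deviation must be in (0, 90) degrees")
  }
  structure(
    list(max_da_distance = max_da_distance,
         max_angle_deviation = max_angle_deviation,
         require_hydrogens = isTRUE(require_hydrogens)),
    class = "hbond_criteria"
  )
}

#' Classify a hydrogen bond by the roles of its two chains
#'
#' `internal`: both endpoints on an inhibitor chain. `intermolecular`: one
#' endpoint on an inhibitor chain and one on a protease chain. Everything else
#' (protease-protease, solvent, ions) is `other` and excluded from network
#' summaries.
#'
#' @param donor_chain,acceptor_chain Chain ids (vectorised).
#' @param chain_roles Named character vector mapping chain id to role.
#' @return Character vector in `c("internal", "intermolecular", "other")`.
#' @export
classify_bond <- function(donor_chain, acceptor_chain, chain_roles) {
  role_of <- function(ch) {
    r <- chain_roles[ch]
    ifelse(is.na(r), "other", unname(r))
  }
  dr <- role_of(donor_chain)
  ar <- role_of(acceptor_chain)
  dplyr::case_when(
    dr == "inhibitor" & ar == "inhibitor" ~ "internal",
    (dr == "inhibitor" & ar == "protease") |
      (dr == "protease" & ar == "inhibitor") ~ "intermolecular",
    TRUE ~ "other"
  )
}

# Core engine: evaluates the distance+angle predicate for all candidate
# donor/acceptor pairs across the frames of one run. Returns per-bond presence
# counts and per-frame per-class counts. Vectorised over acceptors x frames
# for each donor, so cost is O(n_donors * n_acceptors * n_frames) flops.
hbond_engine_run <- function(coords, roles, criteria) {
  n_fr <- dim(coords)[3]
  donors <- which(roles$is_donor)
  acceptors <- which(roles$is_acceptor)
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(list(bonds = empty_bond_counts(), per_frame = NULL, n_frames = n_fr))
  }
  if (criteria$require_hydrogens) {
    has_h <- donors %in% roles$hydrogen_of
    if (!all(has_h)) {
      bad <- donors[!has_h]
      abort(paste0(
        "require_hydrogens is TRUE but donors lack hydrogens: ",
        paste(sprintf("%s/%d/%s", roles$chain_id[bad],
                      roles$residue_number[bad], roles$name[bad]),
              collapse = ", ")
      ))
    }
  }
  cos_cut <- cos((180 - criteria$max_angle_deviation) * pi / 180)
  d_cut2 <- criteria$max_da_distance^2

  res_id <- paste(roles$chain_id, roles$residue_number)
  class_counts <- matrix(0L, nrow = 3, ncol = n_fr,
                         dimnames = list(c("internal", "intermolecular",
                                           "other"), NULL))
  chain_roles <- attr(roles, "chain_roles")
  out <- vector("list", length(donors))

  for (di in seq_along(donors)) {
    d <- donors[di]
    keep <- acceptors[res_id[acceptors] != res_id[d]]
    if (length(keep) == 0) next
    A <- coords[keep, , , drop = FALSE]           # nA x 3 x F
    D <- coords[d, , , drop = FALSE]              # 1 x 3 x F
    axis <- function(arr, k) matrix(arr[, k, ], nrow = dim(arr)[1])
    dvec <- function(k) as.vector(D[1, k, ])
    dx <- sweep(axis(A, 1), 2, dvec(1))
    dy <- sweep(axis(A, 2), 2, dvec(2))
    dz <- sweep(axis(A, 3), 2, dvec(3))
    present <- (dx * dx + dy * dy + dz * dz) <= d_cut2

    if (criteria$require_hydrogens && any(present)) {
      hyds <- which(roles$hydrogen_of == d)
      angle_ok <- matrix(FALSE, nrow = length(keep), ncol = n_fr)
      for (h in hyds) {
        H <- matrix(coords[h, , ], nrow = 3)      # 3 x F
        u1 <- dvec(1) - H[1, ]; u2 <- dvec(2) - H[2, ]
        u3 <- dvec(3) - H[3, ]
        ulen <- sqrt(u1^2 + u2^2 + u3^2)
        v1 <- sweep(axis(A, 1), 2, H[1, ])
        v2 <- sweep(axis(A, 2), 2, H[2, ])
        v3 <- sweep(axis(A, 3), 2, H[3, ])
        dot <- sweep(v1, 2, u1, `*`) + sweep(v2, 2, u2, `*`) +
          sweep(v3, 2, u3, `*`)
        vlen <- sqrt(v1^2 + v2^2 + v3^2)
        cosang <- dot / sweep(vlen, 2, ulen, `*`)
        angle_ok <- angle_ok | (cosang <= cos_cut)
      }
      present <- present & angle_ok
    }

    n_present <- rowSums(present)
    hit <- which(n_present > 0)
    if (length(hit) > 0) {
      acc_hit <- keep[hit]
      cls <- classify_bond(rep(roles$chain_id[d], length(acc_hit)),
                           roles$chain_id[acc_hit], chain_roles)
      for (ci in seq_along(hit)) {
        class_counts[cls[ci], ] <- class_counts[cls[ci], ] +
          as.integer(present[hit[ci], ])
      }
      out[[di]] <- tibble(
        donor_chain = roles$chain_id[d],
        donor_resno = roles$residue_number[d],
        donor_atom = roles$name[d],
        acceptor_chain = roles$chain_id[acc_hit],
        acceptor_resno = roles$residue_number[acc_hit],
        acceptor_atom = roles$name[acc_hit],
        bond_class = cls,
        n_present = n_present[hit]
      )
    }
  }
  bonds <- dplyr::bind_rows(out)
  if (nrow(bonds) == 0) bonds <- empty_bond_counts()
  list(bonds = bonds, per_frame = class_counts, n_frames = n_fr)
}

empty_bond_counts <- function() {
  tibble(donor_chain = character(), donor_resno = integer(),
         donor_atom = character(), acceptor_chain = character(),
         acceptor_resno = integer(), acceptor_atom = character(),
         bond_class = character(), n_present = numeric())
}

prepare_roles <- function(traj, roles) {
  if (is.null(roles)) roles <- assign_roles(traj)
  if (!"inhibitor" %in% traj$chain_roles) {
    abort("no chain labelled 'inhibitor'; call set_chain_roles() first")
  }
  attr(roles, "chain_roles") <- traj$chain_roles
  roles
}

#' Detect hydrogen bonds in a single frame
#'
#' Applies the geometric criteria to every donor/acceptor pair of the frame.
#' One bond key is emitted per (donor-heavy, acceptor) pair regardless of how
#' many hydrogens satisfy the angular test; pairs within one residue are
#' excluded.
#'
#' @param traj A [trajectory_set()] with chain roles assigned.
#' @param run,frame 1-based indices of the frame to analyse.
#' @param criteria An [hbond_criteria()].
#' @param roles Optional precomputed [assign_roles()] table.
#' @return A tibble with one row per detected bond: donor and acceptor
#'   (chain, residue number, atom name) and `bond_class`.
#' @export
detect_hbonds_frame <- function(traj, run = 1, frame = 1,
                                criteria = hbond_criteria(), roles = NULL) {
  roles <- prepare_roles(traj, roles)
  coords <- traj$runs[[run]][, , frame, drop = FALSE]
  res <- hbond_engine_run(coords, roles, criteria)
  dplyr::select(res$bonds, -"n_present")
}

#' Per-bond occupancy over the frames of each run
#'
#' Occupancy is the fraction of frames in which a directed (donor-heavy,
#' acceptor) pair satisfies the geometric criteria. Bonds never observed are
#' absent from the result (their occupancy is 0).
#'
#' @inheritParams detect_hbonds_frame
#' @param burn_in Number of initial frames per run to discard before
#'   computing occupancies (default 0: all saved frames are analysed).
#' @return A tibble with one row per (run, bond): the key columns,
#'   `bond_class`, `run`, `n_frames`, `n_present`, `occupancy`.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(), roles = NULL,
                            burn_in = 0) {
  roles <- prepare_roles(traj, roles)
  if (n_frames(traj) - burn_in < 1) abort("no frames left after burn-in")
  purrr::map_dfr(seq_len(n_runs(traj)), function(r) {
    coords <- traj$runs[[r]]
    if (burn_in > 0) {
      coords <- coords[, , -seq_len(burn_in), drop = FALSE]
    }
    res <- hbond_engine_run(coords, roles, criteria)
    dplyr::mutate(res$bonds, run = r, n_frames = res$n_frames,
                  occupancy = .data$n_present / res$n_frames)
  })
}

#' Persistence-filtered bond network
#'
#' Keeps bonds whose occupancy strictly exceeds the threshold ("occurring in
#' more than 50 percent of trajectory frames" at the default).
#'
#' @param records A tibble with an `occupancy` column.
#' @param threshold Occupancy threshold (strict inequality).
#' @return The filtered tibble.
#' @export
persistent_network <- function(records, threshold = 0.5) {
  dplyr::filter(records, .data$occupancy > threshold)
}

#' Per-residue hydrogen-bond frequency
#'
#' For each residue, sums the occupancies of all bonds in which any of its
#' atoms participates; a bond within a single pair of residues contributes to
#' both residues' totals. Values are stored unrounded; round to one decimal
#' for display.
#'
#' @param records A bond-level tibble with key columns and `occupancy` (e.g.
#'   run-averaged records from [summarize_hbonds()]).
#' @return A tibble `chain_id`, `residue_number`, `frequency`.
#' @export
per_residue_frequency <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(chain_id = character(), residue_number = integer(),
                  frequency = numeric()))
  }
  ends <- dplyr::bind_rows(
    dplyr::transmute(records, chain_id = .data$donor_chain,
                     residue_number = .data$donor_resno,
                     occupancy = .data$occupancy),
    dplyr::transmute(records, chain_id = .data$acceptor_chain,
                     residue_number = .data$acceptor_resno,
                     occupancy = .data$occupancy)
  )
  dplyr::summarise(dplyr::group_by(ends, .data$chain_id, .data$residue_number),
                   frequency = sum(.data$occupancy), .groups = "drop")
}

#' Replicate-averaged hydrogen-bond network summary
#'
#' Runs the detector over every run of the trajectory set and aggregates:
#' per-run per-frame bond counts by class, the across-run mean and standard
#' error of the mean count (SEM over run means, n = number of runs), run-mean
#' per-bond occupancies, the persistence-filtered network, and per-residue
#' frequencies.
#'
#' @inheritParams hbond_occupancy
#' @param persistence Occupancy threshold for the persistent network.
#' @return An object of class `hbond_summary`: a list with tibbles `records`
#'   (bond-level, run-mean occupancy plus per-run occupancies nested in
#'   `replicate_occupancies`), `class_summary` (`bond_class`, `mean_count`,
#'   `sem_count`, `n_runs`), `per_frame_counts` (`run`, `frame`, one column per
#'   class), `persistent`, `per_residue`, and the criteria used.
#' @export
summarize_hbonds <- function(traj, criteria = hbond_criteria(), roles = NULL,
                             persistence = 0.5, burn_in = 0) {
  roles <- prepare_roles(traj, roles)
  if (n_frames(traj) - burn_in < 1) abort("zero frames to analyse")

  runs <- lapply(seq_len(n_runs(traj)), function(r) {
    coords <- traj$runs[[r]]
    if (burn_in > 0) coords <- coords[, , -seq_len(burn_in), drop = FALSE]
    hbond_engine_run(coords, roles, criteria)
  })
  n_fr <- runs[[1]]$n_frames

  occ <- purrr::imap_dfr(runs, function(res, r) {
    dplyr::mutate(res$bonds, run = r, occupancy = .data$n_present / res$n_frames)
  })
  key_cols <- c("donor_chain", "donor_resno", "donor_atom",
                "acceptor_chain", "acceptor_resno", "acceptor_atom",
                "bond_class")
  if (nrow(occ) > 0) {
    records <- occ |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
      dplyr::summarise(
        replicate_occupancies = list({
          v <- numeric(length(runs))
          v[.data$run] <- .data$occupancy
          v
        }),
        occupancy = sum(.data$occupancy) / length(runs),
        .groups = "drop"
      )
  } else {
    records <- dplyr::mutate(dplyr::select(empty_bond_counts(), -"n_present"),
                             replicate_occupancies = list(),
                             occupancy = numeric(0))
  }

  per_frame <- purrr::imap_dfr(runs, function(res, r) {
    cc <- res$per_frame
    if (is.null(cc)) {
      cc <- matrix(0L, nrow = 3, ncol = res$n_frames,
                   dimnames = list(c("internal", "intermolecular", "other")))
    }
    tibble(run = r, frame = seq_len(ncol(cc)),
           internal = cc["internal", ],
           intermolecular = cc["intermolecular", ],
           other = cc["other", ])
  })

  class_summary <- per_frame |>
    tidyr::pivot_longer(c("internal", "intermolecular", "other"),
                        names_to = "bond_class", values_to = "count") |>
    dplyr::group_by(.data$run, .data$bond_class) |>
    dplyr::summarise(run_mean = mean(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$bond_class) |>
    dplyr::summarise(
      mean_count = mean(.data$run_mean),
      sem_count = if (dplyr::n() > 1) sd(.data$run_mean) / sqrt(dplyr::n())
                  else NA_real_,
      n_runs = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(
      records = records,
      class_summary = class_summary,
      per_frame_counts = per_frame,
      persistent = persistent_network(records, persistence),
      per_residue = per_residue_frequency(records),
      criteria = criteria,
      persistence = persistence,
      n_frames = n_fr,
      n_runs = n_runs(traj)
    ),
    class = "hbond_summary"
  )
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("<hbond_summary> %d run(s) x %d frame(s)%s\n",
              x$n_runs, x$n_frames,
              if (!x$criteria$require_hydrogens)
                " [distance-only mode, no hydrogens]" else ""))
  print(x$class_summary)
  invisible(x)
}

#' @export
tidy.hbond_summary <- function(x, ...) x$records

#' @export
glance.hbond_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$class_summary, names_from = "bond_class",
    values_from = c("mean_count", "sem_count"), id_cols = "n_runs"
  )
  dplyr::relocate(wide, "n_runs", .after = dplyr::last_col())
}

#' Mean hydrogen-bond count of one class
#'
#' @param summary An [summarize_hbonds()] result.
#' @param class One of `"internal"`, `"intermolecular"`, `"other"`.
#' @return The across-run mean per-frame count.
#' @export
mean_bond_count <- function(summary, class = "internal") {
  row <- summary$class_summary[summary$class_summary$bond_class == class, ]
  if (nrow(row) == 0) return(0)
  row$mean_count
}

#' Half-up rounding for display values
#'
#' Tables round frequencies and percent changes half-up ("to the nearest
#' tenth"), whereas [round()] rounds half to even; this helper matches the
#' tabulation convention. Internal storage is always unrounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percent change of a variant mean relative to a reference variant
#'
#' `100 * (variant - reference) / reference`, returned unrounded; tables
#' display it to one decimal.
#'
#' @param variant_mean,reference_mean Mean bond counts; `reference_mean` must
#'   be positive.
#' @return Percent change (vectorised over `variant_mean`).
#' @export
percent_change <- function(variant_mean, reference_mean) {
  if (any(reference_mean <= 0)) abort("reference_mean must be > 0")
  100 * (variant_mean - reference_mean) / reference_mean
}
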