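#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' deviations between two paired coordinate sets. Reflections are excluded by
#' correcting the sign of the smallest singular vector, so the returned
#' rotation always has determinant +1.
#'
#' @param mobile,reference Matrices of equal dimension (n x 3), n >= 3.
#' @return An object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), and `rmsd` (Angstrom) after the fit. Apply as
#'   `coords %*% rotation + translation` (rows are points).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    abort("mobile and reference must have identical dimensions")
  }
  if (nrow(mobile) < 3) abort("at least 3 points are required")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  P <- sweep(mobile, 2, mc)
  Q <- sweep(reference, 2, rc)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps mobile-frame to ref-frame
  rotation <- t(R)                          # row-vector convention x %*% rotation
  translation <- rc - as.vector(mc %*% rotation)
  fitted <- sweep(mobile %*% rotation, 2, translation, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = rotation, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame C-alpha RMSD profile of a chain
#'
#' Superposes the selected atoms of every frame onto a reference - either the
#' starting structure (frame 1 of each run) or the trajectory-average
#' structure - and records the post-fit RMSD per frame. Low, stable values
#' against the start indicate the loop holds its initial conformation; low
#' values against the average indicate the (possibly shifted) conformation is
#' stable.
#'
#' @param traj A [trajectory_set()].
#' @param chain_id Chain to analyse (typically the inhibitor).
#' @param reference `"start"` or `"average"`.
#' @param selection Atom name(s) used for both fitting and readout
#'   (default `"CA"`).
#' @return A tibble of class `rigidity_profile` with columns `run`, `frame`,
#'   `rmsd`; attributes carry the reference kind and a pooled mean.
#' @export
rmsd_profile <- function(traj, chain_id, reference = c("start", "average"),
                         selection = "CA") {
  reference <- match.arg(reference)
  idx <- selection_indices(traj, chain_id, selection)
  ref_coords <- switch(reference,
    start = frame_coords(traj, 1, 1)[idx, , drop = FALSE],
    average = average_structure(traj, chain_id, selection = selection)
  )
  prof <- purrr::map_dfr(seq_len(n_runs(traj)), function(r) {
    rmsds <- vapply(seq_len(n_frames(traj)), function(f) {
      m <- traj$runs[[r]][idx, , f]
      kabsch_superpose(m, ref_coords)$rmsd
    }, numeric(1))
    tibble(run = r, frame = seq_len(n_frames(traj)), rmsd = rmsds)
  })
  structure(prof, class = c("rigidity_profile", class(prof)),
            reference = reference, chain_id = chain_id,
            pooled_mean = mean(prof$rmsd))
}

selection_indices <- function(traj, chain_id, selection) {
  top <- traj$topology
  idx <- which(top$chain_id == chain_id & top$name %in% selection)
  if (length(idx) == 0) abort("empty atom selection")
  idx[order(top$residue_number[idx])]
}

#' Trajectory-average structure of a chain
#'
#' Superposes the selection of every frame (all runs pooled) onto frame 1 of
#' run 1, then takes the per-atom arithmetic mean. With `iterate = TRUE` the
#' superposition target is replaced by the current average and the procedure
#' repeats until the average moves less than `tol` Angstrom.
#'
#' @inheritParams rmsd_profile
#' @param iterate Repeat superposition against the running average.
#' @param tol Convergence threshold on the average's displacement, Angstrom.
#' @return An n x 3 coordinate matrix.
#' @export
average_structure <- function(traj, chain_id, selection = "CA",
                              iterate = FALSE, tol = 1e-4) {
  idx <- selection_indices(traj, chain_id, selection)
  frames <- list()
  k <- 0
  for (r in seq_len(n_runs(traj))) {
    for (f in seq_len(n_frames(traj))) {
      k <- k + 1
      frames[[k]] <- traj$runs[[r]][idx, , f]
    }
  }
  if (length(frames) < 2) abort("at least 2 frames are required")
  target <- frames[[1]]
  repeat {
    fitted <- lapply(frames, function(m) {
      apply_superposition(m, kabsch_superpose(m, target))
    })
    avg <- Reduce(`+`, fitted) / length(fitted)
    if (!iterate || rmsd_between(avg, target) < tol) break
    target <- avg
  }
  dimnames(avg) <- list(traj$topology$residue_number[idx], c("x", "y", "z"))
  avg
}

#' Per-residue C-alpha RMSD against a reference structure
#'
#' Each frame is globally superposed onto the reference over the whole
#' selection; the deviation is then read out per residue as the
#' root-mean-square over frames (all runs pooled) of that residue's CA
#' displacement. This is the quantity used to colour average structures from
#' rigid (low) to mobile (high).
#'
#' @inheritParams rmsd_profile
#' @param reference `"start"`, `"average"`, or an n x 3 matrix matching the
#'   selection.
#' @return A tibble `residue_number`, `rmsd`.
#' @export
per_residue_rmsd <- function(traj, chain_id, reference = "average",
                             selection = "CA") {
  idx <- selection_indices(traj, chain_id, selection)
  if (is.matrix(reference)) {
    ref_coords <- reference
  } else {
    ref_coords <- switch(match.arg(reference, c("start", "average")),
      start = frame_coords(traj, 1, 1)[idx, , drop = FALSE],
      average = average_structure(traj, chain_id, selection = selection)
    )
  }
  dev2 <- rep(0, length(idx)); n <- 0
  for (r in seq_len(n_runs(traj))) {
    for (f in seq_len(n_frames(traj))) {
      m <- traj$runs[[r]][idx, , f]
      fitted <- apply_superposition(m, kabsch_superpose(m, ref_coords))
      dev2 <- dev2 + rowSums((fitted - ref_coords)^2)
      n <- n + 1
    }
  }
  tibble(
    residue_number = sort(traj$topology$residue_number[idx]),
    rmsd = sqrt(dev2 / n)[order(traj$topology$residue_number[idx])]
  )
}
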