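# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, grid searches, root finders) so they
# share no code with the implementation paths they check.

# Brute-force geometric H-bond detector: enumerate every donor/acceptor pair
# and evaluate the distance + angle predicate with plain scalar arithmetic.
brute_force_hbonds <- function(coords, roles, criteria) {
  donors <- which(roles$is_donor)
  acceptors <- which(roles$is_acceptor)
  out <- list()
  k <- 0
  for (d in donors) {
    for (a in acceptors) {
      if (roles$chain_id[d] == roles$chain_id[a] &&
          roles$residue_number[d] == roles$residue_number[a]) next
      dist <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dist > criteria$max_da_distance) next
      ok <- TRUE
      if (criteria$require_hydrogens) {
        ok <- FALSE
        for (h in which(roles$hydrogen_of == d)) {
          u <- coords[d, ] - coords[h, ]
          v <- coords[a, ] - coords[h, ]
          ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
          if (ang >= 180 - criteria$max_angle_deviation) ok <- TRUE
        }
      }
      if (ok) {
        k <- k + 1
        out[[k]] <- data.frame(
          donor_chain = roles$chain_id[d], donor_resno = roles$residue_number[d],
          donor_atom = roles$name[d], acceptor_chain = roles$chain_id[a],
          acceptor_resno = roles$residue_number[a],
          acceptor_atom = roles$name[a], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0) {
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character()))
  }
  do.call(rbind, out)
}

# Brute-force Morrison oracle: solve the binding isotherm numerically for the
# free inhibitor concentration, then v_i/v_0 = free E fraction.
morrison_oracle <- function(E, I, Ki_app) {
  if (I == 0) return(1)
  # [EI] = E_free * I_free / Ki_app; conservation E = E_free + EI, I = I_free + EI
  f <- function(EI) (E - EI) * (I - EI) - Ki_app * EI
  upper <- min(E, I)
  EI <- uniroot(f, c(0, upper), tol = 1e-14)$root
  (E - EI) / E
}

# Brute-force rigid-fit oracle: minimise RMSD over rotations parameterised by
# Euler angles with a generic optimiser (centres handled analytically).
rmsd_rotation_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) mean(rowSums((P %*% t(rot(ang)) - Q)^2))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(0, 0, pi / 2), c(pi, pi / 4, -pi / 4))) {
    o <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# Spearman oracle: explicit average ranks + the Pearson product-moment formula.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# A single frame holding one donor group (N, H) and one acceptor (O), placed
# at explicit positions; returns a trajectory_set with roles pre-assigned.
make_dha_frame <- function(D, H, A, acceptor_chain = "I") {
  top <- tibble::tibble(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_number = c(1L, 1L, 2L), residue_name = "ALA",
    chain_id = c("I", "I", acceptor_chain)
  )
  coords <- array(NA_real_, dim = c(3, 3, 1))
  coords[1, , 1] <- D; coords[2, , 1] <- H; coords[3, , 1] <- A
  trajectory_set(top, list(coords), c(I = "inhibitor", E = "protease"))
}

# Random small protein-like frame for property tests: n residues on one or
# two chains, each with N/H/CA/C/O at uniformly random positions in a box.
random_frame <- function(n_residues, box = 12, two_chains = FALSE) {
  per_res <- c("N", "H", "CA", "C", "O")
  chains <- if (two_chains) {
    rep(c("I", "E"), length.out = n_residues)
  } else rep("I", n_residues)
  top <- purrr::map_dfr(seq_len(n_residues), function(i) {
    tibble::tibble(name = per_res, element = substr(per_res, 1, 1),
                   residue_number = i, residue_name = "ALA",
                   chain_id = chains[i])
  })
  top$serial <- seq_len(nrow(top))
  coords <- array(runif(nrow(top) * 3, 0, box), dim = c(nrow(top), 3, 1))
  trajectory_set(top, list(coords), c(I = "inhibitor", E = "protease"))
}
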