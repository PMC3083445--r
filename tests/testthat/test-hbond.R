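test_that("collinear geometry at 2.9 A is a bond; distance and angle cuts reject", {
  # D-H...A collinear, D...A = 2.9 A
  traj <- make_dha_frame(D = c(0, 0, 0), H = c(1, 0, 0), A = c(2.9, 0, 0))
  expect_equal(nrow(detect_hbonds_frame(traj)), 1)

  # distance 5.0 > 3.3: no bond
  far <- make_dha_frame(D = c(0, 0, 0), H = c(1, 0, 0), A = c(5, 0, 0))
  expect_equal(nrow(detect_hbonds_frame(far)), 0)

  # D...A = 3.0 A but D-H...A = 135 deg < 140: rejected, and the brute-force
  # oracle agrees
  ang <- 135 * pi / 180
  H <- c(1, 0, 0)
  A <- H + 2.2 * c(cos(pi - ang), sin(pi - ang), 0)
  bent <- make_dha_frame(D = c(0, 0, 0), H = H, A = A)
  dist_da <- sqrt(sum(A^2))
  expect_lt(dist_da, 3.3)
  expect_equal(nrow(detect_hbonds_frame(bent)), 0)
  oracle <- brute_force_hbonds(frame_coords(bent), assign_roles(bent),
                               hbond_criteria())
  expect_equal(nrow(oracle), 0)

  # hydrogen-free mode accepts the same pair on distance alone
  crit <- hbond_criteria(require_hydrogens = FALSE)
  expect_equal(nrow(detect_hbonds_frame(bent, criteria = crit)), 1)
})

test_that("detector equals the brute-force oracle on random frames", {
  set.seed(42)
  criteria <- hbond_criteria()
  for (i in 1:24) {
    traj <- random_frame(n_residues = sample(5:40, 1), box = 10,
                         two_chains = i %% 2 == 0)
    roles <- assign_roles(traj)
    got <- detect_hbonds_frame(traj, criteria = criteria, roles = roles)
    want <- brute_force_hbonds(frame_coords(traj), roles, criteria)
    key <- function(df) sort(paste(df$donor_chain, df$donor_resno,
                                   df$donor_atom, df$acceptor_chain,
                                   df$acceptor_resno, df$acceptor_atom))
    expect_identical(key(got), key(want))
  }
})

test_that("tightening the criteria never adds bonds", {
  set.seed(99)
  loose <- hbond_criteria(max_da_distance = 3.6, max_angle_deviation = 60)
  for (i in 1:8) {
    traj <- random_frame(n_residues = 30, box = 9)
    roles <- assign_roles(traj)
    key <- function(cr) {
      df <- detect_hbonds_frame(traj, criteria = cr, roles = roles)
      paste(df$donor_resno, df$donor_atom, df$acceptor_resno, df$acceptor_atom)
    }
    base <- key(loose)
    expect_true(all(key(hbond_criteria(3.3, 60)) %in% base))
    expect_true(all(key(hbond_criteria(3.6, 40)) %in% base))
    expect_true(all(key(hbond_criteria(3.0, 30)) %in% base))
  }
})

test_that("missing donor hydrogens raise an error naming the donor", {
  top <- tibble::tibble(
    serial = 1:2, name = c("N", "O"), element = c("N", "O"),
    residue_number = c(1L, 2L), residue_name = "ALA", chain_id = "I"
  )
  traj <- trajectory_set(top, list(array(0, dim = c(2, 3, 1))),
                         c(I = "inhibitor"))
  expect_error(detect_hbonds_frame(traj), "I/1/N")
})

test_that("bond classification follows chain roles", {
  roles <- c(I = "inhibitor", E = "protease")
  expect_equal(classify_bond("I", "I", roles), "internal")
  expect_equal(classify_bond("I", "E", roles), "intermolecular")
  expect_equal(classify_bond("E", "I", roles), "intermolecular")
  expect_equal(classify_bond("E", "E", roles), "other")
  expect_equal(classify_bond("W", "I", roles), "other")
})

test_that("occupancy is the presence fraction, with binomial recovery", {
  # always-on and never-on extremes
  bonds <- tibble::tibble(donor_resno = 2L, acceptor_resno = 6L,
                          class = "internal", occupancy = 1)
  res <- make_trajectory(trajectory_spec(
    programmed_bonds = bonds, n_frames = 100, n_runs = 1,
    jitter_sigma = 0, seed = 5))
  occ <- hbond_occupancy(res$trajectory)
  expect_equal(occ$occupancy, 1)
  expect_equal(occ$n_frames, 100)

  # programmed probability 0.6, 5000 frames: inside the binomial 99% interval
  bonds$occupancy <- 0.6
  res <- make_trajectory(trajectory_spec(
    programmed_bonds = bonds, n_frames = 5000, n_runs = 1,
    jitter_sigma = 0, seed = 17))
  occ <- hbond_occupancy(res$trajectory)
  expect_lt(abs(occ$occupancy - 0.6), 0.018)
  # and matches the generator's own realised truth exactly
  expect_equal(occ$occupancy, res$truth$bond_occupancy$realized_occupancy)
})

test_that("persistence filter is strict at the threshold", {
  rec <- tibble::tibble(occupancy = c(0.2, 0.5, 0.501, 0.9))
  kept <- persistent_network(rec, 0.5)
  expect_equal(kept$occupancy, c(0.501, 0.9))
  expect_equal(nrow(persistent_network(tibble::tibble(occupancy = 0.5))), 0)
})

test_that("per-residue frequency sums occupancies over both endpoints", {
  rec <- tibble::tibble(
    donor_chain = c("I", "I"), donor_resno = c(3L, 5L), donor_atom = "N",
    acceptor_chain = c("I", "I"), acceptor_resno = c(5L, 3L),
    acceptor_atom = "O", occupancy = c(0.8, 0.35)
  )
  freq <- per_residue_frequency(rec)
  # residue 3 donates 0.8 and accepts 0.35: 1.15, displayed as 1.2
  f3 <- freq$frequency[freq$residue_number == 3]
  expect_equal(f3, 1.15)
  expect_equal(round_half_up(f3, 1), 1.2)
  # every bond counts once for each residue it touches
  expect_equal(freq$frequency[freq$residue_number == 5], 1.15)
  expect_equal(nrow(per_residue_frequency(rec[0, ])), 0)
})

test_that("replicate summary: mean over runs, SEM over run means", {
  # three runs engineered to have different bond counts: occupancy 1 bonds
  # present in run-specific numbers via variant seeds is fragile; instead
  # check the documented arithmetic directly on per-run means {3, 4, 5}
  expect_equal(sd(c(3, 4, 5)) / sqrt(3), 1 / sqrt(3))

  bonds <- tibble::tibble(
    donor_resno = c(2L, 4L, 6L, 8L, 10L),
    acceptor_resno = c(5L, 9L, 12L, 3L, 13L),
    class = "internal",
    occupancy = c(1, 1, 0.9, 0.6, 0.2)
  )
  res <- make_trajectory(trajectory_spec(
    programmed_bonds = bonds, n_frames = 400, n_runs = 3,
    jitter_sigma = 0.05, seed = 23))
  s <- summarize_hbonds(res$trajectory)

  truth_runs <- dplyr::summarise(
    dplyr::group_by(res$truth$per_frame_counts, run),
    m = mean(internal))
  cs <- s$class_summary[s$class_summary$bond_class == "internal", ]
  expect_equal(cs$mean_count, mean(truth_runs$m), tolerance = 1e-12)
  expect_equal(cs$sem_count, sd(truth_runs$m) / sqrt(3), tolerance = 1e-12)

  # mean-count identity: per-run mean equals the sum of per-run occupancies
  occ <- hbond_occupancy(res$trajectory)
  for (r in 1:3) {
    run_occ <- occ[occ$run == r & occ$bond_class == "internal", ]
    run_mean <- mean(s$per_frame_counts$internal[s$per_frame_counts$run == r])
    expect_equal(sum(run_occ$occupancy), run_mean, tolerance = 1e-12)
  }

  # single-run summaries have no SEM
  one <- trajectory_set(res$trajectory$topology, res$trajectory$runs[1],
                        res$trajectory$chain_roles)
  s1 <- summarize_hbonds(one)
  expect_true(is.na(s1$class_summary$sem_count[1]))
})

test_that("per-frame class counts conserve the total bond count", {
  bonds <- tibble::tibble(
    donor_resno = c(2L, 4L, 6L), acceptor_resno = c(5L, 9L, 7L),
    class = c("internal", "internal", "intermolecular"),
    occupancy = c(0.7, 0.5, 0.6)
  )
  res <- make_trajectory(trajectory_spec(
    programmed_bonds = bonds, n_frames = 200, n_runs = 1,
    jitter_sigma = 0.05, seed = 31))
  s <- summarize_hbonds(res$trajectory)
  pf <- s$per_frame_counts
  totals <- pf$internal + pf$intermolecular + pf$other
  # per frame, classes partition all detected bonds
  per_frame_detected <- vapply(seq_len(200), function(f) {
    nrow(detect_hbonds_frame(res$trajectory, 1, f))
  }, numeric(1))
  expect_equal(totals, per_frame_detected)
})

test_that("percent change reproduces the screen's self-consistent rows", {
  expect_equal(round(percent_change(4.68, 3.70), 1), 26.5)
  expect_equal(round(percent_change(2.56, 3.70), 1), -30.8)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(1, 0), "reference")
})
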