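#' Donor/acceptor chemistry table for hydrogen-bond detection
#'
#' Lists, per residue type, the heavy atoms that can donate a hydrogen bond
#' (N or O carrying at least one polar hydrogen) and those that can accept
#' (N or O with a lone pair). Backbone amide N (donor, with its amide H) and
#' carbonyl O (acceptor) are implied for every residue; side-chain entries
#' cover the standard amino acids, e.g. the guanidino nitrogens of arginine or
#' the carboxylate oxygens of aspartate. Hydroxyl oxygens (Ser OG, Thr OG1,
#' Tyr OH) are both donor and acceptor. Proline has no amide hydrogen and is
#' not a backbone donor. Which atoms count as donors/acceptors is configurable
#' because trajectory post-processing tools differ in their default selections.
#'
#' @return A list with tibbles `donors` (`residue_name`, `atom`, `hydrogens`
#'   list-column) and `acceptors` (`residue_name`, `atom`). `residue_name`
#'   `"*"` denotes the backbone entry applied to every residue.
#' @export
default_donor_acceptor_table <- function() {
  bb_h <- list(c("H", "HN", "H1", "H2", "H3", "HT1", "HT2", "HT3"))
  donors <- dplyr::bind_rows(
    tibble(residue_name = "*", atom = "N", hydrogens = bb_h),
    tibble(residue_name = "ARG", atom = "NE", hydrogens = list("HE")),
    tibble(residue_name = "ARG", atom = "NH1", hydrogens = list(c("HH11", "HH12"))),
    tibble(residue_name = "ARG", atom = "NH2", hydrogens = list(c("HH21", "HH22"))),
    tibble(residue_name = "LYS", atom = "NZ", hydrogens = list(c("HZ1", "HZ2", "HZ3"))),
    tibble(residue_name = "HIS", atom = "ND1", hydrogens = list("HD1")),
    tibble(residue_name = "HIS", atom = "NE2", hydrogens = list("HE2")),
    tibble(residue_name = "TRP", atom = "NE1", hydrogens = list("HE1")),
    tibble(residue_name = "ASN", atom = "ND2", hydrogens = list(c("HD21", "HD22"))),
    tibble(residue_name = "GLN", atom = "NE2", hydrogens = list(c("HE21", "HE22"))),
    tibble(residue_name = "SER", atom = "OG", hydrogens = list(c("HG", "HG1"))),
    tibble(residue_name = "THR", atom = "OG1", hydrogens = list("HG1")),
    tibble(residue_name = "TYR", atom = "OH", hydrogens = list("HH"))
  )
  acceptors <- dplyr::bind_rows(
    tibble(residue_name = "*", atom = "O"),
    tibble(residue_name = "*", atom = "OXT"),
    tibble(residue_name = "ASP", atom = c("OD1", "OD2")),
    tibble(residue_name = "GLU", atom = c("OE1", "OE2")),
    tibble(residue_name = "ASN", atom = "OD1"),
    tibble(residue_name = "GLN", atom = "OE1"),
    tibble(residue_name = "SER", atom = "OG"),
    tibble(residue_name = "THR", atom = "OG1"),
    tibble(residue_name = "TYR", atom = "OH"),
    tibble(residue_name = "HIS", atom = c("ND1", "NE2")),
    tibble(residue_name = "MET", atom = character(0))
  )
  list(donors = donors, acceptors = acceptors)
}

#' Flag donor, acceptor and hydrogen atoms in a trajectory topology
#'
#' Annotates every atom as donor-heavy, acceptor, donor-hydrogen, or none,
#' according to a chemistry table. An atom may be both donor-heavy and
#' acceptor (hydroxyl oxygens). Residue types absent from the table fall back
#' to backbone-only chemistry (amide N donor, carbonyl O acceptor) with a
#' warning. Proline backbone N is never a donor. The assignment is
#' deterministic and idempotent.
#'
#' @param traj A [trajectory_set()].
#' @param table A chemistry table as returned by
#'   [default_donor_acceptor_table()].
#' @return A tibble: the topology plus logical columns `is_donor`,
#'   `is_acceptor`, and an integer column `hydrogen_of` giving, for each
#'   hydrogen attached to a donor, the row index of its parent heavy atom
#'   (`NA` otherwise).
#' @export
assign_roles <- function(traj, table = default_donor_acceptor_table()) {
  top <- traj$topology
  known <- unique(c(table$donors$residue_name, table$acceptors$residue_name,
                    "ALA", "GLY", "VAL", "LEU", "ILE", "PHE", "PRO", "MET",
                    "CYS", "ASP", "GLU"))
  unknown <- setdiff(unique(top$residue_name), known)
  if (length(unknown) > 0) {
    warn(paste0("residue type(s) not in chemistry table, using backbone-only",
                " fallback: ", paste(unknown, collapse = ", ")))
  }

  n <- nrow(top)
  is_donor <- logical(n)
  is_acceptor <- logical(n)
  hydrogen_of <- rep(NA_integer_, n)

  res_key <- paste(top$chain_id, top$residue_number)
  res_split <- split(seq_len(n), res_key)

  don <- table$donors
  acc <- table$acceptors
  for (rows in res_split) {
    resname <- top$residue_name[rows[1]]
    d <- don[don$residue_name %in% c("*", resname), , drop = FALSE]
    a <- acc[acc$residue_name %in% c("*", resname), , drop = FALSE]
    names_here <- top$name[rows]
    # backbone N of proline carries no hydrogen and cannot donate
    if (identical(resname, "PRO")) d <- d[d$atom != "N", , drop = FALSE]
    for (k in seq_len(nrow(d))) {
      heavy <- rows[names_here == d$atom[k]]
      if (length(heavy) == 0) next
      heavy <- heavy[1]
      hyds <- rows[names_here %in% d$hydrogens[[k]]]
      is_donor[heavy] <- TRUE
      hydrogen_of[hyds] <- heavy
    }
    is_acceptor[rows[names_here %in% a$atom]] <- TRUE
  }
  dplyr::mutate(top, is_donor = is_donor, is_acceptor = is_acceptor,
                hydrogen_of = hydrogen_of)
}
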