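## Noncovalent interaction detection for protein-DNA and intramolecular
## contacts, in-silico mutagenesis with interaction rewiring, rigid-body
## docking onto ideal B-DNA, and groove occupancy assignment.
##
## Category cutoffs (Angstrom, inclusive <=):
##   salt bridge 5.0; hydrogen bond (H...acceptor) 2.5, heavy-atom fallback
##   3.5; attractive charge 5.6; pi-pi stacking (ring centroids) 5.5; alkyl
##   (group centroids) 5.5; pi-alkyl 6.0.

.positive_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                        HIS = c("ND1", "NE2"))
.negative_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                        DA = c("OP1", "OP2"), DT = c("OP1", "OP2"),
                        DG = c("OP1", "OP2"), DC = c("OP1", "OP2"))

.ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
  DA = list(c("N9", "C8", "N7", "C5", "C4"),
            c("C4", "C5", "C6", "N1", "C2", "N3")),
  DG = list(c("N9", "C8", "N7", "C5", "C4"),
            c("C4", "C5", "C6", "N1", "C2", "N3")),
  DT = list(c("N1", "C2", "N3", "C4", "C5", "C6")),
  DC = list(c("N1", "C2", "N3", "C4", "C5", "C6")))

## aliphatic groups: protein side-chain carbons (and Met SD), plus the
## thymine methyl on the DNA side
.alkyl_atoms <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), PRO = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "SD", "CE"), LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG", "CD"), DT = "C7")

## rows of `atoms` that belong to named charged groups
charged_rows <- function(atoms, table) {
  sel <- rep(FALSE, nrow(atoms))
  for (rn in names(table))
    sel <- sel | (atoms$resname == rn & atoms$atom %in% table[[rn]])
  sel
}

## split one model of a structure into the two partner selections; partners
## is list(receptor = chains, ligand = chains) or "intra"
partner_atoms <- function(struct, partners, model = 1L) {
  a <- struct$atoms[struct$atoms$model == model, , drop = FALSE]
  if (identical(partners, "intra"))
    return(list(A = a, B = a, intra = TRUE))
  A <- a[a$chain %in% partners[[1]], , drop = FALSE]
  B <- a[a$chain %in% partners[[2]], , drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("empty partner selection")
  list(A = A, B = B, intra = FALSE)
}

## pair up rows of two atom subsets within a distance cutoff; returns a
## record data.frame. Same-residue pairs are excluded; in intra mode each
## unordered pair is reported once.
pair_records <- function(category, from_atoms, to_atoms, cutoff,
                         intra = FALSE, with_atom = TRUE) {
  empty <- data.frame(category = character(0), from = character(0),
                      to = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(from_atoms) == 0L || nrow(to_atoms) == 0L) return(empty)
  d2 <- cross_dist2(coords(from_atoms), coords(to_atoms))
  hit <- which(d2 <= cutoff * cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  same_res <- from_atoms$chain[i] == to_atoms$chain[j] &
    from_atoms$resno[i] == to_atoms$resno[j]
  keep <- !same_res
  if (intra) {
    ## drop duplicate unordered pairs
    ka <- paste(from_atoms$chain[i], from_atoms$resno[i], from_atoms$atom[i])
    kb <- paste(to_atoms$chain[j], to_atoms$resno[j], to_atoms$atom[j])
    keep <- keep & (ka < kb)
  }
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)
  data.frame(category = category,
             from = atom_spec_str(from_atoms[i, ], with_atom = with_atom),
             to = atom_spec_str(to_atoms[j, ], with_atom = with_atom),
             distance = sqrt(d2[cbind(i, j)]),
             stringsAsFactors = FALSE)
}

#' Detect salt bridges
#'
#' Atom-pairwise contacts between a positively charged nitrogen (Lys NZ;
#' Arg NH1/NH2/NE; His ND1/NE2) and a negatively charged oxygen (Asp
#' OD1/OD2; Glu OE1/OE2; DNA phosphate OP1/OP2; C-terminal OXT) at most
#' `max_dist` Angstrom apart (inclusive). Atom names should be normalized
#' ([normalize_atom_names()]) so phosphate oxygens read OP1/OP2.
#'
#' @param struct a `structure3d`.
#' @param partners `list(receptor_chains, ligand_chains)` or `"intra"`.
#' @param max_dist cutoff, Angstrom.
#' @param his_positive treat histidine as positively charged.
#' @param model model number.
#' @return data.frame `category`, `from`, `to`, `distance`.
#' @export
detect_salt_bridges <- function(struct, partners = "intra", max_dist = 5.0,
                                his_positive = TRUE, model = 1L) {
  p <- partner_atoms(struct, partners, model)
  pos_tab <- .positive_atoms
  if (!his_positive) pos_tab$HIS <- NULL
  neg_rows <- function(a) charged_rows(a, .negative_atoms) | a$atom == "OXT"
  recs <- rbind(
    pair_records("salt_bridge", p$A[charged_rows(p$A, pos_tab), ],
                 p$B[neg_rows(p$B), ], max_dist, intra = p$intra),
    pair_records("salt_bridge", p$A[neg_rows(p$A), ],
                 p$B[charged_rows(p$B, pos_tab), ], max_dist,
                 intra = p$intra))
  unique(recs)
}

## polar hydrogens: H atoms within `bond` A of an N or O in the same residue;
## returns indices into `a` plus the parent heavy-atom index
polar_hydrogens <- function(a, bond = 1.25) {
  h_idx <- which(a$element == "H")
  if (length(h_idx) == 0L)
    return(data.frame(h = integer(0), parent = integer(0)))
  out_h <- integer(0); out_p <- integer(0)
  for (i in h_idx) {
    same <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                    a$element %in% c("N", "O"))
    if (length(same) == 0L) next
    d <- sqrt(cross_dist2(coords(a[i, , drop = FALSE]),
                          coords(a[same, , drop = FALSE])))[1, ]
    k <- which.min(d)
    if (d[k] <= bond) { out_h <- c(out_h, i); out_p <- c(out_p, same[k]) }
  }
  data.frame(h = out_h, parent = out_p)
}

#' Detect hydrogen bonds
#'
#' Pairs a polar hydrogen (bound to N or O) with an O/N acceptor at most
#' `max_dist` Angstrom away (H...acceptor distance, inclusive). Records list
#' the donor hydrogen and the acceptor. When the structure carries no
#' hydrogens at all, a heavy-atom fallback pairs donor N/O with acceptor O/N
#' at `heavy_dist` and sets the `fallback` flag.
#'
#' @param struct a `structure3d`.
#' @param partners `list(receptor_chains, ligand_chains)` or `"intra"`.
#' @param max_dist H...acceptor cutoff, Angstrom.
#' @param heavy_dist donor-acceptor heavy-atom fallback cutoff, Angstrom.
#' @param model model number.
#' @return data.frame `category`, `from`, `to`, `distance`, `fallback`.
#' @export
detect_hydrogen_bonds <- function(struct, partners = "intra", max_dist = 2.5,
                                  heavy_dist = 3.5, model = 1L) {
  p <- partner_atoms(struct, partners, model)
  has_h <- any(p$A$element == "H") || any(p$B$element == "H")
  one_way <- function(donor_side, acceptor_side) {
    if (has_h) {
      ph <- polar_hydrogens(donor_side)
      donors <- donor_side[ph$h, , drop = FALSE]
      acceptors <- acceptor_side[acceptor_side$element %in% c("N", "O"), ,
                                 drop = FALSE]
      recs <- pair_records("hydrogen_bond", donors, acceptors, max_dist,
                           intra = FALSE)
      recs$fallback <- rep(FALSE, nrow(recs))
    } else {
      donors <- donor_side[donor_side$element %in% c("N", "O"), , drop = FALSE]
      acceptors <- acceptor_side[acceptor_side$element %in% c("N", "O"), ,
                                 drop = FALSE]
      recs <- pair_records("hydrogen_bond", donors, acceptors, heavy_dist,
                           intra = FALSE)
      recs$fallback <- rep(TRUE, nrow(recs))
    }
    recs
  }
  recs <- rbind(one_way(p$A, p$B), one_way(p$B, p$A))
  if (p$intra && nrow(recs) > 0L) {
    key <- t(apply(cbind(recs$from, recs$to), 1, sort))
    recs <- recs[!duplicated(paste(key[, 1], key[, 2])), , drop = FALSE]
  }
  unique(recs)
}

## centroids of ring or alkyl groups present in an atom subset; returns a
## pseudo-atom table usable by pair_records (one row per group)
group_centroids <- function(a, table, require_all = TRUE) {
  rows <- list()
  res <- unique(a[, c("chain", "resno", "resname")])
  for (k in seq_len(nrow(res))) {
    groups <- table[[res$resname[k]]]
    if (is.null(groups)) next
    if (!is.list(groups)) groups <- list(groups)
    sub <- a[a$chain == res$chain[k] & a$resno == res$resno[k], , drop = FALSE]
    for (g in groups) {
      got <- sub[sub$atom %in% g, , drop = FALSE]
      if (require_all && nrow(got) < length(g)) next
      if (nrow(got) == 0L) next
      cen <- colMeans(coords(got))
      rows[[length(rows) + 1L]] <- data.frame(
        model = sub$model[1], chain = res$chain[k], resno = res$resno[k],
        resname = res$resname[k], atom = "", element = "",
        x = cen[1], y = cen[2], z = cen[3], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(a[0, , drop = FALSE])
  do.call(rbind, rows)
}

#' Detect electrostatic and hydrophobic interactions
#'
#' Three further categories of the interface report:
#' * `electrostatic_attractive` - oppositely charged group atoms at most
#'   5.6 Angstrom apart,
#' * `pi_pi_stacked` - aromatic ring centroids (His/Phe/Tyr/Trp side chains,
#'   DNA base rings) at most 5.5 Angstrom apart,
#' * `alkyl` - aliphatic side-chain group centroids (thymine methyl counts
#'   on the DNA side) at most 5.5 Angstrom apart,
#' * `pi_alkyl` - ring centroid to aliphatic group centroid at most 6.0
#'   Angstrom.
#'
#' @param struct a `structure3d`.
#' @param partners `list(receptor_chains, ligand_chains)` or `"intra"`.
#' @param cutoffs named numeric vector of category cutoffs, Angstrom.
#' @param his_positive treat histidine as positively charged.
#' @param model model number.
#' @return data.frame `category`, `from`, `to`, `distance`.
#' @export
detect_other_interactions <- function(struct, partners = "intra",
                                      cutoffs = c(attractive = 5.6,
                                                  pi_pi = 5.5,
                                                  alkyl = 5.5,
                                                  pi_alkyl = 6.0),
                                      his_positive = TRUE, model = 1L) {
  p <- partner_atoms(struct, partners, model)
  pos_tab <- .positive_atoms
  if (!his_positive) pos_tab$HIS <- NULL
  neg_rows <- function(a) charged_rows(a, .negative_atoms) | a$atom == "OXT"

  elec <- rbind(
    pair_records("electrostatic_attractive",
                 p$A[charged_rows(p$A, pos_tab), ], p$B[neg_rows(p$B), ],
                 cutoffs[["attractive"]], intra = p$intra),
    pair_records("electrostatic_attractive",
                 p$A[neg_rows(p$A), ], p$B[charged_rows(p$B, pos_tab), ],
                 cutoffs[["attractive"]], intra = p$intra))

  rings_a <- group_centroids(p$A, .ring_atoms)
  rings_b <- group_centroids(p$B, .ring_atoms)
  alkyl_a <- group_centroids(p$A, .alkyl_atoms, require_all = FALSE)
  alkyl_b <- group_centroids(p$B, .alkyl_atoms, require_all = FALSE)

  pipi <- pair_records("pi_pi_stacked", rings_a, rings_b,
                       cutoffs[["pi_pi"]], intra = p$intra, with_atom = FALSE)
  alk <- pair_records("alkyl", alkyl_a, alkyl_b,
                      cutoffs[["alkyl"]], intra = p$intra, with_atom = FALSE)
  pialk <- rbind(
    pair_records("pi_alkyl", rings_a, alkyl_b, cutoffs[["pi_alkyl"]],
                 intra = FALSE, with_atom = FALSE),
    pair_records("pi_alkyl", rings_b, alkyl_a, cutoffs[["pi_alkyl"]],
                 intra = FALSE, with_atom = FALSE))
  if (p$intra && nrow(pialk) > 0L) {
    key <- t(apply(cbind(pialk$from, pialk$to), 1, sort))
    pialk <- pialk[!duplicated(paste(key[, 1], key[, 2])), , drop = FALSE]
  }
  unique(rbind(elec, pipi, alk, pialk))
}

## residue-level key "chain:resno" from a spec string such as "A:Arg60:NH2"
## or "C:A7"
res_key_from_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)
  vapply(parts, function(x) {
    paste0(x[1], ":", gsub("[^0-9]", "", x[2]))
  }, character(1))
}

#' Full interface interaction report
#'
#' Union of the salt-bridge, hydrogen-bond and electrostatic/hydrophobic
#' detectors across the receptor/ligand chain selection, deduplicated and
#' sorted by category then distance. An atom pair already reported as a
#' salt bridge is not repeated as an attractive-charge contact. Also usable
#' intramolecularly with `partners = "intra"`. Atom names are normalized
#' first.
#'
#' @param complex a `structure3d`.
#' @param receptor_chains,ligand_chains chain id vectors; give
#'   `receptor_chains = "intra"` for an intramolecular report.
#' @param his_positive treat histidine as positively charged.
#' @param model model number.
#' @return data.frame `category`, `from`, `to`, `distance`, `fallback`.
#' @export
interaction_report <- function(complex, receptor_chains, ligand_chains = NULL,
                               his_positive = TRUE, model = 1L) {
  complex <- normalize_atom_names(complex)
  partners <- if (identical(receptor_chains, "intra")) "intra"
              else list(receptor_chains, ligand_chains)
  sb <- detect_salt_bridges(complex, partners, his_positive = his_positive,
                            model = model)
  hb <- detect_hydrogen_bonds(complex, partners, model = model)
  ot <- detect_other_interactions(complex, partners,
                                  his_positive = his_positive, model = model)
  ## salt bridge takes precedence over attractive charge for the same pair
  if (nrow(ot) > 0L && nrow(sb) > 0L) {
    sb_keys <- c(paste(sb$from, sb$to), paste(sb$to, sb$from))
    drop <- ot$category == "electrostatic_attractive" &
      paste(ot$from, ot$to) %in% sb_keys
    ot <- ot[!drop, , drop = FALSE]
  }
  sb$fallback <- rep(FALSE, nrow(sb))
  ot$fallback <- rep(FALSE, nrow(ot))
  out <- rbind(sb, hb, ot)
  out <- unique(out)
  order_cat <- c("salt_bridge", "hydrogen_bond", "electrostatic_attractive",
                 "pi_pi_stacked", "alkyl", "pi_alkyl")
  out <- out[order(match(out$category, order_cat), out$distance), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- in-silico mutagenesis ---------------------------------------------------

## side-chain chains built along the CA->CB direction; each entry: atom
## names in chain order, then terminal branch atoms
.mutation_templates <- list(
  ALA = list(chain = character(0), branch = character(0), el = character(0)),
  ASP = list(chain = "CG", branch = c("OD1", "OD2"),
             el = c(CG = "C", OD1 = "O", OD2 = "O")),
  GLU = list(chain = c("CG", "CD"), branch = c("OE1", "OE2"),
             el = c(CG = "C", CD = "C", OE1 = "O", OE2 = "O")),
  LYS = list(chain = c("CG", "CD", "CE", "NZ"), branch = character(0),
             el = c(CG = "C", CD = "C", CE = "C", NZ = "N")),
  ARG = list(chain = c("CG", "CD", "NE", "CZ"), branch = c("NH1", "NH2"),
             el = c(CG = "C", CD = "C", NE = "N", CZ = "C",
                    NH1 = "N", NH2 = "N")))

#' Mutate residues in silico
#'
#' Replaces the side chains of the targeted residues with an idealized
#' side chain of the new type, built along the original CA->CB direction
#' (backbone and CB kept). Supported new types: Glu, Asp, Lys, Arg, Ala.
#' This is an idealized geometric substitution (no relaxation); it is meant
#' for sign-flip rewiring analyses, not for reproducing relaxed mutant
#' geometry.
#'
#' @param struct a `structure3d`.
#' @param substitutions named character vector: names are `"chain:resno"`,
#'   values are 3-letter target types (case-insensitive).
#' @return mutated `structure3d`.
#' @export
mutate_residues <- function(struct, substitutions) {
  a <- struct$atoms
  backbone <- c("N", "CA", "C", "O", "H", "OXT", "CB")
  for (k in seq_along(substitutions)) {
    tgt <- strsplit(names(substitutions)[k], ":", fixed = TRUE)[[1]]
    newtype <- toupper(substitutions[[k]])
    if (!(newtype %in% names(.mutation_templates)))
      stop("unsupported substitution type: ", newtype)
    chain <- tgt[1]; resno <- as.integer(tgt[2])
    sel <- a$chain == chain & a$resno == resno
    if (!any(sel)) stop("no such residue: ", names(substitutions)[k])
    for (m in unique(a$model[sel])) {
      rows <- which(sel & a$model == m)
      sub <- a[rows, , drop = FALSE]
      ca <- sub[sub$atom == "CA", ]; cb <- sub[sub$atom == "CB", ]
      if (nrow(cb) == 0L)
        stop("target residue has no CB (cannot rebuild side chain): ",
             names(substitutions)[k])
      if (sub$resname[1] == toupper(newtype)) {
        a$resname[rows] <- newtype
        next
      }
      pca <- as.numeric(ca[1, c("x", "y", "z")])
      pcb <- as.numeric(cb[1, c("x", "y", "z")])
      u <- unitv(pcb - pca)
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p1 <- unitv(c(u[2] * ref[3] - u[3] * ref[2],
                    u[3] * ref[1] - u[1] * ref[3],
                    u[1] * ref[2] - u[2] * ref[1]))
      tmpl <- .mutation_templates[[newtype]]
      new_rows <- list()
      pos <- pcb
      step <- 0L
      for (nm in tmpl$chain) {
        step <- step + 1L
        pos <- pcb + u * (1.3 * step) + p1 * (0.45 * (step %% 2L))
        new_rows[[nm]] <- pos
      }
      for (i in seq_along(tmpl$branch)) {
        nm <- tmpl$branch[i]
        sgn <- if (i == 1L) 1 else -1
        new_rows[[nm]] <- pos + u * 0.6 + p1 * (sgn * 1.1)
      }
      ## drop the old side chain beyond CB, relabel, append new atoms
      drop_rows <- rows[!(a$atom[rows] %in% backbone)]
      keep_rows <- setdiff(rows, drop_rows)
      a$resname[keep_rows] <- newtype
      if (length(drop_rows) > 0L) a <- a[-drop_rows, , drop = FALSE]
      add <- if (length(new_rows) > 0L) data.frame(
        model = m, chain = chain, resno = resno, resname = newtype,
        atom = names(new_rows),
        element = unname(tmpl$el[names(new_rows)]),
        x = vapply(new_rows, `[`, numeric(1), 1),
        y = vapply(new_rows, `[`, numeric(1), 2),
        z = vapply(new_rows, `[`, numeric(1), 3),
        stringsAsFactors = FALSE) else NULL
      if (!is.null(add)) a <- rbind(a, add)
      ## recompute selection after row changes
      sel <- a$chain == chain & a$resno == resno
    }
  }
  a <- a[order(a$model, match(a$chain, unique(a$chain)), a$resno), ,
         drop = FALSE]
  new_structure3d(a)
}

#' Interaction rewiring between wild type and mutant
#'
#' Compares two interaction reports at the residue level: records are keyed
#' by (category, unordered residue pair), where a residue is identified by
#' chain and number (names are ignored, since mutation changes them).
#'
#' @param wt_records,mut_records data.frames from [interaction_report()] (or
#'   any detector).
#' @return list of class `rewiring_report` with `lost`, `gained`,
#'   `conserved` character vectors of record keys.
#' @export
rewiring <- function(wt_records, mut_records) {
  keys <- function(r) {
    if (nrow(r) == 0L) return(character(0))
    a <- res_key_from_spec(r$from); b <- res_key_from_spec(r$to)
    lo <- pmin(a, b); hi <- pmax(a, b)
    unique(paste(r$category, lo, hi, sep = "|"))
  }
  wt <- keys(wt_records); mut <- keys(mut_records)
  structure(list(lost = setdiff(wt, mut),
                 gained = setdiff(mut, wt),
                 conserved = intersect(wt, mut)),
            class = "rewiring_report")
}

## --- rigid-body docking onto B-DNA ------------------------------------------

#' Rigid-body docking onto an ideal B-DNA duplex
#'
#' Generates `n_poses` seeded random rigid placements of the protein around
#' the duplex (random orientation; centroid placed just outside the
#' phosphate cylinder at a random height and azimuth) and scores each pose
#' as
#' `w_attractive * (attractive-charge pairs <= 5.6 A) - w_clash *
#'  (heavy-atom pairs < 2.5 A)`.
#' Poses are greedily clustered at 3 Angstrom interface RMSD (C-alpha RMSD
#' in the DNA frame, best-scoring pose founds each cluster); clusters are
#' ranked by their best member's score.
#'
#' @param protein single-model protein `structure3d`.
#' @param dna duplex from [build_bdna()].
#' @param n_poses number of random poses (>= 1).
#' @param seed integer seed.
#' @param weights named vector `c(attractive = , clash = )`.
#' @param cluster_rmsd greedy clustering radius, Angstrom.
#' @param his_positive treat histidine as positively charged.
#' @return list of class `dock_result`: `poses` (data.frame pose, cluster,
#'   score, n_attractive, n_clash), `transforms` (per pose rotation +
#'   translation), `top_score`, ranked `clusters`.
#' @export
dock_to_bdna <- function(protein, dna, n_poses = 500, seed = NULL,
                         weights = c(attractive = 1, clash = 1),
                         cluster_rmsd = 3, his_positive = TRUE) {
  stopifnot(n_poses >= 1)
  protein <- normalize_atom_names(protein)
  dna <- normalize_atom_names(dna)
  prot <- protein$atoms[protein$atoms$model == protein$atoms$model[1], ]
  dn <- dna$atoms[dna$atoms$model == dna$atoms$model[1], ]

  pos_tab <- .positive_atoms
  if (!his_positive) pos_tab$HIS <- NULL
  prot_xyz <- coords(prot)
  cm <- colMeans(prot_xyz)
  prot_c <- sweep(prot_xyz, 2, cm)
  r_prot <- sqrt(max(rowSums(prot_c^2)))
  idx_pos <- which(charged_rows(prot, pos_tab))
  idx_heavy <- which(prot$element != "H")
  idx_ca <- which(prot$atom == "CA")

  dna_neg <- coords(dn[dn$atom %in% c("OP1", "OP2"), , drop = FALSE])
  dna_heavy <- coords(dn[dn$element != "H", , drop = FALSE])
  rise <- if (!is.null(dna$bdna)) dna$bdna$rise else 3.38
  n_bp <- if (!is.null(dna$bdna)) dna$bdna$n_bp
          else length(unique(dn$resno)) / 2
  axis_len <- (n_bp - 1) * rise

  with_seed(seed, {
    score <- n_attr <- n_clash <- numeric(n_poses)
    transforms <- vector("list", n_poses)
    ca_list <- vector("list", n_poses)
    for (k in seq_len(n_poses)) {
      rot <- random_rotation()
      az <- stats::runif(1, 0, 2 * pi)
      zc <- stats::runif(1, 0, axis_len)
      rad <- 9 + 0.8 * r_prot + stats::runif(1, -2, 4)
      t <- c(rad * cos(az), rad * sin(az), zc)
      xyz <- sweep(prot_c %*% t(rot), 2, t, "+")
      na_k <- sum(cross_dist2(xyz[idx_pos, , drop = FALSE], dna_neg) <= 5.6^2)
      nc_k <- sum(cross_dist2(xyz[idx_heavy, , drop = FALSE],
                              dna_heavy) < 2.5^2)
      n_attr[k] <- na_k; n_clash[k] <- nc_k
      score[k] <- weights[["attractive"]] * na_k - weights[["clash"]] * nc_k
      transforms[[k]] <- list(rotation = rot, translation = t)
      ca_list[[k]] <- xyz[idx_ca, , drop = FALSE]
    }
    ## greedy clustering, best score first
    ord <- order(-score, seq_len(n_poses))
    cluster <- integer(n_poses)
    founders <- integer(0)
    for (k in ord) {
      assigned <- FALSE
      for (ci in seq_along(founders)) {
        rms <- sqrt(mean(rowSums((ca_list[[k]] -
                                    ca_list[[founders[ci]]])^2)))
        if (rms <= cluster_rmsd) { cluster[k] <- ci; assigned <- TRUE; break }
      }
      if (!assigned) {
        founders <- c(founders, k)
        cluster[k] <- length(founders)
      }
    }
    poses <- data.frame(pose = seq_len(n_poses), cluster = cluster,
                        score = score, n_attractive = n_attr,
                        n_clash = n_clash)
    best <- tapply(poses$score, poses$cluster, max)
    clusters <- data.frame(cluster = as.integer(names(best)),
                           best_score = as.numeric(best))
    clusters <- clusters[order(-clusters$best_score, clusters$cluster), ]
    rownames(clusters) <- NULL
    structure(list(poses = poses, transforms = transforms,
                   clusters = clusters, top_score = max(score)),
              class = "dock_result")
  })
}

## DNA backbone/sugar atom names for groove classification
.dna_backbone_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                         "C3'", "O3'", "C2'", "C1'")

#' Assign a point to a DNA groove
#'
#' Classifies a point against a duplex built by [build_bdna()]: `distal`
#' when more than 10 Angstrom from the nearest DNA atom; `backbone` when the
#' nearest atom is a phosphate/sugar atom within 4 Angstrom; otherwise
#' `minor` or `major` by the angular sector around the local helical axis,
#' relative to the dyad direction of the nearest base pair (the bisector of
#' the two glycosidic bonds, which points into the minor groove in this
#' fiber model).
#'
#' @param dna duplex from [build_bdna()] (in its construction frame).
#' @param point length-3 coordinate vector.
#' @return one of `"minor"`, `"major"`, `"backbone"`, `"distal"`.
#' @export
groove_assignment <- function(dna, point) {
  if (is.null(dna$bdna))
    stop("groove assignment needs a duplex built by build_bdna()")
  a <- dna$atoms
  d <- sqrt(colSums((t(coords(a)) - point)^2))
  k <- which.min(d)
  if (d[k] > 10) return("distal")
  if (a$atom[k] %in% .dna_backbone_atoms && d[k] <= 4) return("backbone")
  rise <- dna$bdna$rise; twist <- dna$bdna$twist; n_bp <- dna$bdna$n_bp
  i <- min(max(round(point[3] / rise), 0), n_bp - 1)
  theta <- i * twist
  az <- rad2deg(atan2(point[2], point[1]))
  delta <- ((az - theta + 180) %% 360) - 180
  if (abs(delta) <= 90) "minor" else "major"
}
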