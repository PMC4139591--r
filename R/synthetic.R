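## Synthetic-data generators. Every stage of the pipeline can be exercised on
## structures and sequences built here, with known ground truth and fixed
## seeds; no external downloads are required.

## Evaluate expr with the RNG temporarily seeded; global RNG state restored.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
  }
  expr
}

## ideal backbone geometry (Angstrom / degrees); dihedral-level realism is
## what the downstream assignment rules consume
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_n_h = 1.010,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1)

## Build backbone coordinates for given per-residue phi/psi (degrees).
## Returns the atom table for chain `chain`, model `model`. Atoms per
## residue: N, H (except residue 1 and Pro), CA, C, O, CB (except Gly).
build_backbone <- function(sequence, phi, psi, chain = "A", model = 1L) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seq1)
  stopifnot(length(phi) == n, length(psi) == n)
  res3 <- aa1_to_3(seq1)

  N <- CA <- C <- O <- CB <- H <- matrix(NA_real_, n, 3)
  ## seed the chain in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.geom$b_n_ca, 0, 0)
  th <- deg2rad(.geom$a_n_ca_c)
  C[1, ] <- CA[1, ] + .geom$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           .geom$b_c_n, .geom$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            .geom$b_n_ca, .geom$a_c_n_ca, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           .geom$b_ca_c, .geom$a_n_ca_c, phi[i])
    }
    ## carbonyl O in the peptide plane, anti to the next N
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         .geom$b_c_o, .geom$a_ca_c_o, psi[i] + 180)
    if (res3[i] != "GLY")
      CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ],
                            .geom$b_ca_cb, .geom$a_c_ca_cb, -122.6)
    if (i > 1L && res3[i] != "PRO") {
      ## amide H: planar, along the bisector away from C(i-1) and CA(i)
      d <- unitv(unitv(N[i, ] - C[i - 1, ]) + unitv(N[i, ] - CA[i, ]))
      H[i, ] <- N[i, ] + .geom$b_n_h * d
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    el <- c("N", "C", "C", "O")
    if (!is.na(H[i, 1])) { nm <- c(nm, "H"); xyz <- rbind(xyz, H[i, ]); el <- c(el, "H") }
    if (!is.na(CB[i, 1])) { nm <- c(nm, "CB"); xyz <- rbind(xyz, CB[i, ]); el <- c(el, "C") }
    rows[[i]] <- data.frame(model = model, chain = chain, resno = i,
                            resname = res3[i], atom = nm, element = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## per-residue phi/psi for a set of helical spans (alpha inside, extended out)
span_dihedrals <- function(n, helical_spans) {
  phi <- rep(-120, n); psi <- rep(120, n)
  for (sp in helical_spans) {
    if (sp[1] < 1 || sp[2] > n || sp[1] > sp[2])
      stop("helical span out of range: (", sp[1], ", ", sp[2], ")")
    phi[sp[1]:sp[2]] <- -57
    psi[sp[1]:sp[2]] <- -47
  }
  list(phi = phi, psi = psi)
}

#' Build an idealized protein model
#'
#' Constructs backbone coordinates (N, CA, C, O, amide H, and CB except for
#' Gly) with alpha-helical dihedrals (phi = -57, psi = -47) inside the given
#' spans and extended dihedrals (phi = -120, psi = +120) elsewhere, then adds
#' seeded Gaussian positional noise.
#'
#' @param sequence one-letter amino-acid string.
#' @param helical_spans list of `c(start, end)` residue spans (1-based,
#'   inclusive on both ends).
#' @param seed integer seed for the noise (NULL for no seeding).
#' @param noise Gaussian noise amplitude in Angstrom (standard deviation per
#'   coordinate).
#' @param chain chain identifier.
#' @return a single-model `structure3d`.
#' @export
build_ideal_helix <- function(sequence, helical_spans = list(), seed = NULL,
                              noise = 0, chain = "A") {
  n <- nchar(sequence)
  dh <- span_dihedrals(n, helical_spans)
  atoms <- build_backbone(sequence, dh$phi, dh$psi, chain = chain)
  if (noise > 0) {
    atoms <- with_seed(seed, {
      jit <- matrix(stats::rnorm(3L * nrow(atoms), sd = noise), ncol = 3)
      atoms$x <- atoms$x + jit[, 1]
      atoms$y <- atoms$y + jit[, 2]
      atoms$z <- atoms$z + jit[, 3]
      atoms
    })
  }
  new_structure3d(atoms)
}

## --- B-DNA fiber model -----------------------------------------------------

## schematic cylindrical backbone template: (radius, azimuth offset from the
## base-pair dyad direction, z offset along the axis); strand 2 is generated
## by the duplex dyad (azimuth and z offsets negated)
.bdna_backbone <- data.frame(
  atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
           "C2'", "C1'"),
  element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C"),
  r = c(8.9, 9.9, 9.2, 7.7, 7.3, 6.6, 5.7, 7.0, 7.9, 6.3, 5.8),
  dphi = c(77, 83, 68, 73, 66, 70, 63, 79, 84, 76, 64),
  dz = c(-1.9, -2.4, -2.9, -1.4, -0.5, 0.4, 0.2, 1.0, 1.4, 1.3, 0.5),
  stringsAsFactors = FALSE)

## in-plane base templates: a = toward the helix axis from the glycosidic
## nitrogen, b = lateral (toward the partner strand); approximate ring
## geometry with 1.4 A bonds
.base_2d <- list(
  pyrimidine = data.frame(
    atom = c("N1", "C2", "N3", "C4", "C5", "C6", "O2"),
    element = c("N", "C", "N", "C", "C", "C", "O"),
    a = c(0, 0.7, 2.1, 2.8, 2.1, 0.7, 0.085),
    b = c(0, 1.21, 1.21, 0, -1.21, -1.21, 2.273)),
  purine = data.frame(
    atom = c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3"),
    element = c("N", "C", "N", "C", "C", "C", "N", "C", "N"),
    a = c(0, 0.83, 2.17, 2.17, 0.83, 3.21, 2.91, 1.58, 0.54),
    b = c(0, 1.14, 0.71, -0.71, -1.14, -1.65, -3.02, -3.44, -2.50)))

.base_subst <- list(
  DT = data.frame(atom = c("O4", "C7"), element = c("O", "C"),
                  a = c(4.03, 2.85), b = c(0, -2.51)),
  DC = data.frame(atom = "N4", element = "N", a = 4.03, b = 0),
  DA = data.frame(atom = "N6", element = "N", a = 4.49, b = -1.24),
  DG = data.frame(atom = c("O6", "N2"), element = c("O", "N"),
                  a = c(4.49, 1.30), b = c(-1.24, -4.75)))

.dna_complement <- c(A = "T", T = "A", G = "C", C = "G")

## nucleotide atom table at base-pair index i (0-based), strand sign +1/-1
bdna_nucleotide <- function(base, i, sign, twist, rise, chain, resno) {
  theta <- deg2rad(i * twist)
  z0 <- i * rise
  resname <- .dna_alias[[base]]
  bb <- .bdna_backbone
  az <- theta + sign * deg2rad(bb$dphi)
  bb_xyz <- cbind(bb$r * cos(az), bb$r * sin(az), z0 + sign * bb$dz)

  ## glycosidic nitrogen
  ngly_az <- theta + sign * deg2rad(54)
  ngly <- c(4.7 * cos(ngly_az), 4.7 * sin(ngly_az), z0 + sign * 0.2)
  ## base plane frame: u toward the axis, w lateral toward the partner strand
  u <- c(-cos(ngly_az), -sin(ngly_az), 0)
  w <- sign * c(sin(ngly_az), -cos(ngly_az), 0)
  tmpl <- if (resname %in% c("DA", "DG")) .base_2d$purine else .base_2d$pyrimidine
  tmpl <- rbind(tmpl, .base_subst[[resname]])
  base_xyz <- t(vapply(seq_len(nrow(tmpl)), function(k) {
    ngly + tmpl$a[k] * u + tmpl$b[k] * w
  }, numeric(3)))

  data.frame(model = 1L, chain = chain, resno = resno, resname = resname,
             atom = c(bb$atom, tmpl$atom),
             element = c(bb$element, tmpl$element),
             x = c(bb_xyz[, 1], base_xyz[, 1]),
             y = c(bb_xyz[, 2], base_xyz[, 2]),
             z = c(bb_xyz[, 3], base_xyz[, 3]),
             stringsAsFactors = FALSE)
}

#' Build an ideal B-DNA duplex
#'
#' Rigid fiber-model geometry: twist 36 degrees per base pair, rise 3.38
#' Angstrom per base pair, no sequence-dependent bending. The given strand
#' becomes chain `C` (residues 1..n, 5' to 3'); its reverse complement
#' becomes chain `D` (residues n+1..2n), echoing the chain labels used in
#' protein-DNA interface reports. Each nucleotide carries the phosphate
#' group (P, OP1, OP2), sugar atoms (O5', C5', C4', O4', C3', O3', C2', C1')
#' and base ring atoms.
#'
#' @param sequence DNA string over A/C/G/T for the leading strand.
#' @return a `structure3d` with a `bdna` element recording the helical frame
#'   parameters (used by [groove_assignment()]).
#' @export
build_bdna <- function(sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 1L) stop("empty DNA sequence")
  bad <- setdiff(bases, c("A", "C", "G", "T"))
  if (length(bad) > 0L) stop("invalid DNA base: ", paste(bad, collapse = ", "))
  n <- length(bases)
  twist <- 36; rise <- 3.38

  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    rows[[i]] <- bdna_nucleotide(bases[i], i - 1L, +1, twist, rise, "C", i)
  }
  comp <- .dna_complement[bases]
  ## chain D 5'->3' is the reverse complement; D residue n+j pairs C residue
  ## n+1-j and sits at base-pair index n-j
  for (j in seq_len(n)) {
    rows[[n + j]] <- bdna_nucleotide(comp[n + 1L - j], n - j, -1,
                                     twist, rise, "D", n + j)
  }
  struct <- new_structure3d(do.call(rbind, rows))
  struct$bdna <- list(twist = twist, rise = rise, n_bp = n,
                      backbone_half_angle = 77)
  struct
}

## --- conformational ensembles ----------------------------------------------

#' Helix order/disorder schedule
#'
#' @param spans list of `c(start, end)` residue spans.
#' @param probs per-span probability, in `[0, 1]`, that the span is helical
#'   (ordered) in any given frame.
#' @param noise Gaussian coordinate noise amplitude per frame, Angstrom.
#' @return a `helix_schedule` object.
#' @export
helix_schedule <- function(spans, probs, noise = 0.05) {
  if (length(spans) != length(probs))
    stop("spans and probs must have equal length")
  if (any(probs < 0 | probs > 1)) stop("order probabilities must be in [0, 1]")
  starts <- vapply(spans, `[`, numeric(1), 1)
  ends <- vapply(spans, `[`, numeric(1), 2)
  o <- order(starts)
  if (length(spans) > 1L && any(starts[o][-1] <= ends[o][-length(ends)]))
    stop("helical spans overlap")
  structure(list(spans = spans, probs = probs, noise = noise),
            class = "helix_schedule")
}

#' Generate a conformational ensemble with a known order/disorder schedule
#'
#' Each frame independently keeps each scheduled span helical with the
#' span's order probability; otherwise the span is re-dihedralized to random
#' coil (phi uniform in \[-170, -60\], psi uniform in \[60, 175\], i.e. the
#' generously allowed extended region, unambiguously non-helical).
#' Residues outside every span stay extended. All frames share one topology.
#'
#' @param base single-model `structure3d` built by [build_ideal_helix()]
#'   (its protein sequence is reused; one chain).
#' @param schedule a [helix_schedule()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return a multi-model `structure3d` (the ensemble).
#' @export
generate_ensemble <- function(base, schedule, n_frames, seed = NULL) {
  stopifnot(inherits(schedule, "helix_schedule"), n_frames >= 1)
  a <- base$atoms[base$atoms$model == base$atoms$model[1], , drop = FALSE]
  ca <- a[a$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  sequence <- paste(aa3_to_1(ca$resname), collapse = "")
  chain <- ca$chain[1]
  n <- nchar(sequence)

  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      phi <- rep(-120, n); psi <- rep(120, n)
      for (k in seq_along(schedule$spans)) {
        sp <- schedule$spans[[k]]
        idx <- sp[1]:sp[2]
        if (stats::runif(1) <= schedule$probs[k]) {
          phi[idx] <- -57; psi[idx] <- -47
        } else {
          phi[idx] <- stats::runif(length(idx), -170, -60)
          psi[idx] <- stats::runif(length(idx), 60, 175)
        }
      }
      atoms <- build_backbone(sequence, phi, psi, chain = chain, model = f)
      if (schedule$noise > 0) {
        jit <- matrix(stats::rnorm(3L * nrow(atoms), sd = schedule$noise),
                      ncol = 3)
        atoms$x <- atoms$x + jit[, 1]
        atoms$y <- atoms$y + jit[, 2]
        atoms$z <- atoms$z + jit[, 3]
      }
      frames[[f]] <- atoms
    }
    new_structure3d(do.call(rbind, frames))
  })
}

## --- predictor tables -------------------------------------------------------

#' Specification for a synthetic site-prediction table
#'
#' @param n_sites number of candidate modification sites.
#' @param programs named list: modification class (phospho, acetyl, methyl,
#'   ubiq, sumo) -> character vector of program names.
#' @param agreement probability, in `[0, 1]`, that any given program calls
#'   any given site modified.
#' @param seed integer seed.
#' @return a `prediction_table_spec` object.
#' @export
prediction_table_spec <- function(n_sites, programs, agreement, seed = NULL) {
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  if (is.null(names(programs)) || any(!nzchar(names(programs))))
    stop("programs must be a named list keyed by modification class")
  structure(list(n_sites = n_sites, programs = programs,
                 agreement = agreement, seed = seed),
            class = "prediction_table_spec")
}

.class_residue <- c(phospho = "S", acetyl = "K", methyl = "K",
                    ubiq = "K", sumo = "K")

#' Generate a synthetic per-site per-program prediction table
#'
#' For every site and program the table carries a raw score and the program's
#' cutoff, arranged so that a program calls the site modified (raw score
#' strictly above cutoff) with probability equal to the spec's agreement
#' level.
#'
#' @param spec a [prediction_table_spec()].
#' @return data.frame with columns `site`, `residue`, `class`, `program`,
#'   `score`, `cutoff` (a SitePredictionTable).
#' @export
generate_prediction_table <- function(spec) {
  stopifnot(inherits(spec, "prediction_table_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (cls in names(spec$programs)) {
      progs <- spec$programs[[cls]]
      for (p in progs) {
        cutoff <- round(stats::runif(1, 0.3, 0.7), 3)
        predicted <- stats::runif(spec$n_sites) < spec$agreement
        delta <- stats::runif(spec$n_sites, 0.05, 0.3)
        score <- ifelse(predicted, cutoff + delta, cutoff - delta)
        rows[[length(rows) + 1L]] <- data.frame(
          site = seq_len(spec$n_sites),
          residue = unname(.class_residue[cls]),
          class = cls, program = p,
          score = round(score, 4), cutoff = cutoff,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

## --- interface fixtures ------------------------------------------------------

engineered_atom <- function(chain, resno, resname, atom, element, xyz) {
  data.frame(model = 1L, chain = chain, resno = resno, resname = resname,
             atom = atom, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

#' Two-chain complex with one engineered contact per interface category
#'
#' Constructs chains A and B carrying exactly one contact of each category
#' across the A/B interface, each in its own well-separated region:
#' a salt bridge (Lys NZ to Asp OD1, 4.80 A), a hydrogen bond (Ser HG to
#' Ser OG, 2.00 A), an attractive charge (Arg NH1 to Glu OE1, 5.30 A,
#' beyond the salt-bridge cutoff), a pi-pi stack (two Phe rings, centroids
#' 4.00 A), an alkyl contact (Ala CB to Leu side-chain centroid) and a
#' pi-alkyl contact (His ring to Val side-chain centroid). All other pairs
#' are out of range by construction.
#'
#' @return a `structure3d` (chains A and B).
#' @export
engineered_contact_fixture <- function() {
  reg <- function(k) c(40 * k, 0, 0)
  hex <- function(center, radius = 1.39) {
    ang <- deg2rad(seq(0, 300, 60))
    sweep(cbind(radius * cos(ang), radius * sin(ang), 0), 2, center, "+")
  }
  rows <- list(
    ## 1: salt bridge (CB present so the residue can be mutated in silico)
    engineered_atom("A", 1, "LYS", "CA", "C", reg(1) + c(0, 0, 2)),
    engineered_atom("A", 1, "LYS", "CB", "C", reg(1) + c(0, 1.2, 2.9)),
    engineered_atom("A", 1, "LYS", "NZ", "N", reg(1)),
    engineered_atom("B", 1, "ASP", "CA", "C", reg(1) + c(4.8, 0, 2)),
    engineered_atom("B", 1, "ASP", "OD1", "O", reg(1) + c(4.8, 0, 0)),
    ## 2: hydrogen bond
    engineered_atom("A", 2, "SER", "CA", "C", reg(2) + c(0, 0, 2)),
    engineered_atom("A", 2, "SER", "OG", "O", reg(2) + c(0, 0, 1)),
    engineered_atom("A", 2, "SER", "HG", "H", reg(2)),
    engineered_atom("B", 2, "SER", "CA", "C", reg(2) + c(2, 0, 2)),
    engineered_atom("B", 2, "SER", "OG", "O", reg(2) + c(2, 0, 0)),
    ## 3: attractive charge (beyond the salt-bridge cutoff)
    engineered_atom("A", 3, "ARG", "CA", "C", reg(3) + c(0, 0, 2)),
    engineered_atom("A", 3, "ARG", "CB", "C", reg(3) + c(0, 1.2, 2.9)),
    engineered_atom("A", 3, "ARG", "NH1", "N", reg(3)),
    engineered_atom("B", 3, "GLU", "CA", "C", reg(3) + c(5.3, 0, 2)),
    engineered_atom("B", 3, "GLU", "OE1", "O", reg(3) + c(5.3, 0, 0)))
  ## 4: pi-pi stack (two Phe rings 4 A apart)
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ha <- hex(reg(4)); hb <- hex(reg(4) + c(0, 0, 4))
  for (i in seq_along(ring_names)) {
    rows[[length(rows) + 1L]] <-
      engineered_atom("A", 4, "PHE", ring_names[i], "C", ha[i, ])
    rows[[length(rows) + 1L]] <-
      engineered_atom("B", 4, "PHE", ring_names[i], "C", hb[i, ])
  }
  rows <- c(rows, list(
    engineered_atom("A", 4, "PHE", "CA", "C", reg(4) + c(0, 0, 3)),
    engineered_atom("B", 4, "PHE", "CA", "C", reg(4) + c(0, 0, 7)),
    ## 5: alkyl contact
    engineered_atom("A", 5, "ALA", "CA", "C", reg(5) + c(0, 0, 2)),
    engineered_atom("A", 5, "ALA", "CB", "C", reg(5)),
    engineered_atom("B", 5, "LEU", "CA", "C", reg(5) + c(4.5, 0, 2)),
    engineered_atom("B", 5, "LEU", "CB", "C", reg(5) + c(4.5, 0, 0.75)),
    engineered_atom("B", 5, "LEU", "CG", "C", reg(5) + c(4.5, 0, -0.75)),
    engineered_atom("B", 5, "LEU", "CD1", "C", reg(5) + c(5.4, 0, -1.5)),
    engineered_atom("B", 5, "LEU", "CD2", "C", reg(5) + c(3.6, 0, -1.5))))
  ## 6: pi-alkyl (His ring to Val side chain)
  pent_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
  pent_el <- c("C", "N", "C", "N", "C")
  ang <- deg2rad(c(0, 72, 144, 216, 288))
  pent <- sweep(cbind(1.2 * cos(ang), 1.2 * sin(ang), 0), 2, reg(6), "+")
  for (i in seq_along(pent_names)) {
    rows[[length(rows) + 1L]] <-
      engineered_atom("A", 6, "HIS", pent_names[i], pent_el[i], pent[i, ])
  }
  rows <- c(rows, list(
    engineered_atom("A", 6, "HIS", "CA", "C", reg(6) + c(0, 0, 3)),
    engineered_atom("B", 6, "VAL", "CA", "C", reg(6) + c(0, 2, 5.5)),
    engineered_atom("B", 6, "VAL", "CB", "C", reg(6) + c(0, 0, 5.2)),
    engineered_atom("B", 6, "VAL", "CG1", "C", reg(6) + c(0.75, 0, 5.9)),
    engineered_atom("B", 6, "VAL", "CG2", "C", reg(6) + c(-0.75, 0, 5.9))))
  new_structure3d(do.call(rbind, rows))
}

#' Toy DNA binder for docking experiments
#'
#' A 16-residue Ser/Ala peptide; the cationic version carries four basic
#' side chains (two Lys, two Arg, built by [mutate_residues()]) forming a
#' positive patch, the neutral control has none. Used for docking
#' enrichment checks.
#'
#' @param charged build the cationic version.
#' @param seed integer seed (coordinate noise).
#' @return a single-model `structure3d`, chain A.
#' @export
build_toy_binder <- function(charged = TRUE, seed = NULL) {
  base <- build_ideal_helix("SAAASAAASAAASAAA", list(c(2, 15)), seed = seed,
                            noise = 0.05)
  if (!charged) return(base)
  mutate_residues(base, c("A:3" = "LYS", "A:7" = "ARG",
                          "A:11" = "LYS", "A:15" = "ARG"))
}

## --- motif-embedded sequences ----------------------------------------------

#' Embed motifs in a synthetic background sequence
#'
#' The background is drawn from a flat distribution over amino acids that
#' excludes the anchor letters of the common scanned motifs (K, R, L, G), so
#' planted NLS/NES/AT-hook motifs cannot acquire spurious copies or
#' extensions; motifs are placed verbatim.
#'
#' @param length total sequence length.
#' @param placements list of `list(motif = <string>, start = <1-based int>)`.
#' @param seed integer seed.
#' @return one-letter amino-acid string.
#' @export
embed_motifs <- function(length, placements = list(), seed = NULL) {
  background <- c("A", "C", "D", "E", "F", "H", "M", "N", "P", "Q",
                  "S", "T", "V", "W", "Y")
  occupied <- rep(FALSE, length)
  for (pl in placements) {
    end <- pl$start + nchar(pl$motif) - 1L
    if (pl$start < 1L || end > length)
      stop("motif placement out of range: start ", pl$start)
    if (any(occupied[pl$start:end]))
      stop("motif placements overlap at position ", pl$start)
    occupied[pl$start:end] <- TRUE
  }
  with_seed(seed, {
    letters_out <- sample(background, length, replace = TRUE)
    for (pl in placements) {
      end <- pl$start + nchar(pl$motif) - 1L
      letters_out[pl$start:end] <- strsplit(toupper(pl$motif), "")[[1]]
    }
    paste(letters_out, collapse = "")
  })
}
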