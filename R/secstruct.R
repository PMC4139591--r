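## Secondary-structure assignment: helix spans from backbone dihedrals,
## beta- and gamma-turn detection, solvent accessibility and buried/exposed
## labels.

## helical dihedral window (degrees): alpha basin +/- 35 around (-57, -47)
.helix_phi <- c(-57 - 35, -57 + 35)
.helix_psi <- c(-47 - 35, -47 + 35)

#' Assign helical spans
#'
#' A residue is helical when its (phi, psi) fall within (-57 +/- 35,
#' -47 +/- 35) degrees; maximal runs of at least 4 consecutive helical
#' residues become spans. Residues with undefined dihedrals (termini, gaps)
#' are non-helical. Span lengths are inclusive: `length = end - start + 1`.
#'
#' @param struct a `structure3d`.
#' @param model model number.
#' @return data.frame `kind`, `chain`, `start`, `end`, `length`; zero rows
#'   when no helix is found.
#' @export
assign_helices <- function(struct, model = 1L) {
  dh <- backbone_dihedrals(struct, model = model)
  helical <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= .helix_phi[1] & dh$phi <= .helix_phi[2] &
    dh$psi >= .helix_psi[1] & dh$psi <= .helix_psi[2]
  spans <- list()
  for (ch in unique(dh$chain)) {
    sel <- dh$chain == ch
    resnos <- dh$resno[sel]
    h <- helical[sel]
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 4L)) {
      idx <- starts[k]:ends[k]
      ## split at numbering gaps inside the run
      sub <- split(idx, cumsum(c(TRUE, diff(resnos[idx]) != 1L)))
      for (s in sub) {
        if (length(s) >= 4L)
          spans[[length(spans) + 1L]] <- data.frame(
            kind = "helix", chain = ch,
            start = resnos[s[1]], end = resnos[s[length(s)]],
            length = length(s), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(spans) == 0L)
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, spans)
  out[order(out$chain, out$start), ]
}

#' Detect beta-turns
#'
#' A beta-turn is a window of 4 consecutive residues, all outside helix
#' spans, whose first and fourth C-alpha atoms are less than 7 Angstrom
#' apart (strict inequality). Overlapping windows are reduced to maximal
#' non-overlapping turns scanning N- to C-terminus.
#'
#' @param struct a `structure3d`.
#' @param helix_spans data.frame from [assign_helices()] (computed when
#'   omitted).
#' @param model model number.
#' @param max_dist C-alpha(i) to C-alpha(i+3) cutoff, Angstrom (strict `<`).
#' @return data.frame `kind`, `chain`, `start`, `end`, `length`, `ca_dist`.
#' @export
detect_beta_turns <- function(struct, helix_spans = NULL, model = 1L,
                              max_dist = 7) {
  if (is.null(helix_spans)) helix_spans <- assign_helices(struct, model)
  a <- struct$atoms[struct$atoms$model == model &
                      struct$atoms$atom == "CA", , drop = FALSE]
  turns <- list()
  for (ch in unique(a$chain)) {
    ac <- a[a$chain == ch, , drop = FALSE]
    ac <- ac[order(ac$resno), , drop = FALSE]
    in_helix <- rep(FALSE, nrow(ac))
    hs <- helix_spans[helix_spans$chain == ch, , drop = FALSE]
    for (k in seq_len(nrow(hs)))
      in_helix <- in_helix | (ac$resno >= hs$start[k] & ac$resno <= hs$end[k])
    xyz <- coords(ac)
    last_end <- -Inf
    for (i in seq_len(max(0L, nrow(ac) - 3L))) {
      idx <- i:(i + 3L)
      if (any(diff(ac$resno[idx]) != 1L)) next
      if (any(in_helix[idx])) next
      if (ac$resno[i] <= last_end) next   # maximal non-overlapping, N->C
      d <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
      if (d < max_dist) {
        turns[[length(turns) + 1L]] <- data.frame(
          kind = "beta_turn", chain = ch, start = ac$resno[i],
          end = ac$resno[i + 3L], length = 4L, ca_dist = d,
          stringsAsFactors = FALSE)
        last_end <- ac$resno[i + 3L]
      }
    }
  }
  if (length(turns) == 0L)
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), ca_dist = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, turns)
}

#' Detect gamma-turns
#'
#' A gamma-turn is a window of 3 consecutive residues with a hydrogen bond
#' between the first and third: carbonyl O(i) to amide H(i+2) at most 2.5
#' Angstrom when amide hydrogens are present, else O(i) to N(i+2) at most
#' 3.5 Angstrom (heavy-atom fallback). The turn is flagged `classic` when
#' the central residue's (phi, psi) are within +/- 30 degrees of
#' (75, -64). Maximal non-overlapping windows, scanning N- to C-terminus.
#'
#' @param struct a `structure3d`.
#' @param model model number.
#' @return data.frame `kind`, `chain`, `start`, `end`, `length`, `classic`,
#'   `hbond_dist`.
#' @export
detect_gamma_turns <- function(struct, model = 1L) {
  a <- struct$atoms[struct$atoms$model == model, , drop = FALSE]
  dh <- backbone_dihedrals(struct, model = model)
  turns <- list()
  for (ch in unique(a$chain)) {
    ac <- a[a$chain == ch, , drop = FALSE]
    resnos <- sort(unique(ac$resno))
    getatom <- function(rn, nm) {
      row <- ac[ac$resno == rn & ac$atom == nm, , drop = FALSE]
      if (nrow(row) == 0L) NULL else as.numeric(row[1, c("x", "y", "z")])
    }
    last_end <- -Inf
    for (i in seq_len(max(0L, length(resnos) - 2L))) {
      rn <- resnos[i:(i + 2L)]
      if (any(diff(rn) != 1L)) next
      if (rn[1] <= last_end) next
      o1 <- getatom(rn[1], "O")
      if (is.null(o1)) next
      h3 <- getatom(rn[3], "H")
      n3 <- getatom(rn[3], "N")
      hit <- FALSE; d <- NA_real_
      if (!is.null(h3)) {
        d <- vnorm(o1 - h3)
        hit <- d <= 2.5
      } else if (!is.null(n3)) {
        d <- vnorm(o1 - n3)
        hit <- d <= 3.5
      }
      if (!hit) next
      mid <- dh[dh$chain == ch & dh$resno == rn[2], , drop = FALSE]
      classic <- nrow(mid) == 1L && !is.na(mid$phi) && !is.na(mid$psi) &&
        abs(mid$phi - 75) <= 30 && abs(mid$psi - (-64)) <= 30
      turns[[length(turns) + 1L]] <- data.frame(
        kind = "gamma_turn", chain = ch, start = rn[1], end = rn[3],
        length = 3L, classic = classic, hbond_dist = d,
        stringsAsFactors = FALSE)
      last_end <- rn[3]
    }
  }
  if (length(turns) == 0L)
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), classic = logical(0),
                      hbond_dist = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, turns)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area by quasi-uniform sphere point sampling
#' (Fibonacci lattice) with a rolling probe, summed per residue. Hydrogens
#' are included (they are first-class atoms here). Relative ASA divides by a
#' Gly-X-Gly maximal-exposure reference per residue type; residues without a
#' reference value (e.g. nucleotides) get `NA` relative ASA.
#'
#' @param struct a `structure3d`.
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @param model model number.
#' @return data.frame `chain`, `resno`, `resname`, `asa` (Angstrom^2),
#'   `rel_asa`.
#' @export
asa_shrake_rupley <- function(struct, probe = 1.4, n_points = 960,
                              model = 1L) {
  a <- struct$atoms[struct$atoms$model == model, , drop = FALSE]
  unknown <- setdiff(unique(a$element), names(.vdw_radii))
  if (length(unknown) > 0L)
    stop("unknown element (no van der Waals radius): ",
         paste(unknown, collapse = ", "))
  radii <- .vdw_radii[a$element] + probe
  xyz <- coords(a)
  pts <- sphere_points(n_points)
  n <- nrow(a)
  atom_asa <- numeric(n)
  ## neighbor pruning via squared-distance matrix (fine at these sizes)
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    if (length(nb) > 0L) {
      pd2 <- cross_dist2(p, xyz[nb, , drop = FALSE])
      buried <- rowSums(sweep(pd2, 2, radii[nb]^2, "<")) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    atom_asa[i] <- 4 * pi * ri * ri * acc / n_points
  }
  res_key <- paste(a$chain, a$resno)
  agg <- rowsum(atom_asa, res_key)
  first <- !duplicated(res_key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resname = a$resname[first],
                    asa = agg[match(res_key[first], rownames(agg)), 1],
                    stringsAsFactors = FALSE)
  out$rel_asa <- out$asa / unname(.max_asa[out$resname])
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Buried/exposed labels
#'
#' Residues with relative ASA strictly below the threshold are buried
#' (`"b"`); at or above it, exposed (`"e"`).
#'
#' @param records data.frame from [asa_shrake_rupley()] (needs `rel_asa`).
#' @param threshold relative-ASA threshold.
#' @return the records with an added `label` column.
#' @export
classify_exposure <- function(records, threshold = 0.25) {
  records$label <- ifelse(records$rel_asa < threshold, "b", "e")
  records
}
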