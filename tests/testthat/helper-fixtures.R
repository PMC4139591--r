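## Shared fixtures, built in code.

## quick atom-table row constructor
atom_row <- function(chain, resno, resname, atom, element, x, y, z,
                     model = 1L) {
  data.frame(model = model, chain = chain, resno = resno, resname = resname,
             atom = atom, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

mini_structure <- function(...) new_structure3d(rbind(...))

## the helix-loop-helix demo layout used throughout: 100 residues with
## helices at 20-33, 65-72, 80-98
hlh_spans <- list(c(20, 33), c(65, 72), c(80, 98))

hlh_structure <- function(noise = 0, seed = NULL) {
  build_ideal_helix(strrep("A", 100), hlh_spans, seed = seed, noise = noise)
}

## three-residue chain with a chosen middle (phi, psi) and the amide H of
## residue 3 repositioned at a chosen distance from O(1) (H placement does
## not affect dihedrals)
gamma_fixture <- function(mid_phi, mid_psi, oh_dist) {
  atoms <- nuprtools:::build_backbone("AAA",
                                      phi = c(-120, mid_phi, -120),
                                      psi = c(120, mid_psi, 120))
  o1 <- unlist(atoms[atoms$resno == 1 & atoms$atom == "O", c("x", "y", "z")])
  n3 <- unlist(atoms[atoms$resno == 3 & atoms$atom == "N", c("x", "y", "z")])
  dir <- (n3 - o1) / sqrt(sum((n3 - o1)^2))
  h3 <- o1 + oh_dist * dir
  i <- which(atoms$resno == 3 & atoms$atom == "H")
  atoms$x[i] <- h3[1]; atoms$y[i] <- h3[2]; atoms$z[i] <- h3[3]
  new_structure3d(atoms)
}

## a pair of atoms of given types at a given distance, on two chains
two_atom_fixture <- function(res1, atom1, el1, res2, atom2, el2, dist,
                             chain2 = "B") {
  mini_structure(
    atom_row("A", 1, res1, atom1, el1, 0, 0, 0),
    atom_row(chain2, 1, res2, atom2, el2, dist, 0, 0))
}

## random-coil ensemble frames as standalone structures (unrelated folds)
random_fold <- function(n, seed, noise = 2.5, spans = list()) {
  build_ideal_helix(strrep("A", n), spans, seed = seed, noise = noise)
}
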