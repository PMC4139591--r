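test_that("salt bridges pair charged N/O atoms within 5.0 A inclusive", {
  s <- two_atom_fixture("LYS", "NZ", "N", "DA", "OP2", "O", 2.53,
                        chain2 = "C")
  rec <- detect_salt_bridges(s, list("A", "C"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$distance, 2.53, tolerance = 1e-9)
  expect_equal(rec$from, "A:Lys1:NZ")
  expect_equal(rec$to, "C:A1:OP2")

  ## boundary behavior: inclusive at the cutoff, strict beyond
  for (d in c(4.99, 5.00)) {
    s2 <- two_atom_fixture("LYS", "NZ", "N", "ASP", "OD1", "O", d)
    expect_equal(nrow(detect_salt_bridges(s2, list("A", "B"))), 1L)
  }
  for (d in c(5.01, 5.05)) {
    s2 <- two_atom_fixture("LYS", "NZ", "N", "ASP", "OD1", "O", d)
    expect_equal(nrow(detect_salt_bridges(s2, list("A", "B"))), 0L)
  }

  ## same-sign pairs never bridge
  pp <- two_atom_fixture("LYS", "NZ", "N", "ARG", "NH1", "N", 3)
  expect_equal(nrow(detect_salt_bridges(pp, list("A", "B"))), 0L)
})

test_that("hydrogen bonds need a polar donor H within 2.5 A of an acceptor", {
  arg_h <- function(d) mini_structure(
    atom_row("A", 60, "ARG", "NH1", "N", 0, 0, 0.9),
    atom_row("A", 60, "ARG", "HH12", "H", 0, 0, 0),
    atom_row("C", 8, "DA", "OP1", "O", 0, 0, -d))
  rec <- detect_hydrogen_bonds(arg_h(1.87), list("A", "C"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$distance, 1.87, tolerance = 1e-9)
  expect_equal(rec$from, "A:Arg60:HH12")
  expect_false(rec$fallback)

  expect_equal(nrow(detect_hydrogen_bonds(arg_h(2.50), list("A", "C"))), 1L)
  expect_equal(nrow(detect_hydrogen_bonds(arg_h(2.51), list("A", "C"))), 0L)

  ## carbon-bound hydrogens are not donors
  ch <- mini_structure(
    atom_row("A", 1, "ALA", "CB", "C", 0, 0, 1.0),
    atom_row("A", 1, "ALA", "HB1", "H", 0, 0, 0),
    atom_row("B", 1, "SER", "OG", "O", 0, 0, -1.8))
  expect_equal(nrow(detect_hydrogen_bonds(ch, list("A", "B"))), 0L)

  ## heavy-atom fallback when the structure carries no hydrogens
  heavy <- two_atom_fixture("SER", "OG", "O", "DA", "O5'", "O", 2.9,
                            chain2 = "C")
  rec2 <- detect_hydrogen_bonds(heavy, list("A", "C"))
  expect_gt(nrow(rec2), 0L)
  expect_true(all(rec2$fallback))
})

test_that("electrostatic and hydrophobic categories follow their cutoffs", {
  att <- two_atom_fixture("ARG", "NH2", "N", "ASP", "OD1", "O", 5.53)
  rec <- detect_other_interactions(att, list("A", "B"))
  expect_equal(rec$category, "electrostatic_attractive")
  expect_equal(rec$distance, 5.53, tolerance = 1e-9)

  ## stacked DNA bases in the fiber-model duplex
  d <- build_bdna(strrep("A", 4))
  pp <- detect_other_interactions(d, "intra")
  pp <- pp[pp$category == "pi_pi_stacked", ]
  expect_gt(nrow(pp), 0L)
  expect_true(all(pp$distance <= 5.5))

  ## two Leu side chains 8 A apart are out of range
  far <- mini_structure(
    atom_row("A", 1, "LEU", "CB", "C", 0, 0, 0),
    atom_row("A", 1, "LEU", "CG", "C", 0, 0, 1.5),
    atom_row("B", 1, "LEU", "CB", "C", 8, 0, 0),
    atom_row("B", 1, "LEU", "CG", "C", 8, 0, 1.5))
  expect_equal(nrow(detect_other_interactions(far, list("A", "B"))), 0L)
})

test_that("the engineered fixture yields exactly one record per category", {
  fx <- engineered_contact_fixture()
  rep <- interaction_report(fx, "A", "B")
  expect_equal(nrow(rep), 6L)
  expect_setequal(rep$category,
                  c("salt_bridge", "hydrogen_bond",
                    "electrostatic_attractive", "pi_pi_stacked",
                    "alkyl", "pi_alkyl"))
  expect_true(all(table(rep$category) == 1))
  ## sorted by category then distance; every distance within its cutoff
  cutoffs <- c(salt_bridge = 5.0, hydrogen_bond = 2.5,
               electrostatic_attractive = 5.6, pi_pi_stacked = 5.5,
               alkyl = 5.5, pi_alkyl = 6.0)
  expect_true(all(rep$distance <= cutoffs[rep$category]))

  ## report is stable under chain relabeling
  relab <- fx
  relab$atoms$chain <- ifelse(relab$atoms$chain == "A", "X", "Y")
  rep2 <- interaction_report(relab, "X", "Y")
  expect_equal(rep2$category, rep$category)
  expect_equal(rep2$distance, rep$distance)

  ## protein-only intramolecular report carries no DNA-phosphate contacts
  intra <- interaction_report(hlh_structure(), "intra")
  expect_false(any(grepl("OP[12]", c(intra$from, intra$to))))

  expect_error(interaction_report(fx, "Z", "B"), "empty partner")
})

test_that("in-silico mutation rewires detected contacts", {
  fx <- engineered_contact_fixture()
  wt <- interaction_report(fx, "A", "B")

  mut <- mutate_residues(fx, c("A:1" = "GLU"))
  expect_equal(unique(mut$atoms$resname[mut$atoms$chain == "A" &
                                          mut$atoms$resno == 1]), "GLU")
  mt <- interaction_report(mut, "A", "B")
  rw <- rewiring(wt, mt)
  expect_equal(rw$lost, "salt_bridge|A:1|B:1")
  expect_equal(length(rw$gained), 0L)
  expect_equal(length(rw$conserved), 5L)

  ## same-type substitution leaves the report unchanged
  same <- mutate_residues(fx, c("A:1" = "LYS"))
  expect_equal(interaction_report(same, "A", "B"), wt)

  ## Gly target has no CB to build from
  gly <- mini_structure(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
                        atom_row("A", 1, "GLY", "N", "N", 1.4, 0, 0))
  expect_error(mutate_residues(gly, c("A:1" = "GLU")), "no CB")
  expect_error(mutate_residues(fx, c("A:1" = "TRP")), "unsupported")
})

test_that("rewiring is a keyed set difference", {
  rec <- function(cat, from, to) data.frame(
    category = cat, from = from, to = to, distance = 3,
    stringsAsFactors = FALSE)
  wt <- rbind(
    rec("salt_bridge", "C:A7:OP2", "A:Arg60:NH1"),
    rec("salt_bridge", "D:T29:OP2", "A:Lys61:NZ"),
    rec("salt_bridge", "C:A7:OP2", "A:Lys65:NZ"),
    rec("salt_bridge", "D:T22:OP2", "A:Arg96:NH1"),
    rec("salt_bridge", "D:T21:OP2", "A:Arg99:NH1"),
    rec("salt_bridge", "D:T22:OP2", "A:Arg100:NH1"))
  mut <- rbind(
    rec("salt_bridge", "D:T31:OP1", "A:Arg66:NH2"),
    rec("salt_bridge", "C:A5:OP2", "A:Arg66:NE"),
    rec("salt_bridge", "D:T25:OP2", "A:Arg93:NH1"),
    rec("salt_bridge", "C:A9:OP1", "A:Lys95:NZ"))
  rw <- rewiring(wt, mut)
  expect_equal(length(rw$lost), 6L)
  expect_equal(length(rw$gained), 4L)
  expect_equal(length(rw$conserved), 0L)

  same <- rewiring(wt, wt)
  expect_equal(length(same$lost), 0L)
  expect_equal(length(same$gained), 0L)

  subset_rw <- rewiring(wt, wt[1:3, ])
  expect_equal(length(subset_rw$gained), 0L)
  expect_equal(length(subset_rw$lost), 3L)
})

test_that("docking scores favor the cationic binder and are seed-stable", {
  dna <- build_bdna(strrep("A", 10))
  cationic <- build_toy_binder(TRUE, seed = 3)
  neutral <- build_toy_binder(FALSE, seed = 3)

  r_neu <- dock_to_bdna(neutral, dna, n_poses = 100, seed = 21)
  expect_true(all(r_neu$poses$score <= 0))

  wins <- vapply(1:3, function(k) {
    rc <- dock_to_bdna(cationic, dna, n_poses = 300, seed = 30 + k)
    rn <- dock_to_bdna(neutral, dna, n_poses = 300, seed = 30 + k)
    rc$top_score > rn$top_score
  }, logical(1))
  expect_true(all(wins))

  a <- dock_to_bdna(cationic, dna, n_poses = 50, seed = 77)
  b <- dock_to_bdna(cationic, dna, n_poses = 50, seed = 77)
  expect_identical(a$poses, b$poses)
  expect_identical(a$clusters, b$clusters)
})

test_that("groove assignment distinguishes minor, major, backbone, distal", {
  d <- build_bdna(strrep("A", 10))
  rise <- 3.38
  th <- nuprtools:::deg2rad(4.5 * 36)
  expect_equal(groove_assignment(d, c(4.5 * cos(th), 4.5 * sin(th),
                                      4.5 * rise)), "minor")
  expect_equal(groove_assignment(d, c(-6 * cos(th), -6 * sin(th),
                                      4.5 * rise)), "major")
  expect_equal(groove_assignment(d, c(40, 0, 0)), "distal")
  p <- d$atoms[d$atoms$atom == "P", ][3, ]
  expect_equal(groove_assignment(d, c(p$x + 0.5, p$y, p$z)), "backbone")
  expect_error(groove_assignment(hlh_structure(), c(0, 0, 0)), "build_bdna")
})
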