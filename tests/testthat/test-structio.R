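test_that("a single ATOM record parses into a one-atom structure", {
  line <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  s <- parse_pdb(line)
  a <- s$atoms
  expect_equal(nrow(a), 1L)
  expect_equal(a$atom, "CA")
  expect_equal(a$resname, "ALA")
  expect_equal(a$chain, "A")
  expect_equal(unname(unlist(a[, c("x", "y", "z")])), c(0, 0, 0))
})

test_that("MODEL blocks yield multiple models with identical topology", {
  base <- build_ideal_helix("GAKLME", list(c(2, 5)))
  sch <- helix_schedule(list(c(2, 5)), 0.5)
  ens <- generate_ensemble(base, sch, n_frames = 2, seed = 1)
  s <- parse_pdb(write_pdb(ens))
  expect_equal(n_models(s), 2L)
  m1 <- get_model(s, 1)$atoms
  m2 <- get_model(s, 2)$atoms
  expect_identical(m1[, c("chain", "resno", "resname", "atom")],
                   m2[, c("chain", "resno", "resname", "atom")])
})

test_that("write/parse round trip preserves hierarchy and coordinates", {
  s <- build_ideal_helix("GAKLMESTVWYDNQH", list(c(3, 12)), seed = 7,
                         noise = 0.4)
  r1 <- parse_pdb(write_pdb(s))
  r2 <- parse_pdb(write_pdb(r1))
  expect_equal(nrow(r1$atoms), nrow(s$atoms))
  expect_identical(r1$atoms[, c("chain", "resno", "resname", "atom")],
                   s$atoms[, c("chain", "resno", "resname", "atom")])
  ## coordinates preserved to the 3-decimal output precision, then exactly
  expect_true(max(abs(as.matrix(r1$atoms[, c("x", "y", "z")]) -
                        as.matrix(s$atoms[, c("x", "y", "z")]))) <= 5e-4)
  expect_identical(r1$atoms, r2$atoms)
})

test_that("the parser agrees with bio3d on a generated file", {
  skip_if_not_installed("bio3d")
  s <- build_ideal_helix("GAKLMESTVW", list(c(2, 9)), seed = 3, noise = 0.2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  ours <- read_pdb(path)$atoms
  theirs <- bio3d::read.pdb(path)$atom
  expect_equal(nrow(ours), nrow(theirs))
  expect_equal(ours$atom, theirs$elety)
  expect_equal(ours$x, theirs$x, tolerance = 1e-6)
  expect_equal(ours$resno, theirs$resno)
})

test_that("malformed records raise errors naming the line", {
  txt <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1      bad")
  expect_error(parse_pdb(txt), "line 2")
  expect_error(parse_pdb("HEADER only"), "no ATOM/HETATM")
})

test_that("altlocs keep the first copy with a warning", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  1.00  0.00           C")
  expect_warning(s <- parse_pdb(txt), "altloc")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 0)
})

test_that("single-letter DNA residue names are stored canonically", {
  txt <- c(
    "ATOM      1  P     A C   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  P    DT D   1       5.000   0.000   0.000  1.00  0.00           P")
  s <- parse_pdb(txt)
  expect_setequal(s$atoms$resname, c("DA", "DT"))
  expect_equal(unname(chain_types(s)), c("dna", "dna"))
})

test_that("atom-name normalization maps O1P/O2P and nothing else, idempotently", {
  s <- mini_structure(
    atom_row("C", 1, "DA", "O1P", "O", 0, 0, 0),
    atom_row("C", 1, "DA", "O2P", "O", 1, 0, 0),
    atom_row("A", 1, "ALA", "CA", "C", 5, 0, 0))
  n1 <- normalize_atom_names(s)
  expect_equal(n1$atoms$atom, c("OP1", "OP2", "CA"))
  expect_identical(normalize_atom_names(n1)$atoms, n1$atoms)
  expect_equal(nrow(n1$atoms), nrow(s$atoms))
  expect_equal(n1$atoms$x, s$atoms$x)
})

test_that("atom specs parse, format, and round-trip", {
  sp <- parse_atom_spec("A:Arg60:NH2")
  expect_equal(sp$chain_id, "A")
  expect_equal(sp$residue_name, "Arg")
  expect_equal(sp$residue_number, 60L)
  expect_equal(sp$atom_name, "NH2")

  sp2 <- parse_atom_spec("C:A7:OP2")
  expect_equal(sp2$residue_name, "A")
  expect_equal(sp2$residue_number, 7L)

  for (txt in c("A:Arg60:NH2", "C:A7:OP2", "D:T29:O1P", "B:Lys100:OXT"))
    expect_identical(format_atom_spec(parse_atom_spec(txt)), txt)

  expect_error(parse_atom_spec("A:Arg60"), "three colon-separated")
  expect_error(parse_atom_spec("A:Arg:NH2"), "residue number")
})
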