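test_that("NLS scanning finds cores and bipartite extensions", {
  hits <- scan_nls("AAKKRKAA")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$match, "KKRK")

  expect_equal(nrow(scan_nls("AAAASTDE")), 0L)

  ## core at 82, second basic cluster at 93-96: bipartite span 82-96
  seq <- embed_motifs(120, list(list(motif = "KKRK", start = 82),
                                list(motif = "RKKR", start = 93)), seed = 4)
  hits <- scan_nls(seq)
  bip <- hits[hits$motif == "nls_bipartite", ]
  expect_equal(nrow(bip), 1L)
  expect_equal(bip$start, 82L)
  expect_equal(bip$end, 96L)
  expect_equal(bip$match, substr(seq, 82, 96))
})

test_that("NES scanning matches the leucine spacing pattern", {
  hits <- scan_nes("LAAALAALAL")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$end - hits$start + 1L, 10L)
  expect_equal(hits$score, 1)

  expect_equal(nrow(scan_nes("LLLLAAAAAA")), 0L)

  seq <- embed_motifs(60, list(list(motif = "LAAALAALAL", start = 29)),
                      seed = 2)
  expect_equal(scan_nes(seq)$start, 29L)

  ## wide anchors admit other hydrophobics, strict anchors do not
  v <- "IAAALAALAL"
  expect_equal(nrow(scan_nes(v)), 0L)
  expect_equal(nrow(scan_nes(v, wide_anchors = TRUE)), 1L)
})

test_that("DBD scanning scores G/R/K-rich cores and pairs bipartite hits", {
  h1 <- scan_dbd("RKGRTKR")
  expect_equal(h1$motif, "dbd_core")
  expect_equal(h1$score, 6 / 7)
  h2 <- scan_dbd("KKRGARR")
  expect_equal(h2$score, 6 / 7)

  expect_equal(nrow(scan_dbd(strrep("A", 50))), 0L)

  seq <- embed_motifs(120, list(list(motif = "RKGRTKR", start = 60),
                                list(motif = "KKRGARR", start = 81)),
                      seed = 3)
  hits <- scan_dbd(seq)
  cores <- hits[hits$motif == "dbd_core", ]
  expect_equal(cores$start, c(60L, 81L))
  expect_equal(cores$end, c(66L, 87L))
  bip <- hits[hits$motif == "dbd_bipartite", ]
  expect_equal(nrow(bip), 1L)   # gap of 14 residues between the cores
  expect_equal(c(bip$start, bip$end), c(60L, 87L))
})

test_that("hydropathy profile is a centered Kyte-Doolittle window mean", {
  prof <- hydropathy_profile(strrep("I", 20), window = 9)
  expect_true(all(abs(prof$hydropathy - 4.5) < 1e-12))
  expect_equal(nrow(prof), 20 - 9 + 1)

  seq <- paste(rep(c("I", "R"), 10), collapse = "")
  prof2 <- hydropathy_profile(seq, window = 9)
  kd <- c(I = 4.5, R = -4.5)
  vals <- kd[strsplit(seq, "")[[1]]]
  direct <- vapply(seq_len(nchar(seq) - 8), function(i) mean(vals[i:(i + 8)]),
                   numeric(1))
  expect_equal(prof2$hydropathy, unname(direct))

  expect_error(hydropathy_profile("AAAA", window = 2), "odd")
})

test_that("molecular weight and pI behave like the standard models", {
  pc <- physchem("G")
  expect_equal(pc$mw, 75.07, tolerance = 0.01)

  for (seq in c("GASKLLED", strrep("K", 12), strrep("D", 12))) {
    pi <- physchem(seq)$pi
    expect_lt(abs(oracle_net_charge(seq, pi)), 1e-3)
  }
  expect_gt(physchem(strrep("K", 12))$pi, 10)
  expect_lt(physchem(strrep("D", 12))$pi, 4)
  expect_error(physchem("AB2"), "unknown residue")
})

test_that("pI is in the neighborhood of seqinr's estimate", {
  skip_if_not_installed("seqinr")
  for (seq in c("MATFPPTSSDSLEVLAPHNE", "KRKRAAADDE")) {
    ours <- physchem(seq)$pi
    theirs <- seqinr::computePI(strsplit(seq, "")[[1]])
    expect_lt(abs(ours - theirs), 1.0)   # different pKa sets
  }
})

test_that("identity matrix excludes gap-gap columns", {
  m <- identity_matrix(c(a = "AAAA", b = "AATT"))
  expect_equal(m["a", "b"], 50)
  expect_equal(diag(m), c(a = 100, b = 100))

  g <- identity_matrix(c(x = "A-A", y = "A-T"))
  expect_equal(g["x", "y"], 50)

  expect_identical(m, t(m))
  expect_error(identity_matrix(c("AA", "AAA")), "ragged")
})

test_that("aligned FASTA reads into the MSA container", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "LAV-K", ">h1", "LAI-K", ">h2", "LTMAK"), f)
  msa <- read_alignment(f)
  expect_equal(names(msa), c("ref", "h1", "h2"))
  m <- identity_matrix(msa)
  expect_equal(m["ref", "h1"], 75)
})

test_that("conservation percentages and grades follow the counting rule", {
  msa <- c(ref = "LAV", h1 = "LAI", h2 = "LTM", h3 = "LCW")
  cons <- conservation_map(msa, "ref")
  expect_equal(cons$conservation, c(100, 50, 25))
  expect_equal(cons$grade, c(9L, 5L, 3L))

  s <- build_ideal_helix("LAV", list())
  with_struct <- conservation_map(msa, "ref", struct = s)
  expect_equal(with_struct$resno, 1:3)
  s4 <- build_ideal_helix("LAVA", list())
  expect_error(conservation_map(msa, "ref", struct = s4), "mismatch")
})

test_that("meta-scores are the fraction of predicting programs per class", {
  mk_table <- function(n_above, n_total) data.frame(
    site = 1L, residue = "S", class = "phospho",
    program = paste0("p", seq_len(n_total)),
    score = c(rep(0.9, n_above), rep(0.1, n_total - n_above)),
    cutoff = 0.5, stringsAsFactors = FALSE)
  expect_equal(ptm_meta_score(mk_table(30, 30))$meta_score, 1.0)
  expect_equal(nrow(ptm_meta_score(mk_table(0, 30))), 0L)
  expect_equal(ptm_meta_score(mk_table(0, 30),
                              include_zero = TRUE)$meta_score, 0.0)
  expect_equal(ptm_meta_score(mk_table(15, 30))$meta_score, 0.5)

  ## a score exactly at the cutoff does not predict (strict >)
  at <- mk_table(1, 2)
  at$score <- c(0.5, 0.9)
  expect_equal(ptm_meta_score(at)$meta_score, 0.5)

  ## per-class totals are independent
  two <- rbind(mk_table(2, 4),
               within(mk_table(1, 2), class <- "acetyl"))
  ms <- ptm_meta_score(two)
  expect_equal(ms$meta_score[ms$class == "phospho"], 0.5)
  expect_equal(ms$meta_score[ms$class == "acetyl"], 0.5)

  bad <- mk_table(1, 2)
  bad$cutoff[1] <- NA
  expect_error(ptm_meta_score(bad), "without a cutoff")
})

test_that("meta-score is monotone as programs flip to predicting", {
  base <- data.frame(site = 1L, residue = "S", class = "phospho",
                     program = paste0("p", 1:10),
                     score = rep(0.1, 10), cutoff = 0.5)
  prev <- 0
  for (k in 1:10) {
    base$score[k] <- 0.9
    cur <- ptm_meta_score(base)$meta_score
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 1)
})
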