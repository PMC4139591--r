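test_that("superposition is exact for rigid copies and excludes reflections", {
  s <- hlh_structure()
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-10)

  rot <- nuprtools:::euler_zyz(pi / 2, 0, 0)
  moved <- transform_structure(s, rot, c(5, 0, 0))
  sp <- superpose(moved, s)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-6)
  ## recovered rotation inverts the applied one
  expect_equal(sp$rotation %*% rot, diag(3), tolerance = 1e-6)

  ## rmsd invariant under rigid motion of either input
  a <- hlh_structure(noise = 1, seed = 1)
  b <- hlh_structure(noise = 1, seed = 2)
  r0 <- superpose(a, b)$rmsd
  r1 <- superpose(transform_structure(a, rot, c(3, -2, 8)), b)$rmsd
  r2 <- superpose(a, transform_structure(b, rot, c(-4, 1, 2)))$rmsd
  expect_equal(r1, r0, tolerance = 1e-9)
  expect_equal(r2, r0, tolerance = 1e-9)
})

test_that("superposition rejects degenerate and mismatched inputs", {
  tiny <- mini_structure(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                         atom_row("A", 2, "ALA", "CA", "C", 1, 0, 0))
  expect_error(superpose(tiny, tiny), "at least 3")

  a <- build_ideal_helix("GAKL", list())
  b <- build_ideal_helix("GAEL", list())
  expect_error(superpose(a, b), "A:3: LYS vs GLU")
})

test_that("superposition matches the rotation-grid oracle on random point sets", {
  set.seed(11)
  for (k in 1:20) {
    p <- matrix(stats::rnorm(18, sd = 3), 6)
    q <- matrix(stats::rnorm(18, sd = 3), 6)
    mk <- function(m) new_structure3d(data.frame(
      model = 1, chain = "A", resno = 1:6, resname = "ALA", atom = "CA",
      element = "C", x = m[, 1], y = m[, 2], z = m[, 3]))
    expect_lt(abs(superpose(mk(p), mk(q))$rmsd - grid_rmsd_oracle(p, q)),
              1e-3)
  }
})

test_that("superposition RMSD agrees with bio3d", {
  skip_if_not_installed("bio3d")
  a <- hlh_structure(noise = 1.5, seed = 4)
  b <- hlh_structure(noise = 1.5, seed = 5)
  ours <- superpose(a, b)$rmsd
  xa <- as.vector(t(nuprtools:::coords(nuprtools:::ca_atoms(a))))
  xb <- as.vector(t(nuprtools:::coords(nuprtools:::ca_atoms(b))))
  theirs <- bio3d::rmsd(xa, xb, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("RMSD matrices are symmetric, zero-diagonal and noise-monotone", {
  base <- hlh_structure()
  models <- list(ref = base,
                 n1 = hlh_structure(noise = 0.3, seed = 1),
                 n2 = hlh_structure(noise = 0.8, seed = 2),
                 n3 = hlh_structure(noise = 1.6, seed = 3),
                 n4 = hlh_structure(noise = 3.0, seed = 4))
  m <- rmsd_matrix(models)
  expect_identical(m$values, t(m$values))
  expect_true(all(diag(m$values) == 0))
  expect_true(all(diff(m$values["ref", c("n1", "n2", "n3", "n4")]) > 0))

  two <- rmsd_matrix(list(a = base, b = base))
  expect_equal(max(abs(two$values)), 0, tolerance = 1e-10)
})

test_that("Z-scores separate identical from unrelated structures", {
  a <- build_ideal_helix(strrep("A", 40), list(c(5, 20)))
  z_self <- alignment_zscore(a, a, seed = 1)
  expect_gt(z_self$z, 3)
  expect_identical(alignment_zscore(a, a, seed = 5)$z,
                   alignment_zscore(a, a, seed = 5)$z)

  spanopts <- list(list(c(5, 18)), list(c(20, 33)),
                   list(c(8, 15), c(25, 35)), list(c(10, 22)),
                   list(c(28, 38)))
  zs <- vapply(1:20, function(k) {
    sa <- spanopts[[((2 * k - 2) %% 5) + 1]]
    sb <- spanopts[[((2 * k - 1) %% 5) + 1]]
    alignment_zscore(random_fold(40, 100 + k, spans = sa),
                     random_fold(40, 200 + k, spans = sb),
                     seed = k)$z
  }, numeric(1))
  expect_lte(mean(abs(zs)), 1)

  expect_error(alignment_zscore(a, a, null_size = 5), ">= 10")
})

test_that("consensus statistics reproduce the reference best-model aggregates", {
  ref <- load_reference_scores()
  st <- consensus_stats(ref$rmsd, ref$zscore, "Phf19")
  it <- st[st$label == "I-TASSER", ]
  expect_equal(it$mean_rmsd, mean(c(4.99, 4.16, 5.16, 4.76)))
  expect_equal(round(it$mean_rmsd, 2), 4.77)
  expect_equal(round(it$sd_rmsd, 2), 0.38)
  expect_equal(it$mean_z, mean(c(3.29, 3.7, 4.42, 2.3, 1.24)))
  expect_true(all(st$pearson_r >= -1 & st$pearson_r <= 1))
  expect_equal(it$rank, 1L)
})

test_that("degenerate consensus inputs are handled", {
  labels <- c("m1", "m2", "m3", "m4", "ctl")
  vals <- matrix(2, 5, 5, dimnames = list(labels, labels))
  diag(vals) <- 0
  zv <- matrix(1, 5, 5, dimnames = list(labels, labels))
  st <- consensus_stats(score_matrix(vals, "rmsd", "ctl"),
                        score_matrix(zv, "zscore", "ctl"), "ctl")
  expect_true(all(st$sd_rmsd == 0))
  expect_true(all(is.na(st$pearson_r)))

  small <- c("m1", "m2", "ctl")
  v3 <- vals[small, small]
  expect_error(consensus_stats(score_matrix(v3, "rmsd", "ctl"),
                               score_matrix(zv[small, small], "zscore", "ctl"),
                               "ctl"),
               "at least 3 candidate")
})

test_that("model ranking uses mean RMSD with the Z-score tie-break", {
  st <- data.frame(label = c("a", "b", "c"),
                   mean_rmsd = c(4, 4, 5),
                   mean_z = c(2, 3, 9))
  expect_equal(rank_models(st), c("b", "a", "c"))
  expect_equal(rank_models(data.frame(label = "only", mean_rmsd = 1,
                                      mean_z = 0)), "only")
})

test_that("Ramachandran classification places the canonical points", {
  expect_equal(rama_region(-57, -47), "favored")
  expect_equal(rama_region(-120, 120), "favored")
  expect_equal(rama_region(0, 0), "disallowed")
  ## the classic gamma-turn center is classified (recorded, whatever region)
  expect_true(rama_region(75, -64) %in%
                c("favored", "allowed", "disallowed"))

  s <- hlh_structure()
  r <- ramachandran(s)
  expect_equal(sum(r$percentages), 100, tolerance = 0.1)
  helix_res <- r$residues[r$residues$resno %in% 21:32, ]
  expect_true(all(helix_res$region == "favored"))
})

test_that("residues with missing backbone atoms are skipped with a warning", {
  s <- build_ideal_helix(strrep("A", 10), list(c(2, 9)))
  broken <- new_structure3d(rbind(
    s$atoms,
    atom_row("A", 11, "ALA", "CA", "C", 50, 0, 0)))
  expect_warning(r <- ramachandran(broken), "A 11")
  expect_false(11 %in% r$residues$resno)
})
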