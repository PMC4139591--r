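## a small ensemble builder: n identical copies of a base structure
replicate_frames <- function(base, n) {
  a <- base$atoms
  frames <- do.call(rbind, lapply(seq_len(n), function(f) {
    a$model <- f
    a
  }))
  new_structure3d(frames)
}

test_that("even-spaced frame sampling includes both endpoints", {
  base <- build_ideal_helix(strrep("A", 10), list(c(2, 9)))
  ens <- replicate_frames(base, 120)
  sub <- sample_frames(ens, 6)
  expect_equal(sort(unique(sub$atoms$model)), c(1L, 25L, 49L, 73L, 97L, 120L))

  expect_identical(sample_frames(ens, 120)$atoms, ens$atoms)
  s1 <- sample_frames(ens, 7, seed = 5)
  s2 <- sample_frames(ens, 7, seed = 5)
  expect_identical(unique(s1$atoms$model), unique(s2$atoms$model))
  expect_error(sample_frames(ens, 121), "cannot sample")
})

test_that("RMSF is zero for identical frames and tracks injected jitter", {
  base <- build_ideal_helix(strrep("A", 30), list(c(5, 26)))
  still <- replicate_frames(base, 10)
  expect_lt(max(rmsf_per_residue(still)$rmsf), 1e-9)

  ## jitter one residue's CA with sigma = 1 A over 200 frames and compare
  ## to a direct Monte-Carlo oracle of the same process
  n_frames <- 200
  set.seed(8)
  ens <- replicate_frames(base, n_frames)
  tgt <- which(ens$atoms$resno == 15 & ens$atoms$atom == "CA")
  jit <- matrix(stats::rnorm(3 * length(tgt), sd = 1), ncol = 3)
  ens$atoms$x[tgt] <- ens$atoms$x[tgt] + jit[, 1]
  ens$atoms$y[tgt] <- ens$atoms$y[tgt] + jit[, 2]
  ens$atoms$z[tgt] <- ens$atoms$z[tgt] + jit[, 3]
  got <- rmsf_per_residue(ens)$rmsf[15]

  oracle <- mean(replicate(50, {
    x <- matrix(stats::rnorm(3 * n_frames, sd = 1), ncol = 3)
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }))
  expect_lt(abs(got - oracle) / oracle, 0.15)
})

test_that("the always-ordered span fluctuates less than the rest of the chain", {
  base <- hlh_structure()
  sch <- helix_schedule(hlh_spans, c(1.0, 0.15, 0.5))
  ens <- generate_ensemble(base, sch, n_frames = 200, seed = 12)
  rmsf <- rmsf_per_residue(ens)
  helix1 <- rmsf$rmsf[rmsf$resno %in% 20:33]
  rest <- rmsf$rmsf[!(rmsf$resno %in% 20:33)]
  expect_lt(mean(helix1), mean(rest))
})

test_that("RMSF is invariant under a global rigid transform of every frame", {
  base <- build_ideal_helix(strrep("A", 20), list(c(4, 17)))
  sch <- helix_schedule(list(c(4, 17)), 0.5)
  ens <- generate_ensemble(base, sch, n_frames = 20, seed = 3)
  moved <- transform_structure(ens, nuprtools:::euler_zyz(1, 0.5, -2),
                               c(12, -7, 30))
  expect_equal(rmsf_per_residue(moved)$rmsf, rmsf_per_residue(ens)$rmsf,
               tolerance = 1e-9)
})

test_that("pairwise frame RMSD separates disordered from ordered ensembles", {
  base <- build_ideal_helix(strrep("A", 40), list(c(5, 20), c(25, 36)))
  spans <- list(c(5, 20), c(25, 36))
  dis <- generate_ensemble(base, helix_schedule(spans, c(0, 0)), 12, seed = 4)
  ord <- generate_ensemble(base, helix_schedule(spans, c(1, 1)), 12, seed = 4)
  m_dis <- pairwise_frame_rmsd(dis)$values
  m_ord <- pairwise_frame_rmsd(ord)$values
  expect_identical(m_dis, t(m_dis))
  expect_true(all(diag(m_dis) == 0))
  expect_gt(mean(m_dis[upper.tri(m_dis)]), mean(m_ord[upper.tri(m_ord)]))

  dup <- replicate_frames(base, 5)
  expect_lt(max(pairwise_frame_rmsd(dup)$values), 1e-9)
})

test_that("helix persistence is the fraction of helical frames", {
  base <- build_ideal_helix(strrep("A", 30), list(c(8, 23)))
  sch1 <- helix_schedule(list(c(8, 23)), 1.0, noise = 0)
  sch0 <- helix_schedule(list(c(8, 23)), 0.0, noise = 0)
  helical <- generate_ensemble(base, sch1, 3, seed = 1)$atoms
  coil <- generate_ensemble(base, sch0, 17, seed = 2)$atoms
  coil$model <- coil$model + 3L
  mixed <- new_structure3d(rbind(helical, coil))
  expect_equal(helix_persistence(mixed, c(8, 23)), 0.15)

  all_h <- generate_ensemble(base, sch1, 10, seed = 3)
  expect_equal(helix_persistence(all_h, c(8, 23)), 1.0)

  ## parameter recovery at p = 0.5
  n <- 200
  ens <- generate_ensemble(base, helix_schedule(list(c(8, 23)), 0.5), n,
                           seed = 9)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(helix_persistence(ens, c(8, 23)) - 0.5), 3 * se)
})

test_that("disorder consensus applies the strict > 0.5 rule and majority vote", {
  tab <- rbind(c(0.9, 0.9, 0.9),
               c(0.5, 0.5, 0.5),
               c(0.6, 0.4, 0.7))
  out <- disorder_consensus(tab)
  expect_equal(out$disordered, c(TRUE, FALSE, TRUE))
  expect_equal(out$agreement, c(1, 0, 2 / 3))

  expect_error(disorder_consensus(matrix(1.2, 1, 1)), "\\[0, 1\\]")
  one <- disorder_consensus(matrix(c(0.4, 0.8), ncol = 1))
  expect_equal(one$disordered, c(FALSE, TRUE))
})
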