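## Independent oracles used by the tests.

## Brute-force rotation-grid RMSD: hierarchical search over ZYZ Euler
## angles. Uses the identity rmsd^2(R) = (S_p + S_q - 2 * sum(R * M)) / n
## with M[j,k] = sum_i q_ij * p_ik, so each grid rotation costs one
## 9-element dot product. Independent of the SVD route it checks.
grid_rmsd_oracle <- function(p, q) {
  p <- sweep(p, 2, colMeans(p)); q <- sweep(q, 2, colMeans(q))
  m <- t(q) %*% p
  const <- sum(p * p) + sum(q * q)
  n <- nrow(p)
  eval_grid <- function(alpha, beta, gamma) {
    grid <- expand.grid(a = alpha, b = beta, g = gamma)
    gmat <- t(vapply(seq_len(nrow(grid)), function(i) {
      as.vector(nuprtools:::euler_zyz(grid$a[i], grid$b[i], grid$g[i]))
    }, numeric(9)))
    v <- as.numeric(gmat %*% as.vector(m))
    best <- which.max(v)
    list(angles = unlist(grid[best, ]), v = v[best])
  }
  step <- pi / 18   # 10 degrees
  ctr <- c(0, pi / 2, 0)
  span <- c(pi, pi / 2, pi)
  best <- NULL
  for (stage in 1:5) {
    alpha <- seq(ctr[1] - span[1], ctr[1] + span[1], by = step)
    beta <- seq(max(0, ctr[2] - span[2]), min(pi, ctr[2] + span[2]),
                by = step)
    gamma <- seq(ctr[3] - span[3], ctr[3] + span[3], by = step)
    best <- eval_grid(alpha, beta, gamma)
    ctr <- best$angles
    span <- rep(step, 3)
    step <- step / 5
  }
  sqrt(max(0, (const - 2 * best$v) / n))
}

## net peptide charge with the EMBOSS pKa set (independent re-statement of
## the Henderson-Hasselbalch model used to check physchem()'s pI)
oracle_net_charge <- function(sequence, ph) {
  aa <- strsplit(sequence, "")[[1]]
  pos_pka <- c(K = 10.8, R = 12.5, H = 6.5)
  neg_pka <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  ch <- 1 / (1 + 10^(ph - 8.6)) - 1 / (1 + 10^(3.6 - ph))
  for (r in names(pos_pka))
    ch <- ch + sum(aa == r) / (1 + 10^(ph - pos_pka[[r]]))
  for (r in names(neg_pka))
    ch <- ch - sum(aa == r) / (1 + 10^(neg_pka[[r]] - ph))
  ch
}
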