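## Consensus quality assessment of candidate structural models: Kabsch
## superposition, all-against-all C-alpha RMSD and shuffle-null Z-score
## matrices with a designated negative control, aggregate statistics,
## ranking, and Ramachandran summaries.

## matched C-alpha coordinate pair for two single-model structures: common
## (chain, resno) intersection, with a residue-identity check
matched_ca <- function(a, b, check_resname = TRUE) {
  ca_a <- ca_atoms(a); ca_b <- ca_atoms(b)
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  if (check_resname) {
    mism <- which(ca_a$resname[ia] != ca_b$resname[ib])
    if (length(mism) > 0L) {
      k <- mism[1]
      stop(sprintf("mismatched residue at %s:%d: %s vs %s",
                   ca_a$chain[ia[k]], ca_a$resno[ia[k]],
                   ca_a$resname[ia[k]], ca_b$resname[ib[k]]))
    }
  }
  list(a = coords(ca_a[ia, ]), b = coords(ca_b[ib, ]), n = length(common))
}

## Kabsch: optimal rotation (reflections excluded) mapping centered x onto
## centered y; x, y are n x 3
kabsch_rotation <- function(x, y) {
  h <- t(x) %*% y
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  s$v %*% corr %*% t(s$u)
}

#' Superpose one structure onto another
#'
#' Least-squares optimal rigid-body superposition (Kabsch algorithm via SVD,
#' reflections excluded) of the matched selection atoms, by default the
#' C-alpha atoms common to both structures (matched on chain and residue
#' number). RMSD is computed over the matched atoms after applying the
#' transform.
#'
#' @param mobile,reference single-model `structure3d` objects.
#' @param selection `"CA"` (default) or `"all"` (all matched heavy atoms by
#'   chain/residue/atom name).
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd` (Angstrom) and `n` matched
#'   atoms. The transform maps mobile coordinates as
#'   `rotation %*% (x - center_mobile) + center_reference`.
#' @export
superpose <- function(mobile, reference, selection = c("CA", "all")) {
  selection <- match.arg(selection)
  if (selection == "CA") {
    m <- matched_ca(mobile, reference)
    xm <- m$a; xr <- m$b
  } else {
    am <- mobile$atoms[mobile$atoms$model == mobile$atoms$model[1], ]
    ar <- reference$atoms[reference$atoms$model == reference$atoms$model[1], ]
    key_m <- paste(am$chain, am$resno, am$atom)
    key_r <- paste(ar$chain, ar$resno, ar$atom)
    common <- intersect(key_m, key_r)
    xm <- coords(am[match(common, key_m), ])
    xr <- coords(ar[match(common, key_r), ])
  }
  if (nrow(xm) < 3L)
    stop("need at least 3 matched atoms for superposition, got ", nrow(xm))
  cm <- colMeans(xm); cr <- colMeans(xr)
  xm_c <- sweep(xm, 2, cm); xr_c <- sweep(xr, 2, cr)
  rot <- kabsch_rotation(xm_c, xr_c)
  fitted <- xm_c %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - xr_c)^2)))
  translation <- as.numeric(cr - rot %*% cm)
  structure(list(rotation = rot, translation = translation,
                 rmsd = rmsd, n = nrow(xm), center_mobile = cm,
                 center_reference = cr),
            class = "superposition")
}

#' Apply a rigid transform to a structure
#' @param struct a `structure3d`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, applied after rotation.
#' @return transformed `structure3d`.
#' @export
transform_structure <- function(struct, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(struct$atoms) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  out <- struct
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

#' Labeled square score matrix
#'
#' @param values square numeric matrix with dimnames.
#' @param kind `"rmsd"` or `"zscore"`.
#' @param control_label label of the negative-control model (optional).
#' @return a `score_matrix` object.
#' @export
score_matrix <- function(values, kind = c("rmsd", "zscore"),
                         control_label = NULL) {
  kind <- match.arg(kind)
  if (nrow(values) != ncol(values)) stop("score matrix must be square")
  labels <- rownames(values)
  if (is.null(labels) || !identical(labels, colnames(values)))
    stop("score matrix needs matching row and column labels")
  if (max(abs(values - t(values))) > 1e-6)
    stop("score matrix must be symmetric")
  if (kind == "rmsd" && max(abs(diag(values))) > 1e-6)
    stop("RMSD matrix must have a zero diagonal")
  if (!is.null(control_label) && !(control_label %in% labels))
    stop("control label not among matrix labels: ", control_label)
  structure(list(labels = labels, values = values, kind = kind,
                 control_label = control_label),
            class = "score_matrix")
}

#' All-against-all C-alpha RMSD matrix
#'
#' @param models named list of single-model `structure3d` objects (>= 2).
#' @param control_label optional negative-control label.
#' @return a `score_matrix` of kind `"rmsd"` (symmetric, zero diagonal).
#' @export
rmsd_matrix <- function(models, control_label = NULL) {
  if (length(models) < 2L) stop("need at least 2 models")
  labels <- names(models)
  if (is.null(labels) || any(!nzchar(labels))) stop("models must be named")
  n <- length(models)
  vals <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sp <- superpose(models[[i]], models[[j]])
    vals[i, j] <- vals[j, i] <- sp$rmsd
  }
  score_matrix(vals, "rmsd", control_label)
}

## alignment-quality statistic: number of matched CA pairs within `cut` A
## after optimal superposition of pairing x[i] <-> y[i]
alignment_stat <- function(x, y, cut = 4) {
  cmx <- colMeans(x); cmy <- colMeans(y)
  xc <- sweep(x, 2, cmx); yc <- sweep(y, 2, cmy)
  rot <- kabsch_rotation(xc, yc)
  d2 <- rowSums((xc %*% t(rot) - yc)^2)
  sum(d2 < cut * cut)
}

## seeded random-coil decoy: CA trace of an n-residue chain with dihedrals
## drawn uniformly from the generously allowed extended region
coil_decoy_ca <- function(n) {
  phi <- stats::runif(n, -170, -60)
  psi <- stats::runif(n, 60, 175)
  atoms <- build_backbone(strrep("A", n), phi, psi)
  coords(atoms[atoms$atom == "CA", ])
}

#' Structural-alignment Z-score against a random-structure null
#'
#' The alignment statistic S is the number of matched C-alpha pairs within
#' 4 Angstrom after optimal superposition (the size of the well-aligned
#' path). The null distribution is a random-structure comparison at desk
#' scale: S is recomputed against `null_size` seeded length-matched
#' random-coil decoys (dihedrals drawn uniformly from the generously
#' allowed extended region). The Z-score is
#' `(S_obs - mean(S_null)) / sd(S_null)`: identical structures score far
#' above the null, unrelated folds score near zero.
#'
#' @param a,b single-model `structure3d` objects with matched residues.
#' @param null_size number of decoys (>= 10).
#' @param seed integer seed.
#' @param decoys optional precomputed list of n x 3 decoy C-alpha traces
#'   (matching the matched-residue count), reused across pairs.
#' @return list with `z` and a `null` record (observed statistic, null mean,
#'   null sd, null size, seed).
#' @export
alignment_zscore <- function(a, b, null_size = 200, seed = NULL,
                             decoys = NULL) {
  if (null_size < 10) stop("null_size must be >= 10")
  m <- matched_ca(a, b, check_resname = FALSE)
  s_obs <- alignment_stat(m$a, m$b)
  if (is.null(decoys))
    decoys <- with_seed(seed, lapply(seq_len(null_size),
                                     function(k) coil_decoy_ca(m$n)))
  if (any(vapply(decoys, nrow, integer(1)) != m$n))
    stop("decoy traces must match the matched-residue count")
  s_null <- vapply(decoys, function(d) alignment_stat(m$a, d), numeric(1))
  sdn <- stats::sd(s_null)
  if (sdn == 0)
    stop("zero variance in the decoy null; increase null_size")
  z <- (s_obs - mean(s_null)) / sdn
  list(z = z,
       null = list(s_obs = s_obs, mean = mean(s_null), sd = sdn,
                   size = length(decoys), seed = seed))
}

#' All-against-all Z-score matrix
#'
#' Off-diagonal entries from [alignment_zscore()]; the diagonal carries each
#' model's self-comparison Z-score computed against the same kind of null.
#'
#' @param models named list of single-model `structure3d` objects.
#' @param null_size,seed passed to [alignment_zscore()].
#' @param control_label optional negative-control label.
#' @return a `score_matrix` of kind `"zscore"`.
#' @export
zscore_matrix <- function(models, null_size = 200, seed = NULL,
                          control_label = NULL) {
  labels <- names(models)
  n <- length(models)
  vals <- matrix(0, n, n, dimnames = list(labels, labels))
  decoy_cache <- list()
  for (i in seq_len(n)) for (j in i:n) {
    m <- matched_ca(models[[i]], models[[j]], check_resname = FALSE)
    key <- as.character(m$n)
    if (is.null(decoy_cache[[key]]))
      decoy_cache[[key]] <- with_seed(
        if (is.null(seed)) NULL else seed + m$n,
        lapply(seq_len(null_size), function(k) coil_decoy_ca(m$n)))
    z <- alignment_zscore(models[[i]], models[[j]], null_size = null_size,
                          decoys = decoy_cache[[key]])$z
    vals[i, j] <- vals[j, i] <- z
  }
  score_matrix(vals, "zscore", control_label)
}

#' Consensus statistics over candidate models
#'
#' Per candidate model (the negative control is summarized but never treated
#' as a candidate):
#' * mean RMSD to the *other candidates* (control excluded),
#' * population standard deviation of those RMSDs,
#' * mean Z-score over the other candidates *plus* the control,
#' * Pearson r between the model's off-diagonal RMSD and Z-score entries
#'   (control included; reported descriptively, `NA` when degenerate).
#'
#' @param rmsd a `score_matrix` of kind `"rmsd"`.
#' @param zscores a `score_matrix` of kind `"zscore"` with the same labels.
#' @param control_label negative-control label present in both matrices.
#' @return data.frame of class `consensus_stats` with one row per candidate:
#'   `label`, `mean_rmsd`, `sd_rmsd`, `mean_z`, `pearson_r`, `rank`.
#' @export
consensus_stats <- function(rmsd, zscores, control_label) {
  if (!identical(rmsd$labels, zscores$labels))
    stop("RMSD and Z-score matrices must share labels")
  if (!(control_label %in% rmsd$labels))
    stop("control label not found: ", control_label)
  candidates <- setdiff(rmsd$labels, control_label)
  if (length(candidates) < 3L)
    stop("need at least 3 candidate models, got ", length(candidates))

  rows <- lapply(candidates, function(lb) {
    others <- setdiff(candidates, lb)
    r_vals <- rmsd$values[lb, others]
    z_vals <- zscores$values[lb, c(others, control_label)]
    ## off-diagonal vectors over all other labels (control included)
    offd <- setdiff(rmsd$labels, lb)
    rv <- rmsd$values[lb, offd]; zv <- zscores$values[lb, offd]
    r_p <- if (stats::sd(rv) == 0 || stats::sd(zv) == 0) NA_real_
           else stats::cor(rv, zv)
    data.frame(label = lb,
               mean_rmsd = mean(r_vals),
               sd_rmsd = sqrt(mean((r_vals - mean(r_vals))^2)),
               mean_z = mean(z_vals),
               pearson_r = r_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- match(out$label, rank_models(out))
  class(out) <- c("consensus_stats", "data.frame")
  out
}

#' Rank candidate models
#'
#' Ascending mean RMSD; ties broken by descending mean Z-score, then by
#' label order. The negative control is never ranked (it is absent from the
#' consensus table by construction).
#'
#' @param stats a `consensus_stats` data.frame (or any data.frame with
#'   `label`, `mean_rmsd`, `mean_z`).
#' @return character vector of labels, best model first.
#' @export
rank_models <- function(stats) {
  if (nrow(stats) == 0L) stop("empty consensus statistics")
  ord <- order(stats$mean_rmsd, -stats$mean_z, seq_len(nrow(stats)))
  stats$label[ord]
}

#' Load the bundled reference model-comparison matrices
#'
#' Published pairwise C-alpha RMSD and structural-alignment Z-score matrices
#' for five NUPR1a threading/ab-initio models (I-TASSER, MUSTER, QUARK,
#' Pro-sp3, Chunk-TASSER) and the all-beta negative control Phf19, shipped
#' as TSV under `extdata/`.
#'
#' @return list with `rmsd` and `zscore` `score_matrix` objects
#'   (control label `"Phf19"`).
#' @export
load_reference_scores <- function() {
  read_one <- function(file, kind) {
    path <- system.file("extdata", file, package = "nuprtools",
                        mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$label
    score_matrix(m, kind, control_label = "Phf19")
  }
  list(rmsd = read_one("threading_rmsd_matrix.tsv", "rmsd"),
       zscore = read_one("threading_zscore_matrix.tsv", "zscore"))
}

## --- Ramachandran ------------------------------------------------------------

## favored-region boxes (phi_min, phi_max, psi_min, psi_max): right-handed
## alpha basin, beta/extended basin (split across the psi wrap), left-handed
## alpha basin. Allowed = within 20 degrees (Chebyshev) of a favored box.
.rama_favored <- list(
  alpha_r = c(-100, -40, -70, -10),
  beta = c(-170, -50, 100, 180),
  beta_wrap = c(-170, -50, -180, -160),
  alpha_l = c(40, 90, 0, 70))

.rama_region <- function(phi, psi) {
  inbox <- function(b, pad = 0) {
    phi >= b[1] - pad & phi <= b[2] + pad & psi >= b[3] - pad & psi <= b[4] + pad
  }
  fav <- Reduce(`|`, lapply(.rama_favored, inbox))
  alw <- Reduce(`|`, lapply(.rama_favored, inbox, pad = 20))
  ifelse(fav, "favored", ifelse(alw, "allowed", "disallowed"))
}

#' Backbone dihedral angles
#'
#' Computes phi and psi (degrees) for every residue of one model; phi is NA
#' for a chain's first residue (or after a numbering gap), psi for the last.
#'
#' @param struct a `structure3d`.
#' @param model model number.
#' @return data.frame `chain`, `resno`, `resname`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(struct, model = 1L) {
  a <- struct$atoms[struct$atoms$model == model, , drop = FALSE]
  a <- a[a$atom %in% c("N", "CA", "C"), , drop = FALSE]
  out <- lapply(split(a, a$chain), function(ac) {
    resnos <- sort(unique(ac$resno))
    pick <- function(name) {
      idx <- match(paste(resnos, name), paste(ac$resno, ac$atom))
      coords(ac)[idx, , drop = FALSE]
    }
    N <- pick("N"); CA <- pick("CA"); C <- pick("C")
    n <- length(resnos)
    phi <- psi <- rep(NA_real_, n)
    complete <- !is.na(N[, 1]) & !is.na(CA[, 1]) & !is.na(C[, 1])
    consec <- c(FALSE, diff(resnos) == 1L)
    ## phi(i): C(i-1)-N(i)-CA(i)-C(i)
    ok <- which(consec & complete & c(FALSE, complete[-n]))
    if (length(ok) > 0L)
      phi[ok] <- dihedral_angles(C[ok - 1L, , drop = FALSE],
                                 N[ok, , drop = FALSE],
                                 CA[ok, , drop = FALSE],
                                 C[ok, , drop = FALSE])
    ## psi(i): N(i)-CA(i)-C(i)-N(i+1)
    consec_next <- c(diff(resnos) == 1L, FALSE)
    ok <- which(consec_next & complete & c(complete[-1], FALSE))
    if (length(ok) > 0L)
      psi[ok] <- dihedral_angles(N[ok, , drop = FALSE],
                                 CA[ok, , drop = FALSE],
                                 C[ok, , drop = FALSE],
                                 N[ok + 1L, , drop = FALSE])
    rn <- ac$resname[match(resnos, ac$resno)]
    data.frame(chain = ac$chain[1], resno = resnos, resname = rn,
               phi = phi, psi = psi, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ramachandran summary
#'
#' Classifies every residue with defined (phi, psi) into favored, allowed or
#' disallowed regions of a three-level general-case phi/psi map (rectangular
#' basins for the right-handed alpha, beta/extended and left-handed alpha
#' regions; allowed = within 20 degrees of a favored basin). Chain termini
#' (undefined phi or psi) are skipped. Residues with missing backbone atoms
#' are skipped with a warning.
#'
#' @param struct a `structure3d`.
#' @param model model number.
#' @return list of class `ramachandran_summary`: `residues` (per-residue
#'   phi, psi, region) and `percentages` (named, sums to 100 over classified
#'   residues).
#' @export
ramachandran <- function(struct, model = 1L) {
  dh <- backbone_dihedrals(struct, model = model)
  bb <- struct$atoms[struct$atoms$model == model &
                       struct$atoms$atom %in% c("N", "CA", "C"), ]
  res_key <- unique(paste(bb$chain, bb$resno))
  complete <- vapply(res_key, function(k) {
    sub <- bb[paste(bb$chain, bb$resno) == k, "atom"]
    all(c("N", "CA", "C") %in% sub)
  }, logical(1))
  if (any(!complete))
    warning("residues with missing backbone atoms skipped: ",
            paste(res_key[!complete], collapse = ", "))
  keep <- !is.na(dh$phi) & !is.na(dh$psi)
  res <- dh[keep, , drop = FALSE]
  if (nrow(res) == 0L) stop("no residue with both phi and psi defined")
  res$region <- .rama_region(res$phi, res$psi)
  pct <- 100 * table(factor(res$region,
                            levels = c("favored", "allowed", "disallowed"))) /
    nrow(res)
  structure(list(residues = res, percentages = c(pct)),
            class = "ramachandran_summary")
}

#' Classify a single (phi, psi) pair
#' @param phi,psi backbone dihedrals in degrees.
#' @return `"favored"`, `"allowed"` or `"disallowed"`.
#' @export
rama_region <- function(phi, psi) .rama_region(phi, psi)
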