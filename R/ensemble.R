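## Conformational-ensemble analytics: frame sampling, per-residue RMSF about
## the iteratively refined mean structure, pairwise frame-RMSD matrices,
## helix persistence, and disorder-prediction consensus.

ensemble_frames <- function(ens) sort(unique(ens$atoms$model))

#' Sample frames from an ensemble
#'
#' Without a seed, frames are taken evenly spaced including both endpoints
#' (indices `ceiling(k * (N - 1) / (n - 1))` for `k = 0..n-1`, 0-based).
#' With a seed, a uniform random subset is drawn. Frame order is preserved.
#'
#' @param ens multi-model `structure3d`.
#' @param n number of frames to keep (`1 <= n <=` frame count).
#' @param seed integer seed for random sampling (NULL = even spacing).
#' @return multi-model `structure3d` with `n` frames (model numbers kept).
#' @export
sample_frames <- function(ens, n, seed = NULL) {
  frames <- ensemble_frames(ens)
  N <- length(frames)
  if (n < 1 || n > N)
    stop("cannot sample ", n, " frames from an ensemble of ", N)
  if (is.null(seed)) {
    idx <- if (n == 1L) 1L else ceiling((seq_len(n) - 1L) * (N - 1) / (n - 1)) + 1L
  } else {
    idx <- with_seed(seed, sort(sample.int(N, n)))
  }
  keep <- frames[idx]
  new_structure3d(ens$atoms[ens$atoms$model %in% keep, , drop = FALSE])
}

## C-alpha coordinate array (frames x residues x 3) with a shared residue order
ca_array <- function(ens) {
  frames <- ensemble_frames(ens)
  ca1 <- ca_atoms(ens, frames[1])
  key <- paste(ca1$chain, ca1$resno)
  arr <- array(NA_real_, c(length(frames), nrow(ca1), 3))
  for (f in seq_along(frames)) {
    caf <- ca_atoms(ens, frames[f])
    if (!identical(paste(caf$chain, caf$resno), key))
      stop("ensemble frames do not share one topology")
    arr[f, , ] <- coords(caf)
  }
  list(arr = arr, chain = ca1$chain, resno = ca1$resno,
       resname = ca1$resname, frames = frames)
}

## superpose every frame of arr onto ref (n_res x 3); returns fitted array
fit_frames <- function(arr, ref) {
  cref <- colMeans(ref)
  ref_c <- sweep(ref, 2, cref)
  out <- arr
  for (f in seq_len(dim(arr)[1])) {
    x <- arr[f, , ]
    cx <- colMeans(x)
    xc <- sweep(x, 2, cx)
    rot <- kabsch_rotation(xc, ref_c)
    out[f, , ] <- sweep(xc %*% t(rot), 2, cref, "+")
  }
  out
}

#' Per-residue RMSF
#'
#' Every frame is superposed (C-alpha, Kabsch) onto an iteratively refined
#' mean structure (two refinement passes, removing reference bias toward any
#' single frame); the RMSF of residue i is the root mean square deviation of
#' its C-alpha from the mean position across frames.
#'
#' @param ens multi-model `structure3d` (>= 2 frames).
#' @return data.frame `chain`, `resno`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(ens) {
  ca <- ca_array(ens)
  if (dim(ca$arr)[1] < 2L) stop("RMSF needs at least 2 frames")
  ref <- ca$arr[1, , ]
  fitted <- ca$arr
  for (pass in 1:2) {
    fitted <- fit_frames(ca$arr, ref)
    ref <- apply(fitted, c(2, 3), mean)
  }
  dev2 <- sweep(fitted, c(2, 3), ref)^2
  rmsf <- sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))
  data.frame(chain = ca$chain, resno = ca$resno, resname = ca$resname,
             rmsf = rmsf, stringsAsFactors = FALSE)
}

#' Pairwise frame-RMSD matrix
#'
#' Symmetric, zero-diagonal matrix of C-alpha RMSDs between every pair of
#' frames (each pair optimally superposed), the heat-map substrate for
#' ensemble-stability comparisons.
#'
#' @param ens multi-model `structure3d` (>= 2 frames).
#' @return a `score_matrix` of kind `"rmsd"` labeled by frame number.
#' @export
pairwise_frame_rmsd <- function(ens) {
  ca <- ca_array(ens)
  nf <- dim(ca$arr)[1]
  if (nf < 2L) stop("need at least 2 frames")
  labels <- as.character(ca$frames)
  vals <- matrix(0, nf, nf, dimnames = list(labels, labels))
  centered <- lapply(seq_len(nf), function(f) {
    x <- ca$arr[f, , ]; sweep(x, 2, colMeans(x))
  })
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    rot <- kabsch_rotation(centered[[i]], centered[[j]])
    vals[i, j] <- vals[j, i] <-
      sqrt(mean(rowSums((centered[[i]] %*% t(rot) - centered[[j]])^2)))
  }
  score_matrix(vals, "rmsd")
}

#' Helix persistence across an ensemble
#'
#' Fraction of frames in which the span is helical: a frame counts when a
#' single assigned helix ([assign_helices()]) covers at least `coverage` of
#' the span's residues.
#'
#' @param ens multi-model `structure3d`.
#' @param span `c(start, end)` residue span (inclusive).
#' @param chain chain id.
#' @param coverage minimum fraction of span residues covered by one helix.
#' @return persistence fraction in `[0, 1]`.
#' @export
helix_persistence <- function(ens, span, chain = "A", coverage = 0.75) {
  frames <- ensemble_frames(ens)
  span_len <- span[2] - span[1] + 1
  hits <- vapply(frames, function(f) {
    sp <- assign_helices(ens, model = f)
    sp <- sp[sp$chain == chain, , drop = FALSE]
    if (nrow(sp) == 0L) return(FALSE)
    overlap <- pmax(0, pmin(sp$end, span[2]) - pmax(sp$start, span[1]) + 1)
    max(overlap) / span_len >= coverage
  }, logical(1))
  mean(hits)
}

#' Disorder-prediction consensus
#'
#' Per predictor, a residue is disordered iff its probability is strictly
#' greater than the threshold; the consensus call is the majority vote and
#' the agreement is the fraction of predictors calling disorder.
#'
#' @param table numeric matrix or data.frame, residues in rows, predictors
#'   in columns, values in `[0, 1]`.
#' @param threshold disorder probability threshold (strict `>`).
#' @return data.frame `residue`, `agreement`, `disordered`.
#' @export
disorder_consensus <- function(table, threshold = 0.5) {
  m <- as.matrix(table)
  if (ncol(m) < 1L) stop("need at least one predictor")
  if (any(m < 0 | m > 1)) stop("disorder probabilities must be in [0, 1]")
  calls <- m > threshold
  agreement <- rowMeans(calls)
  data.frame(residue = if (!is.null(rownames(m))) rownames(m)
                       else seq_len(nrow(m)),
             agreement = agreement,
             disordered = agreement > 0.5,
             stringsAsFactors = FALSE, row.names = NULL)
}
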