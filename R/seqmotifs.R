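## Sequence-level analyses: NLS/NES/AT-hook motif scanning, hydropathy and
## physicochemical profiles, alignment identity and conservation, and
## consensus scoring of modification-site predictions.
##
## Positions are 1-based and inclusive throughout.

## all (possibly overlapping) match starts of a regex
regex_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

motif_hit <- function(id, start, end, sequence, score) {
  data.frame(motif = id, start = start, end = end,
             match = substr(sequence, start, end),
             score = score, stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(motif = character(0), start = integer(0), end = integer(0),
             match = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

basic_fraction <- function(sequence, start, end) {
  win <- strsplit(substr(sequence, start, end), "")[[1]]
  mean(win %in% c("K", "R"))
}

#' Scan for nuclear localization signals
#'
#' Finds every match of the bipartite-core pattern `K-(K/R)-X-(K/R)`. A
#' bipartite extension is reported when a second basic cluster (at least 2
#' of K/R within a 4-residue window) starts 8-14 residues downstream of the
#' core start; the bipartite hit spans from the core start to the last basic
#' residue of the cluster window. Scores are the K/R fraction of the
#' reported window.
#'
#' @param sequence one-letter amino-acid string.
#' @return data.frame of hits: `motif` (`nls` / `nls_bipartite`), `start`,
#'   `end`, `match`, `score`.
#' @export
scan_nls <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  starts <- regex_starts(sequence, "K[KR].[KR]")
  if (length(starts) == 0L) return(empty_hits())
  letters1 <- strsplit(sequence, "")[[1]]
  basic <- letters1 %in% c("K", "R")
  hits <- lapply(starts, function(s) {
    core <- motif_hit("nls", s, s + 3L, sequence,
                      basic_fraction(sequence, s, s + 3L))
    ## bipartite extension: cluster window starting 8-14 residues downstream
    for (off in 8:14) {
      ws <- s + off
      we <- min(ws + 3L, n)
      if (ws > n || we - ws + 1L < 2L) next
      idx <- ws:we
      if (sum(basic[idx]) >= 2L) {
        end <- max(idx[basic[idx]])
        while (end < n && basic[end + 1L]) end <- end + 1L
        return(rbind(core,
                     motif_hit("nls_bipartite", s, end, sequence,
                               basic_fraction(sequence, s, end))))
      }
    }
    core
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Scan for leucine-rich nuclear export signals
#'
#' Matches the spacing pattern `L-x(3)-L-x(2)-L-x-L` (10 residues). Anchors
#' are strict leucines by default; `wide_anchors = TRUE` widens them to the
#' hydrophobic set L/I/V/F/M.
#'
#' @param sequence one-letter amino-acid string.
#' @param wide_anchors widen anchor positions to L/I/V/F/M.
#' @return data.frame of hits (`motif` = `nes`); score is the anchor count
#'   that are leucine divided by 4.
#' @export
scan_nes <- function(sequence, wide_anchors = FALSE) {
  sequence <- toupper(sequence)
  anchor <- if (wide_anchors) "[LIVFM]" else "L"
  pat <- paste0(anchor, "...", anchor, "..", anchor, ".", anchor)
  starts <- regex_starts(sequence, pat)
  if (length(starts) == 0L) return(empty_hits())
  out <- do.call(rbind, lapply(starts, function(s) {
    anchors <- strsplit(substr(sequence, s, s + 9L), "")[[1]][c(1, 5, 8, 10)]
    motif_hit("nes", s, s + 9L, sequence, mean(anchors == "L"))
  }))
  rownames(out) <- NULL
  out
}

#' Scan for AT-hook-like DNA-binding cores
#'
#' Slides a window over the sequence; windows whose G/R/K fraction reaches
#' the threshold are collapsed (overlapping qualifying windows merged, then
#' trimmed to the first/last G/R/K residue) into `dbd_core` hits with the
#' core's G/R/K fraction as score. Two cores whose gap is 10-40 residues are
#' additionally paired into a `dbd_bipartite` hit.
#'
#' @param sequence one-letter amino-acid string.
#' @param window window length (>= 3).
#' @param grk_threshold minimum G/R/K fraction of a qualifying window.
#' @return data.frame of hits (`dbd_core` and `dbd_bipartite`).
#' @export
scan_dbd <- function(sequence, window = 7, grk_threshold = 0.7) {
  if (window < 3) stop("window must be >= 3")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < window) return(empty_hits())
  letters1 <- strsplit(sequence, "")[[1]]
  grk <- letters1 %in% c("G", "R", "K")
  frac <- stats::filter(as.numeric(grk), rep(1 / window, window),
                        sides = 1)
  ## frac[i] = mean over window ending at i; window starting at s ends at
  ## s + window - 1
  starts <- which(frac[window:n] >= grk_threshold - 1e-9)
  if (length(starts) == 0L) return(empty_hits())
  ## merge overlapping qualifying windows, then trim to G/R/K edges
  ends <- starts + window - 1L
  grp <- cumsum(c(TRUE, starts[-1] > ends[-length(ends)] + 0L))
  cores <- lapply(split(seq_along(starts), grp), function(ii) {
    s <- min(starts[ii]); e <- max(ends[ii])
    idx <- s:e
    core_idx <- idx[grk[idx]]
    if (length(core_idx) == 0L) return(NULL)
    s <- min(core_idx); e <- max(core_idx)
    motif_hit("dbd_core", s, e, sequence, mean(grk[s:e]))
  })
  cores <- do.call(rbind, cores[!vapply(cores, is.null, logical(1))])
  if (is.null(cores) || nrow(cores) == 0L) return(empty_hits())
  out <- cores
  if (nrow(cores) >= 2L) {
    for (i in seq_len(nrow(cores) - 1L)) for (j in (i + 1L):nrow(cores)) {
      gap <- cores$start[j] - cores$end[i] - 1L
      if (gap >= 10L && gap <= 40L) {
        out <- rbind(out, motif_hit(
          "dbd_bipartite", cores$start[i], cores$end[j], sequence,
          mean(c(cores$score[i], cores$score[j]))))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Kyte-Doolittle hydropathy profile
#'
#' Centered sliding-window mean of the Kyte-Doolittle scale; the profile has
#' `length(sequence) - window + 1` positions (ends truncated).
#'
#' @param sequence one-letter amino-acid string.
#' @param window odd window length, at most the sequence length.
#' @return data.frame `position` (window center) and `hydropathy`.
#' @export
hydropathy_profile <- function(sequence, window = 9) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- nchar(sequence)
  if (window > n) stop("window longer than sequence")
  vals <- .kd_scale[strsplit(toupper(sequence), "")[[1]]]
  if (anyNA(vals)) stop("unknown residue letter in sequence")
  sums <- stats::filter(vals, rep(1, window), sides = 2)
  centers <- ((window + 1) %/% 2):(n - window %/% 2)
  data.frame(position = centers,
             hydropathy = as.numeric(sums[centers]) / window)
}

## net charge of a peptide at a given pH (Henderson-Hasselbalch)
peptide_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - .pka_nterm))
  for (r in names(.pka_pos))
    pos <- pos + counts[[r]] / (1 + 10^(ph - .pka_pos[[r]]))
  neg <- 1 / (1 + 10^(.pka_cterm - ph))
  for (r in names(.pka_neg))
    neg <- neg + counts[[r]] / (1 + 10^(.pka_neg[[r]] - ph))
  pos - neg
}

#' Molecular weight and isoelectric point
#'
#' Average molecular weight (sum of residue masses plus one water) and pI by
#' bisection on the Henderson-Hasselbalch net-charge function with the
#' EMBOSS pKa set (N-terminus 8.6, C-terminus 3.6; K 10.8, R 12.5, H 6.5,
#' D 3.9, E 4.1, C 8.5, Y 10.1).
#'
#' @param sequence nonempty one-letter amino-acid string.
#' @return list with `mw` (Da) and `pi`.
#' @export
physchem <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0L) stop("empty sequence")
  unknown <- setdiff(letters1, names(.residue_mass))
  if (length(unknown) > 0L)
    stop("unknown residue letter: ", paste(unknown, collapse = ", "))
  mw <- sum(.residue_mass[letters1]) + .water_mass
  counts <- vapply(c(names(.pka_pos), names(.pka_neg)),
                   function(r) sum(letters1 == r), numeric(1))
  lo <- 0; hi <- 14
  for (k in 1:100) {
    mid <- (lo + hi) / 2
    if (peptide_charge(as.list(counts), mid) > 0) lo <- mid else hi <- mid
  }
  list(mw = mw, pi = (lo + hi) / 2)
}

#' Read a multiple sequence alignment
#'
#' Thin wrapper over Biostrings for aligned FASTA or Clustal input,
#' returning the named character vector consumed by [identity_matrix()] and
#' [conservation_map()].
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  s <- as.character(aln)
  stats::setNames(as.character(s), names(s))
}

#' Percent-identity matrix of an alignment
#'
#' Pairwise percent of identical columns; columns where both sequences have
#' a gap are excluded from the denominator. Symmetric with a 100 diagonal.
#'
#' @param msa named character vector of aligned sequences (equal lengths;
#'   gaps as `-`).
#' @return square numeric matrix of percentages.
#' @export
identity_matrix <- function(msa) {
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  rows <- lapply(msa, function(s) strsplit(toupper(s), "")[[1]])
  n <- length(rows)
  labels <- if (!is.null(names(msa))) names(msa) else paste0("seq", seq_len(n))
  out <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- rows[[i]]; b <- rows[[j]]
    keep <- !(a == "-" & b == "-")
    out[i, j] <- out[j, i] <- 100 * sum(a[keep] == b[keep]) / sum(keep)
  }
  out
}

#' Per-position conservation of a reference sequence
#'
#' For every non-gap position of the reference row, the percent of
#' alignment rows (reference included) sharing the reference letter, binned
#' linearly into conservation grades 1-9.
#'
#' @param msa named character vector of aligned sequences.
#' @param reference_row index or name of the reference sequence.
#' @param struct optional single-chain `structure3d` whose residues (in
#'   order) correspond to the reference sequence; conservation is attached
#'   per residue number.
#' @return data.frame `position` (1-based in the ungapped reference),
#'   `letter`, `conservation` (percent), `grade` (1-9), and `resno` when a
#'   structure is given.
#' @export
conservation_map <- function(msa, reference_row = 1, struct = NULL) {
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  rows <- lapply(msa, function(s) strsplit(toupper(s), "")[[1]])
  ref <- rows[[reference_row]]
  cols <- which(ref != "-")
  mat <- do.call(rbind, rows)
  pct <- vapply(cols, function(cc) 100 * mean(mat[, cc] == ref[cc]),
                numeric(1))
  out <- data.frame(position = seq_along(cols), letter = ref[cols],
                    conservation = pct,
                    grade = pmax(1L, as.integer(ceiling(pct * 9 / 100))),
                    stringsAsFactors = FALSE)
  if (!is.null(struct)) {
    ca <- ca_atoms(struct)
    if (nrow(ca) != nrow(out))
      stop("structure/sequence length mismatch at position ",
           min(nrow(ca), nrow(out)) + 1L, ": structure has ", nrow(ca),
           " residues, reference has ", nrow(out))
    out$resno <- ca$resno
  }
  out
}

#' Consensus meta-score of modification-site predictions
#'
#' A program predicts a site iff its raw score is strictly above the
#' program's cutoff. The meta-score of a (site, class) pair is the number of
#' predicting programs divided by the number of programs registered for that
#' class in the table, so a site predicted by every program scores 1.
#' Sites with zero predicting programs are omitted from the report unless
#' `include_zero = TRUE`.
#'
#' @param table data.frame with columns `site`, `class`, `program`, `score`,
#'   `cutoff` (e.g. from [generate_prediction_table()]).
#' @param include_zero keep (site, class) rows with meta-score 0.
#' @return data.frame `site`, `class`, `n_predicting`, `n_programs`,
#'   `meta_score`.
#' @export
ptm_meta_score <- function(table, include_zero = FALSE) {
  needed <- c("site", "class", "program", "score", "cutoff")
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0L)
    stop("prediction table is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(table$cutoff)))
    stop("program without a cutoff: ",
         paste(unique(table$program[is.na(table$cutoff)]), collapse = ", "))
  per_class_total <- tapply(table$program, table$class,
                            function(p) length(unique(p)))
  table$predicts <- table$score > table$cutoff
  agg <- stats::aggregate(predicts ~ site + class, data = table, FUN = sum)
  agg$n_programs <- as.integer(per_class_total[agg$class])
  names(agg)[names(agg) == "predicts"] <- "n_predicting"
  agg$meta_score <- agg$n_predicting / agg$n_programs
  if (!include_zero) agg <- agg[agg$n_predicting > 0L, , drop = FALSE]
  agg <- agg[order(agg$class, agg$site), ]
  rownames(agg) <- NULL
  agg
}
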