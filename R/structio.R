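#' @title Structure container
#'
#' @description
#' `nuprtools` represents a macromolecular structure as a flat atom table
#' wrapped in an S3 class, in the spirit of bio3d's `pdb` object. The table
#' has one row per atom with columns:
#'
#' * `model`  - integer model number (conformational ensembles are
#'   multi-model structures sharing one topology),
#' * `chain`  - one-character chain identifier,
#' * `resno`  - integer residue number (1-based, need not be contiguous),
#' * `resname` - 3-letter amino-acid code or canonical DNA code
#'   (`DA`/`DT`/`DG`/`DC`),
#' * `atom`   - PDB atom name (e.g. `CA`, `NZ`, `OP2`),
#' * `element` - element symbol,
#' * `x`, `y`, `z` - coordinates in Angstrom.
#'
#' @param atoms data.frame with the columns listed above.
#' @return an object of class `structure3d`.
#' @export
new_structure3d <- function(atoms) {
  needed <- c("model", "chain", "resno", "resname", "atom", "element",
              "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0L)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, needed]
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  for (cc in c("chain", "resname", "atom", "element"))
    atoms[[cc]] <- as.character(atoms[[cc]])
  if (nrow(atoms) > 0L) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (any(!nzchar(atoms$atom)))
      stop("empty atom names in atom table")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  nm <- length(unique(a$model))
  cat(sprintf("structure3d: %d atoms, %d model%s, chains: %s\n",
              nrow(a), nm, if (nm == 1L) "" else "s",
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

## canonical DNA residue names; single-letter table style is accepted on input
.dna_resnames <- c("DA", "DT", "DG", "DC")
.dna_alias <- c(A = "DA", T = "DT", G = "DG", C = "DC",
                DA = "DA", DT = "DT", DG = "DG", DC = "DC")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa3_to_1 <- function(x) {
  out <- .aa1[match(toupper(x), .aa3)]
  out[is.na(out)] <- "X"
  out
}

aa1_to_3 <- function(x) {
  out <- .aa3[match(toupper(x), .aa1)]
  if (anyNA(out)) stop("unknown one-letter residue code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' Is a chain DNA or protein?
#'
#' Polymer type is inferred per chain from residue names: chains whose
#' residues are all `DA`/`DT`/`DG`/`DC` are `"dna"`, all others `"protein"`.
#'
#' @param struct a `structure3d`.
#' @return named character vector, one entry per chain.
#' @export
chain_types <- function(struct) {
  a <- struct$atoms
  vapply(split(a$resname, a$chain), function(r) {
    if (all(r %in% .dna_resnames)) "dna" else "protein"
  }, character(1))
}

#' Extract one model from a structure
#'
#' @param struct a `structure3d`.
#' @param model model number to keep.
#' @return single-model `structure3d`.
#' @export
get_model <- function(struct, model = 1L) {
  a <- struct$atoms[struct$atoms$model == model, , drop = FALSE]
  if (nrow(a) == 0L) stop("no such model: ", model)
  new_structure3d(a)
}

#' Number of models in a structure
#' @param struct a `structure3d`.
#' @return integer count.
#' @export
n_models <- function(struct) length(unique(struct$atoms$model))

## coordinate matrix for a subset of atoms
coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

## C-alpha rows of one model, ordered by chain then residue number
ca_atoms <- function(struct, model = 1L) {
  a <- struct$atoms
  a <- a[a$model == model & a$atom == "CA", , drop = FALSE]
  a[order(a$chain, a$resno), , drop = FALSE]
}

#' Parse PDB-format text
#'
#' Reads `ATOM`/`HETATM`, `MODEL`/`ENDMDL` and `TER` records from a character
#' scalar (or vector of lines) of PDB fixed-column text. Alternate locations:
#' only the first altloc of each atom is kept and a warning is issued. DNA
#' residue names given in single-letter table style (`A`/`T`/`G`/`C`) are
#' stored canonically as `DA`/`DT`/`DG`/`DC`.
#'
#' @param text PDB text (single string with newlines, or character vector of
#'   lines).
#' @return a `structure3d`.
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  rec <- trimws(substr(lines, 1, 6))
  is_atom <- rec %in% c("ATOM", "HETATM")
  is_model <- rec == "MODEL"
  if (!any(is_atom))
    stop("no ATOM/HETATM records found in PDB text")

  ## model number per line: cumulative over MODEL records, 1 if none
  model_no <- cumsum(is_model)
  model_no[model_no == 0L] <- 1L

  idx <- which(is_atom)
  al <- lines[idx]
  short <- which(nchar(al) < 54)
  if (length(short) > 0L)
    stop("malformed ATOM/HETATM record (shorter than 54 columns) at line ",
         idx[short[1]])

  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0L)
    stop("malformed coordinate field in ATOM/HETATM record at line ",
         idx[bad[1]])
  resno <- suppressWarnings(as.integer(substr(al, 23, 26)))
  bad <- which(is.na(resno))
  if (length(bad) > 0L)
    stop("malformed residue number in ATOM/HETATM record at line ",
         idx[bad[1]])

  atom_name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  icode <- substr(al, 27, 27)
  element <- trimws(substr(al, 77, 78))
  ## infer element from the atom name when column 77-78 is absent/blank
  noel <- !nzchar(element)
  if (any(noel))
    element[noel] <- substr(gsub("[^A-Za-z]", "", atom_name[noel]), 1, 1)
  element <- toupper(element)

  if (any(altloc != " " & altloc != "A" & altloc != ""))
    warning("alternate locations present; keeping first altloc only")
  if (any(icode != " " & icode != ""))
    warning("insertion codes present; they are ignored")
  keep <- altloc %in% c(" ", "", "A")

  ## canonicalize DNA residue names (table style A/T/G/C)
  canon <- .dna_alias[resname]
  resname <- unname(ifelse(is.na(canon), resname, canon))

  atoms <- data.frame(
    model = model_no[idx], chain = chain, resno = resno, resname = resname,
    atom = atom_name, element = element, x = xs, y = ys, z = zs,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  ## drop duplicate altloc copies beyond the first per (model, residue, atom)
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$atom)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  new_structure3d(atoms)
}

#' Read a structure from a PDB file
#' @param path file path.
#' @return a `structure3d`.
#' @export
read_pdb <- function(path) parse_pdb(readLines(path, warn = FALSE))

#' Write a structure as PDB-format text
#'
#' Emits fixed-column `ATOM` records (coordinates to 3 decimals), `TER`
#' records between chains, and `MODEL`/`ENDMDL` blocks when the structure has
#' more than one model.
#'
#' @param struct a `structure3d`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly, the PDB text as a single string.
#' @export
write_pdb <- function(struct, path = NULL) {
  a <- struct$atoms
  models <- sort(unique(a$model))
  multi <- length(models) > 1L
  out <- character(0)
  serial <- 0L
  for (m in models) {
    am <- a[a$model == m, , drop = FALSE]
    am <- am[order(match(am$chain, unique(am$chain)), am$resno), , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    chains <- unique(am$chain)
    for (ch in chains) {
      ac <- am[am$chain == ch, , drop = FALSE]
      serials <- serial + seq_len(nrow(ac))
      serial <- serial + nrow(ac)
      ## atom name justification: names of <4 chars start in column 14
      nm <- ac$atom
      nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
      recs <- sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serials %% 100000L, nm4, ac$resname, ch, ac$resno,
        ac$x, ac$y, ac$z, ac$element)
      out <- c(out, recs)
      serial <- serial + 1L
      out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                            serial %% 100000L,
                            ac$resname[nrow(ac)], ch, ac$resno[nrow(ac)]))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(txt)
}

#' Normalize atom-name dialects
#'
#' Older PDB dialects name the phosphate oxygens `O1P`/`O2P`; the canonical
#' names are `OP1`/`OP2`. This maps `O1P -> OP1` and `O2P -> OP2` and leaves
#' every other atom name unchanged. Idempotent; coordinates and atom count
#' are never altered.
#'
#' @param struct a `structure3d`.
#' @return a `structure3d` with canonical phosphate-oxygen names.
#' @export
normalize_atom_names <- function(struct) {
  a <- struct$atoms
  a$atom[a$atom == "O1P"] <- "OP1"
  a$atom[a$atom == "O2P"] <- "OP2"
  new_structure3d(a)
}

#' Parse an atom specification
#'
#' Atom specs are the compact contact labels used in interface reports, e.g.
#' `"A:Arg60:NH2"` (protein) or `"C:A7:OP2"` (DNA, single-letter residue
#' style). The residue field splits into name and number at the first digit.
#'
#' @param text spec string `"chain:ResnameNumber:atomname"`.
#' @return list with fields `chain_id`, `residue_name`, `residue_number`,
#'   `atom_name`, of class `atom_spec`.
#' @export
parse_atom_spec <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts)))
    stop("atom spec must have three colon-separated fields: ", text)
  m <- regexpr("[0-9]", parts[2])
  if (m < 1L) stop("no residue number in atom spec: ", text)
  rname <- substr(parts[2], 1, m - 1L)
  rnum <- suppressWarnings(as.integer(substr(parts[2], m, nchar(parts[2]))))
  if (!nzchar(rname) || is.na(rnum))
    stop("malformed residue field in atom spec: ", text)
  structure(list(chain_id = parts[1], residue_name = rname,
                 residue_number = rnum, atom_name = parts[3]),
            class = "atom_spec")
}

#' Format an atom specification
#'
#' Exact inverse of [parse_atom_spec()]: `format_atom_spec(parse_atom_spec(s))`
#' returns `s` for every well-formed spec.
#'
#' @param spec an `atom_spec`.
#' @return spec string.
#' @export
format_atom_spec <- function(spec) {
  paste0(spec$chain_id, ":", spec$residue_name, spec$residue_number,
         ":", spec$atom_name)
}

## residue name as it appears in atom specs: Arg60 / A7
spec_resname <- function(resname) {
  ifelse(resname %in% .dna_resnames, substr(resname, 2, 2),
         paste0(substr(resname, 1, 1),
                tolower(substr(resname, 2, nchar(resname)))))
}

## build spec strings for rows of an atom table (vectorized)
atom_spec_str <- function(atoms, with_atom = TRUE) {
  base <- paste0(atoms$chain, ":", spec_resname(atoms$resname), atoms$resno)
  if (with_atom) paste0(base, ":", atoms$atom) else base
}
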