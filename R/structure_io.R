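#' Wimley-White interfacial hydrophobicity scale
#'
#' Per-residue transfer free energies (kcal/mol) from water to the
#' POPC bilayer interface (Wimley & White, 1996, Nat Struct Biol 3:842-848;
#' whole-residue interfacial scale, Asp/Glu/Lys/Arg in their charged forms,
#' His neutral). Negative values mark residues favourable in a hydrophobic
#' interfacial environment. Every atom of a residue inherits the residue's
#' value.
#'
#' @format Named numeric vector of length 20, names are 3-letter residue
#'   codes.
#' @export
wimley_white <- c(
  ALA =  0.17, ARG =  0.81, ASN =  0.42, ASP =  1.23, CYS = -0.24,
  GLN =  0.58, GLU =  2.02, GLY =  0.01, HIS =  0.17, ILE = -0.31,
  LEU = -0.56, LYS =  0.99, MET = -0.23, PHE = -1.13, PRO =  0.45,
  SER =  0.13, THR =  0.14, TRP = -1.85, TYR = -0.94, VAL =  0.07)

# united-atom van der Waals radii by element (Angstrom), applied when no PQR
# radii are available
element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
default_radius <- 1.70

atom_columns <- c("serial", "atom_name", "residue_name", "chain_id",
                  "residue_seq", "icode", "x", "y", "z", "radius", "charge",
                  "hydrophobicity", "conservation", "is_hydrogen")

new_structure <- function(atoms, label = "structure") {
  atoms <- as_tibble(atoms)[, atom_columns]
  attr(atoms, "label") <- label
  atoms
}

structure_label <- function(structure) {
  lbl <- attr(structure, "label", exact = TRUE)
  if (is.null(lbl)) "structure" else lbl
}

# residue key: author chain + residue number with any insertion code
# concatenated, e.g. "A:100" or "A:100A"
res_key <- function(structure) {
  paste(structure$chain_id, paste0(structure$residue_seq, structure$icode),
        sep = ":")
}

guess_hydrogen <- function(atom_name, element = NULL) {
  if (!is.null(element) && any(nzchar(element) & !is.na(element))) {
    el <- toupper(trimws(element))
    out <- el == "H"
    miss <- is.na(element) | !nzchar(trimws(element))
    if (any(miss))
      out[miss] <- guess_hydrogen(atom_name[miss])
    return(out)
  }
  stripped <- sub("^[0-9]+", "", trimws(atom_name))
  toupper(substr(stripped, 1, 1)) == "H"
}

assign_default_radii <- function(structure) {
  missing_r <- is.na(structure$radius)
  if (!any(missing_r)) return(structure)
  el <- toupper(sub("^[0-9]+", "", trimws(structure$atom_name)))
  el2 <- substr(el, 1, 2)
  el1 <- substr(el, 1, 1)
  r <- unname(element_radii[el2])
  r[is.na(r)] <- unname(element_radii[el1[is.na(r)]])
  r[is.na(r)] <- default_radius
  structure$radius[missing_r] <- r[missing_r]
  structure
}

bio3d_to_atoms <- function(atom_df) {
  icode <- atom_df$insert
  icode[is.na(icode)] <- ""
  chain <- atom_df$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "
  tibble(
    serial = as.integer(atom_df$eleno),
    atom_name = trimws(atom_df$elety),
    residue_name = trimws(atom_df$resid),
    chain_id = chain,
    residue_seq = as.integer(atom_df$resno),
    icode = icode,
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    radius = NA_real_, charge = NA_real_,
    hydrophobicity = NA_real_, conservation = NA_integer_,
    is_hydrogen = guess_hydrogen(atom_df$elety, atom_df$elesy))
}

check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  short <- rec & nchar(lines) < 54
  if (any(short))
    stop(sprintf("malformed fixed-column record at line %d of %s",
                 which(short)[1], path))
  invisible(lines)
}

drop_duplicate_altloc <- function(atoms, alt) {
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$icode,
               atoms$atom_name, sep = "|")
  keep <- !duplicated(key)
  atoms[keep, , drop = FALSE]
}

#' Read a PDB file into an atom tibble
#'
#' Parses fixed-column ATOM records (via bio3d). HETATM records, waters and
#' alternate-location duplicates beyond the first are dropped; hydrogens are
#' kept and flagged.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector of chain identifiers to keep.
#' @param label Label stored on the returned structure (defaults to the file
#'   name).
#' @return A tibble with one row per atom (coordinates in Angstrom) and a
#'   `label` attribute.
#' @export
read_pdb <- function(path, chains = NULL, label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  check_pdb_lines(path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB ", path, ": ",
                         conditionMessage(e)))
  df <- pdb$atom
  df <- df[df$type == "ATOM" & !(df$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!is.null(chains)) df <- df[df$chain %in% chains, , drop = FALSE]
  if (nrow(df) == 0) stop("no atoms in ", path, " after filtering")
  atoms <- bio3d_to_atoms(df)
  atoms <- drop_duplicate_altloc(atoms, df$alt)
  new_structure(atoms, label = label %||% basename(path))
}

parse_pqr_whitespace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0) stop("no ATOM records in PQR ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  n <- lengths(toks)
  if (any(n < 10))
    stop("PQR record with missing charge/radius field in ", path)
  parse_one <- function(tk) {
    has_chain <- length(tk) >= 11 && is.na(suppressWarnings(as.numeric(tk[5])))
    if (has_chain) {
      chain <- tk[5]; rest <- tk[6:11]
    } else {
      chain <- " "; rest <- tk[5:10]
    }
    resno <- rest[1]
    icode <- sub("^-?[0-9]+", "", resno)
    c(tk[2], tk[3], tk[4], chain, sub("[A-Za-z]+$", "", resno), icode,
      rest[2:6])
  }
  m <- t(vapply(toks, parse_one, character(11)))
  num <- function(j) as.numeric(m[, j])
  if (anyNA(num(7)) || anyNA(num(8)) || anyNA(num(9)) || anyNA(num(10)) ||
      anyNA(num(11)))
    stop("PQR record with non-numeric coordinate/charge/radius field in ",
         path)
  tibble(
    serial = as.integer(num(1)), atom_name = m[, 2], residue_name = m[, 3],
    chain_id = m[, 4], residue_seq = as.integer(num(5)), icode = m[, 6],
    x = num(7), y = num(8), z = num(9), charge = num(10), radius = num(11),
    hydrophobicity = NA_real_, conservation = NA_integer_,
    is_hydrogen = guess_hydrogen(m[, 2]))
}

#' Read a PQR file (atoms with per-atom charge and radius)
#'
#' PQR is the whitespace-tolerant PDB variant produced by PDB2PQR-style
#' tools, with partial charge (elementary charge units) and van der Waals
#' radius (Angstrom) in the two fields following z.
#'
#' @inheritParams read_pdb
#' @return An atom tibble with `charge` and `radius` populated on every atom.
#' @export
read_pqr <- function(path, label = NULL) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  atoms <- parse_pqr_whitespace(path)
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("non-positive radius in PQR ", path)
  new_structure(atoms, label = label %||% basename(path))
}

#' Read a per-residue conservation grade table
#'
#' Reads ConSurf-style tabular output: one row per residue with an integer
#' conservation grade on the 1 (variable) to 9 (conserved) scale.
#'
#' @param path Path to a whitespace- or tab-separated table with a header.
#' @param chain_col,seq_col,grade_col Column names (or indices) of the chain
#'   identifier, author residue number and grade.
#' @return A tibble with columns `chain_id`, `residue_seq`, `grade`. Residues
#'   absent from the table are simply absent from the result.
#' @export
read_conservation <- function(path, chain_col = "chain", seq_col = "resi",
                              grade_col = "grade") {
  if (!file.exists(path)) stop("conservation file not found: ", path)
  raw <- tryCatch(read.table(path, header = TRUE, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0)
    return(tibble(chain_id = character(), residue_seq = integer(),
                  grade = integer()))
  pick <- function(col) if (is.character(col)) raw[[col]] else raw[, col]
  out <- tibble(chain_id = as.character(pick(chain_col)),
                residue_seq = as.integer(pick(seq_col)),
                grade = as.integer(pick(grade_col)))
  if (any(is.na(out$grade)) || any(out$grade < 1 | out$grade > 9))
    stop("conservation grades must be integers in 1..9")
  out
}

#' Assign Wimley-White hydrophobicity values to every atom
#'
#' Each atom receives the residue-level interfacial transfer free energy of
#' the amino acid it belongs to. Unknown residue names get the neutral value
#' 0 with a warning.
#'
#' @param structure An atom tibble.
#' @param scale Named numeric vector mapping 3-letter residue codes to
#'   values; defaults to [wimley_white].
#' @return The structure with `hydrophobicity` populated. Idempotent.
#' @export
assign_hydrophobicity <- function(structure, scale = wimley_white) {
  vals <- unname(scale[structure$residue_name])
  unknown <- is.na(vals)
  if (any(unknown)) {
    warning("unknown residue name(s) assigned neutral hydrophobicity 0: ",
            paste(unique(structure$residue_name[unknown]), collapse = ", "))
    vals[unknown] <- 0
  }
  structure$hydrophobicity <- vals
  structure
}

#' Merge PQR charges/radii and conservation grades into a base structure
#'
#' Atoms are matched by (chain, residue number + insertion code, atom name).
#' At least 90 percent of the base structure's heavy atoms must find a PQR
#' match. PQR hydrogens absent from the base are appended (they carry charge)
#' and flagged `is_hydrogen`; base coordinates are never altered.
#'
#' @param base Structure from [read_pdb()] (its coordinates are kept).
#' @param pqr Optional structure from [read_pqr()].
#' @param conservation Optional tibble from [read_conservation()].
#' @return The merged structure carrying every available property.
#' @export
merge_properties <- function(base, pqr = NULL, conservation = NULL) {
  out <- base
  if (!is.null(pqr)) {
    base_key <- paste(res_key(base), base$atom_name, sep = "|")
    pqr_key <- paste(res_key(pqr), pqr$atom_name, sep = "|")
    idx <- match(base_key, pqr_key)
    heavy <- !base$is_hydrogen
    matched <- !is.na(idx)
    frac <- mean(matched[heavy])
    if (frac < 0.9) {
      miss <- head(base_key[heavy & !matched], 10)
      stop(sprintf(
        "only %.0f%% of heavy atoms matched the PQR; first mismatches: %s",
        100 * frac, paste(miss, collapse = ", ")))
    }
    if (any(!matched))
      message(sum(!matched), " base atom(s) had no PQR match")
    out$charge[matched] <- pqr$charge[idx[matched]]
    out$radius[matched] <- pqr$radius[idx[matched]]
    extra_h <- pqr[pqr$is_hydrogen & !(pqr_key %in% base_key), , drop = FALSE]
    if (nrow(extra_h) > 0) {
      extra_h$hydrophobicity <- NA_real_
      extra_h$conservation <- NA_integer_
      out <- new_structure(dplyr::bind_rows(out, extra_h),
                           label = structure_label(base))
    }
  }
  if (!is.null(conservation) && nrow(conservation) > 0) {
    key <- paste(out$chain_id, out$residue_seq, sep = ":")
    ckey <- paste(conservation$chain_id, conservation$residue_seq, sep = ":")
    cidx <- match(key, ckey)
    out$conservation <- conservation$grade[cidx]
  }
  new_structure(out, label = structure_label(base))
}

#' Write a structure to PDB, optionally annotating predicted residues
#'
#' @param structure Atom tibble.
#' @param path Output path.
#' @param remark_residues Optional tibble with columns `chain_id`,
#'   `residue_seq`: residues listed in REMARK 999 header lines (predicted
#'   interface annotation).
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, remark_residues = NULL) {
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = structure$residue_seq,
                   resid = structure$residue_name,
                   eleno = structure$serial,
                   elety = structure$atom_name,
                   chain = structure$chain_id,
                   insert = structure$icode,
                   o = rep(1, nrow(structure)),
                   b = rep(0, nrow(structure)))
  if (!is.null(remark_residues) && nrow(remark_residues) > 0) {
    remarks <- sprintf("REMARK 999 PREDICTED INTERFACE %s %s",
                       remark_residues$chain_id, remark_residues$residue_seq)
    body <- readLines(path, warn = FALSE)
    writeLines(c(remarks, body), path)
  }
  invisible(path)
}

#' Write a structure to PQR (whitespace-delimited, charge then radius)
#'
#' @param structure Atom tibble with `charge` and `radius` populated.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pqr <- function(structure, path) {
  if (anyNA(structure$charge) || anyNA(structure$radius))
    stop("charge and radius must be populated to write a PQR")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f %8.4f %7.4f",
    structure$serial, structure$atom_name, structure$residue_name,
    structure$chain_id, structure$residue_seq, structure$icode,
    structure$x, structure$y, structure$z,
    structure$charge, structure$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a plain-text residue list
#'
#' @param residues Tibble with `chain_id` and `residue_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_list <- function(residues, path) {
  writeLines(sprintf("%s %s", residues$chain_id, residues$residue_seq), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
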