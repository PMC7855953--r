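#' Specification of a synthetic blob protein
#'
#' Describes a pseudo-protein whose atoms lie quasi-uniformly on a closed
#' surface (with small seeded jitter), grouped into contiguous residues.
#' The defaults emulate a small globular subunit at the scale of the
#' engineered-charge proof-of-concept experiments: 80 residues of 4
#' pseudo-atoms on a 16 Angstrom sphere.
#'
#' @param n_residues Number of residues.
#' @param atoms_per_residue Pseudo-atoms per residue.
#' @param shape One of "sphere", "ellipsoid", "two_blob".
#' @param radius Shape radius in Angstrom.
#' @param patch_fraction Fraction of residues in a planted property patch
#'   (used by conservation-patch engineering).
#' @param patch_contrast Property amplitude of the planted patch.
#' @param jitter Half-width (Angstrom) of the uniform coordinate jitter.
#' @param seed Integer seed; fixtures are bit-reproducible from (spec, seed).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 80L, atoms_per_residue = 4L,
                         shape = c("sphere", "ellipsoid", "two_blob"),
                         radius = 16, patch_fraction = 0.15,
                         patch_contrast = 1, jitter = 0.3, seed = 1L) {
  shape <- match.arg(shape)
  if (radius <= 0) stop("radius must be positive")
  if (patch_fraction <= 0 || patch_fraction >= 1)
    stop("patch_fraction must be in (0, 1)")
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 shape = shape, radius = radius,
                 patch_fraction = patch_fraction,
                 patch_contrast = patch_contrast,
                 jitter = jitter, seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_atom_names <- function(apr) {
  base <- c("CA", "CB", "CG", "CD", "CE", "CZ")
  if (apr <= length(base)) base[seq_len(apr)]
  else c(base, paste0("C", seq_len(apr - length(base)) + 6))
}

#' Generate a synthetic blob protein
#'
#' Pseudo-atoms are placed quasi-uniformly on the requested closed surface
#' (golden-spiral construction plus small seeded jitter) and grouped into
#' contiguous residues of `atoms_per_residue` along the spiral, so residues
#' are spatially compact. All residues are alanine records with neutral
#' charge, so every downstream property path runs unmodified. Deterministic
#' given the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param label Structure label.
#' @param chain Chain identifier.
#' @param center Translation applied to the finished structure.
#' @return An atom tibble.
#' @export
make_blob_protein <- function(spec = fixture_spec(), label = "blob",
                              chain = "A", center = c(0, 0, 0)) {
  n_atoms <- spec$n_residues * spec$atoms_per_residue
  pts <- unit_sphere_points(n_atoms)
  pts <- switch(spec$shape,
    sphere = pts * spec$radius,
    ellipsoid = sweep(pts, 2, spec$radius * c(1, 0.8, 0.65), "*"),
    two_blob = {
      half <- pts * (0.75 * spec$radius)
      shift <- 0.5 * spec$radius
      rbind(sweep(half[seq_len(ceiling(n_atoms / 2)), , drop = FALSE],
                  2, c(-shift, 0, 0), "+"),
            sweep(half[seq_len(n_atoms) > ceiling(n_atoms / 2), ,
                       drop = FALSE],
                  2, c(shift, 0, 0), "+"))
    })
  pts <- with_seed(spec$seed, {
    pts + matrix(runif(3 * n_atoms, -spec$jitter, spec$jitter), n_atoms, 3)
  })
  pts <- sweep(pts, 2, center, "+")
  res <- rep(seq_len(spec$n_residues), each = spec$atoms_per_residue)
  new_structure(tibble(
    serial = seq_len(n_atoms),
    atom_name = rep(fixture_atom_names(spec$atoms_per_residue),
                    spec$n_residues),
    residue_name = "ALA",
    chain_id = chain,
    residue_seq = res,
    icode = "",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = 1.7, charge = 0,
    hydrophobicity = unname(wimley_white["ALA"]),
    conservation = NA_integer_,
    is_hydrogen = FALSE), label = label)
}

#' Generate a posed pair of blob proteins in contact
#'
#' Builds two blobs on chains A and B and translates B along +x so the
#' surface gap between them is `gap` Angstrom, giving a well-defined
#' contact patch for engineered-interface experiments.
#'
#' @param spec_a,spec_b [fixture_spec()]s for the two partners (`spec_b`
#'   defaults to `spec_a` with seed + 1000).
#' @param gap Surface-to-surface gap along x in Angstrom.
#' @return List with structures `a` and `b`.
#' @export
make_fixture_pair <- function(spec_a = fixture_spec(),
                              spec_b = NULL, gap = 1.5) {
  if (is.null(spec_b)) {
    spec_b <- spec_a
    spec_b$seed <- spec_a$seed + 1000L
  }
  a <- make_blob_protein(spec_a, label = "blob_a", chain = "A")
  b <- make_blob_protein(spec_b, label = "blob_b", chain = "B",
                         center = c(spec_a$radius + spec_b$radius + gap,
                                    0, 0))
  list(a = a, b = b)
}

#' Engineer a complementary-charge interface on a posed pair
#'
#' Reproduces the engineered-charge construction: every charge is set to 0,
#' then atoms on the true contact interface of partner A receive +1 and
#' those on partner B's receive -1. The ground-truth residue patches are
#' the [true_interface()] residue sets at the same cutoff.
#'
#' @param struct_a,struct_b Atom tibbles posed in contact.
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom.
#' @param contrast Patch charge amplitude (elementary charges).
#' @return List: modified `a` and `b`, ground-truth `patch_a`, `patch_b`
#'   residue tibbles.
#' @export
engineer_charge_interface <- function(struct_a, struct_b,
                                      contact_cutoff = 5, contrast = 1) {
  ha <- which(!struct_a$is_hydrogen)
  hb <- which(!struct_b$is_hydrogen)
  da <- min_dist_cpp(as.matrix(struct_a[ha, c("x", "y", "z")]),
                     as.matrix(struct_b[hb, c("x", "y", "z")]))
  db <- min_dist_cpp(as.matrix(struct_b[hb, c("x", "y", "z")]),
                     as.matrix(struct_a[ha, c("x", "y", "z")]))
  if (!any(da < contact_cutoff))
    stop("no contact between the structures within ", contact_cutoff,
         " Angstrom")
  struct_a$charge <- 0
  struct_b$charge <- 0
  struct_a$charge[ha[da < contact_cutoff]] <- contrast
  struct_b$charge[hb[db < contact_cutoff]] <- -contrast
  ti <- true_interface(struct_a, struct_b, contact_cutoff)
  list(a = struct_a, b = struct_b,
       patch_a = ti$residues_a, patch_b = ti$residues_b)
}

#' Plant a conserved patch into the conservation column
#'
#' Residues in `patch` receive the high grade, all others the low grade,
#' emulating a mutually conserved binding patch.
#'
#' @param structure Atom tibble.
#' @param patch Residue tibble (`chain_id`, `residue_seq`).
#' @param high,low Conservation grades (1..9).
#' @return The structure with `conservation` populated.
#' @export
engineer_conservation_patch <- function(structure, patch, high = 9L,
                                        low = 1L) {
  keys <- paste(structure$chain_id, structure$residue_seq, sep = ":")
  pkeys <- paste(patch$chain_id, patch$residue_seq, sep = ":")
  structure$conservation <- ifelse(keys %in% pkeys, as.integer(high),
                                   as.integer(low))
  structure
}

#' Smoothly distort a structure to a target RMSD
#'
#' Applies a sum of three seeded long-wavelength sinusoidal displacement
#' modes, scaled so the RMSD over the first atom of each residue (the
#' C-alpha equivalent) equals `target_rmsd`. The field is spatially smooth:
#' neighbouring residues move coherently, emulating the low-frequency
#' collective motions produced by normal-mode analysis at a controlled
#' distortion amplitude. Topology and residue identities are unchanged.
#'
#' @param structure Atom tibble.
#' @param target_rmsd Target C-alpha-equivalent RMSD in Angstrom.
#' @param seed Integer seed for the mode directions, wavelengths and phases.
#' @return The distorted structure.
#' @export
perturb_structure <- function(structure, target_rmsd, seed = 1L) {
  if (target_rmsd < 0) stop("target_rmsd must be >= 0")
  if (target_rmsd == 0) return(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  extent <- max(apply(xyz, 2, function(v) diff(range(v))))
  disp <- with_seed(seed, {
    d <- matrix(0, nrow(xyz), 3)
    for (k in 1:3) {
      amp <- rnorm(3)
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      lambda <- runif(1, 1.5 * extent, 3 * extent)
      phase <- runif(1, 0, 2 * pi)
      w <- sin(2 * pi * (xyz %*% u) / lambda + phase)
      d <- d + outer(as.vector(w), amp)
    }
    d
  })
  key <- res_key(structure)
  first <- !duplicated(key)
  rmsd0 <- sqrt(mean(rowSums(disp[first, , drop = FALSE]^2)))
  if (rmsd0 == 0) stop("degenerate displacement field")
  xyz <- xyz + disp * (target_rmsd / rmsd0)
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' C-alpha-equivalent RMSD between two conformations of one structure
#'
#' RMSD over the first atom of each residue; the two structures must share
#' atom order.
#'
#' @param s1,s2 Atom tibbles.
#' @return RMSD in Angstrom.
#' @export
calpha_rmsd <- function(s1, s2) {
  key <- res_key(s1)
  first <- !duplicated(key)
  d <- as.matrix(s1[first, c("x", "y", "z")]) -
    as.matrix(s2[first, c("x", "y", "z")])
  sqrt(mean(rowSums(d^2)))
}

#' Write fixture files (PDB, PQR, conservation table)
#'
#' @param structure Atom tibble.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(structure, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pdb = file.path(dir, paste0(name, ".pdb")),
             pqr = file.path(dir, paste0(name, ".pqr")),
             cons = file.path(dir, paste0(name, ".cons.tsv")))
  write_structure_pdb(structure, paths["pdb"])
  write_structure_pqr(structure, paths["pqr"])
  res <- structure[!duplicated(res_key(structure)), ]
  res <- res[!is.na(res$conservation), ]
  df <- data.frame(chain = res$chain_id, resi = res$residue_seq,
                   grade = res$conservation)
  write.table(df, paths["cons"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
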