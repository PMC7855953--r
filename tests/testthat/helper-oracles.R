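# independent brute-force oracle for the full 2D cross-correlation:
# plain double loop over all lags, same lag convention as cross_correlate()
brute_xcorr <- function(a, b) {
  Ra <- nrow(a); Ca <- ncol(a); Rb <- nrow(b); Cb <- ncol(b)
  out <- matrix(0, Ra + Rb - 1, Ca + Cb - 1)
  for (p in seq_len(nrow(out))) for (q in seq_len(ncol(out))) {
    dr <- p - Rb; dc <- q - Cb
    s <- 0
    for (i in seq_len(Ra)) for (j in seq_len(Ca)) {
      bi <- i - dr; bj <- j - dc
      if (bi >= 1 && bi <= Rb && bj >= 1 && bj <= Cb)
        s <- s + a[i, j] * b[bi, bj]
    }
    out[p, q] <- s
  }
  out
}

# hand-build a bare structure tibble from a coordinate matrix
toy_structure <- function(coords, chain = "A", atoms_per_residue = 1L,
                          radius = 1.7, charge = 0, label = "toy") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  res <- rep(seq_len(ceiling(n / atoms_per_residue)),
             each = atoms_per_residue)[seq_len(n)]
  s <- tibble::tibble(
    serial = seq_len(n),
    atom_name = paste0("C", (seq_len(n) - 1) %% atoms_per_residue + 1),
    residue_name = "ALA", chain_id = chain, residue_seq = res, icode = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = radius, charge = charge,
    hydrophobicity = 0.17, conservation = NA_integer_,
    is_hydrogen = FALSE)
  attr(s, "label") <- label
  s
}

# engineered complementary-charge pair under the study conditions
engineered_pair <- function(seed, ...) {
  pair <- make_fixture_pair(fixture_spec(seed = seed, ...))
  engineer_charge_interface(pair$a, pair$b)
}

# face holding most of a planted atom set, in a given segmentation
modal_face <- function(segmentation, surface_atoms, atoms) {
  lab <- segmentation$labels[match(atoms, surface_atoms)]
  lab <- lab[!is.na(lab)]
  as.integer(names(which.max(table(lab))))
}

res_set <- function(residues) {
  paste(residues$chain_id, residues$residue_seq)
}

patch_recall <- function(predicted, patch) {
  mean(res_set(patch) %in% res_set(predicted))
}

# planted vs winning face pair for an engineered-charge prediction
planted_pair_recovered <- function(pred, eng) {
  wi <- pred$winning$initialization
  fa <- modal_face(pred$internals$builds$a[[wi]]$segmentation,
                   pred$internals$surface_a$surface_atoms,
                   which(eng$a$charge > 0))
  fb <- modal_face(pred$internals$builds$b[[wi]]$segmentation,
                   pred$internals$surface_b$surface_atoms,
                   which(eng$b$charge < 0))
  pred$winning$hit$face_a == fa && pred$winning$hit$face_b == fb
}
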