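#' Full 2D cross-correlation of two grids
#'
#' Computes the lag-indexed sum of elementwise products over every
#' overlapping placement of grid B on grid A, including partial corner
#' overlaps (zero padding outside), the complementarity score underlying the
#' interface search. The output has dimensions
#' (Ra + Rb - 1) x (Ca + Cb - 1); entry (p, q) is the lag
#' (dr, dc) = (p - Rb, q - Cb), where (dr, dc) is the offset of B's (1,1)
#' cell relative to A's (1,1) cell.
#'
#' @param a,b Numeric matrices or `face_grid` objects.
#' @return The lag-score matrix, with `lag_rows` and `lag_cols` attributes
#'   giving the lag coordinates of its rows and columns.
#' @export
#' @examples
#' cross_correlate(matrix(1), matrix(1))
cross_correlate <- function(a, b) {
  av <- if (inherits(a, "face_grid")) a$values else as.matrix(a)
  bv <- if (inherits(b, "face_grid")) b$values else as.matrix(b)
  if (length(av) == 0 || length(bv) == 0) stop("empty grid")
  out <- xcorr2_cpp(av, bv)
  attr(out, "lag_rows") <- seq_len(nrow(out)) - nrow(bv)
  attr(out, "lag_cols") <- seq_len(ncol(out)) - ncol(bv)
  out
}

# Nearest-neighbour cell map for rotating an nr x nc grid about its center.
# Returns the output dimensions and an integer matrix of source cells
# (column-major linear indices; 0 where the output cell falls outside the
# input). Multiples of 90 degrees reduce to exact cell permutations.
rotation_index_map <- function(nr, nc, angle_deg) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  out_nr <- max(1L, as.integer(ceiling(nr * abs(co) + nc * abs(si) - 1e-9)))
  out_nc <- max(1L, as.integer(ceiling(nr * abs(si) + nc * abs(co) - 1e-9)))
  cin <- c((nr + 1) / 2, (nc + 1) / 2)
  cout <- c((out_nr + 1) / 2, (out_nc + 1) / 2)
  ii <- matrix(seq_len(out_nr), out_nr, out_nc) - cout[1]
  jj <- matrix(seq_len(out_nc), out_nr, out_nc, byrow = TRUE) - cout[2]
  # inverse rotation back into the source frame
  u <- co * ii + si * jj
  v <- -si * ii + co * jj
  si_idx <- round(cin[1] + u)
  sj_idx <- round(cin[2] + v)
  ok <- si_idx >= 1 & si_idx <= nr & sj_idx >= 1 & sj_idx <= nc
  map <- matrix(0L, out_nr, out_nc)
  map[ok] <- as.integer((sj_idx[ok] - 1) * nr + si_idx[ok])
  list(nrow = out_nr, ncol = out_nc, map = map)
}

#' Rotate a face grid in its plane
#'
#' Rotates values and occupancy about the grid center into a bounding grid
#' by nearest-neighbour resampling; the bin-to-atom map is carried through
#' the same cell mapping, so rotated cells still trace back to atoms.
#' Multiples of 90 degrees are exact cell permutations.
#'
#' @param grid A `face_grid`.
#' @param angle_deg Rotation angle in degrees.
#' @return The rotated `face_grid` (with a `source_cells` field giving each
#'   output cell's source cell, 0 for none).
#' @export
rotate_grid <- function(grid, angle_deg) {
  if (angle_deg %% 360 == 0) {
    grid$source_cells <- matrix(seq_along(grid$values),
                                nrow(grid$values), ncol(grid$values))
    return(grid)
  }
  rm <- rotation_index_map(nrow(grid$values), ncol(grid$values), angle_deg)
  vals <- matrix(0, rm$nrow, rm$ncol)
  occ <- matrix(FALSE, rm$nrow, rm$ncol)
  hit <- rm$map > 0L
  vals[hit] <- grid$values[rm$map[hit]]
  occ[hit] <- grid$occupancy[rm$map[hit]]
  bin_atoms <- vector("list", rm$nrow * rm$ncol)
  bin_atoms[which(hit)] <- grid$bin_atoms[rm$map[hit]]
  out <- grid
  out$values <- vals
  out$occupancy <- occ
  out$bin_atoms <- bin_atoms
  out$source_cells <- rm$map
  out
}

grid_matrices <- function(grids, property) {
  list(vals = lapply(grids, function(g) g[[property]]$values),
       occ = lapply(grids, function(g) g[[property]]$occupancy * 1))
}

rotation_angles <- function(config) {
  as.integer(seq(0L, 360L - config$rotation_step_deg,
                 by = config$rotation_step_deg))
}

#' Score every face-pair placement of two proteins
#'
#' For each of the k x k face pairs (36 canonically), each in-plane rotation
#' of partner B's grid in steps of `rotation_step_deg`, and each
#' cross-correlation lag, the complementarity score is recorded. Ranking is
#' descending for hydrophobicity and conservation (maximum score = best) and
#' ascending for charge, whose complementarity pairs negative with positive
#' values so the most negative score is best. Ties are broken by
#' (face_a, face_b, rotation, lag) lexicographic order. Placements whose
#' occupied-cell overlap is below `min_overlap_bins` are excluded.
#'
#' @param grids_a,grids_b Grid lists from [build_face_grids()] (`$grids`).
#' @param property Property tag scored.
#' @param config A [grid_config()].
#' @param top_k Number of ranked hits returned.
#' @param initialization Tag recorded on the hits.
#' @return A tibble of hits, best first: `face_a`, `face_b`, `rotation_deg`,
#'   `lag_row`, `lag_col`, `score`, `property`, `initialization`, `rank`.
#' @export
score_all_pairs <- function(grids_a, grids_b, property,
                            config = grid_config(), top_k = config$n_hits,
                            initialization = "axis_extremes") {
  ga <- grid_matrices(grids_a, property)
  angles <- rotation_angles(config)
  b_vals <- vector("list", length(grids_b))
  b_occ <- vector("list", length(grids_b))
  for (f in seq_along(grids_b)) {
    g <- grids_b[[f]][[property]]
    rots <- lapply(angles, function(a) rotate_grid(g, a))
    b_vals[[f]] <- lapply(rots, `[[`, "values")
    b_occ[[f]] <- lapply(rots, function(r) r$occupancy * 1)
  }
  hits <- top_hits_cpp(ga$vals, ga$occ, b_vals, b_occ, angles,
                       minimize = identical(property, "charge"),
                       min_overlap = config$min_overlap_bins,
                       top_k = as.integer(top_k))
  out <- as_tibble(hits)
  out$property <- property
  out$initialization <- initialization
  out$rank <- seq_len(nrow(out))
  out
}

#' Choose between the unrotated and the 45/45-rotated initialization
#'
#' The sums of the `top_m` scores of the two hit lists are compared; the
#' larger sum wins for hydrophobicity and conservation, the smaller (more
#' negative) for charge. A tie keeps the unrotated initialization. When a
#' list holds fewer than `top_m` hits, the comparison uses the smaller
#' common count.
#'
#' @param hits_init1,hits_init2 Ranked hit tibbles from [score_all_pairs()].
#' @param property Property tag.
#' @param top_m Number of top scores summed.
#' @return List: `chosen` (1 or 2), `hits` (the winning list), `sums`
#'   (the two compared sums).
#' @export
select_initialization <- function(hits_init1, hits_init2, property,
                                  top_m = 10L) {
  m <- min(top_m, nrow(hits_init1), nrow(hits_init2))
  if (m == 0) stop("no hits to compare")
  s1 <- sum(hits_init1$score[seq_len(m)])
  s2 <- sum(hits_init2$score[seq_len(m)])
  better2 <- if (identical(property, "charge")) s2 < s1 else s2 > s1
  list(chosen = if (better2) 2L else 1L,
       hits = if (better2) hits_init2 else hits_init1,
       sums = c(init1 = s1, init2 = s2))
}

#' Consistency rule over the top placements
#'
#' A prediction is consistent when all `top_m` top-ranked placements are
#' (different subsets of) the same two faces. Otherwise the modal face pair
#' is returned with `consistent = FALSE`; modal ties go to the pair holding
#' the best-ranked hit.
#'
#' @param hits Ranked hit tibble.
#' @param top_m Number of top hits inspected.
#' @return List: `consistent` (logical), `face_pair` (length-2 integer
#'   vector).
#' @export
consistency_check <- function(hits, top_m = 10L) {
  if (nrow(hits) == 0) stop("consistency check needs at least one hit")
  top <- hits[seq_len(min(top_m, nrow(hits))), ]
  pair <- paste(top$face_a, top$face_b, sep = "-")
  if (length(unique(pair)) == 1)
    return(list(consistent = TRUE,
                face_pair = c(top$face_a[1], top$face_b[1])))
  counts <- table(pair)
  modal <- names(counts)[counts == max(counts)]
  first <- top[pair %in% modal, ][1, ]
  list(consistent = FALSE, face_pair = c(first$face_a, first$face_b))
}

#' Map a winning placement back to residues on both partners
#'
#' Recomputes the overlap region of the two grids at the hit's rotation and
#' lag; every overlapping cell pair in which both cells are occupied
#' contributes its atoms (partner B's traced through the rotation's cell
#' mapping), and the residues of those atoms form the predicted interface.
#'
#' @param hit One row of a hit tibble.
#' @param grids_a,grids_b Grid lists of the initialization the hit came from.
#' @param structure_a,structure_b The corresponding atom tibbles.
#' @param property Property tag of the scored grids.
#' @return List: `residues_a`, `residues_b` (tibbles with `chain_id`,
#'   `residue_seq`, `icode`), `atoms_a`, `atoms_b` (row indices).
#' @export
extract_interface <- function(hit, grids_a, grids_b, structure_a,
                              structure_b, property) {
  ga <- grids_a[[hit$face_a]][[property]]
  gb <- rotate_grid(grids_b[[hit$face_b]][[property]], hit$rotation_deg)
  ra <- nrow(ga$values); ca <- ncol(ga$values)
  rb <- nrow(gb$values); cb <- ncol(gb$values)
  dr <- hit$lag_row; dc <- hit$lag_col
  is <- max(1, 1 + dr):min(ra, rb + dr)
  js <- max(1, 1 + dc):min(ca, cb + dc)
  atoms_a <- integer(0)
  atoms_b <- integer(0)
  for (i in is) for (j in js) {
    bi <- i - dr; bj <- j - dc
    if (ga$occupancy[i, j] && gb$occupancy[bi, bj]) {
      atoms_a <- c(atoms_a, ga$bin_atoms[[(j - 1) * ra + i]])
      atoms_b <- c(atoms_b, gb$bin_atoms[[(bj - 1) * rb + bi]])
    }
  }
  atoms_a <- sort(unique(atoms_a))
  atoms_b <- sort(unique(atoms_b))
  if (length(atoms_a) == 0 || length(atoms_b) == 0)
    stop("empty interface: no occupied overlap at the winning placement")
  list(residues_a = atom_residues(structure_a, atoms_a),
       residues_b = atom_residues(structure_b, atoms_b),
       atoms_a = atoms_a, atoms_b = atoms_b)
}

atom_residues <- function(structure, atom_idx) {
  sub <- structure[atom_idx, c("chain_id", "residue_seq", "icode")]
  dplyr::distinct(sub)
}

check_property_present <- function(structure, property) {
  heavy <- !structure$is_hydrogen
  col <- switch(property, charge = structure$charge,
                hydrophobicity = structure$hydrophobicity,
                conservation = structure$conservation,
                stop("unknown property: ", property))
  if (all(is.na(col[heavy])))
    stop("property '", property, "' is absent on ",
         structure_label(structure))
  invisible(TRUE)
}

#' Predict the interaction interface of two partner proteins
#'
#' Runs the full pipeline: optional principal-axis orientation, accessible
#' surface and residue depth, surface-atom selection, biased k-means face
#' segmentation and property gridding under the unrotated and the
#' 45/45-degree-rotated initialization, exhaustive cross-correlation scoring
#' of all face pairs over in-plane rotations and lags for each requested
#' property, initialization selection by top-10 score sum, the consistency
#' rule, and mapping of the winning placement back to residues on both
#' partners.
#'
#' The final prediction is the first consistent property in
#' `config$property_order`; with `config$antibody_mode` the top charge
#' placement is used regardless of consistency (variable-region binding is
#' not captured by conservation or hydrophobicity). When no property is
#' consistent, the first requested property's modal-pair top placement is
#' used and flagged `consistent = FALSE`.
#'
#' @param structure_a,structure_b Atom tibbles with the requested properties
#'   populated.
#' @param properties Character vector of property tags to score.
#' @param config A [grid_config()].
#' @param second_interface Also report the best consistent interface after
#'   excluding the winning face pair (candidate secondary binding site).
#' @return An `interface_prediction` object; see [tidy.interface_prediction()]
#'   and [glance.interface_prediction()].
#' @export
predict_interface <- function(structure_a, structure_b,
                              properties = "charge",
                              config = grid_config(),
                              second_interface = FALSE) {
  config <- as_grid_config(config)
  properties <- match.arg(properties,
                          c("charge", "conservation", "hydrophobicity"),
                          several.ok = TRUE)
  for (p in properties) {
    check_property_present(structure_a, p)
    check_property_present(structure_b, p)
  }
  if (config$antibody_mode && !("charge" %in% properties))
    stop("antibody_mode requires the charge property")
  if (config$use_pca_orientation) {
    structure_a <- orient_pca(structure_a)
    structure_b <- orient_pca(structure_b)
  }
  surf_a <- residue_depth(structure_a,
                          compute_surface_points(structure_a,
                                                 config$probe_radius,
                                                 config$n_sphere_points),
                          config$depth_cutoff)
  surf_b <- residue_depth(structure_b,
                          compute_surface_points(structure_b,
                                                 config$probe_radius,
                                                 config$n_sphere_points),
                          config$depth_cutoff)
  init_tag <- if (config$use_pca_orientation)
    "pca_then_axis_extremes" else "axis_extremes"
  builds <- list(
    a = list(build_face_grids(structure_a, surf_a, properties, config,
                              init_tag),
             build_face_grids(
               rotate_structure(structure_a, config$reinit_angles_deg[1],
                                config$reinit_angles_deg[2]),
               surf_a, properties, config, "axis_extremes_rotated45")),
    b = list(build_face_grids(structure_b, surf_b, properties, config,
                              init_tag),
             build_face_grids(
               rotate_structure(structure_b, config$reinit_angles_deg[1],
                                config$reinit_angles_deg[2]),
               surf_b, properties, config, "axis_extremes_rotated45")))

  per_property <- list()
  for (p in properties) {
    hits1 <- score_all_pairs(builds$a[[1]]$grids, builds$b[[1]]$grids, p,
                             config, initialization = init_tag)
    hits2 <- score_all_pairs(builds$a[[2]]$grids, builds$b[[2]]$grids, p,
                             config,
                             initialization = "axis_extremes_rotated45")
    sel <- select_initialization(hits1, hits2, p, config$top_m)
    cons <- consistency_check(sel$hits, config$top_m)
    per_property[[p]] <- list(
      hits = sel$hits, chosen_init = sel$chosen, init_sums = sel$sums,
      consistent = cons$consistent, face_pair = cons$face_pair,
      top_hit = sel$hits[1, ])
  }

  ordered <- intersect(config$property_order, properties)
  if (config$antibody_mode) {
    win_prop <- "charge"
    win_hit <- per_property$charge$top_hit
  } else {
    consistent_props <- ordered[vapply(per_property[ordered],
                                       `[[`, TRUE, "consistent")]
    if (length(consistent_props) > 0) {
      win_prop <- consistent_props[1]
      win_hit <- per_property[[win_prop]]$top_hit
    } else {
      win_prop <- ordered[1]
      pp <- per_property[[win_prop]]
      in_modal <- pp$hits$face_a == pp$face_pair[1] &
        pp$hits$face_b == pp$face_pair[2]
      win_hit <- pp$hits[in_modal, ][1, ]
    }
  }
  wi <- per_property[[win_prop]]$chosen_init
  iface <- extract_interface(win_hit, builds$a[[wi]]$grids,
                             builds$b[[wi]]$grids,
                             structure_a, structure_b, win_prop)

  second <- NULL
  if (second_interface) {
    pp <- per_property[[win_prop]]
    rest <- pp$hits[!(pp$hits$face_a == win_hit$face_a &
                        pp$hits$face_b == win_hit$face_b), ]
    if (nrow(rest) > 0) {
      cons2 <- consistency_check(rest, config$top_m)
      hit2 <- rest[rest$face_a == cons2$face_pair[1] &
                     rest$face_b == cons2$face_pair[2], ][1, ]
      iface2 <- tryCatch(
        extract_interface(hit2, builds$a[[wi]]$grids, builds$b[[wi]]$grids,
                          structure_a, structure_b, win_prop),
        error = function(e) NULL)
      if (!is.null(iface2))
        second <- list(hit = hit2, consistent = cons2$consistent,
                       residues_a = iface2$residues_a,
                       residues_b = iface2$residues_b)
    }
  }

  structure(list(
    residues_a = iface$residues_a, residues_b = iface$residues_b,
    atoms_a = iface$atoms_a, atoms_b = iface$atoms_b,
    winning = list(property = win_prop, hit = win_hit,
                   initialization = wi,
                   consistent = per_property[[win_prop]]$consistent,
                   face_pair = c(win_hit$face_a, win_hit$face_b)),
    per_property = per_property, second = second,
    labels = c(a = structure_label(structure_a),
               b = structure_label(structure_b)),
    config = config,
    internals = list(surface_a = surf_a, surface_b = surf_b,
                     builds = builds,
                     structure_a = structure_a, structure_b = structure_b)),
    class = "interface_prediction")
}

#' @export
print.interface_prediction <- function(x, ...) {
  w <- x$winning
  cat(sprintf(
    paste0("<interface_prediction> %s vs %s\n",
           "  property: %s (%s), faces (%d, %d), rotation %d deg, ",
           "score %.4g\n  residues: %d on A, %d on B\n"),
    x$labels["a"], x$labels["b"], w$property,
    if (w$consistent) "consistent" else "not consistent",
    w$hit$face_a, w$hit$face_b, w$hit$rotation_deg, w$hit$score,
    nrow(x$residues_a), nrow(x$residues_b)))
  invisible(x)
}
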