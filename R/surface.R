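#' Quasi-uniform points on the unit sphere (golden-spiral construction)
#'
#' @param n Number of points.
#' @return An n x 3 matrix of unit vectors.
#' @keywords internal
unit_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

heavy_coords <- function(structure) {
  as.matrix(structure[!structure$is_hydrogen, c("x", "y", "z")])
}

#' Solvent-accessible surface point cloud (Shrake-Rupley)
#'
#' Each heavy atom is expanded by the probe radius and covered with
#' `n_sphere_points` quasi-uniform test points; points falling inside any
#' other atom's expanded sphere are discarded. The surviving points trace the
#' solvent-accessible surface. Fully buried atoms contribute no points.
#'
#' @param structure Atom tibble; atoms without radii get united-atom element
#'   defaults.
#' @param probe_radius Probe radius in Angstrom (1.4 is the standard water
#'   probe).
#' @param n_sphere_points Test points per atom.
#' @return Tibble of surface point coordinates (`x`, `y`, `z`) with the
#'   contributing heavy atom's row index in `atom`.
#' @export
compute_surface_points <- function(structure, probe_radius = 1.4,
                                   n_sphere_points = 240L) {
  structure <- assign_default_radii(structure)
  heavy <- which(!structure$is_hydrogen)
  if (length(heavy) == 0) stop("structure has no heavy atoms")
  xyz <- as.matrix(structure[heavy, c("x", "y", "z")])
  rr <- structure$radius[heavy] + probe_radius
  unit <- unit_sphere_points(n_sphere_points)
  n <- length(heavy)
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- sweep(unit * rr[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      keep <- rep(TRUE, nrow(pts))
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        keep <- keep & dj2 >= rr[j]^2
        if (!any(keep)) break
      }
      pts <- pts[keep, , drop = FALSE]
    }
    out[[i]] <- pts
  }
  pts <- do.call(rbind, out)
  tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
         atom = rep(heavy, vapply(out, nrow, integer(1))))
}

#' Residue depth and surface-atom selection
#'
#' Atom depth is the minimum Euclidean distance from a heavy atom to any
#' accessible-surface point; residue depth is the mean over the residue's
#' heavy atoms. Residues with depth below `depth_cutoff` count as surface
#' residues, and all their heavy atoms become the surface-atom set used by
#' the face segmentation. The extra depth allowance (default 5 Angstrom)
#' keeps sub-surface atoms that can still contribute binding properties.
#'
#' @param structure Atom tibble.
#' @param points Surface point tibble from [compute_surface_points()].
#' @param depth_cutoff Depth cutoff in Angstrom.
#' @return A `surface_model` list: `points` (matrix), `atom_depths`
#'   (NA for hydrogens), `residue_depths` tibble, and `surface_atoms`
#'   (row indices into `structure`).
#' @export
residue_depth <- function(structure, points, depth_cutoff = 5) {
  pts <- as.matrix(as_tibble(points)[, c("x", "y", "z")])
  if (nrow(pts) == 0) stop("empty surface point cloud")
  heavy <- which(!structure$is_hydrogen)
  xyz <- as.matrix(structure[heavy, c("x", "y", "z")])
  d <- min_dist_cpp(xyz, pts)
  atom_depths <- rep(NA_real_, nrow(structure))
  atom_depths[heavy] <- d
  key <- res_key(structure)[heavy]
  rd <- tapply(d, key, mean)
  surf_keys <- names(rd)[rd < depth_cutoff]
  surface_atoms <- heavy[key %in% surf_keys]
  first <- !duplicated(key)
  residue_depths <- tibble(
    chain_id = structure$chain_id[heavy][first],
    residue_seq = structure$residue_seq[heavy][first],
    icode = structure$icode[heavy][first],
    depth = as.numeric(rd[key[first]]))
  structure(list(points = pts, atom_depths = atom_depths,
                 residue_depths = residue_depths,
                 surface_atoms = surface_atoms,
                 depth_cutoff = depth_cutoff),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf(
    "<surface_model> %d surface points, %d surface atoms, %d residues\n",
    nrow(x$points), length(x$surface_atoms), nrow(x$residue_depths)))
  invisible(x)
}

#' Orient a structure along its principal axes
#'
#' Rotates the heavy-atom cloud so its principal axes align with x, y, z in
#' decreasing variance order, and moves the heavy-atom centroid to the
#' origin. A pure rigid transform: pairwise distances are preserved.
#'
#' @param structure Atom tibble with at least 3 non-collinear atoms.
#' @return The rotated structure.
#' @export
orient_pca <- function(structure) {
  xyz <- heavy_coords(structure)
  if (nrow(xyz) < 3) stop("need at least 3 heavy atoms for PCA orientation")
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  e <- eigen(cov(cc), symmetric = TRUE)
  if (e$values[2] < 1e-10 * max(e$values[1], 1e-300))
    stop("degenerate (collinear) atom cloud: PCA orientation undefined")
  v <- e$vectors
  if (det(v) < 0) v[, 3] <- -v[, 3]
  all_xyz <- sweep(as.matrix(structure[, c("x", "y", "z")]), 2, ctr) %*% v
  structure$x <- all_xyz[, 1]
  structure$y <- all_xyz[, 2]
  structure$z <- all_xyz[, 3]
  structure
}

rotation_matrix_xy <- function(angle_x_deg, angle_y_deg) {
  ax <- angle_x_deg * pi / 180
  ay <- angle_y_deg * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(ax), -sin(ax),
                 0, sin(ax), cos(ax)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay),
                 0, 1, 0,
                 -sin(ay), 0, cos(ay)), 3, 3, byrow = TRUE)
  ry %*% rx
}

#' Rigidly rotate a structure about its heavy-atom centroid
#'
#' Right-handed rotation about x then y, used for the 45/45 degree
#' re-initialization of the face clustering (so interfaces split along a
#' face edge in one initialization fall inside a face in the other).
#'
#' @param structure Atom tibble.
#' @param angle_x_deg,angle_y_deg Rotation angles in degrees.
#' @return The rotated structure.
#' @export
rotate_structure <- function(structure, angle_x_deg, angle_y_deg) {
  rot <- rotation_matrix_xy(angle_x_deg, angle_y_deg)
  ctr <- colMeans(heavy_coords(structure))
  xyz <- sweep(as.matrix(structure[, c("x", "y", "z")]), 2, ctr) %*% t(rot)
  xyz <- sweep(xyz, 2, ctr, "+")
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Write surface points as an XYZ file
#'
#' @param points Tibble from [compute_surface_points()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_xyz <- function(points, path) {
  lines <- c(as.character(nrow(points)), "accessible surface points",
             sprintf("S %10.4f %10.4f %10.4f", points$x, points$y, points$z))
  writeLines(lines, path)
  invisible(path)
}
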