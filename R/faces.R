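#' Six-face segmentation of the surface atoms by biased k-means
#'
#' Lloyd's algorithm seeded from the atoms attaining the maximum and minimum
#' of each coordinate (max x, min x, max y, min y, max z, min z; ties go to
#' the lowest atom index), so the six faces start on opposite sides of the
#' protein. Iteration stops when the label assignment is stable or after 300
#' rounds. An emptied cluster is re-seeded with the point farthest from its
#' current centroid. Deterministic: no random restarts.
#'
#' @param coords n x 3 matrix of surface-atom coordinates.
#' @param k Number of faces (6 canonically; the first k biased seeds are
#'   used when k < 6).
#' @param max_iter Iteration cap.
#' @param initialization Tag recorded on the result.
#' @return A `face_segmentation` list: `labels` (per atom, in 1..k),
#'   `centroids` (k x 3), `initialization`.
#' @export
biased_kmeans_faces <- function(coords, k = 6L, max_iter = 300L,
                                initialization = "axis_extremes") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k) stop("fewer surface atoms (", n, ") than faces (", k, ")")
  seeds <- c(which.max(coords[, 1]), which.min(coords[, 1]),
             which.max(coords[, 2]), which.min(coords[, 2]),
             which.max(coords[, 3]), which.min(coords[, 3]))
  centroids <- coords[seeds[seq_len(min(k, 6))], , drop = FALSE]
  if (k > 6) stop("biased initialization defines at most 6 seeds")
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(coords^2), rep(1, nrow(centroids))) -
      2 * coords %*% t(centroids) +
      outer(rep(1, n), rowSums(centroids^2))
    new_labels <- max.col(-d2, ties.method = "first")
    for (cl in seq_len(k)) {
      if (!any(new_labels == cl)) {
        # re-seed an emptied cluster with the point farthest from its
        # centroid, never emptying another cluster in the process
        sizes <- tabulate(new_labels, k)
        cand <- which(sizes[new_labels] > 1)
        if (length(cand) == 0) next
        worst <- cand[which.max(d2[cbind(cand, new_labels[cand])])]
        new_labels[worst] <- cl
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (cl in seq_len(k))
      if (any(labels == cl))
        centroids[cl, ] <- colMeans(coords[labels == cl, , drop = FALSE])
  }
  structure(list(labels = labels, centroids = centroids,
                 initialization = initialization),
            class = "face_segmentation")
}

#' @export
print.face_segmentation <- function(x, ...) {
  cat(sprintf("<face_segmentation> %d atoms, %d faces (%s); sizes: %s\n",
              length(x$labels), nrow(x$centroids), x$initialization,
              paste(tabulate(x$labels, nrow(x$centroids)), collapse = " ")))
  invisible(x)
}

#' Project one face's atoms onto its least-squares plane
#'
#' The plane is spanned by the first two principal axes of the face's
#' coordinate covariance, centered on the face centroid; coordinates are
#' orthogonally projected, so the projected extent stays proportional to the
#' cluster extent (Angstrom units preserved). Axis signs are fixed by making
#' the skewness of each projected coordinate non-negative, for determinism.
#'
#' @param coords m x 3 matrix of one face's atom coordinates.
#' @return List with `coords2d` (m x 2) and `plane_basis` (list: `origin`,
#'   `axes` as a 3 x 2 matrix of orthonormal columns).
#' @export
project_face <- function(coords) {
  coords <- matrix(as.matrix(coords), ncol = 3)
  origin <- colMeans(coords)
  cc <- sweep(coords, 2, origin)
  if (nrow(coords) == 1) {
    axes <- cbind(c(1, 0, 0), c(0, 1, 0))
    return(list(coords2d = matrix(0, 1, 2),
                plane_basis = list(origin = origin, axes = axes)))
  }
  e <- eigen(cov(cc), symmetric = TRUE)
  axes <- e$vectors[, 1:2, drop = FALSE]
  p <- cc %*% axes
  for (j in 1:2) {
    sk <- sum(p[, j]^3)
    if (sk < 0) {
      axes[, j] <- -axes[, j]
      p[, j] <- -p[, j]
    }
  }
  list(coords2d = p, plane_basis = list(origin = origin, axes = axes))
}

#' Bin a projected face into a 2D property grid
#'
#' Bins are half-open squares of `bin_size` anchored at the minimum corner of
#' the projected coordinates; a bin's value is the arithmetic mean of its
#' member atoms' property and unoccupied bins hold 0 (neutral for all three
#' centered properties, so empty space does not contribute to the
#' cross-correlation).
#'
#' @param coords2d m x 2 projected coordinates from [project_face()].
#' @param values Property value per atom (finite, no NA).
#' @param bin_size Bin edge length in Angstrom.
#' @param atom_ids Atom identifiers (e.g. row indices into the structure)
#'   recorded per bin for mapping grid cells back to atoms.
#' @param face_id,property Metadata tags carried on the grid.
#' @param plane_basis Projection basis carried along for reporting.
#' @return A `face_grid`: `values` matrix, logical `occupancy`, `bin_atoms`
#'   (list indexed by the column-major linear cell index, matching R matrix
#'   indexing), `bin_size`,
#'   `face_id`, `property`, `plane_basis`.
#' @export
grid_face <- function(coords2d, values, bin_size, atom_ids = seq_along(values),
                      face_id = 1L, property = "charge",
                      plane_basis = NULL) {
  coords2d <- matrix(as.matrix(coords2d), ncol = 2)
  m <- nrow(coords2d)
  if (length(values) != m) stop("one property value per atom required")
  if (anyNA(values) || any(!is.finite(values)))
    stop("property '", property, "' is missing on some face atoms")
  mins <- apply(coords2d, 2, min)
  ri <- floor((coords2d[, 1] - mins[1]) / bin_size) + 1L
  ci <- floor((coords2d[, 2] - mins[2]) / bin_size) + 1L
  nr <- max(ri)
  nc <- max(ci)
  vals <- matrix(0, nr, nc)
  count <- matrix(0L, nr, nc)
  bin_atoms <- vector("list", nr * nc)
  cell <- (ci - 1L) * nr + ri  # column-major linear index
  for (a in seq_len(m)) {
    vals[cell[a]] <- vals[cell[a]] + values[a]
    count[cell[a]] <- count[cell[a]] + 1L
    bin_atoms[[cell[a]]] <- c(bin_atoms[[cell[a]]], atom_ids[a])
  }
  occ <- count > 0L
  vals[occ] <- vals[occ] / count[occ]
  structure(list(values = vals, occupancy = occ, bin_atoms = bin_atoms,
                 bin_size = bin_size, face_id = as.integer(face_id),
                 property = property, plane_basis = plane_basis),
            class = "face_grid")
}

#' @export
print.face_grid <- function(x, ...) {
  cat(sprintf("<face_grid> face %d, %s, %d x %d bins (%.3g occupied)\n",
              x$face_id, x$property, nrow(x$values), ncol(x$values),
              mean(x$occupancy)))
  invisible(x)
}

#' @export
dim.face_grid <- function(x) dim(x$values)

property_values <- function(structure, property, center_conservation = TRUE) {
  v <- switch(property,
    charge = structure$charge,
    hydrophobicity = structure$hydrophobicity,
    conservation = {
      g <- as.numeric(structure$conservation)
      if (center_conservation) g - 5 else g
    },
    stop("unknown property: ", property))
  v
}

#' Build the per-face property grids of one structure
#'
#' Runs the face segmentation on the surface atoms and grids every requested
#' property on every face. Conservation grades are centered (grade - 5)
#' before gridding by default so that 0 is neutral.
#'
#' @param structure Atom tibble with the requested properties populated on
#'   its surface atoms.
#' @param surface `surface_model` from [residue_depth()].
#' @param properties Character vector of property tags.
#' @param config A [grid_config()].
#' @param initialization Tag recorded on the segmentation.
#' @return List: `segmentation`, `grids` (list indexed `[[face]][[property]]`),
#'   `surface_atoms`.
#' @export
build_face_grids <- function(structure, surface,
                             properties = "charge",
                             config = grid_config(),
                             initialization = "axis_extremes") {
  idx <- surface$surface_atoms
  coords <- as.matrix(structure[idx, c("x", "y", "z")])
  seg <- biased_kmeans_faces(coords, k = config$k_faces,
                             initialization = initialization)
  k <- nrow(seg$centroids)
  grids <- vector("list", k)
  for (f in seq_len(k)) {
    sel <- seg$labels == f
    proj <- project_face(coords[sel, , drop = FALSE])
    grids[[f]] <- lapply(setNames(properties, properties), function(p) {
      v <- property_values(structure, p, config$center_conservation)[idx[sel]]
      if (anyNA(v))
        stop("property '", p, "' is missing on surface atoms of ",
             structure_label(structure))
      grid_face(proj$coords2d, v, config$bin_size, atom_ids = idx[sel],
                face_id = f, property = p, plane_basis = proj$plane_basis)
    })
  }
  list(segmentation = seg, grids = grids, surface_atoms = idx)
}

#' Export a face grid as a plain-text matrix
#'
#' @param grid A `face_grid`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_grid_txt <- function(grid, path) {
  write.table(grid$values, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
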