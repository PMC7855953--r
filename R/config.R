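#' Pipeline configuration
#'
#' Collects every tunable constant of the surface-reduction and
#' cross-correlation pipeline in one validated list. The defaults are the
#' method's canonical settings: a 1.4 Angstrom water probe for the accessible
#' surface, a 5 Angstrom residue-depth cutoff for surface membership, 5 x 5
#' Angstrom grid bins, six k-means faces seeded from the axis extremes, a
#' 45 degree x/y re-initialization, a 10 degree in-plane rotation search,
#' top-10 score sums for choosing the initialization and for the consistency
#' rule, 1000 shuffle replicates, and a 5 Angstrom true-interface cutoff.
#'
#' @param probe_radius Water probe radius in Angstrom used by the
#'   Shrake-Rupley accessible-surface construction.
#' @param depth_cutoff Residue depth (Angstrom) below which a residue counts
#'   as part of the surface.
#' @param bin_size Edge length (Angstrom) of the square bins of each face
#'   grid.
#' @param k_faces Number of k-means faces.
#' @param rotation_step_deg In-plane rotation sampling step for partner B's
#'   grids; must divide 360.
#' @param reinit_angles_deg Length-2 vector: rigid rotation about x then y
#'   (degrees) defining the second clustering initialization.
#' @param top_m Number of top placements summed when choosing the
#'   initialization and inspected by the consistency rule.
#' @param n_shuffles Number of property permutations in the shuffle
#'   significance test.
#' @param interface_cutoff Heavy-atom distance (Angstrom) defining a true
#'   interface residue in the bound complex.
#' @param rng_seed Integer seed from which all randomness flows.
#' @param use_pca_orientation Orient each structure by its principal axes
#'   before clustering.
#' @param antibody_mode Always take the top charge placement (variable-region
#'   binding is not captured by conservation or hydrophobicity).
#' @param n_sphere_points Quasi-uniform test points per atom sphere in the
#'   accessible-surface construction.
#' @param min_overlap_bins Placements overlapping in fewer occupied bin pairs
#'   than this are discarded (raw correlation at one-cell overlaps is
#'   noise-prone); set to 1 to keep every placement.
#' @param center_conservation Shift conservation grades by -5 before gridding
#'   so that 0 is neutral, as for charge and hydrophobicity.
#' @param property_order Priority order in which a consistent property is
#'   accepted as the final prediction.
#' @param n_hits Number of ranked placements retained per scoring pass.
#'
#' @return A validated list with class `ppigrid_config`.
#' @export
#' @examples
#' cfg <- grid_config(rotation_step_deg = 30)
#' cfg$bin_size
grid_config <- function(probe_radius = 1.4,
                        depth_cutoff = 5,
                        bin_size = 5,
                        k_faces = 6L,
                        rotation_step_deg = 10L,
                        reinit_angles_deg = c(45, 45),
                        top_m = 10L,
                        n_shuffles = 1000L,
                        interface_cutoff = 5,
                        rng_seed = 1L,
                        use_pca_orientation = FALSE,
                        antibody_mode = FALSE,
                        n_sphere_points = 240L,
                        min_overlap_bins = 4L,
                        center_conservation = TRUE,
                        property_order = c("charge", "conservation",
                                           "hydrophobicity"),
                        n_hits = 100L) {
  cfg <- list(
    probe_radius = probe_radius, depth_cutoff = depth_cutoff,
    bin_size = bin_size, k_faces = as.integer(k_faces),
    rotation_step_deg = as.integer(rotation_step_deg),
    reinit_angles_deg = reinit_angles_deg, top_m = as.integer(top_m),
    n_shuffles = as.integer(n_shuffles), interface_cutoff = interface_cutoff,
    rng_seed = as.integer(rng_seed),
    use_pca_orientation = isTRUE(use_pca_orientation),
    antibody_mode = isTRUE(antibody_mode),
    n_sphere_points = as.integer(n_sphere_points),
    min_overlap_bins = as.integer(min_overlap_bins),
    center_conservation = isTRUE(center_conservation),
    property_order = match.arg(property_order,
                               c("charge", "conservation", "hydrophobicity"),
                               several.ok = TRUE),
    n_hits = as.integer(n_hits))
  validate_config(cfg)
  structure(cfg, class = "ppigrid_config")
}

validate_config <- function(cfg) {
  lengths_pos <- c("probe_radius", "depth_cutoff", "bin_size",
                   "interface_cutoff")
  for (nm in lengths_pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop(sprintf("config field '%s' must be a positive length", nm))
  }
  if (cfg$k_faces < 1) stop("k_faces must be >= 1")
  if (cfg$rotation_step_deg < 1 || 360 %% cfg$rotation_step_deg != 0)
    stop("rotation_step_deg must divide 360")
  if (length(cfg$reinit_angles_deg) != 2)
    stop("reinit_angles_deg must have two angles (about x then y)")
  if (cfg$top_m < 1) stop("top_m must be >= 1")
  if (cfg$n_sphere_points < 1) stop("n_sphere_points must be >= 1")
  if (cfg$min_overlap_bins < 1) stop("min_overlap_bins must be >= 1")
  if (cfg$n_hits < cfg$top_m) stop("n_hits must be >= top_m")
  invisible(cfg)
}

as_grid_config <- function(config) {
  if (is.null(config)) return(grid_config())
  if (inherits(config, "ppigrid_config")) return(config)
  do.call(grid_config, config)
}

#' @export
print.ppigrid_config <- function(x, ...) {
  cat("<ppigrid_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
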