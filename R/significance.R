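#' True interface residues of a bound complex
#'
#' A residue is on the interaction interface if any of its heavy atoms lies
#' within `cutoff` (default 5 Angstrom) of a heavy atom of the partner; the
#' definition is symmetric.
#'
#' @param bound_a,bound_b Atom tibbles of the two subunits of the bound
#'   complex.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return List with `residues_a` and `residues_b` tibbles (`chain_id`,
#'   `residue_seq`, `icode`).
#' @export
true_interface <- function(bound_a, bound_b, cutoff = 5) {
  ha <- which(!bound_a$is_hydrogen)
  hb <- which(!bound_b$is_hydrogen)
  xa <- as.matrix(bound_a[ha, c("x", "y", "z")])
  xb <- as.matrix(bound_b[hb, c("x", "y", "z")])
  da <- min_dist_cpp(xa, xb)
  db <- min_dist_cpp(xb, xa)
  list(residues_a = atom_residues(bound_a, ha[da < cutoff]),
       residues_b = atom_residues(bound_b, hb[db < cutoff]))
}

residue_keys <- function(residues) {
  if (nrow(residues) == 0) return(character(0))
  icode <- if ("icode" %in% names(residues)) residues$icode else ""
  paste(residues$chain_id, paste0(residues$residue_seq, icode), sep = ":")
}

#' Confusion-matrix statistics of a predicted residue set
#'
#' Counts true/false positives/negatives of the predicted interface against
#' the actual interface over a residue universe, and derives precision
#' TP/(TP+FP), recall TP/(TP+FN), accuracy (TP+TN)/(TP+TN+FP+FN) and
#' F1 = 2 * precision * recall / (precision + recall). A metric whose
#' denominator is 0 is reported as 0.
#'
#' @param predicted,truth Residue tibbles (or character keys), subsets of
#'   the universe.
#' @param universe All residues under evaluation (every residue of the
#'   subunit by default in [evaluate_prediction()]).
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `accuracy`, `f1`.
#' @export
#' @examples
#' confusion_stats(c("A:1", "A:2"), c("A:2", "A:3"), paste0("A:", 1:10))
confusion_stats <- function(predicted, truth, universe) {
  pk <- if (is.character(predicted)) predicted else residue_keys(predicted)
  tk <- if (is.character(truth)) truth else residue_keys(truth)
  uk <- if (is.character(universe)) universe else residue_keys(universe)
  uk <- unique(uk)
  if (length(uk) == 0) stop("empty evaluation universe")
  pk <- unique(pk[pk %in% uk])
  tk <- unique(tk[tk %in% uk])
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  tn <- length(uk) - tp - fp - fn
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
         recall = recall, accuracy = accuracy, f1 = f1)
}

#' Evaluate a prediction against the bound complex
#'
#' Maps the predicted residues of each unbound partner onto the bound
#' subunit by (chain, residue number), computes the true interface at
#' `cutoff`, and reports confusion statistics per partner plus a combined
#' row (macro average of the metrics by default; set `pooled = TRUE` to
#' compute the combined metrics from the summed counts instead). The
#' evaluation universe is every residue of the bound subunit.
#'
#' @param prediction An `interface_prediction`, or a list with `residues_a`
#'   and `residues_b` tibbles.
#' @param bound_a,bound_b Atom tibbles of the bound complex subunits.
#' @param cutoff True-interface cutoff in Angstrom (5 standard; 10 is the
#'   forgiving variant).
#' @param pooled Combine partners by pooling counts rather than averaging
#'   metrics.
#' @return Tibble with rows `A`, `B` and `combined`.
#' @export
evaluate_prediction <- function(prediction, bound_a, bound_b, cutoff = 5,
                                pooled = FALSE) {
  truth <- true_interface(bound_a, bound_b, cutoff)
  universe_a <- residue_keys(atom_residues(bound_a, seq_len(nrow(bound_a))))
  universe_b <- residue_keys(atom_residues(bound_b, seq_len(nrow(bound_b))))
  pa <- residue_keys(prediction$residues_a)
  pb <- residue_keys(prediction$residues_b)
  for (nm in list(list(pa, universe_a, "A"), list(pb, universe_b, "B"))) {
    unmapped <- setdiff(nm[[1]], nm[[2]])
    if (length(unmapped) > 0)
      warning("predicted residues not present in bound partner ", nm[[3]],
              " (excluded): ", paste(head(unmapped, 10), collapse = ", "))
  }
  sa <- confusion_stats(pa, truth$residues_a, universe_a)
  sb <- confusion_stats(pb, truth$residues_b, universe_b)
  if (pooled) {
    comb <- confusion_stats(
      c(paste0("a|", pa[pa %in% universe_a]),
        paste0("b|", pb[pb %in% universe_b])),
      c(paste0("a|", residue_keys(truth$residues_a)),
        paste0("b|", residue_keys(truth$residues_b))),
      c(paste0("a|", universe_a), paste0("b|", universe_b)))
  } else {
    comb <- tibble(tp = sa$tp + sb$tp, fp = sa$fp + sb$fp,
                   fn = sa$fn + sb$fn, tn = sa$tn + sb$tn,
                   precision = (sa$precision + sb$precision) / 2,
                   recall = (sa$recall + sb$recall) / 2,
                   accuracy = (sa$accuracy + sb$accuracy) / 2,
                   f1 = (sa$f1 + sb$f1) / 2)
  }
  dplyr::bind_rows(
    dplyr::mutate(sa, partner = "A", .before = 1),
    dplyr::mutate(sb, partner = "B", .before = 1),
    dplyr::mutate(comb, partner = "combined", .before = 1))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# rebuild one face's grid values from a (possibly permuted) per-atom
# property vector; geometry (bin membership) is fixed
rebuild_grid_values <- function(grid, values_by_atom) {
  vals <- matrix(0, nrow(grid$values), ncol(grid$values))
  occ_cells <- which(grid$occupancy)
  for (cell in occ_cells) {
    ids <- grid$bin_atoms[[cell]]
    vals[cell] <- mean(values_by_atom[ids])
  }
  vals
}

#' Shuffle (permutation) significance test of the top score
#'
#' Permutes the property values among the surface atoms of each protein
#' (geometry, faces and bin memberships unchanged), rebuilds the grids from
#' the shuffled values and re-scores all placements; repeating this
#' `n_shuffles` times yields a null distribution for the observed top score.
#' The empirical p-value is the fraction of replicates at least as extreme
#' as the observation (at most, for charge, whose best scores are the most
#' negative). An extreme observed score means the property is spatially
#' clustered at the predicted interface rather than randomly spread.
#'
#' @param structure_a,structure_b Atom tibbles.
#' @param property Property tag to test.
#' @param config A [grid_config()] (`n_shuffles`, `rng_seed` and the scoring
#'   settings are honoured).
#' @param prediction Optional precomputed [predict_interface()] result on
#'   the same inputs, to reuse its grids.
#' @param corrected Use the (count + 1)/(n + 1) small-sample correction
#'   instead of the plain empirical fraction.
#' @return A `shuffle_result`: `observed_score`, `null_scores`, `p_value`,
#'   `property`, `seed`, `n_shuffles`.
#' @export
shuffle_test <- function(structure_a, structure_b, property = "charge",
                         config = grid_config(), prediction = NULL,
                         corrected = FALSE) {
  config <- as_grid_config(config)
  if (config$n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (is.null(prediction))
    prediction <- predict_interface(structure_a, structure_b, property,
                                    config)
  pp <- prediction$per_property[[property]]
  if (is.null(pp)) stop("prediction does not cover property ", property)
  observed <- pp$top_hit$score
  sa <- prediction$internals$structure_a
  sb <- prediction$internals$structure_b
  idx_a <- prediction$internals$surface_a$surface_atoms
  idx_b <- prediction$internals$surface_b$surface_atoms
  pv_a <- property_values(sa, property, config$center_conservation)
  pv_b <- property_values(sb, property, config$center_conservation)
  minimize <- identical(property, "charge")
  angles <- rotation_angles(config)

  # static pieces per initialization: occupancy and the rotation cell maps
  # never change under a property shuffle
  inits <- lapply(1:2, function(i) {
    grids_a <- prediction$internals$builds$a[[i]]$grids
    grids_b <- prediction$internals$builds$b[[i]]$grids
    ga_occ <- lapply(grids_a, function(g) g[[property]]$occupancy * 1)
    b_occ <- vector("list", length(grids_b))
    b_maps <- vector("list", length(grids_b))
    for (f in seq_along(grids_b)) {
      g <- grids_b[[f]][[property]]
      rots <- lapply(angles, function(a) rotate_grid(g, a))
      b_occ[[f]] <- lapply(rots, function(r) r$occupancy * 1)
      b_maps[[f]] <- lapply(rots, `[[`, "source_cells")
    }
    list(grids_a = grids_a, grids_b = grids_b, ga_occ = ga_occ,
         b_occ = b_occ, b_maps = b_maps)
  })

  # each replicate recomputes the observed statistic's full selection:
  # score both initializations, pick by top_m-sum, take that top score
  replicate_top <- function(shuf_a, shuf_b) {
    per_init <- lapply(inits, function(ini) {
      a_vals <- lapply(ini$grids_a, function(g)
        rebuild_grid_values(g[[property]], shuf_a))
      b_vals <- vector("list", length(ini$grids_b))
      for (f in seq_along(ini$grids_b)) {
        base_vals <- rebuild_grid_values(ini$grids_b[[f]][[property]],
                                         shuf_b)
        b_vals[[f]] <- lapply(ini$b_maps[[f]], function(map) {
          out <- matrix(0, nrow(map), ncol(map))
          hit <- map > 0L
          out[hit] <- base_vals[map[hit]]
          out
        })
      }
      top_hits_cpp(a_vals, ini$ga_occ, b_vals, ini$b_occ, angles,
                   minimize = minimize,
                   min_overlap = config$min_overlap_bins,
                   top_k = config$top_m)
    })
    m <- min(config$top_m, nrow(per_init[[1]]), nrow(per_init[[2]]))
    sums <- vapply(per_init, function(h) sum(h$score[seq_len(m)]),
                   numeric(1))
    pick <- if (minimize) which.min(sums) else which.max(sums)
    h <- per_init[[pick]]
    if (nrow(h) == 0) NA_real_ else h$score[1]
  }

  null_scores <- with_seed(config$rng_seed, {
    vapply(seq_len(config$n_shuffles), function(r) {
      shuf_a <- pv_a
      shuf_a[idx_a] <- pv_a[sample(idx_a)]
      shuf_b <- pv_b
      shuf_b[idx_b] <- pv_b[sample(idx_b)]
      replicate_top(shuf_a, shuf_b)
    }, numeric(1))
  })
  extreme <- if (minimize) sum(null_scores <= observed, na.rm = TRUE)
             else sum(null_scores >= observed, na.rm = TRUE)
  p <- if (corrected) (extreme + 1) / (config$n_shuffles + 1)
       else extreme / config$n_shuffles
  structure(list(observed_score = observed, null_scores = null_scores,
                 p_value = p, property = property, seed = config$rng_seed,
                 n_shuffles = config$n_shuffles),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "<shuffle_result> %s: observed %.4g, p = %.4g (%d shuffles, seed %d)\n",
    x$property, x$observed_score, x$p_value, x$n_shuffles, x$seed))
  invisible(x)
}
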