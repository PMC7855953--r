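#' Tidy an interface prediction
#'
#' One row per scored property: the selected initialization, the
#' consistency verdict and the top placement.
#'
#' @param x An `interface_prediction`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.interface_prediction <- function(x, ...) {
  purrr::map_dfr(names(x$per_property), function(p) {
    pp <- x$per_property[[p]]
    tibble(property = p,
           initialization = pp$chosen_init,
           consistent = pp$consistent,
           face_a = pp$top_hit$face_a, face_b = pp$top_hit$face_b,
           rotation_deg = pp$top_hit$rotation_deg,
           lag_row = pp$top_hit$lag_row, lag_col = pp$top_hit$lag_col,
           score = pp$top_hit$score)
  })
}

#' One-row summary of an interface prediction
#'
#' @param x An `interface_prediction`.
#' @param ... Unused.
#' @return A tibble with the winning property, faces, score and predicted
#'   residue counts.
#' @export
glance.interface_prediction <- function(x, ...) {
  w <- x$winning
  tibble(property = w$property, consistent = w$consistent,
         face_a = w$hit$face_a, face_b = w$hit$face_b,
         rotation_deg = w$hit$rotation_deg, score = w$hit$score,
         n_residues_a = nrow(x$residues_a),
         n_residues_b = nrow(x$residues_b))
}

#' Tidy a shuffle test: the null score distribution
#'
#' @param x A `shuffle_result`.
#' @param ... Unused.
#' @return A tibble with `replicate` and `score`.
#' @export
tidy.shuffle_result <- function(x, ...) {
  tibble(replicate = seq_along(x$null_scores), score = x$null_scores)
}

#' One-row summary of a shuffle test
#'
#' @param x A `shuffle_result`.
#' @param ... Unused.
#' @return A tibble with the observed score, p-value and replicate count.
#' @export
glance.shuffle_result <- function(x, ...) {
  tibble(property = x$property, observed_score = x$observed_score,
         p_value = x$p_value, n_shuffles = x$n_shuffles, seed = x$seed)
}
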