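#' Plot a face grid as a property heat map
#'
#' @param object A `face_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.face_grid <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$value <- object$values[cbind(df$row, df$col)]
  df$occupied <- object$occupancy[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value,
                                   alpha = .data$occupied)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Face %d: %s", object$face_id,
                                  object$property),
                  x = sprintf("col (%g Å bins)", object$bin_size),
                  y = "row", fill = object$property) +
    ggplot2::theme_minimal()
}

#' Plot all faces of one structure for one property
#'
#' @param grids Grid list from [build_face_grids()] (`$grids`).
#' @param property Property tag.
#' @return A ggplot facetted by face.
#' @export
plot_face_grids <- function(grids, property) {
  df <- purrr::map_dfr(seq_along(grids), function(f) {
    g <- grids[[f]][[property]]
    d <- tidyr::expand_grid(row = seq_len(nrow(g$values)),
                            col = seq_len(ncol(g$values)))
    d$value <- g$values[cbind(d$row, d$col)]
    d$face <- f
    d
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::facet_wrap(~face, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = property) +
    ggplot2::theme_minimal()
}

#' Plot the null score distribution of a shuffle test
#'
#' Histogram of the permutation null scores with the observed top score
#' marked; an observation in the far tail indicates the property is
#' spatially clustered at the predicted interface.
#'
#' @param object A `shuffle_result`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shuffle_result <- function(object, bins = 40, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_score,
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("Shuffle null (%s): p = %.3g", object$property,
                      object$p_value),
      x = "top complementarity score", y = "replicates") +
    ggplot2::theme_minimal()
}
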