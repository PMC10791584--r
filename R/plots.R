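#' Plot methods
#'
#' ggplot2 views of the package's result objects: contribution maps and
#' mutagenesis matrices as per-position tracks/heatmaps, activity calls as a
#' logFC-significance panel, virtual templates as lobule maps, zonation fits
#' as smooth curves, and perturbation arrows on an embedding.
#'
#' @param object,x Object to plot.
#' @param ... Unused.
#' @name zonereg_plots
NULL

#' @rdname zonereg_plots
#' @export
autoplot.contribution_map <- function(object, ...) {
  df <- tibble::tibble(
    position = seq_len(nrow(object$map)),
    contribution = rowSums(object$map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$contribution)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      title = paste("Nucleotide contributions:", object$class),
      x = "position (bp)", y = "contribution"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname zonereg_plots
#' @export
autoplot.mutagenesis_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$delta) |>
      dplyr::mutate(position = dplyr::row_number()),
    cols = dplyr::all_of(DNA_BASES), names_to = "base", values_to = "delta"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      title = paste("Saturation mutagenesis:", object$class),
      x = "position (bp)", y = NULL, fill = "delta score"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname zonereg_plots
#' @export
autoplot.activity_calls <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      shuffled ~ "shuffled control",
      active ~ "active",
      TRUE ~ "inactive"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logfc, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change (cDNA / plasmid)", y = "enhancers") +
    ggplot2::theme_minimal()
}

#' @rdname zonereg_plots
#' @param colour_by Optional named vector (by `virtual_id`) colouring the
#'   template cells, e.g. a mapped feature.
#' @export
plot_template <- function(x, colour_by = NULL, ...) {
  df <- tibble::as_tibble(x)
  if (!is.null(colour_by)) {
    df$value <- unname(colour_by[df$virtual_id])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$value))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$cell_type))
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @rdname zonereg_plots
#' @param features Which features of a zonation fit to draw (default: top 6
#'   by statistic).
#' @export
autoplot.zonation_fit <- function(object, features = NULL, ...) {
  grid <- attr(object, "pseudotime_grid")
  if (is.null(features)) {
    features <- object$feature[order(-object$statistic)][seq_len(min(6L, nrow(object)))]
  }
  sel <- object[object$feature %in% features, ]
  df <- tidyr::unnest(
    tibble::tibble(
      feature = rep(sel$feature, each = length(grid)),
      pseudotime = rep(grid, times = nrow(sel)),
      fitted = unlist(sel$curve)
    ),
    cols = c()
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime, y = .data$fitted,
                                   colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime (rank scale)", y = "fitted value") +
    ggplot2::theme_minimal()
}

#' @rdname zonereg_plots
#' @param arrows Output of [embedding_shift()].
#' @param min_magnitude Hide arrows shorter than this.
#' @export
plot_embedding_shift <- function(arrows, min_magnitude = 0, ...) {
  df <- arrows[arrows$magnitude >= min_magnitude, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$dx, yend = .data$y + .data$dy,
                   colour = .data$magnitude),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm"))
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
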