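
#' Plot a read-length distribution
#'
#' One line per tissue over lengths 1-35 nt, reads per million 1-35-nt
#' reads on the y axis. Somatic small RNA libraries peak at 22 nt
#' (miRNAs); gonadal libraries at 26-28 nt (putative piRNAs).
#'
#' @param x An `srna_size_distribution` tibble from [size_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$length, y = .data$rpm,
                               colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "read length (nt)",
                  y = "reads per million 1-35-nt reads",
                  colour = "tissue") +
    ggplot2::theme_minimal()
}

#' @rdname plot_size_distribution
#' @param object An `srna_size_distribution` tibble.
#' @export
autoplot.srna_size_distribution <- function(object, ...) {
  plot_size_distribution(object, ...)
}

#' Plot annotation-category proportions
#'
#' Stacked per-tissue bars of the five cascade categories as fractions of
#' the 18-25-nt population.
#'
#' @param x An `srna_category_proportions` tibble (unstratified) from
#'   [category_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_category_proportions <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$tissue, y = .data$fraction,
                               fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of 18-25-nt reads",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' @rdname plot_category_proportions
#' @param object An `srna_category_proportions` tibble.
#' @export
autoplot.srna_category_proportions <- function(object, ...) {
  plot_category_proportions(object, ...)
}

#' Heatmap of miRNA expression across tissues
#'
#' log10(RPM + 1) tile map of the `top` most-expressed families.
#'
#' @param x An `srna_expression` tibble from [expression_matrix()].
#' @param top Number of families to show (by maximal RPM).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(x, top = 30L, ...) {
  tb <- as_tibble(x)
  keep <- tb |>
    group_by(.data$mirna_id) |>
    summarise(max_rpm = max(.data$rpm), .groups = "drop") |>
    arrange(desc(.data$max_rpm)) |>
    slice_head(n = top) |>
    pull("mirna_id")
  ggplot2::ggplot(filter(tb, .data$mirna_id %in% keep),
                  ggplot2::aes(x = .data$tissue, y = .data$mirna_id,
                               fill = log10(.data$rpm + 1))) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10(RPM+1)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_expression_heatmap
#' @param object An `srna_expression` tibble.
#' @export
autoplot.srna_expression <- function(object, top = 30L, ...) {
  plot_expression_heatmap(object, top = top, ...)
}
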