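# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @export
tidy.ternary_points <- function(x, ...) x$points

#' @export
glance.ternary_points <- function(x, ...) {
  tibble(n_genes = nrow(x$points), n_dropped = length(x$dropped),
         spread_mean = x$spread_mean, spread_median = x$spread_median)
}

#' @export
tidy.supported_tree <- function(x, ...) {
  if (is.null(x$splits)) return(tibble(split = character(), support = numeric()))
  x$splits
}

#' @export
glance.supported_tree <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label),
         n_splits = if (is.null(x$splits)) NA_integer_ else nrow(x$splits),
         min_support = if (is.null(x$splits) || !nrow(x$splits)) NA_real_ else
           min(x$splits$support))
}

#' @export
tidy.cleanup_report <- function(x, ...) x$mapped

#' @export
glance.cleanup_report <- function(x, ...) x$summary

#' @export
tidy.ortholog_catalog <- function(x, ...) x$clusters

#' @export
glance.ortholog_catalog <- function(x, ...) {
  tibble(n_clusters = dplyr::n_distinct(x$clusters$cluster),
         n_genes = nrow(x$clusters),
         n_retained = sum(x$clusters$retained))
}

#' Ternary (simplex) plot of relative dS triplets
#'
#' Projects each normalised triplet into the 2-simplex and colours points by
#' the maximum raw dS category (yellow < 0.1, orange >= 0.1, red >= 1).
#'
#' @param object a `ternary_points` object from [ternary_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ternary_points <- function(object, ...) {
  p <- object$points
  df <- tibble(X = p$y + p$z / 2, Y = p$z * sqrt(3) / 2,
               category = factor(p$category, levels = c("yellow", "orange", "red")))
  tri <- tibble(X = c(0, 1, 0.5, 0), Y = c(0, 0, sqrt(3) / 2, 0))
  lab <- tibble(X = c(0, 1, 0.5), Y = c(-0.04, -0.04, sqrt(3) / 2 + 0.04),
                txt = object$pair_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$X, .data$Y)) +
    ggplot2::geom_path(data = tri, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 1.2, alpha = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$txt), size = 3) +
    ggplot2::scale_colour_manual(values = c(yellow = "#E6C300", orange = "#E07B00",
                                            red = "#C0392B"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "max dS")
}

#' Plot a sliding-window divergence track
#'
#' @param track tibble from [sliding_window_divergence()].
#' @param highlight optional 2-vector (start, end) shading a region of
#'   interest, e.g. a known conversion tract.
#' @return a ggplot object.
#' @export
plot_window_track <- function(track, highlight = NULL) {
  g <- ggplot2::ggplot(track, ggplot2::aes(.data$midpoint, .data$divergence))
  if (!is.null(highlight)) {
    g <- g + ggplot2::annotate("rect", xmin = highlight[1], xmax = highlight[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  g + ggplot2::geom_line() +
    ggplot2::labs(x = "alignment position (nt)",
                  y = "JC-corrected divergence") +
    ggplot2::theme_minimal()
}
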