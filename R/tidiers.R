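#' @method tidy stepwise_de
#' @export
tidy.stepwise_de <- function(x, ...) x$tests

#' @method glance stepwise_de
#' @export
glance.stepwise_de <- function(x, ...) {
  tibble(n_step2_pair1 = length(x$sets$step2_pair1),
         n_step2_pair2 = length(x$sets$step2_pair2),
         n_step3_pair1 = length(x$sets$step3_pair1),
         n_step3_pair2 = length(x$sets$step3_pair2),
         n_final = nrow(x$genes),
         n_up = sum(x$genes$direction == "Up"),
         n_down = sum(x$genes$direction == "Down"),
         dispersion = x$dispersion,
         alpha = x$alpha)
}

#' Plot the stepwise filtering funnel
#'
#' Bar chart of the gene-set sizes produced by each step of the
#' intersection procedure, per NIL pair where applicable.
#'
#' @param object A `stepwise_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stepwise_de
#' @export
autoplot.stepwise_de <- function(object, ...) {
  sizes <- tibble(
    step = factor(c("II pair 1", "II pair 2", "III pair 1", "III pair 2",
                    "final"),
                  levels = c("II pair 1", "II pair 2", "III pair 1",
                             "III pair 2", "final")),
    n = c(length(object$sets$step2_pair1), length(object$sets$step2_pair2),
          length(object$sets$step3_pair1), length(object$sets$step3_pair2),
          nrow(object$genes)))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Stepwise introgression-specific DE") +
    ggplot2::theme_minimal()
}

#' Plot a co-expression network
#'
#' Fruchterman-Reingold layout with nodes coloured by module and edges by
#' correlation sign.
#'
#' @param object A `coexpr_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coexpr_network
#' @export
autoplot.coexpr_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, gene_a = "gene_id",
                                   xa = "x", ya = "y"), by = "gene_a") |>
    dplyr::left_join(dplyr::select(nodes, gene_b = "gene_id",
                                   xb = "x", yb = "y"), by = "gene_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$r > 0),
      alpha = 0.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("TRUE" = "firebrick",
                                            "FALSE" = "steelblue")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2, colour = "grey20") +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("|PCC| > %s co-expression network",
                                  format(object$threshold)))
}

#' Plot a positional motif profile with its background model
#'
#' Bin occurrence rates along the TSS-relative axis, the fitted background
#' line over [-1000, -300) and its 95% upper prediction bound, with the
#' search region shaded.
#'
#' @param object A `motif_profile`.
#' @param model Optional `plm_model`; fitted from the profile when `NULL`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_profile
#' @export
autoplot.motif_profile <- function(object, model = NULL, ...) {
  model <- model %||% fit_background(object)
  dat <- object[!is.na(object$rate), ]
  dat$bound <- upper_bound(model, dat$midpoint)
  dat$fit <- model$a * dat$midpoint + model$b
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$midpoint)) +
    ggplot2::annotate("rect", xmin = -300, xmax = max(dat$bin_hi),
                      ymin = -Inf, ymax = Inf, alpha = 0.08,
                      fill = "goldenrod") +
    ggplot2::geom_col(ggplot2::aes(y = .data$rate), width = 8,
                      fill = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bound), colour = "firebrick",
                       linetype = 2) +
    ggplot2::labs(x = "position relative to TSS (bases)",
                  y = "occurrences per promoter") +
    ggplot2::theme_minimal()
}

#' Clustered expression heatmap matrix
#'
#' Orders genes by UPGMA leaves and returns a long tibble ready for a tile
#' plot, plus a convenience ggplot.
#'
#' @param expr Tibble `gene_id` + numeric columns.
#' @return A ggplot heatmap of the row-ordered matrix.
#' @export
plot_expression_heatmap <- function(expr) {
  ord <- cluster_order(hcluster(expr))
  long <- tidyr::pivot_longer(expr, -"gene_id", names_to = "unit",
                              values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$unit, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick",
                                  midpoint = mean(long$value)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
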