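#' Diagnostic plot of the effect-size decomposition
#'
#' Per trait: the composition-driven effect (filled bar), the intraspecific
#' contribution stacked on top of it (open bar) and the realized local-CWM
#' effect (point). Bars of the same sign amplify each other; opposite signs
#' mean intraspecific change countered the compositional shift.
#'
#' @param decomposition Output of [decompose_traits()] (or the
#'   `decomposition` element of a [run_pipeline()] result).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  d <- tibble::as_tibble(decomposition)
  d$trait <- factor(d$trait, levels = trait_names())
  bars <- dplyr::bind_rows(
    tibble::tibble(trait = d$trait, component = "composition (E_fixed)",
                   ymin = pmin(0, d$e_fixed), ymax = pmax(0, d$e_fixed)),
    tibble::tibble(trait = d$trait, component = "intraspecific (E_intra)",
                   ymin = pmin(d$e_fixed, d$e_local),
                   ymax = pmax(d$e_fixed, d$e_local)))
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$trait)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = as.numeric(.data$trait) - 0.35,
                   xmax = as.numeric(.data$trait) + 0.35,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$component),
      colour = "grey20", linewidth = 0.2, alpha = 0.8) +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(y = .data$e_local), size = 2) +
    ggplot2::scale_fill_manual(
      values = c("composition (E_fixed)" = "grey35",
                 "intraspecific (E_intra)" = "white")) +
    ggplot2::labs(x = NULL, y = "standardized effect (inner vs outer)",
                  fill = NULL,
                  title = "Origins of assemblage trait change") +
    ggplot2::theme_minimal()
}

#' Trait-space ordination plot
#'
#' Colonies on the first two principal components, coloured by location
#' class, with trait loading vectors overlaid.
#'
#' @param pca A `trait_pca` from [run_pca()].
#' @param loading_scale Multiplier applied to loading vectors for display.
#' @return A ggplot object.
#' @export
plot_trait_space <- function(pca, loading_scale = NULL) {
  sc <- cbind(pca$colonies,
              tibble::as_tibble(pca$scores[, 1:2, drop = FALSE]))
  ld <- tibble::as_tibble(as.data.frame(pca$loadings[, 1:2, drop = FALSE]),
                          rownames = "trait")
  if (is.null(loading_scale)) {
    loading_scale <- 0.8 * max(abs(pca$scores[, 1:2])) /
      max(abs(pca$loadings[, 1:2]))
  }
  pct <- round(100 * pca$explained_variance[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$location_class),
                        alpha = 0.7) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * loading_scale,
                   yend = .data$PC2 * loading_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30") +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * loading_scale * 1.08,
                   y = .data$PC2 * loading_scale * 1.08,
                   label = .data$trait),
      size = 3, colour = "grey20") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]),
                  colour = "location") +
    ggplot2::theme_minimal()
}
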