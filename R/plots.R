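# ggplot2 displays for the main result types.

#' Plot an interaction matrix
#'
#' Tile view of the per-site bipartite network: pollinator species against
#' plant taxa, shaded by the number of individuals carrying the taxon.
#'
#' @param object An `interaction_matrix` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon,
                                   y = .data$pollinator_species,
                                   fill = .data$n_individuals)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "individuals") +
    ggplot2::labs(
      x = "plant taxon", y = "pollinator species",
      title = if (!is.null(attr(object, "site"))) {
        paste("Pollen transport network,", attr(object, "site"))
      } else "Pollen transport network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a contrast battery
#'
#' Unadjusted permutation p-values per contrast on a log scale against the
#' Dunn-Sidak cutoff for the family.
#'
#' @param object A `comparison_suite` from [run_contrast_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_suite
#' @export
autoplot.comparison_suite <- function(object, ...) {
  cutoff <- attr(object, "sidak_cutoff")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$contrast,
                                                      .data$p),
                                   y = .data$p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "permutation p-value",
                  title = sprintf("Contrast battery (Sidak cutoff %.5f)",
                                  cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot species-level specialisation
#'
#' Dot plot of d' by pollinator species, optionally faceted by site when a
#' combined tibble from several sites is supplied.
#'
#' @param dprime Tibble from [species_dprime()] (rows from several sites
#'   may be bound together).
#' @return A ggplot object.
#' @export
plot_dprime <- function(dprime) {
  p <- ggplot2::ggplot(dprime,
                       ggplot2::aes(x = .data$dprime,
                                    y = stats::reorder(.data$species,
                                                       .data$dprime))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "d' (0 = no exclusivity, 1 = complete exclusivity)",
                  y = NULL, title = "Species-level specialisation") +
    ggplot2::theme_minimal()
  if ("site" %in% names(dprime)) {
    p <- p + ggplot2::facet_wrap(~site)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
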