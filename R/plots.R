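#' Plot enzyme-dense regions along scaffolds
#'
#' Draws each scaffold as a horizontal bar with enriched regions overlaid,
#' optionally marking labelled genes as ticks — the usual genome-overview
#' figure for cluster analyses.
#'
#' @param regions Region tibble from [merge_regions()] (optionally after
#'   [subtelomeric_classify()], in which case sub-telomeric regions are
#'   coloured distinctly).
#' @param genome A [genome_model()] supplying scaffold lengths and gene
#'   positions.
#' @param label Label whose genes are shown as ticks.
#' @return A ggplot object.
#' @export
plot_genome_regions <- function(regions, genome, label = "cazyme") {
  stopifnot(inherits(genome, "genome_model"))
  col <- label_column(label)
  scaff <- genome$scaffolds |>
    dplyr::mutate(scaffold_id = factor(.data$scaffold_id,
                                       levels = rev(.data$scaffold_id)))
  genes <- genome$genes[genome$genes[[col]], ]
  p <- ggplot2::ggplot(scaff) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$length, y = .data$scaffold_id,
                   yend = .data$scaffold_id),
      linewidth = 2, colour = "grey80"
    ) +
    ggplot2::geom_point(
      data = genes,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = .data$scaffold_id),
      shape = "|", size = 2, colour = "grey40"
    )
  if (nrow(regions) > 0) {
    regions <- dplyr::mutate(
      regions,
      fill_group = if ("is_subtelomeric" %in% names(regions)) {
        dplyr::if_else(.data$is_subtelomeric, "sub-telomeric", "interior")
      } else "region"
    )
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = as.integer(factor(.data$scaffold_id,
                                            levels = levels(scaff$scaffold_id))) - 0.3,
                   ymax = as.integer(factor(.data$scaffold_id,
                                            levels = levels(scaff$scaffold_id))) + 0.3,
                   fill = .data$fill_group),
      alpha = 0.6
    ) +
      ggplot2::labs(fill = NULL)
  }
  p + ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of percent-of-maximum category counts
#'
#' @param pct Tibble from [percent_of_max()] (first column category, rest
#'   species percentages).
#' @return A ggplot object.
#' @export
plot_percent_of_max <- function(pct) {
  cat_col <- names(pct)[1]
  long <- tidyr::pivot_longer(pct, -1, names_to = "species",
                              values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[cat_col]],
                                     y = .data$percent,
                                     fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "% of per-category maximum", x = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for a cluster-enrichment fit
#'
#' P-value profile of all candidate clusters with the significance
#' threshold marked.
#'
#' @param object A `cluster_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_enrichment
#' @export
autoplot.cluster_enrichment <- function(object, ...) {
  cand <- object$candidates
  if (nrow(cand) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no candidate clusters"))
  }
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$first_ordinal,
                                     y = -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~scaffold_id, scales = "free_x") +
    ggplot2::labs(x = "first gene ordinal", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
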