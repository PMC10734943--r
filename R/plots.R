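#' Plot per-genome class counts
#'
#' Bar chart of the four-class composition of one or more genome summary
#' rows (one panel group per genome when several rows are given).
#'
#' @param summaries Genome summary tibble ([summarize_genome()] rows).
#' @return A ggplot object.
#' @export
plot_class_counts <- function(summaries) {
  long <- tidyr::pivot_longer(summaries, dplyr::all_of(sina_classes()),
                              names_to = "sina_class", values_to = "n")
  long$sina_class <- factor(long$sina_class, levels = sina_classes())
  long$genome <- trimws(paste(long$species_tag, long$variety_tag))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$sina_class, y = .data$n,
                               fill = .data$sina_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~genome) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "SINA class composition") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the chromosomal distribution of a gene family
#'
#' @param distribution Output of [gene_distribution()].
#' @return A ggplot object.
#' @export
plot_chrom_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$chromosome, y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "chromosome", y = "family genes",
                  title = "Chromosomal distribution") +
    ggplot2::theme_minimal()
}

#' Plot family-gene positions and tandem clusters along chromosomes
#'
#' @param loci Locus tibble from [read_loci()].
#' @param clusters Optional output of [detect_clusters()]; cluster spans
#'   are drawn as shaded rectangles.
#' @return A ggplot object.
#' @export
plot_gene_map <- function(loci, clusters = NULL) {
  fam <- dplyr::filter(loci, .data$is_family_member)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = fam,
      ggplot2::aes(x = .data$start_bp / 1e6, y = .data$chromosome),
      shape = 124, size = 4, colour = "firebrick"
    ) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Family gene anchorage") +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && nrow(clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = clusters,
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   ymin = as.numeric(factor(.data$chromosome)) - 0.3,
                   ymax = as.numeric(factor(.data$chromosome)) + 0.3),
      alpha = 0.2, fill = "steelblue"
    )
  }
  p
}

#' Boxplot of normalized family sizes by species group
#'
#' @param data Data frame with `value` and `group` columns (or override
#'   with the `value`/`group` arguments as column names).
#' @param value,group Column names (strings) holding the per-genome
#'   normalized count and the group label.
#' @return A ggplot object.
#' @export
plot_group_counts <- function(data, value = "value", group = "group") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[group]], y = .data[[value]],
                               fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::labs(x = NULL, y = "SINA genes per haploid genome") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sina_ancestral <- function(object, ...) {
  nodes <- object$node
  internal <- nodes[nodes$type == "internal", ]
  ggplot2::ggplot(internal,
                  ggplot2::aes(x = .data$node)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper),
                            colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$estimate),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "internal node", y = "reconstructed family size",
                  title = sprintf("Parsimony reconstruction (cost %s)",
                                  format(object$cost))) +
    ggplot2::theme_minimal()
}
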