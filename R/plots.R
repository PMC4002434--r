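#' Ideogram-style DMR distribution plot
#'
#' One horizontal track per chromosome with DMR midpoints drawn as vertical
#' ticks, hypermethylation above and hypomethylation below the axis — the
#' usual genome-wide view of direction asymmetry between regions.
#'
#' @param object A `dmr_calls` object (or DMR tibble with chrom/start/end/
#'   direction).
#' @param layout Optional [genome_layout()] to fix the x extent.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmr_calls
#' @export
autoplot.dmr_calls <- function(object, layout = NULL, ...) {
  d <- if (inherits(object, "dmr_calls")) object$dmrs else object
  d <- dplyr::mutate(d,
    mid = (.data$start + .data$end) / 2,
    y = ifelse(.data$direction == "hyper", 1, -1)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, xend = .data$mid,
                                       y = 0, yend = .data$y,
                                       colour = .data$direction)) +
    ggplot2::geom_segment(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::scale_colour_manual(
      values = c(hyper = "#c0392b", hypo = "#27ae60")
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "DMR distribution along chromosomes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(layout)) {
    p <- p + ggplot2::xlim(0, max(layout$length))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked element-distribution bars for DMR sets
#'
#' Single-label (precedence-collapsed) element composition of one or more
#' DMR sets, as proportions.
#'
#' @param dmr_sets Named list of DMR tibbles (or `dmr_calls`).
#' @param elements An `element_map`.
#' @param cgi_context Optional `cgi_context`.
#' @return A ggplot object.
#' @export
plot_element_distribution <- function(dmr_sets, elements,
                                      cgi_context = NULL) {
  tab <- purrr::map_dfr(dmr_sets, .id = "set", function(d) {
    if (inherits(d, "dmr_calls")) d <- d$dmrs
    ann <- assign_primary_element(
      annotate_intervals(d[, c("chrom", "start", "end")], elements,
                         cgi_context)
    )
    dplyr::count(ann, .data$element_primary)
  })
  tab$element_primary <- factor(
    tab$element_primary,
    levels = c("promoter", "utr5", "exon", "intron", "utr3", "intergenic")
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$set, y = .data$n,
                                    fill = .data$element_primary)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of DMRs", fill = "element") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' @param profile Tibble from [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin,
                                        y = .data$mean_coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = range(profile$bin[profile$zone == "body"]) + c(-0.5, 0.5),
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::labs(x = "bin (5' to 3')",
                  y = "mean coverage (per 1e6 fragments)") +
    ggplot2::theme_minimal()
}

#' Separation ARI matrix plot
#'
#' Feature source x evaluation cohort heat map of adjusted Rand indices,
#' faceted by modality — the at-a-glance version of the cross-cohort
#' transferability contrast.
#'
#' @param separation Separation tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_separation_matrix <- function(separation) {
  ggplot2::ggplot(separation,
                  ggplot2::aes(x = .data$cohort, y = .data$feature_source,
                               fill = .data$ari)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$ari, 2)),
                       size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$modality)) +
    ggplot2::scale_fill_gradient2(limits = c(-0.5, 1), low = "#2c7bb6",
                                  mid = "white", high = "#d7191c",
                                  midpoint = 0.5) +
    ggplot2::labs(x = "evaluation cohort", y = "feature source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' PCA overview plot
#'
#' @param pca Tibble from [pca_overview()].
#' @param samples Optional sample sheet to colour by group / shape by
#'   region.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, samples = NULL) {
  if (!is.null(samples)) {
    pca <- dplyr::left_join(pca, samples, by = "sample_id")
    aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2,
                        colour = .data$group,
                        shape = if ("region" %in% names(pca))
                          .data$region else NULL)
  } else {
    aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(pca, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(shape = "region") +
    ggplot2::theme_minimal()
}
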