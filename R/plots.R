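#' Plot radial QISP profiles
#'
#' Line plot of one or more genes' profiles along the ventricular-to-pial
#' axis (sROI 1 deep, sROI 20 superficial).
#'
#' @param qisps A `qisp` tibble.
#' @param variant Which variant(s) to draw; default all three.
#' @return A ggplot object.
#' @export
plot_qisp <- function(qisps, variant = c("raw", "corrected", "smoothed")) {
  variant <- match.arg(variant, several.ok = TRUE)
  long <- tidyr::pivot_longer(qisps, cols = dplyr::all_of(variant),
                              names_to = "variant", values_to = "density")
  long$variant <- factor(long$variant,
                         levels = c("raw", "corrected", "smoothed"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sroi, y = .data$density,
                                     colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id)) +
    ggplot2::labs(x = "sROI (1 = ventricular, 20 = pial)",
                  y = "optical density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qisp <- function(object, ...) plot_qisp(object, ...)

#' Plot cluster centroids by laminar zone
#'
#' One standardized centroid profile per cluster, coloured by the zone its
#' peak falls in.
#'
#' @param object A `qisp_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qisp_clusters <- function(object, ...) {
  cent <- tibble::as_tibble(object$centroids, rownames = "cluster")
  long <- tidyr::pivot_longer(cent, cols = -"cluster", names_to = "sroi",
                              values_to = "density")
  long$sroi <- as.integer(sub("sroi_", "", long$sroi))
  long$zone <- object$zone_of_cluster[long$cluster]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sroi, y = .data$density,
                                     group = .data$cluster,
                                     colour = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sROI (1 = ventricular, 20 = pial)",
                  y = "standardized density",
                  colour = "zone", title = "Cluster centroid profiles") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized profiles in dendrogram order
#'
#' @param clusters A `qisp_clusters` object.
#' @return A ggplot object (tile heatmap, genes ordered as in the tree).
#' @export
plot_qisp_heatmap <- function(clusters) {
  stopifnot(inherits(clusters, "qisp_clusters"))
  ord <- clusters$tree$labels[clusters$tree$order]
  m <- clusters$normalized[ord, , drop = FALSE]
  df <- tibble::tibble(
    gene_id = factor(rep(rownames(m), 20), levels = rev(ord)),
    sroi = rep(seq_len(20), each = nrow(m)),
    z = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sroi, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black",
                                  high = "red", name = "z") +
    ggplot2::labs(x = "sROI (1 = ventricular, 20 = pial)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
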