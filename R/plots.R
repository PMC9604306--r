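#' Plot a permutation null distribution
#'
#' Violin of the replicate richness and Shannon values, one panel per
#' metric, optionally with the observed garden values marked as triangles —
#' the standard distribution-vs-observed figure for a permutation test.
#'
#' @param object A `perm_null`.
#' @param garden Optional named numeric vector `c(richness = , shannon = )`
#'   of observed garden values to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_null <- function(object, garden = NULL, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              cols = c("richness", "shannon"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("richness", "shannon"),
                        labels = c("Species richness", "Shannon's index"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = "null replicates", y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Permutation null (R = %d rectangles of %.3g x %.3g deg)",
                                  object$R, object$dims$width_lon,
                                  object$dims$height_lat)) +
    ggplot2::theme_minimal()
  if (!is.null(garden)) {
    obs <- tibble(
      metric = factor(c("Species richness", "Shannon's index"),
                      levels = c("Species richness", "Shannon's index")),
      value = c(garden[["richness"]], garden[["shannon"]])
    )
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(x = "null replicates", y = .data$value),
                                 shape = 17, size = 3, colour = "#c0392b")
  }
  p
}

#' Plot a hotspot assessment
#'
#' The assessment's null distributions with the garden's observed richness
#' and diversity overlaid.
#'
#' @param object A `hotspot_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hotspot_assessment <- function(object, ...) {
  autoplot(object$null,
           garden = c(richness = object$garden_richness,
                      shannon = object$garden_shannon)) +
    ggplot2::labs(
      title = sprintf("'%s' vs %d same-size city rectangles", object$garden_name,
                      object$R),
      subtitle = sprintf("richness percentile %.1f, diversity percentile %.1f (hotspot > %g)",
                         object$richness_percentile,
                         object$diversity_percentile, object$threshold))
}
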