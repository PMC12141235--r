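#' Ranked risk-index bar chart
#'
#' Bars of the aggregate risk index by category or province, colored by
#' risk class, with the acceptable threshold drawn as a dashed line.
#'
#' @param aggregate Output of [aggregate_risk()].
#' @param threshold A [risk_threshold()] (drawn as the reference line).
#' @return A ggplot object.
#' @export
plot_risk_ranking <- function(aggregate, threshold = risk_threshold()) {
  d <- tibble::as_tibble(aggregate)
  key <- intersect(c("vegetable", "province"), names(d))[1]
  d$key <- stats::reorder(d[[key]], d$ir)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ir, y = .data$key,
                                  fill = .data$risk_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold$ir0, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(high = "#c0392b",
                                          low = "#2980b9")) +
    ggplot2::labs(x = "risk index IR = P × S", y = NULL,
                  fill = "risk class") +
    ggplot2::theme_minimal()
}

#' Centroid trajectory plot
#'
#' The yearly risk-weighted centre of gravity as a labelled path in
#' coordinate space, one panel per scope when several are present.
#'
#' @param centroids Centroid tibble from [risk_centroid()] /
#'   [centroid_track()].
#' @return A ggplot object.
#' @export
plot_centroid_track <- function(centroids) {
  d <- tibble::as_tibble(centroids)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$longitude,
                                       y = .data$latitude)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$year), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "longitude (°E)", y = "latitude (°N)") +
    ggplot2::theme_minimal()
  if ("scope" %in% names(d) && length(unique(d$scope)) > 1) {
    p <- p + ggplot2::facet_wrap(~scope, scales = "free")
  }
  p
}

#' Plot a pipeline run
#'
#' @param object A `vegrisk_run`.
#' @param type `"vegetable"` or `"province"` ranking, or `"centroid"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vegrisk_run
#' @export
autoplot.vegrisk_run <- function(object,
                                 type = c("vegetable", "province",
                                          "centroid"), ...) {
  type <- match.arg(type)
  switch(type,
    vegetable = plot_risk_ranking(object$vegetable_risk, object$threshold),
    province = plot_risk_ranking(object$province_risk, object$threshold),
    centroid = {
      if (nrow(object$centroids) == 0) {
        abort("this run has no centroid track (single year or no violations)")
      }
      plot_centroid_track(object$centroids)
    }
  )
}
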