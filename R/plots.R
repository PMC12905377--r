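#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_ribbon
#'   geom_point geom_vline scale_fill_viridis_c labs theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Response heatmap of a trace cohort
#'
#' Cells are drawn in descending order of their ligand-window response (see
#' [heatmap_order()]); dashed lines mark ligand onset and washout.
#'
#' @param object A [trace_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.trace_matrix <- function(object, ...) {
  ord <- heatmap_order(object)
  long <- trace_tibble(object[ord, ])
  long$row <- match(long$cell_id, unique(long$cell_id))
  onset <- object$grid$lh_start / object$grid$rate
  offset <- object$grid$lh_end / object$grid$rate
  ggplot(long, aes(x = .data$time_s, y = .data$row, fill = .data$df_f0)) +
    geom_raster() +
    geom_vline(xintercept = c(onset, offset), linetype = "dashed",
               colour = "white", linewidth = 0.3) +
    scale_fill_viridis_c(name = expression(Delta * F / F[0])) +
    labs(x = "Time (s)", y = "Cell (sorted by LH response)") +
    theme_minimal()
}

#' Group mean +/- SD traces
#'
#' @param group_traces Output of [group_mean_traces()].
#' @param grid Optional [time_grid()] to mark the ligand window.
#' @return A ggplot.
#' @export
plot_group_traces <- function(group_traces, grid = NULL) {
  p <- ggplot(group_traces, aes(x = .data$time_s, colour = .data$group,
                                fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                alpha = 0.2, colour = NA) +
    geom_line(aes(y = .data$mean)) +
    labs(x = "Time (s)", y = expression(Delta * F / F[0])) +
    theme_minimal()
  if (!is.null(grid)) {
    p <- p + geom_vline(xintercept = c(grid$lh_start, grid$lh_end) / grid$rate,
                        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Scatter plot of a 2D embedding
#'
#' @param object A `trace_embedding` (from [embed_pca()], [embed_tsne()],
#'   [embed_umap()] or [project_feature_space()]).
#' @param colour_by Column to colour points by (default `group` when
#'   present).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.trace_embedding <- function(object, colour_by = NULL, ...) {
  colour_by <- colour_by %||% if ("group" %in% names(object)) "group"
  p <- ggplot(object, aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(colour_by)) p + geom_point(size = 0.8) else
    p + geom_point(aes(colour = .data[[colour_by]]), size = 0.8)
  p + labs(title = attr(object, "method"), x = "dim 1", y = "dim 2") +
    theme_minimal()
}

#' Saliency heatmap
#'
#' @param object A `saliency_map` from [grad_cam_saliency()].
#' @param grid Optional [time_grid()] to mark the ligand window.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.saliency_map <- function(object, grid = NULL, ...) {
  long <- saliency_tibble(object)
  long$row <- match(long$cell_id, unique(long$cell_id))
  p <- ggplot(long, aes(x = .data$frame, y = .data$row, fill = .data$relevance)) +
    geom_raster() +
    scale_fill_viridis_c(name = "relevance", option = "inferno") +
    labs(x = "Frame", y = "Cell") +
    theme_minimal()
  if (!is.null(grid)) {
    p <- p + geom_vline(xintercept = c(grid$lh_start, grid$lh_end),
                        linetype = "dashed", colour = "white", linewidth = 0.3)
  }
  p
}
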