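# ggplot2 views of the result types: the annotated measurement overlay
# (fitted curves, key points, the 1/2/3 PD circles), a scene preview,
# and the thickness-by-angle-group trend.

.circle_df <- function(center, radius, label) {
  th <- seq(0, 2 * pi, length.out = 181L)
  data.frame(x = center[1] + radius * cos(th),
             y = center[2] + radius * sin(th),
             ring = label)
}

.raster_layer <- function(img) {
  # EBImage arrays are [x, y, ch]; as.raster wants [row = y, col = x]
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  r <- grDevices::as.raster(aperm(a, c(2, 1, 3)))
  nx <- dim(a)[1]
  ny <- dim(a)[2]
  list(
    ggplot2::annotation_raster(r, xmin = 0, xmax = nx, ymin = ny, ymax = 0),
    ggplot2::scale_y_reverse(limits = c(ny, 0), expand = c(0, 0)),
    ggplot2::scale_x_continuous(limits = c(0, nx), expand = c(0, 0)),
    ggplot2::coord_fixed(),
    ggplot2::theme_void()
  )
}

#' Annotated measurement overlay
#'
#' Reproduces the standard annotation of an arcade-angle measurement:
#' the fitted Bezier curves in red, the 1, 2 and 3 PD circles, and the
#' labelled points O, B, C, D, E, F, G.
#'
#' @param object A [measure_vaa()] result with artifacts kept.
#' @param image The measured image (path, `Image` or scene); required
#'   because the measurement itself stores only geometry.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot vaa_measurement
autoplot.vaa_measurement <- function(object, image, ...) {
  if (inherits(image, "fundus_scene")) image <- image$image
  img <- .as_rgb_array(image)
  p <- ggplot2::ggplot() + .raster_layer(img)
  if (is.null(object$O) || is.na(object$pd_px)) return(p)
  O <- object$O
  pd <- object$pd_px
  rings <- do.call(rbind, list(.circle_df(O, pd, "1PD"),
                               .circle_df(O, 2 * pd, "2PD"),
                               .circle_df(O, 3 * pd, "3PD")))
  p <- p + ggplot2::geom_path(
    data = rings,
    ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring),
    colour = "white", linewidth = 0.3, linetype = "dashed"
  )
  if (!is.null(object$artifacts$arcs)) {
    tt <- seq(0, 1, length.out = 200L)
    for (arc in object$artifacts$arcs) {
      b <- bezier_point(arc$p0, arc$p1, arc$p2, tt)
      p <- p + ggplot2::geom_path(
        data = data.frame(x = b[, 1], y = b[, 2]),
        ggplot2::aes(x = .data$x, y = .data$y),
        colour = "red", linewidth = 0.8
      )
    }
  }
  pts <- list(O = object$O, B = object$B, C = object$C, D = object$D,
              E = object$E, F = object$F, G = object$G)
  pts <- pts[!vapply(pts, is.null, logical(1))]
  if (length(pts) > 0) {
    pd_df <- data.frame(
      x = vapply(pts, `[`, numeric(1), 1),
      y = vapply(pts, `[`, numeric(1), 2),
      label = names(pts)
    )
    p <- p +
      ggplot2::geom_point(data = pd_df,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          colour = "yellow", size = 1.2) +
      ggplot2::geom_text(data = pd_df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$label),
                         colour = "yellow", size = 3, vjust = -0.8)
  }
  p
}

#' Scene preview with its ground-truth arcades
#'
#' @param object A [generate_fundus_scene()] result.
#' @param show_truth Overlay the true arcade Beziers and disc circle.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fundus_scene
autoplot.fundus_scene <- function(object, show_truth = TRUE, ...) {
  p <- ggplot2::ggplot() + .raster_layer(object$image)
  if (show_truth && !is.null(object$truth$arcade_beziers)) {
    tt <- seq(0, 1, length.out = 200L)
    for (arc in object$truth$arcade_beziers) {
      b <- bezier_point(arc$p0, arc$p1, arc$p2, tt)
      p <- p + ggplot2::geom_path(
        data = data.frame(x = b[, 1], y = b[, 2]),
        ggplot2::aes(x = .data$x, y = .data$y),
        colour = "cyan", linewidth = 0.4, linetype = "dotted"
      )
    }
  }
  p
}

#' Thickness across angle groups
#'
#' Group means with +/- 1 SD bars against the ordinal angle group, the
#' visual counterpart of the p-for-trend.
#'
#' @param object A [trend_by_group()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot vaa_trend
autoplot.vaa_trend <- function(object, ...) {
  gm <- object$group_means
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$group, y = .data$cht_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cht_mean - .data$cht_sd,
                   ymax = .data$cht_mean + .data$cht_sd),
      width = 0.2
    ) +
    ggplot2::labs(
      x = paste(object$vaa_variable, "quantile group"),
      y = paste(object$cht_variable, "(mean ± SD)"),
      subtitle = sprintf("p for trend = %.3g", object$p_for_trend)
    ) +
    ggplot2::theme_minimal()
}

#' Save the annotated overlay PNG for a measurement
#'
#' @param m A [measure_vaa()] result.
#' @param image The measured image.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_qc_overlay <- function(m, image, path) {
  p <- autoplot.vaa_measurement(m, image)
  ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 120)
  invisible(path)
}
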