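ellipse_path <- function(ellipse, n = 120) {
  # boundary of the 2D covariance ellipse at `scale` SDs
  ang <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(ang), sin(ang))
  ev <- eigen(ellipse$covariance[1:2, 1:2, drop = FALSE])
  half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2, 2)
  pts <- ellipse$scale * circ %*% t(half)
  tibble::tibble(x = pts[, 1] + ellipse$center[1],
                 y = pts[, 2] + ellipse$center[2],
                 label = ellipse$label %||% NA_character_)
}

#' Plot an ordination map
#'
#' First two retained dimensions, colored by species; optional class
#' annotations add 1.6-SD dispersion ellipses per class.
#'
#' @param object an `ordination`.
#' @param classes optional named vector (gene id -> class label).
#' @param ellipse_scale SD multiplier for the class ellipses.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ordination <- function(object, classes = NULL, ellipse_scale = 1.6,
                                ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$species),
                        size = 1, alpha = 0.7) +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2",
                  title = sprintf("MDS map (%s)", object$method)) +
    ggplot2::theme_minimal()
  if (!is.null(classes)) {
    cls <- classes[df$gene_id]
    paths <- purrr::map_dfr(unique(stats::na.omit(cls)), function(lb) {
      pts <- object$coordinates[which(!is.na(cls) & cls == lb), 1:2,
                                drop = FALSE]
      if (nrow(pts) < 3) return(NULL)
      ellipse_path(dispersion_ellipse(pts, scale = ellipse_scale, label = lb))
    })
    if (nrow(paths) > 0) {
      p <- p + ggplot2::geom_path(
        data = paths,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$label,
                     linetype = .data$label),
        color = "grey30")
    }
  }
  p
}

#' Plot a density field
#'
#' @param object a `density_field`.
#' @param ... unused.
#' @return a ggplot raster heat map.
#' @exportS3Method ggplot2::autoplot
autoplot.density_field <- function(object, ...) {
  grid <- expand.grid(x = object$x, y = object$y)
  grid$density <- as.vector(object$z)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise-correlation distribution profile
#'
#' Histogram of the off-diagonal tau values with the kernel density overlay
#' and the bimodality verdict in the title.
#'
#' @param object a `tau_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tau_profile <- function(object, ...) {
  mids <- (head(object$breaks, -1) + object$breaks[-1]) / 2
  width <- diff(object$breaks[1:2])
  hist_df <- tibble::tibble(
    tau = mids,
    density = object$counts / (sum(object$counts) * width)
  )
  ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$tau, y = .data$density)) +
    ggplot2::geom_col(width = width, fill = "grey75") +
    ggplot2::geom_line(data = object$density,
                       ggplot2::aes(x = .data$tau, y = .data$density),
                       color = "firebrick") +
    ggplot2::labs(
      x = "Kendall tau", y = "density",
      title = sprintf("Pairwise correlations: bimodality %.3f (%s)",
                      object$bimodality_coefficient,
                      if (object$bimodal) "bimodal" else "unimodal")) +
    ggplot2::theme_minimal()
}
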