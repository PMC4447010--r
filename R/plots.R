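# ggplot2 visualization and broom-style tidiers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

map_to_long <- function(values, value_name) {
  tibble::tibble(
    x = rep(seq_len(ncol(values)) - 1L, each = nrow(values)),
    y = rep(seq_len(nrow(values)) - 1L, times = ncol(values)),
    !!value_name := as.vector(values)
  )
}

#' Plot a label map with the class palette
#'
#' @param object A [label_map()].
#' @param ... Unused.
#' @return A ggplot raster plot (y axis pointing down, image convention).
#' @method autoplot label_map
#' @export
autoplot.label_map <- function(object, ...) {
  pal <- sp_palette()
  df <- map_to_long(object$labels, "label")
  df$class <- factor(names(sp_labels)[match(df$label, sp_labels)],
                     levels = names(sp_labels))
  cols <- setNames(grDevices::rgb(pal$r, pal$g, pal$b, maxColorValue = 255),
                   pal$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a depth map
#'
#' @param object A [depth_map()]; invalid pixels are blank.
#' @param ... Unused.
#' @return A ggplot raster plot, near = red to far = blue.
#' @method autoplot depth_map
#' @export
autoplot.depth_map <- function(object, ...) {
  v <- object$values
  v[!object$valid_mask] <- NA
  df <- map_to_long(v, "depth")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "red", high = "blue",
                                 na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "depth") +
    ggplot2::theme_minimal()
}

#' Plot a disparity map
#'
#' @param object A [disparity_map()].
#' @param ... Unused.
#' @return A ggplot raster plot.
#' @method autoplot disparity_map
#' @export
autoplot.disparity_map <- function(object, ...) {
  v <- object$values
  v[!object$valid_mask] <- NA
  df <- map_to_long(v, "disparity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$disparity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a growth series with replicate spread
#'
#' @param series Output of [growth_series()].
#' @return A ggplot line plot per genotype with a +-1 SD ribbon where
#'   replicates exist.
#' @export
plot_growth_series <- function(series) {
  stopifnot(is.data.frame(series))
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$day_of_year,
                                    y = .data$leaf_area_mean,
                                    color = .data$genotype,
                                    fill = .data$genotype))
  if (any(!is.na(series$leaf_area_sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$leaf_area_mean - .data$leaf_area_sd,
                   ymax = .data$leaf_area_mean + .data$leaf_area_sd),
      alpha = 0.2, color = NA, na.rm = TRUE)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "day of year", y = "digital leaf area [%]") +
    ggplot2::theme_minimal()
}

#' Plot the leaf-area regression
#'
#' @param object An [area_regression()].
#' @param ... Unused.
#' @return Scatter of predicted vs. true leaf areas with the fitted line
#'   and the identity.
#' @method autoplot area_regression
#' @export
autoplot.area_regression <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predicted, y = .data$truth)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "computed leaf area [%]",
                  y = "ground-truth leaf area [%]") +
    ggplot2::theme_minimal()
}

#' Tidy the coefficients of a leaf-area regression
#' @param x An `area_regression`.
#' @param ... Unused.
#' @return Tibble (term, estimate).
#' @method tidy area_regression
#' @export
tidy.area_regression <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a leaf-area regression
#' @param x An `area_regression`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance area_regression
#' @export
glance.area_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n = x$n,
                 orientation = x$orientation)
}

#' Tidy a validation report
#'
#' @param x A [validation_report()].
#' @param ... Unused.
#' @return Long tibble of the confusion matrix (truth, predicted, percent).
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    truth = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    percent = as.vector(cm)
  )
}

#' One-row summary of a validation report
#'
#' @param x A [validation_report()].
#' @param ... Unused.
#' @return Tibble with slope, intercept, R^2, RMSE and mean residual.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    slope = x$regression$slope, intercept = x$regression$intercept,
    r_squared = x$regression$r_squared, rmse = x$rmse,
    residual_mean = x$residual_mean, n_images = nrow(x$leaf_areas)
  )
}
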