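# Domain containers shared by all pipeline stages. Raster-like objects are
# plain S3 lists over base arrays; intensities are floats on the 0..255 scale
# (classifier thresholds such as c_color = 20 are defined on that scale).

#' Label set of the segmentation
#'
#' Integer codes and display colors for the four phenotypic classes.
#' @format Named integer vector: background = 0, leaf = 1, stem = 2, grape = 3.
#' @export
sp_labels <- c(background = 0L, leaf = 1L, stem = 2L, grape = 3L)

# Fixed display palette (background white, leaf green, stem brown, grape dark
# blue), used by the indexed-PNG writer and by autoplot().
sp_palette <- function() {
  data.frame(
    index = unname(sp_labels),
    name  = names(sp_labels),
    r = c(255L, 0L, 139L, 0L),
    g = c(255L, 160L, 69L, 0L),
    b = c(255L, 0L, 19L, 139L)
  )
}

#' RGB image container
#'
#' Holds an H x W x 3 array of channel intensities as floats in \[0, 255\].
#' All color classifiers in the package are defined on this scale.
#'
#' @param pixels Numeric H x W x 3 array (or H x W matrix, replicated to three
#'   channels), all values finite and in \[0, 255\].
#' @return An object of class `rgb_image` with elements `pixels`, `height`,
#'   `width`.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    sp_validation_error("`pixels` must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L) {
    sp_validation_error("images must be at least 8 x 8 pixels")
  }
  if (!all(is.finite(pixels))) {
    sp_validation_error("image intensities must all be finite")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    sp_validation_error("image intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, intensities [%.1f, %.1f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Camera geometry of a rectified stereo pair
#'
#' @param focal_px Focal length f in pixel units (> 0).
#' @param baseline Baseline b, the distance between the two camera positions,
#'   in world units (> 0). Depth follows d = f b / v for disparity v.
#' @param gamma_max Maximum disparity searched, pixels (> 0).
#' @param levels Number of discrete disparity levels Gamma (>= 2); the level
#'   spacing is `gamma_max / (levels - 1)`.
#' @return An object of class `camera_geometry`.
#' @export
camera_geometry <- function(focal_px, baseline, gamma_max, levels) {
  check_scalar(focal_px, "focal_px", 0, strict_lo = TRUE)
  check_scalar(baseline, "baseline", 0, strict_lo = TRUE)
  check_scalar(gamma_max, "gamma_max", 0, strict_lo = TRUE)
  check_scalar(levels, "levels", 2)
  levels <- as.integer(levels)
  structure(
    list(focal_px = focal_px, baseline = baseline,
         gamma_max = gamma_max, levels = levels,
         delta_gamma = gamma_max / (levels - 1)),
    class = "camera_geometry"
  )
}

# Disparity values (pixels) of each discrete level, 0 .. gamma_max.
disparity_levels <- function(geom) {
  seq(0, geom$gamma_max, length.out = geom$levels)
}

#' Disparity map container
#'
#' @param values H x W numeric matrix of disparities in pixel units.
#' @param valid_mask H x W logical matrix; invalid pixels carry no estimate.
#' @param gamma_max Upper bound of the disparity range (valid values must lie
#'   in \[0, gamma_max\]).
#' @return Object of class `disparity_map`.
#' @export
disparity_map <- function(values, valid_mask = NULL, gamma_max = Inf) {
  if (!is.matrix(values)) sp_validation_error("`values` must be a matrix")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(identical(dim(values), dim(valid_mask)))
  v <- values[valid_mask]
  if (length(v) && (any(!is.finite(v)) || min(v) < 0 || max(v) > gamma_max)) {
    sp_validation_error("valid disparities must lie in [0, gamma_max]")
  }
  structure(list(values = values, valid_mask = valid_mask,
                 gamma_max = gamma_max),
            class = "disparity_map")
}

#' Depth map container
#'
#' @param values H x W numeric matrix of depths in world units (> 0 where
#'   valid).
#' @param valid_mask H x W logical matrix.
#' @return Object of class `depth_map`.
#' @export
depth_map <- function(values, valid_mask = NULL) {
  if (!is.matrix(values)) sp_validation_error("`values` must be a matrix")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(identical(dim(values), dim(valid_mask)))
  v <- values[valid_mask]
  if (length(v) && (any(!is.finite(v)) || min(v) <= 0)) {
    sp_validation_error("valid depths must be strictly positive and finite")
  }
  structure(list(values = values, valid_mask = valid_mask),
            class = "depth_map")
}

#' Label map container
#'
#' @param labels H x W integer matrix with entries in
#'   \{0 background, 1 leaf, 2 stem, 3 grape\}.
#' @return Object of class `label_map`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) sp_validation_error("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || !all(labels %in% sp_labels)) {
    sp_validation_error("labels must all be in {0, 1, 2, 3}")
  }
  structure(list(labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  counts <- table(factor(x$labels, levels = sp_labels, labels = names(sp_labels)))
  cat(sprintf("<label_map %d x %d>\n", nrow(x$labels), ncol(x$labels)))
  print(counts)
  invisible(x)
}

# Operator-norm bound of the discrete gradient used by the lifted solver
# (forward differences along x, y and gamma): ||K||^2 <= 12.
sp_grad_norm2 <- 12

#' Solver configuration for the lifted stereo energy
#'
#' @param lambda_smooth Smoothness weight lambda >= 0 multiplying the
#'   anisotropic total-variation regularizer. Defined relative to matching
#'   costs on the 0..255 intensity scale; the default 5 corresponds to about
#'   0.02 for costs on a unit intensity scale.
#' @param iterations Number of primal-dual iterations (>= 1).
#' @param step_primal,step_dual Primal/dual step sizes; their product must not
#'   exceed `1 / 12`, the reciprocal operator-norm bound of the discrete
#'   gradient, or the scheme may diverge. Defaults `1/sqrt(12)` each.
#' @param aniso_alpha,aniso_beta Edge-stopping parameters of the anisotropy
#'   tensor, `exp(-alpha * |grad|^beta)`; defaults 5/255 and 1.
#' @param seed Integer seed recorded for provenance.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(lambda_smooth = 5, iterations = 500,
                          step_primal = 1 / sqrt(sp_grad_norm2),
                          step_dual = 1 / sqrt(sp_grad_norm2),
                          aniso_alpha = 5 / 255, aniso_beta = 1,
                          seed = 0L) {
  check_scalar(lambda_smooth, "lambda_smooth", 0)
  check_scalar(iterations, "iterations", 1)
  check_scalar(step_primal, "step_primal", 0, strict_lo = TRUE)
  check_scalar(step_dual, "step_dual", 0, strict_lo = TRUE)
  check_scalar(aniso_alpha, "aniso_alpha", 0)
  check_scalar(aniso_beta, "aniso_beta", 0)
  if (step_primal * step_dual > 1 / sp_grad_norm2 + 1e-12) {
    sp_validation_error(
      "step_primal * step_dual exceeds 1/12, the stability bound of the discrete gradient")
  }
  structure(
    list(lambda_smooth = lambda_smooth, iterations = as.integer(iterations),
         step_primal = step_primal, step_dual = step_dual,
         aniso_alpha = aniso_alpha, aniso_beta = aniso_beta,
         seed = as.integer(seed)),
    class = "solver_config"
  )
}

#' Segmentation configuration
#'
#' @param c_depth Depth threshold separating plant from background, world
#'   units. No default: it depends on the capture distance and is set per
#'   image pair.
#' @param c_color Green-minus-blue vegetation threshold, intensity units on
#'   the 0..255 scale (default 20).
#' @param c_grape Red/blue-excess grape threshold, intensity units (default
#'   20).
#' @param nu Spatial regularization weight of the Potts segmentation (>= 0,
#'   default 0.5). `nu = 0` reduces to the pointwise classification rule.
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(c_depth, c_color = 20, c_grape = 20,
                                nu = 0.5) {
  check_scalar(c_depth, "c_depth")
  check_scalar(c_color, "c_color", 0, 255)
  check_scalar(c_grape, "c_grape", 0, 255)
  check_scalar(nu, "nu", 0)
  structure(list(c_depth = c_depth, c_color = c_color, c_grape = c_grape,
                 nu = nu),
            class = "segmentation_config")
}
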