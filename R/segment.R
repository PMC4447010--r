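# Depth + color segmentation into background / leaf / stem / grape.
# Two scalar classifiers drive the labeling: f_depth = d - c_depth separates
# the distant field background from the near plant, and the vegetation index
# f_color = green - blue - c_color separates leaf from stem within the
# foreground. A third score flags red/blue excess over green as grapes. The
# pointwise rule is optionally regularized spatially by an edge-weighted
# relaxed Potts model.

#' Depth classifier field
#'
#' `f_depth(x) = d(x) - c_depth`: positive values lie on the background side.
#' Pixels with no valid depth estimate receive a large positive score and are
#' therefore treated as background.
#'
#' @param d A [depth_map()].
#' @param c_depth Depth threshold, world units; set per image pair.
#' @return Object of class `scalar_field` (`values` matrix, `kind`).
#' @export
depth_score <- function(d, c_depth) {
  stopifnot(inherits(d, "depth_map"))
  check_scalar(c_depth, "c_depth")
  v <- d$values - c_depth
  v[!d$valid_mask] <- 1e6
  scalar_field(v, "depth_score")
}

#' Vegetation color classifier field
#'
#' `f_color(x) = green(x) - blue(x) - c_color` on the 0..255 intensity scale;
#' positive values indicate vegetation (leaf side).
#'
#' @param I1 Reference [rgb_image()].
#' @param c_color Threshold in intensity units (default 20).
#' @return A `scalar_field`.
#' @export
color_score <- function(I1, c_color = 20) {
  stopifnot(inherits(I1, "rgb_image"))
  check_scalar(c_color, "c_color", 0, 255)
  scalar_field(I1$pixels[, , 2] - I1$pixels[, , 3] - c_color, "color_score")
}

#' Grape color classifier field
#'
#' `f_grape(x) = max(red - green, blue - green) - c_grape`: red or blue
#' excess over green marks berry pixels (covers both red and blue cultivars).
#'
#' @param I1 Reference [rgb_image()].
#' @param c_grape Threshold in intensity units (default 20).
#' @return A `scalar_field`.
#' @export
grape_score <- function(I1, c_grape = 20) {
  stopifnot(inherits(I1, "rgb_image"))
  check_scalar(c_grape, "c_grape", 0, 255)
  r <- I1$pixels[, , 1]; g <- I1$pixels[, , 2]; b <- I1$pixels[, , 3]
  scalar_field(pmax(r - g, b - g) - c_grape, "grape_score")
}

#' Scalar classifier field container
#'
#' @param values H x W matrix of finite reals.
#' @param kind One of `"depth_score"`, `"color_score"`, `"grape_score"`.
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(values, kind) {
  if (!is.matrix(values) || !all(is.finite(values))) {
    sp_validation_error("scalar field values must be a finite matrix")
  }
  kind <- match.arg(kind, c("depth_score", "color_score", "grape_score"))
  structure(list(values = values, kind = kind), class = "scalar_field")
}

#' Per-label data costs from the classifier fields
#'
#' Combines the three classifier fields into per-pixel label scores:
#' background `fd`, leaf `min(-fd, fc)`, stem `min(-fd, -fc, -fg)`, grape
#' `min(-fd, fg)`; costs are the negated scores. The pointwise argmax of the
#' scores reproduces the classification hierarchy (far => background; near
#' and grape-colored => grape; near and green => leaf; near otherwise =>
#' stem). The source fields are retained on the object so exact boundary
#' ties can be resolved by the hierarchy.
#'
#' @param fd,fc,fg `scalar_field`s from [depth_score()], [color_score()],
#'   [grape_score()], sharing dimensions.
#' @return Object of class `label_costs`: `costs` H x W x 4 array (layers
#'   ordered background, leaf, stem, grape) plus the source fields.
#' @export
assemble_costs <- function(fd, fc, fg) {
  stopifnot(inherits(fd, "scalar_field"), inherits(fc, "scalar_field"),
            inherits(fg, "scalar_field"))
  if (!identical(dim(fd$values), dim(fc$values)) ||
      !identical(dim(fd$values), dim(fg$values))) {
    sp_validation_error("classifier fields must share dimensions")
  }
  d <- dim(fd$values)
  s_bg <- fd$values
  s_leaf <- pmin(-fd$values, fc$values)
  s_stem <- pmin(-fd$values, -fc$values, -fg$values)
  s_grape <- pmin(-fd$values, fg$values)
  costs <- array(c(-s_bg, -s_leaf, -s_stem, -s_grape), dim = c(d, 4L))
  structure(list(costs = costs, fd = fd$values, fc = fc$values,
                 fg = fg$values),
            class = "label_costs")
}

# Deterministic classification hierarchy: strictly positive f_depth =>
# background; otherwise strictly positive f_grape => grape; otherwise
# strictly positive f_color => leaf; else stem. Boundary scores of exactly 0
# therefore fall to the foreground / stem side.
classify_hierarchy <- function(fd, fc, fg) {
  lab <- matrix(sp_labels[["stem"]], nrow(fd), ncol(fd))
  lab[fc > 0] <- sp_labels[["leaf"]]
  lab[fg > 0] <- sp_labels[["grape"]]
  lab[fd > 0] <- sp_labels[["background"]]
  label_map(lab)
}

# Project the rows of an n x 4 matrix onto the probability simplex
# (vectorized over rows; the 4-element sort uses a fixed sorting network).
project_simplex4 <- function(z) {
  a <- z[, 1]; b <- z[, 2]; c <- z[, 3]; d <- z[, 4]
  s1 <- pmax(a, b); s2 <- pmin(a, b); s3 <- pmax(c, d); s4 <- pmin(c, d)
  t1 <- pmax(s1, s3); t3 <- pmin(s1, s3); t2 <- pmax(s2, s4); t4 <- pmin(s2, s4)
  u2 <- pmax(t2, t3); u3 <- pmin(t2, t3)
  z1 <- t1; z2 <- u2; z3 <- u3; z4 <- t4          # descending
  c1 <- z1; c2 <- c1 + z2; c3 <- c2 + z3; c4 <- c3 + z4
  k <- 1 + (z2 + (1 - c2) / 2 > 0) + (z3 + (1 - c3) / 3 > 0) +
    (z4 + (1 - c4) / 4 > 0)
  ck <- cbind(c1, c2, c3, c4)[cbind(seq_along(k), k)]
  theta <- (ck - 1) / k
  pmax(z - theta, 0)
}

#' Multi-label segmentation with optional spatial regularization
#'
#' With `nu = 0` each pixel takes the label of its minimal data cost (exact
#' boundary ties resolved by the classification hierarchy when the cost
#' object carries its source fields, otherwise by ascending label index).
#' With `nu > 0` a convex relaxed Potts energy
#' `sum_l <cost_l, u_l> + nu * sum_l int g(x) |grad u_l|` is minimized over
#' the label simplex by a primal-dual scheme, where
#' `g = exp(-alpha |grad gray(I1)|)` downweights boundaries along image
#' edges; hard labels are the per-pixel argmax of the relaxed solution (ties
#' by ascending label index: background < leaf < stem < grape).
#'
#' @param costs A `label_costs` from [assemble_costs()].
#' @param I1 Reference [rgb_image()] used for the edge weights.
#' @param nu Regularization weight >= 0.
#' @param alpha Edge-stopping parameter of the boundary weight (default
#'   5/255, matching the stereo anisotropy).
#' @param iterations Primal-dual iterations when `nu > 0` (default 200).
#' @return A [label_map()].
#' @export
segment_labels <- function(costs, I1, nu = 0.5, alpha = 5 / 255,
                           iterations = 200) {
  stopifnot(inherits(costs, "label_costs"), inherits(I1, "rgb_image"))
  check_scalar(nu, "nu", 0)
  if (!all(is.finite(costs$costs))) {
    sp_validation_error("label costs must be finite")
  }
  d <- dim(costs$costs)
  h <- d[1]; w <- d[2]
  if (h != I1$height || w != I1$width) {
    sp_validation_error("cost and image dimensions disagree")
  }
  if (nu == 0) {
    if (!is.null(costs$fd)) {
      return(classify_hierarchy(costs$fd, costs$fc, costs$fg))
    }
    flat <- matrix(costs$costs, h * w, 4L)
    lab <- max.col(-flat, ties.method = "first") - 1L
    return(label_map(matrix(lab, h, w)))
  }
  gray <- to_gray(I1)
  gmag <- sqrt(cdiff_x(gray)^2 + cdiff_y(gray)^2)
  g <- exp(-alpha * gmag)
  bound <- nu * g

  # cost scaling keeps step sizes meaningful across intensity scales
  tau <- 1 / sqrt(8); sig <- 1 / sqrt(8)
  u <- array(0, dim = d)
  flat <- matrix(costs$costs, h * w, 4L)
  init <- max.col(-flat, ties.method = "first")
  for (l in 1:4) u[, , l] <- matrix(as.numeric(init == l), h, w)
  ubar <- u
  q1 <- array(0, dim = d); q2 <- array(0, dim = d)
  for (it in seq_len(iterations)) {
    for (l in 1:4) {
      q1l <- q1[, , l] + sig * fdiff_x(ubar[, , l])
      q2l <- q2[, , l] + sig * fdiff_y(ubar[, , l])
      nrm <- sqrt(q1l^2 + q2l^2)
      scale <- ifelse(nrm > bound, bound / pmax(nrm, .Machine$double.eps), 1)
      q1[, , l] <- q1l * scale
      q2[, , l] <- q2l * scale
    }
    u_old <- u
    for (l in 1:4) {
      u[, , l] <- u[, , l] - tau * (costs$costs[, , l] +
                                      fdiff_x_adj(q1[, , l]) +
                                      fdiff_y_adj(q2[, , l]))
    }
    u <- array(project_simplex4(matrix(u, h * w, 4L)), dim = d)
    ubar <- 2 * u - u_old
  }
  lab <- max.col(matrix(u, h * w, 4L), ties.method = "first") - 1L
  label_map(matrix(lab, h, w))
}

#' One-call segmentation from image and depth
#'
#' Convenience wrapper building the three classifier fields from a
#' [segmentation_config()] and running [segment_labels()].
#'
#' @param I1 Reference [rgb_image()].
#' @param d A [depth_map()].
#' @param cfg A [segmentation_config()].
#' @param ... Passed to [segment_labels()].
#' @return A [label_map()].
#' @export
segment_image <- function(I1, d, cfg, ...) {
  stopifnot(inherits(cfg, "segmentation_config"))
  costs <- assemble_costs(depth_score(d, cfg$c_depth),
                          color_score(I1, cfg$c_color),
                          grape_score(I1, cfg$c_grape))
  segment_labels(costs, I1, nu = cfg$nu, ...)
}
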