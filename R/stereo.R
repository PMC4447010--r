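# Dense disparity by functional lifting. The per-pixel disparity choice is
# lifted to a field phi on (image domain) x (disparity range) constrained to
# phi(x, 0) = 1, phi(x, gamma_max) = 0, and the resulting convex energy
#
#   E(phi) = sum_{x,g} rho(x,g) |d_gamma phi| + lambda sum_{x,g} |D grad_xy phi|
#
# is minimized globally by a first-order primal-dual scheme. The anisotropy
# tensor D attenuates spatial smoothing across image edges so fine plant
# structures survive regularization.

#' Matching cost volume of a rectified stereo pair
#'
#' For each pixel x of the reference image and each disparity level gamma the
#' cost is the mean absolute channel difference |I1(x) - I2(x + gamma)|, with
#' linear interpolation along the row for fractional gamma. Samples beyond
#' the right image border receive the maximum possible cost 255 so border
#' pixels prefer in-range disparities without being hard-excluded.
#'
#' @param I1,I2 Rectified [rgb_image()] pair of identical size (I1 is the
#'   reference view).
#' @param geom [camera_geometry()] defining the disparity range and level
#'   count.
#' @return Object of class `cost_volume`: list with `rho` (H x W x levels,
#'   non-negative), `geom`, and `out_of_range_cost`.
#' @export
compute_cost_volume <- function(I1, I2, geom) {
  stopifnot(inherits(I1, "rgb_image"), inherits(I2, "rgb_image"),
            inherits(geom, "camera_geometry"))
  if (I1$height != I2$height || I1$width != I2$width) {
    sp_validation_error("stereo images must have identical dimensions")
  }
  h <- I1$height; w <- I1$width
  levels <- disparity_levels(geom)
  rho <- array(0, dim = c(h, w, geom$levels))
  oor <- 255
  cols <- seq_len(w)
  for (j in seq_along(levels)) {
    g <- levels[j]
    src <- cols + g                      # sample position in I2, per column
    f0 <- floor(src); t <- src - f0
    acc <- matrix(0, h, w)
    for (ch in 1:3) {
      m2 <- I2$pixels[, , ch]
      lo <- m2[, clamp(f0, 1, w), drop = FALSE]
      hi <- m2[, clamp(f0 + 1, 1, w), drop = FALSE]
      samp <- sweep(lo, 2, 1 - t, "*") + sweep(hi, 2, t, "*")
      acc <- acc + abs(I1$pixels[, , ch] - samp)
    }
    lev <- acc / 3
    out <- src > w                        # x + gamma beyond the right border
    if (any(out)) lev[, out] <- oor
    rho[, , j] <- lev
  }
  structure(list(rho = rho, geom = geom, out_of_range_cost = oor),
            class = "cost_volume")
}

#' Anisotropy tensor of the reference image
#'
#' Builds the per-pixel edge-stopping tensor
#' `D = exp(-alpha |g|^beta) n n' + n_perp n_perp'` where `g` is the central
#' difference gradient of the grayscale image and `n = g/|g|` (taken as
#' (1, 0) where the gradient vanishes). Eigenvalues lie in (0, 1]: smoothing
#' across an edge is damped by `exp(-alpha |g|^beta)` while smoothing along
#' the edge is untouched.
#'
#' @param I1 Reference [rgb_image()].
#' @param alpha,beta Edge-stopping parameters (>= 0); defaults 5/255 and 1.
#' @return Object of class `anisotropy_tensor`: list of H x W matrices
#'   `d11`, `d12`, `d22` (the symmetric tensor entries).
#' @export
compute_anisotropy <- function(I1, alpha = 5 / 255, beta = 1) {
  stopifnot(inherits(I1, "rgb_image"))
  check_scalar(alpha, "alpha", 0)
  check_scalar(beta, "beta", 0)
  gray <- to_gray(I1)
  gx <- cdiff_x(gray); gy <- cdiff_y(gray)
  gn <- sqrt(gx^2 + gy^2)
  nx <- ifelse(gn > 0, gx / pmax(gn, .Machine$double.eps), 1)
  ny <- ifelse(gn > 0, gy / pmax(gn, .Machine$double.eps), 0)
  e <- exp(-alpha * gn^beta)
  # D = e*n n' + n_perp n_perp', with n_perp = (-ny, nx)
  d11 <- e * nx^2 + ny^2
  d12 <- e * nx * ny - ny * nx
  d22 <- e * ny^2 + nx^2
  structure(list(d11 = d11, d12 = d12, d22 = d22, alpha = alpha, beta = beta),
            class = "anisotropy_tensor")
}

#' Winner-takes-all initialization of the lifted field
#'
#' Sets `phi(x, j) = 1` for levels up to the per-pixel cost argmin (searched
#' over levels `0 .. Gamma-2`, since the last level is pinned to 0 by the
#' boundary constraints; ties resolve to the smallest level) and 0 above it.
#'
#' @param rho A `cost_volume`.
#' @return Object of class `lifted_field` with element `phi`
#'   (H x W x levels in \[0, 1\], `phi[,,1] == 1`, `phi[,,levels] == 0`).
#' @export
initialize_lifted <- function(rho) {
  stopifnot(inherits(rho, "cost_volume"))
  d <- dim(rho$rho)
  h <- d[1]; w <- d[2]; G <- d[3]
  flat <- matrix(rho$rho[, , seq_len(G - 1)], nrow = h * w, ncol = G - 1)
  m <- max.col(-flat, ties.method = "first")   # 1-based selected level
  phi <- array(0, dim = d)
  for (j in seq_len(G - 1)) {
    phi[, , j] <- matrix(as.numeric(m >= j), h, w)
  }
  # phi[,,G] stays 0; phi[,,1] == 1 because m >= 1 always
  lifted_field(phi)
}

#' Lifted field container
#'
#' @param phi H x W x levels array in \[0, 1\] with the boundary constraints
#'   `phi[,,1] == 1`, `phi[,,levels] == 0`.
#' @param tol Tolerance for constraint validation.
#' @return Object of class `lifted_field`.
#' @export
lifted_field <- function(phi, tol = 1e-6) {
  if (!is.array(phi) || length(dim(phi)) != 3L) {
    sp_validation_error("`phi` must be an H x W x levels array")
  }
  G <- dim(phi)[3]
  if (G < 2L) sp_validation_error("lifted field needs at least 2 levels")
  if (min(phi) < -tol || max(phi) > 1 + tol) {
    sp_validation_error("phi must lie in [0, 1]")
  }
  if (max(abs(phi[, , 1] - 1)) > tol || max(abs(phi[, , G])) > tol) {
    sp_validation_error(
      "boundary constraints violated: phi(x, 0) = 1 and phi(x, gamma_max) = 0 are required")
  }
  structure(list(phi = phi), class = "lifted_field")
}

# Apply the anisotropy tensor to a spatial gradient field (per level).
apply_tensor <- function(D, gx, gy) {
  list(a1 = D$d11 * gx + D$d12 * gy,
       a2 = D$d12 * gx + D$d22 * gy)
}

#' Globally optimize the lifted stereo energy
#'
#' Runs a Chambolle-Pock primal-dual scheme on the discretized lifted energy
#' (forward differences, Neumann boundary). The gamma-derivative carries the
#' matching cost (data term); the anisotropy tensor acts on the spatial
#' gradient only. After every iteration the primal variable is clipped to
#' \[0, 1\] and the boundary constraints are re-imposed, so the constraint
#' set holds exactly at all times.
#'
#' @param rho A `cost_volume`.
#' @param D An `anisotropy_tensor` of matching spatial dimensions.
#' @param cfg A [solver_config()].
#' @param trace_every Record the primal energy every this many iterations
#'   (0 disables tracing).
#' @return A `lifted_field`; attribute `energy_trace` holds a tibble
#'   (iteration, energy) when tracing is enabled.
#' @export
solve_lifted <- function(rho, D, cfg = solver_config(), trace_every = 0L) {
  stopifnot(inherits(rho, "cost_volume"), inherits(D, "anisotropy_tensor"),
            inherits(cfg, "solver_config"))
  d <- dim(rho$rho)
  if (!identical(d[1:2], dim(D$d11))) {
    sp_validation_error("cost volume and anisotropy tensor dimensions disagree")
  }
  h <- d[1]; w <- d[2]; G <- d[3]
  tau <- cfg$step_primal; sig <- cfg$step_dual

  # The minimizer is invariant to scaling rho and lambda jointly, so the
  # problem is normalized by the largest cost: duals then live on an O(1)
  # scale and the default symmetric steps are well conditioned.
  s <- max(rho$rho, 1e-12)
  lam <- cfg$lambda_smooth / s

  phi <- initialize_lifted(rho)$phi
  phibar <- phi
  # duals: p for the gamma-differences (weight rho at the lower level),
  # q1/q2 for the spatial gradient per level
  p <- array(0, dim = c(h, w, G - 1))
  q1 <- array(0, dim = d); q2 <- array(0, dim = d)
  wgt <- rho$rho[, , seq_len(G - 1), drop = FALSE] / s

  trace_it <- integer(0); trace_en <- numeric(0)
  for (it in seq_len(cfg$iterations)) {
    # dual ascent
    p <- p + sig * (phibar[, , 2:G, drop = FALSE] -
                      phibar[, , 1:(G - 1), drop = FALSE])
    p <- pmin(pmax(p, -wgt), wgt)
    if (lam > 0) {
      for (j in seq_len(G)) {
        sl <- phibar[, , j]
        a <- apply_tensor(D, fdiff_x(sl), fdiff_y(sl))
        q1j <- q1[, , j] + sig * a$a1
        q2j <- q2[, , j] + sig * a$a2
        nrm <- sqrt(q1j^2 + q2j^2)
        scale <- ifelse(nrm > lam, lam / nrm, 1)
        q1[, , j] <- q1j * scale
        q2[, , j] <- q2j * scale
      }
    }
    # primal descent: phi <- phi - tau * (Kgamma' p + Kxy' D q)
    phi_old <- phi
    adj <- array(0, dim = d)
    adj[, , 1] <- -p[, , 1]
    if (G > 2) {
      adj[, , 2:(G - 1)] <- p[, , 1:(G - 2), drop = FALSE] -
        p[, , 2:(G - 1), drop = FALSE]
    }
    adj[, , G] <- p[, , G - 1]
    if (lam > 0) {
      for (j in seq_len(G)) {
        r <- apply_tensor(D, q1[, , j], q2[, , j])
        adj[, , j] <- adj[, , j] + fdiff_x_adj(r$a1) + fdiff_y_adj(r$a2)
      }
    }
    phi <- phi - tau * adj
    phi <- clamp(phi, 0, 1)
    phi[, , 1] <- 1
    phi[, , G] <- 0
    if (!all(is.finite(phi))) {
      sp_abort(sprintf("non-finite lifted field at iteration %d", it),
               "stereophyte_numeric_error")
    }
    phibar <- 2 * phi - phi_old
    if (trace_every > 0 && (it %% trace_every == 0L || it == cfg$iterations)) {
      trace_it <- c(trace_it, it)
      trace_en <- c(trace_en, primal_energy(lifted_field(phi), rho, D,
                                            cfg$lambda_smooth))
    }
  }
  out <- lifted_field(phi)
  if (trace_every > 0) {
    attr(out, "energy_trace") <- tibble::tibble(iteration = trace_it,
                                                energy = trace_en)
  }
  out
}

#' Primal energy of a lifted field
#'
#' Evaluates the discretized lifted stereo objective: the cost-weighted total
#' variation along the disparity axis plus `lambda` times the anisotropic
#' spatial total variation.
#'
#' @param phi A `lifted_field`.
#' @param rho A `cost_volume` of matching dimensions.
#' @param D An `anisotropy_tensor`.
#' @param lambda Smoothness weight (>= 0).
#' @return Non-negative finite scalar.
#' @export
primal_energy <- function(phi, rho, D, lambda) {
  stopifnot(inherits(phi, "lifted_field"), inherits(rho, "cost_volume"))
  check_scalar(lambda, "lambda", 0)
  ph <- phi$phi
  d <- dim(ph); G <- d[3]
  if (!identical(d, dim(rho$rho))) {
    sp_validation_error("lifted field and cost volume dimensions disagree")
  }
  dg <- ph[, , 2:G, drop = FALSE] - ph[, , 1:(G - 1), drop = FALSE]
  en <- sum(rho$rho[, , seq_len(G - 1), drop = FALSE] * abs(dg))
  if (lambda > 0) {
    for (j in seq_len(G)) {
      a <- apply_tensor(D, fdiff_x(ph[, , j]), fdiff_y(ph[, , j]))
      en <- en + lambda * sum(sqrt(a$a1^2 + a$a2^2))
    }
  }
  en
}

#' Disparity from a lifted field
#'
#' Integrates the lifted field over the disparity axis:
#' `v(x) = delta_gamma * sum_{j>=1} phi(x, j)` (levels above the pinned
#' first one), which retains sub-level precision for fractional fields.
#' A thresholded variant counts levels where `phi >= 0.5`.
#'
#' @param phi A `lifted_field` satisfying the boundary constraints (violation
#'   beyond 1e-6 raises a validation error).
#' @param geom [camera_geometry()] supplying the level spacing.
#' @param method `"integrate"` (default) or `"threshold"`.
#' @return A [disparity_map()] with all pixels valid, values clamped to
#'   \[0, gamma_max\].
#' @export
extract_disparity <- function(phi, geom, method = c("integrate", "threshold")) {
  stopifnot(inherits(phi, "lifted_field"), inherits(geom, "camera_geometry"))
  method <- match.arg(method)
  ph <- phi$phi
  G <- dim(ph)[3]
  if (G != geom$levels) {
    sp_validation_error("lifted field level count does not match the geometry")
  }
  lifted_field(ph, tol = 1e-6)   # re-validate constraints
  h <- dim(ph)[1]; w <- dim(ph)[2]
  body <- ph[, , 2:G, drop = FALSE]
  if (method == "threshold") body <- (body >= 0.5) * 1
  v <- geom$delta_gamma * matrix(rowSums(matrix(body, h * w, G - 1)), h, w)
  disparity_map(clamp(v, 0, geom$gamma_max),
                matrix(TRUE, h, w),
                gamma_max = geom$gamma_max)
}

#' Depth from disparity
#'
#' Applies `d = f * b / v`. Pixels whose disparity falls below `v_min`
#' (default a quarter of a level spacing) would map to implausibly large
#' depths and are marked invalid instead.
#'
#' @param v A [disparity_map()].
#' @param geom [camera_geometry()] with focal length (pixels) and baseline
#'   (world units).
#' @param v_min Smallest disparity considered reliable, pixels; default
#'   `0.25 * delta_gamma`.
#' @return A [depth_map()] in world units.
#' @export
disparity_to_depth <- function(v, geom, v_min = 0.25 * geom$delta_gamma) {
  stopifnot(inherits(v, "disparity_map"), inherits(geom, "camera_geometry"))
  check_scalar(v_min, "v_min", 0, strict_lo = TRUE)
  valid <- v$valid_mask & v$values >= v_min
  d <- matrix(NA_real_, nrow(v$values), ncol(v$values))
  d[valid] <- geom$focal_px * geom$baseline / v$values[valid]
  depth_map(d, valid)
}
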