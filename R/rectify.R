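# Epipolar rectification. Feature correspondences (Harris corners with
# normalized patch descriptors, mutual-nearest matching under a 0.8 ratio
# test) feed a seeded RANSAC around the normalized 8-point algorithm; the
# rectifying homographies map the epipoles to infinity (projective
# rectification with an affine correction minimizing the horizontal
# discrepancy of inliers). Pixel coordinates are 0-based, x rightward,
# y downward.

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

hom_apply <- function(H, x, y) {
  p <- H %*% rbind(x, y, 1)
  list(x = p[1, ] / p[3, ], y = p[2, ] / p[3, ])
}

#' Detect and match features between two images
#'
#' Harris corners (structure tensor smoothed at sigma 1.5) with 9 x 9
#' zero-mean unit-norm grayscale patch descriptors. Matches must be mutual
#' nearest neighbours and pass a 0.8 nearest/second-nearest distance ratio
#' test; they are returned sorted by decreasing score (1 - ratio).
#'
#' @param I1,I2 [rgb_image()]s, each at least 32 x 32.
#' @param max_features Keep at most this many matches (default 500).
#' @return A `correspondence_set`: tibble with columns `x1, y1, x2, y2`
#'   (0-based pixel coordinates) and `score`.
#' @export
detect_and_match <- function(I1, I2, max_features = 500) {
  stopifnot(inherits(I1, "rgb_image"), inherits(I2, "rgb_image"))
  if (min(I1$height, I1$width, I2$height, I2$width) < 32) {
    sp_validation_error("feature matching needs images of at least 32 x 32")
  }
  k1 <- harris_keypoints(I1, 4L)
  k2 <- harris_keypoints(I2, 4L)
  if (nrow(k1$pts) < 8 || nrow(k2$pts) < 8) {
    insufficient_matches("fewer than 8 keypoints detected (structureless image?)")
  }
  # squared descriptor distances via the unit-norm identity |a-b|^2 = 2 - 2ab
  S <- k1$desc %*% t(k2$desc)
  d2 <- pmax(2 - 2 * S, 0)
  best2 <- apply(d2, 1, function(r) {
    o <- order(r)[1:2]
    c(o[1], r[o[1]], r[o[2]])
  })
  nn12 <- best2[1, ]
  ratio <- sqrt(best2[2, ] / pmax(best2[3, ], .Machine$double.eps))
  nn21 <- apply(d2, 2, which.min)
  mutual <- nn21[nn12] == seq_len(nrow(d2))
  keep <- which(mutual & ratio <= 0.8)
  if (length(keep) < 8) {
    insufficient_matches(sprintf(
      "only %d matches survive the ratio test (need 8)", length(keep)))
  }
  out <- tibble::tibble(
    x1 = k1$pts[keep, 1], y1 = k1$pts[keep, 2],
    x2 = k2$pts[nn12[keep], 1], y2 = k2$pts[nn12[keep], 2],
    score = 1 - ratio[keep]
  )
  out <- out[order(-out$score), ]
  out <- out[seq_len(min(nrow(out), max_features)), ]
  class(out) <- c("correspondence_set", class(tibble::tibble()))
  out
}

# Harris corner detection + patch descriptors. Returns 0-based (x, y)
# positions and row-wise unit-norm descriptors.
harris_keypoints <- function(img, patch_r = 4L, max_pts = 800L) {
  gray <- to_gray(img)
  gx <- cdiff_x(gray); gy <- cdiff_y(gray)
  A <- gaussian_blur(gx * gx, 1.5)
  B <- gaussian_blur(gy * gy, 1.5)
  C <- gaussian_blur(gx * gy, 1.5)
  R <- A * B - C * C - 0.04 * (A + B)^2
  h <- nrow(R); w <- ncol(R)
  m <- patch_r + 1L
  # 3x3 non-maximum suppression
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- R
  is_max <- R >= pmax(
    pad[1:h, 1:w], pad[1:h, 2:(w + 1)], pad[1:h, 3:(w + 2)],
    pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)],
    pad[3:(h + 2), 1:w], pad[3:(h + 2), 2:(w + 1)], pad[3:(h + 2), 3:(w + 2)])
  # tiny relative floor only: warp borders can carry responses orders of
  # magnitude above real texture corners, so selection is top-N by response
  thr <- max(R) * 1e-6
  cand <- which(is_max & R > thr & R > 1e-12, arr.ind = TRUE)
  cand <- cand[cand[, 1] > m & cand[, 1] <= h - m &
                 cand[, 2] > m & cand[, 2] <= w - m, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(pts = matrix(numeric(0), 0, 2), desc = matrix(numeric(0), 0, 0)))
  }
  o <- order(-R[cand])
  cand <- cand[o[seq_len(min(nrow(cand), max_pts))], , drop = FALSE]
  side <- 2L * patch_r + 1L
  desc <- matrix(0, nrow(cand), side * side)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- gray[(cand[i, 1] - patch_r):(cand[i, 1] + patch_r),
              (cand[i, 2] - patch_r):(cand[i, 2] + patch_r)]
    v <- as.numeric(p) - mean(p)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      desc[i, ] <- v / nv
      keep[i] <- TRUE
    }
  }
  list(pts = cbind(x = cand[keep, 2] - 1, y = cand[keep, 1] - 1),
       desc = desc[keep, , drop = FALSE])
}

# Normalized 8-point estimate of the fundamental matrix (x2' F x1 = 0).
# Returns NULL for degenerate configurations (rank-deficient design matrix).
eight_point <- function(x1, y1, x2, y2) {
  n <- length(x1)
  norm_pts <- function(x, y) {
    cx <- mean(x); cy <- mean(y)
    s <- sqrt(2) / max(mean(sqrt((x - cx)^2 + (y - cy)^2)), 1e-12)
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * cx, -s * cy, 1), 3, 3)
    list(x = s * (x - cx), y = s * (y - cy), T = T)
  }
  n1 <- norm_pts(x1, y1); n2 <- norm_pts(x2, y2)
  A <- cbind(n2$x * n1$x, n2$x * n1$y, n2$x,
             n2$y * n1$x, n2$y * n1$y, n2$y,
             n1$x, n1$y, 1)
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[min(n, 8)] / sv$d[1] < 1e-10) return(NULL)   # degenerate sample
  Fm <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  # enforce rank 2
  sf <- svd(Fm)
  Fm <- sf$u %*% diag(c(sf$d[1], sf$d[2], 0)) %*% t(sf$v)
  Fm <- t(n2$T) %*% Fm %*% n1$T
  Fm / sqrt(sum(Fm^2))
}

# Symmetric epipolar distance (RMS of the two point-to-epipolar-line
# distances) for each correspondence.
sym_epipolar_dist <- function(Fm, x1, y1, x2, y2) {
  p1 <- rbind(x1, y1, 1); p2 <- rbind(x2, y2, 1)
  l2 <- Fm %*% p1
  l1 <- t(Fm) %*% p2
  num <- abs(colSums(p2 * l2))
  d2 <- num / sqrt(l2[1, ]^2 + l2[2, ]^2)
  d1 <- num / sqrt(l1[1, ]^2 + l1[2, ]^2)
  sqrt((d1^2 + d2^2) / 2)
}

# Cartesian epipoles (right null vectors of F and F'); `infinite` flags
# epipoles numerically at infinity.
epipole_of <- function(Fm) {
  e <- svd(Fm)$v[, 3]
  inf <- abs(e[3]) < 1e-10 * sqrt(e[1]^2 + e[2]^2)
  list(h = e, cart = if (!inf) e[1:2] / e[3], infinite = inf)
}

#' Estimate epipolar geometry from correspondences
#'
#' Seeded RANSAC around the normalized 8-point algorithm. Inliers are
#' correspondences with symmetric epipolar distance at most `inlier_px`;
#' the final model is refit on all inliers and the rank-2 constraint is
#' enforced by singular-value truncation. Rectifying homographies (epipole
#' to infinity, affine correction from the inliers) are attached.
#'
#' @param matches A `correspondence_set` with at least 8 rows.
#' @param ransac_iters Number of RANSAC samples (default 500).
#' @param inlier_px Inlier threshold in pixels (default 1.0).
#' @param seed RANSAC seed (default 0); fixed seeds are bit-reproducible.
#' @return An `epipolar_model`: `fundamental` (Frobenius-normalized, rank 2),
#'   `inlier_mask`, `homographies` (list `H1`, `H2`), `matches`, `epipoles`.
#' @export
estimate_epipolar <- function(matches, ransac_iters = 500, inlier_px = 1.0,
                              seed = 0L) {
  stopifnot(inherits(matches, "correspondence_set") || is.data.frame(matches))
  n <- nrow(matches)
  if (n < 8) reconstruction_failure("need at least 8 correspondences")
  x1 <- matches$x1; y1 <- matches$y1; x2 <- matches$x2; y2 <- matches$y2

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  best_F <- NULL; best_in <- logical(n); best_n <- 0L
  for (it in seq_len(ransac_iters)) {
    idx <- if (n == 8) 1:8 else sample.int(n, 8L)
    Fm <- eight_point(x1[idx], y1[idx], x2[idx], y2[idx])
    if (is.null(Fm)) next
    d <- sym_epipolar_dist(Fm, x1, y1, x2, y2)
    inl <- d <= inlier_px
    if (sum(inl) > best_n) {
      best_n <- sum(inl); best_in <- inl; best_F <- Fm
    }
    if (n == 8) break
  }
  if (is.null(best_F) || best_n < 8) {
    reconstruction_failure(sprintf(
      "epipolar geometry could not be reconstructed (%d inliers, need 8; degenerate or structureless correspondences)",
      best_n))
  }
  Fm <- eight_point(x1[best_in], y1[best_in], x2[best_in], y2[best_in])
  if (is.null(Fm)) {
    reconstruction_failure("inlier set is degenerate (e.g. collinear points)")
  }
  inl <- sym_epipolar_dist(Fm, x1, y1, x2, y2) <= inlier_px
  e1 <- epipole_of(Fm)          # epipole in image 1 (F e1 = 0)
  e2 <- epipole_of(t(Fm))       # epipole in image 2 (F' e2 = 0)
  H <- rectifying_homographies(Fm, e2, x1[inl], y1[inl], x2[inl], y2[inl])
  structure(
    list(fundamental = Fm, inlier_mask = inl, homographies = H,
         matches = tibble::as_tibble(matches), epipoles = list(e1 = e1, e2 = e2),
         inlier_px = inlier_px, seed = as.integer(seed)),
    class = "epipolar_model"
  )
}

# Hartley-style rectification: translate the inlier centroid to the origin,
# rotate the second epipole onto the x axis, map it to infinity, then find
# the matching transform for the first image plus an affine correction that
# minimizes the horizontal discrepancy over inliers.
rectifying_homographies <- function(Fm, e2, x1, y1, x2, y2) {
  cx <- mean(x2); cy <- mean(y2)
  T <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3, 3)
  Tb <- matrix(c(1, 0, 0, 0, 1, 0, cx, cy, 1), 3, 3)
  if (e2$infinite) {
    theta <- atan2(e2$h[2], e2$h[1])
  } else {
    et <- c(e2$cart[1] - cx, e2$cart[2] - cy)
    theta <- atan2(et[2], et[1])
  }
  # wrap to (-pi/2, pi/2]: aligning with the negative x axis avoids flips
  if (theta > pi / 2) theta <- theta - pi
  if (theta <= -pi / 2) theta <- theta + pi
  R <- rot2(-theta)
  if (e2$infinite) {
    G <- diag(3)
  } else {
    er <- R %*% matrix(c(e2$cart[1] - cx, e2$cart[2] - cy, 1), 3, 1)
    ef <- er[1] / er[3]
    G <- diag(3); G[3, 1] <- -1 / ef
  }
  H2 <- Tb %*% G %*% R %*% T
  # matching transform for image 1: H0 = H2 * M with M a homography
  # compatible with F (M = [e2]x F + e2 a')
  e2h <- e2$h / sqrt(sum(e2$h^2))
  M <- skew3(e2h) %*% Fm + e2h %*% t(c(1, 1, 1))
  H0 <- H2 %*% M
  p1 <- hom_apply(H0, x1, y1)
  p2 <- hom_apply(H2, x2, y2)
  # affine x-correction: minimize sum (a x + b y + c - x2')^2
  X <- cbind(p1$x, p1$y, 1)
  ab <- tryCatch(solve(crossprod(X), crossprod(X, p2$x)),
                 error = function(e) c(1, 0, 0))
  Ha <- matrix(c(ab[1], 0, 0, ab[2], 1, 0, ab[3], 0, 1), 3, 3)
  H1 <- Ha %*% H0
  norm_h <- function(H) if (abs(H[3, 3]) > 1e-12) H / H[3, 3] else H / sqrt(sum(H^2))
  list(H1 = norm_h(H1), H2 = norm_h(H2))
}

#' Median vertical disparity of inliers after rectification
#'
#' Quality metric of the rectification stage: applies the model's
#' homographies to each inlier correspondence and reports the median
#' absolute difference of the transformed y coordinates.
#'
#' @param matches A `correspondence_set`.
#' @param model An `epipolar_model` with homographies.
#' @return Median |y1' - y2'| in pixels.
#' @export
vertical_disparity_residual <- function(matches, model) {
  stopifnot(inherits(model, "epipolar_model"))
  inl <- model$inlier_mask
  if (length(inl) != nrow(matches)) inl <- rep(TRUE, nrow(matches))
  if (!any(inl)) sp_validation_error("no inlier correspondences")
  m <- matches[inl, ]
  p1 <- hom_apply(model$homographies$H1, m$x1, m$y1)
  p2 <- hom_apply(model$homographies$H2, m$x2, m$y2)
  median(abs(p1$y - p2$y))
}

#' Rectify a stereo pair
#'
#' Warps both images by the model's rectifying homographies with bilinear
#' resampling; pixels mapping outside the source frame are black and flagged
#' in the `valid` attribute of each output. Raises a rectification failure
#' when an epipole lies inside an image frame (projective rectification
#' would tear the image) or when the post-warp vertical residual of the
#' inliers exceeds `max_residual`.
#'
#' @param I1,I2 The [rgb_image()] pair.
#' @param model An `epipolar_model` from [estimate_epipolar()].
#' @param max_residual Largest acceptable median vertical inlier disparity
#'   after warping, pixels (default 2).
#' @return List with rectified `left`, `right` ([rgb_image()]s carrying a
#'   `valid` mask attribute) and the achieved `residual`.
#' @export
rectify_pair <- function(I1, I2, model, max_residual = 2) {
  stopifnot(inherits(I1, "rgb_image"), inherits(I2, "rgb_image"),
            inherits(model, "epipolar_model"))
  for (ep in list(list(e = model$epipoles$e1, img = I1),
                  list(e = model$epipoles$e2, img = I2))) {
    if (!ep$e$infinite) {
      c0 <- ep$e$cart
      if (c0[1] >= 0 && c0[1] <= ep$img$width - 1 &&
          c0[2] >= 0 && c0[2] <= ep$img$height - 1) {
        rectification_failure("epipole lies inside the image frame")
      }
    }
  }
  res <- vertical_disparity_residual(model$matches, model)
  if (res > max_residual) {
    rectification_failure(sprintf(
      "post-rectification vertical residual %.2f px exceeds %.2f px", res,
      max_residual))
  }
  list(left = warp_image(I1, model$homographies$H1),
       right = warp_image(I2, model$homographies$H2),
       residual = res)
}

# Inverse-map bilinear warp; out-of-frame pixels black with valid = FALSE.
warp_image <- function(img, H) {
  h <- img$height; w <- img$width
  Hi <- solve(H)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  src <- hom_apply(Hi, xs, ys)
  row <- src$y + 1; col <- src$x + 1
  valid <- matrix(row >= 1 & row <= h & col >= 1 & col <= w, h, w)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(bilinear_sample(img$pixels[, , ch], row, col, fill = 0),
                         h, w)
  }
  out <- rgb_image(px)
  attr(out, "valid") <- valid
  out
}
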