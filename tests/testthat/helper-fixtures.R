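# Test helpers: small deterministic images, cost volumes and scenes.

# Random textured image with intensities in [0, 255].
random_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

# Smoothly textured image (band-limited), so feature matching has structure.
textured_image <- function(h = 64, w = 64, seed = 1, amplitude = 100) {
  set.seed(seed)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    n <- stereophyte:::gaussian_blur(matrix(rnorm(h * w), h, w), 1.2)
    n <- n / max(abs(n))
    px[, , ch] <- 128 + amplitude * n
  }
  rgb_image(stereophyte:::clamp(px, 0, 255))
}

# Cost volume with arbitrary entries (bypasses image construction).
raw_cost_volume <- function(rho, geom = NULL) {
  if (is.null(geom)) {
    geom <- camera_geometry(100, 0.1, dim(rho)[3] - 1, dim(rho)[3])
  }
  structure(list(rho = rho, geom = geom, out_of_range_cost = 255),
            class = "cost_volume")
}

# Integer-valued costs give a meaningful "unique minimizer" notion: distinct
# costs differ by at least 1, exact ties are excluded by wta_unique().
random_cost_volume <- function(h = 16, w = 16, G = 8, seed = 1, max_cost = 50,
                               integer = FALSE) {
  set.seed(seed)
  v <- runif(h * w * G, 0, max_cost)
  if (integer) v <- round(v)
  raw_cost_volume(array(v, dim = c(h, w, G)))
}

# Identity anisotropy tensor (constant image).
identity_tensor <- function(h, w) {
  structure(list(d11 = matrix(1, h, w), d12 = matrix(0, h, w),
                 d22 = matrix(1, h, w), alpha = 0, beta = 1),
            class = "anisotropy_tensor")
}

# Per-pixel exhaustive disparity search (independent of the solver path):
# argmin of the cost over levels 0..G-2, ties to the smallest level.
wta_oracle <- function(rho) {
  d <- dim(rho$rho)
  sel <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      costs <- rho$rho[i, j, seq_len(d[3] - 1)]
      sel[i, j] <- which.min(costs) - 1L
    }
  }
  sel
}

# Whether each pixel's restricted cost minimizer is unique (up to tol).
wta_unique <- function(rho, tol = 1e-9) {
  d <- dim(rho$rho)
  out <- matrix(TRUE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      costs <- sort(rho$rho[i, j, seq_len(d[3] - 1)])
      if (d[3] > 2 && costs[2] - costs[1] < tol) out[i, j] <- FALSE
    }
  }
  out
}

# Independently coded classification hierarchy (per-pixel if/else).
hierarchy_oracle <- function(fd, fc, fg) {
  out <- matrix(0L, nrow(fd), ncol(fd))
  for (i in seq_len(nrow(fd))) {
    for (j in seq_len(ncol(fd))) {
      out[i, j] <- if (fd[i, j] > 0) 0L
        else if (fg[i, j] > 0) 3L
        else if (fc[i, j] > 0) 1L
        else 2L
    }
  }
  out
}

# Correspondences synthesized from a known two-camera geometry.
# Returns the true fundamental matrix and projected point pairs.
two_view_correspondences <- function(n = 60, seed = 1, outlier_frac = 0,
                                     noise = 0) {
  set.seed(seed)
  f <- 300; cx <- 64; cy <- 48
  K <- matrix(c(f, 0, 0, 0, f, 0, cx, cy, 1), 3, 3)
  ang <- 0.05
  R <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  t <- c(0.3, 0.05, 0.02)
  X <- rbind(runif(n, -2, 2), runif(n, -1.5, 1.5), runif(n, 4, 9))
  p1 <- K %*% X
  p2 <- K %*% (R %*% X + t)
  x1 <- p1[1, ] / p1[3, ]; y1 <- p1[2, ] / p1[3, ]
  x2 <- p2[1, ] / p2[3, ]; y2 <- p2[2, ] / p2[3, ]
  if (noise > 0) {
    x1 <- x1 + rnorm(n, 0, noise); y1 <- y1 + rnorm(n, 0, noise)
    x2 <- x2 + rnorm(n, 0, noise); y2 <- y2 + rnorm(n, 0, noise)
  }
  is_outlier <- rep(FALSE, n)
  if (outlier_frac > 0) {
    k <- floor(outlier_frac * n)
    idx <- sample.int(n, k)
    x2[idx] <- x2[idx] + runif(k, 20, 80) * sample(c(-1, 1), k, TRUE)
    y2[idx] <- y2[idx] + runif(k, 20, 80) * sample(c(-1, 1), k, TRUE)
    is_outlier[idx] <- TRUE
  }
  Ki <- solve(K)
  tx <- matrix(c(0, t[3], -t[2], -t[3], 0, t[1], t[2], -t[1], 0), 3, 3)
  F_true <- t(Ki) %*% tx %*% R %*% Ki
  F_true <- F_true / sqrt(sum(F_true^2))
  m <- tibble::tibble(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                      score = rep(1, n))
  class(m) <- c("correspondence_set", class(tibble::tibble()))
  list(matches = m, F_true = F_true, is_outlier = is_outlier)
}

# Angular distance between two fundamental matrices viewed as 9-vectors
# (scale and sign invariant).
fmat_angle <- function(A, B) {
  a <- as.vector(A) / sqrt(sum(A^2))
  b <- as.vector(B) / sqrt(sum(B^2))
  acos(pmin(1, abs(sum(a * b))))
}
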