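# Discrete differential operators. Forward differences with Neumann boundary
# (last difference zero) and their exact adjoints; central differences for
# gradient-direction estimates; a separable Gaussian blur for the corner
# detector. Row index = y (downward), column index = x (rightward).

# Forward difference along columns (x direction); zero at the last column.
fdiff_x <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  if (ncol(m) > 1) out[, -ncol(m)] <- m[, -1] - m[, -ncol(m)]
  out
}

# Forward difference along rows (y direction); zero at the last row.
fdiff_y <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  if (nrow(m) > 1) out[-nrow(m), ] <- m[-1, ] - m[-nrow(m), ]
  out
}

# Adjoints: <fdiff_x(a), b> == <a, fdiff_x_adj(b)> with b's last column
# ignored (the operator maps into fields whose last column is zero).
fdiff_x_adj <- function(b) {
  n <- ncol(b)
  out <- matrix(0, nrow(b), n)
  if (n > 1) {
    out[, 1] <- -b[, 1]
    if (n > 2) out[, 2:(n - 1)] <- b[, 1:(n - 2)] - b[, 2:(n - 1)]
    out[, n] <- b[, n - 1]
  }
  out
}

fdiff_y_adj <- function(b) {
  n <- nrow(b)
  out <- matrix(0, n, ncol(b))
  if (n > 1) {
    out[1, ] <- -b[1, ]
    if (n > 2) out[2:(n - 1), ] <- b[1:(n - 2), ] - b[2:(n - 1), ]
    out[n, ] <- b[n - 1, ]
  }
  out
}

# Central differences with replicated borders (symmetric under 90-degree
# rotation of the input, which the anisotropy tensor's equivariance relies
# on).
cdiff_x <- function(m) {
  w <- ncol(m)
  left <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  (right - left) / 2
}

cdiff_y <- function(m) {
  h <- nrow(m)
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  down <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  (down - up) / 2
}

# Grayscale as the channel mean, on the 0..255 scale.
to_gray <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
}

# Separable Gaussian blur with replicated borders.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], r), v, rep(v[n], r))
    out <- numeric(n)
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1)]
    }
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# Bilinear sampling of a matrix at fractional (row, col) positions, with
# replicated borders inside the domain. Out-of-domain samples return `fill`.
bilinear_sample <- function(m, row, col, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  ok <- row >= 1 & row <= h & col >= 1 & col <= w
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  r0c <- clamp(r0, 1, h); c0c <- clamp(c0, 1, w)
  r1 <- clamp(r0c + 1, 1, h); c1 <- clamp(c0c + 1, 1, w)
  i00 <- (c0c - 1) * h + r0c
  i10 <- (c0c - 1) * h + r1
  i01 <- (c1 - 1) * h + r0c
  i11 <- (c1 - 1) * h + r1
  val <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i10] +
    (1 - fr) * fc * m[i01] + fr * fc * m[i11]
  val[!ok] <- fill
  val
}
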