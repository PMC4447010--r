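# Depth + color segmentation.

const_image <- function(r, g, b, h = 8, w = 8) {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  rgb_image(px)
}

test_that("classifier fields implement their closed forms", {
  d <- depth_map(matrix(5, 8, 8))
  expect_equal(depth_score(d, 3)$values[1, 1], 2)    # positive: background
  expect_equal(depth_score(d, 5)$values[1, 1], 0)    # boundary

  dm <- matrix(5, 8, 8); mask <- matrix(TRUE, 8, 8); mask[2, 2] <- FALSE
  fs <- depth_score(depth_map(dm, mask), 3)
  expect_gte(fs$values[2, 2], 1e5)                   # invalid pixel: background

  expect_equal(color_score(const_image(50, 150, 60), 20)$values[1, 1], 70)
  expect_equal(color_score(const_image(120, 80, 60), 20)$values[1, 1], 0)

  expect_equal(grape_score(const_image(150, 60, 70), 20)$values[1, 1], 70)
  expect_equal(grape_score(const_image(50, 150, 60), 20)$values[1, 1], -110)
  expect_equal(grape_score(const_image(100, 100, 100), 20)$values[1, 1], -20)
})

test_that("assembled costs reproduce the classification hierarchy", {
  h <- 1; w <- 1
  mkf <- function(v, kind) scalar_field(matrix(v, 4, 4), kind)

  # far pixel: background has the strictly largest score whatever the colors
  lc <- assemble_costs(mkf(2, "depth_score"), mkf(70, "color_score"),
                       mkf(50, "grape_score"))
  expect_true(all(c(lc$costs[, , 1]) < apply(lc$costs[, , 2:4], c(1, 2), min) - 1e-12))

  # near green pixel: leaf wins
  lc <- assemble_costs(mkf(-3, "depth_score"), mkf(70, "color_score"),
                       mkf(-110, "grape_score"))
  flat <- matrix(lc$costs, 16, 4)
  expect_true(all(max.col(-flat, "first") == 2))

  # rule-table oracle over a grid of field values, including exact
  # boundaries (resolved by the hierarchy's strict tests)
  vals <- c(-30, -5, 0, 5, 30)
  grid <- expand.grid(fd = vals, fc = vals, fg = vals)
  n <- nrow(grid)
  side <- ceiling(sqrt(n))
  pad <- side * side - n
  fd <- matrix(c(grid$fd, rep(100, pad)), side, side)
  fc <- matrix(c(grid$fc, rep(0, pad)), side, side)
  fg <- matrix(c(grid$fg, rep(0, pad)), side, side)
  lc <- assemble_costs(scalar_field(fd, "depth_score"),
                       scalar_field(fc, "color_score"),
                       scalar_field(fg, "grape_score"))
  img <- rgb_image(array(100, dim = c(side, side, 3)))
  seg <- segment_labels(lc, img, nu = 0)
  expect_identical(seg$labels, hierarchy_oracle(fd, fc, fg))
})

test_that("nu = 0 equals the pointwise cost argmin where it is unique", {
  set.seed(10)
  h <- 12; w <- 12
  costs <- array(runif(h * w * 4, -50, 50), dim = c(h, w, 4))
  lc <- structure(list(costs = costs), class = "label_costs")  # no fields
  img <- random_image(h, w, seed = 2)
  seg <- segment_labels(lc, img, nu = 0)
  flat <- matrix(costs, h * w, 4)
  oracle <- max.col(-flat, "first") - 1L
  expect_identical(as.vector(seg$labels), oracle)
  # pixel-count conservation: labels partition the domain
  expect_equal(sum(table(seg$labels)), h * w)
})

test_that("equal costs everywhere give all-background by the tie rule", {
  lc <- structure(list(costs = array(1, dim = c(8, 8, 4))),
                  class = "label_costs")
  seg <- segment_labels(lc, const_image(10, 10, 10), nu = 0)
  expect_true(all(seg$labels == 0L))
})

test_that("Potts regularization preserves a clean two-region scene and
           removes isolated label noise", {
  h <- 24; w <- 24
  # green disk (near) on a distant background
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- 60; px[, , 2] <- 70; px[, , 3] <- 80      # bluish background
  truth <- matrix(0L, h, w)
  for (i in 1:h) for (j in 1:w) {
    if ((i - 12)^2 + (j - 12)^2 <= 64) {
      truth[i, j] <- 1L
      px[i, j, ] <- c(40, 150, 40)
    }
  }
  img <- rgb_image(px)
  dvals <- matrix(10, h, w); dvals[truth == 1L] <- 2
  d <- depth_map(dvals)
  cfg <- segmentation_config(c_depth = 5, nu = 0.5)
  seg <- segment_image(img, d, cfg)
  expect_gte(mean(seg$labels == truth), 0.99)

  # single-pixel cost noise: flip one interior disk pixel's evidence weakly
  # toward stem; nu = 0 keeps the speck, nu > 0 removes it
  fd <- depth_score(d, 5)
  fc <- color_score(img, 20)
  fg <- grape_score(img, 20)
  fc$values[12, 12] <- -0.4          # weak anti-vegetation evidence
  lc <- assemble_costs(fd, fc, fg)
  seg0 <- segment_labels(lc, img, nu = 0)
  seg1 <- segment_labels(lc, img, nu = 0.5)
  expect_identical(seg0$labels[12, 12], sp_labels[["stem"]])
  expect_identical(seg1$labels[12, 12], sp_labels[["leaf"]])
})

test_that("stronger regularization never increases boundary length", {
  boundary_len <- function(u) {
    sum(u$labels[, -1] != u$labels[, -ncol(u$labels)]) +
      sum(u$labels[-1, ] != u$labels[-nrow(u$labels), ])
  }
  for (seed in 1:5) {
    sc <- build_scene(width = 32, height = 32, seed = seed, n_leaves = 2,
                      gamma_max = 12, levels = 13)
    r <- render_stereo(sc)
    d <- depth_map(matrix(vapply(seq_along(r$labels$labels), function(i) 0,
                                 numeric(1)), 32, 32) +
                     ifelse(r$labels$labels == 0L, 10, 3))
    lens <- vapply(c(0, 0.5, 2), function(nu) {
      seg <- segment_image(r$left, d, segmentation_config(c_depth = 6, nu = nu))
      boundary_len(seg)
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})
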