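# Feature matching, epipolar estimation, rectification.

test_that("self-matching and known shifts are recovered by detect_and_match", {
  I1 <- textured_image(64, 64, seed = 2)
  m <- detect_and_match(I1, I1)
  disp <- sqrt((m$x1 - m$x2)^2 + (m$y1 - m$y2)^2)
  expect_gte(mean(disp == 0), 0.95)

  # 5 px right translation
  px <- I1$pixels
  px2 <- px
  px2[, 6:64, ] <- px[, 1:59, ]
  I2 <- rgb_image(px2)
  m <- detect_and_match(I1, I2)
  expect_lt(abs(median(m$x2 - m$x1) - 5), 0.5)
  expect_lt(abs(median(m$y2 - m$y1)), 0.5)

  # structureless images cannot be matched
  flat <- rgb_image(array(128, dim = c(64, 64, 3)))
  expect_error(detect_and_match(flat, flat),
               class = "stereophyte_insufficient_matches")
  expect_error(detect_and_match(random_image(16, 16), random_image(16, 16)),
               class = "stereophyte_validation_error")
})

test_that("epipolar geometry is recovered from exact correspondences", {
  tv <- two_view_correspondences(n = 60, seed = 1)
  model <- estimate_epipolar(tv$matches, seed = 0)
  expect_lt(fmat_angle(model$fundamental, tv$F_true), 1e-6)
  expect_true(all(model$inlier_mask))
  # rank-2 with unit Frobenius norm
  sv <- svd(model$fundamental)$d
  expect_lt(sv[3], 1e-8 * sv[1])
  expect_equal(sum(model$fundamental^2), 1)
})

test_that("RANSAC rejects 30% gross outliers and is seed-reproducible", {
  tv <- two_view_correspondences(n = 80, seed = 3, outlier_frac = 0.3)
  model <- estimate_epipolar(tv$matches, seed = 0)
  expect_lt(fmat_angle(model$fundamental, tv$F_true), 1e-4)
  expect_true(all(!model$inlier_mask[tv$is_outlier]))
  expect_true(all(model$inlier_mask[!tv$is_outlier]))

  model2 <- estimate_epipolar(tv$matches, seed = 0)
  expect_identical(model$fundamental, model2$fundamental)

  # true inliers satisfy the recovered model within the threshold
  d <- stereophyte:::sym_epipolar_dist(model$fundamental,
                                       tv$matches$x1, tv$matches$y1,
                                       tv$matches$x2, tv$matches$y2)
  expect_true(all(d[!tv$is_outlier] <= 1.0))
})

test_that("degenerate configurations raise a reconstruction failure", {
  # 8 collinear matches
  x <- seq(0, 70, by = 10)
  m <- tibble::tibble(x1 = x, y1 = 2 * x + 1, x2 = x + 3, y2 = 2 * x + 1,
                      score = 1)
  class(m) <- c("correspondence_set", class(tibble::tibble()))
  expect_error(estimate_epipolar(m, seed = 0),
               class = "stereophyte_reconstruction_failure")
  expect_error(estimate_epipolar(m[1:4, ], seed = 0),
               class = "stereophyte_reconstruction_failure")
})

test_that("an already rectified pair yields near-identity homographies", {
  # purely horizontal displacements: epipole at infinity along x
  set.seed(8)
  n <- 40
  x1 <- runif(n, 5, 90); y1 <- runif(n, 5, 70)
  disp <- runif(n, 4, 9)
  m <- tibble::tibble(x1 = x1, y1 = y1, x2 = x1 + disp, y2 = y1, score = 1)
  class(m) <- c("correspondence_set", class(tibble::tibble()))
  model <- estimate_epipolar(m, seed = 0)
  expect_lt(max(abs(model$homographies$H2 - diag(3))), 1e-3)
  expect_lt(vertical_disparity_residual(m, model), 1e-6)

  # a constructed residual vertical shift of 2 px is reported as 2
  m2 <- m
  m2$y2 <- m2$y2 + 2
  shifted <- model
  shifted$inlier_mask <- rep(TRUE, n)
  expect_lt(abs(vertical_disparity_residual(m2, shifted) - 2), 0.1)

  # single inlier: exactly that pair's residual
  one <- model
  one$inlier_mask <- c(TRUE, rep(FALSE, n - 1))
  expect_equal(vertical_disparity_residual(m2, one), 2)
})

test_that("rectification drives vertical disparities of a warped pair to zero", {
  tv <- two_view_correspondences(n = 80, seed = 5, noise = 0.05)
  model <- estimate_epipolar(tv$matches, seed = 0)
  res <- vertical_disparity_residual(tv$matches, model)
  expect_lte(res, 0.5)
  m <- tv$matches[model$inlier_mask, ]
  p1 <- stereophyte:::hom_apply(model$homographies$H1, m$x1, m$y1)
  p2 <- stereophyte:::hom_apply(model$homographies$H2, m$x2, m$y2)
  expect_gte(mean(abs(p1$y - p2$y) <= 0.5), 0.9)
})

test_that("rectify_pair warps images and flags failure modes", {
  # render a synthetic pair, inject a small vertical misalignment, and
  # check the full match -> estimate -> warp path
  sc <- build_scene(width = 72, height = 72, seed = 4, n_leaves = 3,
                    noise_sigma = 0, gain_mismatch = 0)
  r <- render_stereo(sc)
  px <- r$right$pixels
  shifted <- px
  shifted[2:72, , ] <- px[1:71, , ]    # 1 px vertical shift
  I2 <- rgb_image(shifted)
  m <- detect_and_match(r$left, I2)
  model <- estimate_epipolar(m, seed = 0)
  rect <- rectify_pair(r$left, I2, model)
  expect_s3_class(rect$left, "rgb_image")
  expect_lte(rect$residual, 0.5)
  # re-matching the rectified pair shows horizontal epipolar lines
  m2 <- detect_and_match(rect$left, rect$right)
  expect_lte(median(abs(m2$y1 - m2$y2)), 1)

  # forged matches from a 90-degree rotation never silently pass
  set.seed(2)
  n <- 30
  x1 <- runif(n, 10, 60); y1 <- runif(n, 10, 60)
  forged <- tibble::tibble(x1 = x1, y1 = y1, x2 = 71 - y1, y2 = x1, score = 1)
  class(forged) <- c("correspondence_set", class(tibble::tibble()))
  res <- tryCatch({
    mod <- estimate_epipolar(forged, seed = 0)
    rectify_pair(r$left, I2, mod)
    "silent pass"
  }, stereophyte_error = function(e) "raised")
  expect_identical(res, "raised")
})
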