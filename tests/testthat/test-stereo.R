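# Lifted stereo: cost volume, anisotropy tensor, solver, extraction, depth.

test_that("cost volume matches a pixel-by-pixel brute-force evaluation", {
  geom <- camera_geometry(100, 0.1, gamma_max = 2, levels = 3)  # integer levels
  set.seed(3)
  I1 <- random_image(8, 8, seed = 3)
  I2 <- random_image(8, 8, seed = 4)
  cv <- compute_cost_volume(I1, I2, geom)

  # independent brute force over integer shifts
  for (j in 1:3) {
    g <- j - 1
    for (x in 1:8) {
      for (y in c(1, 5, 8)) {
        expected <- if (x + g > 8) 255 else
          mean(abs(I1$pixels[y, x, ] - I2$pixels[y, x + g, ]))
        expect_equal(cv$rho[y, x, j], expected)
      }
    }
  }

  # identical images have zero cost at disparity 0
  cv0 <- compute_cost_volume(I1, I1, geom)
  expect_true(all(cv0$rho[, , 1] == 0))

  expect_error(compute_cost_volume(I1, random_image(8, 9, 1), geom),
               class = "stereophyte_validation_error")
})

test_that("cost volume interpolates fractional disparity levels linearly", {
  # gamma levels 0, 0.5, 1 -> middle level is the average of the neighbors
  geom <- camera_geometry(100, 0.1, gamma_max = 1, levels = 3)
  I1 <- random_image(8, 8, seed = 5)
  I2 <- random_image(8, 8, seed = 6)
  cv <- compute_cost_volume(I1, I2, geom)
  x <- 3; y <- 2
  interp <- (I2$pixels[y, x, ] + I2$pixels[y, x + 1, ]) / 2
  expect_equal(cv$rho[y, x, 2], mean(abs(I1$pixels[y, x, ] - interp)))
})

test_that("anisotropy tensor is identity on flat images, damped across edges,
           and equivariant under rotation", {
  flat <- rgb_image(array(80, dim = c(10, 10, 3)))
  D <- compute_anisotropy(flat)
  expect_true(all(D$d11 == 1) && all(D$d22 == 1) && all(D$d12 == 0))

  # vertical step edge of height 100: at the edge column the central
  # difference is 100/2 = 50 and the across-edge eigenvalue exp(-5*50/255)
  px <- array(0, dim = c(10, 10, 3))
  px[, 6:10, ] <- 100
  edge <- rgb_image(px)
  D <- compute_anisotropy(edge, alpha = 5 / 255, beta = 1)
  expect_equal(D$d11[5, 5], exp(-5 * 50 / 255))   # n = (1,0): d11 = e
  expect_equal(D$d22[5, 5], 1)                     # along the edge untouched
  expect_equal(D$d12[5, 5], 0)

  # eigenvalues within (0, 1] everywhere on a random image
  img <- random_image(12, 12, seed = 9)
  D <- compute_anisotropy(img)
  tr <- D$d11 + D$d22
  det <- D$d11 * D$d22 - D$d12^2
  lam1 <- (tr + sqrt(pmax(tr^2 - 4 * det, 0))) / 2
  lam2 <- (tr - sqrt(pmax(tr^2 - 4 * det, 0))) / 2
  expect_true(all(lam1 <= 1 + 1e-12) && all(lam2 > 0))
  expect_equal(max(abs(D$d12 - D$d12)), 0)   # symmetric by construction

  # rotating the image by 90 degrees conjugates each tensor by the rotation
  rot90 <- function(m) t(m)[, nrow(m):1]     # clockwise
  px_r <- array(0, dim = c(12, 12, 3))
  for (ch in 1:3) px_r[, , ch] <- rot90(img$pixels[, , ch])
  Dr <- compute_anisotropy(rgb_image(px_r))
  # under (x,y) -> (-y,x): d11' = d22, d22' = d11, d12' = -d12 at the
  # rotated position
  expect_equal(Dr$d11, rot90(D$d22), tolerance = 1e-10)
  expect_equal(Dr$d22, rot90(D$d11), tolerance = 1e-10)
  expect_equal(Dr$d12, -rot90(D$d12), tolerance = 1e-10)
})

test_that("winner-takes-all initialization steps at the brute-force argmin", {
  # zero cost everywhere: tie-break to level 0, phi = (1, 0, ..., 0)
  cv <- raw_cost_volume(array(0, dim = c(4, 4, 5)))
  phi <- initialize_lifted(cv)
  expect_true(all(phi$phi[, , 1] == 1))
  expect_true(all(phi$phi[, , 2:5] == 0))

  # per-pixel costs (3, 1, 2, 4): step after level 1
  rho <- array(rep(c(3, 1, 2, 4), each = 16), dim = c(4, 4, 4))
  phi <- initialize_lifted(raw_cost_volume(rho))
  expect_true(all(phi$phi[, , 1] == 1) && all(phi$phi[, , 2] == 1))
  expect_true(all(phi$phi[, , 3] == 0) && all(phi$phi[, , 4] == 0))

  # random volumes match the brute-force argmin (last level excluded)
  for (seed in 1:3) {
    cv <- random_cost_volume(6, 7, 5, seed = seed)
    phi <- initialize_lifted(cv)
    geom <- camera_geometry(100, 0.1, 4, 5)
    v <- extract_disparity(phi, geom)
    expect_equal(v$values, wta_oracle(cv) + 0)
  }
})

test_that("disparity extraction integrates phi with sub-level precision", {
  geom <- camera_geometry(100, 0.1, 4, 5)   # delta_gamma = 1
  mk <- function(vals) {
    phi <- array(0, dim = c(1, 1, 5))
    phi[1, 1, ] <- vals
    # embed in an 2x2 field to use the container
    big <- array(rep(vals, each = 4), dim = c(2, 2, 5))
    lifted_field(big)
  }
  expect_equal(extract_disparity(mk(c(1, 1, 1, 0, 0)), geom)$values[1, 1], 2)
  expect_equal(extract_disparity(mk(c(1, 0, 0, 0, 0)), geom)$values[1, 1], 0)
  expect_equal(extract_disparity(mk(c(1, 0.5, 0, 0, 0)), geom)$values[1, 1], 0.5)

  # violated boundary constraints are rejected
  bad <- array(0.5, dim = c(2, 2, 5))
  expect_error(lifted_field(bad), class = "stereophyte_validation_error")
})

test_that("primal energy agrees with brute force and scale invariance holds", {
  # rho = 0 and spatially constant phi: zero energy
  cv <- raw_cost_volume(array(0, dim = c(4, 4, 4)))
  phi <- initialize_lifted(cv)
  D <- identity_tensor(4, 4)
  expect_equal(primal_energy(phi, cv, D, 0.5), 0)

  # lambda = 0, binary step at the argmin: energy equals the summed minima
  cv <- random_cost_volume(4, 4, 5, seed = 11)
  phi <- initialize_lifted(cv)
  D <- identity_tensor(4, 4)
  brute <- 0
  for (i in 1:4) for (j in 1:4) {
    brute <- brute + min(cv$rho[i, j, 1:4])
  }
  expect_equal(primal_energy(phi, cv, D, 0), brute)

  # scale property: multiplying rho and lambda by the same constant scales
  # the energy and leaves the extracted minimizer unchanged
  cfg <- solver_config(lambda_smooth = 0.2, iterations = 60)
  geom <- camera_geometry(100, 0.1, 4, 5)
  out1 <- solve_lifted(cv, D, cfg)
  cv2 <- raw_cost_volume(cv$rho * 3)
  cfg2 <- solver_config(lambda_smooth = 0.6, iterations = 60)
  out2 <- solve_lifted(cv2, D, cfg2)
  v1 <- extract_disparity(out1, geom)$values
  v2 <- extract_disparity(out2, geom)$values
  expect_lt(max(abs(v1 - v2)), 0.05)
})

test_that("solver with lambda = 0 converges to the exhaustive per-pixel search", {
  geom <- camera_geometry(100, 0.1, 7, 8)
  for (seed in 21:23) {
    cv <- random_cost_volume(8, 8, 8, seed = seed, integer = TRUE)
    cfg <- solver_config(lambda_smooth = 0, iterations = 400)
    D <- identity_tensor(8, 8)
    out <- solve_lifted(cv, D, cfg)
    v <- extract_disparity(out, geom)$values
    sel <- round(v / geom$delta_gamma)
    oracle <- wta_oracle(cv)
    uniq <- wta_unique(cv, tol = 0.5)
    expect_true(all(sel[uniq] == oracle[uniq]))
  }
})

test_that("solver decreases the primal energy and conserves the constraints", {
  geom <- camera_geometry(100, 0.1, 5, 6)
  img <- random_image(10, 10, seed = 31)
  D <- compute_anisotropy(img)
  for (seed in c(41, 42)) {
    cv <- random_cost_volume(10, 10, 6, seed = seed)
    cfg <- solver_config(lambda_smooth = 0.3, iterations = 150)
    out <- solve_lifted(cv, D, cfg)
    e0 <- primal_energy(initialize_lifted(cv), cv, D, 0.3)
    e1 <- primal_energy(out, cv, D, 0.3)
    expect_lte(e1, e0 + 1e-9)
    # constraints hold on the output (projected every iteration)
    G <- dim(out$phi)[3]
    expect_true(all(out$phi >= 0 & out$phi <= 1))
    expect_true(all(out$phi[, , 1] == 1) && all(out$phi[, , G] == 0))
  }
})

test_that("a noiseless constant-shift pair is recovered at the true disparity", {
  sc <- build_scene(width = 48, height = 48, n_leaves = 0, stem = 0,
                    n_grape_clusters = 0, background_depth = 7.5,
                    gamma_max = 8, levels = 9, noise_sigma = 0,
                    gain_mismatch = 0, seed = 2)
  r <- render_stereo(sc)   # true disparity f*b/7.5 = 4 everywhere
  expect_true(all(r$disparity$values == 4))
  cv <- compute_cost_volume(r$left, r$right, r$geom)
  D <- compute_anisotropy(r$left)
  out <- solve_lifted(cv, D, solver_config(lambda_smooth = 0.1,
                                           iterations = 250))
  v <- extract_disparity(out, r$geom)$values
  ok <- abs(v - 4) <= 0.5
  expect_gte(mean(ok[r$unoccluded]), 0.99)
})

test_that("depth conversion inverts algebraically and guards small disparities", {
  geom <- camera_geometry(1000, 0.08, 30, 31)
  v <- disparity_map(matrix(20, 4, 4), gamma_max = 30)
  d <- disparity_to_depth(v, geom)
  expect_equal(d$values[1, 1], 4.0)   # 1000 * 0.08 / 20

  vm <- matrix(c(0, 10, 20, 25), 2, 2)
  d <- disparity_to_depth(disparity_map(vm, gamma_max = 30), geom)
  expect_false(d$valid_mask[1, 1])    # v = 0 cannot be inverted
  back <- geom$focal_px * geom$baseline / d$values[d$valid_mask]
  expect_equal(back, vm[d$valid_mask])
})
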