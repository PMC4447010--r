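# Validation statistics vs. independent brute-force implementations.

test_that("confusion matrix matches a triple-loop counting oracle", {
  # identity case
  set.seed(1)
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  u <- label_map(lab)
  cm <- confusion_matrix(u, u)
  expect_equal(unname(diag(cm)), rep(100, 3))
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))

  # truth all leaf, prediction all stem
  cm <- confusion_matrix(label_map(matrix(2L, 8, 8)),
                         label_map(matrix(1L, 8, 8)))
  expect_equal(unname(cm["leaf", ]), c(0, 0, 100))
  expect_true(all(is.na(cm["background", ])))   # empty truth row undefined

  # random maps vs. independent triple loop
  for (seed in 1:5) {
    set.seed(seed)
    pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
    truth <- matrix(sample(0:2, 64, TRUE), 8, 8)
    cm <- confusion_matrix(label_map(pred), label_map(truth))
    for (i in 0:2) for (j in 0:2) {
      n_ij <- 0; n_i <- 0
      for (k in seq_along(pred)) {
        if (truth[k] == i) {
          n_i <- n_i + 1
          if (pred[k] == j) n_ij <- n_ij + 1
        }
      }
      expect_equal(cm[i + 1, j + 1], 100 * n_ij / n_i)
    }
    # conservation: row counts sum to the class's ground-truth pixel count
    counts <- attr(cm, "counts")
    expect_equal(unname(rowSums(counts)),
                 unname(vapply(0:2, function(l) sum(truth == l), numeric(1))))
  }
})

test_that("regression recovers exact linear relations and matches normal
           equations", {
  x <- c(1, 5, 9, 13, 20)
  r <- area_regression(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)

  r <- area_regression(x, 2 * x + 5)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 5)
  expect_equal(r$r_squared, 1)

  # 22 random pairs vs. hand-coded normal equations
  set.seed(4)
  px <- runif(22, 0, 100); ty <- 0.9 * px + rnorm(22, 0, 3)
  r <- area_regression(px, ty)
  X <- cbind(1, px)
  beta <- solve(t(X) %*% X, t(X) %*% ty)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  rho <- sum((px - mean(px)) * (ty - mean(ty))) /
    sqrt(sum((px - mean(px))^2) * sum((ty - mean(ty))^2))
  expect_equal(r$r_squared, rho^2, tolerance = 1e-10)

  # invariance: shifting both variables moves only the intercept
  r2 <- area_regression(px + 7, ty + 7)
  expect_equal(r2$slope, r$slope, tolerance = 1e-9)
  expect_equal(r2$r_squared, r$r_squared, tolerance = 1e-9)
  expect_equal(r2$intercept, r$intercept + 7 * (1 - r$slope), tolerance = 1e-8)

  expect_error(area_regression(rep(3, 5), 1:5),
               class = "stereophyte_degenerate_regression")
  expect_error(area_regression(1:2, 1:2),
               class = "stereophyte_validation_error")

  # tidiers
  expect_equal(tidy(r)$estimate, c(r$intercept, r$slope))
  expect_equal(glance(r)$r_squared, r$r_squared)
})

test_that("rmse and residual-bound fractions match direct counting", {
  r <- rmse_residuals(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$rmse, 0)
  expect_true(all(r$within_fractions$fraction == 1))

  # residuals {3, 4}: forced arithmetic
  r <- rmse_residuals(c(10, 10), c(13, 6))
  expect_equal(r$rmse, sqrt(12.5))
  expect_equal(r$residual_mean, 3.5)

  # 100 random pairs vs. a direct count, at the standard bounds
  set.seed(9)
  p <- runif(100, 0, 100); t <- p + rnorm(100, 0, 4)
  r <- rmse_residuals(p, t, bounds = c(2.5, 3.9, 7.7))
  res <- abs(p - t); m <- mean(res)
  for (k in 1:3) {
    b <- c(2.5, 3.9, 7.7)[k]
    expect_equal(r$within_fractions$fraction[k],
                 sum(res >= m - b & res <= m + b) / 100, tolerance = 1e-12)
  }
  # root-mean-square dominates the mean for non-negative residuals
  expect_gte(r$rmse, r$residual_mean - 1e-12)
})

test_that("validation_report pools images and summarises cleanly", {
  set.seed(11)
  preds <- truths <- list()
  for (i in 1:5) {
    truth <- matrix(sample(0:2, 100, TRUE, prob = c(0.5, 0.35, 0.15)), 10, 10)
    pred <- truth
    flip <- sample(100, 12)
    pred[flip] <- (pred[flip] + 1L) %% 3L
    preds[[i]] <- label_map(pred)
    truths[[i]] <- label_map(truth)
  }
  rep <- validation_report(preds, truths)
  expect_equal(unname(rowSums(rep$confusion)), rep(100, 3), tolerance = 1e-6)
  expect_true(rep$regression$r_squared >= 0 && rep$regression$r_squared <= 1)
  g <- glance(rep)
  expect_equal(g$rmse, rep$rmse)
  td <- tidy(rep)
  expect_equal(nrow(td), 9)
})
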