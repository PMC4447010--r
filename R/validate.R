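# Evaluation machinery: confusion matrices against manually labelled ground
# truth, predicted-vs-true leaf-area regression, RMSE and residual-bound
# summaries.

#' Confusion matrix of a predicted against a true label map
#'
#' Rows are actual (ground-truth) classes, columns predicted classes; each
#' row is normalized to percentages of that class's ground-truth pixel
#' count. Pixels whose truth or prediction lies outside `classes` are
#' excluded. A truth class with zero pixels yields an all-NA row (undefined,
#' not zero). Raw counts are attached as attribute `counts`.
#'
#' @param pred,truth [label_map()]s of identical size.
#' @param classes Label codes to evaluate; default `c(0, 1, 2)` (background,
#'   leaf, stem — grapes are excluded from the 3-class evaluation).
#' @return `length(classes)` square matrix of row percentages with class
#'   names as dimnames.
#' @export
confusion_matrix <- function(pred, truth, classes = c(0L, 1L, 2L)) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    sp_validation_error("prediction and truth dimensions disagree")
  }
  classes <- as.integer(classes)
  if (!all(classes %in% sp_labels)) {
    sp_validation_error("requested classes outside the label set")
  }
  keep <- pred$labels %in% classes & truth$labels %in% classes
  t_f <- factor(truth$labels[keep], levels = classes)
  p_f <- factor(pred$labels[keep], levels = classes)
  counts <- table(truth = t_f, predicted = p_f)
  cn <- names(sp_labels)[match(classes, sp_labels)]
  dimnames(counts) <- list(truth = cn, predicted = cn)
  rs <- rowSums(counts)
  perc <- 100 * sweep(unclass(counts), 1, pmax(rs, 1), "/")
  perc[rs == 0, ] <- NA_real_
  structure(perc, counts = unclass(counts))
}

#' Leaf-area regression of ground truth on prediction
#'
#' Ordinary least squares with the computed (predicted) leaf areas as x and
#' the ground-truth areas as y, so the fitted line predicts the true leaf
#' area from a segmentation result; the reversed orientation is available
#' via `orientation`. R^2 is the squared Pearson correlation.
#'
#' @param predicted,truth Equal-length numeric vectors (>= 3 values).
#' @param orientation `"truth_on_predicted"` (default) or
#'   `"predicted_on_truth"`.
#' @return Object of class `area_regression` with elements `slope`,
#'   `intercept`, `r_squared`, `fit` (the underlying `lm`), `n`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
area_regression <- function(predicted, truth,
                            orientation = c("truth_on_predicted",
                                            "predicted_on_truth")) {
  orientation <- match.arg(orientation)
  if (length(predicted) != length(truth)) {
    sp_validation_error("predicted and truth must have equal length")
  }
  if (length(predicted) < 3) {
    sp_validation_error("regression needs at least 3 observations")
  }
  x <- if (orientation == "truth_on_predicted") predicted else truth
  y <- if (orientation == "truth_on_predicted") truth else predicted
  if (sd(x) == 0) {
    degenerate_regression("constant predictor: regression undefined")
  }
  fit <- lm(y ~ x)
  r2 <- stats::cor(x, y)^2
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, fit = fit, n = length(x),
         orientation = orientation,
         data = tibble::tibble(predicted = predicted, truth = truth)),
    class = "area_regression"
  )
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf("<area_regression n=%d> y = %.4f x + %.4f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' RMSE and residual-bound summary
#'
#' Residuals are absolute differences `|predicted - truth|`. Reports the
#' root-mean-square error, the mean residual, and for each bound `b` the
#' fraction of residuals falling inside `[mean - b, mean + b]`.
#'
#' @param predicted,truth Equal-length numeric vectors (>= 1 value).
#' @param bounds Residual bounds; default `c(2.5, 3.9, 7.7)` percentage
#'   points, matching 1/2/3-sigma-style reporting of leaf-area residuals.
#' @return List with `rmse`, `residual_mean`, and `within_fractions`, a
#'   tibble (bound, fraction).
#' @export
rmse_residuals <- function(predicted, truth, bounds = c(2.5, 3.9, 7.7)) {
  if (length(predicted) != length(truth) || length(predicted) < 1) {
    sp_validation_error("predicted and truth must be equal-length, non-empty")
  }
  r <- abs(predicted - truth)
  m <- mean(r)
  fracs <- vapply(bounds, function(b) mean(r >= m - b & r <= m + b),
                  numeric(1))
  list(rmse = sqrt(mean(r^2)), residual_mean = m,
       within_fractions = tibble::tibble(bound = bounds, fraction = fracs))
}

#' Full validation report of a set of segmentations
#'
#' Pools pixels of all image pairs into one confusion matrix and regresses
#' the per-image ground-truth leaf-area percentages on the predicted ones.
#'
#' @param pred_maps,truth_maps Lists of [label_map()]s of equal length
#'   (>= 3 for the regression part).
#' @param classes Classes for the confusion matrix (default background,
#'   leaf, stem).
#' @param bounds Residual bounds for [rmse_residuals()].
#' @return Object of class `validation_report`: `confusion`, `regression`
#'   (an `area_regression`), `rmse`, `residual_mean`, `within_fractions`,
#'   `leaf_areas` (per-image tibble).
#' @export
validation_report <- function(pred_maps, truth_maps, classes = c(0L, 1L, 2L),
                              bounds = c(2.5, 3.9, 7.7)) {
  stopifnot(is.list(pred_maps), is.list(truth_maps),
            length(pred_maps) == length(truth_maps))
  pooled_pred <- do.call(rbind, lapply(pred_maps, function(m) m$labels))
  pooled_truth <- do.call(rbind, lapply(truth_maps, function(m) m$labels))
  confusion <- confusion_matrix(label_map(pooled_pred),
                                label_map(pooled_truth), classes)
  la_pred <- vapply(pred_maps, leaf_area_percent, numeric(1))
  la_truth <- vapply(truth_maps, leaf_area_percent, numeric(1))
  reg <- area_regression(la_pred, la_truth)
  rr <- rmse_residuals(la_pred, la_truth, bounds)
  structure(
    list(confusion = confusion, regression = reg, rmse = rr$rmse,
         residual_mean = rr$residual_mean,
         within_fractions = rr$within_fractions,
         leaf_areas = tibble::tibble(image = seq_along(pred_maps),
                                     predicted = la_pred, truth = la_truth)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\nConfusion matrix (row %):\n")
  print(round(x$confusion, 1))
  cat(sprintf("Leaf-area regression: y = %.3f x + %.3f, R^2 = %.3f\n",
              x$regression$slope, x$regression$intercept,
              x$regression$r_squared))
  cat(sprintf("RMSE %.3f%%, mean residual %.3f%%\n", x$rmse, x$residual_mean))
  invisible(x)
}
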