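# Phenotypic quantities from a segmentation and a depth map. A pixel at
# depth d subtends a world area of (d/f)^2 (world length per pixel at depth
# d is d/f with f in pixel units), so depth weighting converts pixel counts
# into 3D surface areas and corrects the near-objects-look-bigger projection
# bias in fruit-to-leaf ratios.

#' Depth-weighted 3D surface area of a label region
#'
#' `Area = sum over pixels with the label and valid depth of (d(x)/f)^2`,
#' in world units squared. Pixels without a valid depth contribute zero;
#' their count is attached as attribute `n_invalid`.
#'
#' @param u A [label_map()].
#' @param d A [depth_map()] of the same size.
#' @param geom [camera_geometry()] supplying the focal length in pixels.
#' @param label Label code from [sp_labels] (or its name).
#' @return Numeric area (>= 0) with attribute `n_invalid`.
#' @export
region_area_3d <- function(u, d, geom, label) {
  stopifnot(inherits(u, "label_map"), inherits(d, "depth_map"),
            inherits(geom, "camera_geometry"))
  if (is.character(label)) {
    if (!label %in% names(sp_labels)) {
      sp_validation_error(sprintf("unknown label '%s'", label))
    }
    label <- sp_labels[[label]]
  }
  if (!label %in% sp_labels) {
    sp_validation_error(sprintf("unknown label code %s", format(label)))
  }
  if (!identical(dim(u$labels), dim(d$values))) {
    sp_validation_error("label map and depth map dimensions disagree")
  }
  in_region <- u$labels == label
  ok <- in_region & d$valid_mask
  area <- sum((d$values[ok] / geom$focal_px)^2)
  structure(area, n_invalid = sum(in_region & !d$valid_mask))
}

#' Digital 2D leaf area percentage
#'
#' Fraction of the image domain labelled leaf, scaled to 0..100.
#'
#' @param u A [label_map()].
#' @return Percentage in \[0, 100\].
#' @export
leaf_area_percent <- function(u) {
  stopifnot(inherits(u, "label_map"))
  100 * sum(u$labels == sp_labels[["leaf"]]) / length(u$labels)
}

#' Fruit-to-leaf ratio
#'
#' Grape area divided by leaf area. In 2D mode areas are pixel counts; in 3D
#' mode both regions are depth-weighted through [region_area_3d()], which
#' corrects for grapes and leaves sitting at different distances from the
#' camera.
#'
#' @param u A [label_map()].
#' @param d A [depth_map()]; required for `mode = "3d"`.
#' @param geom A [camera_geometry()]; required for `mode = "3d"`.
#' @param mode `"2d"` or `"3d"`.
#' @return Non-negative ratio; an error of class
#'   `stereophyte_undefined_ratio` when the leaf area is zero.
#' @export
fruit_to_leaf_ratio <- function(u, d = NULL, geom = NULL,
                                mode = c("2d", "3d")) {
  stopifnot(inherits(u, "label_map"))
  mode <- match.arg(mode)
  if (mode == "2d") {
    n_leaf <- sum(u$labels == sp_labels[["leaf"]])
    if (n_leaf == 0) undefined_ratio("no leaf pixels: 2D ratio undefined")
    return(sum(u$labels == sp_labels[["grape"]]) / n_leaf)
  }
  if (is.null(d) || is.null(geom)) {
    sp_validation_error("3D ratio needs a depth map and camera geometry")
  }
  a_leaf <- as.numeric(region_area_3d(u, d, geom, sp_labels[["leaf"]]))
  if (a_leaf == 0) undefined_ratio("zero 3D leaf area: ratio undefined")
  as.numeric(region_area_3d(u, d, geom, sp_labels[["grape"]])) / a_leaf
}

#' Phenotype record of one analyzed image
#'
#' Bundles the per-image phenotypic quantities into a one-row tibble: 2D
#' leaf-area percentage, 3D areas of all four classes, and the 2D/3D
#' fruit-to-leaf ratios (NA when undefined, e.g. no leaf pixels).
#'
#' @param u A [label_map()].
#' @param d A [depth_map()].
#' @param geom A [camera_geometry()].
#' @param plant_id Plant identifier.
#' @param day_of_year Acquisition day (integer).
#' @param genotype Optional genotype/cultivar grouping; defaults to
#'   `plant_id`.
#' @return One-row tibble with columns `plant_id`, `genotype`,
#'   `day_of_year`, `leaf_area_percent_2d`, `area_3d_background`,
#'   `area_3d_leaf`, `area_3d_stem`, `area_3d_grape`, `ratio_2d`,
#'   `ratio_3d`.
#' @export
phenotype_record <- function(u, d, geom, plant_id, day_of_year,
                             genotype = plant_id) {
  stopifnot(inherits(u, "label_map"), inherits(d, "depth_map"))
  areas <- vapply(names(sp_labels), function(nm)
    as.numeric(region_area_3d(u, d, geom, nm)), numeric(1))
  safe_ratio <- function(mode) {
    tryCatch(fruit_to_leaf_ratio(u, d, geom, mode),
             stereophyte_undefined_ratio = function(e) NA_real_)
  }
  tibble::tibble(
    plant_id = as.character(plant_id),
    genotype = as.character(genotype),
    day_of_year = as.integer(day_of_year),
    leaf_area_percent_2d = leaf_area_percent(u),
    area_3d_background = areas[["background"]],
    area_3d_leaf = areas[["leaf"]],
    area_3d_stem = areas[["stem"]],
    area_3d_grape = areas[["grape"]],
    ratio_2d = safe_ratio("2d"),
    ratio_3d = safe_ratio("3d")
  )
}

#' Growth time series across plants and days
#'
#' Sorts records by day and aggregates replicate plants of the same genotype
#' per day: mean and sample (n-1) standard deviation of the 2D leaf-area
#' percentage. The deviation is NA for single replicates (as for unreplicated
#' breeding lines).
#'
#' @param records Tibble of [phenotype_record()] rows (a `genotype` column is
#'   optional; it defaults to `plant_id`).
#' @return Tibble with columns `genotype`, `day_of_year`, `n_plants`,
#'   `leaf_area_mean`, `leaf_area_sd`, sorted by genotype and day.
#' @export
growth_series <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (!"genotype" %in% names(records)) records$genotype <- records$plant_id
  dup <- duplicated(records[, c("plant_id", "day_of_year")])
  if (any(dup)) {
    sp_validation_error(sprintf(
      "duplicate (plant_id, day_of_year) entries: %s",
      paste(unique(records$plant_id[dup]), collapse = ", ")))
  }
  records |>
    dplyr::arrange(.data$genotype, .data$day_of_year, .data$plant_id) |>
    dplyr::group_by(.data$genotype, .data$day_of_year) |>
    dplyr::summarise(
      n_plants = dplyr::n(),
      leaf_area_mean = mean(.data$leaf_area_percent_2d),
      leaf_area_sd = if (dplyr::n() > 1) sd(.data$leaf_area_percent_2d)
        else NA_real_,
      .groups = "drop"
    )
}
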