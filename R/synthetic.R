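# Synthetic stereo scenes with analytic ground truth. A near foreground
# "plant" (green textured leaf ellipses, one brown stem band, optional
# red/blue grape disk clusters) floats in front of a distant textured
# background plane; two pinhole views separated horizontally by the baseline
# are rendered rectified by construction (zero vertical disparity), with
# z-buffer visibility. Every surface is frontoparallel, so the true
# disparity of a primitive at depth z is exactly gamma = f b / z and its 3D
# area is pixel count times (z/f)^2. Textures are band-limited noise:
# uniform colors would leave the matching cost flat and disparity ill-posed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Band-limited noise texture on an h x w grid: white noise blurred at
# `smooth` px, standardized and scaled to RMS contrast `amplitude`. The
# band limit is just below the pixel scale: coarser textures leave adjacent
# disparity candidates with sub-noise cost differences (aperture ambiguity),
# defeating the purpose of texturing the scene.
noise_texture <- function(h, w, amplitude, smooth = 1.0) {
  n <- gaussian_blur(matrix(rnorm(h * w), h, w), smooth)
  n <- (n - mean(n)) / max(sd(n), 1e-12)
  amplitude / 2 * n
}

scene_defaults <- function() {
  list(
    width = 128, height = 128,
    focal_px = 300, baseline = 0.1, gamma_max = 15, levels = 16,
    background_depth = 10,
    background_color_r = 95, background_color_g = 105, background_color_b = 60,
    n_leaves = 3, leaf_depth_min = 2.5, leaf_depth_max = 4.5,
    leaf_radius_min = 12, leaf_radius_max = 22,
    stem = 1, stem_depth = 3.2, stem_half_width = 4,
    n_grape_clusters = 1, grape_depth = 2.8, grape_cluster_radius = 10,
    texture_amplitude = 40, background_texture_amplitude = 40,
    noise_sigma = 2, gain_mismatch = 0.02,
    seed = 0
  )
}

#' Build a synthetic grapevine scene
#'
#' Deterministically (given `seed`) places green-textured leaf ellipses, a
#' brown stem band and grape disk clusters over a distant green-brown
#' textured background whose color distribution overlaps the foreground's —
#' color alone cannot separate plant from field, depth can. All depths are
#' world units; disparities follow gamma = f b / z.
#'
#' @param ... Scene parameters overriding the defaults (see
#'   `stereophyte:::scene_defaults()`): image size, camera
#'   (`focal_px`, `baseline`, `gamma_max`, `levels`), `background_depth`,
#'   leaf/stem/grape counts, depth ranges and sizes, texture amplitudes,
#'   second-view `noise_sigma` (intensity units on 0..255) and
#'   `gain_mismatch`, and `seed`.
#' @return Object of class `synthetic_scene` with the primitive list, the
#'   [camera_geometry()], and the full generating config.
#' @export
build_scene <- function(...) {
  config <- modifyList(scene_defaults(), list(...))
  extra <- setdiff(names(list(...)), names(scene_defaults()))
  if (length(extra)) {
    sp_validation_error(paste("unknown scene parameters:",
                              paste(extra, collapse = ", ")))
  }
  geom <- camera_geometry(config$focal_px, config$baseline,
                          config$gamma_max, config$levels)
  check_scalar(config$background_depth, "background_depth", 0, strict_lo = TRUE)
  check_scalar(config$noise_sigma, "noise_sigma", 0)
  check_scalar(config$gain_mismatch, "gain_mismatch", 0)
  w <- config$width; h <- config$height
  fb <- geom$focal_px * geom$baseline

  prims <- with_seed(config$seed, {
    out <- list(list(shape = "background", label = sp_labels[["background"]],
                     z = config$background_depth,
                     color = c(config$background_color_r,
                               config$background_color_g,
                               config$background_color_b),
                     amplitude = config$background_texture_amplitude))
    if (config$stem >= 1) {
      out <- c(out, list(list(
        shape = "rectangle", label = sp_labels[["stem"]],
        z = config$stem_depth,
        cx = runif(1, 0.35 * w, 0.65 * w), cy = h / 2,
        hw = config$stem_half_width, hh = h / 2 + 2,
        angle = runif(1, -0.08, 0.08),
        color = c(85, 78, 68), amplitude = config$texture_amplitude)))
    }
    if (config$n_leaves >= 1) {
      for (i in seq_len(config$n_leaves)) {
        out <- c(out, list(list(
          shape = "ellipse", label = sp_labels[["leaf"]],
          z = runif(1, config$leaf_depth_min, config$leaf_depth_max),
          cx = runif(1, 0.2 * w, 0.8 * w), cy = runif(1, 0.2 * h, 0.8 * h),
          ax = runif(1, config$leaf_radius_min, config$leaf_radius_max),
          ay = runif(1, 0.6, 0.9) * runif(1, config$leaf_radius_min,
                                          config$leaf_radius_max),
          angle = runif(1, 0, pi),
          color = c(55, 140, 50), amplitude = config$texture_amplitude)))
      }
    }
    if (config$n_grape_clusters >= 1) {
      for (i in seq_len(config$n_grape_clusters)) {
        ccx <- runif(1, 0.25 * w, 0.75 * w)
        ccy <- runif(1, 0.55 * h, 0.8 * h)
        nb <- 5 + sample.int(4, 1)
        berries <- cbind(
          cx = ccx + runif(nb, -1, 1) * config$grape_cluster_radius,
          cy = ccy + runif(nb, -1, 1) * config$grape_cluster_radius,
          r = runif(nb, 2.5, 4.5))
        out <- c(out, list(list(
          shape = "disk_cluster", label = sp_labels[["grape"]],
          z = config$grape_depth, berries = berries,
          color = c(50, 45, 130), amplitude = config$texture_amplitude)))
      }
    }
    out
  })

  for (p in prims) {
    if (p$shape != "background" && p$z >= config$background_depth) {
      sp_validation_error(
        "impossible geometry: foreground primitive at or behind the background")
    }
    if (p$z <= 0) sp_validation_error("primitive depths must be positive")
  }
  structure(list(primitives = prims, camera = geom, config = config,
                 width = w, height = h),
            class = "synthetic_scene")
}

# Membership test of a primitive at continuous view-1 coordinates
# (1-based pixel centers).
prim_contains <- function(p, x, y) {
  switch(p$shape,
    background = rep(TRUE, length(x)),
    ellipse = {
      u <- (x - p$cx) * cos(p$angle) + (y - p$cy) * sin(p$angle)
      v <- -(x - p$cx) * sin(p$angle) + (y - p$cy) * cos(p$angle)
      (u / p$ax)^2 + (v / p$ay)^2 <= 1
    },
    rectangle = {
      u <- (x - p$cx) * cos(p$angle) + (y - p$cy) * sin(p$angle)
      v <- -(x - p$cx) * sin(p$angle) + (y - p$cy) * cos(p$angle)
      abs(u) <= p$hw & abs(v) <= p$hh
    },
    disk_cluster = {
      hit <- rep(FALSE, length(x))
      for (i in seq_len(nrow(p$berries))) {
        hit <- hit | ((x - p$berries[i, "cx"])^2 +
                        (y - p$berries[i, "cy"])^2 <= p$berries[i, "r"]^2)
      }
      hit
    },
    sp_validation_error(sprintf("unknown primitive shape '%s'", p$shape))
  )
}

#' Render a synthetic scene into a stereo pair with ground truth
#'
#' Renders the two pinhole views (rectified by construction), the true
#' disparity and label maps of the reference view, an unocclusion mask
#' (pixels whose surface is visible in both views), and pixel-exact 3D areas
#' per label. Additive Gaussian noise (`noise_sigma`) and a multiplicative
#' gain `(1 + gain_mismatch)` are applied to the second view only.
#'
#' @param scene A [build_scene()] result.
#' @return List: `left`, `right` ([rgb_image()]s), `disparity`
#'   ([disparity_map()], truth), `labels` ([label_map()], truth),
#'   `unoccluded` (logical H x W), `areas` (tibble label, label_name,
#'   n_pixels, area_3d), `geom`, `scene`.
#' @export
render_stereo <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  h <- scene$height; w <- scene$width
  geom <- scene$camera
  fb <- geom$focal_px * geom$baseline
  gammas <- vapply(scene$primitives, function(p) fb / p$z, numeric(1))
  pad <- ceiling(max(gammas)) + 2L

  # textures on the extended grid (columns 1-pad .. w of view-1 coordinates)
  textures <- with_seed(scene$config$seed + 1000L, {
    lapply(scene$primitives, function(p) {
      tex <- array(0, dim = c(h, w + pad, 3))
      base_noise <- noise_texture(h, w + pad, p$amplitude)
      for (ch in 1:3) {
        chn <- 0.85 * base_noise + 0.15 * noise_texture(h, w + pad, p$amplitude)
        tex[, , ch] <- clamp(p$color[ch] + chn, 0, 255)
      }
      tex
    })
  })

  render_view <- function(shift_by_prim) {
    xs <- rep(seq_len(w), each = h)   # 1-based x (columns)
    ys <- rep(seq_len(h), times = w)  # 1-based y (rows)
    id <- matrix(0L, h, w)
    zb <- matrix(Inf, h, w)
    px <- array(0, dim = c(h, w, 3))
    ord <- order(-vapply(scene$primitives, `[[`, numeric(1), "z"))
    for (i in ord) {
      p <- scene$primitives[[i]]
      s <- shift_by_prim[i]
      src_x <- xs - s
      hit <- prim_contains(p, src_x, ys) & p$z < zb[cbind(ys, xs)]
      if (!any(hit)) next
      sel <- which(hit)
      id[cbind(ys[sel], xs[sel])] <- i
      zb[cbind(ys[sel], xs[sel])] <- p$z
      for (ch in 1:3) {
        vals <- bilinear_sample(textures[[i]][, , ch], ys[sel],
                                src_x[sel] + pad, fill = p$color[ch])
        px[cbind(ys[sel], xs[sel], rep(ch, length(sel)))] <- vals
      }
    }
    list(id = id, z = zb, px = px)
  }

  v1 <- render_view(rep(0, length(scene$primitives)))
  v2 <- render_view(gammas)

  disp_true <- matrix(gammas[v1$id], h, w)
  labels_true <- matrix(
    vapply(scene$primitives, function(p) as.integer(p$label), integer(1))[v1$id],
    h, w)

  # unoccluded: the same primitive is visible at (x + gamma) in view 2
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  x2 <- cols + disp_true
  lo <- floor(x2); hi <- ceiling(x2)
  in2 <- x2 <= w & x2 >= 1
  id_at <- function(cc) {
    cc <- clamp(cc, 1, w)
    matrix(v2$id[cbind(as.vector(rows), as.vector(cc))], h, w)
  }
  unocc <- in2 & id_at(lo) == v1$id & id_at(hi) == v1$id

  right_px <- with_seed(scene$config$seed + 2000L, {
    g <- 1 + scene$config$gain_mismatch
    noisy <- g * v2$px
    if (scene$config$noise_sigma > 0) {
      noisy <- noisy + array(rnorm(length(noisy), 0, scene$config$noise_sigma),
                             dim = dim(noisy))
    }
    clamp(noisy, 0, 255)
  })

  zf2 <- (v1$z / geom$focal_px)^2
  areas <- tibble::tibble(
    label = unname(sp_labels),
    label_name = names(sp_labels),
    n_pixels = vapply(sp_labels, function(l) sum(labels_true == l), numeric(1)),
    area_3d = vapply(sp_labels, function(l) sum(zf2[labels_true == l]),
                     numeric(1))
  )
  areas <- areas[areas$n_pixels > 0, ]

  list(left = rgb_image(v1$px), right = rgb_image(right_px),
       disparity = disparity_map(disp_true, matrix(TRUE, h, w),
                                 gamma_max = max(geom$gamma_max, max(gammas))),
       labels = label_map(labels_true),
       unoccluded = unocc,
       areas = areas,
       geom = geom,
       scene = scene)
}

#' Analytic world areas of the scene's primitives
#'
#' Closed-form 3D areas (ellipse pi a b, rectangle 4 hw hh, grape disks sum
#' pi r^2, in pixel^2 at the primitive's depth, scaled by (z/f)^2) ignoring
#' occlusion and frame clipping — the reference for fully visible
#' primitives.
#'
#' @param scene A [build_scene()] result.
#' @return Tibble: primitive index, label, label_name, z, area_analytic.
#' @export
scene_analytic_areas <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  f <- scene$camera$focal_px
  rows <- lapply(seq_along(scene$primitives), function(i) {
    p <- scene$primitives[[i]]
    a_px <- switch(p$shape,
      background = scene$width * scene$height,
      ellipse = pi * p$ax * p$ay,
      rectangle = 4 * p$hw * p$hh,
      disk_cluster = sum(pi * p$berries[, "r"]^2))
    tibble::tibble(primitive = i, label = as.integer(p$label),
                   label_name = names(sp_labels)[match(p$label, sp_labels)],
                   z = p$z, area_analytic = a_px * (p$z / f)^2)
  })
  dplyr::bind_rows(rows)
}

#' Write a synthetic scene to disk as a regression fixture
#'
#' Emits the rendered pair (PNG), truth disparity (PFM), truth labels
#' (paletted PNG + legend), the truth-area CSV and the generating config so
#' the fixture can be re-rendered bit-identically from config + seed.
#'
#' @param scene A [build_scene()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
scene_to_fixture <- function(scene, out_dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    sp_io_error(sprintf("cannot create fixture directory: %s", out_dir))
  }
  r <- render_stereo(scene)
  paths <- list(
    left = file.path(out_dir, "left.png"),
    right = file.path(out_dir, "right.png"),
    disparity = file.path(out_dir, "disparity_truth.pfm"),
    labels = file.path(out_dir, "labels_truth.png"),
    areas = file.path(out_dir, "areas_truth.csv"),
    config = file.path(out_dir, "scene.cfg")
  )
  write_rgb_image(r$left, paths$left)
  write_rgb_image(r$right, paths$right)
  write_scalar_map(r$disparity, paths$disparity)
  write_label_map(r$labels, paths$labels)
  utils::write.csv(r$areas, paths$areas, row.names = FALSE)
  write_config(scene$config, paths$config)
  invisible(paths)
}

#' Rebuild a scene from a fixture's config file
#'
#' @param path A `scene.cfg` written by [scene_to_fixture()].
#' @return A `synthetic_scene` identical to the one that produced the
#'   fixture.
#' @export
scene_from_config <- function(path) {
  do.call(build_scene, read_config(path))
}
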