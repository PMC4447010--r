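# Raster and configuration I/O. Images travel as PNG or JPEG; scalar rasters
# (disparity, depth) as PFM, a minimal 32-bit float format whose roundtrip is
# bit-exact; label maps as paletted RGB PNG with a sidecar CSV legend.

#' Read an RGB image
#'
#' Reads a PNG or JPEG file into an [rgb_image()] on the 0..255 intensity
#' scale. Grayscale inputs are replicated to three channels; an alpha channel
#' is dropped. Sub-8-bit and 16-bit PNG samples are rescaled by max-value
#' division, so intensities always span \[0, 255\].
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `rgb_image`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    sp_io_error(sprintf("image file does not exist: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    sp_format_error(sprintf(
      "unsupported image format '.%s' (supported: png, jpg, jpeg)", ext))
  )
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  if (dim(px)[3] == 2L) px <- px[, , 1L, drop = FALSE]       # gray + alpha
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]      # rgb + alpha
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  rgb_image(px * 255)
}

#' Write an RGB image as PNG
#'
#' @param img An [rgb_image()].
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_rgb_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  ok <- try(png::writePNG(img$pixels / 255, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    sp_io_error(sprintf("cannot write image: %s", path))
  }
  invisible(path)
}

#' Write a disparity or depth map as a 32-bit float PFM raster
#'
#' Invalid pixels are encoded as NaN. The PFM roundtrip through
#' [read_scalar_map()] is bit-exact at 32-bit float precision.
#'
#' @param map A [disparity_map()] or [depth_map()].
#' @param path Output `.pfm` path.
#' @return Invisibly, `path`.
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "disparity_map") || inherits(map, "depth_map"))
  v <- map$values
  v[!map$valid_mask] <- NaN
  h <- nrow(v); w <- ncol(v)
  con <- suppressWarnings(try(file(path, "wb"), silent = TRUE))
  if (inherits(con, "try-error")) {
    sp_io_error(sprintf("cannot open for writing: %s", path))
  }
  on.exit(close(con))
  writeLines(c("Pf", sprintf("%d %d", w, h), "-1.0"), con, sep = "\n")
  # PFM stores rows bottom-to-top, samples left-to-right, little-endian.
  for (i in h:1) {
    writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a PFM scalar raster back into a map container
#'
#' @param path `.pfm` file written by [write_scalar_map()] (grayscale `Pf`).
#' @param kind `"disparity"` or `"depth"`, selecting the returned container.
#' @param gamma_max Disparity bound, forwarded to [disparity_map()].
#' @return A `disparity_map` or `depth_map`; NaN samples become invalid
#'   pixels.
#' @export
read_scalar_map <- function(path, kind = c("disparity", "depth"),
                            gamma_max = Inf) {
  kind <- match.arg(kind)
  if (!file.exists(path)) sp_io_error(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "Pf")) {
    sp_format_error("not a grayscale PFM file (missing 'Pf' magic)")
  }
  dims <- scan(text = readLines(con, n = 1L), quiet = TRUE)
  scale <- as.numeric(readLines(con, n = 1L))
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  endian <- if (scale < 0) "little" else "big"
  raw <- readBin(con, "numeric", n = w * h, size = 4L, endian = endian)
  v <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    v[h - i + 1L, ] <- raw[((i - 1L) * w + 1L):(i * w)]
  }
  mask <- is.finite(v)
  if (kind == "disparity") disparity_map(v, mask, gamma_max = gamma_max)
  else depth_map(v, mask)
}

#' Write a label map as a paletted PNG plus CSV legend
#'
#' Colors follow the fixed convention background = white, leaf = green,
#' stem = brown, grape = dark blue. The sidecar CSV (`<path>.legend.csv` by
#' default) maps index to class name and RGB triple.
#'
#' @param u A [label_map()].
#' @param path Output `.png` path.
#' @param legend_path CSV legend path; default appends `.legend.csv`.
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(u, path, legend_path = paste0(path, ".legend.csv")) {
  stopifnot(inherits(u, "label_map"))
  pal <- sp_palette()
  h <- nrow(u$labels); w <- ncol(u$labels)
  idx <- match(u$labels, pal$index)
  px <- array(0, dim = c(h, w, 3L))
  px[, , 1] <- matrix(pal$r[idx], h, w) / 255
  px[, , 2] <- matrix(pal$g[idx], h, w) / 255
  px[, , 3] <- matrix(pal$b[idx], h, w) / 255
  ok <- try(png::writePNG(px, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    sp_io_error(sprintf("cannot write label map: %s", path))
  }
  utils::write.csv(pal, legend_path, row.names = FALSE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path `.png` path with the fixed class palette.
#' @return A `label_map`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) sp_io_error(sprintf("no such file: %s", path))
  px <- round(png::readPNG(path) * 255)
  if (length(dim(px)) == 2L) sp_format_error("label PNG must be RGB")
  pal <- sp_palette()
  key <- px[, , 1] * 65536 + px[, , 2] * 256 + px[, , 3]
  pal_key <- pal$r * 65536 + pal$g * 256 + pal$b
  idx <- match(key, pal_key)
  if (anyNA(idx)) {
    sp_format_error("label PNG contains colors outside the class palette")
  }
  label_map(matrix(pal$index[idx], dim(px)[1], dim(px)[2]))
}

# ---- plain-text key=value configuration -----------------------------------

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Numeric-looking
#' values are converted to numbers. Unknown keys are kept verbatim so callers
#' can validate against their own schema.
#'
#' @param path Configuration file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) sp_io_error(sprintf("no such config file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      sp_format_error(sprintf("malformed config line: '%s'", ln))
    }
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a key=value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}
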