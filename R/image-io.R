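#' Load an image file as a gray-scale image
#'
#' Reads TIFF (including OME-TIFF; multi-page pyramids resolve to
#' `pyramid_level`) or PNG rasters. Multi-channel inputs are reduced by
#' `channel_policy`: `"first_plane"` keeps the first channel, `"luminance"`
#' computes Rec. 601 luminance. Intensities are rescaled to `[0, 255]`
#' (`L = 255`): 8-bit data passes through unchanged, deeper data (e.g.
#' 16-bit DAPI planes) is min-max stretched.
#'
#' @param path file path.
#' @param channel_policy `"first_plane"` or `"luminance"`.
#' @param pyramid_level 0-based page index for multi-page TIFFs.
#' @return a [gray_image()].
#' @export
load_gray_image <- function(path, channel_policy = c("first_plane", "luminance"),
                            pyramid_level = 0L) {
  channel_policy <- match.arg(channel_policy)
  raw <- read_raster(path, pyramid_level)
  m <- reduce_channels(raw$data, channel_policy)
  m <- normalize_intensity(m, raw$bits)
  gray_image(m, 255)
}

#' Load an RGB raster
#'
#' @inheritParams load_gray_image
#' @return numeric array `length x width x 3` with values in `[0, 255]`.
#' @export
load_rgb_image <- function(path, pyramid_level = 0L) {
  raw <- read_raster(path, pyramid_level)
  a <- raw$data
  if (length(dim(a)) != 3L || dim(a)[3] < 3L) {
    stop(sprintf("'%s' is not an RGB image", path), call. = FALSE)
  }
  a <- a[, , 1:3, drop = FALSE]
  if (raw$bits <= 8) a else a / (2^raw$bits - 1) * 255
}

# shared raster reader; returns list(data, bits) with data on its native
# integer scale (0..2^bits - 1)
read_raster <- function(path, pyramid_level = 0L) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) == 0L) stop(sprintf("'%s' has no image pages", path),
                                  call. = FALSE)
    if (pyramid_level + 1L > length(pages)) {
      stop(sprintf("pyramid level %d not present in '%s' (%d page(s))",
                   pyramid_level, path, length(pages)), call. = FALSE)
    }
    data <- pages[[pyramid_level + 1L]]
    mx <- max(data)
    bits <- if (mx <= 255) 8L else if (mx <= 65535) 16L else 32L
  } else if (ext == "png") {
    data <- png::readPNG(path) * 255
    bits <- 8L
  } else if (ext %in% c("jpg", "jpeg")) {
    stop(sprintf("JPEG input is not supported ('%s'); convert to TIFF or PNG",
                 path), call. = FALSE)
  } else {
    stop(sprintf("unrecognised raster format: '%s'", path), call. = FALSE)
  }
  if (length(data) == 0L || prod(dim(data)[1:2]) == 0L) {
    stop(sprintf("'%s' is a zero-sized image", path), call. = FALSE)
  }
  list(data = data, bits = bits)
}

reduce_channels <- function(a, channel_policy) {
  if (length(dim(a)) == 2L) return(a)
  if (channel_policy == "first_plane") return(a[, , 1])
  if (dim(a)[3] < 3L) return(a[, , 1])
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

normalize_intensity <- function(m, bits) {
  if (bits <= 8) {
    pmin(pmax(m, 0), 255)
  } else {
    stretch_matrix_0_255(m)
  }
}

#' Inverted gray-scale rendering of an H&E image
#'
#' H&E nuclei are dark on a light background; DAPI nuclei are bright on a
#' dark background. Comparing the two modalities by MSE/PSNR requires a
#' common polarity, so the H&E luminance is inverted (`255 - luminance`) to
#' make nuclei bright.
#'
#' @param he_rgb numeric array `length x width x 3`, values in `[0, 255]`.
#' @return a [gray_image()] with bright nuclei.
#' @export
to_grayscale_inverted <- function(he_rgb) {
  if (length(dim(he_rgb)) != 3L || dim(he_rgb)[3] != 3L) {
    stop("`he_rgb` must be a length x width x 3 array", call. = FALSE)
  }
  lum <- 0.299 * he_rgb[, , 1] + 0.587 * he_rgb[, , 2] + 0.114 * he_rgb[, , 3]
  gray_image(pmin(pmax(255 - lum, 0), 255), 255)
}

#' Auto-orient an H&E image against the DAPI layout
#'
#' Tries all eight discrete orientations of the (inverted gray-scale) H&E
#' image, resizes both images to a square thumbnail, and keeps the
#' orientation minimising the MSE against the DAPI thumbnail. Ties are
#' broken toward the identity (candidates are scanned identity-first).
#'
#' @param he a [gray_image()] of the H&E image, already inverted so nuclei
#'   are bright (see [to_grayscale_inverted()]).
#' @param dapi a [gray_image()] of the DAPI morphology image.
#' @param thumbnail_side side of the square comparison thumbnail (>= 16).
#' @param candidates list of [orientation_code()]s to search (default all 8).
#' @return list with `oriented` (the H&E `gray_image` at full resolution
#'   under the best orientation), `orientation` (an `orientation_code`) and
#'   `mse_table` (data frame of per-candidate scores).
#' @export
auto_orient_he <- function(he, dapi, thumbnail_side = 512L,
                           candidates = all_orientations()) {
  if (thumbnail_side < 16L) stop("`thumbnail_side` must be >= 16", call. = FALSE)
  dapi_thumb <- resize_gray(dapi, thumbnail_side, thumbnail_side)
  scores <- vapply(candidates, function(o) {
    cand <- apply_orientation(he, o)
    mse(resize_gray(cand, thumbnail_side, thumbnail_side), dapi_thumb)
  }, numeric(1))
  best <- which.min(scores)
  tab <- data.frame(
    rotation = vapply(candidates, function(o) o$rotation, numeric(1)),
    mirrored = vapply(candidates, function(o) o$mirrored, logical(1)),
    mse = scores
  )
  list(oriented = apply_orientation(he, candidates[[best]]),
       orientation = candidates[[best]],
       mse_table = tab)
}
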