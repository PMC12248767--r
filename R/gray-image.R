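#' Gray-scale image container
#'
#' A `gray_image` is a numeric matrix of pixel intensities with an attached
#' maximum representable value `L` (255 throughout this package). Rows index
#' the image length (the y axis), columns the width (the x axis). The
#' coordinate convention everywhere in xenalign is 0-based with pixel centers
#' at integer coordinates: pixel `(x, y)` lives at `pixels[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix of intensities in `[0, max_value]`.
#' @param max_value maximum representable intensity (default 255).
#' @return an object of class `gray_image` (a matrix with a `max_value`
#'   attribute).
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2))
#' img_width(img)
#' @export
gray_image <- function(pixels, max_value = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains NA intensities", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > max_value) {
    stop(sprintf("intensities must lie in [0, %s]", format(max_value)),
         call. = FALSE)
  }
  structure(pixels, max_value = max_value, class = c("gray_image", "matrix"))
}

#' @rdname gray_image
#' @param img a `gray_image` or plain matrix.
#' @export
img_width <- function(img) ncol(img)

#' @rdname gray_image
#' @export
img_length <- function(img) nrow(img)

#' @rdname gray_image
#' @export
img_max_value <- function(img) {
  mv <- attr(img, "max_value")
  if (is.null(mv)) 255 else mv
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d (width x length), L = %s>\n",
              img_width(x), img_length(x), format(img_max_value(x))))
  invisible(x)
}

# strip class/attrs for raw matrix arithmetic
as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "max_value") <- NULL
  m
}

#' Mean square error between two equal-shape gray images
#'
#' MSE(a, b) = mean of the squared per-pixel intensity differences. This is
#' the quality index used both to auto-orient the H&E image and, through
#' [psnr()], to rank candidate nucleus patches.
#'
#' @param a,b numeric matrices (or `gray_image`s) of identical dimensions.
#' @return a single non-negative number.
#' @examples
#' mse(matrix(0, 2, 2), matrix(2, 2, 2)) # 4
#' @seealso [psnr()]
#' @export
mse <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("image dimensions differ: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio between two gray images
#'
#' `PSNR(a, b) = 10 * log10(L^2 / MSE(a, b))` where `L` is the maximum
#' representable intensity. Identical images have zero MSE; the limit is
#' +Inf, which this function returns as a sentinel and which ranks above
#' every finite score.
#'
#' @inheritParams mse
#' @param L maximum pixel value (default taken from `a`, else 255).
#' @return PSNR in decibels, or `Inf` when the images are identical.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(255, 2, 2)) # 0 dB
#' @export
psnr <- function(a, b, L = img_max_value(a)) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

# min-max stretch a matrix to [0, 255]; constant input maps to 0
stretch_0_255 <- function(m) {
  m <- as.numeric(m)
  rng <- range(m)
  if (rng[2] == rng[1]) return(array(0, dim = c(length(m))))
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

stretch_matrix_0_255 <- function(m) {
  d <- dim(m)
  out <- stretch_0_255(m)
  dim(out) <- d
  out
}

#' Bilinear resize of a gray image
#'
#' @param img matrix or `gray_image`.
#' @param width,height target width (columns) and length (rows) in pixels.
#' @return plain numeric matrix of dimension `height x width`.
#' @export
resize_gray <- function(img, width, height) {
  m <- as_pixel_matrix(img)
  # EBImage treats dim 1 as x; our matrices store y in dim 1, so swap targets
  out <- EBImage::resize(m, w = height, h = width)
  out <- as.matrix(out)
  out[out < 0] <- 0
  out
}
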