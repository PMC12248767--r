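#' Discrete image orientations
#'
#' An orientation is one of the eight symmetries of the pixel grid: an
#' optional horizontal mirror (applied first) followed by a rotation of 0,
#' 90, 180 or 270 degrees clockwise in display coordinates (x right, y
#' down). Scanned H&E slides can arrive rotated and/or flipped relative to
#' the instrument's DAPI morphology image; this discrete set covers the
#' plausible cases, while sub-degree alignment is left to Xenium Explorer's
#' own least-squares fit of the keypoints.
#'
#' @param rotation one of 0, 90, 180, 270 (degrees, clockwise).
#' @param mirrored logical; horizontal flip applied before the rotation.
#' @return an `orientation_code` object.
#' @examples
#' orientation_code(180)
#' @export
orientation_code <- function(rotation = 0, mirrored = FALSE) {
  if (!rotation %in% c(0, 90, 180, 270)) {
    stop("`rotation` must be one of 0, 90, 180, 270", call. = FALSE)
  }
  if (!is.logical(mirrored) || length(mirrored) != 1L || is.na(mirrored)) {
    stop("`mirrored` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(rotation = rotation, mirrored = mirrored),
            class = "orientation_code")
}

#' @export
print.orientation_code <- function(x, ...) {
  cat(sprintf("<orientation %d degrees%s>\n", x$rotation,
              if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

#' @export
format.orientation_code <- function(x, ...) {
  sprintf("rot%d%s", x$rotation, if (x$mirrored) "_mirror" else "")
}

#' All eight candidate orientations, identity first
#' @return list of `orientation_code`s.
#' @export
all_orientations <- function() {
  out <- list()
  for (m in c(FALSE, TRUE)) {
    for (r in c(0, 90, 180, 270)) out[[length(out) + 1L]] <- orientation_code(r, m)
  }
  out
}

orientation_equal <- function(a, b) {
  a$rotation == b$rotation && a$mirrored == b$mirrored
}

#' Inverse of an orientation
#'
#' Mirrored orientations are involutions (mirror-then-rotate composed with
#' itself is the identity); pure rotations invert to the complementary
#' rotation.
#' @param o an `orientation_code`.
#' @return the `orientation_code` that undoes `o`.
#' @export
orientation_inverse <- function(o) {
  if (o$mirrored) o else orientation_code((360 - o$rotation) %% 360, FALSE)
}

rot90cw_matrix <- function(m) {
  # pixel (x, y) -> (L - 1 - y, x); output dims swap
  t(m)[, seq(nrow(m), 1L), drop = FALSE]
}

mirror_matrix <- function(m) m[, seq(ncol(m), 1L), drop = FALSE]

#' Apply an orientation to an image
#'
#' Works on gray images (matrices) and on RGB arrays (`y x x x channel`).
#' The mirror, when requested, is applied before the rotation.
#'
#' @param img matrix, `gray_image`, or 3-d array.
#' @param orientation an `orientation_code`.
#' @return image of the same kind, possibly with width/length swapped.
#' @export
apply_orientation <- function(img, orientation) {
  stopifnot(inherits(orientation, "orientation_code"))
  one <- function(m) {
    if (orientation$mirrored) m <- mirror_matrix(m)
    k <- orientation$rotation / 90
    while (k > 0) { m <- rot90cw_matrix(m); k <- k - 1 }
    m
  }
  if (length(dim(img)) == 3L) {
    planes <- lapply(seq_len(dim(img)[3]), function(c) one(img[, , c]))
    out <- array(0, dim = c(dim(planes[[1]]), length(planes)))
    for (c in seq_along(planes)) out[, , c] <- planes[[c]]
    out
  } else if (inherits(img, "gray_image")) {
    gray_image(one(as_pixel_matrix(img)), img_max_value(img))
  } else {
    one(img)
  }
}

#' Map point coordinates through an orientation
#'
#' Transforms 0-based pixel coordinates the same way [apply_orientation()]
#' transforms pixels, so planted geometry can be followed through the
#' synthetic fixtures and the pipeline.
#'
#' @param xy numeric matrix (n x 2) or length-2 vector of `(x, y)`.
#' @param orientation an `orientation_code`.
#' @param dims `c(width, length)` of the image the points live in (before
#'   the orientation is applied).
#' @return list with `xy` (transformed coordinates) and `dims` (the
#'   width/length of the oriented image).
#' @export
orient_points <- function(xy, orientation, dims) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  w <- dims[1]; l <- dims[2]
  x <- xy[, 1]; y <- xy[, 2]
  if (orientation$mirrored) x <- w - 1 - x
  k <- orientation$rotation / 90
  while (k > 0) {
    # (x, y) -> (L - 1 - y, x), dims (W, L) -> (L, W)
    tmp <- l - 1 - y
    y <- x
    x <- tmp
    t2 <- w; w <- l; l <- t2
    k <- k - 1
  }
  list(xy = cbind(x = x, y = y), dims = c(w, l))
}
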