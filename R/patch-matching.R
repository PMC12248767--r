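#' Map an H&E point into DAPI coordinates
#'
#' Proportional mapping by image dimensions:
#' `X_DAPI = W_DAPI * X_HE / W_HE` and `Y_DAPI = L_DAPI * Y_HE / L_HE`.
#' The result is real-valued (not rounded) and is used as the center of a
#' square search region in the DAPI image.
#'
#' @param he_point length-2 `(x, y)` in H&E pixel coordinates, or an
#'   n x 2 matrix of points.
#' @param he_dims,dapi_dims `c(width, length)` of the two images.
#' @return mapped coordinates, same shape as `he_point`.
#' @export
map_center <- function(he_point, he_dims, dapi_dims) {
  if (any(he_dims <= 0) || any(dapi_dims <= 0)) {
    stop("image dimensions must be strictly positive", call. = FALSE)
  }
  was_vec <- is.null(dim(he_point))
  p <- if (was_vec) matrix(he_point, ncol = 2) else he_point
  if (any(p[, 1] < 0 | p[, 1] > he_dims[1] - 1 |
          p[, 2] < 0 | p[, 2] > he_dims[2] - 1)) {
    stop("point lies outside the H&E image bounds", call. = FALSE)
  }
  out <- cbind(x = dapi_dims[1] * p[, 1] / he_dims[1],
               y = dapi_dims[2] * p[, 2] / he_dims[2])
  if (was_vec) c(out) else out
}

#' Build a square search region in the DAPI image
#'
#' The region is the axis-aligned square of half-side
#' `radius = ratio * min(W_DAPI, L_DAPI)` around the mapped center; its
#' members are the DAPI nuclei whose centers fall inside. Regions with
#' fewer than `min_cells` members are rejected (returned as `NULL`, not an
#' error) — too few candidates make the PSNR ranking unreliable.
#'
#' @param dapi_center `(x, y)` region center in DAPI coordinates.
#' @param ratio region half-side as a fraction of the smaller DAPI image
#'   dimension, in (0, 1].
#' @param dapi_image_dims `c(width, length)` of the DAPI image.
#' @param dapi_nuclei list of [nucleus_record()]s.
#' @param min_cells minimum member count to retain the region.
#' @return a `search_region` (list with `center`, `radius`, `member_ids`,
#'   `member_idx`) or `NULL` when rejected.
#' @export
build_search_region <- function(dapi_center, ratio, dapi_image_dims,
                                dapi_nuclei, min_cells = 50L) {
  if (ratio <= 0 || ratio > 1) stop("`ratio` must be in (0, 1]", call. = FALSE)
  if (min_cells < 1L) stop("`min_cells` must be >= 1", call. = FALSE)
  radius <- ratio * min(dapi_image_dims[1], dapi_image_dims[2])
  centers <- nuclei_centers(dapi_nuclei)
  inside <- abs(centers[, 1] - dapi_center[1]) <= radius &
            abs(centers[, 2] - dapi_center[2]) <= radius
  if (sum(inside) < min_cells) return(NULL)
  structure(list(center = dapi_center, radius = radius,
                 member_ids = nuclei_ids(dapi_nuclei)[inside],
                 member_idx = which(inside)),
            class = "search_region")
}

crop_window <- function(img, cx, cy, rx, ry) {
  m <- as_pixel_matrix(img)
  ix <- floor(cx + 0.5)
  iy <- floor(cy + 0.5)
  x0 <- ix - rx; x1 <- ix + rx    # half-open [x0, x1)
  y0 <- iy - ry; y1 <- iy + ry
  if (x0 < 0 || y0 < 0 || x1 > ncol(m) || y1 > nrow(m)) return(NULL)
  m[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
}

#' Crop five directional patches around a point
#'
#' Crops the square (or, with per-axis radii, rectangular) window of
#' half-side `crop_radius` centered at the point and at the four points
#' displaced by `move_distance` up (decreasing y), down, left and right,
#' then resizes every crop to `patch_size x patch_size`. The five
#' directions widen the image context used for matching. If any crop
#' would extend past the image bounds the whole set is rejected (`NULL`)
#' rather than padded, so no synthetic signal enters the PSNR.
#'
#' @param image matrix or [gray_image()].
#' @param center `(x, y)` pixel coordinates.
#' @param crop_radius half side of the crop in pixels; length 1 or 2
#'   `(rx, ry)`.
#' @param move_distance directional displacement in pixels; length 1 or 2
#'   `(mx, my)`.
#' @param patch_size side of the resized patch (default 224).
#' @return named list of five `patch_size x patch_size` matrices
#'   (`center`, `up`, `down`, `left`, `right`), or `NULL` when rejected.
#' @export
crop_directional_patches <- function(image, center, crop_radius,
                                     move_distance, patch_size = 224L) {
  if (any(crop_radius <= 0)) stop("`crop_radius` must be > 0", call. = FALSE)
  if (any(move_distance < 0)) stop("`move_distance` must be >= 0", call. = FALSE)
  r <- round(rep_len(crop_radius, 2L))
  mv <- round(rep_len(move_distance, 2L))
  offs <- list(center = c(0, 0), up = c(0, -mv[2]), down = c(0, mv[2]),
               left = c(-mv[1], 0), right = c(mv[1], 0))
  out <- vector("list", 5L)
  names(out) <- names(offs)
  for (d in names(offs)) {
    w <- crop_window(image, center[1] + offs[[d]][1], center[2] + offs[[d]][2],
                     r[1], r[2])
    if (is.null(w)) return(NULL)
    out[[d]] <- resize_gray(w, patch_size, patch_size)
  }
  out
}

#' Directional patches of the binary H&E segmentation rendering
#'
#' The H&E side of the PSNR comparison is not the raw stain but the
#' segmentation rendered as a binary mask (nucleus pixels 255, background
#' 0), which exposes the nucleus layout that DAPI also shows.
#'
#' @param seg a `segmentation_result`.
#' @inheritParams crop_directional_patches
#' @return as [crop_directional_patches()].
#' @export
render_he_patch_for_psnr <- function(seg, center, crop_radius, move_distance,
                                     patch_size = 224L) {
  mask <- (seg$label_image > 0L) * 255
  crop_directional_patches(mask, center, crop_radius, move_distance,
                           patch_size)
}

# per-candidate DAPI directional patches, min-max stretched to [0, 255]
# per patch; cached across sampled H&E nuclei since they depend only on
# the candidate
dapi_candidate_patches <- function(dapi_image, nucleus, crop_radius,
                                   move_distance, patch_size, cache = NULL) {
  key <- as.character(nucleus$id)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    return(if (identical(cache[[key]], "rejected")) NULL else cache[[key]])
  }
  ps <- crop_directional_patches(dapi_image, nucleus$center, crop_radius,
                                 move_distance, patch_size)
  if (!is.null(ps)) ps <- lapply(ps, stretch_matrix_0_255)
  if (!is.null(cache)) cache[[key]] <- if (is.null(ps)) "rejected" else ps
  ps
}

#' Consensus top-1 match for one H&E nucleus
#'
#' Scores every candidate DAPI nucleus in the search region against the
#' sampled H&E nucleus by PSNR in each of the five directions: the H&E
#' patches come from the binary segmentation rendering around the H&E
#' nucleus center; each candidate's patches are cropped around the
#' candidate's own center with the same radius/move scheme and min-max
#' stretched to `[0, 255]`. The per-direction best candidate is the one
#' with maximal PSNR (ties to the smallest candidate id; +Inf outranks
#' all finite scores). A match is returned only when the same candidate
#' wins all five directions; otherwise `NULL`.
#'
#' @param he_nucleus a [nucleus_record()] (`source = "HE"`).
#' @param seg the H&E `segmentation_result`.
#' @param dapi_image the DAPI [gray_image()].
#' @param region a `search_region` from [build_search_region()].
#' @param dapi_nuclei full list of DAPI [nucleus_record()]s (indexed by
#'   `region$member_idx`).
#' @param cfg a [pipeline_config()] (uses `crop_radius_pixel`,
#'   `center_move_pixel`, `patch_size`).
#' @param cache optional environment for caching candidate patches across
#'   calls.
#' @return a `match_candidate` (list with `he_id`, `dapi_id`,
#'   `psnr_by_direction`, `consensus = TRUE`) or `NULL`.
#' @export
consensus_match <- function(he_nucleus, seg, dapi_image, region, dapi_nuclei,
                            cfg, cache = NULL) {
  dims_he <- c(ncol(seg$label_image), nrow(seg$label_image))
  dims_dapi <- c(img_width(dapi_image), img_length(dapi_image))
  sx <- dims_he[1] / dims_dapi[1]
  sy <- dims_he[2] / dims_dapi[2]
  r_he <- pmax(1, round(c(cfg$crop_radius_pixel * sx, cfg$crop_radius_pixel * sy)))
  m_he <- round(c(cfg$center_move_pixel * sx, cfg$center_move_pixel * sy))

  he_patches <- render_he_patch_for_psnr(seg, he_nucleus$center, r_he, m_he,
                                         cfg$patch_size)
  if (is.null(he_patches)) return(NULL)

  cand_order <- region$member_idx[order(region$member_ids)]
  directions <- names(he_patches)
  best_id <- stats::setNames(rep(NA_character_, 5L), directions)
  best_psnr <- stats::setNames(rep(-Inf, 5L), directions)
  all_scores <- list()
  for (ci in cand_order) {
    cand <- dapi_nuclei[[ci]]
    ps <- dapi_candidate_patches(dapi_image, cand, cfg$crop_radius_pixel,
                                 cfg$center_move_pixel, cfg$patch_size, cache)
    if (is.null(ps)) next   # crop out of bounds: excluded from rankings
    sc <- vapply(directions, function(d) psnr(he_patches[[d]], ps[[d]], 255),
                 numeric(1))
    all_scores[[as.character(cand$id)]] <- sc
    for (d in directions) {
      if (sc[[d]] > best_psnr[[d]]) {     # strict: ties keep earlier (smaller) id
        best_psnr[[d]] <- sc[[d]]
        best_id[[d]] <- as.character(cand$id)
      }
    }
  }
  if (anyNA(best_id)) return(NULL)
  if (length(unique(best_id)) != 1L) return(NULL)
  win <- best_id[[1]]
  structure(list(he_id = he_nucleus$id, dapi_id = win,
                 psnr_by_direction = all_scores[[win]], consensus = TRUE),
            class = "match_candidate")
}
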