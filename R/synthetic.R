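#' Specification of a synthetic paired test scene
#'
#' Describes a planted layout of elliptical nuclei rendered twice: once as
#' a DAPI-like image (bright nuclei on a dark background, additive
#' Gaussian noise) in the DAPI frame, and once as an H&E-like RGB image
#' (dark purple nuclei on a light background) in a frame scaled down by
#' `scale` and then transformed by `orientation`. The generator also emits
#' the DAPI nucleus boundary polygons (24 vertices each), a ground-truth
#' label image in the H&E frame, and the planted correspondence table, so
#' every pipeline stage can be scored against known truth.
#'
#' Nuclei are placed on a jittered grid, which enforces the minimum
#' center spacing by construction; `n_nuclei` beyond the grid capacity is
#' a generation error. Decoy nuclei (present in only one modality) can be
#' added to stress the matching.
#'
#' @param n_nuclei number of corresponding nuclei.
#' @param dapi_dims `c(width, length)` of the DAPI image in pixels.
#' @param scale DAPI-to-H&E linear scale factor (H&E dims are
#'   `dapi_dims / scale`, rounded).
#' @param orientation [orientation_code()] applied to the H&E rendering.
#' @param nucleus_radius_range `c(min, max)` ellipse semi-axis range in
#'   DAPI pixels.
#' @param intensity_noise_sd additive Gaussian noise sd on the DAPI image
#'   (intensity units, clipped to `[0, 255]`).
#' @param seed RNG seed; the whole scene is a pure function of the spec.
#' @param min_center_spacing minimum pairwise center distance in DAPI
#'   pixels.
#' @param margin keep-out border for nucleus centers, DAPI pixels.
#' @param n_decoy_dapi,n_decoy_he nuclei rendered in only one modality.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(n_nuclei = 300L,
                       dapi_dims = c(600L, 900L),
                       scale = 1.5,
                       orientation = orientation_code(0),
                       nucleus_radius_range = c(5, 9),
                       intensity_noise_sd = 8,
                       seed = 1L,
                       min_center_spacing = 26,
                       margin = 20,
                       n_decoy_dapi = 0L,
                       n_decoy_he = 0L) {
  stopifnot(n_nuclei >= 0, scale > 0, length(dapi_dims) == 2,
            inherits(orientation, "orientation_code"),
            nucleus_radius_range[1] > 0,
            nucleus_radius_range[2] >= nucleus_radius_range[1])
  he_dims <- round(dapi_dims / scale)
  structure(list(n_nuclei = as.integer(n_nuclei), dapi_dims = dapi_dims,
                 he_dims = he_dims, scale = scale, orientation = orientation,
                 nucleus_radius_range = nucleus_radius_range,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed),
                 min_center_spacing = min_center_spacing, margin = margin,
                 n_decoy_dapi = as.integer(n_decoy_dapi),
                 n_decoy_he = as.integer(n_decoy_he)),
            class = "scene_spec")
}

# jittered-grid placement guaranteeing pairwise spacing
place_centers <- function(n, dims, spacing, margin) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  usable <- dims - 2 * margin
  # grid cell side: spacing + 2 * jitter, jitter as large as the cell allows
  cell <- max(spacing * 1.2, spacing + 2)
  nx <- floor(usable[1] / cell); ny <- floor(usable[2] / cell)
  if (nx * ny < n) {
    stop(sprintf(paste0(
      "cannot place %d nuclei at spacing %.0f in a %dx%d image; ",
      "reduce n_nuclei or min_center_spacing"), n, spacing,
      dims[1], dims[2]), call. = FALSE)
  }
  jit <- (cell - spacing) / 2
  cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  pick <- cells[sample(nrow(cells), n), ]
  cx <- margin + (pick$ix + 0.5) * cell + stats::runif(n, -jit, jit)
  cy <- margin + (pick$iy + 0.5) * cell + stats::runif(n, -jit, jit)
  cbind(x = cx, y = cy)
}

ellipse_polygon <- function(cx, cy, a, b, theta, n = 24L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cx + a * cos(phi) * cos(theta) - b * sin(phi) * sin(theta)
  y <- cy + a * cos(phi) * sin(theta) + b * sin(phi) * cos(theta)
  cbind(x = x, y = y)
}

# paint one ellipse into img (matrix, y rows / x cols, 0-based coords);
# `frame_to_dapi` maps the frame's pixel coords into DAPI coords where the
# ellipse is defined. Returns the painted pixel linear indices.
ellipse_pixels <- function(dims, cx, cy, a, b, theta, frame_scale = c(1, 1)) {
  # bounding box in frame coordinates
  r <- max(a, b)
  x0 <- max(0, floor((cx - r) / frame_scale[1]) - 1)
  x1 <- min(dims[1] - 1, ceiling((cx + r) / frame_scale[1]) + 1)
  y0 <- max(0, floor((cy - r) / frame_scale[2]) - 1)
  y1 <- min(dims[2] - 1, ceiling((cy + r) / frame_scale[2]) + 1)
  if (x1 < x0 || y1 < y0) return(cbind(x = integer(0), y = integer(0)))
  gx <- x0:x1; gy <- y0:y1
  # map frame pixel centers into DAPI coordinates
  dx <- outer(rep(1, length(gy)), gx * frame_scale[1]) - cx
  dy <- outer(gy * frame_scale[2], rep(1, length(gx))) - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(x = gx[idx[, 2]], y = gy[idx[, 1]])
}

#' Generate a synthetic paired scene
#'
#' @param spec a [scene_spec()].
#' @return list with `dapi` ([gray_image()]), `he_rgb` (array in the
#'   stored H&E frame), `boundaries` (data frame `cell_id`, `vertex_x`,
#'   `vertex_y` in DAPI coordinates), `label_image` (integer matrix in the
#'   stored H&E frame), `correspondences` (data frame: `he_label`,
#'   `dapi_id`, planted centers in DAPI, pre-orientation H&E, and stored
#'   H&E frames), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n_total <- spec$n_nuclei + spec$n_decoy_dapi + spec$n_decoy_he
  centers <- place_centers(n_total, spec$dapi_dims, spec$min_center_spacing,
                           spec$margin)
  rr <- spec$nucleus_radius_range
  a <- stats::runif(n_total, rr[1], rr[2])
  b <- stats::runif(n_total, rr[1], rr[2])
  theta <- stats::runif(n_total, 0, 2 * pi)

  role <- rep("both", n_total)
  if (n_total > spec$n_nuclei) {
    extra <- seq_len(n_total) > spec$n_nuclei
    role[extra] <- rep(c(rep("dapi_only", spec$n_decoy_dapi),
                         rep("he_only", spec$n_decoy_he)), length.out = sum(extra))
  }

  W_D <- spec$dapi_dims[1]; L_D <- spec$dapi_dims[2]
  W_H <- spec$he_dims[1]; L_H <- spec$he_dims[2]
  # H&E (pre-orientation) pixel -> DAPI coordinate scale, matching the
  # proportional mapping used by map_center()
  fs <- c(W_D / W_H, L_D / L_H)

  dapi_m <- matrix(10, nrow = L_D, ncol = W_D)
  he_mask <- matrix(0L, nrow = L_H, ncol = W_H)
  boundaries <- list()
  rows <- list()

  for (k in seq_len(n_total)) {
    in_dapi <- role[k] != "he_only"
    in_he <- role[k] != "dapi_only"
    dapi_id <- sprintf("synthcell-%04d-1", k)
    if (in_dapi) {
      px <- ellipse_pixels(c(W_D, L_D), centers[k, 1], centers[k, 2],
                           a[k], b[k], theta[k])
      if (nrow(px) > 0L) dapi_m[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- 200
      poly <- ellipse_polygon(centers[k, 1], centers[k, 2], a[k], b[k], theta[k])
      boundaries[[length(boundaries) + 1L]] <-
        data.frame(cell_id = dapi_id, vertex_x = poly[, 1], vertex_y = poly[, 2])
    }
    if (in_he) {
      px <- ellipse_pixels(c(W_H, L_H), centers[k, 1], centers[k, 2],
                           a[k], b[k], theta[k], frame_scale = fs)
      if (nrow(px) > 0L) he_mask[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- k
    }
    if (role[k] == "both") {
      rows[[length(rows) + 1L]] <-
        data.frame(he_label = k, dapi_id = dapi_id,
                   dapi_x = centers[k, 1], dapi_y = centers[k, 2],
                   he0_x = centers[k, 1] / fs[1], he0_y = centers[k, 2] / fs[2])
    }
  }

  noise <- matrix(stats::rnorm(L_D * W_D, 0, spec$intensity_noise_sd),
                  nrow = L_D)
  dapi_m <- pmin(pmax(round(dapi_m + noise), 0), 255)

  # H&E RGB in the pre-orientation frame, then orient image + labels
  fg <- he_mask > 0L
  he_rgb0 <- array(0, dim = c(L_H, W_H, 3))
  bg_cols <- c(235, 228, 238); nuc_cols <- c(96, 60, 140)
  for (c in 1:3) {
    plane <- matrix(bg_cols[c], nrow = L_H, ncol = W_H)
    plane[fg] <- nuc_cols[c]
    he_rgb0[, , c] <- plane
  }
  he_rgb <- apply_orientation(he_rgb0, spec$orientation)
  label_image <- apply_orientation(he_mask, spec$orientation)

  corr <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(he_label = integer(0), dapi_id = character(0),
               dapi_x = numeric(0), dapi_y = numeric(0),
               he0_x = numeric(0), he0_y = numeric(0))
  if (nrow(corr) > 0L) {
    op <- orient_points(cbind(corr$he0_x, corr$he0_y), spec$orientation,
                        c(W_H, L_H))
    corr$he_stored_x <- op$xy[, 1]
    corr$he_stored_y <- op$xy[, 2]
  } else {
    corr$he_stored_x <- numeric(0)
    corr$he_stored_y <- numeric(0)
  }

  boundaries <- if (length(boundaries) > 0L) do.call(rbind, boundaries) else
    data.frame(cell_id = character(0), vertex_x = numeric(0),
               vertex_y = numeric(0))

  list(dapi = gray_image(dapi_m, 255), he_rgb = he_rgb,
       boundaries = boundaries, label_image = label_image,
       correspondences = corr, spec = spec)
}

#' Closed-form planted transform of a scene
#'
#' Returns the exact map from stored-H&E pixel coordinates to DAPI pixel
#' coordinates implied by the scene spec: undo the planted orientation,
#' then scale up by the image-dimension ratios. Used as the oracle for
#' scoring emitted keypoints.
#'
#' @param spec a [scene_spec()].
#' @return `function(xy)` mapping an n x 2 matrix (or length-2 vector) of
#'   stored-H&E coordinates to DAPI coordinates.
#' @export
planted_transform <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  inv <- orientation_inverse(spec$orientation)
  # dims of the stored (oriented) H&E image
  stored_dims <- orient_points(matrix(c(0, 0), ncol = 2), spec$orientation,
                               spec$he_dims)$dims
  fs <- c(spec$dapi_dims[1] / spec$he_dims[1],
          spec$dapi_dims[2] / spec$he_dims[2])
  function(xy) {
    was_vec <- is.null(dim(xy))
    if (was_vec) xy <- matrix(xy, ncol = 2)
    he0 <- orient_points(xy, inv, stored_dims)$xy
    out <- cbind(x = he0[, 1] * fs[1], y = he0[, 2] * fs[2])
    if (was_vec) c(out) else out
  }
}

#' Write a scene to disk in the pipeline's input dialects
#'
#' DAPI as an 8-bit TIFF, H&E as PNG, boundaries as CSV
#' (`cell_id,vertex_x,vertex_y`), labels as 16-bit TIFF.
#'
#' @param scene output of [generate_scene()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(dapi = file.path(dir, "morphology.tif"),
                he = file.path(dir, "he_image.png"),
                boundaries = file.path(dir, "nucleus_boundaries.csv"),
                labels = file.path(dir, "he_labels.tif"))
  tiff::writeTIFF(as_pixel_matrix(scene$dapi) / 255, paths$dapi,
                  bits.per.sample = 8L)
  png::writePNG(scene$he_rgb / 255, paths$he)
  utils::write.csv(scene$boundaries, paths$boundaries, row.names = FALSE)
  if (max(scene$label_image) > 65535) stop("too many labels for 16-bit TIFF")
  tiff::writeTIFF(scene$label_image / 65535, paths$labels,
                  bits.per.sample = 16L)
  paths
}
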