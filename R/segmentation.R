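#' Nucleus record
#'
#' One nucleus from either modality: an id (an integer label for H&E
#' segments, a barcode string such as `"gggbgpij-1"` for DAPI nuclei), the
#' ordered boundary vertices in the source image's 0-based pixel
#' coordinates, and the derived center point. The center is the mean of the
#' minimum and maximum boundary coordinates per axis (the bounding-box
#' midpoint), which is also the coordinate written to the keypoint file.
#'
#' @param id nucleus identifier.
#' @param source `"HE"` or `"DAPI"`.
#' @param boundary numeric matrix (n x 2) of `(x, y)` vertices, n >= 1.
#' @return a `nucleus_record` (list with `id`, `source`, `boundary`,
#'   `center`).
#' @export
nucleus_record <- function(id, source = c("HE", "DAPI"), boundary) {
  source <- match.arg(source)
  if (is.null(dim(boundary))) boundary <- matrix(boundary, ncol = 2)
  if (nrow(boundary) < 1L) stop("boundary needs at least one vertex", call. = FALSE)
  center <- bbox_midpoint(boundary)
  structure(list(id = id, source = source, boundary = boundary,
                 center = center),
            class = "nucleus_record")
}

bbox_midpoint <- function(xy) {
  c(x = (min(xy[, 1]) + max(xy[, 1])) / 2,
    y = (min(xy[, 2]) + max(xy[, 2])) / 2)
}

nuclei_centers <- function(nuclei) {
  t(vapply(nuclei, function(n) n$center, numeric(2)))
}

nuclei_ids <- function(nuclei) vapply(nuclei, function(n) as.character(n$id),
                                      character(1))

#' Segment nuclei in an H&E image
#'
#' Dispatches to a segmentation backend and returns the label image plus
#' bookkeeping. The `ground_truth` backend takes a caller-supplied label
#' image (0 = background, k > 0 = nucleus k) and is what the test suite
#' uses; `cellpose` and `stardist` are thin adapters around the optional
#' Python models and raise a dependency error when those are not installed.
#' A custom backend can be supplied as `backend_params$runner`, a
#' `function(he_image, params)` returning a label matrix.
#'
#' Backend defaults follow common practice for these models: Cellpose with
#' a minimum mask size of 15 pixels and an error/flow threshold of 0.8 on
#' one H&E channel (green by default; "channel 1" is ambiguous between 0-
#' and 1-based counting), StarDist with an object probability threshold of
#' 0.3.
#'
#' @param he_image numeric RGB array (`length x width x 3`) in `[0, 255]`.
#' @param backend `"ground_truth"`, `"cellpose"`, `"stardist"` or
#'   `"custom"`.
#' @param backend_params list of backend parameters; for `ground_truth`
#'   must contain `label_image`.
#' @param expected_cells expected nucleus count (usually the DAPI nucleus
#'   count) used to compute the segment ratio; `NA` if unknown.
#' @return a `segmentation_result`: list with `label_image`, `backend_used`,
#'   `segment_ratio`, `n_labels`, `params`.
#' @seealso [apply_fallback_rule()], [labels_to_nuclei()]
#' @export
segment_he <- function(he_image, backend = c("ground_truth", "cellpose",
                                             "stardist", "custom"),
                       backend_params = list(), expected_cells = NA_real_) {
  backend <- match.arg(backend)
  labels <- switch(
    backend,
    ground_truth = {
      li <- backend_params$label_image
      if (is.null(li)) {
        stop("ground_truth backend requires `backend_params$label_image`",
             call. = FALSE)
      }
      if (!is.null(dim(he_image)) &&
          !identical(dim(li)[1:2], dim(he_image)[1:2])) {
        stop("label image dimensions do not match the H&E image", call. = FALSE)
      }
      li
    },
    custom = {
      if (!is.function(backend_params$runner)) {
        stop("custom backend requires `backend_params$runner`", call. = FALSE)
      }
      backend_params$runner(he_image, backend_params)
    },
    cellpose = run_python_backend("cellpose", he_image, backend_params),
    stardist = run_python_backend("stardist", he_image, backend_params)
  )
  segmentation_result(labels, backend, expected_cells, backend_params)
}

segmentation_result <- function(label_image, backend_used, expected_cells,
                                params = list()) {
  storage.mode(label_image) <- "integer"
  n_labels <- length(setdiff(unique(as.vector(label_image)), 0L))
  ratio <- if (is.na(expected_cells) || expected_cells <= 0) {
    NA_real_
  } else {
    min(n_labels / expected_cells, 1)
  }
  structure(list(label_image = label_image, backend_used = backend_used,
                 segment_ratio = ratio, n_labels = n_labels, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d nuclei via %s, segment ratio %s>\n",
              x$n_labels, x$backend_used,
              ifelse(is.na(x$segment_ratio), "unknown",
                     sprintf("%.2f", x$segment_ratio))))
  invisible(x)
}

run_python_backend <- function(which, he_image, params) {
  py <- Sys.which("python")
  ok <- FALSE
  if (nzchar(py)) {
    status <- suppressWarnings(system2(
      py, c("-c", shQuote(sprintf("import %s", which))),
      stdout = FALSE, stderr = FALSE))
    ok <- identical(status, 0L)
  }
  if (!ok) {
    stop(sprintf(paste0(
      "the '%s' segmentation backend requires the Python package '%s', ",
      "which is not available; install it (pip install %s), supply a label ",
      "image via the ground_truth backend, or plug in a custom runner"),
      which, which, which), call. = FALSE)
  }
  stop(sprintf(paste0(
    "the '%s' backend adapter needs a runner: pass ",
    "`backend_params$runner` wrapping your %s invocation"),
    which, which), call. = FALSE)
}

#' Segmentation fallback rule
#'
#' When the primary model recovers fewer than half of the expected nuclei
#' (segment ratio strictly below 0.5), the secondary model is run instead;
#' otherwise the primary result is kept unchanged. A ratio of exactly 0.5
#' keeps the primary.
#'
#' @param primary a `segmentation_result`.
#' @param expected_cells expected nucleus count (> 0); used to (re)compute
#'   the segment ratio.
#' @param run_secondary zero-argument function returning a
#'   `segmentation_result` (only called when the fallback triggers).
#' @return a `segmentation_result`.
#' @export
apply_fallback_rule <- function(primary, expected_cells, run_secondary) {
  if (!is.numeric(expected_cells) || expected_cells <= 0) {
    stop("`expected_cells` must be > 0", call. = FALSE)
  }
  ratio <- primary$n_labels / expected_cells
  primary$segment_ratio <- min(ratio, 1)
  if (ratio < 0.5) run_secondary() else primary
}

#' Convert a label image to H&E nucleus records
#'
#' One record per distinct nonzero label. The boundary is the convex hull
#' of the label's pixel corner points (each pixel contributes its four
#' corners, i.e. the pixel-center hull dilated by half a pixel — an
#' unbiased outline of the underlying nucleus when nuclei are only a few
#' pixels across); the center is the bounding-box midpoint, which the
#' half-pixel dilation leaves unchanged. Labels of fewer than 3 pixels
#' cannot form a polygon and are dropped with a message.
#'
#' @param seg a `segmentation_result`.
#' @return list of [nucleus_record()]s with `source = "HE"`.
#' @export
labels_to_nuclei <- function(seg) {
  li <- seg$label_image
  idx <- which(li > 0L)
  if (length(idx) == 0L) return(list())
  labs <- li[idx]
  ys <- (idx - 1L) %% nrow(li)         # 0-based row = y
  xs <- (idx - 1L) %/% nrow(li)        # 0-based col = x
  by_lab <- split(seq_along(idx), labs)
  dropped <- 0L
  out <- list()
  for (lab in names(by_lab)) {
    sel <- by_lab[[lab]]
    if (length(sel) < 3L) { dropped <- dropped + 1L; next }
    px <- xs[sel]; py <- ys[sel]
    corners <- cbind(x = c(px - 0.5, px + 0.5, px - 0.5, px + 0.5),
                     y = c(py - 0.5, py - 0.5, py + 0.5, py + 0.5))
    hull <- convex_hull(corners)
    if (is.null(hull)) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <-
      nucleus_record(as.integer(lab), "HE", hull$vertices)
  }
  if (dropped > 0L) {
    message(sprintf("labels_to_nuclei: dropped %d label(s) too small to form a polygon",
                    dropped))
  }
  out
}

#' Load DAPI nucleus boundary polygons
#'
#' Reads the nucleus boundary export of a Xenium run — a table of
#' `(cell_id, vertex_x, vertex_y)` rows, one row per polygon vertex — from
#' a CSV or Parquet file or an in-memory data frame, and derives each
#' nucleus center by the bounding-box-midpoint rule. Column names are
#' configurable for other dialects.
#'
#' @param boundary_source file path (csv/parquet) or data frame.
#' @param id_col,x_col,y_col column names.
#' @return list of [nucleus_record()]s with `source = "DAPI"`.
#' @export
load_dapi_nuclei <- function(boundary_source, id_col = "cell_id",
                             x_col = "vertex_x", y_col = "vertex_y") {
  df <- if (is.data.frame(boundary_source)) {
    boundary_source
  } else if (is.character(boundary_source)) {
    ext <- tolower(tools::file_ext(boundary_source))
    if (ext == "parquet") {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("reading parquet boundaries requires the 'arrow' package",
             call. = FALSE)
      }
      as.data.frame(arrow::read_parquet(boundary_source))
    } else {
      utils::read.csv(boundary_source, stringsAsFactors = FALSE)
    }
  } else {
    stop("`boundary_source` must be a file path or a data frame", call. = FALSE)
  }
  for (cl in c(id_col, x_col, y_col)) {
    if (!cl %in% names(df)) {
      stop(sprintf("boundary table lacks column '%s'", cl), call. = FALSE)
    }
  }
  if (nrow(df) == 0L) stop("boundary source is empty", call. = FALSE)
  by_id <- split(seq_len(nrow(df)), df[[id_col]])
  # preserve first-appearance order of ids
  by_id <- by_id[unique(as.character(df[[id_col]]))]
  skipped <- 0L
  out <- list()
  for (id in names(by_id)) {
    sel <- by_id[[id]]
    if (length(sel) < 3L) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <-
      nucleus_record(id, "DAPI", cbind(x = df[[x_col]][sel],
                                       y = df[[y_col]][sel]))
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d nucleus(ei) with fewer than 3 boundary vertices",
                    skipped), call. = FALSE)
  }
  if (length(out) == 0L) stop("no usable nuclei in boundary source", call. = FALSE)
  out
}
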