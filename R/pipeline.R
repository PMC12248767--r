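#' Run the full keypoint identification pipeline
#'
#' Orchestrates the whole method: load and auto-orient the images, segment
#' the H&E nuclei, then loop over epochs — sample `cell_num_each_epoch`
#' H&E nuclei (without replacement across epochs), find consensus PSNR
#' matches in each one's DAPI search region, filter the epoch's matches by
#' Delaunay edge consistency and by nucleus-polygon overlap, and add the
#' survivors to the accumulated keypoint set (deduplicated and one-to-one:
#' a nucleus already matched to a different partner is not re-matched).
#' The loop stops when `keypoints_min` keypoints are accumulated, the
#' sampling pool is exhausted, or `max_epochs` is reached.
#'
#' @param cfg a [pipeline_config()].
#' @param inputs a list describing the inputs. Either file paths
#'   (`he_image_path`, `dapi_image_path`, `boundaries_path`, and for the
#'   ground_truth backend `label_image_path`) or in-memory objects
#'   (`he_rgb` array, `dapi` [gray_image()], `boundaries` data frame,
#'   `label_image` matrix in the same frame as the H&E image).
#' @param out_csv optional path; when given and at least 3 keypoints were
#'   found, the keypoint alignment CSV (plus a JSON run manifest at
#'   `<out_csv>.manifest.json`) is written.
#' @return list with `pairs` (data frame: `he_id`, `dapi_id`, `fixedX`,
#'   `fixedY`, `alignmentX`, `alignmentY`), `report` (a `run_report`),
#'   `orientation` (the recovered `orientation_code`), `segmentation`
#'   (the `segmentation_result`).
#' @export
run_pipeline <- function(cfg, inputs, out_csv = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))

  # [[ ]] with exact names: $ would partial-match e.g. dapi -> dapi_image_path
  he_rgb <- inputs[["he_rgb"]] %||% load_rgb_image(inputs[["he_image_path"]])
  dapi <- inputs[["dapi"]] %||%
    load_gray_image(inputs[["dapi_image_path"]],
                    pyramid_level = inputs[["pyramid_level"]] %||% 0L)
  label_image <- inputs[["label_image"]]
  if (is.null(label_image) && !is.null(inputs[["label_image_path"]])) {
    label_image <- read_label_image(inputs[["label_image_path"]])
  }
  boundaries <- inputs[["boundaries"]] %||% inputs[["boundaries_path"]]

  # --- orientation ---------------------------------------------------------
  he_gray_inv <- to_grayscale_inverted(he_rgb)
  ao <- auto_orient_he(he_gray_inv, dapi, cfg$thumbnail_side)
  orientation <- ao$orientation
  he_rgb <- apply_orientation(he_rgb, orientation)
  if (!is.null(label_image)) {
    label_image <- apply_orientation(label_image, orientation)
  }

  # --- nuclei --------------------------------------------------------------
  dapi_nuclei <- load_dapi_nuclei(boundaries)
  expected <- length(dapi_nuclei)
  seg <- segment_he(he_rgb, cfg$segmentation_backend,
                    backend_params = c(inputs[["backend_params"]],
                                       list(label_image = label_image)),
                    expected_cells = expected)
  if (!is.null(cfg$fallback_backend)) {
    seg <- apply_fallback_rule(seg, expected, function() {
      segment_he(he_rgb, cfg$fallback_backend,
                 backend_params = inputs[["backend_params"]] %||% list(),
                 expected_cells = expected)
    })
  }
  he_nuclei <- labels_to_nuclei(seg)
  if (length(he_nuclei) == 0L) {
    stop("no nuclei found in the H&E segmentation; cannot identify keypoints",
         call. = FALSE)
  }

  dims_he <- c(ncol(seg$label_image), nrow(seg$label_image))
  dims_dapi <- c(img_width(dapi), img_length(dapi))
  scale_he_to_dapi <- c(dims_dapi[1] / dims_he[1], dims_dapi[2] / dims_he[2])

  # --- epoch loop ----------------------------------------------------------
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$rng_seed)

  pool <- seq_along(he_nuclei)
  cache <- new.env(parent = emptyenv())
  acc <- list()           # accumulated keypoints keyed by he_id
  used_he <- character(0); used_dapi <- character(0)
  per_epoch <- integer(0)
  skipped <- c(region_rejected = 0L,
               no_consensus = 0L, graph_filtered = 0L,
               polygon_filtered = 0L, duplicate_or_conflict = 0L)
  epochs <- 0L

  while (length(acc) < cfg$keypoints_min && length(pool) > 0L &&
         epochs < cfg$max_epochs) {
    epochs <- epochs + 1L
    take <- min(cfg$cell_num_each_epoch, length(pool))
    sampled <- sample(pool, take)
    pool <- setdiff(pool, sampled)

    # stage 1: consensus PSNR matches
    matches <- list()
    for (hi in sampled) {
      hn <- he_nuclei[[hi]]
      dapi_center <- map_center(hn$center, dims_he, dims_dapi)
      region <- build_search_region(dapi_center, cfg$crop_radius_ratio,
                                    dims_dapi, dapi_nuclei,
                                    cfg$extracted_region_min)
      if (is.null(region)) { skipped["region_rejected"] <- skipped["region_rejected"] + 1L; next }
      mc <- consensus_match(hn, seg, dapi, region, dapi_nuclei, cfg, cache)
      if (is.null(mc)) { skipped["no_consensus"] <- skipped["no_consensus"] + 1L; next }
      mc$he_idx <- hi
      mc$dapi_idx <- region$member_idx[match(mc$dapi_id, region$member_ids)]
      matches[[length(matches) + 1L]] <- mc
    }

    # stage 2: Delaunay edge-consistency filter on this epoch's matches
    if (length(matches) >= 3L) {
      pa <- t(vapply(matches, function(m) he_nuclei[[m$he_idx]]$center, numeric(2)))
      pb <- t(vapply(matches, function(m) dapi_nuclei[[m$dapi_idx]]$center, numeric(2)))
      ids <- seq_along(matches) - 1L
      if (!anyDuplicated(pa) && !anyDuplicated(pb)) {
        keep_ids <- consistency_filter(build_trigraph(pa, ids),
                                       build_trigraph(pb, ids))
        skipped["graph_filtered"] <- skipped["graph_filtered"] +
          length(matches) - length(keep_ids)
        matches <- matches[keep_ids + 1L]
      }
    }

    # stage 3: nucleus-polygon overlap filter
    if (length(matches) > 0L) {
      pairs_in <- lapply(matches, function(m) {
        list(he_boundary = he_nuclei[[m$he_idx]]$boundary,
             dapi_boundary = dapi_nuclei[[m$dapi_idx]]$boundary,
             match = m)
      })
      kept <- polygon_filter(pairs_in, cfg$overlap_mode,
                             cfg$overlap_threshold, scale_he_to_dapi)
      skipped["polygon_filtered"] <- skipped["polygon_filtered"] +
        length(pairs_in) - length(kept)
      matches <- lapply(kept, function(p) p$match)
    }

    # accumulate, deduplicating and enforcing one-to-one matching
    added <- 0L
    for (m in matches) {
      he_key <- as.character(m$he_id)
      dapi_key <- as.character(m$dapi_id)
      if (he_key %in% used_he || dapi_key %in% used_dapi) {
        skipped["duplicate_or_conflict"] <- skipped["duplicate_or_conflict"] + 1L
        next
      }
      used_he <- c(used_he, he_key)
      used_dapi <- c(used_dapi, dapi_key)
      acc[[length(acc) + 1L]] <- m
      added <- added + 1L
    }
    per_epoch <- c(per_epoch, added)
  }

  # optional global consistency pass over the accumulated set
  if (cfg$global_graph_pass && length(acc) >= 4L) {
    pa <- t(vapply(acc, function(m) he_nuclei[[m$he_idx]]$center, numeric(2)))
    pb <- t(vapply(acc, function(m) dapi_nuclei[[m$dapi_idx]]$center, numeric(2)))
    ids <- seq_along(acc) - 1L
    keep_ids <- consistency_filter(build_trigraph(pa, ids),
                                   build_trigraph(pb, ids))
    acc <- acc[keep_ids + 1L]
  }

  report <- structure(list(epochs_run = epochs,
                           keypoints_per_epoch = per_epoch,
                           total_keypoints = length(acc),
                           skipped_nuclei_reasons = as.list(skipped)),
                      class = "run_report")

  if (length(acc) < 3L) {
    stop(sprintf(paste0(
      "pipeline found only %d keypoint(s); Xenium Explorer requires at ",
      "least three. Epochs run: %d; skip reasons: %s"),
      length(acc), epochs,
      paste(sprintf("%s=%d", names(skipped), skipped), collapse = ", ")),
      call. = FALSE)
  }
  if (length(acc) < cfg$keypoints_min) {
    warning(sprintf("sampling pool exhausted at %d keypoints (minimum requested %d)",
                    length(acc), cfg$keypoints_min), call. = FALSE)
  }

  pairs <- data.frame(
    he_id = vapply(acc, function(m) as.character(m$he_id), character(1)),
    dapi_id = vapply(acc, function(m) as.character(m$dapi_id), character(1)),
    fixedX = vapply(acc, function(m) dapi_nuclei[[m$dapi_idx]]$center[1], numeric(1)),
    fixedY = vapply(acc, function(m) dapi_nuclei[[m$dapi_idx]]$center[2], numeric(1)),
    alignmentX = vapply(acc, function(m) he_nuclei[[m$he_idx]]$center[1], numeric(1)),
    alignmentY = vapply(acc, function(m) he_nuclei[[m$he_idx]]$center[2], numeric(1)),
    stringsAsFactors = FALSE
  )

  if (!is.null(out_csv)) {
    write_keypoint_csv(pairs, out_csv)
    write_run_manifest(paste0(out_csv, ".manifest.json"),
                       dims_he = dims_he, dims_dapi = dims_dapi,
                       orientation = orientation, cfg = cfg, report = report)
  }

  list(pairs = pairs, report = report, orientation = orientation,
       segmentation = seg)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %d keypoints in %d epoch(s) [%s]>\n",
              x$total_keypoints, x$epochs_run,
              paste(x$keypoints_per_epoch, collapse = ", ")))
  invisible(x)
}

#' Read a label image stored as a 16-bit TIFF
#' @param path TIFF file of integer labels (0 = background).
#' @return integer matrix.
#' @export
read_label_image <- function(path) {
  raw <- read_raster(path)
  m <- raw$data
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
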