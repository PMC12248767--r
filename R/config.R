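#' Pipeline configuration
#'
#' All tunable hyperparameters of the keypoint identification pipeline,
#' with the fresh-frozen (FF) tissue defaults; `preset = "ffpe"` switches
#' to the formalin-fixed paraffin-embedded settings (smaller crop radius
#' and move distance, lower keypoint minimum).
#'
#' @param cell_num_each_epoch H&E nuclei sampled per epoch (default 100).
#' @param keypoints_min minimum number of keypoints to emit before
#'   stopping (default 15; FFPE preset 10).
#' @param crop_radius_ratio search-region half-side as a fraction of the
#'   smaller DAPI dimension (default 0.125; 0.06 and 0.5 are the other
#'   presets used in practice depending on tissue aspect ratio).
#' @param extracted_region_min minimum nuclei in a search region to keep
#'   it (default 50).
#' @param crop_radius_pixel patch crop half-side in DAPI pixels (default
#'   400; FFPE 200).
#' @param center_move_pixel directional patch displacement in DAPI pixels
#'   (default 300; FFPE 150).
#' @param patch_size resized patch side (default 224).
#' @param overlap_mode `"average"` or `"minimum"` polygon overlap index.
#' @param overlap_threshold keep threshold for the overlap index (default
#'   0.9 for average mode, 0.92 for minimum mode).
#' @param max_epochs epoch cap (default 100).
#' @param rng_seed integer seed for the epoch sampling.
#' @param thumbnail_side square thumbnail side for orientation search.
#' @param segmentation_backend backend name for [segment_he()].
#' @param fallback_backend backend run when the segment ratio is below
#'   0.5 (`NULL` disables the fallback).
#' @param global_graph_pass also run the Delaunay consistency filter over
#'   the accumulated keypoint set after the epoch loop (default FALSE; the
#'   per-epoch filters are the standard behaviour).
#' @param preset `"ff"` (default) or `"ffpe"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cell_num_each_epoch = 100L,
                            keypoints_min = NULL,
                            crop_radius_ratio = 0.125,
                            extracted_region_min = 50L,
                            crop_radius_pixel = NULL,
                            center_move_pixel = NULL,
                            patch_size = 224L,
                            overlap_mode = c("average", "minimum"),
                            overlap_threshold = NULL,
                            max_epochs = 100L,
                            rng_seed = 1L,
                            thumbnail_side = 512L,
                            segmentation_backend = "ground_truth",
                            fallback_backend = NULL,
                            global_graph_pass = FALSE,
                            preset = c("ff", "ffpe")) {
  preset <- match.arg(preset)
  overlap_mode <- match.arg(overlap_mode)
  if (is.null(keypoints_min)) keypoints_min <- if (preset == "ff") 15L else 10L
  if (is.null(crop_radius_pixel)) crop_radius_pixel <- if (preset == "ff") 400L else 200L
  if (is.null(center_move_pixel)) center_move_pixel <- if (preset == "ff") 300L else 150L
  if (is.null(overlap_threshold)) {
    overlap_threshold <- if (overlap_mode == "average") 0.9 else 0.92
  }
  cfg <- list(cell_num_each_epoch = as.integer(cell_num_each_epoch),
              keypoints_min = as.integer(keypoints_min),
              crop_radius_ratio = crop_radius_ratio,
              extracted_region_min = as.integer(extracted_region_min),
              crop_radius_pixel = crop_radius_pixel,
              center_move_pixel = center_move_pixel,
              patch_size = as.integer(patch_size),
              overlap_mode = overlap_mode,
              overlap_threshold = overlap_threshold,
              max_epochs = as.integer(max_epochs),
              rng_seed = as.integer(rng_seed),
              thumbnail_side = as.integer(thumbnail_side),
              segmentation_backend = segmentation_backend,
              fallback_backend = fallback_backend,
              global_graph_pass = isTRUE(global_graph_pass),
              preset = preset)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  counts <- c("cell_num_each_epoch", "keypoints_min", "extracted_region_min",
              "max_epochs", "patch_size")
  for (k in counts) {
    if (cfg[[k]] < 1L) stop(sprintf("`%s` must be >= 1", k), call. = FALSE)
  }
  if (cfg$crop_radius_ratio <= 0 || cfg$crop_radius_ratio > 1) {
    stop("`crop_radius_ratio` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$overlap_threshold <= 0 || cfg$overlap_threshold > 1) {
    stop("`overlap_threshold` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$crop_radius_pixel <= 0) stop("`crop_radius_pixel` must be > 0", call. = FALSE)
  if (cfg$center_move_pixel < 0) stop("`center_move_pixel` must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the [pipeline_config()] arguments; unknown keys raise an
#' error. `overrides` (e.g. from CLI flags) take precedence.
#'
#' @param path YAML or JSON file, or `NULL` for pure defaults.
#' @param overrides named list merged over the file values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    vals <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}
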