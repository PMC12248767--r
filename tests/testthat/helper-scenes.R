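# Shared synthetic scenes, generated once per test run. Small dimensions
# keep individual tests fast; the full-size end-to-end scene lives in
# test-acceptance.R.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(name, spec) {
  if (is.null(.scene_cache[[name]])) {
    .scene_cache[[name]] <- generate_scene(spec)
  }
  .scene_cache[[name]]
}

small_scene <- function() {
  cached_scene("small", scene_spec(
    n_nuclei = 150L, dapi_dims = c(420L, 630L), scale = 1.5,
    orientation = orientation_code(0), seed = 42L,
    min_center_spacing = 26, nucleus_radius_range = c(5, 9)))
}

# configuration matched to desk-scale scenes: region ratio 0.5 so regions
# still hold >= 50 nuclei, patch radii shrunk proportionally from the
# full-scale 400/300 settings
scene_config <- function(...) {
  args <- utils::modifyList(
    list(crop_radius_ratio = 0.5, crop_radius_pixel = 48,
         center_move_pixel = 36, thumbnail_side = 256L),
    list(...))
  do.call(pipeline_config, args)
}

expect_pairs_correct <- function(pairs, scene) {
  corr <- scene$correspondences
  idx <- match(as.integer(pairs$he_id), corr$he_label)
  expect_false(anyNA(idx))
  expect_identical(pairs$dapi_id, corr$dapi_id[idx])
}
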