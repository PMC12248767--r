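test_that("map_center applies proportional scaling exactly", {
  expect_equal(map_center(c(50, 50), c(100, 100), c(200, 200)), c(100, 100),
               ignore_attr = TRUE)
  expect_equal(map_center(c(0, 0), c(123, 456), c(789, 1011)), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(map_center(c(25, 75), c(100, 200), c(300, 100)), c(75, 37.5),
               ignore_attr = TRUE)
  expect_error(map_center(c(120, 0), c(100, 100), c(50, 50)), "outside")
})

test_that("map_center is linear and maps corners to corners", {
  he <- c(200, 300); dapi <- c(500, 450)
  corner <- map_center(c(he[1] - 1, he[2] - 1), he, dapi)
  expect_equal(unname(corner),
               c(dapi[1] * (he[1] - 1) / he[1], dapi[2] * (he[2] - 1) / he[2]))
  set.seed(4)
  p <- matrix(runif(20, 0, 150), ncol = 2)
  m1 <- map_center(p, he, dapi)
  expect_equal(map_center(p / 2, he, dapi), m1 / 2, ignore_attr = TRUE)
})

test_that("search regions enforce radius and membership rules", {
  set.seed(5)
  centers <- cbind(runif(200, 0, 1000), runif(200, 0, 2000))
  nuclei <- lapply(seq_len(200), function(i) {
    nucleus_record(sprintf("c%03d", i), "DAPI",
                   rbind(centers[i, ] - 1, centers[i, ] + 1,
                         centers[i, ] + c(-1, 1)))
  })
  reg <- build_search_region(c(500, 1000), 0.5, c(1000, 2000), nuclei, 1L)
  expect_equal(reg$radius, 500)
  ctr <- t(vapply(nuclei, function(n) n$center, numeric(2)))
  manual <- which(abs(ctr[, 1] - 500) <= 500 & abs(ctr[, 2] - 1000) <= 500)
  expect_identical(reg$member_idx, manual)

  # rejection when membership is below the minimum (not an error)
  expect_null(build_search_region(c(500, 1000), 0.01, c(1000, 2000),
                                  nuclei, 50L))
  exact <- build_search_region(c(500, 1000), 0.5, c(1000, 2000), nuclei,
                               length(manual))
  expect_false(is.null(exact))
  expect_null(build_search_region(c(500, 1000), 0.5, c(1000, 2000), nuclei,
                                  length(manual) + 1L))
})

test_that("directional crops sit at the documented offsets", {
  # linear ramp image: patch means recover the crop-center offsets
  img <- outer(seq_len(2000) - 1, seq_len(2000) - 1,
               function(y, x) x + 3 * y)
  ps <- crop_directional_patches(img, c(1000, 1000), 400, 300, patch_size = 32)
  expect_named(ps, c("center", "up", "down", "left", "right"))
  expect_true(all(vapply(ps, function(p) all(dim(p) == 32), logical(1))))
  expect_equal(mean(ps$up), mean(ps$center) - 3 * 300, tolerance = 0.01)
  expect_equal(mean(ps$down), mean(ps$center) + 3 * 300, tolerance = 0.01)
  expect_equal(mean(ps$left), mean(ps$center) - 300, tolerance = 0.01)
  expect_equal(mean(ps$right), mean(ps$center) + 300, tolerance = 0.01)

  # out-of-bounds crop rejects the whole set
  expect_null(crop_directional_patches(img, c(100, 100), 400, 300))
  # constant image stays constant through resize
  flat <- crop_directional_patches(matrix(7, 500, 500), c(250, 250), 100, 50,
                                   patch_size = 16)
  for (p in flat) expect_true(all(abs(p - 7) < 1e-9))
})

test_that("psnr matches hand-evaluated cases", {
  expect_identical(psnr(matrix(5, 3, 3), matrix(5, 3, 3), 255), Inf)
  expect_equal(psnr(matrix(0, 2, 2), matrix(255, 2, 2), 255), 0)
  one_off <- matrix(c(255, 0, 0, 0), 2, 2)
  expect_equal(psnr(matrix(0, 2, 2), one_off, 255), 10 * log10(4),
               tolerance = 1e-12)
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 2, 2), L = 0), "positive")
})

test_that("psnr is strictly decreasing in mse at fixed L", {
  set.seed(6)
  a <- matrix(runif(256, 0, 255), 16)
  prev_mse <- NULL
  scores <- t(replicate(200, {
    b <- matrix(runif(256, 0, 255), 16)
    c(mse(a, b), psnr(a, b, 255))
  }))
  ord <- order(scores[, 1])
  expect_true(all(diff(scores[ord, 2]) < 0))
})

test_that("binary segmentation rendering crops as a mask", {
  li <- matrix(0L, 300, 300)
  li[100:200, 100:200] <- 1L
  seg <- segment_he(array(0, dim = c(300, 300, 3)), "ground_truth",
                    list(label_image = li))
  inside <- render_he_patch_for_psnr(seg, c(150, 150), 20, 10, patch_size = 16)
  for (p in inside) expect_true(all(abs(p - 255) < 1e-9))
  outside <- render_he_patch_for_psnr(seg, c(260, 260), 20, 10, patch_size = 16)
  for (p in outside) expect_true(all(p == 0))

  # foreground fraction survives the resize within tolerance
  ps <- render_he_patch_for_psnr(seg, c(120, 120), 50, 0, patch_size = 224)
  mask <- (li > 0) * 255
  raw_frac <- mean(mask[(120 - 50 + 1):(120 + 50), (120 - 50 + 1):(120 + 50)] > 0)
  resized_frac <- mean(ps$center > 127)
  expect_lt(abs(raw_frac - resized_frac), 0.02)
})

test_that("consensus matching finds the planted counterpart", {
  sc <- small_scene()
  cfg <- scene_config()
  seg <- segment_he(sc$he_rgb, "ground_truth",
                    list(label_image = sc$label_image))
  he_nuclei <- labels_to_nuclei(seg)
  dapi_nuclei <- load_dapi_nuclei(sc$boundaries)
  dims_he <- c(ncol(seg$label_image), nrow(seg$label_image))
  dims_dapi <- c(img_width(sc$dapi), img_length(sc$dapi))
  corr <- sc$correspondences

  cache <- new.env(parent = emptyenv())
  set.seed(7)
  tried <- 0L; hits <- 0L
  for (hn in sample(he_nuclei, 40)) {
    center_dapi <- map_center(hn$center, dims_he, dims_dapi)
    region <- build_search_region(center_dapi, cfg$crop_radius_ratio,
                                  dims_dapi, dapi_nuclei,
                                  cfg$extracted_region_min)
    if (is.null(region)) next
    mc <- consensus_match(hn, seg, sc$dapi, region, dapi_nuclei, cfg, cache)
    if (is.null(mc)) next
    tried <- tried + 1L
    truth <- corr$dapi_id[corr$he_label == hn$id]
    if (identical(mc$dapi_id, truth)) hits <- hits + 1L
    # matches can only come from the region membership
    expect_true(mc$dapi_id %in% region$member_ids)
  }
  expect_gte(tried, 15L)
  expect_gte(hits / tried, 0.9)
})

test_that("zero move distance makes any argmax an automatic consensus", {
  sc <- small_scene()
  cfg <- scene_config(center_move_pixel = 0)
  seg <- segment_he(sc$he_rgb, "ground_truth",
                    list(label_image = sc$label_image))
  he_nuclei <- labels_to_nuclei(seg)
  dapi_nuclei <- load_dapi_nuclei(sc$boundaries)
  dims_he <- c(ncol(seg$label_image), nrow(seg$label_image))
  dims_dapi <- c(img_width(sc$dapi), img_length(sc$dapi))

  hn <- he_nuclei[[which.min(vapply(he_nuclei, function(n)
    sum((n$center - dims_he / 2)^2), numeric(1)))]]
  region <- build_search_region(map_center(hn$center, dims_he, dims_dapi),
                                cfg$crop_radius_ratio, dims_dapi,
                                dapi_nuclei, cfg$extracted_region_min)
  mc <- consensus_match(hn, seg, sc$dapi, region, dapi_nuclei, cfg)
  expect_false(is.null(mc))
  expect_equal(length(unique(unlist(mc$psnr_by_direction))), 1L)
})
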