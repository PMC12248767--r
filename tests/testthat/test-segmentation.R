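test_that("ground_truth backend passes labels through with bookkeeping", {
  li <- matrix(0L, 20, 20)
  li[2:5, 2:5] <- 1L
  li[10:14, 10:13] <- 2L
  seg <- segment_he(array(0, dim = c(20, 20, 3)), "ground_truth",
                    list(label_image = li), expected_cells = 4)
  expect_s3_class(seg, "segmentation_result")
  expect_identical(seg$backend_used, "ground_truth")
  expect_identical(seg$n_labels, 2L)
  expect_equal(seg$segment_ratio, 0.5)

  empty <- segment_he(array(0, dim = c(4, 4, 3)), "ground_truth",
                      list(label_image = matrix(0L, 4, 4)), expected_cells = 10)
  expect_identical(empty$n_labels, 0L)
  expect_equal(empty$segment_ratio, 0)

  expect_error(segment_he(array(0, dim = c(4, 4, 3)), "ground_truth"),
               "label_image")
})

test_that("external backends raise a dependency error with remediation", {
  expect_error(segment_he(array(0, dim = c(4, 4, 3)), "cellpose"),
               "cellpose")
  expect_error(segment_he(array(0, dim = c(4, 4, 3)), "stardist"),
               "stardist")
})

test_that("fallback triggers strictly below a segment ratio of one half", {
  # primary result with exactly n labels (2x2 blocks on a sparse grid)
  make_primary <- function(n) {
    li <- matrix(0L, 40, 120)
    for (k in seq_len(n)) {
      r <- ((k - 1) %/% 30) * 4 + 1
      c <- ((k - 1) %% 30) * 4 + 1
      li[r:(r + 1), c:(c + 1)] <- k
    }
    segment_he(array(0, dim = c(40, 120, 3)), "ground_truth",
               list(label_image = li))
  }
  secondary_called <- FALSE
  secondary <- function() {
    secondary_called <<- TRUE
    out <- make_primary(65)
    out$backend_used <- "stardist"
    out
  }
  # ratios observed in practice (0.28/0.40 fall back, 0.75 does not)
  # plus the exact boundary
  cases <- data.frame(ratio = c(0.28, 0.40, 0.49, 0.50, 0.51, 0.75),
                      falls_back = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  for (i in seq_len(nrow(cases))) {
    primary <- make_primary(round(cases$ratio[i] * 100))
    secondary_called <- FALSE
    out <- apply_fallback_rule(primary, 100, secondary)
    if (cases$falls_back[i]) {
      expect_identical(out$backend_used, "stardist", label = cases$ratio[i])
      expect_true(secondary_called, label = cases$ratio[i])
    } else {
      expect_identical(out$backend_used, "ground_truth", label = cases$ratio[i])
      expect_false(secondary_called, label = cases$ratio[i])
      expect_equal(out$segment_ratio, cases$ratio[i])
    }
  }
  expect_error(apply_fallback_rule(make_primary(10), 0, secondary),
               "expected_cells")
})

test_that("labels_to_nuclei derives bounding-box-midpoint centers", {
  li <- matrix(0L, 20, 20)
  li[1:10, 1:10] <- 1L              # square label, pixels (0,0)-(9,9)
  seg <- segment_he(array(0, dim = c(20, 20, 3)), "ground_truth",
                    list(label_image = li))
  recs <- labels_to_nuclei(seg)
  expect_length(recs, 1L)
  expect_equal(unname(recs[[1]]$center), c(4.5, 4.5))

  li[15:18, 3:5] <- 2L              # second disjoint label
  seg2 <- segment_he(array(0, dim = c(20, 20, 3)), "ground_truth",
                     list(label_image = li))
  recs2 <- labels_to_nuclei(seg2)
  expect_length(recs2, 2L)
  expect_setequal(vapply(recs2, function(r) r$id, integer(1)), c(1L, 2L))

  # sub-polygon labels (< 3 px) are dropped with a message
  li3 <- matrix(0L, 5, 5); li3[1, 1] <- 1L; li3[3:4, 3:4] <- 2L
  seg3 <- segment_he(array(0, dim = c(5, 5, 3)), "ground_truth",
                     list(label_image = li3))
  expect_message(recs3 <- labels_to_nuclei(seg3), "dropped 1")
  expect_length(recs3, 1L)
})

test_that("H&E record centers match planted ellipse centers within 1 px", {
  sc <- small_scene()
  seg <- segment_he(sc$he_rgb, "ground_truth",
                    list(label_image = sc$label_image))
  recs <- labels_to_nuclei(seg)
  corr <- sc$correspondences
  for (r in recs) {
    row <- corr[corr$he_label == r$id, ]
    expect_equal(nrow(row), 1L)
    expect_lt(max(abs(r$center - c(row$he0_x, row$he0_y))), 1)
  }
})

test_that("load_dapi_nuclei applies the min/max center rule and skips tiny polygons", {
  df <- data.frame(
    cell_id = c(rep("a", 4), rep("b", 3), rep("tiny", 2)),
    vertex_x = c(0, 2, 2, 0,   0, 4, 1,   0, 1),
    vertex_y = c(0, 0, 4, 4,   0, 0, 3,   0, 0))
  expect_warning(recs <- load_dapi_nuclei(df), "fewer than 3")
  expect_length(recs, 2L)
  expect_equal(unname(recs[[1]]$center), c(1, 2))
  expect_equal(unname(recs[[2]]$center), c(2, 1.5))
  expect_identical(recs[[1]]$source, "DAPI")

  expect_error(load_dapi_nuclei(df[0, ]), "empty")
})

test_that("boundary CSV round-trips with ids preserved", {
  sc <- small_scene()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sc$boundaries, path, row.names = FALSE)
  recs <- load_dapi_nuclei(path)
  expect_length(recs, length(unique(sc$boundaries$cell_id)))
  expect_identical(vapply(recs, function(r) r$id, character(1)),
                   unique(sc$boundaries$cell_id))
  # centers equal the planted ellipse centers (24-gon is symmetric)
  corr <- sc$correspondences
  for (r in recs[1:10]) {
    row <- corr[corr$dapi_id == r$id, ]
    expect_lt(max(abs(r$center - c(row$dapi_x, row$dapi_y))), 1e-9)
  }
})

test_that("center invariant holds for every record form", {
  set.seed(3)
  for (i in 1:25) {
    pts <- matrix(runif(16, 0, 50), ncol = 2)
    rec <- nucleus_record(i, "DAPI", pts)
    expect_equal(unname(rec$center),
                 c((min(pts[, 1]) + max(pts[, 1])) / 2,
                   (min(pts[, 2]) + max(pts[, 2])) / 2))
  }
})
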