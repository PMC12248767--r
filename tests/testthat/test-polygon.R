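test_that("convex_hull absorbs interior points and orients CCW", {
  sq_plus_center <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq_plus_center)
  expect_equal(nrow(h$vertices), 4L)
  expect_equal(h$area, 1)

  tri <- convex_hull(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(nrow(tri$vertices), 3L)
  expect_equal(tri$area, 6)

  # degenerate signals
  expect_null(convex_hull(rbind(c(0, 0), c(1, 1))))
  expect_null(convex_hull(cbind(0:5, 0:5 * 3)))
})

test_that("every input point lies inside or on the hull", {
  set.seed(12)
  inside_hull <- function(v, p) {
    m <- nrow(v)
    for (i in seq_len(m)) {
      p1 <- v[i, ]; p2 <- v[if (i == m) 1L else i + 1L, ]
      if ((p2[1] - p1[1]) * (p[2] - p1[2]) -
          (p2[2] - p1[2]) * (p[1] - p1[1]) < -1e-9) return(FALSE)
    }
    TRUE
  }
  pts <- matrix(runif(100, 0, 10), ncol = 2)
  h <- convex_hull(pts)
  for (i in seq_len(nrow(pts))) {
    expect_true(inside_hull(h$vertices, pts[i, ]))
  }
})

test_that("normalize_pair scales then centers at the origin", {
  sq2 <- convex_hull(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  sq4 <- convex_hull(rbind(c(10, 10), c(14, 10), c(14, 14), c(10, 14)))
  np <- normalize_pair(sq2, sq4, scale = c(2, 2))
  expect_equal(np$he$area, np$dapi$area)
  expect_equal(intersection_area(np$he, np$dapi), 16)
  for (p in np) {
    bb <- c((min(p$vertices[, 1]) + max(p$vertices[, 1])) / 2,
            (min(p$vertices[, 2]) + max(p$vertices[, 2])) / 2)
    expect_equal(bb, c(0, 0))
  }
})

test_that("intersection_area matches analytic cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(intersection_area(sq, sq), 1)
  expect_equal(intersection_area(sq, sq + 5), 0)
  shifted <- sq; shifted[, 1] <- shifted[, 1] + 0.5
  expect_equal(intersection_area(sq, shifted), 0.5)
  expect_equal(intersection_area(shifted, sq), 0.5)
  # MC oracle cross-check of the analytic case
  expect_lt(abs(oracle_intersection_area_mc(sq, shifted, 2e4) - 0.5), 0.02)
})

test_that("intersection is symmetric, bounded and oracle-consistent", {
  set.seed(13)
  for (i in 1:30) {
    va <- random_convex_polygon(center = runif(2, -2, 2))
    vb <- random_convex_polygon(center = runif(2, -2, 2))
    ia <- intersection_area(va, vb)
    expect_equal(intersection_area(vb, va), ia, tolerance = 1e-9)
    a_a <- abs(xenalign_shoelace(va)); a_b <- abs(xenalign_shoelace(vb))
    expect_lte(ia, min(a_a, a_b) + 1e-9)
    mc <- oracle_intersection_area_mc(va, vb, 2e4)
    expect_lt(abs(ia - mc), 0.03 * max(a_a, a_b))
  }
})

test_that("overlap indexes follow their closed forms", {
  sq <- convex_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(overlap_indexes(sq, sq)$index_avg, 1)
  expect_equal(overlap_indexes(sq, sq)$index_min, 1)

  inner <- convex_hull(rbind(c(0.25, 0.25), c(0.75, 0.25),
                             c(0.75, 0.75), c(0.25, 0.75)))
  sc <- overlap_indexes(sq, inner)
  expect_equal(sc$intersection_area, 0.25)
  expect_equal(sc$index_avg, 0.625)
  expect_equal(sc$index_min, 0.25)

  far <- convex_hull(rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6)))
  expect_equal(overlap_indexes(sq, far)$index_avg, 0)
  expect_equal(overlap_indexes(sq, far)$index_min, 0)
})

test_that("index_min never exceeds index_avg", {
  set.seed(14)
  for (i in 1:50) {
    pa <- convex_hull(random_convex_polygon(center = runif(2, -1, 1)))
    pb <- convex_hull(random_convex_polygon(center = runif(2, -1, 1)))
    sc <- overlap_indexes(pa, pb)
    expect_lte(sc$index_min, sc$index_avg + 1e-12)
    expect_gte(sc$index_min, 0)
    expect_lte(sc$index_avg, 1 + 1e-12)
  }
})

test_that("polygon_filter keeps pairs at or above the threshold", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  near <- rbind(c(0.1, 0), c(4, 0.1), c(3.9, 4), c(0, 3.9))
  small <- rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))
  pairs <- list(list(he_boundary = sq, dapi_boundary = sq, tag = "identical"),
                list(he_boundary = near, dapi_boundary = sq, tag = "near"),
                list(he_boundary = small, dapi_boundary = sq, tag = "mismatch"))
  kept <- polygon_filter(pairs, "average", 0.9)
  expect_setequal(vapply(kept, `[[`, "", "tag"), c("identical", "near"))
  # stricter minimum mode at 0.92
  kept_min <- polygon_filter(pairs, "minimum", 0.92)
  expect_true(all(vapply(kept_min, `[[`, "", "tag") %in% c("identical", "near")))
  # degenerate boundary is dropped with a warning, not an error
  degen <- list(list(he_boundary = cbind(0:3, 0:3), dapi_boundary = sq))
  expect_warning(out <- polygon_filter(degen, "average", 0.9), "degenerate")
  expect_length(out, 0L)
})

test_that("a pair kept at minimum 0.92 passes any average threshold <= 0.92", {
  set.seed(15)
  for (i in 1:40) {
    base <- random_convex_polygon(center = c(0, 0), radius = 4)
    jit <- base + matrix(rnorm(length(base), 0, 0.1), ncol = 2)
    hb <- convex_hull(base); jb <- convex_hull(jit)
    if (is.null(jb)) next
    sc <- overlap_indexes(hb, jb)
    if (sc$index_min >= 0.92) expect_gte(sc$index_avg, 0.92)
  }
})

test_that("observed sub-threshold indexes are removal decisions at 0.9", {
  # overlap indexes reported for mismatched nucleus pairs in practice
  for (idx in c(0.755, 0.847)) {
    expect_true(idx < 0.9)
    # as a decision: a pair with this average index is removed
    side <- sqrt(1)                      # unit square
    shrink <- sqrt(2 * idx - 1)          # nested squares give avg = (s2/s1+1)/2
    inner <- rbind(c(0, 0), c(shrink, 0), c(shrink, shrink), c(0, shrink))
    outer <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
    pairs <- list(list(he_boundary = inner, dapi_boundary = outer))
    sc <- overlap_indexes(convex_hull(inner), convex_hull(outer))
    expect_equal(sc$index_avg, idx, tolerance = 1e-9)
    expect_length(polygon_filter(pairs, "average", 0.9, scale = c(1, 1)), 0L)
  }
})
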