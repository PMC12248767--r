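# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: the Delaunay oracle enumerates triangles
# and tests empty circumcircles directly, the polygon-area oracle samples
# points, and the similarity fit is a closed-form Procrustes solution.

# Brute-force Delaunay edges: a triangle belongs to the triangulation iff
# no other point lies strictly inside its circumcircle. O(n^4); for tiny n.
oracle_delaunay_edges <- function(points) {
  n <- nrow(points)
  incircle_det <- function(a, b, c, d) {
    o <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (o < 0) { tmp <- b; b <- c; c <- tmp }
    m <- rbind(c(a - d, sum((a - d)^2)),
               c(b - d, sum((b - d)^2)),
               c(c - d, sum((c - d)^2)))
    det(m)
  }
  edges <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- points[i, ]; b <- points[j, ]; c <- points[k, ]
    area2 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(area2) < 1e-12) next
    empty <- TRUE
    for (m in seq_len(n)) {
      if (m %in% c(i, j, k)) next
      if (incircle_det(a, b, c, points[m, ]) > 1e-9) { empty <- FALSE; break }
    }
    if (empty) edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Monte-Carlo intersection area of two convex polygons by uniform point
# sampling over the joint bounding box
oracle_intersection_area_mc <- function(va, vb, n_samples = 1e5) {
  inside_convex <- function(v, px, py) {
    if (xenalign_shoelace(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    ok <- rep(TRUE, length(px))
    m <- nrow(v)
    for (i in seq_len(m)) {
      p1 <- v[i, ]; p2 <- v[if (i == m) 1L else i + 1L, ]
      ok <- ok & ((p2[1] - p1[1]) * (py - p1[2]) -
                  (p2[2] - p1[2]) * (px - p1[1]) >= -1e-12)
    }
    ok
  }
  xs <- range(c(va[, 1], vb[, 1])); ys <- range(c(va[, 2], vb[, 2]))
  px <- runif(n_samples, xs[1], xs[2])
  py <- runif(n_samples, ys[1], ys[2])
  hit <- inside_convex(va, px, py) & inside_convex(vb, px, py)
  mean(hit) * diff(xs) * diff(ys)
}

xenalign_shoelace <- function(v) {
  n <- nrow(v); j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# random convex polygon: convex hull vertices of random points
random_convex_polygon <- function(n_points = 12, center = c(0, 0), radius = 5) {
  repeat {
    pts <- cbind(center[1] + runif(n_points, -radius, radius),
                 center[2] + runif(n_points, -radius, radius))
    h <- grDevices::chull(pts)
    if (length(h) >= 3) {
      v <- pts[h, , drop = FALSE]
      if (abs(xenalign_shoelace(v)) > 1e-6) return(v)
    }
  }
}

# closed-form least-squares similarity transform (rotation + uniform scale
# + translation) mapping `from` onto `to`
fit_similarity <- function(from, to) {
  mf <- colMeans(from); mt <- colMeans(to)
  a <- sweep(from, 2, mf); b <- sweep(to, 2, mt)
  sxx <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  sxy <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  denom <- sum(a^2)
  s_cos <- sxx / denom
  s_sin <- sxy / denom
  function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    pc <- sweep(p, 2, mf)
    cbind(mt[1] + s_cos * pc[, 1] - s_sin * pc[, 2],
          mt[2] + s_sin * pc[, 1] + s_cos * pc[, 2])
  }
}
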