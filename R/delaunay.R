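# Delaunay triangulation (Bowyer-Watson incremental insertion).
#
# Point counts here are small (one epoch's consensus pairs, typically well
# under a hundred), so a plain O(n^2) R implementation is ample. Cocircular
# quadruples are resolved deterministically by the strict in-circle test
# (points exactly on the circumcircle are treated as outside), which yields
# one of the valid triangulations.

# >0 iff d lies strictly inside the circumcircle of triangle abc (any
# orientation; the triangle is reoriented CCW first)
incircle <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  if (orient < 0) { # swap b and c to make CCW
    t1 <- bx; bx <- cx; cx <- t1
    t2 <- by; by <- cy; cy <- t2
  }
  adx <- ax - dx; ady <- ay - dy
  bdx <- bx - dx; bdy <- by - dy
  cdx <- cx - dx; cdy <- cy - dy
  ad <- adx * adx + ady * ady
  bd <- bdx * bdx + bdy * bdy
  cd <- cdx * cdx + cdy * cdy
  adx * (bdy * cd - bd * cdy) -
    ady * (bdx * cd - bd * cdx) +
    ad * (bdx * cdy - bdy * cdx)
}

#' Delaunay triangulation edges of a planar point set
#'
#' @param points numeric matrix (n x 2), n >= 3, no duplicate points.
#' @return integer matrix (m x 2) of edges as 1-based row indices into
#'   `points`, each row `i < j`, sorted lexicographically; `NULL` when the
#'   points are all collinear (no triangle exists).
#' @export
delaunay_edges <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (anyDuplicated(points)) stop("duplicate points are not allowed", call. = FALSE)

  px <- points[, 1]; py <- points[, 2]
  # super-triangle comfortably enclosing everything
  # The super-triangle must lie outside the circumcircle of every triangle
  # of the final triangulation, including hull slivers whose circumradius
  # can be orders of magnitude larger than the data extent; 1e5 x the
  # extent keeps those correct while staying well inside double precision.
  minx <- min(px); maxx <- max(px); miny <- min(py); maxy <- max(py)
  dmax <- max(maxx - minx, maxy - miny, 1)
  midx <- (minx + maxx) / 2; midy <- (miny + maxy) / 2
  big <- 1e5 * dmax
  sx <- c(midx - big, midx, midx + big)
  sy <- c(midy - big / 2, midy + big, midy - big / 2)
  X <- c(px, sx); Y <- c(py, sy)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- matrix(c(s1, s2, s3), ncol = 3)   # rows: vertex index triples
  for (p in seq_len(n)) {
    bad <- logical(nrow(tris))
    for (t in seq_len(nrow(tris))) {
      v <- tris[t, ]
      bad[t] <- incircle(X[v[1]], Y[v[1]], X[v[2]], Y[v[2]],
                         X[v[3]], Y[v[3]], X[p], Y[p]) > 0
    }
    if (!any(bad)) {
      # p collinear-degenerate w.r.t. current triangulation can't happen
      # with a finite super-triangle; guard anyway
      next
    }
    # boundary polygon: edges of bad triangles not shared by two bad ones
    edges <- NULL
    for (t in which(bad)) {
      v <- tris[t, ]
      edges <- rbind(edges,
                     c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    single <- !(key %in% key[duplicated(key)])
    edges <- edges[single, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    if (nrow(edges) > 0L) {
      tris <- rbind(tris, cbind(edges[, 1], edges[, 2], p))
    }
  }
  # drop triangles touching the super-triangle
  keep <- rowSums(tris > n) == 0L
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L) return(NULL)      # collinear input
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}
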