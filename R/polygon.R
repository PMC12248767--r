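#' Convex hull polygon of a point set
#'
#' Smallest convex polygon containing all the points, with vertices in
#' counterclockwise order (in the image convention: x right, y down, so
#' "counterclockwise" means positive shoelace value). Degenerate inputs
#' (fewer than 3 distinct points, or all collinear) yield `NULL`, the
#' degenerate-polygon signal; callers skip the correspondence with a
#' warning.
#'
#' @param points numeric matrix (n x 2) of `(x, y)`.
#' @param source `"HE"` or `"DAPI"` provenance tag.
#' @return a `nucleus_polygon` (list with `vertices`, `area`, `source`) or
#'   `NULL` when degenerate.
#' @export
convex_hull <- function(points, source = "HE") {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pts <- unique(points)
  if (nrow(pts) < 3L) return(NULL)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(NULL)
  verts <- pts[h, , drop = FALSE]
  a <- shoelace_area(verts)
  if (abs(a) < 1e-12) return(NULL)       # collinear
  if (a < 0) {
    verts <- verts[rev(seq_len(nrow(verts))), , drop = FALSE]
    a <- -a
  }
  colnames(verts) <- c("x", "y")
  structure(list(vertices = verts, area = a, source = source),
            class = "nucleus_polygon")
}

# signed shoelace area; positive for counterclockwise order under the
# image-axis convention used throughout
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

poly_vertices <- function(p) if (inherits(p, "nucleus_polygon")) p$vertices else p

poly_area <- function(p) {
  if (inherits(p, "nucleus_polygon")) return(p$area)
  abs(shoelace_area(p))
}

#' Map a polygon pair into a shared frame
#'
#' The H&E polygon is scaled by the per-axis image-dimension ratios
#' (`sx = W_DAPI / W_HE`, `sy = L_DAPI / L_HE`, matching the proportional
#' center mapping of [map_center()]), then both polygons are translated so
#' their bounding-box midpoints sit at the origin. Centering on the
#' keypoint makes the subsequent overlap a pure shape-and-size comparison.
#'
#' @param p_he,p_dapi `nucleus_polygon`s (or vertex matrices).
#' @param scale length-2 numeric `(sx, sy)` applied to the H&E polygon;
#'   `c(1, 1)` disables rescaling.
#' @return list of two centered `nucleus_polygon`s (`he`, `dapi`).
#' @export
normalize_pair <- function(p_he, p_dapi, scale = c(1, 1)) {
  if (any(scale <= 0)) stop("`scale` components must be > 0", call. = FALSE)
  vh <- poly_vertices(p_he)
  vh <- cbind(vh[, 1] * scale[1], vh[, 2] * scale[2])
  vd <- poly_vertices(p_dapi)
  center <- function(v) {
    mid <- bbox_midpoint(v)
    cbind(x = v[, 1] - mid[1], y = v[, 2] - mid[2])
  }
  list(he = convex_hull(center(vh), source = "HE"),
       dapi = convex_hull(center(vd), source = "DAPI"))
}

#' Intersection area of two convex polygons
#'
#' Clips one convex polygon against the other (Sutherland-Hodgman) and
#' returns the shoelace area of the intersection; 0 when disjoint.
#'
#' @param p_a,p_b convex `nucleus_polygon`s or CCW vertex matrices.
#' @return intersection area in squared pixels.
#' @export
intersection_area <- function(p_a, p_b) {
  a <- ccw_vertices(p_a)
  b <- ccw_vertices(p_b)
  out <- clip_convex(a, b)
  if (is.null(out) || nrow(out) < 3L) return(0)
  abs(shoelace_area(out))
}

ccw_vertices <- function(p) {
  v <- poly_vertices(p)
  if (shoelace_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

# Sutherland-Hodgman: clip subject polygon against each edge of the convex
# CCW clipper; vertices deduplicated at 1e-9 for numeric robustness
clip_convex <- function(subject, clipper) {
  out <- subject
  n <- nrow(clipper)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    p1 <- clipper[i, ]
    p2 <- clipper[if (i == n) 1L else i + 1L, ]
    # inside = left of directed edge p1->p2 (CCW polygon interior)
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    side <- ex * (out[, 2] - p1[2]) - ey * (out[, 1] - p1[1])
    inside <- side >= -1e-12
    m <- nrow(out)
    nxt <- c(2:m, 1L)
    res <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(m)) {
      cur <- out[k, ]; nx <- out[nxt[k], ]
      if (inside[k]) res <- rbind(res, cur)
      if (xor(inside[k], inside[nxt[k]])) {
        d <- side[k] - side[nxt[k]]
        t <- if (abs(d) < 1e-300) 0 else side[k] / d
        res <- rbind(res, cur + t * (nx - cur))
      }
    }
    out <- dedup_vertices(res)
  }
  out
}

dedup_vertices <- function(v, tol = 1e-9) {
  if (is.null(v) || nrow(v) < 2L) return(v)
  keep <- rep(TRUE, nrow(v))
  for (k in 2:nrow(v)) {
    if (all(abs(v[k, ] - v[k - 1L, ]) < tol)) keep[k] <- FALSE
  }
  v <- v[keep, , drop = FALSE]
  if (nrow(v) > 1L && all(abs(v[nrow(v), ] - v[1L, ]) < tol)) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  v
}

#' Overlap indexes of two nucleus polygons
#'
#' With intersection area `I` and polygon areas `S` (H&E) and `T` (DAPI):
#' the average index is `(I/S + I/T) / 2` and the minimum index is
#' `min(I/S, I/T)`. Both equal 1 exactly when the polygons coincide; the
#' minimum index is the stricter of the two.
#'
#' @param p_a,p_b convex `nucleus_polygon`s with positive area.
#' @return an `overlap_score`: list with `intersection_area`, `index_avg`,
#'   `index_min`.
#' @export
overlap_indexes <- function(p_a, p_b) {
  s <- poly_area(p_a)
  t <- poly_area(p_b)
  if (s <= 0 || t <= 0) stop("polygon areas must be positive", call. = FALSE)
  i <- intersection_area(p_a, p_b)
  structure(list(intersection_area = i,
                 index_avg = (i / s + i / t) / 2,
                 index_min = min(i / s, i / t)),
            class = "overlap_score")
}

#' Filter correspondences by nucleus-polygon overlap
#'
#' For each correspondence, builds the convex hull of the H&E boundary and
#' of the DAPI boundary, maps them into the shared frame
#' ([normalize_pair()]), computes the overlap index of the configured mode,
#' and keeps the pair iff the index is at or above the threshold (pairs
#' strictly below it are removed). Degenerate polygons drop the pair with
#' a warning.
#'
#' @param pairs list of correspondences; each element needs `he_boundary`
#'   and `dapi_boundary` vertex matrices.
#' @param mode `"average"` (default threshold 0.9) or `"minimum"` (default
#'   threshold 0.92).
#' @param threshold keep threshold in (0, 1].
#' @param scale length-2 H&E-to-DAPI scale passed to [normalize_pair()].
#' @return the kept subset of `pairs`, each element annotated with an
#'   `overlap` score.
#' @export
polygon_filter <- function(pairs, mode = c("average", "minimum"),
                           threshold = NULL, scale = c(1, 1)) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "average") 0.9 else 0.92
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  kept <- list()
  degenerate <- 0L
  for (p in pairs) {
    hh <- convex_hull(p$he_boundary, "HE")
    hd <- convex_hull(p$dapi_boundary, "DAPI")
    if (is.null(hh) || is.null(hd)) { degenerate <- degenerate + 1L; next }
    np <- normalize_pair(hh, hd, scale)
    if (is.null(np$he) || is.null(np$dapi)) { degenerate <- degenerate + 1L; next }
    sc <- overlap_indexes(np$he, np$dapi)
    idx <- if (mode == "average") sc$index_avg else sc$index_min
    if (idx >= threshold) {
      p$overlap <- sc
      kept[[length(kept) + 1L]] <- p
    }
  }
  if (degenerate > 0L) {
    warning(sprintf("polygon_filter: dropped %d degenerate pair(s)", degenerate),
            call. = FALSE)
  }
  kept
}
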