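#' Delaunay triangulation graph of correspondence keypoints
#'
#' Builds the Delaunay triangulation of the given points and stores its
#' edge set keyed by the caller's correspondence indices (node ids), with
#' each edge normalised to `i < j` and the edge list sorted
#' lexicographically. Two such graphs — one per modality over the same
#' node ids — are the inputs to [consistency_filter()].
#'
#' @param points numeric matrix (n x 2) of `(x, y)` keypoint coordinates.
#' @param node_ids integer ids of the correspondences (defaults to
#'   `0:(n-1)`).
#' @return a `trigraph`: list with `node_ids`, `points`, `edges` (m x 2
#'   integer matrix of node-id pairs), `degenerate` flag.
#' @export
build_trigraph <- function(points, node_ids = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (length(node_ids) != n) stop("`node_ids` length mismatch", call. = FALSE)
  if (n < 3L) {
    return(structure(list(node_ids = as.integer(node_ids), points = points,
                          edges = matrix(integer(0), ncol = 2),
                          degenerate = TRUE),
                     class = "trigraph"))
  }
  pe <- delaunay_edges(points)     # errors on duplicates
  if (is.null(pe)) {
    return(structure(list(node_ids = as.integer(node_ids), points = points,
                          edges = matrix(integer(0), ncol = 2),
                          degenerate = TRUE),
                     class = "trigraph"))
  }
  ids <- as.integer(node_ids)
  e <- cbind(ids[pe[, 1]], ids[pe[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  structure(list(node_ids = ids, points = points, edges = e,
                 degenerate = FALSE),
            class = "trigraph")
}

#' @export
print.trigraph <- function(x, ...) {
  cat(sprintf("<trigraph: %d nodes, %d edges%s>\n", length(x$node_ids),
              nrow(x$edges), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# first position where two sorted edge lists disagree; returns the pair of
# trigger edges (either may be NULL when one list is exhausted)
first_edge_mismatch <- function(ea, eb) {
  na <- nrow(ea); nb <- nrow(eb)
  k <- 1L
  while (k <= na && k <= nb) {
    if (ea[k, 1] != eb[k, 1] || ea[k, 2] != eb[k, 2]) {
      return(list(a = ea[k, ], b = eb[k, ]))
    }
    k <- k + 1L
  }
  if (na == nb) return(NULL)
  if (k <= na) list(a = ea[k, ], b = NULL) else list(a = NULL, b = eb[k, ])
}

#' Remove outlier correspondences by Delaunay edge consistency
#'
#' Iteratively compares the sorted Delaunay edge sets of the two graphs
#' (which share node ids). While the edge sets differ: the first
#' disagreeing edge in each sorted list is located, the node with the
#' smaller first index among those two edges is removed from both point
#' sets, and both triangulations are rebuilt. Iteration stops when the
#' edge sets are identical or fewer than 3 nodes remain. Each pass removes
#' exactly one node, so termination is guaranteed.
#'
#' @param g_a,g_b `trigraph`s over the same `node_ids` (e.g. H&E-side and
#'   DAPI-side keypoints).
#' @param verbose emit a message for each removed node.
#' @return integer vector of surviving node ids, with attribute `removed`
#'   (ids in removal order). Degenerate inputs (< 3 nodes or collinear)
#'   skip filtering and return all ids with a warning.
#' @export
consistency_filter <- function(g_a, g_b, verbose = FALSE) {
  stopifnot(inherits(g_a, "trigraph"), inherits(g_b, "trigraph"))
  if (!identical(g_a$node_ids, g_b$node_ids)) {
    stop("graphs must share the same node ids", call. = FALSE)
  }
  if (g_a$degenerate || g_b$degenerate) {
    warning("degenerate triangulation: consistency filter skipped",
            call. = FALSE)
    out <- g_a$node_ids
    attr(out, "removed") <- integer(0)
    return(out)
  }
  ids <- g_a$node_ids
  pa <- g_a$points
  pb <- g_b$points
  ea <- g_a$edges
  eb <- g_b$edges
  removed <- integer(0)
  repeat {
    mm <- first_edge_mismatch(ea, eb)
    if (is.null(mm)) break
    firsts <- c(if (!is.null(mm$a)) mm$a[1], if (!is.null(mm$b)) mm$b[1])
    drop_id <- min(firsts)
    if (verbose) message(sprintf("consistency_filter: removing node %d", drop_id))
    removed <- c(removed, drop_id)
    keep <- ids != drop_id
    ids <- ids[keep]
    pa <- pa[keep, , drop = FALSE]
    pb <- pb[keep, , drop = FALSE]
    if (length(ids) < 3L) break
    ga <- build_trigraph(pa, ids)
    gb <- build_trigraph(pb, ids)
    if (ga$degenerate || gb$degenerate) {
      warning("triangulation became degenerate; stopping filter", call. = FALSE)
      break
    }
    ea <- ga$edges
    eb <- gb$edges
  }
  out <- ids
  attr(out, "removed") <- removed
  out
}
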