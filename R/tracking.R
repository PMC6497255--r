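# Skeleton analysis: thinning, crossing numbers, junction counting and
# ordered branch extraction.

#' Skeletonize a binary mask
#'
#' Topology-preserving medial-axis thinning (Zhang-Suen). Junction counts
#' depend only on topology, which any correct thinning preserves; this
#' variant keeps 8-connectivity and reduces shapes to 1-px centerlines.
#'
#' @param mask Binary matrix or [vessel_map()] object.
#' @return Integer 0/1 matrix of the same size.
#' @export
skeletonize <- function(mask) {
  px <- if (inherits(mask, "vessel_map")) mask$pixels else mask
  stopifnot(is.matrix(px))
  if (!is.integer(px)) px <- matrix(as.integer(px != 0), nrow(px), ncol(px))
  .cpp_thin(px)
}

#' Crossing number of a 3x3 skeleton neighborhood
#'
#' Half the sum of absolute binary transitions around the 8 neighbors taken
#' in cyclic order (the minutiae "ridge flow" rule): 1 = terminal, 2 = ridge
#' interior, 3 = fork, >= 4 = crossing.
#'
#' @param window 3x3 binary matrix whose center pixel must be foreground.
#' @return Integer crossing number.
#' @export
crossing_number <- function(window) {
  stopifnot(is.matrix(window), all(dim(window) == c(3, 3)))
  if (window[2, 2] == 0) stop("center pixel of the window is background")
  # cyclic order N, NE, E, SE, S, SW, W, NW
  p <- as.integer(window[cbind(
    c(1, 1, 2, 3, 3, 3, 2, 1),
    c(2, 3, 3, 3, 2, 1, 1, 1)
  )] != 0)
  sum(abs(p - c(p[-1], p[1]))) %/% 2L
}

#' Crossing numbers for every skeleton pixel
#'
#' @param skeleton Binary skeleton matrix.
#' @return Integer matrix: crossing number at skeleton pixels, `NA` elsewhere.
#' @export
crossing_numbers <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  .cpp_crossing_numbers(matrix(as.integer(skeleton != 0), nrow(skeleton),
                               ncol(skeleton)))
}

# Junction region: skeleton pixels within `radius` (Chebyshev) of any pixel
# with crossing number >= 3. Thick forks thin into junction pixels a few px
# apart; merging within a small radius keeps one counted junction per fork.
.junction_region <- function(skeleton, cn, radius = 1) {
  junc <- matrix(0L, nrow(skeleton), ncol(skeleton))
  junc[!is.na(cn) & cn >= 3] <- 1L
  if (!any(junc == 1L) || radius == 0) return(junc)
  dil <- .cpp_dilate8(junc, as.integer(radius))
  matrix(as.integer(dil != 0 & skeleton != 0), nrow(skeleton),
         ncol(skeleton))
}

# Shared traversal: junction clusters, their attachment degrees, and the
# ordered branches of the skeleton minus the junction region.
.skeleton_analysis <- function(skeleton, merge_radius = 2) {
  sk <- if (is.integer(skeleton)) {
    skeleton
  } else {
    matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  }
  cn <- .cpp_crossing_numbers(sk)
  region <- .junction_region(sk, cn, merge_radius)
  clusters <- .cpp_label8(region)
  nclust <- max(clusters, 0L)
  res <- .cpp_trace_branches(sk, region)
  H <- nrow(sk)
  W <- ncol(sk)
  adj_clusters <- function(pt) {
    rs <- max(1, pt[1] - 1):min(H, pt[1] + 1)
    cs <- max(1, pt[2] - 1):min(W, pt[2] + 1)
    u <- unique(as.vector(clusters[rs, cs]))
    u[u > 0]
  }
  degree <- integer(nclust)
  touches <- vector("list", length(res$branches))
  branches <- vector("list", length(res$branches))
  for (i in seq_along(res$branches)) {
    b <- res$branches[[i]]
    pts <- b$points
    n <- nrow(pts)
    ends <- if (n == 1) list(pts[1, ]) else list(pts[1, ], pts[n, ])
    at_cl <- lapply(ends, adj_clusters)
    for (u in at_cl) degree[u] <- degree[u] + 1L
    touches[[i]] <- unique(unlist(at_cl))
    len <- if (n >= 2) {
      sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-n, , drop = FALSE])^2)))
    } else {
      0
    }
    branches[[i]] <- list(points = pts, closed = b$closed, length_px = len)
  }
  # flag branches attached to a crossing cluster: their centerline near the
  # overlap is projection geometry, not vessel geometry
  crossing <- which(degree >= 4L)
  for (i in seq_along(branches)) {
    branches[[i]]$near_crossing <- any(touches[[i]] %in% crossing)
  }
  # terminal clusters: 8-connected groups of crossing-number-1 pixels
  term <- matrix(0L, H, W)
  term[!is.na(cn) & cn == 1] <- 1L
  j1 <- max(.cpp_label8(term), 0L)
  list(
    branches = branches, branch_id = res$branch_id, cn = cn,
    region = region, clusters = clusters, degree = degree,
    junctions = list(
      j1 = j1,
      j2 = sum(degree == 3L),
      j3 = sum(degree >= 4L)
    )
  )
}

#' Count skeleton junctions
#'
#' Terminal points (j1) are 8-connected clusters of pixels with crossing
#' number 1. Forks and crossings are found by merging junction pixels
#' (crossing number >= 3) that lie within `merge_radius` pixels of each
#' other -- thinning a thick fork or an overlap crossing leaves junction
#' pixels a few pixels apart -- and typing each merged cluster by the
#' number of branches attached to it: 3 attachments is a bifurcation (j2),
#' 4 or more a crossing (j3). Crossings are where two distinct vessels
#' overlap in projection rather than truly joining.
#'
#' @param skeleton Binary skeleton matrix.
#' @param merge_radius Chebyshev merge radius for junction pixels
#'   (default 2).
#' @return List with integer counts `j1`, `j2`, `j3`.
#' @export
count_junctions <- function(skeleton, merge_radius = 2) {
  .skeleton_analysis(skeleton, merge_radius)$junctions
}

#' Extract ordered branches from a skeleton
#'
#' The merged junction region (see [count_junctions()]) is removed; every
#' remaining 8-connected run of skeleton pixels becomes one branch with its
#' pixels in walk order. Components without endpoints are cycles and are
#' flagged closed. Branch pixel sets cover the skeleton minus the junction
#' clusters.
#'
#' @param skeleton Binary skeleton matrix.
#' @param merge_radius Junction merge radius (default 2).
#' @return List with `branches` (each a list `points` (n x 2 matrix of
#'   row/col indices), `closed`, `length_px` arc length in px) and
#'   `branch_id` (integer matrix mapping skeleton pixels to branch ids,
#'   0 in the junction region).
#' @export
extract_branches <- function(skeleton, merge_radius = 2) {
  a <- .skeleton_analysis(skeleton, merge_radius)
  list(branches = a$branches, branch_id = a$branch_id)
}
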