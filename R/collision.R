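#' Needle segment
#'
#' The needle is modeled as a rigid straight segment from the tip to the end
#' of the exposed shaft.
#'
#' @param tip,tail 3D points in mm; must differ.
#' @return An object of class `needle_segment`.
#' @export
needle_segment <- function(tip, tail) {
  tip <- as.numeric(tip)
  tail <- as.numeric(tail)
  stopifnot(length(tip) == 3, length(tail) == 3)
  if (!all(is.finite(c(tip, tail))))
    stop("needle segment endpoints must be finite", call. = FALSE)
  if (all(tip == tail))
    stop("needle segment tip and tail must differ", call. = FALSE)
  structure(list(tip = tip, tail = tail), class = "needle_segment")
}

# Gather all triangles of active structures into a flat "soup":
# corner matrices, structure names, face indices, per-triangle bboxes.
scene_soup <- function(scene) {
  act <- names(scene$structures)[vapply(scene$structures,
                                        function(s) s$active, logical(1))]
  if (!length(act))
    stop("scene has no active structures", call. = FALSE)
  parts <- lapply(act, function(nm) {
    co <- mesh_corners(scene$structures[[nm]]$mesh)
    list(A = co$A, B = co$B, C = co$C,
         structure = rep(nm, nrow(co$A)),
         face = seq_len(nrow(co$A)))
  })
  A <- do.call(rbind, lapply(parts, `[[`, "A"))
  B <- do.call(rbind, lapply(parts, `[[`, "B"))
  C <- do.call(rbind, lapply(parts, `[[`, "C"))
  list(A = A, B = B, C = C,
       structure = unlist(lapply(parts, `[[`, "structure")),
       face = unlist(lapply(parts, `[[`, "face")),
       tlo = pmin(A, B, C), thi = pmax(A, B, C),
       n = nrow(A))
}

#' Build an octree over a scene's active triangles
#'
#' Recursively partitions the scene's bounding box into eight octants; a cell
#' is subdivided while it holds more than `leaf_capacity` triangles, is above
#' `min_cell` in edge length and `max_depth` has not been reached. One shared
#' octree spans all active structures; each leaf references the (structure,
#' face) pairs whose bounding boxes overlap it.
#'
#' @param scene A [needle_scene()] with at least one active structure.
#' @param max_depth Maximum subdivision depth (root = depth 1).
#' @param min_cell Minimum child cell edge length in mm.
#' @param leaf_capacity Triangles per leaf below which subdivision stops.
#' @return An object of class `needle_octree` (root node, triangle soup,
#'   statistics).
#' @export
build_octree <- function(scene, max_depth = 10, min_cell = 1,
                         leaf_capacity = 16) {
  stopifnot(max_depth >= 1)
  soup <- scene_soup(scene)
  pad <- 1e-9 + 1e-9 * max(abs(soup$thi))
  lo <- apply(soup$tlo, 2, min) - pad
  hi <- apply(soup$thi, 2, max) + pad
  stats <- new.env(parent = emptyenv())
  stats$nodes <- 0L
  stats$leaves <- 0L
  stats$max_depth <- 0L

  build <- function(idx, lo, hi, depth) {
    stats$nodes <- stats$nodes + 1L
    stats$max_depth <- max(stats$max_depth, depth)
    if (length(idx) <= leaf_capacity || depth >= max_depth ||
        min(hi - lo) / 2 < min_cell) {
      stats$leaves <- stats$leaves + 1L
      return(list(lo = lo, hi = hi, depth = depth, tri = idx,
                  children = NULL))
    }
    mid <- (lo + hi) / 2
    children <- vector("list", 8)
    k <- 1L
    tlo <- soup$tlo
    thi <- soup$thi
    for (iz in 0:1) for (iy in 0:1) for (ix in 0:1) {
      clo <- c(if (ix) mid[1] else lo[1],
               if (iy) mid[2] else lo[2],
               if (iz) mid[3] else lo[3])
      chi <- c(if (ix) hi[1] else mid[1],
               if (iy) hi[2] else mid[2],
               if (iz) hi[3] else mid[3])
      sel <- idx[tlo[idx, 1] <= chi[1] & thi[idx, 1] >= clo[1] &
                 tlo[idx, 2] <= chi[2] & thi[idx, 2] >= clo[2] &
                 tlo[idx, 3] <= chi[3] & thi[idx, 3] >= clo[3]]
      children[[k]] <- build(sel, clo, chi, depth + 1L)
      k <- k + 1L
    }
    list(lo = lo, hi = hi, depth = depth, tri = NULL, children = children)
  }

  root <- build(seq_len(soup$n), lo, hi, 1L)
  structure(list(root = root, soup = soup,
                 params = list(max_depth = max_depth, min_cell = min_cell,
                               leaf_capacity = leaf_capacity),
                 stats = list(nodes = stats$nodes, leaves = stats$leaves,
                              depth = stats$max_depth)),
            class = "needle_octree")
}

#' @export
print.needle_octree <- function(x, ...) {
  cat(sprintf("<needle_octree: %d triangles, %d nodes (%d leaves), depth %d>\n",
              x$soup$n, x$stats$nodes, x$stats$leaves, x$stats$depth))
  invisible(x)
}

#' Octree statistics
#'
#' @param octree A [build_octree()] result.
#' @return List with `nodes`, `leaves`, `depth`, `triangles`.
#' @export
octree_stats <- function(octree) {
  c(octree$stats, list(triangles = octree$soup$n))
}

.proximity_result <- function(distance, structure, face, closest_point) {
  structure(list(distance = distance, structure = structure, face = face,
                 closest_point = closest_point),
            class = "proximity_result")
}

# Best candidate among soup triangles `idx`; ties broken by lexicographic
# (structure, face).
.best_of <- function(soup, idx, p, q) {
  r <- segment_triangles_distance(p, q,
                                  soup$A[idx, , drop = FALSE],
                                  soup$B[idx, , drop = FALSE],
                                  soup$C[idx, , drop = FALSE])
  ord <- order(r$dist, soup$structure[idx], soup$face[idx])[1]
  list(distance = r$dist[ord], structure = soup$structure[idx[ord]],
       face = soup$face[idx[ord]], closest_point = r$point[ord, ])
}

.better <- function(a, b) {
  # is candidate a better than incumbent b?
  if (a$distance < b$distance) return(TRUE)
  if (a$distance > b$distance) return(FALSE)
  if (a$structure < b$structure) return(TRUE)
  if (a$structure > b$structure) return(FALSE)
  a$face < b$face
}

#' Nearest triangle to a needle segment
#'
#' Best-first branch-and-bound descent of the octree: octants are visited in
#' order of their box-to-segment distance lower bound and pruned once that
#' bound exceeds the best distance found, so the result is the exact global
#' minimum over all indexed triangles (it matches [brute_force_nearest()] to
#' floating-point precision). Equidistant faces are tie-broken by lowest
#' (structure name, face index).
#'
#' @param octree A [build_octree()] result.
#' @param segment A [needle_segment()].
#' @return A `proximity_result`: `distance` (mm), `structure`, `face`,
#'   `closest_point` (on the reported face).
#' @export
query_nearest <- function(octree, segment) {
  soup <- octree$soup
  p <- segment$tip
  q <- segment$tail
  slo <- pmin(p, q)
  shi <- pmax(p, q)
  best <- list(distance = Inf, structure = "", face = 0L,
               closest_point = c(NA_real_, NA_real_, NA_real_))
  visit <- function(node) {
    if (.aabb_gap_dist(slo, shi, node$lo, node$hi) > best$distance) return()
    if (is.null(node$children)) {
      if (!length(node$tri)) return()
      cand <- .best_of(soup, node$tri, p, q)
      if (.better(cand, best)) best <<- cand
    } else {
      bounds <- vapply(node$children, function(ch)
        .aabb_gap_dist(slo, shi, ch$lo, ch$hi), numeric(1))
      for (j in order(bounds)) {
        if (bounds[j] > best$distance) break
        visit(node$children[[j]])
      }
    }
  }
  visit(octree$root)
  .proximity_result(best$distance, best$structure, best$face,
                    best$closest_point)
}

#' Exhaustive nearest-triangle oracle
#'
#' Scans every triangle of every active structure. Same contract and
#' tie-breaking as [query_nearest()]; used as the reference the octree query
#' is verified against.
#'
#' @param scene A [needle_scene()].
#' @param segment A [needle_segment()].
#' @return A `proximity_result`.
#' @export
brute_force_nearest <- function(scene, segment) {
  soup <- scene_soup(scene)
  b <- .best_of(soup, seq_len(soup$n), segment$tip, segment$tail)
  .proximity_result(b$distance, b$structure, b$face, b$closest_point)
}

#' Segment-triangle intersection
#'
#' Exact parametric intersection of a needle segment with one triangle.
#' Boundary touches count as hits.
#'
#' @param segment A [needle_segment()].
#' @param triangle 3 x 3 numeric matrix, one vertex per row.
#' @return The intersection point (3-vector) or `NULL`.
#' @export
segment_triangle_intersection <- function(segment, triangle) {
  triangle <- matrix(as.numeric(triangle), ncol = 3)
  stopifnot(nrow(triangle) == 3)
  if (.norm3(.cross3(triangle[2, ] - triangle[1, ],
                     triangle[3, ] - triangle[1, ])) <=
      .Machine$double.eps * 100)
    stop("degenerate triangle", call. = FALSE)
  r <- segment_triangles_intersect(segment$tip, segment$tail,
                                   triangle[1, , drop = FALSE],
                                   triangle[2, , drop = FALSE],
                                   triangle[3, , drop = FALSE])
  if (!r$hit[1]) return(NULL)
  as.numeric(r$point[1, ])
}

#' Surface crossings along a needle step
#'
#' All points where the straight step from `p0` to `p1` crosses an active
#' structure's surface, ordered by the step parameter. Each crossing is
#' classified `entering` or `exiting` from the orientation of the (watertight,
#' outward-wound) face it crosses. Grazing contacts parallel to a face are not
#' crossings and are dropped; coincident duplicate hits (a step passing
#' through a shared edge or vertex) are collapsed.
#'
#' @param octree A [build_octree()] result for the scene.
#' @param p0,p1 Step endpoints (tip positions), mm.
#' @return Data frame with columns `t` (step parameter in `[0, 1]`),
#'   `structure`, `x`, `y`, `z`, `type` (`"entering"`/`"exiting"`).
#' @export
crossings_along_step <- function(octree, p0, p1) {
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  if (!all(is.finite(c(p0, p1))))
    stop("step endpoints must be finite", call. = FALSE)
  empty <- data.frame(t = numeric(0), structure = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (all(p0 == p1)) return(empty)
  soup <- octree$soup
  r <- segment_triangles_intersect(p0, p1, soup$A, soup$B, soup$C)
  if (!any(r$hit)) return(empty)
  idx <- which(r$hit)
  nrm <- .cross_rows(soup$B[idx, , drop = FALSE] - soup$A[idx, , drop = FALSE],
                     soup$C[idx, , drop = FALSE] - soup$A[idx, , drop = FALSE])
  dd <- as.vector(nrm %*% (p1 - p0))
  keep <- dd != 0
  idx <- idx[keep]
  if (!length(idx)) return(empty)
  dd <- dd[keep]
  df <- data.frame(t = pmin(1, pmax(0, r$t[idx])),
                   structure = soup$structure[idx],
                   x = r$point[idx, 1], y = r$point[idx, 2],
                   z = r$point[idx, 3],
                   type = ifelse(dd < 0, "entering", "exiting"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$t, df$type == "entering", df$structure), , drop = FALSE]
  # collapse coincident duplicates (same structure + type within tolerance)
  if (nrow(df) > 1) {
    dup <- logical(nrow(df))
    for (i in 2:nrow(df)) {
      prev <- which(!dup[seq_len(i - 1)])
      prev <- prev[df$structure[prev] == df$structure[i] &
                   df$type[prev] == df$type[i] &
                   abs(df$t[prev] - df$t[i]) < 1e-9]
      if (length(prev)) dup[i] <- TRUE
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
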