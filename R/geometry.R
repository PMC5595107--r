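# Low-level vectorized geometry kernels. All routines take one query point or
# segment and N triangles/edges as row matrices, and are exact up to floating
# point: no spatial approximation happens at this level.

.dot3 <- function(a, b) sum(a * b)

.norm3 <- function(a) sqrt(sum(a * a))

.unit3 <- function(a) {
  n <- .norm3(a)
  if (n == 0) stop("zero-length vector cannot be normalized", call. = FALSE)
  a / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of two N x 3 matrices.
.cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

.rep_row <- function(v, n) matrix(v, nrow = n, ncol = 3, byrow = TRUE)

.clamp01 <- function(x) pmin(1, pmax(0, x))

# Closest point on each triangle (A,B,C rows) to a single point p.
# Region-based algorithm over the triangle's Voronoi regions (vertices, edges,
# interior), fully vectorized. Returns list(point = N x 3, dist = N).
closest_point_triangles <- function(p, A, B, C) {
  n <- nrow(A)
  ab <- B - A
  ac <- C - A
  P <- .rep_row(p, n)
  ap <- P - A
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  out <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  safe <- function(x) ifelse(is.finite(x), x, 0)

  m <- !done & d1 <= 0 & d2 <= 0                       # vertex A
  out[m, ] <- A[m, , drop = FALSE]
  done <- done | m
  m <- !done & d3 >= 0 & d4 <= d3                      # vertex B
  out[m, ] <- B[m, , drop = FALSE]
  done <- done | m
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0             # edge AB
  v <- safe(d1 / (d1 - d3))
  out[m, ] <- A[m, , drop = FALSE] + v[m] * ab[m, , drop = FALSE]
  done <- done | m
  m <- !done & d6 >= 0 & d5 <= d6                      # vertex C
  out[m, ] <- C[m, , drop = FALSE]
  done <- done | m
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0             # edge AC
  w <- safe(d2 / (d2 - d6))
  out[m, ] <- A[m, , drop = FALSE] + w[m] * ac[m, , drop = FALSE]
  done <- done | m
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  w <- safe((d4 - d3) / ((d4 - d3) + (d5 - d6)))
  out[m, ] <- B[m, , drop = FALSE] +
    w[m] * (C[m, , drop = FALSE] - B[m, , drop = FALSE])
  done <- done | m
  m <- !done                                           # interior
  if (any(m)) {
    denom <- va + vb + vc
    v <- safe(vb / denom)
    w <- safe(vc / denom)
    out[m, ] <- A[m, , drop = FALSE] +
      v[m] * ab[m, , drop = FALSE] + w[m] * ac[m, , drop = FALSE]
  }
  list(point = out, dist = sqrt(rowSums((out - P)^2)))
}

# Closest points between one segment (p1,q1) and N segments (rows of P2,Q2).
# Returns list(dist, on_seg = N x 3 points on (p1,q1), on_other = N x 3).
closest_segment_segments <- function(p1, q1, P2, Q2) {
  n <- nrow(P2)
  d1 <- q1 - p1
  D2 <- Q2 - P2
  R <- .rep_row(p1, n) - P2
  a <- .dot3(d1, d1)
  e <- rowSums(D2 * D2)
  f <- rowSums(D2 * R)
  cc <- as.vector(R %*% d1)     # dot(d1, p1 - P2) per row
  b <- as.vector(D2 %*% d1)
  denom <- a * e - b * b
  eps <- 1e-14 * pmax(1, a * e)
  s <- ifelse(denom > eps, .clamp01((b * f - cc * e) / denom), 0)
  t <- ifelse(e > 0, (b * s + f) / e, 0)
  lo <- t < 0
  hi <- t > 1
  t[lo] <- 0
  t[hi] <- 1
  if (a > 0) {
    s[lo] <- .clamp01(-cc[lo] / a)
    s[hi] <- .clamp01((b[hi] - cc[hi]) / a)
  }
  on_seg <- .rep_row(p1, n) + s * .rep_row(d1, n)
  on_other <- P2 + t * D2
  list(dist = sqrt(rowSums((on_seg - on_other)^2)),
       on_seg = on_seg, on_other = on_other)
}

# Parametric intersection of segment (p,q) with N triangles. Boundary touches
# count as hits (barycentric tolerance). Near-parallel (coplanar) segments
# report no hit here; the distance kernel still resolves them through edge and
# vertex terms. Returns list(hit = logical N, t = N, point = N x 3).
segment_triangles_intersect <- function(p, q, A, B, C, tol = 1e-10) {
  n <- nrow(A)
  d <- q - p
  nrm <- .cross_rows(B - A, C - A)
  denom <- as.vector(nrm %*% d)
  scale <- sqrt(rowSums(nrm^2)) * .norm3(d)
  ap <- A - .rep_row(p, n)
  tnum <- rowSums(nrm * ap)
  t <- ifelse(abs(denom) > 1e-13 * pmax(scale, 1e-300), tnum / denom, NA_real_)
  cand <- !is.na(t) & t >= -tol & t <= 1 + tol
  X <- .rep_row(p, n) + .clamp01(ifelse(is.na(t), 0, t)) * .rep_row(d, n)
  # barycentric inside test for candidate rows
  v0 <- B - A
  v1 <- C - A
  v2 <- X - A
  d00 <- rowSums(v0 * v0)
  d01 <- rowSums(v0 * v1)
  d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0)
  d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- ifelse(den > 0, (d11 * d20 - d01 * d21) / den, -1)
  w <- ifelse(den > 0, (d00 * d21 - d01 * d20) / den, -1)
  u <- 1 - v - w
  hit <- cand & v >= -tol & w >= -tol & u >= -tol
  list(hit = hit, t = t, point = X)
}

# Exact segment-to-triangle distance for N triangles: zero when intersecting,
# otherwise the minimum over endpoint-triangle and edge-edge distances.
# Returns list(dist = N, point = N x 3 closest point on each triangle).
segment_triangles_distance <- function(p, q, A, B, C) {
  n <- nrow(A)
  best <- rep(Inf, n)
  bp <- matrix(NA_real_, n, 3)
  take <- function(d, pts) {
    m <- d < best
    if (any(m)) {
      best[m] <<- d[m]
      bp[m, ] <<- pts[m, , drop = FALSE]
    }
  }
  r <- closest_point_triangles(p, A, B, C)
  take(r$dist, r$point)
  r <- closest_point_triangles(q, A, B, C)
  take(r$dist, r$point)
  for (edge in list(list(A, B), list(B, C), list(C, A))) {
    r <- closest_segment_segments(p, q, edge[[1]], edge[[2]])
    take(r$dist, r$on_other)
  }
  ints <- segment_triangles_intersect(p, q, A, B, C)
  if (any(ints$hit)) {
    best[ints$hit] <- 0
    bp[ints$hit, ] <- ints$point[ints$hit, , drop = FALSE]
  }
  list(dist = best, point = bp)
}

# Distance lower bound between the AABB of a segment and a node box.
.aabb_gap_dist <- function(slo, shi, blo, bhi) {
  gap <- pmax(0, blo - shi, slo - bhi)
  sqrt(sum(gap^2))
}
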