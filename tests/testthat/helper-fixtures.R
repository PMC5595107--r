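# Shared fixtures: random triangle soups, reference slab, independent oracles.

# A scene holding a random soup of small triangles: centroids uniform in
# [0, span]^3, vertices within +/- tri_size of the centroid.
random_soup_scene <- function(seed, n_tri = 50, span = 20, tri_size = 1.5) {
  set.seed(seed)
  ctr <- matrix(runif(3 * n_tri, 0, span), n_tri, 3)
  v <- matrix(NA_real_, 3 * n_tri, 3)
  for (i in seq_len(n_tri))
    v[(3 * i - 2):(3 * i), ] <- matrix(ctr[i, ], 3, 3, byrow = TRUE) +
      matrix(runif(9, -tri_size, tri_size), 3, 3)
  f <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  mesh <- triangle_mesh("soup", v, f, drop_degenerate = TRUE)
  needle_scene(list(soup = list(mesh = mesh,
                                tissue = tissue_model("soup", 0.1),
                                active = TRUE)))
}

random_segment <- function(seed, span = 20) {
  set.seed(seed)
  needle_segment(runif(3, 0, span), runif(3, 0, span))
}

# Three-layer slab used across the haptics and session tests.
ref_slab <- function() {
  generate_slab_phantom(data.frame(name = c("mucosa", "muscle", "bone"),
                                   thickness = c(2, 10, 8),
                                   stiffness = c(0.25, 0.35, 2.5)),
                        lateral_size = 30, seed = 1)
}

ref_slab_calibration <- function() {
  calibration_table(k = c(mucosa = 0.25, muscle = 0.35, bone = 2.5),
                    device_max_force = 1e6)  # no clamping in analytic checks
}

# Straight -z trajectory through the slab center hitting the given depths
# (depth = -z below the surface z = 0).
slab_trajectory <- function(depths, start_z = 2) {
  z <- c(start_z, -depths)
  data.frame(t = seq_along(z) * 0.05, x = 0, y = 0, z = z,
             dx = 0, dy = 0, dz = -1)
}

# Analytic piecewise-linear force-depth curve for the reference slab:
# within layer i the force is k_i * (depth - layer_top), restarting at zero
# at each boundary (current-tissue-only model).
slab_analytic_force <- function(depth, ks = c(0.25, 0.35, 2.5),
                                bounds = c(0, 2, 12, 20)) {
  i <- findInterval(depth, bounds, rightmost.closed = TRUE)
  ifelse(depth <= 0 | depth >= max(bounds), NA_real_, ks[i] * (depth - bounds[i]))
}

# Independent segment-triangle intersection oracle via signed volumes
# (orientation predicates), used to cross-check the parametric kernel.
orient3d <- function(a, b, c, d) {
  det(rbind(b - a, c - a, d - a))
}

segtri_intersect_oracle <- function(p, q, A, B, C, tol = 1e-12) {
  d1 <- orient3d(A, B, C, p)
  d2 <- orient3d(A, B, C, q)
  if (d1 * d2 > tol) return(FALSE)          # both endpoints strictly same side
  s1 <- orient3d(p, q, A, B)
  s2 <- orient3d(p, q, B, C)
  s3 <- orient3d(p, q, C, A)
  pos <- c(s1, s2, s3) >= -tol
  neg <- c(s1, s2, s3) <= tol
  all(pos) || all(neg)
}

# Rigid transform (rotation + translation) from a seed.
random_rigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, tr = runif(3, -5, 5))
}

apply_rigid_scene <- function(scene, rigid) {
  for (nm in names(scene$structures)) {
    v <- scene$structures[[nm]]$mesh$vertices
    scene$structures[[nm]]$mesh$vertices <-
      v %*% t(rigid$R) + matrix(rigid$tr, nrow(v), 3, byrow = TRUE)
  }
  if (!is.null(scene$occlusal_plane)) {
    scene$occlusal_plane$point <-
      as.numeric(rigid$R %*% scene$occlusal_plane$point + rigid$tr)
    scene$occlusal_plane$normal <- as.numeric(rigid$R %*% scene$occlusal_plane$normal)
  }
  scene
}
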