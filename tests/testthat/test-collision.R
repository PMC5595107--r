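test_that("octree subdivision yields exactly eight children per internal node", {
  sc <- generate_ianb_scene(seed = 1)
  oct <- build_octree(sc, max_depth = 6, leaf_capacity = 16)
  counts <- integer(0)
  walk <- function(node) {
    if (!is.null(node$children)) {
      counts <<- c(counts, length(node$children))
      for (ch in node$children) walk(ch)
    }
  }
  walk(oct$root)
  expect_gt(length(counts), 0)
  expect_true(all(counts == 8L))

  # capacity rule: a scene below capacity keeps the root as a leaf
  tiny <- random_soup_scene(1, n_tri = 3)
  oct1 <- build_octree(tiny, leaf_capacity = 4)
  expect_null(oct1$root$children)
  expect_equal(octree_stats(oct1)$depth, 1L)
})

test_that("query_nearest matches the brute-force oracle on random scenes", {
  worst <- 0
  for (s in 1:200) {
    sc <- random_soup_scene(s)
    seg <- random_segment(10000 + s)
    a <- query_nearest(build_octree(sc), seg)
    b <- brute_force_nearest(sc, seg)
    worst <- max(worst, abs(a$distance - b$distance))
    expect_equal(a$face, b$face)
    expect_identical(a$structure, b$structure)
  }
  expect_lt(worst, 1e-9)
})

test_that("nearest queries handle contact, separation and planes exactly", {
  # segment 1 mm above a flat floor
  floor_v <- rbind(c(-10, -10, 0), c(10, -10, 0), c(10, 10, 0), c(-10, 10, 0))
  floor <- triangle_mesh("floor", floor_v, rbind(c(1, 2, 3), c(1, 3, 4)))
  sc <- needle_scene(list(floor = list(mesh = floor,
                                       tissue = tissue_model("floor", 1),
                                       active = TRUE)))
  seg <- needle_segment(c(0, 0, 1), c(3, 0, 1))
  expect_equal(query_nearest(build_octree(sc), seg)$distance, 1.0)
  expect_equal(brute_force_nearest(sc, seg)$distance, 1.0)

  # segment piercing the floor: distance 0 and the pierced face reported
  seg2 <- needle_segment(c(-1, -1, 1), c(-1, -1, -1))
  hit <- query_nearest(build_octree(sc), seg2)
  expect_equal(hit$distance, 0)
  expect_equal(hit$structure, "floor")
  expect_equal(hit$closest_point, c(-1, -1, 0))

  expect_error(brute_force_nearest(
    set_structure_active(sc, "floor", FALSE), seg), "no active structures")
})

test_that("brute-force distance agrees with dense point sampling", {
  sc <- random_soup_scene(99, n_tri = 10)
  seg <- needle_segment(c(30, 30, 30), c(32, 35, 31))  # far outside
  d <- brute_force_nearest(sc, seg)$distance
  # lower bound: sample many points on the segment and all triangle surfaces
  ts <- seq(0, 1, length.out = 400)
  pts_seg <- outer(ts, seg$tail - seg$tip)
  pts_seg <- sweep(pts_seg, 2, seg$tip, "+")
  soup <- needlesim:::scene_soup(sc)
  u <- runif(5000); v <- runif(5000)
  sw <- u + v > 1
  u[sw] <- 1 - u[sw]; v[sw] <- 1 - v[sw]
  i <- sample(soup$n, 5000, replace = TRUE)
  pts_tri <- (1 - u - v) * soup$A[i, ] + u * soup$B[i, ] + v * soup$C[i, ]
  dmin_sample <- min(sqrt(outer(rowSums(pts_seg^2), rowSums(pts_tri^2), "+") -
                            2 * pts_seg %*% t(pts_tri)))
  expect_lte(d, dmin_sample + 1e-9)     # exact min below any sampled distance
  expect_lt(dmin_sample - d, 0.5)       # and the sampling approaches it
})

test_that("segment-triangle intersection matches the signed-volume oracle", {
  tri <- rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 1, 0))
  seg <- needle_segment(c(0, 0, 1), c(0, 0, -1))
  expect_equal(segment_triangle_intersection(seg, tri), c(0, 0, 0))
  # coplanar non-crossing segment: no hit
  seg_cop <- needle_segment(c(2, 2, 0), c(3, 2, 0))
  expect_null(segment_triangle_intersection(seg_cop, tri))
  expect_error(segment_triangle_intersection(
    seg, rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))), "degenerate")

  set.seed(77)
  n_checked <- 0
  for (i in 1:500) {
    tri <- matrix(runif(9, -1, 1), 3, 3)
    p <- runif(3, -1.5, 1.5)
    q <- runif(3, -1.5, 1.5)
    o1 <- orient3d(tri[1, ], tri[2, ], tri[3, ], p)
    o2 <- orient3d(tri[1, ], tri[2, ], tri[3, ], q)
    if (abs(o1) < 1e-6 || abs(o2) < 1e-6) next  # skip near-degenerate setups
    got <- !is.null(segment_triangle_intersection(needle_segment(p, q), tri))
    want <- segtri_intersect_oracle(p, q, tri[1, ], tri[2, ], tri[3, ])
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 400)
})

test_that("nearest query is invariant under joint rigid transformation", {
  for (s in 1:20) {
    sc <- random_soup_scene(s, n_tri = 30)
    seg <- random_segment(500 + s)
    d0 <- query_nearest(build_octree(sc), seg)$distance
    rg <- random_rigid(900 + s)
    sc_t <- apply_rigid_scene(sc, rg)
    seg_t <- needle_segment(as.numeric(rg$R %*% seg$tip + rg$tr),
                            as.numeric(rg$R %*% seg$tail + rg$tr))
    d1 <- query_nearest(build_octree(sc_t), seg_t)$distance
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("crossings along a step respect closed-surface parity and order", {
  sc <- ref_slab()
  oct <- build_octree(sc)

  # full pass through the 3-layer slab: entering events in layer order
  cr <- crossings_along_step(oct, c(0, 0, 5), c(0, 0, -25))
  ent <- cr[cr$type == "entering", ]
  expect_equal(ent$structure, c("mucosa", "muscle", "bone"))
  ext <- cr[cr$type == "exiting", ]
  expect_equal(nrow(ext), 3)           # parity: 3 in, 3 out
  expect_true(all(diff(cr$t) >= 0))
  expect_equal(ent$z, c(0, -2, -12))   # crossing points at layer boundaries

  # zero-length step
  expect_equal(nrow(crossings_along_step(oct, c(0, 0, 5), c(0, 0, 5))), 0)

  # passing fully through one closed box: one entering + one exiting
  cube <- needle_scene(list(c1 = list(mesh = box_mesh("c1", c(0, 0, 0), c(2, 2, 2)),
                                      tissue = tissue_model("c1", 1),
                                      active = TRUE)))
  cr2 <- crossings_along_step(build_octree(cube), c(1, 1, 3), c(1, 1, -3))
  expect_equal(cr2$type, c("entering", "exiting"))
  expect_equal(cr2$structure, c("c1", "c1"))

  # parity property on random diagonal steps through the slab
  set.seed(11)
  for (i in 1:25) {
    p0 <- c(runif(2, -10, 10), runif(1, 3, 8))
    p1 <- c(runif(2, -10, 10), runif(1, -28, -22))
    cr3 <- crossings_along_step(oct, p0, p1)
    for (nm in unique(cr3$structure)) {
      sub <- cr3[cr3$structure == nm, ]
      expect_equal(sum(sub$type == "entering"), sum(sub$type == "exiting"))
    }
  }
})
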