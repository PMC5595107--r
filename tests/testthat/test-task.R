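test_that("insertion angle against the occlusal plane is exact", {
  plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  expect_equal(insertion_angle(c(1, 0, -1) / sqrt(2), plane), 45.0)
  expect_equal(insertion_angle(c(1, 0, 0), plane), 0)        # in-plane
  expect_equal(insertion_angle(c(0, 0, 1), plane), 90)       # along normal
  expect_error(insertion_angle(c(0, 0, 0), plane), "zero-length")

  # invariant under joint rigid transformation
  for (s in 1:20) {
    set.seed(s)
    d <- needlesim:::.unit3(rnorm(3))
    a0 <- insertion_angle(d, plane)
    rg <- random_rigid(300 + s)
    plane_t <- list(point = as.numeric(rg$R %*% plane$point + rg$tr),
                    normal = as.numeric(rg$R %*% plane$normal))
    a1 <- insertion_angle(as.numeric(rg$R %*% d), plane_t)
    expect_equal(a1, a0, tolerance = 1e-6)
  }
})

test_that("entry-point check applies the zone radius at the boundary", {
  zone <- list(center = c(0, 10, 7), radius = 4)
  hit <- check_entry_point(c(0, 10, 7), zone)
  expect_true(hit$pass)
  expect_equal(hit$distance, 0)
  edge <- check_entry_point(c(0, 10, 7 - 4.1), zone)   # radius + 0.1 mm
  expect_false(edge$pass)
  miss <- check_entry_point(NULL, zone)
  expect_false(miss$pass)
  expect_match(miss$message, "No insertion")
})

test_that("depth check measures tip-to-nerve distance analytically", {
  sc <- generate_ianb_scene(seed = 1, patient_profile = "child")
  A <- sc$landmarks$nerve_point
  r <- sc$landmarks$nerve_radius
  d45 <- needlesim:::.unit3(c(0, 1, -1))
  target <- mean(c(0.5, 3))                     # middle of the depth window
  tip <- A - (r + target) * d45
  chk <- check_depth(tip, sc, c(0.5, 3))
  expect_true(chk$pass)
  # analytic point-to-cylinder distance, up to the faceting of the 24-gon
  expect_equal(chk$distance, target, tolerance = 0.02)

  far <- check_depth(A - (r + 6) * d45, sc, c(0.5, 3))
  expect_false(far$pass)
  expect_match(far$message, "Too shallow")

  # tip exactly on the nerve surface: contact error under forbid_nerve_contact
  surf_pt <- sc$structures$nerve$mesh$vertices[1, ]
  surf <- check_depth(surf_pt, sc, c(0.5, 3))
  expect_false(surf$pass)
  expect_match(surf$message, "contact of the needle with the nerve")
})

test_that("archetype sessions fail exactly the intended checks", {
  sc <- generate_ianb_scene(seed = 1, patient_profile = "child")
  spec <- default_task_spec(sc)
  expect_equal(spec$target_angle, 45)

  intended_fail <- list(ideal = character(0),
                        shallow = "depth",
                        wrong_angle = "angle",
                        nerve_hit = "nerve_contact")
  for (noise in c(0, 0.05)) {
    for (arch in names(intended_fail)) {
      traj <- generate_archetype_trajectory(sc, arch, seed = 9,
                                            noise_sd = noise)
      log <- run_session(sc, traj, seed = 9)
      res <- evaluate_session(log, sc, spec)
      failed <- names(res$checks)[!vapply(res$checks, `[[`, logical(1),
                                          "pass")]
      expect_equal(failed, intended_fail[[arch]],
                   info = sprintf("%s (noise %.2f)", arch, noise))
      expect_equal(res$passed, length(intended_fail[[arch]]) == 0)
    }
  }

  # nerve-hit records at least one contact event
  traj <- generate_archetype_trajectory(sc, "nerve_hit", seed = 9, noise_sd = 0)
  log <- run_session(sc, traj)
  res <- evaluate_session(log, sc, spec)
  expect_gte(res$checks$nerve_contact$contacts, 1)

  # wrong-angle measures ~25 degrees
  traj <- generate_archetype_trajectory(sc, "wrong_angle", seed = 9,
                                        noise_sd = 0)
  res <- evaluate_session(run_session(sc, traj), sc, spec)
  expect_equal(res$checks$angle$angle, 25, tolerance = 1e-6)
})

test_that("a session that never reaches the mucosa fails with no-insertion", {
  sc <- generate_ianb_scene(seed = 1)
  traj <- data.frame(t = c(0, 1), x = 0, y = c(-30, -25), z = 20,
                     dx = 0, dy = 1, dz = 0)
  log <- run_session(sc, traj)
  res <- evaluate_session(log, sc, default_task_spec(sc))
  expect_false(res$passed)
  expect_match(res$checks$entry_point$message, "No insertion")
})

test_that("evaluation is a pure function and guards scene identity", {
  sc <- generate_ianb_scene(seed = 1)
  spec <- default_task_spec(sc)
  traj <- generate_archetype_trajectory(sc, "ideal", seed = 4)
  log <- run_session(sc, traj, seed = 4)
  expect_identical(evaluate_session(log, sc, spec),
                   evaluate_session(log, sc, spec))

  other <- generate_ianb_scene(seed = 2)   # different jitter, different id
  expect_error(evaluate_session(log, other, spec), "different scene")
})

test_that("task specs validate and round-trip", {
  expect_error(task_spec(target_angle = 95), "\\(0, 90\\)")
  expect_error(task_spec(depth_window = c(3, 1)), "min < max")
  expect_error(task_spec(entry_zone = list(center = c(0, 0, 0), radius = 0)),
               "radius")
  sp <- task_spec(entry_zone = list(center = c(1, 2, 3), radius = 5),
                  angle_tolerance = 7)
  f <- tempfile(fileext = ".json")
  write_task_spec(sp, f)
  expect_equal(read_task_spec(f), sp, tolerance = 0)
})
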