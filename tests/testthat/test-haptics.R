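test_that("axial resistance follows Hooke's law exactly", {
  expect_equal(axial_resistance(0.5, 0, -4), 2.0)   # k=0.5, 4 mm penetration
  expect_equal(axial_resistance(7.3, 1.2, 1.2), 0)  # zero penetration
  expect_error(axial_resistance(-1, 0, -1), "k must be")
  expect_error(axial_resistance(1, 0, 0.5), "x1 must not exceed x0")

  # linearity in k and in penetration, property-style
  set.seed(21)
  for (i in 1:200) {
    k <- runif(1, 0, 5)
    x0 <- runif(1, -10, 10)
    pen <- runif(1, 0, 15)
    f <- axial_resistance(k, x0, x0 - pen)
    expect_equal(f, k * pen, tolerance = 1e-12)
    expect_equal(axial_resistance(2 * k, x0, x0 - pen), 2 * f,
                 tolerance = 1e-12)
    expect_equal(axial_resistance(k, x0, x0 - 2 * pen), 2 * f,
                 tolerance = 1e-12)
  }
})

test_that("penetration bookkeeping tracks layers through the slab", {
  sc <- ref_slab()
  oct <- build_octree(sc)
  st <- penetration_state()
  dirz <- c(0, 0, -1)

  # enter mucosa at z=0, tip at z=-3 (inside muscle after the z=-2 boundary)
  cr <- crossings_along_step(oct, c(0, 0, 1), c(0, 0, -1.5))
  st <- update_penetration(st, cr, c(0, 0, -1.5), dirz)
  expect_equal(st$current_tissue, "mucosa")
  expect_equal(st$penetration, 1.5)
  expect_equal(st$x0, 0)

  cr <- crossings_along_step(oct, c(0, 0, -1.5), c(0, 0, -5))
  st <- update_penetration(st, cr, c(0, 0, -5), dirz)
  expect_equal(st$current_tissue, "muscle")
  expect_equal(st$x0, -2)             # x0 reset at the mucosa/muscle boundary
  expect_equal(st$x1, -5)
  expect_equal(st$penetration, 3)
  expect_equal(st$total_depth, 5)
  expect_equal(st$layers_traversed, c("mucosa", "muscle"))

  # full retraction: no tissue, zero force
  cr <- crossings_along_step(oct, c(0, 0, -5), c(0, 0, 4))
  st <- update_penetration(st, cr, c(0, 0, 4), dirz)
  expect_true(is.na(st$current_tissue))
  fv <- total_feedback(st, ref_slab_calibration())
  expect_equal(fv$axial, 0)
  expect_equal(fv$lateral, c(0, 0, 0))

  # exiting a structure never entered is inconsistent
  bad <- data.frame(t = 0.5, structure = "bone", x = 0, y = 0, z = -12,
                    type = "exiting", stringsAsFactors = FALSE)
  expect_error(update_penetration(penetration_state(), bad, c(0, 0, -13), dirz),
               "inconsistent event ordering")
})

test_that("lateral force is linear in depth and restores toward the axis", {
  expect_equal(lateral_force(0, c(1, 0, 0)), c(0, 0, 0))
  expect_equal(lateral_force(5, c(0, 0, 0)), c(0, 0, 0))
  f2 <- lateral_force(2, c(0.5, 0.25, 0), coefficient = 0.02)
  f4 <- lateral_force(4, c(0.5, 0.25, 0), coefficient = 0.02)
  expect_equal(f4, 2 * f2)                      # exactly 2x at double depth
  expect_lt(sum(f2 * c(0.5, 0.25, 0)), 0)       # points back toward the axis
  expect_equal(sqrt(sum(f2^2)), 0.02 * 2 * sqrt(0.5^2 + 0.25^2))
  expect_error(lateral_force(-1, c(1, 0, 0)), ">= 0")
})

test_that("total feedback clamps to the device limit and caps hard tissue", {
  cal <- calibration_table(k = c(bone = 2.5), device_max_force = 3.3,
                           max_force = c(bone = 3.0))
  st <- penetration_state()
  st$stack <- list(list(name = "bone", point = c(0, 0, -12)))
  st$first_entry <- c(0, 0, 0)
  st$axis_dir <- c(0, 0, -1)
  st <- update_penetration(st, data.frame(), c(0, 0, -18), c(0, 0, -1))
  fv <- total_feedback(st, cal)
  expect_equal(fv$axial_raw, 2.5 * 6)       # unclamped model value
  expect_true(fv$blocked)                   # yield cap reached
  expect_equal(fv$axial, 3.0)               # capped, below device max
  expect_false(fv$clamped)

  cal2 <- calibration_table(k = c(bone = 2.5), device_max_force = 2.0)
  fv2 <- total_feedback(st, cal2)
  expect_true(fv2$clamped)
  expect_equal(sqrt(fv2$axial^2 + sum(fv2$lateral^2)), 2.0)

  st$stack[[1]]$name <- "mystery"
  st$current_tissue <- "mystery"
  expect_error(total_feedback(st, cal), "missing from the calibration")
})

test_that("force is zero iff the tip is outside every structure", {
  sc <- ref_slab()
  cal <- ref_slab_calibration()
  depths <- c(-3, -1, 0.5, 1.9, 2.5, 11, 13, 19)  # negative = above surface
  traj <- slab_trajectory(depths[depths > 0], start_z = 3)
  log <- run_session(sc, traj, cal)
  inside <- !is.na(log$forces$tissue)
  expect_true(all(log$forces$axial[inside & log$forces$penetration > 0] > 0))
  expect_true(all(log$forces$axial[!inside] == 0))
})

test_that("calibration recovers known stiffness from samples", {
  # noiseless: exact
  p <- seq(0.5, 8, length.out = 12)
  fit <- calibrate_stiffness(data.frame(penetration = p, force = 1.2 * p))
  expect_equal(fit$k, 1.2, tolerance = 1e-12)
  expect_equal(fit$residual_rmse, 0, tolerance = 1e-12)

  # noisy: recovery within 3 standard errors (n = 50, sd = 0.05 N)
  set.seed(123)
  p <- runif(50, 0.5, 10)
  f <- 0.8 * p + rnorm(50, 0, 0.05)
  fit <- calibrate_stiffness(data.frame(penetration = p, force = f))
  expect_lt(abs(fit$k - 0.8), 3 * fit$se)
  expect_lt(abs(fit$k - 0.8), 0.05)

  expect_error(calibrate_stiffness(data.frame(penetration = 1, force = 1)),
               "at least two")
  expect_error(calibrate_stiffness(data.frame(penetration = c(2, 2),
                                              force = c(1, 2))), "degenerate")
})

test_that("calibration tables round-trip through YAML", {
  cal <- default_calibration()
  f <- tempfile(fileext = ".yaml")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$k[sort(names(back$k))], cal$k[sort(names(cal$k))])
  expect_equal(back$device_max_force, cal$device_max_force)
  expect_equal(back$max_force[sort(names(back$max_force))],
               cal$max_force[sort(names(cal$max_force))])
  expect_error(calibration_table(k = c(a = -1)), ">= 0")
  expect_error(calibration_table(k = c(a = 1), device_max_force = 0), "> 0")
})
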