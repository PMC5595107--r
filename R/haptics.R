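#' Calibration table
#'
#' Maps structure names to Hooke resistance constants and holds the device
#' limits. Users calibrate these values per structure (skin, mucosa, tongue,
#' gums, bones, muscles, nerves) to tune the perceived resistance.
#'
#' @param k Named numeric vector of stiffness constants, N/mm (>= 0).
#' @param device_max_force Force the device can render, N (> 0). Total output
#'   is clamped to this magnitude.
#' @param lateral_coeff Coefficient of the depth-dependent lateral restoring
#'   force, N/mm^2.
#' @param max_force Named numeric vector of per-structure yield caps in N;
#'   structures absent from it are fully penetrable.
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(k, device_max_force = 3.3, lateral_coeff = 0.01,
                              max_force = numeric(0)) {
  if (is.null(names(k)) || anyDuplicated(names(k)))
    stop("k must be a uniquely named numeric vector", call. = FALSE)
  if (any(k < 0)) stop("all stiffness values must be >= 0", call. = FALSE)
  if (device_max_force <= 0)
    stop("device_max_force must be > 0", call. = FALSE)
  structure(list(k = k, device_max_force = device_max_force,
                 lateral_coeff = lateral_coeff, max_force = max_force),
            class = "calibration_table")
}

#' Default calibration for the seven anatomical structure classes
#'
#' Placeholder resistances (N/mm) for skin, mucosa, tongue, gums, bones,
#' muscles and nerves, intended to be refined by user calibration, plus the
#' structures of the generated scenes (singular aliases and the vessel).
#' Bones and teeth carry a yield cap: the needle cannot penetrate them past
#' the cap force.
#'
#' @return A [calibration_table()].
#' @export
default_calibration <- function() {
  calibration_table(
    k = c(skin = 0.4, mucosa = 0.25, tongue = 0.15, gums = 0.5, bones = 2.5,
          muscles = 0.35, nerves = 0.6,
          bone = 2.5, muscle = 0.35, nerve = 0.6, teeth = 2.5, vessel = 0.3),
    device_max_force = 3.3,
    lateral_coeff = 0.01,
    max_force = c(bones = 3.0, bone = 3.0, teeth = 3.0))
}

#' Calibration config I/O (YAML)
#'
#' @param calibration A [calibration_table()].
#' @param path File path.
#' @export
write_calibration <- function(calibration, path) {
  yaml::write_yaml(list(stiffness = as.list(calibration$k),
                        device_max_force = calibration$device_max_force,
                        lateral_coeff = calibration$lateral_coeff,
                        max_force = as.list(calibration$max_force)), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    stop("calibration file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  calibration_table(k = unlist(x$stiffness),
                    device_max_force = x$device_max_force %||% 3.3,
                    lateral_coeff = x$lateral_coeff %||% 0.01,
                    max_force = if (length(x$max_force)) unlist(x$max_force)
                                else numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hooke's-law axial resistance
#'
#' The axial force resisting insertion is `k * (x0 - x1)`, where `x0` is the
#' coordinate of the current tissue's surface along the insertion axis and
#' `x1` the needle tip's coordinate (the axis coordinate decreases as the
#' needle advances, so `x0 - x1` is the penetration depth).
#'
#' @param k Resistance constant, N/mm (>= 0).
#' @param x0 Tissue surface position along the insertion axis, mm.
#' @param x1 Current tip position along the insertion axis, mm (`x1 <= x0`).
#' @return Force in N.
#' @export
axial_resistance <- function(k, x0, x1) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  if (any(x1 > x0 + 1e-12))
    stop("x1 must not exceed x0 (tip at or beyond the tissue surface)",
         call. = FALSE)
  k * (x0 - x1)
}

#' Depth-dependent lateral force
#'
#' Restoring force pulling the needle back toward its entry axis; its
#' magnitude grows linearly with both the total insertion depth and the
#' lateral offset of the tip from the entry axis, so deeper insertions feel
#' stiffer laterally.
#'
#' @param total_depth Insertion depth from the first tissue entry, mm (>= 0).
#' @param tip_offset 3D vector from the entry axis to the tip (perpendicular
#'   component), mm.
#' @param coefficient N/mm^2.
#' @return 3D force vector in N (directed back toward the axis).
#' @export
lateral_force <- function(total_depth, tip_offset, coefficient = 0.01) {
  if (total_depth < 0) stop("total_depth must be >= 0", call. = FALSE)
  off <- .norm3(tip_offset)
  if (off == 0 || total_depth == 0) return(c(0, 0, 0))
  -coefficient * total_depth * tip_offset
}

#' Penetration state
#'
#' Bookkeeping of which tissues the needle is currently inside. The state
#' holds a containment stack (innermost structure last), the 3D entry point
#' and axis-coordinate `x0` of the current tissue, the first entry point of
#' the session (origin for total depth and the lateral axis), the ordered list
#' of layers traversed, and the derived `x1`, `penetration`, `total_depth`
#' and perpendicular `tip_offset`.
#'
#' @return An object of class `penetration_state`.
#' @export
penetration_state <- function() {
  structure(list(stack = list(), first_entry = NULL, axis_dir = NULL,
                 current_tissue = NA_character_, x0 = NA_real_, x1 = NA_real_,
                 penetration = 0, total_depth = 0,
                 tip_offset = c(0, 0, 0), layers_traversed = character(0)),
            class = "penetration_state")
}

# Axis coordinate: decreases along the insertion direction, matching the
# convention that x0 - x1 >= 0 while penetrating.
.axis_coord <- function(point, dir) -.dot3(point, dir)

#' Advance the penetration state across one needle step
#'
#' Applies the surface crossings of one step (from
#' [crossings_along_step()]) in order, then recomputes the derived
#' quantities at the new tip. Entering a structure resets that structure's
#' surface position `x0`; the current tissue is the innermost (most recently
#' entered) structure still containing the tip.
#'
#' @param state A [penetration_state()].
#' @param crossings Data frame from [crossings_along_step()] for this step.
#' @param tip New tip position, mm.
#' @param dir Unit insertion direction at the tip.
#' @return The updated `penetration_state`.
#' @export
update_penetration <- function(state, crossings, tip, dir) {
  dir <- .unit3(as.numeric(dir))
  if (nrow(crossings)) {
    for (i in seq_len(nrow(crossings))) {
      ev <- crossings[i, ]
      pt <- c(ev$x, ev$y, ev$z)
      if (ev$type == "entering") {
        state$stack[[length(state$stack) + 1]] <-
          list(name = ev$structure, point = pt)
        state$layers_traversed <- c(state$layers_traversed, ev$structure)
        if (is.null(state$first_entry)) {
          state$first_entry <- pt
          state$axis_dir <- dir
        }
      } else {
        nm <- vapply(state$stack, `[[`, character(1), "name")
        j <- which(nm == ev$structure)
        if (!length(j))
          stop("inconsistent event ordering: exit from '", ev$structure,
               "' without a matching entry", call. = FALSE)
        state$stack[[max(j)]] <- NULL
      }
    }
  }
  if (length(state$stack)) {
    cur <- state$stack[[length(state$stack)]]
    state$current_tissue <- cur$name
    state$x0 <- .axis_coord(cur$point, dir)
    state$x1 <- .axis_coord(tip, dir)
    state$penetration <- max(0, state$x0 - state$x1)
    rel <- tip - state$first_entry
    along <- .dot3(rel, state$axis_dir)
    state$total_depth <- max(0, along)
    state$tip_offset <- rel - along * state$axis_dir
  } else {
    state$current_tissue <- NA_character_
    state$x0 <- NA_real_
    state$x1 <- NA_real_
    state$penetration <- 0
    state$total_depth <- 0
    state$tip_offset <- c(0, 0, 0)
    state$first_entry <- NULL
    state$axis_dir <- NULL
  }
  state
}

#' Total haptic feedback for the current state
#'
#' Axial Hooke resistance from the current (innermost) tissue plus the
#' depth-dependent lateral restoring force. If the tissue carries a yield cap
#' (bone, teeth), the axial force saturates at the cap and the tip is treated
#' as blocked. The combined output is clamped to the device's maximum force;
#' the unclamped model values are reported alongside.
#'
#' @param state A [penetration_state()].
#' @param calibration A [calibration_table()] containing the state's tissue.
#' @return An object of class `force_vector`: `axial` (N, >= 0), `lateral`
#'   (3D, N), `clamped`, `blocked`, plus unclamped `axial_raw`/`lateral_raw`.
#' @export
total_feedback <- function(state, calibration) {
  zero <- structure(list(axial = 0, lateral = c(0, 0, 0), clamped = FALSE,
                         blocked = FALSE, axial_raw = 0,
                         lateral_raw = c(0, 0, 0)),
                    class = "force_vector")
  if (is.na(state$current_tissue)) return(zero)
  nm <- state$current_tissue
  if (!nm %in% names(calibration$k))
    stop("tissue '", nm, "' missing from the calibration table", call. = FALSE)
  k <- calibration$k[[nm]]
  axial_raw <- axial_resistance(k, state$x0, min(state$x1, state$x0))
  blocked <- FALSE
  axial <- axial_raw
  if (nm %in% names(calibration$max_force) &&
      axial > calibration$max_force[[nm]]) {
    axial <- calibration$max_force[[nm]]
    blocked <- TRUE
  }
  lat_raw <- lateral_force(state$total_depth, state$tip_offset,
                           calibration$lateral_coeff)
  axial_out <- axial
  lat <- lat_raw
  mag <- sqrt(axial_out^2 + sum(lat^2))
  clamped <- mag > calibration$device_max_force
  if (clamped) {
    sc <- calibration$device_max_force / mag
    axial_out <- axial_out * sc
    lat <- lat * sc
  }
  structure(list(axial = axial_out, lateral = lat, clamped = clamped,
                 blocked = blocked, axial_raw = axial_raw,
                 lateral_raw = lat_raw),
            class = "force_vector")
}

#' Estimate a tissue stiffness from force-displacement samples
#'
#' Least-squares slope through the origin of force against penetration, the
#' fit users perform when calibrating a structure's resistance.
#'
#' @param samples Data frame (or matrix) with columns `penetration` (mm) and
#'   `force` (N); at least two samples with unequal penetrations.
#' @return List with `k` (N/mm), `residual_rmse`, `se` (standard error of the
#'   slope) and `n`.
#' @export
calibrate_stiffness <- function(samples) {
  samples <- as.data.frame(samples)
  if (!all(c("penetration", "force") %in% names(samples)))
    stop("samples need 'penetration' and 'force' columns", call. = FALSE)
  p <- samples$penetration
  f <- samples$force
  if (length(p) < 2)
    stop("need at least two calibration samples", call. = FALSE)
  if (diff(range(p)) == 0)
    stop("degenerate samples: penetrations are all equal", call. = FALSE)
  k <- sum(p * f) / sum(p * p)
  res <- f - k * p
  n <- length(p)
  rss <- sum(res^2)
  list(k = k,
       residual_rmse = sqrt(mean(res^2)),
       se = sqrt(rss / (n - 1) / sum(p * p)),
       n = n)
}
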