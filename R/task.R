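#' IANB task specification
#'
#' Encodes the direct-technique task: insert through the mucosa of the medial
#' ramus within `entry_zone` of the landmark, at approximately the target
#' angle to the occlusal plane, advancing until the tip sits within
#' `depth_window` of the nerve surface, without touching the nerve.
#'
#' @param target_angle Target insertion angle to the occlusal plane, degrees
#'   (0 < angle < 90; the clinical reference is 45).
#' @param angle_tolerance Allowed deviation, degrees.
#' @param entry_zone `list(center = 3D point on the mucosa, radius = mm > 0)`.
#' @param depth_window `c(min, max)` allowed tip-to-nerve-surface distance,
#'   mm, `0 <= min < max`.
#' @param forbid_nerve_contact Fail the session on any nerve contact.
#' @param entry_structure Name of the structure whose first crossing counts as
#'   the insertion.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(target_angle = 45, angle_tolerance = 10,
                      entry_zone = NULL, depth_window = c(0.5, 3),
                      forbid_nerve_contact = TRUE,
                      entry_structure = "mucosa") {
  if (!(target_angle > 0 && target_angle < 90))
    stop("target_angle must be in (0, 90) degrees", call. = FALSE)
  if (!is.null(entry_zone) && entry_zone$radius <= 0)
    stop("entry zone radius must be > 0", call. = FALSE)
  if (!(depth_window[1] >= 0 && depth_window[1] < depth_window[2]))
    stop("depth_window must satisfy 0 <= min < max", call. = FALSE)
  structure(list(target_angle = target_angle,
                 angle_tolerance = angle_tolerance,
                 entry_zone = entry_zone,
                 depth_window = as.numeric(depth_window),
                 forbid_nerve_contact = isTRUE(forbid_nerve_contact),
                 entry_structure = entry_structure),
            class = "task_spec")
}

#' Default task specification for a generated IANB scene
#'
#' Target angle 45 degrees (+/- 10), entry zone of radius 4 mm around the
#' scene's mucosal entry landmark, tip-to-nerve window 0.5-3 mm, nerve contact
#' forbidden.
#'
#' @param scene A [generate_ianb_scene()] scene.
#' @return A [task_spec()].
#' @export
default_task_spec <- function(scene) {
  task_spec(entry_zone = list(center = scene$landmarks$entry_point, radius = 4))
}

#' Task spec file I/O (JSON)
#'
#' @param spec A [task_spec()].
#' @param path File path.
#' @export
write_task_spec <- function(spec, path) {
  writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_task_spec
#' @export
read_task_spec <- function(path) {
  if (!file.exists(path)) stop("task file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  ez <- x$entry_zone
  if (!is.null(ez)) ez <- list(center = as.numeric(ez$center),
                               radius = as.numeric(ez$radius))
  task_spec(target_angle = x$target_angle,
            angle_tolerance = x$angle_tolerance,
            entry_zone = ez,
            depth_window = as.numeric(x$depth_window),
            forbid_nerve_contact = x$forbid_nerve_contact,
            entry_structure = x$entry_structure)
}

#' Insertion angle relative to the occlusal plane
#'
#' Angle between the needle direction and the occlusal plane, in `[0, 90]`
#' degrees (0 = within the plane, 90 = along the plane normal).
#'
#' @param direction Needle direction (any nonzero 3D vector).
#' @param occlusal_plane `list(point, normal)`.
#' @return Angle in degrees.
#' @export
insertion_angle <- function(direction, occlusal_plane) {
  d <- .unit3(as.numeric(direction))
  n <- .unit3(occlusal_plane$normal)
  asin(min(1, abs(.dot3(d, n)))) * 180 / pi
}

#' Check the insertion point against the entry zone
#'
#' @param point First mucosa crossing point (3D, mm), or `NULL` if the session
#'   never entered the mucosa.
#' @param entry_zone `list(center, radius)`.
#' @return List `pass`, `distance` (mm, `NA` when no insertion), `message`.
#' @export
check_entry_point <- function(point, entry_zone) {
  if (is.null(point))
    return(list(pass = FALSE, distance = NA_real_,
                message = "No insertion: the needle never entered the mucosa."))
  d <- .norm3(as.numeric(point) - entry_zone$center)
  if (d <= entry_zone$radius)
    list(pass = TRUE, distance = d,
         message = sprintf("Correct insertion point (%.1f mm from the target spot).", d))
  else
    list(pass = FALSE, distance = d,
         message = sprintf("Incorrect insertion point: %.1f mm from the target spot (allowed %.1f mm).",
                           d, entry_zone$radius))
}

#' Check the final depth against the nerve
#'
#' Distance from the tip to the nerve surface, measured with the octree
#' nearest-triangle query restricted to the nerve structure.
#'
#' @param tip Needle tip position (3D, mm).
#' @param scene Scene containing the target nerve.
#' @param depth_window `c(min, max)` allowed distance, mm.
#' @param forbid_nerve_contact Report contact (distance 0) as an error.
#' @return List `pass`, `distance` (mm), `message`.
#' @export
check_depth <- function(tip, scene, depth_window, forbid_nerve_contact = TRUE) {
  d <- .tip_to_nerve_distance(tip, scene)
  if (forbid_nerve_contact && d <= 0)
    return(list(pass = FALSE, distance = d,
                message = "Error: contact of the needle with the nerve."))
  if (d < depth_window[1])
    list(pass = FALSE, distance = d,
         message = sprintf("Too deep: tip %.2f mm from the nerve (minimum %.2f mm).",
                           d, depth_window[1]))
  else if (d > depth_window[2])
    list(pass = FALSE, distance = d,
         message = sprintf("Too shallow: tip %.2f mm from the nerve (maximum %.2f mm).",
                           d, depth_window[2]))
  else
    list(pass = TRUE, distance = d,
         message = sprintf("Correct point to deposit the anesthetic solution (tip %.2f mm from the nerve).",
                           d))
}

# Tip-to-nerve distance via the octree query on the nerve alone. The query
# contract requires a proper segment, so a 1e-9 mm probe stands in for the
# point; the error is far below every tolerance in use.
.tip_to_nerve_distance <- function(tip, scene) {
  nerve <- scene_nerve_name(scene)
  sub <- scene
  sub$structures <- sub$structures[nerve]
  oct <- build_octree(sub)
  seg <- needle_segment(tip, tip + c(0, 0, 1e-9))
  query_nearest(oct, seg)$distance
}

#' Evaluate a recorded session against the IANB task
#'
#' Aggregates the four checks: entry point (first crossing into the entry
#' structure), insertion angle (needle direction at the entry crossing),
#' depth (tip-to-nerve distance at the deepest sample, so retracting after a
#' correct placement still passes), and nerve contact count. Deterministic:
#' replaying a stored log yields the identical result.
#'
#' @param log A [run_session()] log (or one re-read via [read_log()]).
#' @param scene The scene the log was recorded against.
#' @param spec A [task_spec()].
#' @return An object of class `task_result`: `passed`, `checks` (named list
#'   with `pass`, measured value, `message`), `messages` (ordered user-facing
#'   strings).
#' @export
evaluate_session <- function(log, scene, spec) {
  if (!nrow(log$samples)) stop("empty session log", call. = FALSE)
  if (!identical(log$scene_id, scene_fingerprint(scene)))
    stop("session log was recorded against a different scene", call. = FALSE)
  nerve <- scene_nerve_name(scene)

  entries <- log$events[log$events$type == "entering" &
                        log$events$structure == spec$entry_structure, ,
                        drop = FALSE]
  entry_point <- if (nrow(entries))
    as.numeric(entries[1, c("x", "y", "z")]) else NULL
  entry_check <- check_entry_point(entry_point, spec$entry_zone)

  if (!is.null(entry_point)) {
    t_entry <- entries$t[1]
    i <- which(log$samples$t >= t_entry - 1e-12)[1]
    if (is.na(i)) i <- nrow(log$samples)
    dir_entry <- as.numeric(log$samples[i, c("dx", "dy", "dz")])
    ang <- insertion_angle(dir_entry, scene$occlusal_plane)
    angle_check <- list(
      pass = abs(ang - spec$target_angle) <= spec$angle_tolerance,
      angle = ang,
      message = if (abs(ang - spec$target_angle) <= spec$angle_tolerance)
        sprintf("Correct insertion angle (%.1f degrees).", ang)
      else
        sprintf("Error: incorrect angle for insertion (%.1f degrees; target %.0f +/- %.0f).",
                ang, spec$target_angle, spec$angle_tolerance))
    deepest <- which.max(log$forces$total_depth)
    tip_deep <- as.numeric(log$samples[deepest, c("x", "y", "z")])
    depth_check <- check_depth(tip_deep, scene, spec$depth_window,
                               spec$forbid_nerve_contact)
  } else {
    angle_check <- list(pass = FALSE, angle = NA_real_,
                        message = "Insertion angle not measurable: no insertion.")
    depth_check <- list(pass = FALSE, distance = NA_real_,
                        message = "Depth not measurable: no insertion.")
  }

  contacts <- sum(log$events$type == "nerve_contact")
  if (contacts == 0)
    contacts <- sum(log$events$type == "entering" &
                    log$events$structure == nerve)
  nerve_check <- if (!spec$forbid_nerve_contact)
    list(pass = TRUE, contacts = contacts,
         message = sprintf("Nerve contacts: %d (not penalized).", contacts))
  else if (contacts > 0)
    list(pass = FALSE, contacts = contacts,
         message = sprintf("Error: contact of the needle with the nerve (%d time%s).",
                           contacts, if (contacts > 1) "s" else ""))
  else
    list(pass = TRUE, contacts = 0L,
         message = "No nerve contact.")

  checks <- list(entry_point = entry_check, angle = angle_check,
                 depth = depth_check, nerve_contact = nerve_check)
  structure(list(
    passed = all(vapply(checks, `[[`, logical(1), "pass")),
    checks = checks,
    messages = vapply(checks, `[[`, character(1), "message")),
    class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("Task %s\n", if (x$passed) "PASSED" else "FAILED"))
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}
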