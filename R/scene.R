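#' Tissue model
#'
#' Per-structure tissue properties used by the haptic force model. `stiffness_k`
#' is the Hooke constant of resistance in N/mm; `max_force` is an optional
#' yield cap in N above which the tissue blocks further penetration (used for
#' hard tissues such as bone and teeth).
#'
#' @param name Structure name.
#' @param stiffness_k Resistance constant, N per mm of penetration (>= 0).
#' @param is_target_nerve Whether this structure is the block target nerve.
#' @param is_removable Whether the structure may be toggled inactive.
#' @param max_force Optional yield force cap in N (`Inf` = fully penetrable).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(name, stiffness_k, is_target_nerve = FALSE,
                         is_removable = TRUE, max_force = Inf) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(stiffness_k) || stiffness_k < 0)
    stop("stiffness_k must be >= 0", call. = FALSE)
  structure(list(name = name, stiffness_k = as.numeric(stiffness_k),
                 is_target_nerve = isTRUE(is_target_nerve),
                 is_removable = isTRUE(is_removable),
                 max_force = as.numeric(max_force)),
            class = "tissue_model")
}

#' Anatomical scene
#'
#' A scene maps structure names to (mesh, tissue model, active flag) and
#' carries the landmarks the IANB task is scored against: the occlusal plane
#' (point + unit normal), the mandibular foramen, and the mucosal entry point.
#' Units are millimeters throughout.
#'
#' @param structures Named list; each element is `list(mesh, tissue, active)`.
#' @param occlusal_plane `list(point, normal)`; the normal is normalized.
#' @param foramen 3D point or `NULL` (phantoms without a foramen).
#' @param patient_profile `"child"`, `"adult"`, or `"phantom"`.
#' @param landmarks Extra named landmarks (entry point, nerve axis, ...).
#' @param seed Integer seed the generator was called with (metadata).
#' @return An object of class `needle_scene`.
#' @export
needle_scene <- function(structures, occlusal_plane = NULL, foramen = NULL,
                         patient_profile = "phantom", landmarks = list(),
                         seed = NA_integer_) {
  if (!length(structures) || is.null(names(structures)) ||
      anyDuplicated(names(structures)))
    stop("structures must be a uniquely named, non-empty list", call. = FALSE)
  if (!is.null(occlusal_plane))
    occlusal_plane$normal <- .unit3(occlusal_plane$normal)
  sc <- structure(list(structures = structures,
                       occlusal_plane = occlusal_plane,
                       foramen = foramen,
                       patient_profile = patient_profile,
                       landmarks = landmarks,
                       seed = as.integer(seed)),
                  class = "needle_scene")
  validate_scene(sc)
  sc
}

#' @rdname needle_scene
#' @param scene A `needle_scene`.
#' @export
validate_scene <- function(scene) {
  nerve_flags <- vapply(scene$structures,
                        function(s) s$tissue$is_target_nerve, logical(1))
  if (sum(nerve_flags) > 1)
    stop("scene has more than one target nerve structure", call. = FALSE)
  if (identical(scene$patient_profile, "child")) {
    if (is.null(scene$foramen) || is.null(scene$occlusal_plane))
      stop("child scene requires a foramen and an occlusal plane", call. = FALSE)
    h <- .dot3(scene$foramen - scene$occlusal_plane$point,
               scene$occlusal_plane$normal)
    if (h >= 0)
      stop("child scene: foramen must lie strictly below the occlusal plane",
           call. = FALSE)
  }
  invisible(scene)
}

#' @export
print.needle_scene <- function(x, ...) {
  act <- vapply(x$structures, function(s) s$active, logical(1))
  cat(sprintf("<needle_scene: %d structures (%d active), profile '%s'>\n",
              length(x$structures), sum(act), x$patient_profile))
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    cat(sprintf("  %-14s %5d faces  k=%.2f N/mm%s%s\n", nm,
                nrow(s$mesh$faces), s$tissue$stiffness_k,
                if (s$tissue$is_target_nerve) "  [target nerve]" else "",
                if (!s$active) "  (inactive)" else ""))
  }
  invisible(x)
}

# Name of the unique target nerve structure (error if absent).
scene_nerve_name <- function(scene) {
  nm <- names(scene$structures)[vapply(scene$structures,
                                       function(s) s$tissue$is_target_nerve,
                                       logical(1))]
  if (length(nm) != 1)
    stop("scene must contain exactly one target nerve structure", call. = FALSE)
  nm
}

#' Toggle a structure's active flag
#'
#' Inactive structures are excluded from collision, force and traversal
#' computations (the simulator's "remove the skin to view internal structures"
#' facility). The target nerve cannot be deactivated.
#'
#' @param scene A [needle_scene()].
#' @param name Structure name.
#' @param active Logical flag.
#' @return The modified scene.
#' @export
set_structure_active <- function(scene, name, active) {
  if (!name %in% names(scene$structures))
    stop("unknown structure: '", name, "'", call. = FALSE)
  s <- scene$structures[[name]]
  if (!active && s$tissue$is_target_nerve)
    stop("the target nerve structure cannot be deactivated", call. = FALSE)
  if (!active && !s$tissue$is_removable)
    stop("structure '", name, "' is not removable", call. = FALSE)
  scene$structures[[name]]$active <- isTRUE(active)
  scene
}

.structure <- function(mesh, tissue, active = TRUE)
  list(mesh = mesh, tissue = tissue, active = active)

#' Generate a layered slab phantom
#'
#' Builds a stack of axis-aligned closed boxes, one per tissue layer, tiling
#' the depth range `[0, sum(thickness)]` along the insertion axis (-z): the
#' first layer's outer surface is the plane z = 0 and insertion proceeds
#' toward negative z. This is the bench phantom used to verify the
#' piecewise-linear force-depth behaviour of the haptic model.
#'
#' @param layer_specs Data frame or list of lists with columns/fields
#'   `name`, `thickness` (mm, > 0), `stiffness` (N/mm).
#' @param lateral_size Edge length of the slab in x and y (mm).
#' @param seed Integer seed (stored; the construction is deterministic).
#' @return A [needle_scene()] with one structure per layer, outermost first.
#' @export
generate_slab_phantom <- function(layer_specs, lateral_size = 30, seed = 1L) {
  if (is.data.frame(layer_specs))
    layer_specs <- lapply(seq_len(nrow(layer_specs)),
                          function(i) as.list(layer_specs[i, ]))
  if (!length(layer_specs)) stop("need at least one layer", call. = FALSE)
  th <- vapply(layer_specs, function(l) as.numeric(l$thickness), numeric(1))
  if (any(!is.finite(th) | th <= 0))
    stop("layer thicknesses must be positive", call. = FALSE)
  half <- lateral_size / 2
  z_top <- c(0, -cumsum(th))
  structures <- list()
  for (i in seq_along(layer_specs)) {
    l <- layer_specs[[i]]
    mesh <- box_mesh(l$name, lo = c(-half, -half, z_top[i + 1]),
                     hi = c(half, half, z_top[i]))
    structures[[l$name]] <- .structure(mesh, tissue_model(l$name, l$stiffness))
  }
  needle_scene(structures,
               occlusal_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
               patient_profile = "phantom",
               landmarks = list(surface_point = c(0, 0, 0),
                                insertion_dir = c(0, 0, -1),
                                layer_depths = cumsum(th)),
               seed = seed)
}

#' Generate the stylized IANB training scene
#'
#' A seeded, synthetic stand-in for the modeled patient: a mucosa sheet on the
#' medial side of the mandibular ramus, a muscle volume behind it, the ramus
#' bone block, and the inferior alveolar nerve as a watertight cylinder whose
#' posterior surface meets the foramen landmark on the medial bone face.
#' Decorative structures from the anatomical inventory (facial skin, teeth,
#' tongue, a blood vessel) are included but sit off the task path; their
#' placement is jittered by the seed. For the child profile the foramen sits
#' 2 mm below the occlusal plane; for the adult profile it sits on the plane.
#'
#' The scene stores the landmarks the task and the archetype trajectory
#' generator need: entry point on the mucosa (chosen so that a 45-degree
#' insertion aims exactly at the nerve axis), mucosa outward normal, nerve
#' axis point/direction/radius.
#'
#' @param seed Integer seed.
#' @param patient_profile `"child"` (default) or `"adult"`.
#' @return A [needle_scene()].
#' @export
generate_ianb_scene <- function(seed = 1L, patient_profile = c("child", "adult")) {
  patient_profile <- match.arg(patient_profile)
  z_f <- if (patient_profile == "child") -2 else 0
  half_x <- 15

  mucosa <- box_mesh("mucosa", c(-half_x, 10, -12), c(half_x, 12, 10))
  muscle <- box_mesh("muscle", c(-half_x, 12, -12), c(half_x, 20, 10))
  bone <- box_mesh("bone", c(-half_x, 20, -14), c(half_x, 30, 11))  # ramus ~30x25x10
  nerve_center <- c(0, 19, z_f)
  nerve <- cylinder_mesh("nerve", nerve_center, axis = c(1, 0, 0),
                         radius = 1, half_length = 12, n_seg = 24)
  foramen <- c(0, 20, z_f)  # medial bone face, tangent to the nerve surface

  jit <- .with_seed(seed, stats::runif(4, -0.5, 0.5))
  skin <- box_mesh("skin", c(-half_x, -12 + jit[1], -14), c(half_x, -10 + jit[1], 11))
  teeth <- box_mesh("teeth", c(-half_x, 2 + jit[2], -4), c(half_x, 8 + jit[2], 4))
  tongue <- box_mesh("tongue", c(-10, -8 + jit[3], -10), c(10, 2 + jit[3], 2))
  vessel <- cylinder_mesh("vessel", c(jit[4], 18, -8), axis = c(1, 0, 0),
                          radius = 0.8, half_length = 10, n_seg = 12)

  # Mucosal entry point: where the 45-degree line through the nerve axis
  # (in the x = 0 sagittal slice) meets the mucosa outer face y = 10.
  insertion_45 <- .unit3(c(0, 1, -1))
  t_face <- (10 - nerve_center[2]) / insertion_45[2]
  entry <- nerve_center + t_face * insertion_45

  structures <- list(
    mucosa = .structure(mucosa, tissue_model("mucosa", 0.25)),
    muscle = .structure(muscle, tissue_model("muscle", 0.35)),
    bone = .structure(bone, tissue_model("bone", 2.5, max_force = 3.0)),
    nerve = .structure(nerve, tissue_model("nerve", 0.6, is_target_nerve = TRUE,
                                           is_removable = FALSE)),
    skin = .structure(skin, tissue_model("skin", 0.4)),
    teeth = .structure(teeth, tissue_model("teeth", 2.5, max_force = 3.0)),
    tongue = .structure(tongue, tissue_model("tongue", 0.15)),
    vessel = .structure(vessel, tissue_model("vessel", 0.3))
  )
  needle_scene(structures,
               occlusal_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
               foramen = foramen,
               patient_profile = patient_profile,
               landmarks = list(entry_point = entry,
                                entry_normal = c(0, -1, 0),
                                nerve_point = nerve_center,
                                nerve_axis = c(1, 0, 0),
                                nerve_radius = 1),
               seed = seed)
}

# Run expr with a local, restored RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic scene fingerprint used to guard log/scene pairing.
scene_fingerprint <- function(scene) {
  nf <- vapply(scene$structures, function(s) nrow(s$mesh$faces), integer(1))
  csum <- sum(vapply(scene$structures,
                     function(s) sum(s$mesh$vertices) + sum(s$mesh$faces),
                     numeric(1)))
  sprintf("%s|%s|f%d|%.9e", scene$patient_profile,
          paste(names(scene$structures), collapse = ","), sum(nf), csum)
}

.scene_to_list <- function(scene) {
  list(
    format = "needlesim-scene",
    version = 1L,
    patient_profile = scene$patient_profile,
    seed = scene$seed,
    occlusal_plane = scene$occlusal_plane,
    foramen = scene$foramen,
    landmarks = scene$landmarks,
    structures = lapply(scene$structures, function(s) list(
      tissue = unclass(s$tissue),
      active = s$active,
      vertices = s$mesh$vertices,
      faces = s$mesh$faces
    ))
  )
}

#' Scene serialization
#'
#' Scenes round-trip losslessly through a structured JSON document (full
#' double precision, deterministic field order, so identical scenes produce
#' byte-identical files).
#'
#' @param scene A [needle_scene()].
#' @param path Output / input file path.
#' @return `write_scene` returns the path invisibly; `read_scene` the scene.
#' @export
write_scene <- function(scene, path) {
  json <- jsonlite::toJSON(.scene_to_list(scene), auto_unbox = TRUE,
                           digits = I(17), null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("scene file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyMatrix = TRUE)
  if (!identical(x$format, "needlesim-scene"))
    stop("not a needlesim scene file: ", path, call. = FALSE)
  structures <- lapply(names(x$structures), function(nm) {
    s <- x$structures[[nm]]
    mf <- if (is.null(s$tissue$max_force)) Inf else s$tissue$max_force
    .structure(triangle_mesh(nm, s$vertices, s$faces),
               tissue_model(nm, s$tissue$stiffness_k,
                            is_target_nerve = s$tissue$is_target_nerve,
                            is_removable = s$tissue$is_removable,
                            max_force = mf),
               active = s$active)
  })
  names(structures) <- names(x$structures)
  op <- x$occlusal_plane
  if (!is.null(op)) op <- list(point = as.numeric(op$point),
                               normal = as.numeric(op$normal))
  lm <- lapply(x$landmarks, function(v) if (is.numeric(v)) as.numeric(v) else v)
  needle_scene(structures, occlusal_plane = op,
               foramen = if (is.null(x$foramen)) NULL else as.numeric(x$foramen),
               patient_profile = x$patient_profile,
               landmarks = lm, seed = x$seed)
}
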