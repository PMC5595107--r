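#' Trajectory sample tables
#'
#' A trajectory is an ordered table of time-stamped needle samples with
#' columns `t` (seconds, strictly increasing), `x`, `y`, `z` (tip position,
#' mm) and `dx`, `dy`, `dz` (unit needle direction). [read_trajectory()] and
#' [write_trajectory()] exchange the table as CSV with exactly that header.
#'
#' @param samples Data frame with the columns above.
#' @return The validated data frame.
#' @export
validate_trajectory <- function(samples) {
  need <- c("t", "x", "y", "z", "dx", "dy", "dz")
  if (!all(need %in% names(samples)))
    stop("trajectory needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (nrow(samples) < 2)
    stop("trajectory needs at least two samples", call. = FALSE)
  if (any(diff(samples$t) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  dn <- sqrt(samples$dx^2 + samples$dy^2 + samples$dz^2)
  if (any(abs(dn - 1) > 1e-6))
    stop("trajectory directions must be unit vectors", call. = FALSE)
  samples[, need]
}

#' @rdname validate_trajectory
#' @param path CSV file path.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  validate_trajectory(utils::read.csv(path))
}

#' @rdname validate_trajectory
#' @export
write_trajectory <- function(samples, path) {
  utils::write.csv(validate_trajectory(samples), path, row.names = FALSE)
  invisible(path)
}

#' Run a simulated insertion session
#'
#' Steps through the trajectory samples: for each step the surface crossings
#' are detected, the penetration state advanced, and the haptic feedback the
#' device would render computed. Entirely deterministic.
#'
#' @param scene A [needle_scene()].
#' @param samples Trajectory table (see [validate_trajectory()]). The first
#'   sample must lie outside every active structure.
#' @param calibration A [calibration_table()]; defaults to
#'   [default_calibration()].
#' @param seed Seed recorded as session metadata (the run itself is
#'   deterministic).
#' @return An object of class `session_log` with elements `samples`, `events`
#'   (time, structure, point, entering/exiting/nerve_contact), `forces`
#'   (per-sample axial/lateral/clamped plus penetration bookkeeping),
#'   `scene_id`, `seed`.
#' @export
run_session <- function(scene, samples, calibration = default_calibration(),
                        seed = NA_integer_) {
  samples <- validate_trajectory(samples)
  octree <- build_octree(scene)
  nerve <- tryCatch(scene_nerve_name(scene), error = function(e) NA_character_)
  state <- penetration_state()

  ev_list <- list()
  force_rows <- vector("list", nrow(samples))
  tips <- as.matrix(samples[, c("x", "y", "z")])
  dirs <- as.matrix(samples[, c("dx", "dy", "dz")])
  prev_tail <- NULL  # crossings at the very end of the previous step
  for (i in seq_len(nrow(samples))) {
    if (i == 1) {
      cr <- crossings_along_step(octree, tips[1, ], tips[1, ])
    } else {
      cr <- crossings_along_step(octree, tips[i - 1, ], tips[i, ])
      # a sample landing exactly on a surface reports the crossing at the end
      # of one step and again at the start of the next; keep only the first
      if (!is.null(prev_tail) && nrow(cr)) {
        head_dup <- cr$t < 1e-9 &
          paste(cr$structure, cr$type) %in%
            paste(prev_tail$structure, prev_tail$type)
        cr <- cr[!head_dup, , drop = FALSE]
      }
      prev_tail <- cr[cr$t > 1 - 1e-9, , drop = FALSE]
      if (nrow(cr)) {
        cr$t_abs <- samples$t[i - 1] + cr$t * (samples$t[i] - samples$t[i - 1])
        ev_list[[length(ev_list) + 1]] <- cr
      }
    }
    state <- update_penetration(state, cr, tips[i, ], dirs[i, ])
    fv <- total_feedback(state, calibration)
    force_rows[[i]] <- data.frame(
      t = samples$t[i], tissue = state$current_tissue,
      penetration = state$penetration, total_depth = state$total_depth,
      axial = fv$axial, lat_x = fv$lateral[1], lat_y = fv$lateral[2],
      lat_z = fv$lateral[3], clamped = fv$clamped, blocked = fv$blocked,
      axial_raw = fv$axial_raw, stringsAsFactors = FALSE)
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(t = numeric(0), structure = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), type = character(0),
               t_abs = numeric(0), stringsAsFactors = FALSE)
  events <- data.frame(t = events$t_abs, structure = events$structure,
                       x = events$x, y = events$y, z = events$z,
                       type = events$type, stringsAsFactors = FALSE)
  # explicit nerve-contact events mirror every entry into the target nerve
  if (!is.na(nerve)) {
    hit <- events[events$structure == nerve & events$type == "entering", ,
                  drop = FALSE]
    if (nrow(hit)) {
      hit$type <- "nerve_contact"
      events <- rbind(events, hit)
      events <- events[order(events$t, events$type), , drop = FALSE]
    }
  }
  rownames(events) <- NULL
  forces <- do.call(rbind, force_rows)
  rownames(forces) <- NULL
  rownames(samples) <- NULL
  structure(list(samples = samples, events = events, forces = forces,
                 scene_id = scene_fingerprint(scene),
                 seed = as.integer(seed)),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log: %d samples, %d events, scene %s>\n",
              nrow(x$samples), nrow(x$events),
              substr(x$scene_id, 1, 40)))
  invisible(x)
}

#' Summarize a recorded session
#'
#' The interaction summary the recording requirement calls for: training time,
#' needle path length, the ordered structures traversed, per-structure contact
#' counts and maximum insertion depth.
#'
#' @param log A [run_session()] log.
#' @return List of class `session_summary`.
#' @export
summarize_session <- function(log) {
  if (!nrow(log$samples)) stop("empty session log", call. = FALSE)
  tips <- as.matrix(log$samples[, c("x", "y", "z")])
  seg <- diff(tips)
  entering <- log$events[log$events$type == "entering", , drop = FALSE]
  counts <- if (nrow(entering)) table(entering$structure) else table(character(0))
  structure(list(
    training_time = max(log$samples$t) - min(log$samples$t),
    path_length = sum(sqrt(rowSums(seg^2))),
    structures_traversed = unique(entering$structure),
    contact_counts = as.list(counts),
    max_depth = if (nrow(log$forces)) max(log$forces$total_depth) else 0,
    n_samples = nrow(log$samples)),
    class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("Session summary\n")
  cat(sprintf("  training time : %.2f s\n", x$training_time))
  cat(sprintf("  path length   : %.2f mm\n", x$path_length))
  cat(sprintf("  max depth     : %.2f mm\n", x$max_depth))
  cat(sprintf("  traversed     : %s\n",
              if (length(x$structures_traversed))
                paste(x$structures_traversed, collapse = " > ") else "(none)"))
  for (nm in names(x$contact_counts))
    cat(sprintf("  contacts[%s] = %d\n", nm, as.integer(x$contact_counts[[nm]])))
  invisible(x)
}

#' Session log persistence (JSON lines)
#'
#' One self-describing record per line: a header (scene id, seed), then one
#' record per sample, event and force row. `read_log(write_log(log))`
#' reproduces the log exactly.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @export
write_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  j <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                                    null = "null", na = "null")
  writeLines(j(list(record = "header", scene_id = log$scene_id,
                    seed = log$seed)), con)
  for (i in seq_len(nrow(log$samples)))
    writeLines(j(c(list(record = "sample"), as.list(log$samples[i, ]))), con)
  for (i in seq_len(nrow(log$events)))
    writeLines(j(c(list(record = "event"), as.list(log$events[i, ]))), con)
  for (i in seq_len(nrow(log$forces)))
    writeLines(j(c(list(record = "force"), as.list(log$forces[i, ]))), con)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty log file: ", path, call. = FALSE)
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e)
               stop("malformed log record at line ", i, ": ",
                    conditionMessage(e), call. = FALSE))
  })
  types <- vapply(recs, function(r) r$record %||% "", character(1))
  if (types[1] != "header")
    stop("malformed log file: missing header at line 1", call. = FALSE)
  pick <- function(type) {
    rows <- recs[types == type]
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(r) {
      r$record <- NULL
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
  }
  samples <- pick("sample")
  events <- pick("event")
  forces <- pick("force")
  if (is.null(samples))
    stop("malformed log file: no sample records", call. = FALSE)
  if (is.null(events))
    events <- data.frame(t = numeric(0), structure = character(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         type = character(0), stringsAsFactors = FALSE)
  if ("tissue" %in% names(forces)) forces$tissue <- as.character(forces$tissue)
  rownames(samples) <- NULL
  rownames(events) <- NULL
  rownames(forces) <- NULL
  structure(list(samples = samples, events = events, forces = forces,
                 scene_id = recs[[1]]$scene_id,
                 seed = as.integer(recs[[1]]$seed %||% NA)),
            class = "session_log")
}

#' Generate a synthetic student trajectory
#'
#' Seeded straight-line trajectories standing in for student input, built from
#' the scene's landmarks to realize four archetypes: `ideal` (45 degrees
#' through the entry point, stopping next to the nerve), `shallow` (correct
#' entry and angle, stops too far from the nerve), `wrong_angle` (25-degree
#' insertion, otherwise correct), and `nerve_hit` (45 degrees but aimed
#' through the nerve, then past it to a correct depth). Gaussian jitter of
#' `noise_sd` mm is added to every tip position after the first sample.
#'
#' @param scene A scene from [generate_ianb_scene()] (needs entry/nerve
#'   landmarks).
#' @param archetype One of `"ideal"`, `"shallow"`, `"wrong_angle"`,
#'   `"nerve_hit"`.
#' @param seed Integer seed for the jitter.
#' @param noise_sd Tip position noise, mm.
#' @param n_samples Number of samples.
#' @param speed Insertion speed, mm/s (sets the timestamps).
#' @return A trajectory table (see [validate_trajectory()]).
#' @export
generate_archetype_trajectory <- function(scene,
                                          archetype = c("ideal", "shallow",
                                                        "wrong_angle",
                                                        "nerve_hit"),
                                          seed = 1L, noise_sd = 0.05,
                                          n_samples = 80, speed = 5) {
  archetype <- match.arg(archetype)
  lm <- scene$landmarks
  need <- c("entry_point", "entry_normal", "nerve_point", "nerve_axis",
            "nerve_radius")
  if (!all(need %in% names(lm)))
    stop("scene lacks the task landmarks required for archetype generation",
         call. = FALSE)
  zhat <- scene$occlusal_plane$normal
  h <- .unit3(-lm$entry_normal)          # horizontal, into the tissue
  u <- .unit3(lm$nerve_axis)             # normal of the insertion plane
  r <- lm$nerve_radius
  A <- lm$nerve_point

  dir_at <- function(deg) {
    th <- deg * pi / 180
    .unit3(cos(th) * h - sin(th) * zhat)
  }
  # entry point shifted by `o` mm downward (along -zhat) from the landmark
  entry_at <- function(o) lm$entry_point - o * zhat
  # signed distance from the nerve axis to the line (entry_at(o), d);
  # linear in o, so solve s0 + o*slope = +/-D and take the smaller offset.
  solve_offset <- function(d, D) {
    s_of <- function(o) .dot3(.cross3(d, A - entry_at(o)), u)
    s0 <- s_of(0)
    slope <- s_of(1) - s0
    cand <- c((D - s0) / slope, (-D - s0) / slope)
    cand[which.min(abs(cand))]
  }

  spec <- switch(archetype,
    ideal = list(angle = 45, miss = 0, stop = "before", at = r + 1.75),
    shallow = list(angle = 45, miss = 0, stop = "before", at = r + 6),
    wrong_angle = list(angle = 25, miss = r + 1.0, stop = "closest", at = NA),
    nerve_hit = list(angle = 45, miss = 0.7 * r, stop = "after", at = r + 1.0))

  d <- dir_at(spec$angle)
  o <- if (spec$miss == 0) 0 else solve_offset(d, spec$miss)
  E <- entry_at(o)
  dmin <- abs(.dot3(.cross3(d, A - E), u))
  t_closest <- .dot3(A - E, d)
  t_stop <- switch(spec$stop,
    before = t_closest - sqrt(max(0, spec$at^2 - dmin^2)),
    closest = t_closest,
    after = t_closest + sqrt(max(0, spec$at^2 - dmin^2)))

  start <- E - 5 * d
  tip_end <- E + t_stop * d
  s <- seq(0, 1, length.out = n_samples)
  tips <- .rep_row(start, n_samples) +
    outer(s, as.numeric(tip_end - start))
  if (noise_sd > 0) {
    jitter <- .with_seed(seed,
      matrix(stats::rnorm(3 * (n_samples - 1), 0, noise_sd),
             n_samples - 1, 3))
    tips[-1, ] <- tips[-1, ] + jitter
  }
  total_len <- .norm3(tip_end - start)
  data.frame(t = s * total_len / speed,
             x = tips[, 1], y = tips[, 2], z = tips[, 3],
             dx = d[1], dy = d[2], dz = d[3])
}
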