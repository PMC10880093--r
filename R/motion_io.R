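#' Trial recording: one repeat's 3D joint-centre trajectory
#'
#' @param participant_id participant identifier string.
#' @param session \code{"pre"} or \code{"post"}.
#' @param action \code{"squat"} or \code{"sit_to_stand"}.
#' @param repeat_index integer >= 0 identifying the repeat.
#' @param fps frames per second (> 0).
#' @param positions numeric array \code{[n_frames, 3, n_joints]} in metres,
#'   with joint names as the third dimnames, or a long data frame with
#'   columns \code{frame, joint, x, y, z} (frames contiguous from 0).
#' @param skeleton a \code{"skeleton"} object the joints must belong to.
#' @return An object of class \code{"trial_recording"}.
#' @export
trial_recording <- function(participant_id, session, action, repeat_index,
                            fps, positions, skeleton = skeleton_clinical17()) {
  if (!session %in% c("pre", "post"))
    stop("session must be 'pre' or 'post'")
  if (!action %in% c("squat", "sit_to_stand"))
    stop("action must be 'squat' or 'sit_to_stand'")
  if (repeat_index < 0 || fps <= 0)
    stop("repeat_index must be >= 0 and fps > 0")
  if (is.data.frame(positions))
    positions <- positions_long_to_array(positions, skeleton)
  if (length(dim(positions)) != 3L || dim(positions)[2L] != 3L)
    stop("positions must be an [n_frames, 3, n_joints] array")
  jn <- dimnames(positions)[[3L]]
  if (is.null(jn)) stop("positions array must carry joint names")
  if (!all(is.finite(positions))) stop("non-finite coordinates in positions")
  rec <- structure(
    list(participant_id = as.character(participant_id), session = session,
         action = action, repeat_index = as.integer(repeat_index),
         fps = fps, positions = positions, skeleton_name = skeleton$name),
    class = "trial_recording")
  rec
}

recording_id <- function(rec) {
  paste(rec$participant_id, rec$session, rec$action, rec$repeat_index,
        sep = "/")
}

#' @export
print.trial_recording <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trial_recording> %s: %d frames x %d joints @ %g fps\n",
              recording_id(x), d[1L], d[3L], x$fps))
  invisible(x)
}

# Long (frame, joint, x, y, z) data frame -> [frames, 3, joints] array.
# Enforces contiguous 0-based frames and a complete frame x joint grid.
positions_long_to_array <- function(df, skeleton) {
  need <- c("frame", "joint", "x", "y", "z")
  if (length(miss <- setdiff(need, names(df))))
    stop("trajectory table lacks columns: ", paste(miss, collapse = ", "))
  df$joint <- canonical_joints(as.character(df$joint), skeleton)
  frames <- sort(unique(df$frame))
  if (frames[1L] != 0L) df$frame <- df$frame - frames[1L]  # normalise start
  frames <- sort(unique(df$frame))
  gap <- which(diff(frames) != 1L)
  if (length(gap))
    stop("non-contiguous frames at index ", frames[gap[1L]] + 1L)
  joints <- intersect(skeleton$joints, unique(df$joint))  # skeleton order
  tab <- table(df$frame, df$joint)
  if (any(tab != 1L))
    stop("every frame must contain every joint exactly once")
  o <- order(match(df$joint, joints), df$frame)
  arr <- array(NA_real_, dim = c(length(frames), 3L, length(joints)),
               dimnames = list(NULL, c("x", "y", "z"), joints))
  arr[, 1L, ] <- df$x[o]
  arr[, 2L, ] <- df$y[o]
  arr[, 3L, ] <- df$z[o]
  arr
}

positions_array_to_long <- function(arr) {
  joints <- dimnames(arr)[[3L]]
  nf <- dim(arr)[1L]
  data.frame(
    frame = rep(seq_len(nf) - 1L, times = length(joints)),
    joint = rep(joints, each = nf),
    x = as.vector(arr[, 1L, ]), y = as.vector(arr[, 2L, ]),
    z = as.vector(arr[, 3L, ]))
}

#' Read joint-centre trajectories
#'
#' Reads one or more trial recordings from disk. Three dialects are
#' supported: \code{"csv_long"} (header \code{frame,joint,x,y,z}; one
#' recording per file, metadata from \code{meta} or filename-free
#' arguments), \code{"json"} (a cohort manifest written by
#' [write_manifest()]), and \code{"trc"} (read-only mocap interchange;
#' marker names are canonicalised through the skeleton alias map).
#'
#' @param path file path.
#' @param skeleton a \code{"skeleton"}; joint names are canonicalised
#'   through its alias map, unknown names are an error.
#' @param format \code{"csv_long"}, \code{"json"} or \code{"trc"}.
#' @param meta named list with \code{participant_id}, \code{session},
#'   \code{action}, \code{repeat_index}, \code{fps} for dialects that do not
#'   carry metadata (csv_long, trc); \code{fps} in \code{meta} overrides file
#'   metadata where both exist.
#' @return List of \code{"trial_recording"} objects.
#' @export
read_trajectories <- function(path, skeleton = skeleton_clinical17(),
                              format = c("csv_long", "json", "trc"),
                              meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  defaults <- list(participant_id = "P0", session = "pre", action = "squat",
                   repeat_index = 0L, fps = 30)
  meta <- utils::modifyList(defaults, meta)
  switch(format,
    csv_long = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      list(trial_recording(meta$participant_id, meta$session, meta$action,
                           meta$repeat_index, meta$fps, df, skeleton))
    },
    json = read_manifest(path, skeleton = skeleton)$recordings,
    trc = {
      parsed <- read_trc(path)
      fps <- if (!is.null(meta$fps_override)) meta$fps_override else parsed$fps
      list(trial_recording(meta$participant_id, meta$session, meta$action,
                           meta$repeat_index, fps, parsed$long, skeleton))
    })
}

# Minimal TRC reader: tab-separated, standard 5-line header
# (PathFileType / field names / values / marker names / coordinate labels).
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("truncated TRC file: ", path)
  hdr_names <- strsplit(lines[2L], "\t")[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t")[[1L]]
  fps <- suppressWarnings(as.numeric(hdr_vals[match("DataRate", hdr_names)]))
  if (!isTRUE(is.finite(fps)) || fps <= 0)
    stop("TRC DataRate missing or invalid in ", path)
  markers <- strsplit(lines[4L], "\t")[[1L]]
  markers <- markers[nzchar(markers)][-(1:2)]  # drop Frame#, Time
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t", header = FALSE,
                           fill = TRUE, stringsAsFactors = FALSE)
  dat <- dat[stats::complete.cases(dat[, 1:2]), , drop = FALSE]
  nf <- nrow(dat)
  long <- do.call(rbind, lapply(seq_along(markers), function(i) {
    col0 <- 2L + (i - 1L) * 3L
    data.frame(frame = seq_len(nf) - 1L, joint = markers[i],
               x = as.numeric(dat[[col0 + 1L]]),
               y = as.numeric(dat[[col0 + 2L]]),
               z = as.numeric(dat[[col0 + 3L]]))
  }))
  list(fps = fps, long = long)
}

#' Write one recording as canonical long CSV
#'
#' Header \code{frame,joint,x,y,z}, UTF-8, "." decimal; coordinates are
#' written with 17 significant digits so doubles round-trip exactly.
#'
#' @param recording a \code{"trial_recording"}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(recording, path) {
  df <- positions_array_to_long(recording$positions)
  df$x <- formatC(df$x, format = "g", digits = 17)
  df$y <- formatC(df$y, format = "g", digits = 17)
  df$z <- formatC(df$z, format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort manifest
#'
#' Bundles a cohort's recordings with capture metadata. The capture-protocol
#' defaults (camera height 1.2 m, camera distance 3 m, 30 fps, subject facing
#' the camera) are stored as metadata only; no computation uses them.
#'
#' @param recordings list of \code{"trial_recording"} objects.
#' @param skeleton the \code{"skeleton"} shared by all recordings.
#' @param metadata named list; merged over the protocol defaults.
#' @return An object of class \code{"cohort_manifest"}.
#' @export
cohort_manifest <- function(recordings, skeleton = skeleton_clinical17(),
                            metadata = list()) {
  defaults <- list(camera_height_m = 1.2, camera_distance_m = 3,
                   fps = 30, coordinate_convention =
                     "right-handed; +X anatomical left, +Y up, +Z subject-to-camera; metres")
  cohort <- structure(
    list(recordings = recordings, skeleton = skeleton,
         metadata = utils::modifyList(defaults, metadata)),
    class = "cohort_manifest")
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort against the study-design invariants
#'
#' Checks that every recording is internally valid, that each participant has
#' both a pre and a post session, and that every session/action cell holds at
#' least one recording; fewer than 3 repeats per cell triggers a warning
#' (the capture protocol asks for at least 3).
#'
#' @param cohort a \code{"cohort_manifest"}.
#' @return The cohort, invisibly; errors/warnings otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_manifest"))
  if (!length(cohort$recordings)) stop("cohort has no recordings")
  for (rec in cohort$recordings) {
    stopifnot(inherits(rec, "trial_recording"))
    if (!all(is.finite(rec$positions)))
      stop("non-finite coordinates in ", recording_id(rec))
  }
  idx <- cohort_index(cohort)
  tab <- table(idx$participant_id,
               factor(idx$session, levels = c("pre", "post")), idx$action)
  for (pid in rownames(tab)) {
    per_session <- apply(tab[pid, , , drop = FALSE], 2L, sum)
    if (any(per_session == 0))
      stop("participant ", pid, " lacks session(s): ",
           paste(names(per_session)[per_session == 0], collapse = ", "))
    if (any(tab[pid, , ] > 0 & tab[pid, , ] < 3L))
      warning("participant ", pid, " has fewer than 3 repeats in some ",
              "session/action cells (protocol asks for at least 3)",
              call. = FALSE)
  }
  invisible(cohort)
}

cohort_index <- function(cohort) {
  recs <- cohort$recordings
  data.frame(
    i = seq_along(recs),
    participant_id = vapply(recs, `[[`, "", "participant_id"),
    session = vapply(recs, `[[`, "", "session"),
    action = vapply(recs, `[[`, "", "action"),
    repeat_index = vapply(recs, `[[`, 0L, "repeat_index"),
    stringsAsFactors = FALSE)
}

#' Write a cohort manifest (JSON + per-recording CSV)
#'
#' Writes \code{path} as a JSON manifest listing participants, sessions,
#' actions, repeats and capture metadata, and each recording as a long CSV
#' under \code{<dir>/trajectories/}. [read_manifest()] restores an identical
#' object.
#'
#' @param cohort a valid \code{"cohort_manifest"}.
#' @param path path of the manifest JSON file to create.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  validate_cohort(cohort)
  dir <- dirname(path)
  tdir <- file.path(dir, "trajectories")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$recordings, function(rec) {
    fn <- paste0(gsub("/", "_", recording_id(rec)), ".csv")
    write_trajectory_csv(rec, file.path(tdir, fn))
    list(participant_id = rec$participant_id, session = rec$session,
         action = rec$action, repeat_index = rec$repeat_index,
         fps = rec$fps, file = file.path("trajectories", fn))
  })
  manifest <- list(
    skeleton = list(name = cohort$skeleton$name,
                    joints = cohort$skeleton$joints,
                    aliases = as.list(cohort$skeleton$aliases)),
    metadata = cohort$metadata,
    recordings = entries)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest written by [write_manifest()]
#'
#' @param path manifest JSON path.
#' @param skeleton optional \code{"skeleton"} override; by default the
#'   skeleton embedded in the manifest is reconstructed.
#' @return A \code{"cohort_manifest"}.
#' @export
read_manifest <- function(path, skeleton = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(skeleton))
    skeleton <- skeleton(m$skeleton$name,
                         unlist(m$skeleton$joints, use.names = FALSE),
                         unlist(m$skeleton$aliases))
  dir <- dirname(path)
  recs <- lapply(m$recordings, function(e) {
    df <- utils::read.csv(file.path(dir, e$file), stringsAsFactors = FALSE)
    trial_recording(e$participant_id, e$session, e$action, e$repeat_index,
                    e$fps, df, skeleton)
  })
  cohort_manifest(recs, skeleton = skeleton,
                  metadata = lapply(m$metadata, identity))
}

#' @export
print.cohort_manifest <- function(x, ...) {
  idx <- cohort_index(x)
  cat(sprintf("<cohort_manifest> %d participants, %d recordings (%s)\n",
              length(unique(idx$participant_id)), nrow(idx),
              paste(unique(idx$action), collapse = ", ")))
  invisible(x)
}
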