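#' Planar triplet angle definitions
#'
#' A joint angle is defined by three joint centres — a vertex \code{k}, a
#' proximal joint \code{h} and a distal joint \code{a} — and the anatomical
#' plane into which the points are projected before the angle is measured.
#' Under the package coordinate convention (+X anatomical left, +Y up,
#' +Z subject-to-camera) the sagittal plane is Y-Z (X discarded) and the
#' coronal plane is X-Y (Z discarded).
#'
#' @param name unique angle name, e.g. \code{"right_knee_flexion"}.
#' @param vertex,proximal,distal canonical joint names; must be distinct.
#' @param plane \code{"sagittal"} or \code{"coronal"}.
#' @return An object of class \code{"angle_definition"}.
#' @export
angle_definition <- function(name, vertex, proximal, distal,
                             plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  joints <- c(vertex, proximal, distal)
  stopifnot(is.character(name), length(name) == 1L)
  if (anyDuplicated(joints))
    stop("angle '", name, "': vertex, proximal and distal joints must be distinct")
  structure(list(name = name, vertex = vertex, proximal = proximal,
                 distal = distal, plane = plane),
            class = "angle_definition")
}

#' @export
print.angle_definition <- function(x, ...) {
  cat(sprintf("<angle> %s: %s-[%s]-%s (%s plane)\n",
              x$name, x$proximal, x$vertex, x$distal, x$plane))
  invisible(x)
}

#' Default clinical angle registry
#'
#' Ten planar angles covering both sides: knee flexion/extension
#' (hip-knee-ankle, sagittal), ankle flexion/extension (knee-ankle-foot,
#' sagittal), hip abduction/adduction (spine-hip-knee, coronal), arm
#' (shoulder) abduction (hip-shoulder-elbow, coronal) and elbow flexion
#' (shoulder-elbow-wrist, sagittal).
#'
#' @return Named list of \code{"angle_definition"} objects.
#' @export
default_angle_registry <- function() {
  defs <- list()
  for (side in c("left", "right")) {
    j <- function(x) paste0(side, "_", x)
    defs[[j("knee_flexion")]] <- angle_definition(
      j("knee_flexion"), vertex = j("knee"), proximal = j("hip"),
      distal = j("ankle"), plane = "sagittal")
    defs[[j("ankle_flexion")]] <- angle_definition(
      j("ankle_flexion"), vertex = j("ankle"), proximal = j("knee"),
      distal = j("foot"), plane = "sagittal")
    defs[[j("hip_abduction")]] <- angle_definition(
      j("hip_abduction"), vertex = j("hip"), proximal = "spine",
      distal = j("knee"), plane = "coronal")
    defs[[j("arm_abduction")]] <- angle_definition(
      j("arm_abduction"), vertex = j("shoulder"), proximal = j("hip"),
      distal = j("elbow"), plane = "coronal")
    defs[[j("elbow_flexion")]] <- angle_definition(
      j("elbow_flexion"), vertex = j("elbow"), proximal = j("shoulder"),
      distal = j("wrist"), plane = "sagittal")
  }
  defs
}

# Project n x 3 coordinates into a named anatomical plane (n x 2).
project_plane <- function(xyz, plane) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  switch(plane,
         sagittal = xyz[, c(2L, 3L), drop = FALSE],  # drop X
         coronal  = xyz[, c(1L, 2L), drop = FALSE],  # drop Z
         stop("unknown plane: ", plane))
}
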