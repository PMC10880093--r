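#' Skeleton definitions
#'
#' A skeleton definition names the ordered set of joint-centre labels a
#' trajectory file is expected to contain, together with an alias map that
#' translates external naming dialects (e.g. \code{"LKnee"}) to the canonical
#' names used throughout the package.
#'
#' @param name identifier for the skeleton.
#' @param joints character vector of unique, non-empty joint names.
#' @param aliases named character vector mapping external names to canonical
#'   joint names; every alias target must be one of \code{joints}.
#'
#' @return An object of class \code{"skeleton"}: a list with elements
#'   \code{name}, \code{joints} and \code{aliases}.
#' @seealso [skeleton_clinical17()], [skeleton_smplx()]
#' @export
#' @examples
#' sk <- skeleton("mini", c("hip", "knee", "ankle"), c(Knee = "knee"))
#' sk$joints
skeleton <- function(name, joints, aliases = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(joints) == 0L || anyNA(joints) || any(!nzchar(joints)))
    stop("skeleton joints must be a non-empty vector of non-empty names")
  if (anyDuplicated(joints))
    stop("duplicate joint names: ",
         paste(unique(joints[duplicated(joints)]), collapse = ", "))
  aliases <- stats::setNames(as.character(aliases), names(aliases))
  if (length(aliases)) {
    bad <- setdiff(aliases, joints)
    if (length(bad))
      stop("alias targets not in skeleton: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, joints = joints, aliases = aliases),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton>", x$name, "-", length(x$joints), "joints,",
      length(x$aliases), "aliases\n")
  invisible(x)
}

#' Minimal 17-joint clinical skeleton
#'
#' Pelvis, spine, head, and left/right hip, knee, ankle, foot, shoulder,
#' elbow and wrist: the joints required by the default angle registry.
#' Common external dialects (CamelCase, L/R prefixes) are aliased.
#'
#' @return A \code{"skeleton"} object with 17 joints.
#' @export
skeleton_clinical17 <- function() {
  sided <- c("hip", "knee", "ankle", "foot", "shoulder", "elbow", "wrist")
  joints <- c("pelvis", "spine", "head",
              paste0("left_", sided), paste0("right_", sided))
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  aliases <- c(
    stats::setNames(paste0("left_", sided), paste0("L", cap(sided))),
    stats::setNames(paste0("right_", sided), paste0("R", cap(sided))),
    Pelvis = "pelvis", Spine = "spine", Head = "head")
  skeleton("clinical17", joints, aliases)
}

#' Default 54-joint skeleton for mesh-recovery front ends
#'
#' Marker-less mesh-recovery pipelines built on the SMPL-X body model export
#' a 54-joint skeleton: 21 body joints plus jaw, two eyes, and 15 finger
#' joints per hand. This definition enumerates those joints (the pelvis root
#' is not counted as a joint in that convention, so \code{"pelvis"} and
#' \code{"spine"} are provided as aliases of the nearest spine joints for
#' compatibility with the clinical registry).
#'
#' @return A \code{"skeleton"} object with 54 joints.
#' @export
skeleton_smplx <- function() {
  body <- c("left_hip", "right_hip", "spine1", "left_knee", "right_knee",
            "spine2", "left_ankle", "right_ankle", "spine3", "left_foot",
            "right_foot", "neck", "left_collar", "right_collar", "head",
            "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
            "left_wrist", "right_wrist")
  face <- c("jaw", "left_eye", "right_eye")
  fingers <- c("index", "middle", "pinky", "ring", "thumb")
  hand <- function(side)
    paste0(side, "_", rep(fingers, each = 3L), rep(1:3, times = 5L))
  joints <- c(body, face, hand("left"), hand("right"))
  stopifnot(length(joints) == 54L)
  skeleton("smplx54", joints,
           aliases = c(pelvis = "spine1", spine = "spine1"))
}

#' Canonicalise joint names under a skeleton's alias map
#'
#' @param names character vector of joint names as found in a file.
#' @param skeleton a \code{"skeleton"} object.
#' @return Character vector of canonical names; unknown names that are
#'   neither canonical nor aliased raise an error.
#' @export
canonical_joints <- function(names, skeleton) {
  out <- names
  hit <- out %in% names(skeleton$aliases)
  out[hit] <- unname(skeleton$aliases[out[hit]])
  unknown <- setdiff(unique(out), skeleton$joints)
  if (length(unknown))
    stop("unknown joint names (no alias in skeleton '", skeleton$name, "'): ",
         paste(unknown, collapse = ", "))
  out
}
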