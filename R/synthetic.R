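#' Motion template for a squat or sit-to-stand action
#'
#' A template gives, per base angle name (applied to both sides), a
#' parametric curve: a start angle, an extreme angle, and a raised-cosine
#' shape — \code{"bump"} (start to extreme and back, e.g. the knee dip of a
#' squat) or \code{"step"} (monotone start to extreme, e.g. knee extension
#' when rising from a chair).
#'
#' @param action \code{"squat"} or \code{"sit_to_stand"}.
#' @param duration_s nominal repeat duration in seconds (> 0).
#' @param angle_profiles named list; each element
#'   \code{list(start =, extreme =, shape =)} with angles in degrees inside
#'   (0, 180].
#' @param segment_lengths named numeric: limb segment lengths in metres
#'   (thigh, shank, foot, upper_arm, forearm), all > 0.
#' @return An object of class \code{"motion_template"}.
#' @export
motion_template <- function(action, duration_s, angle_profiles,
                            segment_lengths = c(thigh = 0.45, shank = 0.45,
                                                foot = 0.20, upper_arm = 0.30,
                                                forearm = 0.28)) {
  action <- match.arg(action, c("squat", "sit_to_stand"))
  stopifnot(duration_s > 0, all(segment_lengths > 0))
  for (nm in names(angle_profiles)) {
    p <- angle_profiles[[nm]]
    if (!all(c("start", "extreme", "shape") %in% names(p)))
      stop("profile '", nm, "' needs start, extreme, shape")
    if (any(c(p$start, p$extreme) <= 0) || any(c(p$start, p$extreme) > 180))
      stop("profile '", nm, "' angles must lie in (0, 180]")
    if (!p$shape %in% c("bump", "step"))
      stop("profile '", nm, "' shape must be 'bump' or 'step'")
  }
  structure(list(action = action, duration_s = duration_s,
                 angle_profiles = angle_profiles,
                 segment_lengths = segment_lengths),
            class = "motion_template")
}

#' Default action templates
#'
#' Squat (3 s): deep knee flexion dip (175 to 70 deg) with accompanying
#' ankle dorsiflexion, slight hip ab/adduction, and a modest arm
#' raise/elbow bend for balance. Sit-to-stand (2.5 s): knee extension rise
#' (95 to 172 deg), ankle plantar shift, and a pronounced elbow
#' flexion-extension burst with arm abduction from pushing off the chair.
#' Values are typical of the motion-capture literature for these tasks.
#'
#' @return Named list of two \code{"motion_template"} objects.
#' @export
default_templates <- function() {
  list(
    squat = motion_template("squat", duration_s = 3, angle_profiles = list(
      knee_flexion  = list(start = 175, extreme = 70,  shape = "bump"),
      ankle_flexion = list(start = 112, extreme = 80,  shape = "bump"),
      hip_abduction = list(start = 175, extreme = 166, shape = "bump"),
      arm_abduction = list(start = 8,   extreme = 30,  shape = "bump"),
      elbow_flexion = list(start = 170, extreme = 140, shape = "bump"))),
    sit_to_stand = motion_template("sit_to_stand", duration_s = 2.5,
                                   angle_profiles = list(
      knee_flexion  = list(start = 95,  extreme = 172, shape = "step"),
      ankle_flexion = list(start = 82,  extreme = 108, shape = "step"),
      hip_abduction = list(start = 172, extreme = 166, shape = "bump"),
      arm_abduction = list(start = 8,   extreme = 50,  shape = "bump"),
      elbow_flexion = list(start = 160, extreme = 85,  shape = "bump"))))
}

#' Pre/post effect specification
#'
#' Describes the contrast the generator injects between the pre and post
#' sessions: targeted angles receive high-frequency band-limited noise of
#' amplitude \code{noise_amp_pre} before the intervention and
#' \code{noise_amp_post} after (post smoother when pre > post), and their
#' post-session range is extended by \code{range_shift_deg} (fuller movement
#' once pain-driven guarding is removed). Untargeted angles carry
#' \code{noise_amp_base} in both sessions. \code{per_participant_sd} is the
#' SD of per-participant, per-side offsets on each profile's extreme angle,
#' identical across sessions so the paired design isolates the injected
#' effect.
#'
#' @param target_angles base angle names the effect applies to.
#' @param noise_amp_pre,noise_amp_post noise SD in degrees (>= 0).
#' @param noise_freq_band length-2 Hz band; must stay below Nyquist.
#' @param range_shift_deg degrees by which the post-session extreme extends.
#' @param per_participant_sd degrees.
#' @param noise_amp_base baseline noise SD (deg) for untargeted angles.
#' @return An object of class \code{"effect_spec"}.
#' @export
effect_spec <- function(target_angles = c("knee_flexion", "elbow_flexion"),
                        noise_amp_pre = 2, noise_amp_post = 0.8,
                        noise_freq_band = c(6, 10), range_shift_deg = 5,
                        per_participant_sd = 8, noise_amp_base = 0.5) {
  stopifnot(noise_amp_pre >= 0, noise_amp_post >= 0, noise_amp_base >= 0,
            length(noise_freq_band) == 2L, noise_freq_band[1L] > 0,
            diff(noise_freq_band) >= 0, per_participant_sd >= 0)
  structure(list(target_angles = target_angles,
                 noise_amp_pre = noise_amp_pre,
                 noise_amp_post = noise_amp_post,
                 noise_freq_band = noise_freq_band,
                 range_shift_deg = range_shift_deg,
                 per_participant_sd = per_participant_sd,
                 noise_amp_base = noise_amp_base),
            class = "effect_spec")
}

# Raised-cosine basis on normalised phase s in [0, 1].
profile_weight <- function(s, shape) {
  switch(shape,
         bump = 0.5 * (1 - cos(2 * pi * s)),
         step = 0.5 * (1 - cos(pi * s)))
}

# Band-limited noise: sum of K random-phase sinusoids with frequencies
# uniform in `band`; amplitudes set so the theoretical SD equals `amp`.
band_noise <- function(t, amp, band, K = 8L) {
  if (amp <= 0) return(numeric(length(t)))
  f <- stats::runif(K, band[1L], band[2L])
  phi <- stats::runif(K, 0, 2 * pi)
  a <- amp * sqrt(2 / K)
  colSums(a * sin(outer(2 * pi * f, t) + phi))
}

base_pose <- function() {
  rbind(pelvis = c(0, 0.95, 0), spine = c(0, 1.25, 0), head = c(0, 1.65, 0),
        left_hip = c(0.12, 0.95, 0), right_hip = c(-0.12, 0.95, 0),
        left_shoulder = c(0.18, 1.45, 0), right_shoulder = c(-0.18, 1.45, 0))
}

rot2 <- function(u1, u2, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  list(x = c_ * u1 - s_ * u2, y = s_ * u1 + c_ * u2)
}

# Planar forward kinematics: given per-frame angle curves (degrees) for the
# ten registry angles, build the 17-joint position array so that extracting
# each triplet angle in its plane recovers the generating curve exactly.
forward_kinematics <- function(theta, seg) {
  nf <- nrow(theta)
  sk <- skeleton_clinical17()
  P <- array(0, dim = c(nf, 3L, length(sk$joints)),
             dimnames = list(NULL, c("x", "y", "z"), sk$joints))
  fixed <- base_pose()
  for (j in rownames(fixed))
    P[, , j] <- matrix(fixed[j, ], nf, 3L, byrow = TRUE)
  d2r <- pi / 180
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    j <- function(x) paste0(side, "_", x)
    hip <- fixed[j("hip"), ]; sho <- fixed[j("shoulder"), ]
    # hip abduction: coronal rotation of the hip->spine direction
    u <- (fixed["spine", 1:2] - hip[1:2]); u <- u / sqrt(sum(u^2))
    d <- rot2(u[1L], u[2L], -sgn * theta[, j("hip_abduction")] * d2r)
    P[, 1L, j("knee")] <- hip[1L] + seg["thigh"] * d$x
    P[, 2L, j("knee")] <- hip[2L] + seg["thigh"] * d$y
    # knee flexion: sagittal rotation of the knee->hip direction
    wy <- hip[2L] - P[, 2L, j("knee")]; wz <- -P[, 3L, j("knee")]
    wl <- sqrt(wy^2 + wz^2); wy <- wy / wl; wz <- wz / wl
    d <- rot2(wy, wz, theta[, j("knee_flexion")] * d2r)
    P[, 1L, j("ankle")] <- P[, 1L, j("knee")]
    P[, 2L, j("ankle")] <- P[, 2L, j("knee")] + seg["shank"] * d$x
    P[, 3L, j("ankle")] <- P[, 3L, j("knee")] + seg["shank"] * d$y
    # ankle flexion: sagittal rotation of the ankle->knee direction
    uy <- P[, 2L, j("knee")] - P[, 2L, j("ankle")]
    uz <- P[, 3L, j("knee")] - P[, 3L, j("ankle")]
    ul <- sqrt(uy^2 + uz^2); uy <- uy / ul; uz <- uz / ul
    d <- rot2(uy, uz, theta[, j("ankle_flexion")] * d2r)
    P[, 1L, j("foot")] <- P[, 1L, j("ankle")]
    P[, 2L, j("foot")] <- P[, 2L, j("ankle")] + seg["foot"] * d$x
    P[, 3L, j("foot")] <- P[, 3L, j("ankle")] + seg["foot"] * d$y
    # arm abduction: coronal rotation of the shoulder->hip direction
    u <- hip[1:2] - sho[1:2]; u <- u / sqrt(sum(u^2))
    d <- rot2(u[1L], u[2L], sgn * theta[, j("arm_abduction")] * d2r)
    P[, 1L, j("elbow")] <- sho[1L] + seg["upper_arm"] * d$x
    P[, 2L, j("elbow")] <- sho[2L] + seg["upper_arm"] * d$y
    # elbow flexion: sagittal rotation of the elbow->shoulder direction
    uy <- sho[2L] - P[, 2L, j("elbow")]; uz <- -P[, 3L, j("elbow")]
    ul <- sqrt(uy^2 + uz^2); uy <- uy / ul; uz <- uz / ul
    d <- rot2(uy, uz, theta[, j("elbow_flexion")] * d2r)
    P[, 1L, j("wrist")] <- P[, 1L, j("elbow")]
    P[, 2L, j("wrist")] <- P[, 2L, j("elbow")] + seg["forearm"] * d$x
    P[, 3L, j("wrist")] <- P[, 3L, j("elbow")] + seg["forearm"] * d$y
  }
  P
}

#' Generate one simulated repeat
#'
#' Draws a repeat duration within ±10% of the template duration, evaluates
#' the (side-resolved) angle profiles, adds band-limited noise at the
#' session's amplitude, clamps to (0, 180), and runs planar forward
#' kinematics so that triplet-angle extraction recovers the generating
#' (noise-inclusive) curves to machine precision.
#'
#' Uses the current RNG state; seed upstream (see [generate_cohort()]) for
#' reproducibility.
#'
#' @param template a \code{"motion_template"}.
#' @param effect an \code{"effect_spec"}.
#' @param session \code{"pre"} or \code{"post"}.
#' @param fps frames per second; the noise band must stay below fps/2.
#' @param participant_id,repeat_index identification for the recording.
#' @param extreme_offsets named numeric (side-resolved angle names) of
#'   per-participant offsets added to each profile's extreme; default 0.
#' @return List with \code{recording} (a \code{"trial_recording"}),
#'   \code{truth} (frames x angles matrix of the noisy generating curves,
#'   degrees), \code{clean} (noise-free curves) and \code{noise}.
#' @export
generate_repeat <- function(template, effect, session, fps = 30,
                            participant_id = "P0", repeat_index = 0L,
                            extreme_offsets = NULL) {
  if (!session %in% c("pre", "post")) stop("session must be 'pre' or 'post'")
  if (effect$noise_freq_band[2L] >= fps / 2)
    stop("noise band reaches Nyquist frequency (", fps / 2, " Hz) for fps = ", fps)
  dur <- template$duration_s * stats::runif(1L, 0.9, 1.1)
  nf <- max(3L, floor(dur * fps) + 1L)
  t <- (seq_len(nf) - 1L) / fps
  s <- t / t[nf]
  angle_names <- as.vector(outer(c("left_", "right_"),
                                 names(template$angle_profiles), paste0))
  clean <- noise <- matrix(0, nf, length(angle_names),
                           dimnames = list(NULL, angle_names))
  for (base in names(template$angle_profiles)) {
    p <- template$angle_profiles[[base]]
    targeted <- base %in% effect$target_angles
    amp <- if (!targeted) effect$noise_amp_base
           else if (session == "pre") effect$noise_amp_pre
           else effect$noise_amp_post
    for (side in c("left", "right")) {
      nm <- paste0(side, "_", base)
      extreme <- p$extreme
      if (!is.null(extreme_offsets) && nm %in% names(extreme_offsets))
        extreme <- extreme + extreme_offsets[[nm]]
      if (targeted && session == "post")
        extreme <- extreme + sign(extreme - p$start) * effect$range_shift_deg
      clean[, nm] <- p$start + (extreme - p$start) * profile_weight(s, p$shape)
      noise[, nm] <- band_noise(t, amp, effect$noise_freq_band)
    }
  }
  truth <- pmin(pmax(clean + noise, 0.5), 179.5)
  rec <- trial_recording(participant_id, session, template$action,
                         repeat_index, fps,
                         forward_kinematics(truth, template$segment_lengths))
  list(recording = rec, truth = truth, clean = clean, noise = truth - clean)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a full simulated cohort with ground truth
#'
#' Default study conditions: 20 participants, 3 repeats, both actions
#' (squat and sit-to-stand), pre and post sessions at 30 fps — 240
#' recordings. Per participant and side, each profile's extreme angle is
#' offset by a draw with SD \code{effect$per_participant_sd}, held constant
#' across sessions.
#'
#' @param n_participants number of participants (>= 2).
#' @param templates named list of \code{"motion_template"}s (one per action).
#' @param effect an \code{"effect_spec"}.
#' @param n_repeats repeats per session/action cell (>= 1; the capture
#'   protocol expects >= 3, fewer triggers a validation warning).
#' @param fps frames per second.
#' @param seed integer; identical seeds reproduce the cohort bit-for-bit.
#' @return An object of class \code{"simulated_cohort"}: list with
#'   \code{cohort} (a \code{"cohort_manifest"}), \code{ground_truth}
#'   (per-recording truth/clean/noise curves and per-participant draws) and
#'   \code{seed}.
#' @export
generate_cohort <- function(n_participants = 20, templates = default_templates(),
                            effect = effect_spec(), n_repeats = 3, fps = 30,
                            seed = 1) {
  stopifnot(n_participants >= 2, n_repeats >= 1)
  with_seed(seed, {
    recordings <- list()
    ground_truth <- list()
    draws <- list()
    for (i in seq_len(n_participants)) {
      pid <- sprintf("P%02d", i)
      offs <- list()
      for (tmpl in templates)
        for (base in names(tmpl$angle_profiles))
          for (side in c("left", "right")) {
            nm <- paste0(side, "_", base)
            if (is.null(offs[[nm]]))
              offs[[nm]] <- stats::rnorm(1L, 0, effect$per_participant_sd)
          }
      draws[[pid]] <- unlist(offs)
      for (session in c("pre", "post"))
        for (action in names(templates))
          for (r in seq_len(n_repeats)) {
            g <- generate_repeat(templates[[action]], effect, session, fps,
                                 participant_id = pid, repeat_index = r - 1L,
                                 extreme_offsets = offs)
            id <- recording_id(g$recording)
            recordings[[id]] <- g$recording
            ground_truth[[id]] <- g[c("truth", "clean", "noise")]
          }
    }
    cohort <- suppressWarnings(
      cohort_manifest(unname(recordings), metadata = list(fps = fps)))
    if (n_repeats < 3L)
      warning("fewer than 3 repeats per cell (protocol asks for at least 3)",
              call. = FALSE)
    structure(list(cohort = cohort, ground_truth = ground_truth,
                   participant_draws = draws, seed = seed),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> seed", x$seed, "-")
  print(x$cohort)
  invisible(x)
}

#' Concatenate repeats into a continuous trace
#'
#' Joins per-repeat angle curves with rest (baseline hold) periods in
#' between, as a continuous capture would look before repeat segmentation.
#' Returns the trace and the ground-truth half-open repeat boundaries.
#'
#' @param theta_list list of numeric angle curves (degrees).
#' @param rest_value baseline angle held between repeats; defaults to the
#'   first sample of the first repeat.
#' @param rest_frames frames of rest before, between and after repeats.
#' @return List with \code{theta} and \code{boundaries} (data frame of
#'   \code{start}, \code{end} frame indices, 0-based half-open).
#' @export
concatenate_repeats <- function(theta_list, rest_value = NULL,
                                rest_frames = 20L) {
  stopifnot(length(theta_list) >= 1L)
  if (is.null(rest_value)) rest_value <- theta_list[[1L]][1L]
  rest <- rep(rest_value, rest_frames)
  theta <- rest
  starts <- ends <- integer(length(theta_list))
  for (i in seq_along(theta_list)) {
    starts[i] <- length(theta)
    theta <- c(theta, theta_list[[i]])
    ends[i] <- length(theta)
    theta <- c(theta, rest)
  }
  list(theta = theta, boundaries = data.frame(start = starts, end = ends))
}
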