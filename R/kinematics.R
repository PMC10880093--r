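#' Joint angle from three joint centres
#'
#' The angle at vertex \code{k} subtended by proximal joint \code{h} and
#' distal joint \code{a}, measured after projecting all three points into the
#' named anatomical plane. With \code{m = h - k}, \code{n = a - k} and
#' \code{p = h - a}, the angle is
#' \deqn{\theta = \arccos\!\left(\frac{|m|^2 + |n|^2 - |p|^2}{2|m||n|}\right)}
#' in degrees, the arccos argument clamped to \eqn{[-1, 1]} so near-collinear
#' configurations never produce NaN. The result lies in [0, 180].
#'
#' @param k,h,a numeric length-3 vectors (x, y, z in metres), or matrices with
#'   one row per frame for vectorised evaluation.
#' @param plane \code{"sagittal"} (Y-Z) or \code{"coronal"} (X-Y).
#' @param eps projected vectors shorter than this (metres) are degenerate.
#' @return Angle(s) in degrees, one per row.
#' @export
#' @examples
#' compute_joint_angle(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), "sagittal")  # 90
compute_joint_angle <- function(k, h, a, plane = c("sagittal", "coronal"),
                                eps = 1e-9) {
  plane <- match.arg(plane)
  k2 <- project_plane(k, plane)
  h2 <- project_plane(h, plane)
  a2 <- project_plane(a, plane)
  m <- h2 - k2
  n <- a2 - k2
  p <- h2 - a2
  m2 <- rowSums(m * m)
  n2 <- rowSums(n * n)
  p2 <- rowSums(p * p)
  if (any(bad <- m2 <= eps^2))
    stop("degenerate angle: proximal-vertex vector collapsed at frame ",
         which(bad)[1L])
  if (any(bad <- n2 <= eps^2))
    stop("degenerate angle: distal-vertex vector collapsed at frame ",
         which(bad)[1L])
  arg <- (m2 + n2 - p2) / (2 * sqrt(m2) * sqrt(n2))
  arg <- pmin(1, pmax(-1, arg))
  acos(arg) * 180 / pi
}

#' Joint-angle time series for one angle definition
#'
#' Evaluates a planar triplet angle at every frame of a recording.
#'
#' @param recording a \code{"trial_recording"} object.
#' @param definition an \code{"angle_definition"} object.
#' @return An object of class \code{"angle_series"}: a list with
#'   \code{definition}, \code{theta} (degrees, one per frame), \code{fps}
#'   and a \code{provenance} string.
#' @export
angle_series <- function(recording, definition) {
  stopifnot(inherits(recording, "trial_recording"),
            inherits(definition, "angle_definition"))
  need <- c(definition$vertex, definition$proximal, definition$distal)
  have <- dimnames(recording$positions)[[3L]]
  if (length(miss <- setdiff(need, have)))
    stop("recording lacks joints required by angle '", definition$name,
         "': ", paste(miss, collapse = ", "))
  P <- recording$positions
  theta <- tryCatch(
    compute_joint_angle(P[, , definition$vertex, drop = TRUE],
                        P[, , definition$proximal, drop = TRUE],
                        P[, , definition$distal, drop = TRUE],
                        plane = definition$plane),
    error = function(e) stop("angle '", definition$name, "': ",
                             conditionMessage(e), call. = FALSE))
  new_angle_series(definition, theta, recording$fps,
                   provenance = recording_id(recording))
}

new_angle_series <- function(definition, theta, fps, provenance = NA_character_) {
  structure(list(definition = definition, theta = as.numeric(theta),
                 fps = fps, provenance = provenance),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s: %d frames @ %g fps, range [%.1f, %.1f] deg\n",
              x$definition$name, length(x$theta), x$fps,
              min(x$theta), max(x$theta)))
  invisible(x)
}

#' Angular velocity and acceleration by finite differences
#'
#' Forward differences of the angle sequence:
#' \eqn{\omega_i = (\theta_{i+1} - \theta_i)/\Delta t} (deg/s) and
#' \eqn{\alpha_i = (\omega_{i+1} - \omega_i)/\Delta t} (deg/s^2), with
#' \eqn{\Delta t = 1/\mathrm{fps}}. A central-difference scheme is available
#' for sensitivity checks; lengths then remain \code{n - 1} and \code{n - 2}
#' by evaluating interior points only.
#'
#' @param series an \code{"angle_series"} (or plain numeric vector, in which
#'   case \code{fps} must be supplied).
#' @param fps frames per second; taken from \code{series} when absent.
#' @param scheme \code{"forward"} (default) or \code{"central"}.
#' @return An object of class \code{"angular_derivatives"}: list with
#'   \code{omega} (deg/s), \code{alpha} (deg/s^2) and \code{dt} (s).
#' @export
derivatives <- function(series, fps = NULL, scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  theta <- if (inherits(series, "angle_series")) series$theta else as.numeric(series)
  if (is.null(fps)) fps <- series$fps
  if (length(theta) < 3L)
    stop("need at least 3 samples for angular derivatives, got ", length(theta))
  dt <- 1 / fps
  if (scheme == "forward") {
    omega <- diff(theta) / dt
    alpha <- diff(omega) / dt
  } else {
    n <- length(theta)
    omega <- (theta[-(1:2)] - theta[1:(n - 2L)]) / (2 * dt)
    omega <- c(omega, (theta[n] - theta[n - 1L]) / dt)  # one-sided tail
    alpha <- diff(omega) / dt
  }
  structure(list(omega = omega, alpha = alpha, dt = dt),
            class = "angular_derivatives")
}

#' Gradient-SD smoothness of an angle curve
#'
#' The gradients \eqn{m_i} are forward differences of the curve with respect
#' to time (deg/s); their sample standard deviation
#' \deqn{\sigma_m = \sqrt{\sum_i (m_i - \bar m)^2 / (n - 1)}}
#' measures how much the slope varies from point to point. Because
#' \eqn{\sigma_m} is unbounded and smaller-is-smoother, it is also mapped to
#' a bounded score \eqn{1 / (1 + \sigma_m / \sigma_{\mathrm{ref}})} in (0, 1],
#' equal to 1 exactly when the curve is linear; \code{sigma_ref} (default
#' 100 deg/s) sets the scale of that mapping and is recorded in reports.
#'
#' @param series an \code{"angle_series"} or numeric vector.
#' @param fps frames per second (required if \code{series} is a bare vector).
#' @param sigma_ref reference gradient SD (deg/s) for the bounded score.
#' @return An object of class \code{"smoothness_result"}: list with
#'   \code{sigma_m} (deg/s), \code{smoothness} in (0, 1], and
#'   \code{sigma_ref}.
#' @export
smoothness <- function(series, fps = NULL, sigma_ref = 100) {
  theta <- if (inherits(series, "angle_series")) series$theta else as.numeric(series)
  if (is.null(fps)) fps <- series$fps
  if (length(theta) < 3L)
    stop("need at least 3 samples for smoothness, got ", length(theta))
  m <- diff(theta) * fps
  sigma_m <- stats::sd(m)
  structure(list(sigma_m = sigma_m,
                 smoothness = 1 / (1 + sigma_m / sigma_ref),
                 sigma_ref = sigma_ref),
            class = "smoothness_result")
}

#' Cumulative absolute rotational acceleration
#'
#' \deqn{J = \int |\alpha| \, dt}
#' evaluated by the trapezoidal rule over the acceleration samples; a single
#' scalar (deg/s) summarising the abruptness/explosiveness of the movement at
#' one joint. J is 0 exactly when the angular velocity is constant.
#'
#' @param deriv an \code{"angular_derivatives"} object (or numeric alpha
#'   vector with \code{dt} supplied).
#' @param dt sample spacing in seconds (required for a bare vector).
#' @return An object of class \code{"cumulative_acceleration"}: list with
#'   \code{J} (deg/s).
#' @export
cumulative_acceleration <- function(deriv, dt = NULL) {
  alpha <- if (inherits(deriv, "angular_derivatives")) deriv$alpha else as.numeric(deriv)
  if (is.null(dt)) dt <- deriv$dt
  if (length(alpha) < 1L) stop("empty acceleration sequence")
  a <- abs(alpha)
  J <- if (length(a) == 1L) 0 else sum((a[-1L] + a[-length(a)]) / 2) * dt
  structure(list(J = J), class = "cumulative_acceleration")
}
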