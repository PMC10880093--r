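#' Segment a continuous angle trace into action repeats
#'
#' Repeats are detected as excursions of the primary angle (e.g. knee
#' flexion, which dips during a squat and during the seated phase of a
#' sit-to-stand cycle) below a standing baseline, taken as the 90th
#' percentile of the series. A candidate excursion must dip at least
#' \code{min_prominence} degrees below the baseline and last at least
#' \code{min_duration_s}; its boundaries are widened to the nearest
#' crossings of the baseline (less a small tolerance) on either side.
#'
#' @param series an \code{"angle_series"} (or numeric vector with
#'   \code{fps}).
#' @param min_prominence minimum dip below baseline, degrees.
#' @param min_duration_s minimum repeat duration, seconds.
#' @param fps frames per second (for a bare vector).
#' @return Data frame with columns \code{start}, \code{end} (0-based,
#'   half-open), ordered and non-overlapping; empty (with a warning) when no
#'   excursion reaches the prominence threshold.
#' @export
segment_repeats <- function(series, min_prominence = 20, min_duration_s = 0.5,
                            fps = NULL) {
  theta <- if (inherits(series, "angle_series")) series$theta else as.numeric(series)
  if (is.null(fps)) fps <- series$fps
  n <- length(theta)
  if (n < 2 * min_duration_s * fps)
    stop("series too short to hold a repeat of ", min_duration_s, " s")
  baseline <- stats::quantile(theta, 0.9, names = FALSE, type = 7)
  below <- theta < baseline - min_prominence
  if (!any(below)) {
    warning("no excursion exceeds min_prominence = ", min_prominence,
            " deg; returning no segments", call. = FALSE)
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(below)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1L
  runs <- which(r$values)
  tol <- 0.5  # deg: boundary = crossing of (baseline - tol)
  segs <- lapply(runs, function(k) {
    i0 <- starts_at[k]; i1 <- ends_at[k]
    while (i0 > 1L && theta[i0 - 1L] < baseline - tol) i0 <- i0 - 1L
    while (i1 < n && theta[i1 + 1L] < baseline - tol) i1 <- i1 + 1L
    c(i0, i1)
  })
  segs <- do.call(rbind, segs)
  # widening can merge adjacent runs into identical spans
  segs <- unique(segs)
  keep <- (segs[, 2L] - segs[, 1L] + 1L) >= min_duration_s * fps
  segs <- segs[keep, , drop = FALSE]
  if (!nrow(segs)) {
    warning("all excursions shorter than min_duration_s; returning no segments",
            call. = FALSE)
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = segs[, 1L] - 1L, end = segs[, 2L])  # 0-based half-open
}

#' Aggregate repeats into frame-wise mean/min/max curves
#'
#' Repeats are aligned at their start frame and compared at the same frame
#' index — no time normalisation, since a changed action length may itself
#' be pathological. Under \code{"truncate_shortest"} (default) only frames
#' present in every repeat (0 .. L_min - 1) are aggregated; under
#' \code{"nan_pad"} each frame aggregates whichever repeats reach it, up to
#' the longest.
#'
#' @param series_per_repeat list of \code{"angle_series"} sharing one angle
#'   definition and fps.
#' @param policy \code{"truncate_shortest"} or \code{"nan_pad"}.
#' @return An object of class \code{"curve_summary"}: list with
#'   \code{angle}, \code{mean_curve}, \code{min_curve}, \code{max_curve},
#'   \code{n_repeats}, \code{aggregated_length}, \code{fps}.
#' @export
aggregate_repeats <- function(series_per_repeat,
                              policy = c("truncate_shortest", "nan_pad")) {
  policy <- match.arg(policy)
  stopifnot(length(series_per_repeat) >= 1L)
  defs <- vapply(series_per_repeat, function(s) s$definition$name, "")
  if (length(unique(defs)) != 1L)
    stop("mixed angle definitions: ", paste(unique(defs), collapse = ", "))
  fps <- series_per_repeat[[1L]]$fps
  lens <- vapply(series_per_repeat, function(s) length(s$theta), 0L)
  L <- if (policy == "truncate_shortest") min(lens) else max(lens)
  M <- matrix(NA_real_, L, length(series_per_repeat))
  for (i in seq_along(series_per_repeat)) {
    th <- series_per_repeat[[i]]$theta
    M[seq_len(min(L, length(th))), i] <- th[seq_len(min(L, length(th)))]
  }
  cols <- lapply(seq_len(ncol(M)), function(i) M[, i])
  structure(list(
    angle = defs[1L],
    mean_curve = rowMeans(M, na.rm = TRUE),
    min_curve = do.call(pmin, c(cols, na.rm = TRUE)),
    max_curve = do.call(pmax, c(cols, na.rm = TRUE)),
    n_repeats = length(series_per_repeat),
    aggregated_length = L, fps = fps),
    class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("<curve_summary> %s: %d frames over %d repeats @ %g fps\n",
              x$angle, x$aggregated_length, x$n_repeats, x$fps))
  invisible(x)
}
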