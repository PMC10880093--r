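#' Paired pre/post sample for one biomarker metric
#'
#' @param biomarker feature name (e.g. \code{"right_knee_flexion_max"}).
#' @param metric \code{"smoothness"} or \code{"cumulative_acceleration"}.
#' @param pre,post numeric vectors of per-participant values, aligned.
#' @param participant_ids character vector aligned with \code{pre}.
#' @return An object of class \code{"paired_sample"}.
#' @export
paired_sample <- function(biomarker, metric, pre, post,
                          participant_ids = NULL) {
  metric <- match.arg(metric, c("smoothness", "cumulative_acceleration",
                                "sigma_m"))
  if (length(pre) != length(post))
    stop("pre and post must be aligned by participant")
  if (length(pre) < 2L) stop("need at least 2 paired observations")
  if (!all(is.finite(pre)) || !all(is.finite(post)))
    stop("non-finite values in paired sample")
  if (is.null(participant_ids))
    participant_ids <- sprintf("P%02d", seq_along(pre))
  structure(list(biomarker = biomarker, metric = metric,
                 pre = as.numeric(pre), post = as.numeric(post),
                 participant_ids = participant_ids),
            class = "paired_sample")
}

#' Two-tailed paired t-test
#'
#' On differences \eqn{d_i = \mathrm{post}_i - \mathrm{pre}_i}:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with \eqn{n - 1} degrees of freedom
#' and a two-tailed p from the Student-t distribution. Identical pre and
#' post give t = 0, p = 1 by convention.
#'
#' @param sample a \code{"paired_sample"} (or list with \code{pre},
#'   \code{post}).
#' @param alpha significance level for the \code{significant} flag.
#' @return An object of class \code{"ttest_result"}: list with \code{t},
#'   \code{p}, \code{df}, \code{significant}, \code{alpha},
#'   \code{mean_diff}.
#' @export
paired_ttest <- function(sample, alpha = 0.05) {
  d <- sample$post - sample$pre
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired observations")
  dbar <- mean(d)
  s_d <- stats::sd(d)
  if (s_d == 0) {
    if (dbar != 0)
      stop("degenerate zero-variance differences (all equal, nonzero)")
    t <- 0; p <- 1
  } else {
    t <- dbar / (s_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  structure(list(t = t, p = p, df = n - 1L, significant = p < alpha,
                 alpha = alpha, mean_diff = dbar),
            class = "ttest_result")
}

#' Bland-Altman agreement analysis
#'
#' For each pair, the difference \eqn{d_i = \mathrm{post}_i -
#' \mathrm{pre}_i} is set against the pair mean. Limits of agreement are
#' \eqn{\bar d \pm 1.96\, s_d}; the approximate confidence intervals are
#' \eqn{\bar d \pm t_{0.975, n-1}\, s_d/\sqrt n} for the mean difference and
#' \eqn{\mathrm{LoA} \pm t_{0.975, n-1}\, s_d \sqrt{3/n}} for each limit
#' (the standard large-sample variance approximation
#' \eqn{\mathrm{Var}(\mathrm{LoA}) \approx 3 s_d^2 / n}).
#'
#' @param sample a \code{"paired_sample"}.
#' @param loa_multiplier multiplier of \eqn{s_d} for the limits (1.96).
#' @return An object of class \code{"bland_altman_result"}: list with
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{ci_mean}, \code{ci_loa_low}, \code{ci_loa_high} (length-2
#'   vectors; NA below n = 3), and \code{points} (data frame of
#'   \code{mean}, \code{difference}).
#' @export
bland_altman <- function(sample, loa_multiplier = 1.96) {
  d <- sample$post - sample$pre
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired observations")
  dbar <- mean(d)
  s_d <- stats::sd(d)
  loa <- c(low = dbar - loa_multiplier * s_d, high = dbar + loa_multiplier * s_d)
  if (n >= 3L) {
    tq <- stats::qt(0.975, df = n - 1L)
    ci_mean <- dbar + c(-1, 1) * tq * s_d / sqrt(n)
    half <- tq * s_d * sqrt(3 / n)
    ci_low <- loa[["low"]] + c(-1, 1) * half
    ci_high <- loa[["high"]] + c(-1, 1) * half
  } else {
    ci_mean <- ci_low <- ci_high <- c(NA_real_, NA_real_)
  }
  structure(list(mean_diff = dbar, sd_diff = s_d,
                 loa_low = loa[["low"]], loa_high = loa[["high"]],
                 ci_mean = ci_mean, ci_loa_low = ci_low,
                 ci_loa_high = ci_high,
                 points = data.frame(mean = (sample$pre + sample$post) / 2,
                                     difference = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$mean_diff, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference against pair mean with the mean-difference line and the 1.96
#' limits of agreement (dashed).
#'
#' @param x a \code{"bland_altman_result"}.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, main = "Bland-Altman", ...) {
  graphics::plot(x$points$mean, x$points$difference,
                 xlab = "Mean of pre and post", ylab = "Difference (post - pre)",
                 main = main, pch = 19, ...)
  graphics::abline(h = x$mean_diff, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

#' Percentage change from pre to post
#'
#' \eqn{100 (\mathrm{post}_i - \mathrm{pre}_i)/\mathrm{pre}_i} per
#' participant; participants with a zero pre value are excluded with a
#' warning (the ratio is undefined). Median and quartiles use
#' linear-interpolation quantiles.
#'
#' @param sample a \code{"paired_sample"}.
#' @return An object of class \code{"percent_change_summary"}: list with
#'   \code{biomarker}, \code{metric}, \code{changes} (named by participant),
#'   \code{median}, \code{q1}, \code{q3}, \code{excluded}.
#' @export
percent_change <- function(sample) {
  zero <- sample$pre == 0
  if (any(zero))
    warning("excluding participant(s) with zero pre value: ",
            paste(sample$participant_ids[zero], collapse = ", "),
            call. = FALSE)
  pre <- sample$pre[!zero]; post <- sample$post[!zero]
  changes <- 100 * (post - pre) / pre
  names(changes) <- sample$participant_ids[!zero]
  q <- stats::quantile(changes, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(biomarker = sample$biomarker, metric = sample$metric,
                 changes = changes, median = q[2L], q1 = q[1L], q3 = q[3L],
                 excluded = sample$participant_ids[zero]),
            class = "percent_change_summary")
}
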