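#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one snapshot that is embedded
#' verbatim in the report, so each reported number is traceable to its
#' settings.
#'
#' @param sigma_ref reference gradient SD (deg/s) for the bounded smoothness
#'   score.
#' @param top_k ranks counted per participant in the biomarker histogram.
#' @param n_select biomarkers selected per action.
#' @param standardize PCA column treatment, \code{"center"} or
#'   \code{"zscore"}.
#' @param policy repeat aggregation policy.
#' @param alpha significance level for paired tests.
#' @param diff_scheme finite-difference scheme for angular derivatives.
#' @param min_prominence,min_duration_s repeat segmentation parameters.
#' @param registry angle definitions to extract (default
#'   [default_angle_registry()]).
#' @return An object of class \code{"kinemark_config"} (a named list).
#' @export
kinemark_config <- function(sigma_ref = 100, top_k = 5, n_select = 5,
                            standardize = "center",
                            policy = "truncate_shortest", alpha = 0.05,
                            diff_scheme = "forward", min_prominence = 20,
                            min_duration_s = 0.5,
                            registry = default_angle_registry()) {
  structure(list(sigma_ref = sigma_ref, top_k = top_k, n_select = n_select,
                 standardize = standardize, policy = policy, alpha = alpha,
                 diff_scheme = diff_scheme, min_prominence = min_prominence,
                 min_duration_s = min_duration_s, registry = registry),
            class = "kinemark_config")
}

# Extract every registry angle from every recording; returns a nested list
# curves[[pid]][[session]][[action]][[angle]] = list of angle_series (repeats).
extract_all_series <- function(cohort, registry) {
  per_rec <- lapply(cohort$recordings, function(rec)
    lapply(registry, function(def) angle_series(rec, def)))
  idx <- cohort_index(cohort)
  key <- interaction(idx$participant_id, idx$session, idx$action, drop = TRUE)
  curves <- list()
  for (g in split(seq_len(nrow(idx)), key)) {
    pid <- idx$participant_id[g[1L]]
    sess <- idx$session[g[1L]]
    act <- idx$action[g[1L]]
    g <- g[order(idx$repeat_index[g])]
    curves[[pid]][[sess]][[act]] <- lapply(
      stats::setNames(nm = names(registry)), function(nm)
        lapply(per_rec[g], `[[`, nm))
  }
  curves
}

# Aggregate repeats into curve summaries per participant/session/action/angle.
summarise_curves <- function(curves, policy) {
  rapply_depth3 <- function(by_angle)
    lapply(by_angle, aggregate_repeats, policy = policy)
  lapply(curves, function(by_session)
    lapply(by_session, function(by_action)
      lapply(by_action, rapply_depth3)))
}

metric_value <- function(curve, fps, metric, config) {
  if (metric == "smoothness")
    smoothness(curve, fps = fps, sigma_ref = config$sigma_ref)$smoothness
  else
    cumulative_acceleration(
      derivatives(curve, fps = fps, scheme = config$diff_scheme))$J
}

#' Run the full biomarker pipeline on a cohort
#'
#' Stages: validate the cohort; extract all registry angles per recording;
#' aggregate repeats into frame-wise mean/min/max curves (no time
#' normalisation); build per-participant, per-action feature matrices; rank
#' features by two-component PCA importance; build cross-participant
#' top-k histograms and select the representative biomarkers per action;
#' compute smoothness and cumulative absolute rotational acceleration on
#' each selected feature's curve per participant and session; paired
#' two-tailed t-tests (with a Holm-adjusted column reported alongside the
#' raw p-values; the significance flag uses the raw p at \code{alpha},
#' mirroring standard practice for these reports), Bland-Altman agreement
#' and percentage-change summaries; assemble everything into a clinical
#' report object. Deterministic given the cohort and config.
#'
#' @param cohort a \code{"cohort_manifest"} or \code{"simulated_cohort"}.
#' @param config a \code{"kinemark_config"}.
#' @return An object of class \code{"kinemark_report"}.
#' @export
run_pipeline <- function(cohort, config = kinemark_config()) {
  if (inherits(cohort, "simulated_cohort")) cohort <- cohort$cohort
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  stage("validate", validate_cohort(cohort))
  curves <- stage("extract", extract_all_series(cohort, config$registry))
  summaries <- stage("aggregate", summarise_curves(curves, config$policy))
  idx <- cohort_index(cohort)
  actions <- sort(unique(idx$action))
  pids <- sort(unique(idx$participant_id))
  fps <- cohort$recordings[[1L]]$fps

  rankings <- stage("pca", {
    out <- list()
    for (action in actions)
      out[[action]] <- lapply(pids, function(pid) {
        fm <- feature_matrix(
          list(pre = summaries[[pid]][["pre"]][[action]],
               post = summaries[[pid]][["post"]][[action]]),
          participant_id = pid, action = action)
        pca_importance(fm, standardize = config$standardize)
      })
    out
  })
  histograms <- stage("histogram", lapply(rankings, build_histogram,
                                          top_k = config$top_k))
  selected <- stage("select", lapply(histograms, select_biomarkers,
                                     n_select = config$n_select))

  metrics <- c("cumulative_acceleration", "smoothness")
  tables <- list(); ba <- list(); pct <- list(); samples <- list()
  stage("stats", for (action in actions) {
    rows <- list()
    for (feature in selected[[action]]) {
      pf <- parse_feature_name(feature)
      for (metric in metrics) {
        vals <- vapply(c("pre", "post"), function(session)
          vapply(pids, function(pid) {
            cs <- summaries[[pid]][[session]][[action]][[pf$angle]]
            metric_value(cs[[paste0(pf$stat, "_curve")]], fps, metric, config)
          }, 0), numeric(length(pids)))
        sm <- paired_sample(feature, metric, vals[, "pre"], vals[, "post"],
                            participant_ids = pids)
        tt <- paired_ttest(sm, alpha = config$alpha)
        key <- paste(action, feature, metric, sep = "|")
        samples[[key]] <- sm
        ba[[key]] <- bland_altman(sm)
        pct[[key]] <- percent_change(sm)
        rows[[key]] <- data.frame(
          biomarker = feature, metric = metric, t = tt$t, p = tt$p,
          df = tt$df, significant = tt$significant,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
    tables[[action]] <- tab
  })

  structure(list(
    cohort_metadata = c(cohort$metadata,
                        list(n_participants = length(pids),
                             n_recordings = nrow(idx), actions = actions,
                             fps = fps)),
    histograms = histograms, selected = selected, tables = tables,
    bland_altman = ba, percent_change = pct, samples = samples,
    config = config_snapshot(config)),
    class = "kinemark_report")
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$registry <- lapply(config$registry, function(d)
    list(name = d$name, vertex = d$vertex, proximal = d$proximal,
         distal = d$distal, plane = d$plane))
  snap
}

#' @export
print.kinemark_report <- function(x, ...) {
  md <- x$cohort_metadata
  cat("Motion-biomarker clinical report\n")
  cat(sprintf("  %d participants, %d recordings @ %g fps\n",
              md$n_participants, md$n_recordings, md$fps))
  for (action in names(x$tables)) {
    tab <- x$tables[[action]]
    sig <- tab[tab$significant, ]
    cat(sprintf("  %s: %d biomarkers selected, %d significant at alpha = %g\n",
                action, length(x$selected[[action]]), nrow(sig),
                x$config$alpha))
    if (nrow(sig))
      cat(paste0("    * ", sig$biomarker, " [", sig$metric, "], p = ",
                 signif(sig$p, 3), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
summary.kinemark_report <- function(object, ...) {
  for (action in names(object$tables)) {
    cat("\n==", action, "==\n")
    tab <- object$tables[[action]]
    tab$t <- round(tab$t, 3); tab$p <- signif(tab$p, 3)
    tab$p_holm <- signif(tab$p_holm, 3)
    print(tab, row.names = FALSE)
  }
  invisible(object)
}

#' Plot method for clinical reports
#'
#' \code{which = "histogram"} draws the per-action biomarker frequency
#' histograms; \code{which = "bland_altman"} the agreement plots for
#' significant biomarkers; \code{which = "percent_change"} box summaries of
#' per-participant percentage change.
#'
#' @param x a \code{"kinemark_report"}.
#' @param which one of \code{"histogram"}, \code{"bland_altman"},
#'   \code{"percent_change"}.
#' @param ... ignored.
#' @export
plot.kinemark_report <- function(x, which = c("histogram", "bland_altman",
                                              "percent_change"), ...) {
  which <- match.arg(which)
  actions <- names(x$histograms)
  if (which == "histogram") {
    old <- graphics::par(mfrow = c(length(actions), 1), mar = c(9, 4, 2, 1))
    on.exit(graphics::par(old))
    for (action in actions) {
      h <- x$histograms[[action]]
      graphics::barplot(h$counts, las = 2, cex.names = 0.6,
                        main = paste("Representative features:", action),
                        ylab = sprintf("count (top-%d)", h$top_k))
    }
  } else if (which == "bland_altman") {
    keys <- names(x$bland_altman)
    sig_keys <- keys[vapply(keys, function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      tab <- x$tables[[parts[1L]]]
      any(tab$biomarker == parts[2L] & tab$metric == parts[3L] &
            tab$significant)
    }, TRUE)]
    if (!length(sig_keys)) sig_keys <- keys
    sig_keys <- utils::head(sig_keys, 6L)
    old <- graphics::par(mfrow = c(ceiling(length(sig_keys) / 2), 2))
    on.exit(graphics::par(old))
    for (k in sig_keys) plot(x$bland_altman[[k]], main = k)
  } else {
    old <- graphics::par(mar = c(12, 4, 2, 1))
    on.exit(graphics::par(old))
    ch <- lapply(x$percent_change, function(p) p$changes)
    graphics::boxplot(ch, las = 2, cex.axis = 0.5,
                      ylab = "% change (post vs pre)")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Write a report as canonical JSON
#'
#' Machine-readable report including the config snapshot; byte-identical
#' across runs with the same cohort, seed and config.
#'
#' @param report a \code{"kinemark_report"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- list(
    cohort_metadata = report$cohort_metadata,
    config = report$config,
    selected = report$selected,
    histograms = lapply(report$histograms, function(h)
      list(action = h$action, counts = as.list(h$counts), top_k = h$top_k,
           n_participants = h$n_participants)),
    tables = report$tables,
    bland_altman = lapply(report$bland_altman, function(b)
      list(mean_diff = b$mean_diff, sd_diff = b$sd_diff,
           loa = c(b$loa_low, b$loa_high), ci_mean = b$ci_mean,
           ci_loa_low = b$ci_loa_low, ci_loa_high = b$ci_loa_high,
           points = b$points)),
    percent_change = lapply(report$percent_change, function(p)
      list(biomarker = p$biomarker, metric = p$metric,
           median = p$median, q1 = p$q1, q3 = p$q3,
           changes = as.list(p$changes))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
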