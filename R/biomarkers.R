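#' Build the per-participant feature matrix for one action
#'
#' Rows are frame indices of the aggregated window (the pre- and
#' post-session curve summaries stacked row-wise, truncated to their common
#' length); columns are kinematic features named
#' \code{<side>_<angle>_<statistic>} with statistic one of mean, min, max.
#' Values are degrees. This frames-by-features matrix is what the
#' per-participant PCA ranks.
#'
#' @param summaries_by_session named list (\code{pre}, \code{post}); each a
#'   named list of \code{"curve_summary"} objects keyed by angle name.
#' @param participant_id,action identification.
#' @return An object of class \code{"feature_matrix"}: list with
#'   \code{participant_id}, \code{action}, \code{values} (numeric matrix).
#' @export
feature_matrix <- function(summaries_by_session, participant_id, action) {
  stopifnot(all(c("pre", "post") %in% names(summaries_by_session)))
  angles <- names(summaries_by_session$pre)
  stopifnot(identical(sort(angles), sort(names(summaries_by_session$post))))
  block <- function(session) {
    ss <- summaries_by_session[[session]]
    L <- min(vapply(ss, function(s) s$aggregated_length, 0L))
    cols <- lapply(angles, function(a)
      cbind(ss[[a]]$mean_curve[seq_len(L)], ss[[a]]$min_curve[seq_len(L)],
            ss[[a]]$max_curve[seq_len(L)]))
    M <- do.call(cbind, cols)
    colnames(M) <- as.vector(t(outer(angles, c("mean", "min", "max"),
                                     paste, sep = "_")))
    M
  }
  pre <- block("pre"); post <- block("post")
  values <- rbind(pre, post[, colnames(pre), drop = FALSE])
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("feature matrix needs at least 2 rows and 2 columns")
  if (anyNA(values)) stop("missing values in aggregated window")
  structure(list(participant_id = participant_id, action = action,
                 values = values),
            class = "feature_matrix")
}

#' Two-component PCA feature importance
#'
#' Columns are centred (optionally scaled to unit variance), a
#' singular-value-decomposition PCA is fitted, and each feature's importance
#' is the explained-variance-weighted sum of its absolute loadings on the
#' first two components:
#' \deqn{I_j = \sum_{c=1}^{2} \mathrm{EVR}_c \, |L_{cj}|}
#' where loadings are unit-norm component vectors and EVR the explained
#' variance ratio. Loading signs follow the convention that each component's
#' largest-magnitude loading is positive (importance itself is
#' sign-invariant). Ties in the ranking are broken by feature name.
#'
#' @param matrix a \code{"feature_matrix"} (or plain numeric matrix with
#'   column names).
#' @param n_components number of components (default 2).
#' @param standardize \code{"center"} (default; features share degree units,
#'   so variance magnitude is signal) or \code{"zscore"}.
#' @return An object of class \code{"importance_ranking"}: list with
#'   \code{participant_id}, \code{action}, \code{ranking} (data frame of
#'   \code{feature}, \code{importance}, sorted descending) and
#'   \code{explained_variance_ratio}.
#' @export
pca_importance <- function(matrix, n_components = 2,
                           standardize = c("center", "zscore")) {
  standardize <- match.arg(standardize)
  pid <- action <- NA_character_
  if (inherits(matrix, "feature_matrix")) {
    pid <- matrix$participant_id; action <- matrix$action
    matrix <- matrix$values
  }
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (nrow(matrix) <= n_components)
    stop("need more rows than components (", nrow(matrix), " rows)")
  varying <- apply(matrix, 2L, stats::var) > 0
  if (!any(varying))
    stop("constant-only matrix: no variance for PCA to rank")
  pc <- stats::prcomp(matrix, center = TRUE, scale. = standardize == "zscore",
                      rank. = n_components)
  rot <- pc$rotation
  # deterministic sign: largest-|loading| entry of each component positive
  for (c_ in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, c_]))
    if (rot[i, c_] < 0) rot[, c_] <- -rot[, c_]
  }
  evr <- pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2)
  importance <- as.vector(abs(rot) %*% evr)
  names(importance) <- rownames(rot)
  o <- order(-importance, names(importance))
  structure(list(participant_id = pid, action = action,
                 ranking = data.frame(feature = names(importance)[o],
                                      importance = unname(importance[o]),
                                      stringsAsFactors = FALSE),
                 explained_variance_ratio = evr),
            class = "importance_ranking")
}

#' Cross-participant frequency histogram of top-ranked features
#'
#' Counts, over all participants' rankings for one action, how often each
#' feature appears among a participant's \code{top_k} highest importances
#' (default 5, matching the representative-feature histograms; 10 is the
#' other commonly used cut and is available via the argument). Features in
#' nobody's top-k are omitted.
#'
#' @param rankings list of \code{"importance_ranking"} objects, same action.
#' @param top_k ranks counted per participant (>= 1).
#' @return An object of class \code{"biomarker_histogram"}: list with
#'   \code{action}, \code{counts} (named integer, sorted by decreasing count
#'   then name), \code{top_k}, \code{n_participants} and
#'   \code{mean_importance} (per feature, used for tie-breaks).
#' @export
build_histogram <- function(rankings, top_k = 5) {
  stopifnot(length(rankings) >= 1L, top_k >= 1)
  actions <- unique(vapply(rankings, function(r) r$action, ""))
  if (length(actions) != 1L)
    stop("rankings mix actions: ", paste(actions, collapse = ", "))
  tops <- lapply(rankings, function(r)
    utils::head(r$ranking$feature, top_k))
  counts <- table(unlist(tops))
  imp <- do.call(rbind, lapply(rankings, function(r) r$ranking))
  mean_imp <- tapply(imp$importance, imp$feature, mean)
  counts <- counts[order(-as.integer(counts), names(counts))]
  structure(list(action = actions,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 top_k = top_k, n_participants = length(rankings),
                 mean_importance = mean_imp),
            class = "biomarker_histogram")
}

#' @export
print.biomarker_histogram <- function(x, ...) {
  cat(sprintf("<biomarker_histogram> %s (top-%d of %d participants)\n",
              x$action, x$top_k, x$n_participants))
  print(x$counts)
  invisible(x)
}

#' Select the most representative biomarkers
#'
#' The \code{n_select} features with the highest cross-participant counts;
#' ties broken by mean importance score, then lexicographically. If fewer
#' features than requested are available, all are returned with a warning.
#'
#' @param histogram a \code{"biomarker_histogram"}.
#' @param n_select number of biomarkers to select (default 5).
#' @return Character vector of feature names, most representative first.
#' @export
select_biomarkers <- function(histogram, n_select = 5) {
  stopifnot(inherits(histogram, "biomarker_histogram"))
  feats <- names(histogram$counts)
  if (!length(feats)) stop("empty histogram")
  mi <- histogram$mean_importance[feats]
  mi[is.na(mi)] <- 0
  o <- order(-histogram$counts, -mi, feats)
  if (n_select > length(feats)) {
    warning("only ", length(feats), " features available (requested ",
            n_select, ")", call. = FALSE)
    n_select <- length(feats)
  }
  feats[o][seq_len(n_select)]
}

# Split "left_knee_flexion_max" -> angle "left_knee_flexion", stat "max".
parse_feature_name <- function(feature) {
  stat <- sub(".*_", "", feature)
  stopifnot(stat %in% c("mean", "min", "max"))
  list(angle = sub("_[a-z]+$", "", feature), stat = stat)
}
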