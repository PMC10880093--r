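random_feature_matrix <- function(nrow = 5, ncol = 4) {
  M <- matrix(rnorm(nrow * ncol), nrow)
  colnames(M) <- paste0("f", seq_len(ncol))
  M
}

test_that("a single varying column carries all the importance", {
  M <- cbind(a = rep(1, 10), b = rep(2, 10), c = seq(0, 9))
  r <- pca_importance(M)
  expect_error(pca_importance(cbind(a = rep(1, 5), b = rep(2, 5))),
               "constant-only")
  expect_equal(r$ranking$feature[1], "c")
  others <- r$ranking$importance[r$ranking$feature != "c"]
  expect_equal(others, c(0, 0), tolerance = 1e-12)
})

test_that("importance matches a brute-force covariance eigendecomposition", {
  set.seed(53)
  for (i in 1:20) {
    M <- random_feature_matrix()
    r <- pca_importance(M)
    want <- oracle_pca_importance(M)
    got <- stats::setNames(r$ranking$importance, r$ranking$feature)[names(want)]
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("duplicated columns receive equal importance", {
  set.seed(59)
  M <- random_feature_matrix(8, 3)
  M <- cbind(M, f1copy = M[, "f1"])
  r <- pca_importance(M)
  imp <- stats::setNames(r$ranking$importance, r$ranking$feature)
  expect_equal(unname(imp["f1"]), unname(imp["f1copy"]), tolerance = 1e-10)
})

test_that("importance is invariant to column shifts and row order", {
  set.seed(61)
  M <- random_feature_matrix(12, 5)
  r0 <- pca_importance(M)
  M2 <- M; M2[, 2] <- M2[, 2] + 100
  r2 <- pca_importance(M2)
  expect_equal(r0$ranking, r2$ranking, tolerance = 1e-10)
  M3 <- M[sample(nrow(M)), ]
  r3 <- pca_importance(M3)
  expect_equal(r0$ranking, r3$ranking, tolerance = 1e-10)
})

test_that("explained variance ratios lie in [0, 1] and sum below 1", {
  set.seed(67)
  r <- pca_importance(random_feature_matrix(10, 6))
  expect_true(all(r$explained_variance_ratio >= 0))
  expect_true(all(r$explained_variance_ratio <= 1))
  expect_lte(sum(r$explained_variance_ratio), 1 + 1e-12)
})

fake_ranking <- function(features, action = "squat", pid = "P1") {
  structure(list(participant_id = pid, action = action,
                 ranking = data.frame(feature = features,
                                      importance = rev(seq_along(features)) / 10,
                                      stringsAsFactors = FALSE)),
            class = "importance_ranking")
}

test_that("histogram counts top-k membership across participants", {
  rks <- lapply(1:3, function(i)
    fake_ranking(c("F", paste0("x", i, 1:5)), pid = paste0("P", i)))
  h <- build_histogram(rks, top_k = 5)
  expect_equal(unname(h$counts["F"]), 3L)
  expect_equal(sum(h$counts), 3L * 5L)
  expect_equal(h$n_participants, 3L)

  # one participant: histogram is the indicator of their top-k
  h1 <- build_histogram(rks[1], top_k = 5)
  expect_setequal(names(h1$counts), rks[[1]]$ranking$feature[1:5])
  expect_true(all(h1$counts == 1L))

  # participant order does not matter
  h2 <- build_histogram(rev(rks), top_k = 5)
  expect_equal(h$counts[sort(names(h$counts))],
               h2$counts[sort(names(h2$counts))])

  expect_error(build_histogram(list(rks[[1]], fake_ranking("F", action = "sit_to_stand"))),
               "mix actions")
})

test_that("biomarker selection ranks by count with deterministic tie-breaks", {
  h <- structure(list(action = "squat",
                      counts = c(A = 5L, B = 3L, C = 1L),
                      top_k = 5, n_participants = 5,
                      mean_importance = c(A = 0.5, B = 0.4, C = 0.3)),
                 class = "biomarker_histogram")
  expect_equal(select_biomarkers(h, 2), c("A", "B"))

  # equal counts: mean importance, then lexicographic
  h$counts <- c(B = 2L, A = 2L, C = 2L)
  h$mean_importance <- c(A = 0.1, B = 0.1, C = 0.9)
  expect_equal(select_biomarkers(h, 3), c("C", "A", "B"))

  expect_warning(sel <- select_biomarkers(h, 10), "available")
  expect_length(sel, 3)
})

test_that("selection returns five biomarkers per action on the default cohort", {
  rep_ <- cached("report7", run_pipeline(default_sim_cohort()))
  expect_length(rep_$selected$squat, 5)
  expect_length(rep_$selected$sit_to_stand, 5)
})

test_that("cohorts with variance concentrated at the knee select knee features", {
  # quiet arms/ankles: knee keeps the dominant range in both actions
  tmpls <- default_templates()
  for (a in names(tmpls)) {
    tmpls[[a]]$angle_profiles$elbow_flexion$extreme <-
      tmpls[[a]]$angle_profiles$elbow_flexion$start - 5
    tmpls[[a]]$angle_profiles$arm_abduction$extreme <-
      tmpls[[a]]$angle_profiles$arm_abduction$start + 5
    tmpls[[a]]$angle_profiles$ankle_flexion$extreme <-
      tmpls[[a]]$angle_profiles$ankle_flexion$start + 5
  }
  sim <- generate_cohort(n_participants = 6, templates = tmpls, seed = 71)
  rep_ <- run_pipeline(sim)
  for (a in c("squat", "sit_to_stand"))
    expect_true(all(grepl("knee_flexion", rep_$selected[[a]])))
})
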