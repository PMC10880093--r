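mini_skeleton <- function()
  skeleton("mini", c("hip", "knee", "ankle"), c(Knee = "knee"))

write_mini_csv <- function(path, frames = 0:1, joints = c("hip", "knee", "ankle")) {
  df <- expand.grid(frame = frames, joint = joints, stringsAsFactors = FALSE)
  df <- df[order(df$frame, df$joint), ]
  df$x <- seq_len(nrow(df)) / 10
  df$y <- 1; df$z <- 0
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

test_that("csv_long reading echoes the input and canonicalises aliases", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_mini_csv(path)
  recs <- read_trajectories(path, skeleton = mini_skeleton(),
                            format = "csv_long",
                            meta = list(fps = 30))
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_equal(dim(rec$positions), c(2L, 3L, 3L))
  expect_setequal(dimnames(rec$positions)[[3]], c("hip", "knee", "ankle"))
  expect_equal(rec$fps, 30)

  # alias "Knee" maps to canonical "knee"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_mini_csv(path2, joints = c("hip", "Knee", "ankle"))
  rec2 <- read_trajectories(path2, skeleton = mini_skeleton())[[1]]
  expect_true("knee" %in% dimnames(rec2$positions)[[3]])
  expect_false("Knee" %in% dimnames(rec2$positions)[[3]])

  # unknown joint without alias errors
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_mini_csv(path3, joints = c("hip", "shin", "ankle"))
  expect_error(read_trajectories(path3, skeleton = mini_skeleton()), "shin")
})

test_that("non-contiguous frames are rejected with the first gap named", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_mini_csv(path, frames = c(0:4, 6:10))
  expect_error(read_trajectories(path, skeleton = mini_skeleton()),
               "non-contiguous frames at index 5")
})

test_that("reading a file twice yields identical recordings", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_mini_csv(path)
  r1 <- read_trajectories(path, skeleton = mini_skeleton())[[1]]
  r2 <- read_trajectories(path, skeleton = mini_skeleton())[[1]]
  expect_identical(r1, r2)
})

test_that("TRC files are read with fps from the header", {
  path <- withr::local_tempfile(fileext = ".trc")
  hdr <- c(
    "PathFileType\t4\t(X/Y/Z)\ttest.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "60\t60\t2\t3\tm\t60\t1\t2",
    "Frame#\tTime\thip\t\t\tKnee\t\t\tankle\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2\tX3\tY3\tZ3",
    "1\t0\t0\t1\t0\t0\t0.5\t0\t0\t0\t0.1",
    "2\t0.0167\t0\t1\t0\t0\t0.5\t0.01\t0\t0\t0.1")
  writeLines(hdr, path)
  recs <- read_trajectories(path, skeleton = mini_skeleton(), format = "trc")
  rec <- recs[[1]]
  expect_equal(rec$fps, 60)
  expect_equal(dim(rec$positions)[1], 2L)
  expect_true("knee" %in% dimnames(rec$positions)[[3]])
  expect_equal(rec$positions[1, "y", "hip"], 1)
})

test_that("manifests round-trip field-by-field", {
  sim <- generate_cohort(n_participants = 2, n_repeats = 3, seed = 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "manifest.json")
  write_manifest(sim$cohort, path)
  back <- read_manifest(path)
  expect_equal(length(back$recordings), length(sim$cohort$recordings))
  expect_equal(back$metadata$fps, sim$cohort$metadata$fps)
  for (i in seq_along(back$recordings)) {
    a <- sim$cohort$recordings[[i]]; b <- back$recordings[[i]]
    expect_equal(a$participant_id, b$participant_id)
    expect_equal(a$session, b$session)
    expect_equal(a$action, b$action)
    expect_equal(a$repeat_index, b$repeat_index)
    expect_equal(a$fps, b$fps)
    expect_equal(unname(a$positions), unname(b$positions), tolerance = 0)
  }
})

test_that("cohort validation enforces the study design", {
  sim <- default_sim_cohort()
  # 20 participants x 2 sessions x 2 actions x 3 repeats
  expect_length(sim$cohort$recordings, 240)
  expect_silent(validate_cohort(sim$cohort))

  # dropping a participant's post session is an error
  keep <- vapply(sim$cohort$recordings, function(r)
    !(r$participant_id == "P01" && r$session == "post"), TRUE)
  broken <- sim$cohort
  broken$recordings <- sim$cohort$recordings[keep]
  expect_error(validate_cohort(broken), "P01 lacks session")

  # fewer than 3 repeats warns but is valid
  expect_warning(generate_cohort(n_participants = 2, n_repeats = 1, seed = 1),
                 "fewer than 3 repeats")
})
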