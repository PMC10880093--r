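test_that("triplet angle matches known configurations and the dot-product oracle", {
  # perpendicular and collinear-opposite configurations in the coronal plane
  expect_equal(compute_joint_angle(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0),
                                   "coronal"), 90)
  expect_equal(compute_joint_angle(c(0, 0, 0), c(0, 1, 0), c(0, -1, 0),
                                   "coronal"), 180)
  # oblique case, independently computed from normalised dot product
  k <- c(2, 1, 0); h <- c(5, 3, 0); a <- c(1, 4, 0)
  got <- compute_joint_angle(k, h, a, "coronal")
  expect_equal(got, oracle_angle_2d((h - k)[1:2], (a - k)[1:2]),
               tolerance = 1e-12)
  expect_equal(got, 74.7449, tolerance = 1e-4)

  # random triplets: law-of-cosines route == dot-product oracle
  set.seed(42)
  for (i in 1:50) {
    p <- matrix(rnorm(9), 3)
    th <- compute_joint_angle(p[1, ], p[2, ], p[3, ], "sagittal")
    expect_equal(th, oracle_angle_2d((p[2, ] - p[1, ])[2:3],
                                     (p[3, ] - p[1, ])[2:3]),
                 tolerance = 1e-9)
  }
})

test_that("triplet angle is symmetric in h/a and invariant to in-plane rigid motion", {
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(rnorm(9), 3)
    th <- compute_joint_angle(p[1, ], p[2, ], p[3, ], "coronal")
    # swap proximal and distal
    expect_equal(compute_joint_angle(p[1, ], p[3, ], p[2, ], "coronal"), th,
                 tolerance = 1e-9)
    # translate in-plane
    shift <- c(rnorm(2), 0)
    q <- sweep(p, 2, shift, "+")
    expect_equal(compute_joint_angle(q[1, ], q[2, ], q[3, ], "coronal"), th,
                 tolerance = 1e-9)
    # rotate in-plane about the origin
    phi <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
    r <- p %*% t(R)
    expect_equal(compute_joint_angle(r[1, ], r[2, ], r[3, ], "coronal"), th,
                 tolerance = 1e-9)
  }
})

test_that("near-collinear points are clamped into [0, 180] and degenerate ones error", {
  # numerically just-beyond-collinear: arccos argument would exceed 1
  th <- compute_joint_angle(c(0, 0, 0), c(0, 1, 0), c(0, 2 + 1e-15, 0),
                            "coronal")
  expect_false(is.nan(th))
  expect_true(th >= 0 && th <= 180)
  expect_error(
    compute_joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), "coronal"),
    "proximal-vertex")
  expect_error(
    compute_joint_angle(c(0, 0, 0), c(0, 1, 0), c(0, 0, 0), "coronal"),
    "distal-vertex")
})

test_that("forward differences match hand-computed and loop oracles", {
  d <- derivatives(c(0, 30, 60), fps = 30)
  expect_equal(d$omega, c(900, 900))
  expect_equal(d$alpha, 0)

  d <- derivatives(c(0, 1, 3, 6, 10), fps = 1)
  expect_equal(d$omega, c(1, 2, 3, 4))
  expect_equal(d$alpha, c(1, 1, 1))

  d <- derivatives(rep(45, 10), fps = 30)
  expect_true(all(d$omega == 0) && all(d$alpha == 0))

  expect_error(derivatives(c(1, 2), fps = 30), "at least 3")

  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:100, 1)
    theta <- runif(n, 0, 180)
    fps <- sample(c(24, 30, 60), 1)
    got <- derivatives(theta, fps = fps)
    want <- oracle_derivatives(theta, 1 / fps)
    expect_equal(got$omega, want$omega, tolerance = 1e-12)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
  }
})

test_that("smoothness is 1 for linear curves and matches the hand SD oracle", {
  lin <- seq(0, 90, length.out = 30)
  s <- smoothness(lin, fps = 30)
  expect_equal(s$sigma_m, 0)
  expect_equal(s$smoothness, 1)

  s <- smoothness(c(0, 1, 3, 6, 10), fps = 1)
  expect_equal(s$sigma_m, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s$smoothness, 1 / (1 + sqrt(5 / 3) / 100), tolerance = 1e-12)

  # sigma_ref rescales the bounded score but not sigma_m
  s50 <- smoothness(c(0, 1, 3, 6, 10), fps = 1, sigma_ref = 50)
  expect_equal(s50$sigma_m, s$sigma_m)
  expect_equal(s50$smoothness, 1 / (1 + sqrt(5 / 3) / 50), tolerance = 1e-12)

  expect_error(smoothness(c(1, 2), fps = 30), "at least 3")
})

test_that("cumulative acceleration matches trapezoid oracle and closed forms", {
  expect_equal(cumulative_acceleration(c(0, 0, 0), dt = 1 / 30)$J, 0)
  expect_equal(cumulative_acceleration(c(1, 1, 1), dt = 1)$J, 2)

  # constant alpha over duration T: J -> alpha0 * T as the grid refines
  alpha0 <- 12; T_ <- 2; fps <- 120
  alpha <- rep(alpha0, T_ * fps + 1)
  expect_equal(cumulative_acceleration(alpha, dt = 1 / fps)$J, alpha0 * T_,
               tolerance = 0.01)

  set.seed(13)
  for (i in 1:20) {
    alpha <- rnorm(sample(2:100, 1), sd = 50)
    dt <- 1 / sample(c(24, 30, 60), 1)
    expect_equal(cumulative_acceleration(alpha, dt = dt)$J,
                 oracle_trapz_abs(alpha, dt), tolerance = 1e-12)
  }
})

test_that("scaling deviations about a baseline scales sigma_m and J linearly", {
  set.seed(17)
  base <- 90
  dev <- cumsum(rnorm(50))
  for (c_ in c(2, 3.5)) {
    s1 <- smoothness(base + dev, fps = 30)
    s2 <- smoothness(base + c_ * dev, fps = 30)
    expect_equal(s2$sigma_m, c_ * s1$sigma_m, tolerance = 1e-9)
    j1 <- cumulative_acceleration(derivatives(base + dev, fps = 30))$J
    j2 <- cumulative_acceleration(derivatives(base + c_ * dev, fps = 30))$J
    expect_equal(j2, c_ * j1, tolerance = 1e-9)
  }
})

test_that("angle_series evaluates every frame and propagates fps", {
  g <- generate_repeat(default_templates()$squat, noise_free_effect(), "pre")
  def <- default_angle_registry()$left_knee_flexion
  s <- angle_series(g$recording, def)
  expect_length(s$theta, nrow(g$truth))
  expect_equal(s$fps, 30)
  expect_equal(s$theta, unname(g$truth[, "left_knee_flexion"]),
               tolerance = 1e-9)
  # deepest squat angle equals the template extreme
  expect_equal(min(s$theta), 70, tolerance = 1e-6)

  # static pose held over frames -> constant series
  pose <- g$recording$positions[rep(1L, 5L), , ]
  rec <- trial_recording("P0", "pre", "squat", 0, 30, pose)
  s2 <- angle_series(rec, def)
  expect_equal(diff(range(s2$theta)), 0)

  # recordings lacking a required joint raise a named error
  rec3 <- rec
  rec3$positions <- rec$positions[, , setdiff(dimnames(rec$positions)[[3]],
                                              "left_ankle")]
  expect_error(angle_series(rec3, def), "left_ankle")
})
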