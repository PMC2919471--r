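test_that("cumulative contour distance handles straight, degenerate and curved paths", {
  expect_equal(cumulative_contour_distance(rbind(c(0, 0), c(3, 4))), c(0, 5))
  expect_equal(cumulative_contour_distance(c(7, 2)), 0)
  expect_error(cumulative_contour_distance(matrix(numeric(0), ncol = 2)),
               "empty path")

  # semicircle of radius 100: polyline arc length approaches pi * r
  t <- seq(0, pi, length.out = 2000)
  semi <- cbind(100 * cos(t), 100 * sin(t))
  expect_equal(max(cumulative_contour_distance(semi)), pi * 100,
               tolerance = 0.01 / (pi * 100))
})

test_that("contour distance is invariant under rigid motions", {
  set.seed(11)
  for (rep in 1:5) {
    pts <- cbind(cumsum(runif(40)), cumsum(rnorm(40)))
    d0 <- cumulative_contour_distance(pts)
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    moved <- t(R %*% t(pts)) + matrix(rnorm(2, sd = 50), nrow(pts), 2, byrow = TRUE)
    expect_equal(cumulative_contour_distance(moved), d0, tolerance = 1e-9)
  }
})

test_that("refining the sampling density increases polyline length toward the smooth value", {
  a <- 280; b <- 92
  arc_len <- function(n) {
    t <- seq(0, pi, length.out = n)
    max(cumulative_contour_distance(cbind(a * cos(t), b * sin(t))))
  }
  lens <- vapply(c(32, 128, 512, 2048), arc_len, numeric(1))
  expect_true(all(diff(lens) > 0))
  exact <- stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                            0, pi, rel.tol = 1e-10)$value
  expect_true(all(lens < exact + 1e-9))
  expect_equal(lens[4], exact, tolerance = 1e-4)
})

test_that("projection onto the A-P axis is anchored at the poles and rotation-invariant", {
  expect_equal(project_to_axis(c(100, 50), c(0, 0), c(560, 0)), 100)
  expect_equal(project_to_axis(c(0, 0), c(0, 0), c(560, 0)), 0)
  expect_equal(project_to_axis(c(30, 100), c(0, 0), c(0, 560)), 100)
  expect_error(project_to_axis(c(1, 1), c(5, 5), c(5, 5)), "coincide")
})

test_that("semi-ellipsoid arcs match the quadrature arc length and echo their parameters", {
  p <- shape_params(560, 220, 92, 128)
  sh <- build_semi_ellipsoid_shape(p, n_points = 4001L)
  a <- 280
  quad <- function(b) {
    stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                     0, pi, rel.tol = 1e-10)$value
  }
  expect_equal(sh$contour$C_D, quad(92), tolerance = 1e-3)
  expect_equal(sh$contour$C_V, quad(128), tolerance = 1e-3)
  expect_identical(sh$params, p)
  expect_error(shape_params(560, -1, 92, 128), "positive")

  # contour length always exceeds the projected axis length
  expect_gte(sh$contour$C_D, sh$contour$L)
  expect_gte(sh$contour$C_V, sh$contour$L)
})

test_that("the shape-difference profile is zero for symmetric shapes and matches dense sampling", {
  sym <- build_semi_ellipsoid_shape(shape_params(560, 220, 100, 100))
  prof <- delta_c_embryo_profile(sym$contour)
  expect_true(all(abs(prof$delta_c) < 1e-6))

  asym <- build_semi_ellipsoid_shape(shape_params(560, 220, 92, 128))
  grid <- seq(0.05, 0.95, by = 0.05)
  prof2 <- delta_c_embryo_profile(asym$contour, grid)
  # brute-force oracle: same quantity from a 1e5-point sampling of the arcs
  dense <- build_semi_ellipsoid_shape(shape_params(560, 220, 92, 128),
                                      n_points = 100001L)
  oracle <- delta_c_embryo_profile(dense$contour, grid)
  expect_equal(prof2$delta_c_rel, oracle$delta_c_rel, tolerance = 1e-3)

  # taller ventral half-ellipse has the longer arc at mid-embryo
  mid <- delta_c_embryo_profile(asym$contour, 0.5)
  expect_lt(mid$delta_c, 0)
  expect_error(delta_c_embryo_profile(asym$contour, 1.2), "\\[0, 1\\]")
})

test_that("average embryo frame reproduces single shapes, mirrors, and cohort means", {
  sh <- build_semi_ellipsoid_shape(shape_params(560, 220, 92, 128))
  fr <- average_embryo_frame(list(sh$contour, sh$contour))
  expect_equal(fr$yD_over_L[fr$x_over_L == 0.5], 92 / 560, tolerance = 1e-4)
  expect_true(all(fr$yD_over_L >= 0) && all(fr$yV_over_L <= 0))

  mirror <- build_semi_ellipsoid_shape(shape_params(560, 220, 128, 92))
  fr2 <- average_embryo_frame(list(sh$contour, mirror$contour))
  expect_equal(fr2$yD_over_L, -fr2$yV_over_L, tolerance = 1e-9)

  expect_error(average_embryo_frame(list()), "empty")

  # Monte-Carlo oracle: mean frame of sampled shapes approaches the mean shape
  set.seed(7)
  cohort <- replicate(100, {
    build_semi_ellipsoid_shape(shape_params(560, 220,
                                            max(rnorm(1, 92, 5), 20),
                                            max(rnorm(1, 128, 5), 20)))$contour
  }, simplify = FALSE)
  frm <- average_embryo_frame(cohort)
  expect_equal(frm$yD_over_L[frm$x_over_L == 0.5], 92 / 560,
               tolerance = 1 / 92)
})

test_that("contours are re-aligned into the canonical pole frame", {
  sh <- build_semi_ellipsoid_shape(shape_params(560, 220, 92, 128),
                                   n_points = 501L)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  move <- function(m) t(R %*% t(m)) + matrix(c(120, -45), nrow(m), 2, byrow = TRUE)
  ct <- midsagittal_contour(move(sh$contour$dorsal_arc),
                            move(sh$contour$ventral_arc), align = TRUE)
  expect_equal(ct$L, sh$contour$L, tolerance = 1e-6)
  expect_equal(ct$C_D, sh$contour$C_D, tolerance = 1e-9)
  expect_true(all(ct$dorsal_arc[, 2] >= -1e-6))
  expect_true(all(ct$ventral_arc[, 2] <= 1e-6))
})
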