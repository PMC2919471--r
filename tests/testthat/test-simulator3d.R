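test_that("initialization builds consistent masks on the semi-ellipsoid grid", {
  p <- sim_params(grid_h = 5, dt = 0.5)
  st <- initialize_simulation(p)

  # voxelized volume matches the analytic joined semi-ellipsoid volume
  V_analytic <- (2 * pi / 3) * 280 * 110 * (92 + 128)
  expect_equal(st$V_int, V_analytic, tolerance = 0.02)

  # the source sphere lies inside the embryo
  src_xyz <- st$coords[st$source, , drop = FALSE]
  expect_true(all((src_xyz[, 1] - 75)^2 + src_xyz[, 2]^2 + src_xyz[, 3]^2 <=
                    45^2 + 1e-9))
  expect_true(length(st$source) * st$h^3 > 0.5 * (4 * pi / 3) * 45^3)

  # cortical classification agrees with an independent surface point cloud
  t1 <- seq(0, pi, length.out = 200)
  t2 <- seq(0, 2 * pi, length.out = 400)
  grid <- expand.grid(u = t1, v = t2)
  surf <- function(b) cbind(280 + 280 * cos(grid$u),
                            b * sin(grid$u) * cos(grid$v),
                            110 * sin(grid$u) * sin(grid$v))
  cloud <- rbind(surf(92)[surf(92)[, 2] >= 0, ], surf(128)[surf(128)[, 2] <= 0, ])
  set.seed(4)
  probe <- sample(length(st$T), 400)
  for (i in probe) {
    d <- min(sqrt((cloud[, 1] - st$coords[i, 1])^2 +
                    (cloud[, 2] - st$coords[i, 2])^2 +
                    (cloud[, 3] - st$coords[i, 3])^2))
    if (d < 8) expect_true(st$cortical[i])
    if (d > 12) expect_false(st$cortical[i])
  }

  expect_error(initialize_simulation(sim_params(grid_h = 2, dt = 1)),
               "unstable")
})

test_that("a uniform field without source or decay is a fixed point of the stencil", {
  p <- small_sim_params(omega = 0)
  st <- initialize_simulation(p)
  st$T <- rep(1.5, length(st$T))
  st$source <- integer(0)
  st2 <- step_simulation(st, p, nsteps = 25)
  expect_equal(st2$T, rep(1.5, length(st2$T)), tolerance = 1e-14)
})

test_that("mass is conserved to near machine precision without degradation", {
  p <- small_sim_params(omega = 0)
  st <- initialize_simulation(p)
  st <- step_simulation(st, p, nsteps = 10000)
  expected <- p$J * 10000 * p$dt
  expect_lt(abs(total_molecules(st) - expected) / expected, 1e-8)
})

test_that("with degradation the mass budget is strictly below the synthesized total", {
  p <- small_sim_params(omega = 5e-4)
  st <- initialize_simulation(p)
  st <- step_simulation(st, p, nsteps = 2000)
  expect_lt(total_molecules(st), p$J * 2000 * p$dt)
})

test_that("the pure-R reference step and the compiled kernel agree", {
  p <- small_sim_params()
  a <- step_simulation(initialize_simulation(p), p, 60, use_compiled = FALSE)
  b <- step_simulation(initialize_simulation(p), p, 60, use_compiled = TRUE)
  expect_equal(a$T, b$T, tolerance = 1e-14)
})

test_that("equilibrium binding enriches the nuclear cortical layer", {
  # short schedule to keep the run fast; physics, not duration, is under test
  sched <- data.frame(cycle = 1:13,
                      duration_s = c(rep(40, 9), 60, 60, 60, 120))
  p <- small_sim_params(cycle_schedule = sched, readout_offset_s = 300)
  st <- run_simulation(p)
  r14 <- p$r10 * 2^4
  # compare cortical voxels with adjacent interior voxels (shared faces)
  ratio <- numeric(0)
  for (i in which(st$cortical)[seq(1, sum(st$cortical), by = 23)]) {
    nb <- st$nbr[i, ]
    nb <- nb[nb > 0]
    inner <- nb[!st$cortical[nb]]
    if (length(inner) > 0) ratio <- c(ratio, st$T[i] / mean(st$T[inner]))
  }
  expect_gt(stats::median(ratio), 1 + 0.5 * r14)
  expect_lt(stats::median(ratio), 1 + 1.5 * r14)
})

test_that("a dorsoventrally symmetric embryo yields identical side profiles", {
  sched <- data.frame(cycle = 1:13, duration_s = c(rep(40, 9), 60, 60, 60, 120))
  p <- sim_params(shape = shape_params(280, 110, 55, 55), grid_h = 5, dt = 0.5,
                  source_center = c(40, 0, 0), source_radius = 25,
                  cycle_schedule = sched, readout_offset_s = 300)
  st <- run_simulation(p)
  prof <- extract_simulated_profiles(st, p, spacing = 4)
  d <- prof[prof$side == "D", ]
  v <- prof[prof$side == "V", ]
  m <- min(nrow(d), nrow(v))
  expect_equal(d$conc[1:m], v$conc[1:m], tolerance = 5e-3)
  # the contour support always exceeds the projected support
  expect_gt(max(d$c_um) - min(d$c_um), max(d$x_um) - min(d$x_um))
})

test_that("length constants are robust to grid and time-step refinement", {
  sched <- data.frame(cycle = 1:13, duration_s = c(rep(40, 9), 60, 60, 60, 120))
  lam <- function(h, dt) {
    p <- sim_params(shape = shape_params(280, 110, 46, 64), grid_h = h,
                    dt = dt, source_center = c(40, 0, 0), source_radius = 25,
                    cycle_schedule = sched, readout_offset_s = 300)
    prof <- extract_simulated_profiles(run_simulation(p), p, spacing = 2)
    vapply(c(D = "D", V = "V"), function(sn) {
      sub <- prof[prof$side == sn, ]
      fit_exponential(sub$c_um, sub$conc,
                      range = c(0.10, 0.60) * max(sub$c_um),
                      axis = "contour")$lambda
    }, numeric(1))
  }
  coarse <- lam(5, 2)
  fine <- lam(2.5, 0.4)
  expect_lt(max(abs(fine - coarse) / coarse), 0.05)
  expect_gt(coarse[["V"]], coarse[["D"]])
  expect_gt(fine[["V"]], fine[["D"]])
})

test_that("the 1-D rod recovers the analytic screening length", {
  rod <- run_rod_1d(D = 2, omega = 5e-5)
  expect_true(rod$converged)
  expect_equal(rod$lambda_fit, 200, tolerance = 0.05)

  rod4 <- run_rod_1d(D = 2, omega = 2e-4)
  expect_equal(rod4$lambda_fit, 100, tolerance = 0.05)

  expect_error(run_rod_1d(dt = 10), "unstable")
})

test_that("schedule validation and nuclear-region bookkeeping are enforced", {
  bad <- data.frame(cycle = c(1:5, 7:13), duration_s = 60)
  expect_error(sim_params(cycle_schedule = bad), "cycles 1 to 13")
  p <- small_sim_params()
  st <- initialize_simulation(p)
  expect_true(all(st$nuclear))               # pre-cycle-10: whole interior
  st10 <- bcdgeom:::set_cycle(st, 10L, p)
  expect_identical(st10$nuclear, st10$cortical)
  expect_equal(max(st10$r), p$r10)
  st14 <- bcdgeom:::set_cycle(st, 14L, p)
  expect_equal(max(st14$r), p$r10 * 16)
  # capacity is conserved across the cortical relocation
  cap9 <- sum(bcdgeom:::set_cycle(st, 9L, p)$r) * st$h^3
  cap10 <- sum(st10$r) * st$h^3
  expect_equal(cap9 * 2, cap10, tolerance = 1e-9)
})
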