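#' Parameters of the 3-D nuclear-cycle reaction-diffusion model
#'
#' Bcd molecules are synthesized at a constant aggregate rate inside an
#' anterior mRNA sphere, diffuse between the six face neighbours of each
#' voxel (free molecules only), degrade uniformly, and bind reversibly to
#' non-specific nuclear DNA at local equilibrium: the free fraction of the
#' total local concentration T is T/(1+r), where r is the bound-to-free
#' ratio of the current nuclear region. The nuclear binding capacity doubles
#' at every nuclear cycle; before cycle 10 the nuclei occupy the whole
#' interior, at the onset of cycle 10 they relocate to a cortical layer
#' under the embryo surface.
#'
#' Reference parameter values: D = 2 um^2/s, omega = 5e-5 /s, J = 1000
#' molecules/s, bound/free ratio 0.15 at cycle 10, source sphere of radius
#' 45 um centred at (75, 0, 0) um, cortical depth 10 um.
#'
#' @param shape a [shape_params()] (semi-ellipsoid embryo geometry).
#' @param D free-Bcd diffusion constant, um^2/s.
#' @param omega spatially uniform degradation rate, 1/s.
#' @param J aggregate synthesis rate, molecules/s.
#' @param r10 bound-to-free concentration ratio at cycle 10 onset.
#' @param source_center,source_radius mRNA sphere geometry, um (anterior
#'   pole is at the origin; A-P axis is +x, dorsal is +y).
#' @param cortical_depth nuclear-layer depth from cycle 10 on, um.
#' @param grid_h voxel edge, um.
#' @param dt time step, s; must satisfy dt < h^2/(6 D).
#' @param cycle_schedule data.frame with columns `cycle` and `duration_s`
#'   for cycles 1-13; defaults to 8 min for each of cycles 1-9 and 9, 10,
#'   12, 21 min for cycles 10-13.
#' @param readout_offset_s time into cycle 14 at which the gradient is read
#'   out, s (default 14 min).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(shape = shape_params(560, 220, 92, 128),
                       D = 2, omega = 5e-5, J = 1000, r10 = 0.15,
                       source_center = c(75, 0, 0), source_radius = 45,
                       cortical_depth = 10, grid_h = 2, dt = 0.2,
                       cycle_schedule = default_cycle_schedule(),
                       readout_offset_s = 14 * 60) {
  stopifnot(inherits(shape, "shape_params"))
  if (any(c(D, J, r10, source_radius, cortical_depth, grid_h, dt) <= 0) ||
      omega < 0) {
    stop("rates and geometric parameters must be positive (omega >= 0)")
  }
  if (!identical(sort(cycle_schedule$cycle), 1:13)) {
    stop("cycle_schedule must cover cycles 1 to 13 without gaps")
  }
  p <- list(shape = shape, D = D, omega = omega, J = J, r10 = r10,
            source_center = source_center, source_radius = source_radius,
            cortical_depth = cortical_depth, grid_h = grid_h, dt = dt,
            cycle_schedule = cycle_schedule[order(cycle_schedule$cycle), ],
            readout_offset_s = readout_offset_s)
  class(p) <- "sim_params"
  p
}

#' Default nuclear-cycle schedule
#'
#' Durations of nuclear cycles 1-13 in seconds: cycles 1-9 (pre-cortical)
#' 8 min each, cycles 10-13 at 9, 10, 12 and 21 min. Interphase lengthening
#' over the late syncytial cycles follows the published staging of the
#' Drosophila blastoderm; the readout is taken 14 min into cycle 14.
#'
#' @return data.frame with columns `cycle`, `duration_s`.
#' @export
default_cycle_schedule <- function() {
  data.frame(cycle = 1:13,
             duration_s = c(rep(8 * 60, 9), 9 * 60, 10 * 60, 12 * 60, 21 * 60))
}

# Distance from interior points to the surface of an axis-aligned ellipsoid
# centred at the origin, by bisection on the Lagrange parameter of the
# closest-point problem. Vectorized over points.
ellipsoid_surface_distance <- function(x, y, z, a, b, cc) {
  f <- function(t) {
    (a * x / (a^2 + t))^2 + (b * y / (b^2 + t))^2 + (cc * z / (cc^2 + t))^2 - 1
  }
  t_lo <- rep(-min(a, b, cc)^2 * (1 - 1e-9), length(x))
  t_hi <- rep(0, length(x))
  # guard points exactly at the centre (distance = smallest semi-axis)
  centre <- x == 0 & y == 0 & z == 0
  for (i in 1:80) {
    t_mid <- (t_lo + t_hi) / 2
    pos <- f(t_mid) > 0   # f decreases with t: root lies above t_mid
    t_lo[pos] <- t_mid[pos]
    t_hi[!pos] <- t_mid[!pos]
  }
  t <- (t_lo + t_hi) / 2
  qx <- a^2 * x / (a^2 + t)
  qy <- b^2 * y / (b^2 + t)
  qz <- cc^2 * z / (cc^2 + t)
  d <- sqrt((qx - x)^2 + (qy - y)^2 + (qz - z)^2)
  d[centre] <- min(a, b, cc)
  d
}

#' Initialize the reaction-diffusion state
#'
#' Builds the voxel grid over the embryo bounding box, the interior mask
#' from the semi-ellipsoid predicate, the cortical mask (interior voxels
#' within `cortical_depth` of the embryo surface), the source mask (mRNA
#' sphere intersected with the interior), the face-neighbour table used by
#' the stepping kernel (missing neighbours encode the zero-flux surface),
#' and a zero concentration field. The nuclear region starts as the whole
#' interior (cycles before 10).
#'
#' @param params a [sim_params()].
#' @return object of class `sim_state`.
#' @export
initialize_simulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  h <- params$grid_h
  dt_max <- h^2 / (6 * params$D)
  if (params$dt >= dt_max) {
    stop(sprintf("explicit scheme unstable: dt must be < h^2/(6 D) = %.4g s", dt_max))
  }
  sp <- params$shape
  a <- sp$length / 2
  bd <- sp$dorsal_height
  bv <- sp$ventral_height
  cl <- sp$lateral_diameter / 2

  xs <- seq(h / 2, sp$length - h / 2 + 1e-9, by = h)
  ny_d <- ceiling(bd / h); ny_v <- ceiling(bv / h)
  ys <- seq(-(ny_v - 0.5) * h, (ny_d - 0.5) * h + 1e-9, by = h)
  nz <- ceiling(cl / h)
  zs <- seq(-(nz - 0.5) * h, (nz - 0.5) * h + 1e-9, by = h)
  dims <- c(length(xs), length(ys), length(zs))

  coords <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  shape3 <- build_semi_ellipsoid_shape(sp, n_points = 721L)
  inside <- shape3$interior(coords$x, coords$y, coords$z)
  interior_flat <- which(inside)
  n_int <- length(interior_flat)
  if (n_int == 0L) stop("no interior voxels; grid too coarse for the shape")

  ix <- coords$x[interior_flat]
  iy <- coords$y[interior_flat]
  iz <- coords$z[interior_flat]

  # compacted index lookup: full-grid flat index -> interior index (0 if out)
  lut <- integer(prod(dims))
  lut[interior_flat] <- seq_len(n_int)

  # 6-face neighbour table (0 = embryo surface, zero-flux)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  xi <- ((interior_flat - 1L) %% dims[1]) + 1L
  yi <- (((interior_flat - 1L) %/% dims[1]) %% dims[2]) + 1L
  zi <- ((interior_flat - 1L) %/% (dims[1] * dims[2])) + 1L
  nbr <- matrix(0L, nrow = n_int, ncol = 6L)
  dirs <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
               c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (k in seq_along(dirs)) {
    d <- dirs[[k]]
    okx <- xi + d[1] >= 1L & xi + d[1] <= dims[1]
    oky <- yi + d[2] >= 1L & yi + d[2] <= dims[2]
    okz <- zi + d[3] >= 1L & zi + d[3] <= dims[3]
    ok <- okx & oky & okz
    nf <- interior_flat[ok] + d[1] * strides[1] + d[2] * strides[2] + d[3] * strides[3]
    nbr[ok, k] <- lut[nf]
  }

  # cortical layer: within cortical_depth of the side-specific ellipsoid
  # surface (x measured from the embryo centre)
  xc <- ix - a
  b_side <- ifelse(iy >= 0, bd, bv)
  implicit <- (xc / a)^2 + (iy / b_side)^2 + (iz / cl)^2
  # only voxels reasonably close to the surface need the exact distance
  near <- implicit > (1 - 2.5 * params$cortical_depth / min(a, bd, bv, cl))^2
  dist_surf <- rep(Inf, n_int)
  for (side in c("D", "V")) {
    sel <- near & (if (side == "D") iy >= 0 else iy < 0)
    if (any(sel)) {
      b <- if (side == "D") bd else bv
      dist_surf[sel] <- ellipsoid_surface_distance(xc[sel], iy[sel], iz[sel],
                                                   a, b, cl)
    }
  }
  cortical <- dist_surf <= params$cortical_depth

  src <- which((ix - params$source_center[1])^2 +
                 (iy - params$source_center[2])^2 +
                 (iz - params$source_center[3])^2 <= params$source_radius^2)
  if (length(src) == 0L) stop("source sphere does not intersect the embryo interior")

  state <- list(
    T = numeric(n_int),
    dims = dims, h = h, axes = list(x = xs, y = ys, z = zs),
    coords = cbind(x = ix, y = iy, z = iz),
    interior_flat = interior_flat,
    nbr = nbr, cortical = cortical, source = src,
    nuclear = rep(TRUE, n_int),   # pre-cycle-10: whole interior
    r = numeric(n_int),
    cycle = 1L, time_s = 0,
    V_int = n_int * h^3, V_cort = sum(cortical) * h^3
  )
  class(state) <- "sim_state"
  set_cycle(state, 1L, params)
}

# Nuclear region and bound-to-free ratio for a given cycle. Total binding
# capacity (r x nuclear volume) doubles each cycle and is conserved across
# the cycle-10 relocation from the whole interior to the cortical layer.
set_cycle <- function(state, cycle, params) {
  state$cycle <- as.integer(cycle)
  if (cycle >= 10L) {
    state$nuclear <- state$cortical
    r_nuc <- params$r10 * 2^(cycle - 10)
  } else {
    state$nuclear <- rep(TRUE, length(state$T))
    r_nuc <- params$r10 * 2^(cycle - 10) * state$V_cort / state$V_int
  }
  state$r <- ifelse(state$nuclear, r_nuc, 0)
  state
}

#' Advance the simulation by explicit time steps
#'
#' One explicit step: local equilibrium partition of total concentration
#' into free (T/(1+r)) and bound; 6-neighbour diffusion of the free
#' concentration with zero-flux boundaries at the embryo surface;
#' first-order degradation of total Bcd; constant synthesis spread
#' uniformly over the source voxels. The pure-R path is a reference
#' implementation kept for verification; the compiled path is numerically
#' identical.
#'
#' @param state a `sim_state`.
#' @param params the matching [sim_params()].
#' @param nsteps number of steps of length `dt`.
#' @param use_compiled use the compiled kernel (default) or the R reference.
#' @return the advanced `sim_state`.
#' @export
step_simulation <- function(state, params, nsteps = 1L, use_compiled = TRUE) {
  h <- state$h
  ddt_h2 <- params$D * params$dt / h^2
  omega_dt <- params$omega * params$dt
  src_add <- if (length(state$source) > 0L) {
    params$J * params$dt / (length(state$source) * h^3)
  } else 0
  if (use_compiled) {
    state$T <- rd_steps_cpp(state$T, state$nbr, state$r, ddt_h2, omega_dt,
                            state$source, src_add, as.integer(nsteps))
  } else {
    T <- state$T
    nbr <- state$nbr
    r <- state$r
    for (s in seq_len(nsteps)) {
      Bf <- T / (1 + r)
      lap <- numeric(length(T))
      for (k in 1:6) {
        j <- nbr[, k]
        ok <- j > 0L
        lap[ok] <- lap[ok] + Bf[j[ok]] - Bf[ok]
      }
      T <- T + ddt_h2 * lap - omega_dt * T
      T[state$source] <- T[state$source] + src_add
    }
    state$T <- T
  }
  if (any(state$T < 0)) {
    stop(sprintf("negative concentration after stepping (min %.3g): scheme unstable",
                 min(state$T)))
  }
  state$time_s <- state$time_s + nsteps * params$dt
  state
}

#' Run the nuclear-cycle simulation to the readout time
#'
#' Advances through the cycle schedule (doubling the nuclear binding
#' capacity at every cycle boundary and relocating the nuclear region to the
#' cortical layer at the onset of cycle 10) and stops `readout_offset_s`
#' into cycle 14. Per-cycle snapshots of the maximal cortical concentration
#' and the mass budget are recorded.
#'
#' @param params a [sim_params()].
#' @param use_compiled use the compiled stepping kernel.
#' @param verbose print per-cycle progress.
#' @return the final `sim_state`, with a `snapshots` data.frame attached
#'   (columns `cycle`, `time_s`, `total_molecules`, `max_cortical`).
#' @export
run_simulation <- function(params, use_compiled = TRUE, verbose = FALSE) {
  state <- initialize_simulation(params)
  snaps <- list()
  phases <- rbind(params$cycle_schedule,
                  data.frame(cycle = 14L, duration_s = params$readout_offset_s))
  for (i in seq_len(nrow(phases))) {
    state <- set_cycle(state, phases$cycle[i], params)
    nsteps <- round(phases$duration_s[i] / params$dt)
    state <- step_simulation(state, params, nsteps, use_compiled = use_compiled)
    snaps[[i]] <- data.frame(
      cycle = phases$cycle[i], time_s = state$time_s,
      total_molecules = total_molecules(state),
      max_cortical = max(state$T[state$cortical])
    )
    if (verbose) {
      message(sprintf("cycle %2d done at t = %6.0f s; max cortical T = %.3g",
                      phases$cycle[i], state$time_s, snaps[[i]]$max_cortical))
    }
  }
  state$snapshots <- do.call(rbind, snaps)
  state
}

#' Total number of molecules in the embryo
#'
#' @param state a `sim_state`.
#' @return sum of concentration times voxel volume, molecules.
#' @export
total_molecules <- function(state) sum(state$T) * state$h^3

#' Extract cortical concentration profiles from a simulated embryo
#'
#' Samples the total (nuclear) Bcd concentration in the midsagittal cortical
#' band with the same sliding-window geometry as the experimental pipeline:
#' window centres follow each side's midsagittal outline offset inward by
#' `inset`, and each window averages the cortical voxels of the midsagittal
#' slab within the window radius. The result satisfies the cortical-trace
#' contract, so all gradient statistics apply unchanged.
#'
#' @param state a readout `sim_state`.
#' @param params the matching [sim_params()].
#' @param window_area window area, um^2.
#' @param inset window-centre inset from the perimeter, um.
#' @param spacing A-P window spacing, um.
#' @return data.frame with columns `embryo`, `side`, `window_index`, `x_um`,
#'   `y_um`, `c_um`, `conc` (molecules/um^3).
#' @export
extract_simulated_profiles <- function(state, params, window_area = 25,
                                       inset = 6, spacing = 2) {
  contour <- build_semi_ellipsoid_shape(params$shape, n_points = 1201L)$contour
  radius <- max(sqrt(window_area / pi), 0.75 * state$h)
  mid <- state$cortical & abs(state$coords[, "z"]) <= state$h
  if (!any(mid)) stop("no cortical voxels on the midsagittal slab")
  mx <- state$coords[mid, "x"]
  my <- state$coords[mid, "y"]
  mv <- state$T[mid]
  out <- lapply(c(D = "D", V = "V"), function(sn) {
    arc <- if (sn == "D") contour$dorsal_arc else contour$ventral_arc
    w <- window_centres(arc, inset, spacing, contour$L)
    on_side <- if (sn == "D") my >= -state$h else my <= state$h
    sx <- mx[on_side]; sy <- my[on_side]; sv <- mv[on_side]
    conc <- vapply(seq_len(nrow(w$centres)), function(k) {
      d2 <- (sx - w$centres[k, 1])^2 + (sy - w$centres[k, 2])^2
      sel <- d2 <= radius^2
      if (!any(sel)) {
        sel <- d2 <= (2 * state$h)^2
      }
      mean(sv[sel])
    }, numeric(1))
    data.frame(embryo = 1L, side = sn, window_index = seq_along(conc),
               x_um = w$centres[, 1], y_um = w$centres[, 2], c_um = w$c,
               conc = conc)
  })
  rownames(out$D) <- rownames(out$V) <- NULL
  rbind(out$D, out$V)
}

#' One-dimensional rod model (stencil validation)
#'
#' Explicit diffusion-degradation on a rod with a source at the anterior
#' end and reflecting boundaries, run to (approximate) steady state. Away
#' from the source and the far end the steady profile is exponential with
#' the screening length lambda = sqrt(D/omega), which the returned fit
#' recovers.
#'
#' @param D,omega,J diffusion constant (um^2/s), degradation rate (1/s) and
#'   synthesis rate (molecules/s).
#' @param length rod length, um.
#' @param h,dt cell size (um) and time step (s).
#' @param source_width anterior source extent, um.
#' @param fit_range positions used for the exponential fit, um.
#' @param t_max maximum simulated time, s.
#' @param tol convergence threshold on the relative profile change per 1000
#'   steps.
#' @return list with `x`, `conc`, `lambda_fit`, `lambda_theory`,
#'   `converged`, `time_s`.
#' @export
run_rod_1d <- function(D = 2, omega = 5e-5, J = 1000, length = 1200,
                       h = 5, dt = 5, source_width = 25,
                       fit_range = c(100, 700), t_max = 3e5, tol = 1e-6) {
  if (dt >= h^2 / (2 * D)) {
    stop(sprintf("unstable: dt must be < h^2/(2 D) = %.4g s", h^2 / (2 * D)))
  }
  n <- round(length / h)
  x <- (seq_len(n) - 0.5) * h
  src <- which(x <= source_width)
  src_add <- J * dt / (length(src) * h)
  conc <- numeric(n)
  lam <- D * dt / h^2
  steps_per_check <- 1000L
  t <- 0
  converged <- FALSE
  while (t < t_max) {
    prev <- conc
    for (s in seq_len(steps_per_check)) {
      lap <- c(conc[2] - conc[1],
               conc[c(-1, -n)] * -2 + conc[-c(n - 1, n)] + conc[-c(1, 2)],
               conc[n - 1] - conc[n])
      conc <- conc + lam * lap - omega * dt * conc
      conc[src] <- conc[src] + src_add
    }
    t <- t + steps_per_check * dt
    rel <- max(abs(conc - prev)) / max(conc)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("rod did not reach steady state (relative change %.2g)", rel))
  }
  fit <- fit_exponential(x, conc, range = fit_range, axis = "projected")
  list(x = x, conc = conc, lambda_fit = fit$lambda,
       lambda_theory = sqrt(D / omega), converged = converged, time_s = t)
}
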