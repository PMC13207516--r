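#' Fluid properties
#'
#' Density and dynamic viscosity of the working fluid. Defaults are typical
#' values for blood treated as a Newtonian fluid.
#'
#' @param density Density rho in kg/m^3.
#' @param viscosity Dynamic viscosity mu in Pa s.
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0)
    abort("density and viscosity must be strictly positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

new_wall_shear_series <- function(mesh, times, wss) {
  stopifnot(inherits(mesh, "tube_mesh"),
            length(times) == dim(wss)[2], nrow(mesh$points) == dim(wss)[1])
  if (length(times) > 1 && any(diff(times) <= 0))
    abort("`times` must be strictly increasing")
  if (!all(is.finite(wss))) abort("wall shear stress values must be finite")
  structure(list(mesh = mesh, times = times, wss = wss),
            class = "wall_shear_series")
}

#' @export
print.wall_shear_series <- function(x, ...) {
  cat("<wall_shear_series> ", dim(x$wss)[1], " points x ", length(x$times),
      " time steps over [", format(min(x$times)), ", ",
      format(max(x$times)), "] s\n", sep = "")
  invisible(x)
}

#' @export
print.flow_field_series <- function(x, ...) {
  cat("<flow_field_series> ", nrow(x$sample_points), " sample points x ",
      length(x$times), " time steps, ports: ",
      paste(vapply(x$ports, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# interior cylindrical grid for volume sampling; midpoint ring radii give an
# exact-total-area quadrature of the circular cross-section
tube_volume_grid <- function(mesh, n_r = 24, n_theta = 16, n_z = 8) {
  R <- mesh$radius; L <- mesh$length
  dr <- R / n_r
  r <- (seq_len(n_r) - 0.5) * dr
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  z <- seq(0, L, length.out = n_z)
  idx <- function(ir, it, iz) ((iz - 1L) * n_r + (ir - 1L)) * n_theta + it
  n <- n_r * n_theta * n_z
  pts <- matrix(0, n, 3)
  for (iz in seq_len(n_z)) for (ir in seq_len(n_r)) {
    i <- idx(ir, seq_len(n_theta), iz)
    pts[i, 1] <- r[ir] * cos(theta)
    pts[i, 2] <- r[ir] * sin(theta)
    pts[i, 3] <- z[iz]
  }
  # +/-2 index stencil in each grid direction: enough points for the
  # quadratic-diagonal least-squares gradient used downstream, which stays
  # second-order accurate at one-sided (wall / port-plane) points
  neighbors <- vector("list", n)
  wrap <- function(it) ((it - 1L) %% n_theta) + 1L
  for (iz in seq_len(n_z)) for (ir in seq_len(n_r)) for (it in seq_len(n_theta)) {
    i <- idx(ir, it, iz)
    nb <- integer(0)
    for (s in c(-2L, -1L, 1L, 2L)) {
      if (ir + s >= 1L && ir + s <= n_r) nb <- c(nb, idx(ir + s, it, iz))
      nb <- c(nb, idx(ir, wrap(it + s), iz))
      if (iz + s >= 1L && iz + s <= n_z) nb <- c(nb, idx(ir, it, iz + s))
    }
    neighbors[[i]] <- unique(nb[nb != i])
  }
  # annulus areas, divided evenly over the ring's theta points (mm^2)
  ring_area <- pi * ((seq_len(n_r) * dr)^2 - ((seq_len(n_r) - 1L) * dr)^2)
  plane_ids <- function(iz) {
    unlist(lapply(seq_len(n_r), function(ir) idx(ir, seq_len(n_theta), iz)))
  }
  plane_w <- unlist(lapply(seq_len(n_r), function(ir)
    rep(ring_area[ir] / n_theta, n_theta)))
  list(points = pts, neighbors = neighbors, radii = rep(rep(r, each = n_theta),
       times = n_z), n_r = n_r, n_theta = n_theta, n_z = n_z,
       plane_ids = plane_ids, plane_w = plane_w)
}

new_flow_field_series <- function(grid, times, velocity, pressure, ports) {
  structure(list(sample_points = grid$points, times = times,
                 velocity = velocity, pressure = pressure,
                 neighbors = grid$neighbors, ports = ports),
            class = "flow_field_series")
}

poiseuille_snapshot <- function(grid, mesh, Q, fluid) {
  R <- mesh$radius; L <- mesh$length; mu <- fluid$viscosity
  vz <- 2 * Q / (pi * R^2) * (1 - (grid$radii / R)^2)  # mm/s
  dp <- 8 * mu * L * Q / (pi * R^4)                    # Pa
  p <- dp * (1 - grid$points[, 3] / L)
  list(vz = vz, p = p)
}

#' Steady Poiseuille flow and wall shear on a tube
#'
#' Analytic fully developed laminar pipe flow: parabolic axial velocity,
#' linear axial pressure with end-to-end drop `8 mu L Q / (pi R^4)`, and a
#' spatially uniform, axially aligned wall shear stress of magnitude
#' `4 mu Q / (pi R^3)`. Serves as a closed-form oracle for the indicator
#' computations; every time step is identical.
#'
#' @param mesh A `tube_mesh`.
#' @param Q Volumetric flow rate (mm^3/s).
#' @param fluid A [fluid_properties()] object.
#' @param n_steps Number of time steps (>= 1).
#' @param period Cycle duration in seconds (used only when `n_steps > 1`).
#' @param n_r,n_theta,n_z Volume sampling resolution (radial rings,
#'   circumferential points, axial planes).
#' @return List with components `wall` (a `wall_shear_series`) and `flow`
#'   (a `flow_field_series`; velocity in mm/s, pressure in Pa).
#' @export
poiseuille_fields <- function(mesh, Q, fluid = fluid_properties(),
                              n_steps = 1, period = 1,
                              n_r = 24, n_theta = 16, n_z = 8) {
  if (n_steps < 1) abort("`n_steps` must be >= 1")
  R <- mesh$radius; mu <- fluid$viscosity
  times <- if (n_steps == 1) 0 else seq(0, period, length.out = n_steps)

  n_pts <- nrow(mesh$points)
  tau <- 4 * mu * Q / (pi * R^3)
  wss <- array(0, dim = c(n_pts, length(times), 3))
  wss[, , 3] <- tau
  wall <- new_wall_shear_series(mesh, times, wss)

  grid <- tube_volume_grid(mesh, n_r, n_theta, n_z)
  snap <- poiseuille_snapshot(grid, mesh, Q, fluid)
  nv <- nrow(grid$points)
  vel <- array(0, dim = c(nv, length(times), 3))
  prs <- matrix(0, nv, length(times))
  for (t in seq_along(times)) {
    vel[, t, 3] <- snap$vz
    prs[, t] <- snap$p
  }
  ports <- list(
    in1 = list(name = "in1", point_ids = grid$plane_ids(1L),
               weights = grid$plane_w, flow_dir = c(0, 0, 1)),
    out = list(name = "out", point_ids = grid$plane_ids(grid$n_z),
               weights = grid$plane_w, flow_dir = c(0, 0, 1))
  )
  flow <- new_flow_field_series(grid, times, vel, prs, ports)
  list(wall = wall, flow = flow)
}

#' Rotating-direction wall shear field with closed-form OSI and transWSS
#'
#' Generates a wall shear vector of constant magnitude `tau0` whose in-plane
#' direction sweeps linearly over `[-alpha, alpha]` (relative to the axial
#' direction) across one cycle. Direct integration gives
#' `OSI = (1 - sin(alpha)/alpha) / 2` and
#' `transWSS = tau0 (1 - cos(alpha)) / alpha`, making this the oracle for the
#' direction-sensitive indicators.
#'
#' @param mesh A `tube_mesh`.
#' @param tau0 Shear magnitude (Pa), > 0.
#' @param alpha Sweep half-angle in radians, within `[0, pi]`.
#' @param period Cycle duration (s).
#' @param n_steps Time steps (>= 16).
#' @return A `wall_shear_series`.
#' @export
oscillatory_wss_fields <- function(mesh, tau0, alpha, period = 1,
                                   n_steps = 64) {
  if (alpha < 0 || alpha > pi) abort("`alpha` must lie in [0, pi]")
  if (n_steps < 16) abort("`n_steps` must be >= 16")
  times <- seq(0, period, length.out = n_steps)
  theta_t <- if (alpha == 0) rep(0, n_steps) else -alpha + 2 * alpha * times / period
  n_pts <- nrow(mesh$points)
  phi <- atan2(mesh$points[, 2], mesh$points[, 1])
  e_circ <- cbind(-sin(phi), cos(phi), 0)
  wss <- array(0, dim = c(n_pts, n_steps, 3))
  for (t in seq_len(n_steps)) {
    wss[, t, 1] <- tau0 * sin(theta_t[t]) * e_circ[, 1]
    wss[, t, 2] <- tau0 * sin(theta_t[t]) * e_circ[, 2]
    wss[, t, 3] <- tau0 * cos(theta_t[t])
  }
  new_wall_shear_series(mesh, times, wss)
}

#' Quasi-steady pulsatile Poiseuille fields
#'
#' Flow rate `Q(t) = Q_mean (1 + a sin(2 pi t / T))` with instantaneous
#' fields given by the steady Poiseuille solution at `Q(t)`. A quasi-steady
#' stand-in for a transient simulation: closed-form indicator values are
#' retained (no Womersley profile).
#'
#' @param mesh A `tube_mesh`.
#' @param Q_mean Mean flow rate (mm^3/s).
#' @param amplitude_fraction Pulsation amplitude `a` (>= 0; `a < 1` is
#'   non-reversing, `a >= 1` allows flow reversal).
#' @param period Cycle duration (s).
#' @param n_steps Time steps (>= 2).
#' @param fluid A [fluid_properties()].
#' @inheritParams poiseuille_fields
#' @return List with `wall` and `flow` series as in [poiseuille_fields()].
#' @export
pulsatile_poiseuille_fields <- function(mesh, Q_mean, amplitude_fraction,
                                        period = 1, n_steps = 64,
                                        fluid = fluid_properties(),
                                        n_r = 24, n_theta = 16, n_z = 8) {
  if (amplitude_fraction < 0) abort("`amplitude_fraction` must be >= 0")
  if (n_steps < 2) abort("`n_steps` must be >= 2")
  R <- mesh$radius; mu <- fluid$viscosity
  times <- seq(0, period, length.out = n_steps)
  Qt <- Q_mean * (1 + amplitude_fraction * sin(2 * pi * times / period))

  n_pts <- nrow(mesh$points)
  wss <- array(0, dim = c(n_pts, n_steps, 3))
  for (t in seq_len(n_steps)) wss[, t, 3] <- 4 * mu * Qt[t] / (pi * R^3)
  wall <- new_wall_shear_series(mesh, times, wss)

  grid <- tube_volume_grid(mesh, n_r, n_theta, n_z)
  nv <- nrow(grid$points)
  vel <- array(0, dim = c(nv, n_steps, 3))
  prs <- matrix(0, nv, n_steps)
  for (t in seq_len(n_steps)) {
    snap <- poiseuille_snapshot(grid, mesh, Qt[t], fluid)
    vel[, t, 3] <- snap$vz
    prs[, t] <- snap$p
  }
  ports <- list(
    in1 = list(name = "in1", point_ids = grid$plane_ids(1L),
               weights = grid$plane_w, flow_dir = c(0, 0, 1)),
    out = list(name = "out", point_ids = grid$plane_ids(grid$n_z),
               weights = grid$plane_w, flow_dir = c(0, 0, 1))
  )
  flow <- new_flow_field_series(grid, times, vel, prs, ports)
  list(wall = wall, flow = flow)
}
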