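# Wall-shear-stress indicator computations. All temporal integrals use the
# trapezoid rule on the (possibly non-uniform) time grid of the series;
# geometric units are mm, stresses Pa, so WSSG is Pa/mm and vorticity 1/s.

# trapezoid quadrature weights for a strictly increasing grid
trapz_weights <- function(times) {
  nt <- length(times)
  if (nt == 1) return(1)
  dt <- diff(times)
  w <- numeric(nt)
  w[1] <- dt[1] / 2
  w[nt] <- dt[nt - 1] / 2
  if (nt > 2) w[2:(nt - 1)] <- (dt[-(nt - 1)] + dt[-1]) / 2
  w
}

wss_component <- function(ws, k) {
  m <- ws$wss[, , k]
  if (is.null(dim(m))) m <- matrix(m, ncol = length(ws$times))
  m
}

wss_magnitude <- function(ws) {
  sqrt(wss_component(ws, 1)^2 + wss_component(ws, 2)^2 +
         wss_component(ws, 3)^2)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-point time average of the wall shear magnitude over one cycle,
#' `TAWSS_j = (1/T) int ||tau_j(t)|| dt` (trapezoid rule). A single-step
#' steady series returns the instantaneous magnitude.
#'
#' @param ws A `wall_shear_series`.
#' @return Numeric vector, one value (Pa) per surface point.
#' @export
tawss <- function(ws) {
  stopifnot(inherits(ws, "wall_shear_series"))
  m <- wss_magnitude(ws)
  if (length(ws$times) == 1) return(as.numeric(m[, 1]))
  Tspan <- max(ws$times) - min(ws$times)
  as.numeric(m %*% trapz_weights(ws$times)) / Tspan
}

#' Oscillatory shear index (OSI)
#'
#' `OSI_j = (1 - ||int tau_j dt|| / int ||tau_j|| dt) / 2`, clipped to
#' `[0, 0.5]`. Zero for unidirectional shear, 0.5 for shear whose time mean
#' vanishes. Points with zero integrated magnitude get OSI 0 by convention.
#'
#' @param ws A `wall_shear_series`.
#' @return Numeric vector in `[0, 0.5]`, one value per surface point.
#' @export
osi <- function(ws) {
  stopifnot(inherits(ws, "wall_shear_series"))
  if (length(ws$times) == 1) return(rep(0, dim(ws$wss)[1]))
  w <- trapz_weights(ws$times)
  ix <- wss_component(ws, 1) %*% w
  iy <- wss_component(ws, 2) %*% w
  iz <- wss_component(ws, 3) %*% w
  num <- sqrt(ix^2 + iy^2 + iz^2)
  den <- wss_magnitude(ws) %*% w
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(as.numeric(out), 0), 0.5)
}

#' Relative residence time (RRT)
#'
#' `RRT_j = 1 / ((1 - 2 OSI_j) TAWSS_j)` (1/Pa), a surrogate for near-wall
#' residence of blood. Where the denominator falls below `1e-12` the value is
#' `Inf`; downstream median reductions exclude such points (the count is
#' attached as attribute `"n_infinite"`).
#'
#' @param tawss_field Per-point TAWSS values.
#' @param osi_field Per-point OSI values.
#' @return Numeric vector (1/Pa) with attribute `n_infinite`.
#' @export
rrt <- function(tawss_field, osi_field) {
  stopifnot(length(tawss_field) == length(osi_field))
  den <- (1 - 2 * osi_field) * tawss_field
  out <- ifelse(den < 1e-12, Inf, 1 / den)
  attr(out, "n_infinite") <- sum(!is.finite(out))
  out
}

#' Transverse wall shear stress (transWSS)
#'
#' Time-averaged magnitude of the shear component perpendicular (within the
#' tangent plane) to the dominant shear direction:
#' `transWSS_j = (1/T) int |tau_j(t) . (n_j x p_j)| dt`, with `p_j` the unit
#' vector of the time-averaged shear. Points whose mean shear vector is
#' degenerate (below `1e-12`) contribute 0 and are counted in attribute
#' `"n_degenerate"`.
#'
#' @param ws A `wall_shear_series`.
#' @return Numeric vector (Pa) per surface point.
#' @export
transwss <- function(ws) {
  stopifnot(inherits(ws, "wall_shear_series"))
  n_pts <- dim(ws$wss)[1]
  if (length(ws$times) == 1) {
    out <- rep(0, n_pts)
    attr(out, "n_degenerate") <- 0L
    return(out)
  }
  w <- trapz_weights(ws$times)
  mx <- wss_component(ws, 1); my <- wss_component(ws, 2)
  mz <- wss_component(ws, 3)
  px <- as.numeric(mx %*% w); py <- as.numeric(my %*% w)
  pz <- as.numeric(mz %*% w)
  pn <- sqrt(px^2 + py^2 + pz^2)
  degen <- pn < 1e-12
  pn_safe <- ifelse(degen, 1, pn)
  px <- px / pn_safe; py <- py / pn_safe; pz <- pz / pn_safe
  nrm <- ws$mesh$wall_normals
  # c = n x p per point
  cx <- nrm[, 2] * pz - nrm[, 3] * py
  cy <- nrm[, 3] * px - nrm[, 1] * pz
  cz <- nrm[, 1] * py - nrm[, 2] * px
  integrand <- abs(mx * cx + my * cy + mz * cz)
  Tspan <- max(ws$times) - min(ws$times)
  out <- as.numeric(integrand %*% w) / Tspan
  out[degen] <- 0
  attr(out, "n_degenerate") <- sum(degen)
  out
}

#' Surface gradient magnitude of TAWSS (WSSG)
#'
#' Per-triangle linear (P1) surface gradient of the TAWSS scalar, combined
#' into a per-point value by area-weighted averaging of incident-triangle
#' gradient magnitudes. Degenerate (zero-area) triangles are skipped with a
#' warning.
#'
#' @param tawss_field Per-point TAWSS values (Pa).
#' @param mesh The `tube_mesh` carrying the triangulation.
#' @return Numeric vector (Pa/mm) per surface point.
#' @export
wssg <- function(tawss_field, mesh) {
  p <- mesh$points; tr <- mesh$triangles
  stopifnot(length(tawss_field) == nrow(p))
  e1 <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  e2 <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  d1 <- tawss_field[tr[, 2]] - tawss_field[tr[, 1]]
  d2 <- tawss_field[tr[, 3]] - tawss_field[tr[, 1]]
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  det <- g11 * g22 - g12^2
  area2 <- sqrt(pmax(det, 0))  # 2 * area
  ok <- area2 > 1e-12
  if (!all(ok)) warn(sprintf("%d zero-area triangles skipped", sum(!ok)))
  a <- ifelse(ok, (g22 * d1 - g12 * d2) / det, 0)
  b <- ifelse(ok, (g11 * d2 - g12 * d1) / det, 0)
  gx <- a * e1[, 1] + b * e2[, 1]
  gy <- a * e1[, 2] + b * e2[, 2]
  gz <- a * e1[, 3] + b * e2[, 3]
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  area <- area2 / 2
  num <- den <- numeric(nrow(p))
  for (v in 1:3) {
    idx <- tr[ok, v]
    num_add <- gmag[ok] * area[ok]
    num <- num + unname(tapply_add(num_add, idx, nrow(p)))
    den <- den + unname(tapply_add(area[ok], idx, nrow(p)))
  }
  ifelse(den > 0, num / den, 0)
}

# sum `vals` into bins given by `idx` over 1..n (sparse accumulate)
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# least-squares velocity gradient Jacobians J[c,d] = dv_c/dx_d for every
# point/time; returns list(J = array(n, nt, 3, 3), excluded = integer ids).
# The local model is quadratic-diagonal (x, y, z, x^2, y^2, z^2 around the
# point), which keeps one-sided boundary stencils second-order accurate and
# is exact for linear fields and for isotropic-curvature profiles such as
# the parabolic pipe profile.
velocity_gradients <- function(ff) {
  pts <- ff$sample_points
  n <- nrow(pts); nt <- length(ff$times)
  J <- array(NA_real_, dim = c(n, nt, 3, 3))
  excluded <- integer(0)
  pinv <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- ff$neighbors[[i]]
    if (length(nb) < 6) { excluded <- c(excluded, i); next }
    d <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ])
    D <- cbind(d, d^2)  # k x 6
    G <- crossprod(D)
    if (rcond_sym(G) < 1e-12) { excluded <- c(excluded, i); next }
    pinv[[i]] <- solve(G, t(D))  # 6 x k
  }
  for (t in seq_len(nt)) {
    vt <- ff$velocity[, t, , drop = FALSE]
    dim(vt) <- c(n, 3)
    for (i in seq_len(n)) {
      P <- pinv[[i]]
      if (is.null(P)) next
      nb <- ff$neighbors[[i]]
      dv <- vt[nb, , drop = FALSE] -
        matrix(vt[i, ], length(nb), 3, byrow = TRUE)
      G <- P %*% dv               # rows 1:3 give d v_c / d x_d
      J[i, t, , ] <- t(G[1:3, , drop = FALSE])
    }
  }
  if (length(excluded))
    warn(sprintf("%d points lack a well-posed gradient stencil; excluded",
                 length(excluded)))
  list(J = J, excluded = excluded)
}

rcond_sym <- function(G) {
  e <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 0) return(0)
  min(e) / max(e)
}

#' Vorticity and helicity density of a flow field series
#'
#' Computes the velocity gradient at every sample point by a least-squares
#' linear fit over its spatial neighbors, then `omega = curl v` (1/s) and the
#' helicity density `h = v . omega`. Points without a well-posed stencil are
#' excluded (NA) with a warning.
#'
#' @param ff A `flow_field_series` (velocity in mm/s, coordinates mm).
#' @return List with `vorticity` (n x nt x 3 array, 1/s), `vorticity_mag`
#'   (n x nt), `helicity` (n x nt, mm/s^2), and `excluded` point indices.
#' @export
vorticity_and_helicity <- function(ff) {
  stopifnot(inherits(ff, "flow_field_series"))
  vg <- velocity_gradients(ff)
  n <- dim(vg$J)[1]; nt <- dim(vg$J)[2]
  wx <- vg$J[, , 3, 2] - vg$J[, , 2, 3]
  wy <- vg$J[, , 1, 3] - vg$J[, , 3, 1]
  wz <- vg$J[, , 2, 1] - vg$J[, , 1, 2]
  fix_dim <- function(m) { dim(m) <- c(n, nt); m }
  wx <- fix_dim(wx); wy <- fix_dim(wy); wz <- fix_dim(wz)
  vort <- array(c(wx, wy, wz), dim = c(n, nt, 3))
  vmag <- sqrt(wx^2 + wy^2 + wz^2)
  hx <- ff$velocity[, , 1]; hy <- ff$velocity[, , 2]
  hz <- ff$velocity[, , 3]
  hx <- fix_dim(hx); hy <- fix_dim(hy); hz <- fix_dim(hz)
  hel <- hx * wx + hy * wy + hz * wz
  list(vorticity = vort, vorticity_mag = vmag, helicity = hel,
       excluded = vg$excluded)
}

#' Scalar strain rate of a flow field series
#'
#' Symmetric part of the velocity gradient, `S = (grad v + grad v^T)/2`,
#' reported as the scalar shear rate `gamma_dot = sqrt(2 S:S)` (1/s).
#'
#' @param ff A `flow_field_series`.
#' @return Matrix (points x times) of strain rates (1/s); excluded points NA.
#' @export
strain_rate <- function(ff) {
  stopifnot(inherits(ff, "flow_field_series"))
  vg <- velocity_gradients(ff)
  n <- dim(vg$J)[1]; nt <- dim(vg$J)[2]
  out <- matrix(NA_real_, n, nt)
  for (t in seq_len(nt)) {
    for (i in seq_len(n)) {
      Jm <- matrix(vg$J[i, t, , ], 3, 3)
      if (anyNA(Jm)) next
      S <- (Jm + t(Jm)) / 2
      out[i, t] <- sqrt(2 * sum(S * S))
    }
  }
  out
}

#' Per-port flow rate, pressure and speed series
#'
#' Area-weighted discrete surface integrals over each port cross-section:
#' flow rate `Q = sum w_i (v_i . d)` (mm^3/s, `d` the port's flow direction,
#' into the domain for inlets and out of it for the outlet), area-averaged
#' static pressure `p_bar` (Pa) and area-averaged speed `v_bar` (mm/s).
#'
#' @param ff A `flow_field_series` with port definitions.
#' @return Tibble with columns `port`, `time`, `Q`, `p_bar`, `v_bar`.
#' @export
port_series <- function(ff) {
  stopifnot(inherits(ff, "flow_field_series"))
  rows <- purrr::map(ff$ports, function(p) {
    ids <- p$point_ids
    if (!length(ids)) abort(sprintf("port %s has an empty cross-section",
                                    p$name))
    w <- p$weights
    A <- sum(w)
    purrr::map(seq_along(ff$times), function(t) {
      v <- ff$velocity[ids, t, , drop = FALSE]
      dim(v) <- c(length(ids), 3)
      vn <- v %*% p$flow_dir
      speed <- sqrt(rowSums(v^2))
      tibble::tibble(
        port = p$name, time = ff$times[t],
        Q = sum(w * vn),
        p_bar = sum(w * ff$pressure[ids, t]) / A,
        v_bar = sum(w * speed) / A
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Energy loss and energy efficiency from port series
#'
#' Instantaneous total-pressure flux per port,
#' `Phi = Q (p_bar + rho v_bar^2 / 2)`; the loss is the inlet-minus-outlet
#' flux and the efficiency its complement relative to the inlet flux:
#' `E_loss = median_t(sum Phi_in - Phi_out)` (W),
#' `E_eff = median_t(1 - (sum Phi_in - Phi_out) / sum Phi_in)`.
#' For a single-inlet steady tube this reduces to `E_loss = Q dp_total`.
#'
#' @param ps Port series tibble from [port_series()].
#' @param fluid A [fluid_properties()].
#' @return List with `E_loss` (W), `E_eff` (dimensionless) and the per-time
#'   tibble `per_time`. Zero inlet flux yields `E_eff = NA` with a warning.
#' @export
energy_loss_efficiency <- function(ps, fluid = fluid_properties()) {
  ports <- unique(ps$port)
  if (!any(grepl("^in", ports)) || !("out" %in% ports))
    abort("port series must contain at least one inlet and the outlet")
  rho <- fluid$density
  ph <- ps |>
    dplyr::mutate(
      phi = .data$Q * (.data$p_bar + 0.5 * rho * (.data$v_bar * 1e-3)^2),
      role = ifelse(grepl("^in", .data$port), "inlet", "outlet")
    ) |>
    dplyr::summarise(phi = sum(.data$phi),
                     .by = c("time", "role")) |>
    tidyr::pivot_wider(names_from = "role", values_from = "phi")
  # phi carries mm^3/s * Pa = nW; convert losses to W
  per_time <- ph |>
    dplyr::mutate(
      loss_W = (.data$inlet - .data$outlet) * 1e-9,
      eff = ifelse(abs(.data$inlet) > 0,
                   1 - (.data$inlet - .data$outlet) / .data$inlet, NA_real_)
    )
  if (anyNA(per_time$eff)) warn("zero inlet flux: E_eff undefined there")
  eff <- if (all(is.na(per_time$eff))) NA_real_ else
    median(per_time$eff, na.rm = TRUE)
  list(E_loss = median(per_time$loss_W), E_eff = eff, per_time = per_time)
}

# median over finite values; errors (naming the feature) if none remain
median_finite <- function(x, feature) {
  v <- x[is.finite(x)]
  if (!length(v))
    abort(sprintf("all values non-finite for feature %s", feature))
  median(v)
}
max_finite <- function(x, feature) {
  v <- x[is.finite(x)]
  if (!length(v))
    abort(sprintf("all values non-finite for feature %s", feature))
  max(v)
}

#' Reduce indicator fields to the 19-feature vector
#'
#' Applies the reduction convention of the feature table: features without a
#' `_max` suffix are medians over their spatial and/or temporal dimensions
#' (time reduced first per point, then the spatial median); `_max` features
#' are maxima over all points and times. Velocities are converted from mm/s
#' to m/s, helicity to m/s^2, energy loss to W. `Reynolds_max` uses
#' `rho v_max D / mu` with `D` the reference (standardized) diameter.
#' Non-finite values are excluded from medians; an all-non-finite constituent
#' raises an error naming the feature.
#'
#' @param ind Named list of indicator arrays: `tawss`, `osi`, `transwss`,
#'   `wssg`, `rrt` (per-point vectors); `vorticity_mag`, `strain`, `helicity`,
#'   `speed` (points x times matrices, mm-based units); `pressure`
#'   (points x times, Pa).
#' @param ps Port series tibble from [port_series()].
#' @param energy Result of [energy_loss_efficiency()].
#' @param fluid A [fluid_properties()].
#' @param reference_diameter Characteristic diameter (mm) for the Reynolds
#'   number; 3 mm, the standardized inner diameter.
#' @return One-row tibble with the 19 named features.
#' @export
reduce_features <- function(ind, ps, energy, fluid = fluid_properties(),
                            reference_diameter = 3.0) {
  time_then_space <- function(m, feature) {
    if (is.null(dim(m))) return(median_finite(m, feature))
    per_point <- apply(m, 1, function(r) {
      v <- r[is.finite(r)]
      if (!length(v)) NA_real_ else median(v)
    })
    median_finite(per_point, feature)
  }
  port_stat <- function(name, col) {
    x <- ps[ps$port == name, ][[col]]
    if (!length(x)) return(0)  # absent second inlet: convention 0
    median_finite(x, paste0(name, ":", col))
  }
  dp_in1 <- if (any(ps$port == "in1"))
    median_finite(ps$p_bar[ps$port == "in1"] - ps$p_bar[ps$port == "out"],
                  "dp_in1-out") else 0
  dp_in2 <- if (any(ps$port == "in2"))
    median_finite(ps$p_bar[ps$port == "in2"] - ps$p_bar[ps$port == "out"],
                  "dp_in2-out") else 0
  v_max <- max_finite(ind$speed, "v_max") * 1e-3          # m/s
  rho <- fluid$density; mu <- fluid$viscosity
  out <- tibble::tibble(
    "WSS_trans" = median_finite(ind$transwss, "WSS_trans"),
    "WSSG" = median_finite(ind$wssg, "WSSG"),
    "dp_in2-out" = dp_in2,
    "Vorticity_max" = max_finite(ind$vorticity_mag, "Vorticity_max"),
    "TAWSS" = median_finite(ind$tawss, "TAWSS"),
    "Strain_max" = max_finite(ind$strain, "Strain_max"),
    "RRT" = median_finite(ind$rrt, "RRT"),
    "v_max" = v_max,
    "Helicity_max" = max_finite(ind$helicity, "Helicity_max") * 1e-3, # m/s^2
    "v_average" = time_then_space(ind$speed, "v_average") * 1e-3,     # m/s
    "E_loss" = energy$E_loss,
    "dp_in1-out" = dp_in1,
    "p_max" = max_finite(ind$pressure, "p_max"),
    "OSI" = median_finite(ind$osi, "OSI"),
    "E_eff" = energy$E_eff,
    "v_out" = port_stat("out", "v_bar") * 1e-3,           # m/s
    "Reynolds_max" = rho * v_max * (reference_diameter * 1e-3) / mu,
    "Q_in1" = port_stat("in1", "Q"),
    "Q_in2" = port_stat("in2", "Q")
  )
  out[FEATURE_NAMES]
}

#' Compute the full 19-feature vector from field series
#'
#' Convenience pipeline over the individual indicator operations: TAWSS, OSI,
#' transWSS, WSSG, RRT from the wall series; vorticity, helicity, strain
#' rate, port series and energy loss from the volume series; then the
#' median/max reduction of [reduce_features()].
#'
#' @param wall A `wall_shear_series`.
#' @param flow A `flow_field_series`.
#' @param fluid A [fluid_properties()].
#' @param reference_diameter Reference diameter (mm) for Reynolds.
#' @return One-row tibble with the 19 named features.
#' @export
#' @examples
#' m <- make_tube_mesh(1.5, 20, 8, 16)
#' f <- poiseuille_fields(m, Q = 500, n_r = 8, n_theta = 8, n_z = 4)
#' compute_features(f$wall, f$flow)
compute_features <- function(wall, flow, fluid = fluid_properties(),
                             reference_diameter = 3.0) {
  ta <- tawss(wall)
  os <- osi(wall)
  tw <- transwss(wall)
  gr <- wssg(ta, wall$mesh)
  rr <- rrt(ta, os)
  vh <- vorticity_and_helicity(flow)
  st <- strain_rate(flow)
  n <- nrow(flow$sample_points); nt <- length(flow$times)
  sp <- sqrt(flow$velocity[, , 1]^2 + flow$velocity[, , 2]^2 +
               flow$velocity[, , 3]^2)
  dim(sp) <- c(n, nt)
  ps <- port_series(flow)
  en <- energy_loss_efficiency(ps, fluid)
  reduce_features(
    list(tawss = ta, osi = os, transwss = tw, wssg = gr, rrt = rr,
         vorticity_mag = vh$vorticity_mag, strain = st,
         helicity = vh$helicity, speed = sp,
         pressure = flow$pressure),
    ps, en, fluid, reference_diameter
  )
}
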