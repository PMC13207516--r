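# Closed-form oracle checks for the wall-shear indicators. The rotating
# field with half-angle alpha has, by direct integration,
#   OSI      = (1 - sin(a)/a) / 2
#   transWSS = tau0 (1 - cos(a)) / a

test_that("TAWSS matches closed forms on analytic fields", {
  fl <- fix_fluid()
  f <- fix_poiseuille()
  tau_ref <- 4 * fl$viscosity * 500 / (pi * 1.5^3)
  expect_lt(max(abs(tawss(f$wall) / tau_ref - 1)), 1e-10)
  # constant-magnitude rotating field: TAWSS = tau0 exactly
  w <- oscillatory_wss_fields(fix_mesh(), 2.5, pi / 2, n_steps = 64)
  expect_lt(max(abs(tawss(w) - 2.5)), 1e-12)
})

test_that("OSI matches the sweep closed form and its conventions", {
  m <- fix_mesh()
  expect_equal(max(osi(fix_poiseuille()$wall)), 0)  # unidirectional
  w <- oscillatory_wss_fields(m, 2, pi / 2, n_steps = 256)
  expect_lt(max(abs(osi(w) - 0.5 * (1 - 2 / pi))), 1e-3)
  wf <- oscillatory_wss_fields(m, 2, pi, n_steps = 256)
  expect_lt(max(abs(osi(wf) - 0.5)), 1e-3)
})

test_that("transWSS matches the sweep closed form and flags degeneracy", {
  m <- fix_mesh()
  tw0 <- transwss(fix_poiseuille()$wall)
  expect_equal(max(tw0), 0)
  w <- oscillatory_wss_fields(m, 2, pi / 2, n_steps = 256)
  expect_lt(max(abs(transwss(w) - 2 * 2 / pi)), 1e-3 * 2)
  # full rotation: mean direction degenerate -> 0 with flag
  wf <- oscillatory_wss_fields(m, 2, pi, n_steps = 257)
  tw <- transwss(wf)
  expect_equal(max(tw), 0)
  expect_equal(attr(tw, "n_degenerate"), nrow(m$points))
})

test_that("RRT collapses correctly and flags infinities", {
  expect_equal(rrt(c(2, 4), c(0, 0)), c(0.5, 0.25), ignore_attr = TRUE)
  r <- rrt(c(2, 3), c(0.5, 0))
  expect_true(is.infinite(r[1]))
  expect_equal(attr(r, "n_infinite"), 1L)
  # sweep field: RRT = alpha / (tau0 sin(alpha)) = pi / (2 tau0)
  w <- oscillatory_wss_fields(fix_mesh(), 2, pi / 2, n_steps = 256)
  expect_lt(max(abs(rrt(tawss(w), osi(w)) - pi / (2 * 2))), 5e-3)
})

test_that("WSSG is exact for linear fields and frame-independent", {
  m <- make_tube_mesh(1.5, 20, 50, 32)
  expect_equal(max(wssg(rep(3, nrow(m$points)), m)), 0)
  b <- 0.25
  g <- wssg(1 + b * m$axial_coordinate, m)
  expect_lt(max(abs(g / b - 1)), 0.02)
  # rigid rotation of the mesh leaves the gradient magnitude unchanged
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$points <- m$points %*% Rz
  g2 <- wssg(1 + b * m$axial_coordinate, m2)
  expect_lt(max(abs(g - g2)), 1e-9)
})

test_that("velocity gradients reproduce rigid rotation and simple shear", {
  f <- fix_poiseuille(n_r = 6, n_theta = 8, n_z = 4)
  ff <- f$flow
  # rigid rotation v = Omega x r, Omega = (0, 0, 3): omega = 2 Omega
  ff$velocity[, 1, 1] <- -3 * ff$sample_points[, 2]
  ff$velocity[, 1, 2] <- 3 * ff$sample_points[, 1]
  ff$velocity[, 1, 3] <- 0
  vh <- vorticity_and_helicity(ff)
  expect_lt(max(abs(vh$vorticity_mag[, 1] - 6), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(strain_rate(ff)), na.rm = TRUE), 1e-6)  # antisymmetric
  # simple shear v_x = k y: gamma_dot = k, |omega| = k
  k <- 1.7
  ff$velocity[, 1, 1] <- k * ff$sample_points[, 2]
  ff$velocity[, 1, 2] <- 0
  expect_lt(max(abs(strain_rate(ff)[, 1] - k), na.rm = TRUE), 1e-6)
  # uniform translation: everything zero
  ff$velocity[, 1, ] <- 5
  expect_lt(max(abs(strain_rate(ff)), na.rm = TRUE), 1e-9)
  vh2 <- vorticity_and_helicity(ff)
  expect_lt(max(abs(vh2$vorticity_mag), na.rm = TRUE), 1e-9)
})

test_that("port series integrate flow rate and pressure accurately", {
  f <- fix_poiseuille(n_r = 24, n_theta = 32, n_z = 4)
  ps <- port_series(f$flow)
  expect_lt(abs(ps$Q[ps$port == "in1"][1] / 500 - 1), 0.01)
  # mass conservation across ports
  expect_lt(abs(ps$Q[ps$port == "in1"][1] - ps$Q[ps$port == "out"][1]),
            1e-9)
  # area-average of a z-linear pressure equals the section value
  fl <- fix_fluid()
  dp <- 8 * fl$viscosity * 20 * 500 / (pi * 1.5^4)
  expect_lt(abs(ps$p_bar[ps$port == "in1"][1] - dp), 1e-9)
  expect_equal(ps$p_bar[ps$port == "out"][1], 0)
})

test_that("energy loss matches Q * dp for steady Poiseuille and scales as
          Q^2", {
  fl <- fix_fluid()
  en <- lapply(c(300, 600), function(Q) {
    f <- poiseuille_fields(fix_mesh(), Q, fl, n_r = 24, n_theta = 16,
                           n_z = 4)
    energy_loss_efficiency(port_series(f$flow), fl)
  })
  dp300 <- 8 * fl$viscosity * 20 * 300 / (pi * 1.5^4)
  expect_lt(abs(en[[1]]$E_loss / (300 * dp300 * 1e-9) - 1), 0.01)
  expect_lt(abs(en[[2]]$E_loss / en[[1]]$E_loss - 4), 0.1)  # doubling Q
  # lossless plug flow: equal fluxes, E_eff = 1
  f <- fix_poiseuille(n_r = 6, n_theta = 8, n_z = 4)
  ff <- f$flow
  ff$velocity[, 1, 3] <- 100
  ff$pressure[, 1] <- 50
  en0 <- energy_loss_efficiency(port_series(ff), fl)
  expect_equal(en0$E_loss, 0)
  expect_equal(en0$E_eff, 1)
})

test_that("feature reduction has the 19 names and matches a flat-sort
          oracle", {
  f <- fix_poiseuille(n_r = 8, n_theta = 8, n_z = 4)
  fv <- compute_features(f$wall, f$flow, fix_fluid())
  expect_identical(names(fv), feature_names())
  expect_equal(fv$OSI, 0)
  expect_equal(fv$WSS_trans, 0)
  expect_equal(fv$RRT * fv$TAWSS, 1)
  expect_equal(fv[["dp_in2-out"]], 0)  # single-inlet convention
  expect_equal(fv$Q_in2, 0)
  # independent flat-sort oracle for the median and max reductions
  ta <- tawss(f$wall)
  expect_equal(fv$TAWSS, sort(ta)[ceiling(length(ta) / 2)], tolerance = 1e-12)
  vh <- vorticity_and_helicity(f$flow)
  flat <- sort(as.vector(vh$vorticity_mag[is.finite(vh$vorticity_mag)]),
               decreasing = TRUE)
  expect_equal(fv$Vorticity_max, flat[1], tolerance = 1e-12)
})

test_that("indicators obey scale covariance in the shear magnitude", {
  w <- oscillatory_wss_fields(fix_mesh(), 1.3, pi / 3, n_steps = 64)
  w2 <- w
  w2$wss <- w$wss * 7
  expect_equal(tawss(w2), 7 * tawss(w), tolerance = 1e-12)
  expect_equal(transwss(w2), 7 * transwss(w), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(osi(w2), osi(w), tolerance = 1e-12)
  expect_equal(rrt(tawss(w2), osi(w2)), rrt(tawss(w), osi(w)) / 7,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("time-grid refinement converges at second order", {
  m <- fix_mesh(n_axial = 3, n_circ = 8)
  ref <- 0.5 * (1 - sin(pi / 2) / (pi / 2))
  err <- sapply(c(64, 128, 256), function(ns)
    abs(mean(osi(oscillatory_wss_fields(m, 2, pi / 2, n_steps = ns))) - ref))
  # halving dt should cut the error by about 4; allow generous slack
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
})
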