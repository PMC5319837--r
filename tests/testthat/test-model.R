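test_that("astral potential is flat on the circle and 180-degree periodic", {
  circ <- mk_ellipse(10, 10, 0, n = 360)
  pp <- fraction_params()
  E0 <- placement_energy(circ, c(0, 0), 0, 8, pp)
  for (ang in c(13, 45, 90, 121)) {
    # flat up to the 360-gon's breaking of continuous rotational symmetry
    expect_equal(placement_energy(circ, c(0, 0), ang, 8, pp), E0,
                 tolerance = 1e-5)
  }
  blob <- mk_ellipse(15, 9, 20, n = 48)
  for (ang in c(0, 30, 77)) {
    expect_equal(placement_energy(blob, c(1, -1), ang, 6, pp),
                 placement_energy(blob, c(1, -1), ang + 180, 6, pp),
                 tolerance = 1e-12)
  }
  expect_error(placement_energy(blob, c(14, 0), 0, 6, pp), "infeasible")
})

test_that("astral potential is invariant under rigid motions of contour and placement", {
  blob <- mk_ellipse(14, 8, 0, n = 48)
  pp <- fraction_params(n_rays = 720)  # fine fan: lab-frame anisotropy vanishes
  E0 <- placement_energy(blob, c(2, 1), 25, 6, pp)
  for (rot in c(18, 60, 143)) {
    v2 <- sweep(blob$vertices %*% t(rot2(rot)), 2, c(-7, 4), `+`)
    ct2 <- contour2d(v2)
    c2 <- as.numeric(c(2, 1) %*% t(rot2(rot))) + c(-7, 4)
    expect_equal(placement_energy(ct2, c2, 25 + rot, 6, pp), E0,
                 tolerance = 1e-4 * abs(E0))
  }
})

test_that("net force and torque behave mechanically", {
  ell <- mk_ellipse(20, 10, 0, n = 96)
  pp <- fraction_params()
  # centered along an axis of symmetry: zero net force and torque
  f0 <- placement_force(ell, c(0, 0), 0, 8, pp)
  expect_equal(unname(f0["Fx"]), 0, tolerance = 1e-6 * f0[["potential"]])
  expect_equal(unname(f0["torque"]), 0, tolerance = 1e-6 * f0[["potential"]])
  # off-axis placement: torque rotates the spindle toward the long axis
  f30 <- placement_force(ell, c(0, 0), 30, 8, pp)
  expect_lt(f30[["torque"]], 0)
  # mirror symmetry: mirrored orientation has opposite torque
  fm <- placement_force(ell, c(0, 0), -30, 8, pp)
  expect_equal(fm[["torque"]], -f30[["torque"]], tolerance = 1e-9)
  # force restores a decentred spindle
  fr <- placement_force(ell, c(5, 0), 0, 8, pp)
  expect_lt(fr[["Fx"]], 0)
})

test_that("energy landscape has its minimum at the long axis with consistent torque", {
  ell <- mk_ellipse(16, 8, 40, n = 64)
  ls <- energy_landscape(ell, 6, fraction_params())
  expect_false(ls$degenerate)
  expect_equal(ls$angles[which.min(ls$energies)], 40, tolerance = 1)
  expect_equal(max(ls$energies), 0)
  # landscape torque operation reproduces the scanned torques
  tq <- torque(ls)
  taut <- ls$torques - mean(ls$torques)
  inner <- 2:(length(taut) - 1)
  expect_equal(tq$torque[inner],
               (taut[inner - 1] + 2 * taut[inner] + taut[inner + 1]) / 4,
               tolerance = 1e-6 * max(abs(taut)))
  # net rotational work over the period is zero by construction
  dth <- diff(ls$angles[1:2]) * pi / 180
  expect_equal(sum(tq$torque) * dth, 0, tolerance = 1e-8 * max(abs(ls$energies)))

  circ <- mk_ellipse(10, 10, 0, n = 128)
  lc <- energy_landscape(circ, 6, fraction_params())
  expect_true(lc$degenerate)
  expect_lt(max(abs(lc$torques)), 1e-4 * mean(lc$potentials))
})

test_that("prediction recovers ellipse axes and centers, circle flagged degenerate", {
  for (ang in c(0, 25, 90, 154)) {
    ell <- mk_ellipse(20, 10, ang, n = 48)
    p <- predict_spindle(ell, params = fraction_params())
    expect_false(p$degenerate)
    expect_lt(axial_difference(axis_angle(p$axis), ang), 1)
    expect_lt(sqrt(sum(axis_center(p$axis)^2)), 0.4)  # 1% of the 40 um axis
  }
  circ <- mk_ellipse(10, 10, 0, n = 64)
  pc <- predict_spindle(circ, params = fraction_params())
  expect_true(pc$degenerate)
})

test_that("observed spindle length is used and clamped to fit the cell", {
  ell <- mk_ellipse(15, 9, 0, n = 48)
  obs <- spindle_axis(c(-4, 0.5), c(4, -0.5))
  p <- predict_spindle(ell, observed = obs, params = model_params())
  expect_equal(axis_length(p$axis), axis_length(obs), tolerance = 1e-9)
  # a spindle longer than the minor width is shrunk until it fits everywhere
  long_obs <- spindle_axis(c(-13, 0), c(13, 0))
  p2 <- predict_spindle(ell, observed = long_obs, params = model_params())
  expect_lt(axis_length(p2$axis), 18)
  expect_true(all(spindle2d:::points_inside(ell, rbind(p2$axis$pole_a, p2$axis$pole_b))))
  expect_error(predict_spindle(ell, params = model_params()), "observed")
})

test_that("predictions are equivariant under rotation and translation", {
  cts <- make_contours(6, family = "fourier_blob", aspect_range = c(1.4, 2.5),
                       size_range = c(18, 26), seed = 21)
  pp <- fraction_params()
  for (ct in cts[1:4]) {
    base <- axis_angle(predict_spindle(ct, params = pp)$axis)
    for (rot in c(22.5, 90, 137)) {
      v2 <- sweep(ct$vertices %*% t(rot2(rot)), 2, c(11, -6), `+`)
      p2 <- predict_spindle(contour2d(v2), params = pp)
      expect_lt(axial_difference(axis_angle(p2$axis), (base + rot) %% 180), 0.5)
    }
  }
})

test_that("predicted orientation is scale-invariant", {
  cts <- make_contours(4, family = "fourier_blob", aspect_range = c(1.4, 2.5),
                       size_range = c(18, 26), seed = 22)
  pp <- fraction_params()
  for (ct in cts) {
    a1 <- axis_angle(predict_spindle(ct, params = pp)$axis)
    a2 <- axis_angle(predict_spindle(contour2d(ct$vertices * 2.7), params = pp)$axis)
    expect_lt(axial_difference(a1, a2), 0.5)
  }
})

test_that("prediction is stable under grid refinement", {
  cts <- make_contours(5, family = "fourier_blob", aspect_range = c(1.3, 2.5),
                       size_range = c(18, 26), seed = 23)
  for (ct in cts) {
    a0 <- axis_angle(predict_spindle(ct, params = fraction_params())$axis)
    a_rays <- axis_angle(predict_spindle(ct, params = fraction_params(n_rays = 720))$axis)
    a_grid <- axis_angle(predict_spindle(ct, params = fraction_params(dtheta = 0.25))$axis)
    expect_lt(axial_difference(a0, a_rays), 1)
    expect_lt(axial_difference(a0, a_grid), 1)
  }
})

test_that("centroid center mode stays at the centroid", {
  ell <- mk_ellipse(18, 10, 65, n = 48, center = c(4, 9))
  p <- predict_spindle(ell, params = fraction_params(center_mode = "centroid"))
  expect_equal(unname(axis_center(p$axis)), c(4, 9), tolerance = 1e-6)
  expect_lt(axial_difference(axis_angle(p$axis), 65), 1)
})

test_that("landscape CSV export matches the landscape", {
  ell <- mk_ellipse(15, 9, 10, n = 48)
  ls <- energy_landscape(ell, 5, fraction_params())
  f <- tempfile(fileext = ".csv")
  write_landscape_csv(ls, f)
  d <- read.csv(f)
  expect_equal(d$theta_deg, ls$angles)
  expect_equal(d$energy, ls$energies, tolerance = 1e-9)
})
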