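test_that("area and centroid match closed forms and are orientation-invariant", {
  sq <- contour2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  ac <- area_centroid(sq)
  expect_equal(ac$area, 1)
  expect_equal(unname(ac$centroid), c(0.5, 0.5))

  sq_cw <- contour2d(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_equal(area_centroid(sq_cw), ac)

  ell <- mk_ellipse(20, 10, 30, n = 256, center = c(3, -2))
  ac2 <- area_centroid(ell)
  expect_equal(ac2$area, pi * 20 * 10, tolerance = 1e-3)
  expect_equal(unname(ac2$centroid), c(3, -2), tolerance = 1e-6)
})

test_that("invalid contours are rejected", {
  expect_error(contour2d(rbind(c(0, 0), c(1, 0), c(2, 0))), "at least 4")
  expect_error(contour2d(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))), "zero enclosed area")
  crossed <- rbind(c(0, 0), c(4, 0), c(1, 3), c(3, 3))  # edges 2 and 4 cross
  expect_error(contour2d(crossed), "self-intersecting")
})

test_that("polygon area agrees with a Monte-Carlo point-in-polygon estimate", {
  set.seed(99)
  v <- NULL
  repeat {
    t <- sort(runif(12, 0, 2 * pi))
    r <- runif(12, 6, 14)
    v <- cbind(r * cos(t), r * sin(t))
    ok <- tryCatch({ ct <- contour2d(v); TRUE }, error = function(e) FALSE)
    if (ok) break
  }
  ac <- area_centroid(ct)
  n_mc <- 1e6
  pts <- cbind(runif(n_mc, -14, 14), runif(n_mc, -14, 14))
  inside <- spindle2d:::points_inside(ct, pts, margin = 0)
  mc_area <- mean(inside) * 28^2
  expect_equal(ac$area, mc_area, tolerance = 0.01)
})

test_that("principal axes recover orientation, aspect and degeneracy", {
  r <- principal_axes(mk_rect(2, 1))
  expect_equal(r$angle_major, 0, tolerance = 1e-8)
  expect_equal(r$aspect_ratio, 2, tolerance = 1e-8)

  e <- principal_axes(mk_ellipse(30, 15, 37, n = 128))
  expect_equal(e$angle_major, 37, tolerance = 0.5)
  expect_equal(e$aspect_ratio, 2, tolerance = 0.01)
  expect_equal(e$length_major, 60, tolerance = 0.5)

  circ <- principal_axes(mk_ellipse(10, 10, 0, n = 64))
  expect_true(circ$degenerate)
  expect_true(is.na(circ$angle_major))
})

test_that("geometry descriptors are invariant to rigid motions and scaling", {
  set.seed(4)
  base <- mk_ellipse(18, 9, 14, n = 60)
  for (i in 1:5) {
    ang <- runif(1, 0, 180)
    shift <- runif(2, -30, 30)
    s <- runif(1, 0.5, 3)
    v2 <- sweep(base$vertices %*% t(rot2(ang)), 2, shift, `+`)
    moved <- contour2d(v2)
    scaled <- contour2d(base$vertices * s)
    expect_equal(area_centroid(moved)$area, area_centroid(base)$area,
                 tolerance = 1e-9)
    pa0 <- principal_axes(base); pam <- principal_axes(moved)
    expect_equal(axial_difference(pam$angle_major, (pa0$angle_major + ang) %% 180),
                 0, tolerance = 1e-6)
    expect_equal(pam$aspect_ratio, pa0$aspect_ratio, tolerance = 1e-9)
    expect_equal(principal_axes(scaled)$angle_major, pa0$angle_major,
                 tolerance = 1e-9)
    expect_equal(principal_axes(scaled)$aspect_ratio, pa0$aspect_ratio,
                 tolerance = 1e-9)
  }
})

test_that("ray casting matches closed forms and the exhaustive oracle", {
  sq <- contour2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(ray_to_boundary(sq, c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(ray_to_boundary(sq, c(0.5, 0.5), c(0, -1)), 0.5)

  # circle: |o + L d| = r closed form
  circ <- mk_ellipse(7, 7, 0, n = 720)
  o <- c(2, -1)
  for (ang in c(0, 33, 90, 201)) {
    d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    L <- ray_to_boundary(circ, o, d)
    q <- -sum(o * d) + sqrt(sum(o * d)^2 - (sum(o^2) - 49))
    expect_equal(L, q, tolerance = 1e-3)
  }

  # non-convex: first hit equals the independent plain-R edge-scan oracle
  L_shape <- mk_lshape(10)
  set.seed(8)
  for (i in 1:20) {
    o <- c(runif(1, 1, 9), runif(1, 1, 9))  # inside the lower-left block
    ang <- runif(1, 0, 2 * pi)
    d <- c(cos(ang), sin(ang))
    expect_equal(ray_to_boundary(L_shape, o, d), ray_oracle(L_shape, o, d),
                 tolerance = 1e-9)
  }
  # a ray crossing the notch must stop at the first boundary
  expect_equal(ray_to_boundary(L_shape, c(5, 5), c(cos(pi / 4), sin(pi / 4))),
               ray_oracle(L_shape, c(5, 5), c(cos(pi / 4), sin(pi / 4))),
               tolerance = 1e-12)

  expect_error(ray_to_boundary(sq, c(2, 2), c(1, 0)), "strictly inside")
  expect_error(ray_to_boundary(sq, c(0, 0.5), c(1, 0)), "strictly inside")
})

test_that("convex chords through the centroid equal oracle chord lengths", {
  ct <- mk_ellipse(15, 8, 25, n = 64)
  ctr <- area_centroid(ct)$centroid
  for (ang in seq(5, 175, by = 30)) {
    d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    chord <- ray_to_boundary(ct, ctr, d) + ray_to_boundary(ct, ctr, -d)
    chord_oracle <- ray_oracle(ct, ctr, d) + ray_oracle(ct, ctr, -d)
    expect_equal(chord, chord_oracle, tolerance = 1e-9)
  }
})

test_that("contour CSV round trip preserves vertices", {
  ct <- mk_ellipse(12, 8, 40, n = 32)
  f <- tempfile(fileext = ".csv")
  write_contour_csv(ct, f)
  back <- read_contour_csv(f)
  expect_equal(back$vertices, ct$vertices, tolerance = 1e-12)
})
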