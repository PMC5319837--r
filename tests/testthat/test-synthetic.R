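test_that("contour generator records recoverable ground truth", {
  cts <- make_contours(8, family = "ellipse", aspect_range = c(2, 2),
                       size_range = c(24, 24), seed = 41)
  truth <- attr(cts, "truth")
  for (i in seq_along(cts)) {
    pa <- principal_axes(cts[[i]])
    expect_lt(axial_difference(pa$angle_major, truth$angle[i]), 0.5)
    expect_equal(pa$aspect_ratio, 2, tolerance = 0.01)
  }
})

test_that("fourier blobs reduce to their base ellipse at zero noise", {
  a <- make_contours(5, family = "fourier_blob", fourier_noise = 0, seed = 42)
  truth <- attr(a, "truth")
  for (i in 1:5) {
    base <- mk_ellipse(truth$length_major[i] / 2,
                       truth$length_major[i] / 2 / truth$aspect[i],
                       truth$angle[i], n = nrow(a[[i]]$vertices))
    expect_equal(area_centroid(a[[i]])$area, area_centroid(base)$area,
                 tolerance = 1e-9)
    expect_equal(a[[i]]$vertices, base$vertices, tolerance = 1e-9)
  }
})

test_that("generated contours always satisfy the contour invariants", {
  cts <- make_contours(100, family = "fourier_blob", fourier_noise = 0.06,
                       seed = 43)
  expect_length(cts, 100)
  for (ct in cts) {
    expect_s3_class(ct, "contour2d")  # constructor enforces the invariants
    expect_gt(area_centroid(ct)$area, 0)
  }
})

test_that("generators are pure functions of their seed", {
  a <- make_contours(6, seed = 44)
  b <- make_contours(6, seed = 44)
  expect_identical(lapply(a, `[[`, "vertices"), lapply(b, `[[`, "vertices"))
  o1 <- synthesize_observations(a, angular_noise_sd = 10,
                                rotating_fraction = 0.5, seed = 45)
  o2 <- synthesize_observations(b, angular_noise_sd = 10,
                                rotating_fraction = 0.5, seed = 45)
  expect_identical(o1$ground_truth, o2$ground_truth)
  expect_identical(lapply(o1$cells, `[[`, "observed"),
                   lapply(o2$cells, `[[`, "observed"))
  t1 <- make_timing_data(seed = 46)
  expect_identical(t1, make_timing_data(seed = 46))
  # the caller's RNG stream is untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(make_contours(2, seed = 9)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noise-free observations are recovered exactly by the pipeline", {
  cts <- make_contours(6, aspect_range = c(1.5, 2.5), seed = 47)
  obs <- synthesize_observations(cts, angular_noise_sd = 0,
                                 rotating_fraction = 0, center_noise_sd = 0,
                                 seed = 48)
  an <- suppressWarnings(  # near-zero deviations tie in the exact KS test
    run_analysis(obs$cells, run_config(model = fraction_params(), seed = 48)))
  expect_true(all(an$table$orienting_deg < 1))
  expect_true(all(an$table$centering_pct < 0.5))
})

test_that("axial noise shows up as the folded-normal mean deviation", {
  cts <- make_contours(60, aspect_range = c(1.3, 3), seed = 49)
  obs <- synthesize_observations(cts, angular_noise_sd = 15, seed = 50)
  an <- run_analysis(obs$cells, run_config(model = fraction_params(), seed = 50))
  meta <- an$table[an$table$phase == "metaphase", ]
  expect_equal(mean(meta$orienting_deg), 15 * sqrt(2 / pi), tolerance = 0.2)
})

test_that("planted rotating cells separate prophase from metaphase deviations", {
  cts <- make_contours(60, aspect_range = c(1.3, 3), seed = 51)
  obs <- synthesize_observations(cts, angular_noise_sd = 5,
                                 rotating_fraction = 0.4, seed = 52)
  gt <- obs$ground_truth
  an <- run_analysis(obs$cells, run_config(model = fraction_params(), seed = 52))
  pro <- an$table[an$table$phase == "prophase", ]
  meta <- an$table[an$table$phase == "metaphase", ]
  rot <- gt$rotates[match(sub("_prophase", "", pro$cell_id), paste0(gt$label))]
  # rotators have large prophase deviations, non-rotators do not
  expect_gt(mean(pro$orienting_deg[rot] > 30), 0.9)
  expect_lt(mean(pro$orienting_deg[!rot] > 30), 0.1)
  expect_gt(mean(meta$orienting_deg < 20), 0.9)
})

test_that("labeled test meshes match their planted partitions", {
  for (f in c(0.1, 0.3, 0.5)) {
    m <- make_labeled_mesh("icosphere", "cap_fraction", cap_fraction = f,
                           subdivisions = 3)
    expect_equal(apical_surface_ratio(m), f, tolerance = 0.05)
  }
  gt <- attr(make_labeled_mesh("icosphere", "hemisphere"), "ground_truth")
  expect_equal(gt$plane_normal, c(0, 0, 1))
  expect_null(attr(make_labeled_mesh("icosphere", "random", subdivisions = 2,
                                     seed = 3), "ground_truth"))
})

test_that("timing generator recovers the planted asynchrony", {
  hits15 <- hits7 <- 0
  for (s in 1:40) {
    t15 <- make_timing_data(dt = 15, jitter_sd = 1, n_per_group = 10, seed = s)
    if (abs(asynchrony(t15$animal, t15$vegetal) - 15) <= 1) hits15 <- hits15 + 1
    t7 <- make_timing_data(dt = 7, jitter_sd = 1, n_per_group = 10, seed = s)
    d7 <- asynchrony(t7$animal, t7$vegetal)
    if (d7 >= 6 && d7 <= 8) hits7 <- hits7 + 1
  }
  expect_gte(hits15 / 40, 0.95)
  expect_gte(hits7 / 40, 0.9)
  t0 <- make_timing_data(dt = 0, jitter_sd = 1, n_per_group = 20, seed = 77)
  expect_lt(abs(asynchrony(t0$animal, t0$vegetal)), 1.5)
  expect_gt(group_compare(t0$animal, t0$vegetal, "t_two_tailed")$p, 0.05)
})
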