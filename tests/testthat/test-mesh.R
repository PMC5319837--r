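test_that("mesh volume, area and sphericity match closed forms", {
  cube <- make_labeled_mesh("box", "hemisphere", radius = 0.5)  # unit cube
  va <- mesh_volume_area(cube)
  expect_equal(va$volume, 1)
  expect_equal(va$area, 6)
  expect_equal(sphericity(cube), (pi / 6)^(1 / 3), tolerance = 1e-12)

  ico <- make_labeled_mesh("icosphere", "hemisphere", radius = 1, subdivisions = 4)
  va <- mesh_volume_area(ico)
  expect_equal(va$volume, 4 * pi / 3, tolerance = 0.01)
  expect_equal(va$area, 4 * pi, tolerance = 0.01)
  expect_gte(sphericity(ico), 0.995)

  ellip <- make_labeled_mesh("ellipsoid", "hemisphere", radius = 1, subdivisions = 4)
  expect_equal(mesh_volume_area(ellip)$volume, 4 * pi / 3 * 2, tolerance = 0.01)
})

test_that("sphericity is scale-invariant and maximal for the sphere", {
  ico3 <- make_labeled_mesh("icosphere", "hemisphere", radius = 2, subdivisions = 3)
  big <- labeled_mesh(ico3$vertices * 17.3, ico3$faces, ico3$face_label)
  expect_equal(sphericity(big), sphericity(ico3), tolerance = 1e-9)

  flat <- make_labeled_mesh("flattened", "hemisphere", radius = 2, subdivisions = 3)
  box <- make_labeled_mesh("box", "hemisphere", radius = 2)
  expect_lt(sphericity(flat), sphericity(ico3))
  expect_lt(sphericity(box), sphericity(ico3))
})

test_that("apical surface ratio follows the face labeling", {
  hemi <- make_labeled_mesh("icosphere", "hemisphere", subdivisions = 4)
  expect_equal(apical_surface_ratio(hemi), 0.5, tolerance = 0.02)

  all_ap <- labeled_mesh(hemi$vertices, hemi$faces, "apical")
  expect_equal(apical_surface_ratio(all_ap), 1.0)

  cube <- make_labeled_mesh("box", "hemisphere", radius = 1)
  one_face <- ifelse(seq_len(12) %in% c(3, 4), "apical", "basolateral")  # +z face
  cube1 <- labeled_mesh(cube$vertices, cube$faces, one_face)
  expect_equal(apical_surface_ratio(cube1), 1 / 6, tolerance = 1e-12)

  cap <- make_labeled_mesh("icosphere", "cap_fraction", cap_fraction = 0.2,
                           subdivisions = 4)
  expect_equal(apical_surface_ratio(cap), 0.2, tolerance = 0.02)

  expect_error(labeled_mesh(cube$vertices, cube$faces, rep("apex", 12)),
               "apical")
})

test_that("non-watertight and inconsistent meshes are rejected with diagnostics", {
  ico <- make_labeled_mesh("icosphere", "hemisphere", subdivisions = 2)
  open_mesh <- tryCatch(
    labeled_mesh(ico$vertices, ico$faces[-1, ], ico$face_label[-1]),
    error = function(e) conditionMessage(e))
  expect_match(open_mesh, "not watertight")
  expect_match(open_mesh, "3 open edges")

  flipped <- ico$faces
  flipped[2, ] <- flipped[2, c(1, 3, 2)]
  expect_error(labeled_mesh(ico$vertices, flipped, ico$face_label),
               "inconsistently wound")
})

test_that("apical plane extraction recovers planted separating planes", {
  m <- make_labeled_mesh("icosphere", "hemisphere", radius = 10, subdivisions = 4)
  poles <- rbind(c(-5, 0, 0), c(5, 0, 0))
  ap <- extract_apical_plane(m, poles)
  ang_err <- acos(min(1, abs(sum(ap$plane$normal * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang_err, 2)
  expect_gte(ap$plane$separation_score, 0.98)
  # cross-section of the sphere through a diameter: radius-10 circle
  expect_equal(area_centroid(ap$contour)$area, pi * 100, tolerance = 0.01)
  expect_equal(axis_length(ap$poles2d), 10)

  # labels rotated 30 degrees about the pole axis -> plane rotates with them
  fc <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
           m$vertices[m$faces[, 3], ]) / 3
  rot <- 30 * pi / 180
  lab <- ifelse(fc[, 3] * cos(rot) - fc[, 2] * sin(rot) > 0, "apical", "basolateral")
  m2 <- labeled_mesh(m$vertices, m$faces, lab)
  ap2 <- extract_apical_plane(m2, poles)
  want <- c(0, -sin(rot), cos(rot))
  ang_err2 <- acos(min(1, abs(sum(ap2$plane$normal * want)))) * 180 / pi
  expect_lt(ang_err2, 2)
  expect_gte(ap2$plane$separation_score, 0.99)

  # random labels: no planar signal
  mr <- make_labeled_mesh("icosphere", "random", subdivisions = 3, seed = 5)
  expect_warning(apr <- extract_apical_plane(mr, poles), "low separation")
  expect_lt(apr$plane$separation_score, 0.6)

  expect_error(extract_apical_plane(m, rbind(c(1, 1, 1), c(1, 1, 1))),
               "coincident")
})

test_that("OFF and PLY round trips preserve geometry and labels", {
  m <- make_labeled_mesh("icosphere", "cap_fraction", cap_fraction = 0.3,
                         subdivisions = 2, radius = 4)
  off <- tempfile(fileext = ".off")
  write_off(m, off)
  back <- read_labeled_mesh(off, label_path = paste0(off, ".labels.csv"))
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$faces, m$faces)
  expect_equal(back$face_label, m$face_label)

  ply <- tempfile(fileext = ".ply")
  write_ply(m, ply)
  back2 <- read_labeled_mesh(ply)
  expect_equal(back2$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back2$face_label, m$face_label)
})

test_that("binary little-endian PLY with a face label property is read", {
  m <- make_labeled_mesh("box", "hemisphere", radius = 1)
  path <- tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices",
               "property int label", "end_header"), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
    writeBin(as.integer(m$face_label[i] == "apical"), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- read_labeled_mesh(path)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$faces, m$faces)
  expect_equal(back$face_label, m$face_label)
})
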