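test_that("enclosed volume and area match closed forms on lofted solids", {
  tube <- tube_surface(2, 10, n_theta = 96, spacing = 0.5)
  expect_true(is_watertight(tube))
  # 96-gon cross-section: area deficit is the polygon-vs-circle factor
  poly_factor <- 96 / (2 * pi) * sin(2 * pi / 96)
  expect_equal(mesh_volume(tube), pi * 4 * 10 * poly_factor,
               tolerance = 1e-3)
  expect_lt(abs(mesh_volume(tube) - pi * 4 * 10) / (pi * 4 * 10), 0.01)
})

test_that("watertightness detects open and non-manifold surfaces", {
  tube <- tube_surface(2, 5)
  expect_true(is_watertight(tube))
  open <- surface_mesh(tube$vertices, tube$faces[-1, , drop = FALSE])
  expect_false(is_watertight(open))
  dup <- surface_mesh(tube$vertices, rbind(tube$faces, tube$faces[1, ]))
  expect_false(is_watertight(dup))
})

test_that("STL writes and reads back watertight in both dialects", {
  tube <- tube_surface(1.5, 4, n_theta = 24, spacing = 1)
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_stl(tube, path, binary = binary)
    back <- read_stl(path, name = "lumen")
    expect_true(is_watertight(back))
    expect_equal(mesh_volume(back), mesh_volume(tube),
                 tolerance = if (binary) 1e-5 else 1e-7)
    unlink(path)
  }
})

test_that("point containment and signed distance agree with geometry", {
  tube <- tube_surface(2, 10, n_theta = 64, spacing = 0.5)
  pts <- rbind(c(0, 0, 5), c(1.5, 0, 5), c(2.5, 0, 5), c(0, 0, 11))
  expect_equal(as.vector(points_in_mesh(pts, tube)),
               c(TRUE, TRUE, FALSE, FALSE))
  sd <- signed_distance(pts, tube)
  expect_equal(sd[2], -0.5, tolerance = 0.01)
  expect_equal(sd[3], 0.5, tolerance = 0.01)
  expect_lt(sd[1], 0)
})

test_that("planar slicing recovers cross-section area and topology", {
  tube <- tube_surface(2, 10, n_theta = 96, spacing = 0.5)
  polys <- slice_mesh_z(tube, 5.1)
  expect_length(polys, 1)
  expect_equal(polygon_area(polys[[1]]), pi * 4, tolerance = 0.01)
  # plane tangent to a convex surface: degenerate contour dropped
  blob <- random_blob(5, n = 60, axes = c(1, 1, 1))
  ztop <- max(blob$vertices[, 3])
  expect_length(slice_mesh_z(blob, ztop - 1e-6), 0)
  # bifurcated lumen above the split yields two contours
  an <- make_anatomy(1, small_params())
  two <- slice_mesh_z(an$lumen, 25.2)
  expect_length(two, 2)
})

test_that("closest-point query matches a brute-force oracle", {
  blob <- random_blob(7, n = 40)
  set.seed(11)
  pts <- matrix(runif(60, -3, 3), ncol = 3)
  fast <- mesh_closest(pts, blob)$dist
  slow <- brute_mesh_dist(pts, blob)
  expect_equal(fast, slow, tolerance = 1e-9)
})
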