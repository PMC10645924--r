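test_that("lofting concentric circles reproduces cylinder volume", {
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  stations <- lapply(seq(0, 6, by = 1), function(z)
    list(z = z, contours = list(cbind(2 * cos(th), 2 * sin(th)))))
  tube <- loft_stations(stations, fillet_radius = 0)
  expect_true(is_watertight(tube))
  expect_equal(mesh_volume(tube), pi * 4 * 6, tolerance = 0.01)
  # identical contours: an extrusion (all cross-sections congruent)
  areas <- vapply(seq(0.5, 5.5, by = 1), function(z)
    polygon_area(slice_mesh_z(tube, z)[[1]]), 0)
  expect_lt(diff(range(areas)), 1e-6)
})

test_that("wall solid volume equals outer minus inner (Boolean difference)", {
  inner <- tube_surface(3, 8, n_theta = 64, spacing = 0.5)
  outer <- tube_surface(3.9, 8, n_theta = 64, spacing = 0.5)
  wall <- build_wall_solid(inner, outer)
  expect_true(is_watertight(wall))
  expect_equal(mesh_volume(wall), pi * (3.9^2 - 9) * 8, tolerance = 0.01)
  # volume additivity: wall + inner = outer
  expect_equal(mesh_volume(wall) + mesh_volume(inner), mesh_volume(outer),
               tolerance = 1e-6)
  # coincident surfaces leave no volume and are rejected
  expect_error(build_wall_solid(inner, inner), "does not enclose")
})

test_that("healthy lumen inverts the 30% enlargement rule", {
  recs <- lapply(seq(0, 6, by = 1), function(z)
    list(z = z, branch = "CCA", poly = circle_poly(2.6, n = 96)))
  stack <- carofem:::contour_stack(recs, 1)
  healthy <- build_healthy_lumen(stack, shrink = 1.3, fillet_radius = 0)
  expect_true(is_watertight(healthy))
  polys <- slice_mesh_z(healthy, 3.2)
  expect_equal(equivalent_radius(polys[[1]]), 2.0, tolerance = 0.01)
})

test_that("fibrous fill of an annular stenosis matches the closed form", {
  # stenotic lumen r = 2 inside a healthy lumen r = 3 over the full length:
  # the gap is the annulus pi (3^2 - 2^2) L
  healthy <- tube_surface(3, 8, n_theta = 64, spacing = 0.5)
  stenotic <- tube_surface(2, 8, n_theta = 64, spacing = 0.5)
  fib <- build_fibrous_component(healthy, stenotic, spacing = 0.5)
  expect_true(is_watertight(fib))
  L_eff <- 8 - 2 * 0.5   # stations are inset one spacing from each end
  expect_equal(mesh_volume(fib), pi * (9 - 4) * L_eff, tolerance = 0.03)
})

test_that("full reconstruction conserves volume and containment", {
  an <- make_anatomy(4, small_params(), list(small_stenosis()))
  wm <- reconstruct_wall(an$lumen, an$components, an$centerlines)
  expect_true(is_watertight(wm$wall_solid))
  expect_true(is_watertight(wm$healthy_lumen))
  expect_true(is_watertight(wm$fibrous))
  # Boolean bookkeeping: wall = outer - inner
  expect_equal(mesh_volume(wm$wall_solid),
               mesh_volume(wm$outer) - mesh_volume(wm$inner),
               tolerance = 0.02)
  # healthy lumen contains the stenotic lumen (away from the cut ends)
  V <- an$lumen$vertices
  zin <- V[, 3] > 1.5 & V[, 3] < 28.5
  excess <- signed_distance(V[zin, ][seq(1, sum(zin), by = 5), ],
                            wm$healthy_lumen)
  expect_lt(max(excess), 0.15)
  expect_gte(mesh_volume(wm$healthy_lumen), mesh_volume(wm$inner))
  # set algebra: components inside the gap cannot exceed it
  v_gap <- mesh_volume(wm$healthy_lumen) - mesh_volume(wm$inner)
  v_parts <- mesh_volume(wm$fibrous) +
    sum(vapply(an$components, mesh_volume, 0))
  expect_lt(v_parts, v_gap * 1.1 + 5)
})

test_that("a healthy vessel reconstructs with an empty fibrous component", {
  an <- make_anatomy(4, small_params())
  wm <- reconstruct_wall(an$lumen, list(), an$centerlines)
  expect_true(carofem:::is_empty_mesh(wm$fibrous))
  # healthy lumen tracks the lumen; the convex per-section merge inflates
  # the bifurcation crotch slightly, a straight vessel agrees within 2%
  expect_equal(mesh_volume(wm$healthy_lumen), mesh_volume(wm$inner),
               tolerance = 0.05)
  tube <- tube_surface(3, 10, n_theta = 64, spacing = 0.5)
  wt <- reconstruct_wall(tube, list(), NULL)
  expect_true(carofem:::is_empty_mesh(wt$fibrous))
  expect_equal(mesh_volume(wt$healthy_lumen), mesh_volume(wt$inner),
               tolerance = 0.02)
})

test_that("reconstructed fibrous recovers the generator ground truth", {
  an <- make_anatomy(11, small_params(), list(small_stenosis()))
  wm <- reconstruct_wall(an$lumen, an$components, an$centerlines)
  rep <- signed_distance_report(an$reference_fibrous, wm$fibrous)
  expect_lt(mean(abs(rep$distances)), 0.5)
})
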