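test_that("hull of a tetrahedron is the tetrahedron (determinant volume)", {
  tet <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
  hull <- convex_hull_3d(tet)
  expect_equal(nrow(hull$faces), 4)
  v_det <- abs(det(rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                         tet[4, ] - tet[1, ]))) / 6
  expect_equal(mesh_volume(hull), v_det, tolerance = 1e-12)
})

test_that("hull encloses every input point and is watertight", {
  set.seed(3)
  pts <- matrix(rnorm(600), ncol = 3)
  hull <- convex_hull_3d(pts)
  expect_true(is_watertight(hull))
  sd <- signed_distance(pts, hull)
  expect_true(all(sd <= 1e-7))
})

test_that("plaque envelope bridges separated components", {
  cube <- function(origin) {
    v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    convex_hull_3d(sweep(v, 2, origin, "+"))
  }
  c1 <- cube(c(0, 0, 0)); c2 <- cube(c(3, 0, 0))
  hull <- plaque_hull(list(c1, c2))
  expect_gt(mesh_volume(hull), 2)           # fills the 2 mm gap
  expect_identical(hull$name, "plaque_hull")
  # single convex component: hull volume equals the component volume
  single <- plaque_hull(list(c1))
  expect_equal(mesh_volume(single), 1, tolerance = 1e-9)
})

test_that("coplanar input is rejected with an explanatory error", {
  flat <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_error(convex_hull_3d(flat), "coplanar")
})
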