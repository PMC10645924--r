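test_that("shoelace area, centroid and equivalent radius are exact on squares", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(polygon_area(sq), 4)
  expect_equal(polygon_centroid(sq), c(1, 1))
  expect_equal(equivalent_radius(sq), sqrt(4 / pi))
  expect_equal(polygon_area(sq[4:1, ]), -4)   # orientation flips the sign
})

test_that("per-plane merge is the convex hull of all contour vertices", {
  lumen <- circle_poly(2)
  inside <- circle_poly(0.5, n = 16, center = c(0.5, 0))
  expect_equal(polygon_area(merge_lumen_plaque(lumen, list(inside))),
               polygon_area(convex_hull_2d(lumen)))
  blob <- circle_poly(0.8, n = 16, center = c(2.4, 0))
  merged <- merge_lumen_plaque(lumen, list(blob))
  expect_gt(polygon_area(merged), polygon_area(lumen))
  # brute-force support test: every input vertex lies inside or on the hull
  pts <- rbind(lumen, blob)
  for (k in seq_len(nrow(merged))) {
    i <- k; j <- if (k == nrow(merged)) 1 else k + 1
    e <- merged[j, ] - merged[i, ]
    s <- (pts[, 1] - merged[i, 1]) * e[2] - (pts[, 2] - merged[i, 2]) * e[1]
    expect_true(all(s <= 1e-9))   # all points on the inner side of each edge
  }
})

test_that("section enlargement hits the target equivalent radius", {
  circ <- circle_poly(2, n = 128)
  out <- enlarge_section(circ, 2.6)
  expect_equal(equivalent_radius(out), 2.6, tolerance = 1e-9)
  expect_false(attr(out, "narrowed"))
  # identity when the target equals the current equivalent radius
  idem <- enlarge_section(circ, equivalent_radius(circ))
  expect_equal(unclass(idem)[, ], circ, tolerance = 1e-12,
               ignore_attr = TRUE)
  # non-circular contour: area = pi * target^2 within 1% (shoelace)
  egg <- cbind(2 * cos(seq(0, 2 * pi, length.out = 65)[-65]),
               1.2 * sin(seq(0, 2 * pi, length.out = 65)[-65]))
  big <- enlarge_section(egg, 3)
  expect_equal(polygon_area(big), pi * 9, tolerance = 0.01)
  # target below the current radius flags a narrowed section
  expect_true(attr(enlarge_section(circ, 1.5), "narrowed"))
})

test_that("B-spline contour rebuild smooths without shrinking valid input", {
  circ <- circle_poly(2, n = 64)
  sm <- rebuild_smooth(circ, n_control = 16)
  expect_equal(polygon_area(sm), pi * 4, tolerance = 0.01)
  expect_false(isTRUE(all.equal(sm, circ)))
  # square: corners rounded, perimeter decreases, area within 5%
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sqd <- carofem:::resample_polygon(sq, 40)
  smq <- rebuild_smooth(sqd, n_control = 16)
  expect_lt(carofem:::polygon_perimeter(smq), 4)
  expect_equal(polygon_area(smq), 1, tolerance = 0.05)
  # output is a closed polygon traversed once
  expect_false(carofem:::self_intersects(smq))
})
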