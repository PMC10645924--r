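test_that("healthy vessel: smooth bifurcated tube, no plaque, no fibrous", {
  an <- make_anatomy(1, small_params())
  expect_true(is_watertight(an$lumen))
  expect_length(an$components, 0)
  expect_true(carofem:::is_empty_mesh(an$reference_fibrous))
})

test_that("single-component stenosis yields exactly one calcific mesh", {
  an <- make_anatomy(1, small_params(),
                     list(small_stenosis(frac_calcific = 1,
                                         frac_lipid = 0)))
  expect_named(an$components, "calcific")
  expect_true(is_watertight(an$components$calcific))
})

test_that("identical seeds give bit-identical geometry", {
  a <- make_anatomy(5, small_params(), list(small_stenosis()))
  b <- make_anatomy(5, small_params(), list(small_stenosis()))
  expect_identical(a$lumen$vertices, b$lumen$vertices)
  expect_identical(a$components$lipid$vertices, b$components$lipid$vertices)
  c <- make_anatomy(6, small_params(), list(small_stenosis()))
  expect_false(identical(a$lumen$vertices, c$lumen$vertices))
})

test_that("all emitted surfaces are watertight and nested in the vessel", {
  an <- make_anatomy(2, small_params(), list(small_stenosis()))
  for (m in c(list(an$lumen, an$reference_fibrous), an$components))
    expect_true(is_watertight(m))
  # plaque component interiors are disjoint from the stenotic lumen (they
  # may share its surface, so interior points are probed)
  set.seed(7)
  for (m in an$components) {
    lo <- apply(m$vertices, 2, min); hi <- apply(m$vertices, 2, max)
    pts <- cbind(runif(600, lo[1], hi[1]), runif(600, lo[2], hi[2]),
                 runif(600, lo[3], hi[3]))
    in_comp <- points_in_mesh(pts, m)
    in_lumen <- points_in_mesh(pts, an$lumen)
    expect_lt(mean(in_comp & in_lumen), 0.01)
    expect_gt(sum(in_comp), 10)
  }
})

test_that("invalid stenosis specifications are rejected", {
  expect_error(stenosis_spec(severity = 1), "strictly in")
  expect_error(stenosis_spec(frac_calcific = 0.7, frac_lipid = 0.5),
               "sum to at most 1")
  expect_error(
    make_anatomy(1, small_params(),
                 list(small_stenosis(), small_stenosis(center_z = 24.5))),
    "overlapping")
  expect_error(
    make_anatomy(1, small_params(), list(stenosis_spec(center_z = 12))),
    "separated branch zone")
})

test_that("voxel HU values respect the attenuation classes", {
  an <- make_anatomy(1, small_params(), list(small_stenosis()))
  vol <- voxelize_to_hu(an$lumen, an$components, spacing = 0.6, seed = 1)
  # probe voxels at known locations: deep lumen / deep calcific
  d <- dim(vol$values)
  gx <- vol$origin[1] + (seq_len(d[1]) - 0.5) * vol$spacing
  gy <- vol$origin[2] + (seq_len(d[2]) - 0.5) * vol$spacing
  gz <- vol$origin[3] + (seq_len(d[3]) - 0.5) * vol$spacing
  nearest <- function(p) c(which.min(abs(gx - p[1])),
                           which.min(abs(gy - p[2])),
                           which.min(abs(gz - p[3])))
  i <- nearest(c(0, 0, 5))            # CCA core: contrast blood
  v_lumen <- vol$values[i[1], i[2], i[3]]
  expect_gte(v_lumen, 200); expect_lte(v_lumen, 700)
  # a voxel deep inside the calcific component
  cal <- an$components$calcific
  cal_ctr <- colMeans(cal$vertices)
  ins <- points_in_mesh(rbind(cal_ctr), cal)
  if (ins) {
    j <- nearest(cal_ctr)
    expect_gte(vol$values[j[1], j[2], j[3]], 800)
  }
  # empty component list: nothing reaches the calcific range
  v0 <- voxelize_to_hu(tube_surface(2, 6), list(), spacing = 0.6, seed = 1)
  expect_true(all(v0$values < 800))
  # determinism under the seed
  v1 <- voxelize_to_hu(tube_surface(2, 6), list(), spacing = 0.6, seed = 1)
  expect_identical(v0$values, v1$values)
})

test_that("threshold segmentation recovers analytic and degenerate cases", {
  # a single 900 HU voxel among soft tissue: one calcific region, one voxel
  vals <- array(100, c(8, 8, 8))
  vals[4, 4, 4] <- 900
  vol <- structure(list(values = vals, spacing = 0.5, origin = c(0, 0, 0)),
                   class = "hu_volume")
  seg <- threshold_segment(vol)
  expect_length(seg$calcific, 1)
  expect_equal(mesh_volume(seg$calcific[[1]]), 0.5^3)
  expect_length(seg$lipid, 0)
  # uniform 100 HU sits between all ranges: everything empty
  seg0 <- threshold_segment(structure(list(values = array(100, c(5, 5, 5)),
                                           spacing = 0.5,
                                           origin = c(0, 0, 0)),
                                      class = "hu_volume"))
  expect_true(carofem:::is_empty_mesh(seg0$lumen))
  expect_length(seg0$calcific, 0)
  expect_length(seg0$lipid, 0)
  # lipid sphere radius 5 mm at 0.5 mm spacing: volume within 5% of 4/3 pi r^3
  n <- 24
  g <- (seq_len(n) - 0.5) * 0.5 - 6
  dist2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  vals <- ifelse(dist2 <= 25, 50, 100)
  vol <- structure(list(values = vals, spacing = 0.5, origin = c(-6, -6, -6)),
                   class = "hu_volume")
  seg <- threshold_segment(vol)
  expect_length(seg$lipid, 1)
  expect_equal(mesh_volume(seg$lipid[[1]]), 4 / 3 * pi * 125,
               tolerance = 0.05)
})

test_that("voxelize/segment round trip conserves component volumes", {
  an <- make_anatomy(3, small_params(), list(small_stenosis()))
  spacing <- 0.4
  vol <- voxelize_to_hu(an$lumen, an$components, spacing = spacing, seed = 3)
  seg <- threshold_segment(vol, min_voxels = 2)
  v_true <- mesh_volume(an$lumen)
  v_seg <- mesh_volume(seg$lumen)
  shell <- mesh_area(an$lumen) * spacing     # one-voxel surface shell
  expect_lt(abs(v_seg - v_true), 2 * shell)
  v_cal_true <- mesh_volume(an$components$calcific)
  v_cal_seg <- sum(vapply(seg$calcific, mesh_volume, 0))
  expect_lt(abs(v_cal_seg - v_cal_true),
            2 * mesh_area(an$components$calcific) * spacing)
})

test_that("HU volumes round-trip through the text layout", {
  vol <- voxelize_to_hu(tube_surface(2, 4), list(), spacing = 0.8, seed = 2)
  base <- tempfile()
  write_hu_volume(vol, base)
  back <- read_hu_volume(base)
  expect_equal(dim(back$values), dim(vol$values))
  expect_equal(back$values, vol$values, tolerance = 1e-5)
  expect_equal(back$origin, vol$origin, tolerance = 1e-7)
  unlink(paste0(base, c(".meta", ".grid")))
})
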