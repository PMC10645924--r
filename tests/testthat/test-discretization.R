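test_that("lattice meshing fills a unit cube exactly", {
  cube <- convex_hull_3d(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  m <- tetrahedralize(cube, NULL, 0.8, 0.8)
  expect_equal(sum(m$volumes), 1, tolerance = 0.01)
  expect_true(all(m$volumes > 1e-6))
})

test_that("lattice meshing captures a curved annulus within 1%", {
  tw <- annulus_solid(3, 3.9, 8)
  m <- tetrahedralize(tw, NULL, 0.35, 0.35)
  expect_equal(sum(m$volumes), mesh_volume(tw), tolerance = 0.01)
})

test_that("plaque-local refinement shortens edges inside the region", {
  cube <- convex_hull_3d(as.matrix(expand.grid(0:1, 0:1, 0:1)) * 4)
  blob <- convex_hull_3d(as.matrix(expand.grid(0:1, 0:1, 0:1)) + 1.5)
  m <- tetrahedralize(cube, blob, 0.8, 0.4, dilate = 0.2)
  edge_len <- function(sel) {
    t <- m$tets[sel, , drop = FALSE]
    e <- rbind(t[, c(1, 2)], t[, c(1, 3)], t[, c(1, 4)],
               t[, c(2, 3)], t[, c(2, 4)], t[, c(3, 4)])
    sqrt(rowSums((m$nodes[e[, 1], ] - m$nodes[e[, 2], ])^2))
  }
  inside <- rowSums(m$centroids > 1.5 & m$centroids < 2.5) == 3
  expect_lt(median(edge_len(inside)), median(edge_len(!inside)))
  # empty plaque region: uniform sizing
  m0 <- tetrahedralize(cube, NULL, 0.8, 0.4)
  expect_gt(min(cpp_volumes <- m0$volumes), 1e-6)
})

test_that("subset assignment follows the minimum-distance-vector rule", {
  sphere <- random_blob(1, n = 200, axes = c(1, 1, 1))
  m <- tube_tet_mesh(3, 3.9, 6, 0.45)
  # deep interior: centroid at the blob center is labelled the component
  inside <- carofem:::min_distance_vector_inside(rbind(c(0, 0, 0)), sphere)
  expect_true(inside)
  # far outside: wall
  expect_false(carofem:::min_distance_vector_inside(rbind(c(50, 0, 0)),
                                                    sphere))
  labelled <- assign_subsets(m, list(calcific = sphere))
  expect_true(all(labelled$subset %in% c("wall", "calcific")))
})

test_that("rule agrees with the ray-parity oracle on random geometries", {
  set.seed(99)
  for (s in 1:2) {
    blob <- random_blob(s + 20)
    pts <- cbind(runif(300, -3, 3), runif(300, -3, 3), runif(300, -2, 2))
    keep <- mesh_closest(pts, blob)$dist > 0.05
    rule <- carofem:::min_distance_vector_inside(pts, blob)
    oracle <- points_in_mesh(pts, blob)
    expect_identical(rule[keep], oracle[keep])
  }
})

test_that("overlap priority is calcific over lipid over fibrous", {
  m <- tube_tet_mesh(3, 3.9, 6, 0.45)
  big <- random_blob(2, n = 100, axes = c(5, 5, 4))
  big$vertices[, 3] <- big$vertices[, 3] + 3
  labelled <- assign_subsets(m, list(fibrous = big, calcific = big))
  claimed <- labelled$subset != "wall"
  expect_true(any(claimed))
  expect_true(all(labelled$subset[claimed] == "calcific"))
})

test_that("boundary tagging partitions facets and recovers the lumen area", {
  # smooth-boundary path: structured tube re-tagged from scratch recovers
  # the analytic inner area 2 pi a L
  ms <- tube_tet_mesh(3, 3.9, 8, 0.35)
  ms$boundary_tags <- NULL
  lumen_surf <- tube_surface(3, 8, n_theta = 96, spacing = 1)
  ms <- tag_boundary(ms, lumen_surf,
                     list(cca_end = list(z = 0), ica_end = list(z = 8)))
  areas_s <- carofem:::face_areas(surface_mesh(ms$nodes, ms$boundary_faces))
  expect_equal(sum(areas_s[ms$boundary_tags == "lumen"]), 2 * pi * 3 * 8,
               tolerance = 0.02)
  # lattice path: the tag partition holds on the snapped boundary
  tw <- annulus_solid(3, 3.9, 8)
  m <- tetrahedralize(tw, NULL, 0.35, 0.35)
  m <- tag_boundary(m, lumen_surf,
                    list(cca_end = list(z = 0), ica_end = list(z = 8)))
  expect_setequal(unique(m$boundary_tags),
                  c("lumen", "cca_end", "ica_end", "outer"))
  expect_equal(length(m$boundary_tags), nrow(m$boundary_faces))
  expect_gt(sum(m$boundary_tags == "cca_end"), 0)
  expect_gt(sum(m$boundary_tags == "ica_end"), 0)
  # empty lumen tag set is rejected
  far <- tube_surface(0.5, 2, n_theta = 16, spacing = 1)
  far$vertices <- far$vertices + 100
  expect_error(tag_boundary(m, far, list(cca_end = list(z = 0))),
               "pressure load would be zero")
})

test_that("subset volumes partition the wall-solid volume", {
  tw <- annulus_solid(3, 3.9, 8)
  m <- tetrahedralize(tw, NULL, 0.4, 0.4)
  blob <- random_blob(5, n = 60, axes = c(1, 1, 1))
  blob$vertices[, 1] <- blob$vertices[, 1] + 3.4
  blob$vertices[, 3] <- blob$vertices[, 3] + 4
  m <- assign_subsets(m, list(lipid = blob))
  vols <- tapply(m$volumes, m$subset, sum)
  expect_equal(sum(vols), mesh_volume(tw), tolerance = 0.01)
  expect_true(all(c("wall", "lipid") %in% names(vols)))
})

test_that("mesh exports carry nodes, elements and tags", {
  m <- tube_tet_mesh(3, 3.9, 3, 0.6)
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(m, vtk, cell_data = list(vm = seq_len(nrow(m$tets))))
  lines <- readLines(vtk)
  expect_equal(as.integer(strsplit(grep("^POINTS", lines, value = TRUE),
                                   " ")[[1]][2]), nrow(m$nodes))
  expect_equal(as.integer(strsplit(grep("^CELLS", lines, value = TRUE),
                                   " ")[[1]][2]), nrow(m$tets))
  expect_true(any(grepl("SCALARS vm", lines)))
  msh <- tempfile(fileext = ".msh")
  write_gmsh(m, msh)
  glines <- readLines(msh)
  n_nodes <- as.integer(glines[which(glines == "$Nodes") + 1])
  expect_equal(n_nodes, nrow(m$nodes))
  n_elem <- as.integer(glines[which(glines == "$Elements") + 1])
  expect_equal(n_elem, nrow(m$tets) + nrow(m$boundary_faces))
  unlink(c(vtk, msh))
})
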