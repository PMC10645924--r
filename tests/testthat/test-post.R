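test_that("differential pressure reproduces the bundled patient table", {
  tab <- carotid_pressures()
  expect_equal(nrow(tab), 10)
  expect_equal(differential_pressure(tab$p_systolic, tab$p_diastolic),
               tab$delta_p)
  expect_equal(differential_pressure(100, 100), 0)
  expect_error(differential_pressure(70, 80), "below diastolic")
})

mk_field <- function(vm_kpa, volume, subset = "fibrous") {
  n <- length(vm_kpa)
  out <- data.frame(element = seq_len(n), subset = subset, volume = volume,
                    x = 0, y = 0, z = seq_len(n), vm_mpa = vm_kpa / 1e3,
                    vm_kpa = vm_kpa)
  class(out) <- c("stress_field", "data.frame")
  out
}

test_that("volume-stress curves sort by stress and normalize to one", {
  # two elements, volumes 1 and 3, stresses 2 and 1 (hand enumeration)
  f <- mk_field(c(2, 1), c(1, 3))
  cv <- volume_stress_curve(f)
  expect_equal(cv$vm_kpa, c(1, 2))
  expect_equal(cv$cum_volume, c(0.75, 1.0))
  # uniform stress: a step jumping to 1 at that stress
  fu <- mk_field(rep(5, 4), rep(2, 4))
  cu <- volume_stress_curve(fu)
  expect_true(all(cu$vm_kpa == 5))
  expect_equal(cu$cum_volume[4], 1)
  expect_error(volume_stress_curve(f, "lipid"), "empty")
})

test_that("VM99 takes the first element crossing 99% cumulative volume", {
  # single element: its own stress
  expect_equal(vm99(mk_field(7, 2))$vm99_kpa, 7)
  # 100 equal-volume elements, stresses 1..100: exhaustive cumulative sum
  f <- mk_field(sample(1:100), rep(1, 100))
  expect_equal(vm99(f)$vm99_kpa, 99)
  # scaling property
  f2 <- f; f2$vm_kpa <- 3 * f2$vm_kpa
  expect_equal(vm99(f2)$vm99_kpa, 3 * vm99(f)$vm99_kpa)
  # two-path equivalence: curve route equals field route
  expect_equal(vm99(volume_stress_curve(f))$vm99_kpa, vm99(f)$vm99_kpa)
  # the reported element localizes the statistic
  r <- vm99(f)
  expect_equal(f$vm_kpa[f$element == r$element], 99)
})

test_that("composition percentages normalize against the plaque total", {
  p <- composition_percentages(c(calcific = 1, lipid = 1, fibrous = 2))
  expect_equal(unname(p), c(25, 25, 50))
  single <- composition_percentages(c(calcific = 3))
  expect_equal(unname(single), c(100, 0, 0))
  set.seed(1)
  rnd <- composition_percentages(c(calcific = runif(1), lipid = runif(1),
                                   fibrous = runif(1)))
  expect_equal(sum(rnd), 100, tolerance = 1e-9)
  expect_error(composition_percentages(c(calcific = 0)), "positive")
})

test_that("percentage difference matches its definition and edge cases", {
  expect_equal(percentage_difference(174.54, 92.65), 88.39,
               tolerance = 5e-5)
  expect_equal(percentage_difference(41.14, 37.85), 8.69, tolerance = 5e-4)
  expect_equal(percentage_difference(5, 5), 0)
  expect_error(percentage_difference(1, 0), "non-zero")
})

test_that("signed distances carry the outside-positive convention", {
  s1 <- random_blob(31, n = 150, axes = c(2, 2, 2))
  expect_equal(signed_distance_report(s1, s1)$mean, 0, tolerance = 1e-12)
  expect_equal(signed_distance_report(s1, s1)$sd, 0, tolerance = 1e-12)
  # nested spheres: reference radius 2, proposed radius 1 -> mean ~ +1
  sph <- function(r) {
    m <- random_blob(8, n = 300, axes = c(1, 1, 1))
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2)) * r
    convex_hull_3d(m$vertices)
  }
  ref <- sph(2); prop <- sph(1)
  rep1 <- signed_distance_report(ref, prop)
  expect_equal(rep1$mean, 1, tolerance = 0.05)
  rep2 <- signed_distance_report(prop, ref)
  expect_lt(rep2$mean, 0)
  # statistics agree with a brute-force all-pairs computation
  small_ref <- random_blob(12, n = 40)
  small_prop <- random_blob(13, n = 40)
  r <- signed_distance_report(small_ref, small_prop)
  brute <- brute_mesh_dist(small_ref$vertices, small_prop)
  sgn <- ifelse(points_in_mesh(small_ref$vertices, small_prop), -1, 1)
  expect_equal(r$distances, brute * sgn, tolerance = 1e-8)
  expect_equal(r$mean, mean(brute * sgn), tolerance = 1e-8)
  expect_equal(r$p05, unname(quantile(brute * sgn, 0.05)), tolerance = 1e-8)
})

test_that("fibrous-cap thickness measures the lumen-lipid separation", {
  lumen <- tube_surface(3, 6, n_theta = 96, spacing = 1)
  lipid <- build_wall_solid(tube_surface(3.5, 6, n_theta = 96, spacing = 1),
                            tube_surface(3.8, 6, n_theta = 96, spacing = 1))
  lipid$name <- "lipid"
  res <- structure(list(vm99_kpa = 1, element = 1,
                        centroid = c(3.2, 0, 3), z_station = 3),
                   class = "vm99_result")
  expect_equal(fc_thickness(res, lumen, lipid), 0.5, tolerance = 0.02)
  # no lipid contour on the plane -> not applicable
  expect_true(is.na(fc_thickness(res, lumen, empty <- structure(
    list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
         name = "lipid"), class = "surface_mesh"))))
  res9 <- res; res9$z_station <- 9; res9$centroid <- c(3.2, 0, 9)
  expect_true(is.na(fc_thickness(res9, lumen, lipid)))
})

test_that("sensitivity sweep is deterministic and respects its baseline", {
  mesh <- tube_tet_mesh(3, 3.9, 4, 0.45)
  # paint a fibrous patch so the sweep changes something
  mesh$subset <- ifelse(mesh$centroids[, 3] < 2, "fibrous", "wall")
  mat <- material_table(nu = 0.3)
  load <- load_case(delta_p = 50, ends = c("cca_end", "ica_end"))
  sw <- sensitivity_sweep(mesh, mat, load, multipliers = c(0.5, 1, 1.5))
  expect_true(sw$complete)
  base <- fem_solve(mesh, mat, load)
  expect_identical(sw$table$vm99_kpa[2], vm99(base$field)$vm99_kpa)
  expect_false(sw$table$vm99_kpa[1] == sw$table$vm99_kpa[3])
  # geometry without the swept subset: identical results per multiplier
  mesh0 <- tube_tet_mesh(3, 3.9, 4, 0.45)
  sw0 <- sensitivity_sweep(mesh0, mat, load, multipliers = c(0.5, 1, 1.5))
  expect_equal(sw0$table$vm99_kpa, rep(sw0$table$vm99_kpa[1], 3),
               tolerance = 1e-12)
})

test_that("VM99 location tagging follows the proximity rules", {
  lipid <- random_blob(3, n = 80, axes = c(1, 1, 1))
  calcific <- random_blob(4, n = 80, axes = c(1, 1, 1))
  calcific$vertices[, 1] <- calcific$vertices[, 1] + 10
  res <- structure(list(vm99_kpa = 1, element = 1,
                        centroid = c(1.35, 0, 0), z_station = 0),
                   class = "vm99_result")
  expect_equal(vm99_location(res, lipid, calcific, apex = c(50, 0, 0)),
               "fibrous cap")
  res$centroid <- c(11.35, 0, 0)
  expect_equal(vm99_location(res, lipid, calcific, apex = c(50, 0, 0)),
               "calcific plaque shoulder")
  res$centroid <- c(49, 0, 0)
  expect_equal(vm99_location(res, lipid, calcific, apex = c(50, 0, 0)),
               "bifurcation")
  res$centroid <- c(25, 0, 0)
  expect_true(is.na(vm99_location(res, lipid, calcific,
                                  apex = c(50, 0, 0))))
})
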