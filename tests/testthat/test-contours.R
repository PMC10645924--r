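test_that("contour stacks assign branches and serialize losslessly", {
  an <- make_anatomy(1, small_params())
  st <- slice_contours(an$lumen, an$centerlines, spacing = 1,
                       z_range = c(1, 29))
  brs <- carofem:::stack_branches(st)
  expect_setequal(brs, c("CCA", "ICA", "ECA"))
  # above the split each plane contributes one ICA + one ECA contour
  z <- vapply(st$records, `[[`, 0, "z")
  top <- st$records[z == 28]
  expect_setequal(vapply(top, `[[`, "", "branch"), c("ICA", "ECA"))
  path <- tempfile(fileext = ".txt")
  write_contour_stack(st, path)
  back <- read_contour_stack(path)
  expect_equal(back$spacing, st$spacing)
  expect_equal(length(back$records), length(st$records))
  expect_equal(back$records[[5]]$poly, st$records[[5]]$poly,
               tolerance = 1e-7)
  unlink(path)
})

test_that("narrowing removal drops dipped stations and re-interpolates", {
  # healthy monotone taper: nothing removed
  mk <- function(radii) {
    recs <- lapply(seq_along(radii), function(i)
      list(z = i * 0.5, branch = "CCA", poly = circle_poly(radii[i])))
    carofem:::contour_stack(recs, 0.5)
  }
  taper <- mk(seq(4, 3.5, length.out = 11))
  kept <- drop_narrowed_sections(taper)
  r_kept <- vapply(kept$records, function(r) equivalent_radius(r$poly), 0)
  expect_equal(r_kept, seq(4, 3.5, length.out = 11), tolerance = 1e-3)
  # one station 20% below its neighbors: removed and refilled
  radii <- rep(4, 11); radii[6] <- 3.2
  fixed <- drop_narrowed_sections(mk(radii))
  r_fix <- vapply(fixed$records, function(r) equivalent_radius(r$poly), 0)
  expect_equal(r_fix[6], 4, tolerance = 1e-3)
  # idempotence: running twice equals running once
  again <- drop_narrowed_sections(fixed)
  r_again <- vapply(again$records, function(r) equivalent_radius(r$poly), 0)
  expect_equal(r_again, r_fix, tolerance = 1e-9)
})

test_that("fewer than two stations per branch is rejected", {
  one <- carofem:::contour_stack(
    list(list(z = 0, branch = "CCA", poly = circle_poly(3))), 0.5)
  expect_error(drop_narrowed_sections(one), "fewer than 2")
})
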