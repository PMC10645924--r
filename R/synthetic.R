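## Seeded synthetic atherosclerotic carotid anatomies.
##
## The generator emulates what threshold-based CTA segmentation delivers: a
## watertight stenotic lumen surface plus calcific and lipid plaque component
## surfaces, together with a ground-truth fibrous solid filling the stenotic
## gap (the synthetic stand-in for an expert's manual segmentation of the
## fibrous tissue). Geometry is contour-based: every branch cross-section is
## a star-shaped radius function about its centerline, which keeps all
## downstream per-plane Boolean work well-posed.

#' Default centerline parameters of the synthetic carotid bifurcation
#'
#' The common carotid (CCA) runs along the z axis and bifurcates into the
#' internal (ICA) and external (ECA) branches, whose circular cross-sections
#' drift apart linearly with z. In the transition zone the lumen section is
#' the planar union of the two branch disks; the single-to-double contour
#' split happens where the disks separate. Radii are constant per branch
#' (apart from a small seeded wobble), so that the 30-percent outer-wall
#' rule anchored at the distal inner branch radius is exactly consistent
#' with the generated healthy vessel.
#'
#' @param ... overrides for the defaults.
#' @return named list of parameters (mm and radians).
#' @export
centerline_params <- function(...) {
  p <- list(z_min = 0, z_bif = 14, z_top = 40,
            r_cca = 3.0, r_ica = 3.0, r_eca = 2.2,
            slope_ica = 0.35, slope_eca = -0.30,
            sep_gap = 0.4,        # clearance at the contour split (mm)
            spacing = 0.5, n_theta = 64,
            wobble = 0.03,        # seeded radius wobble amplitude (mm)
            fillet_radius = 1.5)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Centerline set of the synthetic anatomy
#'
#' @param params a [centerline_params()] list.
#' @return list with per-branch centerline matrices (columns z, x, y), the
#'   bifurcation station `z_bif`, the contour-split station `z_sep` and the
#'   apex point used for the bifurcation fillet and location tagging.
#' @export
carotid_centerlines <- function(params = centerline_params()) {
  p <- params
  dslope <- p$slope_ica - p$slope_eca
  z_sep <- p$z_bif + (p$r_ica + p$r_eca + p$sep_gap) / dslope
  zs <- seq(p$z_min, p$z_top, by = p$spacing)
  cca <- cbind(zs[zs <= z_sep], 0, 0)
  z_up <- zs[zs >= p$z_bif]
  ica <- cbind(z_up, p$slope_ica * (z_up - p$z_bif), 0)
  eca <- cbind(z_up, p$slope_eca * (z_up - p$z_bif), 0)
  apex_x <- (p$slope_ica + p$slope_eca) / 2 * (z_sep - p$z_bif)
  list(branches = list(CCA = cca, ICA = ica, ECA = eca),
       z_bif = p$z_bif, z_sep = z_sep, apex = c(apex_x, 0, z_sep),
       params = p)
}

branch_center <- function(cl, branch, z) {
  p <- cl$params
  switch(branch,
         CCA = c(0, 0),
         ICA = c(p$slope_ica * max(0, z - p$z_bif), 0),
         ECA = c(p$slope_eca * max(0, z - p$z_bif), 0))
}

branch_radius <- function(cl, branch) {
  p <- cl$params
  switch(branch, CCA = p$r_cca, ICA = p$r_ica, ECA = p$r_eca)
}

#' Specify a stenosis for the synthetic generator
#'
#' @param branch `"CCA"`, `"ICA"` or `"ECA"`.
#' @param center_z axial center of the narrowing (mm).
#' @param extent axial extent (mm).
#' @param severity maximal cross-sectional area reduction, in (0, 1).
#' @param angle angular position of the plaque bulk (radians).
#' @param frac_calcific,frac_lipid target volume fractions of the stenotic
#'   gap occupied by the calcific and lipid components (sum <= 1; the rest
#'   is fibrous tissue).
#' @param cap_thickness fibrous-cap thickness separating the lipid pool from
#'   the lumen (mm).
#' @param sharpness angular localization exponent of the narrowing profile;
#'   automatically relaxed when the requested severity cannot be reached
#'   with a localized bump.
#' @return a `stenosis_spec` list.
#' @export
stenosis_spec <- function(branch = "ICA", center_z = 31, extent = 10,
                          severity = 0.5, angle = 0,
                          frac_calcific = 0.25, frac_lipid = 0.15,
                          cap_thickness = 0.4, sharpness = 2) {
  if (!is.finite(severity) || severity <= 0 || severity >= 1)
    stop("stenosis severity (area reduction) must lie strictly in (0, 1)")
  if (frac_calcific < 0 || frac_lipid < 0 || frac_calcific + frac_lipid > 1)
    stop("component fractions must be non-negative and sum to at most 1")
  if (extent <= 0) stop("stenosis extent must be positive")
  structure(list(branch = branch, center_z = center_z, extent = extent,
                 severity = severity, angle = angle,
                 frac_calcific = frac_calcific, frac_lipid = frac_lipid,
                 cap_thickness = cap_thickness, sharpness = sharpness),
            class = "stenosis_spec")
}

validate_stenoses <- function(specs, cl) {
  p <- cl$params
  for (s in specs) {
    lo <- s$center_z - s$extent / 2
    hi <- s$center_z + s$extent / 2
    if (s$branch == "CCA") {
      if (lo < p$z_min + 1 || hi > p$z_bif - 0.5)
        stop("CCA stenosis [", lo, ", ", hi, "] must lie below the ",
             "bifurcation station ", p$z_bif)
    } else {
      if (lo < cl$z_sep + 0.5 || hi > p$z_top - 1.5)
        stop(s$branch, " stenosis [", lo, ", ", hi, "] must lie in the ",
             "separated branch zone (", round(cl$z_sep + 0.5, 2), ", ",
             p$z_top - 1.5, "); narrowings across the bifurcation ",
             "transition are not supported")
    }
  }
  if (length(specs) > 1) {
    for (i in seq_len(length(specs) - 1))
      for (j in (i + 1):length(specs)) {
        a <- specs[[i]]; b <- specs[[j]]
        if (a$branch == b$branch &&
            abs(a$center_z - b$center_z) < (a$extent + b$extent) / 2)
          stop("overlapping stenoses on branch ", a$branch)
      }
  }
  invisible(specs)
}

# angular narrowing profile and its amplitude for a target area reduction
stenosis_profile <- function(severity, angle, sharpness, n_theta) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  k <- sharpness
  repeat {
    w <- ((1 + cos(thetas - angle)) / 2)^k
    W1 <- mean(w); W2 <- mean(w^2)
    disc <- W1^2 - W2 * severity
    if (disc >= 0) {
      A <- (W1 - sqrt(disc)) / W2
      if (A * max(w) <= 0.95) break
    }
    k <- k / 2
    if (k < 1e-3) {   # uniform ring narrowing always reaches the target
      w <- rep(1, n_theta)
      A <- 1 - sqrt(1 - severity)
      break
    }
  }
  list(thetas = thetas, w = w, A = A, k = k)
}

axial_profile <- function(z, center_z, extent) {
  u <- (z - center_z) / (extent / 2)
  ifelse(abs(u) < 1, (1 + cos(pi * u))^1 / 2, 0)
}

#' Generate a synthetic atherosclerotic carotid anatomy
#'
#' Builds a watertight stenotic lumen surface, calcific/lipid plaque
#' component surfaces hugging the lumen inside the stenotic gap, and the
#' ground-truth fibrous solid filling the remainder of the gap (the solid a
#' manual segmentation of the fibrous tissue would deliver). Identical seed
#' and parameters give bit-identical output.
#'
#' @param seed integer random seed (radius wobble phases).
#' @param params a [centerline_params()] list.
#' @param stenoses list of [stenosis_spec()] objects (may be empty for a
#'   healthy vessel).
#' @return object of class `carotid_anatomy`: list with `lumen`,
#'   `components` (list of tagged surface meshes), `reference_fibrous`,
#'   `centerlines`, `stenoses` and `params`.
#' @export
make_anatomy <- function(seed = 1, params = centerline_params(),
                         stenoses = list()) {
  if (inherits(stenoses, "stenosis_spec")) stenoses <- list(stenoses)
  cl <- carotid_centerlines(params)
  p <- cl$params
  validate_stenoses(stenoses, cl)

  seed_state <- preserve_seed()
  on.exit(restore_seed(seed_state))
  set.seed(seed)
  wob_phase <- runif(1, 0, 2 * pi)
  wob_wavelength <- runif(1, 18, 28)
  wobble_factor <- function(z)
    1 + p$wobble / max(p$r_cca, 1e-9) * sin(2 * pi * z / wob_wavelength + wob_phase)

  nth <- p$n_theta
  profs <- lapply(stenoses, function(s)
    stenosis_profile(s$severity, s$angle, s$sharpness, nth))
  thetas <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]

  # stenotic radius function of one branch at station z (healthy when no
  # stenosis covers z)
  branch_r <- function(branch, z, stenotic = TRUE) {
    r <- branch_radius(cl, branch) * wobble_factor(z)
    rr <- rep(r, nth)
    if (stenotic) {
      for (i in seq_along(stenoses)) {
        s <- stenoses[[i]]
        if (s$branch != branch) next
        g <- axial_profile(z, s$center_z, s$extent)
        if (g > 0) rr <- rr * (1 - profs[[i]]$A * g * profs[[i]]$w)
      }
    }
    rr
  }

  zs <- seq(p$z_min, p$z_top, by = p$spacing)
  stations <- list()
  for (z in zs) {
    if (z <= p$z_bif + 1e-9) {
      ctr <- c(0, 0)
      poly <- radius_to_poly(branch_r("CCA", z), ctr, thetas)
      stations[[length(stations) + 1]] <- list(z = z, contours = list(poly))
    } else {
      c_ica <- branch_center(cl, "ICA", z)
      c_eca <- branch_center(cl, "ECA", z)
      r_ica <- branch_r("ICA", z)
      r_eca <- branch_r("ECA", z)
      if (z < cl$z_sep - 1e-9) {
        poly <- union_two_circles(c_ica, max(r_ica), c_eca, max(r_eca),
                                  r_ica, r_eca, thetas)
        stations[[length(stations) + 1]] <- list(z = z, contours = list(poly))
      } else {
        stations[[length(stations) + 1]] <- list(
          z = z,
          contours = list(radius_to_poly(r_ica, c_ica, thetas),
                          radius_to_poly(r_eca, c_eca, thetas)))
      }
    }
  }
  lumen <- loft_stations(stations, cap_ends = TRUE,
                         fillet_radius = p$fillet_radius, name = "lumen")

  components <- list()
  fib_parts <- list()
  for (i in seq_along(stenoses)) {
    s <- stenoses[[i]]
    pr <- profs[[i]]
    res <- build_plaque_components(s, pr, cl, branch_r, zs, thetas)
    components <- c(components, res$components)
    if (!is_empty_mesh(res$fibrous))
      fib_parts[[length(fib_parts) + 1]] <- res$fibrous
  }
  reference_fibrous <-
    if (length(fib_parts) == 0) empty_mesh("fibrous_reference")
    else do.call(merge_meshes, c(fib_parts, list(weld = FALSE,
                                                 name = "fibrous_reference")))

  structure(list(lumen = lumen, components = components,
                 reference_fibrous = reference_fibrous,
                 centerlines = cl, stenoses = stenoses, params = p,
                 seed = seed,
                 wobble_factor = wobble_factor),
            class = "carotid_anatomy")
}

#' @export
print.carotid_anatomy <- function(x, ...) {
  cat(sprintf("carotid_anatomy (seed %d): %d stenoses, %d plaque components\n",
              x$seed, length(x$stenoses), length(x$components)))
  print(x$lumen)
  invisible(x)
}

preserve_seed <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# union contour of two branch disks about a star point between them. Near
# the branch separation the disks pass through tangency; a small bridging
# radius keeps the crotch saddle open so no station ever degenerates into a
# bowtie (the real bifurcation crotch is exactly such a saddle).
union_two_circles <- function(c1, R1, c2, R2, r1_fun, r2_fun, thetas,
                              bridge = 0.8) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-9) {
    ctr <- c1
  } else {
    u <- (c2 - c1) / d
    lo <- d - R2; hi <- R1
    ctr <- c1 + u * (lo + hi) / 2
  }
  r <- pmax(ray_circle_r(ctr, c1, R1, thetas),
            ray_circle_r(ctr, c2, R2, thetas), bridge)
  radius_to_poly(r, ctr, thetas)
}

# largest positive ray-circle intersection distance from point p (0 if none)
ray_circle_r <- function(p, c, R, thetas) {
  rel <- c - p
  proj <- rel[1] * cos(thetas) + rel[2] * sin(thetas)
  perp2 <- sum(rel^2) - proj^2
  disc <- R^2 - perp2
  out <- rep(0, length(thetas))
  ok <- disc >= 0
  out[ok] <- pmax(0, proj[ok] + sqrt(disc[ok]))
  out
}

# calcific/lipid bands inside the stenotic gap plus the ground-truth fibrous
# annulus (gap minus components)
build_plaque_components <- function(s, pr, cl, branch_r, zs, thetas) {
  nth <- length(thetas)
  zi <- zs[abs(zs - s$center_z) <= s$extent / 2 + 1e-9]
  ctr_of <- function(z) branch_center(cl, s$branch, z)
  r_sten <- t(vapply(zi, function(z) branch_r(s$branch, z), numeric(nth)))
  r_heal <- t(vapply(zi, function(z) branch_r(s$branch, z, stenotic = FALSE),
                     numeric(nth)))
  gap <- r_heal - r_sten                      # nz x ntheta radial gap
  dz <- cl$params$spacing
  dth <- 2 * pi / nth

  band_volume <- function(r_in, r_out)
    sum(0.5 * (pmax(r_out, r_in)^2 - r_in^2) * dth * dz)
  gap_vol <- band_volume(r_sten, r_heal)

  shift <- function(center) ((thetas - center + pi) %% (2 * pi)) - pi
  window <- function(center, width)
    (1 + cos(pi * pmin(abs(shift(center)) / width, 1))) / 2

  # band volume for a given angular window: r_in_mat is the per-station inner
  # radius, h_avail the height available to the component at window weight 1
  band_vol_of <- function(width, center, r_in_mat, h_avail, h_frac) {
    sw <- window(center, width)
    v <- 0
    for (iz in seq_along(zi)) {
      h <- h_frac * h_avail[iz, ] * sw
      v <- v + sum(0.5 * ((r_in_mat[iz, ] + h)^2 - r_in_mat[iz, ]^2) * dth * dz)
    }
    v
  }
  # angular window width reproducing a target band volume (monotone in width)
  solve_width <- function(target, center, r_in_mat, h_avail, h_frac) {
    if (target <= 0) return(NULL)
    if (band_vol_of(pi, center, r_in_mat, h_avail, h_frac) <= target) return(pi)
    uniroot(function(wd) band_vol_of(wd, center, r_in_mat, h_avail, h_frac) -
              target, c(0.05, pi), tol = 1e-3)$root
  }

  th_cal <- s$angle - 0.9
  th_lip <- s$angle + 0.9

  # calcific band: attached to the lumen, up to 85% of the local gap
  w_cal <- solve_width(s$frac_calcific * gap_vol, th_cal, r_sten, gap, 0.85)
  cal_sw <- if (is.null(w_cal)) rep(0, nth) else window(th_cal, w_cal)
  cal_h <- t(vapply(seq_along(zi), function(iz) 0.85 * gap[iz, ] * cal_sw,
                    numeric(nth)))

  # lipid band: separated from the lumen by the fibrous cap and from the
  # calcific band radially
  lip_in <- r_sten + pmax(cal_h, s$cap_thickness)
  lip_head <- pmax(r_heal - lip_in, 0)        # available height
  w_lip <- solve_width(s$frac_lipid * gap_vol, th_lip, lip_in, lip_head, 0.8)
  lip_sw <- if (is.null(w_lip)) rep(0, nth) else window(th_lip, w_lip)
  lip_h <- t(vapply(seq_along(zi), function(iz) 0.8 * lip_head[iz, ] * lip_sw,
                    numeric(nth)))

  comps <- list()
  cal_mesh <- loft_band(zi, thetas, r_sten, r_sten + cal_h, ctr_of, "calcific")
  if (!is_empty_mesh(cal_mesh)) comps$calcific <- cal_mesh
  lip_mesh <- loft_band(zi, thetas, lip_in, lip_in + lip_h, ctr_of, "lipid")
  if (!is_empty_mesh(lip_mesh)) comps$lipid <- lip_mesh

  # ground-truth fibrous: gap minus calcific (radial) minus lipid (cavity)
  fib_in <- r_sten + cal_h
  fib <- loft_annulus(zi, thetas, fib_in, r_heal, ctr_of, "fibrous_reference",
                      min_gap = 0.08)
  if (!is_empty_mesh(fib) && !is_empty_mesh(lip_mesh))
    fib <- merge_meshes(fib, reverse_faces(lip_mesh), weld = FALSE,
                        name = "fibrous_reference")
  list(components = comps, fibrous = fib)
}

# loft an angularly windowed radial band [r_in, r_out] into a watertight
# C-section solid; empty when the band is nowhere thicker than h_min
loft_band <- function(zi, thetas, r_in, r_out, ctr_of, name, h_min = 0.05) {
  h <- r_out - r_in
  active <- which(apply(h, 1, max) > h_min * 2)
  if (length(active) < 2) return(empty_mesh(name))
  active <- active[1]:active[length(active)]
  rings <- list()
  for (iz in active) {
    sel <- which(h[iz, ] > h_min)
    if (length(sel) >= 3) sel <- contiguous_angular_run(sel, length(thetas))
    if (length(sel) < 3) { rings[length(rings) + 1] <- list(NULL); next }
    ctr <- ctr_of(zi[iz])
    thw <- thetas[sel]
    outer <- cbind(ctr[1] + r_out[iz, sel] * cos(thw),
                   ctr[2] + r_out[iz, sel] * sin(thw), zi[iz])
    inner <- cbind(ctr[1] + r_in[iz, sel] * cos(thw),
                   ctr[2] + r_in[iz, sel] * sin(thw), zi[iz])
    rings[[length(rings) + 1]] <- rbind(outer, inner[rev(seq_len(nrow(inner))), ])
  }
  ok <- !vapply(rings, is.null, TRUE)
  rings <- rings[ok]
  rings <- Filter(function(r) polygon_perimeter(r[, 1:2]) > 1e-3, rings)
  if (length(rings) < 2) return(empty_mesh(name))
  pieces <- list()
  for (i in seq_len(length(rings) - 1)) {
    f <- stitch_rings(rings[[i]], rings[[i + 1]])
    pieces[[length(pieces) + 1]] <-
      surface_mesh(rbind(rings[[i]], rings[[i + 1]]), f)
  }
  m1 <- nrow(rings[[1]]) / 2
  pieces[[length(pieces) + 1]] <- cap_band(rings[[1]], m1, direction = -1)
  mn <- nrow(rings[[length(rings)]]) / 2
  pieces[[length(pieces) + 1]] <- cap_band(rings[[length(rings)]], mn,
                                           direction = 1)
  out <- do.call(merge_meshes, c(pieces, list(weld = TRUE, tol = 1e-6,
                                              name = name)))
  orient_mesh(out)
}

contiguous_angular_run <- function(sel, n) {
  # returns the longest contiguous run of indices on the circle
  is_sel <- logical(n); is_sel[sel] <- TRUE
  gaps <- which(!is_sel)
  if (length(gaps) == 0) return(seq_len(n))
  start <- (max(gaps) %% n) + 1
  run <- integer(0)
  i <- start
  while (is_sel[i]) {
    run <- c(run, i)
    i <- (i %% n) + 1
    if (i == start) break
  }
  run
}

# planar strip cap of a C-shaped band ring (outer arc then reversed inner arc)
cap_band <- function(ring, m, direction = 1) {
  idx_in <- function(j) 2 * m + 1 - j
  faces <- matrix(0L, 0, 3)
  for (j in seq_len(m - 1)) {
    faces <- rbind(faces,
                   c(j, j + 1, idx_in(j + 1)),
                   c(j, idx_in(j + 1), idx_in(j)))
  }
  if (direction < 0) faces <- faces[, c(1, 3, 2), drop = FALSE]
  surface_mesh(ring, faces)
}

# full annular solid between radius functions r_in(z,theta) < r_out(z,theta)
loft_annulus <- function(zi, thetas, r_in, r_out, ctr_of, name,
                         min_gap = 0.08) {
  gap <- r_out - r_in
  active <- which(apply(gap, 1, max) > min_gap)
  if (length(active) < 2) return(empty_mesh(name))
  active <- active[1]:active[length(active)]
  # keep a positive gap everywhere on retained stations so caps stay manifold
  inner_rings <- list(); outer_rings <- list()
  for (iz in active) {
    ctr <- ctr_of(zi[iz])
    ri <- pmin(r_in[iz, ], r_out[iz, ] - min_gap / 2)
    inner_rings[[length(inner_rings) + 1]] <-
      cbind(ctr[1] + ri * cos(thetas), ctr[2] + ri * sin(thetas), zi[iz])
    outer_rings[[length(outer_rings) + 1]] <-
      cbind(ctr[1] + r_out[iz, ] * cos(thetas),
            ctr[2] + r_out[iz, ] * sin(thetas), zi[iz])
  }
  pieces <- list()
  nr <- length(outer_rings)
  for (i in seq_len(nr - 1)) {
    fo <- stitch_rings(outer_rings[[i]], outer_rings[[i + 1]])
    pieces[[length(pieces) + 1]] <-
      surface_mesh(rbind(outer_rings[[i]], outer_rings[[i + 1]]), fo)
    fi <- stitch_rings(inner_rings[[i]], inner_rings[[i + 1]])
    pieces[[length(pieces) + 1]] <-
      reverse_faces(surface_mesh(rbind(inner_rings[[i]], inner_rings[[i + 1]]), fi))
  }
  pieces[[length(pieces) + 1]] <- cap_annulus(outer_rings[[1]],
                                              inner_rings[[1]], direction = -1)
  pieces[[length(pieces) + 1]] <- cap_annulus(outer_rings[[nr]],
                                              inner_rings[[nr]], direction = 1)
  out <- do.call(merge_meshes, c(pieces, list(weld = TRUE, tol = 1e-6,
                                              name = name)))
  orient_mesh(out)
}

#' Simple cylinder surface (straight-tube mode)
#'
#' Single-branch straight tube used for analytic verification fixtures.
#'
#' @param radius tube radius (mm).
#' @param length tube length along z (mm).
#' @param n_theta angular resolution.
#' @param spacing axial station spacing (mm).
#' @param center xy center.
#' @param name mesh tag.
#' @return watertight [surface_mesh].
#' @export
tube_surface <- function(radius, length, n_theta = 48, spacing = 1,
                         center = c(0, 0), name = NULL) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, length, by = spacing)
  if (zs[length(zs)] < length) zs <- c(zs, length)
  stations <- lapply(zs, function(z)
    list(z = z, contours = list(radius_to_poly(rep(radius, n_theta), center,
                                               thetas))))
  loft_stations(stations, cap_ends = TRUE, fillet_radius = 0, name = name)
}

## ---- Hounsfield-unit volumes ------------------------------------------------

#' Voxelize an anatomy into a Hounsfield-unit volume
#'
#' Emulates a contrast-enhanced CT angiography volume: voxels whose centers
#' fall inside the lumen receive contrast-enhanced blood values in
#' [200, 700] HU, calcific plaque >= 800 HU, lipid plaque <= 60 HU, and all
#' remaining voxels a constant intermediate soft-tissue value of 100 HU
#' (strictly between the lipid and blood ranges, so threshold classification
#' is unambiguous).
#'
#' @param lumen watertight lumen [surface_mesh].
#' @param components list of watertight plaque component meshes whose `name`
#'   is `"calcific"` or `"lipid"`.
#' @param spacing voxel spacing in mm.
#' @param margin bounding-box margin in mm.
#' @param seed seed for the per-voxel HU draws.
#' @return object of class `hu_volume`: list with 3-D `values` array,
#'   `spacing` and `origin`.
#' @export
voxelize_to_hu <- function(lumen, components = list(), spacing = 0.5,
                           margin = 2, seed = 1) {
  stopifnot(spacing > 0)
  if (!is_watertight(lumen)) stop("lumen surface must be watertight")
  for (m in components)
    if (!is_watertight(m)) stop("plaque component surface must be watertight")
  seed_state <- preserve_seed()
  on.exit(restore_seed(seed_state))
  set.seed(seed)
  allv <- rbind(lumen$vertices,
                do.call(rbind, lapply(components, `[[`, "vertices")))
  lo <- apply(allv, 2, min) - margin
  hi <- apply(allv, 2, max) + margin
  xs <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  ys <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  zs <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  vals <- rep(100, nrow(grid))                       # soft tissue
  in_lumen <- points_in_mesh(grid, lumen)
  vals[in_lumen] <- runif(sum(in_lumen), 200, 700)   # contrast-enhanced blood
  for (m in components) {
    inside <- points_in_mesh(grid, m)
    if (identical(m$name, "lipid")) {
      vals[inside] <- runif(sum(inside), 0, 60)
    } else if (identical(m$name, "calcific")) {
      vals[inside] <- runif(sum(inside), 800, 1200)
    }
  }
  structure(list(values = array(vals, dim = c(length(xs), length(ys),
                                              length(zs))),
                 spacing = spacing, origin = lo),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("hu_volume: %s voxels at %.3g mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = " x "), x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a Hounsfield-unit volume as metadata + raw grid text pair
#'
#' The layout is a small header file (`<path>.meta`: dims, spacing, origin)
#' and a flat text grid file with one value per line in column-major order.
#'
#' @param vol an `hu_volume`.
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_hu_volume <- function(vol, path) {
  meta <- c(sprintf("dims %d %d %d", dim(vol$values)[1], dim(vol$values)[2],
                    dim(vol$values)[3]),
            sprintf("spacing %.9g", vol$spacing),
            sprintf("origin %.9g %.9g %.9g", vol$origin[1], vol$origin[2],
                    vol$origin[3]))
  writeLines(meta, paste0(path, ".meta"))
  writeLines(sprintf("%.6g", as.vector(vol$values)), paste0(path, ".grid"))
  invisible(path)
}

#' @rdname write_hu_volume
#' @export
read_hu_volume <- function(path) {
  meta <- readLines(paste0(path, ".meta"))
  dims <- as.integer(strsplit(meta[1], " ")[[1]][-1])
  spacing <- as.numeric(strsplit(meta[2], " ")[[1]][2])
  origin <- as.numeric(strsplit(meta[3], " ")[[1]][-1])
  vals <- as.numeric(readLines(paste0(path, ".grid")))
  structure(list(values = array(vals, dim = dims), spacing = spacing,
                 origin = origin), class = "hu_volume")
}

#' Threshold-based segmentation of a Hounsfield-unit volume
#'
#' Classifies voxels by the standard attenuation ranges (calcific plaque
#' >= 800 HU, lipid plaque <= 60 HU, contrast-enhanced blood 200-700 HU),
#' labels 6-connected regions, and extracts a watertight voxel-boundary
#' isosurface per region. The lumen is the largest blood region.
#'
#' @param vol an `hu_volume`.
#' @param hu_calcific,hu_lipid,hu_blood threshold ranges.
#' @param min_voxels drop regions smaller than this many voxels.
#' @return list with `lumen` (surface mesh or empty), `calcific` and `lipid`
#'   (lists of surface meshes).
#' @export
threshold_segment <- function(vol, hu_calcific = c(800, Inf),
                              hu_lipid = c(-Inf, 60),
                              hu_blood = c(200, 700), min_voxels = 1) {
  v <- vol$values
  stopifnot(all(is.finite(v)))
  seg_class <- function(lo, hi, tag) {
    mask <- v >= lo & v <= hi
    if (!any(mask)) return(list())
    lab <- array(cpp_label_components(as.vector(mask), dim(v)), dim = dim(v))
    out <- list()
    for (id in seq_len(max(lab))) {
      n_vox <- sum(lab == id)
      if (n_vox < min_voxels) next
      out[[length(out) + 1]] <- lego_surface(lab == id, vol$spacing,
                                             vol$origin, tag)
    }
    out
  }
  blood <- seg_class(hu_blood[1], hu_blood[2], "lumen")
  lumen <- if (length(blood) == 0) empty_mesh("lumen") else
    blood[[which.max(vapply(blood, mesh_volume, 0))]]
  list(lumen = lumen,
       calcific = seg_class(hu_calcific[1], hu_calcific[2], "calcific"),
       lipid = seg_class(hu_lipid[1], hu_lipid[2], "lipid"))
}

# watertight voxel-boundary surface of a logical 3-D mask
lego_surface <- function(mask, spacing, origin, name = NULL) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  quads <- list()
  # for each axis, faces where inside meets outside
  corner <- function(i, j, k)
    cbind(origin[1] + (i - 1) * spacing, origin[2] + (j - 1) * spacing,
          origin[3] + (k - 1) * spacing)
  idx <- which(pad, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    ii <- i - 1; jj <- j - 1; kk <- k - 1      # unpadded one-based voxel
    # voxel spans corners (ii-1..ii, jj-1..jj, kk-1..kk) in grid units
    if (!pad[i - 1, j, k]) quads[[length(quads) + 1]] <-
      rbind(corner(ii - 1, jj - 1, kk - 1), corner(ii - 1, jj - 1, kk),
            corner(ii - 1, jj, kk), corner(ii - 1, jj, kk - 1))
    if (!pad[i + 1, j, k]) quads[[length(quads) + 1]] <-
      rbind(corner(ii, jj - 1, kk - 1), corner(ii, jj, kk - 1),
            corner(ii, jj, kk), corner(ii, jj - 1, kk))
    if (!pad[i, j - 1, k]) quads[[length(quads) + 1]] <-
      rbind(corner(ii - 1, jj - 1, kk - 1), corner(ii, jj - 1, kk - 1),
            corner(ii, jj - 1, kk), corner(ii - 1, jj - 1, kk))
    if (!pad[i, j + 1, k]) quads[[length(quads) + 1]] <-
      rbind(corner(ii - 1, jj, kk - 1), corner(ii - 1, jj, kk),
            corner(ii, jj, kk), corner(ii, jj, kk - 1))
    if (!pad[i, j, k - 1]) quads[[length(quads) + 1]] <-
      rbind(corner(ii - 1, jj - 1, kk - 1), corner(ii - 1, jj, kk - 1),
            corner(ii, jj, kk - 1), corner(ii, jj - 1, kk - 1))
    if (!pad[i, j, k + 1]) quads[[length(quads) + 1]] <-
      rbind(corner(ii - 1, jj - 1, kk), corner(ii, jj - 1, kk),
            corner(ii, jj, kk), corner(ii - 1, jj, kk))
  }
  V <- do.call(rbind, quads)
  nq <- length(quads)
  base <- (seq_len(nq) - 1) * 4
  F <- rbind(cbind(base + 1, base + 2, base + 3),
             cbind(base + 1, base + 3, base + 4))
  merge_meshes(surface_mesh(V, F, name), weld = TRUE,
               tol = spacing * 1e-6, name = name)
}
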