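## Semi-automatic reconstruction of the atherosclerotic vessel wall and of
## the fibrous plaque component from segmented lumen + plaque surfaces:
##   i)   inner wall surface from the smoothed stenotic-lumen contours;
##   ii)  outer wall surface from the per-plane convex-hull merge of lumen
##        and plaque-hull contours, radially enlarged by the 30-percent rule
##        and cleaned of narrowed sections;
##   iii) wall solid as the Boolean difference of outer and inner surfaces;
##   iv)  fibrous component filling the stenotic gap of the lumen around the
##        lipid and calcific regions (healthy lumen minus stenotic lumen
##        minus components), with the healthy lumen obtained by shrinking
##        the outer-wall sections by the inverse of the enlargement rule.
## All Boolean work is done per cross-sectional plane on star-shaped radius
## functions and re-lofted, which avoids fragile 3-D mesh Booleans.

#' Loft a contour stack into a surface
#'
#' Groups the stack's contours by station and skins them; the one-to-two
#' contour transition at the bifurcation is handled by the branch split
#' construction, with an apex fillet.
#'
#' @param stack a `contour_stack`.
#' @param cap_ends close the end rings with planar caps.
#' @param fillet_radius apex blend radius (mm).
#' @param name mesh tag.
#' @return a [surface_mesh].
#' @export
loft_branch <- function(stack, cap_ends = TRUE, fillet_radius = 1.5,
                        name = NULL) {
  z <- vapply(stack$records, `[[`, 0, "z")
  zs <- sort(unique(z))
  stations <- lapply(zs, function(zi) {
    recs <- stack$records[abs(z - zi) < 1e-9]
    list(z = zi, contours = lapply(recs, `[[`, "poly"))
  })
  loft_stations(stations, cap_ends = cap_ends, fillet_radius = fillet_radius,
                name = name)
}

#' Boolean difference of outer and inner surfaces as a wall solid
#'
#' Both inputs must be watertight solids sharing their end planes (the
#' proximal CCA and distal ICA/ECA cut planes). The end caps of both are
#' stripped, the inner side walls reversed, and the boundary rings joined by
#' annular caps, yielding the closed wall solid whose volume is
#' volume(outer) - volume(inner).
#'
#' @param inner stenotic-lumen solid (inside).
#' @param outer outer-wall solid.
#' @param tol tolerance for identifying end-plane faces (mm).
#' @return watertight [surface_mesh] named `"wall"`.
#' @export
build_wall_solid <- function(inner, outer, tol = 1e-4) {
  vol_i <- mesh_volume(inner); vol_o <- mesh_volume(outer)
  if (vol_o - vol_i < 1e-6 * max(vol_o, 1))
    stop("outer surface does not enclose additional volume over the inner")
  # inner must lie inside outer
  sd <- signed_distance(inner$vertices[seq(1, nrow(inner$vertices),
                                           length.out = min(200, nrow(inner$vertices))), ],
                        outer)
  if (any(sd > 0.2))
    stop("inner surface is not contained in the outer surface ",
         "(max excursion ", round(max(sd), 3), " mm)")
  zr <- range(outer$vertices[, 3])
  oi <- strip_end_caps(outer, zr, tol)
  ii <- strip_end_caps(inner, zr, tol)
  caps <- pair_end_rings(oi$rings, ii$rings)
  wall <- do.call(merge_meshes,
                  c(list(oi$mesh, reverse_faces(ii$mesh)), caps,
                    list(weld = TRUE, tol = 1e-6, name = "wall")))
  wall <- orient_mesh(drop_unused_vertices(wall))
  if (!is_watertight(wall))
    stop("wall solid is not watertight; inner and outer end sections ",
         "probably do not share their cut planes")
  wall
}

# remove planar faces lying on the z = zr end planes; return open mesh and
# its boundary rings
strip_end_caps <- function(mesh, zr, tol) {
  V <- mesh$vertices; F <- mesh$faces
  vz <- V[, 3]
  on_plane <- (abs(vz - zr[1]) < tol) | (abs(vz - zr[2]) < tol)
  drop <- on_plane[F[, 1]] & on_plane[F[, 2]] & on_plane[F[, 3]]
  open <- surface_mesh(V, F[!drop, , drop = FALSE], mesh$name)
  list(mesh = open, rings = boundary_loops(open))
}

# ordered boundary loops (lists of 3-D vertex rings) of an open mesh
boundary_loops <- function(mesh) {
  F <- mesh$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bnd <- he[cnt[key] == 1, , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  nxt <- setNames(bnd[, 2], bnd[, 1])
  loops <- list()
  used <- rep(FALSE, nrow(bnd))
  starts <- bnd[, 1]
  visited <- character(0)
  for (s in starts) {
    if (as.character(s) %in% visited) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      visited <- c(visited, as.character(v))
      v <- nxt[[as.character(v)]]
      if (is.null(v) || v == s) break
    }
    if (length(loop) >= 3)
      loops[[length(loops) + 1]] <- mesh$vertices[loop, , drop = FALSE]
  }
  loops
}

# pair outer and inner boundary rings by plane + centroid and close with
# annular caps
pair_end_rings <- function(outer_rings, inner_rings) {
  caps <- list()
  for (oring in outer_rings) {
    zo <- mean(oring[, 3])
    co <- colMeans(oring)[1:2]
    cand <- Filter(function(r) abs(mean(r[, 3]) - zo) < 1e-3, inner_rings)
    if (length(cand) == 0) next
    d <- vapply(cand, function(r) sum((colMeans(r)[1:2] - co)^2), 0)
    iring <- cand[[which.min(d)]]
    caps[[length(caps) + 1]] <- cap_annulus(oring, iring)
  }
  caps
}

#' Healthy lumen from shrinkage of the outer-wall sections
#'
#' Each outer contour is shrunk radially about its centroid by the inverse
#' of the 30-percent enlargement rule (equivalent radius divided by 1.3) and
#' the result is lofted, under the assumption that a healthy carotid lumen
#' traces the outer wall of the vessel.
#'
#' @param outer_stack outer-wall `contour_stack`.
#' @param shrink factor dividing the outer equivalent radius (default 1.3).
#' @param fillet_radius apex blend radius for the loft.
#' @return watertight [surface_mesh] named `"healthy_lumen"`.
#' @export
build_healthy_lumen <- function(outer_stack, shrink = 1.3,
                                fillet_radius = 1.5) {
  shrink_poly <- function(poly) {
    ctr <- polygon_centroid(poly)
    out <- sweep(sweep(poly, 2, ctr), 2, c(shrink, shrink), `/`)
    sweep(out, 2, ctr, `+`)
  }
  recs <- list()
  for (rec in outer_stack$records) {
    if (!is.null(rec$parts)) {
      # trunk section built as a union of two branch lobes: shrink each
      # lobe about its own centroid, re-union if they still overlap
      lobes <- lapply(rec$parts, shrink_poly)
      two <- list(list(poly = lobes[[1]]), list(poly = lobes[[2]]))
      if (sections_overlap(two)) {
        u <- union_star_sections(lobes[[1]], lobes[[2]], nrow(rec$poly))
        recs[[length(recs) + 1]] <- list(z = rec$z, branch = "CCA", poly = u)
      } else {
        recs[[length(recs) + 1]] <- list(z = rec$z, branch = "ICA",
                                         poly = lobes[[1]])
        recs[[length(recs) + 1]] <- list(z = rec$z, branch = "ECA",
                                         poly = lobes[[2]])
      }
    } else {
      poly <- shrink_poly(rec$poly)
      if (self_intersects(poly))
        stop("shrunk contour self-intersects at z = ", rec$z)
      recs[[length(recs) + 1]] <- list(z = rec$z, branch = rec$branch,
                                       poly = poly)
    }
  }
  loft_branch(contour_stack(recs, outer_stack$spacing),
              fillet_radius = fillet_radius, name = "healthy_lumen")
}

#' Fibrous plaque component by per-plane Boolean difference
#'
#' The fibrous solid fills the stenotic area of the lumen around the lipid
#' and calcific regions: healthy lumen minus stenotic lumen, with
#' lumen-attached components subtracted radially per plane and fully
#' interior components subtracted as reversed cavity surfaces.
#'
#' @param healthy_lumen watertight healthy-lumen mesh.
#' @param stenotic_lumen watertight stenotic-lumen mesh.
#' @param other_components list of calcific/lipid component meshes.
#' @param centerlines centerline set for branch assignment.
#' @param spacing contour spacing (mm).
#' @param min_gap gap threshold below which a station contributes no fibrous
#'   material (mm).
#' @param n_theta angular resolution of the per-plane radial subtraction.
#' @return a [surface_mesh] named `"fibrous"`; empty when there is no
#'   stenosis.
#' @export
build_fibrous_component <- function(healthy_lumen, stenotic_lumen,
                                    other_components = list(),
                                    centerlines = NULL, spacing = 0.5,
                                    min_gap = 0.15, n_theta = 64) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zr <- range(stenotic_lumen$vertices[, 3])
  z_range <- c(zr[1] + spacing, zr[2] - spacing)
  h_stack <- slice_contours(healthy_lumen, centerlines, spacing, z_range)
  s_stack <- slice_contours(stenotic_lumen, centerlines, spacing, z_range)

  # classify components: attached to the lumen (radial subtraction) or
  # strictly interior (cavity subtraction)
  attached <- list(); interior <- list()
  for (m in other_components) {
    if (is_empty_mesh(m)) next
    dmin <- min(mesh_closest(m$vertices, stenotic_lumen)$dist)
    if (dmin < 0.3) attached[[length(attached) + 1]] <- m
    else interior[[length(interior) + 1]] <- m
  }

  parts <- list()
  z_bif <- if (is.null(centerlines)) Inf else centerlines$z_bif
  for (b in stack_branches(s_stack)) {
    s_recs <- stack_branch(s_stack, b)
    h_recs <- stack_branch(h_stack, b)
    hz <- vapply(h_recs, `[[`, 0, "z")
    zi <- c(); r_in_l <- list(); r_out_l <- list(); ctrs <- list()
    for (rec in s_recs) {
      # trunk stations above the bifurcation belong to the merging
      # transition: the gap between the convex healthy section and the
      # two-lobed lumen there is the crotch saddle, not a stenosis
      if (b == "CCA" && rec$z > z_bif) next
      j <- which(abs(hz - rec$z) < 1e-9)
      if (length(j) != 1) next
      ctr <- polygon_centroid(h_recs[[j]]$poly)
      r_out <- poly_to_radius(h_recs[[j]]$poly, ctr, thetas)
      r_in <- poly_to_radius(rec$poly, ctr, thetas)
      for (m in attached) {
        cpolys <- slice_mesh_z(m, rec$z)
        for (cp in cpolys) {
          if (!is.null(centerlines) &&
              assign_branch(polygon_centroid(cp), rec$z, centerlines) != b)
            next
          rc <- ray_polygon_max_r(cp, ctr, thetas)
          r_in <- pmax(r_in, ifelse(is.na(rc), 0, rc))
        }
      }
      zi <- c(zi, rec$z)
      r_in_l[[length(r_in_l) + 1]] <- pmin(r_in, r_out)
      r_out_l[[length(r_out_l) + 1]] <- r_out
      ctrs[[length(ctrs) + 1]] <- ctr
    }
    if (length(zi) < 2) next
    r_in_m <- do.call(rbind, r_in_l)
    r_out_m <- do.call(rbind, r_out_l)
    ctr_of <- function(z) ctrs[[which.min(abs(zi - z))]]
    ann <- loft_annulus(zi, thetas, r_in_m, r_out_m, ctr_of, "fibrous",
                        min_gap = min_gap)
    if (!is_empty_mesh(ann)) parts[[length(parts) + 1]] <- ann
  }
  if (length(parts) == 0) return(empty_mesh("fibrous"))
  fib <- if (length(parts) == 1) parts[[1]] else
    do.call(merge_meshes, c(parts, list(weld = FALSE, name = "fibrous")))
  for (m in interior)
    fib <- merge_meshes(fib, reverse_faces(ensure_outward(m)), weld = FALSE,
                        name = "fibrous")
  fib
}

#' Reconstruct the vessel wall and fibrous component from segmented surfaces
#'
#' Runs the full semi-automatic reconstruction on a segmented stenotic lumen
#' and its plaque component surfaces: plaque quickhull envelope, contour
#' extraction, B-spline smoothing, per-plane convex-hull merging, radial
#' enlargement by the 30-percent rule (anchored per branch at the distal
#' inner ICA/ECA radius; the trunk uses the larger of the two, and the
#' bifurcation transition scales each merged section by 1.3), narrowing
#' removal, lofting, and the per-plane Boolean construction of the wall
#' solid, healthy lumen and fibrous component.
#'
#' @param lumen watertight stenotic-lumen [surface_mesh].
#' @param components list of plaque component meshes (may be empty).
#' @param centerlines centerline set ([carotid_centerlines()]).
#' @param spacing cross-sectional plane spacing (mm, default 0.5).
#' @param n_control B-spline control points for contour smoothing.
#' @param n_theta angular resolution of lofted contours.
#' @param enlarge_factor outer-wall enlargement factor (default 1.3, the
#'   30-percent rule).
#' @param narrow_frac narrowing-removal threshold (default 0.98).
#' @param fillet_radius apex blend radius (mm).
#' @return object of class `wall_model`: list with `inner`, `outer`,
#'   `wall_solid`, `healthy_lumen`, `fibrous`, the outer `contour_stack`
#'   and the per-branch reference radii.
#' @export
reconstruct_wall <- function(lumen, components = list(), centerlines = NULL,
                             spacing = 0.5, n_control = 16, n_theta = 64,
                             enlarge_factor = 1.3, narrow_frac = 0.98,
                             fillet_radius = 1.5) {
  components <- Filter(Negate(is_empty_mesh), components)
  hull <- if (length(components) > 0) plaque_hull(components) else NULL

  zr <- range(lumen$vertices[, 3])
  z_range <- c(zr[1] + spacing, zr[2] - spacing)
  raw_stack <- slice_contours(lumen, centerlines, spacing, z_range)
  smooth_recs <- lapply(raw_stack$records, function(rec) {
    rec$poly <- rebuild_smooth(rec$poly, n_control = n_control,
                               n_out = n_theta)
    rec
  })
  lumen_stack <- contour_stack(smooth_recs, spacing)
  inner <- loft_branch(lumen_stack, fillet_radius = fillet_radius,
                       name = "lumen")

  # distal inner reference radii (top station of each separated branch)
  ref_r <- distal_reference_radii(lumen_stack, centerlines)

  z <- vapply(lumen_stack$records, `[[`, 0, "z")
  zs <- sort(unique(z))
  z_bif <- if (!is.null(centerlines)) centerlines$z_bif else -Inf
  outer_recs <- list()
  for (zi in zs) {
    recs <- lumen_stack$records[abs(z - zi) < 1e-9]
    hull_polys <- if (!is.null(hull)) slice_mesh_z(hull, zi) else list()
    station_out <- list()
    for (rec in recs) {
      hp <- Filter(function(p) {
        is.null(centerlines) ||
          assign_branch(polygon_centroid(p), zi, centerlines) == rec$branch ||
          length(recs) == 1
      }, hull_polys)
      merged <- merge_lumen_plaque(rec$poly, hp)
      target <- if (length(recs) == 1 && zi > z_bif) {
        # bifurcation transition: merged trunk section scaled by the rule
        enlarge_factor * equivalent_radius(merged)
      } else {
        enlarge_factor * ref_r[[rec$branch]]
      }
      out_poly <- enlarge_section(merged, target)
      station_out[[length(station_out) + 1]] <-
        list(z = zi, branch = rec$branch,
             poly = resample_polygon(out_poly, n_theta),
             narrowed = isTRUE(attr(out_poly, "narrowed")))
    }
    # overlapping enlarged branch sections are unioned into one trunk
    # section; the pre-union parts are kept so that the healthy-lumen
    # shrinkage can act on each branch lobe separately
    if (length(station_out) == 2 && sections_overlap(station_out)) {
      u <- union_star_sections(station_out[[1]]$poly, station_out[[2]]$poly,
                               n_theta)
      station_out <- list(list(z = zi, branch = "CCA", poly = u,
                               narrowed = FALSE, exempt = TRUE,
                               parts = list(station_out[[1]]$poly,
                                            station_out[[2]]$poly)))
    }
    outer_recs <- c(outer_recs, station_out)
  }
  outer_stack <- contour_stack(outer_recs, spacing)
  outer_stack <- drop_narrowed_sections(outer_stack, frac = narrow_frac,
                                        n_theta = n_theta)
  outer <- loft_branch(outer_stack, fillet_radius = fillet_radius,
                       name = "outer")

  wall_solid <- build_wall_solid(inner, outer)
  healthy <- build_healthy_lumen(outer_stack, shrink = enlarge_factor,
                                 fillet_radius = fillet_radius)
  fibrous <- build_fibrous_component(healthy, inner, components, centerlines,
                                     spacing = spacing, n_theta = n_theta)
  structure(list(inner = inner, outer = outer, wall_solid = wall_solid,
                 healthy_lumen = healthy, fibrous = fibrous,
                 outer_stack = outer_stack, lumen_stack = lumen_stack,
                 reference_radii = ref_r),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat("wall_model\n")
  cat(sprintf("  inner lumen volume   %8.2f mm^3\n", mesh_volume(x$inner)))
  cat(sprintf("  outer volume         %8.2f mm^3\n", mesh_volume(x$outer)))
  cat(sprintf("  wall solid volume    %8.2f mm^3\n", mesh_volume(x$wall_solid)))
  cat(sprintf("  healthy lumen volume %8.2f mm^3\n",
              mesh_volume(x$healthy_lumen)))
  cat(sprintf("  fibrous volume       %8.2f mm^3\n", mesh_volume(x$fibrous)))
  invisible(x)
}

# distal (top-station) inner equivalent radius per branch; the trunk uses
# the larger of the two daughter radii
distal_reference_radii <- function(lumen_stack, centerlines) {
  branches <- stack_branches(lumen_stack)
  ref <- list()
  for (b in branches) {
    recs <- stack_branch(lumen_stack, b)
    ref[[b]] <- equivalent_radius(recs[[length(recs)]]$poly)
  }
  daughters <- setdiff(branches, "CCA")
  ref[["CCA"]] <- if (length(daughters) > 0)
    max(unlist(ref[daughters])) else ref[["CCA"]]
  ref
}

sections_overlap <- function(station_out) {
  p1 <- station_out[[1]]$poly; p2 <- station_out[[2]]$poly
  c1 <- polygon_centroid(p1); c2 <- polygon_centroid(p2)
  d <- sqrt(sum((c2 - c1)^2))
  r1 <- max(sqrt(rowSums(sweep(p1, 2, c1)^2)))
  r2 <- max(sqrt(rowSums(sweep(p2, 2, c2)^2)))
  d < r1 + r2
}

# union of two overlapping star-shaped sections as one star contour; the
# small bridging radius keeps the crotch saddle open near tangency
union_star_sections <- function(p1, p2, n_theta, bridge = 0.8) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  c1 <- polygon_centroid(p1); c2 <- polygon_centroid(p2)
  r1 <- equivalent_radius(p1); r2 <- equivalent_radius(p2)
  d <- sqrt(sum((c2 - c1)^2))
  ctr <- if (d < 1e-9) c1 else {
    u <- (c2 - c1) / d
    c1 + u * ((d - r2) + r1) / 2
  }
  ra <- ray_polygon_max_r(p1, ctr, thetas)
  rb <- ray_polygon_max_r(p2, ctr, thetas)
  r <- pmax(ifelse(is.na(ra), 0, ra), ifelse(is.na(rb), 0, rb), bridge)
  radius_to_poly(r, ctr, thetas)
}
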