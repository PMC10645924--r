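## ContourStack: ordered planar closed curves per branch per cross-sectional
## plane -- the intermediate representation of the wall reconstruction.
## All cutting planes are perpendicular to the global z axis (the common
## carotid trunk axis), matching the axial cross-sections of the imaging
## frame.

contour_stack <- function(records, spacing) {
  structure(list(records = records, spacing = spacing),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  z <- vapply(x$records, `[[`, 0, "z")
  br <- vapply(x$records, `[[`, "", "branch")
  cat(sprintf("contour_stack: %d contours, %d stations, spacing %.3g mm\n",
              length(x$records), length(unique(z)), x$spacing))
  for (b in unique(br))
    cat(sprintf("  %s: z in [%.2f, %.2f] (%d contours)\n", b,
                min(z[br == b]), max(z[br == b]), sum(br == b)))
  invisible(x)
}

stack_branch <- function(stack, branch) {
  recs <- Filter(function(r) r$branch == branch, stack$records)
  o <- order(vapply(recs, `[[`, 0, "z"))
  recs[o]
}

stack_branches <- function(stack)
  unique(vapply(stack$records, `[[`, "", "branch"))

#' Cut a surface with evenly spaced cross-sectional planes
#'
#' Slices the surface with horizontal planes at the given spacing and chains
#' each plane's intersection into closed contour polygons, assigned to the
#' CCA/ICA/ECA branches by proximity to the centerline set. Near-tangent
#' (degenerate, near-zero-area) contours are dropped.
#'
#' @param surface a watertight [surface_mesh].
#' @param centerlines centerline set as produced by [carotid_centerlines()],
#'   or NULL to label every contour with a single branch `"CCA"`.
#' @param spacing plane spacing in mm (default 0.5).
#' @param z_range optional range of stations; defaults to the surface extent
#'   inset by half a spacing.
#' @return a `contour_stack`.
#' @export
slice_contours <- function(surface, centerlines = NULL, spacing = 0.5,
                           z_range = NULL) {
  stopifnot(spacing > 0)
  if (is.null(z_range)) {
    zr <- range(surface$vertices[, 3])
    z_range <- c(zr[1] + spacing / 2, zr[2] - spacing / 2)
  }
  zs <- seq(z_range[1], z_range[2], by = spacing)
  records <- list()
  for (z in zs) {
    polys <- slice_mesh_z(surface, z)
    for (poly in polys) {
      ctr <- polygon_centroid(poly)
      # a station with a single contour is the (possibly merging) trunk
      branch <- if (length(polys) == 1) "CCA"
                else assign_branch(ctr, z, centerlines)
      records[[length(records) + 1]] <-
        list(z = z, branch = branch, poly = poly)
    }
  }
  contour_stack(records, spacing)
}

assign_branch <- function(center, z, centerlines) {
  if (is.null(centerlines)) return("CCA")
  best <- NULL; bestd <- Inf
  for (b in names(centerlines$branches)) {
    cl <- centerlines$branches[[b]]
    if (z < min(cl[, 1]) - 1e-9 || z > max(cl[, 1]) + 1e-9) next
    cx <- approx(cl[, 1], cl[, 2], xout = z)$y
    cy <- approx(cl[, 1], cl[, 3], xout = z)$y
    d <- (center[1] - cx)^2 + (center[2] - cy)^2
    if (d < bestd) { bestd <- d; best <- b }
  }
  best %||% "CCA"
}

#' Remove narrowed outer-wall sections and re-interpolate
#'
#' After the enlargement step, stations where the outer wall contour shows a
#' narrowing (equivalent radius below `frac` of the linear interpolation
#' between the neighboring retained stations) are removed per branch, and
#' refilled at the original stations by per-vertex linear blending of the
#' adjacent retained contours, modelling the ideal physiological outer wall.
#'
#' @param stack outer-wall `contour_stack` (one contour per station per
#'   branch).
#' @param frac dip threshold as a fraction of the neighbor interpolation
#'   (default 0.98).
#' @param n_theta angular samples used for the blended contours.
#' @return a `contour_stack` with the same stations, narrowed ones replaced.
#' @export
drop_narrowed_sections <- function(stack, frac = 0.98, n_theta = 64) {
  out <- list()
  for (b in stack_branches(stack)) {
    recs <- stack_branch(stack, b)
    z <- vapply(recs, `[[`, 0, "z")
    r <- vapply(recs, function(rec) equivalent_radius(rec$poly), 0)
    n <- length(recs)
    if (n < 2) stop("branch ", b, ": fewer than 2 stations")
    keep <- rep(TRUE, n)
    # sections marked exempt (bifurcation-transition unions, whose radius
    # legitimately necks down) are never treated as narrowed
    exempt <- vapply(recs, function(r) isTRUE(r$exempt), TRUE)
    repeat {
      ki <- which(keep)
      if (length(ki) < 3) break
      interior <- setdiff(ki[-c(1, length(ki))], which(exempt))
      viol <- numeric(0)
      for (i in interior) {
        lo <- max(ki[ki < i]); hi <- min(ki[ki > i])
        rint <- r[lo] + (r[hi] - r[lo]) * (z[i] - z[lo]) / (z[hi] - z[lo])
        if (r[i] < frac * rint) viol <- c(viol, i)
      }
      if (length(viol) == 0) break
      worst <- viol[which.min(r[viol])]
      keep[worst] <- FALSE
    }
    if (sum(keep) < 2) stop("branch ", b, ": fewer than 2 retained stations")
    thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    polar <- lapply(which(keep), function(i) {
      ctr <- polygon_centroid(recs[[i]]$poly)
      list(center = ctr, r = poly_to_radius(recs[[i]]$poly, ctr, thetas))
    })
    kz <- z[keep]
    for (i in seq_len(n)) {
      if (keep[i]) {
        out[[length(out) + 1]] <- recs[[i]]
      } else {
        hi <- min(which(kz > z[i])); lo <- hi - 1
        t <- (z[i] - kz[lo]) / (kz[hi] - kz[lo])
        ctr <- (1 - t) * polar[[lo]]$center + t * polar[[hi]]$center
        rr <- (1 - t) * polar[[lo]]$r + t * polar[[hi]]$r
        out[[length(out) + 1]] <-
          list(z = z[i], branch = b, poly = radius_to_poly(rr, ctr, thetas))
      }
    }
  }
  contour_stack(out, stack$spacing)
}

#' Serialize a contour stack to a plain-text file
#'
#' One record per contour: a header line `contour <branch> <z> <k>` followed
#' by `k` lines of `x y` vertex coordinates (mm).
#'
#' @param stack a `contour_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# carofem contour stack",
               sprintf("spacing %.9g", stack$spacing)), con)
  for (rec in stack$records) {
    writeLines(sprintf("contour %s %.9g %d", rec$branch, rec$z,
                       nrow(rec$poly)), con)
    writeLines(sprintf("%.9g %.9g", rec$poly[, 1], rec$poly[, 2]), con)
  }
  invisible(path)
}

#' Read a contour stack written by [write_contour_stack()]
#' @param path input file.
#' @return a `contour_stack`.
#' @export
read_contour_stack <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  spacing <- as.numeric(strsplit(lines[1], " ")[[1]][2])
  records <- list()
  i <- 2
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    stopifnot(hdr[1] == "contour")
    k <- as.integer(hdr[4])
    xy <- do.call(rbind, lapply(lines[(i + 1):(i + k)], function(l)
      as.numeric(strsplit(l, " ")[[1]])))
    records[[length(records) + 1]] <-
      list(z = as.numeric(hdr[3]), branch = hdr[2], poly = xy)
    i <- i + k + 1
  }
  contour_stack(records, spacing)
}
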