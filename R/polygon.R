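## 2-D closed-polygon utilities underpinning the contour-driven reconstruction.
## Polygons are k x 2 matrices, open storage (no repeated closing vertex),
## counter-clockwise for positive area.

#' Signed polygon area (shoelace formula)
#' @param poly k x 2 matrix of vertices.
#' @return signed area in mm^2 (positive for counter-clockwise).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Area centroid of a simple polygon
#' @param poly k x 2 matrix of vertices.
#' @return length-2 centroid.
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1), ] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Equivalent radius of a planar contour
#'
#' Radius of the circle with the same enclosed area, sqrt(area / pi).
#' @param poly k x 2 matrix.
#' @return radius in mm.
#' @export
equivalent_radius <- function(poly) sqrt(abs(polygon_area(poly)) / pi)

# resample a closed polygon to n vertices uniformly by arc length
resample_polygon <- function(poly, n) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(approx(s, p[, 1], xout = at)$y, approx(s, p[, 2], xout = at)$y)
}

# radius function r(theta) of a star-shaped polygon about `center`,
# linearly interpolated in polar coordinates at the given angles
poly_to_radius <- function(poly, center, thetas) {
  d <- sweep(poly, 2, center)
  ang <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  r <- sqrt(rowSums(d^2))
  o <- order(ang)
  ang <- ang[o]; r <- r[o]
  # periodic extension for interpolation
  ang_ext <- c(ang - 2 * pi, ang, ang + 2 * pi)
  r_ext <- rep(r, 3)
  approx(ang_ext, r_ext, xout = thetas %% (2 * pi), ties = "ordered")$y
}

radius_to_poly <- function(r, center, thetas) {
  cbind(center[1] + r * cos(thetas), center[2] + r * sin(thetas))
}

# largest crossing radius of ray (center, theta) with a polygon, NA if none
ray_polygon_max_r <- function(poly, center, thetas) {
  a <- sweep(poly, 2, center)
  b <- sweep(poly[c(2:nrow(poly), 1), , drop = FALSE], 2, center)
  out <- rep(NA_real_, length(thetas))
  for (i in seq_along(thetas)) {
    u <- c(cos(thetas[i]), sin(thetas[i]))
    # solve a + t (b - a) = r u, r >= 0, t in [0,1]
    ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
    den <- ex * u[2] - ey * u[1]
    ok <- abs(den) > 1e-14
    t <- (a[, 2] * u[1] - a[, 1] * u[2]) / den
    r <- if (abs(u[1]) > abs(u[2])) (a[, 1] + t * ex) / u[1]
         else (a[, 2] + t * ey) / u[2]
    hit <- ok & t >= -1e-9 & t <= 1 + 1e-9 & r > 0
    if (any(hit)) out[i] <- max(r[hit])
  }
  out
}

# does a closed polygon self-intersect? brute-force segment pair test
self_intersects <- function(poly) {
  k <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:k, 1), , drop = FALSE]
  for (i in seq_len(k - 2)) {
    js <- (i + 2):k
    js <- js[!(i == 1 & js == k)]        # skip adjacent segments
    if (length(js) == 0) next
    if (any(segments_cross(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                           p2[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(a1, a2, B1, B2) {
  d1 <- cross2(a2 - a1, sweep(B1, 2, a1))
  d2 <- cross2(a2 - a1, sweep(B2, 2, a1))
  d3 <- cross2_rows(B2 - B1, sweep(-B1, 2, -a1))
  d4 <- cross2_rows(B2 - B1, sweep(-B1, 2, -a2))
  (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
}

cross2 <- function(u, M) u[1] * M[, 2] - u[2] * M[, 1]
cross2_rows <- function(U, M) U[, 1] * M[, 2] - U[, 2] * M[, 1]

#' Convex hull of 2-D points as a closed polygon
#' @param pts n x 2 matrix.
#' @return hull polygon, counter-clockwise.
#' @export
convex_hull_2d <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])   # clockwise order
  poly <- pts[rev(idx), , drop = FALSE]
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

#' Merge lumen and plaque contours of one cross-sectional plane
#'
#' The per-plane merge of the outer-wall construction: the single closed
#' curve delimiting lumen and plaque together is their planar convex hull.
#' With no plaque contours the hull of the lumen alone is returned.
#'
#' @param lumen_polygon k x 2 lumen contour.
#' @param plaque_polygons list of plaque contours in the same plane (may be
#'   empty).
#' @return convex polygon containing every input vertex.
#' @export
merge_lumen_plaque <- function(lumen_polygon, plaque_polygons = list()) {
  pts <- do.call(rbind, c(list(lumen_polygon), plaque_polygons))
  convex_hull_2d(pts)
}

#' Radially enlarge a merged section to a target outer radius
#'
#' Every vertex is shifted radially outward from the section centroid so that
#' the equivalent radius sqrt(area/pi) of the result equals
#' `target_outer_radius`; the input region stays enclosed between the inner
#' and outer profile. The target implements the outer-wall sizing rule: the
#' distal inner radius of the respective branch increased by 30 percent.
#' A section whose equivalent radius already exceeds the target is returned
#' shrunk and flagged with attribute `narrowed = TRUE` for the subsequent
#' narrowing-removal step.
#'
#' @param merged_polygon convex merged contour (k x 2).
#' @param target_outer_radius target equivalent radius in mm.
#' @return enlarged polygon; attribute `narrowed` set when the target was
#'   smaller than the input equivalent radius.
#' @export
enlarge_section <- function(merged_polygon, target_outer_radius) {
  stopifnot(target_outer_radius > 0)
  r0 <- equivalent_radius(merged_polygon)
  f <- target_outer_radius / r0
  ctr <- polygon_centroid(merged_polygon)
  out <- sweep(sweep(merged_polygon, 2, ctr), 2, c(f, f), `*`)
  out <- sweep(out, 2, ctr, `+`)
  attr(out, "narrowed") <- f < 1
  out
}

#' Rebuild a contour as a smooth periodic B-spline curve
#'
#' Least-squares fit of a closed uniform periodic cubic B-spline with
#' `n_control` control points, sampled back to a polygon. This is the
#' contour-smoothing step applied to every cross-section before lofting;
#' for well-resolved inputs the enclosed area changes by less than 5 percent.
#' A self-intersecting result is retried with more control points.
#'
#' @param polygon simple closed k x 2 polygon.
#' @param n_control number of control points (>= 4).
#' @param n_out number of output samples.
#' @return smooth closed polygon (`n_out` x 2), counter-clockwise.
#' @export
rebuild_smooth <- function(polygon, n_control = 16, n_out = 64) {
  stopifnot(n_control >= 4)
  if (polygon_area(polygon) < 0)
    polygon <- polygon[rev(seq_len(nrow(polygon))), , drop = FALSE]
  for (nc in unique(c(n_control, n_control * 2, n_control * 4))) {
    out <- bspline_fit_closed(polygon, nc, n_out)
    if (!self_intersects(out)) return(out)
  }
  stop("contour smoothing produced a self-intersecting curve even after ",
       "increasing the number of control points")
}

# periodic uniform cubic B-spline least-squares fit + resampling
bspline_fit_closed <- function(poly, n_control, n_out) {
  k <- nrow(poly)
  # arc-length parameters of the data in [0, n_control)
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))[-(k + 1)] / sum(seg) * n_control
  A <- bspline_basis_closed(s, n_control)
  AtA <- crossprod(A) + diag(1e-10, n_control)
  ctrl <- solve(AtA, crossprod(A, poly))
  t_out <- seq(0, n_control, length.out = n_out + 1)[-(n_out + 1)]
  B <- bspline_basis_closed(t_out, n_control)
  as.matrix(B %*% ctrl)
}

# basis matrix: rows = parameters t, cols = periodic control points
bspline_basis_closed <- function(t, n) {
  i <- floor(t)
  u <- t - i
  b <- cbind((1 - u)^3, 3 * u^3 - 6 * u^2 + 4, -3 * u^3 + 3 * u^2 + 3 * u + 1,
             u^3) / 6
  A <- matrix(0, length(t), n)
  for (k in 0:3) {
    col <- ((i + k - 1) %% n) + 1
    A[cbind(seq_along(t), col)] <- A[cbind(seq_along(t), col)] + b[, k + 1]
  }
  A
}
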