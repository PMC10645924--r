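## Incremental 3-D convex hull (quickhull-family algorithm): points are added
## one at a time, visible faces are removed and the horizon re-triangulated.
## Used to delimit the region of space enclosing the plaque components with a
## single watertight surface.

#' 3-D convex hull of a point set
#'
#' @param pts n x 3 matrix of points.
#' @return a watertight [surface_mesh] of the hull; every input point lies
#'   inside or on it.
#' @export
convex_hull_3d <- function(pts) {
  pts <- unique(round(rbind(pts), 10))
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs at least 4 distinct points")
  scale <- max(apply(pts, 2, function(x) diff(range(x))))
  eps <- 1e-9 * max(scale, 1)
  init <- initial_simplex(pts, eps)
  if (is.null(init))
    stop("degenerate input: points are coplanar, no 3-D hull exists")
  faces <- init                                   # f x 3 outward triangles
  geom <- hull_face_geom(pts, faces)
  ord <- order(-rowSums(sweep(pts, 2, colMeans(pts))^2))  # far points first
  for (p in ord) {
    d <- geom$normals %*% pts[p, ] - geom$offsets
    visible <- which(d > eps)
    if (length(visible) == 0) next
    vis_faces <- faces[visible, , drop = FALSE]
    dir_edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                       vis_faces[, c(3, 1)])
    ekey <- paste(dir_edges[, 1], dir_edges[, 2])
    rkey <- paste(dir_edges[, 2], dir_edges[, 1])
    horizon <- dir_edges[!(ekey %in% rkey), , drop = FALSE]
    faces <- faces[-visible, , drop = FALSE]
    newf <- cbind(horizon, p)
    faces <- rbind(faces, newf)
    geom <- hull_face_geom(pts, faces)
  }
  used <- sort(unique(as.vector(faces)))
  remap <- match(faces, used)
  mesh <- surface_mesh(pts[used, , drop = FALSE], matrix(remap, ncol = 3))
  mesh <- ensure_outward(mesh)
  if (!is_watertight(mesh)) stop("internal error: hull not watertight")
  mesh
}

hull_face_geom <- function(pts, faces) {
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c <- pts[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  list(normals = nrm, offsets = rowSums(nrm * a))
}

# pick 4 affinely independent points and orient the initial tetrahedron
initial_simplex <- function(pts, eps) {
  i1 <- which.min(pts[, 1])
  d <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d)
  if (d[i2] < eps^2) return(NULL)
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(w[, 2] * u[3] - w[, 3] * u[2],
              w[, 3] * u[1] - w[, 1] * u[3],
              w[, 1] * u[2] - w[, 2] * u[1])
  a2 <- rowSums(cr^2)
  i3 <- which.max(a2)
  if (a2[i3] < (eps * sqrt(sum(u^2)))^2) return(NULL)
  nrm <- crossprod_vec(u, pts[i3, ] - pts[i1, ])
  h <- abs(w %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < eps) return(NULL)
  tet <- c(i1, i2, i3, i4)
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4))
  faces <- matrix(tet[f], ncol = 3)
  # orient all faces outward w.r.t. the tetrahedron centroid
  ctr <- colMeans(pts[tet, ])
  g <- hull_face_geom(pts, faces)
  flip <- (g$normals %*% ctr - g$offsets) > 0
  faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
  faces
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Envelope of the plaque components
#'
#' Delimits the region of space enclosing all plaque component surfaces with
#' a single convex watertight surface (quickhull of all component vertices),
#' the first step of the outer-wall construction.
#'
#' @param components list of plaque component [surface_mesh] objects (at
#'   least one, non-degenerate).
#' @return a [surface_mesh] named `"plaque_hull"`.
#' @export
plaque_hull <- function(components) {
  components <- Filter(Negate(is_empty_mesh), components)
  if (length(components) == 0) stop("at least one plaque component required")
  pts <- do.call(rbind, lapply(components, `[[`, "vertices"))
  mesh <- convex_hull_3d(pts)
  mesh$name <- "plaque_hull"
  mesh
}
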