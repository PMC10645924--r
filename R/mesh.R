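#' @useDynLib carofem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median quantile runif sd setNames uniroot
#' @importFrom utils head read.csv tail write.csv
NULL

#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface in millimetres: the
#' currency of segmentation output, CAD reconstruction and distance analysis.
#' Faces are one-based triangle indices; solids are expected to be watertight
#' (every edge shared by exactly two consistently oriented triangles) with
#' outward orientation and positive enclosed volume.
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of one-based vertex indices.
#' @param name optional tag, e.g. "lumen", "calcific", "lipid",
#'   "fibrous_reference" or "wall".
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, name = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh%s: %d vertices, %d faces\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0)
    cat(sprintf("  enclosed volume %.3f mm^3, watertight: %s\n",
                mesh_volume(x), is_watertight(x)))
  invisible(x)
}

empty_mesh <- function(name = NULL) {
  surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3), name)
}

is_empty_mesh <- function(mesh) is.null(mesh) || nrow(mesh$faces) == 0

#' Signed enclosed volume of a closed surface
#'
#' Divergence-theorem volume: one sixth of the sum of triple products over
#' faces. Positive for outward-oriented watertight surfaces.
#'
#' @param mesh a [surface_mesh].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
                 b[, 3] * c[, 1] - b[, 1] * c[, 3],
                 b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

face_centroids <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' Edge-manifold watertightness check
#'
#' A surface is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).
#'
#' @param mesh a [surface_mesh].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (is_empty_mesh(mesh)) return(FALSE)
  F <- mesh$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  # opposite traversal: each directed edge must appear exactly once
  dkey <- paste(he[, 1], he[, 2])
  !any(duplicated(dkey))
}

#' Reverse face orientation
#' @param mesh a [surface_mesh].
#' @return the mesh with all faces flipped.
#' @export
reverse_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

ensure_outward <- function(mesh) {
  if (!is_empty_mesh(mesh) && mesh_volume(mesh) < 0) reverse_faces(mesh) else mesh
}

#' Concatenate meshes into one
#'
#' Vertices are concatenated and optionally welded (duplicates within `tol`
#' merged) so that composed boundary pieces share their ring vertices.
#'
#' @param ... surface_mesh objects.
#' @param weld merge coincident vertices.
#' @param tol welding tolerance in mm.
#' @param name optional tag for the result.
#' @return a single [surface_mesh].
#' @export
merge_meshes <- function(..., weld = TRUE, tol = 1e-6, name = NULL) {
  parts <- Filter(Negate(is_empty_mesh), list(...))
  if (length(parts) == 0) return(empty_mesh(name))
  V <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  off <- cumsum(c(0, head(vapply(parts, function(m) nrow(m$vertices), 1L), -1)))
  F <- do.call(rbind, Map(function(m, o) m$faces + o, parts, off))
  if (weld) {
    key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
    idx <- match(key, key)                 # representative per coincident group
    keep <- sort(unique(idx))
    remap <- match(idx, keep)
    V <- V[keep, , drop = FALSE]
    F <- matrix(remap[F], ncol = 3)
    deg <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 3] == F[, 1]
    F <- F[!deg, , drop = FALSE]
  }
  surface_mesh(V, F, name)
}

#' Point-in-solid test by ray parity
#'
#' Casts a ray from each point and counts surface crossings.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight [surface_mesh].
#' @return logical vector, TRUE where the point lies inside.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- rbind(points)
  if (is_empty_mesh(mesh)) return(rep(FALSE, nrow(points)))
  cpp_ray_parity(points, mesh$vertices, mesh$faces)
}

#' Closest point on a mesh
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a [surface_mesh].
#' @return list with `dist` (mm), `face` (one-based index of nearest
#'   triangle) and `point` (n x 3 matrix of closest surface points).
#' @export
mesh_closest <- function(points, mesh) {
  points <- rbind(points)
  cpp_closest_point(points, mesh$vertices, mesh$faces)
}

#' Signed distance to a watertight surface
#'
#' Unsigned closest distance with sign from ray parity: negative inside the
#' enclosed solid, positive outside.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight [surface_mesh].
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance <- function(points, mesh) {
  points <- rbind(points)
  d <- mesh_closest(points, mesh)$dist
  inside <- points_in_mesh(points, mesh)
  d * ifelse(inside, -1, 1)
}

## ---- STL input/output -------------------------------------------------------

#' Write a mesh to STL
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @param binary write the 80-byte-header binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices; F <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste0("carofem ", mesh$name %||% "mesh")))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (f in seq_len(nrow(F))) {
      writeBin(as.numeric(c(n[f, ], t(V[F[f, ], ]))), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    tri <- cbind(n, V[F[, 1], , drop = FALSE], V[F[, 2], , drop = FALSE],
                 V[F[, 3], , drop = FALSE])
    lines <- c(sprintf("solid %s", mesh$name %||% "mesh"),
               as.vector(t(cbind(
                 sprintf("  facet normal %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 4], tri[, 5], tri[, 6]),
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 7], tri[, 8], tri[, 9]),
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 10], tri[, 11], tri[, 12]),
                 "    endloop",
                 "  endfacet"))),
               sprintf("endsolid %s", mesh$name %||% "mesh"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' Coincident vertices are welded so that a valid solid reads back watertight.
#'
#' @param path STL file.
#' @param name optional tag for the resulting mesh.
#' @return a [surface_mesh].
#' @export
read_stl <- function(path, name = NULL) {
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", 512)
  close(con)
  txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    tri <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- matrix(NA_real_, nf, 9)
    for (f in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      rec[f, ] <- vals[4:12]
    }
    tri <- matrix(t(rec), ncol = 3, byrow = TRUE)
  }
  nf <- nrow(tri) / 3
  F <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  merge_meshes(surface_mesh(tri, F, name), weld = TRUE, tol = 1e-5, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop vertices not referenced by any face (e.g. after cap stripping)
drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  mesh$faces <- matrix(match(mesh$faces, used), ncol = 3)
  mesh
}

## ---- planar slicing ---------------------------------------------------------

#' Intersect a surface with a horizontal plane
#'
#' Cuts the mesh with the plane z = `z` and chains the triangle intersection
#' segments into closed planar polygons. Near-degenerate (tangent) contours
#' whose area falls below `min_area` are dropped.
#'
#' @param mesh a watertight [surface_mesh].
#' @param z plane station (mm).
#' @param min_area area threshold for dropping degenerate contours (mm^2).
#' @return list of k x 2 matrices of (x, y) vertices, counter-clockwise.
#' @export
slice_mesh_z <- function(mesh, z, min_area = 1e-3) {
  V <- mesh$vertices; F <- mesh$faces
  zz <- V[, 3] - z
  zz[abs(zz) < 1e-9] <- 1e-9        # on-plane vertices count as above
  tz <- matrix(zz[F], ncol = 3)
  cross <- (apply(tz, 1, max) > 0) & (apply(tz, 1, min) < 0)
  if (!any(cross)) return(list())
  segs <- vector("list", sum(cross))
  si <- 0
  for (f in which(cross)) {
    idx <- F[f, ]
    d <- zz[idx]
    pts <- matrix(NA_real_, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- d[e[1]]; d2 <- d[e[2]]
      if ((d1 > 0) != (d2 > 0)) {
        t <- d1 / (d1 - d2)
        p <- V[idx[e[1]], 1:2] + t * (V[idx[e[2]], 1:2] - V[idx[e[1]], 1:2])
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) == 2) {
      si <- si + 1
      segs[[si]] <- pts
    }
  }
  segs <- segs[seq_len(si)]
  chain_segments(segs, min_area = min_area)
}

# chain unordered 2-D segments into closed polygons
chain_segments <- function(segs, tol = 1e-6, min_area = 1e-3) {
  if (length(segs) == 0) return(list())
  ends <- do.call(rbind, segs)                       # 2 rows per segment
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  n <- length(segs)
  k1 <- key[seq(1, 2 * n, by = 2)]
  k2 <- key[seq(2, 2 * n, by = 2)]
  # adjacency: key -> segment ids
  adj <- split(rep(seq_len(n), 2), c(k1, k2))
  used <- logical(n)
  polys <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    used[s0] <- TRUE
    pts <- segs[[s0]]
    start_key <- k1[s0]
    cur_key <- k2[s0]
    chain <- list(pts[1, ], pts[2, ])
    repeat {
      if (identical(cur_key, start_key)) break
      cand <- adj[[cur_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break                  # open chain: discard
      s <- cand[1]
      used[s] <- TRUE
      if (identical(k1[s], cur_key)) {
        chain[[length(chain) + 1]] <- segs[[s]][2, ]
        cur_key <- k2[s]
      } else {
        chain[[length(chain) + 1]] <- segs[[s]][1, ]
        cur_key <- k1[s]
      }
    }
    if (identical(cur_key, start_key) && length(chain) >= 4) {
      poly <- do.call(rbind, chain[-length(chain)])  # drop repeated closing pt
      if (abs(polygon_area(poly)) >= min_area) {
        if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
        polys[[length(polys) + 1]] <- poly
      }
    }
  }
  polys
}
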