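## Tetrahedral volume meshes: a structured annulus mesher for straight-tube
## verification fixtures, and a body-centered-cubic lattice mesher with
## signed-distance boundary snapping for general watertight solids, with
## plaque-local refinement via a graded background grid.

tet_mesh <- function(nodes, tets, subset = NULL, boundary_faces = NULL,
                     boundary_tags = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  vols <- cpp_tet_volumes(nodes, tets)
  if (any(vols <= 0)) stop("tet mesh contains inverted elements")
  if (is.null(subset)) subset <- rep("wall", nrow(tets))
  structure(list(nodes = nodes, tets = tets, subset = subset,
                 volumes = vols,
                 centroids = (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
                              nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4,
                 boundary_faces = boundary_faces,
                 boundary_tags = boundary_tags),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, volume %.2f mm^3\n",
              nrow(x$nodes), nrow(x$tets), sum(x$volumes)))
  tab <- table(x$subset)
  cat("  subsets:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  if (!is.null(x$boundary_tags)) {
    tt <- table(x$boundary_tags)
    cat("  boundary:", paste(sprintf("%s (%d)", names(tt), tt),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

# boundary faces of a tet mesh (faces belonging to exactly one element)
tet_boundary_faces <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  cnt <- table(key)
  once <- cnt[key] == 1
  out <- faces[once, , drop = FALSE]
  attr(out, "owner") <- rep(seq_len(nrow(tets)), 4)[once]
  out
}

# the canonical conforming 6-tet split of a hexahedron (VTK corner order)
hex6_template <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                       c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

#' Structured tetrahedral mesh of a thick-walled straight tube
#'
#' Annulus (inner radius `a`, outer radius `b`, length along z) discretized
#' by a structured cylindrical hexahedral grid split into tetrahedra. This
#' is the straight-tube verification fixture used for the Lame closed-form
#' benchmark; boundary facets are pre-tagged (`lumen`, `outer`, `cca_end`
#' at z = 0, `ica_end` at z = length).
#'
#' @param a inner radius (mm).
#' @param b outer radius (mm).
#' @param length tube length (mm).
#' @param size target element size (mm).
#' @return a `tet_mesh`.
#' @export
tube_tet_mesh <- function(a = 3, b = 3.9, length = 8, size = 0.3) {
  stopifnot(b > a, size > 0)
  nr <- max(2L, as.integer(round((b - a) / size)))
  nt <- max(16L, as.integer(round(2 * pi * (a + b) / 2 / size)))
  nz <- max(2L, as.integer(round(length / size)))
  rs <- seq(a, b, length.out = nr + 1)
  ths <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  zs <- seq(0, length, length.out = nz + 1)
  nid <- function(ir, it, iz)       # 1-based layers: r slowest, theta wraps
    (iz - 1) * (nr + 1) * nt + (ir - 1) * nt + ((it - 1) %% nt) + 1
  nodes <- matrix(0, (nr + 1) * nt * (nz + 1), 3)
  for (iz in seq_len(nz + 1))
    for (ir in seq_len(nr + 1)) {
      ids <- nid(ir, seq_len(nt), iz)
      nodes[ids, ] <- cbind(rs[ir] * cos(ths), rs[ir] * sin(ths), zs[iz])
    }
  tets <- matrix(0L, 6 * nr * nt * nz, 4)
  row <- 0L
  for (iz in seq_len(nz))
    for (ir in seq_len(nr))
      for (it in seq_len(nt)) {
        # hex corners in VTK order (r ~ x, theta ~ y, z ~ z)
        c000 <- nid(ir, it, iz);     c100 <- nid(ir + 1, it, iz)
        c110 <- nid(ir + 1, it + 1, iz); c010 <- nid(ir, it + 1, iz)
        c001 <- nid(ir, it, iz + 1); c101 <- nid(ir + 1, it, iz + 1)
        c111 <- nid(ir + 1, it + 1, iz + 1); c011 <- nid(ir, it + 1, iz + 1)
        corners <- c(c000, c100, c110, c010, c001, c101, c111, c011)
        for (t in seq_len(6)) {
          row <- row + 1L
          tets[row, ] <- corners[hex6_template[t, ]]
        }
      }
  mesh <- tet_mesh(nodes, tets)
  bf <- tet_boundary_faces(tets)
  ctr <- (mesh$nodes[bf[, 1], , drop = FALSE] +
          mesh$nodes[bf[, 2], , drop = FALSE] +
          mesh$nodes[bf[, 3], , drop = FALSE]) / 3
  r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  tol <- 1e-6
  tags <- rep("outer", nrow(bf))
  tags[abs(ctr[, 3]) < tol] <- "cca_end"
  tags[abs(ctr[, 3] - length) < tol] <- "ica_end"
  inner_r <- (a + rs[2]) / 2
  tags[tags == "outer" & r < inner_r] <- "lumen"
  mesh$boundary_faces <- bf
  mesh$boundary_tags <- tags
  mesh
}

# graded 1-D axis: fine step inside [box_lo, box_hi], coarse elsewhere
graded_axis <- function(lo, hi, h_coarse, box = NULL, h_fine = h_coarse) {
  if (is.null(box) || box[1] >= hi || box[2] <= lo || h_fine >= h_coarse) {
    n <- max(1L, ceiling((hi - lo) / h_coarse))
    return(seq(lo, hi, length.out = n + 1))
  }
  b1 <- max(lo, box[1]); b2 <- min(hi, box[2])
  pieces <- list()
  if (b1 > lo) {
    n <- max(1L, ceiling((b1 - lo) / h_coarse))
    pieces[[length(pieces) + 1]] <- seq(lo, b1, length.out = n + 1)
  }
  n <- max(1L, ceiling((b2 - b1) / h_fine))
  pieces[[length(pieces) + 1]] <- seq(b1, b2, length.out = n + 1)
  if (hi > b2) {
    n <- max(1L, ceiling((hi - b2) / h_coarse))
    pieces[[length(pieces) + 1]] <- seq(b2, hi, length.out = n + 1)
  }
  sort(unique(round(unlist(pieces), 10)))
}

#' Tetrahedralize a watertight solid on a body-centered lattice
#'
#' Fills the solid with body-centered-cubic lattice tetrahedra on a graded
#' background grid (target edge length about `global_size`, refined to about
#' `local_size` inside the 1 mm-dilated bounding box of the plaque region),
#' snaps near-surface lattice nodes onto the solid boundary, and keeps the
#' elements whose nodes are all inside or on the surface. Elements with
#' volume below 1e-6 mm^3 are discarded.
#'
#' @param wall_solid watertight [surface_mesh] to fill.
#' @param plaque_region optional [surface_mesh] (or list of meshes) whose
#'   dilated bounding box receives local refinement.
#' @param global_size background cell size outside the plaque region (mm).
#' @param local_size cell size inside the plaque region (mm).
#' @param dilate plaque-box dilation (mm).
#' @return a `tet_mesh` with all elements labelled `"wall"`.
#' @export
tetrahedralize <- function(wall_solid, plaque_region = NULL,
                           global_size = 0.5, local_size = 0.3,
                           dilate = 1) {
  stopifnot(local_size > 0, local_size <= global_size)
  if (!is_watertight(wall_solid)) stop("wall solid must be watertight")
  V <- wall_solid$vertices
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  box <- NULL
  if (!is.null(plaque_region)) {
    pl <- if (inherits(plaque_region, "surface_mesh")) list(plaque_region)
          else plaque_region
    pl <- Filter(Negate(is_empty_mesh), pl)
    if (length(pl) > 0) {
      pv <- do.call(rbind, lapply(pl, `[[`, "vertices"))
      box <- rbind(apply(pv, 2, min) - dilate, apply(pv, 2, max) + dilate)
    }
  }
  ax <- lapply(1:3, function(k)
    graded_axis(lo[k], hi[k], global_size,
                if (is.null(box)) NULL else box[, k], local_size))
  res <- bcc_lattice(ax)
  nodes <- res$nodes; tets <- res$tets
  hnode <- res$hnode; hnode_max <- res$hnode_max

  inside <- points_in_mesh(nodes, wall_solid)
  # candidate nodes for snapping: nodes of cells mixing inside/outside
  mixed <- inside[tets[, 1]] + inside[tets[, 2]] + inside[tets[, 3]] +
    inside[tets[, 4]]
  near <- sort(unique(as.vector(tets[mixed > 0 & mixed < 4, ])))
  ok <- inside
  if (length(near) > 0) {
    cp <- mesh_closest(nodes[near, , drop = FALSE], wall_solid)
    # inside nodes are pulled out conservatively (fine scale); outside nodes
    # must reach the surface across the coarsest local step (ghost centers)
    thr <- ifelse(inside[near], 0.45 * hnode[near], 0.6 * hnode_max[near])
    snap <- cp$dist < thr
    nodes[near[snap], ] <- cp$point[snap, , drop = FALSE]
    ok[near[snap]] <- TRUE
  }
  keep <- ok[tets[, 1]] & ok[tets[, 2]] & ok[tets[, 3]] & ok[tets[, 4]]
  tets <- tets[keep, , drop = FALSE]
  # weld nodes that snapped onto the same surface point, so no hinge dofs
  # survive, and drop the slivers this collapses
  key <- paste(round(nodes[, 1], 8), round(nodes[, 2], 8),
               round(nodes[, 3], 8))
  rep_id <- match(key, key)
  tets <- matrix(rep_id[tets], ncol = 4)
  degen <- tets[, 1] == tets[, 2] | tets[, 1] == tets[, 3] |
    tets[, 1] == tets[, 4] | tets[, 2] == tets[, 3] |
    tets[, 2] == tets[, 4] | tets[, 3] == tets[, 4]
  tets <- tets[!degen, , drop = FALSE]
  vols <- cpp_tet_volumes(nodes, tets)
  tets <- tets[vols > 1e-6, , drop = FALSE]
  if (nrow(tets) == 0)
    stop("lattice meshing produced no elements; the solid is thinner than ",
         "the background grid (reduce global_size)")
  tets <- largest_connected_elements(tets, cpp_tet_volumes(nodes, tets))
  used <- sort(unique(as.vector(tets)))
  remap <- match(tets, used)
  mesh <- tet_mesh(nodes[used, , drop = FALSE], matrix(remap, ncol = 4))
  mesh$boundary_faces <- tet_boundary_faces(mesh$tets)
  mesh$boundary_tags <- rep("outer", nrow(mesh$boundary_faces))
  mesh
}

# keep only the elements of the (volume-)largest face-connected component.
# Clusters attached to the body through a single node or edge are free to
# hinge (zero-energy modes), so connectivity must go through shared faces.
largest_connected_elements <- function(tets, vols) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  owner <- rep(seq_len(m), 4)
  o <- order(key)
  k2 <- key[o]; ow <- owner[o]
  same <- k2[-1] == k2[-length(k2)]
  pa <- ow[which(same)]; pb <- ow[which(same) + 1]
  lab <- seq_len(m)
  if (length(pa) > 0) {
    repeat {
      l1 <- pmin(lab[pa], lab[pb])
      v <- c(pa, pb); mm <- rep(l1, 2)
      oo <- order(v, mm)
      v <- v[oo]; mm <- mm[oo]
      first <- !duplicated(v)
      new <- lab
      new[v[first]] <- pmin(new[v[first]], mm[first])
      new <- pmin(new, new[new])       # path compression
      if (identical(new, lab)) break
      lab <- new
    }
  }
  vol_by <- rowsum(vols, lab)
  main <- as.integer(rownames(vol_by)[which.max(vol_by)])
  tets[lab == main, , drop = FALSE]
}

# body-centered lattice on a tensor grid: corner nodes + cell centers
# (including one layer of ghost centers outside the box, so boundary cells
# are fully covered), four tetrahedra per cell face between the two
# adjacent cell centers
bcc_lattice <- function(ax) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  corners <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  stepx <- diff(ax[[1]]); stepy <- diff(ax[[2]]); stepz <- diff(ax[[3]])
  ghost <- function(a, st) c(a[1] - st[1] / 2,
                             (a[-1] + a[-length(a)]) / 2,
                             a[length(a)] + st[length(st)] / 2)
  cx <- ghost(ax[[1]], stepx); mx <- length(cx)   # mx = nx + 1 cells
  cy <- ghost(ax[[2]], stepy); my <- length(cy)
  cz <- ghost(ax[[3]], stepz); mz <- length(cz)
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  nodes <- rbind(corners, centers)
  ncorner <- nrow(corners)
  cid <- function(i, j, k) i + nx * ((j - 1) + ny * (k - 1))
  eid <- function(i, j, k) ncorner + i + mx * ((j - 1) + my * (k - 1))
  # local step per node, for snap thresholds
  loc <- function(v, steps)
    pmin(steps[pmax(1, v - 1)], steps[pmin(length(steps), v)])
  gi <- ((seq_len(ncorner) - 1) %% nx) + 1
  gj <- (((seq_len(ncorner) - 1) %/% nx) %% ny) + 1
  gk <- ((seq_len(ncorner) - 1) %/% (nx * ny)) + 1
  hcorner_min <- pmin(loc(gi, stepx), loc(gj, stepy), loc(gk, stepz))
  hcorner_max <- pmax(loc(gi, stepx), loc(gj, stepy), loc(gk, stepz))
  clamp <- function(v, n) pmax(1, pmin(n, v))
  ei <- ((seq_len(nrow(centers)) - 1) %% mx) + 1
  ej <- (((seq_len(nrow(centers)) - 1) %/% mx) %% my) + 1
  ek <- ((seq_len(nrow(centers)) - 1) %/% (mx * my)) + 1
  csx <- stepx[clamp(ei - 1, length(stepx))]
  csy <- stepy[clamp(ej - 1, length(stepy))]
  csz <- stepz[clamp(ek - 1, length(stepz))]
  hcenter_min <- pmin(csx, csy, csz)
  hcenter_max <- pmax(csx, csy, csz)
  hnode <- c(hcorner_min, hcenter_min)
  hnode_max <- c(hcorner_max, hcenter_max)

  tet_list <- list()
  add_axis <- function(axis) {
    # all corner-plane faces orthogonal to `axis`, between (ghost-extended)
    # cell (i,j,k) and its +axis neighbor; face corners live at plane i
    if (axis == 1) { ci <- seq_len(mx - 1); cj <- 2:(my - 1); ck <- 2:(mz - 1) }
    if (axis == 2) { ci <- 2:(mx - 1); cj <- seq_len(my - 1); ck <- 2:(mz - 1) }
    if (axis == 3) { ci <- 2:(mx - 1); cj <- 2:(my - 1); ck <- seq_len(mz - 1) }
    g <- expand.grid(i = ci, j = cj, k = ck)
    i <- g$i; j <- g$j; k <- g$k
    if (axis == 1) {
      c1 <- eid(i, j, k); c2 <- eid(i + 1, j, k)
      p1 <- cid(i, j - 1, k - 1);     p2 <- cid(i, j, k - 1)
      p3 <- cid(i, j, k); p4 <- cid(i, j - 1, k)
    } else if (axis == 2) {
      c1 <- eid(i, j, k); c2 <- eid(i, j + 1, k)
      p1 <- cid(i - 1, j, k - 1);     p2 <- cid(i, j, k - 1)
      p3 <- cid(i, j, k); p4 <- cid(i - 1, j, k)
    } else {
      c1 <- eid(i, j, k); c2 <- eid(i, j, k + 1)
      p1 <- cid(i - 1, j - 1, k);     p2 <- cid(i, j - 1, k)
      p3 <- cid(i, j, k); p4 <- cid(i - 1, j, k)
    }
    rbind(cbind(c1, c2, p1, p2), cbind(c1, c2, p2, p3),
          cbind(c1, c2, p3, p4), cbind(c1, c2, p4, p1))
  }
  for (axis in 1:3) tet_list[[axis]] <- add_axis(axis)
  tets <- do.call(rbind, tet_list)
  # orient positively
  vols <- cpp_tet_volumes(nodes, tets)
  neg <- vols < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  list(nodes = nodes, tets = tets, hnode = hnode, hnode_max = hnode_max)
}

#' Assign plaque subsets to mesh elements by the minimum-distance-vector rule
#'
#' For each element centroid and each plaque component surface, the minimum
#' distance vector to the nearest surface triangle is compared with that
#' triangle's outward normal: the element belongs to the component when the
#' vector opposes the normal (negative dot product, i.e. the centroid lies
#' on the inner side). Elements claimed by several components are resolved
#' with priority calcific > lipid > fibrous; unclaimed elements are wall.
#'
#' @param mesh a `tet_mesh`.
#' @param component_surfaces named list of watertight, outward-oriented
#'   component meshes (names among `"calcific"`, `"lipid"`, `"fibrous"`).
#' @return the mesh with its `subset` labels filled in.
#' @export
assign_subsets <- function(mesh, component_surfaces) {
  subset <- rep("wall", nrow(mesh$tets))
  order_low_to_high <- c("fibrous", "lipid", "calcific")
  for (nm in intersect(order_low_to_high, names(component_surfaces))) {
    m <- component_surfaces[[nm]]
    if (is_empty_mesh(m)) next
    if (!is_watertight(m))
      stop("component surface '", nm, "' is not watertight/oriented")
    inside <- min_distance_vector_inside(mesh$centroids, m)
    subset[inside] <- nm
  }
  mesh$subset <- subset
  mesh
}

# the minimum-distance-vector rule itself (exported for oracle testing).
# When the nearest point falls strictly inside a triangle the triangle's
# outward normal is used, as in the original selection rule; when it falls
# on an edge or vertex the face normal is ambiguous and the angle-weighted
# pseudonormal of that feature is used instead, which makes the sign of the
# minimum-distance vector exact for watertight meshes.
min_distance_vector_inside <- function(points, mesh, bary_tol = 1e-3) {
  cp <- mesh_closest(points, mesh)
  fn <- face_normals(mesh)
  V <- mesh$vertices; F <- mesh$faces
  pseudo <- pseudonormals(mesh, fn)
  f <- cp$face
  a <- V[F[f, 1], , drop = FALSE]
  b <- V[F[f, 2], , drop = FALSE]
  c <- V[F[f, 3], , drop = FALSE]
  # barycentric coordinates of the foot point
  v0 <- b - a; v1 <- c - a; v2 <- cp$point - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- pmax(d00 * d11 - d01 * d01, 1e-300)
  bv <- (d11 * d20 - d01 * d21) / den
  bw <- (d00 * d21 - d01 * d20) / den
  bu <- 1 - bv - bw
  n <- fn[f, , drop = FALSE]
  onv <- cbind(bu, bv, bw) > bary_tol
  nfeat <- rowSums(onv)
  # foot on a vertex: angle-weighted vertex pseudonormal
  at_v <- which(nfeat == 1)
  if (length(at_v) > 0) {
    vid <- F[cbind(f[at_v], max.col(onv[at_v, , drop = FALSE]))]
    n[at_v, ] <- pseudo$vertex[vid, , drop = FALSE]
  }
  # foot on an edge: sum of the two incident face normals
  at_e <- which(nfeat == 2)
  if (length(at_e) > 0) {
    lo_col <- max.col(onv[at_e, , drop = FALSE], ties.method = "first")
    hi_col <- max.col(onv[at_e, , drop = FALSE], ties.method = "last")
    v1 <- F[cbind(f[at_e], lo_col)]
    v2 <- F[cbind(f[at_e], hi_col)]
    key <- paste(pmin(v1, v2), pmax(v1, v2))
    n[at_e, ] <- pseudo$edge[match(key, pseudo$edge_key), , drop = FALSE]
  }
  v <- points - cp$point
  rowSums(v * n) < 0
}

# angle-weighted vertex pseudonormals and per-edge summed face normals
pseudonormals <- function(mesh, fn = face_normals(mesh)) {
  V <- mesh$vertices; F <- mesh$faces
  vp <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    i0 <- F[, k]; i1 <- F[, k %% 3 + 1]; i2 <- F[, (k + 1) %% 3 + 1]
    e1 <- V[i1, , drop = FALSE] - V[i0, , drop = FALSE]
    e2 <- V[i2, , drop = FALSE] - V[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2) * rowSums(e2^2)), 1e-300)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    for (d in 1:3) {
      acc <- rowsum(ang * fn[, d], i0)
      ids <- as.integer(rownames(acc))
      vp[ids, d] <- vp[ids, d] + acc[, 1]
    }
  }
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  efn <- rbind(fn, fn, fn)
  en <- rowsum(efn, ekey)
  list(vertex = vp, edge = en, edge_key = rownames(en))
}

#' Tag boundary facets with load and constraint groups
#'
#' Boundary facets within `tol` of the stenotic lumen surface are tagged
#' `lumen` (pressure load); facets lying on the declared end planes are
#' tagged `cca_end` / `ica_end` / `eca_end` (constraints); everything else
#' is `outer`. End planes win over the lumen tolerance so that the tags
#' partition the boundary.
#'
#' @param mesh a `tet_mesh`.
#' @param stenotic_lumen watertight lumen [surface_mesh].
#' @param end_planes named list of `list(z =, center = c(x, y))` entries for
#'   tags `cca_end`, `ica_end`, `eca_end` (center optional, used to split
#'   coplanar distal ends).
#' @param tol lumen-proximity tolerance (mm, default 0.2).
#' @param plane_tol end-plane tolerance (mm).
#' @return the mesh with `boundary_tags` filled in.
#' @export
tag_boundary <- function(mesh, stenotic_lumen, end_planes, tol = 0.2,
                         plane_tol = 0.05) {
  bf <- mesh$boundary_faces %||% tet_boundary_faces(mesh$tets)
  ctr <- (mesh$nodes[bf[, 1], , drop = FALSE] +
          mesh$nodes[bf[, 2], , drop = FALSE] +
          mesh$nodes[bf[, 3], , drop = FALSE]) / 3
  tags <- rep("outer", nrow(bf))
  # end planes first
  for (nm in names(end_planes)) {
    ep <- end_planes[[nm]]
    onp <- abs(ctr[, 3] - ep$z) < plane_tol
    if (!is.null(ep$center)) {
      others <- Filter(function(e) abs(e$z - ep$z) < plane_tol &&
                         !is.null(e$center), end_planes)
      if (length(others) > 1) {
        dmine <- (ctr[, 1] - ep$center[1])^2 + (ctr[, 2] - ep$center[2])^2
        for (oe in others) {
          if (identical(oe$center, ep$center)) next
          dother <- (ctr[, 1] - oe$center[1])^2 + (ctr[, 2] - oe$center[2])^2
          onp <- onp & (dmine <= dother)
        }
      }
    }
    tags[onp] <- nm
  }
  free <- tags == "outer"
  if (any(free)) {
    d <- mesh_closest(ctr[free, , drop = FALSE], stenotic_lumen)$dist
    lum <- rep(FALSE, nrow(bf))
    lum[which(free)[d < tol]] <- TRUE
    tags[lum] <- "lumen"
  }
  if (!any(tags == "lumen"))
    stop("no boundary facet lies within ", tol,
         " mm of the lumen surface; the pressure load would be zero")
  mesh$boundary_faces <- bf
  mesh$boundary_tags <- tags
  mesh
}

## ---- mesh export ------------------------------------------------------------

#' Write a tetrahedral mesh as legacy VTK unstructured grid (ASCII)
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "carofem tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1, mesh$tets[, 2] - 1,
                     mesh$tets[, 3] - 1, mesh$tets[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  subset_id <- as.integer(factor(mesh$subset,
                                 levels = c("wall", "fibrous", "lipid",
                                            "calcific")))
  cell_data <- c(list(subset = subset_id), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.9g", as.numeric(cell_data[[nm]])), con)
  }
  invisible(path)
}

#' Write a tetrahedral mesh in Gmsh ASCII (MSH 2.2) format
#'
#' Subset labels are stored as physical tags (wall 1, fibrous 2, lipid 3,
#' calcific 4); tagged boundary facets as surface elements (lumen 11,
#' cca_end 12, ica_end 13, eca_end 14, outer 15).
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  subset_id <- as.integer(factor(mesh$subset,
                                 levels = c("wall", "fibrous", "lipid",
                                            "calcific")))
  bf <- mesh$boundary_faces
  tag_id <- c(lumen = 11, cca_end = 12, ica_end = 13, eca_end = 14,
              outer = 15)
  nb <- if (is.null(bf)) 0 else nrow(bf)
  writeLines(c("$Elements", sprintf("%d", nrow(mesh$tets) + nb)), con)
  eid <- 0
  if (nb > 0) {
    writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nb),
                       tag_id[mesh$boundary_tags], tag_id[mesh$boundary_tags],
                       bf[, 1], bf[, 2], bf[, 3]), con)
    eid <- nb
  }
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d",
                     eid + seq_len(nrow(mesh$tets)), subset_id, subset_id,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
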