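## Lofting machinery: skinning ordered cross-sectional contours into
## triangulated surfaces, including the one-to-two contour split at the
## carotid bifurcation and the apex fillet.

# --- ring band stitching ------------------------------------------------------

# triangulate the band between two closed 3-D rings (kA x 3, kB x 3) by greedy
# normalized-arc-length advancing; returns faces indexing c(ringA, ringB)
stitch_rings <- function(A, B) {
  kA <- nrow(A); kB <- nrow(B)
  # rotate B so its seam vertex is nearest to A[1,] (minimizes twist)
  d <- sweep(B, 2, A[1, ])
  j0 <- which.min(rowSums(d^2))
  if (j0 > 1) B_ord <- c(j0:kB, seq_len(j0 - 1)) else B_ord <- seq_len(kB)
  sA <- ring_params(A)
  sB <- ring_params(B[B_ord, , drop = FALSE])
  faces <- matrix(0L, kA + kB, 3)
  nf <- 0L
  i <- 1L; j <- 1L
  idxA <- function(i) if (i > kA) 1L else i
  idxB <- function(j) as.integer(kA + B_ord[if (j > kB) 1L else j])
  while (i <= kA || j <= kB) {
    adv_a <- i <= kA && (j > kB || sA[i + 1] <= sB[j + 1])
    nf <- nf + 1L
    if (adv_a) {
      faces[nf, ] <- c(idxA(i), idxA(i + 1), idxB(j))
      i <- i + 1L
    } else {
      faces[nf, ] <- c(idxA(i), idxB(j + 1), idxB(j))
      j <- j + 1L
    }
  }
  faces[seq_len(nf), , drop = FALSE]
}

ring_params <- function(R) {
  p <- rbind(R, R[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  s / s[length(s)]
}

# planar fan cap over a closed ring; direction +1 caps the top (+z normal)
cap_fan <- function(ring, direction = 1) {
  k <- nrow(ring)
  ctr <- colMeans(ring)
  V <- rbind(ring, ctr)
  f <- cbind(seq_len(k), c(2:k, 1), k + 1)
  if (direction < 0) f <- f[, c(1, 3, 2)]
  surface_mesh(V, f)
}

# annular cap between an outer and an inner ring lying in the same plane
cap_annulus <- function(outer_ring, inner_ring, direction = 1) {
  f <- stitch_rings(outer_ring, inner_ring)
  if (direction < 0) f <- f[, c(1, 3, 2)]
  surface_mesh(rbind(outer_ring, inner_ring), f)
}

# --- global orientation repair ------------------------------------------------

# make face orientation edge-consistent by BFS over face adjacency, then
# outward by the sign of the enclosed volume (per connected component the
# relative orientation is fixed by the BFS; the global flip uses total volume,
# which is correct for solids whose cavities are already stored reversed)
orient_mesh <- function(mesh) {
  F <- mesh$faces
  m <- nrow(F)
  if (m == 0) return(mesh)
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  face_of <- rep(seq_len(m), 3)
  adj <- split(seq_len(3 * m), ekey)
  flipped <- rep(NA, m)
  queue <- integer(m)
  for (seed in seq_len(m)) {
    if (!is.na(flipped[seed])) next
    flipped[seed] <- FALSE
    queue[1] <- seed
    qhead <- 1L; qtail <- 1L
    while (qhead <= qtail) {
      f <- queue[qhead]; qhead <- qhead + 1L
      for (s in 1:3) {
        h <- (s - 1) * m + f
        mates <- adj[[ekey[h]]]
        for (h2 in mates) {
          f2 <- face_of[h2]
          if (f2 == f || !is.na(flipped[f2])) next
          # consistent orientation <=> shared edge traversed oppositely
          flipped[f2] <- xor(flipped[f], he[h, 1] == he[h2, 1])
          qtail <- qtail + 1L
          queue[qtail] <- f2
        }
      }
    }
  }
  if (any(flipped)) F[flipped, ] <- F[flipped, c(1, 3, 2), drop = FALSE]
  out <- mesh
  out$faces <- F
  ensure_outward(out)
}

# --- forest lofting -----------------------------------------------------------

#' Loft a stack of cross-sectional contours into a surface
#'
#' Skins ordered planar contours (one or two per horizontal station) into a
#' triangulated surface. Stations with one contour produce a simple tube
#' band; a one-to-two transition is handled by splitting the lower contour
#' along the perpendicular bisector of the two upper centroids and skinning
#' each half to its branch ("pant" construction), which keeps the result
#' edge-manifold. Ends are closed with planar fan caps unless `cap_ends`
#' is FALSE, and an optional fillet (localized Laplacian smoothing within
#' `fillet_radius` of the bifurcation apex) blends the junction.
#'
#' @param stations list of stations, each `list(z =, contours = list of k x 2
#'   matrices)`, with strictly increasing `z`.
#' @param cap_ends close first/last rings with planar caps.
#' @param fillet_radius radius (mm) of the apex blend; 0 disables it.
#' @param name optional mesh tag.
#' @return a [surface_mesh]; watertight when `cap_ends = TRUE`.
#' @export
loft_stations <- function(stations, cap_ends = TRUE, fillet_radius = 1.5,
                          name = NULL) {
  ns <- length(stations)
  stopifnot(ns >= 2)
  rings <- lapply(stations, function(st)
    lapply(st$contours, function(p) cbind(p, st$z)))
  # pre-pass: at 1 -> 2 transitions, augment the single ring with the chord
  # crossing points so the band below shares exactly the same vertices
  splits <- vector("list", ns)
  for (i in seq_len(ns - 1)) {
    lo <- rings[[i]]; hi <- rings[[i + 1]]
    if (length(lo) == 1 && length(hi) == 2) {
      splits[[i]] <- split_ring(lo[[1]], hi[[1]], hi[[2]])
      rings[[i]][[1]] <- splits[[i]]$full
    } else if (length(lo) == 2 && length(hi) == 1) {
      splits[[i + 1]] <- split_ring(hi[[1]], lo[[1]], lo[[2]])
      rings[[i + 1]][[1]] <- splits[[i + 1]]$full
    }
  }
  pieces <- list()
  apex <- NULL
  for (i in seq_len(ns - 1)) {
    lo <- rings[[i]]; hi <- rings[[i + 1]]
    if (length(lo) == length(hi)) {
      # match contours by centroid proximity
      clo <- t(vapply(lo, function(r) colMeans(r)[1:2], numeric(2)))
      chi <- t(vapply(hi, function(r) colMeans(r)[1:2], numeric(2)))
      used <- logical(length(hi))
      for (a in seq_along(lo)) {
        d2 <- rowSums(sweep(chi, 2, clo[a, ])^2)
        d2[used] <- Inf
        b <- which.min(d2)
        used[b] <- TRUE
        f <- stitch_rings(lo[[a]], hi[[b]])
        pieces[[length(pieces) + 1]] <-
          surface_mesh(rbind(lo[[a]], hi[[b]]), f)
      }
    } else if (length(lo) == 1 && length(hi) == 2) {
      sp <- splits[[i]]
      apex <- sp$apex
      f1 <- stitch_rings(sp$half1, hi[[1]])
      pieces[[length(pieces) + 1]] <- surface_mesh(rbind(sp$half1, hi[[1]]), f1)
      f2 <- stitch_rings(sp$half2, hi[[2]])
      pieces[[length(pieces) + 1]] <- surface_mesh(rbind(sp$half2, hi[[2]]), f2)
    } else if (length(lo) == 2 && length(hi) == 1) {
      sp <- splits[[i + 1]]
      apex <- sp$apex
      f1 <- stitch_rings(lo[[1]], sp$half1)
      pieces[[length(pieces) + 1]] <- surface_mesh(rbind(lo[[1]], sp$half1), f1)
      f2 <- stitch_rings(lo[[2]], sp$half2)
      pieces[[length(pieces) + 1]] <- surface_mesh(rbind(lo[[2]], sp$half2), f2)
    } else {
      stop("unsupported contour transition (", length(lo), " -> ", length(hi),
           ") between stations ", i, " and ", i + 1)
    }
  }
  if (cap_ends) {
    for (r in rings[[1]])
      pieces[[length(pieces) + 1]] <- cap_fan(r, direction = -1)
    for (r in rings[[ns]])
      pieces[[length(pieces) + 1]] <- cap_fan(r, direction = 1)
  }
  out <- do.call(merge_meshes, c(pieces, list(weld = TRUE, tol = 1e-6,
                                              name = name)))
  out <- orient_mesh(out)
  if (!is.null(apex) && fillet_radius > 0)
    out <- fillet_smooth(out, apex, fillet_radius)
  out
}

# split the single lower ring C into two closed halves sharing the chord
# between the crossings of the bisector of the two upper centroids
split_ring <- function(C, A, B, n_chord = 5) {
  ca <- colMeans(A)[1:2]; cb <- colMeans(B)[1:2]
  m <- (ca + cb) / 2
  u <- (cb - ca); u <- u / sqrt(sum(u^2))
  s <- (C[, 1] - m[1]) * u[1] + (C[, 2] - m[2]) * u[2]
  k <- nrow(C)
  nxt <- c(2:k, 1)
  crossing <- which((s > 0) != (s[nxt] > 0))
  if (length(crossing) != 2)
    stop("branch split: lower contour crosses the bisector ",
         length(crossing), " times (expected 2)")
  cross_pt <- function(i) {
    j <- nxt[i]
    t <- s[i] / (s[i] - s[j])
    C[i, ] + t * (C[j, ] - C[i, ])
  }
  p1 <- cross_pt(crossing[1])
  p2 <- cross_pt(crossing[2])
  # the two cyclic arcs of C delimited by the crossing edges
  cyc <- function(from, to) if (from <= to) from:to else c(from:k, 1:to)
  arc1 <- cyc(nxt[crossing[1]], crossing[2])
  arc2 <- cyc(nxt[crossing[2]], crossing[1])
  chord12 <- t(sapply(seq_len(n_chord) / (n_chord + 1),
                      function(t) p1 + t * (p2 - p1)))
  half_a <- rbind(p1, C[arc1, , drop = FALSE], p2, chord12[rev(seq_len(n_chord)), ])
  half_b <- rbind(p2, C[arc2, , drop = FALSE], p1, chord12)
  # the full ring with the crossing points inserted, for the band below
  full <- rbind(C[seq_len(crossing[1]), , drop = FALSE], p1,
                C[cyc(nxt[crossing[1]], crossing[2]), , drop = FALSE], p2,
                if (crossing[2] < k) C[(crossing[2] + 1):k, , drop = FALSE])
  # assign halves to branches by side
  side_a <- mean((half_a[, 1] - m[1]) * u[1] + (half_a[, 2] - m[2]) * u[2])
  halves <- if (side_a > 0) list(half_b, half_a) else list(half_a, half_b)
  # A-side half first (A is on the u < 0 side iff (ca - m).u < 0, always true)
  list(half1 = fix_ccw(halves[[1]]), half2 = fix_ccw(halves[[2]]),
       full = full, apex = c(m, C[1, 3]))
}

fix_ccw <- function(ring) {
  if (polygon_area(ring[, 1:2, drop = FALSE]) < 0)
    ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# localized Laplacian smoothing of vertices within `radius` of point `apex`
fillet_smooth <- function(mesh, apex, radius, iterations = 5, lambda = 0.5) {
  V <- mesh$vertices; F <- mesh$faces
  d2 <- rowSums(sweep(V, 2, apex)^2)
  active <- which(d2 < radius^2)
  if (length(active) == 0) return(mesh)
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  nb <- split(he[, 2], he[, 1])
  for (it in seq_len(iterations)) {
    Vn <- V
    for (v in active) {
      ns <- nb[[as.character(v)]]
      if (is.null(ns)) next
      Vn[v, ] <- (1 - lambda) * V[v, ] + lambda * colMeans(V[ns, , drop = FALSE])
    }
    V <- Vn
  }
  mesh$vertices <- V
  mesh
}
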