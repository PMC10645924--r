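# shared fixtures, built in code at test time

# compact carotid anatomy parameters keeping runtimes small
small_params <- function(...) {
  centerline_params(z_bif = 10, z_top = 30, spacing = 0.5, ...)
}

small_stenosis <- function(...) {
  args <- modifyList(list(branch = "ICA", center_z = 24, extent = 8,
                          severity = 0.5, frac_calcific = 0.25,
                          frac_lipid = 0.15), list(...))
  do.call(stenosis_spec, args)
}

# regular polygon approximating a circle
circle_poly <- function(r = 1, n = 64, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# annular wall solid between two concentric tubes
annulus_solid <- function(a = 3, b = 3.9, length = 8, n_theta = 48,
                          spacing = 1) {
  build_wall_solid(tube_surface(a, length, n_theta, spacing),
                   tube_surface(b, length, n_theta, spacing))
}

# random convex blob mesh (hull of noisy ellipsoid samples)
random_blob <- function(seed, n = 80, axes = c(2, 1.5, 1)) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (1 + 0.3 * runif(n))
  convex_hull_3d(sweep(pts, 2, axes, "*"))
}

# independent point-to-triangle distance, written directly from the
# geometric decomposition (plane foot if interior, else nearest edge or
# vertex), as a brute-force oracle for the compiled closest-point query
pt_tri_dist_oracle <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / max(sum(d * d), 1e-300)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * d))^2))
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sum(n * n)
  best <- min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
  if (nn > 1e-300) {
    t <- sum((p - a) * n) / nn
    foot <- p - t * n
    # barycentric check of the foot point
    v0 <- c - a; v1 <- b - a; v2 <- foot - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= 0 && v >= 0 && u + v <= 1)
      best <- min(best, sqrt(sum((p - foot)^2)))
  }
  best
}

brute_mesh_dist <- function(points, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    min(vapply(seq_len(nrow(F)), function(f)
      pt_tri_dist_oracle(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ]), 0))
  }, 0)
}
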