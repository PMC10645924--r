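## Small-deformation isotropic linear-elastic statics on labelled
## tetrahedral meshes. Unit system: mm / N / MPa, so stresses come out in
## MPa directly (1 kPa = 1e-3 MPa). Constant-strain displacement elements;
## the near-incompressible default (nu = 0.49) reproduces the reference
## modelling choice and its volumetric-locking behaviour is covered by
## dedicated tests rather than worked around.

#' Material table for wall and plaque subsets
#'
#' Young's moduli in kPa (defaults: calcific 20000, lipid 4, fibrous 400,
#' healthy wall 550) and a shared Poisson ratio (default 0.49, nearly
#' incompressible).
#'
#' @param calcific,lipid,fibrous,wall Young's moduli in kPa.
#' @param nu Poisson ratio, in [0, 0.5).
#' @return a `material_table`.
#' @export
material_table <- function(calcific = 20000, lipid = 4, fibrous = 400,
                           wall = 550, nu = 0.49) {
  E <- c(wall = wall, fibrous = fibrous, lipid = lipid, calcific = calcific)
  if (any(E <= 0)) stop("Young's moduli must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must lie in [0, 0.5)")
  structure(list(E_kpa = E, nu = nu), class = "material_table")
}

#' Load case: differential lumen pressure and end constraints
#'
#' The lumen is loaded with the constant uniform differential pressure
#' P_S - P_D (systolic minus diastolic local pressure); the branch end
#' planes are constrained in the longitudinal and circumferential
#' directions, radial direction free.
#'
#' @param p_systolic,p_diastolic local pressures in mmHg, or supply
#'   `delta_p` directly.
#' @param delta_p differential pressure in mmHg (overrides the pair).
#' @param ends boundary tags to constrain.
#' @return a `load_case`.
#' @export
load_case <- function(p_systolic = NULL, p_diastolic = NULL, delta_p = NULL,
                      ends = c("cca_end", "ica_end", "eca_end")) {
  if (is.null(delta_p))
    delta_p <- differential_pressure(p_systolic, p_diastolic)
  if (delta_p < 0) stop("differential pressure must be non-negative")
  structure(list(delta_p_mmhg = delta_p, ends = ends), class = "load_case")
}

#' Convert mmHg to MPa
#'
#' One millimetre of mercury is 133.322387415 Pa.
#'
#' @param p pressure in mmHg.
#' @return pressure in MPa.
#' @export
mmhg_to_mpa <- function(p) p * 133.322387415e-6

#' Assemble the linear-elastic stiffness operator
#'
#' Builds per-subset unit-modulus stiffness blocks from constant-strain
#' tetrahedra, so that the global operator for any set of subset moduli is
#' their modulus-weighted sum (the elasticity matrix is linear in E at fixed
#' Poisson ratio). Before constraints the operator annihilates exactly the
#' six rigid-body modes.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param mat a [material_table()].
#' @return a `fem_system`: mesh, materials and per-subset stiffness parts.
#' @export
fem_assemble <- function(mesh, mat) {
  parts <- list()
  for (s in unique(mesh$subset)) {
    el <- mesh$subset == s
    tri <- cpp_assemble_tets(mesh$nodes, mesh$tets[el, , drop = FALSE],
                             rep(1, sum(el)), mat$nu)
    parts[[s]] <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                       dims = rep(3 * nrow(mesh$nodes), 2))
  }
  structure(list(mesh = mesh, mat = mat, parts = parts,
                 ndof = 3 * nrow(mesh$nodes)), class = "fem_system")
}

# stiffness for the system's material table, with optional modulus
# multipliers per subset (sensitivity sweeps reuse the assembled parts)
fem_stiffness <- function(sys, multipliers = NULL) {
  K <- NULL
  for (s in names(sys$parts)) {
    E_mpa <- sys$mat$E_kpa[[s]] * 1e-3
    if (!is.null(multipliers) && !is.null(multipliers[[s]]))
      E_mpa <- E_mpa * multipliers[[s]]
    K <- if (is.null(K)) E_mpa * sys$parts[[s]] else K + E_mpa * sys$parts[[s]]
  }
  Matrix::forceSymmetric(K)
}

#' Constrain branch end planes in local cylindrical frames
#'
#' At every node of a tagged end plane a cylindrical frame centered at the
#' end-section centroid is erected (radial in-plane, circumferential
#' in-plane, longitudinal along the branch axis). The longitudinal and
#' circumferential displacement components are fixed to zero; the radial
#' one stays free, via a sparse local-frame rotation of the operator.
#'
#' @param K assembled stiffness (sparse, 3n x 3n).
#' @param mesh the `tet_mesh` (with boundary tags).
#' @param load a [load_case()] naming the end tags.
#' @return a `constrained_system`: rotated reduced operator, the rotation,
#'   and the free-dof index.
#' @export
apply_constraints <- function(K, mesh, load) {
  bf <- mesh$boundary_faces
  tags <- mesh$boundary_tags
  n <- nrow(mesh$nodes)
  Ti <- seq_len(3 * n); Tj <- seq_len(3 * n); Tx <- rep(1, 3 * n)
  fixed <- logical(3 * n)
  any_end <- FALSE
  for (tag in intersect(load$ends, unique(tags))) {
    any_end <- TRUE
    vids <- sort(unique(as.vector(bf[tags == tag, , drop = FALSE])))
    ctr <- colMeans(mesh$nodes[vids, , drop = FALSE])
    for (v in vids) {
      rad <- c(mesh$nodes[v, 1] - ctr[1], mesh$nodes[v, 2] - ctr[2], 0)
      nr <- sqrt(sum(rad^2))
      dofs <- 3 * (v - 1) + 1:3
      if (nr < 1e-9) {            # node at the section centroid: fix fully
        fixed[dofs] <- TRUE
        next
      }
      e_r <- rad / nr
      e_t <- c(-e_r[2], e_r[1], 0)
      e_z <- c(0, 0, 1)
      R <- cbind(e_r, e_t, e_z)   # u_global = R %*% u_local
      # replace the identity block of T with the rotation block
      Tx[dofs] <- 0               # zero the identity entries for these dofs
      Ti <- c(Ti, rep(dofs, each = 3))
      Tj <- c(Tj, rep(dofs, times = 3))
      Tx <- c(Tx, as.vector(t(R)))
      fixed[dofs[2:3]] <- TRUE    # circumferential + longitudinal
    }
  }
  if (!any_end) stop("no constrained end plane found among tags: ",
                     paste(load$ends, collapse = ", "))
  T <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(3 * n, 3 * n))
  Kt <- Matrix::forceSymmetric(Matrix::t(T) %*% K %*% T)
  free <- which(!fixed)
  structure(list(K = Kt[free, free, drop = FALSE], T = T, free = free,
                 ndof = 3 * n), class = "constrained_system")
}

#' Assemble the lumen pressure right-hand side
#'
#' Every boundary facet tagged `lumen` contributes a force p * A along the
#' inward normal (from the lumen into the wall), split equally among its
#' three nodes; the pressure is a dead load on the reference configuration.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param load a [load_case()].
#' @return force vector of length 3 * n (N).
#' @export
apply_pressure <- function(mesh, load) {
  bf <- mesh$boundary_faces
  owner <- attr(bf, "owner")
  tags <- mesh$boundary_tags
  lum <- which(tags == "lumen")
  if (length(lum) == 0) stop("no lumen facets tagged; load would be zero")
  p <- mmhg_to_mpa(load$delta_p_mmhg)
  f <- numeric(3 * nrow(mesh$nodes))
  V <- mesh$nodes
  for (fi in lum) {
    tri <- bf[fi, ]
    a <- V[tri[1], ]; b <- V[tri[2], ]; c <- V[tri[3], ]
    nvec <- crossprod_vec(b - a, c - a) / 2     # area-weighted normal
    # orient outward from the solid (away from the owning tet centroid)
    tc <- mesh$centroids[owner[fi], ]
    fc <- (a + b + c) / 3
    if (sum(nvec * (fc - tc)) < 0) nvec <- -nvec
    force <- -p * nvec                          # compressive traction
    for (k in 1:3) {
      dofs <- 3 * (tri[k] - 1) + 1:3
      f[dofs] <- f[dofs] + force / 3
    }
  }
  f
}

#' Solve the constrained static problem
#'
#' Sparse symmetric positive-definite factorization of the reduced operator;
#' the relative residual is verified below 1e-9.
#'
#' @param cs a `constrained_system` from [apply_constraints()].
#' @param f full-length force vector (N).
#' @return full-length nodal displacement vector (mm).
#' @export
solve_static <- function(cs, f) {
  ft <- as.vector(Matrix::t(cs$T) %*% f)[cs$free]
  ch <- tryCatch(Matrix::Cholesky(cs$K, LDL = FALSE),
                 error = function(e)
                   stop("stiffness not positive definite (under-constrained ",
                        "or degenerate mesh): ", conditionMessage(e)))
  ul <- as.vector(Matrix::solve(ch, ft))
  # iterative refinement against round-off on ill-conditioned systems
  for (it in 1:3) {
    r <- ft - as.vector(cs$K %*% ul)
    res <- sqrt(sum(r^2)) / max(sqrt(sum(ft^2)), 1e-30)
    if (res < 1e-10) break
    ul <- ul + as.vector(Matrix::solve(ch, r))
  }
  res <- sqrt(sum((as.vector(cs$K %*% ul) - ft)^2)) /
    max(sqrt(sum(ft^2)), 1e-30)
  if (res > 1e-9)
    stop(sprintf("solver residual %.2e exceeds 1e-9", res))
  u_loc <- numeric(cs$ndof)
  u_loc[cs$free] <- ul
  as.vector(cs$T %*% u_loc)
}

#' Per-element von Mises stress field
#'
#' Recovers the constant element stress tensor through each subset's
#' elasticity matrix and reduces it to the von Mises equivalent stress,
#' with element volume, centroid and subset label attached.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param u nodal displacement vector (mm).
#' @param mat a [material_table()].
#' @return a `stress_field` data frame: element, subset, volume (mm^3),
#'   centroid coordinates (mm), `vm_mpa` and `vm_kpa`.
#' @export
element_vm <- function(mesh, u, mat) {
  E_mpa <- mat$E_kpa[mesh$subset] * 1e-3
  S <- cpp_tet_stress(mesh$nodes, mesh$tets, u, E_mpa, mat$nu)
  vm <- von_mises(S)
  out <- data.frame(element = seq_len(nrow(mesh$tets)),
                    subset = mesh$subset, volume = mesh$volumes,
                    x = mesh$centroids[, 1], y = mesh$centroids[, 2],
                    z = mesh$centroids[, 3],
                    vm_mpa = vm, vm_kpa = vm * 1e3)
  class(out) <- c("stress_field", "data.frame")
  out
}

# von Mises stress from Voigt rows (xx, yy, zz, xy, yz, zx)
von_mises <- function(S) {
  S <- rbind(S)
  sqrt(0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
                (S[, 3] - S[, 1])^2) +
         3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2))
}

#' One-call static solve
#'
#' Assembles, constrains, loads and solves a labelled mesh, returning the
#' displacement and the element von Mises field.
#'
#' @param mesh a tagged, labelled `tet_mesh`.
#' @param mat a [material_table()].
#' @param load a [load_case()].
#' @param multipliers optional named modulus multipliers (e.g.
#'   `list(fibrous = 0.9)`).
#' @param system optionally reuse a pre-assembled `fem_system`.
#' @return list with `u`, `field`, and the `fem_system`.
#' @export
fem_solve <- function(mesh, mat, load, multipliers = NULL, system = NULL) {
  sys <- system %||% fem_assemble(mesh, mat)
  K <- fem_stiffness(sys, multipliers)
  cs <- apply_constraints(K, mesh, load)
  f <- apply_pressure(mesh, load)
  u <- solve_static(cs, f)
  mat_eff <- sys$mat
  if (!is.null(multipliers))
    for (s in names(multipliers))
      mat_eff$E_kpa[[s]] <- mat_eff$E_kpa[[s]] * multipliers[[s]]
  field <- element_vm(mesh, u, mat_eff)
  list(u = u, field = field, system = sys)
}

#' Write a stress field as CSV
#' @param field a `stress_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stress_csv <- function(field, path) {
  write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
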