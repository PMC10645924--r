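## Post-processing of simulation results: the VM99 stress statistic on the
## fibrous plaque subset, cumulative volume-stress curves, plaque
## composition percentages, fibrous-cap thickness at the VM99 section,
## signed mutual surface distances, comparison metrics and the
## fibrous-modulus sensitivity sweep.

#' Differential local carotid pressure
#'
#' The uniform lumen load is the difference between the systolic and
#' diastolic local pressures measured by ultrasound wall tracking.
#'
#' @param p_systolic,p_diastolic local pressures (mmHg).
#' @return P_S - P_D in mmHg.
#' @export
differential_pressure <- function(p_systolic, p_diastolic) {
  if (any(p_systolic < p_diastolic))
    stop("systolic pressure below diastolic pressure")
  p_systolic - p_diastolic
}

#' Bundled per-patient local carotid pressure table
#'
#' Systolic and diastolic local pressures (mmHg) of the ten study patients,
#' with their differential pressure, as shipped with the package.
#'
#' @return data frame with columns `patient`, `p_systolic`, `p_diastolic`,
#'   `delta_p`.
#' @export
carotid_pressures <- function() {
  path <- system.file("extdata", "carotid_pressures.csv", package = "carofem")
  tab <- read.csv(path)
  stopifnot(all(tab$p_systolic > tab$p_diastolic), all(tab$p_diastolic > 0))
  tab
}

#' Cumulative volume-stress curve of a subset
#'
#' Elements of the subset sorted by increasing von Mises stress, with the
#' cumulative element volume normalized by the subset total.
#'
#' @param field a `stress_field`.
#' @param subset subset label (default `"fibrous"`).
#' @return a `volume_stress_curve`: data frame with `vm_kpa` (non-
#'   decreasing) and `cum_volume` (ending at 1), plus the element ids.
#' @export
volume_stress_curve <- function(field, subset = "fibrous") {
  sel <- field[field$subset == subset, , drop = FALSE]
  if (nrow(sel) == 0) stop("subset '", subset, "' is empty")
  o <- order(sel$vm_kpa, sel$element)
  sel <- sel[o, , drop = FALSE]
  out <- data.frame(element = sel$element, vm_kpa = sel$vm_kpa,
                    cum_volume = cumsum(sel$volume) / sum(sel$volume))
  attr(out, "subset") <- subset
  class(out) <- c("volume_stress_curve", "data.frame")
  out
}

#' @export
plot.volume_stress_curve <- function(x, ...) {
  graphics::plot(x$vm_kpa, x$cum_volume, type = "s",
                 xlab = "von Mises stress (kPa)",
                 ylab = "cumulative normalized volume", ...)
  invisible(x)
}

#' VM99: the 99th volume-percentile von Mises stress of a subset
#'
#' Elements are sorted by increasing stress (ties broken by element id) and
#' their volumes accumulated until 99 percent of the subset volume is
#' reached; the stress of the first element crossing that threshold is
#' VM99, so 99 percent of the subset volume carries stresses at or below
#' it. The crossing element's centroid localizes the statistic.
#'
#' @param x a `stress_field` or a `volume_stress_curve`.
#' @param subset subset label (for stress fields).
#' @param quantile volume fraction (default 0.99).
#' @return a `vm99_result`: list with `vm99_kpa`, `element`, `centroid`,
#'   `z_station`.
#' @export
vm99 <- function(x, subset = "fibrous", quantile = 0.99) {
  if (inherits(x, "volume_stress_curve")) {
    idx <- which(x$cum_volume >= quantile - 1e-12)[1]
    res <- list(vm99_kpa = x$vm_kpa[idx], element = x$element[idx],
                centroid = NULL, z_station = NULL)
    class(res) <- "vm99_result"
    return(res)
  }
  curve <- volume_stress_curve(x, subset)
  idx <- which(curve$cum_volume >= quantile - 1e-12)[1]
  el <- curve$element[idx]
  row <- x[x$element == el, , drop = FALSE]
  res <- list(vm99_kpa = curve$vm_kpa[idx], element = el,
              centroid = c(row$x, row$y, row$z), z_station = row$z)
  class(res) <- "vm99_result"
  res
}

#' @export
print.vm99_result <- function(x, ...) {
  cat(sprintf("VM99 = %.2f kPa (element %d", x$vm99_kpa, x$element))
  if (!is.null(x$z_station)) cat(sprintf(", z = %.2f mm", x$z_station))
  cat(")\n")
  invisible(x)
}

#' Anatomical location tag of the VM99 element
#'
#' Rule-based version of the visual labelling of peak-stress locations:
#' within 1 mm of the lipid surface it sits in the fibrous cap, within 1 mm
#' of the calcific surface at the calcific plaque shoulder, within 3 mm of
#' the bifurcation apex at the bifurcation; otherwise unlabelled.
#'
#' @param res a `vm99_result` with a centroid.
#' @param lipid,calcific component meshes (may be empty/NULL).
#' @param apex bifurcation apex coordinates, or NULL.
#' @return character tag or NA.
#' @export
vm99_location <- function(res, lipid = NULL, calcific = NULL, apex = NULL) {
  p <- rbind(res$centroid)
  if (!is_empty_mesh(lipid) && mesh_closest(p, lipid)$dist < 1)
    return("fibrous cap")
  if (!is_empty_mesh(calcific) && mesh_closest(p, calcific)$dist < 1)
    return("calcific plaque shoulder")
  if (!is.null(apex) && sqrt(sum((res$centroid - apex)^2)) < 3)
    return("bifurcation")
  NA_character_
}

#' Plaque composition percentages
#'
#' Component volumes as percentages of the plaque total volume
#' (calcific + lipid + fibrous).
#'
#' @param volumes named numeric vector with entries `calcific`, `lipid`,
#'   `fibrous` (mm^3; missing entries count as 0).
#' @return named percentages summing to 100.
#' @export
composition_percentages <- function(volumes) {
  v <- c(calcific = 0, lipid = 0, fibrous = 0)
  v[names(volumes)] <- volumes
  tot <- sum(v)
  if (tot <= 0) stop("plaque total volume must be positive")
  100 * v / tot
}

#' Percentage difference of a proposed value against a reference
#'
#' @param proposed,reference numeric values; `reference` must be non-zero.
#' @return (proposed - reference) / reference * 100.
#' @export
percentage_difference <- function(proposed, reference) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  (proposed - reference) / reference * 100
}

#' Signed mutual distance between two fibrous models
#'
#' For every vertex of the reference surface: the unsigned minimum distance
#' to the proposed surface, signed positive where the reference vertex lies
#' outside the proposed solid (the reference model is locally larger) and
#' negative inside. Mean, standard deviation and the 5th/95th percentiles
#' are reported.
#'
#' @param reference reference fibrous [surface_mesh] (e.g. from manual
#'   segmentation / the generator's ground truth).
#' @param proposed reconstructed fibrous [surface_mesh]; must be watertight
#'   (the sign is undefined otherwise).
#' @param max_points optional subsample size of reference vertices.
#' @return a `distance_report`: list with `distances`, `mean`, `sd`, `p05`,
#'   `p95` (mm).
#' @export
signed_distance_report <- function(reference, proposed, max_points = NULL) {
  if (!is_watertight(proposed))
    stop("proposed mesh is not watertight; signed distance undefined")
  pts <- reference$vertices
  if (!is.null(max_points) && nrow(pts) > max_points)
    pts <- pts[round(seq(1, nrow(pts), length.out = max_points)), ,
               drop = FALSE]
  d <- signed_distance(pts, proposed)
  structure(list(distances = d, mean = mean(d), sd = sd(d),
                 p05 = unname(quantile(d, 0.05)),
                 p95 = unname(quantile(d, 0.95))),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("signed distance: %.3f +/- %.3f mm (5th %.3f, 95th %.3f)\n",
              x$mean, x$sd, x$p05, x$p95))
  invisible(x)
}

#' Fibrous-cap thickness at the VM99 cross-section
#'
#' Intersects the lumen and lipid surfaces with the transversal plane at
#' the VM99 z-station and measures the minimum distance between the two
#' contours within an angular window about the VM99 centroid. Returns NA
#' ("not applicable") when no lipid contour exists on that plane.
#'
#' @param res a `vm99_result` with centroid.
#' @param lumen stenotic lumen [surface_mesh].
#' @param lipid lipid component [surface_mesh] (may be empty).
#' @param window angular half-window (radians, default 30 degrees).
#' @param n_samples contour resampling density for the distance search.
#' @return thickness in mm, or NA.
#' @export
fc_thickness <- function(res, lumen, lipid, window = pi / 6,
                         n_samples = 200) {
  if (is_empty_mesh(lipid)) return(NA_real_)
  z <- res$z_station
  lum_polys <- slice_mesh_z(lumen, z)
  lip_polys <- slice_mesh_z(lipid, z)
  if (length(lip_polys) == 0 || length(lum_polys) == 0) return(NA_real_)
  ctrd <- function(p) polygon_centroid(p)
  dc <- vapply(lum_polys, function(p)
    sum((ctrd(p) - res$centroid[1:2])^2), 0)
  lum_poly <- resample_polygon(lum_polys[[which.min(dc)]], n_samples)
  ctr <- polygon_centroid(lum_poly)
  ang0 <- atan2(res$centroid[2] - ctr[2], res$centroid[1] - ctr[1])
  ang <- atan2(lum_poly[, 2] - ctr[2], lum_poly[, 1] - ctr[1])
  dang <- abs(((ang - ang0 + pi) %% (2 * pi)) - pi)
  sel <- lum_poly[dang <= window, , drop = FALSE]
  if (nrow(sel) == 0) sel <- lum_poly
  lip_pts <- do.call(rbind, lapply(lip_polys, resample_polygon, n_samples))
  dmin <- min(vapply(seq_len(nrow(sel)), function(i)
    min(sqrt((lip_pts[, 1] - sel[i, 1])^2 + (lip_pts[, 2] - sel[i, 2])^2)),
    0))
  dmin
}

#' Fibrous-modulus sensitivity sweep
#'
#' Re-solves the model with the fibrous Young's modulus scaled by each
#' multiplier, reporting VM99 and the volume-stress curve per run. The
#' assembled per-subset stiffness parts are reused across runs, and results
#' are deterministic.
#'
#' @param mesh tagged, labelled `tet_mesh`.
#' @param mat a [material_table()].
#' @param load a [load_case()].
#' @param multipliers modulus multipliers (default 0.5, 0.8, 0.9, 1.0, 1.1,
#'   1.2, 1.5).
#' @param subset subset whose modulus is swept and whose VM99 is reported.
#' @return list with `table` (data frame multiplier, E_kpa, vm99_kpa) and
#'   `curves` (one `volume_stress_curve` per run).
#' @export
sensitivity_sweep <- function(mesh, mat, load,
                              multipliers = c(0.5, 0.8, 0.9, 1.0, 1.1, 1.2,
                                              1.5),
                              subset = "fibrous") {
  sys <- fem_assemble(mesh, mat)
  has_subset <- any(mesh$subset == subset)
  rows <- list(); curves <- list()
  for (m in multipliers) {
    mult <- setNames(list(m), subset)
    sol <- tryCatch(
      fem_solve(mesh, mat, load, multipliers = mult, system = sys),
      error = function(e) e)
    if (inherits(sol, "error")) {
      warning("sweep aborted at multiplier ", m, ": ",
              conditionMessage(sol))
      break
    }
    vsubset <- if (has_subset) subset else "wall"
    cv <- volume_stress_curve(sol$field, vsubset)
    v99 <- vm99(sol$field, vsubset)
    rows[[length(rows) + 1]] <-
      data.frame(multiplier = m, E_kpa = mat$E_kpa[[subset]] * m,
                 vm99_kpa = v99$vm99_kpa)
    curves[[length(curves) + 1]] <- cv
  }
  list(table = do.call(rbind, rows), curves = curves,
       complete = length(rows) == length(multipliers))
}
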