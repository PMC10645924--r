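## End-to-end workflow binding the stages together: synthetic anatomy (or
## bundled surfaces) -> optional voxelize/segment -> wall reconstruction ->
## tetrahedral meshing + subset assignment -> static solve -> VM99 report,
## with a YAML configuration, per-stage artifacts and a hashed manifest.

#' Default run configuration
#'
#' All defaults carry the reference modelling constants: 0.8 / 0.3 mm
#' global/local mesh sizes (the lattice mesher additionally caps its
#' background cell size at the wall thickness scale), Poisson ratio 0.49,
#' subset moduli 20000 / 4 / 400 / 550 kPa, HU ranges >= 800 (calcific),
#' <= 60 (lipid), 200-700 (blood), the 30 percent outer-wall enlargement
#' and patient-1 pressures.
#'
#' @param ... overrides merged into the defaults (nested lists).
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    stages = list(segment = FALSE, reconstruct = TRUE, solve = TRUE),
    anatomy = list(z_bif = 10, z_top = 30, r_cca = 3.0, r_ica = 3.0,
                   r_eca = 2.2, spacing = 0.5, n_theta = 64,
                   stenosis = list(branch = "ICA", center_z = 24,
                                   extent = 8, severity = 0.5, angle = 0,
                                   frac_calcific = 0.25, frac_lipid = 0.15,
                                   cap_thickness = 0.4)),
    segmentation = list(voxel_spacing = 0.4,
                        hu_calcific = c(800, Inf), hu_lipid = c(-Inf, 60),
                        hu_blood = c(200, 700)),
    reconstruction = list(spacing = 0.5, n_control = 16,
                          enlarge_factor = 1.3, narrow_frac = 0.98,
                          fillet_radius = 1.5),
    mesh = list(global_size = 0.8, local_size = 0.35,
                max_background_cell = 0.5),
    materials = list(calcific = 20000, lipid = 4, fibrous = 400,
                     wall = 550, nu = 0.49),
    load = list(patient = 1, p_systolic = NULL, p_diastolic = NULL),
    output = list(dir = tempfile("carofem_run_"), write_vtk = TRUE))
  modifyList(cfg, list(...))
}

#' Validate a run configuration
#'
#' Schema and range checks run before any stage: positive mesh sizes with
#' local <= global, Poisson ratio in [0, 0.5), positive moduli, coherent HU
#' ranges and a sane enlargement factor.
#'
#' @param cfg a `run_config` list.
#' @return the config, invisibly; errors on violations.
#' @export
validate_config <- function(cfg) {
  m <- cfg$mesh
  stopifnot(m$local_size > 0, m$local_size <= m$global_size)
  mt <- cfg$materials
  stopifnot(mt$nu >= 0, mt$nu < 0.5, mt$calcific > 0, mt$lipid > 0,
            mt$fibrous > 0, mt$wall > 0)
  stopifnot(cfg$reconstruction$enlarge_factor > 1,
            cfg$reconstruction$spacing > 0,
            cfg$reconstruction$narrow_frac > 0,
            cfg$reconstruction$narrow_frac <= 1)
  s <- cfg$segmentation
  stopifnot(s$hu_lipid[2] < s$hu_blood[1], s$hu_blood[2] < s$hu_calcific[1],
            s$voxel_spacing > 0)
  invisible(cfg)
}

#' Write / read a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `path` / the config.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' Run the end-to-end workflow
#'
#' Executes synthetic-anatomy generation, optional HU voxelization +
#' threshold segmentation, wall reconstruction, tetrahedral meshing with
#' subset assignment and boundary tagging, the static solve under the
#' patient's differential pressure, and post-processing into a per-run
#' report. Every stage writes its artifact into the run directory together
#' with a manifest of content hashes; identical configurations reproduce
#' identical results.
#'
#' @param cfg a `run_config` (see [default_config()]).
#' @param quiet suppress stage log lines.
#' @return the run directory path, invisibly; the `report.json` inside it
#'   holds the summary (composition percentages, VM99, location, fibrous
#'   cap thickness, differential pressure).
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  validate_config(cfg)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  out <- cfg$output$dir
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  ## ---- synth ----------------------------------------------------------
  an_par <- cfg$anatomy
  sten <- if (is.null(an_par$stenosis)) list() else
    list(do.call(stenosis_spec, an_par$stenosis))
  params <- do.call(centerline_params,
                    an_par[setdiff(names(an_par), "stenosis")])
  anatomy <- make_anatomy(cfg$seed, params, sten)
  write_stl(anatomy$lumen, file.path(out, "lumen.stl"))
  for (nm in names(anatomy$components))
    write_stl(anatomy$components[[nm]], file.path(out, paste0(nm, ".stl")))
  if (!is_empty_mesh(anatomy$reference_fibrous))
    write_stl(anatomy$reference_fibrous,
              file.path(out, "fibrous_reference.stl"))
  log_stage("synth: lumen %.1f mm^3, %d components",
            mesh_volume(anatomy$lumen), length(anatomy$components))

  ## ---- segment (optional round trip through HU space) -----------------
  lumen <- anatomy$lumen
  components <- anatomy$components
  if (isTRUE(cfg$stages$segment)) {
    vol <- voxelize_to_hu(lumen, components,
                          spacing = cfg$segmentation$voxel_spacing,
                          seed = cfg$seed)
    write_hu_volume(vol, file.path(out, "hu"))
    seg <- threshold_segment(vol, cfg$segmentation$hu_calcific,
                             cfg$segmentation$hu_lipid,
                             cfg$segmentation$hu_blood, min_voxels = 8)
    lumen <- seg$lumen
    components <- list()
    if (length(seg$calcific) > 0)
      components$calcific <- do.call(merge_meshes,
                                     c(seg$calcific, list(weld = FALSE,
                                                          name = "calcific")))
    if (length(seg$lipid) > 0)
      components$lipid <- do.call(merge_meshes,
                                  c(seg$lipid, list(weld = FALSE,
                                                    name = "lipid")))
    log_stage("segment: lumen %.1f mm^3 after threshold segmentation",
              mesh_volume(lumen))
  }

  if (!isTRUE(cfg$stages$reconstruct %||% TRUE)) {
    report <- list(seed = cfg$seed,
                   volumes = list(lumen = mesh_volume(lumen)))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(cfg, file.path(out, "config.yaml"))
    write_manifest(out)
    return(invisible(out))
  }

  ## ---- reconstruct ----------------------------------------------------
  rc <- cfg$reconstruction
  model <- reconstruct_wall(lumen, components, anatomy$centerlines,
                            spacing = rc$spacing, n_control = rc$n_control,
                            n_theta = cfg$anatomy$n_theta %||% 64,
                            enlarge_factor = rc$enlarge_factor,
                            narrow_frac = rc$narrow_frac,
                            fillet_radius = rc$fillet_radius)
  write_stl(model$wall_solid, file.path(out, "wall.stl"))
  write_stl(model$healthy_lumen, file.path(out, "healthy_lumen.stl"))
  if (!is_empty_mesh(model$fibrous))
    write_stl(model$fibrous, file.path(out, "fibrous.stl"))
  write_contour_stack(model$outer_stack, file.path(out, "outer_contours.txt"))
  log_stage("reconstruct: wall %.1f mm^3, fibrous %.1f mm^3",
            mesh_volume(model$wall_solid), mesh_volume(model$fibrous))

  report <- list(seed = cfg$seed,
                 volumes = list(
                   lumen = mesh_volume(lumen),
                   wall = mesh_volume(model$wall_solid),
                   healthy_lumen = mesh_volume(model$healthy_lumen),
                   fibrous = mesh_volume(model$fibrous)))

  if (isTRUE(cfg$stages$solve)) {
    ## ---- mesh ---------------------------------------------------------
    comp_meshes <- c(components, list(fibrous = model$fibrous))
    plaque_all <- Filter(Negate(is_empty_mesh), comp_meshes)
    # lattice background cell capped near the wall-thickness scale so the
    # thin shell stays resolved; refinement follows the imaged (calcific /
    # lipid) components, whose box localizes the stenosis
    gsize <- min(cfg$mesh$global_size, cfg$mesh$max_background_cell)
    refine_on <- Filter(Negate(is_empty_mesh), components)
    if (length(refine_on) == 0) refine_on <- plaque_all
    mesh <- tetrahedralize(model$wall_solid,
                           plaque_region = refine_on,
                           global_size = gsize,
                           local_size = cfg$mesh$local_size)
    mesh <- assign_subsets(mesh, plaque_all)
    p <- anatomy$params
    ends <- list(
      cca_end = list(z = min(model$wall_solid$vertices[, 3])),
      ica_end = list(z = max(model$wall_solid$vertices[, 3]),
                     center = branch_center(anatomy$centerlines, "ICA",
                                            p$z_top)),
      eca_end = list(z = max(model$wall_solid$vertices[, 3]),
                     center = branch_center(anatomy$centerlines, "ECA",
                                            p$z_top)))
    mesh <- tag_boundary(mesh, model$inner, ends)
    write_gmsh(mesh, file.path(out, "mesh.msh"))
    log_stage("mesh: %d elements, %d nodes", nrow(mesh$tets),
              nrow(mesh$nodes))

    ## ---- solve --------------------------------------------------------
    mt <- cfg$materials
    mat <- material_table(mt$calcific, mt$lipid, mt$fibrous, mt$wall, mt$nu)
    ld <- cfg$load
    load <- if (!is.null(ld$p_systolic)) {
      load_case(ld$p_systolic, ld$p_diastolic)
    } else {
      tab <- carotid_pressures()
      row <- tab[tab$patient == ld$patient, ]
      load_case(row$p_systolic, row$p_diastolic)
    }
    sol <- fem_solve(mesh, mat, load)
    write_stress_csv(sol$field, file.path(out, "stress.csv"))
    if (isTRUE(cfg$output$write_vtk))
      write_vtk(mesh, file.path(out, "result.vtk"),
                cell_data = list(vm_mpa = sol$field$vm_mpa))
    log_stage("solve: %d dof, max VM %.1f kPa", 3 * nrow(mesh$nodes),
              max(sol$field$vm_kpa))

    ## ---- post ---------------------------------------------------------
    vsub <- if (any(mesh$subset == "fibrous")) "fibrous" else "wall"
    curve <- volume_stress_curve(sol$field, vsub)
    v99 <- vm99(sol$field, vsub)
    loc <- vm99_location(v99, comp_meshes$lipid, comp_meshes$calcific,
                         anatomy$centerlines$apex)
    fct <- if (!is_empty_mesh(comp_meshes$lipid) &&
               identical(loc, "fibrous cap"))
      fc_thickness(v99, model$inner, comp_meshes$lipid) else NA_real_
    vols <- tapply(mesh$volumes, mesh$subset, sum)
    plaque_vols <- vols[intersect(names(vols),
                                  c("calcific", "lipid", "fibrous"))]
    comp_pct <- if (length(plaque_vols) > 0 && sum(plaque_vols) > 0)
      as.list(composition_percentages(plaque_vols)) else NULL
    write.csv(data.frame(vm_kpa = curve$vm_kpa,
                         cum_volume = curve$cum_volume),
              file.path(out, "volume_stress_curve.csv"), row.names = FALSE)
    report <- c(report, list(
      delta_p_mmhg = load$delta_p_mmhg,
      subset_volumes_mm3 = as.list(vols),
      composition_pct = comp_pct,
      vm99_kpa = v99$vm99_kpa,
      vm99_z = v99$z_station,
      vm99_location = if (is.na(loc)) NULL else loc,
      fc_thickness_mm = if (is.na(fct)) NULL else fct,
      n_elements = nrow(mesh$tets)))
  }

  report <- Filter(Negate(is.null), report)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(cfg, file.path(out, "config.yaml"))
  write_manifest(out)
  log_stage("done in %.1f s -> %s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")), out)
  invisible(out)
}

# manifest: every run artifact with its content hash
write_manifest <- function(dir) {
  files <- setdiff(list.files(dir), "manifest.json")
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- list(files = lapply(seq_along(files), function(i)
    list(name = files[i], md5 = unname(hashes[i]))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Compare simulations with proposed and reference fibrous models
#'
#' Runs two simulations that differ only in the fibrous component model
#' (automatically reconstructed "proposed" vs. externally provided
#' "reference", e.g. the generator's ground truth or a manual
#' segmentation), sharing the same wall geometry, mesh, materials and load
#' (hence the same spatial reference system), and reports the signed
#' distance analysis, both volume-stress curves, both VM99 values and the
#' percentage differences of VM99 and fibrous volume.
#'
#' @param reference_fibrous reference fibrous [surface_mesh] or STL path.
#' @param wall_model a `wall_model` from [reconstruct_wall()] (holds the
#'   proposed fibrous and the shared wall solid).
#' @param components list of calcific/lipid meshes shared by both models.
#' @param mat a [material_table()].
#' @param load a [load_case()].
#' @param mesh optional pre-built `tet_mesh` of the wall solid (tagged).
#' @param mesh_sizes `c(global, local)` for meshing when `mesh` is NULL.
#' @param end_planes end-plane list for [tag_boundary()] when meshing here.
#' @return a `model_comparison`: distance report, per-model VM99 and
#'   fibrous volumes, percentage differences and both curves.
#' @export
compare_models <- function(reference_fibrous, wall_model, components = list(),
                           mat = material_table(), load = load_case(161.5, 73),
                           mesh = NULL, mesh_sizes = c(0.45, 0.3),
                           end_planes = NULL) {
  if (is.character(reference_fibrous))
    reference_fibrous <- read_stl(reference_fibrous, name = "fibrous_reference")
  proposed <- wall_model$fibrous
  if (is_empty_mesh(proposed) || is_empty_mesh(reference_fibrous))
    stop("both fibrous models must be non-empty for a comparison")
  # both models must live on the same wall geometry
  bb_ref <- apply(reference_fibrous$vertices, 2, range)
  bb_wall <- apply(wall_model$wall_solid$vertices, 2, range)
  if (any(bb_ref[1, ] < bb_wall[1, ] - 1) || any(bb_ref[2, ] > bb_wall[2, ] + 1))
    stop("reference fibrous model does not fit the wall geometry")

  dist_rep <- signed_distance_report(reference_fibrous, proposed)

  if (is.null(mesh)) {
    plaque_all <- Filter(Negate(is_empty_mesh),
                         c(components, list(proposed, reference_fibrous)))
    mesh <- tetrahedralize(wall_model$wall_solid, plaque_all,
                           global_size = mesh_sizes[1],
                           local_size = mesh_sizes[2])
    if (is.null(end_planes)) {
      zr <- range(wall_model$wall_solid$vertices[, 3])
      end_planes <- list(cca_end = list(z = zr[1]),
                         ica_end = list(z = zr[2]))
    }
    mesh <- tag_boundary(mesh, wall_model$inner, end_planes)
  }

  run_one <- function(fib) {
    comp <- Filter(Negate(is_empty_mesh), c(components, list(fibrous = fib)))
    m <- assign_subsets(mesh, comp)
    sol <- fem_solve(m, mat, load)
    vsub <- if (any(m$subset == "fibrous")) "fibrous" else "wall"
    list(curve = volume_stress_curve(sol$field, vsub),
         vm99 = vm99(sol$field, vsub),
         fibrous_volume = sum(m$volumes[m$subset == "fibrous"]))
  }
  prop <- run_one(proposed)
  ref <- run_one(reference_fibrous)

  structure(list(
    distance = dist_rep,
    proposed = list(vm99_kpa = prop$vm99$vm99_kpa,
                    fibrous_volume = prop$fibrous_volume),
    reference = list(vm99_kpa = ref$vm99$vm99_kpa,
                     fibrous_volume = ref$fibrous_volume),
    pct_diff_vm99 = percentage_difference(prop$vm99$vm99_kpa,
                                          ref$vm99$vm99_kpa),
    pct_diff_volume = percentage_difference(prop$fibrous_volume,
                                            ref$fibrous_volume),
    curves = list(proposed = prop$curve, reference = ref$curve)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (proposed vs reference fibrous)\n")
  cat(sprintf("  VM99: %.2f vs %.2f kPa (%.2f%%)\n",
              x$proposed$vm99_kpa, x$reference$vm99_kpa, x$pct_diff_vm99))
  cat(sprintf("  fibrous volume: %.1f vs %.1f mm^3 (%.2f%%)\n",
              x$proposed$fibrous_volume, x$reference$fibrous_volume,
              x$pct_diff_volume))
  print(x$distance)
  invisible(x)
}
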