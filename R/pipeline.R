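#' Pipeline run configuration
#'
#' Nested configuration for the end-to-end pipeline with the study constants
#' as defaults. Units at the configuration surface are the field's: g/cm^3,
#' m/s, ms, kg, MPa, mm; conversion to the solver's internal units happens
#' once at ingest. Unknown keys are rejected.
#'
#' @param ... Named blocks overriding the defaults (partial lists are merged
#'   recursively): `phantom` ([phantom_spec()] fields), `calibration`
#'   ([hu_calibration()] fields), `meshing` (`threshold`, `coarsening`,
#'   `elem_type`), `materials` (`nu`, `target_mass`, `sensitivity_factor`),
#'   `impact` ([impact_case()] fields + `enabled`), `static`
#'   ([static_case()] pressures + `enabled`), `analysis` (`rows`, `cols`,
#'   `slice_offset`, `sr_frac`, `psg_frac`), `variants`, `seed`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    variants = "healthy",
    phantom = unclass(phantom_spec())[
      setdiff(names(unclass(phantom_spec())), "rng_seed")],
    calibration = unclass(hu_calibration()),
    meshing = list(threshold = 0.2, coarsening = 3L, elem_type = "hex8"),
    materials = list(nu = 0.3, target_mass = 5, sensitivity_factor = 1.5),
    impact = list(enabled = TRUE, velocity = 3.55, friction = 0.007,
                  contact_stiffness = 12, duration = 3,
                  output_interval = 0.25),
    static = list(enabled = TRUE, dorsal_pressure = 19.5,
                  palmar_pressure = 19.5),
    analysis = list(rows = 8L, cols = 20L, slice_offset = 5,
                    sr_frac = 0.25, psg_frac = 0.6)
  )
  user <- list(...)
  cfg <- merge_config(defaults, user, path = "")
  if (!all(cfg$variants %in% c("healthy", "oa"))) {
    abort("`variants` must be a subset of c('healthy', 'oa').")
  }
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, user, path) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in `", path, "`") else "",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        abort(sprintf("config key `%s` must be a block.", nm))
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, if (nzchar(path)) ".", nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose top-level keys follow [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

variant_spec <- function(config, variant) {
  ph <- config$phantom
  ph$lesion_center <- if (!is.null(ph$lesion_center)) {
    as.numeric(ph$lesion_center)
  }
  spec <- do.call(phantom_spec, c(ph, list(rng_seed = config$seed)))
  if (variant == "oa") spec <- oa_variant(spec) else spec
}

# build volume -> mesh -> materials for one variant; returns all stages
build_model <- function(config, variant) {
  spec <- variant_spec(config, variant)
  cal <- do.call(hu_calibration, config$calibration)
  vol <- generate_condyle_volume(spec)
  hu <- density_to_hu(vol, cal)
  dens <- hu_to_apparent_density(hu, cal)
  mask <- segment_volume(dens, config$meshing$threshold)
  mesh <- build_voxel_mesh(mask, config$meshing$coarsening,
                           config$meshing$elem_type)
  mesh <- label_regions(mesh, spec,
                        sr_frac = config$analysis$sr_frac,
                        psg_frac = config$analysis$psg_frac,
                        slice_offset = config$analysis$slice_offset)
  mat <- assign_element_materials(dens, mesh, nu = config$materials$nu)
  mat <- add_proximal_mass(mesh, mat, config$materials$target_mass)

  cb_vol <- generate_counterbody(spec)
  cb_mask <- segment_volume(cb_vol, config$meshing$threshold,
                            keep_largest = TRUE, fill_cavities = FALSE)
  cb_mesh <- build_voxel_mesh(cb_mask, config$meshing$coarsening,
                              config$meshing$elem_type)
  cb_mat <- assign_element_materials(cb_vol, cb_mesh,
                                     nu = config$materials$nu)
  list(spec = spec, volume = dens, mesh = mesh, materials = mat,
       counterbody = cb_mesh, counterbody_materials = cb_mat)
}

# slice tables (dorsal + palmar) for a per-element field
slice_tables <- function(mesh, field, layout, metadata) {
  lapply(c(dorsal = "dorsal", palmar = "palmar"), function(s) {
    g <- make_sampling_grid(mesh, "slice", slice = s, layout = layout)
    regional_summary(sample_field(g, field, mesh),
                     metadata = c(metadata, list(slice = s)))
  })
}

#' Run the full pipeline
#'
#' Phantom generation, HU round trip, material mapping, meshing, the
#' enabled solves (impact, static), regional analysis, and a run directory
#' with volumes, meshes, tables, the resolved configuration, and a
#' checksummed manifest. With both variants a healthy-versus-OA comparison
#' table is written.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; one subdirectory per variant).
#' @return Invisibly, a list of per-variant results (meshes, histories,
#'   solutions, tables) plus comparison tables.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- c(config$analysis$rows, config$analysis$cols)
  results <- list()

  for (variant in config$variants) {
    vd <- file.path(out_dir, variant)
    dir.create(vd, showWarnings = FALSE)
    model <- build_model(config, variant)
    res <- list(model = model)

    write_volume(model$volume, file.path(vd, "volume.mhd"))
    write_mesh(model$mesh, file.path(vd, "mesh.vtk"),
               cell_data = list(E = model$materials$E,
                                rho = model$materials$rho))
    utils::write.csv(as.data.frame(model$materials),
                     file.path(vd, "materials.csv"), row.names = FALSE)

    if (isTRUE(config$impact$enabled)) {
      icase <- impact_case(
        velocity = config$impact$velocity,
        friction = config$impact$friction,
        contact_stiffness = config$impact$contact_stiffness,
        duration = config$impact$duration,
        output_interval = config$impact$output_interval
      )
      hist <- run_impact(model$mesh, model$materials, icase,
                         counterbody = model$counterbody,
                         counterbody_materials = model$counterbody_materials)
      res$impact <- hist
      res$impact_tables <- slice_tables(
        model$mesh, impact_vm_field(hist), layout,
        list(variant = variant, load_case = "impact"))
      res$contact <- contact_summary(hist, model$mesh)
      utils::write.csv(hist$energies, file.path(vd, "impact_energies.csv"),
                       row.names = FALSE)
      utils::write.csv(res$contact, file.path(vd, "contact_pressure.csv"),
                       row.names = FALSE)
      utils::write.csv(dplyr::bind_rows(res$impact_tables, .id = "slice"),
                       file.path(vd, "impact_von_mises.csv"),
                       row.names = FALSE)
    }
    if (isTRUE(config$static$enabled)) {
      scase <- static_case(c(
        dorsal_patch = config$static$dorsal_pressure,
        palmar_patch = config$static$palmar_pressure
      ))
      sol <- solve_static(model$mesh, model$materials, scase)
      res$static <- sol
      res$static_tables <- slice_tables(
        model$mesh, sol, layout,
        list(variant = variant, load_case = "static"))
      utils::write.csv(dplyr::bind_rows(res$static_tables, .id = "slice"),
                       file.path(vd, "static_von_mises.csv"),
                       row.names = FALSE)
    }
    results[[variant]] <- res
  }

  if (all(c("healthy", "oa") %in% names(results)) &&
      isTRUE(config$impact$enabled)) {
    cmp <- compare_variants(results$healthy$impact_tables$dorsal,
                            results$oa$impact_tables$dorsal,
                            labels = c("healthy", "oa"))
    results$comparison <- cmp
    utils::write.csv(cmp, file.path(out_dir, "healthy_vs_oa.csv"),
                     row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
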