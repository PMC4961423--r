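# full-scale study runs shared by the acceptance tests; computed lazily and
# cached so each expensive solve happens once per test session

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

default_model <- function(variant = "healthy", coarsening = NULL) {
  cfg <- if (is.null(coarsening)) run_config() else
    run_config(meshing = list(coarsening = coarsening))
  cached(paste0("model_", variant, "_", cfg$meshing$coarsening),
         fetlockfe:::build_model(cfg, variant))
}

symmetric_model <- function() {
  cached("model_sym", {
    cfg <- run_config(phantom = list(trabecular_density_sd = 0,
                                     joint_angle = 180))
    fetlockfe:::build_model(cfg, "healthy")
  })
}

impact_of <- function(tag, model, case = impact_case()) {
  cached(paste0("impact_", tag), {
    suppressWarnings(run_impact(
      model$mesh, model$materials, case,
      counterbody = model$counterbody,
      counterbody_materials = model$counterbody_materials
    ))
  })
}

scaled_impact <- function(model) {
  cached("impact_scaled", {
    suppressWarnings(run_impact(
      model$mesh, scale_moduli(model$materials, 1.5), impact_case(),
      counterbody = model$counterbody,
      counterbody_materials = scale_moduli(model$counterbody_materials, 1.5)
    ))
  })
}

static_of <- function(tag, model, case = static_case()) {
  cached(paste0("static_", tag),
         solve_static(model$mesh, model$materials, case))
}

slice_samples <- function(model, field, slice, layout = c(8, 20)) {
  grid <- make_sampling_grid(model$mesh, "slice", slice, layout)
  sample_field(grid, field, model$mesh)
}
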