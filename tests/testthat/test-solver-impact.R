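test_that("the stable time step follows the CFL closed form", {
  E <- 16000; rho_g <- 2.0         # g/cm^3 -> 2e-9 tonne/mm^3
  for (h in c(1, 2)) {
    mesh <- bar_mesh(2, 2, 2, h = h)
    mat <- material_field(rep(E, nrow(mesh$elems)), 0, rho_g)
    expect_equal(stable_timestep(mesh, mat, safety = 0.8),
                 0.8 * h / sqrt(E / (rho_g * 1e-9)), tolerance = 1e-12)
  }
  # mixed materials: equals the brute-force per-element minimum
  set.seed(41)
  mesh <- bar_mesh(3, 3, 3)
  E <- runif(27, 1000, 40000); nu <- 0.3; rho <- runif(27, 0.5, 2)
  mat <- material_field(E, nu, rho)
  cs <- sqrt(E * (1 - nu) / (rho * 1e-9 * (1 + nu) * (1 - 2 * nu)))
  expect_equal(stable_timestep(mesh, mat, 0.8), 0.8 * min(1 / cs),
               tolerance = 1e-12)
  expect_error(stable_timestep(mesh, material_field(E, nu, 0)), "density")
})

test_that("free flight before contact keeps velocity exact and stress zero", {
  mesh <- bar_mesh(3, 3, 6)
  mat <- material_field(rep(16000, nrow(mesh$elems)), 0.3, 2)
  case <- impact_case(velocity = 1, friction = 0, duration = 0.02,
                      output_interval = 0.01,
                      rigid_plane_z = max(mesh$nodes[, 3]) + 5)
  h <- run_impact(mesh, mat, case)
  for (fr in seq_along(h$times)) {
    expect_lt(max(abs(h$v_snapshots[[fr]][, 3] - 1000)), 1e-8)
    expect_lt(max(abs(h$v_snapshots[[fr]][, 1:2])), 1e-8)
    expect_lt(max(h$vm[, fr]), 1e-8)
  }
  expect_true(all(h$pressure == 0))
  # momentum before contact is mass * v0 exactly
  mass <- sum(element_volumes(mesh)) * 2e-9
  v <- h$v_snapshots[[2]]
  m_node <- fetlockfe:::lumped_node_mass(mesh, mat)
  expect_equal(sum(m_node * v[, 3]), mass * 1000, tolerance = 1e-10)
})

test_that("an elastic rod hits the rho*c*v impact plateau", {
  h <- 2; nz <- 50; L <- h * nz
  mesh <- bar_mesh(3, 3, nz, h = h)
  mat <- material_field(rep(16000, nrow(mesh$elems)), 0, 2.0)
  c_wave <- sqrt(16000 / 2e-9)
  t_end <- 2 * L / c_wave / 1e-3          # event duration in ms
  case <- impact_case(velocity = 3.55, friction = 0,
                      contact_stiffness = 2000, duration = t_end,
                      output_interval = t_end / 40, safety = 0.5,
                      rigid_plane_z = max(mesh$nodes[, 3]) + 0.05)
  hist <- run_impact(mesh, mat, case)
  cen <- element_centroids(mesh)
  mid <- which(abs(cen[, 3] - L / 2) < h)
  vm_mid <- colMeans(hist$vm[mid, , drop = FALSE])
  plateau <- median(vm_mid[vm_mid > 0.5 * max(vm_mid)])
  expect_lt(abs(plateau - 20.081832585698) / 20.081832585698, 0.05)
  # energy audit over the whole event
  en <- hist$energies
  expect_lt(max(abs(en$total - hist$initial_ke)) / hist$initial_ke, 0.02)
})

test_that("impact histories are bit-identical across runs", {
  cfg <- small_config()
  m <- fetlockfe:::build_model(cfg, "healthy")
  case <- impact_case(duration = 0.4, output_interval = 0.2)
  h1 <- suppressWarnings(run_impact(m$mesh, m$materials, case,
    counterbody = m$counterbody, counterbody_materials = m$counterbody_materials))
  h2 <- suppressWarnings(run_impact(m$mesh, m$materials, case,
    counterbody = m$counterbody, counterbody_materials = m$counterbody_materials))
  expect_identical(h1$vm, h2$vm)
  expect_identical(h1$pressure, h2$pressure)
  expect_identical(h1$energies, h2$energies)
})

test_that("two-body contact transfers momentum and reports its own force", {
  cfg <- small_config()
  m <- fetlockfe:::build_model(cfg, "healthy")
  case <- impact_case(friction = 0, duration = 1.2, output_interval = 0.1)
  h <- suppressWarnings(run_impact(m$mesh, m$materials, case,
    counterbody = m$counterbody, counterbody_materials = m$counterbody_materials))
  expect_gt(max(h$contact_force), 0)
  # recomputation oracle: total contact force = k * sum(overclosure * area)
  # = sum over articular facets of facet pressure * facet area (the facet
  # pressure is the mean of its nodes' k*overclosure values)
  area <- m$mesh$facet_area[h$contact_facets]
  for (fr in which(h$contact_force > 0.1 * max(h$contact_force))) {
    expect_equal(h$contact_force[fr], sum(h$pressure[, fr] * area),
                 tolerance = 0.05)
  }
  # energy balance of the frictionless event
  en <- h$energies
  expect_lt(max(abs(en$total - h$initial_ke)) / h$initial_ke, 0.02)
  # friction on: dissipated energy is non-negative and monotone
  hf <- suppressWarnings(run_impact(m$mesh, m$materials,
    impact_case(friction = 0.1, duration = 1.2, output_interval = 0.1),
    counterbody = m$counterbody, counterbody_materials = m$counterbody_materials))
  expect_true(all(diff(hf$energies$friction) >= 0))
  expect_gt(max(hf$energies$friction), 0)
})

test_that("contact summaries aggregate uniform pressure exactly", {
  cfg <- small_config()
  m <- fetlockfe:::build_model(cfg, "healthy")
  art <- m$mesh$facet_sets$distal_articular_surface
  hist <- structure(list(
    times = c(0, 0.1),
    pressure = cbind(rep(0, length(art)), rep(7, length(art))),
    contact_facets = art,
    contact_force = c(0, 7 * sum(m$mesh$facet_area[art]))
  ), class = "impact_history")
  cs <- contact_summary(hist, m$mesh)
  expect_true(all(abs(cs$avg_pressure - 7) < 1e-12))
  expect_true(all(abs(cs$peak_pressure - 7) < 1e-12))
  expect_equal(sum(cs$contact_area), sum(m$mesh$facet_area[art]))
})
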