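test_that("HU to apparent density follows the affine chain", {
  cal <- hu_calibration(slope = 1e-3, intercept = 0,
                        ash_to_apparent_ratio = 0.6)
  v <- voxel_volume(array(600, c(1, 1, 1)), 1, value_kind = "HU")
  out <- hu_to_apparent_density(v, cal)
  expect_equal(out$data[1], 1.0)            # ash 0.6 -> apparent 1.0
  expect_identical(out$value_kind, "density")

  # affine root maps to zero density; negative ash clips at zero
  cal2 <- hu_calibration(slope = 2e-3, intercept = 0.4)
  v2 <- voxel_volume(array(c(-200, -500), c(2, 1, 1)), 1, value_kind = "HU")
  out2 <- hu_to_apparent_density(v2, cal2)
  expect_equal(out2$data[1, 1, 1], 0)
  expect_equal(out2$data[2, 1, 1], 0)

  # monotone for any calibration
  set.seed(3)
  for (i in 1:5) {
    cal3 <- hu_calibration(runif(1, 1e-4, 1e-2), runif(1, -1, 1),
                           runif(1, 0.3, 1))
    hu <- sort(runif(10, -1000, 3000))
    vv <- voxel_volume(array(hu, c(10, 1, 1)), 1, value_kind = "HU")
    d <- as.vector(hu_to_apparent_density(vv, cal3)$data)
    expect_true(all(diff(d) >= 0))
  }
  expect_error(hu_to_apparent_density(
    voxel_volume(array(1, c(1, 1, 1)), 1, value_kind = "density")),
    "HU-valued")
})

test_that("the power-law modulus matches its stated values", {
  expect_identical(modulus_from_density(1), 9040)
  expect_identical(modulus_from_density(0), 0)
  # independently evaluated 9040 * 2.47^2.35
  expect_equal(modulus_from_density(2.47), 75684.3822761799,
               tolerance = 1e-9)
  expect_error(modulus_from_density(-0.1), ">= 0")
})

test_that("element materials average modulus before density (Jensen order)", {
  # one element spanning two voxels of different density, built directly
  nodes <- as.matrix(expand.grid(x = c(0, 2), y = c(0, 1), z = c(0, 1)))
  nodes <- nodes[, c("x", "y", "z")]
  elem <- matrix(c(1L, 2L, 4L, 3L, 5L, 6L, 8L, 7L), 1, 8)
  mesh1 <- fe_mesh(nodes, elem, "hex8")
  d1 <- 0.8; d2 <- 1.6
  vol <- voxel_volume(array(c(d1, d2), c(2, 1, 1)), spacing = 1,
                      origin = c(0.5, 0.5, 0.5), value_kind = "density")
  mf <- assign_element_materials(vol, mesh1, nu = 0.3)
  expect_equal(mf$E, (9040 * d1^2.35 + 9040 * d2^2.35) / 2, tolerance = 1e-12)
  expect_gt(mf$E, 9040 * ((d1 + d2) / 2)^2.35)     # convexity direction
  expect_equal(mf$rho, (d1 + d2) / 2)
  expect_equal(mf$nu, 0.3)
})

test_that("element material assignment matches the brute-force voxel loop", {
  set.seed(11)
  for (rep in 1:3) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1); nz <- sample(4:6, 1)
    dens <- array(runif(nx * ny * nz * 8, 0, 2.47),
                  dim = c(2 * nx, 2 * ny, 2 * nz))
    vol <- voxel_volume(dens, spacing = 1, origin = c(0.5, 0.5, 0.5),
                        value_kind = "density")
    mask <- vol; mask$value_kind <- "mask"; mask$data[] <- 1
    mesh <- build_voxel_mesh(mask, coarsening = 2L)
    expect_lte(nrow(mesh$elems), 500)
    mf <- assign_element_materials(vol, mesh)
    oracle <- material_oracle(vol, mesh)
    expect_equal(mf$E, oracle$E, tolerance = 1e-12)
    expect_equal(mf$rho, oracle$rho, tolerance = 1e-12)
  }
})

test_that("a pointwise denser volume never lowers the modulus field", {
  set.seed(5)
  dens <- array(runif(4 * 4 * 4, 0.2, 2), dim = c(4, 4, 4))
  vol <- voxel_volume(dens, 1, c(0.5, 0.5, 0.5), "density")
  vol2 <- vol; vol2$data <- pmin(vol$data + runif(64, 0, 0.4), 2.47)
  mask <- vol; mask$value_kind <- "mask"; mask$data[] <- 1
  mesh <- build_voxel_mesh(mask, 2L)
  expect_true(all(assign_element_materials(vol2, mesh)$E >=
                    assign_element_materials(vol, mesh)$E))
})

test_that("modulus scaling is exact and invertible", {
  f <- material_field(E = c(9040, 100), nu = 0.3, rho = 1)
  s <- scale_moduli(f, 1.5)
  expect_equal(s$E, c(13560, 150))
  expect_equal(s$nu, f$nu)
  expect_equal(s$rho, f$rho)
  back <- scale_moduli(s, 2 / 3)
  expect_equal(back$E, f$E, tolerance = 1e-12)
  expect_identical(scale_moduli(f, 1)$E, f$E)
  expect_error(scale_moduli(f, 0), "positive")
})

test_that("proximal mass augmentation hits the target mass exactly", {
  mesh <- bar_mesh(3, 3, 10)
  f <- material_field(E = rep(9040, nrow(mesh$elems)), nu = 0.3, rho = 1.2)
  m0 <- model_mass(mesh, f)
  target <- m0 * 50
  aug <- add_proximal_mass(mesh, f, target)
  expect_lt(abs(model_mass(mesh, aug) - target) / target, 1e-3)
  expect_equal(unique(aug$E[mesh$elem_sets$proximal_end]), 16000)
  expect_equal(unique(aug$nu[mesh$elem_sets$proximal_end]), 0.3)

  # doubling the proximal volume halves the density needed for the deficit
  mesh2 <- bar_mesh(3, 3, 10)
  mesh2$elem_sets$proximal_end <-
    which(element_centroids(mesh2)[, 3] <= 2)   # two layers instead of one
  f2 <- material_field(E = rep(9040, nrow(mesh2$elems)), nu = 0.3, rho = 0)
  f1 <- material_field(E = rep(9040, nrow(mesh$elems)), nu = 0.3, rho = 0)
  a1 <- add_proximal_mass(mesh, f1, 1)
  a2 <- add_proximal_mass(mesh2, f2, 1)
  expect_equal(attr(a1, "augmented_density") /
                 attr(a2, "augmented_density"), 2, tolerance = 1e-12)

  expect_error(add_proximal_mass(mesh, f, m0 / 2), "below")
})
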