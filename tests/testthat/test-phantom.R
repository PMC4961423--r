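test_that("phantom generation is deterministic and density-bounded", {
  spec <- small_spec()
  v1 <- generate_condyle_volume(spec)
  v2 <- generate_condyle_volume(spec)
  expect_identical(v1$data, v2$data)
  expect_true(all(v1$data >= 0 & v1$data <= 2.47))
  c1 <- generate_counterbody(spec)
  c2 <- generate_counterbody(spec)
  expect_identical(c1$data, c2$data)
})

test_that("degenerate noise and zero-effect lesions leave the volume as is", {
  flat <- small_spec(trabecular_density_sd = 0)
  v <- generate_condyle_volume(flat)
  interior <- v$data[v$data > 0 & v$data != flat$cortical_density]
  expect_true(all(interior == flat$trabecular_density_mean))

  base <- generate_condyle_volume(small_spec())
  null_lesion <- generate_condyle_volume(
    oa_variant(small_spec(), density_delta = 0))
  expect_identical(base$data, null_lesion$data)

  oa <- generate_condyle_volume(oa_variant(small_spec()))
  expect_gt(sum(oa$data), sum(base$data))
  expect_true(all(oa$data <= 2.47))
})

test_that("voxelized bone volume matches the analytic CSG volume within 2%", {
  spec <- phantom_spec()
  v <- generate_condyle_volume(spec)
  va <- analytic_condyle_volume(spec)
  expect_lt(abs(voxel_bone_volume(v) - va) / va, 0.02)
})

test_that("a symmetric lesion-free phantom mirrors about the sagittal plane", {
  v <- generate_condyle_volume(small_spec(trabecular_density_sd = 0))
  m <- mirror_volume(v)
  expect_identical(v$data, m$data)
})

test_that("counterbody honours the congruency gap and the collinear pose", {
  spec <- small_spec(joint_angle = 180, trabecular_density_sd = 0)
  cond <- generate_condyle_volume(spec)
  cb <- generate_counterbody(spec)
  # brute-force nearest surface-voxel distance between the two bodies
  surf <- function(vol) {
    ax <- voxel_axes(vol)
    idx <- which(vol$data > 0, arr.ind = TRUE)
    cbind(ax$x[idx[, 1]], ax$y[idx[, 2]], ax$z[idx[, 3]])
  }
  a <- surf(cond); b <- surf(cb)
  a <- a[a[, 3] > max(a[, 3]) - 3, , drop = FALSE]   # distal crown only
  b <- b[b[, 3] < min(b[, 3]) + 2 * spec$congruency_gap + 3, , drop = FALSE]
  dmin <- sqrt(min(vapply(seq_len(nrow(a)), function(i) {
    min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2)
  }, 0)))
  expect_gte(dmin, spec$congruency_gap - spec$voxel_spacing)
  expect_lte(dmin, spec$congruency_gap + spec$voxel_spacing)
  # collinear pose: counterbody is mirror-symmetric in x and y
  expect_identical(cb$data, mirror_volume(cb)$data)
})

test_that("density/HU conversion round-trips through any affine calibration", {
  set.seed(7)
  for (i in 1:5) {
    cal <- hu_calibration(slope = runif(1, 1e-4, 1e-2),
                          intercept = runif(1, -1, 1),
                          ash_to_apparent_ratio = runif(1, 0.3, 1))
    dens <- array(runif(60, 0, 2.47), dim = c(5, 4, 3))
    v <- voxel_volume(dens, spacing = 1, value_kind = "density")
    back <- hu_to_apparent_density(density_to_hu(v, cal), cal)
    expect_lt(max(abs(back$data - dens)) / max(dens), 1e-9)
    expect_identical(back$value_kind, "density")
  }
  # zero density maps to the intercept of the calibration line
  cal <- hu_calibration(slope = 2e-3, intercept = 0.1)
  v0 <- voxel_volume(array(0, c(1, 1, 1)), 1, value_kind = "density")
  expect_equal(density_to_hu(v0, cal)$data[1], -0.1 / 2e-3)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(voxel_spacing = -1), "positive")
  expect_error(phantom_spec(cortical_density = 3), "2.47")
  expect_error(phantom_spec(condyle_separation = 30, shaft_radius = 40),
               "overlap")
  expect_error(phantom_spec(shaft_radius = 5), "shaft_radius")
  expect_error(generate_condyle_volume(phantom_spec(voxel_spacing = 0.05),
                                       max_voxels = 1e6), "budget")
})
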