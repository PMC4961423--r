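test_that("a full cuboid mask meshes to the closed-form element counts", {
  n <- c(4, 3, 5)
  mesh <- bar_mesh(n[1], n[2], n[3])
  expect_equal(nrow(mesh$elems), prod(n))
  expect_equal(nrow(mesh$facets),
               2 * (n[1] * n[2] + n[2] * n[3] + n[3] * n[1]))
  expect_true(all(element_volumes(mesh) > 0))
  expect_equal(sum(element_volumes(mesh)), prod(n))

  # coarsening 2 on even dims divides the element count by 8
  mesh2 <- build_voxel_mesh(cuboid_mask(4, 4, 6), coarsening = 2L)
  expect_equal(nrow(mesh2$elems), 4 * 4 * 6 / 8)
  expect_equal(sum(element_volumes(mesh2)), 4 * 4 * 6)
})

test_that("the tet split is exact in volume and conforming", {
  tet <- build_voxel_mesh(cuboid_mask(1, 1, 1), elem_type = "tet4")
  expect_equal(nrow(tet$elems), 6)
  v <- element_volumes(tet)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1, tolerance = 1e-12)

  # conformity: every interior triangular face is shared by exactly 2 tets
  tet3 <- build_voxel_mesh(cuboid_mask(3, 2, 2), elem_type = "tet4")
  faces <- c()
  tmpl <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (f in 1:4) {
    tri <- tet3$elems[, tmpl[f, ]]
    faces <- c(faces, apply(tri, 1, function(r) paste(sort(r), collapse = "-")))
  }
  counts <- table(table(faces))
  expect_true(all(names(counts) %in% c("1", "2")))
  expect_equal(sum(element_volumes(tet3)), 12, tolerance = 1e-12)
})

test_that("segmentation thresholds, components and cavities behave", {
  spec <- phantom_spec()
  vol <- generate_condyle_volume(spec)
  mask <- segment_volume(vol, 0.2)
  va <- analytic_condyle_volume(spec)
  expect_lt(abs(sum(mask$data) * prod(mask$spacing) - va) / va, 0.03)
  expect_error(segment_volume(vol, 99), "empty mask")

  # two components: only the largest survives; cavity filled
  arr <- array(0, c(9, 5, 5))
  arr[1:4, , ] <- 1         # big blob
  arr[2, 3, 3] <- 0         # internal cavity
  arr[8, 3, 3] <- 1         # isolated voxel
  v <- voxel_volume(arr, 1, value_kind = "density")
  m <- segment_volume(v, 0.5)
  expect_equal(sum(m$data), 4 * 25)      # cavity refilled, speck dropped
})

test_that("region labels partition the articular surface symmetrically", {
  spec <- small_spec(trabecular_density_sd = 0)
  mesh <- build_voxel_mesh(segment_volume(generate_condyle_volume(spec), 0.2), 2L)
  mesh <- label_regions(mesh, spec)
  art <- mesh$facet_sets$distal_articular_surface
  regions <- c("DLC", "DLPSG", "DMC", "DMPSG",
               "PLC", "PLPSG", "PMC", "PMPSG", "SR")
  counts <- vapply(regions, function(r) length(mesh$facet_sets[[r]]), 0L)
  expect_equal(sum(counts), length(art))    # exactly one label per facet
  expect_equal(length(unique(unlist(mesh$facet_sets[regions]))), length(art))

  a <- function(r) sum(mesh$facet_area[mesh$facet_sets[[r]]])
  expect_lt(abs(a("DMC") - a("DLC")) / a("DMC"), 0.05)
  expect_lt(abs(a("PMPSG") - a("PLPSG")) / a("PMPSG"), 0.05)
})

test_that("band labelling ties break toward SR and dorsal", {
  lm <- list(sr_halfwidth = 1.5, psg_halfwidth = 3.6)
  expect_equal(region_of_point(0, 1, lm), "SR")
  expect_equal(region_of_point(1.5, -1, lm), "SR")    # edge inclusive to SR
  expect_equal(region_of_point(-1.6, 1, lm), "DLPSG")
  expect_equal(region_of_point(3.6, -1, lm), "PMPSG") # edge inclusive to PSG
  expect_equal(region_of_point(3.7, 2, lm), "DMC")
  expect_equal(region_of_point(-4, 0, lm), "DLC")     # y = 0 is dorsal
})

test_that("boundary facets carry outward normals and exact areas", {
  mesh <- bar_mesh(2, 2, 2)
  fc <- facet_centroids(mesh)
  centre <- colMeans(mesh$nodes)
  out <- rowSums(mesh$facet_normal * sweep(fc, 2, centre))
  expect_true(all(out > 0))
  expect_true(all(abs(mesh$facet_area - 1) < 1e-12))
})
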