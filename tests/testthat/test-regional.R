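# a labelled slab mesh whose slice-grid geometry is known in closed form
slab_mesh <- function(nx = 10, nz = 6, h = 1) {
  mesh <- bar_mesh(nx, 3, nz, h = h)
  mesh$landmarks <- list(H = h, mid_x = nx * h / 2, ridge_y = 1.5 * h,
                         z_cut = -Inf,
                         sr_halfwidth = Inf, psg_halfwidth = Inf,
                         slice_y = c(dorsal = 1.5 * h, palmar = 1.5 * h))
  # centre the bands on the slab mid-plane so labels are well defined
  mesh$nodes[, 1] <- mesh$nodes[, 1] - nx * h / 2
  mesh$nodes[, 2] <- mesh$nodes[, 2] - 1.5 * h
  mesh$landmarks$slice_y <- c(dorsal = 0, palmar = 0)
  mesh$landmarks$sr_halfwidth <- 1; mesh$landmarks$psg_halfwidth <- 3
  mesh
}

test_that("the 160-point grid is corner-anchored with closed-form spacing", {
  mesh <- slab_mesh(10, 6)
  g <- make_sampling_grid(mesh, "slice", 0, layout = c(8, 20))
  expect_equal(nrow(g), 160)
  expect_true(all(!is.na(g$region)))
  sp <- attr(g, "spacing")
  expect_equal(sp[[2]], 10 / 19)   # cols span the width w: w/19
  expect_equal(sp[[1]], 6 / 7)     # rows span the height h: h/7
  expect_equal(sort(unique(g$x))[1], -5)
  expect_equal(max(g$x), 5)
  expect_equal(sum(g$projected), 0)

  # affine equivariance: scaling the mesh by 2 scales the grid by 2
  mesh2 <- slab_mesh(10, 6, h = 2)
  g2 <- make_sampling_grid(mesh2, "slice", 0, layout = c(8, 20))
  expect_equal(g2$x, 2 * g$x, tolerance = 1e-12)
  expect_equal(g2$z, 2 * g$z, tolerance = 1e-12)
})

test_that("piecewise-constant sampling matches a point-location oracle", {
  mesh <- slab_mesh(10, 6)
  g <- make_sampling_grid(mesh, "slice", 0, layout = c(8, 20))
  # constant field
  s <- sample_field(g, rep(3.5, nrow(mesh$elems)), mesh)
  expect_true(all(s$value == 3.5))
  # linear-in-x element field against explicit element lookup
  cen <- element_centroids(mesh)
  field <- 2 * cen[, 1] + 1
  s2 <- sample_field(g, field, mesh)
  b <- element_bounds(mesh)
  oracle <- vapply(seq_len(nrow(g)), function(i) {
    e <- which(b$lo[, 1] - 1e-9 <= g$x[i] & g$x[i] <= b$hi[, 1] + 1e-9 &
                 b$lo[, 2] - 1e-9 <= g$y[i] & g$y[i] <= b$hi[, 2] + 1e-9 &
                 b$lo[, 3] - 1e-9 <= g$z[i] & g$z[i] <= b$hi[, 3] + 1e-9)[1]
    field[e]
  }, 0)
  expect_equal(s2$value, oracle)
  # determinism
  expect_identical(sample_field(g, field, mesh)$value, s2$value)
})

test_that("regional summaries do exact arithmetic on toy samples", {
  s <- tibble::tibble(region = c("DLC", "DLC", "DMC"), value = c(5, 9, 7))
  t1 <- regional_summary(s)
  expect_equal(t1$average[t1$region == "DLC"], 7)
  expect_equal(t1$peak[t1$region == "DLC"], 9)
  expect_equal(t1$n[t1$region == "DMC"], 1)

  su <- tibble::tibble(region = rep("SR", 4), value = 7)
  t2 <- regional_summary(su)
  expect_equal(t2$average, 7); expect_equal(t2$peak, 7)

  # pooled means obey the n-weighted identity
  sa <- tibble::tibble(region = c("DLC", "DLC", "DMC"), value = c(2, 4, 9))
  pooled <- regional_summary(sa, by = "location")
  byreg <- regional_summary(sa)
  expect_equal(pooled$average[pooled$region == "dorsal"],
               sum(byreg$n * byreg$average) / sum(byreg$n), tolerance = 1e-12)
})

test_that("the convergence report reproduces the +-5% bookkeeping", {
  mk <- function(vals) {
    t <- tibble::tibble(region = c("MC", "SR"), n = 1,
                        average = vals, peak = vals)
    class(t) <- c("regional_stress_table", class(t)); t
  }
  rep1 <- convergence_check(list(moderate = mk(c(12.85, 13.6)),
                                 fine = mk(c(12.80, 12.8))), 0.05)
  expect_equal(rep1$diff, c(0.05, 0.8), tolerance = 1e-12)
  expect_equal(100 * rep1$rel_diff, c(0.390625, 6.25), tolerance = 1e-12)
  expect_equal(rep1$converged, c(TRUE, FALSE))
  ident <- convergence_check(list(a = mk(c(1, 2)), b = mk(c(1, 2))))
  expect_true(all(ident$diff == 0) && all(ident$converged))
  expect_error(convergence_check(list(mk(c(1, 2)))), "two tables")
  bad <- mk(c(1, 2)); bad$region <- c("MC", "XX")
  expect_error(convergence_check(list(bad, mk(c(1, 2)))), "regions")
})

test_that("the sensitivity report computes ratios and point fractions", {
  mk <- function(vals) {
    t <- tibble::tibble(region = "DMC", n = 1, average = vals, peak = vals)
    class(t) <- c("regional_stress_table", class(t)); t
  }
  rep1 <- sensitivity_compare(mk(12.80), mk(12.94))
  expect_equal(rep1$ratio, 1.0109375, tolerance = 1e-12)
  expect_equal(rep1$pct_change, 1.09375, tolerance = 1e-10)
  ident <- sensitivity_compare(mk(5), mk(5))
  expect_equal(ident$ratio, 1)
  # per-point distribution
  sb <- tibble::tibble(region = "DMC", value = c(10, 10, 10, 10))
  ss <- tibble::tibble(region = "DMC", value = c(10, 10.5, 14.3, 10.001))
  rep2 <- sensitivity_compare(mk(10), mk(11.2), sb, ss)
  pts <- attr(rep2, "points")
  expect_equal(pts$n, 4)
  expect_equal(pts$n_changed, 2)         # 5% and 43%; 0.01% is under tol
  expect_equal(pts$frac_changed, 0.5)
  expect_equal(pts$max_pct_increase, 43, tolerance = 1e-9)
  # monotone: if every sample increased, every ratio >= 1
  expect_true(all(sensitivity_compare(mk(3), mk(3.3))$ratio >= 1))
})

test_that("variant comparisons are signed and antisymmetric", {
  mk <- function(vals) {
    t <- tibble::tibble(region = "DMC", n = 1, average = vals, peak = vals)
    class(t) <- c("regional_stress_table", class(t)); t
  }
  cmp <- compare_variants(mk(12.8), mk(14.1), c("healthy", "oa"))
  expect_equal(cmp$diff_average, 1.3)
  expect_equal(cmp$pct_average, 10.15625, tolerance = 1e-10)
  ab <- compare_variants(mk(3), mk(5))
  ba <- compare_variants(mk(5), mk(3))
  expect_equal(ab$diff_average, -ba$diff_average)
  same <- compare_variants(mk(4), mk(4))
  expect_equal(same$diff_average, 0)
  expect_equal(same$pct_average, 0)
})

test_that("grids are reproducible and carry one label per point", {
  m <- fetlockfe:::build_model(small_config(), "healthy")
  g1 <- make_sampling_grid(m$mesh, "slice", "dorsal")
  g2 <- make_sampling_grid(m$mesh, "slice", "dorsal")
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 160)
  expect_true(all(g1$region %in% c("DLC", "DLPSG", "DMC", "DMPSG", "SR")))
  gs <- make_sampling_grid(m$mesh, "surface")
  expect_equal(nrow(gs), 160)
  expect_true(all(!is.na(gs$region)))
})
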