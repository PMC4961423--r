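test_that("the unconstrained stiffness has exactly the rigid-body kernel", {
  mesh <- bar_mesh(1, 1, 1)
  sys <- assemble_system(mesh, material_field(500, 0.25, 1))
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K - t(K))), 1e-10 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)

  # K annihilates rigid translations
  mesh2 <- bar_mesh(2, 2, 3)
  sys2 <- assemble_system(mesh2, material_field(
    rep(9040, nrow(mesh2$elems)), 0.3, 1))
  ut <- rep(c(1, -2, 3), nrow(mesh2$nodes))
  expect_lt(max(abs(as.numeric(sys2$K %*% ut))),
            1e-8 * max(abs(sys2$K)))
})

test_that("strain energy matches an independent quadrature oracle", {
  set.seed(21)
  mesh <- bar_mesh(1, 1, 1, h = 1.7)
  for (nu in c(0, 0.3)) {
    E <- 12345
    sys <- assemble_system(mesh, material_field(E, nu, 1))
    u <- rnorm(24, 0, 0.01)
    eK <- 0.5 * sum(u * as.numeric(sys$K %*% u))
    corners <- mesh$nodes[mesh$elems[1, ], ]
    # oracle dof order follows the element's node order
    ue <- as.vector(t(matrix(u, ncol = 3, byrow = TRUE)[mesh$elems[1, ], ]))
    eO <- hex_energy_oracle(corners, E, nu, ue)
    expect_equal(eK, eO, tolerance = 1e-8)
  }
})

test_that("a uniaxial bar reproduces pL/E and a uniform stress state", {
  for (etype in c("hex8", "tet4")) {
    mesh <- bar_mesh(4, 4, 20, elem_type = etype)
    mesh <- mesh_add_facet_set(mesh, "top", function(c, n) n[, 3] > 0.5)
    E0 <- 10000; p <- 5; L <- 20
    mat <- material_field(rep(E0, nrow(mesh$elems)), 0, 1)
    sol <- solve_static(mesh, mat, static_case(c(top = p), "proximal_end"))
    expect_lt(abs(max(abs(sol$u[, 3])) - p * L / E0) / (p * L / E0), 0.01)
    expect_lt(max(abs(sol$von_mises - p)) / p, 0.01)
    expect_lt(sol$residual, 1e-8)
    # global equilibrium: reactions balance the applied load
    expect_lt(abs(sum(sol$reactions[, 3]) + sum(sol$applied[, 3])) /
                abs(sum(sol$applied[, 3])), 1e-6)
  }
})

test_that("prescribed linear boundary displacement gives constant stress", {
  mesh <- bar_mesh(3, 3, 3)
  mat <- material_field(rep(7000, 27), 0.3, 1)
  sys <- assemble_system(mesh, mat)
  # manufactured linear field u = A x
  A <- matrix(c(1e-3, 2e-4, 0, 0, -5e-4, 1e-4, 3e-4, 0, 8e-4), 3, 3)
  u <- as.vector(t(mesh$nodes %*% t(A)))
  stress <- fetlockfe:::recover_stress(mesh, mat, sys, u)
  expect_lt(max(apply(stress, 2, function(s) diff(range(s)))),
            1e-8 * max(abs(stress)))
  # and the same field through the solver: fix all boundary nodes at the
  # linear field; interior nodes must land on it
  bnodes <- sort(unique(as.vector(mesh$facets)))
  mesh$node_sets$walls <- bnodes
  f <- numeric(3 * nrow(mesh$nodes))
  fixed <- as.vector(rbind(3 * bnodes - 2, 3 * bnodes - 1, 3 * bnodes))
  free <- setdiff(seq_along(f), fixed)
  ub <- u; rhs <- -as.numeric(sys$K[free, fixed] %*% u[fixed])
  ub[free] <- as.numeric(Matrix::solve(sys$K[free, free], rhs))
  expect_lt(max(abs(ub - u)), 1e-8 * max(abs(u)))
})

test_that("the solution is linear in the load and zero without one", {
  mesh <- bar_mesh(3, 3, 6)
  mesh <- mesh_add_facet_set(mesh, "top", function(c, n) n[, 3] > 0.5)
  mat <- material_field(rep(9040, nrow(mesh$elems)), 0.3, 1)
  s1 <- solve_static(mesh, mat, static_case(c(top = 4), "proximal_end"))
  s2 <- solve_static(mesh, mat, static_case(c(top = 8), "proximal_end"))
  expect_equal(2 * s1$u, s2$u, tolerance = 1e-10)
  expect_equal(2 * s1$von_mises, s2$von_mises, tolerance = 1e-10)
  s0 <- solve_static(mesh, mat, static_case(c(top = 0), "proximal_end"))
  expect_equal(max(abs(s0$u)), 0)
  expect_equal(max(s0$von_mises), 0)
})

test_that("von Mises handles canonical states and is frame-invariant", {
  expect_equal(von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(von_mises(c(3, 3, 3, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))
  set.seed(31)
  for (i in 1:20) {
    s <- rnorm(6, 0, 10)
    R <- random_rotation()
    expect_equal(von_mises(rotate_stress(s, R)), von_mises(s),
                 tolerance = 1e-10)
  }
})
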