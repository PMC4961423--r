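#' Static load case
#'
#' Midstance-style loading: surface pressures applied on named facet sets
#' (directed along the inward normal) with a fully fixed node set. The
#' default magnitude, 19.5 MPa on both contact patches, is the midpoint of
#' the ex-vivo midstance joint-pressure range (about 19 to 20 MPa) used to
#' load the simplified static model; the patch extents come from the region
#' labels.
#'
#' @param pressure_patches Named numeric vector: facet-set name -> pressure
#'   (MPa, >= 0).
#' @param fixed_set Node-set name fixed in all directions.
#' @return An object of class `static_case`.
#' @export
static_case <- function(pressure_patches = c(dorsal_patch = 19.5,
                                             palmar_patch = 19.5),
                        fixed_set = "proximal_end") {
  if (any(pressure_patches < 0)) abort("pressures must be >= 0.")
  structure(list(pressure_patches = pressure_patches, fixed_set = fixed_set),
            class = "static_case")
}

# isotropic elasticity matrix for unit modulus; Voigt order
# (xx, yy, zz, xy, yz, zx), engineering shear strains
d_matrix_unit <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# hex8 shape-function derivative matrix (3 x 8) at natural coords xi,
# for an axis-aligned box with edge lengths h (VTK corner order)
hex8_dN <- function(xi, h) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  dN <- rbind(
    sx * (1 + sy * xi[2]) * (1 + sz * xi[3]) / 8 * 2 / h[1],
    sy * (1 + sx * xi[1]) * (1 + sz * xi[3]) / 8 * 2 / h[2],
    sz * (1 + sx * xi[1]) * (1 + sy * xi[2]) / 8 * 2 / h[3]
  )
  dN
}

# strain-displacement matrix (6 x 24) from dN (3 x 8); dof order
# (u1 v1 w1 u2 v2 w2 ...)
b_from_dN <- function(dN) {
  B <- matrix(0, 6, 3 * ncol(dN))
  for (i in seq_len(ncol(dN))) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[1, i]
    B[2, c0 + 2] <- dN[2, i]
    B[3, c0 + 3] <- dN[3, i]
    B[4, c0 + 1] <- dN[2, i]; B[4, c0 + 2] <- dN[1, i]
    B[5, c0 + 2] <- dN[3, i]; B[5, c0 + 3] <- dN[2, i]
    B[6, c0 + 1] <- dN[3, i]; B[6, c0 + 3] <- dN[1, i]
  }
  B
}

# unit-modulus hex8 stiffness (24 x 24), full 2x2x2 Gauss integration,
# axis-aligned box with edges h
hex8_ke_unit <- function(nu, h) {
  g <- 1 / sqrt(3)
  D <- d_matrix_unit(nu)
  detJ <- prod(h) / 8
  K <- matrix(0, 24, 24)
  for (a in c(-g, g)) for (b in c(-g, g)) for (c in c(-g, g)) {
    B <- b_from_dN(hex8_dN(c(a, b, c), h))
    K <- K + t(B) %*% D %*% B * detJ
  }
  K
}

# constant strain-displacement matrix (6 x 12) of a tet4 element
tet4_b <- function(v) {
  Tm <- rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
  vol6 <- det(Tm)
  grads <- solve(Tm)                      # columns: grad of lambda 2..4
  g <- cbind(-rowSums(grads), grads)      # grads of all 4 barycentrics
  dN <- g                                 # 3 x 4
  list(B = b_from_dN(dN), vol = vol6 / 6)
}

element_dofs <- function(elems) {
  npe <- ncol(elems)
  dofs <- matrix(0L, nrow(elems), 3L * npe)
  for (i in seq_len(npe)) {
    dofs[, 3 * i - 2] <- 3L * elems[, i] - 2L
    dofs[, 3 * i - 1] <- 3L * elems[, i] - 1L
    dofs[, 3 * i] <- 3L * elems[, i]
  }
  dofs
}

#' Assemble the global stiffness operator
#'
#' Small-strain isotropic elasticity, full 2x2x2 Gauss integration for hex8
#' (no hourglass control needed), constant-strain tet4. Voxel hex meshes are
#' assembled per unique Poisson ratio from a single congruent unit-modulus
#' element matrix scaled by each element's modulus.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A [material_field()] aligned with the elements.
#' @return An object of class `fe_system`: sparse symmetric `K`
#'   (3n x 3n, MPa*mm), centroid strain-displacement operator(s) for stress
#'   recovery, and the element dof map. The unconstrained operator has the
#'   six rigid-body zero-energy modes.
#' @export
assemble_system <- function(mesh, materials) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(materials, "material_field"))
  ne <- nrow(mesh$elems)
  if (nrow(materials) != ne) {
    abort("materials must have one row per element.")
  }
  if (any(materials$E < 0)) abort("negative modulus.")
  ndof <- 3L * nrow(mesh$nodes)
  edof <- element_dofs(mesh$elems)
  nk <- ncol(edof)

  if (mesh$elem_type == "hex8") {
    b <- element_bounds(mesh)
    hs <- b$hi - b$lo
    h <- hs[1, ]
    if (max(abs(sweep(hs, 2, h))) > 1e-9 * max(h)) {
      abort("hex assembly expects congruent axis-aligned voxel elements.")
    }
    vals <- matrix(0, ne, nk * nk)
    Bc <- b_from_dN(hex8_dN(c(0, 0, 0), h))
    for (nu in unique(materials$nu)) {
      Ke <- hex8_ke_unit(nu, h)
      sel <- materials$nu == nu
      vals[sel, ] <- materials$E[sel] %o% as.vector(Ke)
    }
    ii <- edof[, rep(seq_len(nk), times = nk)]
    jj <- edof[, rep(seq_len(nk), each = nk)]
    K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                              x = as.vector(vals), dims = c(ndof, ndof))
    sys <- list(K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
                Bc = Bc, edof = edof, ndof = ndof, elem_type = "hex8")
  } else {
    trip_i <- vector("list", ne); trip_j <- trip_i; trip_x <- trip_i
    Bl <- vector("list", ne)
    Dcache <- lapply(setNames(unique(materials$nu), unique(materials$nu)),
                     d_matrix_unit)
    for (e in seq_len(ne)) {
      tb <- tet4_b(mesh$nodes[mesh$elems[e, ], , drop = FALSE])
      D <- Dcache[[as.character(materials$nu[e])]] * materials$E[e]
      Ke <- t(tb$B) %*% D %*% tb$B * tb$vol
      trip_i[[e]] <- rep(edof[e, ], times = nk)
      trip_j[[e]] <- rep(edof[e, ], each = nk)
      trip_x[[e]] <- as.vector(Ke)
      Bl[[e]] <- tb$B
    }
    K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(ndof, ndof))
    sys <- list(K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
                Bc = Bl, edof = edof, ndof = ndof, elem_type = "tet4")
  }
  class(sys) <- "fe_system"
  sys
}

# element-centroid stress recovery: u is the full dof vector
recover_stress <- function(mesh, materials, sys, u) {
  Ue <- matrix(u[sys$edof], nrow = nrow(sys$edof))
  if (sys$elem_type == "hex8") {
    stress <- matrix(0, nrow(Ue), 6)
    for (nu in unique(materials$nu)) {
      sel <- materials$nu == nu
      M <- d_matrix_unit(nu) %*% sys$Bc       # 6 x 24
      stress[sel, ] <- (Ue[sel, , drop = FALSE] %*% t(M)) * materials$E[sel]
    }
  } else {
    stress <- matrix(0, nrow(Ue), 6)
    for (e in seq_len(nrow(Ue))) {
      D <- d_matrix_unit(materials$nu[e]) * materials$E[e]
      stress[e, ] <- D %*% (sys$Bc[[e]] %*% Ue[e, ])
    }
  }
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  stress
}

# consistent nodal forces of the pressure patches (inward normal)
pressure_forces <- function(mesh, pressure_patches) {
  f <- numeric(3L * nrow(mesh$nodes))
  for (nm in names(pressure_patches)) {
    fs <- mesh$facet_sets[[nm]]
    if (is.null(fs)) abort(sprintf("facet set `%s` not on mesh.", nm))
    p <- pressure_patches[[nm]]
    if (length(fs) == 0L) next
    npf <- ncol(mesh$facets)
    share <- -p * mesh$facet_area[fs] / npf   # inward = -outward normal
    idx <- integer(0); val <- numeric(0)
    for (i in seq_len(npf)) {
      base <- 3L * (mesh$facets[fs, i] - 1L)
      for (ax in 1:3) {
        idx <- c(idx, base + ax)
        val <- c(val, share * mesh$facet_normal[fs, ax])
      }
    }
    acc <- rowsum(val, idx)
    ii <- as.integer(rownames(acc))
    f[ii] <- f[ii] + acc[, 1]
  }
  f
}

#' Solve the static load case
#'
#' Direct sparse (Cholesky) solution of the constrained linear system;
#' element-centroid stresses through the material law; relative equilibrium
#' residual checked to 1e-8.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A [material_field()].
#' @param case A [static_case()].
#' @return An object of class `solution_field`: nodal displacements `u`
#'   (n x 3, mm), per-element `stress` (6 Voigt components, MPa),
#'   `von_mises` (MPa), reaction forces at the fixed set, the equilibrium
#'   residual, and the strain energy (mJ).
#' @export
solve_static <- function(mesh, materials, case = static_case()) {
  stopifnot(inherits(case, "static_case"))
  sys <- assemble_system(mesh, materials)
  f <- pressure_forces(mesh, case$pressure_patches)

  fixed_nodes <- mesh$node_sets[[case$fixed_set]]
  if (is.null(fixed_nodes) || length(fixed_nodes) == 0L) {
    abort(sprintf("fixed node set `%s` missing or empty.", case$fixed_set))
  }
  fixed <- as.vector(rbind(3 * fixed_nodes - 2, 3 * fixed_nodes - 1,
                           3 * fixed_nodes))
  free <- setdiff(seq_len(sys$ndof), fixed)

  u <- numeric(sys$ndof)
  Kff <- sys$K[free, free]
  sol <- tryCatch(
    Matrix::solve(Kff, f[free]),
    error = function(e) abort(paste0("static solve failed (singular or ",
                                     "under-constrained system): ",
                                     conditionMessage(e)))
  )
  u[free] <- as.numeric(sol)

  r <- as.numeric(sys$K %*% u) - f
  fn <- sqrt(sum(f[free]^2))
  residual <- if (fn > 0) sqrt(sum(r[free]^2)) / fn else sqrt(sum(r[free]^2))
  if (is.finite(residual) && residual > 1e-8 && fn > 0) {
    warn(sprintf("equilibrium residual %.2e exceeds 1e-8.", residual))
  }
  reactions <- matrix(0, nrow(mesh$nodes), 3)
  reactions[fixed_nodes, ] <- matrix(r[fixed], ncol = 3, byrow = TRUE)

  stress <- recover_stress(mesh, materials, sys, u)
  structure(
    list(
      u = matrix(u, ncol = 3, byrow = TRUE),
      stress = stress,
      von_mises = von_mises(stress),
      reactions = reactions,
      applied = matrix(f, ncol = 3, byrow = TRUE),
      residual = residual,
      strain_energy = 0.5 * sum(u * as.numeric(sys$K %*% u)),
      case = case
    ),
    class = "solution_field"
  )
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(
    "<solution_field> %d nodes, %d elements | residual %.2e | peak vM %.4g MPa\n",
    nrow(x$u), length(x$von_mises), x$residual, max(x$von_mises)))
  invisible(x)
}

#' Von Mises stress of a stress tensor
#'
#' `sqrt(0.5*((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2) +
#' 3*(sxy^2 + syz^2 + szx^2))`.
#'
#' @param stress Length-6 Voigt vector `(sxx, syy, szz, sxy, syz, szx)` or
#'   an m x 6 matrix.
#' @return Von Mises stress (scalar or vector), MPa.
#' @export
von_mises <- function(stress) {
  s <- if (is.matrix(stress)) stress else matrix(stress, nrow = 1)
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                       (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.matrix(stress)) out else out[[1]]
}
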