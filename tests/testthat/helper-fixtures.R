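# shared fixtures: small meshes and volumes built in code

# solid cuboid voxel mask (nx x ny x nz voxels of edge h), mesh-ready
cuboid_mask <- function(nx, ny, nz, h = 1) {
  voxel_volume(array(1, dim = c(nx, ny, nz)), spacing = h,
               origin = c(h, h, h) / 2, value_kind = "mask")
}

bar_mesh <- function(nx, ny, nz, h = 1, elem_type = "hex8") {
  build_voxel_mesh(cuboid_mask(nx, ny, nz, h), 1L, elem_type = elem_type)
}

# a small phantom spec that keeps unit tests fast
small_spec <- function(...) {
  phantom_spec(voxel_spacing = 1.0, shaft_length = 12, condyle_radius = 5,
               condyle_separation = 6, ridge_height = 1, shaft_radius = 8,
               cortical_thickness = 1, counterbody_thickness = 6,
               rng_seed = 42L, ...)
}

small_config <- function(...) {
  run_config(
    phantom = list(voxel_spacing = 1.0, shaft_length = 12,
                   condyle_radius = 5, condyle_separation = 6,
                   ridge_height = 1, shaft_radius = 8,
                   cortical_thickness = 1, counterbody_thickness = 6),
    meshing = list(coarsening = 2L),
    impact = list(duration = 0.6, output_interval = 0.1),
    ...
  )
}

# brute-force oracle: per-element mean modulus / density by a triple loop
# over voxels with an explicit point-in-box test (hex meshes)
material_oracle <- function(volume, mesh, nu = 0.3) {
  ax <- voxel_axes(volume)
  ne <- nrow(mesh$elems)
  E <- numeric(ne); rho <- numeric(ne)
  for (e in seq_len(ne)) {
    v <- mesh$nodes[mesh$elems[e, ], ]
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    Es <- c(); rs <- c()
    for (i in seq_along(ax$x)) for (j in seq_along(ax$y)) {
      for (k in seq_along(ax$z)) {
        p <- c(ax$x[i], ax$y[j], ax$z[k])
        if (all(p > lo) && all(p < hi)) {
          d <- volume$data[i, j, k]
          Es <- c(Es, 9040 * max(d, 0)^2.35)
          rs <- c(rs, d)
        }
      }
    }
    E[e] <- mean(Es); rho[e] <- mean(rs)
  }
  list(E = E, rho = rho)
}

# independent strain-energy oracle for one hex8 element: dense 4x4x4
# Gauss-Legendre quadrature of the elastic energy density with analytic
# trilinear shape-function gradients (coded apart from the assembly path)
hex_energy_oracle <- function(corners, E, nu, ue) {
  gp <- c(-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526)
  gw <- c(0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538)
  h <- apply(corners, 2, max) - apply(corners, 2, min)
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  U <- matrix(ue, nrow = 3)             # 3 x 8 displacements
  total <- 0
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    xi <- c(gp[a], gp[b], gp[c])
    dN <- rbind(sx * (1 + sy * xi[2]) * (1 + sz * xi[3]) / 8 * 2 / h[1],
                sy * (1 + sx * xi[1]) * (1 + sz * xi[3]) / 8 * 2 / h[2],
                sz * (1 + sx * xi[1]) * (1 + sy * xi[2]) / 8 * 2 / h[3])
    G <- U %*% t(dN)                    # displacement gradient
    eps <- (G + t(G)) / 2
    dens <- 0.5 * lam * sum(diag(eps))^2 + mu * sum(eps * eps)
    total <- total + dens * gw[a] * gw[b] * gw[c] * prod(h) / 8
  }
  total
}

# rotate a Voigt stress vector by rotation matrix R
rotate_stress <- function(s, R) {
  S <- matrix(c(s[1], s[4], s[6],
                s[4], s[2], s[5],
                s[6], s[5], s[3]), 3, 3)
  S2 <- R %*% S %*% t(R)
  c(S2[1, 1], S2[2, 2], S2[3, 3], S2[1, 2], S2[2, 3], S2[3, 1])
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
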