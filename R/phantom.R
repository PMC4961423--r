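#' Phantom specification for a synthetic distal-condyle CT volume
#'
#' Describes a constructive-solid condyle phantom standing in for a micro-CT
#' scan of a distal third-metacarpal (MC3) condyle: a shaft cylinder capped by
#' two partially overlapping condylar lobes (spheres) and a central
#' sagittal-ridge sphere, with a cortical shell, a noisy trabecular core and
#' an optional focal subchondral sclerotic lesion (the osteoarthritic
#' variant). All lengths in mm, densities in apparent g/cm^3.
#'
#' The distal articular surface is the height field
#' `z = shaft_length + f(x, y)` with
#' `f = max(0, lobe_lat, lobe_med, ridge)`, where the lobes are spheres of
#' radius `condyle_radius` centred at `x = +-condyle_separation/2` on the cap
#' plane and the ridge is a sphere centred on the shaft axis with radius
#' `sqrt(condyle_radius^2 - (condyle_separation/2)^2) + ridge_height`, so the
#' ridge protrudes `ridge_height` above the inter-lobe saddle. Because
#' `shaft_radius >= condyle_separation/2 + condyle_radius`, the solid is an
#' exact generalized cylinder and its volume has the closed form
#' `pi * shaft_radius^2 * shaft_length + integral(f)`.
#'
#' Default geometry is a life-size adult equine distal MC3 (condylar width
#' about 43 mm) at 0.8 mm voxels - the impact constants this phantom is
#' solved under (a 5 kg effective distal-limb mass, a 12 MPa/mm contact
#' law) are defined for a joint of this scale, so geometry and loading stay
#' consistent. Spacing is a knob, and the mesh-convergence harness
#' quantifies the discretization consequences.
#'
#' @param voxel_spacing Isotropic voxel spacing, mm.
#' @param shaft_length Length of the shaft cylinder, mm.
#' @param condyle_radius Radius of each condylar lobe sphere, mm.
#' @param condyle_separation Medial-lateral distance between lobe centres, mm.
#' @param ridge_height Sagittal-ridge prominence above the inter-lobe
#'   saddle, mm.
#' @param shaft_radius Shaft cylinder radius, mm. Must be at least
#'   `condyle_separation/2 + condyle_radius`.
#' @param cortical_thickness Cortical shell thickness, mm (realized on the
#'   voxel grid as an integer number of erosion layers).
#' @param cortical_density Apparent density of the cortical shell, g/cm^3.
#' @param trabecular_density_mean,trabecular_density_sd Mean and SD of the
#'   i.i.d. Gaussian trabecular density field, g/cm^3.
#' @param lesion_center Centre of the focal sclerotic lesion (mm, 3-vector),
#'   or `NULL` for the healthy variant.
#' @param lesion_radius Lesion radius, mm.
#' @param lesion_density_delta Density increment inside the lesion, g/cm^3.
#' @param joint_angle Metacarpophalangeal joint angle in degrees between the
#'   counterbody axis and the shaft axis (180 = collinear; impact posture is
#'   165-175).
#' @param congruency_gap Initial surface-to-surface clearance between condyle
#'   and counterbody, mm.
#' @param counterbody_thickness Thickness of the counterbody block above its
#'   articular imprint, mm.
#' @param counterbody_density Uniform apparent density of the counterbody,
#'   g/cm^3.
#' @param rng_seed Integer seed for the volume's RNG stream.
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing = 0.8,
                         shaft_length = 60,
                         condyle_radius = 14,
                         condyle_separation = 15,
                         ridge_height = 2,
                         shaft_radius = 22,
                         cortical_thickness = 1.6,
                         cortical_density = 1.9,
                         trabecular_density_mean = 0.85,
                         trabecular_density_sd = 0.10,
                         lesion_center = NULL,
                         lesion_radius = 4,
                         lesion_density_delta = 0.5,
                         joint_angle = 165,
                         congruency_gap = 2.5,
                         counterbody_thickness = 12,
                         counterbody_density = 1.5,
                         rng_seed = 1L) {
  spec <- list(
    voxel_spacing = voxel_spacing, shaft_length = shaft_length,
    condyle_radius = condyle_radius, condyle_separation = condyle_separation,
    ridge_height = ridge_height, shaft_radius = shaft_radius,
    cortical_thickness = cortical_thickness,
    cortical_density = cortical_density,
    trabecular_density_mean = trabecular_density_mean,
    trabecular_density_sd = trabecular_density_sd,
    lesion_center = lesion_center, lesion_radius = lesion_radius,
    lesion_density_delta = lesion_density_delta,
    joint_angle = joint_angle, congruency_gap = congruency_gap,
    counterbody_thickness = counterbody_thickness,
    counterbody_density = counterbody_density,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  pos <- c("voxel_spacing", "shaft_length", "condyle_radius",
           "condyle_separation", "shaft_radius", "cortical_thickness",
           "lesion_radius", "counterbody_thickness", "congruency_gap")
  for (f in pos) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1L ||
        !is.finite(spec[[f]]) || spec[[f]] <= 0) {
      abort(sprintf("phantom spec field `%s` must be a positive number.", f))
    }
  }
  if (spec$ridge_height < 0) abort("`ridge_height` must be >= 0.")
  if (spec$condyle_separation >= 2 * spec$condyle_radius) {
    abort("lobes must overlap: `condyle_separation` < 2 * `condyle_radius`.")
  }
  if (spec$shaft_radius < spec$condyle_separation / 2 + spec$condyle_radius) {
    abort(paste0("`shaft_radius` must be >= condyle_separation/2 + ",
                 "condyle_radius (generalized-cylinder geometry)."))
  }
  dens <- c(spec$cortical_density, spec$trabecular_density_mean,
            spec$counterbody_density)
  if (any(dens < 0) || any(dens > RHO_MAX)) {
    abort(sprintf("densities must lie in [0, %.2f] g/cm^3.", RHO_MAX))
  }
  if (spec$trabecular_density_sd < 0) abort("`trabecular_density_sd` >= 0.")
  if (!is.null(spec$lesion_center) && length(spec$lesion_center) != 3L) {
    abort("`lesion_center` must be NULL or a 3-vector (mm).")
  }
  if (spec$joint_angle <= 90 || spec$joint_angle > 180) {
    abort("`joint_angle` must be in (90, 180] degrees.")
  }
  invisible(spec)
}

#' Osteoarthritic variant of a phantom spec
#'
#' Adds a focal subchondral sclerotic lesion beneath the palmar-medial
#' condylar surface (the site where sclerosis is seen in advanced fetlock
#' osteoarthritis). The lesion centre sits at 72% of the lobe radius from the
#' medial lobe centre along a palmar-distal direction, i.e. a few millimetres
#' beneath the articular surface, within the subchondral bone.
#'
#' @param spec A healthy [phantom_spec()].
#' @param density_delta Density elevation inside the lesion, g/cm^3.
#' @param radius Lesion radius, mm.
#' @return The spec with lesion fields populated.
#' @export
oa_variant <- function(spec, density_delta = spec$lesion_density_delta,
                       radius = spec$lesion_radius) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir <- c(0, -0.55, 0.835)
  dir <- dir / sqrt(sum(dir^2))
  centre <- c(spec$condyle_separation / 2, 0, spec$shaft_length) +
    0.72 * spec$condyle_radius * dir
  spec$lesion_center <- centre
  spec$lesion_radius <- radius
  spec$lesion_density_delta <- density_delta
  validate_phantom_spec(spec)
  spec
}

# height field of the distal articular surface above the cap plane z = L.
# x, y may be vectors (recycled together); returns f >= 0.
condyle_height_field <- function(spec, x, y) {
  R <- spec$condyle_radius
  s2 <- spec$condyle_separation / 2
  Rsr <- sqrt(R^2 - s2^2) + spec$ridge_height
  f1 <- R^2 - (x - s2)^2 - y^2
  f2 <- R^2 - (x + s2)^2 - y^2
  f3 <- Rsr^2 - x^2 - y^2
  f <- pmax(0, f1, f2, f3)
  sqrt(f)
}

# apex of the articular surface above the cap plane
condyle_apex_height <- function(spec) {
  max(spec$condyle_radius,
      sqrt(spec$condyle_radius^2 - (spec$condyle_separation / 2)^2) +
        spec$ridge_height)
}

#' Analytic volume of the phantom solid
#'
#' Closed-form shaft cylinder plus a high-resolution 2D quadrature of the
#' articular height field (independent of the voxelizer); serves as the
#' oracle for voxel-count volume checks.
#'
#' @param spec A [phantom_spec()].
#' @param n Quadrature points per axis (midpoint rule).
#' @return Volume in mm^3.
#' @export
analytic_condyle_volume <- function(spec, n = 2801) {
  r <- spec$shaft_radius
  h <- 2 * r / n
  u <- seq(-r + h / 2, r - h / 2, length.out = n)
  g <- expand.grid(x = u, y = u)
  f <- condyle_height_field(spec, g$x, g$y)
  pi * r^2 * spec$shaft_length + sum(f) * h^2
}

# symmetric voxel-centre axis of m cells covering [-half, half]; m is a
# multiple of `mult` (12 divides by every supported mesh coarsening, so
# coarsened block lattices stay mirror-symmetric about the mid-plane)
sym_axis <- function(half, spacing, mult = 12L) {
  m <- mult * ceiling(2 * half / (mult * spacing))
  (seq_len(m) - (m + 1) / 2) * spacing
}

# erode a logical 3D array by one 6-connected layer, k times
erode6 <- function(mask, k) {
  for (i in seq_len(k)) {
    d <- dim(mask)
    e <- mask
    sh <- function(m, ax, by) {
      out <- array(FALSE, dim(m))
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      src <- idx; dst <- idx
      n <- d[ax]
      if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
      else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
      out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (ax in 1:3) {
      e <- e & sh(mask, ax, 1L) & sh(mask, ax, -1L)
    }
    mask <- e
  }
  mask
}

#' Generate the synthetic condyle CT volume
#'
#' Voxelizes the phantom solid on a grid symmetric about the sagittal
#' mid-plane, assigns `cortical_density` to the outer shell
#' (`cortical_thickness` worth of 6-connected erosion layers), draws the
#' trabecular interior i.i.d. from
#' `N(trabecular_density_mean, trabecular_density_sd)`, applies the focal
#' lesion if present, and clips all densities to `[0, 2.47]` g/cm^3.
#' Background is exactly 0. Identical spec and seed give a bit-identical
#' volume.
#'
#' @param spec A [phantom_spec()].
#' @param max_voxels Memory budget: error if the grid exceeds this many
#'   voxels.
#' @return A density-valued [voxel_volume()]; `meta` records the spec and
#'   seed.
#' @export
generate_condyle_volume <- function(spec, max_voxels = 2e7) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  L <- spec$shaft_length
  apex <- condyle_apex_height(spec)
  ax_x <- sym_axis(spec$shaft_radius + sp, sp)
  ax_y <- sym_axis(spec$shaft_radius + sp, sp)
  nz <- ceiling((L + apex + sp) / sp)
  ax_z <- (seq_len(nz) - 0.5) * sp
  if (length(ax_x) * length(ax_y) * nz > max_voxels) {
    abort(sprintf("phantom grid exceeds the %g-voxel memory budget.",
                  max_voxels))
  }

  # solid indicator: footprint disk, 0 <= z <= L + f(x, y)
  rr <- outer(ax_x^2, ax_y^2, `+`)
  in_disk <- rr <= spec$shaft_radius^2
  fmap <- matrix(0, length(ax_x), length(ax_y))
  fmap[in_disk] <- condyle_height_field(
    spec,
    rep(ax_x, times = length(ax_y))[as.vector(in_disk)],
    rep(ax_y, each = length(ax_x))[as.vector(in_disk)]
  )
  zmax <- L + fmap            # per-column top surface (0 outside disk -> L)
  zmax[!in_disk] <- -Inf
  mask <- outer(zmax, ax_z, function(zm, z) z <= zm & z >= 0)
  mask <- array(mask, dim = c(length(ax_x), length(ax_y), nz))

  k <- max(1L, as.integer(round(spec$cortical_thickness / sp)))
  core <- erode6(mask, k)
  shell <- mask & !core

  data <- array(0, dim = dim(mask))
  n_core <- sum(core)
  trab <- with_seed_(spec$rng_seed, {
    rnorm(n_core, spec$trabecular_density_mean, spec$trabecular_density_sd)
  })
  data[core] <- trab
  data[shell] <- spec$cortical_density

  if (!is.null(spec$lesion_center) && spec$lesion_density_delta != 0) {
    cx <- spec$lesion_center
    d2 <- outer(outer((ax_x - cx[1])^2, (ax_y - cx[2])^2, `+`),
                (ax_z - cx[3])^2, `+`)
    les <- d2 <= spec$lesion_radius^2
    if (!any(les & mask)) {
      warn("lesion sphere lies entirely outside the bone envelope.")
    }
    data[les & mask] <- data[les & mask] + spec$lesion_density_delta
  }
  data[mask] <- pmin(pmax(data[mask], 0), RHO_MAX)

  voxel_volume(
    data, spacing = sp,
    origin = c(ax_x[1], ax_y[1], ax_z[1]),
    value_kind = "density",
    meta = list(role = "condyle", seed = spec$rng_seed,
                spec = unclass(spec))
  )
}

# signed pose rotation (radians) about the x axis: the flexed joint tilts
# the counterbody so its dorsal (+y) side approaches the condyle first, as
# at impact posture
pose_angle <- function(spec) (180 - spec$joint_angle) * pi / 180

# distal lift (mm) applied to the posed counterbody so the pose rotation
# does not consume the congruency gap on the approaching (dorsal) side
pose_lift <- function(spec) {
  abs(sin(pose_angle(spec))) * (spec$shaft_radius - spec$voxel_spacing)
}

# rotation taking world coordinates into the counterbody (condyle-aligned)
# frame: rotation by the pose angle about the x axis through the pivot
# (0, 0, shaft_length), after removing the pose lift
counterbody_to_frame <- function(spec, x, y, z) {
  a <- pose_angle(spec)
  zc <- spec$shaft_length
  ca <- cos(a); sa <- sin(a)
  z <- z - pose_lift(spec)
  yf <- ca * y - sa * (z - zc)
  zf <- sa * y + ca * (z - zc) + zc
  list(x = x, y = yf, z = zf)
}

#' Generate the counterbody (proximal-phalanx style) volume
#'
#' A uniform-density block whose lower surface is the negative imprint of
#' the condylar profile offset by `congruency_gap`, posed at `joint_angle`
#' to the shaft axis (rotation about the mediolateral x axis; 180 deg is
#' collinear). Deterministic: no RNG is consumed.
#'
#' @inheritParams generate_condyle_volume
#' @return A density-valued [voxel_volume()] (`meta$role = "counterbody"`).
#' @export
generate_counterbody <- function(spec, max_voxels = 2e7) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  L <- spec$shaft_length
  apex <- condyle_apex_height(spec)
  gap <- spec$congruency_gap
  r_cb <- spec$shaft_radius - sp      # footprint slightly inside the condyle
  top <- L + apex + gap + spec$counterbody_thickness

  # world-frame bounding box of the posed block (frame bbox corners rotated)
  a <- pose_angle(spec)
  corners <- as.matrix(expand.grid(x = c(-r_cb, r_cb), y = c(-r_cb, r_cb),
                                   z = c(L + gap, top)))
  yw <- cos(a) * corners[, 2] + sin(a) * (corners[, 3] - L)
  zw <- -sin(a) * corners[, 2] + cos(a) * (corners[, 3] - L) + L +
    pose_lift(spec)
  ax_x <- sym_axis(r_cb + sp, sp)
  half_y <- max(abs(yw)) + sp
  ax_y <- sym_axis(half_y, sp)
  nz0 <- floor(min(zw) / sp)
  nz1 <- ceiling(max(zw) / sp)
  ax_z <- (seq(nz0, nz1) + 0.5) * sp
  if (length(ax_x) * length(ax_y) * length(ax_z) > max_voxels) {
    abort(sprintf("counterbody grid exceeds the %g-voxel memory budget.",
                  max_voxels))
  }

  g <- expand.grid(x = ax_x, y = ax_y, z = ax_z)
  fr <- counterbody_to_frame(spec, g$x, g$y, g$z)
  inside <- fr$x^2 + fr$y^2 <= r_cb^2 & fr$z <= top
  fh <- numeric(length(inside))
  fh[inside] <- condyle_height_field(spec, fr$x[inside], fr$y[inside])
  inside <- inside & fr$z >= L + fh + gap
  data <- array(0, dim = c(length(ax_x), length(ax_y), length(ax_z)))
  data[inside] <- spec$counterbody_density

  voxel_volume(
    data, spacing = sp,
    origin = c(ax_x[1], ax_y[1], ax_z[1]),
    value_kind = "density",
    meta = list(role = "counterbody", seed = spec$rng_seed,
                spec = unclass(spec))
  )
}

#' Convert a density volume to Hounsfield units
#'
#' Exact inverse of [hu_to_apparent_density()] under the same calibration:
#' `HU = (rho * ash_to_apparent_ratio - intercept) / slope`. Used to give the
#' phantom an HU-valued face so the full mapping chain can be exercised and
#' round-trip tested.
#'
#' @param volume A density-valued [voxel_volume()].
#' @param calibration An [hu_calibration()].
#' @return An HU-valued [voxel_volume()].
#' @export
density_to_hu <- function(volume, calibration = hu_calibration()) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (volume$value_kind != "density") {
    abort("`density_to_hu()` needs a density-valued volume.")
  }
  volume$data <- (volume$data * calibration$ash_to_apparent_ratio -
                    calibration$intercept) / calibration$slope
  volume$value_kind <- "HU"
  volume
}
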