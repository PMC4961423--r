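#' Impact load case
#'
#' The primary-impact event: every node of the moving body starts at
#' `velocity` m/s directed distally (+z), the counterbody is stationary with
#' its far end fixed, contact follows a linear pressure-overclosure law with
#' Coulomb friction, and the solve runs to `duration` recording every
#' `output_interval`. Defaults are the study constants: 3.55 m/s, friction
#' 0.007, 12 MPa/mm, 3 ms, 0.25 ms.
#'
#' The 0.25 ms value is the recording interval, not the integration step: an
#' explicit central-difference step is bounded by the CFL limit (fractions
#' of a microsecond at these element sizes and wave speeds), so the true
#' step comes from [stable_timestep()] and is logged on the returned
#' history.
#'
#' @param velocity Initial speed, m/s (> 0), directed +z.
#' @param friction Coulomb friction coefficient (>= 0).
#' @param contact_stiffness Linear pressure-overclosure slope, MPa/mm (> 0).
#' @param duration Event duration, ms.
#' @param output_interval Recording interval, ms (<= duration).
#' @param counterbody_fixed_set Node set of the counterbody fixed in all
#'   directions.
#' @param slave_set Node/facet set on the moving body whose surface carries
#'   the contact (defaults to the labelled articular surface; meshes without
#'   labels fall back to up-facing boundary facets).
#' @param rigid_plane_z If not `NULL`, replace the counterbody by an
#'   analytic rigid plane at this z (mm) - used for verification cases.
#' @param safety CFL safety factor for the time step.
#' @param search_every Contact-search refresh period, in steps.
#' @param max_overclosure Hard abort threshold on interpenetration (mm).
#'   Beyond one element length a warning is emitted; the default keeps
#'   running because the linear soft-contact law with the study constants
#'   legitimately produces multi-millimetre "settling" overclosure.
#' @param mass_damping Optional mass-proportional damping coefficient (1/s),
#'   default 0 (cleanest energy audit).
#' @return An object of class `impact_case`.
#' @export
impact_case <- function(velocity = 3.55, friction = 0.007,
                        contact_stiffness = 12, duration = 3,
                        output_interval = 0.25,
                        counterbody_fixed_set = "distal_end",
                        slave_set = "distal_articular_surface",
                        rigid_plane_z = NULL, safety = 0.8,
                        search_every = 25L, max_overclosure = Inf,
                        mass_damping = 0) {
  if (velocity <= 0) abort("`velocity` must be > 0.")
  if (contact_stiffness <= 0) abort("`contact_stiffness` must be > 0.")
  if (friction < 0) abort("`friction` must be >= 0.")
  if (duration <= 0) abort("`duration` must be > 0.")
  if (output_interval > duration) {
    abort("`output_interval` must be <= `duration`.")
  }
  structure(
    list(velocity = velocity, friction = friction,
         contact_stiffness = contact_stiffness, duration = duration,
         output_interval = output_interval,
         counterbody_fixed_set = counterbody_fixed_set,
         slave_set = slave_set, rigid_plane_z = rigid_plane_z,
         safety = safety, search_every = as.integer(search_every),
         max_overclosure = max_overclosure, mass_damping = mass_damping),
    class = "impact_case"
  )
}

# characteristic element length (mm): hex = min edge, tet = min altitude
element_char_length <- function(mesh) {
  if (mesh$elem_type == "hex8") {
    b <- element_bounds(mesh)
    apply(b$hi - b$lo, 1, min)
  } else {
    v <- element_volumes(mesh)
    amax <- rep(0, nrow(mesh$elems))
    for (f in seq_len(nrow(tet_faces_))) {
      tri <- tet_faces_[f, ]
      p1 <- mesh$nodes[mesh$elems[, tri[1]], , drop = FALSE]
      p2 <- mesh$nodes[mesh$elems[, tri[2]], , drop = FALSE]
      p3 <- mesh$nodes[mesh$elems[, tri[3]], , drop = FALSE]
      amax <- pmax(amax, 0.5 * row_norm(cross3(p2 - p1, p3 - p1)))
    }
    3 * v / amax
  }
}

#' Stable explicit time step
#'
#' CFL bound: `dt = safety * min(L_char / c)` over elements, with the
#' dilatational wave speed `c = sqrt(E (1 - nu) / (rho (1 + nu) (1 - 2 nu)))`.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A [material_field()].
#' @param safety Safety factor (default 0.8).
#' @return Time step in seconds.
#' @export
stable_timestep <- function(mesh, materials, safety = 0.8) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(materials, "material_field"))
  if (any(materials$rho <= 0 & materials$E > 0)) {
    abort("zero density with nonzero stiffness: wave speed unbounded.")
  }
  act <- materials$E > 0
  if (!any(act)) abort("all elements have zero stiffness.")
  rho <- materials$rho * GCM3_TO_TMM3
  c_dil <- sqrt(materials$E[act] * (1 - materials$nu[act]) /
                  (rho[act] * (1 + materials$nu[act]) *
                     (1 - 2 * materials$nu[act])))
  L <- element_char_length(mesh)[act]
  safety * min(L / c_dil)
}

# lumped (row-sum equivalent) nodal mass vector, tonnes, one entry per node
lumped_node_mass <- function(mesh, materials) {
  v <- element_volumes(mesh)
  em <- v * materials$rho * GCM3_TO_TMM3
  npe <- ncol(mesh$elems)
  m <- numeric(nrow(mesh$nodes))
  for (i in seq_len(npe)) {
    s <- rowsum(em / npe, mesh$elems[, i])
    m[as.integer(rownames(s))] <- m[as.integer(rownames(s))] + s[, 1]
  }
  m
}

# plan-lattice heights and slopes of a z-facing voxel surface patch.
# Returns per-facet lattice indices, the (min-z per cell) height lattice,
# slope lattices from central differences, and the per-facet slope.
plan_lattice <- function(centroids, H, x0, y0) {
  ix <- floor((centroids[, 1] - x0) / H) + 1L
  iy <- floor((centroids[, 2] - y0) / H) + 1L
  ncx <- max(ix); ncy <- max(iy)
  z <- matrix(NA_real_, ncx, ncy)
  ord <- order(centroids[, 3], decreasing = TRUE)
  z[cbind(ix[ord], iy[ord])] <- centroids[ord, 3]
  d_ctr <- function(zm, ax) {
    up <- zm; dn <- zm
    if (ax == 1) { up[-ncx, ] <- zm[-1, ]; dn[-1, ] <- zm[-ncx, ] }
    else { up[, -ncy] <- zm[, -1]; dn[, -1] <- zm[, -ncy] }
    g <- (up - dn) / (2 * H)
    g1 <- (up - zm) / H; g2 <- (zm - dn) / H
    out <- ifelse(is.na(g), ifelse(is.na(g1), g2, g1), g)
    ifelse(is.na(out), 0, out)
  }
  sx <- d_ctr(z, 1); sy <- d_ctr(z, 2)
  list(ix = ix, iy = iy, ncx = ncx, ncy = ncy, z = z,
       slope_x = sx, slope_y = sy,
       facet_slope = sqrt(sx[cbind(ix, iy)]^2 + sy[cbind(ix, iy)]^2))
}

# Contact-carrying surface of the moving body: the articular facet set when
# labelled, else all up-facing boundary facets. Facets locally steeper than
# `slope_max` (rise per run, 1 = 45 degrees) are excluded: vertical
# projection is invalid there and on voxel surfaces those block-quantized
# flanks would fake interpenetration; their normals are mostly lateral and
# carry no distal impact load.
slave_surface <- function(mesh, slave_set, slope_max = 1) {
  fs <- mesh$facet_sets[[slave_set]]
  if (is.null(fs)) fs <- which(mesh$facet_normal[, 3] > 0.5)
  if (length(fs) == 0L) abort("no slave contact facets found.")
  H <- mesh$landmarks$H %||% {
    b <- element_bounds(mesh); min(b$hi - b$lo)
  }
  fc <- facet_centroids(mesh, fs)
  pl <- plan_lattice(fc, H, min(mesh$nodes[, 1]), min(mesh$nodes[, 2]))
  fs <- fs[pl$facet_slope <= slope_max]
  if (length(fs) == 0L) abort("no contact facets within the slope limit.")
  npf <- ncol(mesh$facets)
  nodes <- sort(unique(as.vector(mesh$facets[fs, ])))
  area <- numeric(length(nodes))
  for (i in seq_len(npf)) {
    s <- rowsum(mesh$facet_area[fs] / npf, mesh$facets[fs, i])
    j <- match(as.integer(rownames(s)), nodes)
    area[j] <- area[j] + s[, 1]
  }
  list(facets = fs, nodes = nodes, area = area)
}

#' Run the explicit impact solve
#'
#' Central-difference time integration with lumped mass, node-to-facet
#' penalty contact (normal pressure = `contact_stiffness` x overclosure) and
#' a penalty-regularized stick-slip Coulomb friction capped at `mu * N`.
#' The moving body's nodes all start at the case velocity directed +z; the
#' counterbody's `counterbody_fixed_set` nodes are fixed. Master facets are
#' the counterbody's down-facing boundary facets (or an analytic rigid
#' plane). The solve aborts with a diagnostic if the total energy grows
#' beyond 10x the initial kinetic energy.
#'
#' @param mesh Moving-body [fe_mesh()] (the MC3 condyle).
#' @param materials Its [material_field()].
#' @param case An [impact_case()].
#' @param counterbody Counterbody [fe_mesh()] (the P1 imprint), or `NULL`
#'   with `case$rigid_plane_z` set.
#' @param counterbody_materials Its [material_field()].
#' @return An `impact_history`: recorded times (ms), an energy ledger
#'   (mJ: kinetic, strain, contact, friction, total), per-element von Mises
#'   snapshots for both bodies, contact pressure per articular facet,
#'   contact force/area traces, displacement and velocity snapshots, and the
#'   integration metadata (`dt`, `n_steps`).
#' @export
run_impact <- function(mesh, materials, case = impact_case(),
                       counterbody = NULL, counterbody_materials = NULL) {
  stopifnot(inherits(case, "impact_case"))
  rigid <- is.null(counterbody)
  if (rigid && is.null(case$rigid_plane_z)) {
    abort("either supply a counterbody mesh or set `rigid_plane_z`.")
  }

  sysA <- assemble_system(mesh, materials)
  nA <- nrow(mesh$nodes)
  mA <- lumped_node_mass(mesh, materials)
  dtA <- stable_timestep(mesh, materials, case$safety)
  if (!rigid) {
    sysB <- assemble_system(counterbody, counterbody_materials)
    nB <- nrow(counterbody$nodes)
    mB <- lumped_node_mass(counterbody, counterbody_materials)
    dtB <- stable_timestep(counterbody, counterbody_materials, case$safety)
    K <- Matrix::bdiag(sysA$K, sysB$K)
    nodes <- rbind(mesh$nodes, counterbody$nodes)
    node_mass <- c(mA, mB)
    dt <- min(dtA, dtB)
  } else {
    K <- sysA$K
    nodes <- mesh$nodes
    node_mass <- mA
    dt <- dtA
  }
  n <- nrow(nodes)
  ndof <- 3L * n
  if (any(node_mass <= 0)) abort("every node needs positive lumped mass.")
  mdof <- rep(node_mass, each = 3L)

  # choose the step so recording frames land exactly on the output grid
  dur <- case$duration * MS_TO_S
  n_out <- max(1L, round(case$duration / case$output_interval))
  out_every <- ceiling(dur / dt / n_out)
  n_steps <- out_every * n_out
  dt <- dur / n_steps

  cm <- make_contact_model(mesh, counterbody, case, nodes, nA)
  sl <- cm$slave

  # fixed dofs
  if (!rigid) {
    fix_nodes <- counterbody$node_sets[[case$counterbody_fixed_set]]
    if (is.null(fix_nodes) || length(fix_nodes) == 0L) {
      abort(sprintf("counterbody node set `%s` missing or empty.",
                    case$counterbody_fixed_set))
    }
    fixed <- as.vector(rbind(3 * (fix_nodes + nA) - 2,
                             3 * (fix_nodes + nA) - 1,
                             3 * (fix_nodes + nA)))
  } else {
    fixed <- integer(0)
  }
  run_impact_core(mesh, materials, case, counterbody, counterbody_materials,
                  sysA, if (!rigid) sysB, K, nodes, nA,
                  if (!rigid) nB else 0L, mdof, dt, n_steps, out_every,
                  fixed, cm)
}

# contact machinery shared by run_impact and its tests: precomputes the
# slave surface, the master plan lattice (heights, slopes, donor fill) and
# returns an evaluator of the penalty/friction forces at a given state
make_contact_model <- function(mesh, counterbody, case, nodes, nA) {
  rigid <- is.null(counterbody)
  ndof <- 3L * nrow(nodes)
  sl <- slave_surface(mesh, case$slave_set)
  ns <- length(sl$nodes)
  s_ix <- 3L * (sl$nodes - 1L) + 1L
  s_iy <- s_ix + 1L; s_iz <- s_ix + 2L
  Xs <- nodes[sl$nodes, , drop = FALSE]
  kA <- case$contact_stiffness * sl$area      # N/mm per node
  if (!rigid) {
    mf <- which(counterbody$facet_normal[, 3] < -0.5)
    if (length(mf) == 0L) abort("counterbody has no down-facing facets.")
    MF <- counterbody$facets[mf, , drop = FALSE] + nA   # combined node ids
    npf <- ncol(MF)
    n0 <- counterbody$facet_normal[mf, , drop = FALSE]
    # Plan-view lattice of the master surface: each slave node is matched
    # by vertical projection to the facet whose x-y footprint contains it
    # (footprints tile the surface, so the match is unique, stable in time
    # and mirror-symmetric), and the gap is measured against a bilinear
    # interpolation of the surrounding facet-centroid heights. The
    # interpolation makes the gap continuous in the slave's plan position:
    # with the multi-millimetre settling overclosure of the soft-contact
    # law, stepping the gap at the 1-element staircase ledges of a voxel
    # surface would inject energy on every lateral crossing.
    Hm <- counterbody$landmarks$H %||% {
      b <- element_bounds(counterbody); min(b$hi - b$lo)
    }
    mc0 <- facet_centroids(counterbody, mf)
    m_x0 <- min(counterbody$nodes[, 1]); m_y0 <- min(counterbody$nodes[, 2])
    pl <- plan_lattice(mc0, Hm, m_x0, m_y0)
    ncx <- pl$ncx; ncy <- pl$ncy
    mix <- pl$ix; miy <- pl$iy
    slope_x <- pl$slope_x; slope_y <- pl$slope_y
    cellmap <- matrix(0L, ncx, ncy)
    ord <- order(mc0[, 3], decreasing = TRUE)  # keep lowest-z facet per cell
    cellmap[cbind(mix[ord], miy[ord])] <- ord
    mfz_dof <- 3L * as.vector(MF)              # z dofs of master facet nodes
    # cells steeper than 45 degrees are excluded (see slave_surface)
    steep <- sqrt(slope_x^2 + slope_y^2) > 1
    cell_has <- cellmap > 0L & !steep
    cellmap[!cell_has] <- 0L
    if (!any(cell_has)) abort("no master contact cells within the slope limit.")
    # donor map: every lattice cell inherits its nearest valid cell, so the
    # reconstructed surface (and hence the penalty potential) is continuous
    # over the whole lattice - a stencil that renormalized away invalid
    # cells would jump at stencil changes and pump energy
    donor <- matrix(NA_integer_, ncx, ncy)
    donor[cell_has] <- which(cell_has)
    zbase <- as.vector(pl$z)      # undeformed heights, for tie-breaking
    repeat {
      if (!anyNA(donor)) break
      best_z <- matrix(Inf, ncx, ncy)
      best_d <- matrix(NA_integer_, ncx, ncy)
      for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        src <- donor
        if (sh[1] == 1) src <- rbind(NA, src[-ncx, , drop = FALSE])
        if (sh[1] == -1) src <- rbind(src[-1, , drop = FALSE], NA)
        if (sh[2] == 1) src <- cbind(NA, src[, -ncy, drop = FALSE])
        if (sh[2] == -1) src <- cbind(src[, -1, drop = FALSE], NA)
        zc <- matrix(Inf, ncx, ncy)
        zc[!is.na(src)] <- zbase[src[!is.na(src)]]
        take <- is.na(donor) & !is.na(src) & zc < best_z
        best_z[take] <- zc[take]
        best_d[take] <- src[take]
      }
      fill <- is.na(donor) & !is.na(best_d)
      if (!any(fill)) break
      donor[fill] <- best_d[fill]
    }
    lincell <- (miy - 1L) * ncx + mix          # lattice cell of each facet
    cmap_lin <- as.vector(cellmap)             # facet id per lattice cell
    donorv <- as.vector(donor)
  }

  xi <- matrix(0, ns, 3)           # tangential stick anchors
  e_fric <- 0
  asgn <- rep(NA_integer_, ns)     # slave-node -> master-facet assignment
  h_elem <- min(element_char_length(mesh))
  warned_pen <- FALSE

  # per-node contact evaluation. `advance` gates the friction-state update
  # (stick anchors, dissipated energy) so that diagnostic re-evaluations at
  # recording frames do not double-advance the state.
  contact_forces <- function(u, vh, dt, advance = TRUE) {
    f <- numeric(ndof)
    xs <- Xs + cbind(u[s_ix], u[s_iy], u[s_iz])
    if (rigid) {
      gap <- case$rigid_plane_z - xs[, 3]     # >0 while separated
      nrm <- matrix(rep(c(0, 0, -1), each = ns), ns, 3)
      vm_nodes <- matrix(0, ns, 3)
    } else {
      # current master surface heights per lattice cell
      zfac <- rowMeans(matrix(nodes[, 3][as.vector(MF)] + u[mfz_dof],
                              nrow = nrow(MF)))
      zlin <- rep(NA_real_, ncx * ncy)
      zlin[lincell] <- zfac

      # Bilinear interpolation of the surface height at the slave's plan
      # position (fractional cell coordinates relative to cell centres).
      # The penalty is the potential U = 0.5 k A <z_s - zint(x_s, y_s)>^2;
      # all contact forces below are its exact gradient: the slave feels
      # (k A d) * (dzint/dx, dzint/dy, -1) and each contributing master
      # facet's nodes feel the z reaction weighted by its bilinear weight,
      # which keeps the deep-settling contact non-dissipative.
      fx <- (xs[, 1] - m_x0) / Hm + 0.5
      fy <- (xs[, 2] - m_y0) / Hm + 0.5
      # Quadratic B-spline interpolation over a 3x3 stencil of cells:
      # unlike bilinear interpolation, the surface is C1, so the slope
      # force is *continuous* across cell lines - with the deep settling
      # overclosure, nodes chattering across a bilinear force jump ratchet
      # energy into the system at a rate independent of the time step.
      # Stencil indices are clamped into the lattice (flat outward
      # extension), so the weights sum to one exactly and the analytic
      # gradient below is the true gradient of the interpolant.
      ib <- round(fx); jb <- round(fy)
      tx <- fx - ib; ty <- fy - jb
      wxs <- cbind((0.5 - tx)^2 / 2, 0.75 - tx^2, (0.5 + tx)^2 / 2)
      wys <- cbind((0.5 - ty)^2 / 2, 0.75 - ty^2, (0.5 + ty)^2 / 2)
      dxs <- cbind(-(0.5 - tx), -2 * tx, 0.5 + tx)
      dys <- cbind(-(0.5 - ty), -2 * ty, 0.5 + ty)
      zint <- numeric(ns)
      gx <- numeric(ns); gy <- numeric(ns)
      Wk <- matrix(0, ns, 9)       # spline weight of each stencil cell
      Fc <- matrix(0L, ns, 9)      # master facet (local id) of that cell
      k <- 0L
      for (di in -1:1) for (dj in -1:1) {
        k <- k + 1L
        ii <- pmin(pmax(ib + di, 1L), ncx)
        jj <- pmin(pmax(jb + dj, 1L), ncy)
        dlin <- (jj - 1L) * ncx + ii
        dc <- donorv[dlin]
        wxi <- wxs[, di + 2L]; wyj <- wys[, dj + 2L]
        w <- wxi * wyj
        zv <- zlin[dc]
        zint <- zint + w * zv
        gx <- gx + dxs[, di + 2L] * wyj * zv
        gy <- gy + wxi * dys[, dj + 2L] * zv
        Wk[, k] <- w
        Fc[, k] <- cmap_lin[dc]
      }
      gx <- gx / Hm
      gy <- gy / Hm
      has <- rep(TRUE, ns)

      # containing cell (for master velocity and friction reaction)
      ix <- pmin(pmax(floor((xs[, 1] - m_x0) / Hm) + 1L, 1L), ncx)
      iy <- pmin(pmax(floor((xs[, 2] - m_y0) / Hm) + 1L, 1L), ncy)
      asgn <<- cmap_lin[donor[cbind(ix, iy)]]
      nrm <- matrix(0, ns, 3); nrm[, 3] <- -1
      nrm[, 1] <- gx
      nrm[, 2] <- gy
      gap <- rep(Inf, ns)
      gap[has] <- zint[has] - xs[has, 3]
      vm_nodes <- matrix(0, ns, 3)
      hasf <- has & asgn > 0L
      if (case$friction > 0 && any(hasf)) {
        vmat <- matrix(vh, ncol = 3, byrow = TRUE)
        acc <- matrix(0, sum(hasf), 3)
        for (i in seq_len(npf)) {
          acc <- acc + vmat[MF[asgn[hasf], i], , drop = FALSE]
        }
        vm_nodes[hasf, ] <- acc / npf
      }
    }
    pen <- gap < 0
    delta <- pmax(-gap, 0)
    if (any(pen)) {
      dmax <- max(delta)
      if (dmax > h_elem && !warned_pen) {
        warned_pen <<- TRUE
        warn(sprintf(paste0("contact overclosure %.2f mm exceeds one ",
                            "element length (%.2f mm); the linear ",
                            "soft-contact law is in its settling regime."),
                     dmax, h_elem))
      }
      if (dmax > case$max_overclosure) {
        abort(sprintf("interpenetration %.2f mm exceeds max_overclosure.",
                      dmax))
      }
    }
    press <- case$contact_stiffness * delta
    Fn <- kA * delta                       # normal force magnitude per node
    fvec <- nrm * Fn                       # on slave, along outward-master n
    ffric <- matrix(0, ns, 3)              # friction part (tracked apart)

    # stick-slip friction (penalty anchor, capped at mu N)
    if (case$friction > 0 && any(pen)) {
      un <- nrm / row_norm(nrm)     # unit normal for tangential projection
      vs <- cbind(vh[s_ix], vh[s_iy], vh[s_iz])
      vrel <- vs - (if (rigid) 0 else vm_nodes)
      vt <- vrel - un * rowSums(vrel * un)
      xi_new <- xi + vt * dt
      xi_new <- xi_new - un * rowSums(xi_new * un)
      xi_new[!pen, ] <- 0
      ft <- kA * row_norm(xi_new)
      fmax <- case$friction * Fn
      slip <- pen & ft > fmax & ft > 0
      if (any(slip)) {
        over <- (ft[slip] - fmax[slip]) / kA[slip]
        if (advance) e_fric <<- e_fric + sum(fmax[slip] * over)
        xi_new[slip, ] <- xi_new[slip, , drop = FALSE] *
          (fmax[slip] / ft[slip])
      }
      if (advance) xi <<- xi_new
      ffric <- -kA * xi_new
      fvec <- fvec + ffric
    } else if (advance && any(xi != 0)) {
      xi <<- xi * 0
    }

    f[s_ix] <- fvec[, 1]; f[s_iy] <- fvec[, 2]; f[s_iz] <- fvec[, 3]
    if (!rigid && any(pen)) {
      w <- which(pen)
      idx <- integer(0); val <- numeric(0)
      # z reaction of the penalty potential, spline weights per facet
      for (k in seq_len(ncol(Fc))) {
        wk <- which(pen & Fc[, k] > 0L & Wk[, k] > 0)
        if (!length(wk)) next
        share <- Fn[wk] * Wk[wk, k] / npf    # +z on master nodes
        for (i in seq_len(npf)) {
          idx <- c(idx, 3L * MF[Fc[wk, k], i])
          val <- c(val, share)
        }
      }
      # friction reaction to the containing facet's nodes
      wf <- which(pen & asgn > 0L & rowSums(ffric^2) > 0)
      if (length(wf)) {
        for (i in seq_len(npf)) {
          base <- 3L * (MF[asgn[wf], i] - 1L)
          idx <- c(idx, base + 1L, base + 2L, base + 3L)
          val <- c(val, -ffric[wf, 1] / npf, -ffric[wf, 2] / npf,
                   -ffric[wf, 3] / npf)
        }
      }
      if (length(idx)) {
        acc <- rowsum(val, idx)
        ii <- as.integer(rownames(acc))
        f[ii] <- f[ii] + acc[, 1]
      }
    }
    list(f = f, pressure = press, delta = delta)
  }

  list(eval = contact_forces, slave = sl, kA = kA,
       friction_energy = function() e_fric)
}

# central-difference time integration (internal; run_impact prepares the
# systems and the contact model)
run_impact_core <- function(mesh, materials, case, counterbody,
                            counterbody_materials, sysA, sysB, K, nodes,
                            nA, nB, mdof, dt, n_steps, out_every, fixed,
                            cm) {
  rigid <- is.null(counterbody)
  ndof <- 3L * nrow(nodes)
  sl <- cm$slave
  kA <- cm$kA
  contact_forces <- cm$eval

  # initial state: all moving-body nodes at v0 (+z)
  v0 <- case$velocity * M_S_TO_MM_S
  u <- numeric(ndof)
  vh <- numeric(ndof)
  vh[seq(3, 3 * nA, by = 3)] <- v0

  ke0 <- 0.5 * sum(mdof * vh^2)
  n_frames <- floor(n_steps / out_every) + 1L
  times <- numeric(n_frames)
  en <- matrix(0, n_frames, 5,
               dimnames = list(NULL, c("kinetic", "strain", "contact",
                                       "friction", "total")))
  vmA <- matrix(0, nrow(mesh$elems), n_frames)
  vmB <- if (!rigid) matrix(0, nrow(counterbody$elems), n_frames) else NULL
  p_fac <- matrix(0, length(sl$facets), n_frames)
  f_trace <- numeric(n_frames)
  a_trace <- numeric(n_frames)
  u_snap <- vector("list", n_frames)
  v_snap <- vector("list", n_frames)
  max_pressure <- 0
  max_force <- 0

  record <- function(frame, t_now, vcorr) {
    v_full <- vh - vcorr
    ke <- 0.5 * sum(mdof * v_full^2)
    se <- 0.5 * sum(u * as.numeric(K %*% u))
    cf <- contact_forces(u, vh, dt, advance = FALSE)
    cen_e <- 0.5 * sum(kA * cf$delta^2)
    e_fric <- cm$friction_energy()
    times[frame] <<- t_now / MS_TO_S
    en[frame, ] <<- c(ke, se, cen_e, e_fric, ke + se + cen_e + e_fric)
    uA <- u[seq_len(3 * nA)]
    vmA[, frame] <<- von_mises(recover_stress(mesh, materials, sysA, uA))
    if (!rigid) {
      uB <- u[3 * nA + seq_len(3 * nB)]
      vmB[, frame] <<- von_mises(
        recover_stress(counterbody, counterbody_materials, sysB, uB))
    }
    # facet pressure = mean of its slave-node pressures
    pn <- cf$pressure
    pf <- numeric(length(sl$facets))
    fac <- mesh$facets[sl$facets, , drop = FALSE]
    for (i in seq_len(ncol(fac))) {
      pf <- pf + pn[match(fac[, i], sl$nodes)]
    }
    p_fac[, frame] <<- pf / ncol(fac)
    f_trace[frame] <<- sum(kA * cf$delta)
    a_trace[frame] <<- sum(mesh$facet_area[sl$facets][p_fac[, frame] > 0])
    u_snap[[frame]] <<- matrix(u, ncol = 3, byrow = TRUE)
    v_snap[[frame]] <<- matrix(v_full, ncol = 3, byrow = TRUE)
    max_pressure <<- max(max_pressure, pn)
    max_force <<- max(max_force, f_trace[frame])
  }

  # initial acceleration and half-step velocity
  cf0 <- contact_forces(u, vh, dt, advance = FALSE)
  f0 <- cf0$f - as.numeric(K %*% u)
  a <- f0 / mdof
  if (length(fixed)) a[fixed] <- 0
  record(1L, 0, vcorr = 0)
  vh <- vh + 0.5 * dt * a

  frame <- 1L
  for (step in seq_len(n_steps)) {
    u <- u + dt * vh
    if (length(fixed)) u[fixed] <- 0
    cf <- contact_forces(u, vh, dt)
    f <- cf$f - as.numeric(K %*% u)
    if (case$mass_damping > 0) f <- f - case$mass_damping * mdof * vh
    a <- f / mdof
    if (length(fixed)) a[fixed] <- 0
    vh <- vh + dt * a
    if (length(fixed)) vh[fixed] <- 0

    if (step %% out_every == 0L) {
      frame <- frame + 1L
      record(frame, step * dt, vcorr = 0.5 * dt * a)
      if (en[frame, "total"] > 10 * ke0) {
        abort(sprintf(paste0("instability: total energy %.3g mJ exceeds ",
                             "10x initial kinetic energy %.3g mJ at ",
                             "t = %.3f ms."),
                      en[frame, "total"], ke0, times[frame]))
      }
    }
  }

  structure(
    list(
      times = times[seq_len(frame)],
      energies = tibble::as_tibble(en[seq_len(frame), , drop = FALSE]) |>
        dplyr::mutate(time = times[seq_len(frame)], .before = 1),
      initial_ke = ke0,
      vm = vmA[, seq_len(frame), drop = FALSE],
      vm_counterbody = if (!rigid) vmB[, seq_len(frame), drop = FALSE],
      pressure = p_fac[, seq_len(frame), drop = FALSE],
      contact_facets = sl$facets,
      contact_force = f_trace[seq_len(frame)],
      contact_area = a_trace[seq_len(frame)],
      u_snapshots = u_snap[seq_len(frame)],
      v_snapshots = v_snap[seq_len(frame)],
      n_nodes_body = nA,
      dt = dt, n_steps = n_steps,
      max_pressure = max_pressure, max_force = max_force,
      case = case
    ),
    class = "impact_history"
  )
}

#' @export
print.impact_history <- function(x, ...) {
  drift <- 100 * (x$energies$total[length(x$times)] - x$initial_ke) /
    x$initial_ke
  cat(sprintf(
    paste0("<impact_history> %d frames to %.3g ms | dt %.3g us, %d steps\n",
           "  peak contact pressure %.4g MPa, energy drift %+.2f%%\n"),
    length(x$times), max(x$times), x$dt * 1e6, x$n_steps,
    x$max_pressure, drift))
  invisible(x)
}

#' Regional contact-pressure summary of an impact event
#'
#' For every labelled articular region: the event maximum of the
#' facet-area-weighted mean contact pressure, the event peak pointwise
#' facet pressure, and the contact area (pressurized facet area at the
#' frame of peak total contact force).
#'
#' @param history An `impact_history` from [run_impact()].
#' @param mesh The region-labelled moving-body mesh the history was run on.
#' @return A tibble with columns `region`, `n_facets`, `avg_pressure`,
#'   `peak_pressure`, `contact_area` (class `regional_pressure_table`).
#' @export
contact_summary <- function(history, mesh) {
  stopifnot(inherits(history, "impact_history"), inherits(mesh, "fe_mesh"))
  if (is.null(mesh$facet_regions)) abort("mesh has no region labels.")
  if (all(history$pressure == 0)) {
    warn("no contact during the event; pressures are all zero.")
  }
  lab <- mesh$facet_regions[as.character(history$contact_facets)]
  area <- mesh$facet_area[history$contact_facets]
  peak_frame <- which.max(history$contact_force)
  regions <- sort(unique(lab))
  rows <- lapply(regions, function(r) {
    i <- which(lab == r)
    wmean <- colSums(history$pressure[i, , drop = FALSE] * area[i]) /
      sum(area[i])
    pk_fr <- history$pressure[i, peak_frame]
    tibble::tibble(
      region = r, n_facets = length(i),
      avg_pressure = max(wmean),
      peak_pressure = max(history$pressure[i, ]),
      contact_area = sum(area[i][pk_fr > 0])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("regional_pressure_table", class(out))
  out
}
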