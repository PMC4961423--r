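#' Finite-element mesh container
#'
#' Nodes, homogeneous solid elements (hex8 or tet4), boundary facets with
#' outward normals, and named node/facet/element sets. Node and element
#' indices are 1-based throughout (exporters translate to each format's
#' convention). Coordinate convention is fixed package-wide: x lateral to
#' medial, y palmar to dorsal, z proximal to distal, all in mm.
#'
#' @param nodes n x 3 numeric matrix of node coordinates (mm).
#' @param elems m x 8 (hex8) or m x 4 (tet4) integer connectivity matrix.
#'   Hex corners follow the VTK ordering (bottom quad counter-clockwise,
#'   then top quad).
#' @param elem_type `"hex8"` or `"tet4"`.
#' @param node_sets,facet_sets,elem_sets Named lists of integer index
#'   vectors.
#' @param landmarks Free-form list of geometric landmarks (mid-plane,
#'   transverse-ridge plane, slice planes) attached by [label_regions()].
#' @return An object of class `fe_mesh`. Boundary facets are extracted on
#'   construction: fields `facets` (quad or tri node indices), `facet_elem`
#'   (owning element), `facet_normal` (outward unit normals),
#'   `facet_area` (mm^2).
#' @export
fe_mesh <- function(nodes, elems, elem_type = c("hex8", "tet4"),
                    node_sets = list(), facet_sets = list(),
                    elem_sets = list(), landmarks = list()) {
  elem_type <- match.arg(elem_type)
  nodes <- as.matrix(nodes)
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3L) abort("`nodes` must be n x 3.")
  npe <- if (elem_type == "hex8") 8L else 4L
  if (ncol(elems) != npe) {
    abort(sprintf("`elems` must have %d columns for %s.", npe, elem_type))
  }
  if (nrow(elems) == 0L) abort("mesh has no elements.")
  if (min(elems) < 1L || max(elems) > nrow(nodes)) {
    abort("element connectivity indexes outside the node table.")
  }
  mesh <- structure(
    list(nodes = nodes, elems = elems, elem_type = elem_type,
         node_sets = node_sets, facet_sets = facet_sets,
         elem_sets = elem_sets, landmarks = landmarks),
    class = "fe_mesh"
  )
  v <- element_volumes(mesh)
  if (any(v <= 0)) abort("all element volumes must be positive.")
  mesh <- extract_boundary_facets(mesh)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d %s elements, %d boundary facets\n",
              nrow(x$nodes), nrow(x$elems), x$elem_type, nrow(x$facets)))
  if (length(x$facet_sets)) {
    cat("  facet sets:", paste(names(x$facet_sets), collapse = ", "), "\n")
  }
  if (length(x$node_sets)) {
    cat("  node sets: ", paste(names(x$node_sets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Element volumes
#'
#' @param mesh An [fe_mesh()].
#' @return Numeric vector of element volumes (mm^3). Hex elements must be
#'   axis-aligned boxes (the voxel meshes this package builds); tet volumes
#'   use the signed determinant.
#' @export
element_volumes <- function(mesh) {
  if (mesh$elem_type == "hex8") {
    b <- element_bounds(mesh)
    apply(b$hi - b$lo, 1, prod)
  } else {
    v1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
    v2 <- mesh$nodes[mesh$elems[, 2], , drop = FALSE]
    v3 <- mesh$nodes[mesh$elems[, 3], , drop = FALSE]
    v4 <- mesh$nodes[mesh$elems[, 4], , drop = FALSE]
    a <- v2 - v1; b <- v3 - v1; c <- v4 - v1
    det3 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    det3 / 6
  }
}

#' Element centroids
#' @param mesh An [fe_mesh()].
#' @return m x 3 matrix of centroids (mm).
#' @export
element_centroids <- function(mesh) {
  npe <- ncol(mesh$elems)
  cbind(
    rowMeans(matrix(mesh$nodes[mesh$elems, 1], ncol = npe)),
    rowMeans(matrix(mesh$nodes[mesh$elems, 2], ncol = npe)),
    rowMeans(matrix(mesh$nodes[mesh$elems, 3], ncol = npe))
  )
}

# face templates with outward orientation
hex_faces_ <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                    c(4, 8, 7, 3), c(1, 5, 8, 4), c(2, 3, 7, 6))
tet_faces_ <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))

# find element faces that appear exactly once (mesh boundary); set
# facets/facet_elem/facet_normal/facet_area on the mesh
extract_boundary_facets <- function(mesh) {
  tmpl <- if (mesh$elem_type == "hex8") hex_faces_ else tet_faces_
  nf <- nrow(tmpl); npf <- ncol(tmpl)
  ne <- nrow(mesh$elems)
  faces <- matrix(0L, ne * nf, npf)
  for (i in seq_len(nf)) {
    faces[seq_len(ne) + (i - 1) * ne, ] <- mesh$elems[, tmpl[i, ]]
  }
  owner <- rep(seq_len(ne), times = nf)
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  once <- !(key %in% key[duplicated(key)])
  facets <- faces[once, , drop = FALSE]
  facet_elem <- owner[once]

  # outward normals and areas from geometry (orientation checked against
  # the owning element's centroid)
  p1 <- mesh$nodes[facets[, 1], , drop = FALSE]
  p2 <- mesh$nodes[facets[, 2], , drop = FALSE]
  p3 <- mesh$nodes[facets[, 3], , drop = FALSE]
  n <- cross3(p2 - p1, p3 - p1)
  if (npf == 4L) {
    p4 <- mesh$nodes[facets[, 4], , drop = FALSE]
    area <- 0.5 * (row_norm(cross3(p2 - p1, p3 - p1)) +
                     row_norm(cross3(p3 - p1, p4 - p1)))
    fc <- (p1 + p2 + p3 + p4) / 4
  } else {
    area <- 0.5 * row_norm(n)
    fc <- (p1 + p2 + p3) / 3
  }
  n <- n / row_norm(n)
  ec <- element_centroids(mesh)[facet_elem, , drop = FALSE]
  flip <- rowSums(n * (ec - fc)) > 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  if (any(flip)) {
    facets[flip, ] <- facets[flip, rev(seq_len(npf)), drop = FALSE]
  }
  mesh$facets <- facets
  mesh$facet_elem <- facet_elem
  mesh$facet_normal <- n
  mesh$facet_area <- area
  mesh
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
row_norm <- function(m) sqrt(rowSums(m^2))

#' Facet centroids
#' @param mesh An [fe_mesh()].
#' @param which Facet indices (default all).
#' @return Matrix of facet centroids (mm).
#' @export
facet_centroids <- function(mesh, which = seq_len(nrow(mesh$facets))) {
  f <- mesh$facets[which, , drop = FALSE]
  npf <- ncol(f)
  out <- 0
  for (i in seq_len(npf)) out <- out + mesh$nodes[f[, i], , drop = FALSE]
  out / npf
}

#' Segment a density volume into a binary bone mask
#'
#' Threshold stand-in for the tool-based surface segmentation of the source
#' imaging workflow: keeps voxels at or above `threshold`, optionally keeps
#' only the largest 6-connected component and fills interior cavities.
#'
#' @param volume A density-valued [voxel_volume()].
#' @param threshold Density threshold, g/cm^3.
#' @param keep_largest Keep only the largest connected component.
#' @param fill_cavities Fill background regions not connected to the volume
#'   boundary.
#' @return A mask-valued [voxel_volume()] (0/1).
#' @export
segment_volume <- function(volume, threshold = 0.2, keep_largest = TRUE,
                           fill_cavities = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (volume$value_kind != "density") {
    abort("`segment_volume()` needs a density-valued volume.")
  }
  mask <- volume$data >= threshold
  if (!any(mask)) abort("empty mask: threshold exceeds every voxel value.")
  if (keep_largest) mask <- largest_component6(mask)
  if (fill_cavities) mask <- fill_cavities6(mask)
  out <- volume
  out$data <- array(as.numeric(mask), dim = dim(mask))
  out$value_kind <- "mask"
  out$meta$threshold <- threshold
  out
}

dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, ax, by) {
    o <- array(FALSE, d)
    n <- d[ax]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- idx; dst <- idx
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    o[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    o
  }
  for (ax in 1:3) out <- out | sh(mask, ax, 1L) | sh(mask, ax, -1L)
  out
}

# flood fill within `domain` starting from `seed` (logical arrays)
flood6 <- function(seed, domain) {
  visited <- seed & domain
  repeat {
    grown <- dilate6(visited) & domain
    if (sum(grown) == sum(visited)) return(visited)
    visited <- grown
  }
}

largest_component6 <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood6(seed, remaining)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best
}

fill_cavities6 <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  seed <- array(FALSE, d)
  seed[1, , ] <- TRUE; seed[d[1], , ] <- TRUE
  seed[, 1, ] <- TRUE; seed[, d[2], ] <- TRUE
  seed[, , 1] <- TRUE; seed[, , d[3]] <- TRUE
  seed <- seed & bg
  outside <- if (any(seed)) flood6(seed, bg) else array(FALSE, d)
  mask | (bg & !outside)
}

#' Build a voxel finite-element mesh from a binary mask
#'
#' One hex8 element per (coarsened) occupied voxel block; a block is
#' occupied when at least `occupancy` of its member voxels are in the mask.
#' Tet4 mode splits every hex into 6 Kuhn tetrahedra with per-axis parity
#' reflections so the split conforms across neighbouring hexes. Mask
#' dimensions that do not divide by `coarsening` are padded with background
#' at the high end of each axis.
#'
#' Node sets `proximal_end` (minimum-z node layer) and `distal_end`
#' (maximum-z layer) and the element set `proximal_end` (bottom element
#' layer) are attached for boundary conditions and mass augmentation.
#'
#' @param mask A mask-valued [voxel_volume()] from [segment_volume()].
#' @param coarsening Integer block size (>= 1) in voxels per element edge.
#' @param elem_type `"hex8"` (default) or `"tet4"`.
#' @param occupancy Occupied-block threshold, fraction of member voxels.
#' @return An [fe_mesh()].
#' @export
build_voxel_mesh <- function(mask, coarsening = 1L,
                             elem_type = c("hex8", "tet4"),
                             occupancy = 0.5) {
  stopifnot(inherits(mask, "voxel_volume"))
  elem_type <- match.arg(elem_type)
  coarsening <- as.integer(coarsening)
  if (coarsening < 1L) abort("`coarsening` must be >= 1.")
  m <- mask$data > 0.5
  d <- dim(m)
  cpad <- ceiling(d / coarsening) * coarsening - d
  if (any(cpad > 0)) {
    mp <- array(FALSE, dim = d + cpad)
    mp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- m
    m <- mp
    d <- dim(m)
  }
  nb <- d %/% coarsening
  dim(m) <- c(coarsening, nb[1], coarsening, nb[2], coarsening, nb[3])
  occ_cnt <- apply(m, c(2, 4, 6), sum)
  occ <- occ_cnt >= occupancy * coarsening^3
  if (!any(occ)) abort("empty mesh: no occupied blocks.")

  H <- mask$spacing * coarsening
  # node lattice at block corners; node (i,j,k) at low corner of block (i,j,k)
  nn <- nb + 1L
  nid <- array(0L, dim = nn)
  used <- array(FALSE, dim = nn)
  occ_idx <- which(occ, arr.ind = TRUE)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    used[occ_idx + rep(c(dx, dy, dz), each = nrow(occ_idx))] <- TRUE
  }
  nid[used] <- seq_len(sum(used))
  ui <- which(used, arr.ind = TRUE)
  x0 <- mask$origin - mask$spacing / 2
  nodes <- cbind(x0[1] + (ui[, 1] - 1) * H[1],
                 x0[2] + (ui[, 2] - 1) * H[2],
                 x0[3] + (ui[, 3] - 1) * H[3])
  # reorder nodes to nid order
  nodes[nid[used], ] <- nodes

  gid <- function(i, j, k) nid[cbind(i, j, k)]
  i <- occ_idx[, 1]; j <- occ_idx[, 2]; k <- occ_idx[, 3]
  hexes <- cbind(gid(i, j, k),         gid(i + 1, j, k),
                 gid(i + 1, j + 1, k), gid(i, j + 1, k),
                 gid(i, j, k + 1),     gid(i + 1, j, k + 1),
                 gid(i + 1, j + 1, k + 1), gid(i, j + 1, k + 1))

  if (elem_type == "hex8") {
    elems <- hexes
  } else {
    elems <- split_hexes_kuhn(hexes, occ_idx)
    # enforce positive orientation (signed volume) element-wise
    v1 <- nodes[elems[, 1], , drop = FALSE]
    a <- nodes[elems[, 2], , drop = FALSE] - v1
    b <- nodes[elems[, 3], , drop = FALSE] - v1
    cc <- nodes[elems[, 4], , drop = FALSE] - v1
    det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    neg <- det3 < 0
    if (any(neg)) {
      tmp <- elems[neg, 3L]
      elems[neg, 3L] <- elems[neg, 4L]
      elems[neg, 4L] <- tmp
    }
  }

  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  tol <- 1e-9 + 0 * H[3]
  node_sets <- list(
    proximal_end = which(nodes[, 3] <= zmin + 1e-9),
    distal_end = which(nodes[, 3] >= zmax - 1e-9)
  )
  mesh <- fe_mesh(nodes, elems, elem_type, node_sets = node_sets)
  cen <- element_centroids(mesh)
  mesh$elem_sets$proximal_end <- which(cen[, 3] <= zmin + H[3])
  mesh$landmarks$H <- unname(H[1])
  mesh
}

# Kuhn (Freudenthal) 6-tet split with per-axis parity reflection, which is
# conforming across neighbouring cubes. hexes: m x 8 VTK-ordered corners;
# parity from the block index of each hex.
split_hexes_kuhn <- function(hexes, occ_idx) {
  # VTK corner index at local coords (x,y,z) in {0,1}
  vtk_idx <- array(0L, dim = c(2, 2, 2))
  vtk_idx[1, 1, 1] <- 1L; vtk_idx[2, 1, 1] <- 2L
  vtk_idx[2, 2, 1] <- 3L; vtk_idx[1, 2, 1] <- 4L
  vtk_idx[1, 1, 2] <- 5L; vtk_idx[2, 1, 2] <- 6L
  vtk_idx[2, 2, 2] <- 7L; vtk_idx[1, 2, 2] <- 8L
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  m <- nrow(hexes)
  out <- matrix(0L, m * 6L, 4L)
  refl <- (occ_idx - 1L) %% 2L == 1L   # m x 3 logical: reflect this axis
  for (p in seq_len(6L)) {
    # walk from corner 0 adding unit steps in permuted axis order
    loc <- matrix(0L, 4L, 3L)
    for (v in 2:4) {
      loc[v, ] <- loc[v - 1, ]
      loc[v, perms[p, v - 1]] <- 1L
    }
    # per-hex reflected local coords -> VTK corner -> global node
    for (v in 1:4) {
      lx <- ifelse(refl[, 1], 1L - loc[v, 1], loc[v, 1])
      ly <- ifelse(refl[, 2], 1L - loc[v, 2], loc[v, 2])
      lz <- ifelse(refl[, 3], 1L - loc[v, 3], loc[v, 3])
      ci <- vtk_idx[cbind(lx + 1L, ly + 1L, lz + 1L)]
      out[(p - 1L) * m + seq_len(m), v] <- hexes[cbind(seq_len(m), ci)]
    }
  }
  out
}

#' Label anatomical regions on the distal articular surface
#'
#' Partitions the up-facing distal boundary facets into the eight condylar
#' regions (dorsal/palmar x medial/lateral x condyle/parasagittal groove)
#' plus the sagittal-ridge band SR, using mediolateral bands around the
#' sagittal mid-plane: `|x| <= sr_frac * separation` is SR,
#' `|x| <= psg_frac * separation` is PSG, anything wider is condyle; band
#' edges are inclusive toward the mid-line (a facet exactly on the mid-plane
#' is SR) and `y = 0` counts as dorsal. Also attaches contact-patch facet
#' sets (`dorsal_patch`, `palmar_patch` = dorsal/palmar non-SR articular
#' facets), the articular node set, and the two mediolateral slice planes at
#' `+-slice_offset` from the transverse-ridge plane `y = 0`.
#'
#' @param mesh An [fe_mesh()] built from a condyle phantom.
#' @param spec The generating [phantom_spec()] (provides the shaft length
#'   and lobe separation used as landmarks).
#' @param sr_frac,psg_frac Band half-widths as fractions of
#'   `condyle_separation`.
#' @param slice_offset Offset (mm) of the dorsal/palmar analysis slices from
#'   the transverse-ridge plane.
#' @return The mesh with region facet sets, patch sets, the
#'   `distal_articular_surface` facet/node sets, and `landmarks` populated.
#' @export
label_regions <- function(mesh, spec, sr_frac = 0.25, psg_frac = 0.6,
                          slice_offset = 5) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(spec, "phantom_spec"))
  z_cut <- spec$shaft_length - mesh$landmarks$H %||% 0
  fc <- facet_centroids(mesh)
  art <- which(mesh$facet_normal[, 3] > 0.5 & fc[, 3] > z_cut)
  if (length(art) == 0L) abort("no distal articular facets found.")
  s <- spec$condyle_separation
  w_sr <- sr_frac * s
  w_psg <- psg_frac * s
  x <- fc[art, 1]; y <- fc[art, 2]
  lab <- character(length(art))
  sr <- abs(x) <= w_sr
  lab[sr] <- "SR"
  dp <- ifelse(y >= 0, "D", "P")
  ml <- ifelse(x > 0, "M", "L")
  band <- ifelse(abs(x) <= w_psg, "PSG", "C")
  lab[!sr] <- paste0(dp[!sr], ml[!sr], band[!sr])

  mesh$facet_sets$distal_articular_surface <- art
  for (r in c("DLC", "DLPSG", "DMC", "DMPSG",
              "PLC", "PLPSG", "PMC", "PMPSG", "SR")) {
    mesh$facet_sets[[r]] <- art[lab == r]
  }
  mesh$facet_sets$dorsal_patch <- art[!sr & dp == "D"]
  mesh$facet_sets$palmar_patch <- art[!sr & dp == "P"]
  mesh$node_sets$distal_articular_surface <-
    sort(unique(as.vector(mesh$facets[art, ])))
  mesh$facet_regions <- setNames(lab, art)
  mesh$landmarks <- modifyList(mesh$landmarks, list(
    mid_x = 0, ridge_y = 0, z_cut = z_cut,
    sr_halfwidth = w_sr, psg_halfwidth = w_psg,
    slice_y = c(dorsal = slice_offset, palmar = -slice_offset),
    separation = s, condyle_radius = spec$condyle_radius,
    shaft_length = spec$shaft_length
  ))
  mesh
}

#' Region label of a point by the band construction
#'
#' @param x,y Coordinates (mm) relative to the sagittal mid-plane and the
#'   transverse-ridge plane.
#' @param landmarks The `landmarks` list of a region-labelled mesh.
#' @return Character vector of region labels.
#' @export
region_of_point <- function(x, y, landmarks) {
  sr <- abs(x) <= landmarks$sr_halfwidth
  dp <- ifelse(y >= 0, "D", "P")
  ml <- ifelse(x > 0, "M", "L")
  band <- ifelse(abs(x) <= landmarks$psg_halfwidth, "PSG", "C")
  ifelse(sr, "SR", paste0(dp, ml, band))
}

#' Add a named facet or node set by predicate
#'
#' @param mesh An [fe_mesh()].
#' @param name Set name.
#' @param predicate Function of a coordinate matrix returning a logical
#'   vector; for facet sets it receives facet centroids and normals
#'   (`function(centroid, normal)`), for node sets the node coordinates.
#' @return The mesh with the set attached.
#' @export
mesh_add_facet_set <- function(mesh, name, predicate) {
  fc <- facet_centroids(mesh)
  keep <- which(predicate(fc, mesh$facet_normal))
  mesh$facet_sets[[name]] <- keep
  mesh
}

#' @rdname mesh_add_facet_set
#' @export
mesh_add_node_set <- function(mesh, name, predicate) {
  mesh$node_sets[[name]] <- which(predicate(mesh$nodes))
  mesh
}
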