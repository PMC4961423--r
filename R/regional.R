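#' Superimpose the 160-point sampling grid
#'
#' Lays a uniform, corner-anchored `rows x cols` grid (default 8 x 20 = 160
#' points) over either a mediolateral slice plane or the distal articular
#' surface, scaled to the domain's bounding rectangle (so grids on condyles
#' of different size and shape are affinely comparable). Points falling
#' outside the bone outline are projected to the nearest interior location;
#' the count is recorded. Every point carries one anatomical region label
#' from the band construction of [label_regions()].
#'
#' @param mesh A region-labelled [fe_mesh()].
#' @param domain `"slice"` (a plane parallel to the x-z plane) or
#'   `"surface"` (the distal articular surface).
#' @param slice For slice grids: `"dorsal"`, `"palmar"` (the stored slice
#'   planes at +-`slice_offset` from the transverse ridge) or a numeric y
#'   (mm).
#' @param layout `c(rows, cols)`; rows run along z (slice) or y (surface),
#'   columns along x (mediolateral).
#' @return A `sampling_grid`: a tibble of `x, y, z, region, projected` with
#'   the layout, domain and spacing as attributes.
#' @export
make_sampling_grid <- function(mesh, domain = c("slice", "surface"),
                               slice = "dorsal", layout = c(8, 20)) {
  stopifnot(inherits(mesh, "fe_mesh"))
  domain <- match.arg(domain)
  lm <- mesh$landmarks
  if (is.null(lm$sr_halfwidth)) abort("mesh has no region labels.")
  rows <- layout[1]; cols <- layout[2]
  H <- lm$H %||% 1

  if (domain == "slice") {
    y0 <- if (is.character(slice)) lm$slice_y[[slice]] else as.numeric(slice)
    cen <- element_centroids(mesh)
    # the slice covers the distal end (the subchondral region of interest),
    # not the full shaft
    z_lo <- lm$z_cut %||% -Inf
    sel <- which(abs(cen[, 2] - y0) <= H / 2 + 1e-9 & cen[, 3] > z_lo)
    if (length(sel) == 0L) abort("slice plane misses the mesh.")
    b <- element_bounds(mesh)
    xr <- range(b$lo[sel, 1], b$hi[sel, 1])
    zr <- range(b$lo[sel, 3], b$hi[sel, 3])
    gx <- seq(xr[1], xr[2], length.out = cols)
    gz <- seq(zr[1], zr[2], length.out = rows)
    pts <- expand.grid(z = gz, x = gx)
    px <- pts$x; py <- rep(y0, nrow(pts)); pz <- pts$z
    inside <- logical(length(px))
    for (i in seq_along(px)) {
      inside[i] <- any(b$lo[sel, 1] - 1e-9 <= px[i] &
                         px[i] <= b$hi[sel, 1] + 1e-9 &
                         b$lo[sel, 3] - 1e-9 <= pz[i] &
                         pz[i] <= b$hi[sel, 3] + 1e-9)
    }
    if (any(!inside)) {
      cs <- cen[sel, , drop = FALSE]
      for (i in which(!inside)) {
        j <- which.min((cs[, 1] - px[i])^2 + (cs[, 3] - pz[i])^2)
        px[i] <- cs[j, 1]; pz[i] <- cs[j, 3]
      }
    }
    region <- region_of_point(px, py, lm)
    spacing <- c(diff(zr) / (rows - 1), diff(xr) / (cols - 1))
  } else {
    art <- mesh$facet_sets$distal_articular_surface
    if (is.null(art) || length(art) == 0L) abort("no articular facets.")
    fc <- facet_centroids(mesh, art)
    xr <- range(fc[, 1]); yr <- range(fc[, 2])
    gx <- seq(xr[1], xr[2], length.out = cols)
    gy <- seq(yr[1], yr[2], length.out = rows)
    pts <- expand.grid(y = gy, x = gx)
    px <- pts$x; py <- pts$y
    pz <- numeric(length(px))
    inside <- logical(length(px))
    for (i in seq_along(px)) {
      d2 <- (fc[, 1] - px[i])^2 + (fc[, 2] - py[i])^2
      j <- which.min(d2)
      inside[i] <- d2[j] <= 2 * H^2     # within ~ one facet of the outline
      if (!inside[i]) { px[i] <- fc[j, 1]; py[i] <- fc[j, 2] }
      pz[i] <- fc[j, 3] - H / 2         # sample the subchondral element
    }
    region <- region_of_point(px, py, lm)
    spacing <- c(diff(yr) / (rows - 1), diff(xr) / (cols - 1))
  }

  out <- tibble::tibble(x = px, y = py, z = pz, region = region,
                        projected = !inside)
  attr(out, "layout") <- c(rows = rows, cols = cols)
  attr(out, "domain") <- domain
  attr(out, "slice") <- if (domain == "slice") slice else NA
  attr(out, "spacing") <- spacing
  class(out) <- c("sampling_grid", class(out))
  out
}

#' Sample a per-element field at grid points
#'
#' Piecewise-constant (element-centroid) interpolation: each point takes the
#' value of its containing element; points inside no element take the
#' nearest element's value (the count is recorded as an attribute).
#'
#' @param grid A [make_sampling_grid()] grid.
#' @param field A `solution_field` (its von Mises is sampled) or a numeric
#'   vector with one value per element (e.g. one frame of an impact
#'   history's `vm`).
#' @param mesh The mesh the field lives on.
#' @return The grid tibble with a `value` column (class `sampled_field`);
#'   `attr(, "n_fallback")` counts nearest-element fallbacks.
#' @export
sample_field <- function(grid, field, mesh) {
  stopifnot(inherits(grid, "sampling_grid"), inherits(mesh, "fe_mesh"))
  values <- if (inherits(field, "solution_field")) field$von_mises else field
  if (length(values) != nrow(mesh$elems)) {
    abort("field must supply one value per element.")
  }
  b <- element_bounds(mesh)
  cen <- element_centroids(mesh)
  n <- nrow(grid)
  elem <- integer(n)
  fallback <- logical(n)
  p <- cbind(grid$x, grid$y, grid$z)
  if (mesh$elem_type == "tet4") {
    emap <- locate_in_tets(mesh, b, p[, 1], p[, 2], p[, 3])
    elem <- emap
  } else {
    for (i in seq_len(n)) {
      hit <- which(b$lo[, 1] - 1e-9 <= p[i, 1] & p[i, 1] <= b$hi[, 1] + 1e-9 &
                     b$lo[, 2] - 1e-9 <= p[i, 2] & p[i, 2] <= b$hi[, 2] + 1e-9 &
                     b$lo[, 3] - 1e-9 <= p[i, 3] & p[i, 3] <= b$hi[, 3] + 1e-9)
      elem[i] <- if (length(hit)) hit[1] else NA_integer_
    }
  }
  for (i in which(is.na(elem))) {
    fallback[i] <- TRUE
    elem[i] <- which.min((cen[, 1] - p[i, 1])^2 + (cen[, 2] - p[i, 2])^2 +
                           (cen[, 3] - p[i, 3])^2)
  }
  out <- grid
  out$value <- values[elem]
  out$element <- elem
  attr(out, "n_fallback") <- sum(fallback)
  class(out) <- unique(c("sampled_field", class(out)))
  out
}

#' Per-element von Mises field of the contact phase of an impact
#'
#' The time-average of each element's von Mises stress over the recorded
#' frames in which the total contact force is at least `window` times its
#' event maximum. An undamped explicit solve carries high-frequency elastic
#' ringing on top of the quasi-static contact response; averaging over the
#' loaded phase is the stable per-element stress measure for regional
#' comparisons (single-frame sampling aliases the ringing).
#'
#' @param history An `impact_history` from [run_impact()].
#' @param window Fraction of the peak contact force that defines the
#'   contact phase.
#' @return Numeric vector, one value per element of the moving body.
#' @export
impact_vm_field <- function(history, window = 0.25) {
  stopifnot(inherits(history, "impact_history"))
  sel <- which(history$contact_force >= window * max(history$contact_force))
  if (length(sel) == 0L) sel <- seq_along(history$times)
  rowMeans(history$vm[, sel, drop = FALSE])
}

#' Regional peak and average of sampled values
#'
#' Arithmetic mean and maximum of the sampled field per anatomical region
#' (or pooled by dorsal/palmar location, the way the headline by-location
#' averages are reported); regions with no sample are absent from the table
#' (not reported as zero).
#'
#' @param samples A [sample_field()] result (or any tibble with `region` and
#'   `value` columns).
#' @param by `"region"` for the eight regions + SR, `"location"` to pool
#'   dorsal regions, palmar regions and the SR band.
#' @param metadata Optional named list stored as attributes (model variant,
#'   load case, slice id).
#' @return A `regional_stress_table` tibble: `region`, `n`, `average`,
#'   `peak`.
#' @export
regional_summary <- function(samples, by = c("region", "location"),
                             metadata = list()) {
  by <- match.arg(by)
  if (!all(c("region", "value") %in% names(samples))) {
    abort("`samples` needs `region` and `value` columns.")
  }
  g <- samples$region
  if (by == "location") g <- region_location(g)
  out <- tibble::tibble(region = g, value = samples$value) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(), average = mean(.data$value),
                     peak = max(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$region)
  attr(out, "metadata") <- metadata
  class(out) <- c("regional_stress_table", class(out))
  out
}

#' Dorsal/palmar location of a region label
#' @param region Character vector of region labels (DLC, PMPSG, SR, ...).
#' @return `"dorsal"`, `"palmar"` or `"SR"` per element.
#' @export
region_location <- function(region) {
  ifelse(region == "SR", "SR",
         ifelse(substr(region, 1, 1) == "D", "dorsal", "palmar"))
}

check_same_regions <- function(a, b) {
  if (!identical(sort(a$region), sort(b$region))) {
    abort("tables report different regions.")
  }
}

#' Mesh-convergence report
#'
#' Compares each coarser table's regional averages with the finest table's,
#' in absolute MPa and relative terms, and flags convergence at the given
#' criterion (default +-5% of the finest average).
#'
#' @param tables List of [regional_summary()] tables ordered coarse to fine;
#'   names become the resolution labels.
#' @param criterion Relative convergence criterion (fraction).
#' @return A `convergence_report` tibble: `resolution`, `region`,
#'   `average`, `fine_average`, `diff`, `rel_diff`, `converged`.
#' @export
convergence_check <- function(tables, criterion = 0.05) {
  if (length(tables) < 2L) abort("need at least two tables.")
  labs <- names(tables) %||% paste0("mesh", seq_along(tables))
  if (is.null(names(tables))) names(tables) <- labs
  fine <- tables[[length(tables)]]
  rows <- lapply(seq_len(length(tables) - 1L), function(i) {
    tab <- tables[[i]]
    check_same_regions(tab, fine)
    j <- match(tab$region, fine$region)
    tibble::tibble(
      resolution = names(tables)[i],
      region = tab$region,
      average = tab$average,
      fine_average = fine$average[j],
      diff = tab$average - fine$average[j],
      rel_diff = (tab$average - fine$average[j]) / fine$average[j]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$converged <- abs(out$rel_diff) <= criterion
  attr(out, "criterion") <- criterion
  class(out) <- c("convergence_report", class(out))
  out
}

#' Stiffness-sensitivity report
#'
#' Compares regional averages of a baseline model with the same model under
#' scaled moduli (ratio and true percent change per region). When
#' point-level samples are supplied, also reports the per-point change
#' distribution: the fraction of sampled points whose value changed by more
#' than `change_tol` (relative) and the largest percent increase at any
#' point.
#'
#' @param base,scaled [regional_summary()] tables for the baseline and the
#'   scaled-modulus model.
#' @param samples_base,samples_scaled Optional matching [sample_field()]
#'   tibbles for the point-level distribution.
#' @param change_tol Relative change below which a point counts as
#'   unchanged.
#' @return A `sensitivity_report` tibble: `region`, `base_average`,
#'   `scaled_average`, `ratio`, `pct_change`; point-level stats in
#'   `attr(, "points")`.
#' @export
sensitivity_compare <- function(base, scaled, samples_base = NULL,
                                samples_scaled = NULL, change_tol = 0.01) {
  check_same_regions(base, scaled)
  j <- match(base$region, scaled$region)
  out <- tibble::tibble(
    region = base$region,
    base_average = base$average,
    scaled_average = scaled$average[j],
    ratio = scaled$average[j] / base$average,
    pct_change = 100 * (scaled$average[j] - base$average) / base$average
  )
  if (!is.null(samples_base) && !is.null(samples_scaled)) {
    if (nrow(samples_base) != nrow(samples_scaled)) {
      abort("point samples must match one-to-one.")
    }
    rel <- (samples_scaled$value - samples_base$value) /
      pmax(abs(samples_base$value), .Machine$double.eps)
    attr(out, "points") <- list(
      n = length(rel),
      n_changed = sum(abs(rel) > change_tol),
      frac_changed = mean(abs(rel) > change_tol),
      max_pct_increase = 100 * max(rel)
    )
  }
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Compare two model variants region by region
#'
#' Signed absolute and percent differences of regional average and peak
#' values (`b` minus `a`); used for healthy-versus-OA and
#' impact-versus-midstance reports.
#'
#' @param a,b [regional_summary()] tables on the same regions.
#' @param labels Length-2 labels for the two variants.
#' @return A `variant_comparison` tibble.
#' @export
compare_variants <- function(a, b, labels = c("a", "b")) {
  check_same_regions(a, b)
  ma <- attr(a, "metadata"); mb <- attr(b, "metadata")
  if (!is.null(ma$load_case) && !is.null(mb$load_case) &&
      !identical(ma$load_case, mb$load_case)) {
    abort("tables come from different load cases.")
  }
  j <- match(a$region, b$region)
  out <- tibble::tibble(
    region = a$region,
    average_a = a$average, average_b = b$average[j],
    diff_average = b$average[j] - a$average,
    pct_average = 100 * (b$average[j] - a$average) / a$average,
    peak_a = a$peak, peak_b = b$peak[j],
    diff_peak = b$peak[j] - a$peak,
    pct_peak = 100 * (b$peak[j] - a$peak) / a$peak
  )
  attr(out, "labels") <- labels
  class(out) <- c("variant_comparison", class(out))
  out
}
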