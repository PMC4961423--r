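#' Tidy a static solution field
#'
#' @param x A `solution_field` from [solve_static()].
#' @param mesh Optional [fe_mesh()]; when supplied, element centroid
#'   coordinates are included.
#' @param ... Unused.
#' @return A tibble with one row per element: the six Voigt stress
#'   components (MPa) and the von Mises stress.
#' @export
tidy.solution_field <- function(x, mesh = NULL, ...) {
  out <- tibble::as_tibble(as.data.frame(x$stress))
  out <- dplyr::mutate(out, element = dplyr::row_number(),
                       von_mises = x$von_mises, .before = 1)
  if (!is.null(mesh)) {
    cen <- element_centroids(mesh)
    out$x <- cen[, 1]; out$y <- cen[, 2]; out$z <- cen[, 3]
  }
  out
}

#' @rdname tidy.solution_field
#' @export
glance.solution_field <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$u),
    n_elements = length(x$von_mises),
    residual = x$residual,
    max_displacement = max(sqrt(rowSums(x$u^2))),
    peak_von_mises = max(x$von_mises),
    mean_von_mises = mean(x$von_mises),
    strain_energy = x$strain_energy
  )
}

#' Tidy an impact history
#'
#' @param x An `impact_history` from [run_impact()].
#' @param ... Unused.
#' @return A tibble with one row per recorded frame: the energy ledger
#'   (mJ), total contact force (N), contact area (mm^2) and the frame peak
#'   von Mises (MPa) on the moving body.
#' @export
tidy.impact_history <- function(x, ...) {
  dplyr::mutate(x$energies,
                contact_force = x$contact_force,
                contact_area = x$contact_area,
                peak_von_mises = apply(x$vm, 2, max),
                peak_pressure = apply(x$pressure, 2, max))
}

#' @rdname tidy.impact_history
#' @export
glance.impact_history <- function(x, ...) {
  nf <- length(x$times)
  tibble::tibble(
    duration = max(x$times),
    dt = x$dt,
    n_steps = x$n_steps,
    initial_ke = x$initial_ke,
    energy_drift_pct = 100 * (x$energies$total[nf] - x$initial_ke) /
      x$initial_ke,
    peak_contact_force = max(x$contact_force),
    peak_contact_pressure = x$max_pressure,
    peak_von_mises = max(x$vm),
    friction_dissipated = x$energies$friction[nf]
  )
}
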