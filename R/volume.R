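#' Voxel volume container
#'
#' A 3D scalar raster with physical spacing and origin. This is the common
#' currency of the phantom generator and the density-to-material mapper.
#' Axis order is fixed package-wide: array dimension 1 is x (lateral to
#' medial), 2 is y (palmar to dorsal), 3 is z (proximal to distal). The
#' centre of voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres.
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param origin World coordinates (mm) of the centre of voxel (1,1,1).
#' @param value_kind What the values mean: `"density"` (apparent density,
#'   g/cm^3), `"HU"` (Hounsfield units) or `"mask"` (binary segmentation).
#' @param meta Named list of free-form metadata (e.g. the generating spec
#'   and RNG seed); carried through I/O as a JSON sidecar.
#'
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         value_kind = c("density", "HU", "mask"),
                         meta = list()) {
  value_kind <- match.arg(value_kind)
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be positive and finite (length 1 or 3).")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be a finite 3-vector.")
  }
  if (any(!is.finite(data))) {
    abort("voxel values must all be finite.")
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         value_kind = value_kind, meta = meta),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %s mm, kind: %s\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    x$value_kind
  ))
  cat(sprintf("  origin (%s) mm, range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Voxel-centre coordinates along each axis
#'
#' @param volume A [voxel_volume()].
#' @return List with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates (mm).
#' @export
voxel_axes <- function(volume) {
  d <- dim(volume$data)
  list(
    x = volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1],
    y = volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2],
    z = volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  )
}

#' Total volume of voxels above a threshold
#'
#' Voxel count times voxel volume, in mm^3.
#'
#' @param volume A [voxel_volume()].
#' @param threshold Count voxels with value strictly greater than this.
#' @return Scalar volume in mm^3.
#' @export
voxel_bone_volume <- function(volume, threshold = 0) {
  sum(volume$data > threshold) * prod(volume$spacing)
}

#' Mirror a volume about the sagittal mid-plane
#'
#' Reverses the x axis (lateral/medial flip). Useful for symmetry checks.
#'
#' @param volume A [voxel_volume()].
#' @return The mirrored [voxel_volume()].
#' @export
mirror_volume <- function(volume) {
  volume$data <- volume$data[rev(seq_len(dim(volume$data)[1])), , , drop = FALSE]
  volume
}

#' Mid-slice heatmap of a voxel volume
#'
#' @param object A [voxel_volume()].
#' @param axis Axis normal to the displayed slice ("y" shows the sagittal
#'   mid-plane x-z view).
#' @param index Slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_volume <- function(object, axis = c("y", "x", "z"),
                                  index = NULL, ...) {
  axis <- match.arg(axis)
  d <- dim(object$data)
  ax <- voxel_axes(object)
  i <- index %||% ceiling(d[match(axis, c("x", "y", "z"))] / 2)
  sl <- switch(axis,
    x = object$data[i, , ],
    y = object$data[, i, ],
    z = object$data[, , i]
  )
  uv <- switch(axis, x = c("y", "z"), y = c("x", "z"), z = c("x", "y"))
  df <- expand.grid(u = ax[[uv[1]]], v = ax[[uv[2]]])
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$value_kind) +
    ggplot2::labs(x = paste0(uv[1], " (mm)"), y = paste0(uv[2], " (mm)"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a temporarily-seeded RNG, restoring global state afterwards
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
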