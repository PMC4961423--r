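#' Read and write voxel volumes
#'
#' Supported formats, chosen by extension: MetaImage (`.mhd` + `.raw`,
#' double precision, bit-exact round trip) and NIfTI (`.nii` / `.nii.gz`
#' via RNifti). Both carry a JSON sidecar (`<file>.json`) with the value
#' kind, origin and generator metadata, written and restored automatically.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path; extension picks the format.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [voxel_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- volume_ext(path)
  switch(ext,
    mhd = write_mhd(volume, path),
    nii = write_nifti_vol(volume, path)
  )
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(value_kind = volume$value_kind, origin = volume$origin,
         spacing = volume$spacing, meta = volume$meta),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- volume_ext(path)
  vol <- switch(ext,
    mhd = read_mhd(path),
    nii = read_nifti_vol(path)
  )
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vol$value_kind <- sc$value_kind %||% vol$value_kind
    if (!is.null(sc$origin)) vol$origin <- as.numeric(sc$origin)
    vol$meta <- sc$meta %||% list()
  }
  vol
}

volume_ext <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mhd$", low)) return("mhd")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nii")
  abort(sprintf(
    "unrecognized volume format for `%s`; supported: .mhd (MetaImage), .nii / .nii.gz (NIfTI).",
    basename(path)))
}

write_mhd <- function(volume, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(volume$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(c(1, 0, 0, 0, 1, 0, 0, 0, 1), collapse = " ")),
    sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
            volume$origin[2], volume$origin[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", volume$spacing[1],
            volume$spacing[2], volume$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  et <- get("ElementType")
  if (!identical(et, "MET_DOUBLE")) {
    abort(sprintf("unsupported MetaImage element type `%s`.", et))
  }
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
  voxel_volume(array(vals, dim = d), spacing = spacing, origin = origin,
               value_kind = "density")
}

write_nifti_vol <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3],
               origin = c(0, 0, 0), value_kind = "density")
}

#' Write and read meshes (legacy VTK unstructured grid)
#'
#' ASCII legacy VTK with hex (type 12) or tet (type 10) cells, optional
#' per-cell and per-node data arrays. VTK itself has no notion of named
#' sets, so node/facet/element sets and landmarks travel in a JSON sidecar
#' (`<file>.sets.json`) that `read_mesh()` restores - the round trip is
#' lossless.
#'
#' @param mesh An [fe_mesh()].
#' @param path Output `.vtk` path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors or n x 3
#'   matrices (written as VECTORS).
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` the
#'   [fe_mesh()] with `attr(, "cell_data")` / `attr(, "point_data")`.
#' @export
write_mesh <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (!grepl("\\.vtk$", tolower(path))) {
    abort("unrecognized mesh format; supported: .vtk (legacy unstructured grid).")
  }
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems); npe <- ncol(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fetlockfe mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    sprintf("%.17g %.17g %.17g", r[1], r[2], r[3])), con)
  writeLines(sprintf("CELLS %d %d", m, m * (npe + 1)), con)
  writeLines(apply(mesh$elems, 1, function(r)
    paste(c(npe, r - 1L), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(if (npe == 8) 12L else 10L, m)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.17g", cell_data[[nm]])), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      if (is.matrix(pd)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(pd, 1, function(r)
          sprintf("%.17g %.17g %.17g", r[1], r[2], r[3])), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default", sprintf("%.17g", pd)), con)
      }
    }
  }
  close(con)
  on.exit()
  jsonlite::write_json(
    list(node_sets = mesh$node_sets, facet_sets = mesh$facet_sets,
         elem_sets = mesh$elem_sets, landmarks = mesh$landmarks,
         facet_regions = as.list(mesh$facet_regions %||% character())),
    paste0(path, ".sets.json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!grepl("\\.vtk$", tolower(path))) {
    abort("unrecognized mesh format; supported: .vtk (legacy unstructured grid).")
  }
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(as.numeric(unlist(strsplit(lines[(ip + 1):(ip + n)],
                                             "\\s+"))), ncol = 3,
                  byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_rows <- strsplit(lines[(ic + 1):(ic + m)], "\\s+")
  npe <- as.integer(cell_rows[[1]][1])
  elems <- matrix(as.integer(unlist(lapply(cell_rows, `[`, -1))) + 1L,
                  ncol = npe, byrow = TRUE)
  elem_type <- if (npe == 8) "hex8" else "tet4"

  cd <- list(); pd <- list()
  icd <- grep("^CELL_DATA", lines)
  ipd <- grep("^POINT_DATA", lines)
  read_arrays <- function(start, stop, count) {
    out <- list()
    i <- start
    while (i <= stop) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1]][2]
        out[[nm]] <- as.numeric(lines[(i + 2):(i + 1 + count)])
        i <- i + 2 + count
      } else if (grepl("^VECTORS", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1]][2]
        out[[nm]] <- matrix(as.numeric(unlist(
          strsplit(lines[(i + 1):(i + count)], "\\s+"))), ncol = 3,
          byrow = TRUE)
        i <- i + 1 + count
      } else i <- i + 1
    }
    out
  }
  if (length(icd)) {
    stop_at <- if (length(ipd)) ipd[1] - 1 else length(lines)
    cd <- read_arrays(icd[1] + 1, stop_at, m)
  }
  if (length(ipd)) pd <- read_arrays(ipd[1] + 1, length(lines), n)

  sets <- list(node_sets = list(), facet_sets = list(), elem_sets = list(),
               landmarks = list())
  sc <- paste0(path, ".sets.json")
  if (file.exists(sc)) {
    sets <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  mesh <- fe_mesh(nodes, elems, elem_type,
                  node_sets = lapply(sets$node_sets, as.integer),
                  facet_sets = lapply(sets$facet_sets, as.integer),
                  elem_sets = lapply(sets$elem_sets, as.integer),
                  landmarks = sets$landmarks)
  if (!is.null(sets$facet_regions) && length(sets$facet_regions)) {
    mesh$facet_regions <- unlist(sets$facet_regions)
  }
  attr(mesh, "cell_data") <- cd
  attr(mesh, "point_data") <- pd
  mesh
}

#' Export an Abaqus-style .inp deck
#'
#' Nodes, elements (C3D8 / C3D4), node sets as `*NSET`, and one `*ELSET` +
#' `*MATERIAL` + `*SOLID SECTION` per material bin. Moduli are binned into
#' at most `max_bins` groups (elements within a bin share the bin-mean
#' modulus), the standard device for CT-mapped bone models; densities are
#' averaged per bin likewise. Write-only interoperability export.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A [material_field()].
#' @param path Output `.inp` path.
#' @param max_bins Maximum number of material groups.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, materials, path, max_bins = 200) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(materials, "material_field"))
  uE <- sort(unique(materials$E))
  if (length(uE) > max_bins) {
    brk <- seq(min(uE), max(uE), length.out = max_bins + 1)
    bin <- findInterval(materials$E, brk, rightmost.closed = TRUE)
  } else {
    bin <- match(materials$E, uE)
  }
  lines <- c("*HEADING", "fetlockfe export (units: mm, MPa, tonne)",
             "*NODE")
  lines <- c(lines, sprintf("%d, %.10g, %.10g, %.10g",
                            seq_len(nrow(mesh$nodes)), mesh$nodes[, 1],
                            mesh$nodes[, 2], mesh$nodes[, 3]))
  etype <- if (mesh$elem_type == "hex8") "C3D8" else "C3D4"
  lines <- c(lines, sprintf("*ELEMENT, TYPE=%s, ELSET=ALL", etype))
  lines <- c(lines, paste0(seq_len(nrow(mesh$elems)), ", ",
                           apply(mesh$elems, 1, paste, collapse = ", ")))
  for (nm in names(mesh$node_sets)) {
    ids <- mesh$node_sets[[nm]]
    if (!length(ids)) next
    lines <- c(lines, sprintf("*NSET, NSET=%s", toupper(nm)),
               chunk16(ids))
  }
  for (b in sort(unique(bin))) {
    sel <- which(bin == b)
    nm <- sprintf("MAT%03d", b)
    lines <- c(lines,
               sprintf("*ELSET, ELSET=E_%s", nm), chunk16(sel),
               sprintf("*MATERIAL, NAME=%s", nm),
               "*ELASTIC",
               sprintf("%.10g, %.4g", mean(materials$E[sel]),
                       materials$nu[sel][1]),
               "*DENSITY",
               sprintf("%.10g", mean(materials$rho[sel]) * GCM3_TO_TMM3),
               sprintf("*SOLID SECTION, ELSET=E_%s, MATERIAL=%s", nm, nm))
  }
  writeLines(lines, path)
  invisible(path)
}

chunk16 <- function(ids) {
  vapply(split(ids, ceiling(seq_along(ids) / 16)),
         function(x) paste(x, collapse = ", "), "")
}
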