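#' Write a mesh to a legacy-VTK file with named point scalars
#'
#' Tetrahedral meshes are written as `UNSTRUCTURED_GRID`, surface meshes as
#' `POLYDATA`. Coordinates and scalar values use full double precision so
#' that a write/read round trip preserves them. Typical scalar arrays are
#' `"signed_error_mm"` overlays and `"lbs_weight_<fragment>"` fields.
#'
#' @param mesh a [tet_mesh] or [surface_mesh].
#' @param path output file path.
#' @param point_scalars named list of numeric vectors, one value per vertex.
#' @param positions optional `n x 3` matrix overriding the mesh's rest
#'   positions (e.g. deformed positions).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_scalars = list(), positions = NULL) {
  if (inherits(mesh, "tet_mesh")) {
    pts <- if (is.null(positions)) mesh$rest_positions else as_coord_matrix(positions, "positions")
    cells <- mesh$tets
    kind <- "tet"
  } else if (inherits(mesh, "surface_mesh")) {
    pts <- if (is.null(positions)) mesh$vertices else as_coord_matrix(positions, "positions")
    cells <- mesh$faces
    kind <- "tri"
  } else {
    stop("mesh must be a tet_mesh or surface_mesh", call. = FALSE)
  }
  if (nrow(pts) != nrow(if (inherits(mesh, "tet_mesh")) mesh$rest_positions else mesh$vertices)) {
    stop("positions must match the mesh vertex count", call. = FALSE)
  }
  if (length(point_scalars) > 0) {
    if (is.null(names(point_scalars)) || any(!nzchar(names(point_scalars)))) {
      stop("point_scalars must be a named list", call. = FALSE)
    }
    nbad <- names(point_scalars)[vapply(point_scalars, length, 1L) != nrow(pts)]
    if (length(nbad) > 0) {
      stop(sprintf("point scalar length mismatch: %s", paste(nbad, collapse = ", ")),
           call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "orthosim output", "ASCII"), con)
  if (kind == "tet") {
    writeLines("DATASET UNSTRUCTURED_GRID", con)
    writeLines(sprintf("POINTS %d double", nrow(pts)), con)
    writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
    writeLines(sprintf("CELLS %d %d", nrow(cells), 5L * nrow(cells)), con)
    writeLines(sprintf("4 %d %d %d %d", cells[, 1] - 1L, cells[, 2] - 1L,
                       cells[, 3] - 1L, cells[, 4] - 1L), con)
    writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
    writeLines(rep("10", nrow(cells)), con)
  } else {
    writeLines("DATASET POLYDATA", con)
    writeLines(sprintf("POINTS %d double", nrow(pts)), con)
    writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(cells), 4L * nrow(cells)), con)
    writeLines(sprintf("3 %d %d %d", cells[, 1] - 1L, cells[, 2] - 1L,
                       cells[, 3] - 1L), con)
  }
  if (length(point_scalars) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_scalars)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(sprintf("%.17g", as.numeric(point_scalars[[nm]])), con)
    }
  }
  invisible(path)
}

#' Read a legacy-VTK file written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `mesh` (a [tet_mesh] or [surface_mesh]) and
#'   `point_scalars` (named list).
#' @export
read_vtk <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ipts <- grep("^POINTS", lines)[1]
  if (is.na(ipts)) stop("VTK parse error: no POINTS block", call. = FALSE)
  npts <- as.integer(toks[[ipts]][2])
  pts <- matrix(as.numeric(unlist(toks[(ipts + 1):(ipts + npts)])),
                npts, 3, byrow = TRUE)
  is_grid <- any(grepl("UNSTRUCTURED_GRID", lines))
  if (is_grid) {
    ic <- grep("^CELLS", lines)[1]
    ncell <- as.integer(toks[[ic]][2])
    cells <- matrix(as.integer(unlist(toks[(ic + 1):(ic + ncell)])),
                    ncell, 5, byrow = TRUE)[, 2:5, drop = FALSE] + 1L
    mesh <- tet_mesh(pts, cells)
  } else {
    ic <- grep("^POLYGONS", lines)[1]
    ncell <- as.integer(toks[[ic]][2])
    cells <- matrix(as.integer(unlist(toks[(ic + 1):(ic + ncell)])),
                    ncell, 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
    mesh <- surface_mesh(pts, cells)
  }
  scalars <- list()
  isc <- grep("^SCALARS", lines)
  for (k in isc) {
    nm <- toks[[k]][2]
    vals <- as.numeric(unlist(toks[(k + 2):(k + 1 + npts)]))
    scalars[[nm]] <- vals
  }
  list(mesh = mesh, point_scalars = scalars)
}
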