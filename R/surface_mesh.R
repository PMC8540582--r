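#' Triangle surface mesh
#'
#' A triangle mesh in millimetres: an `n x 3` vertex matrix and an `m x 3`
#' integer face matrix (1-based vertex indices, counter-clockwise orientation
#' for outward normals). Optional integer face-group labels partition the
#' faces, e.g. into per-bone-fragment coupling groups.
#'
#' @param vertices numeric matrix `n x 3` (mm).
#' @param faces integer matrix `m x 3` of vertex indices (1-based).
#' @param face_groups optional integer/character vector of length `m`.
#' @param validate check index ranges and degeneracy (default `TRUE`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, face_groups = NULL, validate = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  faces <- as_index_matrix(faces, 3L, "faces")
  if (!is.null(face_groups) && length(face_groups) != nrow(faces)) {
    stop("face_groups must have one entry per face", call. = FALSE)
  }
  if (validate) {
    if (nrow(faces) > 0) {
      bad <- which(faces < 1L | faces > nrow(vertices), arr.ind = TRUE)
      if (length(bad) > 0) {
        stop(sprintf("face indices out of range in faces: %s",
                     paste(unique(bad[, 1]), collapse = ", ")), call. = FALSE)
      }
      degen <- which(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
                       faces[, 1] == faces[, 3])
      if (length(degen) > 0) {
        stop(sprintf("degenerate faces (repeated vertex): %s",
                     paste(degen, collapse = ", ")), call. = FALSE)
      }
    }
  }
  structure(list(vertices = vertices, faces = faces, face_groups = face_groups),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$face_groups))
                sprintf(", %d face groups", length(unique(x$face_groups)))
              else ""))
  invisible(x)
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

as_index_matrix <- function(x, k, what) {
  x <- as.matrix(x)
  if (nrow(x) == 0) x <- matrix(integer(0), 0, k)
  if (ncol(x) != k) stop(sprintf("%s must have %d columns", what, k), call. = FALSE)
  storage.mode(x) <- "integer"
  dimnames(x) <- NULL
  x
}

#' Per-face areas, normals and centroids
#'
#' @param mesh a [surface_mesh].
#' @return `face_areas`: numeric vector (mm^2); `face_normals`: `m x 3` unit
#'   normals; `face_centroids`: `m x 3` matrix (mm).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(e1, e2)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(e1, e2)
  nrm <- sqrt(rowSums(cr^2))
  cr / pmax(nrm, .Machine$double.xmin)
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Area-weighted vertex normals and one-third vertex areas
#'
#' Vertex areas assign each vertex one third of the area of its incident
#' faces; this is the weighting used for "percentage of the surface" error
#' summaries.
#'
#' @param mesh a [surface_mesh].
#' @return `vertex_normals`: `n x 3` unit normals; `vertex_areas`: numeric
#'   vector of length `n` (mm^2).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(e1, e2)  # area-weighted face normal
  nrm <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      nrm[, k] <- nrm[, k] + tabulate2(f[, j], cr[, k], nrow(v))
    }
  }
  len <- sqrt(rowSums(nrm^2))
  nrm / pmax(len, .Machine$double.xmin)
}

#' @rdname vertex_normals
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  out <- numeric(nrow(mesh$vertices))
  for (j in 1:3) out <- out + tabulate2(mesh$faces[, j], fa / 3, nrow(mesh$vertices))
  out
}

tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Is a surface closed and consistently oriented?
#'
#' A mesh is closed when every undirected edge is shared by exactly two faces
#' with opposite directed orientation.
#'
#' @param mesh a [surface_mesh].
#' @return logical scalar.
#' @export
is_closed_surface <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2L)) return(FALSE)
  dkey <- paste(he[, 1], he[, 2])
  !any(duplicated(dkey))  # each directed edge once => opposite orientations
}

#' Volume and centroid of a closed surface
#'
#' Divergence-theorem integrals over an outward-oriented closed triangle
#' mesh; the centroid assumes uniform density and is used as the rigid
#' fragment's center of mass.
#'
#' @param mesh a closed [surface_mesh].
#' @return list with `volume` (mm^3, signed; positive for outward
#'   orientation) and `centroid` (3-vector, mm).
#' @export
surface_volume_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  dets <- rowSums(a * cross3(b, c3))
  vol <- sum(dets) / 6
  cen <- colSums((dets / 6) * (a + b + c3) / 4) / vol
  list(volume = vol, centroid = cen)
}

#' Axis-aligned box surface
#'
#' A closed, outward-oriented 12-triangle box, handy as a rigid obstacle or
#' test fixture.
#'
#' @param min,max opposite box corners (3-vectors, mm).
#' @return a [surface_mesh].
#' @export
box_surface <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  lo <- as.numeric(min); hi <- as.numeric(max)
  v <- rbind(c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
             c(hi[1], hi[2], lo[3]), c(lo[1], hi[2], lo[3]),
             c(lo[1], lo[2], hi[3]), c(hi[1], lo[2], hi[3]),
             c(hi[1], hi[2], hi[3]), c(lo[1], hi[2], hi[3]))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),  # bottom (z = lo)
             c(5, 6, 7), c(5, 7, 8),  # top
             c(1, 2, 6), c(1, 6, 5),  # y = lo
             c(2, 3, 7), c(2, 7, 6),  # x = hi
             c(3, 4, 8), c(3, 8, 7),  # y = hi
             c(4, 1, 5), c(4, 5, 8))  # x = lo
  surface_mesh(v, f)
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tol` (on a rounded-coordinate lattice) and
#' reindexes faces; faces that degenerate after welding are dropped.
#'
#' @param mesh a [surface_mesh].
#' @param tol welding tolerance in mm (default `1e-6`).
#' @return a [surface_mesh].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  surface_mesh(newv, newf[keep, , drop = FALSE],
               face_groups = mesh$face_groups[keep])
}
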