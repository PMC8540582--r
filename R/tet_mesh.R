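#' Tetrahedral volume mesh with precomputed element quantities
#'
#' Stores rest nodal positions `X` (mm), the `ne x 4` connectivity, and the
#' per-element quantities needed for linear-tetrahedron FEM with one
#' quadrature point per element: the inverse rest edge matrix (which yields
#' the shape-function derivatives) and the rest volume as quadrature weight.
#' Tets are reoriented to positive signed volume
#' (`dot(cross(b - a, c - a), d - a) > 0`) by swapping the last two indices.
#'
#' @param rest_positions numeric `n x 3` matrix of rest positions (mm).
#' @param tets integer `ne x 4` matrix of node indices (1-based).
#' @param min_volume tets below this volume (mm^3) are rejected (default `1e-9`).
#' @return An object of class `tet_mesh` with fields `rest_positions`, `tets`,
#'   `element_basis` (3 x 3 x ne array of inverse rest edge matrices),
#'   `quadrature_weights` (rest volumes, mm^3) and `boundary_surface` (a
#'   [surface_mesh] over the same node array whose faces are exactly the tet
#'   faces incident to one tet, outward-oriented).
#' @export
tet_mesh <- function(rest_positions, tets, min_volume = 1e-9) {
  X <- as_coord_matrix(rest_positions, "rest_positions")
  tets <- as_index_matrix(tets, 4L, "tets")
  if (nrow(tets) == 0) stop("tet mesh has no elements", call. = FALSE)
  if (any(tets < 1L | tets > nrow(X))) {
    stop("tet indices out of range", call. = FALSE)
  }
  vol <- tet_volumes(X, tets)
  flip <- which(vol < 0)
  if (length(flip) > 0) {
    tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
    vol <- abs(vol)
  }
  small <- which(vol < min_volume)
  if (length(small) > 0) {
    stop(sprintf("zero-volume tets (|v| < %g mm^3): %s", min_volume,
                 paste(head(small, 10), collapse = ", ")), call. = FALSE)
  }
  ne <- nrow(tets)
  basis <- array(0, c(3, 3, ne))
  for (e in seq_len(ne)) {
    Dm <- t(X[tets[e, 2:4], , drop = FALSE]) - X[tets[e, 1], ]
    basis[, , e] <- solve(Dm)
  }
  structure(list(rest_positions = X, tets = tets, element_basis = basis,
                 quadrature_weights = vol,
                 boundary_surface = extract_boundary(X, tets)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, volume %.6g mm^3\n",
              nrow(x$rest_positions), nrow(x$tets), sum(x$quadrature_weights)))
  invisible(x)
}

tet_volumes <- function(X, tets) {
  a <- X[tets[, 1], , drop = FALSE]
  b <- X[tets[, 2], , drop = FALSE] - a
  c3 <- X[tets[, 3], , drop = FALSE] - a
  d <- X[tets[, 4], , drop = FALSE] - a
  rowSums(cross3(b, c3) * d) / 6
}

# Outward-oriented boundary faces of a positively oriented tet mesh: the four
# faces of tet (a,b,c,d) are (a,c,b), (a,b,d), (a,d,c), (b,c,d); boundary
# faces appear in exactly one tet.
extract_boundary <- function(X, tets) {
  fa <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
              tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
  key <- paste(pmin(fa[, 1], pmin(fa[, 2], fa[, 3])),
               fa[, 1] + fa[, 2] + fa[, 3],
               pmax(fa[, 1], pmax(fa[, 2], fa[, 3])))
  counts <- table(key)
  once <- names(counts)[counts == 1L]
  surface_mesh(X, fa[key %in% once, , drop = FALSE], validate = FALSE)
}

#' Read a tetrahedral mesh in TetGen .node/.ele format
#'
#' Accepts 0- or 1-based files (the base is taken from the first node index,
#' as the mesher writes it); `#` comments are ignored.
#'
#' @param node_path path to the `.node` file.
#' @param ele_path path to the `.ele` file.
#' @return a [tet_mesh].
#' @export
read_tet_mesh <- function(node_path, ele_path) {
  nl <- read_numeric_records(node_path)
  if (length(nl) < 1) stop(sprintf("missing header in %s", node_path), call. = FALSE)
  hdr <- nl[[1]]
  npt <- as.integer(hdr[1])
  if (is.na(npt) || length(hdr) < 2 || hdr[2] != 3) {
    stop(sprintf("bad .node header in %s (need '<n> 3 ...')", node_path), call. = FALSE)
  }
  if (length(nl) < npt + 1) stop(sprintf("truncated .node file %s", node_path), call. = FALSE)
  recs <- do.call(rbind, nl[2:(npt + 1)])
  base <- as.integer(recs[1, 1])
  if (!base %in% c(0L, 1L)) stop(sprintf("node indices must start at 0 or 1 in %s", node_path), call. = FALSE)
  idx <- as.integer(recs[, 1])
  if (!identical(sort(idx), seq.int(base, base + npt - 1L))) {
    stop(sprintf("non-contiguous or mixed-base node indices in %s", node_path), call. = FALSE)
  }
  X <- matrix(NA_real_, npt, 3)
  X[idx - base + 1L, ] <- recs[, 2:4]

  el <- read_numeric_records(ele_path)
  if (length(el) < 1) stop(sprintf("missing header in %s", ele_path), call. = FALSE)
  eh <- el[[1]]
  nte <- as.integer(eh[1])
  if (is.na(nte) || length(eh) < 2 || eh[2] != 4) {
    stop(sprintf("bad .ele header in %s (need '<n> 4 ...')", ele_path), call. = FALSE)
  }
  if (length(el) < nte + 1) stop(sprintf("truncated .ele file %s", ele_path), call. = FALSE)
  erecs <- do.call(rbind, el[2:(nte + 1)])
  conn <- matrix(as.integer(erecs[, 2:5]), ncol = 4)
  if (any(conn < base) || any(conn > base + npt - 1L)) {
    stop(sprintf("element node index out of range in %s (mixed index base?)", ele_path), call. = FALSE)
  }
  tet_mesh(X, conn - base + 1L)
}

read_numeric_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
}

#' Write a tetrahedral mesh in TetGen .node/.ele format (1-based)
#'
#' @param mesh a [tet_mesh].
#' @param node_path,ele_path output paths.
#' @return `node_path`, invisibly.
#' @export
write_tet_mesh <- function(mesh, node_path, ele_path) {
  X <- mesh$rest_positions
  n <- nrow(X)
  writeLines(c(sprintf("%d 3 0 0", n),
               sprintf("%d %.17g %.17g %.17g", seq_len(n), X[, 1], X[, 2], X[, 3])),
             node_path)
  tt <- mesh$tets
  writeLines(c(sprintf("%d 4 0", nrow(tt)),
               sprintf("%d %d %d %d %d", seq_len(nrow(tt)),
                       tt[, 1], tt[, 2], tt[, 3], tt[, 4])),
             ele_path)
  invisible(node_path)
}
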