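#' Voxelized signed distance field of a closed surface
#'
#' Samples the signed closest-point distance on a regular grid over the
#' surface's bounding box (plus padding) for trilinear interpolation during
#' contact detection. Negative values are inside.
#'
#' @param surface a closed [surface_mesh].
#' @param resolution_mm grid spacing in mm (default 1).
#' @param padding_mm extra margin around the bounding box (default
#'   `2 * resolution_mm`).
#' @return An object of class `sdf_grid`.
#' @export
sdf_grid <- function(surface, resolution_mm = 1, padding_mm = NULL) {
  if (!is_closed_surface(surface)) {
    stop("obstacle surface must be closed for signed distance contact", call. = FALSE)
  }
  if (is.null(padding_mm)) padding_mm <- 2 * resolution_mm
  lo <- apply(surface$vertices, 2, min) - padding_mm
  hi <- apply(surface$vertices, 2, max) + padding_mm
  nx <- pmax(2L, as.integer(ceiling((hi - lo) / resolution_mm)) + 1L)
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], length.out = nx[k]))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- signed_distance_query(pts, surface)
  structure(list(values = array(vals, nx), origin = lo,
                 spacing = vapply(1:3, function(k) ax[[k]][2] - ax[[k]][1], 0),
                 dims = nx, surface = surface),
            class = "sdf_grid")
}

#' Evaluate an SDF grid (trilinear) and its gradient
#'
#' Points outside the grid return the distance from the box plus the largest
#' stored value (always positive, so they never register contact).
#'
#' @param grid an [sdf_grid].
#' @param points `k x 3` matrix (mm).
#' @return `sdf_eval`: numeric vector; `sdf_gradient`: `k x 3` matrix of the
#'   trilinear field's gradient (not normalized).
#' @export
sdf_eval <- function(grid, points) {
  sdf_interp(grid, points)$value
}

#' @rdname sdf_eval
#' @export
sdf_gradient <- function(grid, points) {
  sdf_interp(grid, points)$gradient
}

sdf_interp <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  k <- nrow(points)
  val <- numeric(k)
  grd <- matrix(0, k, 3)
  dm <- grid$dims
  for (q in seq_len(k)) {
    u <- (points[q, ] - grid$origin) / grid$spacing
    if (any(u < 0) || any(u > dm - 1)) {
      # outside the sampled box: report a safely positive value
      uc <- pmin(pmax(u, 0), dm - 1)
      off <- sqrt(sum(((u - uc) * grid$spacing)^2))
      val[q] <- off + max(grid$values)
      dirv <- (u - uc) * grid$spacing
      grd[q, ] <- if (off > 0) dirv / off else c(0, 0, 1)
      next
    }
    i0 <- pmin(floor(u), dm - 2)
    tt <- u - i0
    i0 <- as.integer(i0) + 1L
    c000 <- grid$values[i0[1], i0[2], i0[3]]
    c100 <- grid$values[i0[1] + 1, i0[2], i0[3]]
    c010 <- grid$values[i0[1], i0[2] + 1, i0[3]]
    c110 <- grid$values[i0[1] + 1, i0[2] + 1, i0[3]]
    c001 <- grid$values[i0[1], i0[2], i0[3] + 1]
    c101 <- grid$values[i0[1] + 1, i0[2], i0[3] + 1]
    c011 <- grid$values[i0[1], i0[2] + 1, i0[3] + 1]
    c111 <- grid$values[i0[1] + 1, i0[2] + 1, i0[3] + 1]
    tx <- tt[1]; ty <- tt[2]; tz <- tt[3]
    c00 <- c000 * (1 - tx) + c100 * tx
    c10 <- c010 * (1 - tx) + c110 * tx
    c01 <- c001 * (1 - tx) + c101 * tx
    c11 <- c011 * (1 - tx) + c111 * tx
    c0 <- c00 * (1 - ty) + c10 * ty
    c1 <- c01 * (1 - ty) + c11 * ty
    val[q] <- c0 * (1 - tz) + c1 * tz
    dx <- ((c100 - c000) * (1 - ty) + (c110 - c010) * ty) * (1 - tz) +
      ((c101 - c001) * (1 - ty) + (c111 - c011) * ty) * tz
    dy <- ((c10 - c00) * (1 - tz) + (c11 - c01) * tz)
    dz <- (c1 - c0)
    grd[q, ] <- c(dx, dy, dz) / grid$spacing
  }
  list(value = val, gradient = grd)
}

#' Detect penetrating contacts between soft surface vertices and obstacles
#'
#' One-sided activation: a soft surface vertex generates a contact pair only
#' when its signed distance to an obstacle is strictly negative. The witness
#' point is the exact closest point on the obstacle surface, the normal the
#' (normalized) SDF gradient. The pairs are assembled into the linear contact
#' map: point matrix `B` selecting the penetrating vertices' DoFs, offset `d`
#' holding the (fixed) witness points, and normal matrix `U`.
#'
#' @param positions deformed positions of the soft surface vertices
#'   (`k x 3` matrix).
#' @param vertex_ids node indices of those vertices in the simulation mesh.
#' @param obstacles list of closed [surface_mesh] at their current poses,
#'   or of [rigid_fragment]s (posed surfaces are taken).
#' @param n_dofs total soft DoF count of the system.
#' @param stiffness uniform penalty stiffness `k` (default `1e4`).
#' @param sdf_resolution_mm SDF grid spacing (default 1).
#' @param grids optional precomputed list of [sdf_grid] (one per obstacle),
#'   reused across Newton iterations within a substep.
#' @return An object of class `contact_set` with `pairs` (data frame),
#'   sparse `B` (`3p x n_dofs`), `d` (`3p`), `U` (`3p x p`) and `stiffness`.
#' @export
detect_contacts <- function(positions, vertex_ids, obstacles, n_dofs,
                            stiffness = 1e4, sdf_resolution_mm = 1,
                            grids = NULL) {
  positions <- as_coord_matrix(positions, "positions")
  obstacles <- lapply(obstacles, function(o) {
    if (inherits(o, "rigid_fragment")) fragment_posed_surface(o) else o
  })
  if (is.null(grids)) {
    grids <- lapply(obstacles, sdf_grid, resolution_mm = sdf_resolution_mm)
  }
  rows <- list()
  for (ob in seq_along(obstacles)) {
    phi <- sdf_interp(grids[[ob]], positions)
    pen <- which(phi$value < 0)
    if (length(pen) == 0) next
    cp <- closest_surface_points(positions[pen, , drop = FALSE], obstacles[[ob]])
    nrm <- phi$gradient[pen, , drop = FALSE]
    len <- sqrt(rowSums(nrm^2))
    # degenerate gradient: fall back to the closest-point direction (outward)
    fallback <- len < 1e-12
    if (any(fallback)) {
      dir <- positions[pen, , drop = FALSE] - cp$point
      dl <- sqrt(rowSums(dir^2))
      nrm[fallback, ] <- -dir[fallback, , drop = FALSE] / pmax(dl[fallback], 1e-300)
      len[fallback] <- 1
    }
    nrm <- nrm / len
    rows[[length(rows) + 1L]] <- data.frame(
      node = vertex_ids[pen], obstacle = ob, gap = phi$value[pen],
      wx = cp$point[, 1], wy = cp$point[, 2], wz = cp$point[, 3],
      nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), obstacle = integer(0), gap = numeric(0),
               wx = numeric(0), wy = numeric(0), wz = numeric(0),
               nx = numeric(0), ny = numeric(0), nz = numeric(0))
  p <- nrow(pairs)
  if (p > 0) {
    B <- Matrix::sparseMatrix(i = seq_len(3 * p), j = node_dofs(pairs$node),
                              x = 1, dims = c(3 * p, n_dofs))
    d <- -as.numeric(t(as.matrix(pairs[, c("wx", "wy", "wz")])))
    U <- Matrix::sparseMatrix(i = seq_len(3 * p),
                              j = rep(seq_len(p), each = 3),
                              x = as.numeric(t(as.matrix(pairs[, c("nx", "ny", "nz")]))),
                              dims = c(3 * p, p))
  } else {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, n_dofs))
    d <- numeric(0)
    U <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 0))
  }
  structure(list(pairs = pairs, B = B, d = d, U = U, stiffness = stiffness),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d pairs, k = %g\n", nrow(x$pairs), x$stiffness))
  invisible(x)
}

#' Quadratic penalty contact energy
#'
#' `V = 1/2 k |U'(B x + d)|^2` over the active pairs, with gradient
#' `k B'U U'(B x + d)` and constant positive-semidefinite Hessian
#' `k B'U U'B`. The contact set (B, d, U) is held fixed within a Newton
#' iterate so the energy is a true quadratic there.
#'
#' @param contacts a [contact_set].
#' @param x full soft DoF vector.
#' @return list with `energy`, `gradient` (length `n_dofs`) and sparse
#'   `hessian`.
#' @export
contact_energy <- function(contacts, x) {
  n <- ncol(contacts$B)
  if (nrow(contacts$pairs) == 0) {
    return(list(energy = 0, gradient = numeric(n),
                hessian = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0), dims = c(n, n))))
  }
  k <- contacts$stiffness
  viol <- as.numeric(Matrix::t(contacts$U) %*% (contacts$B %*% x + contacts$d))
  BtU <- Matrix::t(contacts$B) %*% contacts$U
  list(energy = 0.5 * k * sum(viol^2),
       gradient = k * as.numeric(BtU %*% viol),
       hessian = k * (BtU %*% Matrix::t(BtU)))
}
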