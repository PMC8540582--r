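#' Specification of a synthetic slab-and-block scene
#'
#' Describes a rectangular soft-tissue slab with embedded rigid bone blocks,
#' optional cut planes splitting blocks into fragments, a fixed outer face,
#' and optional seeded interior-vertex jitter. These scenes emulate the
#' matched tissue-bone interface meshing of a prepared surgical scene (the
#' tissue void walls and the block surfaces share vertices exactly), so
#' coupling assignment is unambiguous.
#'
#' @param dims slab dimensions `(Lx, Ly, Lz)` in mm.
#' @param resolution grid cells per axis (3 integers, each >= 2).
#' @param blocks list of axis-aligned boxes, each `list(min = c(...), max =
#'   c(...))` in mm; snapped to grid planes and required to be strictly
#'   inside the slab.
#' @param cuts list of cut planes, each `list(block = i, point = c(...),
#'   normal = c(...))`; every cut must intersect its block.
#' @param fixed_face which outer slab face is pinned: one of `"xmin"`,
#'   `"xmax"`, `"ymin"`, `"ymax"`, `"zmin"`, `"zmax"`, or `"none"`.
#' @param jitter interior-vertex jitter amplitude as a fraction of the cell
#'   size, in `[0, 0.2]` (default 0).
#' @param seed integer seed for the jitter (default 1).
#' @return An object of class `fixture_spec`.
#' @export
slab_spec <- function(dims = c(40, 20, 12), resolution = c(10, 5, 3),
                      blocks = list(), cuts = list(), fixed_face = "zmax",
                      jitter = 0, seed = 1L) {
  dims <- as.numeric(dims)
  resolution <- as.integer(resolution)
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("dims must be 3 positive lengths (mm)", call. = FALSE)
  }
  if (length(resolution) != 3 || any(resolution < 2L)) {
    stop("resolution must be >= 2 cells per axis", call. = FALSE)
  }
  fixed_face <- match.arg(fixed_face,
                          c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax", "none"))
  if (!is.finite(jitter) || jitter < 0 || jitter > 0.2) {
    stop("jitter must lie in [0, 0.2] (fraction of cell size)", call. = FALSE)
  }
  structure(list(dims = dims, resolution = resolution, blocks = blocks,
                 cuts = cuts, fixed_face = fixed_face, jitter = jitter,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# 5-tet decomposition of the hex cell (i,j,k), parity-alternating so that
# neighboring cells share face diagonals conformally. Corner order:
# v0..v7 = (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).
hex_to_tets <- function(corners, parity_even) {
  if (parity_even) {
    rbind(corners[c(1, 2, 3, 6)], corners[c(1, 3, 4, 8)],
          corners[c(1, 6, 8, 5)], corners[c(3, 8, 6, 7)],
          corners[c(1, 3, 8, 6)])
  } else {
    rbind(corners[c(2, 1, 4, 5)], corners[c(2, 4, 3, 7)],
          corners[c(2, 5, 7, 6)], corners[c(4, 7, 5, 8)],
          corners[c(2, 4, 7, 5)])
  }
}

#' Generate a slab-and-block scene
#'
#' Builds a structured tetrahedral slab (each grid hex split into 5 tets)
#' with bone-block voids whose walls are shared vertex-for-vertex with the
#' rigid fragment surfaces, assigns interface face groups, computes the
#' smooth-coupling weight field, and assembles the coupling system. Cut
#' planes split blocks into separate fragments named `block<i>_a` /
#' `block<i>_b` (by the sign of the centroid against the cut normal); an
#' uncut block is the single fragment `block<i>`.
#'
#' @param spec a [slab_spec].
#' @param mat a [material] (default `material()`).
#' @param ramp_mm smooth-coupling ramp (default 10).
#' @return An object of class `sim_scene`: `mesh` ([tet_mesh]), `material`,
#'   `fragments` (named list of [rigid_fragment]), `interface`
#'   ([surface_mesh] indexed into the volume mesh), `assignment`,
#'   `weight_field`, `fixed_nodes`, `coupling` ([coupling_system]),
#'   `contact` (`NULL` by default), `spec`.
#' @export
make_slab_scene <- function(spec, mat = material(), ramp_mm = 10) {
  stopifnot(inherits(spec, "fixture_spec"))
  nxyz <- spec$resolution
  cell <- spec$dims / nxyz
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  gx <- (0:nx) * cell[1]; gy <- (0:ny) * cell[2]; gz <- (0:nz) * cell[3]
  grid_pts <- as.matrix(expand.grid(gx, gy, gz))
  dimnames(grid_pts) <- NULL

  # snap blocks to grid cell ranges; cell (i,j,k) spans [i-1,i] x ...
  cell_block <- array(0L, c(nx, ny, nz))
  block_rng <- list()
  for (bidx in seq_along(spec$blocks)) {
    b <- spec$blocks[[bidx]]
    lo <- pmax(1L, as.integer(round(b$min / cell)) + 1L)
    hi <- pmin(c(nx, ny, nz), as.integer(round(b$max / cell)))
    if (any(hi < lo)) stop(sprintf("block %d snaps to an empty cell range", bidx), call. = FALSE)
    if (any(lo <= 1L) || any(hi >= c(nx, ny, nz))) {
      stop(sprintf("block %d must be strictly inside the slab (one cell margin)", bidx),
           call. = FALSE)
    }
    if (any(cell_block[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] != 0L)) {
      stop(sprintf("block %d overlaps another block", bidx), call. = FALSE)
    }
    cell_block[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- bidx
    block_rng[[bidx]] <- list(lo = lo, hi = hi)
  }

  # tets per cell
  tissue_tets <- list()
  frag_tets <- list()  # keyed by fragment id
  cut_of_block <- rep(NA_integer_, length(spec$blocks))
  for (ci in seq_along(spec$cuts)) {
    cu <- spec$cuts[[ci]]
    if (is.null(cu$block) || cu$block < 1 || cu$block > length(spec$blocks)) {
      stop(sprintf("cut %d names an unknown block", ci), call. = FALSE)
    }
    if (!is.na(cut_of_block[cu$block])) {
      stop(sprintf("block %d has more than one cut (one cut per block supported)",
                   cu$block), call. = FALSE)
    }
    cut_of_block[cu$block] <- ci
  }
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    corners <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                 nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
    tt <- hex_to_tets(corners, (i + j + k) %% 2L == 0L)
    bid <- cell_block[i, j, k]
    if (bid == 0L) {
      tissue_tets[[length(tissue_tets) + 1L]] <- tt
    } else {
      ci <- cut_of_block[bid]
      fid <- sprintf("block%d", bid)
      if (!is.na(ci)) {
        cen <- (c(gx[i], gy[j], gz[k]) + c(gx[i + 1], gy[j + 1], gz[k + 1])) / 2
        cu <- spec$cuts[[ci]]
        side <- sum((cen - cu$point) * cu$normal)
        fid <- sprintf("block%d_%s", bid, if (side <= 0) "a" else "b")
      }
      if (is.null(frag_tets[[fid]])) frag_tets[[fid]] <- list()
      frag_tets[[fid]][[length(frag_tets[[fid]]) + 1L]] <- tt
    }
  }
  for (bidx in seq_along(spec$blocks)) {
    ci <- cut_of_block[bidx]
    if (!is.na(ci)) {
      have <- sum(startsWith(names(frag_tets), sprintf("block%d_", bidx)))
      if (have < 2) {
        stop(sprintf("cut %d does not intersect block %d (all cells on one side)",
                     ci, bidx), call. = FALSE)
      }
    }
  }
  if (length(tissue_tets) == 0) stop("no tissue cells remain", call. = FALSE)

  tt_all <- do.call(rbind, tissue_tets)
  used <- sort(unique(as.vector(tt_all)))
  remap <- integer(nrow(grid_pts))
  remap[used] <- seq_along(used)
  X <- grid_pts[used, , drop = FALSE]
  conn <- matrix(remap[tt_all], ncol = 4)
  flipc <- tet_volumes(X, conn) < 0
  conn[flipc, c(3, 4)] <- conn[flipc, c(4, 3)]

  # jitter strictly interior tissue nodes (never boundary/interface nodes)
  if (spec$jitter > 0) {
    pre <- tet_mesh(X, conn)
    bnodes <- unique(as.vector(pre$boundary_surface$faces))
    interior <- setdiff(seq_len(nrow(X)), bnodes)
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    X[interior, ] <- X[interior, ] +
      matrix(runif(3 * length(interior), -1, 1), ncol = 3) *
      rep(spec$jitter * cell, each = length(interior))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    vol <- tet_volumes(X, conn)
    if (any(vol <= 1e-9)) {
      stop("jitter inverted tetrahedra; reduce the jitter amplitude", call. = FALSE)
    }
  }
  mesh <- tet_mesh(X, conn)

  # fragment surfaces: boundary of each block-cell tet set, compacted
  fragments <- list()
  for (fid in sort(names(frag_tets))) {
    ft <- do.call(rbind, frag_tets[[fid]])
    flip <- tet_volumes(grid_pts, ft) < 0
    ft[flip, c(3, 4)] <- ft[flip, c(4, 3)]
    surf <- extract_boundary(grid_pts, ft)
    fused <- sort(unique(as.vector(surf$faces)))
    fremap <- integer(nrow(grid_pts))
    fremap[fused] <- seq_along(fused)
    fsurf <- surface_mesh(grid_pts[fused, , drop = FALSE],
                          matrix(fremap[surf$faces], ncol = 3))
    fragments[[fid]] <- rigid_fragment(fid, fsurf)
  }

  # interface faces: tissue boundary faces not on an outer slab plane
  bs <- mesh$boundary_surface
  on_plane <- function(vals, target) abs(vals - target) < 1e-9
  outer_face <- rep(FALSE, nrow(bs$faces))
  for (ax in 1:3) for (tg in c(0, spec$dims[ax])) {
    vx <- matrix(X[bs$faces, ax], ncol = 3)
    outer_face <- outer_face | (on_plane(vx[, 1], tg) & on_plane(vx[, 2], tg) &
                                  on_plane(vx[, 3], tg))
  }
  interface <- surface_mesh(X, bs$faces[!outer_face, , drop = FALSE],
                            validate = FALSE)

  fixed_nodes <- integer(0)
  if (spec$fixed_face != "none") {
    ax <- match(substr(spec$fixed_face, 1, 1), c("x", "y", "z"))
    tg <- if (endsWith(spec$fixed_face, "min")) 0 else spec$dims[ax]
    fixed_nodes <- which(on_plane(X[, ax], tg))
  }

  assignment <- NULL
  weights <- NULL
  if (length(fragments) > 0 && nrow(interface$faces) > 0) {
    assignment <- assign_face_groups(interface, fragments)
    weights <- lbs_weight_field(assignment, interface, ramp_mm = ramp_mm)
  }
  coupling <- build_coupling(mesh, fixed_nodes, weights, fragments)
  structure(list(mesh = mesh, material = mat, fragments = fragments,
                 interface = interface, assignment = assignment,
                 weight_field = weights, fixed_nodes = fixed_nodes,
                 coupling = coupling, contact = NULL, f_ext = NULL,
                 spec = spec, ramp_mm = ramp_mm),
            class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("sim_scene: %d tets, %d fragments (%s), %d fixed nodes, %d coupled nodes\n",
              nrow(x$mesh$tets), length(x$fragments),
              paste(names(x$fragments), collapse = ", "),
              length(x$fixed_nodes),
              if (is.null(x$weight_field)) 0L else length(x$weight_field$node_ids)))
  invisible(x)
}

#' Build a substepped advancement plan for one fragment
#'
#' The target transform rotates by `rotate_deg` about `rotate_axis` through
#' the fragment's center of mass, then advances by `advance_mm`. All other
#' fragments receive identity trajectories.
#'
#' @param scene a `sim_scene`.
#' @param fragment_id which fragment moves.
#' @param advance_mm translation 3-vector (mm).
#' @param rotate_deg rotation angle in degrees (default 0).
#' @param rotate_axis rotation axis (default z).
#' @param substeps number of substeps (default 10).
#' @return list of [make_trajectory()] results, one per fragment.
#' @export
make_advance_plan <- function(scene, fragment_id, advance_mm,
                              rotate_deg = 0, rotate_axis = c(0, 0, 1),
                              substeps = 10L) {
  ids <- names(scene$fragments)
  if (!fragment_id %in% ids) {
    stop(sprintf("unknown fragment '%s' (have: %s)", fragment_id,
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  advance_mm <- as.numeric(advance_mm)
  axis <- as.numeric(rotate_axis)
  axis <- axis / sqrt(sum(axis^2))
  R <- axis_angle_matrix(axis * rotate_deg * pi / 180)
  com <- scene$fragments[[fragment_id]]$com_rest
  target <- rigid_transform(R, com - as.numeric(R %*% com) + advance_mm)
  lapply(ids, function(id) {
    tgt <- if (id == fragment_id) target else rigid_transform()
    make_trajectory(scene$fragments[[id]], tgt, substeps)
  })
}
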