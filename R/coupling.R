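#' Assign interface faces to bone fragments
#'
#' After a bone is cut, the bonded region of the soft-tissue interface must
#' be split into one face group per fragment. Each face is labeled with the
#' fragment whose surface is nearest to the face centroid (ties broken by
#' lexicographically smallest fragment id); vertices incident to faces of
#' two or more labels are the cut-interface vertices, which seed the smooth
#' coupling weights.
#'
#' The interface mesh must share the volume mesh's vertex array (its faces
#' index tissue nodes), as produced by the matched tissue-bone meshing of the
#' scene fixtures.
#'
#' @param interface a [surface_mesh] of bonded tissue faces, vertex-indexed
#'   into the simulation mesh.
#' @param fragments list of [rigid_fragment] (rest pose).
#' @param tie_tol distances within this tolerance (mm) count as ties
#'   (default `1e-9`).
#' @return An object of class `face_group_assignment`: `coupled_faces`
#'   (face indices), `fragment_of_face` (character per face),
#'   `cut_interface_vertices` (vertex indices), `fragment_ids`.
#' @export
assign_face_groups <- function(interface, fragments, tie_tol = 1e-9) {
  if (length(fragments) == 0) stop("fragment list is empty", call. = FALSE)
  ids <- vapply(fragments, function(f) f$id, "")
  ord <- order(ids)  # lexicographic tie-break: evaluate in id order
  cen <- face_centroids(interface)
  dmat <- matrix(Inf, nrow(cen), length(fragments))
  for (k in seq_along(ord)) {
    fr <- fragments[[ord[k]]]
    dmat[, k] <- closest_surface_points(cen, fr$surface)$dist
  }
  best <- max.col(-dmat, ties.method = "first")  # first = smallest id on ties
  tied <- dmat - dmat[cbind(seq_len(nrow(dmat)), best)] <= tie_tol
  best <- apply(tied, 1, which.max)  # earliest (lexicographic) within tol
  labels <- ids[ord][best]
  # cut-interface vertices: incident to faces of >= 2 labels
  vert_labels <- data.frame(v = as.vector(interface$faces),
                            lab = rep(labels, 3))
  nlab <- tapply(vert_labels$lab, vert_labels$v, function(x) length(unique(x)))
  cut <- as.integer(names(nlab)[nlab >= 2])
  structure(list(coupled_faces = seq_len(nrow(interface$faces)),
                 fragment_of_face = labels,
                 cut_interface_vertices = sort(cut),
                 fragment_ids = sort(unique(labels))),
            class = "face_group_assignment")
}

#' @export
print.face_group_assignment <- function(x, ...) {
  cat(sprintf("face_group_assignment: %d faces over %d fragments, %d cut-interface vertices\n",
              length(x$coupled_faces), length(x$fragment_ids),
              length(x$cut_interface_vertices)))
  invisible(x)
}

#' Linear-blend-skinning weight field for smooth coupling at bone cuts
#'
#' At a bone cut the two resulting fragments each receive weight 0.5; the
#' weights then ramp linearly to 1.0 (own fragment) and 0.0 over `ramp_mm`
#' (default 10 mm = 1 cm) of Euclidean distance from the nearest
#' cut-interface vertex. Nodes at or beyond the ramp carry a single weight
#' of 1.0 for their own fragment. Weights are computed once in the rest pose.
#'
#' @param assignment a [face_group_assignment].
#' @param interface the same interface [surface_mesh].
#' @param ramp_mm linear ramp length in mm (default 10).
#' @return An object of class `weight_field`: `node_ids` (vertex indices into
#'   the simulation mesh), `fragment_ids` (list of character vectors per
#'   node), `weights` (list of numeric vectors per node, each summing to 1),
#'   `ramp_mm`.
#' @export
lbs_weight_field <- function(assignment, interface, ramp_mm = 10) {
  if (!is.finite(ramp_mm) || ramp_mm <= 0) {
    stop("ramp_mm must be positive", call. = FALSE)
  }
  f <- interface$faces
  labels <- assignment$fragment_of_face
  nodes <- sort(unique(as.vector(f)))
  # incident labels per node
  inc <- split(rep(labels, 3), as.vector(f))
  inc <- lapply(inc, function(x) sort(unique(x)))
  names(inc) <- NULL
  cutv <- assignment$cut_interface_vertices
  cut_pos <- interface$vertices[cutv, , drop = FALSE]
  frag_ids <- vector("list", length(nodes))
  wts <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    v <- nodes[k]
    labs <- inc[[k]]
    if (v %in% cutv) {
      # on the cut: 0.5 for the two nearest fragments (the incident pair;
      # with >= 3 incident labels the lexicographically first two are kept)
      frag_ids[[k]] <- labs[1:2]
      wts[[k]] <- c(0.5, 0.5)
      next
    }
    own <- labs[1]
    if (length(cutv) == 0) {
      frag_ids[[k]] <- own
      wts[[k]] <- 1
      next
    }
    dd <- sqrt(colSums((t(cut_pos) - interface$vertices[v, ])^2))
    j <- which.min(dd)
    d <- dd[j]
    if (d >= ramp_mm) {
      frag_ids[[k]] <- own
      wts[[k]] <- 1
    } else {
      # complementary weight goes to the nearest other fragment: the other
      # label present at the nearest cut vertex
      other_labs <- setdiff(inc[[match(cutv[j], nodes)]], own)
      other <- if (length(other_labs) > 0) other_labs[1] else own
      w_own <- 0.5 + 0.5 * d / ramp_mm
      if (other == own) {
        frag_ids[[k]] <- own
        wts[[k]] <- 1
      } else {
        frag_ids[[k]] <- c(own, other)
        wts[[k]] <- c(w_own, 1 - w_own)
      }
    }
  }
  structure(list(node_ids = nodes, fragment_ids = frag_ids, weights = wts,
                 ramp_mm = ramp_mm),
            class = "weight_field")
}

#' @export
print.weight_field <- function(x, ...) {
  nlbs <- sum(vapply(x$weights, length, 1L) > 1)
  cat(sprintf("weight_field: %d coupled nodes (%d blended), ramp %g mm\n",
              length(x$node_ids), nlbs, x$ramp_mm))
  invisible(x)
}

node_dofs <- function(nodes) {
  as.vector(t(outer(3L * (as.integer(nodes) - 1L), 1:3, "+")))
}

#' Build the coupling system (selection matrices and linear map)
#'
#' Partitions the soft DoFs into constrained (selected by `S`) and free
#' (selected by the complementary `S_tilde`), and expresses the constrained
#' DoFs as `A z + c` with `z` the free vector (free soft DoFs followed by any
#' free-fragment rigid DoFs, 6 per fragment). Fixed nodes have zero `A` rows
#' and `c` equal to their pinned positions; nodes coupled to prescribed
#' fragments also have zero `A` rows, with `c` the blend
#' `sum_b w_b (R_b X_rel + x_b)` refreshed per substep via
#' [update_coupling()]; nodes coupled to free fragments carry the linearized
#' rigid map in their `A` rows.
#'
#' @param mesh a [tet_mesh].
#' @param fixed_nodes integer node indices pinned in space.
#' @param weight_field optional [weight_field] of bonded/blended nodes.
#' @param fragments list of [rigid_fragment], named or not; every fragment id
#'   referenced by the weight field must be present.
#' @param fixed_positions optional `length(fixed_nodes) x 3` matrix of pinned
#'   positions (default: rest positions).
#' @return An object of class `coupling_system`.
#' @export
build_coupling <- function(mesh, fixed_nodes = integer(0), weight_field = NULL,
                           fragments = list(), fixed_positions = NULL) {
  n <- nrow(mesh$rest_positions)
  ndof <- 3L * n
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  coupled_nodes <- if (is.null(weight_field)) integer(0) else weight_field$node_ids
  overlap <- intersect(fixed_nodes, coupled_nodes)
  if (length(overlap) > 0) {
    stop(sprintf("nodes both fixed and coupled: %s",
                 paste(head(overlap, 10), collapse = ", ")), call. = FALSE)
  }
  frag_ids <- vapply(fragments, function(f) f$id, "")
  names(fragments) <- frag_ids
  if (!is.null(weight_field)) {
    need <- unique(unlist(weight_field$fragment_ids))
    miss <- setdiff(need, frag_ids)
    if (length(miss) > 0) {
      stop(sprintf("weight field references unknown fragments: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  constrained <- sort(c(fixed_nodes, coupled_nodes))
  m <- 3L * length(constrained)
  cdofs <- node_dofs(constrained)
  S <- Matrix::sparseMatrix(i = seq_len(m), j = cdofs, x = 1,
                            dims = c(m, ndof))
  free_dofs <- setdiff(seq_len(ndof), cdofs)
  f <- length(free_dofs)
  Stilde_soft <- Matrix::sparseMatrix(i = seq_len(f), j = free_dofs, x = 1,
                                      dims = c(f, ndof))
  free_frag_ids <- frag_ids[!vapply(fragments, function(fr) fr$prescribed, TRUE)]
  b <- 6L * length(free_frag_ids)

  node_kind <- rep("free", n)
  node_kind[fixed_nodes] <- "fixed"
  if (!is.null(weight_field)) {
    nlab <- vapply(weight_field$weights, length, 1L)
    node_kind[weight_field$node_ids[nlab == 1L]] <- "bonded"
    node_kind[weight_field$node_ids[nlab > 1L]] <- "lbs"
  }

  if (is.null(fixed_positions)) {
    fixed_positions <- mesh$rest_positions[fixed_nodes, , drop = FALSE]
  } else {
    fixed_positions <- as_coord_matrix(fixed_positions, "fixed_positions")
    if (nrow(fixed_positions) != length(fixed_nodes)) {
      stop("fixed_positions must have one row per fixed node", call. = FALSE)
    }
  }

  # per coupled node: fragment ids, weights, rest offsets from fragment COM
  coupled_meta <- NULL
  if (!is.null(weight_field)) {
    coupled_meta <- lapply(seq_along(weight_field$node_ids), function(k) {
      v <- weight_field$node_ids[k]
      fids <- weight_field$fragment_ids[[k]]
      list(node = v, fragment_ids = fids, weights = weight_field$weights[[k]],
           X_rel = lapply(fids, function(id) {
             mesh$rest_positions[v, ] - fragments[[id]]$com_rest
           }))
    })
  }

  coupling <- structure(list(
    n_nodes = n, n_dofs = ndof,
    constrained_nodes = constrained, constrained_dofs = cdofs,
    fixed_nodes = fixed_nodes, fixed_positions = fixed_positions,
    coupled_meta = coupled_meta,
    S = S, Stilde_soft = Stilde_soft, free_dofs = free_dofs,
    n_free_soft = f, free_fragment_ids = free_frag_ids, n_rigid = b,
    node_kind = node_kind,
    A = NULL, c = NULL
  ), class = "coupling_system")
  update_coupling(coupling, fragments)
}

#' @export
print.coupling_system <- function(x, ...) {
  cat(sprintf("coupling_system: %d nodes (%d fixed, %d bonded, %d lbs), %d free soft DoFs, %d rigid DoFs\n",
              x$n_nodes, sum(x$node_kind == "fixed"), sum(x$node_kind == "bonded"),
              sum(x$node_kind == "lbs"), x$n_free_soft, x$n_rigid))
  invisible(x)
}

#' Refresh the coupling offsets (and free-fragment rows) from fragment poses
#'
#' Recomputes `c` for nodes coupled to prescribed fragments from the current
#' fragment rotations and center-of-mass positions, and rebuilds the `A`
#' rows carrying the tangent-space rigid map of any free fragments. Called
#' at every substep once the prescribed trajectory advances.
#'
#' @param coupling a [coupling_system].
#' @param fragments list of [rigid_fragment] at their current poses.
#' @return the updated [coupling_system].
#' @export
update_coupling <- function(coupling, fragments) {
  frag_ids <- vapply(fragments, function(f) f$id, "")
  names(fragments) <- frag_ids
  m <- 3L * length(coupling$constrained_nodes)
  cvec <- numeric(m)
  ai <- integer(0); aj <- integer(0); ax <- numeric(0)
  crow <- function(node) 3L * (match(node, coupling$constrained_nodes) - 1L)

  for (k in seq_along(coupling$fixed_nodes)) {
    cvec[crow(coupling$fixed_nodes[k]) + 1:3] <- coupling$fixed_positions[k, ]
  }
  for (meta in coupling$coupled_meta) {
    r0 <- crow(meta$node)
    acc <- c(0, 0, 0)
    for (q in seq_along(meta$fragment_ids)) {
      id <- meta$fragment_ids[q]
      fr <- fragments[[id]]
      if (is.null(fr)) stop(sprintf("fragment '%s' missing from pose list", id), call. = FALSE)
      w <- meta$weights[q]
      RX <- as.numeric(fr$rotation %*% meta$X_rel[[q]])
      if (fr$prescribed) {
        acc <- acc + w * (RX + fr$center_of_mass)
      } else {
        # rotation-dependent part in c; x_b and theta_b columns in A
        acc <- acc + w * RX
        fi <- match(id, coupling$free_fragment_ids)
        col0 <- coupling$n_free_soft + 6L * (fi - 1L)
        for (i in 1:3) {
          ai <- c(ai, r0 + i); aj <- c(aj, col0 + i); ax <- c(ax, w)
        }
        Sk <- -w * skew3(RX)  # d/dtheta of -(RX) x theta
        for (j in 1:3) for (i in 1:3) {
          if (Sk[i, j] != 0) {
            ai <- c(ai, r0 + i); aj <- c(aj, col0 + 3L + j); ax <- c(ax, Sk[i, j])
          }
        }
      }
    }
    cvec[r0 + 1:3] <- acc
  }
  coupling$c <- cvec
  coupling$A <- Matrix::sparseMatrix(i = ai, j = aj, x = ax,
                                     dims = c(m, coupling$n_free_soft + coupling$n_rigid))
  coupling
}

#' Reconstruct the full soft DoF vector from the free vector
#'
#' `x = S_tilde' z + S' (A z + c)`; the coupling constraint
#' `S x - A z - c = 0` holds exactly by construction.
#'
#' @param coupling a [coupling_system].
#' @param z free DoF vector (free soft DoFs then rigid DoFs).
#' @return full soft DoF vector of length `3 * n_nodes`.
#' @export
reconstruct_full_dofs <- function(coupling, z) {
  nz <- coupling$n_free_soft + coupling$n_rigid
  if (length(z) != nz) {
    stop(sprintf("z must have length %d (free soft + rigid DoFs)", nz), call. = FALSE)
  }
  x <- numeric(coupling$n_dofs)
  if (coupling$n_free_soft > 0) {
    x[coupling$free_dofs] <- z[seq_len(coupling$n_free_soft)]
  }
  if (length(coupling$constrained_dofs) > 0) {
    x[coupling$constrained_dofs] <- as.numeric(coupling$A %*% z) + coupling$c
  }
  x
}

#' Coupling constraint residual
#'
#' @param coupling a [coupling_system].
#' @param x full soft DoF vector.
#' @param z free DoF vector.
#' @return `S x - A z - c`.
#' @export
coupling_constraint <- function(coupling, x, z) {
  as.numeric(coupling$S %*% x) - as.numeric(coupling$A %*% z) - coupling$c
}

#' Extract the free vector from a full DoF vector
#'
#' @param coupling a [coupling_system].
#' @param x full soft DoF vector of length `3 * n_nodes`.
#' @param rigid optional rigid DoF values to append (default zeros).
#' @return free DoF vector `z`.
#' @export
free_vector <- function(coupling, x, rigid = NULL) {
  if (is.null(rigid)) rigid <- numeric(coupling$n_rigid)
  c(x[coupling$free_dofs], rigid)
}
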