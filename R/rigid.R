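#' Rigid bone fragment
#'
#' A bone (or osteotomized bone fragment) modeled as a rigid body: its rest
#' surface mesh, center of mass `x_b`, current rotation `R_b` and an
#' incremental tangent-space rotation `theta_b` (axis-angle). Fragments are
#' prescribed by default: the planned transform drives them and they
#' contribute no elastic energy. Free (solved) fragments append their 6 DoFs
#' to the free vector `z` of the coupled system.
#'
#' @param id fragment label (character scalar).
#' @param surface rest-pose [surface_mesh] of the fragment.
#' @param prescribed is the fragment driven by a planned transform
#'   (default `TRUE`)?
#' @param target optional planned [rigid_transform] (global map `x = R X + t`).
#' @param center_of_mass optional 3-vector; by default computed from the
#'   closed surface assuming uniform density (divergence-theorem integrals),
#'   falling back to the vertex mean for open surfaces.
#' @return An object of class `rigid_fragment` with fields `id`, `surface`,
#'   `com_rest`, `rotation`, `center_of_mass` (current world position of the
#'   rest center of mass), `incremental_rotation`, `prescribed`,
#'   `target_transform`.
#' @export
rigid_fragment <- function(id, surface, prescribed = TRUE, target = NULL,
                           center_of_mass = NULL) {
  stopifnot(inherits(surface, "surface_mesh"))
  if (is.null(center_of_mass)) {
    if (is_closed_surface(surface)) {
      center_of_mass <- surface_volume_centroid(surface)$centroid
    } else {
      center_of_mass <- colMeans(surface$vertices)
    }
  }
  if (!is.null(target)) stopifnot(inherits(target, "rigid_transform"))
  structure(list(id = as.character(id), surface = surface,
                 com_rest = as.numeric(center_of_mass),
                 rotation = diag(3),
                 center_of_mass = as.numeric(center_of_mass),
                 incremental_rotation = c(0, 0, 0),
                 prescribed = isTRUE(prescribed),
                 target_transform = target),
            class = "rigid_fragment")
}

#' @export
print.rigid_fragment <- function(x, ...) {
  cat(sprintf("rigid_fragment '%s': %d surface vertices, %s, com (%.3g, %.3g, %.3g) mm\n",
              x$id, nrow(x$surface$vertices),
              if (x$prescribed) "prescribed" else "free",
              x$com_rest[1], x$com_rest[2], x$com_rest[3]))
  invisible(x)
}

#' World position of a fragment-frame point
#'
#' For a point `X` given relative to the rest center of mass: the exact rigid
#' map `R_b X + x_b` when the incremental rotation is zero, and the
#' tangent-space linearization `R_b X - (R_b X) x theta_b + x_b` otherwise.
#' The linearization error against the exact exponential is second order in
#' the increment angle.
#'
#' @param fragment a [rigid_fragment].
#' @param X 3-vector or `k x 3` matrix of points relative to the rest center
#'   of mass (mm).
#' @return world positions, same shape as `X`.
#' @export
world_position <- function(fragment, X) {
  single <- is.null(dim(X))
  if (single) X <- matrix(X, ncol = 3)
  RX <- X %*% t(fragment$rotation)
  th <- fragment$incremental_rotation
  if (any(th != 0)) {
    RX <- RX - cross3(RX, matrix(th, nrow(RX), 3, byrow = TRUE))
  }
  out <- sweep(RX, 2, fragment$center_of_mass, "+")
  if (single) as.numeric(out) else out
}

#' Fold the incremental rotation into the fragment pose
#'
#' Applies the exact exponential map `R_b <- exp([theta_b]_x) R_b` (Rodrigues
#' form), re-projects to the nearest rotation by polar decomposition, and
#' resets the increment to zero.
#'
#' @param fragment a [rigid_fragment].
#' @return the updated [rigid_fragment].
#' @export
accept_increment <- function(fragment) {
  th <- fragment$incremental_rotation
  if (any(th != 0)) {
    fragment$rotation <- project_rotation(axis_angle_matrix(th) %*% fragment$rotation)
    fragment$incremental_rotation <- c(0, 0, 0)
  }
  fragment
}

#' Substepped transform trajectory for a fragment
#'
#' Decomposes a planned target transform into `substeps` increments applied
#' at successive quasistatic solves: the rotation's axis-angle is scaled by
#' `k / substeps` (geodesic interpolation, so every substep is a valid
#' rotation) and the translation linearly. The final entry reproduces the
#' target.
#'
#' @param fragment a [rigid_fragment] (or a fragment id string).
#' @param target a [rigid_transform] (global map).
#' @param substeps number of substeps (default 10, the planning default).
#' @return An object of class `transform_trajectory`: `fragment_id` and
#'   `substep_transforms` (list of length `substeps`).
#' @export
make_trajectory <- function(fragment, target, substeps = 10L) {
  substeps <- as.integer(substeps)
  if (is.na(substeps) || substeps < 1L) {
    stop("substeps must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(target, "rigid_transform"))
  id <- if (inherits(fragment, "rigid_fragment")) fragment$id else as.character(fragment)
  tfs <- lapply(seq_len(substeps), function(k) {
    interpolate_transform(target, k / substeps)
  })
  structure(list(fragment_id = id, substep_transforms = tfs),
            class = "transform_trajectory")
}

#' Set a fragment's pose from a global rigid transform
#'
#' The global map `x = R X + t` places the rest center of mass `c` at
#' `R c + t`, so `R_b = R`, `x_b = R c + t`.
#'
#' @param fragment a [rigid_fragment].
#' @param tf a [rigid_transform].
#' @return the updated [rigid_fragment].
#' @export
set_fragment_pose <- function(fragment, tf) {
  fragment$rotation <- tf$rotation
  fragment$center_of_mass <- as.numeric(tf$rotation %*% fragment$com_rest +
                                          tf$translation)
  fragment$incremental_rotation <- c(0, 0, 0)
  fragment
}

#' Fragment surface at its current pose
#'
#' @param fragment a [rigid_fragment].
#' @return a [surface_mesh] with vertices mapped through the current pose.
#' @export
fragment_posed_surface <- function(fragment) {
  rel <- sweep(fragment$surface$vertices, 2, fragment$com_rest, "-")
  surface_mesh(world_position(fragment, rel), fragment$surface$faces,
               face_groups = fragment$surface$face_groups, validate = FALSE)
}
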