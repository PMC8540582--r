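#' Rigid transform (rotation + translation)
#'
#' Represents the map `x = R X + t` with `R` a proper rotation and `t` in mm.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (mm).
#' @param tol orthonormality tolerance (default `1e-9`).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > tol || det(rotation) < 0) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3) stop("translation must be a 3-vector", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_log(x$rotation)
  cat(sprintf("rigid_transform: angle %.4g deg, translation (%.4g, %.4g, %.4g) mm\n",
              sqrt(sum(aa^2)) * 180 / pi, x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform].
#' @param points `k x 3` matrix or 3-vector.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(tf, points) {
  if (is.null(dim(points))) {
    return(as.numeric(tf$rotation %*% points + tf$translation))
  }
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Compose two rigid transforms (`a` after `b`)
#'
#' @param a,b [rigid_transform] objects.
#' @return the [rigid_transform] mapping `x` to `a(b(x))`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(project_rotation(a$rotation %*% b$rotation),
                  as.numeric(a$rotation %*% b$translation + a$translation))
}

#' Invert a rigid transform
#' @param tf a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Axis-angle exponential and logarithm
#'
#' `axis_angle_matrix` is the Rodrigues closed form of `exp([theta]_x)`;
#' `rotation_log` recovers the axis-angle vector (angle in `[0, pi]`).
#'
#' @param theta axis-angle 3-vector (radians times unit axis).
#' @return `axis_angle_matrix`: a 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(theta) {
  theta <- as.numeric(theta)
  angle <- sqrt(sum(theta^2))
  if (angle < 1e-300) return(diag(3))
  ax <- theta / angle
  K <- skew3(ax)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname axis_angle_matrix
#' @param R a 3x3 rotation matrix.
#' @export
rotation_log <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  angle <- acos(ca)
  if (angle < 1e-12) return(c(0, 0, 0))
  if (pi - angle < 1e-6) {
    # near pi: axis from the largest diagonal entry of (R + I)/2
    B <- (R + diag(3)) / 2
    k <- which.max(diag(B))
    ax <- B[, k] / sqrt(B[k, k])
    ax <- ax / sqrt(sum(ax^2))
    return(ax * angle)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(angle))
  w * angle
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Nearest rotation by polar decomposition (SVD with reflection guard).
project_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Geodesic interpolation of a rigid transform
#'
#' Scales the rotation's axis-angle by `s` and the translation linearly;
#' every interpolate is a valid rigid transform and `s = 1` reproduces the
#' input exactly.
#'
#' @param tf a [rigid_transform].
#' @param s interpolation parameter in `[0, 1]`.
#' @return a [rigid_transform].
#' @export
interpolate_transform <- function(tf, s) {
  rigid_transform(axis_angle_matrix(s * rotation_log(tf$rotation)),
                  s * tf$translation)
}
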