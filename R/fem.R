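#' Homogeneous isotropic material
#'
#' Neo-Hookean material parameterized by Young modulus and Poisson ratio,
#' with Lame constants `mu = E / (2(1+nu))` and
#' `lambda = E nu / ((1+nu)(1-2nu))`. Defaults are the facial soft-tissue
#' values used throughout this package: 100 kPa and 0.47.
#'
#' @param young_modulus Young modulus in kPa (default 100).
#' @param poisson_ratio Poisson ratio, in the open interval (0, 0.5)
#'   (default 0.47).
#' @return An object of class `material` with fields `young_modulus`,
#'   `poisson_ratio`, `mu`, `lambda`.
#' @export
material <- function(young_modulus = 100, poisson_ratio = 0.47) {
  if (!is.finite(young_modulus) || young_modulus <= 0) {
    stop("young_modulus must be positive", call. = FALSE)
  }
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must lie strictly between 0 and 0.5", call. = FALSE)
  }
  structure(list(
    young_modulus = young_modulus,
    poisson_ratio = poisson_ratio,
    mu = young_modulus / (2 * (1 + poisson_ratio)),
    lambda = young_modulus * poisson_ratio /
      ((1 + poisson_ratio) * (1 - 2 * poisson_ratio))
  ), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material: E = %g kPa, nu = %g (mu = %.6g, lambda = %.6g kPa)\n",
              x$young_modulus, x$poisson_ratio, x$mu, x$lambda))
  invisible(x)
}

#' Neo-Hookean energy density and its derivatives
#'
#' `energy_density` evaluates
#' `Psi(F) = mu/2 (tr(F'F) - 3) - mu log det F + lambda/2 (log det F)^2`
#' (kPa); `first_pk_stress` its gradient, the first Piola-Kirchhoff stress
#' `P = mu (F - F^-T) + lambda log(det F) F^-T`; and `stress_derivative` the
#' second derivative as a symmetric 9x9 matrix in column-major vec layout.
#' States with `det F <= 0` are not evaluable (the log barrier is undefined)
#' and return `NA`, which the solver's line search treats as infinite energy.
#'
#' @param F 3x3 deformation gradient.
#' @param mat a [material].
#' @return `energy_density`: scalar kPa or `NA`; `first_pk_stress`: 3x3
#'   matrix (kPa); `stress_derivative`: 9x9 matrix (kPa).
#' @export
energy_density <- function(F, mat) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) return(NA_real_)
  lj <- log(J)
  mat$mu / 2 * (sum(F * F) - 3) - mat$mu * lj + mat$lambda / 2 * lj^2
}

#' @rdname energy_density
#' @export
first_pk_stress <- function(F, mat) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) return(matrix(NA_real_, 3, 3))
  FinvT <- t(solve(F))
  mat$mu * (F - FinvT) + mat$lambda * log(J) * FinvT
}

#' @rdname energy_density
#' @export
stress_derivative <- function(F, mat) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) return(matrix(NA_real_, 9, 9))
  FinvT <- t(solve(F))
  lj <- log(J)
  H <- matrix(0, 9, 9)
  coef <- mat$mu - mat$lambda * lj
  for (l in 1:3) for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    v <- coef * FinvT[i, l] * FinvT[k, j] + mat$lambda * FinvT[i, j] * FinvT[k, l]
    if (i == k && j == l) v <- v + mat$mu
    H[i + 3 * (j - 1), k + 3 * (l - 1)] <- v
  }
  H
}

#' Per-element deformation gradients
#'
#' `F = (deformed edge matrix) (rest edge matrix)^-1`, constant over each
#' linear tetrahedron.
#'
#' @param mesh a [tet_mesh].
#' @param positions deformed nodal positions: `n x 3` matrix or length-`3n`
#'   vector (dof order `x1 y1 z1 x2 ...`).
#' @param elements element indices (default all).
#' @return a 3x3 matrix for a single element, else a `3 x 3 x k` array.
#' @export
deformation_gradient <- function(mesh, positions, elements = NULL) {
  pos <- as_dof_matrix(positions, nrow(mesh$rest_positions))
  if (is.null(elements)) elements <- seq_len(nrow(mesh$tets))
  out <- array(0, c(3, 3, length(elements)))
  for (k in seq_along(elements)) {
    e <- elements[k]
    Ds <- t(pos[mesh$tets[e, 2:4], , drop = FALSE]) - pos[mesh$tets[e, 1], ]
    out[, , k] <- Ds %*% mesh$element_basis[, , e]
  }
  if (length(elements) == 1) out[, , 1] else out
}

as_dof_matrix <- function(positions, n) {
  if (is.null(dim(positions))) {
    if (length(positions) != 3 * n) {
      stop(sprintf("positions must have length %d (3 x node count)", 3 * n),
           call. = FALSE)
    }
    return(matrix(positions, n, 3, byrow = TRUE))
  }
  positions <- as_coord_matrix(positions, "positions")
  if (nrow(positions) != n) stop("positions must have one row per node", call. = FALSE)
  positions
}

as_dof_vector <- function(positions, n) {
  as.numeric(t(as_dof_matrix(positions, n)))
}

#' Assemble total soft-tissue energy, gradient and Hessian
#'
#' Single-point quadrature over linear tetrahedra:
#' `V = sum_i w_i Psi(F_i) - f_ext' x`. The gradient has one entry per soft
#' degree of freedom (dof order `x1 y1 z1 x2 ...`); the Hessian is assembled
#' from per-element 12x12 blocks, optionally eigen-projected to positive
#' semidefinite so the Newton step's quadratic model stays solvable.
#'
#' @param mesh a [tet_mesh].
#' @param mat a [material].
#' @param positions deformed positions (`n x 3` matrix or length-`3n` vector).
#' @param f_ext external force vector (length `3n`; default zero — gravity is
#'   deliberately omitted since the pre-operative tissue is already load-bearing).
#' @param hessian assemble the Hessian (default `TRUE`).
#' @param project_spd eigen-project element blocks to PSD (default `TRUE`;
#'   disable to compare against finite differences of the gradient).
#' @return An object of class `system_energy`: `total_energy` (kPa mm^3),
#'   `gradient`, `hessian` (sparse symmetric, or `NULL`), `external_forces`,
#'   `evaluable`, and when not evaluable `bad_element` / `det_f`.
#' @export
assemble_energy <- function(mesh, mat, positions, f_ext = NULL,
                            hessian = TRUE, project_spd = TRUE) {
  n <- nrow(mesh$rest_positions)
  pos <- as_dof_matrix(positions, n)
  x <- as.numeric(t(pos))
  if (is.null(f_ext)) {
    f_ext <- numeric(3 * n)
  } else if (length(f_ext) != 3 * n) {
    stop("f_ext must have length 3 x node count", call. = FALSE)
  }
  res <- fem_assemble_cpp(t(pos), mesh$tets, mesh$element_basis,
                          mesh$quadrature_weights, mat$mu, mat$lambda,
                          hessian, project_spd)
  if (!res$evaluable) {
    return(structure(list(total_energy = NA_real_, gradient = NULL,
                          hessian = NULL, external_forces = f_ext,
                          evaluable = FALSE, bad_element = res$bad_element,
                          det_f = res$det_f),
                     class = "system_energy"))
  }
  H <- NULL
  if (hessian) {
    H <- Matrix::sparseMatrix(i = res$hi, j = res$hj, x = res$hx,
                              dims = c(3 * n, 3 * n))
    H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  }
  structure(list(total_energy = res$energy - sum(f_ext * x),
                 gradient = as.numeric(res$gradient) - f_ext,
                 hessian = H, external_forces = f_ext, evaluable = TRUE),
            class = "system_energy")
}

#' @export
print.system_energy <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("system_energy: not evaluable (element %d, det F = %.3g)\n",
                x$bad_element, x$det_f))
  } else {
    cat(sprintf("system_energy: V = %.6g kPa mm^3, |grad|_inf = %.3g\n",
                x$total_energy, max(abs(x$gradient))))
  }
  invisible(x)
}
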