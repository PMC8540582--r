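test_that("material derives Lame constants and rejects invalid ratios", {
  m <- material(100, 0.47)
  expect_equal(m$mu, 100 / (2 * 1.47), tolerance = 1e-12)
  expect_equal(m$lambda, 100 * 0.47 / (1.47 * 0.06), tolerance = 1e-12)
  expect_error(material(100, 0.5), "strictly between")
  expect_error(material(100, 0), "strictly between")
  expect_error(material(-1, 0.3), "positive")
})

test_that("energy density vanishes at identity and under pure rotation", {
  set.seed(5)
  mat <- material(100, 0.47)
  expect_equal(energy_density(diag(3), mat), 0, tolerance = 1e-12)
  expect_equal(max(abs(first_pk_stress(diag(3), mat))), 0, tolerance = 1e-12)
  for (k in 1:5) {
    R <- random_rotation()
    expect_equal(energy_density(R, mat), 0, tolerance = 1e-10)
  }
})

test_that("energy density matches the closed form for uniaxial stretch", {
  mat <- list(mu = 1, lambda = 1)
  F <- diag(c(2, 1, 1))
  expect_equal(energy_density(F, mat), 1.5 - log(2) + log(2)^2 / 2,
               tolerance = 1e-12)
  P <- first_pk_stress(F, mat)
  expect_equal(diag(P), c(1.5 + 0.5 * log(2), log(2), log(2)),
               tolerance = 1e-12)
  expect_equal(P[lower.tri(P) | upper.tri(P)], rep(0, 6))
})

test_that("stress matches finite differences of the energy density", {
  set.seed(21)
  mat <- material(3, 0.35)
  for (trial in 1:5) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
    if (det(F) <= 0.1) next
    P <- first_pk_stress(F, mat)
    Pfd <- matrix(fd_gradient(function(v) energy_density(matrix(v, 3, 3), mat),
                              as.numeric(F)), 3, 3)
    expect_equal(P, Pfd, tolerance = 1e-5)
    H9 <- stress_derivative(F, mat)
    expect_equal(H9, t(H9), tolerance = 1e-12)
    H9fd <- matrix(0, 9, 9)
    for (i in 1:9) {
      H9fd[, i] <- fd_gradient(function(v) {
        first_pk_stress(matrix(v, 3, 3), mat)[((i - 1) %% 3) + 1, ((i - 1) %/% 3) + 1]
      }, as.numeric(F))
    }
    expect_equal(H9, H9fd, tolerance = 1e-4)
  }
})

test_that("states with non-positive volume change are not evaluable", {
  mat <- material()
  expect_true(is.na(energy_density(diag(c(-1, 1, 1)), mat)))
  expect_true(all(is.na(first_pk_stress(diag(c(0, 1, 1)), mat))))
})

test_that("deformation gradient is identity at rest, scales, and ignores translation", {
  tm <- two_tet_mesh()
  X <- tm$rest_positions
  expect_equal(deformation_gradient(tm, X, 1), diag(3), tolerance = 1e-12)
  expect_equal(deformation_gradient(tm, 2 * X, 2), 2 * diag(3), tolerance = 1e-12)
  expect_equal(deformation_gradient(tm, sweep(X, 2, c(5, -1, 2), "+"), 1),
               diag(3), tolerance = 1e-12)
})

test_that("assembly at rest gives zero energy and forces; frame invariance holds", {
  set.seed(9)
  sc <- make_slab_scene(slab_spec(dims = c(8, 8, 8), resolution = c(2, 2, 2),
                                  fixed_face = "none"))
  mat <- material()
  se <- assemble_energy(sc$mesh, mat, sc$mesh$rest_positions)
  expect_equal(se$total_energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(se$gradient)), 0, tolerance = 1e-12)
  R <- random_rotation()
  xr <- sweep(sc$mesh$rest_positions %*% t(R), 2, c(10, -3, 7), "+")
  ser <- assemble_energy(sc$mesh, mat, xr)
  scale <- mat$young_modulus * sum(sc$mesh$quadrature_weights)
  expect_lt(abs(ser$total_energy), 1e-10 * scale)
})

test_that("assembled gradient and Hessian match finite differences", {
  set.seed(33)
  sc <- make_slab_scene(slab_spec(dims = c(2, 1, 1), resolution = c(2, 2, 2),
                                  fixed_face = "none"))
  mesh <- sc$mesh
  mat <- material(2, 0.4)
  n <- nrow(mesh$rest_positions)
  x0 <- as.numeric(t(mesh$rest_positions)) + 0.02 * rnorm(3 * n)
  fext <- 0.1 * rnorm(3 * n)
  se <- assemble_energy(mesh, mat, x0, f_ext = fext, project_spd = FALSE)
  gfd <- fd_gradient(function(v) {
    assemble_energy(mesh, mat, v, f_ext = fext, hessian = FALSE)$total_energy
  }, x0, h = 1e-6)
  expect_equal(se$gradient, gfd, tolerance = 1e-5)
  Hd <- as.matrix(se$hessian)
  expect_equal(Hd, t(Hd), tolerance = 1e-9 * max(abs(Hd)))
  Hfd <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(3 * n)) {
    e <- numeric(3 * n); e[i] <- 1e-5
    gp <- assemble_energy(mesh, mat, x0 + e, f_ext = fext, hessian = FALSE)$gradient
    gm <- assemble_energy(mesh, mat, x0 - e, f_ext = fext, hessian = FALSE)$gradient
    Hfd[, i] <- (gp - gm) / 2e-5
  }
  expect_equal(Hd, Hfd, tolerance = 1e-4)
})

test_that("assembly reports the inverted element of a non-evaluable state", {
  tm <- ref_tet()
  bad <- tm$rest_positions
  bad[4, ] <- c(0, 0, -1)  # flips the single tet
  se <- assemble_energy(tm, material(), bad)
  expect_false(se$evaluable)
  expect_equal(se$bad_element, 1)
  expect_lt(se$det_f, 0)
})

test_that("small-strain uniaxial response matches the linearized stiffness 2mu + lambda", {
  mat <- material(100, 0.47)
  eps <- 1e-5
  P <- first_pk_stress(diag(c(1 + eps, 1, 1)), mat)
  expect_equal(P[1, 1] / eps, 2 * mat$mu + mat$lambda,
               tolerance = 1e-3)
})

test_that("energy is non-negative near the identity", {
  set.seed(13)
  mat <- material(100, 0.47)
  psi <- replicate(1000, {
    energy_density(diag(3) + 1e-3 * matrix(rnorm(9), 3, 3), mat)
  })
  expect_true(all(psi >= 0))
})

test_that("rest-pose Hessian equals the linear-elasticity stiffness on two tets", {
  tm <- two_tet_mesh()
  mat <- material(100, 0.47)
  H <- as.matrix(assemble_energy(tm, mat, tm$rest_positions,
                                 project_spd = FALSE)$hessian)
  K <- linear_stiffness_oracle(tm, mat)
  expect_equal(H, K, tolerance = 1e-6)
})
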