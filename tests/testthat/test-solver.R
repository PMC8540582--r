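test_that("reduction is the identity for an empty coupling and direct for all-fixed", {
  tm <- two_tet_mesh()
  se <- assemble_energy(tm, material(), tm$rest_positions)
  g <- rnorm(15)
  cp0 <- build_coupling(tm)
  red <- reduce_system(se$hessian, g, cp0)
  expect_equal(as.matrix(red$matrix), as.matrix(se$hessian), tolerance = 1e-14)
  expect_equal(red$rhs, -g, tolerance = 1e-12)
  cpf <- build_coupling(tm, fixed_nodes = 1:5)
  redf <- reduce_system(se$hessian, g, cpf)
  expect_equal(dim(redf$matrix), c(0L, 0L))
  x <- reconstruct_full_dofs(cpf, numeric(0))
  expect_equal(matrix(x, 5, 3, byrow = TRUE), tm$rest_positions)
  expect_error(reduce_system(se$hessian, numeric(3), cp0), "dimensions")
})

test_that("reduced solve equals the dense KKT solution on random mixed instances", {
  set.seed(101)
  spec <- slab_spec(dims = c(12, 8, 8), resolution = c(3, 2, 2),
                    fixed_face = "none")
  sc <- make_slab_scene(spec, mat = material(1, 0.3))
  mesh <- sc$mesh
  n <- nrow(mesh$rest_positions)
  topall <- which(abs(mesh$rest_positions[, 3] - 8) < 1e-9)
  worst <- 0
  for (trial in 1:21) {
    fixed <- sample(setdiff(seq_len(n), topall), sample(3:8, 1))
    free_frag <- trial %% 3 != 0  # mix prescribed and free fragments
    bonded <- sample(topall, 6)   # spread nodes: well-posed rigid block
    frag <- rigid_fragment("fr", box_surface(c(2, 2, 8), c(10, 6, 12)),
                           prescribed = !free_frag)
    wf <- structure(list(node_ids = sort(bonded),
                         fragment_ids = rep(list("fr"), length(bonded)),
                         weights = rep(list(1), length(bonded)), ramp_mm = 10),
                    class = "weight_field")
    cp <- build_coupling(mesh, fixed, wf, list(frag))
    pos <- mesh$rest_positions + 0.01 * matrix(rnorm(3 * n), n, 3)
    H <- assemble_energy(mesh, sc$material, pos)$hessian
    g <- 0.01 * rnorm(3 * n)
    red <- reduce_system(H, g, cp)
    z_red <- as.numeric(Matrix::solve(red$matrix, red$rhs))
    # dense KKT (Lagrange multiplier) oracle on min 1/2 x'Hx + g'x
    f <- cp$n_free_soft; b <- cp$n_rigid
    Hd <- as.matrix(H); Sd <- as.matrix(cp$S)
    Std <- as.matrix(cp$Stilde_soft); Ad <- as.matrix(cp$A)
    As <- Ad[, seq_len(f), drop = FALSE]
    Aq <- Ad[, f + seq_len(b), drop = FALSE]
    Cx <- Sd - As %*% Std
    m <- nrow(Sd)
    eps <- if (b > 0) 1e-8 * mean(diag(Hd)) else numeric(0)
    KKT <- rbind(cbind(Hd, matrix(0, 3 * n, b), t(Cx)),
                 if (b > 0) cbind(matrix(0, b, 3 * n), diag(eps, b), t(-Aq)),
                 cbind(Cx, -Aq, matrix(0, m, m)))
    sol <- solve(KKT, c(-g, numeric(b), cp$c))
    z_kkt <- c(as.numeric(Std %*% sol[1:(3 * n)]),
               if (b > 0) sol[3 * n + seq_len(b)])
    worst <- max(worst, max(abs(z_red - z_kkt)))
  }
  expect_lt(worst, 1e-8)
})

test_that("newton returns immediately when started at an equilibrium", {
  sc <- make_slab_scene(slab_spec(dims = c(8, 8, 8), resolution = c(2, 2, 2)))
  obj <- make_fem_objective(sc$mesh, sc$material)
  z0 <- free_vector(sc$coupling, as.numeric(t(sc$mesh$rest_positions)))
  st <- newton_solve(obj, sc$coupling, z0, solver_settings(), scale = 100)
  expect_true(st$converged)
  expect_equal(st$iterations, 0)
  expect_equal(st$energy, 0, tolerance = 1e-12)
})

test_that("newton converges in exactly one iteration on a quadratic objective", {
  set.seed(55)
  n <- 4
  tm <- ref_tet()
  cp <- build_coupling(tm)  # 12 unconstrained dofs
  A <- matrix(rnorm(144), 12, 12)
  Hq <- crossprod(A) + diag(12)
  bq <- rnorm(12)
  quad <- function(x, need_hessian = TRUE, refresh = TRUE) {
    list(energy = 0.5 * sum(x * (Hq %*% x)) - sum(bq * x),
         gradient = as.numeric(Hq %*% x) - bq,
         hessian = Matrix::Matrix(Hq, sparse = TRUE),
         evaluable = TRUE, contact_count = 0L)
  }
  st <- newton_solve(quad, cp, rnorm(12), solver_settings(grad_tol = 1e-10),
                     scale = 1)
  expect_true(st$converged)
  expect_equal(st$iterations, 1)
  expect_equal(st$iterate, as.numeric(solve(Hq, bq)), tolerance = 1e-8)
})

test_that("accepted energies are non-increasing within a solve", {
  sc <- two_fragment_scene()
  plan <- make_advance_plan(sc, "block1_b", c(3, 0, 0), substeps = 3)
  res <- run_plan(sc, plan, solver_settings())
  expect_true(res$converged)
  for (st in res$states) {
    e <- st$trace$energy
    expect_true(all(diff(e) <= 1e-10 * (1 + abs(e[-length(e)]))))
  }
})

test_that("a fully bonded slab under pure translation reaches the exact rigid equilibrium", {
  spec <- slab_spec(dims = c(20, 10, 10), resolution = c(4, 2, 2),
                    fixed_face = "none")
  sc <- make_slab_scene(spec)
  bn <- sort(unique(as.vector(sc$mesh$boundary_surface$faces)))
  frag <- rigid_fragment("f1", sc$mesh$boundary_surface)
  wf <- structure(list(node_ids = bn, fragment_ids = rep(list("f1"), length(bn)),
                       weights = rep(list(1), length(bn)), ramp_mm = 10),
                  class = "weight_field")
  sc$fragments <- list(f1 = frag)
  sc$coupling <- build_coupling(sc$mesh, integer(0), wf, list(frag))
  traj <- make_trajectory(frag, rigid_transform(diag(3), c(5, 0, 0)), 10)
  res <- run_plan(sc, list(traj), solver_settings(grad_tol = 1e-10))
  expect_true(res$converged)
  expect_lt(max(abs(sweep(res$positions - sc$mesh$rest_positions, 2,
                          c(5, 0, 0), "-"))), 1e-6)
  expect_lt(abs(res$states[[10]]$energy), 1e-10)
})

test_that("identity trajectories leave the mesh at rest", {
  sc <- two_fragment_scene()
  plan <- lapply(names(sc$fragments), function(id) {
    make_trajectory(sc$fragments[[id]], rigid_transform(), 3)
  })
  res <- run_plan(sc, plan, solver_settings())
  expect_true(res$converged)
  expect_lt(max(abs(res$positions - sc$mesh$rest_positions)), 1e-10)
})

test_that("doubling the substep count barely changes the quasistatic result", {
  sc <- two_fragment_scene(resolution = c(10, 5, 3))
  run_with <- function(nsub) {
    plan <- make_advance_plan(sc, "block1_b", c(4, 0, 0), substeps = nsub)
    run_plan(sc, plan, solver_settings())$positions
  }
  p10 <- run_with(10)
  p20 <- run_with(20)
  expect_lt(max(sqrt(rowSums((p10 - p20)^2))), 0.1)
})

test_that("coupling constraints hold exactly at every accepted iterate", {
  sc <- two_fragment_scene()
  plan <- make_advance_plan(sc, "block1_b", c(2, 0, 0), substeps = 2)
  res <- run_plan(sc, plan, solver_settings())
  st <- res$states[[2]]
  resid <- coupling_constraint(res$coupling, st$iterate, st$z)
  expect_lt(max(abs(resid)), 1e-10)
})
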