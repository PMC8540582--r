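#' Solver settings
#'
#' @param substeps number of substeps the planned transforms are decomposed
#'   into (default 10).
#' @param max_newton_per_substep Newton iteration cap per substep (default 50).
#' @param grad_tol reduced-gradient tolerance, in units of kPa mm^2, applied
#'   as `|g|_inf <= grad_tol * (1 + |energy| / scale)` with `scale` the
#'   mesh-size-independent normalization `E * (mean tet volume)^(2/3)`
#'   (default 1e-6).
#' @param line_search_shrink backtracking factor in (0, 1) (default 0.5).
#' @param armijo_c Armijo sufficient-decrease constant in (0, 0.5)
#'   (default 1e-4).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(substeps = 10L, max_newton_per_substep = 50L,
                            grad_tol = 1e-6, line_search_shrink = 0.5,
                            armijo_c = 1e-4) {
  substeps <- as.integer(substeps)
  if (is.na(substeps) || substeps < 1L) stop("substeps must be >= 1", call. = FALSE)
  if (!(line_search_shrink > 0 && line_search_shrink < 1)) {
    stop("line_search_shrink must lie in (0, 1)", call. = FALSE)
  }
  if (!(armijo_c > 0 && armijo_c < 0.5)) {
    stop("armijo_c must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(substeps = substeps,
                 max_newton_per_substep = as.integer(max_newton_per_substep),
                 grad_tol = grad_tol, line_search_shrink = line_search_shrink,
                 armijo_c = armijo_c),
            class = "solver_settings")
}

#' Reduce the constrained quadratic model to a linear system on the free DoFs
#'
#' For the quadratic model `min 1/2 x'Hx + g'x` subject to the coupling
#' `S x = A z + c`, substituting `x = S_tilde' z + S'(A z + c)` gives the
#' unconstrained system
#' `(S_tilde + A'S) H (S_tilde' + S'A) z = -(S_tilde + A'S)(g + H S'c)`.
#' Free-fragment rigid DoFs (unloaded and gravity-free, hence otherwise
#' indeterminate) receive a Tikhonov term `1e-8 * mean(diag(H))` on their
#' diagonal.
#'
#' @param H sparse symmetric `3n x 3n` Hessian.
#' @param g gradient of the quadratic model (length `3n`).
#' @param coupling a [coupling_system].
#' @return list with `matrix` (sparse, `(f+b) x (f+b)`), `rhs`, and the
#'   reduction map `T = S_tilde + A'S`.
#' @export
reduce_system <- function(H, g, coupling) {
  if (nrow(H) != coupling$n_dofs || length(g) != coupling$n_dofs) {
    stop("H/g dimensions do not match the coupling system", call. = FALSE)
  }
  f <- coupling$n_free_soft
  b <- coupling$n_rigid
  Tmap <- rbind(coupling$Stilde_soft,
                Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0),
                                     dims = c(b, coupling$n_dofs)))
  Tmap <- Tmap + Matrix::t(coupling$A) %*% coupling$S
  M <- Tmap %*% H %*% Matrix::t(Tmap)
  rhs <- -as.numeric(Tmap %*% (g + H %*% Matrix::t(coupling$S) %*% coupling$c))
  if (b > 0) {
    eps <- 1e-8 * mean(Matrix::diag(H))
    reg <- Matrix::sparseMatrix(i = f + seq_len(b), j = f + seq_len(b),
                                x = eps, dims = dim(M))
    M <- M + reg
  }
  list(matrix = M, rhs = rhs, T = Tmap)
}

#' Objective closure for the coupled soft-tissue problem
#'
#' Builds the callable the Newton solver minimizes: Neo-Hookean FEM energy
#' plus, when configured, the penalty contact energy. The contact set is
#' refreshed at the start of each Newton iterate (`refresh = TRUE`) and held
#' fixed during line-search evaluations so the contact term stays a true
#' quadratic within the iterate.
#'
#' @param mesh a [tet_mesh].
#' @param mat a [material].
#' @param f_ext external force vector (default `NULL` = zero).
#' @param contact optional list: `obstacles` (list of posed closed
#'   [surface_mesh] or [rigid_fragment]), `vertex_ids` (soft surface node
#'   indices checked for penetration; default the mesh boundary vertices),
#'   `stiffness` (default 1e4), `resolution_mm` (default 1), `grids`
#'   (optional precomputed SDF grids).
#' @param project_spd eigen-project element Hessians to PSD (default `TRUE`).
#' @return a function `f(x, need_hessian = TRUE, refresh = TRUE)` returning
#'   a list with `energy`, `gradient`, `hessian`, `evaluable`,
#'   `contact_count`.
#' @export
make_fem_objective <- function(mesh, mat, f_ext = NULL, contact = NULL,
                               project_spd = TRUE) {
  n <- nrow(mesh$rest_positions)
  if (!is.null(contact)) {
    if (is.null(contact$vertex_ids)) {
      contact$vertex_ids <- sort(unique(as.vector(mesh$boundary_surface$faces)))
    }
    if (is.null(contact$stiffness)) contact$stiffness <- 1e4
    if (is.null(contact$resolution_mm)) contact$resolution_mm <- 1
    contact$obstacles <- lapply(contact$obstacles, function(o) {
      if (inherits(o, "rigid_fragment")) fragment_posed_surface(o) else o
    })
    if (is.null(contact$grids)) {
      contact$grids <- lapply(contact$obstacles, sdf_grid,
                              resolution_mm = contact$resolution_mm)
    }
  }
  current_contacts <- NULL
  function(x, need_hessian = TRUE, refresh = TRUE) {
    se <- assemble_energy(mesh, mat, x, f_ext = f_ext, hessian = need_hessian,
                          project_spd = project_spd)
    if (!se$evaluable) {
      return(list(energy = NA_real_, gradient = NULL, hessian = NULL,
                  evaluable = FALSE, bad_element = se$bad_element,
                  det_f = se$det_f, contact_count = 0L))
    }
    energy <- se$total_energy
    gradient <- se$gradient
    hessian <- se$hessian
    ccount <- 0L
    if (!is.null(contact)) {
      if (refresh || is.null(current_contacts)) {
        pos <- matrix(x, n, 3, byrow = TRUE)
        current_contacts <<- detect_contacts(
          pos[contact$vertex_ids, , drop = FALSE], contact$vertex_ids,
          contact$obstacles, 3L * n, stiffness = contact$stiffness,
          sdf_resolution_mm = contact$resolution_mm, grids = contact$grids)
      }
      ce <- contact_energy(current_contacts, x)
      energy <- energy + ce$energy
      gradient <- gradient + ce$gradient
      if (need_hessian) hessian <- hessian + ce$hessian
      ccount <- nrow(current_contacts$pairs)
    }
    list(energy = energy, gradient = gradient, hessian = hessian,
         evaluable = TRUE, contact_count = ccount)
  }
}

#' Reduced Newton solve of one quasistatic equilibrium
#'
#' Minimizes the objective over the free DoFs `z`: at each iterate the
#' energy is approximated quadratically by its (PSD-projected) Hessian and
#' gradient, the coupling constraints are eliminated through
#' [reduce_system()] — so they are satisfied exactly at every iterate, never
#' penalized — and the step passes a backtracking Armijo line search. Steps
#' landing on non-evaluable states (an inverted element, `det F <= 0`) are
#' treated as infinite energy and halved.
#'
#' @param objective a function as returned by [make_fem_objective()].
#' @param coupling a [coupling_system].
#' @param z0 starting free vector (default: not supplied — required).
#' @param settings a [solver_settings].
#' @param scale energy normalization for the gradient tolerance (default 1;
#'   [run_plan()] passes `E * (mean tet volume)^(2/3)`).
#' @return An object of class `newton_state`: `z`, `iterate` (full DoF
#'   vector), `energy`, `iterations`, `converged`, `step_length` (last
#'   accepted), `trace` (per-iteration data frame), `message`.
#' @export
newton_solve <- function(objective, coupling, z0, settings = solver_settings(),
                         scale = 1) {
  z <- as.numeric(z0)
  x <- reconstruct_full_dofs(coupling, z)
  trace <- list()
  msg <- "converged"
  converged <- FALSE
  last_alpha <- NA_real_
  iter_done <- 0L

  for (it in seq_len(settings$max_newton_per_substep + 1L)) {
    ob <- objective(x, need_hessian = TRUE, refresh = TRUE)
    if (!ob$evaluable) {
      msg <- sprintf("non-evaluable state at iterate (element %d, det F = %.3g)",
                     ob$bad_element, ob$det_f)
      break
    }
    red <- reduce_system(ob$hessian, ob$gradient - as.numeric(ob$hessian %*% x),
                         coupling)
    g_red <- as.numeric(red$T %*% ob$gradient)
    gnorm <- if (length(g_red) > 0) max(abs(g_red)) else 0
    tol_eff <- settings$grad_tol * (1 + abs(ob$energy) / scale)
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = it - 1L, energy = ob$energy, grad_norm = gnorm,
      step_length = last_alpha, contacts = ob$contact_count)
    if (gnorm <= tol_eff || length(g_red) == 0) {
      converged <- TRUE
      break
    }
    if (it > settings$max_newton_per_substep) {
      msg <- "maximum Newton iterations reached"
      break
    }
    z_star <- tryCatch(as.numeric(Matrix::solve(red$matrix, red$rhs)),
                       error = function(e) NULL)
    if (is.null(z_star)) {
      # singular reduced matrix: regularize by a small diagonal shift
      shift <- Matrix::Diagonal(nrow(red$matrix),
                                1e-10 * mean(abs(Matrix::diag(red$matrix))) + 1e-300)
      z_star <- as.numeric(Matrix::solve(red$matrix + shift, red$rhs))
    }
    dz <- z_star - z
    gd <- sum(g_red * dz)
    if (!is.finite(gd) || gd >= 0) {
      dz <- -g_red
      gd <- -sum(g_red^2)
    }
    alpha <- 1
    accepted <- FALSE
    while (alpha >= 1e-12) {
      xt <- reconstruct_full_dofs(coupling, z + alpha * dz)
      ot <- objective(xt, need_hessian = FALSE, refresh = FALSE)
      if (ot$evaluable &&
          ot$energy <= ob$energy + settings$armijo_c * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * settings$line_search_shrink
    }
    if (!accepted) {
      msg <- sprintf("line search stagnated below step 1e-12 (|g| = %.3g, energy = %.6g)",
                     gnorm, ob$energy)
      break
    }
    z <- z + alpha * dz
    x <- reconstruct_full_dofs(coupling, z)
    last_alpha <- alpha
    iter_done <- it
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(0), energy = numeric(0),
               grad_norm = numeric(0), step_length = numeric(0),
               contacts = integer(0))
  ob_final <- objective(x, need_hessian = FALSE, refresh = TRUE)
  structure(list(z = z, iterate = x, energy = ob_final$energy,
                 iterations = iter_done, converged = converged,
                 step_length = last_alpha, trace = trace,
                 message = if (converged) "converged" else msg),
            class = "newton_state")
}

#' @export
print.newton_state <- function(x, ...) {
  cat(sprintf("newton_state: %d iterations, energy %.6g, %s\n",
              x$iterations, x$energy, x$message))
  invisible(x)
}

#' Run a substepped surgical plan to equilibrium
#'
#' Decomposed bone transforms are applied substep by substep: at each
#' substep the prescribed fragment poses advance along their trajectories,
#' the coupling offsets are refreshed, obstacle distance fields are rebuilt
#' at the new poses, and the quasistatic problem is solved by [newton_solve()]
#' warm-started from the previous substep's solution.
#'
#' @param scene a `sim_scene` as built by [make_slab_scene()] (fields `mesh`,
#'   `material`, `fragments`, `coupling`, optional `contact`).
#' @param trajectories list of [make_trajectory()] results (one per moved
#'   fragment; fragments without a trajectory hold their rest pose). All
#'   trajectories must share the same substep count.
#' @param settings a [solver_settings]; its `substeps` field is ignored in
#'   favor of the trajectories' length.
#' @return list with `positions` (`n x 3` final deformed positions), `mesh`,
#'   `fragments` (final poses), `log` (per-iteration data frame with substep
#'   column), `converged`, `states` (per-substep [newton_solve()] results).
#' @export
run_plan <- function(scene, trajectories, settings = solver_settings()) {
  mesh <- scene$mesh
  coupling <- scene$coupling
  fragments <- scene$fragments
  ids <- vapply(fragments, function(f) f$id, "")
  names(fragments) <- ids
  if (inherits(trajectories, "transform_trajectory")) {
    trajectories <- list(trajectories)
  }
  for (tr in trajectories) {
    if (!tr$fragment_id %in% ids) {
      stop(sprintf("trajectory names unknown fragment '%s'", tr$fragment_id),
           call. = FALSE)
    }
  }
  lens <- vapply(trajectories, function(tr) length(tr$substep_transforms), 1L)
  if (length(unique(lens)) > 1) {
    stop("all trajectories must have the same substep count", call. = FALSE)
  }
  nsub <- if (length(lens)) lens[1] else settings$substeps

  scale <- scene$material$young_modulus * mean(mesh$quadrature_weights)^(2 / 3)
  z <- free_vector(coupling, as_dof_vector(mesh$rest_positions,
                                           nrow(mesh$rest_positions)))
  logs <- list()
  states <- list()
  converged <- TRUE
  for (k in seq_len(nsub)) {
    for (tr in trajectories) {
      fragments[[tr$fragment_id]] <-
        set_fragment_pose(fragments[[tr$fragment_id]], tr$substep_transforms[[k]])
    }
    coupling <- update_coupling(coupling, fragments)
    contact <- scene$contact
    if (!is.null(contact)) {
      contact$obstacles <- lapply(contact$obstacle_ids, function(id) {
        fragment_posed_surface(fragments[[id]])
      })
      contact$grids <- NULL  # rebuild at the new poses
    }
    objective <- make_fem_objective(mesh, scene$material, f_ext = scene$f_ext,
                                    contact = contact)
    st <- newton_solve(objective, coupling, z, settings, scale = scale)
    z <- st$z
    states[[k]] <- st
    lg <- st$trace
    if (nrow(lg) > 0) lg <- cbind(substep = k, lg)
    logs[[k]] <- lg
    if (!st$converged) {
      converged <- FALSE
      warning(sprintf("substep %d did not converge: %s", k, st$message),
              call. = FALSE)
      break
    }
  }
  x <- reconstruct_full_dofs(coupling, z)
  list(positions = matrix(x, nrow(mesh$rest_positions), 3, byrow = TRUE),
       mesh = mesh, fragments = fragments,
       log = do.call(rbind, logs), converged = converged, states = states,
       coupling = coupling)
}
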