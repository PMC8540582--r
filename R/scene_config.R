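schema_keys <- list(
  top = c("schema_version", "mesh", "material", "fragments", "coupling",
          "contact", "solver", "output"),
  mesh = c("node_file", "ele_file"),
  material = c("young_modulus_kpa", "poisson_ratio"),
  fragment = c("id", "surface_file", "prescribed", "target"),
  target = c("rotation_rowmajor", "translation_mm"),
  coupling = c("interface_file", "fixed_nodes", "lbs_ramp_mm"),
  contact = c("pairs", "penalty_stiffness", "sdf_resolution_mm"),
  solver = c("substeps", "max_newton_per_substep", "grad_tol"),
  output = c("result", "log")
)

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown key%s at %s: %s", if (length(extra) > 1) "s" else "",
                 where, paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' Validate a JSON scene/plan file
#'
#' Parses and schema-checks a scene file, rejects unknown keys (naming the
#' offending JSON location), verifies that referenced files exist, and fills
#' defaults: 10 substeps, 10 mm smooth-coupling ramp, Young modulus 100 kPa
#' and Poisson ratio 0.47.
#'
#' @param path path to the scene JSON file.
#' @return An object of class `scene_config` (the resolved configuration;
#'   `base_dir` holds the scene directory all file paths resolve against).
#' @export
validate_scene <- function(path) {
  if (!file.exists(path)) stop(sprintf("scene file not found: %s", path), call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  check_keys(cfg, schema_keys$top, "/")
  check_keys(cfg$mesh, schema_keys$mesh, "/mesh")
  check_keys(cfg$material, schema_keys$material, "/material")
  check_keys(cfg$coupling, schema_keys$coupling, "/coupling")
  check_keys(cfg$contact, schema_keys$contact, "/contact")
  check_keys(cfg$solver, schema_keys$solver, "/solver")
  check_keys(cfg$output, schema_keys$output, "/output")
  if (is.null(cfg$mesh$node_file) || is.null(cfg$mesh$ele_file)) {
    stop("scene must name /mesh/node_file and /mesh/ele_file", call. = FALSE)
  }
  resolve <- function(f) file.path(base, f)
  for (f in c(cfg$mesh$node_file, cfg$mesh$ele_file)) {
    if (!file.exists(resolve(f))) {
      stop(sprintf("referenced file does not exist: %s", f), call. = FALSE)
    }
  }
  mat <- cfg$material
  if (is.null(mat)) mat <- list()
  if (is.null(mat$young_modulus_kpa)) mat$young_modulus_kpa <- 100
  if (is.null(mat$poisson_ratio)) mat$poisson_ratio <- 0.47
  if (mat$poisson_ratio <= 0 || mat$poisson_ratio >= 0.5) {
    stop("/material/poisson_ratio must lie strictly between 0 and 0.5", call. = FALSE)
  }
  if (mat$young_modulus_kpa <= 0) {
    stop("/material/young_modulus_kpa must be positive", call. = FALSE)
  }
  frags <- cfg$fragments
  if (is.null(frags)) frags <- list()
  for (q in seq_along(frags)) {
    fr <- frags[[q]]
    check_keys(fr, schema_keys$fragment, sprintf("/fragments[%d]", q))
    check_keys(fr$target, schema_keys$target, sprintf("/fragments[%d]/target", q))
    if (is.null(fr$id) || is.null(fr$surface_file)) {
      stop(sprintf("/fragments[%d] needs id and surface_file", q), call. = FALSE)
    }
    if (!file.exists(resolve(fr$surface_file))) {
      stop(sprintf("referenced file does not exist: %s", fr$surface_file), call. = FALSE)
    }
    if (is.null(fr$prescribed)) frags[[q]]$prescribed <- TRUE
    if (!is.null(fr$target)) {
      rr <- unlist(fr$target$rotation_rowmajor)
      tv <- unlist(fr$target$translation_mm)
      if (length(rr) != 9 || length(tv) != 3) {
        stop(sprintf("/fragments[%d]/target needs 9 rotation and 3 translation entries", q),
             call. = FALSE)
      }
      rigid_transform(matrix(rr, 3, 3, byrow = TRUE), tv)  # validates rotation
    }
  }
  cpl <- cfg$coupling
  if (is.null(cpl)) cpl <- list()
  if (is.null(cpl$lbs_ramp_mm)) cpl$lbs_ramp_mm <- 10
  if (cpl$lbs_ramp_mm <= 0) stop("/coupling/lbs_ramp_mm must be positive", call. = FALSE)
  if (!is.null(cpl$interface_file) && !file.exists(resolve(cpl$interface_file))) {
    stop(sprintf("referenced file does not exist: %s", cpl$interface_file), call. = FALSE)
  }
  ctc <- cfg$contact
  if (!is.null(ctc)) {
    if (is.null(ctc$penalty_stiffness)) ctc$penalty_stiffness <- 1e4
    if (is.null(ctc$sdf_resolution_mm)) ctc$sdf_resolution_mm <- 1
    frag_ids <- vapply(frags, function(fr) fr$id, "")
    for (pr in ctc$pairs) {
      pr <- unlist(pr)
      if (length(pr) != 2 || pr[1] != "soft" || !pr[2] %in% frag_ids) {
        stop(sprintf("/contact/pairs entries must be [\"soft\", <fragment id>]; got [%s]",
                     paste(pr, collapse = ", ")), call. = FALSE)
      }
    }
  }
  slv <- cfg$solver
  if (is.null(slv)) slv <- list()
  if (is.null(slv$substeps)) slv$substeps <- 10L
  if (is.null(slv$max_newton_per_substep)) slv$max_newton_per_substep <- 50L
  if (is.null(slv$grad_tol)) slv$grad_tol <- 1e-6
  out <- cfg$output
  if (is.null(out)) out <- list(result = "result.vtk", log = "log.csv")
  structure(list(schema_version = if (is.null(cfg$schema_version)) 1L else cfg$schema_version,
                 mesh = cfg$mesh, material = mat, fragments = frags,
                 coupling = cpl, contact = ctc, solver = slv, output = out,
                 base_dir = base),
            class = "scene_config")
}

#' Load the runtime scene described by a validated configuration
#'
#' @param config a `scene_config` from [validate_scene()].
#' @return a `sim_scene` plus `targets` (named list of [rigid_transform]).
#' @export
load_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  resolve <- function(f) file.path(config$base_dir, f)
  mesh <- read_tet_mesh(resolve(config$mesh$node_file),
                        resolve(config$mesh$ele_file))
  mat <- material(config$material$young_modulus_kpa,
                  config$material$poisson_ratio)
  fragments <- list()
  targets <- list()
  for (fr in config$fragments) {
    surf <- read_surface(resolve(fr$surface_file))
    fragments[[fr$id]] <- rigid_fragment(fr$id, surf,
                                         prescribed = isTRUE(fr$prescribed))
    targets[[fr$id]] <- if (is.null(fr$target)) rigid_transform() else
      rigid_transform(matrix(unlist(fr$target$rotation_rowmajor), 3, 3,
                             byrow = TRUE),
                      unlist(fr$target$translation_mm))
  }
  fixed_nodes <- as.integer(unlist(config$coupling$fixed_nodes))
  assignment <- NULL
  weights <- NULL
  interface <- NULL
  if (!is.null(config$coupling$interface_file)) {
    side <- jsonlite::fromJSON(resolve(config$coupling$interface_file))
    faces <- side$faces
    if (is.list(faces)) faces <- do.call(rbind, faces)
    faces <- matrix(as.integer(faces), ncol = 3)
    interface <- surface_mesh(mesh$rest_positions, faces, validate = FALSE)
    assignment <- assign_face_groups(interface, fragments)
    weights <- lbs_weight_field(assignment, interface,
                                ramp_mm = config$coupling$lbs_ramp_mm)
  }
  coupling <- build_coupling(mesh, fixed_nodes, weights, fragments)
  contact <- NULL
  if (!is.null(config$contact) && length(config$contact$pairs) > 0) {
    contact <- list(
      obstacle_ids = vapply(config$contact$pairs, function(p) unlist(p)[2], ""),
      stiffness = config$contact$penalty_stiffness,
      resolution_mm = config$contact$sdf_resolution_mm)
  }
  structure(list(mesh = mesh, material = mat, fragments = fragments,
                 interface = interface, assignment = assignment,
                 weight_field = weights, fixed_nodes = fixed_nodes,
                 coupling = coupling, contact = contact, f_ext = NULL,
                 targets = targets, ramp_mm = config$coupling$lbs_ramp_mm),
            class = "sim_scene")
}

#' Simulate a scene file end to end
#'
#' Validates and loads the scene, builds substepped trajectories from each
#' fragment's planned target, runs the solver, and writes the deformed mesh
#' (VTK), the per-iteration log (CSV) and a resolved-configuration echo for
#' provenance.
#'
#' @param path scene JSON path.
#' @param out_dir output directory (default: the scene's directory).
#' @param substeps optional override of the configured substep count.
#' @return the [run_plan()] result, invisibly.
#' @export
simulate_scene <- function(path, out_dir = NULL, substeps = NULL) {
  config <- validate_scene(path)
  if (is.null(out_dir)) out_dir <- config$base_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- load_scene(config)
  nsub <- if (is.null(substeps)) config$solver$substeps else as.integer(substeps)
  settings <- solver_settings(substeps = nsub,
                              max_newton_per_substep = config$solver$max_newton_per_substep,
                              grad_tol = config$solver$grad_tol)
  trajectories <- lapply(names(scene$fragments), function(id) {
    make_trajectory(scene$fragments[[id]], scene$targets[[id]], nsub)
  })
  res <- run_plan(scene, trajectories, settings)
  scalars <- list()
  if (!is.null(scene$weight_field)) {
    for (fid in names(scene$fragments)) {
      w <- numeric(nrow(res$positions))
      for (k in seq_along(scene$weight_field$node_ids)) {
        hit <- match(fid, scene$weight_field$fragment_ids[[k]])
        if (!is.na(hit)) {
          w[scene$weight_field$node_ids[k]] <- scene$weight_field$weights[[k]][hit]
        }
      }
      scalars[[paste0("lbs_weight_", fid)]] <- w
    }
  }
  write_vtk(res$mesh, file.path(out_dir, config$output$result),
            point_scalars = scalars, positions = res$positions)
  if (!is.null(res$log)) {
    write.csv(res$log, file.path(out_dir, config$output$log), row.names = FALSE)
  }
  resolved <- unclass(config)
  resolved$base_dir <- NULL
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Write a generated scene to disk as a portable fixture
#'
#' Emits the TetGen-format volume mesh, one OBJ per fragment, the interface
#' sidecar (faces indexed into the volume mesh) and a scene JSON referencing
#' them — the on-disk counterpart of [make_slab_scene()].
#'
#' @param scene a `sim_scene`.
#' @param dir output directory.
#' @param targets optional named list of [rigid_transform] per fragment.
#' @return the scene JSON path, invisibly.
#' @export
write_scene_fixture <- function(scene, dir, targets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tet_mesh(scene$mesh, file.path(dir, "tissue.node"),
                 file.path(dir, "tissue.ele"))
  frag_entries <- list()
  for (fid in names(scene$fragments)) {
    fn <- sprintf("fragment_%s.obj", fid)
    write_surface(scene$fragments[[fid]]$surface, file.path(dir, fn))
    tgt <- if (!is.null(targets) && !is.null(targets[[fid]])) targets[[fid]] else NULL
    entry <- list(id = fid, surface_file = fn, prescribed = TRUE)
    if (!is.null(tgt)) {
      entry$target <- list(rotation_rowmajor = as.numeric(t(tgt$rotation)),
                           translation_mm = tgt$translation)
    }
    frag_entries[[length(frag_entries) + 1L]] <- entry
  }
  if (!is.null(scene$interface) && nrow(scene$interface$faces) > 0) {
    jsonlite::write_json(list(faces = apply(scene$interface$faces, 1, identity,
                                            simplify = FALSE)),
                         file.path(dir, "interface.json"), digits = NA)
    interface_file <- "interface.json"
  } else {
    interface_file <- NULL
  }
  cfg <- list(schema_version = 1,
              mesh = list(node_file = "tissue.node", ele_file = "tissue.ele"),
              material = list(young_modulus_kpa = scene$material$young_modulus,
                              poisson_ratio = scene$material$poisson_ratio),
              fragments = frag_entries,
              coupling = c(list(fixed_nodes = as.integer(scene$fixed_nodes),
                                lbs_ramp_mm = scene$ramp_mm),
                           if (!is.null(interface_file))
                             list(interface_file = interface_file)),
              solver = list(substeps = 10))
  path <- file.path(dir, "scene.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
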