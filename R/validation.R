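#' Rigid registration by iterative closest point
#'
#' Point-to-point ICP: each iteration pairs every source vertex with its
#' closest point on the target surface, fits the best rigid transform by
#' Procrustes (SVD with reflection guard) and applies it. The RMS of
#' correspondence distances is non-increasing; iteration stops when its
#' change drops below `tol` or `max_iters` is reached. Used to recover the
#' transform actually applied to a bone fragment by comparing its pre- and
#' post-operative surfaces.
#'
#' @param source,target [surface_mesh] objects with rough initial overlap.
#' @param max_iters iteration cap (default 100).
#' @param tol stop when the RMS residual changes by less than this (mm,
#'   default 1e-8).
#' @return An object of class `registration_result`: `transform` (the
#'   [rigid_transform] mapping source onto target), `rms_residual` (mm),
#'   `iterations`, `converged`, `rms_history`.
#' @export
icp_register <- function(source, target, max_iters = 100L, tol = 1e-8) {
  if (nrow(source$vertices) == 0 || nrow(target$vertices) == 0 ||
      nrow(target$faces) == 0) {
    stop("source and target meshes must be non-empty", call. = FALSE)
  }
  cur <- source$vertices
  R_acc <- diag(3)
  t_acc <- c(0, 0, 0)
  rms_hist <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    cp <- closest_surface_points(cur, target)
    q <- cp$point
    pc <- colMeans(cur)
    qc <- colMeans(q)
    Hm <- crossprod(sweep(cur, 2, pc), sweep(q, 2, qc))
    s <- svd(Hm)
    R <- s$v %*% t(s$u)
    if (det(R) < 0) {
      v <- s$v
      v[, 3] <- -v[, 3]
      R <- v %*% t(s$u)
    }
    tv <- qc - as.numeric(R %*% pc)
    cur <- sweep(cur %*% t(R), 2, tv, "+")
    R_acc <- R %*% R_acc
    t_acc <- as.numeric(R %*% t_acc + tv)
    rms <- sqrt(mean(rowSums((cur - q)^2)))
    rms_hist <- c(rms_hist, rms)
    if (abs(prev_rms - rms) < tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  structure(list(transform = rigid_transform(project_rotation(R_acc), t_acc),
                 rms_residual = rms_hist[length(rms_hist)],
                 iterations = it, converged = converged,
                 rms_history = rms_hist),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  aa <- rotation_log(x$transform$rotation)
  cat(sprintf("registration_result: %d iterations, rms %.4g mm, angle %.4g deg, %s\n",
              x$iterations, x$rms_residual, sqrt(sum(aa^2)) * 180 / pi,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Signed closest-point error map against a reference surface
#'
#' Per-vertex signed distance of the simulated surface to the reference
#' (negative = inside the reference volume), restricted to a
#' region-of-interest mask, with the cumulative percentage of surface area
#' whose absolute error falls below each threshold. Percentages are
#' area-weighted by default (one third of incident face areas per vertex);
#' vertex counting is available for comparison.
#'
#' @param sim_surface simulated [surface_mesh].
#' @param reference reference [surface_mesh] (closed unless `allow_open`).
#' @param roi optional logical mask per sim vertex (`TRUE` = inside the
#'   clinical region of interest); default all.
#' @param thresholds positive increasing thresholds in mm (default 1:8,
#'   spaced 1 mm).
#' @param allow_open permit an open reference (sign from nearest-face normal).
#' @param area_weighted weight vertices by surface area (default `TRUE`).
#' @return An object of class `error_map`: `per_vertex_signed_error` (mm),
#'   `roi_mask`, `thresholds`, `cumulative_pct`, `vertex_weights`.
#' @export
compute_error_map <- function(sim_surface, reference, roi = NULL,
                              thresholds = 1:8, allow_open = FALSE,
                              area_weighted = TRUE) {
  thresholds <- as.numeric(thresholds)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  }
  nv <- nrow(sim_surface$vertices)
  if (is.null(roi)) roi <- rep(TRUE, nv)
  if (length(roi) != nv || !is.logical(roi)) {
    stop("roi must be a logical mask with one entry per sim vertex", call. = FALSE)
  }
  err <- signed_distance_query(sim_surface$vertices, reference,
                               allow_open = allow_open)
  w <- if (area_weighted) vertex_areas(sim_surface) else rep(1, nv)
  wt <- sum(w[roi])
  if (wt <= 0) stop("ROI covers no surface area", call. = FALSE)
  cum <- vapply(thresholds, function(th) {
    100 * sum(w[roi & abs(err) < th]) / wt
  }, 0)
  structure(list(per_vertex_signed_error = err, roi_mask = roi,
                 thresholds = thresholds, cumulative_pct = cum,
                 vertex_weights = w, area_weighted = area_weighted),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat("error_map:\n")
  for (k in seq_along(x$thresholds)) {
    cat(sprintf("  |error| < %g mm: %6.2f %%\n", x$thresholds[k],
                x$cumulative_pct[k]))
  }
  invisible(x)
}

#' Summarize an error map against the clinical threshold
#'
#' Reports the percentage of (ROI) surface with absolute error at or below
#' the clinically acceptable limit (3 mm by default), signed-error extremes
#' and mean, and optionally writes the cumulative curve as CSV and a VTK
#' overlay carrying the per-vertex `signed_error_mm` scalar. The recommended
#' color-map range for the overlay, -4 to 4 mm, is recorded as metadata.
#'
#' @param map an [error_map].
#' @param clinical_threshold mm (default 3).
#' @param csv_path optional path for the cumulative-curve CSV.
#' @param vtk_path optional path for the VTK overlay (requires `surface`).
#' @param surface the simulated [surface_mesh] (for the VTK overlay).
#' @return An object of class `error_report`.
#' @export
error_report <- function(map, clinical_threshold = 3, csv_path = NULL,
                         vtk_path = NULL, surface = NULL) {
  err <- map$per_vertex_signed_error
  w <- map$vertex_weights
  roi <- map$roi_mask
  pct <- 100 * sum(w[roi & abs(err) <= clinical_threshold]) / sum(w[roi])
  rep <- structure(list(
    clinical_threshold_mm = clinical_threshold,
    pct_within_clinical = pct,
    min_signed_error_mm = min(err[roi]),
    max_signed_error_mm = max(err[roi]),
    mean_signed_error_mm = sum((w * err)[roi]) / sum(w[roi]),
    thresholds = map$thresholds,
    cumulative_pct = map$cumulative_pct,
    colormap_range_mm = c(-4, 4)
  ), class = "error_report")
  if (!is.null(csv_path)) {
    write.csv(data.frame(threshold_mm = map$thresholds,
                         cumulative_pct = map$cumulative_pct),
              csv_path, row.names = FALSE)
  }
  if (!is.null(vtk_path)) {
    if (is.null(surface)) stop("surface is required for the VTK overlay", call. = FALSE)
    write_vtk(surface, vtk_path,
              point_scalars = list(signed_error_mm = err))
  }
  rep
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report: %.2f %% of ROI surface within %g mm\n",
              x$pct_within_clinical, x$clinical_threshold_mm))
  cat(sprintf("  signed error min %.3g / mean %.3g / max %.3g mm\n",
              x$min_signed_error_mm, x$mean_signed_error_mm,
              x$max_signed_error_mm))
  invisible(x)
}
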