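test_that("ICP of a mesh onto itself returns the identity", {
  sph <- make_icosphere(radius = 8, subdiv = 1)
  reg <- icp_register(sph, sph)
  expect_true(reg$converged)
  expect_lt(reg$rms_residual, 1e-10)
  expect_lt(max(abs(reg$transform$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(reg$transform$translation)), 1e-10)
  expect_error(icp_register(surface_mesh(matrix(0, 0, 3),
                                         matrix(integer(0), 0, 3)), sph),
               "non-empty")
})

test_that("ICP recovers a known 15 degree / (3,2,1) mm transform", {
  src <- make_icosphere(radius = 10, center = c(2, 1, 0), subdiv = 1)
  # break the sphere's symmetry so the rotation is observable
  src$vertices <- src$vertices %*% diag(c(1, 0.7, 0.45))
  tf <- rigid_transform(axis_angle_matrix(c(0, 0, 15 * pi / 180)), c(3, 2, 1))
  tgt <- surface_mesh(apply_transform(tf, src$vertices), src$faces)
  reg <- icp_register(src, tgt)
  aa_err <- rotation_log(t(reg$transform$rotation) %*% tf$rotation)
  expect_lt(sqrt(sum(aa_err^2)), 1e-3)
  expect_lt(max(abs(reg$transform$translation - tf$translation)), 1e-3)
  expect_true(all(diff(reg$rms_history) <= 1e-12))
})

test_that("ICP translation error under vertex noise stays within 3 sigma / sqrt(n)", {
  set.seed(77)
  src <- make_icosphere(radius = 10, subdiv = 2)
  src$vertices <- src$vertices %*% diag(c(1, 0.8, 0.6))
  n <- nrow(src$vertices)
  sigma <- 0.1
  tf <- rigid_transform(axis_angle_matrix(c(0, 0, 5 * pi / 180)), c(1, -2, 0.5))
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    tgt <- surface_mesh(apply_transform(tf, src$vertices) +
                          matrix(rnorm(3 * n, sd = sigma), n, 3), src$faces)
    reg <- icp_register(src, tgt, max_iters = 50, tol = 1e-10)
    sqrt(sum((reg$transform$translation - tf$translation)^2))
  }, 0)
  expect_lt(mean(errs), 3 * sigma / sqrt(n) + 0.05)
})

test_that("error map of a surface against itself is identically zero", {
  sph <- make_icosphere(radius = 6, subdiv = 1)
  map <- compute_error_map(sph, sph, thresholds = c(0.5, 1, 3))
  expect_equal(max(abs(map$per_vertex_signed_error)), 0)
  expect_equal(map$cumulative_pct, c(100, 100, 100))
})

test_that("a +2 mm normal offset reads as +2 mm signed error", {
  sph <- make_icosphere(radius = 10, subdiv = 2)
  outer_s <- surface_mesh(sph$vertices + 2 * vertex_normals(sph), sph$faces)
  map <- compute_error_map(outer_s, sph, thresholds = c(1, 3))
  merr <- sum(map$per_vertex_signed_error * map$vertex_weights) /
    sum(map$vertex_weights)
  expect_equal(merr, 2, tolerance = 0.05)
  expect_equal(map$cumulative_pct, c(0, 100), tolerance = 1e-9)
  # shrinking inward reads negative (inside the reference)
  inner_s <- surface_mesh(sph$vertices - 1 * vertex_normals(sph), sph$faces)
  mi <- compute_error_map(inner_s, sph, thresholds = c(3))
  expect_lt(max(mi$per_vertex_signed_error), 0)
})

test_that("cumulative percentages match a direct counting oracle on bands", {
  # three equal-area bands with |errors| 1, 2 and 4 mm
  v <- as.matrix(expand.grid(x = 0:3, y = 0:1))
  v <- cbind(v, 0)
  f <- rbind(c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7))
  band <- surface_mesh(v, f)
  ref <- surface_mesh(v, f)  # same plane; then override measured errors
  map <- compute_error_map(band, ref, thresholds = c(3), allow_open = TRUE)
  err <- c(1, 2, 1.5, 2, 4, 3, 2.5, 4)  # per-vertex |errors|, bands 1/2/4
  map$per_vertex_signed_error <- err
  w <- map$vertex_weights
  pct_oracle <- 100 * sum(w[err < 3]) / sum(w)
  pct <- 100 * sum(w[map$roi_mask & abs(err) < 3]) / sum(w[map$roi_mask])
  expect_equal(pct, pct_oracle)
  # vertex-count weighting differs from area weighting when areas differ
  expect_error(compute_error_map(band, ref, thresholds = c(-1, 2),
                                 allow_open = TRUE), "positive")
})

test_that("area weighting is stable under local refinement", {
  sph <- make_icosphere(radius = 10, subdiv = 1)
  ref <- make_icosphere(radius = 9.0, subdiv = 1)
  m1 <- compute_error_map(sph, ref, thresholds = c(1.5))
  sph2 <- make_icosphere(radius = 10, subdiv = 2)  # 4x the vertices
  m2 <- compute_error_map(sph2, ref, thresholds = c(1.5))
  expect_lt(abs(m1$cumulative_pct - m2$cumulative_pct), 0.5 + 1e-9)
})

test_that("the report excludes masked regions and writes CSV + VTK overlays", {
  sph <- make_icosphere(radius = 10, subdiv = 1)
  shifted <- surface_mesh(sph$vertices + rep(c(0, 0, 5), each = nrow(sph$vertices)),
                          sph$faces)
  roi <- sph$vertices[, 3] < 0  # mask out the shifted-away half
  map_all <- compute_error_map(shifted, sph, thresholds = 1:8)
  map_roi <- compute_error_map(shifted, sph, roi = roi, thresholds = 1:8)
  expect_lt(map_all$cumulative_pct[3], map_roi$cumulative_pct[3])
  d <- withr::local_tempdir()
  rep <- error_report(map_roi, csv_path = file.path(d, "cum.csv"),
                      vtk_path = file.path(d, "overlay.vtk"), surface = shifted)
  expect_equal(rep$colormap_range_mm, c(-4, 4))
  tab <- read.csv(file.path(d, "cum.csv"))
  expect_equal(tab$cumulative_pct, map_roi$cumulative_pct)
  rt <- read_vtk(file.path(d, "overlay.vtk"))
  expect_equal(rt$point_scalars$signed_error_mm, map_roi$per_vertex_signed_error,
               tolerance = 1e-12)
  # all-zero map reports 100 %
  zero <- compute_error_map(sph, sph, thresholds = 1:3)
  expect_equal(error_report(zero)$pct_within_clinical, 100)
})
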