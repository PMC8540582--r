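test_that("surface mesh construction validates indices and degeneracy", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, matrix(c(1, 2, 3), 1))
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_error(surface_mesh(v, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(surface_mesh(v, matrix(c(1, 2, 2), 1)), "degenerate")
})

test_that("OBJ round trip preserves coordinates, connectivity and groups", {
  m <- box_surface(c(0, 0, 0), c(2.123456789012345, 3, 4))
  m$face_groups <- rep(1:2, each = 6)
  path <- withr::local_tempfile(fileext = ".obj")
  write_surface(m, path)
  m2 <- read_surface(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(nrow(m2$faces), 12)
  expect_equal(length(unique(m2$face_groups)), 2)
  # same geometry: identical face areas and total volume
  expect_equal(sort(face_areas(m2)), sort(face_areas(m)), tolerance = 1e-12)
  expect_equal(surface_volume_centroid(m2)$volume,
               surface_volume_centroid(m)$volume, tolerance = 1e-12)
})

test_that("single-triangle OBJ parses and 0-index faces are rejected", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  m <- read_surface(path)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 0 1 2"), path)
  expect_error(read_surface(path), "1-based")
})

test_that("binary STL cube round-trips topology after duplicate-vertex welding", {
  m <- box_surface(c(0, 0, 0), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".stl")
  write_surface(m, path, binary = TRUE)
  m2 <- read_surface(path)
  expect_equal(nrow(m2$faces), 12)
  expect_equal(nrow(m2$vertices), 8)  # welded from 36 stored vertices
  expect_true(is_closed_surface(m2))
  expect_equal(surface_volume_centroid(m2)$volume, 1, tolerance = 1e-6)
})

test_that("ascii STL and PLY round-trip", {
  m <- box_surface(c(-1, 0, 2), c(1, 2, 5))
  stl <- withr::local_tempfile(fileext = ".stl")
  write_surface(m, stl, binary = FALSE)
  m2 <- read_surface(stl)
  expect_equal(nrow(m2$faces), 12)
  expect_true(is_closed_surface(m2))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_surface(m, ply)
  m3 <- read_surface(ply)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(m3$faces, m$faces)
})

test_that("unit reference tet has volume 1/6 and valid element basis", {
  tm <- ref_tet()
  expect_equal(tm$quadrature_weights, 1 / 6, tolerance = 1e-12)
  expect_equal(nrow(tm$boundary_surface$faces), 4)
})

test_that("structured slab tet volumes sum to the bounding box volume", {
  spec <- slab_spec(dims = c(2, 1, 1), resolution = c(2, 2, 2),
                    fixed_face = "none")
  sc <- make_slab_scene(spec)
  expect_equal(nrow(sc$mesh$tets), 2 * 2 * 2 * 5)
  expect_equal(sum(sc$mesh$quadrature_weights), 2, tolerance = 1e-9)
})

test_that("tet meshes read identically from 0-based and 1-based files", {
  tm <- two_tet_mesh()
  d <- withr::local_tempdir()
  write_tet_mesh(tm, file.path(d, "a.node"), file.path(d, "a.ele"))
  # handcraft the 0-based twin
  X <- tm$rest_positions
  writeLines(c(sprintf("%d 3 0 0", nrow(X)),
               sprintf("%d %.17g %.17g %.17g", seq_len(nrow(X)) - 1L,
                       X[, 1], X[, 2], X[, 3])), file.path(d, "b.node"))
  tt <- tm$tets
  writeLines(c(sprintf("%d 4 0", nrow(tt)),
               sprintf("%d %d %d %d %d", seq_len(nrow(tt)) - 1L,
                       tt[, 1] - 1L, tt[, 2] - 1L, tt[, 3] - 1L, tt[, 4] - 1L)),
             file.path(d, "b.ele"))
  m1 <- read_tet_mesh(file.path(d, "a.node"), file.path(d, "a.ele"))
  m0 <- read_tet_mesh(file.path(d, "b.node"), file.path(d, "b.ele"))
  expect_identical(m0$tets, m1$tets)
  expect_equal(m0$rest_positions, m1$rest_positions, tolerance = 1e-15)
  expect_equal(m0$quadrature_weights, m1$quadrature_weights)
})

test_that("tet mesh rejects malformed or degenerate input", {
  d <- withr::local_tempdir()
  writeLines(c("2 3 0 0", "1 0 0 0", "2 1 0 0"), file.path(d, "bad.node"))
  writeLines(c("1 4 0", "1 1 2 1 2"), file.path(d, "bad.ele"))
  expect_error(read_tet_mesh(file.path(d, "bad.node"), file.path(d, "bad.ele")))
  # zero-volume tet (coplanar points)
  expect_error(tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        matrix(1:4, 1)), "zero-volume")
})

test_that("inverted tets are reoriented to positive volume", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tm <- tet_mesh(X, matrix(c(1L, 2L, 4L, 3L), 1))  # negative orientation
  expect_equal(tm$quadrature_weights, 1 / 6, tolerance = 1e-12)
})

test_that("total mesh volume is invariant under rigid motion of rest positions", {
  set.seed(7)
  tm <- two_tet_mesh()
  R <- random_rotation()
  X2 <- sweep(tm$rest_positions %*% t(R), 2, c(3, -2, 5), "+")
  tm2 <- tet_mesh(X2, tm$tets)
  expect_equal(sum(tm2$quadrature_weights), sum(tm$quadrature_weights),
               tolerance = 1e-9)
})

test_that("VTK files round-trip geometry and named point scalars", {
  tm <- two_tet_mesh()
  path <- withr::local_tempfile(fileext = ".vtk")
  sc <- list(signed_error_mm = c(-1.25, 0, 2.5, 1e-7, 3.14159265358979))
  write_vtk(tm, path, point_scalars = sc)
  rt <- read_vtk(path)
  expect_equal(rt$mesh$rest_positions, tm$rest_positions, tolerance = 1e-12)
  expect_identical(rt$mesh$tets, tm$tets)
  expect_equal(rt$point_scalars$signed_error_mm, sc$signed_error_mm,
               tolerance = 1e-12)
  # surface variant with empty scalars writes geometry only
  spath <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(tm$boundary_surface, spath)
  rt2 <- read_vtk(spath)
  expect_s3_class(rt2$mesh, "surface_mesh")
  expect_length(rt2$point_scalars, 0)
  expect_error(write_vtk(tm, path, point_scalars = list(bad = 1:2)),
               "length mismatch")
})
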