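test_that("face groups split a two-fragment interface along the cut plane", {
  sc <- two_fragment_scene()
  a <- sc$assignment
  expect_error(assign_face_groups(sc$interface, list()), "empty")
  expect_setequal(a$fragment_ids, c("block1_a", "block1_b"))
  cen <- face_centroids(sc$interface)
  # labels follow the sign of the centroid x against the cut at x = 20
  expect_true(all(a$fragment_of_face[cen[, 1] < 20 - 1e-9] == "block1_a"))
  expect_true(all(a$fragment_of_face[cen[, 1] > 20 + 1e-9] == "block1_b"))
  # cut-interface vertices lie on the cut plane
  expect_gt(length(a$cut_interface_vertices), 0)
  expect_true(all(abs(sc$interface$vertices[a$cut_interface_vertices, 1] - 20) < 1e-9))
})

test_that("a single uncut fragment yields one group and no cut vertices", {
  spec <- slab_spec(dims = c(20, 20, 12), resolution = c(5, 5, 3),
                    blocks = list(list(min = c(4, 4, 4), max = c(16, 16, 8))))
  sc <- make_slab_scene(spec)
  expect_equal(unique(sc$assignment$fragment_of_face), "block1")
  expect_length(sc$assignment$cut_interface_vertices, 0)
  expect_true(all(vapply(sc$weight_field$weights, identical, TRUE, 1)))
})

test_that("equidistant faces break ties to the lexicographically smallest id", {
  # two identical fragments equidistant from a mid-plane interface strip
  fa2 <- rigid_fragment("beta", box_surface(c(-2, 0, -2), c(0, 1, 2)))
  fb2 <- rigid_fragment("alpha", box_surface(c(1, 0, -2), c(3, 1, 2)))
  asg <- assign_face_groups(surface_mesh(rbind(c(0.4, 0, 0), c(0.6, 0, 0),
                                               c(0.5, 1, 0)),
                                         matrix(1:3, 1)),
                            list(fa2, fb2))
  # centroid at x = 0.5: both fragments at distance 0.5 -> "alpha" wins
  expect_equal(asg$fragment_of_face, "alpha")
})

test_that("LBS weights are 0.5 at the cut, ramp linearly, and sum to one", {
  sc <- two_fragment_scene()
  wf <- sc$weight_field
  cutv <- sc$assignment$cut_interface_vertices
  cut_pos <- sc$interface$vertices[cutv, , drop = FALSE]
  for (k in seq_along(wf$node_ids)) {
    w <- wf$weights[[k]]
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    v <- wf$node_ids[k]
    d <- min(sqrt(colSums((t(cut_pos) - sc$interface$vertices[v, ])^2)))
    if (v %in% cutv) {
      expect_equal(w, c(0.5, 0.5))
    } else if (d >= 10) {
      expect_equal(w, 1)
    } else {
      expect_equal(w[1], 0.5 + 0.5 * d / 10, tolerance = 1e-12)
    }
  }
  # spot values on the printed ramp: 0 mm -> 0.5, 5 mm -> 0.75, >= 10 mm -> 1.0
  dists <- vapply(seq_along(wf$node_ids), function(k) {
    min(sqrt(colSums((t(cut_pos) - sc$interface$vertices[wf$node_ids[k], ])^2)))
  }, 0)
  expect_true(any(abs(dists - 4) < 1e-9))  # 4 mm grid spacing gives d = 4
  k4 <- which(abs(dists - 4) < 1e-9)[1]
  expect_equal(wf$weights[[k4]][1], 0.7, tolerance = 1e-12)
  expect_error(lbs_weight_field(sc$assignment, sc$interface, ramp_mm = 0),
               "positive")
})

test_that("weight field is continuous across interface edges", {
  sc <- two_fragment_scene()
  wf <- sc$weight_field
  wmap <- new.env()
  for (k in seq_along(wf$node_ids)) {
    assign(as.character(wf$node_ids[k]),
           stats::setNames(wf$weights[[k]], wf$fragment_ids[[k]]),
           envir = wmap)
  }
  f <- sc$interface$faces
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  for (r in seq_len(nrow(edges))) {
    wa <- get(as.character(edges[r, 1]), envir = wmap)
    wb <- get(as.character(edges[r, 2]), envir = wmap)
    len <- sqrt(sum((sc$interface$vertices[edges[r, 1], ] -
                       sc$interface$vertices[edges[r, 2], ])^2))
    for (fid in union(names(wa), names(wb))) {
      da <- if (fid %in% names(wa)) wa[[fid]] else 0
      db <- if (fid %in% names(wb)) wb[[fid]] else 0
      expect_lte(abs(da - db), len / wf$ramp_mm + 1e-9)
    }
  }
})

test_that("coupling system partitions the DoFs exactly", {
  sc <- two_fragment_scene()
  cp <- sc$coupling
  StS <- Matrix::t(cp$S) %*% cp$S
  StS2 <- Matrix::t(cp$Stilde_soft) %*% cp$Stilde_soft
  expect_equal(max(abs(StS + StS2 - Matrix::Diagonal(cp$n_dofs))), 0)
  expect_true(all(Matrix::rowSums(cp$S != 0) == 1))
})

test_that("empty and all-fixed couplings reconstruct trivially", {
  tm <- two_tet_mesh()
  cp0 <- build_coupling(tm)
  z <- rnorm(15)
  expect_equal(reconstruct_full_dofs(cp0, z), z)
  cpf <- build_coupling(tm, fixed_nodes = 1:5)
  x <- reconstruct_full_dofs(cpf, numeric(0))
  expect_equal(matrix(x, 5, 3, byrow = TRUE), tm$rest_positions)
  expect_error(reconstruct_full_dofs(cpf, 1), "length")
})

test_that("reconstruction matches index-by-index bookkeeping on a random instance", {
  set.seed(17)
  sc <- make_slab_scene(slab_spec(dims = c(12, 8, 8), resolution = c(3, 2, 2),
                                  fixed_face = "none"))
  mesh <- sc$mesh
  n <- nrow(mesh$rest_positions)
  fixed <- sample(n, 4)
  rest <- setdiff(seq_len(n), fixed)
  bonded <- sample(rest, 6)
  frag <- rigid_fragment("fr", box_surface(c(2, 2, 9), c(10, 6, 12)))
  frag <- set_fragment_pose(frag, rigid_transform(axis_angle_matrix(c(0, 0.1, 0.2)),
                                                  c(1, -2, 0.5)))
  wf <- structure(list(node_ids = sort(bonded),
                       fragment_ids = rep(list("fr"), 6),
                       weights = rep(list(1), 6), ramp_mm = 10),
                  class = "weight_field")
  cp <- build_coupling(mesh, fixed, wf, list(frag))
  z <- rnorm(cp$n_free_soft)
  x <- reconstruct_full_dofs(cp, z)
  # brute-force oracle: place each dof by hand
  xo <- numeric(3 * n)
  free_nodes <- setdiff(seq_len(n), c(fixed, bonded))
  # free dofs appear in z in increasing dof order
  free_dofs <- sort(as.vector(t(outer(3 * (sort(free_nodes) - 1), 1:3, "+"))))
  xo[free_dofs] <- z
  for (v in fixed) xo[3 * (v - 1) + 1:3] <- mesh$rest_positions[v, ]
  for (v in sort(bonded)) {
    xo[3 * (v - 1) + 1:3] <- as.numeric(
      frag$rotation %*% (mesh$rest_positions[v, ] - frag$com_rest)) +
      frag$center_of_mass
  }
  expect_equal(x, xo, tolerance = 1e-14)
  expect_equal(max(abs(coupling_constraint(cp, x, z))), 0, tolerance = 1e-12)
  expect_error(build_coupling(mesh, c(fixed, bonded[1]), wf, list(frag)),
               "both fixed and coupled")
})

test_that("bonded nodes follow a pure fragment translation exactly", {
  sc <- two_fragment_scene()
  frs <- sc$fragments
  for (id in names(frs)) {
    frs[[id]] <- set_fragment_pose(frs[[id]], rigid_transform(diag(3), c(1, 0, 0)))
  }
  cp <- update_coupling(sc$coupling, frs)
  z <- free_vector(cp, as.numeric(t(sc$mesh$rest_positions)))
  x <- reconstruct_full_dofs(cp, z)
  pos <- matrix(x, ncol = 3, byrow = TRUE)
  cn <- sc$weight_field$node_ids
  expect_equal(pos[cn, ], sweep(sc$mesh$rest_positions[cn, ], 2, c(1, 0, 0), "+"),
               tolerance = 1e-12)
})
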