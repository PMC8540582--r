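# Shared fixtures and independent oracles for the test suite.

# Reference tetrahedron: origin plus the three unit axis points (volume 1/6).
ref_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

# Two conforming tets sharing a face.
two_tet_mesh <- function() {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tet_mesh(X, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

# Icosphere by midpoint subdivision (outward-oriented).
make_icosphere <- function(radius = 1, center = c(0, 0, 0), subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- get0(key, envir = mid_cache)
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      idx <- nrow(v)
      assign(key, idx, envir = mid_cache)
      idx
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

# Independent point-triangle closest point: plane projection with barycentric
# test, falling back to the nearest clamped edge projection.
cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

cp_tri_oracle <- function(p, a, b, c) {
  n <- cross_oracle(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric coordinates of q
  m <- cbind(b - a, c - a)
  uv <- qr.solve(crossprod(m), crossprod(m, q - a))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) return(q)
  seg <- function(p, s, e) {
    t <- sum((p - s) * (e - s)) / sum((e - s)^2)
    s + min(1, max(0, t)) * (e - s)
  }
  cands <- rbind(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  cands[which.min(rowSums(sweep(cands, 2, p)^2)), ]
}

closest_dist_oracle <- function(p, mesh) {
  f <- mesh$faces; v <- mesh$vertices
  min(vapply(seq_len(nrow(f)), function(t) {
    cp <- cp_tri_oracle(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
    sqrt(sum((p - cp)^2))
  }, 0))
}

# Central finite differences of a scalar function of a vector.
fd_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, 0)
}

# Small-strain isotropic stiffness matrix (Voigt assembly): the independent
# linear-elasticity limit of the Neo-Hookean model at rest.
linear_stiffness_oracle <- function(mesh, mat) {
  n <- nrow(mesh$rest_positions)
  K <- matrix(0, 3 * n, 3 * n)
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- mat$lambda
  diag(C)[1:3] <- mat$lambda + 2 * mat$mu
  diag(C)[4:6] <- mat$mu
  for (e in seq_len(nrow(mesh$tets))) {
    Bm <- mesh$element_basis[, , e]
    grads <- rbind(-colSums(Bm), Bm)  # shape-function gradients (4 x 3)
    B <- matrix(0, 6, 12)
    for (m in 1:4) {
      g <- grads[m, ]
      col <- 3 * (m - 1)
      B[1, col + 1] <- g[1]; B[2, col + 2] <- g[2]; B[3, col + 3] <- g[3]
      B[4, col + 1] <- g[2]; B[4, col + 2] <- g[1]
      B[5, col + 2] <- g[3]; B[5, col + 3] <- g[2]
      B[6, col + 1] <- g[3]; B[6, col + 3] <- g[1]
    }
    Ke <- mesh$quadrature_weights[e] * t(B) %*% C %*% B
    dof <- as.vector(t(outer(3 * (mesh$tets[e, ] - 1), 1:3, "+")))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  K
}

# A small two-fragment slab scene reused across coupling/solver tests.
two_fragment_scene <- function(mat = material(), ramp_mm = 10,
                               resolution = c(10, 5, 3)) {
  spec <- slab_spec(dims = c(40, 20, 12), resolution = resolution,
                    blocks = list(list(min = c(4, 8, 4), max = c(36, 12, 8))),
                    cuts = list(list(block = 1, point = c(20, 10, 6),
                                     normal = c(1, 0, 0))))
  make_slab_scene(spec, mat = mat, ramp_mm = ramp_mm)
}

random_rotation <- function() {
  project_rotation_test(matrix(rnorm(9), 3, 3))
}

project_rotation_test <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}
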