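#' Signed closest-point distance from points to a surface
#'
#' Magnitude is the Euclidean distance to the closest point on the triangle
#' mesh; the sign is negative when the query point lies inside the enclosed
#' volume (so a simulated surface sitting inside a post-operative scan reads
#' negative). Inside/outside is decided by the generalized winding number at
#' threshold 0.5, which tolerates nearly closed scan surfaces. For open
#' surfaces pass `allow_open = TRUE` to take the sign from the nearest face's
#' normal instead.
#'
#' @param points `k x 3` matrix (or 3-vector) of query points (mm).
#' @param surface a [surface_mesh], closed and outward-oriented unless
#'   `allow_open`.
#' @param allow_open permit open surfaces (sign from nearest-face normal).
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance_query <- function(points, surface, allow_open = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as_coord_matrix(points, "points")
  if (nrow(surface$faces) == 0) stop("surface has no faces", call. = FALSE)
  closed <- is_closed_surface(surface)
  if (!closed && !allow_open) {
    stop("surface is not closed; pass allow_open = TRUE to sign by nearest-face normal",
         call. = FALSE)
  }
  cp <- closest_point_cpp(t(points), t(surface$vertices), surface$faces)
  d <- as.numeric(cp$dist)
  if (closed) {
    wn <- as.numeric(winding_number_cpp(t(points), t(surface$vertices),
                                        surface$faces))
    sgn <- ifelse(wn > 0.5, -1, 1)
  } else {
    fn <- face_normals(surface)[cp$face, , drop = FALSE]
    off <- points - t(cp$point)
    sgn <- ifelse(rowSums(off * fn) < 0, -1, 1)
  }
  out <- sgn * d
  out[d == 0] <- 0
  out
}

#' Closest points on a surface
#'
#' Brute-force exact closest-point query against every triangle (suitable for
#' the mesh sizes this package targets).
#'
#' @param points `k x 3` matrix of query points (mm).
#' @param surface a [surface_mesh].
#' @return list with `dist` (mm), `point` (`k x 3` closest points) and `face`
#'   (1-based nearest face index).
#' @export
closest_surface_points <- function(points, surface) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as_coord_matrix(points, "points")
  cp <- closest_point_cpp(t(points), t(surface$vertices), surface$faces)
  list(dist = as.numeric(cp$dist), point = t(cp$point),
       face = as.integer(cp$face))
}
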