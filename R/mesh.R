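#' Triangle surface mesh
#'
#' A surface model as an n x 3 vertex matrix (mm) plus an m x 3 integer face
#' matrix of 1-based vertex indices. Faces must reference valid vertices and
#' may not repeat a vertex within one triangle.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices, "vertices")
  if (!is.matrix(faces) || ncol(faces) != 3L || nrow(faces) < 1L) {
    stop("`faces` must be a matrix with 3 columns and at least one row",
         call. = FALSE)
  }
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices must lie in [1, n_vertices]", call. = FALSE)
  }
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
          faces[, 1L] == faces[, 3L])) {
    stop("degenerate face: a triangle repeats a vertex index", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("<triangle_mesh>  %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

assert_mesh <- function(x, arg = "mesh") {
  if (!is_triangle_mesh(x)) {
    stop(sprintf("`%s` must be a triangle_mesh", arg), call. = FALSE)
  }
  x
}

# Per-face corner coordinate matrices (a, b, c), each m x 3.
face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1L], , drop = FALSE],
       b = v[f[, 2L], , drop = FALSE],
       c = v[f[, 3L], , drop = FALSE])
}

rowwise_cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Triangle areas of a mesh
#' @param mesh a `triangle_mesh`.
#' @return Numeric vector of per-face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  mesh <- assert_mesh(mesh)
  co <- face_corners(mesh)
  0.5 * row_norms(rowwise_cross(co$b - co$a, co$c - co$a))
}

# Outward-facing (as wound) unit normals; zero-area faces get a zero normal.
face_normals <- function(mesh) {
  co <- face_corners(mesh)
  n <- rowwise_cross(co$b - co$a, co$c - co$a)
  len <- row_norms(n)
  len[len < 1e-300] <- 1
  n / len
}

#' Discrete curvature as angle defect
#'
#' Per-vertex angle defect `2*pi - sum(incident corner angles)`: the standard
#' discrete Gaussian-curvature measure. Sharp convex corners score high
#' (pi/2 at a cube corner), flat or saddle-free interior vertices score near
#' zero.
#'
#' @param mesh a `triangle_mesh`.
#' @return Numeric vector, one defect (radians) per vertex.
#' @export
vertex_angle_defect <- function(mesh) {
  mesh <- assert_mesh(mesh)
  co <- face_corners(mesh)
  ang <- function(p, q, r) {
    # angle at p in triangle (p, q, r)
    u <- q - p
    v <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * v) / (row_norms(u) * row_norms(v)))))
  }
  angles <- cbind(ang(co$a, co$b, co$c),
                  ang(co$b, co$c, co$a),
                  ang(co$c, co$a, co$b))
  total <- rep(0, nrow(mesh$vertices))
  for (k in 1:3) {
    s <- rowsum(angles[, k], mesh$faces[, k])
    idx <- as.integer(rownames(s))
    total[idx] <- total[idx] + s[, 1L]
  }
  2 * pi - total
}
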