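# Geometric fixtures built in code.

# Regular icosahedron: 12 vertices, 20 equilateral faces, uniform angle
# defect pi/3 at every vertex.
icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,  1, phi, 0,  -1, -phi, 0,  1, -phi, 0,
                0, -1, phi,  0, 1, phi,  0, -1, -phi,  0, 1, -phi,
                phi, 0, -1,  phi, 0, 1,  -phi, 0, -1,  -phi, 0, 1),
              ncol = 3, byrow = TRUE)
  f <- matrix(c(1, 12, 6,  1, 6, 2,  1, 2, 8,  1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3,  11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,  4, 3, 7,  4, 7, 9,  4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,  10, 9, 2),
              ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# Unit square in the XY plane as two triangles of equal area.
square_mesh <- function() {
  triangle_mesh(matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0),
                       ncol = 3, byrow = TRUE),
                matrix(c(1, 2, 3,  1, 3, 4), ncol = 3, byrow = TRUE))
}

# Unit cube with each face subdivided into a 2x2 grid (26 welded vertices):
# corners carry angle defect pi/2, edge midpoints and face centres 0.
subdivided_cube_mesh <- function() {
  tris <- list()
  grid2 <- function(p00, pu, pv) {
    # 3x3 grid on a face spanned by unit vectors pu, pv from corner p00
    pts <- list()
    for (i in 0:2) for (j in 0:2) {
      pts[[i * 3 + j + 1]] <- p00 + (i / 2) * pu + (j / 2) * pv
    }
    id <- function(i, j) i * 3 + j + 1
    out <- list()
    for (i in 0:1) for (j in 0:1) {
      a <- pts[[id(i, j)]]; b <- pts[[id(i + 1, j)]]
      cc <- pts[[id(i + 1, j + 1)]]; d <- pts[[id(i, j + 1)]]
      out[[length(out) + 1]] <- rbind(a, b, cc)
      out[[length(out) + 1]] <- rbind(a, cc, d)
    }
    do.call(rbind, out)
  }
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1); o <- c(0, 0, 0)
  tris <- rbind(grid2(o, ey, ex),                 # z = 0
                grid2(ez, ex, ey),                # z = 1
                grid2(o, ex, ez),                 # y = 0
                grid2(ey, ez, ex),                # y = 1
                grid2(o, ez, ey),                 # x = 0
                grid2(ex, ey, ez))                # x = 1
  rownames(tris) <- NULL
  key <- apply(round(tris, 12), 1, paste, collapse = ",")
  first <- !duplicated(key)
  verts <- tris[first, , drop = FALSE]
  faces <- matrix(match(key, key[first]), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

# A small random valid mesh (triangle soup over random points) for I/O
# round-trip tests; geometry only, no topological meaning.
random_soup_mesh <- function(n_tri = 8, sd = 25) {
  v <- matrix(stats::rnorm(9 * n_tri, sd = sd), ncol = 3)
  triangle_mesh(v, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}

random_landmarks <- function(n = 5, sd = 30) {
  m <- matrix(stats::rnorm(3 * n, sd = sd), n, 3)
  rownames(m) <- paste0("lm", seq_len(n))
  m
}

# Write a binary STL of the given (m x 12) facet records is overkill here;
# instead write a minimal 2-facet binary STL sharing an edge, used by the
# binary-reader test.
write_binary_stl_two_facets <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(2L, con, size = 4, endian = "little")
  facet <- function(nrm, a, b, c) {
    writeBin(as.numeric(c(nrm, a, b, c)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  facet(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  facet(c(0, 0, 1), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  invisible(path)
}

expect_transform_close <- function(a, b, tol_deg = 1e-9, tol_mm = 1e-9) {
  expect_lt(rotation_angle_between(a$R, b$R), tol_deg)
  expect_lt(sqrt(sum((a$t - b$t)^2)), tol_mm)
}
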