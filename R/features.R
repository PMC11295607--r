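# Featured-point extraction and dense surface sampling. The feature operator
# stands in for a proprietary image-feature detector: it scores vertices by
# angle-defect discrete curvature and then spreads a subset by greedy
# farthest-point selection, so that high-contour regions are preferred while
# the selection stays well distributed and fully reproducible.

#' Random surface samples from a mesh
#'
#' Draws `n` points uniformly by area: faces are sampled with probability
#' proportional to their area, then a uniform barycentric point is drawn on
#' each sampled face. Deterministic for a fixed seed.
#'
#' @param mesh a `triangle_mesh` with positive total area.
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return n x 3 point matrix (mm).
#' @export
sample_surface_points <- function(mesh, n, seed = 1L) {
  mesh <- assert_mesh(mesh)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  areas <- face_areas(mesh)
  if (sum(areas) <= 0) {
    stop_degenerate("mesh has zero total surface area; cannot sample")
  }
  withr::with_seed(as.integer(seed), {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    u <- stats::runif(n)
    v <- stats::runif(n)
    flip <- u + v > 1           # reflect into the triangle
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    co <- face_corners(mesh)
    pts <- (1 - u - v) * co$a[fi, , drop = FALSE] +
      u * co$b[fi, , drop = FALSE] +
      v * co$c[fi, , drop = FALSE]
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

# Greedy farthest-point subset among `cand` (k x 3), returning `n` row indices
# into cand. Distances are rounded at 1e-9 before comparison and ties broken
# by lowest index, so the selection is invariant under rigid motion of the
# coordinates (distances are intrinsic) and fully deterministic.
farthest_point_indices <- function(cand, n, start = 1L) {
  k <- nrow(cand)
  sel <- integer(n)
  sel[1L] <- start
  mind <- round(row_norms(cand - matrix(cand[start, ], k, 3L, byrow = TRUE)), 9L)
  if (n > 1L) {
    for (j in 2:n) {
      mind[sel[seq_len(j - 1L)]] <- -1
      nxt <- which.max(mind)     # first maximum = lowest index on ties
      sel[j] <- nxt
      d <- round(row_norms(cand - matrix(cand[nxt, ], k, 3L, byrow = TRUE)), 9L)
      mind <- pmin(mind, d)
    }
  }
  sel
}

#' Extract featured 3D points from a mesh
#'
#' Selects `n` mesh vertices to act as the "featured points" used for
#' paired-feature registration. Vertices are ranked by absolute angle-defect
#' curvature (rounded at 1e-9; ties by vertex index); the top quartile (at
#' least `n` vertices, extended through score ties at the cut) forms the
#' candidate pool, from which greedy farthest-point selection picks `n`
#' mutually spread points starting at the highest-curvature candidate.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of feature points, `3 <= n <= n_vertices`.
#' @param seed integer seed, reserved for tie-shuffling; the default ranking
#'   is fully deterministic (index-ordered ties), so the seed does not change
#'   the result but is part of the stable signature.
#' @return n x 3 matrix of selected vertex coordinates, with attribute
#'   `"vertex_index"` giving their indices in the mesh.
#' @export
extract_feature_points <- function(mesh, n, seed = 1L) {
  mesh <- assert_mesh(mesh)
  nv <- nrow(mesh$vertices)
  if (n < 3L) stop("`n` must be at least 3", call. = FALSE)
  if (n > nv) {
    stop(sprintf("`n` (%d) exceeds the mesh vertex count (%d)", n, nv),
         call. = FALSE)
  }
  score <- round(abs(vertex_angle_defect(mesh)), 9L)
  ord <- order(-score, seq_len(nv))
  k <- max(n, ceiling(nv / 4))
  if (k < nv) {
    # extend through ties at the cutoff score
    cut <- score[ord[k]]
    k <- max(which(score[ord] >= cut))
  }
  cand_idx <- ord[seq_len(k)]
  cand <- mesh$vertices[cand_idx, , drop = FALSE]
  sel <- farthest_point_indices(cand, n, start = 1L)
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- c("x", "y", "z")
  attr(out, "vertex_index") <- cand_idx[sel]
  out
}
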