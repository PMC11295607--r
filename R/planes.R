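# Cutting-plane definition and the planned-vs-achieved accuracy metric.
# Coordinate convention (fixed throughout the package): Z = proximal shaft
# axis, X = medial-lateral, Y = anterior-posterior. Cutting planes are
# near-XY planes (near-Z normals), so their orientation errors projected into
# the XZ and YZ coordinate planes read as the two tilt components of the cut.

#' Cutting plane
#'
#' An oriented osteotomy plane: an origin point on the bone surface and a
#' unit normal, tagged with its role (`"main"` vertical cut or `"side"`
#' horizontal cut).
#'
#' @param origin length-3 point on the plane (mm).
#' @param normal length-3 normal vector (normalised internally; must be
#'   non-zero).
#' @param role `"main"` or `"side"`.
#' @return An object of class `cutting_plane`.
#' @export
cutting_plane <- function(origin, normal, role = c("main", "side")) {
  role <- match.arg(role)
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin))) {
    stop("`origin` must be a finite length-3 numeric vector", call. = FALSE)
  }
  if (!is.numeric(normal) || length(normal) != 3L || !all(is.finite(normal))) {
    stop("`normal` must be a finite length-3 numeric vector", call. = FALSE)
  }
  n <- vnorm(normal)
  if (n < 1e-12) stop("`normal` must be non-zero", call. = FALSE)
  structure(list(origin = as.double(origin), normal = as.double(normal / n),
                 role = role),
            class = "cutting_plane")
}

#' @export
print.cutting_plane <- function(x, ...) {
  cat(sprintf("<cutting_plane %s>  origin (%s) mm, normal (%s)\n", x$role,
              paste(sprintf("%.4g", x$origin), collapse = ", "),
              paste(sprintf("%.4g", x$normal), collapse = ", ")))
  invisible(x)
}

assert_plane <- function(x, arg = "plane") {
  if (!inherits(x, "cutting_plane")) {
    stop(sprintf("`%s` must be a cutting_plane", arg), call. = FALSE)
  }
  x
}

#' Cutting-plane configuration
#'
#' Parameters placing the main and side cuts on a tibia model oriented with
#' the shaft along +Z.
#'
#' @param main_height_frac height of the main cut along the shaft, as a
#'   fraction of the bounding-box height measured from the distal end.
#' @param main_tilt_deg tilt of the main cut about the hinge direction
#'   (degrees away from a pure transverse cut).
#' @param side_angle_deg angle between the side and main cut planes
#'   (degrees, 5-90: plane-to-plane angles are folded to \\[0, 90\\]).
#' @param side_offset_mm distal offset of the side-cut origin below the main
#'   cut (mm).
#' @param hinge_dir direction of the osteotomy hinge line (default +Y,
#'   anterior-posterior).
#' @return Named list of settings for [make_cutting_planes()].
#' @export
plane_config <- function(main_height_frac = 0.8, main_tilt_deg = 15,
                         side_angle_deg = 70, side_offset_mm = 12,
                         hinge_dir = c(0, 1, 0)) {
  list(main_height_frac = main_height_frac, main_tilt_deg = main_tilt_deg,
       side_angle_deg = side_angle_deg, side_offset_mm = side_offset_mm,
       hinge_dir = hinge_dir)
}

#' Place planned main and side cutting planes on a tibia model
#'
#' Builds the planned osteotomy plane pair: the main cut normal is the shaft
#' axis (+Z) tilted by `main_tilt_deg` about the hinge direction; the side cut
#' normal is tilted a further `side_angle_deg` about the same hinge, so the
#' mutual plane angle equals `side_angle_deg` exactly and the two planes
#' intersect along a hinge line. Each origin is the mesh surface point
#' (vertex) nearest to its nominal location on the medial cortex.
#'
#' @param mesh a `triangle_mesh`, shaft axis along +Z.
#' @param config settings from [plane_config()].
#' @return List with `main` and `side` [cutting_plane()]s plus `hinge_point`
#'   and `hinge_dir` describing their intersection line.
#' @export
make_cutting_planes <- function(mesh, config = plane_config()) {
  mesh <- assert_mesh(mesh)
  cfg <- utils::modifyList(plane_config(), config)
  h <- cfg$hinge_dir / vnorm(cfg$hinge_dir)
  n_main <- as.double(rotation_about_axis(h, cfg$main_tilt_deg) %*% c(0, 0, 1))
  n_side <- as.double(rotation_about_axis(h, cfg$main_tilt_deg + cfg$side_angle_deg) %*% c(0, 0, 1))
  ang <- rad2deg(atan2(vnorm(cross3(n_main, n_side)), abs(sum(n_main * n_side))))
  if (ang < 5) {
    stop_degenerate("main and side planes are near-parallel (%.3g deg < 5 deg)", ang)
  }
  v <- mesh$vertices
  zr <- range(v[, 3L])
  z_main <- zr[1L] + cfg$main_height_frac * (zr[2L] - zr[1L])
  nominal_main <- c(min(v[, 1L]), 0, z_main)     # medial (-X) cortex
  nominal_side <- c(min(v[, 1L]), 0, z_main - cfg$side_offset_mm)
  nearest_vertex <- function(p) {
    v[which.min(rowSums(sweep(v, 2L, p)^2)), ]
  }
  main <- cutting_plane(nearest_vertex(nominal_main), n_main, "main")
  side <- cutting_plane(nearest_vertex(nominal_side), n_side, "side")
  # hinge = intersection line of the two planes
  dir <- cross3(main$normal, side$normal)
  dir <- dir / vnorm(dir)
  A <- rbind(main$normal, side$normal, dir)
  b <- c(sum(main$normal * main$origin), sum(side$normal * side$origin),
         sum(dir * main$origin))
  hinge_point <- as.double(solve(A, b))
  list(main = main, side = side, hinge_point = hinge_point, hinge_dir = dir)
}

#' Map a cutting plane through a rigid transform
#'
#' Origin maps as a point (`R o + t`), the normal as a direction (`R n`);
#' unit length is preserved.
#'
#' @param transform a `rigid_transform`.
#' @param plane a `cutting_plane`.
#' @return The transformed `cutting_plane`.
#' @export
transform_plane <- function(transform, plane) {
  transform <- assert_transform(transform)
  plane <- assert_plane(plane)
  cutting_plane(as.double(transform$R %*% plane$origin) + transform$t,
                as.double(transform$R %*% plane$normal),
                plane$role)
}

#' Projected angle difference between two cutting planes
#'
#' The accuracy metric for planned-vs-achieved cuts: both plane normals are
#' projected orthogonally into the named coordinate plane (`"XZ"` or `"YZ"`)
#' and the angle between the projections, folded to \\[0, 90\\] degrees
#' (orientation is sign-free), is returned. Computed as
#' `atan2(|u x v|, |u . v|)`, which is accurate near both 0 and 90 degrees.
#'
#' @param planned,achieved `cutting_plane`s (symmetric in the two arguments).
#' @param projection `"XZ"` or `"YZ"`.
#' @return Angle difference in degrees, in \\[0, 90\\].
#' @export
projected_angle_difference <- function(planned, achieved,
                                       projection = c("XZ", "YZ")) {
  planned <- assert_plane(planned, "planned")
  achieved <- assert_plane(achieved, "achieved")
  projection <- match.arg(projection)
  comp <- if (projection == "XZ") c(1L, 3L) else c(2L, 3L)
  u <- planned$normal[comp]
  v <- achieved$normal[comp]
  if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6) {
    stop_degenerate(
      "degenerate %s projection: a plane normal is perpendicular to the projection plane (|proj| = %.3g / %.3g)",
      projection, vnorm(u), vnorm(v))
  }
  cross <- u[1L] * v[2L] - u[2L] * v[1L]
  rad2deg(atan2(abs(cross), abs(sum(u * v))))
}

#' Summarise angle differences by group
#'
#' Groups angle reports by (modality, plane role, projection) and reports n,
#' mean, median, quartiles (linear-interpolation convention, R quantile type
#' 7), min and max, plus a pooled per-modality row (role and projection
#' `"all"`).
#'
#' @param reports data frame with columns `modality`, `role`, `projection`
#'   and `angle_deg` (one row per measured angle difference).
#' @return Data frame of summary statistics, one row per group.
#' @export
summarize_angle_differences <- function(reports) {
  need <- c("modality", "role", "projection", "angle_deg")
  if (!is.data.frame(reports) || !all(need %in% names(reports))) {
    stop("`reports` must be a data frame with columns modality, role, projection, angle_deg",
         call. = FALSE)
  }
  if (nrow(reports) < 1L) stop("`reports` is empty", call. = FALSE)
  one <- function(x, modality, role, projection) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(modality = modality, role = role, projection = projection,
               n = length(x), mean_deg = mean(x), median_deg = q[2L],
               q1_deg = q[1L], q3_deg = q[3L], min_deg = min(x),
               max_deg = max(x))
  }
  keys <- unique(reports[, c("modality", "role", "projection")])
  keys <- keys[order(keys$modality, keys$role, keys$projection), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    x <- reports$angle_deg[reports$modality == k$modality &
                             reports$role == k$role &
                             reports$projection == k$projection]
    one(x, k$modality, k$role, k$projection)
  })
  pooled <- lapply(sort(unique(reports$modality)), function(m) {
    one(reports$angle_deg[reports$modality == m], m, "all", "all")
  })
  out <- do.call(rbind, c(rows, pooled))
  rownames(out) <- NULL
  out
}
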