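# Readers/writers for the toolkit's on-disk formats: STL (ASCII + binary),
# PLY (ASCII 1.0), landmark CSV, cutting-plane JSON, transform JSON and the
# results CSV. Meshes are written in ASCII so fixtures stay diff-able.

#' Read a triangle mesh
#'
#' Reads STL (ASCII or binary, auto-detected) or ASCII PLY. Exactly duplicated
#' STL vertices (bitwise-equal coordinates) are welded into shared vertices.
#'
#' @param path file to read.
#' @param format `"auto"` (default, from content/extension), `"stl"`,
#'   `"stl_ascii"`, `"stl_binary"` or `"ply"`.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "stl_ascii",
                                       "stl_binary", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_usage("mesh file does not exist: %s", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  }
  switch(format,
         ply = read_ply_ascii(path),
         stl = if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path),
         stl_ascii = read_stl_ascii(path),
         stl_binary = read_stl_binary(path))
}

#' Write a triangle mesh
#'
#' Writes ASCII STL or ASCII PLY. Round-tripping through [read_mesh()]
#' preserves vertex coordinates to better than 1e-6 mm.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @param format `"stl_ascii"` or `"ply_ascii"`; default from the extension.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl_ascii", "ply_ascii")) {
  mesh <- assert_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply_ascii" else "stl_ascii"
  }
  if (format == "ply_ascii") write_ply_ascii(mesh, path) else write_stl_ascii(mesh, path)
  invisible(path)
}

stl_is_ascii <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 512L)
  # ASCII STL: printable text starting with "solid". Binary files contain
  # non-text bytes (header padding, packed floats) within the first block.
  if (!all(head %in% as.raw(c(9L, 10L, 13L, 32:126)))) return(FALSE)
  startsWith(trimws(rawToChar(head)), "solid")
}

# Weld bitwise-identical vertices of an STL triangle soup and build the face
# index table. `tri` is a (3*m) x 3 matrix of corner coordinates in face order.
weld_vertices <- function(tri) {
  key <- paste(sprintf("%.17g", tri[, 1L]), sprintf("%.17g", tri[, 2L]),
               sprintf("%.17g", tri[, 3L]))
  first <- !duplicated(key)
  verts <- tri[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L) {
    stop_usage("malformed or empty ASCII STL (no vertex lines): %s", path)
  }
  if (length(vl) %% 3L != 0L) {
    stop_usage("malformed ASCII STL %s: %d vertex lines (not a multiple of 3); near line %d",
               path, length(vl), vl[length(vl)])
  }
  fields <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 4L)
  if (length(bad)) {
    stop_usage("malformed ASCII STL %s: bad vertex at line %d", path, vl[bad[1L]])
  }
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(fields, `[`, 2:4))), ncol = 3L, byrow = TRUE))
  if (anyNA(coords)) {
    bad <- vl[which(rowSums(is.na(coords)) > 0L)[1L]]
    stop_usage("malformed ASCII STL %s: non-numeric coordinate at line %d", path, bad)
  }
  weld_vertices(coords)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_fac <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(n_fac) == 0L || is.na(n_fac) || n_fac < 1L) {
    stop_usage("malformed or empty binary STL (facet count %s): %s",
               if (length(n_fac)) n_fac else "missing", path)
  }
  need <- 84 + 50 * as.double(n_fac)
  if (!is.na(sz) && sz < need) {
    stop_usage("truncated binary STL %s: need %d bytes, have %d (at byte 84)",
               path, need, sz)
  }
  raw <- readBin(con, "raw", n = 50L * n_fac)
  keep <- rep(rep(c(TRUE, FALSE), c(48L, 2L)), n_fac)  # drop attribute bytes
  floats <- readBin(raw[keep], "numeric", size = 4L, n = 12L * n_fac,
                    endian = "little")
  per_fac <- matrix(floats, ncol = 12L, byrow = TRUE)
  tri <- rbind(per_fac[, 4:6, drop = FALSE],
               per_fac[, 7:9, drop = FALSE],
               per_fac[, 10:12, drop = FALSE])
  # interleave back to corner order (a1 b1 c1 a2 b2 c2 ...)
  ord <- as.vector(t(matrix(seq_len(3L * n_fac), ncol = 3L)))
  weld_vertices(tri[ord, , drop = FALSE])
}

write_stl_ascii <- function(mesh, path) {
  co <- face_corners(mesh)
  nrm <- face_normals(mesh)
  m <- nrow(mesh$faces)
  block <- character(7L * m)
  block[seq(1L, by = 7L, length.out = m)] <-
    sprintf("  facet normal %s %s %s", fmt_num(nrm[, 1]), fmt_num(nrm[, 2]),
            fmt_num(nrm[, 3]))
  block[seq(2L, by = 7L, length.out = m)] <- "    outer loop"
  vfmt <- function(p) sprintf("      vertex %s %s %s", fmt_num(p[, 1]),
                              fmt_num(p[, 2]), fmt_num(p[, 3]))
  block[seq(3L, by = 7L, length.out = m)] <- vfmt(co$a)
  block[seq(4L, by = 7L, length.out = m)] <- vfmt(co$b)
  block[seq(5L, by = 7L, length.out = m)] <- vfmt(co$c)
  block[seq(6L, by = 7L, length.out = m)] <- "    endloop"
  block[seq(7L, by = 7L, length.out = m)] <- "  endfacet"
  writeLines(c("solid osteonav", block, "endsolid osteonav"), path)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply") {
    stop_usage("not a PLY file (missing 'ply' magic at line 1): %s", path)
  }
  if (!grepl("^format\\s+ascii\\s+1\\.0", trimws(lines[2L]))) {
    stop_usage("unsupported PLY format at line 2 (only 'format ascii 1.0'): %s", path)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop_usage("PLY header never ends (no end_header): %s", path)
  header <- trimws(lines[seq_len(end)])
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex\\s", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face\\s", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf) || nv < 1L || nf < 1L) {
    stop_usage("PLY header lacks vertex/face element counts: %s", path)
  }
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    stop_usage("truncated PLY body in %s: expected %d data lines, found %d",
               path, nv + nf, length(body))
  }
  vtx <- suppressWarnings(matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                                 nrow = nv, byrow = TRUE))
  if (anyNA(vtx) || ncol(vtx) < 3L) {
    stop_usage("non-numeric vertex data in PLY %s (body line %d)",
               path, which(rowSums(is.na(vtx)) > 0)[1L] %||% 1L)
  }
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  counts <- as.integer(vapply(fl, `[`, "", 1L))
  if (any(counts != 3L)) {
    stop_usage("PLY %s contains a non-triangular face (body line %d)",
               path, nv + which(counts != 3L)[1L])
  }
  faces <- matrix(as.integer(unlist(lapply(fl, `[`, 2:4))), ncol = 3L,
                  byrow = TRUE) + 1L  # PLY indices are 0-based
  triangle_mesh(vtx[, 1:3, drop = FALSE], faces)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  writeLines(c(header,
               sprintf("%s %s %s", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
               sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])),
             path)
}

#' Read / write landmark CSV files
#'
#' Landmark files are UTF-8 CSV with header exactly `label,x,y,z`, "." as the
#' decimal separator and one named point per row. Labels must be unique.
#'
#' @param path CSV file.
#' @return A labelled point matrix (rownames are the landmark labels).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_usage("landmark file does not exist: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  if (!identical(trimws(header), c("label", "x", "y", "z"))) {
    stop_usage("landmark CSV %s must have header exactly 'label,x,y,z'", path)
  }
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric",
                                             "numeric"), strip.white = TRUE)
  if (nrow(df) < 1L) stop_usage("landmark CSV %s contains no landmarks", path)
  dup <- df$label[duplicated(df$label)]
  if (length(dup)) {
    lines <- which(df$label %in% dup) + 1L  # +1 for the header line
    stop_usage("duplicate landmark label(s) %s in %s (lines %s)",
               paste(unique(dup), collapse = ", "), path,
               paste(lines, collapse = ", "))
  }
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    bad <- which(is.na(df$x) | is.na(df$y) | is.na(df$z))[1L] + 1L
    stop_usage("non-numeric coordinate in landmark CSV %s (line %d)", path, bad)
  }
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$label
  as_points(m, "landmarks")
}

#' @rdname read_landmarks
#' @param landmarks labelled point matrix (rownames = labels).
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- as_landmarks(landmarks)
  df <- data.frame(label = rownames(landmarks),
                   x = landmarks[, 1L], y = landmarks[, 2L], z = landmarks[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write cutting-plane JSON
#'
#' Planes are stored as a JSON array of
#' `{"origin": [x,y,z], "normal": [nx,ny,nz], "role": "main"|"side"}`.
#' Normals must be unit length to within 1e-6 (they are re-normalised on
#' read); anything further off is rejected.
#'
#' @param path JSON file.
#' @return A list of [cutting_plane()] objects.
#' @export
read_planes <- function(path) {
  if (!file.exists(path)) stop_usage("plane file does not exist: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0L) stop_usage("plane JSON %s contains no planes", path)
  lapply(seq_along(raw), function(i) {
    p <- raw[[i]]
    if (!all(c("origin", "normal", "role") %in% names(p))) {
      stop_usage("plane %d in %s lacks origin/normal/role", i, path)
    }
    n <- as.numeric(unlist(p$normal))
    if (length(n) != 3L || abs(vnorm(n) - 1) > 1e-6) {
      stop_usage("plane %d in %s has a non-unit normal (|n| = %.8g)",
                 i, path, vnorm(n))
    }
    cutting_plane(as.numeric(unlist(p$origin)), n / vnorm(n), p$role)
  })
}

#' @rdname read_planes
#' @param planes a list of `cutting_plane` objects (or a single one).
#' @export
write_planes <- function(planes, path) {
  if (inherits(planes, "cutting_plane")) planes <- list(planes)
  payload <- lapply(planes, function(p) {
    p <- assert_plane(p)
    list(origin = p$origin, normal = p$normal, role = p$role)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write rigid-transform JSON
#'
#' The on-disk form is `{"rotation": [9 floats, row-major], "translation":
#' [x,y,z], "units": "mm"}`. Extra keys (e.g. a `metrics` block written by the
#' CLI) are ignored on read.
#'
#' @param path JSON file.
#' @return A [rigid_transform()].
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) stop_usage("transform file does not exist: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!all(c("rotation", "translation") %in% names(raw))) {
    stop_usage("transform JSON %s lacks rotation/translation", path)
  }
  R <- matrix(as.numeric(raw$rotation), 3L, 3L, byrow = TRUE)
  rigid_transform(R, as.numeric(raw$translation), tol = 1e-6)
}

#' @rdname read_transform_json
#' @param transform a `rigid_transform`.
#' @param metrics optional named list (e.g. `list(fre_mm = ..., iterations
#'   = ...)`) appended as a `"metrics"` block.
#' @export
write_transform_json <- function(transform, path, metrics = NULL) {
  transform <- assert_transform(transform)
  payload <- list(rotation = as.vector(t(transform$R)),
                  translation = transform$t,
                  units = "mm")
  if (!is.null(metrics)) payload$metrics <- metrics
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write trial-results CSV
#'
#' One row per (trial, modality, plane role, projection), as produced by
#' [run_experiment()].
#'
#' @param results data frame of results.
#' @param path CSV file.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop_usage("results file does not exist: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
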