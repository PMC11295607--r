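# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x * x))

row_norms <- function(m) sqrt(rowSums(m * m))

deg2rad <- function(d) d * pi / 180

rad2deg <- function(r) r * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @description Coerce x to an n x 3 numeric point matrix (mm), preserving
#' rownames as labels. Accepts a bare length-3 vector as one point.
#' @noRd
as_points <- function(x, arg = "points") {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) {
    x <- matrix(x, nrow = 1L)
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L) {
    stop(sprintf("`%s` must be a numeric matrix with 3 columns (x, y, z)", arg),
         call. = FALSE)
  }
  if (nrow(x) < 1L) {
    stop(sprintf("`%s` must contain at least one point", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite coordinates", arg), call. = FALSE)
  }
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

# Landmark semantics: labels present and unique.
as_landmarks <- function(x, arg = "landmarks") {
  x <- as_points(x, arg)
  lab <- rownames(x)
  if (is.null(lab)) {
    stop(sprintf("`%s` must carry labels as rownames", arg), call. = FALSE)
  }
  if (anyDuplicated(lab)) {
    stop(sprintf("`%s` has duplicated labels: %s", arg,
                 paste(unique(lab[duplicated(lab)]), collapse = ", ")),
         call. = FALSE)
  }
  x
}

# Error conditions used for the CLI exit-code contract:
# usage/config problems -> class osteonav_usage (exit 1),
# numerical degeneracy  -> class osteonav_degeneracy (exit 2).
stop_usage <- function(msg, ...) {
  stop(structure(class = c("osteonav_usage", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_degenerate <- function(msg, ...) {
  stop(structure(class = c("osteonav_degeneracy", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @description Draw n reproducible sub-seeds (31-bit) from one seed without
#' disturbing the caller's RNG stream.
#' @noRd
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# FNV-1a over a character scalar; returned as 8 hex digits. Used to fingerprint
# experiment configurations in provenance blocks.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, kept exact in doubles
    # by splitting h into 16-bit halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  hi16 <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi16), as.integer(h %% 65536))
}

fmt_num <- function(x) sprintf("%.10g", x)
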