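#' Construct a reflection set
#'
#' Indexed structure-factor amplitudes on a common orthogonal cell and
#' resolution range. Phases are optional (merged experimental data carry
#' none); sigmas are optional and default to zero.
#'
#' @param hkl Integer n x 3 matrix of Miller indices (unique rows).
#' @param f Non-negative amplitudes (electrons).
#' @param cell Orthogonal cell lengths (a, b, c) in Angstrom.
#' @param phase Phases in degrees, or NULL.
#' @param sigma Amplitude sigmas (>= 0), or NULL for zeros.
#' @param d_min,d_max Resolution range in Angstrom (defaults: observed range).
#' @return An object of class `reflection_set` with fields `hkl`, `f`,
#'   `phase`, `sigma`, `d`, `cell`, `d_min`, `d_max`.
#' @export
reflection_set <- function(hkl, f, cell, phase = NULL, sigma = NULL,
                           d_min = NULL, d_max = NULL) {
  hkl <- as.matrix(hkl)
  storage.mode(hkl) <- "integer"
  stopifnot(ncol(hkl) == 3, length(f) == nrow(hkl), length(cell) == 3)
  if (anyDuplicated(hkl_key(hkl)) > 0) stop("duplicate (h,k,l) indices")
  if (any(f < 0)) stop("amplitudes must be >= 0")
  if (!is.null(phase)) stopifnot(length(phase) == nrow(hkl))
  if (is.null(sigma)) sigma <- numeric(nrow(hkl))
  stopifnot(length(sigma) == nrow(hkl), all(sigma >= 0))
  d <- resolution_of(hkl, cell)
  if (is.null(d_min)) d_min <- if (length(d)) min(d) else NA_real_
  if (is.null(d_max)) d_max <- if (length(d)) max(d) else NA_real_
  structure(list(hkl = hkl, f = as.numeric(f),
                 phase = if (is.null(phase)) NULL else as.numeric(phase),
                 sigma = as.numeric(sigma), d = d, cell = as.numeric(cell),
                 d_min = d_min, d_max = d_max),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections, %.2f-%.2f A, phases: %s\n",
              nrow(x$hkl), x$d_max, x$d_min,
              if (is.null(x$phase)) "absent" else "present"))
  invisible(x)
}

hkl_key <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3], sep = "_")

#' Resolution of Miller indices in an orthogonal cell
#'
#' d = 1/|s| with s = (h/a, k/b, l/c).
#'
#' @param hkl n x 3 index matrix.
#' @param cell (a, b, c) in Angstrom.
#' @return d-spacings in Angstrom (Inf for (0,0,0)).
#' @export
resolution_of <- function(hkl, cell) {
  s2 <- (hkl[, 1] / cell[1])^2 + (hkl[, 2] / cell[2])^2 + (hkl[, 3] / cell[3])^2
  ifelse(s2 == 0, Inf, 1 / sqrt(s2))
}

# |s|^2 = 1/d^2 for each reflection
s_squared <- function(rs) {
  (rs$hkl[, 1] / rs$cell[1])^2 + (rs$hkl[, 2] / rs$cell[2])^2 +
    (rs$hkl[, 3] / rs$cell[3])^2
}

#' Complex structure factors of a reflection set
#'
#' @param rs A `reflection_set` with phases.
#' @return Complex vector F * exp(i * phase).
#' @export
as_complex <- function(rs) {
  stopifnot(inherits(rs, "reflection_set"))
  if (is.null(rs$phase)) stop("reflection set has no phases")
  rs$f * exp(1i * rs$phase * pi / 180)
}

#' Align one reflection set's rows onto another's index order
#'
#' @param rs1,rs2 `reflection_set`s with identical (h,k,l) index sets.
#' @param what Label used in the mismatch error message.
#' @return Integer vector idx such that `rs2$hkl[idx, ] == rs1$hkl`.
#' @export
match_indices <- function(rs1, rs2, what = "reflection sets") {
  k1 <- hkl_key(rs1$hkl)
  k2 <- hkl_key(rs2$hkl)
  idx <- match(k1, k2)
  if (anyNA(idx) || length(k1) != length(k2)) {
    stop(what, " have mismatched (h,k,l) index sets")
  }
  idx
}

# Shared index subset of two sets; returns list(i1, i2) of row indices.
common_indices <- function(rs1, rs2) {
  k1 <- hkl_key(rs1$hkl)
  k2 <- hkl_key(rs2$hkl)
  common <- intersect(k1, k2)
  list(i1 = match(common, k1), i2 = match(common, k2))
}

#' Row subset of a reflection set
#'
#' @param rs A `reflection_set`.
#' @param idx Row indices to keep.
#' @return A `reflection_set`.
#' @export
subset_reflections <- function(rs, idx) {
  reflection_set(rs$hkl[idx, , drop = FALSE], rs$f[idx], rs$cell,
                 phase = if (is.null(rs$phase)) NULL else rs$phase[idx],
                 sigma = rs$sigma[idx], d_min = rs$d_min, d_max = rs$d_max)
}

#' Write a reflection table as delimited text
#'
#' Whitespace-delimited columns `h k l F sigF` and, when phases are present,
#' `phase` (degrees). A `# cell a b c` comment line records the cell.
#'
#' @param rs A `reflection_set`.
#' @param path Output file.
#' @export
write_reflections <- function(rs, path) {
  stopifnot(inherits(rs, "reflection_set"))
  df <- data.frame(h = rs$hkl[, 1], k = rs$hkl[, 2], l = rs$hkl[, 3],
                   F = rs$f, sigF = rs$sigma)
  if (!is.null(rs$phase)) df$phase <- rs$phase
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell %.6f %.6f %.6f", rs$cell[1], rs$cell[2],
                     rs$cell[3]), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE)
}

#' Read a reflection table written by [write_reflections()]
#'
#' @param path Input file.
#' @param cell Cell lengths; if NULL, taken from the `# cell` header line.
#' @return A `reflection_set`.
#' @export
read_reflections <- function(path, cell = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(cell)) {
    if (!grepl("^# cell", first)) {
      stop("no cell given and no '# cell' header in ", path)
    }
    cell <- as.numeric(strsplit(trimws(sub("^# cell", "", first)), "\\s+")[[1]])
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  reflection_set(as.matrix(df[, c("h", "k", "l")]), df$F, cell,
                 phase = if ("phase" %in% names(df)) df$phase else NULL,
                 sigma = if ("sigF" %in% names(df)) df$sigF else NULL)
}
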