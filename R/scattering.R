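#' Structure factors by direct summation
#'
#' F(h) = sum_i occ_i * Z_i * exp(-B_i |s|^2 / 4) * exp(2 pi i h.x_i) over
#' all atoms, with x_i fractional coordinates and |s| = 1/d. The point-atom
#' form factor Z * exp(-B |s|^2/4) makes simulation and analysis exactly
#' self-consistent; amplitudes are not exchangeable with real-data tables
#' computed from Cromer-Mann form factors.
#'
#' @param model An [atomic_model()].
#' @param d_min High-resolution cutoff in Angstrom (> 0).
#' @param d_max Low-resolution cutoff in Angstrom (default 10).
#' @param hemisphere If TRUE (default) return one Friedel mate per pair
#'   (l > 0, or l = 0 and k > 0, or k = l = 0 and h > 0); map synthesis
#'   regenerates the mates. If FALSE, the full sphere is returned.
#' @param include_f000 Include the zero-frequency term F(000) = sum occ*Z.
#' @return A `reflection_set` with amplitudes and phases (degrees).
#' @export
structure_factors <- function(model, d_min, d_max = 10, hemisphere = TRUE,
                              include_f000 = FALSE) {
  stopifnot(inherits(model, "atomic_model"))
  if (d_min <= 0) stop("d_min must be > 0")
  if (d_min >= d_max) stop("d_min must be < d_max")
  cell <- model$cell
  hmax <- floor(cell / d_min)
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = -hmax[3]:hmax[3])
  hkl <- as.matrix(grid)
  d <- resolution_of(hkl, cell)
  keep <- d >= d_min & d <= d_max
  if (hemisphere) {
    keep <- keep & (hkl[, 3] > 0 |
                      (hkl[, 3] == 0 & hkl[, 2] > 0) |
                      (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0))
  }
  hkl <- hkl[keep, , drop = FALSE]
  if (include_f000) hkl <- rbind(c(0L, 0L, 0L), hkl)
  fc <- calc_f_complex(model, hkl)
  reflection_set(hkl, Mod(fc), cell, phase = Arg(fc) * 180 / pi,
                 d_min = d_min, d_max = if (include_f000) d_max else d_max)
}

# Direct summation of complex structure factors for given indices.
# Chunked over reflections to bound the size of the phase matrix.
calc_f_complex <- function(model, hkl, chunk = 8192L) {
  cell <- model$cell
  z <- element_electrons()[model$atoms$element]
  w0 <- model$atoms$occ * z
  frac <- sweep(coords(model), 2, cell, "/")
  b <- model$atoms$b
  n <- nrow(hkl)
  out <- complex(n)
  svec <- sweep(matrix(as.numeric(hkl), ncol = 3), 2, cell, "/")
  s2 <- rowSums(svec^2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    ph <- 2 * pi * (hkl[idx, , drop = FALSE] %*% t(frac))
    damp <- exp(-outer(s2[idx], b) / 4)
    out[idx] <- (damp * exp(1i * ph)) %*% w0
  }
  out
}

#' Mix structure factors of two states
#'
#' Complex mixture F_mix = (1 - f) F_dark + f F_excited, the
#' ensemble-average of a crystal in which a fraction f of molecules is in
#' the excited state.
#'
#' @param f_dark,f_excited `reflection_set`s with phases on the same cell
#'   and index set.
#' @param f Excited-state fraction in \[0, 1\].
#' @return A `reflection_set` with mixture amplitudes and phases.
#' @export
mix_states <- function(f_dark, f_excited, f) {
  stopifnot(inherits(f_dark, "reflection_set"),
            inherits(f_excited, "reflection_set"))
  if (f < 0 || f > 1) stop("mixing fraction must lie in [0, 1]")
  idx <- match_indices(f_dark, f_excited)
  fc <- (1 - f) * as_complex(f_dark) + f * as_complex(f_excited)[idx]
  reflection_set(f_dark$hkl, Mod(fc), f_dark$cell, phase = Arg(fc) * 180 / pi,
                 d_min = f_dark$d_min, d_max = f_dark$d_max)
}

#' Scale light amplitudes onto dark amplitudes (Wilson scaling)
#'
#' Finds k and a relative B factor minimizing
#' sum over common reflections of (k exp(-B_rel |s|^2/4) F_light - F_dark)^2
#' and applies them to the light set. Reflections outside the
#' d_max (default 10 Angstrom) to d_min range are excluded from the fit.
#'
#' @param f_light,f_dark `reflection_set`s sharing at least 20 reflections.
#' @param d_min,d_max Resolution window for the fit; defaults to the light
#'   set's range capped at 10 Angstrom on the low-resolution side.
#' @return List with `scaled` (the light set with k, B_rel applied to F and
#'   sigma), `k`, `b_rel`.
#' @export
scale_light_to_dark <- function(f_light, f_dark, d_min = NULL, d_max = 10) {
  stopifnot(inherits(f_light, "reflection_set"),
            inherits(f_dark, "reflection_set"))
  if (is.null(d_min)) d_min <- f_light$d_min
  ci <- common_indices(f_light, f_dark)
  in_window <- f_light$d[ci$i1] >= d_min & f_light$d[ci$i1] <= d_max
  i1 <- ci$i1[in_window]
  i2 <- ci$i2[in_window]
  if (length(i1) < 20) stop("fewer than 20 common reflections for scaling")
  fl <- f_light$f[i1]
  fd <- f_dark$f[i2]
  s2 <- s_squared(f_light)[i1]
  if (diff(range(s2)) < 1e-12) {
    stop("all reflections at one resolution: relative B is unidentifiable")
  }
  # profile out k: for fixed B the optimal k is a ratio of inner products
  obj <- function(b_rel) {
    flb <- fl * exp(-b_rel * s2 / 4)
    k <- sum(flb * fd) / sum(flb^2)
    sum((k * flb - fd)^2)
  }
  # log-linear init from positive pairs
  pos <- fl > 0 & fd > 0
  init <- if (sum(pos) >= 2) {
    fit <- stats::lm(log(fd[pos] / fl[pos]) ~ s2[pos])
    -4 * unname(stats::coef(fit)[2])
  } else 0
  opt <- stats::optim(init, obj, method = "Brent",
                      lower = init - 200, upper = init + 200,
                      control = list(reltol = 1e-14))
  b_rel <- opt$par
  flb <- fl * exp(-b_rel * s2 / 4)
  k <- sum(flb * fd) / sum(flb^2)
  fac <- k * exp(-b_rel * s_squared(f_light) / 4)
  scaled <- reflection_set(f_light$hkl, f_light$f * fac, f_light$cell,
                           phase = f_light$phase, sigma = f_light$sigma * fac,
                           d_min = f_light$d_min, d_max = f_light$d_max)
  list(scaled = scaled, k = k, b_rel = b_rel)
}

#' Synthesize a real-space density map by inverse Fourier summation
#'
#' rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x), realized on a regular grid
#' with an FFT. Friedel mates of a hemisphere set are filled in
#' automatically so the map is real. F(000) is excluded unless present in
#' the coefficients, so difference maps have (near) zero mean.
#'
#' @param coeffs A `reflection_set` with phases.
#' @param dim Grid dimensions (3 integers); default chosen so the spacing is
#'   at most d_min/3 in each direction.
#' @param provenance Character tag stored on the map (e.g. "difference",
#'   "omit", "fc").
#' @return An object of class `density_grid`: fields `values` (3-d array,
#'   e/A^3), `cell`, `dim`, `provenance`.
#' @export
synthesize_map <- function(coeffs, dim = NULL, provenance = "fc") {
  stopifnot(inherits(coeffs, "reflection_set"))
  if (is.null(coeffs$phase)) stop("map synthesis requires phases")
  cell <- coeffs$cell
  hkl <- coeffs$hkl
  if (is.null(dim)) {
    dim <- vapply(seq_len(3), function(i) {
      nice_grid_size(max(ceiling(cell[i] / (coeffs$d_min / 3)),
                         2L * max(abs(hkl[, i])) + 1L))
    }, integer(1))
  }
  dim <- as.integer(dim)
  if (any(dim <= 2 * apply(abs(hkl), 2, max))) {
    stop("grid dimensions must exceed twice the maximum index")
  }
  spacing <- cell / dim
  if (any(spacing > coeffs$d_min / 3 + 1e-9)) {
    warning("grid spacing exceeds d_min/3; map may be undersampled")
  }
  fc <- as_complex(coeffs)
  arr <- array(0 + 0i, dim)
  i1 <- hkl[, 1] %% dim[1]
  i2 <- hkl[, 2] %% dim[2]
  i3 <- hkl[, 3] %% dim[3]
  lin <- 1 + i1 + dim[1] * (i2 + dim[2] * i3)
  arr[lin] <- arr[lin] + fc
  # Friedel mates for every index whose mate is not itself present
  have <- new.env(hash = TRUE)
  for (k in hkl_key(hkl)) assign(k, TRUE, envir = have)
  mate_key <- hkl_key(-hkl)
  need <- !vapply(mate_key, exists, logical(1), envir = have, USE.NAMES = FALSE)
  if (any(need)) {
    m1 <- (-hkl[need, 1]) %% dim[1]
    m2 <- (-hkl[need, 2]) %% dim[2]
    m3 <- (-hkl[need, 3]) %% dim[3]
    mlin <- 1 + m1 + dim[1] * (m2 + dim[2] * m3)
    arr[mlin] <- arr[mlin] + Conj(fc[need])
  }
  vol <- prod(cell)
  rho <- Re(stats::fft(arr)) / vol
  # keep the (Friedel-completed) coefficients: the map is band-limited, so
  # peak_height can evaluate the density exactly between grid nodes.
  # Per-axis index tables let the phase factors be built from three short
  # exponential tables instead of one big complex exponential.
  hkl_full <- hkl
  fc_full <- fc
  if (any(need)) {
    hkl_full <- rbind(hkl, -hkl[need, , drop = FALSE])
    fc_full <- c(fc, Conj(fc[need]))
  }
  hmin <- apply(hkl_full, 2, min)
  structure(list(values = rho, cell = cell, dim = dim,
                 provenance = provenance,
                 coeffs = list(hkl = hkl_full, fc = fc_full, hmin = hmin,
                               idx = sweep(hkl_full, 2, hmin) + 1L)),
            class = "density_grid")
}

# smallest 2,3,5-smooth integer >= n (keeps the mixed-radix FFT fast)
nice_grid_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s map, %d x %d x %d, range [%.3g, %.3g] e/A^3\n",
              x$provenance, x$dim[1], x$dim[2], x$dim[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Density value at a position (trilinear interpolation)
#'
#' Interpolates the map at a Cartesian position, optionally searching for
#' the local maximum within a radius to compensate grid discretization.
#'
#' @param map A `density_grid`.
#' @param position Cartesian position (Angstrom), wrapped into the cell.
#' @param search_radius If > 0, the maximum over grid nodes within this
#'   radius is located and refined by separable three-point parabolic
#'   interpolation (which compensates the underestimate a node-limited
#'   search makes when the true peak falls between nodes). Default 0
#'   (plain interpolation); the occupancy estimators use 0.8.
#' @return Density in e/A^3.
#' @export
peak_height <- function(map, position, search_radius = 0) {
  stopifnot(inherits(map, "density_grid"), length(position) == 3)
  if (search_radius <= 0) return(trilinear(map, position))
  spacing <- map$cell / map$dim
  nr <- pmax(ceiling(search_radius / spacing), 1)
  offs <- as.matrix(expand.grid(i = -nr[1]:nr[1], j = -nr[2]:nr[2],
                                k = -nr[3]:nr[3]))
  keep <- sqrt(rowSums(t(t(offs) * spacing)^2)) <= search_radius
  offs <- offs[keep, , drop = FALSE]
  node0 <- round(position / spacing)
  node_val <- function(n) {
    ii <- n %% map$dim
    map$values[ii[1] + 1, ii[2] + 1, ii[3] + 1]
  }
  vals <- apply(offs, 1, function(o) node_val(node0 + o))
  best <- node0 + offs[which.max(vals), ]
  v0 <- max(vals)
  refined <- v0
  if (!is.null(map$coeffs)) {
    # Newton refinement of the between-node maximum from the exact
    # band-limited density (the node-limited search underestimates a peak
    # falling between nodes by up to several percent)
    res <- refine_peak(map, best * spacing, max_step = max(spacing))
    if (!is.null(res) &&
        sqrt(sum((res$position - best * spacing)^2)) <=
          search_radius + max(spacing)) {
      refined <- max(refined, res$value)
    }
  }
  max(refined, v0, trilinear(map, position))
}

#' Exact density of a synthesized map at arbitrary positions
#'
#' Direct Fourier summation over the map's stored coefficients:
#' rho(x) = (1/V) Re sum_h F(h) exp(-2 pi i h.x). Exact for the
#' band-limited density the map represents (it reproduces grid-node values
#' to rounding error).
#'
#' @param map A `density_grid` created by [synthesize_map()].
#' @param positions m x 3 matrix (or length-3 vector) of Cartesian
#'   positions in Angstrom.
#' @return Numeric vector of densities (e/A^3).
#' @export
density_at <- function(map, positions) {
  stopifnot(inherits(map, "density_grid"))
  if (is.null(map$coeffs)) stop("map carries no coefficients")
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  vapply(seq_len(nrow(positions)), function(j) {
    Re(sum(coeff_terms(map, positions[j, ]))) / prod(map$cell)
  }, numeric(1))
}

# complex terms F_h * exp(-2 pi i h.x/cell) via per-axis phase tables
coeff_terms <- function(map, position) {
  co <- map$coeffs
  u <- position / map$cell
  nmax <- apply(co$idx, 2, max)
  e1 <- exp(-2i * pi * u[1] * (co$hmin[1] + 0:(nmax[1] - 1)))
  e2 <- exp(-2i * pi * u[2] * (co$hmin[2] + 0:(nmax[2] - 1)))
  e3 <- exp(-2i * pi * u[3] * (co$hmin[3] + 0:(nmax[3] - 1)))
  co$fc * e1[co$idx[, 1]] * e2[co$idx[, 2]] * e3[co$idx[, 3]]
}

# Newton refinement of a local density maximum from the stored
# coefficients; returns list(position, value) or NULL if not a maximum
refine_peak <- function(map, start, max_step = 0.5, n_iter = 3) {
  co <- map$coeffs
  vol <- prod(map$cell)
  h1 <- co$hkl[, 1]; h2 <- co$hkl[, 2]; h3 <- co$hkl[, 3]
  x <- start
  val <- NA_real_
  for (it in seq_len(n_iter)) {
    e <- coeff_terms(map, x)
    val <- Re(sum(e)) / vol
    s1 <- c(sum(h1 * e), sum(h2 * e), sum(h3 * e))
    g <- 2 * pi / map$cell * Im(s1) / vol
    s2 <- matrix(c(sum(h1 * h1 * e), sum(h1 * h2 * e), sum(h1 * h3 * e),
                   sum(h1 * h2 * e), sum(h2 * h2 * e), sum(h2 * h3 * e),
                   sum(h1 * h3 * e), sum(h2 * h3 * e), sum(h3 * h3 * e)),
                 3, 3)
    hess <- -4 * pi^2 * Re(s2) / outer(map$cell, map$cell) / vol
    ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev >= 0)) return(NULL)  # not at a local maximum
    dx <- -solve(hess, g)
    nrm <- sqrt(sum(dx^2))
    if (nrm > max_step) dx <- dx * max_step / nrm
    x <- x + dx
    if (nrm < 1e-4) break
  }
  list(position = x, value = Re(sum(coeff_terms(map, x))) / vol)
}

trilinear <- function(map, position) {
  g <- position / map$cell * map$dim  # fractional grid coordinates
  i0 <- floor(g)
  t <- g - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    if (w == 0) next
    ii <- (i0 + c(dx, dy, dz)) %% map$dim
    acc <- acc + w * map$values[ii[1] + 1, ii[2] + 1, ii[3] + 1]
  }
  acc
}

#' Write / read a density grid as plain text
#'
#' Header lines record the cell, grid dimensions and provenance; values
#' follow in Fortran (x-fastest) order, one per line. A text format keeps
#' desk-scale maps portable and diffable.
#'
#' @param map A `density_grid`.
#' @param path File path.
#' @return `read_map` returns a `density_grid` (without coefficients:
#'   peak refinement between nodes needs a map fresh from
#'   [synthesize_map()]).
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell %.6f %.6f %.6f", map$cell[1], map$cell[2],
                       map$cell[3]),
               sprintf("# dim %d %d %d", map$dim[1], map$dim[2], map$dim[3]),
               sprintf("# provenance %s", map$provenance)), con)
  writeLines(sprintf("%.8g", as.vector(map$values)), con)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  hdr <- readLines(path, n = 3)
  num <- function(line, tag) {
    as.numeric(strsplit(trimws(sub(tag, "", line)), "\\s+")[[1]])
  }
  cell <- num(hdr[1], "^# cell")
  dims <- as.integer(num(hdr[2], "^# dim"))
  prov <- trimws(sub("^# provenance", "", hdr[3]))
  vals <- scan(path, skip = 3, quiet = TRUE)
  structure(list(values = array(vals, dims), cell = cell, dim = dims,
                 provenance = prov), class = "density_grid")
}

#' Isomorphous difference map coefficients
#'
#' (F_light - F_dark) amplitudes with dark-model phases, the standard
#' convention for light-minus-dark difference Fourier maps. Inputs are
#' assumed to be on a common scale (see [scale_light_to_dark()]).
#'
#' @param f_light Amplitudes of the light data (phases ignored).
#' @param f_dark_calc Dark-model calculated structure factors with phases.
#' @return A `reflection_set` of signed-amplitude coefficients encoded as
#'   (|coef|, phase or phase + 180).
#' @export
difference_coefficients <- function(f_light, f_dark_calc) {
  idx <- match_indices(f_dark_calc, f_light)
  dif <- f_light$f[idx] - f_dark_calc$f
  ph <- f_dark_calc$phase + ifelse(dif < 0, 180, 0)
  reflection_set(f_dark_calc$hkl, abs(dif), f_dark_calc$cell, phase = ph,
                 d_min = f_dark_calc$d_min, d_max = f_dark_calc$d_max)
}

#' Fo-Fc (omit) map from observed amplitudes and a partial model
#'
#' Computes Fc from `model`, scales the observed amplitudes onto Fc, and
#' synthesizes the (Fo - Fc) exp(i phi_c) map. With the feature of interest
#' left out of `model`, peaks reveal the omitted atoms (m = 1, D = 1
#' unweighted convention).
#'
#' @param f_obs Observed amplitudes (`reflection_set`, phases ignored).
#' @param model The partial model (e.g. the refined dark state without CO).
#' @param d_min High-resolution cutoff for Fc; defaults to `f_obs$d_min`.
#' @param scale Apply Wilson scaling of Fo onto Fc (default TRUE; synthetic
#'   noise-free data are already on the absolute scale).
#' @return A `density_grid` with provenance "omit".
#' @export
omit_map <- function(f_obs, model, d_min = NULL, scale = TRUE) {
  if (is.null(d_min)) d_min <- f_obs$d_min
  fc <- structure_factors(model, d_min = d_min, d_max = f_obs$d_max)
  ci <- common_indices(fc, f_obs)
  fc <- subset_reflections(fc, ci$i1)
  fo <- subset_reflections(f_obs, ci$i2)
  if (scale) fo <- scale_light_to_dark(fo, fc)$scaled
  synthesize_map(difference_coefficients(fo, fc), provenance = "omit")
}
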